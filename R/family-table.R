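#' Extract duplex tags and build the family table
#'
#' Strips the random tag and constant linker off both mates of every read
#' pair, computes the orientation-normalised (canonical) tag, and returns
#' the long family table with one row per mate. Pairs where either mate is
#' shorter than `tag_len + linker_len` are dropped and counted.
#'
#' The linker is removed by fixed length, not by sequence match;
#' `linker_len = 0` disables linker removal.
#'
#' @param pairs Read-pair tibble from [read_fastq_pairs()] or
#'   [run_simulation()].
#' @param tag_len Length of each random tag (default 12).
#' @param linker_len Length of the constant linker between tag and insert
#'   (default 5).
#' @return A family-table tibble with columns `canonical_tag`, `order`,
#'   `mate`, `read_id`, `seq`, `qual`, sorted by
#'   (`canonical_tag`, `order`, `mate`). The number of dropped pairs is
#'   attached as attribute `"n_dropped"`.
#' @examples
#' pairs <- tibble::tibble(
#'   read_id = "r1",
#'   seq1 = "AAAATTGGG", qual1 = strrep("I", 9),
#'   seq2 = "CCCCTTAAA", qual2 = strrep("I", 9)
#' )
#' extract_tags(pairs, tag_len = 4, linker_len = 2)
#' @export
extract_tags <- function(pairs, tag_len = 12, linker_len = 5) {
  head_len <- tag_len + linker_len
  keep <- nchar(pairs$seq1) >= head_len & nchar(pairs$seq2) >= head_len
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d pair(s) shorter than tag + linker (%d bases)",
                   n_dropped, head_len))
  }
  pairs <- pairs[keep, , drop = FALSE]
  alpha <- substr(pairs$seq1, 1L, tag_len)
  beta <- substr(pairs$seq2, 1L, tag_len)
  key <- canonical_tag(alpha, beta)
  long <- bind_rows(
    tibble(
      canonical_tag = key$canonical_tag, order = key$order, mate = 1L,
      read_id = pairs$read_id,
      seq = substr(pairs$seq1, head_len + 1L, nchar(pairs$seq1)),
      qual = substr(pairs$qual1, head_len + 1L, nchar(pairs$qual1))
    ),
    tibble(
      canonical_tag = key$canonical_tag, order = key$order, mate = 2L,
      read_id = pairs$read_id,
      seq = substr(pairs$seq2, head_len + 1L, nchar(pairs$seq2)),
      qual = substr(pairs$qual2, head_len + 1L, nchar(pairs$qual2))
    )
  )
  out <- sort_family_table(long)
  attr(out, "n_dropped") <- n_dropped
  out
}

family_table_cols <- c("canonical_tag", "order", "mate", "read_id", "seq", "qual")

sort_family_table <- function(tab) {
  ord <- order(tab$canonical_tag, tab$order, tab$mate, tab$read_id, method = "radix")
  tab[ord, , drop = FALSE]
}

check_family_table <- function(tab) {
  missing <- setdiff(family_table_cols, names(tab))
  if (length(missing) > 0) {
    abort(paste0("not a family table; missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(tab)
}

#' Write / read the tab-separated family table
#'
#' The on-disk format is one row per read mate with columns
#' `canonical_tag`, `order`, `mate`, `read_id`, `seq`, `qual`, sorted by
#' (`canonical_tag`, `order`, `mate`); the round trip is lossless.
#'
#' @param records Family-table tibble (see [extract_tags()]).
#' @param path File path.
#' @return `write_family_table()` returns `path` invisibly;
#'   `read_family_table()` returns the family-table tibble.
#' @export
write_family_table <- function(records, path) {
  check_family_table(records)
  readr::write_tsv(sort_family_table(records[family_table_cols]), path)
  invisible(path)
}

#' @rdname write_family_table
#' @export
read_family_table <- function(path) {
  # parse issues surface as a hard error below, not as a vroom warning
  tab <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      canonical_tag = readr::col_character(),
      order = readr::col_character(),
      mate = readr::col_integer(),
      read_id = readr::col_character(),
      seq = readr::col_character(),
      qual = readr::col_character()
    )
  ))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    # problems() rows are physical file lines (header included)
    abort(sprintf("unparseable family table row at line %d of %s",
                  probs$row[1], path))
  }
  check_family_table(tab)
  if (anyNA(tab[family_table_cols])) {
    bad <- which(rowSums(is.na(tab[family_table_cols])) > 0)[1]
    abort(sprintf("unparseable family table row at line %d of %s", bad + 1L, path))
  }
  sort_family_table(as_tibble(tab))
}
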