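#' Minimum inter-tag distance profile
#'
#' Diagnostic for barcode errors: sample `sample_n` tags, and for each
#' sampled tag and its `b + a` arrangement find the minimum substitution
#' distance to every other tag in the full set (each population tag is
#' compared in both arrangements). An excess of minimum distance 1 signals
#' tags that are error derivatives of other tags; after correction at
#' `max_dist = 1` the distance-1 bin empties.
#'
#' @param tags Character vector of distinct canonical tags.
#' @param sample_n Number of tags to sample (default 1000; clamped to the
#'   population size with a warning).
#' @return A tibble of class `tag_distance_profile` with columns
#'   `distance` and `count`; counts sum to `2 * sample_n` (each sampled
#'   tag is queried in both arrangements, which give the same minimum).
#' @export
min_edit_distance_profile <- function(tags, sample_n = 1000) {
  tags <- as.character(tags)
  if (anyDuplicated(tags)) abort("tags must be distinct")
  if (length(tags) < 2) {
    out <- tibble(distance = integer(), count = integer())
    return(structure(out, class = c("tag_distance_profile", class(out))))
  }
  if (sample_n > length(tags)) {
    warn(sprintf("sample_n (%d) exceeds the number of tags (%d); clamping",
                 sample_n, length(tags)))
    sample_n <- length(tags)
  }
  idx <- sort(sample.int(length(tags), sample_n))
  d <- .min_tag_dist_cpp(tags[idx], idx, tags, swap_tag(tags))
  out <- tibble(distance = d) %>%
    count(.data$distance, name = "count") %>%
    mutate(count = 2L * .data$count) %>% # tag and its ba arrangement
    arrange(.data$distance)
  structure(out, class = c("tag_distance_profile", class(out)))
}

#' Family-size histogram
#'
#' Counts read families by size, where a family is one
#' (`canonical_tag`, `order`, `mate`) group; `histogram[1]` is the
#' singleton count, the raw material barcode correction rescues.
#'
#' @param families Family-table tibble.
#' @return A tibble of class `family_size_histogram` with columns
#'   `family_size` and `n_families`.
#' @export
family_size_histogram <- function(families) {
  check_family_table(families)
  out <- families %>%
    count(.data$canonical_tag, .data$order, .data$mate, name = "family_size") %>%
    count(.data$family_size, name = "n_families") %>%
    arrange(.data$family_size)
  structure(out, class = c("family_size_histogram", class(out)))
}

#' Trim N-rich 5' ends of consensus reads
#'
#' Slides a `window`-base window from the 5' end; the read is kept from
#' the first offset where the in-window proportion of `filt_base` no
#' longer exceeds `thres`, after additionally skipping any leading
#' `filt_base` characters. A read with no acceptable window trims to
#' empty. Reads shorter than `window` are evaluated as a single window.
#'
#' @param seqs Character vector of sequences.
#' @param window Window width in bases (default 10).
#' @param thres Proportion of `filt_base` that triggers removal when
#'   exceeded (strictly greater; default 0.3).
#' @param filt_base Base to filter on (default `"N"`).
#' @return Integer vector: the number of leading bases to remove from each
#'   read (equal to `nchar(seqs)` when the whole read is removed).
#' @export
trim_n_windows <- function(seqs, window = 10, thres = 0.3, filt_base = "N") {
  stopifnot(window >= 1)
  vapply(seqs, function(s) {
    L <- nchar(s)
    if (L == 0L) return(0L)
    x <- strsplit(s, "")[[1]] == filt_base
    w <- min(window, L)
    cs <- c(0L, cumsum(x))
    offsets <- seq_len(L - w + 1L)
    frac <- (cs[offsets + w] - cs[offsets]) / w
    ok <- which(frac <= thres)
    if (length(ok) == 0L) return(L)
    start <- ok[1]
    while (start <= L && x[start]) start <- start + 1L
    start - 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Trim and filter consensus read pairs
#'
#' Applies [trim_n_windows()] to both mates of each pair; if either mate's
#' trimmed length falls below `min_length`, both mates are removed.
#'
#' @param pairs A tibble with columns `seq1` and `seq2` (e.g. a DCS table
#'   reshaped to one row per tag, or a read-pair table); optional `qual1`,
#'   `qual2` columns are trimmed alongside.
#' @inheritParams trim_n_windows
#' @param min_length Minimum surviving length per mate (default 75).
#' @return The filtered tibble with trimmed sequences; the number of
#'   removed pairs is attached as attribute `"n_removed"`.
#' @export
trim_read_pairs <- function(pairs, window = 10, thres = 0.3, filt_base = "N",
                            min_length = 75) {
  cut1 <- trim_n_windows(pairs$seq1, window, thres, filt_base)
  cut2 <- trim_n_windows(pairs$seq2, window, thres, filt_base)
  len1 <- nchar(pairs$seq1) - cut1
  len2 <- nchar(pairs$seq2) - cut2
  keep <- len1 >= min_length & len2 >= min_length
  out <- pairs[keep, , drop = FALSE]
  out$seq1 <- substr(out$seq1, cut1[keep] + 1L, nchar(out$seq1))
  out$seq2 <- substr(out$seq2, cut2[keep] + 1L, nchar(out$seq2))
  if ("qual1" %in% names(out)) {
    out$qual1 <- substr(out$qual1, cut1[keep] + 1L, nchar(out$qual1))
  }
  if ("qual2" %in% names(out)) {
    out$qual2 <- substr(out$qual2, cut2[keep] + 1L, nchar(out$qual2))
  }
  attr(out, "n_removed") <- sum(!keep)
  out
}
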