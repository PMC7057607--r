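#' Group a family table into read families
#'
#' Splits a (sorted) family table by the grouping key
#' (`canonical_tag`, `order`, `mate`) and returns a nested tibble with one
#' row per family, in sorted key order.
#'
#' @param families Family-table tibble sorted by the grouping key (as
#'   produced by [extract_tags()] / [read_family_table()]).
#' @return A tibble with columns `canonical_tag`, `order`, `mate`,
#'   `family_size` and a list-column `reads` holding each family's rows.
#' @export
group_families <- function(families) {
  check_family_table(families)
  key <- paste(families$canonical_tag, families$order, families$mate)
  if (is.unsorted(key)) abort("family table is not sorted by (canonical_tag, order, mate)")
  families %>%
    tidyr::nest(reads = all_of(c("read_id", "seq", "qual"))) %>%
    mutate(family_size = vapply(.data$reads, nrow, integer(1))) %>%
    select(all_of(c("canonical_tag", "order", "mate", "family_size", "reads")))
}

#' Multiple sequence alignment of one read family
#'
#' Families of a single read, or of reads that all share one length, are
#' column-stacked unchanged (duplex reads carry no indel signal in that
#' case). Mixed-length families are aligned with a center-star strategy:
#' the longest read is the center, every other read is globally aligned to
#' it (match +1, mismatch -1, gap -2 per base), and the pairwise gap
#' patterns are merged into one gapped block. Ungapping any row recovers
#' the input read.
#'
#' @param seqs Character vector of reads (>= 1).
#' @param quals Optional parallel PHRED+33 quality strings; gap columns
#'   receive the placeholder `!` which carries no vote weight (gaps are
#'   exempt from quality filtering).
#' @return An object of class `msa_family`: list with equal-length `rows`
#'   and `quals`.
#' @export
align_family <- function(seqs, quals = NULL) {
  n <- length(seqs)
  if (n == 0) abort("cannot align an empty family")
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (n == 1 || dplyr::n_distinct(nchar(seqs)) == 1) {
    return(structure(list(rows = seqs, quals = quals), class = "msa_family"))
  }
  center <- which.max(nchar(seqs))
  others <- setdiff(seq_len(n), center)
  submat <- make_submat()
  alns <- lapply(others, function(i) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = seqs[i], subject = seqs[center], type = "global",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2
    )
    list(
      pattern = as.character(Biostrings::alignedPattern(pa)),
      subject = as.character(Biostrings::alignedSubject(pa))
    )
  })
  merge_center_star(seqs, quals, center, others, alns)
}

make_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m
}

# merge pairwise (read vs center) alignments into one MSA: the number of
# insert columns between consecutive center positions is the max over all
# pairwise alignments.
merge_center_star <- function(seqs, quals, center, others, alns) {
  lc <- nchar(seqs[center])
  # ins[[i]][k+1] = inserts after center position k (k = 0 before first base)
  ins_counts <- lapply(alns, function(a) {
    subj <- strsplit(a$subject, "")[[1]]
    counts <- integer(lc + 1)
    pos <- 0L
    for (ch in subj) {
      if (ch == "-") counts[pos + 1L] <- counts[pos + 1L] + 1L else pos <- pos + 1L
    }
    counts
  })
  max_ins <- Reduce(pmax, ins_counts, accumulate = FALSE)

  pad_row <- function(aligned_pattern, aligned_subject) {
    p <- strsplit(aligned_pattern, "")[[1]]
    s <- strsplit(aligned_subject, "")[[1]]
    out <- character(0)
    pos <- 0L
    run <- character(0) # pattern chars sitting in the current insert run
    flush <- function(run, pos) {
      c(run, rep("-", max_ins[pos + 1L] - length(run)))
    }
    for (k in seq_along(s)) {
      if (s[k] == "-") {
        run <- c(run, p[k])
      } else {
        out <- c(out, flush(run, pos), p[k])
        run <- character(0)
        pos <- pos + 1L
      }
    }
    out <- c(out, flush(run, pos))
    paste(out, collapse = "")
  }

  rows <- character(length(seqs))
  # center row: its own bases with gap blocks at every insert point
  center_chars <- strsplit(seqs[center], "")[[1]]
  out <- rep("-", max_ins[1])
  for (k in seq_len(lc)) out <- c(out, center_chars[k], rep("-", max_ins[k + 1L]))
  rows[center] <- paste(out, collapse = "")
  for (j in seq_along(others)) {
    rows[others[j]] <- pad_row(alns[[j]]$pattern, alns[[j]]$subject)
  }
  aligned_quals <- align_quals(seqs, quals, rows)
  structure(list(rows = rows, quals = aligned_quals), class = "msa_family")
}

# thread original quality strings through the gapped rows ('!' at gaps)
align_quals <- function(seqs, quals, rows) {
  vapply(seq_along(rows), function(i) {
    rc <- strsplit(rows[i], "")[[1]]
    qc <- strsplit(quals[i], "")[[1]]
    out <- rep("!", length(rc))
    out[rc != "-"] <- qc
    paste(out, collapse = "")
  }, character(1))
}

#' Ungap an aligned family
#'
#' @param msa An `msa_family` object.
#' @return Character vector of the original (gap-free) reads.
#' @export
ungap_family <- function(msa) {
  gsub("-", "", msa$rows, fixed = TRUE)
}

#' Call the single-strand consensus of one family
#'
#' Per aligned column: bases below `qual_thres` are discarded (gaps always
#' vote); the majority symbol is emitted if it is unique and reaches a
#' fraction `cons_thres` of the surviving votes, otherwise `N`; a winning
#' gap emits nothing (deletion); a column whose votes were all discarded
#' yields `N`. Families smaller than `min_reads` return `NULL`.
#'
#' @param msa An `msa_family` object (or character vector of equal-length
#'   reads).
#' @param cons_thres Minimum vote fraction for a consensus base
#'   (default 0.7).
#' @param min_reads Minimum family size to call a consensus (default 3).
#' @param qual_thres Minimum PHRED score for a base to vote (default 25).
#' @return The consensus sequence (character scalar) or `NULL`.
#' @export
call_sscs <- function(msa, cons_thres = 0.7, min_reads = 3, qual_thres = 25) {
  if (is.character(msa)) msa <- align_family(msa)
  n <- length(msa$rows)
  if (n < min_reads) return(NULL)
  .consensus_batch_cpp(msa$rows, msa$quals, n, cons_thres, as.integer(qual_thres))[[1]]
}

#' Call all single-strand consensus sequences of a family table
#'
#' Groups the table by (`canonical_tag`, `order`, `mate`), drops families
#' below `min_reads`, aligns mixed-length families (see [align_family()])
#' and calls the per-column consensus of every family (see [call_sscs()]).
#' Families are processed in lexicographic tag order, so the output is
#' reproducible and invariant to `workers`.
#'
#' @inheritParams call_sscs
#' @param families Sorted family-table tibble.
#' @param workers Number of worker processes for the alignment/consensus
#'   stage (default 1).
#' @param queue_mult Job-queue size multiplier for the parallel stage
#'   (default 8; the queue holds `workers * queue_mult` jobs).
#' @return SSCS tibble: `canonical_tag`, `order`, `mate`, `seq`,
#'   `family_size`.
#' @export
call_consensi <- function(families, cons_thres = 0.7, min_reads = 3,
                          qual_thres = 25, workers = 1, queue_mult = 8) {
  check_family_table(families)
  families <- sort_family_table(families)
  key <- paste(families$canonical_tag, families$order, families$mate, sep = "\r")
  runs <- rle(key)
  first_rows <- cumsum(runs$lengths) - runs$lengths + 1L
  sizes <- tibble(
    canonical_tag = families$canonical_tag[first_rows],
    order = families$order[first_rows],
    mate = families$mate[first_rows],
    family_size = runs$lengths
  )
  keep <- sizes$family_size >= min_reads
  families <- families[rep(keep, runs$lengths), , drop = FALSE]
  sizes <- sizes[keep, , drop = FALSE]
  if (nrow(sizes) == 0) {
    return(tibble(canonical_tag = character(), order = character(),
                  mate = integer(), seq = character(), family_size = integer()))
  }

  # families whose reads share one length need no alignment and are voted
  # in one vectorised pass; the rest go through the MSA engine
  grp <- rep(seq_len(nrow(sizes)), sizes$family_size)
  len <- nchar(families$seq)
  first_len <- len[match(seq_len(nrow(sizes)), grp)]
  uniform <- !(seq_len(nrow(sizes)) %in% unique(grp[len != first_len[grp]]))

  out_seq <- character(nrow(sizes))
  if (any(uniform)) {
    rows <- uniform[grp]
    out_seq[uniform] <- .consensus_batch_cpp(
      families$seq[rows], families$qual[rows],
      sizes$family_size[uniform], cons_thres, as.integer(qual_thres)
    )
  }
  if (any(!uniform)) {
    idx <- which(!uniform)
    jobs <- lapply(idx, function(i) {
      rows <- grp == i
      list(seqs = families$seq[rows], quals = families$qual[rows])
    })
    res <- ordered_parallel_map(jobs, function(j) {
      msa <- align_family(j$seqs, j$quals)
      .consensus_batch_cpp(msa$rows, msa$quals, length(msa$rows),
                           cons_thres, as.integer(qual_thres))[[1]]
    }, workers = workers, queue_mult = queue_mult)
    out_seq[idx] <- unlist(res)
  }
  sizes %>%
    mutate(seq = out_seq) %>%
    select(all_of(c("canonical_tag", "order", "mate", "seq", "family_size")))
}

#' Merge complementary single-strand consensi into duplex consensi
#'
#' For each canonical tag, the `ab` mate-1 consensus pairs with the `ba`
#' mate-2 consensus (both read the same fragment strand), and `ab` mate 2
#' pairs with `ba` mate 1. Position-wise agreement keeps the base; any
#' disagreement or `N` is masked as `N`. Consensi of unequal length are
#' pairwise-aligned first (same engine as [align_family()]) with
#' disagreements, including gap columns, masked as `N`. Tags lacking
#' either strand yield no DCS.
#'
#' @param sscs SSCS tibble from [call_consensi()].
#' @return DCS tibble: `canonical_tag`, `mate`, `seq`, `fam_size_ab`,
#'   `fam_size_ba` (the `ab`/`ba` family sizes backing that mate's pair).
#' @export
call_dcs <- function(sscs) {
  ab <- sscs %>% filter(.data$order == "ab")
  ba <- sscs %>% filter(.data$order == "ba")
  paired <- bind_rows(
    inner_join(
      ab %>% filter(.data$mate == 1L) %>%
        select(all_of(c("canonical_tag", "seq", "family_size"))) %>%
        rename(seq_ab = "seq", fam_size_ab = "family_size"),
      ba %>% filter(.data$mate == 2L) %>%
        select(all_of(c("canonical_tag", "seq", "family_size"))) %>%
        rename(seq_ba = "seq", fam_size_ba = "family_size"),
      by = "canonical_tag"
    ) %>% mutate(mate = 1L),
    inner_join(
      ab %>% filter(.data$mate == 2L) %>%
        select(all_of(c("canonical_tag", "seq", "family_size"))) %>%
        rename(seq_ab = "seq", fam_size_ab = "family_size"),
      ba %>% filter(.data$mate == 1L) %>%
        select(all_of(c("canonical_tag", "seq", "family_size"))) %>%
        rename(seq_ba = "seq", fam_size_ba = "family_size"),
      by = "canonical_tag"
    ) %>% mutate(mate = 2L)
  )
  if (nrow(paired) == 0) {
    return(tibble(canonical_tag = character(), mate = integer(),
                  seq = character(), fam_size_ab = integer(),
                  fam_size_ba = integer()))
  }
  eq <- nchar(paired$seq_ab) == nchar(paired$seq_ba)
  seq_out <- character(nrow(paired))
  if (any(eq)) {
    seq_out[eq] <- .dcs_combine_cpp(paired$seq_ab[eq], paired$seq_ba[eq])
  }
  if (any(!eq)) {
    seq_out[!eq] <- vapply(which(!eq), function(i) {
      msa <- align_family(c(paired$seq_ab[i], paired$seq_ba[i]))
      a <- chartr("-", "N", msa$rows[1])
      b <- chartr("-", "N", msa$rows[2])
      .dcs_combine_cpp(a, b)[[1]]
    }, character(1))
  }
  paired %>%
    mutate(seq = seq_out) %>%
    select(all_of(c("canonical_tag", "mate", "seq", "fam_size_ab", "fam_size_ba"))) %>%
    arrange(.data$canonical_tag, .data$mate)
}

#' Write consensus tables as FASTQ
#'
#' SSCS records are written one file per strand order
#' (`sscs.ab_1.fq` etc.); DCS records as a mate pair
#' (`dcs_1.fq`, `dcs_2.fq`). Read names carry the canonical tag and family
#' size(s); qualities are a constant PHRED 40 placeholder.
#'
#' @param sscs,dcs Consensus tibbles from [call_consensi()] / [call_dcs()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_consensus_fastq <- function(sscs, dcs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ord in c("ab", "ba")) {
    for (m in 1:2) {
      rec <- sscs %>% filter(.data$order == ord, .data$mate == m)
      p <- file.path(dir, sprintf("sscs.%s_%d.fq", ord, m))
      write_fastq(sprintf("%s.%s:fam=%d", rec$canonical_tag, ord, rec$family_size),
                  rec$seq, strrep("I", nchar(rec$seq)), p)
      paths <- c(paths, p)
    }
  }
  for (m in 1:2) {
    rec <- dcs %>% filter(.data$mate == m)
    p <- file.path(dir, sprintf("dcs_%d.fq", m))
    write_fastq(sprintf("%s:fam=%d/%d", rec$canonical_tag, rec$fam_size_ab,
                        rec$fam_size_ba),
                rec$seq, strrep("I", nchar(rec$seq)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
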