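#' Ground truth per observed family
#'
#' Links every observed raw canonical tag to the true molecule it
#' descends from: the majority true tag (and fragment) over the family's
#' reads, plus whether the raw tag is itself one of the original, true
#' tags.
#'
#' @param families Raw (pre-correction) family-table tibble.
#' @param truth Truth log from [run_simulation()] / [read_truth_log()].
#' @return A tibble with columns `raw_tag`, `true_tag`, `fragment_id`,
#'   `is_true_tag`.
#' @export
truth_families <- function(families, truth) {
  check_family_table(families)
  obs <- distinct(families, .data$read_id, .data$canonical_tag)
  tru <- distinct(truth, .data$read_id, .data$fragment_id,
                  .data$alpha, .data$beta) %>%
    mutate(true_tag = canonical_tag(.data$alpha, .data$beta)$canonical_tag)
  joined <- left_join(obs, tru, by = "read_id")
  if (anyNA(joined$true_tag)) {
    abort(sprintf("%d read(s) missing from the truth log",
                  sum(is.na(joined$true_tag))))
  }
  true_set <- unique(tru$true_tag)
  joined %>%
    count(.data$canonical_tag, .data$true_tag, .data$fragment_id) %>%
    arrange(.data$canonical_tag, dplyr::desc(.data$n),
            .data$true_tag) %>%
    distinct(.data$canonical_tag, .keep_all = TRUE) %>%
    transmute(
      raw_tag = .data$canonical_tag,
      true_tag = .data$true_tag,
      fragment_id = .data$fragment_id,
      is_true_tag = .data$raw_tag %in% true_set
    )
}

#' Classify barcode corrections against the truth log
#'
#' Each observed family (distinct raw canonical tag) is counted once:
#' a corrected tag assigned to its true family is a true positive, a
#' corrected tag assigned elsewhere a false positive; an uncorrected tag
#' that is not one of the original true tags is a false negative, and an
#' uncorrected true tag a true negative. "Its true family" means the
#' family of reads descending from the same original molecule: a
#' correction counts as true when the representative tag's family derives
#' from the same fragment as the corrected reads, whether or not that
#' representative equals the original tag base-for-base (an error
#' derivative can win the canonical election without making the reunion
#' wrong).
#'
#' @param map Correction map from [build_correction_map()] (or
#'   `tidy()` of a [correct_barcodes()] result).
#' @param families Raw (pre-correction) family table the map was built
#'   from.
#' @param truth Truth log tibble.
#' @return An object of class `correction_confusion`: counts `tp`, `fp`,
#'   `tn`, `fn`, rates `recall_of_erroneous` = tp / (tp + fn) and
#'   `fp_rate_of_corrected` = fp / (tp + fp), and `n_families`.
#' @export
classify_corrections <- function(map, families, truth) {
  fam_truth <- truth_families(families, truth)
  d <- fam_truth %>%
    left_join(map, by = "raw_tag") %>%
    mutate(
      corrected_tag = dplyr::coalesce(.data$corrected_tag, .data$raw_tag),
      corrected = .data$corrected_tag != .data$raw_tag
    ) %>%
    left_join(
      fam_truth %>%
        select(all_of(c("raw_tag", "fragment_id"))) %>%
        rename(target_fragment = "fragment_id"),
      by = c(corrected_tag = "raw_tag")
    )
  tp <- sum(d$corrected & d$target_fragment == d$fragment_id, na.rm = TRUE)
  fp <- sum(d$corrected) - tp
  tn <- sum(!d$corrected & d$is_true_tag)
  fn <- sum(!d$corrected & !d$is_true_tag)
  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      recall_of_erroneous = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      fp_rate_of_corrected = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
      n_families = nrow(d)
    ),
    class = "correction_confusion"
  )
}

#' @export
print.correction_confusion <- function(x, ...) {
  cat(sprintf(
    paste0("<correction_confusion> %d families\n",
           "  TP %d  FP %d  TN %d  FN %d\n",
           "  recall of erroneous tags: %.2f%%   FP among corrected: %.3f%%\n"),
    x$n_families, x$tp, x$fp, x$tn, x$fn,
    100 * x$recall_of_erroneous, 100 * x$fp_rate_of_corrected
  ))
  invisible(x)
}

#' @describeIn classify_corrections `tidy()` returns the counts in long
#'   form.
#' @param x A `correction_confusion` object.
#' @param ... Unused.
#' @export
tidy.correction_confusion <- function(x, ...) {
  tibble(
    class = c("tp", "fp", "tn", "fn"),
    families = c(x$tp, x$fp, x$tn, x$fn)
  )
}

#' @describeIn classify_corrections `glance()` returns a one-row summary.
#' @export
glance.correction_confusion <- function(x, ...) {
  tibble(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    recall_of_erroneous = x$recall_of_erroneous,
    fp_rate_of_corrected = x$fp_rate_of_corrected,
    n_families = x$n_families
  )
}

#' Count consensus sequences
#'
#' @param sscs SSCS tibble from [call_consensi()].
#' @param dcs DCS tibble from [call_dcs()].
#' @return One-row tibble with `sscs_ab`, `sscs_ba` (families per strand
#'   order) and `dcs` (duplex families).
#' @export
count_consensi <- function(sscs, dcs) {
  tibble(
    sscs_ab = sscs %>% filter(.data$order == "ab") %>%
      distinct(.data$canonical_tag) %>% nrow(),
    sscs_ba = sscs %>% filter(.data$order == "ba") %>%
      distinct(.data$canonical_tag) %>% nrow(),
    dcs = dcs %>% distinct(.data$canonical_tag) %>% nrow()
  )
}

#' Relative yield increase from barcode correction
#'
#' @param dcs_uncorrected,dcs_corrected DCS counts without and with
#'   correction.
#' @return Percentage increase, `100 * (corrected - uncorrected) /
#'   uncorrected`.
#' @export
yield_increase <- function(dcs_uncorrected, dcs_corrected) {
  if (dcs_uncorrected <= 0) abort("uncorrected DCS count must be positive")
  100 * (dcs_corrected - dcs_uncorrected) / dcs_uncorrected
}

#' Per-base consensus error rate against the simulated truth
#'
#' Compares every DCS base to the fragment sequence it descends from
#' (known exactly from the truth log). A DCS mate reads either the
#' fragment prefix or the reverse-complement prefix; which one depends on
#' the lexicographic orientation of the tag, so both candidates are
#' positionally compared and the matching orientation (fewer differences)
#' is scored. By default an `N` in the consensus counts as a difference
#' from the input; the rate with `N` positions excluded from both
#' numerator and denominator is reported alongside.
#'
#' @param dcs DCS tibble from [call_dcs()].
#' @param tag_map Tibble mapping `raw_tag` (the DCS tag) to `fragment_id`,
#'   e.g. from [truth_families()]. Every DCS tag must be present.
#' @param fragments Fragment tibble from [run_simulation()].
#' @return One-row tibble: `errors_per_base`, `mismatches`, `bases`,
#'   `errors_per_base_excl_n`, `mismatches_excl_n`, `bases_excl_n`.
#' @export
per_base_error_rate <- function(dcs, tag_map, fragments) {
  idx <- match(dcs$canonical_tag, tag_map$raw_tag)
  if (anyNA(idx)) {
    abort(sprintf("%d DCS tag(s) have no truth entry", sum(is.na(idx))))
  }
  frag_idx <- match(tag_map$fragment_id[idx], fragments$fragment_id)
  frag_seq <- fragments$seq[frag_idx]
  len <- nchar(dcs$seq)
  fwd <- substr(frag_seq, 1L, len)
  rev <- substr(revcomp(frag_seq), 1L, len)
  mism_fwd <- .count_mismatches_cpp(dcs$seq, fwd, FALSE)
  mism_rev <- .count_mismatches_cpp(dcs$seq, rev, FALSE)
  use_fwd <- mism_fwd$mismatches <= mism_rev$mismatches
  expected <- if_else(use_fwd, fwd, rev)
  with_n <- .count_mismatches_cpp(dcs$seq, expected, FALSE)
  no_n <- .count_mismatches_cpp(dcs$seq, expected, TRUE)
  tibble(
    errors_per_base = sum(with_n$mismatches) / sum(with_n$bases),
    mismatches = sum(with_n$mismatches),
    bases = sum(with_n$bases),
    errors_per_base_excl_n = sum(no_n$mismatches) / sum(no_n$bases),
    mismatches_excl_n = sum(no_n$mismatches),
    bases_excl_n = sum(no_n$bases)
  )
}
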