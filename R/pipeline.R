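#' Run the duplex consensus pipeline on a family table
#'
#' Optionally corrects barcodes, then calls single-strand and duplex
#' consensus sequences.
#'
#' @inheritParams call_consensi
#' @inheritParams correct_barcodes
#' @param families Family-table tibble from [extract_tags()].
#' @param correct Whether to run barcode error correction first
#'   (default `TRUE`).
#' @return A list of class `duplex_pipeline`: `families` (as consumed by
#'   the consensus stage), `correction` (a [correct_barcodes()] result or
#'   `NULL`), `sscs`, `dcs`, and `counts` (from [count_consensi()]).
#' @export
run_duplex_pipeline <- function(families, correct = TRUE, max_dist = 1,
                                choose_by = c("reads", "edges"),
                                cons_thres = 0.7, min_reads = 3,
                                qual_thres = 25, workers = 1, queue_mult = 8) {
  choose_by <- arg_match(choose_by)
  correction <- NULL
  if (correct) {
    correction <- correct_barcodes(families, max_dist = max_dist,
                                   choose_by = choose_by)
    families <- correction$families
  }
  sscs <- call_consensi(families, cons_thres = cons_thres,
                        min_reads = min_reads, qual_thres = qual_thres,
                        workers = workers, queue_mult = queue_mult)
  dcs <- call_dcs(sscs)
  structure(
    list(families = families, correction = correction, sscs = sscs,
         dcs = dcs, counts = count_consensi(sscs, dcs)),
    class = "duplex_pipeline"
  )
}

#' @export
print.duplex_pipeline <- function(x, ...) {
  cat(sprintf(
    "<duplex_pipeline> %s barcode correction\n  SSCS ab %d, ba %d; DCS %d\n",
    if (is.null(x$correction)) "without" else "with",
    x$counts$sscs_ab, x$counts$sscs_ba, x$counts$dcs
  ))
  invisible(x)
}

#' @describeIn run_duplex_pipeline `glance()` returns the consensus counts
#'   and correction summary in one row.
#' @param x A `duplex_pipeline` object.
#' @param ... Unused.
#' @export
glance.duplex_pipeline <- function(x, ...) {
  out <- x$counts
  if (!is.null(x$correction)) {
    out <- dplyr::bind_cols(out, glance(x$correction))
  }
  out
}
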