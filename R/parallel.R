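#' Order-preserving parallel map with an oversized job queue
#'
#' Applies `.f` to every element of `.x` on `workers` forked processes
#' while emitting results exactly in submission order. To avoid the
#' slowest-job bottleneck of batch scheduling, up to
#' `workers * queue_mult` jobs are kept in flight: as results are collected
#' from the head of the queue, new jobs are submitted at the tail, so fast
#' workers keep busy while a slow job finishes. With `workers = 1` this is
#' a plain sequential map.
#'
#' `.f` must not depend on the random number generator if results are to
#' be invariant to `workers`.
#'
#' @param .x List (or vector) of job inputs, in the order results are
#'   wanted.
#' @param .f Function applied to each element.
#' @param workers Number of worker processes (default 1).
#' @param queue_mult Queue-size multiplier (default 8).
#' @return A list of results, in the order of `.x`. A failing job aborts
#'   the map with an error naming the job's index.
#' @export
ordered_parallel_map <- function(.x, .f, workers = 1, queue_mult = 8) {
  stopifnot(workers >= 1, queue_mult >= 1)
  n <- length(.x)
  .f <- as_function(.f)
  if (workers == 1 || n == 0 || .Platform$OS.type == "windows") {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      out[[i]] <- tryCatch(.f(.x[[i]]), error = function(e) {
        abort(sprintf("job %d failed: %s", i, conditionMessage(e)))
      })
    }
    return(out)
  }
  queue_size <- workers * queue_mult
  jobs <- vector("list", n)
  out <- vector("list", n)
  next_submit <- 1L
  in_flight <- 0L
  for (next_collect in seq_len(n)) {
    while (next_submit <= n && in_flight < queue_size) {
      x_i <- .x[[next_submit]]
      jobs[[next_submit]] <- parallel::mcparallel(.f(x_i))
      next_submit <- next_submit + 1L
      in_flight <- in_flight + 1L
    }
    res <- parallel::mccollect(jobs[[next_collect]], wait = TRUE)[[1]]
    jobs[next_collect] <- list(NULL)
    in_flight <- in_flight - 1L
    if (inherits(res, "try-error")) {
      abort(sprintf("job %d failed: %s", next_collect,
                    attr(res, "condition")$message %||% as.character(res)))
    }
    out[[next_collect]] <- res
  }
  out
}
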