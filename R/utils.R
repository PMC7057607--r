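#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet A, C, G, T, N.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AANT"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Swap the two halves of a concatenated tag
#'
#' Turns the `a + b` arrangement of a 12 + 12 barcode (or any even split)
#' into `b + a`.
#'
#' @param tag Character vector of concatenated tags.
#' @param tag_len Length of one half (default: half the string).
#' @return Character vector with halves exchanged.
#' @export
swap_tag <- function(tag, tag_len = NULL) {
  if (length(tag) == 0) return(character())
  nc <- nchar(tag)
  if (is.null(tag_len)) {
    if (any(nc %% 2L != 0L)) abort("tags must have even length to infer tag_len")
    tag_len <- nc %/% 2L
  } else {
    if (any(nc != 2L * tag_len)) abort("tags must have length 2 * tag_len")
    tag_len <- rep_len(tag_len, length(tag))
  }
  paste0(substr(tag, tag_len + 1L, nc), substr(tag, 1L, tag_len))
}

#' Canonical arrangement of a barcode pair
#'
#' A duplex molecule carries the same two tags in opposite order on its two
#' strands (`ab` on one, `ba` on the other). The canonical tag is the
#' lexicographically smaller of `a + b` and `b + a`, so both strands group
#' under one key; the `order` flag records which arrangement was observed
#' (ties resolve to `"ab"`).
#'
#' @param alpha,beta Character vectors: the first- and second-mate 12-mers.
#' @return A tibble with columns `canonical_tag` and `order`.
#' @examples
#' canonical_tag("TTTT", "AAAA") # canonical AAAATTTT, order ba
#' @export
canonical_tag <- function(alpha, beta) {
  ab <- paste0(alpha, beta)
  ba <- paste0(beta, alpha)
  is_ab <- ab <= ba
  tibble(
    canonical_tag = if_else(is_ab, ab, ba),
    order = if_else(is_ab, "ab", "ba")
  )
}

#' Substitution (Hamming) distance between equal-length sequences
#'
#' Counts positions where the two sequences differ: an `N` mismatches every
#' non-`N` base and matches `N`.
#'
#' @param x,y Character vectors of equal-length sequences, recycled to a
#'   common length.
#' @return Integer vector of distances.
#' @examples
#' edit_distance("ACGT", "ACGA")
#' @export
edit_distance <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.character(x), n)
  y <- rep_len(as.character(y), n)
  .hamming_cpp(x, y)
}

random_dna <- function(n, len) {
  if (n == 0) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
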