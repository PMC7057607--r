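#' Read paired FASTQ files into a read-pair table
#'
#' Reads two record-aligned FASTQ files (Sanger PHRED+33) and returns one
#' row per read pair. Mate order is taken from file order; the files must
#' contain the same number of records.
#'
#' @param path1,path2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A tibble with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`. The `read_id` is the mate-1 record name up to the first
#'   whitespace.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq_one(path1)
  r2 <- read_fastq_one(path2)
  if (nrow(r1) != nrow(r2)) {
    shorter <- if (nrow(r1) < nrow(r2)) path1 else path2
    abort(sprintf(
      "FASTQ files are not record-aligned: %s has fewer records (%d vs %d)",
      shorter, min(nrow(r1), nrow(r2)), max(nrow(r1), nrow(r2))
    ))
  }
  tibble(
    read_id = r1$id,
    seq1 = r1$seq, qual1 = r1$qual,
    seq2 = r2$seq, qual2 = r2$qual
  )
}

read_fastq_one <- function(path) {
  tryCatch({
    seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
    out <- tibble(
      id = sub("\\s.*$", "", names(seqs)),
      seq = as.character(seqs),
      qual = as.character(S4Vectors::mcols(seqs)$qualities)
    )
    bad <- which(nchar(out$seq) != nchar(out$qual))
    if (length(bad) > 0) {
      abort(sprintf("malformed FASTQ in %s: sequence/quality length mismatch at record %d",
                    path, bad[1]))
    }
    out
  }, error = function(e) {
    abort(sprintf("malformed FASTQ in %s: %s", path, conditionMessage(e)))
  })
}

#' Write sequences to a FASTQ file
#'
#' @param ids,seqs,quals Parallel character vectors: record names, bases and
#'   PHRED+33 quality strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(quals)
  )
  invisible(path)
}

#' Write a read-pair table to paired FASTQ files
#'
#' @param pairs A read-pair tibble as returned by [read_fastq_pairs()].
#' @param path1,path2 Output paths for mate 1 and mate 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_fastq(pairs$read_id, pairs$seq1, pairs$qual1, path1)
  write_fastq(pairs$read_id, pairs$seq2, pairs$qual2, path2)
  invisible(c(path1, path2))
}
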