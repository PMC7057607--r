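#' Simulation configuration
#'
#' Bundles the parameters of the duplex-sequencing simulator. Defaults are
#' the reference experiment: 400 bp fragments, 100 bp reads, 12-mer tags,
#' a 5-base constant linker, 25 PCR cycles with replication probability
#' decaying by a factor of 1.05 per cycle, and 0.001 substitution errors
#' per base for both the PCR polymerase and the sequencer.
#'
#' @param n_fragments Number of original DNA fragments to simulate.
#' @param frag_len Fragment length in bases (default 400).
#' @param read_len Read length in bases (default 100).
#' @param tag_len Random tag length per fragment end (default 12).
#' @param linker Constant linker sequence between tag and fragment
#'   (default `"GTCAG"`; use `""` for no linker).
#' @param pcr_cycles Number of simulated PCR cycles (default 25).
#' @param error_rate Per-base substitution probability per replication and
#'   per sequenced base (default 0.001).
#' @param efficiency_decay Per-cycle divisor of the replication
#'   probability: at cycle c it is `1 / efficiency_decay^(c-1)` (default
#'   1.05, so cycle 1 always replicates).
#' @param family_sizes Family-size distribution: a tibble with columns
#'   `size` and `weight` (default [family_size_distribution()]).
#' @param rng_seed Optional integer seed; when non-`NULL`,
#'   [run_simulation()] seeds R's RNG so output is byte-identical across
#'   runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_fragments, frag_len = 400, read_len = 100,
                       tag_len = 12, linker = "GTCAG", pcr_cycles = 25,
                       error_rate = 0.001, efficiency_decay = 1.05,
                       family_sizes = family_size_distribution(),
                       rng_seed = NULL) {
  stopifnot(
    n_fragments >= 1, frag_len >= 1, read_len >= 1, tag_len >= 1,
    error_rate >= 0, error_rate < 1, efficiency_decay >= 1, pcr_cycles >= 0,
    read_len <= tag_len + nchar(linker) + frag_len
  )
  if (nrow(family_sizes) == 0) abort("family-size distribution is empty")
  stopifnot(all(family_sizes$size >= 1), all(family_sizes$weight >= 0))
  structure(
    list(
      n_fragments = as.integer(n_fragments), frag_len = as.integer(frag_len),
      read_len = as.integer(read_len), tag_len = as.integer(tag_len),
      linker = linker, pcr_cycles = as.integer(pcr_cycles),
      error_rate = error_rate, efficiency_decay = efficiency_decay,
      family_sizes = family_sizes, rng_seed = rng_seed
    ),
    class = "sim_config"
  )
}

#' Default family-size distribution
#'
#' Reads per original molecule are drawn from a two-component mixture that
#' emulates the family-size profile of a real duplex experiment: a
#' geometric component (`small_prob`) capturing the striking abundance of
#' singleton and near-singleton families that dominate observed barcode
#' lists, and a discretised log-normal tail whose default
#' `meanlog = log(12)` puts the median size of consensus-forming families
#' at about a dozen reads. The default mixture weight makes roughly one
#' fragment in nine deep enough on both strands to yield a duplex
#' consensus without error correction. Everything is truncated to
#' `[1, max_size]`. Override with any tibble of (`size`, `weight`) pairs,
#' e.g. from [read_family_size_distribution()].
#'
#' @param small_weight Mixture weight of the geometric small-family
#'   component (default 0.8).
#' @param small_prob Success probability of the geometric component
#'   (default 0.5: half of its mass on singletons).
#' @param meanlog,sdlog Log-normal tail parameters (defaults `log(12)`,
#'   0.7).
#' @param max_size Truncation bound (default 200).
#' @return A tibble with columns `size` and `weight` (weights sum to 1).
#' @export
family_size_distribution <- function(small_weight = 0.8, small_prob = 0.5,
                                     meanlog = log(12), sdlog = 0.7,
                                     max_size = 200) {
  size <- seq_len(max_size)
  geom <- small_prob * (1 - small_prob)^(size - 1)
  ln <- plnorm(size + 0.5, meanlog, sdlog) - plnorm(size - 0.5, meanlog, sdlog)
  w <- small_weight * geom / sum(geom) + (1 - small_weight) * ln / sum(ln)
  tibble(size = size, weight = w / sum(w))
}

#' Read a family-size distribution from a TSV file
#'
#' @param path Path to a two-column TSV with columns `size` and `weight`.
#' @return A tibble with columns `size` and `weight`.
#' @export
read_family_size_distribution <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    size = readr::col_integer(), weight = readr::col_double()
  ))
  if (nrow(d) == 0) abort("family-size distribution is empty")
  d
}

#' Sample family sizes
#'
#' @param n Number of draws.
#' @param dist Distribution tibble with columns `size` and `weight`.
#' @return Integer vector of `n` sizes (all >= 1).
#' @export
sample_family_size <- function(n, dist = family_size_distribution()) {
  if (nrow(dist) == 0) abort("family-size distribution is empty")
  idx <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$weight)
  as.integer(dist$size[idx])
}

#' Randomly fragment a reference sequence
#'
#' Draws `n` error-free fragments of exactly `frag_len` bases with uniform
#' start positions and uniform strand; minus-strand fragments are
#' reverse-complemented.
#'
#' @param ref Reference sequence: a character scalar or a
#'   `Biostrings::DNAStringSet`/`DNAString` (first sequence used).
#' @param n Number of fragments.
#' @param frag_len Fragment length (reference must be at least this long).
#' @return A tibble with columns `fragment_id`, `start` (0-based),
#'   `ref_strand` (`"+"`/`"-"`), `seq`.
#' @export
fragment_reference <- function(ref, n, frag_len = 400) {
  ref <- as.character(ref)[1]
  L <- nchar(ref)
  if (L < frag_len) abort("reference is shorter than frag_len")
  start <- sample.int(L - frag_len + 1L, n, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seq <- substr(rep(ref, n), start + 1L, start + frag_len)
  seq[strand == "-"] <- revcomp(seq[strand == "-"])
  tibble(fragment_id = seq_len(n), start = start, ref_strand = strand, seq = seq)
}

#' Synthesise random duplex tag pairs
#'
#' Random oligomer synthesis with a uniform 25% probability per base.
#'
#' @param n Number of tag pairs.
#' @param tag_len Tag length (default 12).
#' @return A tibble with columns `alpha` and `beta`.
#' @export
synthesize_tags <- function(n, tag_len = 12) {
  tibble(alpha = random_dna(n, tag_len), beta = random_dna(n, tag_len))
}

#' Simulate the PCR genealogy of one read family
#'
#' Amplifies a tagged molecule through `cycles` PCR cycles. The family's
#' `n_reads` reads start at the root; at cycle c a node replicates with
#' probability `1 / decay^(c-1)`, its reads split between the two daughter
#' molecules with a fair coin, and each daughter receives fresh
#' `Binomial(len, error_rate)` substitutions that all its descendants
#' inherit.
#'
#' @param molecule The tagged fragment sequence (character scalar).
#' @param n_reads Family size (>= 1).
#' @param cycles,decay,error_rate See [sim_config()].
#' @return A tibble with one row per read: `molecule` (the leaf sequence)
#'   and `errors` (comma-joined `pos:pcr`, 0-based positions; `""` if
#'   none).
#' @export
simulate_pcr_tree <- function(molecule, n_reads, cycles = 25, decay = 1.05,
                              error_rate = 0.001) {
  stopifnot(n_reads >= 1)
  res <- .sim_reads_cpp(molecule, as.integer(n_reads), as.integer(cycles),
                        decay, error_rate, 0, nchar(molecule))
  tibble(molecule = res$seq1, errors = res$errors1)
}

#' Simulate paired-end sequencing of tagged molecules
#'
#' Mate 1 is the first `read_len` bases of the molecule, mate 2 the first
#' `read_len` bases of its reverse complement; each base is substituted
#' independently with probability `error_rate` (uniformly to one of the
#' other three bases). Qualities are a flat PHRED 40.
#'
#' @param molecules Character vector of (possibly PCR-mutated) tagged
#'   molecules, each at least `read_len` long.
#' @param read_len Read length.
#' @param error_rate Per-base sequencing error probability.
#' @return A tibble with columns `seq1`, `qual1`, `seq2`, `qual2`,
#'   `errors1`, `errors2` (0-based `pos:seq` lists).
#' @export
simulate_sequencing <- function(molecules, read_len = 100, error_rate = 0.001) {
  res <- .sim_reads_cpp(molecules, rep(1L, length(molecules)), 0L, 1.05,
                        0, error_rate, as.integer(read_len))
  q <- strrep("I", read_len)
  tibble(seq1 = res$seq1, qual1 = q, seq2 = res$seq2, qual2 = q,
         errors1 = res$errors1, errors2 = res$errors2)
}

#' Run the duplex-sequencing simulator
#'
#' Simulates a whole duplex experiment: fragments the reference, ligates
#' random tag pairs plus the constant linker to both fragment ends, splits
#' each family's reads between the two strands with a fair coin, amplifies
#' each strand through the PCR genealogy, sequences every read with
#' errors, and records the ground truth for each read.
#'
#' The `ab`-strand molecule is
#' `alpha + linker + fragment + revcomp(linker) + revcomp(beta)`; the
#' `ba` strand is its reverse complement, so mate 1 of an `ab` read starts
#' with `alpha + linker` and mate 1 of a `ba` read with `beta + linker`.
#'
#' @param config A [sim_config()].
#' @param reference Reference sequence (character scalar,
#'   `Biostrings` object, or `NULL` to draw a random 10 kb sequence).
#' @return A list of class `duplex_simulation`:
#'   * `reads`: tibble `read_id`, `seq1`, `qual1`, `seq2`, `qual2`;
#'   * `truth`: tibble `read_id`, `fragment_id`, `alpha`, `beta`, `strand`
#'     (`ab`/`ba`), `mate`, `errors` (0-based `pos:src` list per mate);
#'   * `fragments`: tibble `fragment_id`, `start`, `ref_strand`, `seq`,
#'     `alpha`, `beta`, `canonical_tag`;
#'   * `config`: the configuration used.
#' @export
run_simulation <- function(config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  if (is.null(reference)) reference <- random_dna(1, 10000L)
  n <- config$n_fragments
  frags <- fragment_reference(reference, n, config$frag_len)
  tags <- synthesize_tags(n, config$tag_len)
  sizes <- sample_family_size(n, config$family_sizes)

  linker <- config$linker
  mol_ab <- paste0(tags$alpha, linker, frags$seq,
                   revcomp(linker), revcomp(tags$beta))
  mol_ba <- revcomp(mol_ab)
  n_ab <- rbinom(n, sizes, 0.5)
  n_ba <- sizes - n_ab

  jobs <- tibble(
    fragment_id = rep(frags$fragment_id, 2L),
    strand = rep(c("ab", "ba"), each = n),
    molecule = c(mol_ab, mol_ba),
    n_reads = c(n_ab, n_ba)
  ) %>%
    arrange(.data$fragment_id, .data$strand) %>%
    filter(.data$n_reads > 0L)

  res <- .sim_reads_cpp(jobs$molecule, jobs$n_reads, config$pcr_cycles,
                        config$efficiency_decay, config$error_rate,
                        config$error_rate, config$read_len)
  job_idx <- res$family
  n_reads_total <- length(job_idx)
  read_id <- sprintf("sim%08d", seq_len(n_reads_total))
  qual <- strrep("I", config$read_len)

  reads <- tibble(
    read_id = read_id,
    seq1 = res$seq1, qual1 = qual,
    seq2 = res$seq2, qual2 = qual
  )
  frag_of_read <- jobs$fragment_id[job_idx]
  truth <- tibble(
    read_id = rep(read_id, 2L),
    fragment_id = rep(frag_of_read, 2L),
    alpha = rep(tags$alpha[frag_of_read], 2L),
    beta = rep(tags$beta[frag_of_read], 2L),
    strand = rep(jobs$strand[job_idx], 2L),
    mate = rep(1:2, each = n_reads_total),
    errors = c(res$errors1, res$errors2)
  ) %>% arrange(.data$read_id, .data$mate)

  fragments <- frags %>%
    mutate(
      alpha = tags$alpha, beta = tags$beta,
      canonical_tag = canonical_tag(tags$alpha, tags$beta)$canonical_tag
    )
  structure(
    list(reads = reads, truth = truth, fragments = fragments, config = config),
    class = "duplex_simulation"
  )
}

#' @export
print.duplex_simulation <- function(x, ...) {
  cat(sprintf(
    "<duplex_simulation> %d fragments, %d read pairs (%d bp reads, %d PCR cycles, error rate %g)\n",
    nrow(x$fragments), nrow(x$reads), x$config$read_len,
    x$config$pcr_cycles, x$config$error_rate
  ))
  invisible(x)
}

#' Write simulator output to disk
#'
#' Writes `reads_1.fq`, `reads_2.fq`, `truth.tsv` and `fragments.tsv`
#' under `dir`.
#'
#' @param sim A `duplex_simulation` from [run_simulation()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq_pairs(sim$reads, file.path(dir, "reads_1.fq"),
                    file.path(dir, "reads_2.fq"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$fragments, file.path(dir, "fragments.tsv"))
  invisible(dir)
}

#' Read a truth log written by [write_simulation()]
#'
#' @param path Path to `truth.tsv`.
#' @return The truth tibble.
#' @export
read_truth_log <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(),
    fragment_id = readr::col_integer(),
    alpha = readr::col_character(),
    beta = readr::col_character(),
    strand = readr::col_character(),
    mate = readr::col_integer(),
    errors = readr::col_character()
  )) %>%
    mutate(errors = dplyr::coalesce(.data$errors, ""))
}
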