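# brute-force oracles, independent of the package's kernels

brute_hamming <- function(x, y) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  stopifnot(length(xs) == length(ys))
  sum(xs != ys)
}

swap_halves <- function(tag) {
  h <- nchar(tag) %/% 2
  paste0(substr(tag, h + 1, nchar(tag)), substr(tag, 1, h))
}

# O(n^2) all-pairs matcher: min distance over a+b / b+a arrangements
brute_tag_matches <- function(tags, max_dist) {
  n <- length(tags)
  out <- list()
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- min(brute_hamming(tags[i], tags[j]),
               brute_hamming(tags[i], swap_halves(tags[j])))
      if (d <= max_dist) {
        k <- k + 1
        out[[k]] <- tibble::tibble(
          tag_i = min(tags[i], tags[j]),
          tag_j = max(tags[i], tags[j]),
          dist = d
        )
      }
    }
  }
  if (k == 0) {
    return(tibble::tibble(tag_i = character(), tag_j = character(),
                          dist = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), tag_i, tag_j)
}

# plain union-find over the match list
brute_components <- function(tags, matches) {
  uf <- new.env(parent = emptyenv())
  uf$parent <- seq_along(tags)
  find <- function(i) {
    while (uf$parent[i] != i) i <- uf$parent[i]
    i
  }
  for (r in seq_len(nrow(matches))) {
    i <- find(match(matches$tag_i[r], tags))
    j <- find(match(matches$tag_j[r], tags))
    if (i != j) uf$parent[j] <- i
  }
  roots <- vapply(seq_along(tags), find, integer(1))
  split(tags, roots)
}

random_tags <- function(n, len = 24) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  unique(apply(m, 1, paste, collapse = ""))
}

# substitute one random base
mutate_one <- function(tag, pos = NULL) {
  chars <- strsplit(tag, "")[[1]]
  if (is.null(pos)) pos <- sample.int(length(chars), 1)
  chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
  paste(chars, collapse = "")
}

# a small family table built by hand: one row per mate of each read
make_family_rows <- function(tag, order, n_reads, seq, qual = NULL,
                             id_prefix = "r") {
  qual <- qual %||% strrep("I", nchar(seq))
  dplyr::bind_rows(lapply(seq_len(n_reads), function(i) {
    tibble::tibble(
      canonical_tag = tag, order = order, mate = 1:2,
      read_id = paste0(id_prefix, i), seq = seq, qual = qual
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one shared small simulation for tests that need realistic data
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_fragments = 400, rng_seed = 424242)
      cache <<- run_simulation(cfg)
    }
    cache
  }
})
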