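test_that("group_families nests by sorted key and conserves rows", {
  fam <- dplyr::bind_rows(
    make_family_rows("AAAA", "ab", 3, "ACGT", id_prefix = "x"),
    make_family_rows("AAAA", "ba", 2, "ACGT", id_prefix = "y")
  )
  fam <- dureunite:::sort_family_table(fam)
  g <- group_families(fam)
  expect_equal(nrow(g), 4L) # (ab, ba) x (mate 1, 2)
  expect_equal(sum(g$family_size), nrow(fam))
  expect_false(is.unsorted(paste(g$canonical_tag, g$order, g$mate)))

  shuffled <- fam[rev(seq_len(nrow(fam))), ]
  expect_error(group_families(shuffled), "not sorted")

  empty <- fam[0, ]
  expect_equal(nrow(group_families(empty)), 0L)
})

test_that("align_family stacks equal-length reads and ungaps to the inputs", {
  one <- align_family("ACGTACGT")
  expect_equal(one$rows, "ACGTACGT")

  five <- align_family(rep("ACGTAC", 5))
  expect_equal(five$rows, rep("ACGTAC", 5))
  expect_false(any(grepl("-", five$rows, fixed = TRUE)))

  mixed <- align_family(c("ACGT", "AGT"))
  expect_equal(nchar(mixed$rows[1]), nchar(mixed$rows[2]))
  expect_equal(ungap_family(mixed), c("ACGT", "AGT"))

  threeway <- align_family(c("ACGTTGCA", "ACGTGCA", "ACTTGCA"))
  expect_equal(dplyr::n_distinct(nchar(threeway$rows)), 1L)
  expect_equal(ungap_family(threeway), c("ACGTTGCA", "ACGTGCA", "ACTTGCA"))
  # gap columns carry the no-quality placeholder
  expect_equal(nchar(threeway$quals), nchar(threeway$rows))

  expect_error(align_family(character(0)), "empty")
})

msa <- function(rows, quals = NULL) {
  structure(list(rows = rows, quals = quals %||% strrep("I", nchar(rows))),
            class = "msa_family")
}

test_that("consensus columns follow the vote-fraction and quality rules", {
  # 8 A's vs 2 C's at q40: 0.8 >= 0.7
  expect_equal(call_sscs(msa(c(rep("A", 8), rep("C", 2)))), "A")
  # 6 vs 4: 0.6 < 0.7
  expect_equal(call_sscs(msa(c(rep("A", 6), rep("C", 4)))), "N")
  # quality filter: 6 A's at PHRED 10 are discarded, leaving a 2-2 tie
  rows <- c(rep("A", 2), rep("A", 6), rep("C", 2))
  quals <- c(rep("?", 2), rep("+", 6), rep("?", 2)) # PHRED 30 / 10 / 30
  expect_equal(call_sscs(msa(rows, quals)), "N")
  # a column whose votes are all discarded yields N
  expect_equal(call_sscs(msa(rep("A", 3), rep("+", 3))), "N")
  # family below min_reads yields nothing
  expect_null(call_sscs(msa(rep("A", 2))))
  # identical error-free reads reproduce the read at any threshold <= 1
  expect_equal(call_sscs(msa(rep("ACGTT", 4)), cons_thres = 1), "ACGTT")
})

test_that("a winning gap deletes the column; a sub-threshold gap yields N", {
  rows <- c("A-T", "A-T", "A-T", "AGT")
  expect_equal(call_sscs(msa(rows), min_reads = 3), "AT") # gap at 3/4 = 0.75
  rows <- c("A-T", "A-T", "AGT")
  expect_equal(call_sscs(msa(rows), min_reads = 3), "ANT") # 2/3 < 0.7
})

test_that("raising cons_thres only censors, never un-censors", {
  set.seed(13)
  for (rep_i in 1:20) {
    n <- sample(3:8, 1)
    rows <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G"), 12, replace = TRUE, prob = c(.7, .2, .1)),
            collapse = "")
    }, character(1))
    lo <- call_sscs(msa(rows), cons_thres = 0.5)
    hi <- call_sscs(msa(rows), cons_thres = 0.9)
    lo_c <- strsplit(lo, "")[[1]]
    hi_c <- strsplit(hi, "")[[1]]
    expect_true(all(hi_c == lo_c | hi_c == "N"))
  }
})

test_that("call_consensi equals per-family call_sscs, including mixed lengths", {
  fam <- dplyr::bind_rows(
    make_family_rows("AAAACCCC", "ab", 4, "ACGTACGT", id_prefix = "a"),
    make_family_rows("AAAATTTT", "ba", 3, "GGGGCCCC", id_prefix = "b"),
    make_family_rows("CCCCGGGG", "ab", 2, "ACGT", id_prefix = "tiny")
  )
  # make one family mixed-length: drop a base from one of its reads
  fam$seq[fam$canonical_tag == "AAAATTTT" & fam$read_id == "b2"] <- "GGGCCCC"
  fam$qual[fam$canonical_tag == "AAAATTTT" & fam$read_id == "b2"] <- "IIIIIII"
  fam <- dureunite:::sort_family_table(fam)
  out <- call_consensi(fam, min_reads = 3)
  expect_equal(nrow(out), 4L) # the 2-read family is dropped
  grouped <- group_families(fam)
  for (i in seq_len(nrow(out))) {
    reads <- grouped$reads[[which(
      grouped$canonical_tag == out$canonical_tag[i] &
        grouped$order == out$order[i] & grouped$mate == out$mate[i]
    )]]
    expect_equal(out$seq[i], call_sscs(align_family(reads$seq, reads$qual)))
  }
})

test_that("duplex merge pairs complementary strands and masks disagreement", {
  sscs <- tibble::tibble(
    canonical_tag = rep(c("AAAACCCC", "AAAAGGGG", "AAAATTTT"), each = 4),
    order = rep(c("ab", "ab", "ba", "ba"), 3),
    mate = rep(c(1L, 2L, 1L, 2L), 3),
    seq = c(
      "ACGTACGT", "TTTTCCCC", "GGGGAAAA", "ACGTACGT", # tag 1: mate1 pair equal
      "ACGTACGT", "AAAA", "CCCC", "ACGAACGT",          # tag 2: 1 mismatch pos 4
      "ACGT", "AAAA", "CCCC", "NCGT"                   # tag 3: N in one strand
    ),
    family_size = 3L
  )
  dcs <- call_dcs(sscs)
  expect_equal(nrow(dcs), 6L)
  d1 <- dcs[dcs$canonical_tag == "AAAACCCC" & dcs$mate == 1L, ]
  expect_equal(d1$seq, "ACGTACGT") # identical consensi pass through
  expect_equal(d1$fam_size_ab, 3L)
  d2 <- dcs[dcs$canonical_tag == "AAAAGGGG" & dcs$mate == 1L, ]
  expect_equal(d2$seq, "ACGNACGT") # disagreement masked positionally
  d3 <- dcs[dcs$canonical_tag == "AAAATTTT" & dcs$mate == 1L, ]
  expect_equal(d3$seq, "NCGT") # N in either strand stays N

  # a tag with only one strand yields no DCS
  only_ab <- sscs[sscs$order == "ab" & sscs$canonical_tag == "AAAACCCC", ]
  expect_equal(nrow(call_dcs(only_ab)), 0L)
})

test_that("duplex merge aligns consensi of unequal length before masking", {
  sscs <- tibble::tibble(
    canonical_tag = "AAAACCCC",
    order = c("ab", "ba"),
    mate = c(1L, 2L),
    seq = c("ACGTACGT", "ACGACGT"), # second lost the T at position 4
    family_size = 3L
  )
  dcs <- call_dcs(sscs)
  expect_equal(nrow(dcs), 1L)
  expect_equal(nchar(dcs$seq), 8L)
  # agreement outside the indel column, N at it
  expect_equal(substr(dcs$seq, 1, 3), "ACG")
  expect_equal(substr(dcs$seq, 5, 8), "ACGT")
  expect_equal(substr(dcs$seq, 4, 4), "N")
})

test_that("ordered_parallel_map preserves submission order and aborts on failure", {
  xs <- as.list(1:12)
  sq <- function(x) x^2
  expect_equal(ordered_parallel_map(xs, sq, workers = 1), lapply(xs, sq))

  slow <- function(x) {
    Sys.sleep(stats::runif(1, 0, 0.02))
    x * 10L
  }
  out <- ordered_parallel_map(xs, slow, workers = 3, queue_mult = 2)
  expect_equal(out, lapply(xs, function(x) x * 10L))

  boom <- function(x) if (x == 5) stop("bad job") else x
  expect_error(ordered_parallel_map(xs, boom, workers = 1), "job 5")
  expect_error(ordered_parallel_map(xs, boom, workers = 3), "job 5")
})

test_that("consensus output is invariant to worker count", {
  set.seed(99)
  fam <- dplyr::bind_rows(lapply(1:25, function(i) {
    tag <- random_tags(1, 16)
    n <- sample(3:6, 1)
    rows <- make_family_rows(tag, "ab", n, strrep("ACGT", 5),
                             id_prefix = paste0("f", i, "_"))
    # a third of the families need alignment
    if (i %% 3 == 0) rows$seq[1] <- substr(rows$seq[1], 1, 18)
    rows$qual <- strrep("I", nchar(rows$seq))
    rows
  }))
  fam <- dureunite:::sort_family_table(fam)
  s1 <- call_consensi(fam, workers = 1)
  s4 <- call_consensi(fam, workers = 4, queue_mult = 2)
  expect_equal(s1, s4)
})
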