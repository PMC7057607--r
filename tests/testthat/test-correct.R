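test_that("edit_distance matches a brute-force positional count", {
  expect_equal(edit_distance(strrep("ACGT", 6), strrep("ACGT", 6)), 0L)
  expect_equal(edit_distance(paste0(strrep("A", 23), "A"),
                             paste0(strrep("A", 23), "T")), 1L)
  expect_error(edit_distance("ACGT", "ACG"), "equal length")
  # N mismatches any non-N base and matches N
  expect_equal(edit_distance("ANNT", "AANT"), 1L)

  set.seed(11)
  x <- random_tags(200, 24)
  y <- vapply(x, function(t) {
    k <- sample(0:4, 1)
    for (i in seq_len(k)) t <- mutate_one(t)
    t
  }, character(1), USE.NAMES = FALSE)
  expect_equal(edit_distance(x, y),
               mapply(brute_hamming, x, y, USE.NAMES = FALSE))
})

test_that("find_tag_matches equals the all-pairs brute force with planted derivatives", {
  set.seed(23)
  base <- random_tags(300, 24)
  planted <- vapply(sample(base, 60), mutate_one, character(1), USE.NAMES = FALSE)
  tags <- unique(c(base, planted))
  for (d in 1:3) {
    got <- suppressWarnings(find_tag_matches(tags, max_dist = d))
    want <- brute_tag_matches(tags, d)
    expect_equal(got[, c("tag_i", "tag_j", "dist")], want, info = paste("d =", d))
  }
})

test_that("a tag matches the ba arrangement of another tag", {
  t1 <- paste0(strrep("A", 12), strrep("C", 12)) # canonical, alpha=A12 beta=C12
  # molecule with alpha=C12(one error), beta=A12: canonical is A12 + C11G
  t2 <- canonical_tag(mutate_one(strrep("C", 12), pos = 12), strrep("A", 12))$canonical_tag
  expect_equal(edit_distance(t1, t2), 1L) # sanity: differs in arrangement space
  m <- find_tag_matches(c(t1, t2), max_dist = 1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$dist, 1L)
})

test_that("graph components follow transitive closure and match union-find", {
  # no edges: every tag its own component
  counts <- stats::setNames(rep(1L, 5), random_tags(5))
  g <- build_barcode_graph(
    tibble::tibble(tag_i = character(), tag_j = character(), dist = integer()),
    counts
  )
  expect_equal(dplyr::n_distinct(g$nodes$component_id), 5L)

  # chain A-B, B-C merges into one component even if d(A, C) > max_dist
  a <- strrep("A", 24)
  b <- mutate_one(a, 1)
  c2 <- mutate_one(b, 2)
  m <- find_tag_matches(c(a, b, c2), max_dist = 1)
  expect_equal(sort(edit_distance(rep(a, 1), c2)), 2L)
  g <- build_barcode_graph(m, stats::setNames(c(1L, 1L, 1L), c(a, b, c2)))
  expect_equal(dplyr::n_distinct(g$nodes$component_id), 1L)

  # random graph vs union-find oracle
  set.seed(31)
  tags <- unique(c(random_tags(80, 24),
                   vapply(random_tags(40, 24), mutate_one, character(1))))
  m <- find_tag_matches(tags, max_dist = 2)
  g <- build_barcode_graph(m, stats::setNames(rep(1L, length(tags)), tags))
  got <- lapply(
    split(g$nodes$canonical_tag, g$nodes$component_id),
    function(x) sort(unname(x))
  )
  want <- lapply(brute_components(tags, m), function(x) sort(unname(x)))
  key <- function(comps) sort(unname(vapply(comps, paste, character(1), collapse = "|")))
  expect_equal(key(got), key(want))
})

test_that("canonical selection ranks by reads or edges with deterministic ties", {
  tags <- c("CCCC", "AAAA", "GGGG")
  expect_equal(select_canonical(tags, c(10L, 2L, 2L), c(1L, 4L, 1L), "reads"),
               "CCCC")
  # read tie: higher degree wins, then lexicographic
  expect_equal(select_canonical(tags, c(5L, 5L, 5L), c(1L, 1L, 2L), "reads"),
               "GGGG")
  expect_equal(select_canonical(tags, c(5L, 5L, 5L), c(1L, 1L, 1L), "reads"),
               "AAAA")
  # edges mode: star centre beats leaves
  expect_equal(select_canonical(tags, c(1L, 1L, 1L), c(4L, 1L, 1L), "edges"),
               "CCCC")
  # a tag containing N never outranks an all-real-base tag
  expect_equal(select_canonical(c("NAAA", "CCCC"), c(9L, 1L), c(1L, 1L), "reads"),
               "CCCC")
})

test_that("correction map is idempotent and applying it conserves records", {
  t1 <- strrep("A", 8)
  t2 <- mutate_one(t1, 3)
  fam <- dplyr::bind_rows(
    make_family_rows(t1, "ab", 3, "ACGT", id_prefix = "a"),
    make_family_rows(t2, "ab", 1, "ACGT", id_prefix = "b")
  )
  res <- correct_barcodes(fam, max_dist = 1)
  map <- res$map
  # idempotence: every value maps to itself
  expect_equal(map$corrected_tag[match(map$corrected_tag, map$raw_tag)],
               map$corrected_tag)
  expect_true(all(map$raw_tag %in% c(t1, t2)))
  expect_equal(unique(res$families$canonical_tag), t1) # 3 + 1 records reunited
  expect_equal(nrow(res$families), nrow(fam))
  # applying the map twice equals applying it once
  expect_equal(apply_correction(res$families, map), res$families)
})

test_that("identity map leaves the table unchanged; unknown tags pass through", {
  fam <- make_family_rows(strrep("G", 8), "ab", 2, "ACGT")
  id_map <- tibble::tibble(
    raw_tag = strrep("G", 8), corrected_tag = strrep("G", 8),
    component_id = 1L, distance = 0L, flip_order = FALSE
  )
  expect_equal(apply_correction(fam, id_map), dureunite:::sort_family_table(fam))
  other <- make_family_rows(strrep("T", 8), "ba", 1, "ACGT")
  expect_message(out <- apply_correction(dplyr::bind_rows(fam, other), id_map),
                 "absent")
  expect_equal(sum(out$canonical_tag == strrep("T", 8)), 2L)
})

test_that("a raw tag closest to the swapped representative flips its order flag", {
  # molecule alpha = CA, beta = AC: canonical tag is ACCA (the ba arrangement)
  rep_tag <- canonical_tag("CA", "AC")$canonical_tag
  expect_equal(rep_tag, "ACCA")
  # a read observing the ab arrangement CAAC with an error at position 1
  # sees AAAC, whose own canonical form is AAAC with order ab
  raw <- canonical_tag("AA", "AC")
  expect_equal(raw$canonical_tag, "AAAC")
  expect_equal(raw$order, "ab")
  fam <- dplyr::bind_rows(
    make_family_rows(rep_tag, "ba", 3, "ACGT", id_prefix = "g"),
    make_family_rows(raw$canonical_tag, raw$order, 1, "ACGT", id_prefix = "b")
  )
  res <- correct_barcodes(fam, max_dist = 1)
  map <- res$map
  expect_true(map$flip_order[map$raw_tag == "AAAC"]) # closer to CAAC than ACCA
  expect_equal(map$distance[map$raw_tag == "AAAC"], 1L)
  corrected <- res$families[res$families$read_id == "b1", ]
  expect_equal(unique(corrected$canonical_tag), rep_tag)
  expect_equal(unique(corrected$order), "ba")
  expect_equal(nrow(res$families), nrow(fam)) # conservation
})

test_that("max_dist = 0 yields the identity correction", {
  set.seed(5)
  tags <- random_tags(40, 24)
  fam <- dplyr::bind_rows(lapply(seq_along(tags), function(i) {
    make_family_rows(tags[i], "ab", 1, "ACGT", id_prefix = paste0("r", i, "_"))
  }))
  res <- correct_barcodes(fam, max_dist = 0)
  expect_true(all(res$map$raw_tag == res$map$corrected_tag))
  expect_equal(res$families, dureunite:::sort_family_table(fam))
})

test_that("singleton count is non-increasing in max_dist", {
  sim <- shared_sim()
  fam <- suppressMessages(extract_tags(sim$reads))
  singletons <- vapply(0:3, function(d) {
    corrected <- if (d == 0) fam else correct_barcodes(fam, max_dist = d)$families
    h <- family_size_histogram(corrected)
    sum(h$n_families[h$family_size == 1])
  }, numeric(1))
  expect_true(all(diff(singletons) <= 0))
})
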