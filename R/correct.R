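#' Find all pairs of similar tags
#'
#' All-vs-all approximate matching of canonical tags under substitution
#' (Hamming) distance, considering each tag against both the `a + b` and
#' `b + a` arrangements of every other tag. The matcher partitions each
#' tag into `max_dist + 1` disjoint blocks (any pair within distance
#' `max_dist` must agree exactly on at least one block), buckets tags by
#' block content to generate candidates, and verifies exact distances, so
#' the result equals the full quadratic comparison.
#'
#' `min_mapq` and `max_pos_offset` are alignment-quality filters that only
#' make sense for an external aligner backend; the exact matcher reports
#' every pair with `offset = 0`, so they are accepted and recorded but have
#' no effect here.
#'
#' @param tags Character vector of distinct canonical tags, all the same
#'   length (2 x tag length).
#' @param max_dist Maximum substitution distance for a match (default 1).
#' @param min_mapq,max_pos_offset Recorded filter settings for pluggable
#'   aligner backends (defaults 20 and 2).
#' @return A tibble with one row per unordered pair: `tag_i`, `tag_j`
#'   (with `tag_i < tag_j`), `dist`, `offset`, `mapq_proxy`.
#' @export
find_tag_matches <- function(tags, max_dist = 1, min_mapq = 20, max_pos_offset = 2) {
  tags <- as.character(tags)
  if (anyDuplicated(tags)) abort("tags must be distinct canonical tags")
  if (max_dist > 3) {
    warn("max_dist > 3 risks a quadratic blow-up of candidate pairs")
  }
  if (length(tags) < 2 || max_dist < 0) {
    return(tibble(tag_i = character(), tag_j = character(), dist = integer(),
                  offset = integer(), mapq_proxy = integer()))
  }
  m <- .tag_matches_cpp(tags, swap_tag(tags), as.integer(max_dist))
  out <- tibble(
    tag_i = pmin(tags[m$i], tags[m$j]),
    tag_j = pmax(tags[m$i], tags[m$j]),
    dist = m$dist,
    offset = 0L,
    mapq_proxy = NA_integer_
  )
  arrange(out, .data$tag_i, .data$tag_j)
}

#' Build the barcode graph and its connected components
#'
#' Vertices are canonical tags (weighted by how many read pairs they tag);
#' an edge joins two tags whose distance passed the matcher. Each connected
#' component is taken to be one original molecule together with its
#' PCR/sequencing-error derivatives.
#'
#' @param matches Match tibble from [find_tag_matches()].
#' @param read_counts Named integer vector (or tibble with columns
#'   `canonical_tag`, `reads`) giving read-pair counts per tag; its names
#'   define the vertex set, so isolated tags become singleton components.
#' @return An object of class `barcode_graph`: a list with `graph` (the
#'   igraph object) and `nodes`, a tibble with columns `canonical_tag`,
#'   `reads`, `degree`, `component_id`.
#' @export
build_barcode_graph <- function(matches, read_counts) {
  if (is.data.frame(read_counts)) {
    read_counts <- setNames(read_counts$reads, read_counts$canonical_tag)
  }
  tags <- names(read_counts)
  if (is.null(tags)) abort("read_counts must be named by canonical tag")
  g <- igraph::graph_from_data_frame(
    matches[, c("tag_i", "tag_j")],
    directed = FALSE,
    vertices = data.frame(name = tags)
  )
  comp <- igraph::components(g)
  nodes <- tibble(
    canonical_tag = igraph::V(g)$name,
    reads = as.integer(read_counts[igraph::V(g)$name]),
    degree = as.integer(igraph::degree(g)),
    component_id = as.integer(comp$membership)
  )
  structure(list(graph = g, nodes = nodes), class = "barcode_graph")
}

#' @export
print.barcode_graph <- function(x, ...) {
  cat(sprintf(
    "<barcode_graph> %d tags, %d edges, %d components\n",
    nrow(x$nodes), igraph::ecount(x$graph),
    dplyr::n_distinct(x$nodes$component_id)
  ))
  invisible(x)
}

rank_canonical <- function(nodes, choose_by) {
  # tags containing N are never preferred over all-real-base tags
  has_n <- stringr::str_detect(nodes$canonical_tag, "N")
  if (choose_by == "reads") {
    order(has_n, -nodes$reads, -nodes$degree, nodes$canonical_tag, method = "radix")
  } else {
    order(has_n, -nodes$degree, -nodes$reads, nodes$canonical_tag, method = "radix")
  }
}

#' Pick the representative tag of one component
#'
#' The default (`choose_by = "reads"`) picks the tag backing the largest
#' number of reads; `choose_by = "edges"` picks the tag with most edges to
#' other tags. Ties break by the other count, then by the
#' lexicographically smallest tag; a tag containing `N` never beats an
#' all-real-base tag.
#'
#' @param tags Character vector: the component's tags.
#' @param read_counts,degree_counts Integer vectors parallel to `tags`.
#' @param choose_by `"reads"` (default) or `"edges"`.
#' @return The selected tag (length-1 character).
#' @export
select_canonical <- function(tags, read_counts, degree_counts,
                             choose_by = c("reads", "edges")) {
  choose_by <- arg_match(choose_by)
  if (length(tags) == 0) abort("component is empty")
  nodes <- tibble(canonical_tag = tags, reads = read_counts, degree = degree_counts)
  tags[rank_canonical(nodes, choose_by)[1]]
}

#' Build the raw-to-corrected tag map from a barcode graph
#'
#' Every tag maps to its component's representative; representatives map to
#' themselves, so the map is idempotent. The `flip_order` column records
#' whether the raw tag is closer to the `b + a` arrangement of its
#' representative than to the `a + b` arrangement, in which case the
#' record's strand-order flag must flip when the map is applied.
#'
#' @param graph A `barcode_graph` from [build_barcode_graph()].
#' @param choose_by Selection rule, see [select_canonical()].
#' @return A tibble with columns `raw_tag`, `corrected_tag`,
#'   `component_id`, `distance`, `flip_order`.
#' @export
build_correction_map <- function(graph, choose_by = c("reads", "edges")) {
  choose_by <- arg_match(choose_by)
  nodes <- graph$nodes
  nodes <- nodes[rank_canonical(nodes, choose_by), , drop = FALSE]
  reps <- nodes %>%
    group_by(.data$component_id) %>%
    summarise(corrected_tag = .data$canonical_tag[1], .groups = "drop")
  map <- nodes %>%
    left_join(reps, by = "component_id") %>%
    mutate(
      raw_tag = .data$canonical_tag,
      dist_ab = edit_distance(.data$raw_tag, .data$corrected_tag),
      dist_ba = edit_distance(.data$raw_tag, swap_tag(.data$corrected_tag)),
      distance = pmin(.data$dist_ab, .data$dist_ba),
      flip_order = .data$dist_ba < .data$dist_ab
    ) %>%
    select(all_of(c("raw_tag", "corrected_tag", "component_id",
                    "distance", "flip_order"))) %>%
    arrange(.data$raw_tag)
  map
}

#' Apply a correction map to a family table
#'
#' Replaces each record's canonical tag by its corrected tag and flips the
#' `ab`/`ba` order flag for records whose raw tag matched the swapped
#' arrangement of the representative. Tags absent from the map are left
#' unchanged (identity), and their count is reported. The total record
#' count is conserved.
#'
#' @param families Family-table tibble.
#' @param map Correction map from [build_correction_map()].
#' @return The corrected, re-sorted family table.
#' @export
apply_correction <- function(families, map) {
  check_family_table(families)
  idx <- match(families$canonical_tag, map$raw_tag)
  if (any(is.na(idx))) {
    inform(sprintf("%d tag(s) absent from the correction map; left unchanged",
                   dplyr::n_distinct(families$canonical_tag[is.na(idx)])))
  }
  corrected <- map$corrected_tag[idx]
  flip <- map$flip_order[idx]
  out <- families
  out$canonical_tag <- if_else(is.na(idx), families$canonical_tag, corrected)
  out$order <- if_else(
    !is.na(idx) & flip,
    if_else(families$order == "ab", "ba", "ab"),
    families$order
  )
  sort_family_table(out)
}

#' One-call barcode error correction
#'
#' Convenience wrapper running [find_tag_matches()],
#' [build_barcode_graph()], [build_correction_map()] and
#' [apply_correction()] on a family table.
#'
#' @inheritParams find_tag_matches
#' @inheritParams build_correction_map
#' @param families Family-table tibble from [extract_tags()].
#' @param matches Optional precomputed match tibble (pluggable matcher
#'   backend seam); when `NULL` the internal exact matcher is used.
#' @return A list of class `barcode_correction` with elements `families`
#'   (the corrected table), `map`, and `graph`.
#' @export
correct_barcodes <- function(families, max_dist = 1,
                             choose_by = c("reads", "edges"),
                             min_mapq = 20, max_pos_offset = 2,
                             matches = NULL) {
  choose_by <- arg_match(choose_by)
  check_family_table(families)
  counts <- families %>%
    group_by(.data$canonical_tag) %>%
    summarise(reads = n_distinct(.data$read_id), .groups = "drop")
  if (is.null(matches)) {
    matches <- find_tag_matches(counts$canonical_tag, max_dist = max_dist,
                                min_mapq = min_mapq,
                                max_pos_offset = max_pos_offset)
  }
  graph <- build_barcode_graph(matches, counts)
  map <- build_correction_map(graph, choose_by = choose_by)
  structure(
    list(families = apply_correction(families, map), map = map, graph = graph),
    class = "barcode_correction"
  )
}

#' @export
print.barcode_correction <- function(x, ...) {
  n_corr <- sum(x$map$raw_tag != x$map$corrected_tag)
  cat(sprintf("<barcode_correction> %d tags, %d corrected into %d components\n",
              nrow(x$map), n_corr, dplyr::n_distinct(x$map$component_id)))
  invisible(x)
}

#' @describeIn correct_barcodes `tidy()` returns the correction map.
#' @param x A `barcode_correction` object.
#' @param ... Unused.
#' @export
tidy.barcode_correction <- function(x, ...) x$map

#' @describeIn correct_barcodes `glance()` returns one-row summary counts.
#' @export
glance.barcode_correction <- function(x, ...) {
  tibble(
    n_tags = nrow(x$map),
    n_corrected = sum(x$map$raw_tag != x$map$corrected_tag),
    n_components = dplyr::n_distinct(x$map$component_id),
    n_edges = igraph::ecount(x$graph$graph)
  )
}

#' Write / read a correction map TSV
#'
#' @param map Correction map tibble.
#' @param path File path.
#' @return `path` invisibly / the map tibble.
#' @export
write_correction_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' @rdname write_correction_map
#' @export
read_correction_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    raw_tag = readr::col_character(),
    corrected_tag = readr::col_character(),
    component_id = readr::col_integer(),
    distance = readr::col_integer(),
    flip_order = readr::col_logical()
  ))
}
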