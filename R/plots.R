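#' Plot a minimum inter-tag distance profile
#'
#' Bar chart of the number of sampled tags by their minimum substitution
#' distance to the rest of the tag set. A tall bar at distance 1 indicates
#' uncorrected barcode errors.
#'
#' @param object A `tag_distance_profile` from
#'   [min_edit_distance_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tag_distance_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(x = "minimum edit distance to any other tag",
                  y = "number of tags") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tag_distance_profile
#' @param profile A `tag_distance_profile`.
#' @export
plot_distance_profile <- function(profile, ...) autoplot(profile, ...)

#' Plot a family-size histogram
#'
#' Family counts by size on a log10 count scale; the size-1 bar is the
#' singleton pool that barcode correction shrinks.
#'
#' @param object A `family_size_histogram` from [family_size_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.family_size_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$family_size, y = .data$n_families)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "family size (reads)", y = "families") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.family_size_histogram
#' @param hist A `family_size_histogram`.
#' @export
plot_family_sizes <- function(hist, ...) autoplot(hist, ...)
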