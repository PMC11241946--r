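#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a category comparison
#'
#' One row per category pair with the rank-sum statistic and p-value.
#'
#' @param x A `regmark_comparison` ([compare_expression()],
#'   [compare_dnds()]).
#' @param ... Unused.
#' @return Tibble `group1`, `group2`, `statistic`, `p_value`.
#' @method tidy regmark_comparison
#' @export
tidy.regmark_comparison <- function(x, ...) {
  x$pairs
}

#' One-line summary of a category comparison
#'
#' @inheritParams tidy.regmark_comparison
#' @return Tibble with the compared value, total n, number of categories
#'   and the smallest pairwise p-value.
#' @method glance regmark_comparison
#' @export
glance.regmark_comparison <- function(x, ...) {
  tibble(value = x$value, n = sum(x$groups$n),
         n_categories = nrow(x$groups),
         min_p_value = suppressWarnings(min(x$pairs$p_value, na.rm = TRUE)))
}

#' Tidy a peak-overlap diversity comparison
#' @param x A `peak_overlap_comparison` ([compare_peak_overlap()]).
#' @param ... Unused.
#' @return The comparison tibble without attributes.
#' @method tidy peak_overlap_comparison
#' @export
tidy.peak_overlap_comparison <- function(x, ...) {
  out <- x
  attr(out, "windows") <- NULL
  class(out) <- class(tibble())
  out
}
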