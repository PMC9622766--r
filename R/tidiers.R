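#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a depth profile into its per-bin curve
#'
#' @param x a [depth_profile()].
#' @param ... unused.
#' @return A tibble with one row per depth bin: `bin_lo_um`, `bin_hi_um`,
#'   `area_um2`, `compartment`.
#' @export
tidy.depth_profile <- function(x, ...) {
  dplyr::mutate(x$bins, compartment = x$compartment)
}

#' One-row summary of a depth profile
#'
#' @param x a [depth_profile()].
#' @param ... unused.
#' @return A one-row tibble: `compartment`, `integrated_area_um2`, `p90_um`,
#'   `p90_defined`, `n_bins`, `bin_width_um`.
#' @export
glance.depth_profile <- function(x, ...) {
  tibble::tibble(compartment = x$compartment,
                 integrated_area_um2 = x$integrated_area_um2,
                 p90_um = x$p90_um, p90_defined = x$p90_defined,
                 n_bins = nrow(x$bins), bin_width_um = x$bin_width_um)
}

#' Tidy a binwise curve comparison
#'
#' @param x a [compare_profiles_pointwise()] result.
#' @param ... unused.
#' @return The underlying tibble (one row per bin).
#' @export
tidy.curve_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "curve_comparison")
  out
}

#' Tidy Dunn's pairwise comparisons
#'
#' @param x a [kruskal_dunn()] result.
#' @param ... unused.
#' @return The pairwise tibble: `group_i`, `group_j`, `z`, `p_raw`, `p_adj`.
#' @export
tidy.kruskal_dunn_result <- function(x, ...) x$pairwise

#' One-row summary of a Kruskal-Wallis test
#'
#' @param x a [kruskal_dunn()] result.
#' @param ... unused.
#' @return A one-row tibble: `h_statistic`, `df`, `p_value`.
#' @export
glance.kruskal_dunn_result <- function(x, ...) {
  tibble::tibble(h_statistic = x$h_statistic, df = x$df,
                 p_value = x$p_value)
}

#' Tidy a two-way ANOVA table (with Tukey contrasts)
#'
#' @param x a [two_way_anova_tukey()] result.
#' @param which `"anova"` (default) or `"tukey"`.
#' @param ... unused.
#' @return The requested tibble.
#' @export
tidy.anova_tukey_result <- function(x, which = c("anova", "tukey"), ...) {
  which <- match.arg(which)
  if (which == "anova") x$anova else x$tukey
}

#' Tidy a layer-thickness measurement
#'
#' @param x a [layer_thickness()] result.
#' @param ... unused.
#' @return The per-site tibble: `site`, `thickness_um`.
#' @export
tidy.layer_thickness_result <- function(x, ...) x$measurements

#' One-row summary of a layer-thickness measurement
#'
#' @param x a [layer_thickness()] result.
#' @param ... unused.
#' @return A one-row tibble: `median_um`, `iqr_um`, `n_sites`.
#' @export
glance.layer_thickness_result <- function(x, ...) {
  tibble::tibble(median_um = x$median_um, iqr_um = x$iqr_um,
                 n_sites = x$n_sites)
}
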