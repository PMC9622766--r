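#' Generate a synthetic ICG clearance series
#'
#' Emulates the paw fluorescence kinetics of intradermally injected
#' indocyanine green: ROI mean intensity decays exponentially,
#' `I(t) = i0 * exp(-k_per_h * t)`, sampled at the given timepoints with
#' additive Gaussian noise.  The ground truth records the trapezoidal area
#' under the noise-free curve between 1 and 5 h, the window used to compare
#' lymphedematous and control limbs (a larger AUC means slower clearance).
#'
#' @param i0 intensity at time 0 (arbitrary fluorescence units), `> 0`.
#' @param k_per_h clearance rate constant per hour, `>= 0`.
#' @param timepoints_h sampling times in hours, sorted ascending; must include
#'   1 and 5 so the AUC window is defined.  Default `c(0, 1, 3, 5, 7)`.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param seed integer random seed.
#' @param animal_id,limb labels carried into the series.
#' @return A list with `series` (a [clearance_series()] tibble) and `truth`
#'   (list with `true_auc`).
#' @export
generate_icg_series <- function(i0, k_per_h, timepoints_h = c(0, 1, 3, 5, 7),
                                noise_sd = 0, seed = 1L,
                                animal_id = "animal-1", limb = "LD") {
  if (!is.numeric(i0) || i0 <= 0) stop("`i0` must be > 0", call. = FALSE)
  if (k_per_h < 0) stop("`k_per_h` must be >= 0", call. = FALSE)
  if (is.unsorted(timepoints_h, strictly = TRUE))
    stop("`timepoints_h` must be strictly increasing", call. = FALSE)
  if (!all(c(1, 5) %in% timepoints_h))
    stop("`timepoints_h` must include 1 and 5 h: the 1-5 h AUC window is ",
         "undefined otherwise", call. = FALSE)
  set.seed(seed)
  clean <- i0 * exp(-k_per_h * timepoints_h)
  noisy <- pmax(clean + stats::rnorm(length(clean), sd = noise_sd), 0)
  series <- clearance_series(timepoints_h, noisy, animal_id = animal_id,
                             limb = limb)
  inside <- timepoints_h >= 1 & timepoints_h <= 5
  tt <- timepoints_h[inside]; vv <- clean[inside]
  true_auc <- sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2)
  list(series = series, truth = list(true_auc = true_auc))
}

#' Generate a synthetic four-group paw-thickness cohort
#'
#' Emulates the paw caliper design of a hind-limb lymphedema induction study:
#' four experimental groups (by default n = 8, 7, 11, 13 animals) measured on
#' a set of days, each animal contributing the operated-paw thickness `T_mm`
#' and the contralateral control thickness `Tc_mm`.  Control thickness is
#' drawn around `baseline_mm`; the operated paw is `fold * Tc + noise`, where
#' the fold is looked up per group and day in `fold_by_group_day`.
#'
#' @param group_sizes integer vector of four group sizes
#'   (default `c(8, 7, 11, 13)`).
#' @param fold_by_group_day data frame with columns `group` (1-4), `day`
#'   (integer) and `fold` (> 0): the true swelling factor per group and day.
#' @param baseline_mm contralateral paw thickness baseline in millimeters
#'   (default 2); the study design leaves it free.
#' @param baseline_sd_mm animal-to-animal spread of the control thickness.
#' @param noise_sd measurement noise on the operated paw, millimeters.
#' @param seed integer random seed.
#' @return A tibble with one row per animal x day: `animal_id`, `group`,
#'   `day`, `T_mm`, `Tc_mm`.
#' @export
generate_paw_cohort <- function(group_sizes = c(8L, 7L, 11L, 13L),
                                fold_by_group_day,
                                baseline_mm = 2,
                                baseline_sd_mm = 0.05,
                                noise_sd = 0,
                                seed = 1L) {
  if (length(group_sizes) != 4L || any(group_sizes < 1))
    stop("`group_sizes` must be four positive integers", call. = FALSE)
  fold_by_group_day <- tibble::as_tibble(fold_by_group_day)
  stopifnot(all(c("group", "day", "fold") %in% names(fold_by_group_day)))
  if (any(fold_by_group_day$fold <= 0))
    stop("all folds must be > 0", call. = FALSE)
  set.seed(seed)
  animals <- tibble::tibble(
    group = rep(1:4, times = group_sizes),
    animal_id = sprintf("g%d-m%02d", group,
                        unlist(lapply(group_sizes, seq_len))),
    Tc_base = pmax(stats::rnorm(sum(group_sizes), baseline_mm,
                                baseline_sd_mm), 0.1))
  out <- dplyr::inner_join(animals, fold_by_group_day, by = "group",
                           relationship = "many-to-many")
  out$Tc_mm <- out$Tc_base
  out$T_mm <- pmax(out$fold * out$Tc_mm +
                     stats::rnorm(nrow(out), 0, noise_sd), 0.01)
  dplyr::select(out, "animal_id", "group", "day", "T_mm", "Tc_mm")
}
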