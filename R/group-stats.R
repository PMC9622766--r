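#' Binwise Mann-Whitney comparison of depth-distribution curves
#'
#' Compares two groups of depth profiles point by point: in every depth bin,
#' the per-section stained areas of group A are tested against those of
#' group B with a two-sided Mann-Whitney (Wilcoxon rank-sum) test.  The
#' exact null distribution is used when the combined sample size is at most
#' 20 and the bin has no ties; the normal approximation with tie correction
#' otherwise.  A bin in which every observation is identical across both
#' groups is maximally uninformative and gets p = 1.  Because dozens of bins
#' are tested, an optional Benjamini-Hochberg adjusted column is provided;
#' the raw column remains the primary, unadjusted readout.
#'
#' @param group_a,group_b lists of [depth_profile()] objects (>= 3 each) on a
#'   common bin width.
#' @param adjust `"none"` (default) or `"BH"` for an extra adjusted column.
#' @return A tibble of class `curve_comparison`: `bin_lo_um`, `bin_hi_um`,
#'   `statistic` (Mann-Whitney U of group A), `p`, and `p_adj` when
#'   requested.
#' @export
compare_profiles_pointwise <- function(group_a, group_b,
                                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("need at least 3 profiles per group", call. = FALSE)
  profiles <- c(group_a, group_b)
  bw <- unique(vapply(profiles, function(p) p$bin_width_um, 0))
  if (length(bw) != 1L)
    stop("profiles use different bin widths", call. = FALSE)
  n_max <- max(vapply(profiles, function(p) nrow(p$bins), 0L))
  grab <- function(p) c(p$bins$area_um2, rep(0, n_max - nrow(p$bins)))
  a <- vapply(group_a, grab, numeric(n_max))
  b <- vapply(group_b, grab, numeric(n_max))
  a <- matrix(a, nrow = n_max); b <- matrix(b, nrow = n_max)
  res <- lapply(seq_len(n_max), function(i) {
    va <- a[i, ]; vb <- b[i, ]
    if (length(unique(c(va, vb))) == 1L)
      return(c(statistic = length(va) * length(vb) / 2, p = 1))
    ties <- anyDuplicated(c(va, vb)) > 0
    wt <- suppressWarnings(stats::wilcox.test(
      va, vb, exact = (length(va) + length(vb) <= 20L) && !ties,
      correct = TRUE))
    c(statistic = unname(wt$statistic), p = wt$p.value)
  })
  edges <- seq(0, n_max * bw, by = bw)
  out <- tibble::tibble(bin_lo_um = edges[-length(edges)],
                        bin_hi_um = edges[-1],
                        statistic = vapply(res, `[[`, 0, "statistic"),
                        p = vapply(res, `[[`, 0, "p"))
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  attr(out, "method") <- "Mann-Whitney (two-sided), per depth bin"
  class(out) <- c("curve_comparison", class(out))
  out
}

#' Kruskal-Wallis test with Dunn's pairwise post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H test (tie-corrected, via
#' [stats::kruskal.test()]) followed by Dunn's rank-based z tests for all
#' group pairs, computed from the pooled mean ranks with the tie correction
#' term and adjusted for multiplicity (Bonferroni by default).
#'
#' @param groups a list of numeric vectors, or a data frame with columns
#'   `value` and `group`.
#' @param adjust multiplicity adjustment for Dunn's p-values, any method of
#'   [stats::p.adjust()] (default `"bonferroni"`).
#' @return A list of class `kruskal_dunn_result`: `h_statistic`, `df`,
#'   `p_value` for the omnibus test; `pairwise`, a tibble (`group_i`,
#'   `group_j`, `z`, `p_raw`, `p_adj`); and `p_matrix`, the symmetric matrix
#'   of adjusted p-values.
#' @export
kruskal_dunn <- function(groups, adjust = "bonferroni") {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes == 0L))
    stop("group(s) of size 0: ",
         paste(names(groups)[sizes == 0] %||% which(sizes == 0),
               collapse = ", "), call. = FALSE)
  labels <- names(groups) %||% as.character(seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, sizes), levels = labels)
  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  n_tot <- length(x)
  mean_rank <- tapply(r, g, mean)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n_tot - 1))
  var_base <- n_tot * (n_tot + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(groups), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / sizes[i] + 1 / sizes[j]))
    z <- (mean_rank[i] - mean_rank[j]) / se
    tibble::tibble(group_i = labels[i], group_j = labels[j],
                   z = unname(z),
                   p_raw = 2 * stats::pnorm(-abs(unname(z))))
  })
  pw$p_adj <- pmin(stats::p.adjust(pw$p_raw, adjust), 1)
  pmat <- matrix(NA_real_, length(groups), length(groups),
                 dimnames = list(labels, labels))
  diag(pmat) <- 1
  for (k in seq_len(nrow(pw))) {
    pmat[pw$group_i[k], pw$group_j[k]] <- pw$p_adj[k]
    pmat[pw$group_j[k], pw$group_i[k]] <- pw$p_adj[k]
  }
  structure(list(h_statistic = unname(kw$statistic),
                 df = unname(kw$parameter),
                 p_value = kw$p.value,
                 pairwise = pw, p_matrix = pmat, adjust = adjust),
            class = "kruskal_dunn_result")
}

#' @export
print.kruskal_dunn_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g (df = %d), p = %.4g; Dunn's (%s):\n",
              x$h_statistic, x$df, x$p_value, x$adjust))
  print(x$pairwise)
  invisible(x)
}

#' Two-way ANOVA with Tukey's pairwise comparisons
#'
#' Standard two-factor analysis of variance (limb x experimental group, with
#' interaction) followed by Tukey honest significant difference pairwise
#' comparisons, as applied to pipeline readouts such as integrated stained
#' areas.  Delegates to [stats::aov()] and [stats::TukeyHSD()].  A design
#' with an empty cell is rejected by name; a fit with zero residual variance
#' is flagged degenerate (F undefined) instead of reporting infinite
#' statistics.
#'
#' @param data data frame holding the readout and the two factors.
#' @param value,limb,group column names (strings) of the readout, the limb
#'   factor (`LD`/`control`) and the group factor.
#' @return A list of class `anova_tukey_result`: `anova` (tibble: term, df,
#'   sum_sq, mean_sq, f, p), `tukey` (tibble of pairwise contrasts) and
#'   `degenerate`.
#' @export
two_way_anova_tukey <- function(data, value = "value", limb = "limb",
                                group = "group") {
  stopifnot(all(c(value, limb, group) %in% names(data)))
  df <- data.frame(y = data[[value]],
                   limb = factor(data[[limb]]),
                   group = factor(data[[group]]))
  cells <- table(df$limb, df$group)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: limb = ", rownames(cells)[empty[1]],
         ", group = ", colnames(cells)[empty[2]], call. = FALSE)
  }
  fit <- stats::aov(y ~ limb * group, data = df)
  tab <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    term = trimws(rownames(tab)),
    df = tab$Df, sum_sq = tab$`Sum Sq`, mean_sq = tab$`Mean Sq`,
    f = tab$`F value`, p = tab$`Pr(>F)`)
  resid_ms <- anova_tbl$mean_sq[anova_tbl$term == "Residuals"]
  degenerate <- length(resid_ms) == 1L && resid_ms <= 1e-12
  tukey_tbl <- NULL
  if (!degenerate) {
    tk <- stats::TukeyHSD(fit)
    tukey_tbl <- purrr::map_dfr(names(tk), function(term) {
      m <- tk[[term]]
      tibble::tibble(term = term, contrast = rownames(m),
                     diff = m[, "diff"], lwr = m[, "lwr"],
                     upr = m[, "upr"], p_adj = m[, "p adj"])
    })
  }
  structure(list(anova = anova_tbl, tukey = tukey_tbl,
                 degenerate = degenerate),
            class = "anova_tukey_result")
}

#' Spearman rank correlation
#'
#' Spearman's rho with tie handling, reported together with rho^2 (staining
#' co-localization studies often print the squared coefficient) and the
#' two-sided p-value.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return A one-row tibble: `rho`, `rho_sq`, `p`, `n`, `defined` (`FALSE`
#'   when an input is constant, in which case the estimates are `NA`).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(tibble::tibble(rho = NA_real_, rho_sq = NA_real_, p = NA_real_,
                          n = length(x), defined = FALSE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  tibble::tibble(rho = rho, rho_sq = rho^2, p = ct$p.value,
                 n = length(x), defined = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
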