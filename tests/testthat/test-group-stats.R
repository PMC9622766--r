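test_that("binwise Mann-Whitney returns p = 1 on identical groups", {
  set.seed(1)
  g <- profiles_from_values(replicate(4, runif(6, 0, 50), simplify = FALSE))
  cmp <- compare_profiles_pointwise(g, g)
  expect_true(all(cmp$p == 1))
})

test_that("binwise Mann-Whitney matches the exact rank-enumeration oracle", {
  a <- profiles_from_values(list(1, 2, 3))
  b <- profiles_from_values(list(10, 20, 30))
  cmp <- compare_profiles_pointwise(a, b)
  # oracle: of the choose(6,3) = 20 equally likely rank assignments, the
  # observed complete separation has two-sided probability 2/20
  expect_equal(cmp$p[1], 0.1)
  expect_equal(cmp$statistic[1], 0)
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(9)
  va <- replicate(5, rexp(4, 1 / 40), simplify = FALSE)
  vb <- replicate(5, rexp(4, 1 / 90), simplify = FALSE)
  raw <- compare_profiles_pointwise(profiles_from_values(va),
                                    profiles_from_values(vb))
  trans <- compare_profiles_pointwise(
    profiles_from_values(lapply(va, function(x) log1p(x)^3)),
    profiles_from_values(lapply(vb, function(x) log1p(x)^3)))
  expect_equal(raw$p, trans$p)

  x <- c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 0.3, 4)
  expect_equal(spearman_cor(x, y)$rho,
               spearman_cor(exp(x), y^3)$rho)
})

test_that("Benjamini-Hochberg column is monotone above the raw p-values", {
  set.seed(21)
  a <- profiles_from_values(replicate(5, runif(8), simplify = FALSE))
  b <- profiles_from_values(replicate(5, runif(8, 0.3, 1.3),
                                      simplify = FALSE))
  cmp <- compare_profiles_pointwise(a, b, adjust = "BH")
  expect_true(all(cmp$p_adj >= cmp$p - 1e-12))
})

test_that("Kruskal-Wallis/Dunn flags the most separated pair", {
  res <- kruskal_dunn(list(g1 = c(1, 2), g2 = c(3, 4), g3 = c(100, 101)))
  pw <- res$pairwise
  extreme <- pw$p_adj[pw$group_i == "g1" & pw$group_j == "g3"]
  expect_equal(min(pw$p_adj), extreme)
  # hand rank arithmetic: mean ranks 1.5, 3.5, 5.5 of 6 pooled values
  expect_equal(unname(res$h_statistic),
               12 / (6 * 7) * 2 * ((1.5 - 3.5)^2 + (3.5 - 3.5)^2 +
                                     (5.5 - 3.5)^2))

  ident <- kruskal_dunn(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_lt(ident$h_statistic, 1e-10)
  expect_gt(ident$p_value, 0.99)

  expect_error(kruskal_dunn(list(a = 1:3, b = numeric(0))), "size 0")
  expect_true(isSymmetric(res$p_matrix))
})

test_that("two-way ANOVA matches a hand sum-of-squares decomposition", {
  set.seed(5)
  design <- expand.grid(limb = c("LD", "control"), group = 1:4,
                        rep = 1:3)
  mu <- 10 + ifelse(design$limb == "LD", 4, 0) + design$group * 1.5
  design$value <- mu + rnorm(nrow(design), 0, 1)
  res <- two_way_anova_tukey(design)

  y <- design$value
  gm <- mean(y)
  ss <- function(f) {
    means <- tapply(y, f, mean)
    sum(tapply(y, f, length) * (means - gm)^2)
  }
  ss_limb <- ss(design$limb)
  ss_group <- ss(design$group)
  cellf <- interaction(design$limb, design$group)
  ss_cells <- ss(cellf)
  ss_int <- ss_cells - ss_limb - ss_group
  ss_res <- sum((y - ave(y, cellf))^2)
  tab <- res$anova
  expect_equal(tab$sum_sq[tab$term == "limb"], ss_limb)
  expect_equal(tab$sum_sq[tab$term == "group"], ss_group)
  expect_equal(tab$sum_sq[tab$term == "limb:group"], ss_int)
  expect_equal(tab$sum_sq[tab$term == "Residuals"], ss_res)
  expect_false(res$degenerate)
  expect_true(all(c("limb", "group") %in% res$tukey$term))

  # all equal -> zero F is reported as a degenerate fit, not infinity
  flat <- design; flat$value <- 5
  expect_true(two_way_anova_tukey(flat)$degenerate)

  # empty cell named in the error
  holed <- design[!(design$limb == "LD" & design$group == 2), ]
  expect_error(two_way_anova_tukey(holed), "limb = LD, group = 2")
})

test_that("Spearman correlation handles the worked example and edge cases", {
  expect_equal(spearman_cor(1:6, (1:6)^3 + 2)$rho, 1)
  expect_equal(spearman_cor(1:6, rev(1:6))$rho, -1)

  res <- spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6)          # 1 - 6*4 / (4*15)
  expect_equal(res$rho_sq, 0.36)

  expect_warning(out <- spearman_cor(rep(2, 5), 1:5), "constant")
  expect_false(out$defined)

  set.seed(2)
  x <- rnorm(10)
  expect_equal(spearman_cor(x, x)$rho, 1)
})
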