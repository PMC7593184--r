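test_that("compositional fitness has exactly two principal axes", {
  W <- zero_sum_fitness(n = 23, seed = 3)
  pca <- fitness_pca(W)
  expect_lt(abs(pca$eigenvalues[3]), 1e-9)
  expect_equal(sum(pca$variance_explained), 1, tolerance = 1e-9)
  expect_equal(unname(colMeans(pca$scores)), c(0, 0), tolerance = 1e-12)
  # sign convention: largest-magnitude loading positive
  for (k in 1:2)
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, k])), k], 0)
})

test_that("PCA matches an independent eigen-solver on a toy matrix", {
  set.seed(9)
  W <- matrix(rnorm(12), 4, 3)
  pca <- fitness_pca(W)
  # oracle: prcomp on the standardized matrix
  pr <- prcomp(W, scale. = TRUE)
  expect_equal(pca$eigenvalues, pr$sdev^2, tolerance = 1e-10)
  for (k in 1:2) {
    a <- pca$loadings[, k]; b <- pr$rotation[, k]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-10)
    s <- sign(sum(a * b))
    expect_equal(unname(pca$scores[, k]), unname(s * pr$x[, k]),
                 tolerance = 1e-8)
  }
  expect_error(fitness_pca(matrix(1, 5, 3)), "zero-variance")
  expect_error(fitness_pca(W[1:2, ]), ">= 3 lines")
})

test_that("F statistics are invariant to haplotype column order", {
  W <- zero_sum_fitness(n = 23, seed = 6)
  d <- experiment_design()
  f1 <- rm_anova(fitness_pca(W), d)
  # relabeling columns flips PC signs at most; the response magnitudes and
  # F statistics are unchanged
  f2 <- rm_anova(fitness_pca(W[, c(3, 1, 2)]), d)
  expect_equal(abs(f1$F), abs(f2$F), tolerance = 1e-9)
})

test_that("between-subjects ANOVA reproduces a hand partition", {
  # balanced 2 x 3 design, 4 lines per cell; planted additive cell means
  # plus residuals: the sums of squares decompose exactly
  d <- balanced_design(per_cell = 4)
  a_th <- c(`23C` = -1, `35C` = 1)
  b_nu <- c(Brazil = -2, California = 0.5, Yemen = 1.5)
  ab <- outer(a_th, b_nu) * 0.3
  set.seed(13)
  res <- rnorm(nrow(d))
  # remove residual projections onto the effect space so the partition is
  # hand-computable: make residuals orthogonal to all cell indicators
  cellf <- interaction(d$thermal_regime, d$nuclear_background)
  res <- res - ave(res, cellf)
  y <- a_th[d$thermal_regime] + b_nu[d$nuclear_background] +
    ab[cbind(d$thermal_regime, d$nuclear_background)] + res
  out <- rm_anova(matrix(rep(y, 2), ncol = 2), d)

  # residuals are cell-centered, so observed cell means equal the planted
  # ones and the balanced decomposition is exact
  n_cell <- 4; n <- nrow(d)
  cell_mean <- outer(a_th, b_nu, `+`) + ab
  g <- mean(cell_mean)
  ss_th <- n_cell * 3 * sum((rowMeans(cell_mean) - g)^2)
  ss_nu <- n_cell * 2 * sum((colMeans(cell_mean) - g)^2)
  ss_ab <- n_cell * sum((cell_mean - outer(rowMeans(cell_mean), rep(1, 3)) -
                           outer(rep(1, 2), colMeans(cell_mean)) + g)^2)
  ss_err <- sum(res^2)
  df <- c(1, 2, 2, n - 6)
  ms <- c(ss_th / 1, ss_nu / 2, ss_ab / 2, ss_err / (n - 6))
  expect_equal(out$df, df)
  expect_equal(out$SS, c(ss_th, ss_nu, ss_ab, ss_err), tolerance = 1e-9)
  expect_equal(out$F[1:3], ms[1:3] / ms[4], tolerance = 1e-9)
})

test_that("Type III agrees with sequential SS on a balanced design", {
  d <- balanced_design(per_cell = 2)
  set.seed(14)
  y <- rnorm(nrow(d))
  t3 <- mitosel:::anova_typeIII(y, d)
  seqa <- anova(lm(y ~ thermal * nuclear, data = mitosel:::anova_factors(d)))
  expect_equal(t3$SS, unname(seqa$`Sum Sq`), tolerance = 1e-9)
})

test_that("fast F engine matches car::Anova on the unbalanced design", {
  d <- experiment_design()  # 23 lines, unbalanced
  eng <- mitosel:::f_engine(d)
  set.seed(15)
  for (i in 1:10) {
    y <- rnorm(nrow(d))
    expect_equal(eng$f(y), mitosel:::anova_typeIII(y, d)$F[1:3],
                 tolerance = 1e-9)
  }
  expect_equal(eng$df_err, nrow(d) - 6)
})

test_that("permutation p matches brute-force enumeration on 4 lines", {
  d4 <- data.frame(thermal_regime = c("23C", "23C", "35C", "35C"),
                   nuclear_background = "Brazil")
  y <- c(1.2, 0.8, 3.1, 2.9)
  pt <- permutation_test(y, d4, n_perm = 9999)
  expect_true(pt$exact)
  expect_equal(pt$n_perm_used, 6)
  # independent brute force over the 6 assignments of responses to groups
  combs <- combn(4, 2)
  f_of <- function(g1) {
    grp <- rep(2, 4); grp[g1] <- 1
    summary(aov(y ~ factor(grp)))[[1]][["F value"]][1]
  }
  f_all <- apply(combs, 2, f_of)
  f_obs <- f_of(c(1, 2))
  expect_equal(pt$p_rand, mean(f_all >= f_obs - 1e-8), tolerance = 1e-12)

  # constant response: all permuted F equal, p = 1
  expect_equal(permutation_test(rep(5, 4), d4, n_perm = 999)$p_rand, 1)
  expect_error(permutation_test(y, d4, n_perm = 50), ">= 99")
})

test_that("permutation p tracks the parametric p under normal residuals", {
  d <- experiment_design()
  diffs <- vapply(1:60, function(s) {
    set.seed(300 + s)
    y <- rnorm(nrow(d))
    par_p <- mitosel:::anova_typeIII(y, d)$p[1]
    perm_p <- permutation_test(y, d, n_perm = 399, seed = s)$p_rand[1]
    perm_p - par_p
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("per-haplotype ANOVA detects a planted interaction", {
  d <- balanced_design(per_cell = 4)
  set.seed(16)
  ab <- outer(c(`23C` = -1, `35C` = 1),
              c(Brazil = -1, California = 0, Yemen = 1)) * 0.02
  reps <- 200
  hits <- matrix(NA, reps, 3,
                 dimnames = list(NULL, c("thermal", "nuclear", "inter")))
  for (r in 1:reps) {
    w_bra <- 1 + ab[cbind(d$thermal_regime, d$nuclear_background)] +
      rnorm(nrow(d), 0, 0.01)
    W <- cbind(BRA = w_bra, CAL = 1 + rnorm(nrow(d), 0, 0.01),
               YEM = 1 + rnorm(nrow(d), 0, 0.01))
    tabs <- per_haplotype_anova(W, d)
    hits[r, ] <- tabs$BRA$p[1:3] < 0.05
  }
  # interaction-only signal: interaction detected, mains near nominal rate
  expect_gt(mean(hits[, "inter"]), 0.8)
  expect_lt(mean(hits[, "thermal"]), 0.12)
  expect_lt(mean(hits[, "nuclear"]), 0.12)
  expect_error(per_haplotype_anova(matrix(1, nrow(d), 3), d),
               "zero-variance")
})

test_that("empty design cells are reported", {
  d <- experiment_design()
  d <- d[!(d$thermal_regime == "35C" & d$nuclear_background == "Yemen"), ]
  W <- zero_sum_fitness(n = nrow(d), seed = 2)
  expect_error(rm_anova(fitness_pca(W), d), "empty design cell")
})
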