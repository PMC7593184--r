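make_phenotypes <- function() {
  data.frame(
    line_id = rep(c("mix1", "mix2", "calpure"), each = 8),
    line_type = rep(c("mix", "mix", "pure"), each = 8),
    nuclear_background = "California",
    sex = rep(rep(c("female", "male"), each = 4), 3),
    generation = rep(c(3, 3, 33, 33), 6),
    adjusted_eggs = c(30, 30, 30, 30, 30, 30, 30, 30,   # mix1 == reference
                      30, 30, 36, 36, 30, 30, 36, 36,   # mix2 gains 20%
                      30, 30, 30, 30, 30, 30, 30, 30),  # reference
    stringsAsFactors = FALSE)
}

test_that("delta W is relative LRS change against the pure reference", {
  dw <- compute_delta_w(make_phenotypes())
  m1 <- dw[dw$line_id == "mix1", ]
  expect_equal(m1$w_early, c(1, 1))
  expect_equal(m1$w_late, c(1, 1))
  expect_equal(m1$delta_w, c(0, 0))
  # means 30 -> 36 against a flat reference of 30: delta_w = 0.2
  m2 <- dw[dw$line_id == "mix2", ]
  expect_equal(m2$delta_w, c(0.2, 0.2), tolerance = 1e-12)
})

test_that("delta W is invariant to rescaling all egg counts", {
  ph <- make_phenotypes()
  ph2 <- ph; ph2$adjusted_eggs <- ph2$adjusted_eggs * 7
  expect_equal(compute_delta_w(ph), compute_delta_w(ph2))
})

test_that("delta W reports missing cells and degenerate references", {
  ph <- make_phenotypes()
  drop <- ph$line_id == "mix2" & ph$sex == "male" & ph$generation == 33
  expect_warning(dw <- compute_delta_w(ph[!drop, ]), "missing assays")
  expect_false(any(dw$line_id == "mix2" & dw$sex == "male"))
  ph0 <- ph; ph0$adjusted_eggs[ph0$line_id == "calpure"] <- 0
  expect_error(compute_delta_w(ph0), "reference mean egg count is zero")
  expect_error(compute_delta_w(ph, reference_nuclear = "Brazil"),
               "no pure reference")
})

test_that("planted reproductive effects order delta W by CAL gain", {
  # lines whose CAL frequency rises more gain more relative fitness
  gains <- c(0.05, 0.15, 0.30)
  design <- data.frame(
    line_id = c(paste0("mix", 1:3), "calpure"),
    line_type = c(rep("mix", 3), "pure"),
    nuclear_background = "California",
    haplotype = c(NA, NA, NA, "CAL"), stringsAsFactors = FALSE)
  comps <- lapply(gains, function(g)
    list(gen3 = rep(1/3, 3), gen33 = c(1/3 - g / 2, 1/3 + g, 1/3 - g / 2)))
  names(comps) <- paste0("mix", 1:3)
  ph <- simulate_lrs(design, c(BRA = 0, CAL = 0.5, YEM = 0), comps,
                     n_assays = 200, line_sd = 0, sd_log = 0.1, seed = 5)
  dw <- compute_delta_w(ph)
  for (sex in c("female", "male")) {
    dws <- dw$delta_w[dw$sex == sex][match(paste0("mix", 1:3),
                                           dw$line_id[dw$sex == sex])]
    expect_equal(order(dws), 1:3)
  }
})

test_that("rank-1 construction yields a perfect first PLS dimension", {
  dat <- rank1_pls_data(n = 12, seed = 7)
  fit <- pls_first_dimension(dat$X, dat$Y)
  expect_equal(fit$covariance_explained, 1, tolerance = 1e-8)
  # SVD oracle on the standardized cross-covariance
  C <- crossprod(scale(dat$X), scale(dat$Y)) / (nrow(dat$X) - 1)
  sv <- svd(C)
  expect_equal(abs(sum(fit$x_loadings * sv$u[, 1])), 1, tolerance = 1e-8)
  expect_equal(abs(sum(fit$y_loadings * sv$v[, 1])), 1, tolerance = 1e-8)
  # sign alignment: latent scores covary positively
  tx <- scale(dat$X) %*% fit$x_loadings
  ty <- scale(dat$Y) %*% fit$y_loadings
  expect_gt(cov(tx, ty)[1, 1], 0)
})

test_that("first dimension matches the mixOmics implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(18)
  X <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, HAPLOTYPES))
  Y <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(NULL, c("m", "f")))
  fit <- pls_first_dimension(X, Y)
  mo <- mixOmics::pls(X, Y, ncomp = 1, mode = "canonical")
  expect_equal(abs(sum(fit$x_loadings * mo$loadings$X[, 1])), 1,
               tolerance = 1e-8)
  expect_equal(abs(sum(fit$y_loadings * mo$loadings$Y[, 1])), 1,
               tolerance = 1e-8)
})

test_that("loadings are invariant to row order and column rescaling", {
  dat <- rank1_pls_data(n = 14, seed = 8)
  fit <- pls_first_dimension(dat$X, dat$Y)
  perm <- sample(nrow(dat$X))
  fit_p <- pls_first_dimension(dat$X[perm, ], dat$Y[perm, ])
  expect_equal(fit_p$x_loadings, fit$x_loadings, tolerance = 1e-9)
  Xs <- dat$X %*% diag(c(10, 0.1, 3))
  colnames(Xs) <- colnames(dat$X)
  fit_s <- pls_first_dimension(Xs, dat$Y)
  expect_equal(fit_s$x_loadings, fit$x_loadings, tolerance = 1e-9)
  expect_equal(fit_s$covariance_explained, fit$covariance_explained,
               tolerance = 1e-9)
})

test_that("axis-reversal correction restores a flipped replicate", {
  dat <- rank1_pls_data(n = 12, seed = 9)
  fit <- pls_first_dimension(dat$X, dat$Y)
  point <- c(fit$x_loadings, fit$y_loadings)
  flipped <- -point
  corrected <- if (sum(flipped * point) < 0) -flipped else flipped
  expect_gt(cor(corrected, point), 0)
  expect_equal(corrected, point)
})

test_that("bootstrap finds the driving loadings of a strong link", {
  dat <- rank1_pls_data(n = 12, seed = 10)
  # add mild noise so replicates vary
  set.seed(10)
  Y <- dat$Y + matrix(rnorm(length(dat$Y), 0, 0.3), nrow(dat$Y))
  bp <- bootstrap_pls(dat$X, Y, n_boot = 1000, seed = 1)
  driving <- bp$loadings[bp$loadings$variable == "df_BRA", ]
  expect_true(driving$ci_lower > 0 | driving$ci_upper < 0)
  expect_lt(driving$p, 0.05)
  expect_equal(bp$n_dropped, 0)
  # CI brackets the point estimate
  expect_true(all(bp$loadings$ci_lower <= bp$loadings$loading + 1e-9 &
                    bp$loadings$loading <= bp$loadings$ci_upper + 1e-9))
})

test_that("shared sex effects equalize the sex loadings", {
  set.seed(20)
  n <- 24
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, HAPLOTYPES))
  latent <- X %*% c(1, -1, 0)
  Y <- cbind(male = as.numeric(latent) + rnorm(n, 0, 0.4),
             female = as.numeric(latent) + rnorm(n, 0, 0.4))
  bp <- bootstrap_pls(X, Y, n_boot = 1000, seed = 2)
  ym <- bp$loadings[bp$loadings$variable == "male", ]
  yf <- bp$loadings[bp$loadings$variable == "female", ]
  expect_lt(abs(ym$loading - yf$loading),
            2 * sqrt(ym$se^2 + yf$se^2))
})

test_that("degenerate blocks are refused or flagged", {
  X <- matrix(rnorm(20 * 3), 20, 3)
  Xc <- X; Xc[, 2] <- 5
  colnames(Xc) <- HAPLOTYPES
  Y <- matrix(rnorm(20 * 2), 20, 2)
  expect_error(pls_first_dimension(Xc, Y), "zero-variance")
  expect_error(pls_first_dimension(X[1:3, ], Y[1:3, ]), ">= 4 lines")
})
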