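#' Sex-specific change in relative reproductive fitness
#'
#' For each mtDNA-mix line and sex, relative fitness at an assay generation
#' is the line's mean adjusted egg count divided by the reference (CAL
#' pure) line's mean adjusted egg count for the same sex and generation:
#' \deqn{W_g(line, sex) = \bar{e}(line, sex, g) / \bar{e}(ref, sex, g)}
#' and the change over the experiment is \eqn{\Delta W = W_{33} - W_3}.
#' Female counts must already be halved (`adjusted_eggs`) to be comparable
#' with male assays. When several replicate CAL pure lines exist, their
#' assays are averaged together as the reference.
#'
#' @param phenotypes assay-level data.frame with columns `line_id`,
#'   `line_type`, `nuclear_background`, `sex`, `generation`,
#'   `adjusted_eggs` (see [simulate_lrs()]).
#' @param reference_nuclear nuclear background whose pure line anchors
#'   relative fitness (default `"California"`, i.e. the CAL pure line).
#' @param generations the two assay generations (default `c(3, 33)`).
#' @return data.frame with one row per (mix line, sex): `line_id`, `sex`,
#'   `w_early`, `w_late`, `delta_w`.
#' @export
compute_delta_w <- function(phenotypes, reference_nuclear = "California",
                            generations = c(3, 33)) {
  need <- c("line_id", "line_type", "sex", "generation", "adjusted_eggs")
  if (!all(need %in% names(phenotypes)))
    stop("phenotypes needs columns: ", paste(need, collapse = ", "))
  stopifnot(length(generations) == 2)
  ref <- phenotypes[phenotypes$line_type == "pure" &
                      phenotypes$nuclear_background == reference_nuclear, ]
  if (nrow(ref) == 0)
    stop("no pure reference line with nuclear background ",
         reference_nuclear)
  ref_mean <- function(sex, g) {
    x <- ref$adjusted_eggs[ref$sex == sex & ref$generation == g]
    if (length(x) == 0)
      stop("reference line has no assays for sex=", sex, ", generation=", g)
    m <- mean(x)
    if (m == 0) stop("reference mean egg count is zero (sex=", sex,
                     ", generation=", g, ")")
    m
  }
  mix <- phenotypes[phenotypes$line_type == "mix", ]
  rows <- list()
  for (ln in unique(mix$line_id)) for (sex in c("female", "male")) {
    w <- vapply(generations, function(g) {
      x <- mix$adjusted_eggs[mix$line_id == ln & mix$sex == sex &
                               mix$generation == g]
      if (length(x) == 0) return(NA_real_)
      mean(x) / ref_mean(sex, g)
    }, numeric(1))
    if (anyNA(w)) {
      warning("line ", ln, " (", sex,
              ") is missing assays in a generation; excluded")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      line_id = ln, sex = sex, w_early = w[1], w_late = w[2],
      delta_w = w[2] - w[1], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# internal: standardize columns; error on zero-variance columns
standardize_block <- function(M, name) {
  M <- as.matrix(M)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column in ", name, ": ",
         paste(colnames(M)[sds == 0], collapse = ", "))
  scale(M)
}

#' First partial-least-squares dimension linking frequency and fitness change
#'
#' Finds the first pair of latent directions maximizing the covariance
#' between the haplotype-frequency-change block X (per-generation
#' \eqn{\Delta f} of the three haplotypes) and the reproductive-fitness-
#' change block Y (\eqn{\Delta W} per sex). Both blocks are column-wise
#' mean-centered and unit-variance scaled; the loadings are the first left
#' and right singular vectors of the standardized cross-covariance matrix
#' \eqn{C = X^\top Y / (n - 1)}. The fraction of cross-block covariation
#' captured is the squared first singular value over the sum of all squared
#' singular values. Sign convention: the largest-magnitude loading over
#' both blocks is made positive (latent X and Y scores then covary
#' positively).
#'
#' @param X lines x p predictor block (columns: `delta_f` per haplotype).
#' @param Y lines x q response block (columns: `delta_w` per sex).
#' @return list of class `pls_fit` with `x_loadings`, `y_loadings`,
#'   `covariance_explained`, `singular_values`, `n`.
#' @export
pls_first_dimension <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of lines")
  if (nrow(X) < 4) stop("need >= 4 lines")
  Xs <- standardize_block(X, "X")
  Ys <- standardize_block(Y, "Y")
  C <- crossprod(Xs, Ys) / (nrow(Xs) - 1)
  sv <- svd(C)
  if (max(sv$d) < 1e-12) {
    warning("rank-0 cross-covariance: loadings undefined")
    return(structure(list(x_loadings = rep(NA_real_, ncol(X)),
                          y_loadings = rep(NA_real_, ncol(Y)),
                          covariance_explained = 0,
                          singular_values = sv$d, n = nrow(X)),
                     class = "pls_fit"))
  }
  u <- sv$u[, 1]; v <- sv$v[, 1]
  all_load <- c(u, v)
  if (all_load[which.max(abs(all_load))] < 0) { u <- -u; v <- -v }
  structure(list(
    x_loadings = stats::setNames(u, colnames(X)),
    y_loadings = stats::setNames(v, colnames(Y)),
    covariance_explained = sv$d[1]^2 / sum(sv$d^2),
    singular_values = sv$d, n = nrow(X)),
    class = "pls_fit")
}

#' Bootstrap inference for the first PLS dimension
#'
#' Resamples lines with replacement, re-estimates the first PLS dimension
#' in each replicate, and corrects axis reversals: a replicate whose
#' concatenated loading vector has negative dot product with the point
#' estimate is sign-flipped before summarizing (the latent axis is defined
#' only up to a joint sign, so uncorrected replicates would mix the two
#' orientations). Reports, per loading, the bootstrap standard error, a t
#' statistic (estimate / SE, df = n_lines - 1) with its two-sided p-value,
#' and a bias-corrected percentile confidence interval.
#'
#' @inheritParams pls_first_dimension
#' @param n_boot bootstrap replicates (default 10000; >= 1000 recommended).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return list of class `pls_boot` with `fit` (the point estimate),
#'   `loadings` (data.frame: block, variable, loading, se, t, p, ci_lower,
#'   ci_upper), `covariance_explained_ci`, `n_boot_used`, `n_dropped`.
#' @export
bootstrap_pls <- function(X, Y, n_boot = 10000, conf = 0.95, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  fit <- pls_first_dimension(X, Y)
  point <- c(fit$x_loadings, fit$y_loadings)
  if (anyNA(point)) stop("point estimate is degenerate; cannot bootstrap")
  n <- nrow(X)
  set.seed(derive_seed(seed, "bootstrap_pls"))
  boot <- matrix(NA_real_, n_boot, length(point))
  boot_cov <- rep(NA_real_, n_boot)
  dropped <- 0
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch(
      suppressWarnings(pls_first_dimension(X[idx, , drop = FALSE],
                                           Y[idx, , drop = FALSE])),
      error = function(e) NULL)
    if (is.null(rep_fit) || anyNA(rep_fit$x_loadings)) {
      dropped <- dropped + 1
      next
    }
    lo <- c(rep_fit$x_loadings, rep_fit$y_loadings)
    if (sum(lo * point) < 0) lo <- -lo  # axis-reversal correction
    boot[b, ] <- lo
    boot_cov[b] <- rep_fit$covariance_explained
  }
  if (dropped > 0.1 * n_boot)
    warning(dropped, " of ", n_boot, " bootstrap replicates were degenerate")
  a <- (1 - conf) / 2
  tab <- do.call(rbind, lapply(seq_along(point), function(j) {
    bj <- boot[, j][is.finite(boot[, j])]
    se <- stats::sd(bj)
    tt <- point[j] / se
    ci <- bc_ci(bj, point[j], conf)
    data.frame(
      block = if (j <= length(fit$x_loadings)) "X" else "Y",
      variable = names(point)[j], loading = point[j], se = se, t = tt,
      p = 2 * stats::pt(-abs(tt), df = n - 1),
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
      stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  cov_ci <- bc_ci(boot_cov[is.finite(boot_cov)], fit$covariance_explained,
                  conf)
  structure(list(fit = fit, loadings = tab,
                 covariance_explained = fit$covariance_explained,
                 covariance_explained_ci = cov_ci,
                 n_boot_used = n_boot - dropped, n_dropped = dropped),
            class = "pls_boot")
}

#' @export
print.pls_boot <- function(x, ...) {
  cat("First PLS dimension:",
      sprintf("%.1f%%", 100 * x$covariance_explained),
      "of cross-block covariation",
      sprintf("(95%% CI %.1f%%-%.1f%%)\n",
              100 * x$covariance_explained_ci[["lower"]],
              100 * x$covariance_explained_ci[["upper"]]))
  cat("Loadings (", x$n_boot_used, " bootstrap replicates):\n", sep = "")
  print(x$loadings, digits = 3, row.names = FALSE)
  invisible(x)
}
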