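#' Principal components of the compositional fitness matrix
#'
#' The three per-line relative fitnesses are compositional: they sum to a
#' constant per line, so the 3-column matrix has rank 2 and cannot be
#' analysed column-by-column in an omnibus test. This reduces it to two
#' orthogonal axes by a standard PCA on the correlation matrix. The third
#' eigenvalue is numerically zero and the first two components jointly
#' carry 100% of the variance. The sign of each component is fixed by
#' making its largest-magnitude loading positive.
#'
#' @param W lines x 3 relative-fitness matrix (>= 3 lines, no constant
#'   column).
#' @return list of class `fitness_pca` with `scores` (lines x 2, zero
#'   mean), `loadings` (3 x 2), `eigenvalues` (length 3, decreasing),
#'   `variance_explained` (length 2, fractions of total variance).
#' @export
fitness_pca <- function(W) {
  W <- as.matrix(W)
  stopifnot(ncol(W) == 3)
  colnames(W) <- HAPLOTYPES
  if (nrow(W) < 3) stop("need >= 3 lines")
  sds <- apply(W, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance fitness column: ",
         paste(HAPLOTYPES[sds == 0], collapse = ", "))
  eig <- eigen(stats::cor(W), symmetric = TRUE)
  vectors <- eig$vectors[, 1:2, drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (k in 1:2) {
    top <- which.max(abs(vectors[, k]))
    if (vectors[top, k] < 0) vectors[, k] <- -vectors[, k]
  }
  dimnames(vectors) <- list(HAPLOTYPES, c("PC1", "PC2"))
  scores <- scale(W) %*% vectors
  colnames(scores) <- c("PC1", "PC2")
  structure(list(scores = scores, loadings = vectors,
                 eigenvalues = eig$values,
                 variance_explained = eig$values[1:2] / sum(abs(eig$values))),
            class = "fitness_pca")
}

# internal: factor data.frame for the two-way thermal x nuclear layout
anova_factors <- function(design) {
  need <- c("thermal_regime", "nuclear_background")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  data.frame(thermal = factor(design$thermal_regime),
             nuclear = factor(design$nuclear_background))
}

# internal: Type III two-way ANOVA via car with sum-to-zero contrasts
anova_typeIII <- function(y, design) {
  dd <- anova_factors(design)
  tab <- table(dd$thermal, dd$nuclear)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(tab)[empty[, 1]], colnames(tab)[empty[, 2]],
               sep = ":", collapse = ", "))
  }
  dd$y <- y
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  both <- nlevels(dd$thermal) > 1 && nlevels(dd$nuclear) > 1
  form <- if (both) y ~ thermal * nuclear
          else if (nlevels(dd$thermal) > 1) y ~ thermal else y ~ nuclear
  fit <- stats::lm(form, data = dd)
  a <- car::Anova(fit, type = 3)
  keep <- setdiff(rownames(a), "(Intercept)")
  out <- data.frame(source = keep, df = a[keep, "Df"],
                    SS = a[keep, "Sum Sq"],
                    MS = a[keep, "Sum Sq"] / a[keep, "Df"],
                    F = a[keep, "F value"], p = a[keep, "Pr(>F)"],
                    row.names = NULL)
  out$source <- c(thermal = "Thermal regime", nuclear = "Nuclear background",
                  `thermal:nuclear` = "Thermal x Nuclear",
                  Residuals = "Error")[out$source]
  out
}

# internal: fast Type III F engine. Precomputes QR projections of the full
# and each reduced model matrix so that the F statistics for a permuted
# response cost only a few matrix-vector products. Identical (to rounding)
# to car::Anova(type = 3) with sum-to-zero contrasts; cross-checked in the
# test suite.
f_engine <- function(design) {
  dd <- anova_factors(design)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  both <- nlevels(dd$thermal) > 1 && nlevels(dd$nuclear) > 1
  form <- if (both) ~ thermal * nuclear
          else if (nlevels(dd$thermal) > 1) ~ thermal else ~ nuclear
  X <- stats::model.matrix(form, dd)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(form), "term.labels")
  n <- nrow(X)
  Qf <- qr.Q(qr(X))
  df_err <- n - ncol(X)
  Qr <- lapply(seq_along(labels), function(k) {
    Xr <- X[, asgn != k, drop = FALSE]
    qr.Q(qr(Xr))
  })
  df_term <- vapply(seq_along(labels), function(k) sum(asgn == k), integer(1))
  pretty <- c(thermal = "Thermal regime", nuclear = "Nuclear background",
              `thermal:nuclear` = "Thermal x Nuclear")[labels]
  list(
    sources = unname(pretty), df_term = df_term, df_err = df_err,
    f = function(y) {
      rss_full <- sum(y^2) - sum(crossprod(Qf, y)^2)
      fs <- vapply(seq_along(labels), function(k) {
        rss_red <- sum(y^2) - sum(crossprod(Qr[[k]], y)^2)
        ((rss_red - rss_full) / df_term[k]) / (rss_full / df_err)
      }, numeric(1))
      fs[!is.finite(fs)] <- 0  # degenerate (constant) response
      fs
    })
}

#' Between-line repeated-measures ANOVA of compositional fitness
#'
#' The two PCA axes of relative fitness are the (non-focal) within-subject
#' responses of a repeated-measures layout with the evolving line as the
#' subject. The focal between-subjects tests — thermal regime, nuclear
#' background, and their interaction — are computed on the per-line mean of
#' the two responses, which is the standard between-subjects stratum of an
#' RM-ANOVA. Type III sums of squares with sum-to-zero coding are used
#' because the realized design is unbalanced (a lost line); the error has
#' `n_lines - 6` degrees of freedom on the 2 x 3 layout.
#'
#' @param pca a `fitness_pca` object (or any lines x 2 score matrix).
#' @param design design table aligned row-wise with the scores.
#' @return data.frame ANOVA table: `source`, `df`, `SS`, `MS`, `F`, `p`.
#' @export
rm_anova <- function(pca, design) {
  scores <- if (inherits(pca, "fitness_pca")) pca$scores else as.matrix(pca)
  if (nrow(scores) != nrow(design))
    stop("scores and design have different numbers of lines")
  y <- rowMeans(scores)
  anova_typeIII(y, design)
}

#' Permutation test of the between-line ANOVA
#'
#' Recomputes the Type III F statistics after randomly permuting the
#' line-to-treatment assignment (equivalently, permuting the response
#' vector across lines — whole lines are the unit of replication, and the
#' permutation is unrestricted across both factors). When the design admits
#' no more than `n_perm` distinct assignments of responses to cells, all of
#' them are enumerated and the p-value is exact
#' (`#\{F_perm >= F_obs\} / N`); otherwise `n_perm` random permutations are
#' drawn and `p_rand = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1)`.
#'
#' @param pca a `fitness_pca` object, score matrix, or response vector.
#' @param design design table aligned with the response.
#' @param n_perm number of random permutations (default 9999; >= 99).
#' @param seed integer seed.
#' @param strata optional factor: permute only within its levels (e.g.
#'   within thermal regime); default unrestricted.
#' @return data.frame with `source`, `F_obs`, `p_rand`, `n_perm_used`,
#'   `exact`.
#' @export
permutation_test <- function(pca, design, n_perm = 9999, seed = 1,
                             strata = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  y <- if (inherits(pca, "fitness_pca")) rowMeans(pca$scores)
       else if (is.matrix(pca)) rowMeans(pca) else as.numeric(pca)
  if (length(y) != nrow(design))
    stop("response and design have different numbers of lines")
  eng <- f_engine(design)
  f_obs <- eng$f(y)
  n <- length(y)
  dd <- anova_factors(design)
  cell <- interaction(dd$thermal, dd$nuclear, drop = TRUE)
  n_distinct <- exp(lgamma(n + 1) - sum(lgamma(table(cell) + 1)))
  tol <- 1e-8 * (1 + abs(f_obs))
  if (is.null(strata) && n_distinct <= n_perm) {
    perms <- cell_assignments(as.integer(cell), nlevels(cell))
    f_perm <- matrix(vapply(perms, function(ord) eng$f(y[ord]),
                            numeric(length(f_obs))),
                     nrow = length(f_obs))  # sources x permutations
    p_rand <- rowMeans(f_perm >= (f_obs - tol))
    exact <- TRUE
    n_used <- length(perms)
  } else {
    set.seed(derive_seed(seed, "permutation_test"))
    ge <- numeric(length(f_obs))
    for (b in seq_len(n_perm)) {
      ord <- if (is.null(strata)) sample.int(n)
             else stats::ave(seq_len(n), strata, FUN = sample)
      ge <- ge + (eng$f(y[ord]) >= f_obs - tol)
    }
    p_rand <- (1 + ge) / (n_perm + 1)
    exact <- FALSE
    n_used <- n_perm
  }
  data.frame(source = eng$sources, F_obs = f_obs, p_rand = p_rand,
             n_perm_used = n_used, exact = exact, row.names = NULL)
}

# internal: enumerate all distinct assignments of observation indices to
# design cells (order within a cell is irrelevant for the F statistic).
# Returns permutation vectors `ord` such that y[ord] realizes each
# assignment.
cell_assignments <- function(cell, n_levels) {
  n <- length(cell)
  sizes <- tabulate(cell, n_levels)
  res <- list()
  assign_rec <- function(remaining, level, acc) {
    if (level > n_levels) {
      ord <- integer(n)
      for (l in seq_len(n_levels)) ord[cell == l] <- acc[[l]]
      res[[length(res) + 1]] <<- ord
      return(invisible(NULL))
    }
    k <- sizes[level]
    combs <- utils::combn(remaining, k, simplify = FALSE)
    for (cc in combs) {
      acc[[level]] <- cc
      assign_rec(setdiff(remaining, cc), level + 1, acc)
    }
  }
  assign_rec(seq_len(n), 1, vector("list", n_levels))
  res
}

#' Per-haplotype two-way ANOVA of relative fitness
#'
#' Fits thermal regime, nuclear background, and their interaction as fixed
#' effects to each haplotype's relative fitness separately (Type III sums
#' of squares). The three models are not independent — the fitnesses are
#' compositional — so these serve as haplotype-wise follow-ups to
#' [rm_anova()], not as an omnibus test.
#'
#' @param W lines x 3 relative-fitness matrix.
#' @param design design table aligned with `W`.
#' @return named list of three ANOVA tables (one per haplotype).
#' @export
per_haplotype_anova <- function(W, design) {
  W <- as.matrix(W)
  stopifnot(ncol(W) == 3)
  colnames(W) <- HAPLOTYPES
  sds <- apply(W, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance fitness column: ",
         paste(HAPLOTYPES[sds == 0], collapse = ", "))
  stats::setNames(lapply(HAPLOTYPES, function(h)
    anova_typeIII(W[, h], design)), HAPLOTYPES)
}
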