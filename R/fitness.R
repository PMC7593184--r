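#' Per-haplotype relative fitness from end-point frequencies
#'
#' Solves the haploid selection recursion
#' \deqn{p_i(t+1) = p_i(t) W_i / \sum_j p_j(t) W_j}
#' for a constant per-generation fitness vector that carries `f_start` to
#' `f_end` in `t` generations. The solution is geometric:
#' \eqn{r_i = (f_{end,i}/f_{start,i})^{1/t}}, normalized so that the initial
#' mean fitness is one, \eqn{W_i = r_i / \sum_j f_{start,j} r_j}. With
#' `mode = "one_step"` the recursion is instead read as a single update
#' over the whole experiment (a sensitivity analysis that ignores `t`):
#' \eqn{r_i = f_{end,i}/f_{start,i}} with the same normalization.
#'
#' A haplotype lost from the population (`f_end = 0`) yields `W = 0` with a
#' warning — a real outcome of drift at small population size, not an error.
#'
#' @param f_end,f_start length-3 compositions; `f_start` strictly positive.
#' @param t generations elapsed (>= 1).
#' @param mode `"per_generation"` (default) or `"one_step"`.
#' @return named length-3 vector of relative fitnesses; satisfies
#'   `sum(f_start * W) == 1`.
#' @examples
#' relative_fitness(c(0.4712, 0.3171, 0.2117), rep(1/3, 3), t = 20)
#' @export
relative_fitness <- function(f_end, f_start = rep(1/3, 3), t,
                             mode = c("per_generation", "one_step")) {
  mode <- match.arg(mode)
  f_end <- check_composition(f_end, "f_end")
  f_start <- check_composition(f_start, "f_start")
  if (any(f_start <= 0)) stop("f_start components must be > 0")
  if (t < 1) stop("t must be >= 1")
  if (any(f_end == 0))
    warning("haplotype(s) lost (f_end = 0): ",
            paste(HAPLOTYPES[f_end == 0], collapse = ", "),
            "; W = 0 returned")
  ratio <- f_end / f_start
  r <- if (mode == "per_generation") ratio^(1 / t) else ratio
  r / sum(f_start * r)
}

#' Average per-generation haplotype frequency change
#'
#' \eqn{\Delta f_i = (f_{end,i} - f_{start,i}) / t}: the frequency change
#' from the starting composition averaged over the experiment. Components
#' sum to zero since both compositions sum to one.
#'
#' @inheritParams relative_fitness
#' @return named length-3 vector of per-generation frequency changes.
#' @export
delta_f <- function(f_end, f_start = rep(1/3, 3), t) {
  f_end <- check_composition(f_end, "f_end")
  f_start <- check_composition(f_start, "f_start")
  if (t < 1) stop("t must be >= 1")
  (f_end - f_start) / t
}

#' Relative fitness and frequency change for a set of lines
#'
#' Convenience wrapper applying [relative_fitness()] and [delta_f()] to a
#' matrix of per-line end-point frequencies, with per-line generation counts
#' taken from the design.
#'
#' @param freq lines x 3 matrix of end-point haplotype frequencies
#'   (rownames = line ids).
#' @param design design table from [experiment_design()]; matched to `freq`
#'   by line id.
#' @param f_start starting composition (default equal thirds).
#' @param mode passed to [relative_fitness()].
#' @return list with `W` and `delta_f` (both lines x 3 matrices, rows
#'   aligned with `design`).
#' @export
fitness_from_frequencies <- function(freq, design, f_start = rep(1/3, 3),
                                     mode = "per_generation") {
  if (!all(design$line_id %in% rownames(freq)))
    stop("frequency matrix is missing lines: ",
         paste(setdiff(design$line_id, rownames(freq)), collapse = ", "))
  W <- Df <- matrix(NA_real_, nrow(design), 3,
                    dimnames = list(design$line_id, HAPLOTYPES))
  for (i in seq_len(nrow(design))) {
    f_end <- freq[design$line_id[i], ] / sum(freq[design$line_id[i], ])
    t <- design$generations_elapsed[i]
    W[i, ] <- relative_fitness(f_end, f_start, t, mode = mode)
    Df[i, ] <- delta_f(f_end, f_start, t)
  }
  list(W = W, delta_f = Df)
}

# internal: bias-corrected (BC) percentile bootstrap CI
bc_ci <- function(boot, estimate, conf = 0.95) {
  boot <- boot[is.finite(boot)]
  if (length(boot) == 0 || stats::sd(boot) == 0)
    return(c(lower = estimate, upper = estimate))
  prop <- mean(boot < estimate) + 0.5 * mean(boot == estimate)
  prop <- min(max(prop, 1 / (length(boot) + 1)),
              length(boot) / (length(boot) + 1))
  z0 <- stats::qnorm(prop)
  a <- (1 - conf) / 2
  lo <- stats::pnorm(2 * z0 + stats::qnorm(a))
  hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - a))
  ci <- stats::quantile(boot, c(lo, hi), names = FALSE, type = 7)
  c(lower = ci[1], upper = ci[2])
}

#' Test for selection on haplotypes across replicate lines
#'
#' Treats the evolving line as the unit of replication. Per haplotype:
#' the mean relative fitness over lines with a bias-corrected percentile
#' bootstrap confidence interval (lines resampled with replacement) and a
#' one-sample t-test of mean W = 1 (no selection). Haplotypes are compared
#' pairwise with Tukey's HSD on the long-format fitness values.
#'
#' @param W lines x 3 relative-fitness matrix.
#' @param n_boot bootstrap resamples (default 9999).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list of class `selection_test` with `per_haplotype` (mean, CI,
#'   t, p per haplotype), `tukey` (pairwise comparisons), `n_lines`,
#'   `n_boot`.
#' @export
test_selection <- function(W, n_boot = 9999, conf = 0.95, seed = 1) {
  W <- as.matrix(W)
  stopifnot(ncol(W) == 3)
  colnames(W) <- HAPLOTYPES
  n <- nrow(W)
  if (n < 3) stop("need >= 3 lines")
  if (n_boot < 100) warning("n_boot < 100: bootstrap CIs will be unstable")
  set.seed(derive_seed(seed, "test_selection"))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  per_h <- do.call(rbind, lapply(HAPLOTYPES, function(h) {
    x <- W[, h]
    est <- mean(x)
    boot <- rowMeans(matrix(x[idx], n_boot, n))
    ci <- bc_ci(boot, est, conf)
    if (stats::sd(x) == 0) {
      tt <- list(statistic = c(t = if (est == 1) 0 else Inf),
                 p.value = if (est == 1) 1 else 0)
    } else {
      tt <- stats::t.test(x, mu = 1)
    }
    data.frame(haplotype = h, mean_W = est,
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               t = unname(tt$statistic), p = tt$p.value)
  }))
  long <- data.frame(W = as.vector(W),
                     haplotype = factor(rep(HAPLOTYPES, each = n),
                                        levels = HAPLOTYPES))
  if (stats::sd(long$W) == 0) {
    tukey <- data.frame(comparison = c("CAL-BRA", "YEM-BRA", "YEM-CAL"),
                        diff = 0, lwr = 0, upr = 0, p_adj = 1)
  } else {
    th <- stats::TukeyHSD(stats::aov(W ~ haplotype, data = long),
                          conf.level = conf)$haplotype
    tukey <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                        lwr = th[, "lwr"], upr = th[, "upr"],
                        p_adj = th[, "p adj"], row.names = NULL)
  }
  structure(list(per_haplotype = per_h, tukey = tukey, n_lines = n,
                 n_boot = n_boot, conf = conf),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat("Selection test across", x$n_lines, "replicate lines\n")
  cat("Per-haplotype mean relative fitness (BC bootstrap CI,",
      x$n_boot, "resamples):\n")
  print(x$per_haplotype, digits = 4, row.names = FALSE)
  cat("\nTukey HSD pairwise comparisons:\n")
  print(x$tukey, digits = 4, row.names = FALSE)
  invisible(x)
}
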