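#' Simulate a Wright-Fisher haplotype-frequency trajectory
#'
#' Forward-simulates the frequencies of the three competing mitochondrial
#' haplotypes under haploid selection and genetic drift. Each generation
#' applies the selection update
#' \deqn{p_i' = p_i W_i / \sum_j p_j W_j}
#' and then (unless `deterministic_mode`) resamples the composition as a
#' multinomial draw of `n_females` maternal lineages divided by `n_females`.
#' Because mtDNA is maternally inherited, drift acts on the female
#' transmitting pool only.
#'
#' In deterministic mode the trajectory follows the closed form
#' \eqn{f_i(t) = f_i(0) W_i^t / \sum_j f_j(0) W_j^t}.
#'
#' @param start length-3 haplotype composition (BRA, CAL, YEM), summing to 1.
#' @param w length-3 vector of positive per-generation relative fitnesses.
#' @param t number of generations (>= 0; `t = 0` returns the start only).
#' @param params a [sim_params()] object; `n_females` and
#'   `deterministic_mode` are used.
#' @return a `(t + 1) x 3` matrix of compositions, one row per generation
#'   including the start; rows sum to 1.
#' @examples
#' p <- sim_params(deterministic_mode = TRUE)
#' traj <- simulate_wf_trajectory(rep(1/3, 3), c(1.02, 1, 0.98), 20, p)
#' traj[21, ]  # ~ (0.471, 0.317, 0.212)
#' @export
simulate_wf_trajectory <- function(start, w, t, params = sim_params()) {
  start <- check_composition(start, "start")
  if (!is.numeric(w) || length(w) != 3 || any(w <= 0))
    stop("w must be 3 positive fitness values")
  if (t < 0) stop("t must be >= 0")
  out <- matrix(NA_real_, t + 1, 3, dimnames = list(NULL, HAPLOTYPES))
  out[1, ] <- start
  if (t == 0) return(out)
  p <- start
  for (g in seq_len(t)) {
    p <- p * w / sum(p * w)
    if (!params$deterministic_mode) {
      p <- as.numeric(stats::rmultinom(1, params$n_females, p)) /
        params$n_females
    }
    out[g + 1, ] <- p
  }
  out
}

#' Simulate pool-seq read counts for one sample
#'
#' Two-stage sampling consistent with the pool-seq protocol: (1) a pool of
#' `pool_size` individuals is drawn multinomially from the line's haplotype
#' composition; (2) for each gene, a total informative read count is drawn
#' Poisson with mean `reads_per_gene` and reads are allocated multinomially
#' with probabilities proportional to the pool fraction of each haplotype
#' times the gene's per-haplotype mapping-bias factor. Both stages
#' contribute variance to downstream frequency estimates; in
#' `deterministic_mode` both are replaced by expectations (rounded counts).
#'
#' @param composition length-3 haplotype composition.
#' @param params a [sim_params()] object.
#' @param sample_id sample identifier written into the output rows.
#' @param skip_pool if `TRUE`, stage 1 is skipped and reads are drawn from
#'   the exact composition (used for control samples with known 1/3
#'   frequencies).
#' @return long-format data.frame with columns `sample_id`, `gene`,
#'   `haplotype`, `reads`.
#' @export
simulate_poolseq_counts <- function(composition, params = sim_params(),
                                    sample_id = "S1", skip_pool = FALSE) {
  composition <- check_composition(composition)
  if (params$reads_per_gene == 0) {
    warning("zero coverage: no reads simulated for sample ", sample_id)
    return(data.frame(sample_id = character(), gene = character(),
                      haplotype = character(), reads = integer()))
  }
  pool_frac <- composition
  if (!skip_pool && !params$deterministic_mode) {
    pool_frac <- as.numeric(stats::rmultinom(1, params$pool_size,
                                             composition)) / params$pool_size
  }
  genes <- params$genes
  counts <- vapply(seq_along(genes), function(g) {
    pr <- pool_frac * params$bias_factors[g, ]
    if (sum(pr) == 0) return(c(0, 0, 0))
    pr <- pr / sum(pr)
    if (params$deterministic_mode) {
      round(params$reads_per_gene * pr)
    } else {
      n_reads <- stats::rpois(1, params$reads_per_gene)
      as.numeric(stats::rmultinom(1, n_reads, pr))
    }
  }, numeric(3))
  data.frame(sample_id = sample_id,
             gene = rep(genes, each = 3),
             haplotype = rep(HAPLOTYPES, length(genes)),
             reads = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Simulate control samples with known haplotype frequencies
#'
#' Emits `n` samples whose true composition is exactly (1/3, 1/3, 1/3) —
#' mimicking control pools assembled from equal numbers of individuals of
#' each pure haplotype line, so pool sampling is skipped — with the
#' configured per-gene mapping-bias factors. Used to calibrate the gene
#' bias filter ([test_gene_bias()]).
#'
#' @param n number of control samples (>= 1).
#' @param params a [sim_params()] object.
#' @return long-format read-count data.frame as in
#'   [simulate_poolseq_counts()], with sample ids `ctrl1..ctrln` and a
#'   logical column `is_control = TRUE`.
#' @export
simulate_control_samples <- function(n, params = sim_params()) {
  if (n < 1) stop("n must be >= 1")
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_poolseq_counts(rep(1/3, 3), params,
                            sample_id = sprintf("ctrl%d", i),
                            skip_pool = TRUE)
  }))
  out$is_control <- TRUE
  out
}

#' Simulate lifetime-reproductive-success assays
#'
#' Draws lifetime fertile-egg counts log-normally for mtDNA-mix and pure
#' lines assayed at two generations. The log-scale mean of a mix line is
#' the composition-weighted mean of the per-haplotype reproductive effects
#' (pure lines use their single haplotype's effect), plus line, sex and
#' generation terms. Female assays house two focal females (vs one focal
#' male), so female raw counts carry a log(2) offset and the returned
#' `adjusted_eggs` halves female counts to put the sexes on a common scale.
#'
#' @param design data.frame of assayed lines with columns `line_id`,
#'   `line_type` ("mix" or "pure"), `nuclear_background`.
#' @param haplotype_effects named length-3 vector of log-scale reproductive
#'   effects per haplotype.
#' @param compositions named list: for each mix `line_id`, a named list
#'   with components `gen3` and `gen33`, each a length-3 composition at the
#'   assay generation. Pure lines instead need a `haplotype` column in
#'   `design`.
#' @param n_assays assays per line x sex x generation cell (default 19, the
#'   study's average).
#' @param base_log mean log fertile-egg count of the reference genotype
#'   (default `log(30)`).
#' @param sd_log residual log-scale standard deviation between assays
#'   (default 0.4).
#' @param line_sd standard deviation of random line effects (default 0.05).
#' @param generation_effect additive log-scale change from generation 3 to
#'   33 common to all lines (default 0).
#' @param seed integer seed for reproducibility.
#' @return data.frame with columns `line_id`, `line_type`,
#'   `nuclear_background`, `sex`, `generation`, `fertile_eggs`,
#'   `adjusted_eggs`.
#' @export
simulate_lrs <- function(design, haplotype_effects, compositions,
                         n_assays = 19, base_log = log(30), sd_log = 0.4,
                         line_sd = 0.05, generation_effect = 0, seed = 1) {
  stopifnot(all(c("line_id", "line_type", "nuclear_background")
                %in% names(design)), n_assays >= 1)
  haplotype_effects <- haplotype_effects[HAPLOTYPES]
  set.seed(derive_seed(seed, "lrs"))
  line_eff <- stats::setNames(stats::rnorm(nrow(design), 0, line_sd),
                              design$line_id)
  rows <- list()
  for (i in seq_len(nrow(design))) {
    ln <- design[i, ]
    for (gen in c(3L, 33L)) {
      if (ln$line_type == "pure") {
        mt_eff <- haplotype_effects[[ln$haplotype]]
      } else {
        comp <- compositions[[ln$line_id]][[paste0("gen", gen)]]
        comp <- check_composition(comp)
        mt_eff <- sum(comp * haplotype_effects)
      }
      for (sex in c("female", "male")) {
        mu <- base_log + mt_eff + line_eff[[ln$line_id]] +
          (gen == 33L) * generation_effect +
          (sex == "female") * log(2)
        eggs <- round(stats::rlnorm(n_assays, mu, sd_log))
        rows[[length(rows) + 1]] <- data.frame(
          line_id = ln$line_id, line_type = ln$line_type,
          nuclear_background = ln$nuclear_background,
          sex = sex, generation = gen,
          fertile_eggs = as.integer(eggs),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_eggs <- ifelse(out$sex == "female",
                              out$fertile_eggs / 2, out$fertile_eggs)
  out
}

#' Simulate a complete experimental evolution study
#'
#' Generates one realization of the full study: for every line in `design`,
#' a Wright-Fisher trajectory from equal starting frequencies (1/3 each)
#' under the planted per-cell fitnesses for the line's number of
#' generations, followed by pool-seq read sampling of the end-point
#' composition; plus `n_controls` control samples at known frequencies.
#' Per-line random streams are derived deterministically from the root seed
#' and the line id, so results do not depend on line order.
#'
#' @param design design table from [experiment_design()].
#' @param params a [sim_params()] object carrying the planted fitness map.
#' @param n_controls number of control samples (default 3).
#' @param seed root integer seed.
#' @return list with components `counts` (read counts for all line samples,
#'   `is_control = FALSE`), `controls` (control read counts), `truth`
#'   (per-line true end compositions, lines x 3), `trajectories` (named list
#'   of full per-line frequency trajectories), and `design`.
#' @export
simulate_experiment <- function(design = experiment_design(),
                                params = sim_params(), n_controls = 3,
                                seed = 1) {
  truth <- matrix(NA_real_, nrow(design), 3,
                  dimnames = list(design$line_id, HAPLOTYPES))
  trajectories <- stats::setNames(vector("list", nrow(design)),
                                  design$line_id)
  counts <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    ln <- design[i, ]
    set.seed(derive_seed(seed, ln$line_id))
    w <- fitness_for_cell(params, ln$thermal_regime, ln$nuclear_background)
    traj <- simulate_wf_trajectory(rep(1/3, 3), w,
                                   ln$generations_elapsed, params)
    trajectories[[i]] <- traj
    truth[i, ] <- traj[nrow(traj), ]
    counts[[i]] <- simulate_poolseq_counts(truth[i, ], params,
                                           sample_id = ln$line_id)
  }
  counts <- do.call(rbind, counts)
  counts$is_control <- FALSE
  set.seed(derive_seed(seed, "controls"))
  controls <- simulate_control_samples(n_controls, params)
  list(counts = counts, controls = controls, truth = truth,
       trajectories = trajectories, design = design)
}
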