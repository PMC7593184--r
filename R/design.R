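#' Build the experimental evolution design table
#'
#' Constructs the full factorial design: 3 nuclear backgrounds x 2 thermal
#' regimes x 2 maternal-line ("Eve") replicates x 2 technical replicates =
#' 24 mtDNA-mix lines. Lines in the warm regime evolve for 36 generations,
#' lines in the cold regime for 23 (warm generations are shorter, so more
#' elapse in the same calendar time). Lines named in `lost` are dropped,
#' reproducing the realized design in which one warm-regime Yemen-background
#' replicate was lost during culturing (23 lines).
#'
#' @param generations named vector giving generations elapsed per thermal
#'   regime. Default `c("23C" = 23, "35C" = 36)`.
#' @param lost character vector of `line_id`s to drop, or `NULL` to keep all
#'   24. The default drops one Yemen x 35C replicate.
#' @return data.frame with columns `line_id`, `nuclear_background`,
#'   `thermal_regime`, `eve_replicate`, `technical_replicate`,
#'   `generations_elapsed`.
#' @examples
#' d <- experiment_design()
#' nrow(d)            # 23 realized lines
#' table(d$thermal_regime)
#' @export
experiment_design <- function(generations = c("23C" = 23, "35C" = 36),
                              lost = "Yemen_35C_e2_t2") {
  stopifnot(all(THERMAL_REGIMES %in% names(generations)),
            all(generations >= 1))
  d <- expand.grid(technical_replicate = 1:2,
                   eve_replicate = 1:2,
                   thermal_regime = THERMAL_REGIMES,
                   nuclear_background = NUCLEAR_BACKGROUNDS,
                   stringsAsFactors = FALSE)
  d$line_id <- sprintf("%s_%s_e%d_t%d", d$nuclear_background,
                       d$thermal_regime, d$eve_replicate,
                       d$technical_replicate)
  d$generations_elapsed <- as.integer(generations[d$thermal_regime])
  d <- d[, c("line_id", "nuclear_background", "thermal_regime",
             "eve_replicate", "technical_replicate", "generations_elapsed")]
  if (!is.null(lost)) {
    missing_ids <- setdiff(lost, d$line_id)
    if (length(missing_ids))
      stop("unknown line_id in `lost`: ", paste(missing_ids, collapse = ", "))
    d <- d[!d$line_id %in% lost, ]
  }
  rownames(d) <- NULL
  d
}

#' Default per-cell haplotype fitness map for the simulator
#'
#' Relative fitness of each haplotype per (thermal regime, nuclear
#' background) cell. The defaults place the overall haplotype ranking at
#' CAL > BRA > YEM with per-generation magnitudes of roughly 1.01 / 1.00 /
#' 0.99, and superimpose cell-specific deviations: the CAL and YEM
#' haplotypes fare relatively better in the warm regime and BRA in the cold,
#' and at 35C each haplotype gains a small advantage in its native nuclear
#' background (mitonuclear coadaptation). These deviations generate a
#' thermal x nuclear interaction of the kind the compositional ANOVA is
#' designed to detect.
#'
#' @return data.frame with columns `thermal_regime`, `nuclear_background`,
#'   `BRA`, `CAL`, `YEM` (positive per-generation relative fitnesses).
#' @export
default_fitness_map <- function() {
  grid <- expand.grid(thermal_regime = THERMAL_REGIMES,
                      nuclear_background = NUCLEAR_BACKGROUNDS,
                      stringsAsFactors = FALSE)
  base <- c(BRA = 0.999, CAL = 1.010, YEM = 0.991)
  # thermal deviation: BRA favoured in the cold, CAL/YEM in the warm
  thermal_dev <- list(`23C` = c(BRA = +0.004, CAL = -0.002, YEM = -0.002),
                      `35C` = c(BRA = -0.004, CAL = +0.002, YEM = +0.002))
  native <- c(Brazil = "BRA", California = "CAL", Yemen = "YEM")
  w <- t(vapply(seq_len(nrow(grid)), function(i) {
    wi <- base + thermal_dev[[grid$thermal_regime[i]]]
    if (grid$thermal_regime[i] == "35C")
      wi[native[[grid$nuclear_background[i]]]] <-
        wi[native[[grid$nuclear_background[i]]]] + 0.003
    wi
  }, numeric(3)))
  cbind(grid, as.data.frame(w))
}

#' Simulation parameters for the synthetic experiment generator
#'
#' @param n_females effective number of maternally transmitting females per
#'   generation (the drift population size for mtDNA); default 300, half of
#'   the ~600 adults kept per line.
#' @param w_true fitness map as returned by [default_fitness_map()]: one row
#'   per (thermal regime, nuclear background) cell with positive
#'   per-generation relative fitness columns `BRA`, `CAL`, `YEM`.
#' @param pool_size number of individuals pooled for sequencing (default
#'   100).
#' @param n_genes number of protein-coding genes with informative reads
#'   (default 13).
#' @param reads_per_gene mean informative read count per gene per sample
#'   (Poisson mean; default 900, i.e. ~12k informative reads per sample
#'   split over 13 genes, matching 60x effective mitogenome coverage).
#' @param bias_factors `n_genes` x 3 matrix of positive per-gene,
#'   per-haplotype mapping-bias multipliers (1 = unbiased), or `NULL` for no
#'   bias. Row names are gene names.
#' @param deterministic_mode if `TRUE`, all sampling layers (drift, pool,
#'   reads) are replaced by their expectations; used for closed-form oracle
#'   checks.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_females = 300,
                       w_true = default_fitness_map(),
                       pool_size = 100,
                       n_genes = 13,
                       reads_per_gene = 900,
                       bias_factors = NULL,
                       deterministic_mode = FALSE) {
  stopifnot(n_females >= 1, pool_size >= 1, n_genes >= 1,
            reads_per_gene >= 0)
  if (!is.null(w_true)) {
    stopifnot(is.data.frame(w_true),
              all(c("thermal_regime", "nuclear_background", HAPLOTYPES)
                  %in% names(w_true)))
    if (any(as.matrix(w_true[, HAPLOTYPES]) <= 0))
      stop("all fitness values in w_true must be > 0")
  }
  genes <- if (n_genes == 13) MITO_PCGS else sprintf("g%02d", seq_len(n_genes))
  if (is.null(bias_factors)) {
    bias_factors <- matrix(1, n_genes, 3,
                           dimnames = list(genes, HAPLOTYPES))
  } else {
    bias_factors <- as.matrix(bias_factors)
    if (!all(dim(bias_factors) == c(n_genes, 3)))
      stop("bias_factors must be n_genes x 3")
    if (any(bias_factors <= 0)) stop("bias_factors must be > 0")
    if (is.null(rownames(bias_factors))) rownames(bias_factors) <- genes
    colnames(bias_factors) <- HAPLOTYPES
  }
  structure(list(n_females = n_females, w_true = w_true,
                 pool_size = pool_size, n_genes = n_genes,
                 genes = rownames(bias_factors),
                 reads_per_gene = reads_per_gene,
                 bias_factors = bias_factors,
                 deterministic_mode = deterministic_mode),
            class = "sim_params")
}

# internal: look up the fitness vector for a design row
fitness_for_cell <- function(params, thermal, nuclear) {
  w <- params$w_true
  row <- which(w$thermal_regime == thermal & w$nuclear_background == nuclear)
  if (length(row) != 1)
    stop("no fitness entry for cell (", thermal, ", ", nuclear, ")")
  unlist(w[row, HAPLOTYPES])
}
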