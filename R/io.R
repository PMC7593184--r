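# internal: strict TSV reader that checks required columns
read_tsv_checked <- function(path, required, what) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop(what, " file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  d
}

#' Read an experiment design TSV
#'
#' Expected header: `line_id`, `nuclear`, `thermal`, `eve`, `tech`,
#' `generations` (tab-delimited, UTF-8).
#' @param path file path.
#' @return design data.frame in the internal column naming of
#'   [experiment_design()].
#' @export
read_design <- function(path) {
  d <- read_tsv_checked(path, c("line_id", "nuclear", "thermal", "eve",
                                "tech", "generations"), "design")
  data.frame(line_id = d$line_id, nuclear_background = d$nuclear,
             thermal_regime = d$thermal, eve_replicate = d$eve,
             technical_replicate = d$tech,
             generations_elapsed = as.integer(d$generations),
             stringsAsFactors = FALSE)
}

#' Write an experiment design TSV
#' @param design design data.frame.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  out <- data.frame(line_id = design$line_id,
                    nuclear = design$nuclear_background,
                    thermal = design$thermal_regime,
                    eve = design$eve_replicate,
                    tech = design$technical_replicate,
                    generations = design$generations_elapsed)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a long-format read-count TSV
#'
#' Expected header: `sample_id`, `gene`, `haplotype`, `reads`; an optional
#' `is_control` column is preserved.
#' @param path file path.
#' @return read-count data.frame.
#' @export
read_counts <- function(path) {
  d <- read_tsv_checked(path, c("sample_id", "gene", "haplotype", "reads"),
                        "read-count")
  d$reads <- as.integer(d$reads)
  check_count_table(d)
  d
}

#' Write a long-format read-count TSV
#' @param counts read-count data.frame.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a phenotype assay TSV
#'
#' Expected header: `line_id`, `line_type`, `nuclear`, `sex`, `generation`,
#' `fertile_eggs`. The `adjusted_eggs` column (female counts halved) is
#' recomputed on read.
#' @param path file path.
#' @return phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- read_tsv_checked(path, c("line_id", "line_type", "nuclear", "sex",
                                "generation", "fertile_eggs"), "phenotype")
  data.frame(line_id = d$line_id, line_type = d$line_type,
             nuclear_background = d$nuclear, sex = d$sex,
             generation = as.integer(d$generation),
             fertile_eggs = as.integer(d$fertile_eggs),
             adjusted_eggs = ifelse(d$sex == "female",
                                    as.integer(d$fertile_eggs) / 2,
                                    as.integer(d$fertile_eggs)),
             stringsAsFactors = FALSE)
}

#' Write a phenotype assay TSV
#' @param phenotypes phenotype data.frame.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  out <- data.frame(line_id = phenotypes$line_id,
                    line_type = phenotypes$line_type,
                    nuclear = phenotypes$nuclear_background,
                    sex = phenotypes$sex,
                    generation = phenotypes$generation,
                    fertile_eggs = phenotypes$fertile_eggs)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Pipeline configuration
#'
#' Collects all thresholds, sizes and flags for [run_pipeline()]. Unknown
#' arguments are rejected.
#'
#' @param alpha FDR threshold of the gene bias filter (default 0.05).
#' @param n_perm permutations for the ANOVA permutation test (default
#'   9999).
#' @param n_boot bootstrap replicates for selection test and PLS (default
#'   9999).
#' @param seed root seed for every stochastic step (default 1).
#' @param eq1_mode `"per_generation"` or `"one_step"` reading of the
#'   selection recursion.
#' @param pi_region `"whole"` or `"pcg_only"` for nucleotide diversity.
#' @param reference_nuclear nuclear background of the pure reference line
#'   for relative reproductive fitness.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, n_perm = 9999, n_boot = 9999,
                            seed = 1, eq1_mode = "per_generation",
                            pi_region = "whole",
                            reference_nuclear = "California") {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 99, n_boot >= 100)
  structure(list(alpha = alpha, n_perm = n_perm, n_boot = n_boot,
                 seed = seed, eq1_mode = eq1_mode, pi_region = pi_region,
                 reference_nuclear = reference_nuclear),
            class = "pipeline_config")
}

#' Run the full inference pipeline
#'
#' Chains the analysis stages on in-memory inputs: gene bias filter on the
#' control samples, haplotype-frequency estimation for the line samples,
#' relative fitness and per-generation frequency change, selection test,
#' compositional PCA with repeated-measures and per-haplotype ANOVAs plus
#' permutation p-values, and — when phenotype assays are supplied — the
#' PLS analysis linking frequency change to sex-specific reproductive
#' fitness change. Mitogenome divergence is summarized when genomes are
#' supplied. Every sample in `counts` must appear in `design`.
#'
#' @param design design table ([experiment_design()] / [read_design()]).
#' @param counts line-sample read counts ([read_counts()]).
#' @param controls control-sample read counts.
#' @param phenotypes optional phenotype assay table ([read_phenotypes()]).
#' @param genomes optional list of 3 `mito_genome` objects.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: per-stage TSVs and a JSON report are
#'   written there.
#' @return list with components `bias`, `frequencies`, `fitness`,
#'   `selection`, `pca`, `rm_anova`, `permutation`, `per_haplotype`,
#'   and optionally `pls`, `divergence`; plus `config`.
#' @export
run_pipeline <- function(design, counts, controls, phenotypes = NULL,
                         genomes = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  extra <- setdiff(unique(counts$sample_id), design$line_id)
  if (length(extra))
    stop("sample(s) in counts not present in design: ",
         paste(extra, collapse = ", "))
  bias <- test_gene_bias(controls, alpha = config$alpha)
  if (length(bias$genes_retained) == 0)
    stop("no genes passed the bias filter")
  freq <- estimate_frequencies(counts, bias$genes_retained)
  fit <- fitness_from_frequencies(freq$freq, design, mode = config$eq1_mode)
  selection <- test_selection(fit$W, n_boot = config$n_boot,
                              seed = config$seed)
  pca <- fitness_pca(fit$W)
  rm_tab <- rm_anova(pca, design)
  perm <- permutation_test(pca, design, n_perm = config$n_perm,
                           seed = config$seed)
  per_h <- per_haplotype_anova(fit$W, design)
  res <- list(bias = bias, frequencies = freq, fitness = fit,
              selection = selection, pca = pca, rm_anova = rm_tab,
              permutation = perm, per_haplotype = per_h, config = config)
  if (!is.null(phenotypes)) {
    dw <- compute_delta_w(phenotypes,
                          reference_nuclear = config$reference_nuclear)
    wide <- stats::reshape(dw[, c("line_id", "sex", "delta_w")],
                           direction = "wide", idvar = "line_id",
                           timevar = "sex")
    names(wide) <- sub("^delta_w\\.", "", names(wide))
    lines_pls <- intersect(wide$line_id, rownames(fit$delta_f))
    X <- fit$delta_f[lines_pls, , drop = FALSE]
    Y <- as.matrix(wide[match(lines_pls, wide$line_id),
                        c("male", "female"), drop = FALSE])
    rownames(Y) <- lines_pls
    res$delta_w <- dw
    res$pls <- bootstrap_pls(X, Y, n_boot = config$n_boot,
                             seed = config$seed)
  }
  if (!is.null(genomes)) {
    call <- align_and_call(genomes)
    res$divergence <- list(
      call = call,
      substitutions = classify_substitutions(call),
      pi = pairwise_pi(call, region = config$pi_region))
  }
  if (!is.null(out_dir)) write_pipeline_report(res, out_dir)
  res
}

# internal: serialize pipeline results to TSVs + one JSON report
write_pipeline_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(line_id = rownames(res$frequencies$freq),
               res$frequencies$freq),
    file.path(out_dir, "frequencies.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  fit_long <- data.frame(
    line_id = rep(rownames(res$fitness$W), 3),
    haplotype = rep(HAPLOTYPES, each = nrow(res$fitness$W)),
    W = as.vector(res$fitness$W),
    delta_f = as.vector(res$fitness$delta_f))
  utils::write.table(fit_long, file.path(out_dir, "fitness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$rm_anova, file.path(out_dir, "rm_anova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    package_version = as.character(utils::packageVersion("mitosel")),
    config = unclass(res$config),
    genes_retained = res$bias$genes_retained,
    mean_W = as.list(colMeans(res$fitness$W)),
    rm_anova = res$rm_anova,
    permutation = res$permutation,
    selection = res$selection$per_haplotype)
  if (!is.null(res$pls))
    report$pls <- list(
      covariance_explained = res$pls$covariance_explained,
      loadings = res$pls$loadings)
  if (!is.null(res$divergence))
    report$divergence <- list(
      snp_total = res$divergence$call$snp_total,
      indel_total = res$divergence$call$indel_total,
      syn_total = res$divergence$substitutions$syn_total,
      nonsyn_total = res$divergence$substitutions$nonsyn_total,
      pi = res$divergence$pi)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' End-to-end self-test on simulated data
#'
#' Simulates a complete study under the default (study-condition)
#' parameters with the given seed and runs [run_pipeline()] on it,
#' checking structural invariants along the way. Useful as a smoke test of
#' an installation.
#'
#' @param seed root seed (default 1).
#' @param out_dir optional report directory.
#' @return the pipeline result, invisibly.
#' @export
selftest <- function(seed = 1, out_dir = NULL) {
  sim <- simulate_experiment(seed = seed)
  res <- run_pipeline(sim$design, sim$counts, sim$controls,
                      config = pipeline_config(n_perm = 999, n_boot = 999,
                                               seed = seed),
                      out_dir = out_dir)
  stopifnot(all(abs(rowSums(res$frequencies$freq) - 1) < 1e-9),
            all(abs(rowSums(res$fitness$delta_f)) < 1e-9),
            res$pca$eigenvalues[3] < 1e-9)
  invisible(res)
}
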