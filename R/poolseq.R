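# internal: validate a long-format read-count table
check_count_table <- function(counts) {
  need <- c("sample_id", "gene", "haplotype", "reads")
  if (!all(need %in% names(counts)))
    stop("read-count table needs columns: ", paste(need, collapse = ", "))
  if (any(counts$reads < 0)) stop("negative read counts")
  if (anyDuplicated(counts[, c("sample_id", "gene", "haplotype")]))
    stop("duplicated (sample, gene, haplotype) entries")
  if (!all(counts$haplotype %in% HAPLOTYPES))
    stop("unknown haplotype labels: ",
         paste(setdiff(unique(counts$haplotype), HAPLOTYPES), collapse = ", "))
  invisible(counts)
}

# internal: sample x gene x haplotype counts as a list of gene x 3 matrices
counts_by_sample <- function(counts) {
  check_count_table(counts)
  lapply(split(counts, counts$sample_id), function(d) {
    m <- stats::xtabs(reads ~ gene + haplotype, data = d)
    m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
    m[, HAPLOTYPES, drop = FALSE]
  })
}

#' Test protein-coding genes for mapping bias using control samples
#'
#' For every gene in every control sample (where true haplotype frequencies
#' are known), performs a goodness-of-fit chi-square test (df = 2) of the
#' observed per-haplotype read counts against the expected proportions.
#' P-values are Benjamini-Hochberg adjusted across genes within each control
#' sample; a gene is retained only if its adjusted Q-value exceeds `alpha`
#' in every control sample (i.e. a gene significant in any control sample is
#' flagged as biased and dropped). Biased genes are excluded rather than
#' corrected.
#'
#' @param controls long-format read-count table of control samples.
#' @param expected length-3 expected composition (default equal thirds).
#' @param alpha FDR threshold (default 0.05).
#' @return list of class `bias_test` with `tests` (per gene x control
#'   sample: `chi2`, `df`, `p`, `q`), `gene_summary` (per gene: `min_q`,
#'   `retained`), `genes_retained`, and `genes_excluded` (zero-read genes,
#'   never retained).
#' @examples
#' ctrl <- simulate_control_samples(3, sim_params())
#' bt <- test_gene_bias(ctrl)
#' bt$genes_retained
#' @export
test_gene_bias <- function(controls, expected = rep(1/3, 3), alpha = 0.05) {
  expected <- check_composition(expected, "expected")
  mats <- counts_by_sample(controls)
  if (length(mats) < 1) stop("need at least one control sample")
  tests <- do.call(rbind, lapply(names(mats), function(s) {
    m <- mats[[s]]
    do.call(rbind, lapply(rownames(m), function(g) {
      o <- m[g, ]
      n <- sum(o)
      if (n == 0)
        return(data.frame(sample_id = s, gene = g, total = 0,
                          chi2 = NA_real_, df = 2L, p = NA_real_))
      e <- n * expected
      chi2 <- sum((o - e)^2 / e)
      data.frame(sample_id = s, gene = g, total = n, chi2 = chi2, df = 2L,
                 p = stats::pchisq(chi2, df = 2, lower.tail = FALSE))
    }))
  }))
  # BH within each control sample across its genes
  tests$q <- stats::ave(tests$p, tests$sample_id,
                        FUN = function(p) stats::p.adjust(p, "BH"))
  zero_genes <- unique(tests$gene[is.na(tests$p)])
  if (length(zero_genes))
    warning("genes with zero reads in a control sample excluded: ",
            paste(zero_genes, collapse = ", "))
  min_q <- tapply(tests$q, tests$gene, function(q) suppressWarnings(min(q)))
  genes <- sort(unique(tests$gene))
  gene_summary <- data.frame(
    gene = genes,
    min_q = as.numeric(min_q[genes]),
    retained = !(genes %in% zero_genes) &
      vapply(genes, function(g) all(tests$q[tests$gene == g] > alpha,
                                    na.rm = TRUE), logical(1)),
    row.names = NULL)
  structure(list(tests = tests, gene_summary = gene_summary,
                 genes_retained = gene_summary$gene[gene_summary$retained],
                 genes_excluded = zero_genes, alpha = alpha),
            class = "bias_test")
}

#' Estimate haplotype frequencies from pool-seq read counts
#'
#' For each sample and each retained gene, the per-gene haplotype proportion
#' is the gene's read count for that haplotype divided by the gene's total.
#' The sample's haplotype-frequency estimate is the unweighted arithmetic
#' mean of the per-gene proportion vectors over `genes_used` (renormalized
#' to guard against floating-point drift) — mean of proportions, not a
#' pooled-count proportion, so each gene contributes equally regardless of
#' its coverage.
#'
#' @param samples long-format read-count table.
#' @param genes_used character vector of genes to use (typically
#'   `genes_retained` from [test_gene_bias()]).
#' @return list of class `freq_estimate` with `freq` (samples x 3 frequency
#'   matrix), `per_gene` (named list of gene x 3 proportion matrices), and
#'   `genes_used`.
#' @export
estimate_frequencies <- function(samples, genes_used) {
  if (length(genes_used) < 1) stop("genes_used must be non-empty")
  mats <- counts_by_sample(samples)
  per_gene <- list()
  freq <- matrix(NA_real_, length(mats), 3,
                 dimnames = list(names(mats), HAPLOTYPES))
  for (s in names(mats)) {
    m <- mats[[s]][intersect(genes_used, rownames(mats[[s]])), ,
                   drop = FALSE]
    totals <- rowSums(m)
    if (all(totals == 0))
      stop("sample '", s, "' has zero reads across all genes_used")
    if (any(totals == 0)) {
      warning("sample '", s, "' has zero reads in gene(s) ",
              paste(rownames(m)[totals == 0], collapse = ", "),
              "; dropped for this sample")
      m <- m[totals > 0, , drop = FALSE]
      totals <- totals[totals > 0]
    }
    props <- m / totals
    f <- colMeans(props)
    freq[s, ] <- f / sum(f)
    per_gene[[s]] <- props
  }
  structure(list(freq = freq, per_gene = per_gene,
                 genes_used = genes_used),
            class = "freq_estimate")
}

#' Consistency of per-gene frequency estimates across samples
#'
#' Diagnostic mirroring the "mean correlation across lines" check: for each
#' haplotype and each pair of genes, the Pearson correlation across samples
#' of the two genes' per-gene proportion estimates; returns the mean over
#' all gene pairs and haplotypes. Values near 1 indicate that different
#' genes tell the same story about haplotype frequencies.
#'
#' @param estimate a `freq_estimate` from [estimate_frequencies()] covering
#'   at least 3 samples and 2 genes.
#' @return list with `mean_r` and the per-(gene pair, haplotype) table
#'   `pairs`.
#' @export
gene_consistency <- function(estimate) {
  stopifnot(inherits(estimate, "freq_estimate"))
  samples <- names(estimate$per_gene)
  if (length(samples) < 3) stop("need >= 3 samples")
  genes <- Reduce(intersect, lapply(estimate$per_gene, rownames))
  if (length(genes) < 2) stop("need >= 2 genes common to all samples")
  # per haplotype: samples x genes matrix of per-gene proportions
  rows <- list()
  for (h in HAPLOTYPES) {
    m <- vapply(genes, function(g)
      vapply(samples, function(s) estimate$per_gene[[s]][g, h], numeric(1)),
      numeric(length(samples)))
    for (i in seq_len(length(genes) - 1)) for (j in (i + 1):length(genes)) {
      if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) {
        warning("constant per-gene estimates for ", genes[i], "/", genes[j],
                " (", h, "); pair excluded")
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene1 = genes[i], gene2 = genes[j], haplotype = h,
        r = stats::cor(m[, i], m[, j]))
    }
  }
  pairs <- do.call(rbind, rows)
  list(mean_r = mean(pairs$r), pairs = pairs)
}
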