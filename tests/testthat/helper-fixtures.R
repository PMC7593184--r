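# Builders for small synthetic fixtures used across tests.

# long-format read-count table from a gene x 3 matrix of counts
counts_from_matrix <- function(m, sample_id = "S1") {
  data.frame(sample_id = sample_id,
             gene = rep(rownames(m), each = 3),
             haplotype = rep(HAPLOTYPES, nrow(m)),
             reads = as.integer(t(m)),
             stringsAsFactors = FALSE)
}

# balanced two-way design: 4 lines per (thermal x nuclear) cell
balanced_design <- function(per_cell = 4) {
  d <- expand.grid(rep = seq_len(per_cell),
                   thermal_regime = THERMAL_REGIMES,
                   nuclear_background = NUCLEAR_BACKGROUNDS,
                   stringsAsFactors = FALSE)
  d$line_id <- sprintf("L%02d", seq_len(nrow(d)))
  d$generations_elapsed <- ifelse(d$thermal_regime == "35C", 36L, 23L)
  d
}

# a fitness matrix whose rows sum exactly to 3 (initial-mean-fitness
# normalization with uniform start), with noise in the zero-sum plane
zero_sum_fitness <- function(n = 23, seed = 1, sd = 0.01) {
  set.seed(seed)
  e1 <- c(1, -1, 0) / sqrt(2)
  e2 <- c(1, 1, -2) / sqrt(6)
  W <- matrix(1, n, 3) + outer(rnorm(n, 0, sd), e1) +
    outer(rnorm(n, 0, sd), e2)
  colnames(W) <- HAPLOTYPES
  W * 3 / rowSums(W)
}

# a synthetic trio of mitogenomes with known planted differences.
# Reference has two plus-strand genes and one minus-strand gene; planted:
#  - syn SNP   (gene A codon 2, 3rd position: CTT->CTC, both Leu)
#  - nonsyn SNP (gene A codon 4, 1st position: AAA->GAA, Lys->Glu), unique
#    to genome 2
#  - syn SNP under table 5 (gene B, ATA->ATG, both Met), unique to genome 3
#  - nonsyn on the minus-strand gene C, unique to genome 3
#  - one 1-bp deletion in the intergenic spacer of genome 2
#  - one intergenic SNP (genome 3)
synthetic_trio <- function() {
  gene_a <- "ATGCTTGGAAAATGTACCTAA"            # 21 bp, + strand
  spacer1 <- "ACGTACGTAC"
  gene_b <- "ATGATAGCCTTTCATTAA"               # 18 bp, + strand
  spacer2 <- "TTGACA"
  # gene C on minus strand: genomic slice is revcomp of ATGGCACTTTAA
  gene_c_mrna <- "ATGGCACTTTAA"
  gene_c <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gene_c_mrna)))
  ref <- paste0(gene_a, spacer1, gene_b, spacer2, gene_c)
  cds <- data.frame(
    gene = c("geneA", "geneB", "geneC"),
    start = c(0L, nchar(gene_a) + nchar(spacer1),
              nchar(gene_a) + nchar(spacer1) + nchar(gene_b) +
                nchar(spacer2)),
    end = c(nchar(gene_a),
            nchar(gene_a) + nchar(spacer1) + nchar(gene_b),
            nchar(ref)),
    strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  s2 <- ref
  substr(s2, 6, 6) <- "C"    # geneA codon 2 CTT->CTC (Leu/Leu, syn)
  substr(s2, 10, 10) <- "G"  # geneA codon 4 AAA->GAA (Lys->Glu, nonsyn)
  s2 <- paste0(substr(s2, 1, 23), substr(s2, 25, nchar(s2)))  # del spacer1
  s3 <- ref
  substr(s3, 37, 37) <- "G"  # geneB codon 2 ATA->ATG (Met/Met syn, table 5)
  substr(s3, 28, 28) <- "T"  # spacer1 SNP (intergenic)
  # geneC nonsyn: mRNA codon 2 GCA->GTA (Ala->Val); mRNA pos 5 is genomic
  # position (end - 5) on the minus strand; complement of T is A
  pos <- cds$end[3] - 4  # 1-based genomic position of mRNA base 5
  substr(s3, pos, pos) <- "A"
  list(genomes = list(mito_genome("REF", ref, cds),
                      mito_genome("G2", s2),
                      mito_genome("G3", s3)),
       cds = cds)
}

# planted rank-1 PLS construction: Y columns are scalar multiples of a
# single latent score driven by X
rank1_pls_data <- function(n = 12, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, paste0("df_", HAPLOTYPES)))
  latent <- X %*% c(1, -0.5, 0.25)
  Y <- cbind(male = as.numeric(latent) * 2,
             female = as.numeric(latent) * 0.7)
  list(X = X, Y = Y)
}
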