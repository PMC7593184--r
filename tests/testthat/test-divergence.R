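test_that("identical sequences yield no variants", {
  g <- lapply(c("A1", "A2", "A3"), function(id)
    mito_genome(id, strrep("ACGT", 30)))
  call <- align_and_call(g)
  expect_equal(call$snp_total, 0)
  expect_equal(call$indel_total, 0)
  expect_equal(nrow(call$variants), 0)
})

test_that("a single substitution is called and partitioned", {
  g <- list(mito_genome("s1", "ACGTA"), mito_genome("s2", "ACCTA"),
            mito_genome("s3", "ACGTA"))
  call <- align_and_call(g)
  expect_equal(call$snp_total, 1)
  expect_equal(call$variants$ref_pos, 3)
  expect_equal(call$variants$partition, "s2")
})

test_that("planted trio: SNPs, indel, partitions and classification", {
  trio <- synthetic_trio()
  call <- align_and_call(trio$genomes)
  expect_equal(call$snp_total, 5)
  expect_equal(call$indel_total, 1)
  # partitions sum to the SNP total
  expect_equal(sum(table(call$variants$partition)), call$snp_total)
  expect_equal(as.integer(table(call$variants$partition)[c("G2", "G3")]),
               c(2L, 3L))

  cls <- classify_substitutions(call)
  # CTT->CTC (Leu) and ATA->ATG (Met, invertebrate mito code): synonymous;
  # AAA->GAA (Lys->Glu) and the minus-strand GCA->GTA (Ala->Val): nonsyn
  expect_equal(cls$syn_total, 2)
  expect_equal(cls$nonsyn_total, 2)
  pg <- cls$per_gene
  expect_equal(pg$syn[pg$gene == "geneA"], 1)
  expect_equal(pg$nonsyn[pg$gene == "geneA"], 1)
  expect_equal(pg$syn[pg$gene == "geneB"], 1)
  expect_equal(pg$nonsyn[pg$gene == "geneC"], 1)
  # the intergenic SNP is not classified
  expect_equal(nrow(cls$site_detail), 4)
  expect_false(any(cls$site_detail$premature_stop))
})

test_that("pairwise pi counts differences per non-gap site", {
  trio <- synthetic_trio()
  call <- align_and_call(trio$genomes)
  pi <- pairwise_pi(call)
  get <- function(a, b)
    pi$pi[(pi$genome1 == a & pi$genome2 == b) |
            (pi$genome1 == b & pi$genome2 == a)]
  # G2 differs from REF at 2 sites over 66 ungapped columns (1-bp deletion)
  expect_equal(get("REF", "G2"), 2 / 66, tolerance = 1e-12)
  expect_equal(get("REF", "G3"), 3 / 67, tolerance = 1e-12)
  expect_equal(get("G2", "G3"), 5 / 66, tolerance = 1e-12)
  # triangle-like bound on the shared alignment
  expect_lte(get("REF", "G3"), get("REF", "G2") + get("G2", "G3") + 1e-12)

  # PCG-only region restricts the site set
  pi_pcg <- pairwise_pi(call, region = "pcg_only")
  expect_equal(pi_pcg$pi[pi_pcg$genome1 == "REF" & pi_pcg$genome2 == "G3"],
               2 / 51, tolerance = 1e-12)  # 51 CDS bases, 2 CDS SNPs in G3
})

test_that("1 difference over 100 sites gives pi = 0.01", {
  base <- strrep("ACGTT", 20)
  alt <- base
  substr(alt, 50, 50) <- "A"
  call <- align_and_call(list(mito_genome("a", base), mito_genome("b", alt),
                              mito_genome("c", base)))
  pi <- pairwise_pi(call)
  expect_equal(pi$pi[pi$genome1 == "a" & pi$genome2 == "b"], 0.01)
  expect_equal(pi$pi[pi$genome1 == "a" & pi$genome2 == "c"], 0)
})

test_that("minus-strand classification equals the plus-strand equivalent", {
  # the same codon change annotated on either strand must classify the same
  plus_seq <- "ATGGCACTTTAA"
  plus_alt <- "ATGGTACTTTAA"  # GCA->GTA, Ala->Val
  cds_plus <- data.frame(gene = "g", start = 0L, end = 12L, strand = "+")
  call_p <- align_and_call(list(
    mito_genome("r", plus_seq, cds_plus), mito_genome("x", plus_alt),
    mito_genome("y", plus_seq)))
  cls_p <- classify_substitutions(call_p)

  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  cds_minus <- data.frame(gene = "g", start = 0L, end = 12L, strand = "-")
  call_m <- align_and_call(list(
    mito_genome("r", rc(plus_seq), cds_minus), mito_genome("x", rc(plus_alt)),
    mito_genome("y", rc(plus_seq))))
  cls_m <- classify_substitutions(call_m)
  expect_equal(cls_m$site_detail$classification,
               cls_p$site_detail$classification)
  expect_equal(cls_p$nonsyn_total, 1)
})

test_that("premature stops are flagged and counted nonsynonymous", {
  # TGG -> TAG in mid-gene creates a stop (TGA is Trp in table 5, TAG not)
  ref <- "ATGTGGCTTAAA"
  alt <- "ATGTAGCTTAAA"
  cds <- data.frame(gene = "g", start = 0L, end = 12L, strand = "+")
  call <- align_and_call(list(mito_genome("r", ref, cds),
                              mito_genome("x", alt),
                              mito_genome("y", ref)))
  expect_warning(cls <- classify_substitutions(call), "premature stop")
  expect_equal(cls$nonsyn_total, 1)
  expect_true(cls$site_detail$premature_stop)
})

test_that("prealigned input bypasses alignment exactly", {
  aln <- c("ACG-TACGT", "ACGGTACGT", "ACG-TACCT")
  g <- list(mito_genome("a", aln[1]), mito_genome("b", aln[2]),
            mito_genome("c", aln[3]))
  call <- align_and_call(g, prealigned = TRUE)
  expect_equal(call$snp_total, 1)
  expect_equal(call$indel_total, 1)
  expect_equal(call$variants$partition, "c")
})

test_that("non-homologous lengths are refused", {
  g <- list(mito_genome("a", strrep("ACGT", 100)),
            mito_genome("b", strrep("ACGT", 50)),
            mito_genome("c", strrep("ACGT", 100)))
  expect_error(align_and_call(g), "not homologous")
  expect_error(align_and_call(g[1:2]), "exactly 3")
})

test_that("FASTA and annotation round-trip through the readers", {
  trio <- synthetic_trio()
  fa <- tempfile(fileext = ".fasta")
  seqs <- Biostrings::DNAStringSet(vapply(trio$genomes,
                                          function(g) g$sequence, ""))
  names(seqs) <- vapply(trio$genomes, function(g) g$id, "")
  Biostrings::writeXStringSet(seqs, fa)
  ann <- tempfile(fileext = ".tsv")
  cds1 <- trio$cds
  cds1$start <- cds1$start + 1L  # writer/reader convention: 1-based closed
  write.table(cds1, ann, sep = "\t", quote = FALSE, row.names = FALSE)

  genomes <- read_mitogenomes(fa, cds = read_cds_annotation(ann))
  expect_equal(genomes[[1]]$cds$start, trio$cds$start)
  expect_equal(genomes[[1]]$cds$end, trio$cds$end)
  call <- align_and_call(genomes)
  expect_equal(call$snp_total, 5)
  cls <- classify_substitutions(call)
  expect_equal(cls$syn_total, 2)
  expect_equal(cls$nonsyn_total, 2)
})

test_that("CDS validation catches bad annotations", {
  expect_error(mito_genome("x", "ATGAAATAA",
                           data.frame(gene = "g", start = 0L, end = 8L,
                                      strand = "+")),
               "divisible by 3")
  expect_error(mito_genome("x", "ATGAAATAA",
                           data.frame(gene = "g", start = 0L, end = 12L,
                                      strand = "+")),
               "out of range")
})
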