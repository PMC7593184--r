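#' Construct a mitogenome object
#'
#' Bundles a mitochondrial genome sequence with its protein-coding-gene
#' annotation. Coordinates are 0-based half-open (`start` inclusive, `end`
#' exclusive), the internal convention throughout; [read_cds_annotation()]
#' converts from the 1-based closed coordinates of GFF-style input. CDS
#' lengths must be divisible by 3.
#'
#' @param id genome identifier (e.g. the haplotype name).
#' @param sequence DNA sequence as a character string or
#'   [Biostrings::DNAString].
#' @param cds data.frame with columns `gene`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), 0-based half-open.
#' @return list of class `mito_genome`.
#' @export
mito_genome <- function(id, sequence, cds = NULL) {
  seq <- toupper(as.character(sequence))
  if (!is.null(cds)) {
    stopifnot(all(c("gene", "start", "end", "strand") %in% names(cds)))
    if (any(cds$start < 0 | cds$end > nchar(seq) | cds$start >= cds$end))
      stop("CDS coordinates out of range for genome ", id)
    if (any((cds$end - cds$start) %% 3 != 0))
      stop("CDS length not divisible by 3 in genome ", id, ": ",
           paste(cds$gene[(cds$end - cds$start) %% 3 != 0], collapse = ", "))
    if (!all(cds$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  structure(list(id = id, sequence = seq, cds = cds),
            class = "mito_genome")
}

#' Read mitogenomes from FASTA
#'
#' @param fasta path to a (multi-)FASTA file.
#' @param cds optional CDS annotation applied to every genome (see
#'   [read_cds_annotation()]); annotations are interpreted on the first
#'   (reference) genome's coordinates.
#' @return list of `mito_genome` objects.
#' @export
read_mitogenomes <- function(fasta, cds = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  lapply(seq_along(seqs), function(i)
    mito_genome(names(seqs)[i], as.character(seqs[[i]]),
                if (i == 1) cds else NULL))
}

#' Read a CDS annotation table
#'
#' Accepts either GFF3 (CDS features; `gene=` or `ID=` attribute names the
#' gene) or a headered 4-column TSV `gene`, `start`, `end`, `strand` in
#' 1-based closed coordinates. Converted to the internal 0-based half-open
#' convention.
#'
#' @param path annotation file path.
#' @return data.frame `gene`, `start`, `end`, `strand` (0-based half-open).
#' @export
read_cds_annotation <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^##gff", first) || length(strsplit(first, "\t")[[1]]) == 9) {
    g <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
    g <- g[g[[3]] == "CDS", ]
    gene <- sub(".*(?:gene|ID)=([^;]+).*", "\\1", g[[9]])
    out <- data.frame(gene = gene, start = g[[4]] - 1L, end = g[[5]],
                      strand = g[[7]], stringsAsFactors = FALSE)
  } else {
    g <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "start", "end", "strand") %in% names(g)))
    out <- data.frame(gene = g$gene, start = g$start - 1L, end = g$end,
                      strand = g$strand, stringsAsFactors = FALSE)
  }
  out
}

# internal: project pairwise alignments of each genome onto the reference
# to build a joint alignment matrix (rows = genomes, columns = alignment
# columns). Adequate at the ~1% divergence of conspecific mitogenomes.
build_alignment <- function(seqs) {
  ref <- seqs[[1]]
  L <- nchar(ref)
  # per genome: residue aligned to each ref base, and insertions keyed by
  # the ref position they follow (0 = before the first base)
  per_genome <- lapply(seqs[-1], function(s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ref), Biostrings::DNAString(s), type = "global")
    rg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sg <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    at_ref <- character(L)
    ins <- list()
    rp <- 0L
    for (k in seq_along(rg)) {
      if (rg[k] != "-") {
        rp <- rp + 1L
        at_ref[rp] <- sg[k]
      } else {
        key <- as.character(rp)
        ins[[key]] <- c(ins[[key]], sg[k])
      }
    }
    list(at_ref = at_ref, ins = ins)
  })
  ins_keys <- sort(unique(as.integer(unlist(
    lapply(per_genome, function(g) names(g$ins))))))
  ins_len <- vapply(ins_keys, function(p) {
    max(vapply(per_genome, function(g) {
      v <- g$ins[[as.character(p)]]
      if (is.null(v)) 0L else length(v)
    }, integer(1)))
  }, integer(1))
  n_cols <- L + sum(ins_len)
  aln <- matrix("-", length(seqs), n_cols)
  ref_pos <- integer(n_cols)  # 1-based ref base at the column; 0 for inserts
  col <- 0L
  emit_ins <- function(p, col) {
    where <- match(p, ins_keys)
    if (is.na(where)) return(col)
    for (j in seq_len(ins_len[where])) {
      col <- col + 1L
      ref_pos[col] <<- 0L
      aln[1, col] <<- "-"
      for (gi in seq_along(per_genome)) {
        v <- per_genome[[gi]]$ins[[as.character(p)]]
        aln[gi + 1, col] <<- if (!is.null(v) && j <= length(v)) v[j] else "-"
      }
    }
    col
  }
  col <- emit_ins(0L, col)
  ref_chars <- strsplit(ref, "")[[1]]
  for (p in seq_len(L)) {
    col <- col + 1L
    ref_pos[col] <- p
    aln[1, col] <- ref_chars[p]
    for (gi in seq_along(per_genome))
      aln[gi + 1, col] <- per_genome[[gi]]$at_ref[p]
    col <- emit_ins(p, col)
  }
  rownames(aln) <- vapply(seqs, function(s) attr(s, "id") %||% "", "")
  list(aln = aln, ref_pos = ref_pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align mitogenomes and call variants
#'
#' Aligns the competing mitogenomes (the first is the reference whose
#' coordinates anchor the annotation) and calls variant columns: columns
#' with two or more nucleotide states and no gap are SNP sites; maximal
#' runs of gap columns with a constant gap pattern are single
#' insertion/deletion events. Each SNP is assigned its partition: unique to
#' one genome (that genome differs while the others agree) or
#' `all_distinct` when all three states differ. With `prealigned = TRUE`
#' the input sequences are taken as alignment rows (equal lengths, gaps as
#' `-`), bypassing alignment.
#'
#' @param genomes list of 3 `mito_genome` objects of near-equal length
#'   (length ratios outside 0.9-1.1 are refused as non-homologous).
#' @param prealigned logical; input already aligned.
#' @return list of class `divergence_call` with `alignment` (genomes x
#'   columns character matrix), `ref_pos` (reference base per column, 0 at
#'   insertions), `variants` (data.frame: `column`, `ref_pos`, `type`,
#'   `partition`, allele columns), `snp_total`, `indel_total`, and
#'   `genomes`.
#' @export
align_and_call <- function(genomes, prealigned = FALSE) {
  if (length(genomes) != 3) stop("expected exactly 3 mitogenomes")
  ids <- vapply(genomes, function(g) g$id, "")
  seqs <- lapply(genomes, function(g) g$sequence)
  lens <- nchar(unlist(seqs))
  if (!prealigned && (min(lens) / max(lens) < 0.9))
    stop("sequence length ratio outside [0.9, 1.1]: not homologous ",
         "mitogenomes")
  if (prealigned) {
    if (length(unique(lens)) != 1)
      stop("prealigned sequences must have equal lengths")
    aln <- do.call(rbind, strsplit(toupper(unlist(seqs)), ""))
    ref_pos <- cumsum(aln[1, ] != "-")
    ref_pos[aln[1, ] == "-"] <- 0L
  } else {
    ba <- build_alignment(seqs)
    aln <- ba$aln
    ref_pos <- ba$ref_pos
  }
  rownames(aln) <- ids
  is_gap <- colSums(aln == "-") > 0
  states <- apply(aln, 2, function(x) length(unique(x)))
  snp_cols <- which(!is_gap & states >= 2)
  partition <- vapply(snp_cols, function(cc) {
    x <- aln[, cc]
    if (length(unique(x)) == 3) return("all_distinct")
    tab <- table(x)
    ids[x == names(tab)[tab == 1]]
  }, "")
  variants <- data.frame(column = snp_cols, ref_pos = ref_pos[snp_cols],
                         type = rep("snp", length(snp_cols)),
                         partition = partition, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) variants[[ids[i]]] <- aln[i, snp_cols]
  # indel events: maximal runs of gap columns with identical gap pattern
  indel_total <- 0L
  if (any(is_gap)) {
    gap_pattern <- apply(aln == "-", 2, paste, collapse = "")
    runs <- rle(ifelse(is_gap, gap_pattern, "."))
    indel_total <- sum(runs$values != ".")
  }
  structure(list(alignment = aln, ref_pos = ref_pos, variants = variants,
                 snp_total = length(snp_cols), indel_total = indel_total,
                 genomes = genomes),
            class = "divergence_call")
}

#' Classify SNPs as synonymous or nonsynonymous
#'
#' Each SNP falling inside an annotated CDS (reference coordinates) is
#' placed in its codon; the codon of every genome is reconstructed from the
#' alignment columns of the codon's three reference positions
#' (reverse-complemented for minus-strand genes) and translated under the
#' invertebrate mitochondrial genetic code (NCBI table 5). A site is
#' synonymous when all observed codon variants encode the same amino acid
#' and nonsynonymous otherwise; a variant creating a premature stop is
#' counted nonsynonymous and flagged. Codons interrupted by an alignment
#' gap are skipped with a flag.
#'
#' @param call a `divergence_call` from [align_and_call()].
#' @param cds optional CDS table overriding the reference genome's
#'   annotation.
#' @return list with `per_gene` (data.frame: `gene`, `syn`, `nonsyn`),
#'   `syn_total`, `nonsyn_total`, `site_detail` (per classified SNP:
#'   position, gene, classification, `premature_stop`, partition), and
#'   `n_skipped` (codons interrupted by gaps).
#' @export
classify_substitutions <- function(call, cds = NULL) {
  stopifnot(inherits(call, "divergence_call"))
  cds <- cds %||% call$genomes[[1]]$cds
  if (is.null(cds)) stop("no CDS annotation available")
  code <- Biostrings::getGeneticCode("5")
  aln <- call$alignment
  col_of_ref <- match(seq_len(max(call$ref_pos)), call$ref_pos)
  snps <- call$variants[call$variants$type == "snp" &
                          call$variants$ref_pos > 0, ]
  rows <- list(); n_skipped <- 0L
  for (i in seq_len(nrow(snps))) {
    p0 <- snps$ref_pos[i] - 1L  # 0-based
    g <- which(cds$start <= p0 & p0 < cds$end)
    if (length(g) == 0) next
    g <- g[1]
    offset <- p0 - cds$start[g]
    codon_idx <- offset %/% 3
    codon_ref0 <- cds$start[g] + codon_idx * 3 + 0:2  # 0-based ref positions
    cols <- col_of_ref[codon_ref0 + 1L]
    codons <- apply(aln[, cols, drop = FALSE], 1, paste, collapse = "")
    if (any(grepl("-", codons)) || anyNA(cols)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (cds$strand[g] == "-")
      codons <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(codons)))
    aas <- code[codons]
    is_last_codon <- codon_idx == (cds$end[g] - cds$start[g]) %/% 3 - 1
    premature_stop <- any(aas == "*", na.rm = TRUE) && !is_last_codon
    classification <- if (length(unique(aas)) > 1 || premature_stop)
      "nonsynonymous" else "synonymous"
    rows[[length(rows) + 1]] <- data.frame(
      ref_pos = snps$ref_pos[i], gene = cds$gene[g],
      classification = classification, premature_stop = premature_stop,
      partition = snps$partition[i], stringsAsFactors = FALSE)
  }
  detail <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_pos = integer(), gene = character(),
               classification = character(), premature_stop = logical(),
               partition = character())
  if (any(detail$premature_stop))
    warning("premature stop codon introduced at position(s): ",
            paste(detail$ref_pos[detail$premature_stop], collapse = ", "))
  per_gene <- do.call(rbind, lapply(unique(cds$gene), function(gn) {
    d <- detail[detail$gene == gn, ]
    data.frame(gene = gn, syn = sum(d$classification == "synonymous"),
               nonsyn = sum(d$classification == "nonsynonymous"))
  }))
  list(per_gene = per_gene,
       syn_total = sum(detail$classification == "synonymous"),
       nonsyn_total = sum(detail$classification == "nonsynonymous"),
       site_detail = detail, n_skipped = n_skipped)
}

#' Pairwise nucleotide diversity between aligned mitogenomes
#'
#' \eqn{\pi(a, b)} is the proportion of differing sites among aligned
#' columns where neither genome has a gap, over the whole alignment or the
#' annotated protein-coding genes only.
#'
#' @param call a `divergence_call` from [align_and_call()].
#' @param region `"whole"` (default) or `"pcg_only"`.
#' @param cds optional CDS table for `region = "pcg_only"`.
#' @return data.frame with `genome1`, `genome2`, `pi`, `n_sites`.
#' @export
pairwise_pi <- function(call, region = c("whole", "pcg_only"), cds = NULL) {
  stopifnot(inherits(call, "divergence_call"))
  region <- match.arg(region)
  aln <- call$alignment
  keep <- rep(TRUE, ncol(aln))
  if (region == "pcg_only") {
    cds <- cds %||% call$genomes[[1]]$cds
    if (is.null(cds)) stop("no CDS annotation for pcg_only region")
    in_cds <- vapply(call$ref_pos, function(p)
      p > 0 && any(cds$start <= p - 1 & p - 1 < cds$end), logical(1))
    keep <- in_cds
  }
  if (!any(keep)) stop("empty region")
  ids <- rownames(aln)
  rows <- list()
  for (i in 1:(nrow(aln) - 1)) for (j in (i + 1):nrow(aln)) {
    ok <- keep & aln[i, ] != "-" & aln[j, ] != "-"
    rows[[length(rows) + 1]] <- data.frame(
      genome1 = ids[i], genome2 = ids[j],
      pi = sum(aln[i, ok] != aln[j, ok]) / sum(ok),
      n_sites = sum(ok), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
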