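# Independent oracles and toy-data builders shared across tests.

# standard genetic code, hand-typed as the classic 64-codon string over
# codons enumerated T/C/A/G most-significant first (independent of the
# implementation's translation path)
.AA64 <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
.CODONS64 <- as.vector(t(outer(
  as.vector(t(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0))),
  c("T", "C", "A", "G"), paste0)))
CODON_TABLE <- setNames(strsplit(.AA64, "")[[1]], .CODONS64)

oracle_translate <- function(cds) {
  n <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# naive all-offsets substring scan
oracle_motif_scan <- function(protein, motif) {
  w <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(max(0L, nchar(protein) - w + 1L)))
    if (substr(protein, i, i + w - 1L) == motif) hits <- c(hits, i)
  hits
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# single-gene model set: flank | exon1(utr5 + cds head) [| intron | exon2
# (cds tail + utr3)] | flank, laid out on the requested strand
make_toy_set <- function(cds_seq, strand = "+", utr5 = 6, utr3 = 6,
                         intron_after = NULL, intron_len = 30, flank = 12,
                         gene_id = "toy1", chrom = "toyChr") {
  if (is.null(intron_after)) {
    exon_seqs <- list(paste0(random_dna(utr5), cds_seq, random_dna(utr3)))
    cds_off <- list(c(utr5, utr5 + nchar(cds_seq)))
  } else {
    head_ <- substr(cds_seq, 1, intron_after)
    tail_ <- substr(cds_seq, intron_after + 1, nchar(cds_seq))
    exon_seqs <- list(paste0(random_dna(utr5), head_),
                      paste0(tail_, random_dna(utr3)))
    cds_off <- list(c(utr5, utr5 + nchar(head_)), c(0, nchar(tail_)))
  }
  pos <- flank
  exons <- cds <- data.frame(start0 = integer(0), end0 = integer(0))
  contig <- random_dna(flank)
  for (i in seq_along(exon_seqs)) {
    exons <- rbind(exons, data.frame(start0 = pos,
                                     end0 = pos + nchar(exon_seqs[[i]])))
    cds <- rbind(cds, data.frame(start0 = pos + cds_off[[i]][1],
                                 end0 = pos + cds_off[[i]][2]))
    contig <- paste0(contig, exon_seqs[[i]])
    pos <- pos + nchar(exon_seqs[[i]])
    if (i < length(exon_seqs)) {
      contig <- paste0(contig, random_dna(intron_len))
      pos <- pos + intron_len
    }
  }
  span <- c(flank, pos)
  contig <- paste0(contig, random_dna(flank))
  L <- nchar(contig)
  if (strand == "-") {
    contig <- oracle_revcomp(contig)
    flip <- function(iv) {
      out <- data.frame(start0 = L - iv$end0, end0 = L - iv$start0)
      out[order(out$start0), ]
    }
    exons <- flip(exons); cds <- flip(cds)
    span <- c(L - span[2], L - span[1])
  }
  genome <- Biostrings::DNAStringSet(setNames(contig, chrom))
  m <- gene_model(gene_id, chrom, strand, span, exons, cds)
  structure(list(models = setNames(list(m), gene_id), genome = genome),
            class = "gene_model_set")
}

# CDS of n codons with specific codons planted at given indices
planted_cds <- function(n_codons, plant = list()) {
  codons <- rep("GCT", n_codons)
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  for (i in names(plant)) codons[as.integer(i)] <- plant[[i]]
  paste(codons, collapse = "")
}

# write a small GFF3 + FASTA pair for loader tests
write_toy_gff_fasta <- function(dir, strand = "+") {
  # 2-exon gene, CDS 30 bp (18 + 12), intron 10 bp, on a 100 bp contig
  cds <- planted_cds(10)
  head_ <- substr(cds, 1, 18); tail_ <- substr(cds, 19, 30)
  contig <- paste0(strrep("A", 10), head_, strrep("C", 10), tail_,
                   strrep("A", 50))
  if (strand == "-") contig <- oracle_revcomp(contig)
  fa <- file.path(dir, "toy.fa"); gff <- file.path(dir, "toy.gff3")
  writeLines(c(">toyChr", contig), fa)
  g <- function(type, s, e, attr, phase = ".")
    sprintf("toyChr\ttest\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            type, s, e, strand, phase, attr)
  if (strand == "+") {
    ex <- list(c(11, 28), c(39, 50))
  } else {
    ex <- list(c(51, 62), c(73, 90))  # flipped on a 100 bp contig
  }
  writeLines(c(
    "##gff-version 3",
    g("gene", min(ex[[1]][1], ex[[2]][1]), max(ex[[1]][2], ex[[2]][2]),
      "ID=toyG"),
    g("mRNA", min(ex[[1]][1], ex[[2]][1]), max(ex[[1]][2], ex[[2]][2]),
      "ID=toyG.1;Parent=toyG"),
    g("exon", ex[[1]][1], ex[[1]][2], "ID=e1;Parent=toyG.1"),
    g("exon", ex[[2]][1], ex[[2]][2], "ID=e2;Parent=toyG.1"),
    g("CDS", ex[[1]][1], ex[[1]][2], "ID=c1;Parent=toyG.1", "0"),
    g("CDS", ex[[2]][1], ex[[2]][2], "ID=c1;Parent=toyG.1", "0")
  ), gff)
  list(fasta = fa, gff3 = gff, cds = cds)
}
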