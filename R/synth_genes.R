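# Synthetic gene models shaped like the screened sucrose synthase family:
# CDS of 2409-2766 bp split over 12-15 exons, short UTRs on the terminal
# exons, introns of a few hundred bp, genes on both strands, one contig per
# gene. Used to exercise the pipeline without shipping reference annotation.

.NONSTOP_CODONS <- local({
  all <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                               paste0), c("T", "C", "A", "G"), paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

random_bases <- function(n) {
  paste(sample(.DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic gene model set
#'
#' Builds `n_genes` gene models with the exon/CDS architecture of a plant
#' gene family screened by capture sequencing: CDS length drawn from
#' `cds_bp_range` (in whole codons, ATG start, single stop, no internal
#' stops), `exon_range` exons, introns of `intron_bp_range` bp, 60/90 bp
#' 5'/3' UTRs on the terminal exons, and alternating +/- strands. Each gene
#' sits on its own contig with 300 bp flanks.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param cds_bp_range Length-2 range of CDS sizes (bp; rounded to codons).
#' @param exon_range Length-2 range of exon counts.
#' @param intron_bp_range Length-2 range of intron sizes (bp).
#'
#' @return A `gene_model_set` (same container as [load_gene_models()]).
#' @export
#' @examples
#' gs <- synthesize_gene_set(2, seed = 7)
#' gs$models[[1]]
synthesize_gene_set <- function(n_genes = 10, seed = 1L,
                                cds_bp_range = c(2409, 2766),
                                exon_range = c(12, 15),
                                intron_bp_range = c(100, 400)) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  flank <- 300L; utr5 <- 60L; utr3 <- 90L
  models <- vector("list", n_genes)
  seqs <- character(n_genes)
  chroms <- sprintf("chr%02d", seq_len(n_genes))
  ids <- sprintf("SynGene.%02dG%03d00", seq_len(n_genes),
                 sample(100:999, n_genes))

  for (g in seq_len(n_genes)) {
    n_codon <- sample(seq(ceiling(cds_bp_range[1] / 3),
                          floor(cds_bp_range[2] / 3)), 1L)
    cds_seq <- paste0("ATG",
                      paste(sample(.NONSTOP_CODONS, n_codon - 2L,
                                   replace = TRUE), collapse = ""),
                      "TAA")
    cds_len <- nchar(cds_seq)
    n_ex <- sample(seq(exon_range[1], exon_range[2]), 1L)
    cuts <- sort(sample(seq_len(cds_len - 1L), n_ex - 1L))
    part_len <- diff(c(0L, cuts, cds_len))
    introns <- sample(seq(intron_bp_range[1], intron_bp_range[2]),
                      n_ex - 1L, replace = TRUE)

    # lay the gene out on the plus strand of its contig
    pos <- flank
    exon_iv <- cds_iv <- data.frame(start0 = integer(0), end0 = integer(0))
    pieces <- random_bases(flank)
    cds_used <- 0L
    for (e in seq_len(n_ex)) {
      lead <- if (e == 1L) utr5 else 0L
      trail <- if (e == n_ex) utr3 else 0L
      cds_part <- substr(cds_seq, cds_used + 1L, cds_used + part_len[e])
      cds_used <- cds_used + part_len[e]
      ex_seq <- paste0(if (lead) random_bases(lead) else "",
                       cds_part,
                       if (trail) random_bases(trail) else "")
      exon_iv <- rbind(exon_iv,
                       data.frame(start0 = pos, end0 = pos + nchar(ex_seq)))
      cds_iv <- rbind(cds_iv,
                      data.frame(start0 = pos + lead,
                                 end0 = pos + lead + part_len[e]))
      pieces <- paste0(pieces, ex_seq)
      pos <- pos + nchar(ex_seq)
      if (e < n_ex) {
        pieces <- paste0(pieces, random_bases(introns[e]))
        pos <- pos + introns[e]
      }
    }
    span <- c(flank, pos)
    pieces <- paste0(pieces, random_bases(flank))
    L <- nchar(pieces)
    strand <- if (g %% 2L == 1L) "+" else "-"
    if (strand == "-") {
      # flip the contig so the coding strand becomes the minus strand
      pieces <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(pieces)))
      flip <- function(iv) {
        out <- data.frame(start0 = L - iv$end0, end0 = L - iv$start0)
        out[order(out$start0), ]
      }
      exon_iv <- flip(exon_iv); cds_iv <- flip(cds_iv)
      span <- c(L - span[2], L - span[1])
    }
    seqs[g] <- pieces
    models[[g]] <- gene_model(ids[g], chroms[g], strand, span,
                              exon_iv, cds_iv)
  }
  genome <- Biostrings::DNAStringSet(setNames(seqs, chroms))
  names(models) <- ids
  models <- models[order(names(models))]
  structure(list(models = models, genome = genome), class = "gene_model_set")
}

#' Serialize a gene model set to FASTA + GFF3
#'
#' Writes the genome as FASTA and the gene/mRNA/exon/CDS features as GFF3
#' (1-based inclusive coordinates, CDS phase computed in coding order), so a
#' synthetic gene set can be reloaded with [load_gene_models()].
#'
#' @param gene_set A `gene_model_set`.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, `c(fasta_path, gff3_path)`.
#' @export
write_gene_set <- function(gene_set, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(gene_set$genome, fasta_path, width = 80L)
  lines <- c("##gff-version 3")
  for (m in gene_set$models) {
    gid <- m$gene_id; tid <- paste0(gid, ".1")
    row <- function(type, s0, e0, phase, attr)
      sprintf("%s\ttbysim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              m$chrom, type, as.integer(s0) + 1L, as.integer(e0),
              m$strand, phase, attr)
    lines <- c(lines,
               row("gene", m$span[1], m$span[2], ".", paste0("ID=", gid)),
               row("mRNA", m$span[1], m$span[2], ".",
                   paste0("ID=", tid, ";Parent=", gid)))
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, row("exon", m$exons$start0[i], m$exons$end0[i], ".",
                            paste0("ID=", tid, ".exon", i, ";Parent=", tid)))
    cds <- m$cds
    ord <- if (m$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    cum <- 0L
    phases <- integer(nrow(cds))
    for (i in ord) {
      phases[i] <- (3L - cum %% 3L) %% 3L
      cum <- cum + (cds$end0[i] - cds$start0[i])
    }
    for (i in seq_len(nrow(cds)))
      lines <- c(lines, row("CDS", cds$start0[i], cds$end0[i], phases[i],
                            paste0("ID=", tid, ".cds;Parent=", tid)))
  }
  writeLines(lines, gff3_path)
  invisible(c(fasta_path, gff3_path))
}
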