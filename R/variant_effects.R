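# Codon-level classification of induced SNPs.
#
# Change notation follows the screening convention: the CDS change
# "<ref><cds_pos><alt>" is spelled on the coding strand at the 1-based CDS
# coordinate (e.g. G746A), the amino-acid change "<refAA><codon><altAA>"
# uses '*' for stop (e.g. G249E, G486*). Base-change *tabulation* (G>A
# etc.), in contrast, uses plus-strand spelling: that is what a VCF records
# and what screen summaries aggregate across genes on both strands.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

#' Classify a SNP against a gene model
#'
#' Maps a plus-strand SNP to its CDS coordinate (strand-aware), rebuilds the
#' reference and alternate codons, and classifies the change as `missense`,
#' `nonsense`, `silent` or `noncoding` (outside the CDS). Codons containing
#' ambiguous bases translate to `X` and are returned as `unclassified`.
#'
#' @param model A [gene_model].
#' @param genome Genome accessor.
#' @param pos 1-based genomic position.
#' @param ref,alt Plus-strand reference and alternate base; `ref` must match
#'   the genome.
#' @param cds_seq Optional pre-spliced coding-strand CDS (a cache for
#'   repeated calls on one gene).
#'
#' @return List of class `effect_annotation`: `effect_class`, `cds_change`,
#'   `aa_change`, `codon_index`, `cds_pos` (the latter four `NA` for
#'   noncoding sites).
#' @export
classify_snp <- function(model, genome, pos, ref, alt, cds_seq = NULL) {
  pos0 <- pos - 1L
  b <- genome_seq(genome, model$chrom, pos0, pos0 + 1L)
  if (b != ref)
    stop("reference mismatch at ", model$chrom, ":", pos,
         ": genome has ", b, ", input says ", ref)
  if (ref == alt) stop("ref and alt are identical")

  hit <- which(model$cds$start0 <= pos0 & pos0 < model$cds$end0)
  if (!length(hit)) {
    return(structure(list(effect_class = "noncoding", cds_change = NA,
                          aa_change = NA, codon_index = NA, cds_pos = NA),
                     class = "effect_annotation"))
  }
  widths <- model$cds$end0 - model$cds$start0
  plus_offset <- sum(widths[seq_len(hit - 1L)]) + (pos0 - model$cds$start0[hit])
  L <- sum(widths)
  if (model$strand == "+") {
    cds_pos <- plus_offset + 1L
    cref <- ref; calt <- alt
  } else {
    cds_pos <- L - plus_offset
    cref <- unname(.COMPLEMENT[ref]); calt <- unname(.COMPLEMENT[alt])
  }
  if (is.null(cds_seq)) cds_seq <- spliced_cds(model, genome)
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  cp <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substr(cds_seq, 3L * codon_index - 2L, 3L * codon_index)
  if (substr(ref_codon, cp, cp) != cref)
    stop("internal inconsistency: CDS base at ", cds_pos, " of ",
         model$gene_id, " is not ", cref)
  alt_codon <- ref_codon
  substr(alt_codon, cp, cp) <- calt
  ref_aa <- unname(codon_aa(ref_codon))
  alt_aa <- unname(codon_aa(alt_codon))
  effect <-
    if (ref_aa == "X" || alt_aa == "X") "unclassified"
    else if (ref_aa == alt_aa) "silent"
    else if (alt_aa == "*") "nonsense"
    else "missense"
  structure(list(
    effect_class = effect,
    cds_change = paste0(cref, cds_pos, calt),
    aa_change = paste0(ref_aa, codon_index, alt_aa),
    codon_index = codon_index, cds_pos = cds_pos
  ), class = "effect_annotation")
}

#' @export
print.effect_annotation <- function(x, ...) {
  if (x$effect_class == "noncoding")
    cat("<effect_annotation> noncoding\n")
  else
    cat("<effect_annotation> ", x$effect_class, "  ", x$cds_change, " / ",
        x$aa_change, "\n", sep = "")
  invisible(x)
}

# assign each unique variant to the gene whose span contains it
assign_genes <- function(variants, models) {
  gene <- rep(NA_character_, nrow(variants))
  for (m in models) {
    sel <- is.na(gene) & variants$chrom == m$chrom &
      variants$pos - 1L >= m$span[1] & variants$pos - 1L < m$span[2]
    gene[sel] <- m$gene_id
  }
  gene
}

#' Annotate variants with gene and effect
#'
#' Classifies every unique (locus, alt) of a truth or call table against the
#' gene models. Variants outside every gene span are reported with
#' `gene_id = "unassigned"` and effect `noncoding`.
#'
#' @param variants `data.frame` with `chrom`, `pos`, `ref`, `alt` (extra
#'   columns ignored).
#' @param gene_set A `gene_model_set`.
#'
#' @return One row per unique variant: `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `effect_class`, `cds_change`, `aa_change`, `codon_index`.
#' @export
annotate_variants <- function(variants, gene_set) {
  v <- variants[!duplicated(paste(variants$chrom, variants$pos,
                                  variants$alt)),
                c("chrom", "pos", "ref", "alt")]
  v <- v[order(v$chrom, v$pos, v$alt), ]
  rownames(v) <- NULL
  v$gene_id <- assign_genes(v, gene_set$models)
  v$effect_class <- "noncoding"
  v$cds_change <- v$aa_change <- NA_character_
  v$codon_index <- NA_integer_
  for (gid in unique(v$gene_id[!is.na(v$gene_id)])) {
    m <- gene_set$models[[gid]]
    cds_seq <- spliced_cds(m, gene_set$genome)
    for (i in which(v$gene_id == gid)) {
      ann <- classify_snp(m, gene_set$genome, v$pos[i], v$ref[i], v$alt[i],
                          cds_seq = cds_seq)
      v$effect_class[i] <- ann$effect_class
      if (ann$effect_class != "noncoding") {
        v$cds_change[i] <- ann$cds_change
        v$aa_change[i] <- ann$aa_change
        v$codon_index[i] <- ann$codon_index
      }
    }
  }
  v$gene_id[is.na(v$gene_id)] <- "unassigned"
  v
}

#' Tabulate base-change types and effect classes per gene
#'
#' Counts are per unique (line, locus, alt) event. Base-change typing
#' (`G>A`, `C>T`, other) uses plus-strand spelling of ref/alt; effect
#' classes come from [classify_snp()]. Every gene of the model set appears,
#' including genes with zero events; variants in no gene are counted under
#' `unassigned`.
#'
#' @param truth Carrier-level variant table (`line_id`, `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param gene_set A `gene_model_set`.
#'
#' @return `data.frame` with one row per gene: `gene_id`, `base_changes`,
#'   `g_to_a`, `c_to_t`, `other`, `missense`, `nonsense`, `silent`,
#'   `noncoding`, `unclassified`.
#' @export
tabulate_effects <- function(truth, gene_set) {
  gene_ids <- names(gene_set$models)
  zero <- data.frame(gene_id = gene_ids, base_changes = 0L, g_to_a = 0L,
                     c_to_t = 0L, other = 0L, missense = 0L, nonsense = 0L,
                     silent = 0L, noncoding = 0L, unclassified = 0L,
                     stringsAsFactors = FALSE)
  if (!nrow(truth)) return(zero)
  ann <- annotate_variants(truth, gene_set)
  ev <- merge(truth, ann, by = c("chrom", "pos", "ref", "alt"))
  count_effect_events(ev, zero)
}

# ev: one row per (line, locus, alt) event with ref/alt/gene_id/effect_class
count_effect_events <- function(ev, zero) {
  ev$change <- paste0(ev$ref, ">", ev$alt)
  tab <- lapply(split(ev, ev$gene_id), function(d) {
    data.frame(
      gene_id = d$gene_id[1], base_changes = nrow(d),
      g_to_a = sum(d$change == "G>A"), c_to_t = sum(d$change == "C>T"),
      other = sum(!d$change %in% c("G>A", "C>T")),
      missense = sum(d$effect_class == "missense"),
      nonsense = sum(d$effect_class == "nonsense"),
      silent = sum(d$effect_class == "silent"),
      noncoding = sum(d$effect_class == "noncoding"),
      unclassified = sum(d$effect_class == "unclassified"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  out <- rbind(tab, zero[!zero$gene_id %in% tab$gene_id, ])
  extra <- out$gene_id == "unassigned"
  out <- rbind(out[!extra, ][order(out$gene_id[!extra]), ], out[extra, ])
  rownames(out) <- NULL
  out
}

#' Write annotated variants as VCF and TSV
#'
#' VCF 4.2 with INFO keys `GENE`, `EFF`, `CDSCHG`, `AACHG`; the TSV mirror
#' holds the same columns flat.
#'
#' @param annotated An [annotate_variants()] table.
#' @param vcf_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_annotated <- function(annotated, vcf_path = NULL, tsv_path = NULL) {
  if (!is.null(tsv_path))
    write.table(annotated, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(vcf_path)) {
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=tbysim_effects",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
      "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect class\">",
      "##INFO=<ID=CDSCHG,Number=1,Type=String,Description=\"CDS change\">",
      "##INFO=<ID=AACHG,Number=1,Type=String,Description=\"Amino acid change\">",
      if (nrow(annotated)) sprintf("##contig=<ID=%s>",
                                   unique(annotated$chrom)),
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    rec <- if (nrow(annotated)) sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tGENE=%s;EFF=%s;CDSCHG=%s;AACHG=%s",
      annotated$chrom, annotated$pos, annotated$ref, annotated$alt,
      annotated$gene_id, annotated$effect_class,
      ifelse(is.na(annotated$cds_change), ".", annotated$cds_change),
      ifelse(is.na(annotated$aa_change), ".", annotated$aa_change)
    ) else character(0)
    writeLines(c(hdr, rec), vcf_path)
  }
  invisible(c(vcf_path, tsv_path))
}
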