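#' @importFrom stats rbinom rpois runif setNames aggregate pbinom
#' @importFrom utils read.delim write.table head
NULL

# ---- gene model container ---------------------------------------------------
# Internal coordinates are 0-based half-open; GFF3 I/O converts from/to
# 1-based inclusive. All length arithmetic is then end0 - start0.

#' Construct a gene model
#'
#' A gene model holds the gene span, ordered exon list and ordered CDS list of
#' one gene, on one strand. Coordinates are 0-based half-open internally.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param span Numeric length-2 vector `c(start0, end0)` of the gene span.
#' @param exons `data.frame` with columns `start0`, `end0`, one row per exon.
#' @param cds `data.frame` with columns `start0`, `end0`, one row per CDS part.
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, span, exons, cds) {
  stopifnot(is.character(gene_id), nzchar(gene_id), nzchar(chrom))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- exons[order(exons$start0), , drop = FALSE]
  cds <- cds[order(cds$start0), , drop = FALSE]
  if (any(exons$end0 <= exons$start0) || any(cds$end0 <= cds$start0))
    stop("gene ", gene_id, ": empty or inverted interval")
  if (nrow(exons) > 1 && any(exons$start0[-1] < exons$end0[-nrow(exons)]))
    stop("gene ", gene_id, ": overlapping exons")
  if (any(exons$start0 < span[1] | exons$end0 > span[2]))
    stop("gene ", gene_id, ": exon outside gene span [",
         span[1], ", ", span[2], ")")
  # every CDS part must lie inside one exon
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds$start0[i] >= exons$start0 & cds$end0[i] <= exons$end0)
    if (!inside)
      stop("gene ", gene_id, ": CDS [", cds$start0[i], ", ", cds$end0[i],
           ") not contained in any exon")
  }
  if (cds_length(cds) %% 3L != 0L)
    warning("gene ", gene_id, ": CDS length ", cds_length(cds),
            " not divisible by 3")
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         span = as.numeric(span), exons = exons, cds = cds),
    class = "gene_model"
  )
}

cds_length <- function(cds) {
  if (inherits(cds, "gene_model")) cds <- cds$cds
  as.integer(sum(cds$end0 - cds$start0))
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, "  ", x$chrom, ":", x$span[1] + 1, "-",
      x$span[2], " (", x$strand, ")\n", sep = "")
  cat("  exons: ", nrow(x$exons),
      "  CDS: ", cds_length(x), " bp\n", sep = "")
  invisible(x)
}

# ---- genome accessor --------------------------------------------------------

genome_seq <- function(genome, chrom, start0, end0) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in the genome")
  as.character(Biostrings::subseq(genome[[chrom]], start0 + 1L, end0))
}

# coding-strand CDS sequence of a model (spliced, reverse-complemented for -)
spliced_cds <- function(model, genome) {
  parts <- vapply(
    seq_len(nrow(model$cds)),
    function(i) genome_seq(genome, model$chrom,
                           model$cds$start0[i], model$cds$end0[i]),
    character(1)
  )
  s <- paste(parts, collapse = "")
  if (model$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# ---- GFF3 + FASTA loading ---------------------------------------------------

#' Load gene models from GFF3 and genome FASTA
#'
#' Parses gene/mRNA/exon/CDS features from a GFF3 file into [gene_model]
#' objects and loads the genome. Multi-isoform genes are represented by their
#' longest annotated CDS. GFF3 1-based inclusive coordinates are converted to
#' the internal 0-based half-open convention; FASTA sequence is uppercased on
#' load.
#'
#' @param gff3_path Path to a GFF3 file with gene, mRNA (or transcript), exon
#'   and CDS features.
#' @param fasta_path Path to the genome FASTA; must contain every chromosome
#'   referenced by the GFF3.
#'
#' @return A list of class `gene_model_set` with elements `models` (named list
#'   of [gene_model], ordered by gene id) and `genome` (a
#'   [Biostrings::DNAStringSet]).
#' @export
load_gene_models <- function(gff3_path, fasta_path) {
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))

  feat <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gff)),
    start0 = GenomicRanges::start(gff) - 1L,
    end0 = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    type = as.character(gff$type),
    id = if (is.null(gff$ID)) NA_character_ else as.character(gff$ID),
    stringsAsFactors = FALSE
  )
  feat$parent <- vapply(
    if (is.null(gff$Parent)) replicate(nrow(feat), character(0), simplify = FALSE)
    else as.list(gff$Parent),
    function(p) if (length(p)) p[[1]] else NA_character_, character(1)
  )

  missing_chrom <- setdiff(unique(feat$chrom), names(genome))
  if (length(missing_chrom))
    stop("GFF3 references chromosome(s) absent from the FASTA: ",
         paste(missing_chrom, collapse = ", "))

  genes <- feat[feat$type == "gene", , drop = FALSE]
  if (!nrow(genes)) stop("no gene features in ", gff3_path)
  tx <- feat[feat$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx2gene <- setNames(tx$parent, tx$id)

  models <- lapply(seq_len(nrow(genes)), function(g) {
    gid <- genes$id[g]
    tids <- tx$id[tx$parent == gid]
    if (!length(tids))
      stop("gene ", gid, ": no mRNA/transcript children in the GFF3")
    cds_by_tx <- lapply(tids, function(t)
      feat[feat$type == "CDS" & feat$parent == t, , drop = FALSE])
    lens <- vapply(cds_by_tx, function(d) sum(d$end0 - d$start0), numeric(1))
    pick <- which.max(lens)  # longest CDS isoform; first on ties
    exons <- feat[feat$type == "exon" & feat$parent == tids[pick], , drop = FALSE]
    gene_model(
      gene_id = gid, chrom = genes$chrom[g], strand = genes$strand[g],
      span = c(genes$start0[g], genes$end0[g]),
      exons = exons[, c("start0", "end0")],
      cds = cds_by_tx[[pick]][, c("start0", "end0")]
    )
  })
  names(models) <- genes$id
  models <- models[order(names(models))]
  structure(list(models = models, genome = genome), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("<gene_model_set> ", length(x$models), " gene(s), ",
      length(x$genome), " sequence(s)\n", sep = "")
  for (m in x$models) print(m)
  invisible(x)
}

# ---- translation ------------------------------------------------------------

#' Translate the CDS of a gene model
#'
#' Splices the CDS parts, reverse-complements minus-strand genes, and
#' translates with the standard nuclear genetic code. Codons containing
#' ambiguous bases translate to `X`.
#'
#' @param model A [gene_model].
#' @param genome The genome accessor returned by [load_gene_models()] (a
#'   `DNAStringSet`), or any named sequence set containing `model$chrom`.
#'
#' @return Amino-acid string, `*` marking stop codons. An internal stop before
#'   the final codon raises a warning but the translation is still returned.
#' @export
translate_cds <- function(model, genome) {
  s <- spliced_cds(model, genome)
  if (nchar(s) %% 3L != 0L)
    stop("CDS length ", nchar(s), " of ", model$gene_id,
         " is not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "solve"))
  internal <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", internal, fixed = TRUE))
    warning("internal stop codon in ", model$gene_id)
  aa
}

# ---- protein properties -----------------------------------------------------

protein_net_charge <- function(ph, counts) {
  pos <- c(Nterm = 1, counts[c("K", "R", "H")])
  neg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  sum(pos * 1 / (1 + 10^(ph - .PKA_POSITIVE))) -
    sum(neg * 1 / (1 + 10^(.PKA_NEGATIVE - ph)))
}

#' Molecular weight and isoelectric point of a protein
#'
#' Molecular weight is the sum of average residue masses plus one water mass,
#' reported in kDa. The isoelectric point is found by bisection on the net
#' charge as a function of pH, using the EMBOSS pKa set (see
#' [tbysim-constants]). Different pKa sets give pI values differing by a few
#' tenths of a unit; the set used here is fixed for reproducibility.
#'
#' @param protein Amino-acid string of the 20 standard residues (no `*`).
#'
#' @return List with elements `mol_wt` (kDa) and `pI`.
#' @export
#' @examples
#' compute_protein_properties("MGRK")
compute_protein_properties <- function(protein) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    stop("protein must be a non-empty amino-acid string")
  aa <- strsplit(protein, "")[[1]]
  bad <- unique(aa[!aa %in% names(.RESIDUE_MASS)])
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  counts <- setNames(numeric(20), names(.RESIDUE_MASS))
  tab <- table(aa)
  counts[names(tab)] <- as.numeric(tab)
  mw <- (sum(counts * .RESIDUE_MASS) + .WATER_MASS) / 1000

  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(mid, counts) > 0) lo <- mid else hi <- mid
  }
  list(mol_wt = mw, pI = (lo + hi) / 2)
}

# ---- conserved motif scan ---------------------------------------------------

#' Scan a protein for conserved motifs
#'
#' Exact substring scan reporting every occurrence, including overlapping
#' ones. The default motif set contains residues conserved across plant
#' sucrose synthase enzymes ([tbys_conserved_motifs()]).
#'
#' @param protein Amino-acid string.
#' @param motifs Character vector of residue motifs (exact match).
#'
#' @return `data.frame` with columns `motif` and `start` (1-based); zero rows
#'   when nothing matches.
#' @export
#' @examples
#' scan_conserved_motifs("AAAPDTGGQAAA")
scan_conserved_motifs <- function(protein, motifs = tbys_conserved_motifs()) {
  stopifnot(is.character(protein), length(protein) == 1L)
  hits <- lapply(motifs, function(m) {
    # lookahead so overlapping occurrences are all reported
    p <- gregexpr(paste0("(?=", m, ")"), protein, perl = TRUE)[[1]]
    if (p[1] == -1L) integer(0) else as.integer(p)
  })
  data.frame(
    motif = rep(motifs, lengths(hits)),
    start = unlist(hits, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# ---- family table -----------------------------------------------------------

#' Read a gene-family metrics table
#'
#' Reads a TSV with one row per family member: `gene_id`, `gene_length` (bp),
#' `cds_length` (bp), `exon_count`, `protein_length` (aa), `pI`, `mol_wt`
#' (kDa). Protein length is checked against `cds_length/3 - 1` (stop codon
#' excluded) with a tolerance of 1 aa, reflecting rounding in published
#' tables; violations beyond that are a warning, not an error.
#'
#' @param path TSV path.
#' @return `data.frame` of class `family_table`.
#' @export
read_family_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "gene_length", "cds_length", "exon_count",
            "protein_length", "pI", "mol_wt")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("family table missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$gene_length < tab$cds_length))
    stop("gene_length < cds_length for: ",
         paste(tab$gene_id[tab$gene_length < tab$cds_length], collapse = ", "))
  off <- abs(tab$protein_length - (tab$cds_length / 3 - 1)) > 1
  if (any(off))
    warning("protein_length deviates from cds_length/3 - 1 by >1 aa for: ",
            paste(tab$gene_id[off], collapse = ", "))
  class(tab) <- c("family_table", "data.frame")
  tab
}

#' Summarise a gene family
#'
#' Min, max and mean of CDS and gene length plus the exon-count range. The
#' CDS mean is reported to one decimal, the gene-length mean rounded to the
#' nearest integer; unrounded means are kept in `*_mean_raw`.
#'
#' @param table A family table ([read_family_table()] or an equivalent
#'   `data.frame`).
#' @return List of class `family_summary`.
#' @export
family_summary <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("family table is empty")
  cds <- table$cds_length
  gl <- table$gene_length
  structure(list(
    n = nrow(table),
    cds_min = min(cds), cds_max = max(cds),
    cds_mean_raw = mean(cds), cds_mean = round(mean(cds), 1),
    gene_min = min(gl), gene_max = max(gl),
    gene_mean_raw = mean(gl), gene_mean = round(mean(gl)),
    exon_range = range(table$exon_count)
  ), class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat("<family_summary> ", x$n, " genes\n", sep = "")
  cat("  CDS length (bp):  ", x$cds_min, "-", x$cds_max,
      ", mean ", x$cds_mean, "\n", sep = "")
  cat("  gene length (bp): ", x$gene_min, "-", x$gene_max,
      ", mean ", x$gene_mean, "\n", sep = "")
  cat("  exons per gene:   ", x$exon_range[1], "-", x$exon_range[2], "\n",
      sep = "")
  invisible(x)
}

#' Write a family summary as TSV
#'
#' Column order is fixed: `metric`, `min`, `max`, `mean` with one row each for
#' `cds_length`, `gene_length` and `exon_count` (exon mean left blank).
#'
#' @param x A `family_summary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_family_summary <- function(x, path) {
  out <- data.frame(
    metric = c("cds_length", "gene_length", "exon_count"),
    min = c(x$cds_min, x$gene_min, x$exon_range[1]),
    max = c(x$cds_max, x$gene_max, x$exon_range[2]),
    mean = c(x$cds_mean, x$gene_mean, NA)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
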