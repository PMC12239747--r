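# Synthetic EMS-mutagenized M2 population.
#
# The generator emulates the statistical structure a TbyS screen assumes:
# the EMS substitution spectrum (~80% canonical G:C->A:T transitions), a
# per-line mutation density calibrated to the screen scale, M2 zygosity from
# selfing of heterozygous M1 plants (carrier-conditioned 1 hom : 2 het), and
# plate/well placement of lines in 96-well plates.

#' EMS mutation spectrum
#'
#' Probabilities for the 12 directed substitution classes (`A>C` ... `T>G`).
#' `ems_spectrum()` builds the default EMS spectrum: a canonical-transition
#' mass split equally between `G>A` and `C>T`, with the remainder spread
#' uniformly over the other ten classes. `mutation_spectrum()` validates an
#' arbitrary spectrum.
#'
#' @param probs Named numeric vector over the 12 directed classes; must be
#'   non-negative and sum to 1 (tolerance 1e-9).
#' @param canonical_mass Total probability of `G>A` plus `C>T` (default 0.8,
#'   the canonical EMS share).
#'
#' @return Named numeric vector of class `mutation_spectrum`.
#' @export
#' @examples
#' s <- ems_spectrum()
#' sum(s[c("G>A", "C>T")])
mutation_spectrum <- function(probs) {
  if (!all(sort(names(probs)) == sort(.SUB_CLASSES)))
    stop("spectrum must name exactly the 12 directed substitution classes")
  probs <- probs[.SUB_CLASSES]
  if (any(probs < 0)) stop("spectrum probabilities must be >= 0")
  if (abs(sum(probs) - 1) > 1e-9) stop("spectrum must sum to 1")
  structure(probs, class = c("mutation_spectrum", "numeric"))
}

#' @rdname mutation_spectrum
#' @export
ems_spectrum <- function(canonical_mass = 0.8) {
  stopifnot(canonical_mass >= 0, canonical_mass <= 1)
  p <- setNames(rep((1 - canonical_mass) / 10, 12L), .SUB_CLASSES)
  p["G>A"] <- p["C>T"] <- canonical_mass / 2
  mutation_spectrum(p)
}

#' Canonical-transition mass of a spectrum
#' @param spectrum A [mutation_spectrum()].
#' @return `P(G>A) + P(C>T)`.
#' @export
canonical_mass <- function(spectrum) {
  unname(spectrum["G>A"] + spectrum["C>T"])
}

#' Population simulation configuration
#'
#' Defaults encode the scale of the screen the package models: 7,144 pooled
#' DNA samples (from 7,296 selected M2 families; the two bookkeeping counts
#' are carried independently) and a per-line, per-bp mutation probability of
#' 2.43e-6, which over a 63,713 bp target space yields about 1,108 induced
#' mutations in expectation.
#'
#' @param n_lines Number of M2 lines with pooled DNA (>= 1).
#' @param mu Mutation probability per bp per line (must satisfy
#'   `0 <= mu < 1e-3`).
#' @param spectrum A [mutation_spectrum()].
#' @param seed Integer seed; the whole population is reproducible from it.
#' @param n_families Number of selected M2 families (bookkeeping metadata;
#'   may exceed `n_lines` when some families were not pooled).
#' @param cultivar Free-text mutagenesis background label.
#' @param allow_high_load Set `TRUE` to permit `mu * target_bp > 50`
#'   (implausible per-line mutation loads are otherwise refused).
#'
#' @return List of class `population_config`.
#' @export
population_config <- function(n_lines = 7144, mu = 2.43e-6,
                              spectrum = ems_spectrum(), seed = 1L,
                              n_families = 7296, cultivar = "synthetic",
                              allow_high_load = FALSE) {
  if (n_lines < 1) stop("n_lines must be >= 1")
  if (mu < 0 || mu >= 1e-3) stop("mu must satisfy 0 <= mu < 1e-3")
  if (!inherits(spectrum, "mutation_spectrum"))
    spectrum <- mutation_spectrum(spectrum)
  structure(list(n_lines = as.integer(n_lines), mu = mu, spectrum = spectrum,
                 seed = as.integer(seed), n_families = as.integer(n_families),
                 cultivar = cultivar, allow_high_load = isTRUE(allow_high_load)),
            class = "population_config")
}

# line index -> plate/row/column (plates filled in row-major well order)
line_wells <- function(n_lines) {
  i <- seq_len(n_lines) - 1L
  data.frame(
    line_id = sprintf("M2-%05d", i + 1L),
    plate = i %/% 96L + 1L,
    row = .PLATE_ROWS[(i %% 96L) %/% 12L + 1L],
    column = i %% 12L + 1L,
    stringsAsFactors = FALSE
  )
}

#' Target space of a screen
#'
#' Builds the screened target regions from gene models. The default feature
#' is the exon set (the probe-covered space of a capture-seq screen); `"cds"`
#' restricts to coding sequence.
#'
#' @param gene_set A `gene_model_set` from [load_gene_models()] or
#'   [synthesize_gene_set()].
#' @param feature `"exon"` or `"cds"`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start0`, `end0`;
#'   attribute `total_bp` holds the summed width.
#' @export
target_space <- function(gene_set, feature = c("exon", "cds")) {
  feature <- match.arg(feature)
  regs <- do.call(rbind, lapply(gene_set$models, function(m) {
    iv <- if (feature == "exon") m$exons else m$cds
    data.frame(gene_id = m$gene_id, chrom = m$chrom,
               start0 = iv$start0, end0 = iv$end0,
               stringsAsFactors = FALSE)
  }))
  rownames(regs) <- NULL
  attr(regs, "total_bp") <- as.integer(sum(regs$end0 - regs$start0))
  regs
}

# enumerate target sites: chrom/pos0/ref for every base of the regions
target_sites <- function(regions, genome) {
  pieces <- lapply(seq_len(nrow(regions)), function(i) {
    s <- genome_seq(genome, regions$chrom[i],
                    regions$start0[i], regions$end0[i])
    data.frame(chrom = regions$chrom[i],
               pos0 = seq(regions$start0[i], regions$end0[i] - 1L),
               ref = strsplit(s, "")[[1]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Simulate an EMS-mutagenized M2 population
#'
#' Per line, the number of induced mutations is Poisson with mean
#' `mu x target_bp`. Each mutation's substitution class is drawn from the
#' spectrum, so the realized class distribution matches the spectrum
#' marginally (EMS alkylates G/C, concentrating mutations at G/C sites);
#' the site is then uniform among target sites carrying the class's
#' reference base. Zygosity is het with probability 2/3 and hom with 1/3 —
#' the carrier-conditioned 1:2 hom:het ratio among M2 plants from selfing a
#' heterozygous M1. At most one variant is kept per locus per line.
#'
#' @param gene_set A `gene_model_set`, or a target-region `data.frame` as
#'   returned by [target_space()] (then `genome` must be supplied).
#' @param config A [population_config()].
#' @param genome Genome accessor when `gene_set` is a plain region table.
#'
#' @return List of class `tbys_population` with elements `lines` (one row
#'   per line: `line_id`, `plate`, `row`, `column`, `cultivar`,
#'   `n_variants`), `truth` (one row per induced variant: `line_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `zygosity`), `target`,
#'   `config`, and `n_plates`.
#' @export
simulate_population <- function(gene_set, config = population_config(),
                                genome = NULL) {
  if (inherits(gene_set, "gene_model_set")) {
    regions <- target_space(gene_set)
    genome <- gene_set$genome
  } else {
    regions <- gene_set
    if (is.null(genome)) stop("genome accessor required with plain regions")
    if (is.null(attr(regions, "total_bp")))
      attr(regions, "total_bp") <- as.integer(sum(regions$end0 - regions$start0))
  }
  sites <- target_sites(regions, genome)
  target_bp <- nrow(sites)
  load <- config$mu * target_bp
  if (load > 50 && !config$allow_high_load)
    stop("mu x target_bp = ", signif(load, 4),
         " > 50 mutations per line is implausible; set allow_high_load",
         " to override")

  set.seed(config$seed)
  n_mut <- rpois(config$n_lines, load)
  n_tot <- sum(n_mut)
  lines <- line_wells(config$n_lines)
  lines$cultivar <- config$cultivar

  if (n_tot == 0L) {
    truth <- data.frame(line_id = character(0), chrom = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), zygosity = character(0))
  } else {
    line_idx <- rep(seq_len(config$n_lines), n_mut)
    spec <- as.numeric(config$spectrum)
    names(spec) <- names(config$spectrum)
    ref_of_class <- substr(.SUB_CLASSES, 1L, 1L)
    avail <- ref_of_class %in% unique(sites$ref)
    if (!all(avail[spec[.SUB_CLASSES] > 0])) {
      warning("spectrum mass on reference bases absent from the target",
              " space; renormalizing over available classes")
      spec[.SUB_CLASSES[!avail]] <- 0
      spec <- spec / sum(spec)
    }
    cls <- sample(.SUB_CLASSES, n_tot, replace = TRUE,
                  prob = spec[.SUB_CLASSES])
    ref <- substr(cls, 1L, 1L)
    alt <- substr(cls, 3L, 3L)
    site_idx <- integer(n_tot)
    for (b in unique(ref)) {
      sel <- which(ref == b)
      pool <- which(sites$ref == b)
      site_idx[sel] <- pool[sample.int(length(pool), length(sel),
                                       replace = TRUE)]
    }
    truth <- data.frame(
      line_id = lines$line_id[line_idx],
      chrom = sites$chrom[site_idx],
      pos = sites$pos0[site_idx] + 1L,
      ref = ref, alt = alt,
      zygosity = sample(c("het", "hom"), n_tot, replace = TRUE,
                        prob = c(2, 1) / 3),
      stringsAsFactors = FALSE
    )
    truth <- truth[!duplicated(truth[, c("line_id", "chrom", "pos")]), ]
    truth <- truth[order(truth$chrom, truth$pos, truth$line_id), ]
    rownames(truth) <- NULL
  }
  nv <- table(truth$line_id)
  lines$n_variants <- as.integer(nv[lines$line_id])
  lines$n_variants[is.na(lines$n_variants)] <- 0L

  structure(list(lines = lines, truth = truth, target = regions,
                 config = config,
                 n_plates = as.integer(ceiling(config$n_lines / 96))),
            class = "tbys_population")
}

#' @export
print.tbys_population <- function(x, ...) {
  cat("<tbys_population> ", nrow(x$lines), " M2 lines on ", x$n_plates,
      " plates; ", nrow(x$truth), " induced variants over ",
      attr(x$target, "total_bp"), " bp of target\n", sep = "")
  if (nrow(x$truth)) {
    canon <- mean(paste0(x$truth$ref, ">", x$truth$alt) %in% c("G>A", "C>T"))
    cat("  canonical G:C->A:T fraction: ", round(100 * canon, 1), "%; het ",
        round(100 * mean(x$truth$zygosity == "het"), 1), "%\n", sep = "")
  }
  invisible(x)
}

# ---- truth serialization ----------------------------------------------------

#' Write / read the simulation truth as VCF
#'
#' One VCF 4.2 record per (locus, alt); the `CARRIERS` INFO key lists
#' `line_id:zygosity` for every carrier line, `NCAR` their count. Positions
#' are 1-based.
#'
#' @param population A `tbys_population` (or a truth `data.frame`).
#' @param path Output path.
#' @return `write_truth_vcf` returns `path` invisibly; `read_truth_vcf`
#'   returns the carrier-level truth `data.frame` (`line_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `zygosity`).
#' @export
write_truth_vcf <- function(population, path) {
  truth <- if (inherits(population, "tbys_population")) population$truth
           else population
  if (!nrow(truth)) stop("truth table is empty")
  key <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
  agg <- split(seq_len(nrow(truth)), factor(key, levels = unique(key)))
  rec <- vapply(agg, function(ii) {
    r <- truth[ii, ]
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tNCAR=%d;CARRIERS=%s",
            r$chrom[1], r$pos[1], r$ref[1], r$alt[1], length(ii),
            paste0(r$line_id, ":", r$zygosity, collapse = ","))
  }, character(1))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tbysim_truth",
    "##INFO=<ID=NCAR,Number=1,Type=Integer,Description=\"Number of carrier lines\">",
    "##INFO=<ID=CARRIERS,Number=.,Type=String,Description=\"Carrier line_id:zygosity\">",
    sprintf("##contig=<ID=%s>", unique(truth$chrom)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_truth_vcf
#' @export
read_truth_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  carriers <- sub(".*CARRIERS=([^;]*).*", "\\1", fix$INFO)
  parts <- strsplit(carriers, ",", fixed = TRUE)
  n <- lengths(parts)
  flat <- strsplit(unlist(parts), ":", fixed = TRUE)
  truth <- data.frame(
    line_id = vapply(flat, `[`, character(1), 1L),
    chrom = rep(fix$CHROM, n),
    pos = rep(as.integer(fix$POS), n),
    ref = rep(fix$REF, n),
    alt = rep(fix$ALT, n),
    zygosity = vapply(flat, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$chrom, truth$pos, truth$line_id), ]
  rownames(truth) <- NULL
  truth
}

#' Write the line manifest as TSV
#'
#' Columns: `line_id`, `plate`, `row`, `column`, `cultivar`, `n_variants`.
#'
#' @param population A `tbys_population`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lines_tsv <- function(population, path) {
  write.table(population$lines, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_lines_tsv
#' @export
read_lines_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
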