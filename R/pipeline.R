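# Staged pipeline runner. Stages communicate only via plain files (VCF/TSV)
# in the run's output directory; each stage writes a JSON manifest with its
# inputs, outputs, config hash and derived seed, so a run can be audited
# and replayed. Every stage seed derives deterministically from the global
# seed.

.STAGES <- c("design", "simulate", "poolseq", "decode", "annotate", "report")

stop_tbys <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "tbys_error")))
}

#' Default run configuration
#'
#' A small complete screen: 12 source plates fully occupied by 1,152 M2
#' lines over a synthetic 3-gene target, with the default mutation density,
#' spectrum, sequencing depth and detection thresholds.
#'
#' @param outdir Output directory for stage artifacts.
#' @param seed Global seed; all stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_run_config <- function(outdir = tempfile("tbys_run_"), seed = 1L) {
  list(
    seed = as.integer(seed),
    population = list(n_lines = 1152L, mu = 2.43e-6, canonical_mass = 0.8),
    genes = list(n_genes = 3L, gff3 = NULL, fasta = NULL),
    pooling = list(n_plates = NULL),
    poolseq = list(depth = 2000L, error_rate = 1e-3, min_alt_reads = 3,
                   min_af = 0.5 / 96),
    decoding = list(max_pool_hits = 3L),
    paths = list(outdir = outdir)
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML run configuration, fills unset fields from
#' [default_run_config()], and validates types and ranges. Violations raise
#' a condition of class `tbys_config_error` listing the offending fields.
#'
#' @param path YAML file path, or a configuration list.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  def <- default_run_config()
  for (blk in names(def)) {
    if (is.null(cfg[[blk]])) cfg[[blk]] <- def[[blk]]
    else if (is.list(def[[blk]]))
      for (k in names(def[[blk]]))
        if (!k %in% names(cfg[[blk]])) cfg[[blk]][k] <- def[[blk]][k]
  }
  bad <- character(0)
  chk <- function(ok, field) if (!isTRUE(ok)) bad <<- c(bad, field)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed")
  chk(is.numeric(cfg$population$n_lines) && cfg$population$n_lines >= 1,
      "population.n_lines")
  chk(is.numeric(cfg$population$mu) && cfg$population$mu >= 0 &&
        cfg$population$mu < 1e-3, "population.mu")
  chk(is.numeric(cfg$population$canonical_mass) &&
        cfg$population$canonical_mass >= 0 &&
        cfg$population$canonical_mass <= 1, "population.canonical_mass")
  chk(is.numeric(cfg$genes$n_genes) && cfg$genes$n_genes >= 1,
      "genes.n_genes")
  chk(is.null(cfg$pooling$n_plates) ||
        (is.numeric(cfg$pooling$n_plates) && cfg$pooling$n_plates >= 1),
      "pooling.n_plates")
  chk(is.numeric(cfg$poolseq$depth) && cfg$poolseq$depth >= 0,
      "poolseq.depth")
  chk(is.numeric(cfg$poolseq$error_rate) && cfg$poolseq$error_rate >= 0 &&
        cfg$poolseq$error_rate <= 0.01, "poolseq.error_rate")
  chk(is.numeric(cfg$poolseq$min_alt_reads) &&
        cfg$poolseq$min_alt_reads >= 0, "poolseq.min_alt_reads")
  chk(is.numeric(cfg$poolseq$min_af) && cfg$poolseq$min_af >= 0,
      "poolseq.min_af")
  chk(is.character(cfg$paths$outdir) && nzchar(cfg$paths$outdir),
      "paths.outdir")
  if (length(bad))
    stop_tbys("tbys_config_error",
              "invalid run configuration field(s): ",
              paste(bad, collapse = ", "))
  cfg
}

# canonical md5 of a config (names sorted recursively)
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(canon(cfg), f, auto_unbox = TRUE, digits = 15,
                       null = "null")
  unname(tools::md5sum(f))
}

derive_seed <- function(seed, stage) {
  idx <- match(stage, .STAGES)
  as.integer((as.numeric(seed) %% 65536) * 32749 + idx * 7919) %% 2147483647L
}

artifact_path <- function(cfg, name) file.path(cfg$paths$outdir, name)

need_artifact <- function(cfg, name, stage) {
  p <- artifact_path(cfg, name)
  if (!file.exists(p))
    stop_tbys("tbys_missing_artifact",
              "stage '", stage, "' needs missing upstream artifact: ", p)
  p
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  m <- list(stage = stage, inputs = as.list(inputs),
            outputs = as.list(outputs), config_hash = config_hash(cfg),
            seed = derive_seed(cfg$seed, stage),
            package_version = as.character(utils::packageVersion("tbysim")))
  p <- artifact_path(cfg, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(m, p, auto_unbox = TRUE, pretty = TRUE)
  p
}

load_run_gene_set <- function(cfg, stage) {
  if (!is.null(cfg$genes$gff3) && !is.null(cfg$genes$fasta))
    return(load_gene_models(cfg$genes$gff3, cfg$genes$fasta))
  gff <- artifact_path(cfg, "genes.gff3")
  fa <- artifact_path(cfg, "genome.fa")
  if (!file.exists(gff) || !file.exists(fa))
    stop_tbys("tbys_missing_artifact",
              "stage '", stage, "' needs ", gff, " and ", fa,
              " (run the simulate stage first)")
  load_gene_models(gff, fa)
}

run_n_plates <- function(cfg) {
  if (!is.null(cfg$pooling$n_plates)) as.integer(cfg$pooling$n_plates)
  else as.integer(ceiling(cfg$population$n_lines / 96))
}

#' Run a pipeline stage
#'
#' Executes one stage of the screen pipeline (or all of them in order) from
#' a validated configuration, writing its artifacts and a manifest to the
#' configured output directory.
#'
#' Stages and their artifacts: `design` (design.tsv); `simulate` (genome.fa
#' + genes.gff3 when synthetic, truth.vcf, lines.tsv); `poolseq`
#' (pool_calls.vcf, detected.vcf); `decode` (decoded.tsv,
#' performance.tsv); `annotate` (annotated.tsv, annotated.vcf); `report`
#' (report.tsv). A missing upstream artifact raises
#' `tbys_missing_artifact`; configuration violations raise
#' `tbys_config_error`.
#'
#' @param stage One of `"design"`, `"simulate"`, `"poolseq"`, `"decode"`,
#'   `"annotate"`, `"report"`, `"all"`.
#' @param config Configuration list or YAML path ([read_run_config()]).
#' @return Invisibly, a named list of artifact paths written by the
#'   stage(s).
#' @export
run_stage <- function(stage = c("all", .STAGES), config = default_run_config()) {
  stage <- match.arg(stage)
  cfg <- read_run_config(config)
  dir.create(cfg$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    out <- list()
    for (s in .STAGES) out <- c(out, run_stage(s, cfg))
    return(invisible(out))
  }
  message("[tbys:", stage, "] running in ", cfg$paths$outdir)
  out <- switch(stage,
    design = {
      d <- build_design(run_n_plates(cfg))
      p <- artifact_path(cfg, "design.tsv")
      write_design_tsv(d, p)
      write_manifest(cfg, stage, character(0), p)
      list(design = p)
    },
    simulate = {
      ins <- character(0)
      if (is.null(cfg$genes$gff3) || is.null(cfg$genes$fasta)) {
        gs <- synthesize_gene_set(cfg$genes$n_genes,
                                  seed = derive_seed(cfg$seed, "simulate"))
        write_gene_set(gs, artifact_path(cfg, "genome.fa"),
                       artifact_path(cfg, "genes.gff3"))
      } else {
        gs <- load_gene_models(cfg$genes$gff3, cfg$genes$fasta)
        ins <- c(cfg$genes$gff3, cfg$genes$fasta)
      }
      pc <- population_config(
        n_lines = cfg$population$n_lines, mu = cfg$population$mu,
        spectrum = ems_spectrum(cfg$population$canonical_mass),
        seed = derive_seed(cfg$seed, "simulate"))
      pop <- simulate_population(gs, pc)
      pt <- artifact_path(cfg, "truth.vcf")
      pl <- artifact_path(cfg, "lines.tsv")
      write_truth_vcf(pop, pt)
      write_lines_tsv(pop, pl)
      write_manifest(cfg, stage, ins, c(pt, pl))
      list(truth = pt, lines = pl)
    },
    poolseq = {
      dp <- need_artifact(cfg, "design.tsv", stage)
      tp <- need_artifact(cfg, "truth.vcf", stage)
      lp <- need_artifact(cfg, "lines.tsv", stage)
      gs <- load_run_gene_set(cfg, stage)
      design <- read_design_tsv(dp)
      truth <- read_truth_vcf(tp)
      lines <- read_lines_tsv(lp)
      psc <- pool_seq_config(depth = cfg$poolseq$depth,
                             error_rate = cfg$poolseq$error_rate,
                             min_alt_reads = cfg$poolseq$min_alt_reads,
                             min_af = cfg$poolseq$min_af,
                             seed = derive_seed(cfg$seed, "poolseq"))
      calls <- simulate_pool_reads(design, lines, truth, psc,
                                   genome = gs$genome,
                                   target = target_space(gs))
      detected <- call_pool_variants(calls, psc)
      pa <- artifact_path(cfg, "pool_calls.vcf")
      pd <- artifact_path(cfg, "detected.vcf")
      write_pool_vcf(calls, pa)
      write_pool_vcf(detected, pd)
      write_manifest(cfg, stage, c(dp, tp, lp), c(pa, pd))
      list(pool_calls = pa, detected = pd)
    },
    decode = {
      dp <- need_artifact(cfg, "design.tsv", stage)
      vp <- need_artifact(cfg, "detected.vcf", stage)
      tp <- need_artifact(cfg, "truth.vcf", stage)
      lp <- need_artifact(cfg, "lines.tsv", stage)
      decoded <- demultiplex(read_pool_vcf(vp), read_design_tsv(dp),
                             max_pool_hits = cfg$decoding$max_pool_hits)
      perf <- screen_performance(decoded, read_truth_vcf(tp),
                                 read_lines_tsv(lp))
      pd <- artifact_path(cfg, "decoded.tsv")
      pp <- artifact_path(cfg, "performance.tsv")
      write.table(decoded, pd, sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(as.data.frame(perf), pp, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write_manifest(cfg, stage, c(dp, vp, tp, lp), c(pd, pp))
      list(decoded = pd, performance = pp)
    },
    annotate = {
      vp <- need_artifact(cfg, "decoded.tsv", stage)
      gs <- load_run_gene_set(cfg, stage)
      decoded <- read.delim(vp, stringsAsFactors = FALSE)
      ann <- annotate_variants(decoded[decoded$status != "absent", ], gs)
      pt <- artifact_path(cfg, "annotated.tsv")
      pv <- artifact_path(cfg, "annotated.vcf")
      write_annotated(ann, vcf_path = pv, tsv_path = pt)
      write_manifest(cfg, stage, vp, c(pt, pv))
      list(annotated = pt, annotated_vcf = pv)
    },
    report = {
      ap <- need_artifact(cfg, "annotated.tsv", stage)
      tp <- need_artifact(cfg, "truth.vcf", stage)
      gs <- load_run_gene_set(cfg, stage)
      ann <- read.delim(ap, stringsAsFactors = FALSE)
      truth <- read_truth_vcf(tp)
      ev <- merge(truth, ann, by = c("chrom", "pos", "ref", "alt"))
      gene_ids <- names(gs$models)
      zero <- data.frame(gene_id = gene_ids, base_changes = 0L, g_to_a = 0L,
                         c_to_t = 0L, other = 0L, missense = 0L,
                         nonsense = 0L, silent = 0L, noncoding = 0L,
                         unclassified = 0L, stringsAsFactors = FALSE)
      counts <- count_effect_events(ev, zero)
      tg <- target_space(gs)
      amp <- tapply(tg$end0 - tg$start0, tg$gene_id, sum)
      amp <- c(amp, unassigned = 0)
      rep <- mutation_report(counts, amplicon_sizes = amp)
      pr <- artifact_path(cfg, "report.tsv")
      write_report(rep, pr)
      write_manifest(cfg, stage, c(ap, tp), pr)
      list(report = pr)
    }
  )
  invisible(out)
}
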