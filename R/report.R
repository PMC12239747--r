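# Screen-level summary table: per-gene base-change and effect-class counts
# with a Total row and two percentage rows, the shape screening papers
# print. Percentages are computed against the grand total of base changes
# by default; because some events fall outside coding sequence, the
# base-change total and the effect-class sum can differ, and both are
# reported explicitly.

.REPORT_COLS <- c("gene_id", "amplicon_size", "base_changes", "g_to_a",
                  "c_to_t", "other", "missense", "nonsense", "silent")

#' Read a per-gene mutation-count table
#'
#' TSV with columns `gene_id`, `amplicon_size` (bp), `base_changes`,
#' `g_to_a`, `c_to_t`, `other`, `missense`, `nonsense`, `silent`. The
#' per-row identity `g_to_a + c_to_t + other = base_changes` is enforced.
#'
#' @param path TSV path.
#' @return `data.frame` of per-gene counts.
#' @export
read_mutation_counts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.REPORT_COLS, names(tab))
  if (length(miss))
    stop("mutation count table missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- tab$g_to_a + tab$c_to_t + tab$other != tab$base_changes
  if (any(bad))
    stop("base-change components do not sum to base_changes for: ",
         paste(tab$gene_id[bad], collapse = ", "))
  tab
}

#' Build a screen report
#'
#' Assembles the per-gene counts into the standard screen summary: per-gene
#' rows, a totals row, a nucleotide-change percentage row (`G>A`, `C>T`,
#' other) and an amino-acid-change percentage row (missense, nonsense,
#' silent), all percentages against the grand total of base changes and
#' rounded to 2 decimals. Setting `denominator = "effect_classes"` computes
#' the amino-acid row against the effect-class sum instead (the two differ
#' when some events are noncoding).
#'
#' @param counts Per-gene counts with columns `gene_id`, `g_to_a`, `c_to_t`,
#'   `other`, `missense`, `nonsense`, `silent`; `base_changes` and
#'   `amplicon_size` are recomputed/merged if absent.
#' @param amplicon_sizes Optional named vector of per-gene target sizes (bp)
#'   when `counts` has no `amplicon_size` column.
#' @param denominator Denominator for the amino-acid percentage row.
#'
#' @return Object of class `screen_report`: `per_gene`, `totals` (named
#'   vector), `pct_nucleotide`, `pct_amino_acid`, `base_change_total`,
#'   `effect_class_total`, `denominator`, `footnotes`.
#' @export
mutation_report <- function(counts, amplicon_sizes = NULL,
                            denominator = c("base_changes",
                                            "effect_classes")) {
  denominator <- match.arg(denominator)
  need <- c("gene_id", "g_to_a", "c_to_t", "other", "missense", "nonsense",
            "silent")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts missing column(s): ", paste(miss, collapse = ", "))
  num <- counts[setdiff(names(counts), "gene_id")]
  if (any(unlist(num) < 0)) stop("counts must be non-negative")
  counts$base_changes <- counts$g_to_a + counts$c_to_t + counts$other
  if (!"amplicon_size" %in% names(counts)) {
    counts$amplicon_size <- if (is.null(amplicon_sizes))
      rep(NA_integer_, nrow(counts))
    else unname(amplicon_sizes[counts$gene_id])
  }
  per_gene <- counts[, .REPORT_COLS]

  tot_cols <- setdiff(.REPORT_COLS, "gene_id")
  totals <- vapply(per_gene[tot_cols], function(x) sum(as.numeric(x)),
                   numeric(1))
  grand <- totals[["base_changes"]]
  effect_total <- totals[["missense"]] + totals[["nonsense"]] +
    totals[["silent"]]
  if (grand == 0 && effect_total > 0)
    stop("zero base changes but nonzero effect-class counts")

  pct <- function(x, denom) if (denom > 0) round(100 * x / denom, 2) else 0
  pct_nt <- c(g_to_a = pct(totals[["g_to_a"]], grand),
              c_to_t = pct(totals[["c_to_t"]], grand),
              other = pct(totals[["other"]], grand))
  aa_denom <- if (denominator == "base_changes") grand else effect_total
  pct_aa <- c(missense = pct(totals[["missense"]], aa_denom),
              nonsense = pct(totals[["nonsense"]], aa_denom),
              silent = pct(totals[["silent"]], aa_denom))

  foot <- c(
    sprintf("base-change total = %d; effect-class total = %d%s",
            as.integer(grand), as.integer(effect_total),
            if (grand != effect_total)
              " (events outside coding sequence account for the difference)"
            else ""),
    sprintf("percentage rows use the %s total (%d) as denominator",
            if (denominator == "base_changes") "base-change"
            else "effect-class",
            as.integer(aa_denom))
  )
  structure(list(per_gene = per_gene, totals = totals,
                 pct_nucleotide = pct_nt, pct_amino_acid = pct_aa,
                 base_change_total = as.integer(grand),
                 effect_class_total = as.integer(effect_total),
                 denominator = denominator, footnotes = foot),
            class = "screen_report")
}

#' Canonical EMS-transition share of a report
#'
#' The percentage of base changes that are canonical EMS transitions,
#' `(G>A + C>T) / base changes x 100`, to 2 decimals.
#'
#' @param report A `screen_report`.
#' @return Percentage (numeric scalar).
#' @export
ems_spectrum_fraction <- function(report) {
  grand <- report$base_change_total
  if (grand == 0) stop("report has zero base changes")
  round(100 * (report$totals[["g_to_a"]] + report$totals[["c_to_t"]]) /
          grand, 2)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> ", nrow(x$per_gene), " genes, ",
      x$base_change_total, " base changes (",
      x$effect_class_total, " in coding sequence)\n", sep = "")
  print(x$per_gene, row.names = FALSE)
  cat("Total\t", paste(x$totals, collapse = "\t"), "\n", sep = "")
  cat(sprintf("%% nucleotide change: G>A %.2f, C>T %.2f, other %.2f\n",
              x$pct_nucleotide[["g_to_a"]], x$pct_nucleotide[["c_to_t"]],
              x$pct_nucleotide[["other"]]))
  cat(sprintf("%% amino acid change: missense %.2f, nonsense %.2f, silent %.2f\n",
              x$pct_amino_acid[["missense"]], x$pct_amino_acid[["nonsense"]],
              x$pct_amino_acid[["silent"]]))
  for (f in x$footnotes) cat("# ", f, "\n", sep = "")
  invisible(x)
}

.LBL_TOTAL <- "Total"
.LBL_PCT_NT <- "Percentage of each type of nucleotide change (%)"
.LBL_PCT_AA <- "Percentage of each type of amino acid change (%)"

#' Write / read a screen report as TSV
#'
#' Fixed column order (`gene_id`, `amplicon_size`, `base_changes`, `g_to_a`,
#' `c_to_t`, `other`, `missense`, `nonsense`, `silent`); the totals and
#' percentage rows carry the labels `Total`, `Percentage of each type of
#' nucleotide change (%)` and `Percentage of each type of amino acid change
#' (%)` in the `gene_id` column, with blanks in cells where a percentage
#' does not apply.
#'
#' @param report A `screen_report`.
#' @param path TSV path.
#' @return `write_report` returns `path` invisibly; `read_report` returns a
#'   list with `per_gene`, `totals`, `pct_nucleotide`, `pct_amino_acid`.
#' @export
write_report <- function(report, path) {
  pg <- report$per_gene
  fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE,
                                                 scientific = FALSE))
  body <- if (nrow(pg))
    apply(cbind(pg$gene_id, vapply(pg[-1], fmt, character(nrow(pg)))),
          1, paste, collapse = "\t")
  else character(0)
  tot <- paste(c(.LBL_TOTAL, fmt(unname(report$totals))), collapse = "\t")
  nt <- paste(c(.LBL_PCT_NT, "", "", sprintf("%.2f", report$pct_nucleotide),
                "", "", ""), collapse = "\t")
  aa <- paste(c(.LBL_PCT_AA, "", "", "", "", "",
                sprintf("%.2f", report$pct_amino_acid)), collapse = "\t")
  writeLines(c(paste(.REPORT_COLS, collapse = "\t"), body, tot, nt, aa),
             path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  stopifnot(identical(names(raw), .REPORT_COLS))
  lab <- raw$gene_id
  num <- function(row, cols) {
    v <- suppressWarnings(as.numeric(raw[row, cols]))
    setNames(v, cols)
  }
  gene_rows <- which(!lab %in% c(.LBL_TOTAL, .LBL_PCT_NT, .LBL_PCT_AA))
  per_gene <- raw[gene_rows, ]
  for (cl in .REPORT_COLS[-1]) per_gene[[cl]] <- as.numeric(per_gene[[cl]])
  rownames(per_gene) <- NULL
  list(
    per_gene = per_gene,
    totals = num(which(lab == .LBL_TOTAL), .REPORT_COLS[-1]),
    pct_nucleotide = num(which(lab == .LBL_PCT_NT),
                         c("g_to_a", "c_to_t", "other")),
    pct_amino_acid = num(which(lab == .LBL_PCT_AA),
                         c("missense", "nonsense", "silent"))
  )
}
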