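# Pool-level sequencing model.
#
# Reads are simulated per pool and per site rather than as individual
# sequencer reads: for a pool whose carriers contribute c alt copies out of
# 2 x pool_size alleles, the true alt fraction is f = c / (2 x pool_size)
# and the alt read count is Binomial(depth, f(1-e) + (1-f)e/3) with per-base
# miscall probability e. This preserves exactly the quantities a pooled
# screen consumes downstream (DP, alt reads, AF, AC, QUAL) without modeling
# alignment.

#' Pooled sequencing configuration
#'
#' @param depth Reads per pool per site.
#' @param error_rate Per-base miscall probability (0 to 0.01).
#' @param min_alt_reads Detection threshold on alt reads (default 3).
#' @param min_af Detection threshold on allele fraction; the default is half
#'   the expected fraction of a single heterozygous carrier in the largest
#'   (48-sample) pool, 0.5 x 1/96.
#' @param seed Integer seed.
#'
#' @return List of class `pool_seq_config`.
#' @export
pool_seq_config <- function(depth = 2000, error_rate = 1e-3,
                            min_alt_reads = 3, min_af = 0.5 / 96,
                            seed = 1L) {
  if (depth < 0) stop("depth must be >= 0")
  if (error_rate < 0 || error_rate > 0.01)
    stop("error_rate must be in [0, 0.01]")
  if (min_alt_reads < 0 || min_af < 0) stop("thresholds must be >= 0")
  structure(list(depth = as.integer(depth), error_rate = error_rate,
                 min_alt_reads = min_alt_reads, min_af = min_af,
                 seed = as.integer(seed)),
            class = "pool_seq_config")
}

#' Expected alt allele fraction of one carrier in a pool
#'
#' A heterozygous carrier contributes 1 alt copy and a homozygous carrier 2,
#' out of the `2 x pool_size` alleles in the pool.
#'
#' @param zygosity `"het"` or `"hom"`.
#' @param pool_size Number of individuals in the pool (>= 1).
#' @return Expected alt fraction.
#' @export
#' @examples
#' expected_alt_fraction("het", 48)  # 1/96
expected_alt_fraction <- function(zygosity, pool_size) {
  if (any(pool_size < 1)) stop("pool_size must be >= 1")
  copies <- c(het = 1, hom = 2)[zygosity]
  if (any(is.na(copies))) stop("zygosity must be 'het' or 'hom'")
  unname(copies / (2 * pool_size))
}

qual_score <- function(alt_reads, depth, error_rate) {
  # -10 log10 P(X >= alt_reads) under the error-only null X ~ Bin(depth, e/3)
  p0 <- error_rate / 3
  q <- numeric(length(alt_reads))
  pos <- alt_reads > 0
  if (p0 == 0) {
    q[pos] <- 999
  } else {
    q[pos] <- -10 * log10(pbinom(alt_reads[pos] - 1L, depth, p0,
                                 lower.tail = FALSE))
    q[pos] <- pmin(q[pos], 999)
  }
  round(q, 2)
}

#' Simulate pooled sequencing over a design
#'
#' For every occupied pool and every variant locus of the truth table, draws
#' alt read counts from the binomial read model; when `genome` and `target`
#' are supplied, every other target site is also eligible for error-only alt
#' reads (a uniformly chosen non-reference base at rate `error_rate/3`).
#' Pool size is the number of occupied wells in the pool.
#'
#' @param design A [build_design()] result covering every line's well.
#' @param lines Line manifest (`line_id`, `plate`, `row`, `column`), or a
#'   `tbys_population` (then `truth`, `target` and `genome` are taken from
#'   it unless given).
#' @param truth Carrier-level truth table (`line_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `zygosity`).
#' @param config A [pool_seq_config()].
#' @param genome,target Optional genome accessor and target regions for
#'   error-only sites.
#'
#' @return `data.frame` of pool-level observations: `pool_id`,
#'   `orientation`, `pool_size`, `chrom`, `pos`, `ref`, `alt`,
#'   `true_copies`, `depth`, `alt_reads`, `af`, `ac`, `qual`. Rows with
#'   neither carriers nor alt reads are dropped; `depth = 0` gives an empty
#'   table.
#' @export
simulate_pool_reads <- function(design, lines, truth = NULL,
                                config = pool_seq_config(),
                                genome = NULL, target = NULL) {
  if (inherits(lines, "tbys_population")) {
    pop <- lines
    lines <- pop$lines
    if (is.null(truth)) truth <- pop$truth
    if (is.null(target)) target <- pop$target
  }
  empty <- data.frame(pool_id = character(0), orientation = character(0),
                      pool_size = integer(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), true_copies = integer(0),
                      depth = integer(0), alt_reads = integer(0),
                      af = numeric(0), ac = integer(0), qual = numeric(0))
  if (config$depth == 0L) return(empty)

  lw <- merge(lines, design$wells, by = c("plate", "row", "column"),
              all.x = TRUE, sort = FALSE)
  if (anyNA(lw$h_pool) || anyNA(lw$v_pool)) {
    bad <- lw[is.na(lw$h_pool) | is.na(lw$v_pool), ]
    stop("line well(s) not covered by the design: ",
         paste(well_id(bad$plate, bad$row, bad$column), collapse = ", "))
  }
  psize <- c(table(lw$h_pool), table(lw$v_pool))
  orient <- setNames(
    design$pools$orientation[match(names(psize), design$pools$pool_id)],
    names(psize))

  set.seed(config$seed)
  e <- config$error_rate
  out <- list()

  if (!is.null(truth) && nrow(truth)) {
    vkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = "\r")
    variants <- truth[!duplicated(vkey), c("chrom", "pos", "ref", "alt")]
    variants$vkey <- vkey[!duplicated(vkey)]
    tw <- merge(truth, lw[, c("line_id", "h_pool", "v_pool")], by = "line_id")
    tw$copies <- ifelse(tw$zygosity == "hom", 2L, 1L)
    tw$vkey <- paste(tw$chrom, tw$pos, tw$ref, tw$alt, sep = "\r")
    carried <- rbind(
      data.frame(vkey = tw$vkey, pool_id = tw$h_pool, copies = tw$copies),
      data.frame(vkey = tw$vkey, pool_id = tw$v_pool, copies = tw$copies)
    )
    carried <- aggregate(copies ~ vkey + pool_id, carried, sum)

    grid <- expand.grid(vkey = variants$vkey, pool_id = names(psize),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- merge(grid, carried, by = c("vkey", "pool_id"), all.x = TRUE)
    grid$copies[is.na(grid$copies)] <- 0L
    n <- psize[grid$pool_id]
    f <- grid$copies / (2 * n)
    p <- f * (1 - e) + (1 - f) * e / 3
    ar <- rbinom(nrow(grid), config$depth, p)
    vi <- match(grid$vkey, variants$vkey)
    out$truth <- data.frame(
      pool_id = grid$pool_id, orientation = unname(orient[grid$pool_id]),
      pool_size = unname(as.integer(n)),
      chrom = variants$chrom[vi], pos = variants$pos[vi],
      ref = variants$ref[vi], alt = variants$alt[vi],
      true_copies = grid$copies, depth = config$depth, alt_reads = ar,
      stringsAsFactors = FALSE)
    out$truth <- out$truth[out$truth$alt_reads > 0L |
                             out$truth$true_copies > 0L, ]
  }

  if (!is.null(genome) && !is.null(target) && e > 0) {
    sites <- target_sites(target, genome)
    if (!is.null(truth) && nrow(truth))
      sites <- sites[!paste(sites$chrom, sites$pos0 + 1L) %in%
                       paste(truth$chrom, truth$pos), ]
    if (nrow(sites)) {
      # non-ref base lookup: row = ref base, column = uniform 1..3 draw
      alt_of <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                      G = c("A", "C", "T"), T = c("A", "C", "G"))
      err <- lapply(names(psize), function(pid) {
        ar <- rbinom(nrow(sites), config$depth, e / 3)
        hit <- which(ar > 0L)
        if (!length(hit)) return(NULL)
        ref <- sites$ref[hit]
        alt <- alt_of[cbind(match(ref, rownames(alt_of)),
                            sample.int(3L, length(hit), replace = TRUE))]
        data.frame(pool_id = pid, orientation = unname(orient[pid]),
                   pool_size = unname(as.integer(psize[pid])),
                   chrom = sites$chrom[hit], pos = sites$pos0[hit] + 1L,
                   ref = ref, alt = alt, true_copies = 0L,
                   depth = config$depth, alt_reads = ar[hit],
                   stringsAsFactors = FALSE)
      })
      out$error <- do.call(rbind, err)
    }
  }

  calls <- do.call(rbind, out)
  if (is.null(calls) || !nrow(calls)) return(empty)
  calls$af <- calls$alt_reads / calls$depth
  calls$ac <- as.integer(round(calls$af * 2 * calls$pool_size))
  calls$qual <- qual_score(calls$alt_reads, config$depth, e)
  calls <- calls[order(calls$chrom, calls$pos, calls$alt, calls$pool_id), ]
  rownames(calls) <- NULL
  calls
}

#' Filter pool observations to detected variant calls
#'
#' Keeps observations with `alt_reads >= min_alt_reads` and
#' `af >= min_af` (both thresholds from the config).
#'
#' @param calls Output of [simulate_pool_reads()].
#' @param config A [pool_seq_config()].
#' @return The detected subset, same columns.
#' @export
call_pool_variants <- function(calls, config = pool_seq_config()) {
  out <- calls[calls$alt_reads >= config$min_alt_reads &
                 calls$af >= config$min_af, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- VCF serialization ------------------------------------------------------

#' Write / read pool-level calls as VCF
#'
#' One VCF 4.2 record per (pool, variant) observation; the pool is carried
#' in the `POOL` INFO key together with `ORIENT`, `PSIZE`, `DP`, `ALTR`,
#' `AF` (4 decimals), `AC` and `TCOP`. `QUAL` is the error-only-null score
#' from the read model, capped at 999. Records with zero depth are skipped
#' with a warning. On read, `af` is recomputed as `ALTR/DP` so the
#' round-trip is exact.
#'
#' @param calls Pool call table.
#' @param path VCF path.
#' @return `write_pool_vcf` returns `path` invisibly; `read_pool_vcf`
#'   returns the call table.
#' @export
write_pool_vcf <- function(calls, path) {
  if (any(calls$depth == 0L)) {
    warning("skipping ", sum(calls$depth == 0L), " call(s) with zero depth")
    calls <- calls[calls$depth > 0L, ]
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tbysim_poolseq",
    "##INFO=<ID=POOL,Number=1,Type=String,Description=\"Pool id\">",
    "##INFO=<ID=ORIENT,Number=1,Type=String,Description=\"Pool orientation\">",
    "##INFO=<ID=PSIZE,Number=1,Type=Integer,Description=\"Samples in pool\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pool depth\">",
    "##INFO=<ID=ALTR,Number=1,Type=Integer,Description=\"Alt read count\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele fraction\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Estimated alt allele copies\">",
    "##INFO=<ID=TCOP,Number=1,Type=Integer,Description=\"True alt copies in pool\">",
    if (nrow(calls)) sprintf("##contig=<ID=%s>", unique(calls$chrom)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rec <- if (nrow(calls)) sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\tPASS\tPOOL=%s;ORIENT=%s;PSIZE=%d;DP=%d;ALTR=%d;AF=%.4f;AC=%d;TCOP=%d",
    calls$chrom, calls$pos, calls$ref, calls$alt, format(calls$qual),
    calls$pool_id, calls$orientation, calls$pool_size, calls$depth,
    calls$alt_reads, calls$af, calls$ac, calls$true_copies
  ) else character(0)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_pool_vcf
#' @export
read_pool_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_get <- function(key) {
    pat <- paste0("(^|;)", key, "=([^;]*)")
    has <- grepl(pat, fix$INFO)
    if (any(!has))
      stop("malformed pool VCF: INFO key ", key,
           " missing at record ", which(!has)[1])
    sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", fix$INFO)
  }
  out <- data.frame(
    pool_id = info_get("POOL"), orientation = info_get("ORIENT"),
    pool_size = as.integer(info_get("PSIZE")),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    true_copies = as.integer(info_get("TCOP")),
    depth = as.integer(info_get("DP")),
    alt_reads = as.integer(info_get("ALTR")),
    stringsAsFactors = FALSE
  )
  out$af <- out$alt_reads / out$depth
  out$ac <- as.integer(info_get("AC"))
  out$qual <- as.numeric(fix$QUAL)
  out <- out[order(out$chrom, out$pos, out$alt, out$pool_id), ]
  rownames(out) <- NULL
  out
}
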