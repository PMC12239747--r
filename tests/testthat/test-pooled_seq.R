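# small helper screen: n_plates plates fully occupied, variants given directly
make_screen <- function(n_plates, truth_spec, seed = 1) {
  design <- build_design(n_plates)
  lines <- tbysim:::line_wells(n_plates * 96L)
  list(design = design, lines = lines, truth = truth_spec)
}

singleton_truth <- function(line_id, zygosity = "het", pos = 100L) {
  data.frame(line_id = line_id, chrom = "c1", pos = pos, ref = "G",
             alt = "A", zygosity = zygosity)
}

test_that("expected alt fractions follow allele counting", {
  expect_equal(expected_alt_fraction("het", 48), 1 / 96)
  expect_equal(expected_alt_fraction("hom", 24), 1 / 24)
  expect_error(expected_alt_fraction("het", 0), "pool_size")
  expect_error(expected_alt_fraction("carrier", 10), "zygosity")
})

test_that("zero depth yields an empty call table", {
  sc <- make_screen(1, singleton_truth("M2-00001"))
  calls <- simulate_pool_reads(sc$design, sc$lines, sc$truth,
                               pool_seq_config(depth = 0))
  expect_equal(nrow(calls), 0L)
})

test_that("a line in an uncovered well is fatal and names the well", {
  sc <- make_screen(1, singleton_truth("M2-00001"))
  sc$lines$plate[1] <- 99L
  expect_error(
    simulate_pool_reads(sc$design, sc$lines, sc$truth, pool_seq_config()),
    "P099-A01")
})

test_that("mean allele fraction of a singleton het matches 1/96 in a 48-pool", {
  sc <- make_screen(4, singleton_truth("M2-00001"))  # full 48-sample h pools
  af <- vapply(1:200, function(s) {
    calls <- simulate_pool_reads(sc$design, sc$lines, sc$truth,
                                 pool_seq_config(depth = 1000, error_rate = 0,
                                                 seed = s))
    h <- calls[calls$orientation == "horizontal", ]
    expect_equal(unique(h$pool_size), 48L)
    h$af
  }, numeric(1))
  p <- 1 / 96
  se <- sqrt(p * (1 - p) / 1000 / 200)
  expect_lt(abs(mean(af) - p), 3 * se)
})

test_that("carrier-free sites show the error-only alt rate", {
  design <- build_design(1)
  lines <- tbysim:::line_wells(96L)
  genome <- Biostrings::DNAStringSet(setNames(strrep("ACGT", 25), "c1"))
  target <- data.frame(gene_id = "g", chrom = "c1", start0 = 0, end0 = 100)
  e <- 1e-3; depth <- 2000L
  tot_alt <- 0
  n_pools <- 12 + 8  # every pool of a single plate is occupied
  for (s in 1:50) {
    calls <- simulate_pool_reads(design, lines, truth = NULL,
                                 pool_seq_config(depth = depth,
                                                 error_rate = e, seed = s),
                                 genome = genome, target = target)
    expect_true(all(calls$true_copies == 0L))
    tot_alt <- tot_alt + sum(calls$alt_reads)
  }
  n_draws <- 100 * n_pools * 50
  p0 <- e / 3
  se <- sqrt(p0 * (1 - p0) / (n_draws * depth))
  expect_lt(abs(tot_alt / (n_draws * depth) - p0), 3 * se)
})

test_that("detection thresholds behave at the edges", {
  cfg <- pool_seq_config()
  calls <- data.frame(pool_id = "H-x", orientation = "horizontal",
                      pool_size = 48L, chrom = "c1", pos = 1L, ref = "G",
                      alt = "A", true_copies = 1L, depth = 2000L,
                      alt_reads = 2L, af = 2 / 2000, ac = 0L, qual = 10)
  expect_equal(nrow(call_pool_variants(calls, cfg)), 0L)

  calls$alt_reads <- 21L; calls$af <- 21 / 2000
  expect_equal(nrow(call_pool_variants(calls, cfg)), 1L)

  zero <- pool_seq_config(min_alt_reads = 0, min_af = 0)
  calls$alt_reads <- 0L; calls$af <- 0
  expect_equal(nrow(call_pool_variants(calls, zero)), 1L)
})

test_that("a singleton het at high depth is detected in nearly every replicate", {
  sc <- make_screen(4, singleton_truth("M2-00017"))
  cfg0 <- pool_seq_config(depth = 2000, error_rate = 1e-3)
  hits <- vapply(1:200, function(s) {
    cfg <- pool_seq_config(depth = 2000, error_rate = 1e-3, seed = s)
    det <- call_pool_variants(
      simulate_pool_reads(sc$design, sc$lines, sc$truth, cfg), cfg)
    any(det$true_copies > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("true alt copies balance across orientations and are never silently dropped", {
  gs <- synthesize_gene_set(2, seed = 21)
  pop <- simulate_population(gs, population_config(n_lines = 192, mu = 1e-4,
                                                   seed = 4))
  design <- build_design(pop$n_plates)
  cfg <- pool_seq_config(depth = 5000, error_rate = 0, min_alt_reads = 0,
                         min_af = 0, seed = 9)
  calls <- simulate_pool_reads(design, pop, config = cfg)
  byo <- aggregate(true_copies ~ chrom + pos + alt + orientation, calls, sum)
  wide <- reshape(byo, idvar = c("chrom", "pos", "alt"),
                  timevar = "orientation", direction = "wide")
  expect_equal(wide$true_copies.horizontal, wide$true_copies.vertical)

  # error-free, threshold-free: every carrier pool produces alt reads
  expect_true(all(calls$alt_reads[calls$true_copies > 0] > 0))
  det <- call_pool_variants(calls, cfg)
  expect_equal(nrow(det), nrow(calls))
})

test_that("detection sensitivity is monotone non-decreasing in depth", {
  gs <- synthesize_gene_set(3, seed = 31)
  pop <- simulate_population(gs, population_config(n_lines = 1152,
                                                   mu = 1.5e-5, seed = 6))
  design <- build_design(pop$n_plates)
  sens <- vapply(c(100, 500, 1000, 2000), function(depth) {
    cfg <- pool_seq_config(depth = depth, error_rate = 1e-3, seed = 77)
    det <- call_pool_variants(
      simulate_pool_reads(design, pop, config = cfg), cfg)
    dec <- demultiplex(det, design)
    screen_performance(dec, pop$truth, pop$lines)$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[4], 0.95)
})

test_that("pool VCF round-trips and records AF to 4 decimals", {
  sc <- make_screen(1, singleton_truth("M2-00050", zygosity = "hom"))
  cfg <- pool_seq_config(depth = 977, error_rate = 1e-3, seed = 2)
  genome <- Biostrings::DNAStringSet(setNames(strrep("G", 200), "c1"))
  target <- data.frame(gene_id = "g", chrom = "c1", start0 = 0, end0 = 200)
  calls <- simulate_pool_reads(sc$design, sc$lines, sc$truth, cfg,
                               genome = genome, target = target)
  expect_gt(nrow(calls), 0)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_pool_vcf(calls, f)
  back <- read_pool_vcf(f)
  expect_equal(back[names(back) != "qual"], calls[names(calls) != "qual"],
               ignore_attr = TRUE)
  expect_equal(back$qual, calls$qual, tolerance = 1e-6)

  af_txt <- regmatches(readLines(f), regexpr("AF=[0-9.]+", readLines(f)))
  expect_equal(as.numeric(sub("AF=", "", af_txt)), round(calls$af, 4))

  calls0 <- calls; calls0$depth[1] <- 0L
  expect_warning(write_pool_vcf(calls0, f), "zero depth")
})

test_that("QUAL is the error-only tail probability on the phred scale", {
  # depth 100, e = 3e-3 -> p0 = 1e-3; P(X >= 2) for X ~ Bin(100, 1e-3)
  q <- tbysim:::qual_score(2L, 100L, 3e-3)
  expect_equal(q, round(-10 * log10(pbinom(1, 100, 1e-3,
                                           lower.tail = FALSE)), 2))
  expect_equal(tbysim:::qual_score(0L, 100L, 3e-3), 0)
  expect_equal(tbysim:::qual_score(5L, 100L, 0), 999)
})
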