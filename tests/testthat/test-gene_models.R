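test_that("GFF3/FASTA loading builds the expected gene model on both strands", {
  for (strand in c("+", "-")) {
    dir <- withr::local_tempdir()
    set.seed(1)
    toy <- write_toy_gff_fasta(dir, strand)
    gs <- load_gene_models(toy$gff3, toy$fasta)
    expect_length(gs$models, 1L)
    m <- gs$models[["toyG"]]
    expect_equal(nrow(m$exons), 2L)
    expect_equal(sum(m$cds$end0 - m$cds$start0), 30L)
    expect_equal(m$strand, strand)
    # the spliced coding-strand CDS must be the one we planted
    expect_equal(tbysim:::spliced_cds(m, gs$genome), toy$cds)
    # exon space always at least covers CDS space
    expect_gte(sum(m$exons$end0 - m$exons$start0),
               sum(m$cds$end0 - m$cds$start0))
  }
})

test_that("loader fails on a CDS referencing an absent chromosome", {
  dir <- withr::local_tempdir()
  set.seed(1)
  toy <- write_toy_gff_fasta(dir)
  gff <- readLines(toy$gff3)
  writeLines(sub("^toyChr", "ghostChr", gff), toy$gff3)
  expect_error(load_gene_models(toy$gff3, toy$fasta), "ghostChr")
})

test_that("exon outside the gene span is fatal", {
  expect_error(
    gene_model("g", "c", "+", span = c(10, 50),
               exons = data.frame(start0 = 5, end0 = 20),
               cds = data.frame(start0 = 12, end0 = 18)),
    "outside gene span")
})

test_that("CDS translation matches hand examples and handles errors", {
  set.seed(2)
  gs <- make_toy_set("ATGGGAAGGTAA")
  expect_equal(translate_cds(gs$models[[1]], gs$genome), "MGR*")

  # a minus-strand gene whose plus-strand spelling is TTACCTTCCCAT
  # reverse-complements to ATGGGAAGGTAA before translation
  gsm <- make_toy_set("ATGGGAAGGTAA", strand = "-")
  m <- gsm$models[[1]]
  plus_spelled <- tbysim:::genome_seq(gsm$genome, m$chrom,
                                      m$cds$start0[1], m$cds$end0[1])
  expect_equal(plus_spelled, "TTACCTTCCCAT")
  expect_equal(translate_cds(m, gsm$genome), "MGR*")

  # CDS length not divisible by 3 is a precondition error
  gs31 <- suppressWarnings(make_toy_set(paste0("ATGGGAAGGTAA",
                                               strrep("A", 19))))
  expect_error(translate_cds(gs31$models[[1]], gs31$genome),
               "not divisible by 3")
})

test_that("translation agrees with a per-codon lookup oracle on random CDS", {
  set.seed(42)
  for (i in 1:1000) {
    k <- sample(1:50, 1)
    cds <- random_dna(3 * k)
    strand <- sample(c("+", "-"), 1)
    gs <- make_toy_set(cds, strand = strand)
    expect_equal(suppressWarnings(translate_cds(gs$models[[1]], gs$genome)),
                 oracle_translate(cds))
  }
})

test_that("internal stop codons warn but still translate", {
  set.seed(3)
  gs <- make_toy_set("ATGTAAAGGTAA")
  expect_warning(aa <- translate_cds(gs$models[[1]], gs$genome),
                 "internal stop")
  expect_equal(aa, "M*R*")
})

test_that("protein properties match hand-summed masses and charge logic", {
  p <- compute_protein_properties("GG")
  expect_equal(p$mol_wt, (2 * 57.0519 + 18.01524) / 1000, tolerance = 1e-9)

  # a single glycine's pI is the midpoint of the terminal pKa values
  expect_equal(compute_protein_properties("G")$pI, (8.6 + 3.6) / 2,
               tolerance = 1e-3)

  # basic homopolymer must out-pI an acidic one
  expect_gt(compute_protein_properties(strrep("K", 20))$pI,
            compute_protein_properties(strrep("D", 20))$pI)

  expect_error(compute_protein_properties(""), "non-empty")
  expect_error(compute_protein_properties("GGB"), "B")
})

test_that("family summary reproduces fixture statistics and a mean oracle", {
  tab <- read_family_table(tbys_example("table1_family.tsv"))
  s <- family_summary(tab)
  expect_equal(s$cds_mean, 2507.5)
  expect_equal(s$cds_min, 2409)
  expect_equal(s$cds_max, 2766)
  expect_equal(s$gene_mean, 6266)
  expect_equal(s$exon_range, c(12, 15))
  # unrounded means against the one-line oracle
  expect_equal(s$cds_mean_raw, sum(tab$cds_length) / nrow(tab),
               tolerance = 1e-9)
  expect_equal(s$gene_mean_raw, sum(tab$gene_length) / nrow(tab),
               tolerance = 1e-9)

  one <- family_summary(data.frame(gene_id = "g", gene_length = 400,
                                   cds_length = 300, exon_count = 2,
                                   protein_length = 99, pI = 7,
                                   mol_wt = 11))
  expect_equal(unlist(one[c("cds_min", "cds_max", "cds_mean")]),
               c(cds_min = 300, cds_max = 300, cds_mean = 300))
  expect_error(family_summary(data.frame()), "empty")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_family_summary(s, out)
  back <- read.delim(out)
  expect_equal(back$mean[back$metric == "cds_length"], 2507.5)
})

test_that("motif scan finds planted, absent and overlapping hits", {
  hit <- scan_conserved_motifs("AAAPDTGGQAAA")
  expect_equal(hit$motif, "PDTGGQ")
  expect_equal(hit$start, 4L)

  expect_equal(nrow(scan_conserved_motifs("AAAA")), 0L)

  both <- scan_conserved_motifs("DFIIDFII", motifs = "DFII")
  expect_equal(both$start, c(1L, 5L))

  # property: agree with a naive all-offsets oracle, including overlaps
  set.seed(9)
  aas <- c("D", "F", "I", "G", "Q")
  for (i in 1:50) {
    s <- paste(sample(aas, 60, replace = TRUE), collapse = "")
    for (motif in c("DFII", "GQ", "II")) {
      got <- scan_conserved_motifs(s, motifs = motif)$start
      expect_equal(got, oracle_motif_scan(s, motif))
    }
  }
})
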