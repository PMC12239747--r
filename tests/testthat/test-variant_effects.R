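# gene with codon 249 = GGA (CDS 745-747) and codon 486 = GGA (CDS 1456-1458)
planted_set <- function(strand = "+") {
  make_toy_set(planted_cds(500, plant = list(`249` = "GGA", `486` = "GGA")),
               strand = strand, utr5 = 9, utr3 = 9, intron_after = 900,
               intron_len = 40)
}

# genomic 1-based position of a CDS coordinate
genomic_of_cds <- function(m, cds_pos) {
  widths <- m$cds$end0 - m$cds$start0
  if (m$strand == "+") {
    off <- cds_pos - 1L
  } else {
    off <- sum(widths) - cds_pos
  }
  i <- 1L
  while (off >= widths[i]) { off <- off - widths[i]; i <- i + 1L }
  m$cds$start0[i] + off + 1L
}

test_that("classification reproduces the screen's notation for known changes", {
  set.seed(61)
  gs <- planted_set()
  m <- gs$models[[1]]

  # G746A in codon 249 (GGA -> GAA): missense G249E
  pos <- genomic_of_cds(m, 746L)
  ann <- classify_snp(m, gs$genome, pos, "G", "A")
  expect_equal(ann$effect_class, "missense")
  expect_equal(ann$cds_change, "G746A")
  expect_equal(ann$aa_change, "G249E")

  # G1456T in codon 486 (GGA -> TGA): nonsense G486*
  pos <- genomic_of_cds(m, 1456L)
  ann <- classify_snp(m, gs$genome, pos, "G", "T")
  expect_equal(ann$effect_class, "nonsense")
  expect_equal(ann$aa_change, "G486*")
  expect_equal(ann$cds_change, "G1456T")
})

test_that("wobble transitions are silent and intronic SNPs noncoding", {
  set.seed(62)
  gs <- make_toy_set(planted_cds(20, plant = list(`5` = "GGG")),
                     intron_after = 30, intron_len = 50)
  m <- gs$models[[1]]
  # third position of codon 5 (GGG -> GGA) stays glycine
  ann <- classify_snp(m, gs$genome, genomic_of_cds(m, 15L), "G", "A")
  expect_equal(ann$effect_class, "silent")
  expect_equal(ann$aa_change, "G5G")

  intron_pos <- m$cds$end0[1] + 5L  # 1-based position inside the intron
  iref <- tbysim:::genome_seq(gs$genome, m$chrom, intron_pos - 1L, intron_pos)
  ann <- classify_snp(m, gs$genome, intron_pos, iref,
                      setdiff(c("A", "C", "G", "T"), iref)[1])
  expect_equal(ann$effect_class, "noncoding")
  expect_true(is.na(ann$aa_change))

  expect_error(classify_snp(m, gs$genome, genomic_of_cds(m, 15L), "C", "A"),
               "reference mismatch")
})

test_that("classification is strand-symmetric", {
  set.seed(63)
  gsp <- planted_set("+")
  set.seed(63)
  gsm <- planted_set("-")
  mp <- gsp$models[[1]]; mm <- gsm$models[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (cds_pos in c(1L, 2L, 3L, 746L, 1456L, 900L, 1500L)) {
    pp <- genomic_of_cds(mp, cds_pos)
    pm <- genomic_of_cds(mm, cds_pos)
    refp <- tbysim:::genome_seq(gsp$genome, mp$chrom, pp - 1L, pp)
    refm <- tbysim:::genome_seq(gsm$genome, mm$chrom, pm - 1L, pm)
    expect_equal(refm, unname(comp[refp]))
    for (altp in setdiff(c("A", "C", "G", "T"), refp)) {
      a1 <- classify_snp(mp, gsp$genome, pp, refp, altp)
      a2 <- classify_snp(mm, gsm$genome, pm, refm, unname(comp[altp]))
      expect_equal(a2$effect_class, a1$effect_class)
      expect_equal(a2$cds_change, a1$cds_change)
      expect_equal(a2$aa_change, a1$aa_change)
    }
  }
})

test_that("classifier agrees with a brute-force codon oracle over a whole toy CDS", {
  set.seed(64)
  cds <- planted_cds(10)  # 30 bp
  for (strand in c("+", "-")) {
    gs <- make_toy_set(cds, strand = strand)
    m <- gs$models[[1]]
    counts <- c(missense = 0L, nonsense = 0L, silent = 0L)
    oracle_counts <- counts
    for (cds_pos in seq_len(30L)) {
      pos <- genomic_of_cds(m, cds_pos)
      ref <- tbysim:::genome_seq(gs$genome, m$chrom, pos - 1L, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        ann <- classify_snp(m, gs$genome, pos, ref, alt)
        counts[ann$effect_class] <- counts[ann$effect_class] + 1L

        # oracle: mutate the CDS string directly and translate both
        calt <- if (strand == "+") alt else chartr("ACGT", "TGCA", alt)
        mut <- cds
        substr(mut, cds_pos, cds_pos) <- calt
        aa_ref <- oracle_translate(cds)
        aa_mut <- oracle_translate(mut)
        cls <- if (aa_ref == aa_mut) "silent"
               else if (grepl("*", substr(aa_mut, ceiling(cds_pos / 3),
                                          ceiling(cds_pos / 3)),
                              fixed = TRUE)) "nonsense"
               else "missense"
        oracle_counts[cls] <- oracle_counts[cls] + 1L
        expect_equal(ann$effect_class, cls)
      }
    }
    expect_equal(counts, oracle_counts)
    expect_equal(sum(counts), 90L)
  }
})

test_that("effect tabulation counts constructed variants and conserves totals", {
  set.seed(65)
  gs <- make_toy_set(planted_cds(20, plant = list(`5` = "GGG")),
                     intron_after = 30, intron_len = 50)
  m <- gs$models[[1]]
  # three loci: G>A missense (codon 5 GGG first pos), G>A silent (codon 5
  # third pos), and an intronic change
  pos_mis <- genomic_of_cds(m, 13L)
  pos_sil <- genomic_of_cds(m, 15L)
  intron_pos <- m$cds$end0[1] + 3L
  iref <- tbysim:::genome_seq(gs$genome, m$chrom, intron_pos - 1L,
                              intron_pos)
  truth <- data.frame(
    line_id = c("L1", "L2", "L3"),
    chrom = m$chrom,
    pos = c(pos_mis, pos_sil, intron_pos),
    ref = c("G", "G", iref),
    alt = c("A", "A", setdiff(c("A", "C", "G", "T"), iref)[1]),
    zygosity = "het")
  tab <- tabulate_effects(truth, gs)
  expect_equal(sum(tab$base_changes), 3L)
  expect_equal(sum(tab$missense), 1L)
  expect_equal(sum(tab$silent), 1L)
  expect_equal(sum(tab$noncoding), 1L)
  expect_equal(sum(tab$g_to_a) + sum(tab$c_to_t) + sum(tab$other),
               sum(tab$base_changes))

  # empty input: all-zero table with one row per gene
  tab0 <- tabulate_effects(truth[0, ], gs)
  expect_equal(sum(tab0$base_changes), 0L)
  expect_equal(tab0$gene_id, names(gs$models))
})

test_that("effect classes conserve totals and order as expected on simulations", {
  gs <- synthesize_gene_set(3, seed = 41)
  pop <- simulate_population(gs, population_config(n_lines = 2000,
                                                   mu = 1e-4, seed = 8))
  tab <- tabulate_effects(pop$truth, gs)
  expect_equal(sum(tab$missense + tab$nonsense + tab$silent +
                     tab$noncoding + tab$unclassified),
               nrow(pop$truth))
  expect_equal(sum(tab$base_changes), nrow(pop$truth))
  # EMS coding spectrum: missense > silent > nonsense
  expect_gt(sum(tab$missense), sum(tab$silent))
  expect_gt(sum(tab$silent), sum(tab$nonsense))

  # variants outside any gene go to the unassigned bucket
  out <- pop$truth[1, ]
  out$pos <- 5L  # inside the flank, outside the gene span
  out$ref <- tbysim:::genome_seq(gs$genome, out$chrom, 4L, 5L)
  out$alt <- setdiff(c("A", "C", "G", "T"), out$ref)[1]
  tab2 <- tabulate_effects(rbind(pop$truth, out), gs)
  expect_true("unassigned" %in% tab2$gene_id)
  expect_equal(tab2$base_changes[tab2$gene_id == "unassigned"], 1L)
})
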