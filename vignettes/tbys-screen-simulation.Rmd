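---
title: "Models and methods behind tbysim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tbysim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbysim)
```

`tbysim` simulates and decodes TILLING-by-Sequencing (TbyS) screens of
EMS-mutagenized M2 populations. This vignette explains the models behind
each stage, the defaults and why they were chosen, and what the passing
test suite does and does not demonstrate about real screens.

## The bidimensional pooling design

Samples live in 96-well plates (rows A–H, columns 1–12). `build_design()`
assigns every well to one **horizontal** pool (its plate row combined
across a block of 4 consecutive plates: up to 4 × 12 = 48 samples) and
one **vertical** pool (its plate column combined across a triplet of
plates spaced 4 apart: up to 3 × 8 = 24 samples).

The vertical triplets are formed *within aligned blocks of 12 plates*,
as {b+i, b+i+4, b+i+8} for i = 1..4. The published description of this
strategy fixes the stride of 4 ("plate n is followed by plate n+4") but
not the block boundaries; aligning triplets to 12-plate blocks is the
choice that makes every 4-plate block intersect every triplet in exactly
one plate, which is precisely the property that guarantees a unique
(horizontal, vertical) → well decode. `verify_design()` checks the
resulting invariants (one pool per orientation per well, pool capacity,
injectivity of the pool pair) rather than assuming them, and
`decode_address()` treats an intersection larger than one well as a
fatal design error.

Plate counts that do not complete a block (screens are rarely multiples
of 12 plates) produce *reduced* pools — e.g. a single plate yields
12-sample horizontal and 8-sample vertical pools — flagged
`complete = FALSE` in the design table. Decodability is unaffected and
is exhaustively tested for a range of plate counts.

## The synthetic M2 population

`simulate_population()` generates the statistical structure a TbyS
screen assumes:

* **Mutation load.** Each line carries Poisson(μ × target bp) induced
  mutations. The default μ = 2.43 × 10⁻⁶ per bp per line is calibrated
  so that a 7,144-line screen over a 63,713 bp target space carries
  ≈ 1,108 mutations in expectation, the scale of the screen this package
  models. Loads above 50 mutations per line are refused unless
  explicitly overridden, as no plausible EMS titration produces them in
  a target of this size.
* **Substitution spectrum.** The 12 directed substitution classes get
  probabilities from a `mutation_spectrum`; the default `ems_spectrum()`
  puts 0.40 on G>A and 0.40 on C>T (the canonical EMS alkylation
  products, together 80%) and spreads the remaining 0.20 uniformly over
  the other ten classes. The class of each mutation is drawn from this
  spectrum *marginally*, and the site is then drawn uniformly among
  target positions carrying that reference base. The alternative order —
  site first, then class conditional on its base — cannot reproduce an
  80% canonical share on any sequence whose G+C content differs from
  ~88%, whereas the marginal scheme reproduces it on any target and
  matches the chemistry (EMS alkylates G/C, so mutations concentrate at
  G/C sites rather than falling uniformly).
* **Zygosity.** M2 plants descend from selfed heterozygous M1 plants;
  among M2 carriers of a mutation the hom:het ratio is 1:2, so carriers
  are heterozygous with probability 2/3. Wild-type segregants carry no
  alt allele and are absorbed into the non-carrier background — detection
  only depends on the alt copies actually present in the sampled plant.
* **Placement.** Lines fill plates in row-major well order; the line
  manifest and a truth VCF (one record per locus/alt with carrier
  line:zygosity pairs) serialize the population for replay. The whole
  population is reproducible from the config seed.

The generator emulates spectrum, density, zygosity and placement — not
chimeric M1 sectors, linkage between mutations, dose–response of the
mutagen, or cultivar-specific sequence (the mutagenesis background is a
free-text label). Passing tests therefore show that the *pipeline*
behaves correctly under the screen's assumed statistics, not that any
particular wet-lab screen met those assumptions.

### Synthetic gene models

`synthesize_gene_set()` builds target genes shaped like the screened
sucrose synthase family: CDS drawn from 2409–2766 bp in whole codons
(ATG … single stop, no internal stops), 12–15 exons, introns of
100–400 bp, 60/90 bp UTRs on terminal exons, genes alternating between
strands, one contig per gene. The screened **target space** defaults to
the exon set — the probe-covered space of a capture-seq screen — so a
small share of simulated mutations is intentionally noncoding (UTR
exon sequence).

## Pool-level sequencing and detection

Reads are modeled at the pool × site level, not as individual sequencer
reads: with c alt copies among the 2 × pool-size alleles of a pool, the
true alt fraction is f = c/(2n) and the observed alt count is
Binomial(depth, f(1−e) + (1−f)e/3) with per-base miscall probability e.
Alignment, base qualities and capture efficiency are deliberately out of
scope; the binomial site model preserves exactly the quantities the
screen consumes downstream (DP, alt reads, AF, AC). When the genome and
target are supplied, every carrier-free target site is also eligible for
error-only alt reads at rate e/3 toward a uniformly drawn non-reference
base.

Defaults: depth 2000 reads/pool/site, e = 10⁻³, detection thresholds
`min_alt_reads = 3` and `min_af = 0.5 × 1/96` (half the expected
fraction of a single heterozygous carrier in the largest pool). The
published screen names its caller and filter tools but not its depths or
thresholds, so these are declared package defaults, not inferred values;
at them, a singleton heterozygote yields ≈ 21 expected alt reads in a
48-sample pool against an error floor of ≈ 0.7, detected in far more
than 95% of replicates. `QUAL` is defined explicitly (no caller is
wrapped) as −10·log₁₀ P(X ≥ alt reads) under the error-only null
X ~ Binomial(depth, e/3), capped at 999.

Pool size is the number of *occupied* wells, so partially filled plates
raise per-carrier allele fractions exactly as they would at the bench.

## Decoding and performance

`demultiplex()` groups detected calls by variant, splits pool hits by
orientation, and decodes all (h, v) pairs at once. A variant with one
hit per orientation decodes uniquely; shared mutations (≥ 2 carriers)
produce candidate sets that are reported in full rather than resolved —
in practice such cases go to confirmatory genotyping, which the package
models only as comparison against simulation truth. Variants firing in
more than 3 pools per orientation are flagged `hyper` and excluded as
likely systematic artifacts. Orphans (one orientation only) are kept
visible rather than dropped.

`screen_performance()` scores sensitivity (truth variants decoded with
any non-absent status), unique and ambiguous decode rates, and the
false-assignment rate of unique decodes against carrier wells.

## Effect classification and reporting

`classify_snp()` maps a plus-strand SNP to its CDS coordinate
(strand-aware), rebuilds reference and alternate codons, and classifies
by standard-code translation: silent, nonsense (new stop), missense,
`noncoding` outside the CDS. Notation follows screening convention:
`G746A` (coding-strand base at CDS position) and `G249E` / `G486*`
(residue change at the 1-based codon index). Multi-isoform genes use the
longest annotated CDS. Splice-region changes are not a separate class;
the summary table has three coding classes, so non-CDS changes are all
`noncoding`. Base-change *tabulation* (the G>A / C>T / other columns)
uses plus-strand spelling — that is what a VCF records and what screen
summaries aggregate across genes on both strands; ambiguous-base codons
translate to `X` and are counted as `unclassified`.

`mutation_report()` assembles the per-gene table with totals and two
percentage rows. Both percentage rows use the **grand total of base
changes** as denominator: that convention reproduces the published
effect-class percentages (e.g. 713/1108 = 64.35%), while dividing by the
effect-class sum does not. Because some events fall outside coding
sequence, the base-change total and the effect-class sum differ; both
denominators are carried explicitly (the alternative is available via
`denominator = "effect_classes"`) and restated in the report's footnote
field. Percentages are recomputed from counts, never transcribed — which
is why the C>T share of the shipped fixture prints as 40.97, the value
its own counts imply.

## Numerical choices

* Internal coordinates are 0-based half-open; GFF3 and VCF I/O convert
  to/from 1-based. Length arithmetic is then subtraction without
  off-by-one corrections.
* Protein molecular weight is the sum of average residue masses plus one
  water; pI is found by 60 bisection steps on the net-charge function
  over pH 0–14 using the EMBOSS pKa set (N-term 8.6, C-term 3.6, C 8.5,
  D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1), frozen in the package
  constants. Published family tables computed with other pKa sets will
  differ by a few tenths of a pI unit, so exact reproduction of such
  values is not attempted.
* Protein lengths are reported stop-codon-excluded (CDS/3 − 1);
  family-table validation allows ±1 aa because published tables round
  inconsistently.
* Reported CDS-length means are rounded to one decimal and gene-length
  means to integers for display; unrounded values are kept alongside.
* FASTA sequence is uppercased on load; ties in isoform selection go to
  the first transcript in file order.
* Stage seeds derive deterministically from the run's global seed and
  the stage index, and stay below 2³¹.

## Problem sizes in the test suite

The suite exercises complete screens at reduced scale, chosen to keep
estimates statistically meaningful: exhaustive decode checks over all
1,152 wells of a 12-plate block; 1,000 random CDS for the translation
oracle; populations of ≥ 10,000 variants for spectrum and zygosity
marginals (3σ binomial checks); 200 replicates for allele-fraction and
detection-rate checks; and a 20-seed end-to-end screen (12 plates,
1,152 lines, six genes) whose pooled effect-class shares are required to
bracket the published screen's missense and nonsense percentages. The
density calibration is verified at full scale (7,144 lines × 63,713 bp),
which is cheap because only mutation counts are drawn.

## Known limitations

* No FASTQ-level simulation, alignment or caller likelihoods; the
  binomial site model ignores mapping artifacts, strand bias and
  overdispersion, so real pooled data will show a noisier error floor.
* Capture efficiency is uniform across probes and pools; real capture
  varies severalfold.
* No computational resolution of ambiguous decodes (bench confirmation
  is out of scope), and no segregation modeling beyond the carrier
  zygosity ratio.
* The effect classifier handles SNPs only — EMS produces almost
  exclusively point mutations — and does not score splice-site or
  regulatory impact.
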