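---
title: "Tracking interspecific introgression with diagnostic SNP markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking interspecific introgression with diagnostic SNP markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introgressr)
```

## The problem

When a diploid donor species (here *Brassica rapa*, genome A^r) is crossed
into an allotetraploid recipient (*B. juncea*, subgenomes A^j and B), the
resulting backcross-self (BC1S1) lines are mosaics: each A-genome segment is
donor-homozygous (class **A** = A^r A^r), recipient-homozygous (**B** =
A^j A^j), or heterozygous (**H** = A^r A^j); failed assays are missing
(**D**). Three questions drive the analysis:

1. Which SNPs discriminate the donor genome from the recipient's
   homoeologous subgenome reliably enough to serve as KASP markers?
2. Do the observed genotype frequencies match what the crossing scheme
   predicts, and where do they not (segregation distortion)?
3. How much genetic diversity do the new lines add, measured on a
   genome-wide panel rather than the sparse marker set?

`introgressr` implements this workflow end to end, with a crossing-scheme
simulator standing in for plants and resequencing data, so every statistical
claim in the package can be checked against known truth.

## The crossing-scheme model

A `cross_spec` is an ordered list of steps starting from two fully
homozygous founders: `make_f1`, `backcross_to_recipient`, `self`.
`expected_segregation()` propagates a single-locus genotype probability
vector (p_A, p_H, p_B) through these steps exactly:

* `make_f1`: (0, 1, 0);
* `backcross_to_recipient`: a parent with donor-gamete probability
  g = p_A + p_H/2 yields (0, g, 1 - g);
* `self`: A stays A, B stays B, H gives 1/4 A + 1/2 H + 1/4 B.

All intermediate values are dyadic rationals, so double-precision
propagation is exact. For BC1S1 this gives A:B:H = 1:5:2 and a theoretical
donor ("A^r") genotype frequency

f\* = p_A + p_H / 2 = 1/4,

the reference value against which observed frequencies are compared:

```{r}
expected_segregation(cross_spec(
  c("make_f1", "backcross_to_recipient", "self"), n = 1))
```

The observed counterpart is f = (2 n_A + n_H) / (2 (n_A + n_B + n_H)),
computed by `ar_frequency()` over non-missing calls.

### The simulator

`run_cross()` realizes the scheme for `n` independent lines.
Recombination follows a no-interference model: per chromosome the
crossover count is Poisson with mean equal to the map length in Morgans
and crossover positions are uniform on the cM axis, so the recombination
fraction between loci d cM apart is the Haldane value (1 − e^(−2d/100))/2.
We chose this model because the genetic-map semantics of cM assume it and
no interference estimate is available for this material. Haplotypes carry
founder origin (donor/recipient), which makes genotype truth exact and
lets tests verify that every simulated allele traces to a founder.

Selection is modeled zygotically: fitness weights (w_A, w_H, w_B) at named
loci reweight offspring genotype frequencies via rejection sampling. This
is the simplest mechanism that reproduces the recipient-skewed markers
observed in real BC1S1 material (self-incompatibility regions where donor
alleles are strongly disfavoured). Gametic-level selection would be
indistinguishable at the single-locus genotype frequencies we analyze.

`genotype_population()` turns truth into observed calls with independent
per-call error (a uniformly chosen wrong code) and missingness. The
default study conditions — ten chromosomes with the published lengths, a
132-marker panel with the published per-chromosome counts and mean
genetic intervals, six recipient parents contributing 107 plants, and a
missing rate of 322/14124 — are frozen in `a_genome_marker_summary()`,
`study_recipients()`, `study_map()` and `simulate_study_matrix()`.
Per-chromosome map spans are (count − 1) × mean interval, which makes the
simulated panel's genetic spacing match the published one; within a
chromosome markers are evenly spaced, which is idealized (real panels
cluster near centromeres less than physically uniform spacing suggests).

### What the generator does not emulate

B-genome transmission is not simulated: in this material the B
chromosomes are assayed as a presence/absence contrast, and aneuploid
transmission rates for them are not characterized, so any model would be
a guess. Genotyping error is uniform across markers (real KASP failure
is assay-specific), there is no shared pedigree between lines from the
same BC1 plant (lines are treated as independent), and map distances are
taken as exact. Passing tests therefore validate the statistical
machinery, not these biological simplifications.

## Marker design

`filter_a_genome_diagnostic()` applies the design criteria as a
conjunction of per-locus predicates: homozygous in donor and every
recipient; donor concordant with the reference; polymorphic between the
two A genomes; uniform across recipients; clean 100-bp flanking region;
no homoeologous hit in the B-progenitor genome. The last three arrive as
precomputed flags because in real data they come from alignments that are
outside this package's scope. The filters are order-independent and
idempotent; the synthetic `simulate_parental_variants()` table annotates
each locus with the criteria it violates, so the surviving set can be
compared with ground truth exactly. `filter_b_genome_detection()` mirrors
this for B-presence markers (uniform A, contrasting B homoeolog).

Even spacing (`select_evenly_spaced()`) is a greedy maximin: seed with the
candidates nearest the two chromosome ends, then repeatedly add the
candidate maximizing its minimum distance to the chosen set, ties to the
smaller position. "Relatively even" spacing can be realized many ways;
maximin is this package's design choice: it is deterministic, and on
random candidate sets its minimum pairwise gap dominates that of random
subsets of the same size. A target of 1 marker
(degenerate for two-end seeding) picks the candidate nearest the
chromosome midpoint.

`distribution_stats()` reports two physical density variants, because the
published per-chromosome densities are reproducible neither as
length/count nor as span/(count − 1): length-based (chromosome length /
marker count) and span-based (marker span / (count − 1)), plus the mean
genetic interval. Genome-wide figures are arithmetic means of
per-chromosome values; fed the published per-chromosome columns they
reproduce the published genome-wide means (2.142 Mb within the 0.001
rounding width of the printed inputs, and 6.72 cM exactly).

## Genotype matrix cleaning and projection

Missing calls are filled per line from the nearest non-missing marker in
bp on the same chromosome (`fill_missing()`); an equidistant tie goes to
the left neighbor. Nearest-neighbor is the minimal deterministic reading
of "fill from the adjacent locus"; no hidden-state smoothing is applied
because none is justified by a 132-marker panel. Per-line genotype
proportions (`per_line_summary()`) use non-missing denominators — the
choice that reproduces worked proportions such as 10.67/39.41/49.92% from
the counts (1472, 5440, 6890) — and summaries are computed on the
*unfilled* matrix, with filling applied only before projection.

`build_dense_panel()` partitions the genome into n_regions equal-width
windows (the default 2000 over this genome gives ~148-kb windows), keeps
variants homozygous in every parent and accession, and retains per window
the candidate nearest the window midpoint — at most one SNP per region.
`project_genotypes()` then assigns each panel SNP the class of the
nearest marker (same left-tie rule as the missing fill, one consistent
spatial convention across the pipeline) and instantiates alleles: A → the
donor's homozygote, B → the line's recipient parent's homozygote, H → the
heterozygous pair. Cells are stored as alt-allele dosage (0/1/2), which
represents every possible pair of parental alleles, including the case
where donor and recipient agree. Resolution is limited by marker
spacing: a line's donor-dosage fraction over the panel tracks its
marker-level donor coverage only within about one marker interval, which
the tests assert on simulated truth.

## Distortion flagging

`flag_distorted_markers()` tests each marker's 2N non-missing allele
draws against f\* with a two-sided exact binomial test,
Bonferroni-corrected across markers. The binomial treats the two allele
draws within an individual as independent; under BC1S1 the per-individual
donor-allele count is overdispersed relative to binomial (variance 1/2
versus 3/8), so the test is mildly anticonservative for unlinked loci —
acceptable for flagging, and the direction flag (above/below f\*)
carries the biological reading: markers significantly *below* f\* mark
regions where the recipient genotype is retained. No test is named in
the source material; the exact binomial with Bonferroni is this package's
choice. The package-level chi-square (`segregation_test()`) compares the
pooled A/B/H counts against the scheme's expected ratio with df = 2.

## Diversity

`ibs_distance()` uses 1 − IBS allele sharing: identical homozygotes share
2 alleles, a heterozygote shares 1 with either homozygote, opposite
homozygotes share 0; on dosages this is mean |d_i − d_j| / 2 over
pairwise-complete loci. The metric is bounded in [0, 1], matching the
magnitudes reported for this kind of material (0.03 within a narrow
heading-type group, up to ~0.33 among introgression lines); several
bounded metrics would fit that range, and 1 − IBS is the package's
documented choice.
`neighbor_join()` is a from-scratch classical NJ (Q-criterion, standard
branch-length and update formulas) with two determinism rules the
standard implementations leave open: Q ties break toward the
lexicographically smallest cluster pair, and negative branch lengths are
clamped to zero with the total deficit recorded. On additive matrices it
reproduces the generating tree to 1e-9, and it agrees topologically with
`ape::nj`, which the tests use as an independent reference.

## Pipeline and numerical conventions

`run_pipeline()` executes simulate → design → genotypes → stats →
projection → diversity from one config (R list or YAML), with pre-flight
dependency checks naming any missing input artifact. All randomness
derives from the single config seed through fixed per-stage offsets, so
each stage is independently reproducible and identical configs produce
byte-identical tabular outputs; every table carries a comment header with
the config hash. Coordinates are 1-based inclusive (VCF convention); bp
and cM must increase strictly within a chromosome; cM positions at
arbitrary bp are linearly interpolated inside the mapped span and held
flat beyond it.

Problem sizes used by the test-suite and acceptance computations are the
study's own where a size is stated (107 × 132 matrix, 2000 regions,
100 000 individuals for Monte-Carlo checks against the exact 25% value)
and deliberately small elsewhere (oracle comparisons on matrices of a few
hundred cells, NJ property tests at n ≤ 8 where exact reconstruction is
provable), which keeps the full suite under a minute without weakening
any check.

## Known limitations

* Expectations under selection are not computed; selection appears only in
  the simulator, and detection is empirical.
* The projection cannot place recombination breakpoints inside a marker
  interval; dense-panel genotypes are exactly as informative as the
  nearest marker.
* The published per-chromosome density column is reported as-is in
  "supplied values" mode; its derivation from counts and lengths is not
  reconstructable, so the package's own two density definitions are
  labeled explicitly.
* Distances among real accessions depend on real allele frequencies; the
  synthetic accession generator draws genotypes independently per locus
  and therefore carries no linkage disequilibrium or population structure.
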