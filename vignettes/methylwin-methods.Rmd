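---
title: "Sliding-window differential methylation analysis with methylwin"
author: "methylwin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window differential methylation analysis with methylwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`methylwin` analyses two-sample whole-genome bisulfite sequencing (WGBS)
data, the design typical of plant epigenomics studies that compare a mutant
to its wild type with one pooled library per genotype.  Its inputs are
per-cytosine methylation call tables (chromosome, position, strand,
sequence context, methylated read count, total read count), a reference
genome and a gene/transposon annotation.  Its outputs are genome-wide and
chromosomal methylation summaries, gene-body and transposable-element (TE)
metaprofiles, differentially methylated regions (DMRs) and cytosines
(DMCs), differentially methylated genes (DMGs), and hypergeometric term
enrichment for DMG lists.  A synthetic methylome generator with ground
truth makes every stage testable without sequencing data.

# The model and procedure

## Cytosine contexts

Plant cytosine methylation is tracked in three sequence contexts — CG, CHG
and CHH, with H one of A, C or T — read 5′→3′ on the strand carrying the
cytosine.  For a minus-strand cytosine (a G in the reference) the two
upstream reference bases are reverse-complemented before classification.
Contexts spanning an N or running off a chromosome end are undefined and
those sites are dropped from every analysis: an ambiguous base cannot
contribute a defensible count.

## Methylation levels

All levels are read-weighted: the level of a site, region, window or
profile bin is $\sum m_i / \sum t_i$ over its covered, context-matching
sites, where $m_i$ and $t_i$ are methylated and total read counts.  The
read-weighted convention is standard for WGBS because it weights evidence
by coverage; a site-weighted alternative (mean of per-site levels) is
available behind the `weighting`/`pooling` switches of `regionLevel()` and
`metaProfile()` for sensitivity analyses.

Only sites with coverage ≥ 4 enter any analysis, and any two-sample
comparison additionally requires a site to pass that floor in *both*
libraries — otherwise its 2×2 table is undefined.  Methylated *sites* (as
opposed to levels) are called by a one-sided binomial test of $m$ out of
$t$ against the bisulfite non-conversion rate, BH-adjusted at $q < 0.05$;
the non-conversion rate itself is estimated from a biologically
unmethylated control sequence (in plants, the chloroplast genome) as
$1 - \sum m / \sum t$.

## The DMR caller

The caller follows the sliding-window design used throughout the plant
WGBS literature, per context:

1. **Windows.** 200-bp windows every 50 bp along each chromosome; only
   full-size windows are formed.
2. **Window test.** Per window, pooled methylated/unmethylated read counts
   of the two samples form a 2×2 table tested with the two-sided Fisher
   exact test; p-values are Benjamini–Hochberg adjusted across all tested
   windows of that context genome-wide.  BH is stratified by context
   because CHH windows outnumber CG windows by orders of magnitude and
   joint adjustment would let CHH dominate the ranking.
3. **Filtering.** Windows with adjusted $p < 0.01$ and a level fold change
   strictly greater than 2.5 are retained.  Fold change is the ratio of
   the larger to the smaller read-weighted level; when the smaller level
   is exactly 0 and the larger is positive the fold is treated as
   infinite and passes.
4. **Candidate regions.** Overlapping or bookended significant windows of
   the same direction are unioned into maximal candidate regions, so one
   locus is not counted once per overlapping window; opposite-direction
   windows never merge.
5. **DMC refinement.** Every commonly covered context site inside a
   candidate region is tested with the same exact test; sites with
   $p < 0.01$ are DMCs.
6. **Assembly and merging.** Candidate regions containing at least 7 DMCs
   become DMRs, keeping the candidate-region extent as the reported
   interval.  Same-direction DMRs separated by ≤ 100 bp are merged, and
   levels, DMC count and fold are recomputed on the merged span so that
   reported attributes always describe the reported interval.

A DMR is *hyper*methylated when the case (sample B) level exceeds the
control (sample A) level, *hypo* otherwise; equal levels cannot survive
the fold filter.

**Reported DMR extent.**  The literature defines DMRs by their window
tests and DMC content but not their reported coordinates.  We report the
candidate-region extent (the union of significant windows).  Partially
overlapping edge windows fail the fold filter because their pooled levels
are diluted by flanking background, so in practice the union hugs the true
differential segment; trimming instead to the span of significant DMCs was
evaluated and systematically clips region edges (per-site tests at ~15×
coverage have limited power, so the outermost differential cytosines are
often missed).

The two-sided Fisher test is implemented in compiled code (an exact
hypergeometric sum with the conventional $1+10^{-7}$ tie tolerance)
because a genome-wide scan tests tens of thousands of windows per context;
the test suite verifies it against `stats::fisher.test` and against full
enumeration for every table with margins ≤ 30.

## DMGs, composition and enrichment

A gene with a DMR overlapping (≥ 1 bp, configurable) any functional
region — promoter, UTR, exon or intron — is a DMG.  Functional regions are
disjoint within a gene: positions in both UTR and exon are labelled UTR,
introns are the body minus the exons, and the promoter is the 2,000 bp
upstream of the TSS (strand-aware, clipped at chromosome edges).  The
2-kb default matches the flank width used in metaprofiles; it is a
configurable convention, not a biological constant.  Genes are
deduplicated per (context, direction) — "non-repeat" counting — while
region tallies count a gene once per region label it hits, so region
columns may exceed totals.  For DMR genomic composition each DMR is
assigned one compartment with precedence gene region > promoter >
intergenic, giving mutually exclusive fractions that sum to 1.

DMG lists can be filtered by expression (keep TPM ≥ 10) and tested for
term over-representation with the hypergeometric upper tail against a
declared background universe, BH-adjusted with significance at
FDR < 0.01.  No ontology-graph propagation is performed.

## Metaprofiles

Gene bodies and TEs are divided into 20 bins each, flanked by 2-kb
upstream/downstream regions also split into 20 bins, giving 60 ordered
bins 5′→3′ (bin 1 is the distal upstream flank; minus-strand features are
reversed).  When a body length is not divisible by 20 the remainder
widens the leading (5′-most) bins; features shorter than the bin count
are skipped with a warning.  Bin levels pool counts across features
(count-weighted), which is robust when individual features are sparsely
covered; per-feature averaging is available via `pooling = "feature"`.
Overlapping features each receive a site independently — metaprofiles are
descriptive, so double counting within a feature class is accepted.

# The synthetic methylome generator

`simConfig()`/`simulateGenome()`/`simulateMethylomePair()` emulate the
features of a two-sample plant WGBS study that the pipeline's statistics
actually consume:

* uniform-composition chromosomes with non-overlapping gene models (1–5
  exons, terminal UTRs) and TEs placed in the remaining space;
* context- and compartment-dependent true methylation levels, by default
  CG/CHG/CHH = 0.90/0.70/0.15 in TEs, 0.60/0.40/0.08 in intergenic space
  and 0.35/0.08/0.03 in gene bodies — hypermethylated TEs, CG-dominated
  gene bodies, and the CG > CHG > CHH ordering characteristic of plant
  genomes;
* per-site Poisson coverage at ~13× mean (the scale of a typical
  single-library WGBS run; 12–15× in the shipped scenarios) and binomial
  methylated counts with observed probability
  $p(1-\text{oc}) + (1-p)\,\text{nc}$, with non-conversion nc = 0.008
  (conversion rate 99.2%) and over-conversion oc = 0 by default;
* spiked ground-truth differential regions: sample B's per-site
  probability is shifted by exactly `delta` at every context-matching
  site of each truth region.  Truth regions are placed only where at
  least 10 context-matching cytosines exist (so the ≥ 7-DMC rule is
  attainable) and only where a direction exists that keeps all levels in
  [0, 1] *and* implies a level ratio above the 2.5-fold reporting
  threshold — a spiked region should be a differential region by the
  study's own definition, otherwise "truth" would be undetectable in
  principle.  When both directions qualify one is drawn at random.

Read-level noise is collapsed to per-site binomial counts: alignment is
out of scope and counts are the caller's true input, so no FASTQ/BAM is
emitted.  Coverage is Poisson rather than negative binomial; biological
replicate dispersion is not modelled because the two-group single-library
design has no replicates.  The generator does **not** attempt sequence
realism (CpG islands, repeat families, M-bias, strand-biased coverage),
so passing tests demonstrate correctness of the statistical procedure
under its stated sampling model, not robustness to artefacts real
libraries can carry.

Everything is deterministic given `seed`; the generating configuration is
recorded in each track's provenance.

# Numerical choices and degenerate inputs

* Fisher tie tolerance $1+10^{-7}$, matching the conventional
  implementation; p-values clipped at 1.
* Fold thresholds are strict inequalities (`> 2.5`), significance
  thresholds strict (`q < 0.01`), coverage and DMC floors inclusive
  (`≥ 4`, `≥ 7`), merge gap inclusive (`≤ 100`), TPM filter inclusive
  (`≥ 10`) — each matching the side of the boundary its definition
  states.
* Regions with no covered sites raise errors rather than returning 0;
  windows and profile bins with no data are flagged `NA`.
* A track whose sites are all unmethylated reports zero composition with
  an explicit flag instead of dividing by zero.
* Merging uses interval arithmetic on (start, end) only; it is idempotent
  and order-invariant, which the suite checks on random interval sets.

# Problem sizes used in the shipped checks

The test-suite simulations use 1-Mb genomes (2 × 500 kb) at 12–15× depth
for calibration and recovery runs, 200-kb single chromosomes for profile
and summary checks, and 50-kb controls for conversion-rate estimation.
These sizes give the window caller 20,000 windows per context — enough
for the BH adjustment and false-discovery behaviour to be exercised
genome-wide — while keeping a full run of the suite on a laptop-class
single core in minutes.

# Known limitations

* No biological replicates: the caller tests pooled libraries, exactly
  the two-sample design it targets; dispersion-aware designs need a
  different model.
* BH across windows treats overlapping windows as separate tests; the
  subsequent unioning removes duplicate reporting but the adjustment
  itself is approximate under that positive dependence (BH remains
  valid under PRDS).
* The promoter length (2 kb) and the minimum-overlap rule (1 bp) for DMG
  assignment are conventions; both are parameters.
* Term enrichment ignores ontology structure (no true-path propagation)
  and treats the supplied annotation as flat.
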