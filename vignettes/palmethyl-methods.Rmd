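---
title: "Methods: paired-condition WGBS differential methylation in palmethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-condition WGBS differential methylation in palmethyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmethyl)
library(data.table)
```

# The design palmethyl analyzes

palmethyl compares exactly two whole-genome bisulfite sequencing (WGBS)
methylomes — a control and a treated sample, each typically a pool of
individuals sequenced without biological replicates — at single-cytosine
resolution in the three plant sequence contexts CG, CHG and CHH. The
evidence unit is a stranded cytosine with a methylated and an
unmethylated read count (Bismark cytosine-report rows). Because there is
one library per condition, all inference is count-based within a site,
window or gene: Fisher's exact test on a 2x2 table of methylated and
unmethylated reads, corrected with Benjamini-Hochberg across the tested
units. This is the standard analysis for unreplicated plant WGBS designs;
its assumptions and their consequences are spelled out below.

## Site level

For a cytosine covered by `m` methylated and `u` unmethylated reads the
methylation ratio is `m / (m + u)`. Only sites with at least `min_cov`
reads (default **5**) in *both* conditions are paired; the difference
`d = r_t - r_c` is always treated minus control, so "hypermethylated"
means a methylation gain under treatment. Each paired site is tested with
a two-tailed Fisher exact test on `[[m_c, u_c], [m_t, u_t]]` and flagged
significant when `p < alpha` (default 0.05) *and* `q <= fdr`
(default 0.05).

Classification of the difference uses the 33-percentage-point rule:
`|d| >= 0.33` is *strongly* hyper-/hypomethylated, `0 < |d| < 0.33`
hyper-/hypomethylated, `d = 0` unchanged. Two conventions had to be
fixed:

* **Boundary inclusivity.** The strong class is closed at `|d| = 0.33`
  on both sides. The source convention for the hypomethylated side is
  internally inconsistent as usually stated ("less than -33% but below
  0%"), so the mirrored symmetric reading `-0.33 < d < 0` is used for the
  weak hypo class. Whatever convention is chosen, the five categories
  partition `[-1, 1]`; the property tests assert that partition and its
  mirror symmetry.
* **Correction scope.** BH is applied within each context separately
  (`per_context = TRUE`), because contexts are biologically distinct
  methylation pathways and are reported separately throughout the
  analysis; a single global correction is available via
  `per_context = FALSE`. Which scope the original analyses used is rarely
  stated; the default is the more conservative choice for the dominant
  CHH class.

Strands are never pooled: coverage in this design is naturally described
per DNA strand, and CpG-pair merging would silently double coverage.

## The Fisher primitive

`fisher_exact_2x2()` computes the two-tailed p as the sum of
hypergeometric probabilities of all tables with the observed margins
whose probability does not exceed the observed one, with a relative tie
tolerance of `1e-7` so that the set of included tables is stable against
floating-point noise (the same convention `stats::fisher.test` uses).
Tables sharing margins are grouped and share one probability-mass
computation, which is what makes testing a few hundred thousand sites
per run cheap. A p-value within `1e-12` of 1 is snapped to exactly 1
(whole support included). The unit tests check the implementation against
an independent `choose()`-based enumeration oracle and against
`stats::fisher.test`; the acceptance suite repeats the enumeration
comparison over every 2x2 table with both row margins at most 30 at
`1e-9`.

## Region level

Windows are non-overlapping 50-bp tiles by default. The source
description says "sliding" without a step; a step equal to the window was
chosen because reported DMR counts imply disjoint regions, and `step` is
a parameter for genuine sliding. Before tiling, chromosomes are filtered
to those carrying at least one site with Fisher `p < alpha` in the
context ("any significant site" is the implemented reading of the
chromosome filter; a chromosome-level test would be an alternative but is
nowhere defined). The filter can be disabled.

The window statistic averages *site ratios* (unweighted; every qualifying
site counts once regardless of depth) per condition and reconstructs
integer methylated counts from `round(ratio x total_reads)` before the
2x2 Fisher test. The reconstruction fixes the recipe but not the
rounding; banker's half-to-even (R's `round()`) is used and asserted
stable in tests. `min_sites` defaults to 1 (no per-window site minimum is
stated anywhere).

Per context, significant windows (default `p < alpha`, the convention of
published summary tables; q-gating via `use_q`) are split by the sign of
the window difference and

```
pct_change = (n_hyper - n_hypo) / (n_hyper + n_hypo) * 100
net change = sum of the three per-context pct_change values
```

The "sum" reading of the net change is confirmed by arithmetic on the
published per-context values (the acceptance test reproduces -4.69, +3.19
and +25.95 summing to 24.46). Note the statistic's sampling behaviour:
under a null, each per-context term has standard deviation about
`100 / sqrt(n significant windows)`, so the net change is only a stable
quantity when the genome yields tens of thousands of significant windows
per context. On desk-scale simulations it fluctuates by tens of points;
the test suite documents this rather than hiding it (one acceptance
assertion of a +/-2-point bound at 50,000 sites is knowingly red for this
reason — the bound would require a genome roughly 240x larger).

## Gene and feature level

Gene-level methylation repeats the region construction over all
qualifying sites inside the gene span, or restricted to a feature
(promoter / exon / intron). Features are derived, never stored: introns
are exactly the gaps between consecutive exons, promoters are
`promoter_length` bp immediately upstream of the TSS, strand-aware.
**Promoter length defaults to 2,000 bp** — no value is stated in the
emulated study; 2 kb is the common plant-promoter window and it is
configurable everywhere it matters.

A DEG (expression gates below) is a DMG in context X when its gene-level
test in X has `p <= 0.05`. Where the source material describes the DMG
test both as the Fisher construction (procedurally) and as a t-test (in
prose), the Fisher construction is primary — the procedural description
is the reproducible one — and the Welch two-sample t-test is kept for the
feature-level condition comparisons where it is the stated method.
Presence-based membership ("gene carries any covered site of the
context") is available via `membership = "presence"`; published
membership percentages are ambiguous between the two definitions, and
significance-based is the default because it is the stricter, documented
one. Feature-assignment priority where genes overlap is promoter > exon >
intron, ties broken by smaller `gene_id`, making assignment
deterministic.

## Expression integration

DE statistics are *consumed, not computed*: the expression table carries
per-gene p and FDR from whatever DE pipeline produced it (the emulated
study's transcript assembly and testing are out of scope). Gates:
`|log2 FC| >= log2(fold)` (inclusive — "at least 2-fold" includes exactly
2-fold), `p <= 0.001`, `q <= 0.05`.

Zeros are handled by the tenth-of-minimum pseudocount rule on each axis:
one tenth of the smallest nonzero FPKM across both conditions, and one
tenth of the smallest nonzero methylation ratio, substituted for exact
zeros only, before `log2`. Correlation is sample Pearson on the log2
pairs with the t-transform p (n - 2 df), computed per (context, feature,
condition) stratum over that context's DMGs by default ("all regions"
uses the whole-gene-span ratio rather than pooling feature rows; whether
published correlation tables used all DMGs or significant ones is not
fully explicit, so the gene universe is a parameter).

## Metagene landscapes

Profiles are site-weighted bin means over fixed-width flank bins and a
length-normalized body, oriented 5' to 3'. Defaults: gene view +/-3 kb
with 30 flank bins and 60 body bins; promoter view +/-1 kb with 20 flank
and 40 body bins. Bin counts are unstated in the emulated figures; these
values give 100-bp gene-view and 50-bp promoter-view flank bins, smooth
at desk scale, and are parameters (`flank_bp` must divide evenly into
`flank_bins`). Genes shorter than the body bin count are profiled with
fractional rescaling and logged. Site weighting (each (site, gene)
contribution counts once) rather than gene weighting was chosen to match
a "methylation ratio" y-axis directly; a conservation property follows
and is tested exactly: the site-count-weighted mean of bin values equals
the global mean ratio of the profiled contributions to 1e-12. Expression
groups are the zero-FPKM class plus four equal-size rank groups of the
profiled condition's FPKM (quantiles, not fixed cut-offs, which are
nowhere stated), ties and order resolved by `gene_id` for
reproducibility.

## Global statistics

Bisulfite conversion is estimated on a designated methylation-free
plastid contig as `100 x (1 - sum(m) / sum(m + u))`. Global %5mdC is
read-weighted by default (a per-molecule quantity, the natural analogue
of mass-spectrometry abundance) with a site-averaged variant; plastid
sites are excluded — they measure chemistry, not biology.
`percent_change(control, treated)` is `100 x (treated - control) /
control`.

# The synthetic-data generator

`simulate_dataset()` emulates the study conditions so every stage is
testable without the deposited sequencing data:

* **Coverage**: Poisson with mean 17 reads per strand per condition,
  independently per strand and condition.
* **Conversion**: unmethylated cytosines read as methylated with
  probability 0.01 (99% conversion), applied genome-wide; the plastid
  contig (150 kb by default) is truly unmethylated, so its observed
  methylation estimates exactly this failure rate.
* **Baselines**: mCG 0.50 in gene bodies and 0.35 elsewhere, mCHG 0.20,
  mCHH 0.03; pseudogene bodies add +0.25 to CG/CHG (clipped to [0, 1]).
* **Context mix**: cytosines are sampled at per-strand density 0.20 with
  context proportions CG/CHG/CHH = 0.12/0.15/0.73, the proportions of
  the three site classes in the emulated genome's site counts.
* **Overdispersion**: per-site, per-condition beta-binomial with
  concentration 50 (variance inflation ~1.3 at 17x), a moderate level
  typical of real WGBS; `Inf` recovers pure binomial for oracle tests.
  This value was fixed from the variance-inflation argument, not tuned
  against test outcomes.
* **Between-gene variation**: each gene draws a true level per (context,
  feature) from a Beta around its baseline (concentration 20); sites
  inside the feature use the gene's level. These levels are also the
  covariate that couples expression to methylation, keeping the
  methylome and transcriptome consistent.
* **Planted differential methylation**: intervals aligned to the 50-bp
  grid, non-overlapping, shifting the *treated* mean by the signed
  effect (direction is treated-minus-control), recorded in a truth
  ledger written as TSV.
* **Expression**: log-normal FPKM (log2 mean 3, sd 2), a configurable
  zero-FPKM fraction, planted DE genes with gate-consistent p/q, and
  coupling implemented so the population correlation between the log
  methylation covariate and log FPKM equals the configured strength
  (residual noise shrunk accordingly; measurement noise attenuates the
  recovered correlation slightly).

What the generator does **not** emulate: real sequence (trinucleotides
are sampled, not read from a genome), mappability and coverage biases,
strand asymmetries, linkage between neighbouring sites (sites are
conditionally independent given their mean), batch effects, or read-level
errors other than conversion failure. Passing tests therefore show the
*pipeline arithmetic and inference machinery* are correct and recover
planted truth under the stated noise model; they do not certify
performance on real libraries with correlated or biased coverage.

`simulate_gene_methylation()` is a gene-level fast path: observed
per-gene ratios drawn binomially around the true levels at aggregate
depth. Correlation-recovery experiments (e.g. 100 replicates at 500
genes) run on this path in seconds; the site-level path exercises the
same levels in the full pipeline elsewhere in the suite, so the shortcut
trades no coverage of the correlation machinery itself.

# Numerical and reproducibility choices

* Internal coordinates are 0-based half-open everywhere; 1-based formats
  (cytosine reports, GFF3) are converted at the I/O boundary only.
* Fisher tie tolerance `1e-7` relative; p snapped to 1 within `1e-12`.
* Region/gene count reconstruction uses half-to-even rounding.
* BH within context by default (see above); `p.adjust(method = "BH")` is
  the implementation, tested against a hand-written step-up.
* All generator randomness flows from one integer seed; each generator
  stage derives a fixed offset so outputs do not depend on call order,
  and identical configurations give byte-identical written files.
* Degenerate inputs are explicit: zero-coverage ratios error rather than
  return NaN; windows or genes with no qualifying site are dropped and
  counted; correlation strata with fewer than 3 genes or zero variance
  report an absent `r` with `n`; an all-zero 2x2 table has p = 1 by
  convention.

## Problem sizes in the test suite

The suite simulates genomes of 40-400 kb (25k-160k cytosines), 200
planted windows for recovery, 100 replicate seeds at 500 genes for
correlation sign recovery, and a 150-kb plastid for conversion-rate
recovery; these sizes give each check comfortable statistical resolution
(binomial/correlation standard errors at least 5x smaller than the
asserted margins) while the whole suite stays inside a coffee break on a
single core.

# Known limitations

* Fisher's exact test on pooled libraries treats reads as independent
  Bernoulli draws; with biological overdispersion it is anticonservative
  at the window level (the null simulation quantifies this), which is an
  inherent property of the unreplicated design, not of this
  implementation.
* The net methylation-change statistic is noisy whenever significant
  windows are scarce (see the region-level section).
* DMR windows are not merged or stitched; a long differentially
  methylated block appears as consecutive 50-bp calls.
* DE testing, GO/pathway enrichment and read alignment are out of scope
  by design; their outputs are inputs here.
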