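---
title: "Methods and models in rddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models in rddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddm)
```

`rddm` re-implements, as a tested and reusable toolkit, the analysis chain
used to characterize components of the plant RNA-directed DNA methylation
(RdDM) pathway: differential DNA methylation from whole-genome bisulfite
sequencing, hits-normalized small-RNA quantification and siRNA-cluster
calling, mutant-panel classification of siRNA classes, input-normalized
ChIP enrichment, cross-omic integration summaries, and one-site binding
quantification from isothermal titration calorimetry (ITC). This vignette
explains each model, its assumptions, the tunable parameters, and the
synthetic-data generators that provide ground truth for benchmarking.

## Coordinate conventions

All intervals inside the package are tibbles with 0-based, half-open
coordinates (`start` inclusive, `end` exclusive). One-based coordinates
exist only at file boundaries: GFF3 and methratio-style TSVs are converted
on read. This removes off-by-one ambiguity between the tiling, windowing
and overlap modules; interval overlap itself is delegated to
`GenomicRanges`. Strand is carried on every record but deliberately
ignored by all window aggregation — methylation tiles and siRNA windows
pool both strands, as is standard for these assays. Chromosome output
order is lexicographic so that repeated runs diff cleanly.

## Differential methylation and DMR calling

Per-cytosine methylated/total counts are summed per sample and context
over a fixed grid of 500-bp tiles (`tile_size`). Each tile is tested for a
methylation difference between a treatment group (typically the pooled
replicates of two mutant alleles, giving one DMR set per genotype
contrast) and a control group with a likelihood-ratio test of a binomial
logistic regression of methylation on group membership. Because the
group-wise maximum-likelihood estimates of such a model are the pooled
group proportions, the per-sample likelihood collapses analytically into
the G-statistic of the pooled 2x2 table; `diff_methylation()` computes
this closed form, and the test suite verifies equality with `stats::glm`
deviances. When either group has a single sample the regression adds
nothing over the pooled table and the test falls back to Fisher's exact
test (our own hypergeometric enumeration, checked against
`stats::fisher.test`).

The effect size is `meth_diff = 100 * (p_treatment - p_control)` in
percentage points, so mutant hypomethylation is negative and always maps
to `direction = "hypo"`. Tiles with pooled coverage below `min_coverage`
(default 10 reads per group; the upstream method's coverage handling is
not specified, so this is exposed as configuration) are excluded as
untestable rather than failing. Multiple testing uses Benjamini-Hochberg,
a standard and monotone choice; we make no attempt to reproduce any
particular package's alternative q-value scheme or overdispersion
correction. Tiles pass at `|meth_diff| >= 8` pp and `q < 0.01` (the
conventional thresholds for this assay), and overlapping or book-ended
passing tiles of the *same* direction merge into one DMR; opposite
directions never merge because direction is part of the DMR definition.

DMR identification runs on all contexts combined; CG/CHG/CHH levels are
then reported descriptively per region with `context_levels()`
(coverage-weighted `sum(n_meth) / sum(n_total)`; a region with no covered
cytosine is `NA`, never 0). `pca_window_matrix()` emits the 50-kb/10-kb
sliding-window level matrix used for sample-concordance PCA; the
decomposition itself is ordinary `prcomp` and is not wrapped.

## Hits-normalized small-RNA abundance (HNA)

Small-RNA libraries are represented as distinct sequences with per-library
read counts and the set of genomic loci each sequence matches perfectly.
The quantification chain is:

1. **Library totals first.** RPTM (reads per ten million) normalizes each
   sequence's count by the total genome-matched reads of its library.
   The totals are computed *before* length filtering and structural-RNA
   exclusion, matching the stated normalization basis; `srna_totals()`
   exists so pipelines can bank the denominators before filtering.
2. **Filtering.** Sequences outside 18-31 nt are dropped, and a sequence
   is removed entirely if any of its loci overlaps an annotated
   tRNA/rRNA/snRNA/snoRNA by >= 1 bp (degradation products). The filter
   is idempotent.
3. **HNA.** Each sequence's RPTM is divided equally over its hits — the
   number of loci it matches, capped at `max_hits = 10` to mirror the
   `-k 10` reporting limit of the upstream aligner; loci beyond the cap
   (in coordinate order, a deterministic stand-in for the aligner's
   arbitrary subset) are dropped from assignment. With `max_hits = Inf`
   the assignment conserves RPTM exactly, which the tests use as a global
   accounting oracle: the genome-wide sum of window HNA equals the summed
   RPTM of retained sequences.
4. **Windows.** Loci are assigned to non-overlapping 200-bp windows by
   their 5' start coordinate (left end on the plus strand, right end minus
   one on the minus strand) — an unambiguous rule for loci that straddle a
   window edge. Windows carry both all-sizes HNA and 24-nt-only HNA.
5. **Depletion calling.** Replicates are combined by the arithmetic mean
   of window HNA per genotype (the simplest symmetric choice; pooling is
   a trivial variant the caller can apply upstream). A window is an
   siRNA-depleted region when WT + mutant all-sizes HNA is at least 25
   (adequate accumulation in WT) *and* the mutant shows a >= 2-fold
   reduction. A cluster is one 200-bp window; `merge_adjacent = TRUE`
   optionally merges book-ended calls, since whether published cluster
   counts reflect merged or raw windows is not stated.

`region_abundance()` sums window HNA over arbitrary regions by window
midpoint, which is how per-region 24-nt siRNA levels and genotype
differences (`region_sirna_delta()`) are computed.

## siRNA classes from a mutant panel

RdDM separates into an upstream arm (Pol IV-dependent siRNA biogenesis)
and a downstream arm (Pol V/DRM2-dependent methylation guidance).
`classify_sirna()` turns per-window depletion calls in a mutant panel into
the standard classes: depleted in *nrpd1* only (`PolIV_only`, upstream),
depleted in *nrpd1* and in all downstream mutants (`PolV_dependent`,
downstream), depleted nowhere (`unaffected`), and anything else (`other`).
The downstream requirement is an AND over `{nrpe1, drm2}` by default
because downstream siRNAs are reduced in both mutants; a single-mutant
definition (`polv_requires = "nrpe1"`) is available since the boolean
form is a modelling choice, not something the data dictate. The labels
are a partition by construction, and `class_contingency()` cross-tabulates
a factor mutant's depletion against them.

## ChIP enrichment

Fragment counting follows featureCounts `-p -O` semantics: a paired-end
template interval increments every region it overlaps by >= 1 bp, at most
once per region. Fragments are assumed uniquely mapped and deduplicated
by their producer. Enrichment is exactly

```
log2((1 + n_ChIP) / N_ChIP) - log2((1 + n_Input) / N_Input)
```

with `n` the region counts and `N` the total mapped unique fragments per
track. The pseudocount keeps zero-count regions finite and cancels when
both tracks agree; the formula is antisymmetric under swapping tracks and
strictly increasing in `n_ChIP`. `ranked_profile()` orders regions by
their siRNA change (WT minus mutant 24-nt HNA), smooths enrichment with a
centred rolling mean (`smoothing_k = 50` regions by default; the choice
is cosmetic and documented rather than inferred, since no published
smoothing is specified) and reports the Spearman correlation, which is
the quantitative content of "enrichment tracks siRNA dependence" claims.
An all-tied enrichment vector has no rank signal and is reported as
correlation 0. `metagene_profile()` scales gene bodies to a fixed number
of bins with fixed-width flanks, reversing minus-strand genes, and applies
the same enrichment formula to pooled bin counts.

## Cross-omic integration

`overlap_stats()` counts members of set A overlapping (>= 1 bp) at least
one member of B — a directional quantity — and formats the percentage
rounded half-up to an integer, the convention used when reporting DMR-set
overlaps. `feature_composition()` assigns each region one label with
precedence TE > gene > intergenic (a TE inside a gene counts as TE, the
convention of TE-composition summaries in this field); the precedence is
an argument because fractional assignment is a defensible alternative.

## One-site ITC model and fitting

`predict_heats()` implements the single-site (Wiseman) binding isotherm
with stepwise displacement-dilution accounting: each injection of volume
`v` into a cell of volume `V0` first displaces an equal volume of
pre-injection solution (concentrations scale by `1 - v/V0`), ligand is
added, and the bound complex `[PL]` re-equilibrates from the quadratic
mass-action equation with total sites `n * [M]` and association constant
`Ka`. The heat of injection `i` is `dH * V0 * ([PL]_i - [PL]_{i-1} *
(1 - v_i/V0))`, expressed per mole of injectant so that pre-saturation
plateau heats approach `dH` and the fitted enthalpy matches the
generating one. The displaced complex leaves the cell unreacted, so the
running heat total closes against `dH * V0 * ([PL]_final + displaced
complex)`; a test verifies this identity to 1e-6.

`fit_itc()` estimates `(n, log Ka, dH)` by Levenberg-Marquardt least
squares (`minpack.lm`), the log parameterization keeping `Ka` positive;
standard errors come from the Jacobian, with `Kd = 1/Ka` by the delta
method. A Wiseman c-value (`n * Ka * [M]`) outside [1, 1000] triggers a
warning because the isotherm shape then constrains `Ka` poorly. On
noiseless synthetic titrations the fit recovers the generating parameters
to better than 1e-4 relative. With constant-amplitude Gaussian noise at
5% of `|dH|` on the default protocol (19 x 2 uL of 1.2 mM ligand into
0.1 mM protein, 200-uL cell), individual fits show a Kd spread of roughly
15-25% — the information limit of that protocol, since unweighted least
squares is already the maximum-likelihood estimator for constant noise —
while the median over seeded replicates is unbiased to a few percent.
When the noise instead scales with the heat amplitude, passing
`weights = 1/heat^2` makes the weighted fit the MLE and brings single-fit
Kd errors under 10%. Both regimes are exercised in the tests.

## Synthetic data and what it does (not) show

Every stage has a generator that emits data *and* the planted truth, so
no ground truth is ever re-derived from the data:

- `simulate_genome()` lays out non-overlapping genes, TEs and structural
  RNA loci with gamma-distributed lengths around typical plant sizes
  (3 kb TEs, 2 kb genes) and random gaps; realized TE/gene bp fractions
  match the requested ones up to placement noise.
- `simulate_methylome()` puts cytosines on a regular grid (8-bp spacing,
  context mix 20% CG / 20% CHG / 60% CHH) with TE-elevated baselines
  (CG 0.8, CHG 0.4, CHH 0.15 inside TEs, near zero outside) — the
  TE-concentrated methylation regime of a plant genome. Coverage is
  Poisson (default mean 20), methylated counts binomial, and planted
  hypo-DMRs shift the mutant's per-context probabilities by configured
  deltas. The benchmark deltas (CG -40, CHG -30, CHH -12 pp) give an
  aggregate tile difference of roughly -20 pp. No generative parameters
  for real methylomes are available, so these values were fixed once to
  mimic the qualitative regime, not fitted to anything.
- `simulate_srna_library()` emits mostly-24-nt multimapping families at a
  nominal depth of 2e7 genome-matched reads per library — a realistic
  small-RNA library size under which a planted window HNA of 40
  corresponds to ~80 reads, so Poisson count noise keeps recovered HNA
  within ~15% of target. Background families have identical expected
  abundance in both genotypes and avoid the planted windows and
  structural RNAs, so the planted truth is clean; decoy families inside
  structural RNAs exercise the exclusion filter.
- `simulate_chip()` draws input fragments uniformly outside the planted
  regions and ChIP fragments with per-region rate multipliers `2^e`, so
  realized enrichment converges to the planted `e` as fragments grow.
- `simulate_itc()` is the isotherm model plus i.i.d. Gaussian noise.

These generators validate the *computational* chain: coordinate handling,
normalization accounting, test calibration, and parameter recovery under
the stated noise models. They do not emulate sequence composition,
mapping ambiguity from real repeat structure, bisulfite conversion
failure, batch effects, or chromatin-dependent fragment biases — so
passing benchmarks demonstrate correctness of the methods, not expected
performance on any real library.

## Problem sizes and numerical choices

The shipped benchmarks use two 300-kb chromosomes for DMR recovery
(~1,200 testable tiles, 6 samples at 20x), 1e4 distinct sequences for the
HNA conservation check, 1e5 window pairs for the depletion-rule check,
1e6 fragments per ChIP track, and 20 seeded replicates per ITC recovery —
sizes at which every property is sharp while the whole suite runs in a
couple of minutes on one CPU. Ties in DMR merging cannot occur (grid
tiles are disjoint); ties in Spearman correlation are handled by the
standard mid-rank convention, and an all-tied profile reports 0. The
equilibrium quadratic is solved in its numerically stable root form, and
a negative discriminant — impossible for physical inputs — is guarded
with an explicit error.

## Command-line use

`inst/scripts/rddm.R` wraps the exported functions as thin subcommands
(`simulate`, `dmr`, `srna-deplete`, `classify`, `chip-enrich`,
`integrate`, `itc-fit`) for shell pipelines. Configuration files are YAML
with keys mirroring `pipeline_config()`; precedence is flag > file >
default. Every run writes a JSON manifest with input digests, the
effective configuration, the seed and the package version — also on
failure — so runs are reproducible and auditable. Logs go to stderr, data
to files.

## Known limitations

- The differential test assumes within-group binomial homogeneity;
  replicate overdispersion beyond pooling is not modelled.
- The `max_hits` cap drops loci deterministically by coordinate order,
  which matches no particular aligner's arbitrary choice; uncapped mode
  exists for exact accounting.
- `metagene_profile()` pools counts across genes before forming the
  enrichment ratio, so long genes weigh more than short ones within a
  bin.
- The ITC module fits reduced per-injection heats; baseline drift and
  peak integration from raw power traces are upstream of its scope, as
  are multi-site and competitive binding models.
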