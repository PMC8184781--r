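# rddm

Analysis toolkit for RNA-directed DNA methylation (RdDM) studies in
plants. In *Arabidopsis*, 24-nt siRNAs produced by the Pol IV arm of the
pathway guide the Pol V/DRM2 arm to deposit de novo cytosine methylation
at transposable elements; genetic dissection of the pathway rests on a
recurring computational chain that this package implements as tested,
reusable tibble-first functions:

- **Differential methylation** from whole-genome bisulfite data:
  per-cytosine counts are summed over 500-bp tiles, each tile is tested
  with a likelihood-ratio test of a binomial logistic regression of
  methylation on genotype (Fisher's exact test when a group has one
  sample), and tiles with |Δmethylation| ≥ 8 pp and BH q < 0.01 merge
  into differentially methylated regions (DMRs).
- **Hits-normalized small-RNA abundance (HNA)**: per-sequence counts are
  scaled to reads per ten million (RPTM), a sequence's RPTM is divided
  equally over the loci it matches (its "hits", capped at 10), per-locus
  contributions are summed in 200-bp windows, and a window is an
  siRNA-depleted region when WT + mutant HNA ≥ 25 with a ≥ 2-fold
  reduction in the mutant.
- **siRNA class logic**: windows are classified from a mutant panel into
  Pol IV-only (upstream) and Pol V-dependent (downstream) siRNAs, and
  cross-tabulated against a factor mutant of interest.
- **ChIP enrichment**: fragment counts per region converted to
  `log2[(1 + n_ChIP)/N_ChIP] − log2[(1 + n_Input)/N_Input]`, with
  ranked-region profiles against siRNA change and metagene profiles.
- **Integration**: DMR-set overlap percentages, TE/gene/intergenic
  composition, methylation change at siRNA clusters and siRNA change at
  DMRs.
- **ITC**: the one-site (Wiseman) binding isotherm with
  displacement-dilution accounting, simulated titrations, and
  Levenberg–Marquardt fitting of (N, K<sub>a</sub>, ΔH) with
  K<sub>d</sub> = 1/K<sub>a</sub>.
- **Synthetic data with planted truth** for every stage, so each method
  is benchmarked against known ground truth.

Inputs are the standard text formats of the field (methratio-shaped TSV,
BED, GFF3, SAM, CSV); every user-facing function takes a data frame and
returns a tibble, results have `tidy()`/`glance()`/`autoplot()` methods
where that helps, and a thin command-line front end
(`inst/scripts/rddm.R`) wraps the main stages for shell pipelines.

## Worked example

Simulate a small genome with hypomethylated regions planted inside TEs,
call DMRs, and summarize their composition:

```r
library(rddm)
library(dplyr)

ann <- simulate_genome(n_chrom = 2, chrom_len = 3e5, te_fraction = 0.35,
                       gene_fraction = 0.25, seed = 71)
tes <- ann$tes |> filter(end - start >= 2000) |>
  group_by(chrom) |> slice_head(n = 3) |> ungroup()
planted <- tibble::tibble(chrom = tes$chrom,
                          start = ceiling(tes$start / 500) * 500,
                          end = floor(tes$end / 500) * 500,
                          d_cg = -40, d_chg = -30, d_chh = -12)

sim <- simulate_methylome(ann, planted, coverage_mean = 20, seed = 72)
tiles <- tile_methylation(sim$calls, ann$chrom_sizes, tile_size = 500)
res <- diff_methylation(tiles, treatment = c("mut_r1", "mut_r2"),
                        control = c("WT_r1", "WT_r2"))
call_dmrs(res, diff_threshold = 8, q_threshold = 0.01)
#> # A tibble: 6 × 7
#>   chrom start   end direction meth_diff  q_value n_tiles
#>   <chr> <dbl> <dbl> <chr>         <dbl>    <dbl>   <int>
#> 1 chr1   3000  6000 hypo          -20.7 4.52e-85       6
#> 2 chr1  20000 22500 hypo          -20.9 3.36e-85       5
#> 3 chr1  38500 41500 hypo          -21.0 1.70e-82       6
#> 4 chr2   4000  5500 hypo          -21.8 1.05e-83       3
#> 5 chr2  14500 18000 hypo          -20.8 3.50e-86       7
#> 6 chr2  29000 31000 hypo          -20.2 3.24e-81       4
```

All six planted regions come back as hypo-DMRs with tile-mean
methylation losses of ~21 pp (the planted per-context deltas average to
−20 pp over the simulated context mix), and their composition is 100% TE,
as planted. Fitting a noisy synthetic ITC titration generated at
K<sub>d</sub> = 1.47 µM:

```r
truth <- itc_params(n_stoich = 1, kd = 1.47e-6, dh = -10)
fit <- fit_itc(simulate_itc(truth, noise_sd = 0.5, seed = 1))
fit
#> <itc_fit> one-site binding model
#> <itc_params> N = 0.982, Ka = 6.971e+05 M^-1 (Kd = 1.435 uM), dH = -10 kcal/mol
#>   Kd = 1.43 uM, c = 68.5, converged: TRUE
tidy(fit)
#> # A tibble: 4 × 3
#>   term     estimate std_error
#>   <chr>       <dbl>     <dbl>
#> 1 n_stoich  9.82e-1   1.84e-2
#> 2 ka        6.97e+5   1.98e+5
#> 3 dh       -1.00e+1   2.66e-1
#> 4 kd        1.43e-6   4.07e-7
kd_fold_ratio(22.9, 1.47)
#> [1] 15.57823
```

The fit recovers the generating constant within a few percent
(K<sub>d</sub> = 1.43 µM vs 1.47 µM, stoichiometry 0.98 vs 1) and the
fold-affinity ratio between a 22.9-µM and a 1.47-µM interaction is
15.6-fold. `autoplot(fit)` draws the isotherm with the fitted curve.

See `vignettes/rddm-methods.Rmd` for the models, assumptions, parameter
choices, and what the synthetic benchmarks do and do not demonstrate.

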