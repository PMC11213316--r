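# nkdmr — normalized kernel-weighted DMR detection

`nkdmr` detects **differentially methylated regions (DMRs)** — contiguous
stretches of CpG sites whose methylation differs between two biological
conditions — from Illumina-style methylation-array data (450K/EPIC-scale
probe layouts). It is aimed at epigenomics analysts who have a normalized
β-value (or M-value) matrix, a probe annotation, and a two-group (optionally
paired, covariate-adjusted) sample design, and who want region calls that are
well calibrated in sparse probe territory, not only in CpG-dense islands.

## The method

Per-probe evidence comes from limma: M-values `M = log2(β/(1−β))` are fit
with a linear model (condition + covariates + optional subject blocks), and
empirical-Bayes variance moderation yields a moderated t-statistic `t_j` with
total degrees of freedom `ν = df_residual + d0`. The squared statistic
`y_j = t_j²` is then smoothed along each chromosome with **normalized**
Gaussian-kernel weights:

```
S(x_i) = y_i + Σ_{j≠i} w_j(x_i) y_j ,   w_j(x_i) = K((x_j−x_i)/h) / Σ_{j≠i} K((x_j−x_i)/h)
```

with `K(z) = exp(−z²/2)`. Because the neighbor weights of every site sum to
one, each neighborhood contributes a fixed total of information regardless of
local probe density — this is what removes the density bias of raw-kernel
smoothing. Two bandwidth rules are provided:

* **faDMR** — fixed `h = 500` bp on every chromosome;
* **aaDMR** — array-adaptive: `h` equals the median probe spacing of each
  chromosome, so the smoother tracks the spacing of whatever array (450K,
  EPIC, or denser) produced the data.

Under the null, `y_j` is approximately χ²₁ for the large `ν` that variance
moderation provides, so `S(x_i)` is a weighted sum of scaled χ² variables
with mean `1 + Σw_j` and variance `2(1 + Σw_j²)`. Satterthwaite moment
matching approximates `S(x_i) ~ p_i · χ²(q_i)` with

```
p_i = (1 + Σw_j²) / (1 + Σw_j),   q_i = (1 + Σw_j)² / (1 + Σw_j²)
```

giving a per-site p-value from the χ² upper tail of `S/p_i`. P-values are
Benjamini–Hochberg adjusted across all sites genome-wide; sites with adjusted
p < α (default 0.05) are chained into regions whenever consecutive
significant sites lie within `g = 1000` bp, and each region is ranked by its
minimum member p-value.

The package also ships the benchmarking apparatus: an array-layout emulator
(clustered probe spacing with promoter-like candidate regions), a
beta-distribution simulator with known hyper-/hypomethylated true DMRs of
effect size Δβ, and region-level scoring under the **equal-overlap (EO)**
(exact start/end match) and **any-overlap (AO)** (≥1 shared bp) criteria with
precision, recall, F1 and region-level type-I error.

## Worked example

Simulate a small two-chromosome array with 40 true DMRs (Δβ = 0.2, 10 vs 10
samples) and run the array-adaptive detector:

```r
library(nkdmr)

layout <- emulate_layout(layout_config(probes_per_chrom = c(chr1 = 3000, chr2 = 3000)),
                         seed = 42)
truth  <- assign_truth(candidate_regions(layout), n_true = 40, seed = 42)
ds     <- simulate_dataset(layout, truth, sim_config(n_regions = NULL, n_true = 40),
                           seed = 42)

fit <- detect_dmrs(ds$beta, layout, design_info(ds$condition), mode = "aaDMR")
fit
#> Normalized kernel-weighted DMR fit (aaDMR)
#>   sites tested:       6000
#>   significant sites: 287 (alpha = 0.05)
#>   DMRs called:       42 (g = 1000 bp, min_probes = 2)
#>   prior df (d0):      57.35

head(fit$dmrs[order(fit$dmrs$rank), ], 3)
#>    chrom   start     end n_probes    p_rep p_rep_adj rank
#> 4   chr1 1982974 1984053        8 7.73e-12  4.64e-08    1
#> 17  chr2 2638381 2639605       11 3.49e-10  9.50e-07    2
#> 19  chr2 3215278 3216351        5 4.75e-10  9.50e-07    3

evaluate_calls(fit$dmrs, truth)[, c("criterion", "TP", "FP", "precision", "recall", "f1", "type1")]
#>   criterion TP FP precision recall    f1   type1
#> 1        EO 24 18     0.571  0.600 0.585 0.04337
#> 2        AO 39  1     0.975  0.975 0.975 0.00241
```

Reading the output: 287 of 6000 CpG sites pass the genome-wide FDR filter and
collapse into 42 regions. Under the lenient AO criterion 39 of the 40 planted
DMRs are recovered with one false call; under the strict EO criterion (exact
boundaries) 24 regions are recovered exactly and the region-level type-I
error (false calls per null region) sits near the nominal 5%. `p_rep` is the
minimum member p-value used to rank regions.

A command-line front end with `dmr`, `simulate`, `evaluate` and `benchmark`
subcommands is installed at `inst/scripts/nkdmr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "nkdmr.R", package = "nkdmr"))')" \
  dmr --matrix beta.csv --annotation probes.csv --samples sheet.tsv \
      --mode aaDMR --g 1000 --alpha 0.05 --out results/run1
```

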