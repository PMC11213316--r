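---
title: "Normalized kernel-weighted DMR detection: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized kernel-weighted DMR detection: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkdmr)
```

## The problem

DNA methylation at CpG dinucleotides regulates gene expression, and regions
whose methylation differs between conditions (differentially methylated
regions, DMRs) are prime biomarker candidates. On Illumina bead arrays each
probe reports a β-value (fraction methylated, in [0,1]) at one CpG; probes
are spaced very unevenly — dense in CpG islands and promoters, sparse in open
sea. Region callers that smooth site-level statistics with raw kernel
weights concentrate sensitivity in dense regions: a site with many close
neighbors accumulates a large smoothed statistic simply because the weights
add up, while an equally affected site in sparse territory borrows almost
nothing. `nkdmr` implements a normalized kernel weighting that removes this
density bias, in two bandwidth variants, together with the simulation and
scoring machinery needed to benchmark region callers.

## Model

**Site statistics.** β-values are clipped to `[0.001, 0.999]` (configurable)
and mapped to M-values `M = log2(β/(1−β))`, whose approximate
homoscedasticity suits linear modeling. Per probe, an ordinary least-squares
fit of M on condition (plus covariates, plus subject indicator blocks for
paired designs) yields the contrast estimate and residual variance; limma's
empirical-Bayes machinery shrinks the per-probe variances toward a common
prior (moment matching on log variances), giving moderated t-statistics with
total degrees of freedom `ν = df_residual + d0`. We use `y = t²` as the
site-level evidence. Pairing is modeled as fixed-effect blocking, not random
effects: with ten or so subjects the block estimates are stable and the
contrast remains the simple within-pair comparison.

**Smoothing.** For each chromosome with sorted positions `x_1 < … < x_n`,

`S(x_i) = y_i + Σ_{j≠i} w_j(x_i) y_j`, with
`w_j(x_i) = K((x_j−x_i)/h) / Σ_{j≠i} K((x_j−x_i)/h)` and `K(z) = exp(−z²/2)`.

The self term is excluded from the weight sum; a site's neighbors are all
other sites within the truncation window `W`. The normalization makes
`Σ w_j = 1` whenever a neighbor exists, so every neighborhood contributes one
unit of borrowed evidence; what varies with density is only how that unit is
split. An isolated site keeps `S = y` and loses nothing but the borrowing.

**Inference.** Variance moderation keeps `ν` large even for small samples,
so the null law of `y` (exactly `F(1, ν)`) is treated as χ²₁ throughout —
the Kolmogorov distance between `F(1, ν)` and χ²₁ is below 0.02 already at
`ν = 50`, and `ν` is reported so users can judge smaller cases. `S(x_i)` is
then a positively weighted sum of scaled χ² variables with mean `1 + Σw_j`
and variance `2(1 + Σw_j²)`; Satterthwaite matching to `p·χ²(q)` gives
`p = (1+Σw²)/(1+Σw)` and `q = (1+Σw)²/(1+Σw²)`. With normalized weights
`p·q = 2` and `q ∈ [2, 4)`: `q → 2` when one neighbor dominates, `q → 4`
as many neighbors share the weight evenly. P-values come from the χ² upper
tail of `S/p`, are BH-adjusted in one genome-wide family ("all site-level
tests" form a single FDR family; chromosomes are not separate families), and
sites with adjusted p strictly below α survive — ties at exactly α are
removed, the conservative reading of the filtering rule.

**Region calling.** Surviving sites within `g` bp of their neighbor chain
into one region (adjacency linkage, never across chromosomes); boundaries are
the member probe positions without padding; each region carries the minimum
member p-value (raw and adjusted) as its representative and is ranked by it.

## Parameters

| parameter | default | meaning and guidance |
|---|---|---|
| `h` | 500 bp (faDMR) / per-chromosome median gap (aaDMR) | kernel bandwidth; the adaptive rule tracks array density, falling back to 500 bp on chromosomes with fewer than two probes |
| `window_mult` | 5 | truncation `W = 5h`; the largest discarded kernel factor is `exp(−12.5) ≈ 3.7e−6`, negligible against the weight normalization |
| `g` | 1000 bp | agglomeration gap, the value shared by established region callers |
| `alpha` | 0.05 | BH-adjusted significance level |
| `min_probes` | 2 | a single significant CpG is a differentially methylated position, not a region; set 1 to keep singletons (affects simulated counts) |
| `clip` | 0.001 | β clipping before the logit; keeps boundary βs finite |

Duplicate probe coordinates are retained and contribute `K(0) = 1`; the
moderation prior df `d0` is capped at `1e9` as a numerical stand-in for
infinity (constant-variance data).

## The simulator and what it does (not) emulate

`emulate_layout()` builds chromosomes as sequences of promoter-like clusters
(4–12 probes, uniform) and scattered singleton probes. Within-cluster
("island") gaps are log-normal with median 100 bp; between-unit ("open-sea")
gaps are log-normal with median 4 kb; the cluster frequency is set so island
gaps make up 55% of all gaps. These defaults were chosen once, on realism
grounds: the pooled gap distribution then has its mode well below 200 bp, a
heavy right tail, and per-chromosome median spacing of a few hundred base
pairs — the spacing scale of the 450K-class arrays on which the 500 bp
fixed bandwidth was established. Clusters of ≥4 probes become candidate
regions (TSS200-like when spanning ≤200 bp, TSS1500-like otherwise).

`simulate_dataset()` draws β-values from beta distributions parameterized by
their mode: shapes `(m(c−2)+1, (1−m)(c−2)+1)` put the density mode exactly at
`m` for concentration `c > 2` (default 10). Null probes are methylated or
unmethylated (modes 0.9 / 0.1) with probability ½ each, independently per
probe by default (a region-constant status is available via
`status_by_region`). True DMRs shift the treatment mode by ±Δβ from the
opposite baseline: hypermethylated regions rise from the unmethylated mode,
hypomethylated regions fall from the methylated mode, every member probe
affected. The benchmark defaults are 10 control vs 10 treatment samples,
2,136 true DMRs among 21,363 candidate regions (10%), and Δβ = 0.2 (large
effect) or 0.09 (small effect). Note the mode parameterization biases group
*means* toward 0.5, so the realized mean difference is slightly below Δβ.

The emulator does **not** reproduce Infinium I/II chemistry differences,
probe cross-reactivity, batch effects, correlated errors between neighboring
probes, or the exact quantiles of any particular manifest (the genome build
and manifest version behind the published spacing histograms are not fixed,
so the target is qualitative shape). Passing tests on this generator
demonstrate calibration and power under idealized independent beta noise with
block-constant effects; on real arrays, residual correlation and
normalization artifacts can only degrade those figures.

## Scoring conventions

A call is an EO true positive only with exact chromosome/start/end identity
to a true region, and an AO true positive when the closed intervals share at
least one base pair. The confusion table counts `TP` = true regions
detected, `FN = n_true − TP`, `FP` = calls qualifying for no true region,
and `TN = n_null − FP`, which keeps both margins fixed (`TP+FN = n_true`,
`FP+TN = n_null`) exactly as region-benchmark tables are conventionally laid
out; note that under EO an imprecise call inside a true region counts toward
FP even though it touches no null region — the region-level "type I error"
`FP/n_null` inherits this convention. A call spanning two true regions
counts once as a call but credits both regions as detected. Precision,
recall, F1 and `FP/n_null` follow; undefined ratios are reported `NA` and
excluded (with a count) from replicate summaries.

## Numerical and design choices

* Neighbor search uses a sorted sliding window (`findInterval` plus boundary
  refinement), `O(n·k)`; the test suite pins it to an all-pairs evaluation at
  `1e−12`.
* BH adjustment delegates to `stats::p.adjust`; tests verify it against an
  independently coded step-up.
* Region agglomeration over sorted sites uses gap thresholds and is checked
  against a naive transitive-closure oracle.
* The moments of `S` are derived over the neighbor sum with the self term
  excluded everywhere (the `j ≠ i` convention); with normalized weights the
  distinction only matters for `Σw²`, and excluding the self term is the
  consistent reading.
* `satterthwaite_params()` accepts arbitrary non-negative `(Σw, Σw²)`, so
  unnormalized weighting schemes can reuse the same inference path.
* Degenerate inputs: chromosomes with <2 probes fall back to the fixed
  bandwidth with a warning; zero posterior variances yield flagged infinite
  t-statistics excluded from inference; empty significant sets produce empty
  (not failing) region tables.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run reduced-scale versions of the
benchmark, sized so that a full run stays in the tens of seconds on a single
CPU: 30,000–40,000 probes over 6–8 chromosomes, 1,200–2,000 candidate
regions with 10% true DMRs, and 6 replicates per effect size; the pure-null
calibration uses 50,000 probes and 25 replicates. At these sizes the
Monte-Carlo standard error of a recall estimate is about 1–2 percentage
points. Full 450K-scale runs (≈451,000 probes, 21,363 regions, hundreds of
replicates) use the same code paths via `layout_config()` /
`sim_config()` defaults and are intended for dedicated compute.

## Known limitations

* The χ²₁ approximation to `F(1, ν)` is slightly anti-conservative for small
  `ν`; with unmoderated variances and few samples, permutation calibration
  would be preferable (not implemented).
* Neighboring sites share no correlation model: `S` treats neighbor `y`s as
  independent under the null, whereas real co-methylation induces positive
  correlation; the Satterthwaite variance is then an underestimate and the
  genome-wide FDR control leans on BH's robustness.
* Only two-group contrasts are exposed (plus covariates and pairing);
  continuous exposures would require a straightforward but unimplemented
  generalization of the contrast extraction.
* Alternative kernels and data-driven bandwidth optimization beyond the
  median-gap rule are out of scope.

## A minimal run

```{r example, eval = FALSE}
layout <- emulate_layout(layout_config(probes_per_chrom = c(chr1 = 3000, chr2 = 3000)),
                         seed = 42)
truth  <- assign_truth(candidate_regions(layout), n_true = 40, seed = 42)
ds     <- simulate_dataset(layout, truth, sim_config(n_regions = NULL, n_true = 40),
                           seed = 42)
fit    <- detect_dmrs(ds$beta, layout, design_info(ds$condition), mode = "aaDMR")
evaluate_calls(fit$dmrs, truth)
```
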