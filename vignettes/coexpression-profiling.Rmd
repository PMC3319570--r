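---
title: "Profiling coexpression of nuclear receptors and histone methylation modifiers across biological settings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling coexpression of nuclear receptors and histone methylation modifiers across biological settings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexprofiler)
```

## The problem

Endocrine disruptor compounds perturb nuclear-receptor signalling, and there
is growing evidence that part of that perturbation runs through the
epigenome — in particular through enzymes that write and erase histone
methylation marks. Differential expression of these enzymes after exposure
is typically subtle and easy to miss in small studies. An alternative is to
profile *coexpression*: if a receptor and a histone modifier act in the same
regulatory complexes, their transcript levels should covary, and that
covariation should recur across independent biological settings (species,
tissues, exposure experiments). `coexprofiler` implements that profiling
strategy as a reusable pipeline, restricted to a curated analysis geneset,
with a synthetic-data generator that provides ground truth for every stage.

## The analysis geneset

The packaged geneset (`load_geneset()`) holds 137 unique genes in five
functional categories: 41 nuclear receptors, 18 histone demethylases, 45
methyltransferases, 7 nuclear-receptor coregulators (the ASCOM core
Wdr5/Ash2l/Rbbp5/Dpy30, the linker Ncoa6, plus Men1 and Paxip1) and 28
genes chosen for their relevance to endocrine-disruption phenotypes
(sexual differentiation, embryonic development, obesity, spermatogenesis,
steroidogenesis). Men1 and Paxip1 carry dual membership
(methyltransferase-complex components that are also receptor coregulators),
so category slots total 139 while unique symbols number 137. The fixture's
`source` column separates genes named in the source literature from members
reconstructed from the cited nomenclature and modifier reviews; users can
swap in their own TSV with the same columns.

Legacy demethylase names are canonicalized case-insensitively
(`normalize_symbol()`): `Utx` becomes `Kdm6a`, `AOF2` becomes `Kdm1`, and
unknown symbols pass through flagged rather than being dropped silently.

```{r geneset}
gs <- load_geneset()
geneset_counts(gs)
normalize_symbol(c("Utx", "AOF2"), alias_table(gs))[1:2]
```

## From probes to a gene-level matrix

Input matrices are tab-delimited log2 intensities (RMA-style), probes or
genes in rows, samples in columns. The reader validates rather than
repairs: ragged rows, duplicate identifiers and non-numeric cells are
errors naming the offending location, because silent coercion upstream of
a correlation analysis is how phantom edges are born. Values outside
[0, 20] only warn — that range covers any plausibly normalized array.

Where a platform measures a gene with several probes,
`select_probe_per_gene()` keeps the probe with the highest mean over the
setting's control samples; the rule is applied per setting, so a probe
choice in one experiment never leaks into another. Two deliberate
conventions close gaps the rule leaves open: settings with no control
samples fall back to the mean over all samples (with a warning), and exact
ties break toward the lexicographically smallest probe id so the collapse
is deterministic.

## Correlation networks per setting

Within each setting, `build_network()` computes all pairwise Pearson
correlations among geneset genes, with two-sided p-values from
t = r·sqrt(n−2)/sqrt(1−r²). Edges are classified as

* **strong** — |r| ≥ 0.75 and p < 0.05 (strictly: a printed pair
  (r = 0.95, p = 0.05) is *not* strong),
* **approaching** — |r| ≥ 0.75 and 0.05 ≤ p < 0.10,
* **absent** — otherwise.

The |r| threshold of 0.75 and the approaching band are the study-level
defaults and are tunable (`r_min`, `alpha`, `approach_max`). Several of the
source experiments pool samples over generations or cell pools; treating
such pooled samples as exchangeable inflates correlations whenever the
subgroups differ in mean expression. For those settings the pipeline uses
partial correlation (`partial_with_p()`): both genes are residualized on
the subgroup factor (k levels), and the t-test loses k − 1 degrees of
freedom, df = n − 2 − (k − 1). With one level this reduces exactly to plain
Pearson. We control subgroups as fixed means rather than through a
precision-matrix formulation; for a single categorical covariate the two
coincide.

Undefined correlations (zero-variance genes) drop the pair and report it,
rather than imputing r = 0 — silent zeros would corrupt the conservation
tallies downstream.

## Conservation across settings

`conserved_edges()` counts, for every gene pair, the settings in which the
edge is strong with the same sign; pairs strong with opposite signs in
different settings are excluded and reported separately. "Conserved" is
operationalized as *strong classification with identical sign* — the
minimal faithful reading of "similar strength and direction"; no numeric
similarity band on r is imposed beyond the threshold, and approaching
edges never count toward conservation. `occurrence_count()` gives the
hub-occurrence statistic (total strong edges of a gene across settings)
and `hub_partner_comparison()` contrasts a hub's strong partners between
control and exposed networks.

## The gatekeeper concordance classes

The gatekeeper model holds that repressive H3K9 methylation written by
Ehmt1/Ehmt2, Prdm2 and Setdb1, and its removal by the demethylase Kdm1,
gate promoter access for liganded receptors. `gatekeeper_set()` fixes the
six-gene operational set (Esr2, Ehmt2, Ehmt1, Kdm1, Prdm2, Setdb1);
`classify_phenotype_gene()` asks whether a phenotype-relevant gene echoes
that coregulatory pattern:

* **full** — strong link to ≥ 1 receptor (default subset Esr1/Esr2/Ar)
  *and* strong links to every gatekeeper gene on the platform;
* **approaching** — at least approaching on both counts;
* **none** — otherwise.

The source analyses describe a "consistent pattern of correlation or
anti-correlation" without a numeric definition; our class rule is the
minimal operationalization, using significance classes only. Sign is
deliberately not part of the rule (the reported patterns mix signs), but
the signed pattern vector is returned so stricter criteria can be layered
on. Note one consequence: a phenotype gene strongly tied to a single
methyltransferase but to no receptor classifies as *none* — the class
speaks about the full pattern, not about any single link.

## Differential expression from first principles

`run_de()` implements the moderated-t pipeline directly rather than
wrapping an existing implementation, because the estimator itself is part
of what this package exercises end to end:

1. per-gene OLS on the two-group design: log2fc = difference of condition
   means, pooled residual variance s²_g on df_g = n − 2;
2. empirical-Bayes hyperparameters (d0, s0²) by matching the first two
   moments of log s²_g to the scaled-F model: with
   e_g = log s²_g − digamma(df_g/2) + log(df_g/2), the excess of var(e)
   over trigamma(df_g/2) identifies d0 through the inverse trigamma
   function (Newton iteration), and mean(e) identifies s0²;
3. moderated t: s²_post = (d0·s0² + df_g·s²_g)/(d0 + df_g),
   t = log2fc/(stderr_scale·s_post) on df_g + d0 degrees of freedom;
4. Benjamini–Hochberg step-up adjustment, implemented literally
   (adj_(i) = min_{j≥i} p_(j)·m/j, capped at 1);
5. the study filter: fold change 2^|log2fc| ≥ 1.5 and adjusted p < 0.05,
   with near-misses (significant, FC within 7% below the cut-off — the
   band that captures a 1.4-fold change) reported separately instead of
   vanishing.

Degenerate inputs are handled explicitly: exactly homogeneous variances
give d0 = ∞ with s0² the common variance; zero-variance genes are excluded
from the hyperparameter fit (complete-shrinkage fallback if fewer than two
genes remain); zero posterior variance flags an infinite t with p = 0
rather than NaN. d0 = 0 reproduces the ordinary two-sample t exactly, which
the tests verify against `t.test()`, and the whole chain is cross-checked
against the limma reference implementation on random data.

Fold changes are printed as 2^|log2fc| with an up/down flag because the
source tables print positive fold changes for down-regulated genes.

## The synthetic-data generator

`generate_expression()` draws from a latent-factor model:

x_gs = μ_g + β_g·exposed_s + γ_{g,subgroup(s)} + λ_g·f_{m(g),s} + ε_gs

with one standard-normal factor per module per sample and ε ~ N(0, σ²).
A module's loading magnitude is λ = σ·sqrt(ρ/(1−ρ)), giving population
within-module correlation ρ with the sign of the loading product; the
construction is positive-definite by design, which is why we prefer it to
sampling from a hand-specified covariance matrix. Defaults emulate the
source study's shapes: 4–12 samples per setting, residual σ = 0.25 log2
units (a typical array replicate spread), baselines uniform on [6, 10].
Subgroup effects are fixed gene × level shifts — exactly the structure that
makes pooled plain-Pearson correlations spurious and motivates the partial
correlation.

Three preset scenarios (`simulate_scenario()`) mirror the study designs:
three normal-tissue settings sharing modules (cross-species conservation);
a three-generation 6v6 exposure with planted 7.06- and 2.58-fold
knockdowns (the magnitudes reported for the grouped vinclozolin contrast)
and a module wired only in exposed samples; and seven small exposure
groups where the gatekeeper module is wired only under high triadimefon,
at ρ = 0.98 — n = 4 groups need near-perfect correlation for any edge to
clear the significance threshold, which is the regime the reported
networks display.

What the generator does *not* emulate: probe-level effects, spatial array
artifacts, intensity-dependent variance, heavy-tailed noise, or
correlation structure outside the planted modules. Passing tests therefore
show that the pipeline recovers the structure it assumes at the stated
sample sizes; they do not certify performance on real arrays whose
violations of those assumptions are unknown.

## Validation choices and problem sizes

The test suite validates each stage against an independent oracle:
correlations against a direct product-moment implementation (1e−10),
partial correlation against hand residualization, BH against its literal
definition and `p.adjust`, the moderation fit against an independent
root-finder on the moment equations and against limma. Calibration checks
run at study scale: 200 null settings of 50 genes × 12 samples for the
strong-edge false-positive rate (compared to the analytic t-tail
probability, ≈ 0.005 at n = 12); 100 seeds of planted ρ = 0.9 modules at
n = 12 (mean edge sensitivity ≈ 0.96, comfortably above the 0.8 design
target); 50 replicates of 1000-gene global-null differential expression
(raw p < 0.05 rate ≈ 0.05, ~0 filtered genes); 20 replicates of 2000-gene
hyperparameter recovery under (d0 = 4, s0² = 1). These sizes give
Monte-Carlo errors well below the effects being checked while keeping the
default test run fast.

## Known limitations

* Conservation relies on symbol identity across species; no ortholog
  mapping is attempted.
* Only two-group contrasts are supported (optionally run per generation);
  no multi-factor designs, no intensity-trend or robust moderation
  variants.
* The geneset fixture is a reconstruction: membership named explicitly in
  the source literature is marked, the remainder is filled from the cited
  reviews and flagged as such.
* No correlation shrinkage or soft thresholding; the method is the
  thresholded-correlation design it profiles, not a WGCNA replacement.
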