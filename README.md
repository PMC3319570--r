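# coexprofiler

Geneset-restricted coexpression profiling of nuclear receptors and histone
methylation modifiers across biological settings.

## What this is for

Endocrine disruptor compounds act through nuclear-receptor signalling, and
enzymes that write and erase histone methylation marks work in the same
regulatory complexes as the receptors. Changes in the mRNA levels of these
enzymes after exposure are typically small and hard to detect by
differential expression in small studies. This package implements the
complementary strategy: profile *coexpression* within a curated set of
pertinent genes — 137 genes spanning 41 nuclear receptors, 18 histone
demethylases, 45 methyltransferases, 7 coregulators and 28
phenotype-relevant genes — across many biological settings (species,
tissues, exposure experiments), and look for relationships that recur.

It is aimed at toxicogenomics and reproductive-biology analysts working
with small-n expression studies (microarray-era designs of 4–12 samples
per group), and at methodologists who want a fully instrumented,
ground-truthed testbed for thresholded correlation networks.

The pipeline stages:

* **Correlation networks per setting** — all pairwise Pearson
  correlations within the geneset; an edge is *strong* when |r| ≥ 0.75
  with two-sided p < 0.05 (from t = r·√(n−2)/√(1−r²)), *approaching* when
  |r| ≥ 0.75 with 0.05 ≤ p < 0.10. Settings that pool samples over
  generations, cell pools or time points use partial correlation: both
  genes are residualized on the subgroup factor and the test loses k − 1
  degrees of freedom (df = n − 2 − (k − 1)).
* **Conservation across settings** — gene pairs strong with the same sign
  in ≥ k settings; sign-discordant pairs are quarantined; hub-occurrence
  counts and control-vs-exposed hub-partner comparisons.
* **Gatekeeper concordance** — profiles every phenotype gene against the
  six-gene gatekeeper set {Esr2, Ehmt2, Ehmt1, Kdm1, Prdm2, Setdb1} and
  classifies the pattern as full / approaching / none.
* **Differential expression** — per-gene two-group OLS, empirical-Bayes
  moderated t (s²_post = (d0·s0² + df_g·s²_g)/(d0 + df_g), hyperparameters
  by log-variance moment matching), Benjamini–Hochberg adjustment, and the
  study filter FC ≥ 1.5 at adjusted p < 0.05 — implemented from the
  formulas, with limma used only as a cross-check in the tests.
* **Synthetic data** — a latent-factor generator
  (x_gs = μ_g + β_g·condition + γ_{g,subgroup} + λ_g·f_m + ε) with planted
  correlation modules, subgroup shifts, exposure-dependent rewiring and
  planted fold changes, plus ground-truth edge lists and recovery reports.

## Worked example

Simulate a three-generation exposure study (6 control vs 6 exposed, one
module rewired to appear only under exposure, 7.06- and 2.58-fold planted
knockdowns), then ask how the demethylase Kdm1's partners change:

```r
library(coexprofiler)

sc <- simulate_scenario("experiment2", seed = 42)
md <- sc$metadata
ctrl <- md$condition == "control"; expo <- md$condition == "exposed"

# partial correlation over generations, per condition
net_c <- build_network(sc$matrix[, ctrl], method = "partial",
                       groups = md$subgroup[ctrl], setting_id = "control")
net_e <- build_network(sc$matrix[, expo], method = "partial",
                       groups = md$subgroup[expo], setting_id = "exposed")
hub_partner_comparison(net_c, net_e, "Kdm1")$counts
#> control exposed  common
#>       1       3       0

net_e[net_e$gene_a %in% c("Dnmt1", "Esr2", "Kdm1") &
      net_e$gene_b %in% c("Dnmt1", "Esr2", "Kdm1"),
      c("gene_a", "gene_b", "r", "p", "n", "sig_class")]
#>     gene_a gene_b     r      p n sig_class
#> 81   Dnmt1   Esr2 0.831 0.1693 6    absent
#> 101  Dnmt1   Kdm1 0.965 0.0351 6    strong
#> 239   Esr2   Kdm1 0.728 0.2719 6    absent

de <- run_de(sc$matrix, md$condition)
de_filter(de)[, c("gene", "log2fc", "fold_change", "direction", "p_adj")]
#>    gene log2fc fold_change direction    p_adj
#> 1 Ehmt1  -1.08        2.12      down 1.77e-03
#> 2 Kdm6b  -2.72        6.61      down 9.76e-08
```

Reading the output: in control samples Kdm1 has a single strong partner;
in exposed samples it gains the planted partners (including Dnmt1 at
r = 0.965) — exposure-dependent rewiring of a hub. The Esr2 links, planted
at the same module strength, miss the strict threshold at n = 6 with three
generations partialled out (df = 3): a concrete reminder of how little
power these designs have per edge. The differential-expression filter
recovers both planted knockdowns with fold changes near their planted
magnitudes (6.61 vs 7.06, 2.12 vs 2.58).

The same stages run file-to-file: `write_scenario()` writes
`matrix.tsv`/`metadata.tsv`, `run_pipeline(config, out_dir)` executes every
stage from a YAML or list config and writes per-setting edge tables, a
conservation report, gatekeeper profiles, DE tables and a run log. A thin
command-line wrapper lives at `inst/cli/coexprofiler.R`.

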