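# ruminet

Differential expression, GO-style category enrichment and signed
co-expression networks for two-condition transcriptome studies with very
few replicates — the analysis pattern of ruminant-nutrition microarray
work, where liver expression from animals on a high-concentrate diet is
contrasted against a low-concentrate control with only 3–4 arrays per
group.

The package is for analysts who need that workflow as tested, reusable,
reproducible code rather than a chain of one-off scripts:

* **Differential expression** — per-gene log2 fold change
  (condition-B minus condition-A mean), Welch's unequal-variance t-test,
  Benjamini–Hochberg FDR, and joint selection at FC = 2^|log2FC| ≥ 2 and
  FDR < 0.05 (every threshold an argument). A 2^−ΔΔCt helper covers qPCR
  validation of selected genes, and a deterministic average-linkage
  ordering (1 − Pearson distance) supports heatmap-style reporting.
* **Category enrichment** — for a category with `nf` flagged genes out of
  `n`, against `Nf` flagged among `N` background genes: a two-sided
  Fisher's exact test (minimum-likelihood convention), the Pearson χ²
  companion test, the enrichment ratio **Re = (nf/n)/(Nf/N)**, a global
  empirical FDR **1 − Nk/T** (Nk = categories whose Fisher p falls below
  the paired χ² p, out of T tested) and a per-category BH correction.
* **Co-expression networks** — per condition, Pearson correlation across
  that condition's samples; a signed edge wherever |r| > 0.999 (strict);
  raw degree centrality; k-core decomposition; and cross-condition
  "core regulator" ranking by absolute degree difference between the two
  condition networks.
* **Synthetic data** — a generator that plants differential genes,
  perfectly correlated modules (optionally active in one condition only)
  and enrichment-boosted annotation categories, so every stage can be
  validated against known truth without any download.

## Worked example

```r
library(ruminet)

config <- list(simulate = list(
  seed = 33, n_genes = 500, de_fraction = 0.04, noise_sd = 0.05,
  n_categories = 10L, de_enrichment_boost = 25,
  modules = list(module_spec(5, residual_sd = 0),
                 module_spec(6, latent_sd = 0.1, residual_sd = 0,
                             condition_specific = "B_only", de = TRUE))))
manifest <- run_pipeline(config, "demo-run")
manifest$counts[c("deg_selected", "deg_up", "deg_down")]
#> $deg_selected   $deg_up   $deg_down
#> [1] 20          [1] 8     [1] 12

head(read.delim("demo-run/enrichment.tsv"), 2)
#>   category nf  n Nf   N     p_fisher       p_chi2 fdr_empirical       fdr_bh       re
#> 1    C0001 14 38 18 230 2.144344e-09 3.123177e-13           0.9 2.144344e-08 4.707602
#> 2    C0002 12 29 18 230 1.792948e-08 6.176683e-13           0.9 8.964741e-08 5.287356

head(read.delim("demo-run/core_regulators.tsv"), 3)
#>    gene degree_A degree_B degree_diff rank
#> 1 G0229        0        5           5    1
#> 2 G0260        0        5           5    2
#> 3 G0316        0        5           5    3
```

All 20 planted differential genes are recovered (8 up, 12 down, matching
the planted signs). The two annotation categories built to over-sample
differential genes (boost 25) head the enrichment table with Re ≈ 4.7 and
5.3 — flagged genes are ~5× over-represented relative to the 18/230
background rate. The top core regulators are members of the planted
condition-B-specific module: degree 5 inside their clique in the B
network, (near) 0 in A. `render_report("demo-run")` turns the run into a
markdown summary; rerunning the same config reproduces byte-identical
artifacts (checksums are in `demo-run/manifest.json`).

`vignettes/ruminet-methods.Rmd` explains the model, every tunable
parameter, and why the |r| > 0.999 rule must be read cautiously at 3–4
samples.

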