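# pdl1meta

Multi-cohort expression integration and PDL1 (CD274) biomarker analysis in
breast cancer.

## The problem

PDL1 is an immune-checkpoint ligand whose tumor expression predicts response
to PD1/PDL1 blockade in several carcinomas. In breast cancer its prognostic
and predictive value is best assessed at the mRNA level across many
microarray cohorts at once, which raises a chain of methodological problems
before any biology can be read off:

* expression matrices from different platforms must be made comparable
  (per-dataset quantile normalization, probe-to-gene collapse by highest
  within-dataset variance, and per-dataset standardization against a common
  anchor subpopulation — the luminal-A tumors);
* single-gene markers (ESR1, PGR, ERBB2, MKI67) must be dichotomized from
  their bimodal mRNA distributions, and PDL1 upregulation called from the
  tumor/normal-breast ratio (T/NB ≥ 2, i.e. a log2 difference ≥ 1);
* intrinsic molecular subtypes (luminal A/B, basal, ERBB2-enriched,
  normal-like) must be assigned by nearest-centroid correlation so that all
  downstream analyses can be stratified;
* the clinical questions — survival (Kaplan-Meier, log-rank, Cox with a
  subtype-by-expression interaction term), response to neoadjuvant
  chemotherapy (exact 2×2 inference), copy-number association, and a
  differential-expression metagene — each need the field's standard
  statistics with reproducible conventions.

`pdl1meta` implements this pipeline end to end, together with a seeded
multi-cohort simulator that reproduces the statistical structure the
analysis assumes (batch effects, subtype mixture, bimodal markers, a
PDL1-up subpopulation, subtype-specific hazards and odds ratios), so every
stage is testable without access to the original cohorts.

## Statistical core

* **Exact 2×2 inference.** For a table with margins fixed, the odds ratio is
  estimated as the conditional maximum-likelihood value ψ̂ maximizing the
  noncentral hypergeometric likelihood — the root of E[X | ψ] = a, found by
  monotone root-finding — with exact 95% limits from inverting one-sided
  tests at 2.5% per side, and a two-sided Fisher p-value by
  probability-mass ordering. This (and not the sample cross-product ratio)
  is the convention that matches the published per-subtype odds ratios.
* **Moderated t.** Per-gene pooled variances s²_g are shrunk toward an
  ensemble prior, s̃²_g = (d₀s₀² + d·s²_g)/(d₀ + d), with (d₀, s₀²)
  estimated by moment matching on log s²_g (trigamma inversion); the
  statistic is referred to t with d₀ + d degrees of freedom and corrected
  by Benjamini-Hochberg. Signature genes satisfy p < 0.05, q < 0.05 and
  |log2 FC| ≥ 1; the metagene is the mean of the upregulated genes with a
  ROC (Youden J) threshold learned on the training cohort.
* **Survival.** Product-limit estimation with Greenwood intervals, the
  standard (O−E)²/V log-rank statistic, Cox partial likelihood with Efron
  tie handling and Wald tests, and a product-term Wald test for
  subtype-restricted effects. The 5-year rate is the step function at 60
  months.
* **Copy number.** Log2 ratios at the PDL1 locus are discretized at ±log2(1.5)
  (gain/loss) and ±1 (amplification/homozygous deletion), boundaries
  assigned to the altered state, and gains tested against expression with a
  pooled two-sample t.

## Worked example

The predictive analysis from published neoadjuvant counts:

```r
library(pdl1meta)
tab <- matrix(c(153, 36, 40, 36), 2, 2,
              dimnames = list(c("no_up", "up"), c("RD", "pCR")))
contingency_result(tab, label = "pCR vs PDL1 group, neoadjuvant cohort")
#> pCR vs PDL1 group, neoadjuvant cohort
#>        RD pCR
#> no_up 153  40
#> up     36  36
#> Fisher exact p = 6.62e-06, OR = 3.80 [2.05-7.09]
```

The pCR rate is 50% (36/72) with upregulation versus 21% (40/193) without,
and the conditional-MLE odds ratio of 3.80 says the odds of a complete
response are almost four times higher in PDL1-upregulated tumors.

A full synthetic run — three cohorts of 200 tumors, 500 genes — through the
entire pipeline:

```r
cfg <- list(mode = "synth", seed = 1,
            synth = list(n_datasets = 3, samples_per_dataset = 200,
                         n_genes = 500, n_signature_genes = 60, seed = 1))
s <- run_pipeline(cfg, "demo_out")
s$pdl1_up_fraction      #> 0.218  (simulator targets ~20%)
s$n_signature_genes     #> 59    (44 up / 15 down; 60 genes planted)
s$metagene_auc          #> 0.915
```

`demo_out/` then contains the report tables: clinicopathological
associations, whole-cohort and basal-subtype Cox models,
the per-subtype pCR analysis (with "not estimable" flags where a margin is
empty), the signature gene list and the held-out metagene validation
(accuracy 0.995 and 0.945 on the two validation cohorts in this run),
plus `run_summary.json`. A thin command-line wrapper is installed at
`inst/cli/pipeline.R`:

```sh
Rscript inst/cli/pipeline.R run --config cfg.yaml --out out_dir
```

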