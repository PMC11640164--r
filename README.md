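# immunosig

Estimating the infiltration of key T-cell populations in solid tumors from
bulk RNA-seq, and testing what that infiltration correlates with: tumor
type, immunotherapy response, and survival.

The package is for computational oncologists and biostatisticians who have
a genes × samples TPM matrix plus basic clinical annotation (cancer type,
batch, immune-checkpoint-inhibitor treatment flag, overall survival), and
who want the standard signature-score analysis chain as reusable, tested
functions rather than a one-off script.

## What it computes

Each of six T-cell marker panels — stem-like tumor-infiltrating
lymphocytes, tissue-resident memory (TRM) T cells, activated-potentially
anti-tumor T cells, early and late dysfunctional T cells, and the BTN3A
isoform family — is scored per sample as a sign-aware average z-score on
log2(TPM + 1) expression:

    z_gs   = (x_gs − mean_g) / sd_g          (pooled reference, n−1 SD)
    score_s = (1/k) Σ_i  w_i · z_{g_i s}     (w_i = ±1 per marker)

Around that score the package provides:

* **Preprocessing** — TSV/CSV I/O, `log2(TPM+1)` transform, gene-alias
  standardization (PD1 → PDCD1, CD103 → ITGAE, ...), and a self-contained
  parametric empirical-Bayes location/scale batch adjustment
  (`combat_adjust()`).
* **Cross-cancer testing** — Mann–Whitney U per signature for every pair
  of cancer types with per-signature Benjamini–Hochberg adjustment
  (`run_cross_cancer()`).
* **Responder comparison** — responders defined by overall survival
  ≥ 24 months on ICI therapy, non-responders by earlier death; censored-
  before-cutoff samples are excluded (`run_responder_comparison()`).
* **Survival** — median-split high/low strata per signature, Kaplan–Meier
  curves and the two-group log-rank test (`run_survival()`).
* **Validation** — rank AUROC of responder vs. non-responder scores, with
  multi-cohort averaging (`run_auroc_validation()`).
* **Synthetic cohorts** — a seeded generator
  (`synthetic_config()` / `generate_cohort()`) that emulates the
  four-cancer cohort structure (type-specific signature shifts, batch
  location/scale effects, survival coupled to a response signature) so the
  whole pipeline is testable without access-restricted patient data.

The rank-statistics kernel (Mann–Whitney with exact enumeration for small
groups, BH step-up, AUROC, product-limit estimator, log-rank) is
implemented from first principles and verified in the test suite against
independent brute-force oracles and reference implementations.

All user-facing functions take a data frame first and return tibbles, so
calls chain with the pipe; fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

```r
library(immunosig)
library(dplyr)

cohort <- generate_cohort(synthetic_config(
  seed = 7,
  n_per_type = c(melanoma = 60, bladder = 60, ovarian = 60, pancreatic = 60),
  n_background_genes = 50
))
adj <- combat_adjust(cohort$expression, cohort$annotation)

run_responder_comparison(adj, cohort$annotation) |>
  select(signature, n_responder, n_non_responder, p, q, significant)
#> # A tibble: 6 × 6
#>   signature     n_responder n_non_responder        p       q significant
#>   <chr>               <int>           <int>    <dbl>   <dbl> <lgl>
#> 1 stem_like_til         128              56 0.0295   0.0886  FALSE
#> 2 trm                   128              56 0.000354 0.00212 TRUE
#> 3 apa                   128              56 0.216    0.216   FALSE
#> 4 early_dys             128              56 0.115    0.173   FALSE
#> 5 late_dys              128              56 0.149    0.179   FALSE
#> 6 btn3a                 128              56 0.0840   0.168   FALSE

fit <- run_survival(adj, cohort$annotation)
glance(fit)
#> # A tibble: 6 × 8
#>   signature n_high n_low median_os_high median_os_low   chi2       p significant
#>   <chr>      <int> <int>          <dbl>         <dbl>  <dbl>   <dbl> <lgl>
#> 1 stem_lik…    120   120           46.5          39.3  1.62  2.03e-1 FALSE
#> 2 trm          120   120           60.6          32.5 16.4   5.10e-5 TRUE
#> 3 apa          120   120           44.8          41.8  0.942 3.32e-1 FALSE
#> 4 early_dys    120   120           46.5          40.3  1.81  1.79e-1 FALSE
#> 5 late_dys     120   120           45.6          41.1  0.858 3.54e-1 FALSE
#> 6 btn3a        120   120           47.6          39.5  5.59  1.81e-2 TRUE
```

In this synthetic cohort the generator couples survival (and hence
responder status) to the TRM score, and the analysis recovers exactly
that: TRM is the only signature significant after FDR adjustment in the
responder comparison (q = 0.002 < 0.02), its high-expression stratum lives
markedly longer (median OS 60.6 vs 32.5 months, log-rank p = 5×10⁻⁵), and
it has the best responder-prediction AUROC (0.666; a random-responder vs.
random-non-responder win probability of about two-thirds):

```r
run_auroc_validation(adj, cohort$annotation) |> arrange(desc(auroc))
#> # A tibble: 6 × 5
#>   signature     cohort  n_responder n_non_responder auroc
#>   <chr>         <chr>         <int>           <int> <dbl>
#> 1 trm           cohort1         128              56 0.666
#> 2 stem_like_til cohort1         128              56 0.601
#> ...
```

`autoplot(fit)` draws the faceted Kaplan–Meier curves;
`plot_signature_scores(score_signatures(adj), cohort$annotation)` gives
the cross-cancer boxplots. `run_immunosig(expr, annot, out_dir)` runs all
four analyses and writes `cross_cancer.csv`, `responder.csv`,
`survival.csv`, `km_curves.csv`, `auroc.csv` and a run log.

See the methods vignette (`vignettes/immunosig-methods.Rmd`) for the model,
the generator's assumptions and the numerical conventions.

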