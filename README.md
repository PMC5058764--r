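# tpsad

Serum PSA is produced by benign prostate epithelium as well as by tumour, so
a raw PSA value confounds gland size with tumour burden — and, less
obviously, high-grade tumours secrete *less* PSA per unit volume than
low-grade ones. **tpsad** implements the tumour-PSA-density analysis for
prostatectomy cohorts: it deconvolves serum PSA into benign- and
tumour-attributable components, normalizes the tumour component by
pathologically measured tumour volume, and relates the resulting statistic
to grade, stage and biochemical recurrence. Around that core it provides the
full supporting pipeline, aimed at researchers working with radical
prostatectomy series and prostate cancer expression data:

* **Volumetry** — Cavalieri tumour volume from serial whole-mount section
  areas (3.5 mm interval, ×1.25 formalin-shrinkage correction) and ellipsoid
  gland volume.
* **tPSAD** — the core statistic, with the cohort eligibility filters
  (missing PSA, PSA > 20 ng/ml, gland size above the empirical 95th
  percentile) and Gleason grade grouping.
* **Survival** — Kaplan–Meier curves, log-rank tests and Cox
  proportional-hazards regression (Breslow ties), implemented in-package and
  validated against brute-force oracles and the survival package.
* **Expression meta-analysis** — cross-study rank meta-analysis of an
  androgen-regulated gene set with a permutation null, plus CPM, a
  low-expression filter, TMM factors and BH-FDR.
* **IHC densitometry** — H-DAB colour deconvolution and optical density
  (`OD = log10(255 / mean intensity)`) of random triplicate regions.
* **Synthetic data** — a calibrated generator for cohorts, multi-study
  expression matrices and stained-image patches, so every stage is testable
  without patient data.

The central quantity, for a case with serum PSA *P*, prostate volume *V_p*
and tumour volume *V_t* (all post-surgical measurements):

    benign volume   V_b = max(V_p − V_t, 0)
    benign PSA          = f_e · s_b · V_b        (f_e = 0.1, s_b = 0.30 ng/ml per cc)
    cancer PSA          = P − benign PSA
    tPSAD               = cancer PSA / V_t       (ng/ml per cc; analysed as ln tPSAD)

## Worked example

Everything is data-frame-first and pipe-friendly. Simulate a cohort at the
published marginals, filter it, compute tPSAD, and fit the multivariable
recurrence model:

```r
library(tpsad)
library(dplyr)

cohort <- simulate_cohort(n = 1108, seed = 42)
kept   <- apply_cohort_filters(cohort)
exclusion_log(kept)
#> # A tibble: 3 × 2
#>   rule            n_excluded
#>   <chr>                <int>
#> 1 missing_psa              5
#> 2 psa_above_20           193
#> 3 gland_above_p95         46

tab <- bind_cols(kept, compute_tpsad(kept)[-1]) |>
  mutate(grade = grade_group(gleason_primary, gleason_secondary)) |>
  filter(valid_for_log)

tab |>
  group_by(grade) |>
  summarise(geo_mean_tpsad = exp(mean(ln_tpsad)), n = n())
#> # A tibble: 3 × 3
#>   grade        geo_mean_tpsad     n
#>   <fct>                 <dbl> <int>
#> 1 low                    4.02   109
#> 2 intermediate           2.67   669
#> 3 high                   1.83    86
```

Per cc of tumour, low-grade disease raises serum PSA by ~4 ng/ml but
high-grade disease by under 2 — the simulated cohort returns the secretion
gradient it was built with (geometric means, after the same eligibility
filters a real cohort would pass through). The grade difference is the
ANOVA of the next line; the recurrence model shows the adverse-pathology
hazard ratios and that ln(tPSAD) adds nothing once grade and stage are in
the model:

```r
group_compare(tab, ln_tpsad, grade, "anova")
#>   method        statistic   df1   df2  p_value n_groups
#> 1 One-way ANOVA      151.     2   861 8.64e-57        3

fit <- tab |>
  mutate(grade_intermediate = grade == "intermediate",
         grade_high = grade == "high") |>
  cox_fit(c("epe", "svi", "positive_margins",
            "grade_intermediate", "grade_high", "ln_tpsad"),
          time = followup_time, event = recurrence)
tidy(fit)
#>   term               estimate std_error hazard_ratio conf_low conf_high ...
#> 1 epe                   0.219     0.164        1.24     0.903      1.72
#> 2 svi                   0.491     0.227        1.63     1.05       2.55
#> 3 positive_margins      0.750     0.145        2.12     1.59       2.81
#> 4 grade_intermediate    0.491     0.294        1.63     0.918      2.91
#> 5 grade_high            1.44      0.354        4.23     2.11       8.45
#> 6 ln_tpsad             -0.301     0.226        0.740    0.475      1.15
```

`autoplot()` methods draw Kaplan–Meier step curves and hazard-ratio forest
plots; `run_full_pipeline(seed = 1)` chains every stage (simulation,
filtering, tPSAD, group comparisons, quintile survival, Cox, expression
meta-analysis, IHC densitometry) into one reproducible report whose tables
carry the seed and a configuration hash.

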