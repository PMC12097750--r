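# pcqlasso

Bootstrap-stabilized LASSO modelling of the psychosocial consequences
of disease screening.

Screening programs (here: population screening for liver disease) can
burden participants psychologically. The Psychological Consequences
Questionnaire (PCQ) quantifies that burden as a total score (0–36) with
emotional (0–15), physical (0–12) and social (0–9) dysfunction
subscales. Epidemiological survey analyses ask which of ~24 candidate
respondent characteristics — comorbidity burden (KOMO), social support
(OSSS-3), subjective social status (MacArthur ladder), health literacy
(HELP), communication competence (KoKo), satisfaction with care (ZAP),
the screening result itself, sociodemographics — predict these
outcomes. `pcqlasso` is for biostatisticians running that analysis, and
for methodologists probing how stable it is.

## The method

Per outcome $y$ with candidate matrix $X$ (standardized columns):

$$\hat\beta(\lambda) = \arg\min_\beta\ \tfrac{1}{2n}\lVert y - X\beta\rVert_2^2 + \lambda\lVert\beta\rVert_1$$

solved by cyclic coordinate descent (compiled kernel, warm-started
along a 100-point log grid from $\lambda_{\max} = \max_j|x_j^\top y|/n$),
with $\lambda$ chosen by 10-fold cross-validation at the MSE minimum.
Stability layer: $B = 100$ case-bootstrap resamples; a predictor is
retained when its coefficient at that resample's $\lambda_{\min}$ is
nonzero in at least 80% of resamples. The final model refits the
cross-validated LASSO per bootstrap on the retained set; reported
coefficients are bootstrap means (zeros included), standard errors are
bootstrap SDs, 95% CIs are mean ± 1.96·SE, and fit is judged by
bootstrap-averaged RMSE against the outcome SD. A tie-corrected
Mann–Whitney U (exact permutation p-value for small groups) compares
the total PCQ between screening groups. A calibrated synthetic survey
generator reproduces the marginal moments, floor-heavy skew, sparse
signal and mild predictor collinearity the analysis assumes, so the
whole pipeline is testable at desk scale. See the methods vignette
(`vignettes/bootstrap-lasso-methods.Rmd`) for every convention and its
rationale.

## Worked example

```r
library(pcqlasso)

d   <- simulate_survey(sim_config(n = 487, seed = 2024))   # synthetic survey
sel <- bootstrap_selection(d, "pcq_total",
                           predictor_names(default_schema()),
                           B = 100, k = 10, master_seed = 7)
set <- select_predictors(sel, 0.80)
fm  <- summarize_final(refit_selected(d, set, B = 100, k = 10,
                                      master_seed = 7), d, "pcq_total")
print(fm)
```

```
Final bootstrap-averaged model for 'pcq_total' (B = 100)
          term coefficient    se             ci significant
 komo_severity        1.68 0.334   [1.03; 2.34]         yes
  life_partner       -3.46 0.850 [-5.13; -1.80]         yes
    komo_count       -0.35 0.136 [-0.61; -0.08]         yes
           age       -0.06 0.034  [-0.13; 0.00]          no
          RMSE        8.77    NA
   SD of scale        9.20    NA
           MAE        7.08    NA
  well fitted on average (RMSE 8.77 vs outcome SD 9.20)
```

Reading it: severity of comorbidities was retained in 100/100
bootstraps and adds ~1.7 points of total-score dysfunction per severity
unit (its latent planted effect is larger; the floor-clipped outcome
scale attenuates observable slopes — see the vignette). Partnership is
protective. The interval for age touches 0, so it is not flagged
significant. RMSE below the outcome SD marks the model well fitted on
average. `run_pipeline(run_config(...))` does this for all four PCQ
outcomes and writes the descriptive table, the selection-frequency
ranking, the final-model table and a reproducibility manifest;
`compare_screening_groups(d)` adds the Mann–Whitney contrast.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/pcqlasso.R simulate --n 487 --seed 1 --out .
Rscript inst/cli/pcqlasso.R run-all --input survey.csv --seed 1 --out reports/
```

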