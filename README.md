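# bslnet

Counterfactual survival modeling and individualized treatment
recommendation for two-arm observational cohorts, built around the
**balanced survival Lasso-network** (BSL): a shared representation network
balanced across treatment arms with a Sinkhorn optimal-transport penalty,
feeding two treatment-specific **LassoNet** risk heads trained on the Cox
partial likelihood.

The motivating setting is adjuvant therapy choice in diffuse low-grade
glioma — radiotherapy alone (RT) versus chemoradiotherapy (CRT) — where the
average benefit of intensifying therapy is equivocal but specific strata
(younger patients, tumors at unfavorable sites) may gain substantially, and
where registry data are both confounded and right-censored.

## The model in brief

For covariates $x$ with shared representation $z = \Phi(x)$, each arm
$a \in \{\mathrm{RT}, \mathrm{CRT}\}$ has a risk score

$$s_a(x) = \theta_a^\top z + g_a(z), \qquad
\|W_{a,j}\|_\infty \le M\,|\theta_{a,j}|,$$

where $g_a$ is a small ReLU network whose first-layer rows $W_{a,j}$ are
bounded by the penalized linear skip weights — a feature participates
non-linearly only while its linear weight is active (enforced exactly by a
hierarchical proximal operator after every optimizer step). Training
minimizes the two arms' Cox partial likelihoods plus
$\alpha\,S_\varepsilon(z_{RT}, z_{CRT})$, the debiased entropic
optimal-transport divergence between the arms' latent clouds. Per-arm
Breslow baseline hazards turn scores into counterfactual survival curves
$S(t\mid x,a) = \exp\{-H_{0,a}(t)e^{s_a(x)}\}$; the individual treatment
effect is the difference in **Time at Risk** (first time predicted
mortality reaches 50%),

$$\mathrm{ITE}(x) = \mathrm{TaR}_{\mathrm{CRT}}(x) - \mathrm{TaR}_{\mathrm{RT}}(x)
\quad \text{(months)},$$

and CRT is recommended when the ITE is positive. Recommendations are
evaluated by comparing patients treated concordantly vs discordantly with
the model (Rec vs Anti-rec) under inverse-probability-of-treatment
weighting: hazard ratios, 5-year restricted-mean-survival differences,
weighted Kaplan–Meier curves with log-rank tests, balance diagnostics
(standardized mean differences), and per-arm concordance / integrated Brier
scores. A synthetic confounded LGG-like cohort generator with closed-form
ground truth supports every validation in the test suite.

## Worked example

```r
library(bslnet)

cfg    <- simulation_config(n_patients = 2000, seed = 42)
cohort <- simulate_cohort(cfg)
split  <- split_cohort(cohort, test_fraction = 0.2, seed = 42)
enc    <- encode_features(cohort, fit_on = split$train_ids)
tr <- which(cohort$id %in% split$train_ids)
te <- which(cohort$id %in% split$test_ids)

model <- train_bsl(enc$x[tr, ], cohort$time[tr], cohort$event[tr],
                   cohort$treatment[tr],
                   config = bsl_config(shared_layers = c(16L), latent_dim = 8L,
                                       head_hidden_layers = c(8L),
                                       lasso_lambda = 0.01,
                                       max_iterations = 400,
                                       patience_iterations = 150, seed = 42))
print(model)
#> Balanced Survival Lasso-Network
#>   features: 41  shared: 16 -> latent 8  head hidden: 8
#>   lambda = 0.01, M = 10, alpha = 1, epsilon = 0.5
#>   trained 166 iterations (best at 16)
#>   head 0: 8/8 active skip weights
#>   head 1: 8/8 active skip weights

ite <- compute_ite(model, enc$x[te, ], ids = cohort$id[te])
head(ite, 3)
#>   id   tar_rt   tar_crt       ite recommendation ...
#> 1  3 228.4287 133.90701 -94.52172             RT
#> 2 13 228.4287 228.42873   0.00000             RT
#> 3 27 102.2872  83.72643 -18.56078             RT
```

Each row gives the predicted months until 50% mortality under RT and CRT,
their difference (the ITE), and the resulting recommendation (ties and
never-reached medians resolve to RT, the less intensive therapy). Here CRT
is recommended for 128 of 400 test patients.

```r
report <- evaluate_recommendations(cohort[te, ], ite, model = model,
                                   x = enc$x[te, ])
print(report)
#> Recommendation effectiveness report
#>   n = 400 (Rec: 219, Anti-rec: 181)
#>   HR   (Rec vs Anti-rec): 0.79 (95% CI 0.56-1.13)
#>   HR^a (IPTW):            0.74 (95% CI 0.49-1.11)
#>   DRMST   at 60 mo: 1.67 (95% CI -2.48-5.82)
#>   DRMST^a at 60 mo: 3.46 (95% CI -0.78-7.70)
#>   KM^a log-rank at 60 mo: p = 0.1076
#>   KM^a log-rank at 120 mo: p = 0.09283
#>   C-index RT 0.545 / CRT 0.620; IBS RT 0.140 / CRT 0.144
#>   covariates with post-IPTW |SMD| >= 0.1: 0 of 30
```

A hazard ratio below 1 means patients treated in line with the model's
recommendation die of their disease at a lower rate than those treated
against it; the IPTW-adjusted variants control for the covariate mix
(including surgery and the received treatment), and the SMD line confirms
the weighting balanced all covariates below the conventional 0.1 threshold.
`recommendation_or()` and `subgroup_ate_table()` then explain *who* gets
recommended CRT (covariate odds ratios with regional random effects) and
how the CRT effect differs across Overall / RFC / RFR / Group A / Group B
subgroups.

The full pipeline (simulate → split/encode → train → recommend → evaluate →
interpret) is scriptable via `run_experiment(run_config(...))` or the thin
CLI wrapper `inst/scripts/bsl-pipeline.R`; every artifact is plain CSV/JSON
with a checksum manifest, and a rerun with the same configuration is
byte-identical.

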