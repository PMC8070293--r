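# marsurv

Direct modelling of (age-standardized) marginal relative survival from
registry-style cohort data and population lifetables.

## The problem

Cancer registry studies report *marginal relative survival* — the ratio of a
cohort's all-cause survival to the survival expected from population
lifetables, interpretable under assumptions as marginal *net* survival
(survival if the cancer were the only possible cause of death).  The
all-cause mortality rate of a patient with covariates `X` is decomposed as

    h(t | X) = h*(t | X) + λ(t | X)

with `h*` the expected rate from lifetables (by age, sex, calendar year) and
`λ` the excess rate.  Because patients with high expected mortality are
progressively depleted from the risk set, a relative survival model with no
covariates does **not** estimate the marginal curve; the usual remedies are
the non-parametric Pohar Perme estimator or a covariate-rich conditional
model followed by regression standardization.

`marsurv` instead fits a flexible parametric model that targets the marginal
curve directly.  The likelihood carries time-dependent weights
`w_i(t) = w_a_i / S*_i(t)` (inverse expected survival, optionally times an
age-standardization weight `p_R/p_obs`), replaces the individual expected
rate at each event time with the weighted risk-set mean `h̄*(t)`, and models
the log cumulative excess hazard as a restricted cubic spline of log time
(Royston–Parmar scale):

    ln L_i = d_i w_i(t_i) ln[ h̄*(t_i) + λ_m(t_i|γ) ]
             − Σ_k w_i(t_k) [ Λ_m(t_{i(k)}|γ) − Λ_m(t_{i(k−1)}|γ) ]

after splitting follow-up into short intervals with midpoint weights.  The
variance is a subject-clustered sandwich, since the weights induce
within-subject correlation across split rows.  This removes the need to model
covariates that only affect expected rates, supports external
age-standardization via individual weights, and yields directly
interpretable group contrasts (marginal excess mortality rate ratios and
survival differences).

The package also provides the Pohar Perme estimator (plain and
age-standardized), a piecewise weighted-Poisson estimator that reproduces it
exactly (the central cross-check), conditional flexible parametric excess
hazard models with time-dependent effects and regression standardization,
lifetable utilities, a split-width/knot sensitivity sweep, and a simulation
harness comparing all estimators against analytic truth.

## Worked example

Simulate a registry-style cohort (1000 patients, ages Normal(66, 13),
Weibull baseline excess hazard with a non-proportional age effect, Gompertz
lifetable, administrative censoring at 10 years) and estimate marginal
relative survival both ways:

```r
library(marsurv)
set.seed(2030)
tb  <- synthetic_ratetable()                      # a = 5e-5, b = 0.087
ch  <- simulate_cohort(sim_scenario(1, n = 1000), tb)

fit <- fit_marginal(ch, tb)                       # 6 knots, split 0.2y
predict(fit, c(1, 5, 10))
#   time  rel_surv     lower     upper
#      1 0.7544284 0.7266116 0.7798560
#      5 0.5671159 0.5325792 0.6001199
#     10 0.4764830 0.4375044 0.5143820

pp <- pohar_perme(ch, tb)
curve_at(pp, c(1, 5, 10))
#   time  rel_surv     lower     upper
#      1 0.7572103 0.7280846 0.7836924
#      5 0.5638655 0.5284413 0.5977063
#     10 0.4760802 0.4365911 0.5144657
```

The two estimators agree closely (the model is slightly more precise), and
both track this replicate's draw around the analytic truth
`true_marginal_net_survival(sim_scenario(1), c(1, 5, 10))` =
0.737 / 0.582 / 0.493.  For a cohort with a comparison group (a `group`
column) and a chosen reference age distribution, contrasts and external
standardization follow the same pattern:

```r
fit2 <- fit_marginal(cohort, tb, group = "sex",
                     ref = ref_dist(c(0, 45, 55, 65, 75, Inf), ref_props))
contrast(fit2)                       # marginal excess mortality rate ratio
contrast(fit2, "survival_difference", times = c(1, 5, 10))
sensitivity_sweep(ch, tb)            # stability in split width x knots
```

A command-line interface wraps the same functions
(`Rscript inst/cli/marsurv.R pohar-perme --data cohort.csv
--ratetable popmort.csv --at 1,5,10 --out est.csv`), with subcommands
`make-lifetable`, `pohar-perme`, `fit-marginal`, `fit-conditional`,
`simulate` and `sweep`.

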