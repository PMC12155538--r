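# coxsusie

Bayesian fine-mapping for **censored time-to-event outcomes**: which of
many correlated genetic variants in a region affect an age-of-onset trait,
when most individuals never experience the event during follow-up?

`coxsusie` combines the Cox proportional hazards partial likelihood with
the sum-of-single-effects (SuSiE) prior. The regression coefficients over
the `p` variants are modeled as

```
b = Σ_{l=1..L} b_l,    b_l = b_l γ_l,    γ_l ~ Multinom(1, π),    b_l ~ N(0, σ²_{0l}),
```

so at most `L` variants have non-zero log-hazard-ratios, and each sample's
hazard is `λ_i(t) = λ_0(t) exp(bᵀ x_i + c_i)` with an optional fixed-offset
term `c_i` for covariates (sex, genetic PCs). The model is fitted by
**generalized iterative Bayesian stepwise selection (gIBSS)**: cycle over
the `L` effects, each time fitting a single-effect regression (SER) at the
offsets left by the other effects. Per-variant evidence inside each SER is
a **Laplace approximation to the Bayes factor**,

```
log BF̂_j = log ABF_j − z_j²/2 + [log ℓ(b̂_j) − log ℓ(0)],
```

which needs only the univariate MLE `b̂_j`, its standard error `s_j`, and
the likelihood ratio — and is far more accurate than Wakefield's ABF, which
systematically overestimates the evidence. A Gauss–Hermite quadrature gold
standard over the exact partial likelihood is included for verification.

Outputs are per-variant **posterior inclusion probabilities** (PIPs) and
per-effect level-ρ **credible sets** filtered by *purity* (the minimum
absolute pairwise correlation among members; default threshold 0.5).

The package also ships a synthetic-data generator (Binomial(2, MAF)
dosages with AR(1) Gaussian-copula LD; censored survival times from a Cox
model with calibrated censoring) and the standard fine-mapping evaluation
metrics (PIP calibration, power/FDR curves, credible-set
coverage/power/MAS).

## Worked example

```r
library(coxsusie)

# a simulated 200-variant region with two causal variants (+0.7 / -0.7),
# strong AR(1) LD and 20% censoring
cfg <- sim_config(n = 2000, p = 200, ld_rho = 0.9,
                  causal_indices = c(50, 150), effects = c(0.7, -0.7),
                  target_censoring = 0.2, seed = 3)
dat <- make_finemap_dataset(cfg)
dat$outcome
#> Survival outcome: n = 2000, events = 1597, censoring rate = 0.202

fit <- coxph_susie(dat$X, dat$outcome, L = 5)
summary(fit)
#> CoxPH-SuSiE fit (gIBSS)
#>   n = 2000 samples, p = 200 variables, L = 5 single effects
#>   5 sweeps, converged: TRUE; active effects: 5
#>   credible sets (rho = 0.95, purity >= 0.50): 2
#>
#> Top variables by posterior inclusion probability:
#>  variable    pip     coef
#>     snp50 1.0000  0.72046
#>    snp150 1.0000 -0.68987
#>    snp110 0.0691  0.00379
#>    ...
#>
#> Credible sets:
#>  label effect size purity sentinel_id sentinel_pip attained_mass members
#>     L1      1    1      1       snp50            1             1      50
#>     L2      2    1      1      snp150            1             1     150
```

Both causal variants are recovered with PIP ≈ 1 and posterior-mean
log-hazard-ratios (`coef`) close to the simulated ±0.7; each credible set
is a singleton containing exactly one causal variant, despite the ~0.8
correlation between neighbouring variants. The three remaining effects
stay diffuse and produce no credible set that survives the purity filter.

Lower-level entry points mirror the model's structure:
`fit_univariate_coxph()`, `log_laplace_bf()` / `log_abf()` /
`log_quadrature_bf()`, `coxph_ser()` / `em_update_sigma0sq()`,
`credible_sets()`, `pip_calibration()` / `power_fdr_curve()` /
`cs_metrics()`.

A command-line front end with `fit`, `simulate`, `bf` and `evaluate`
subcommands is installed at `inst/cli/coxsusie.R`; outputs are delimited
text tables plus a JSON manifest sufficient to replay the run.

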