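# addhaz — additive hazard regression for attributable-risk analysis

Cox regression answers "how many *times* higher is the risk?". Epidemiologists
planning interventions usually also need "how many *extra cases* per 100
people per year?" — the absolute, attributable scale. `addhaz` is an R package
for that question in right-censored cohorts, written for biostatisticians and
epidemiologists analysing screening-cohort data (for example, incident
HPV detection across host immune-status strata in a semiannual-visit study).

## What it fits

**Semiparametric additive hazard model** (constant effects):

    h(t | Z) = β0(t) + βᵀZ

fitted in closed form by the estimating equations β̂ = A⁻¹b, where
A = Σᵢ ∫ Yᵢ(t) (Zᵢ − Z̄(t))⊗² dt and b = Σᵢ ∫ (Zᵢ − Z̄(t)) dNᵢ(t), with a
sandwich covariance A⁻¹MA⁻¹ and Wald tests. Each β̂ₖ is an excess hazard:
extra events per person-year per unit of Zₖ. The cumulative baseline hazard
B̂0(t) comes with martingale-based pointwise standard errors.

**Nonparametric additive hazard model** (time-varying effects):

    h(t | Z) = β0(t) + β(t)ᵀZ

estimated by per-event-time least squares: dB̂(s) = (XᵀX)⁻¹Xᵀ dN(s), giving
the cumulative regression functions Bₖ(t) = ∫₀ᵗ βₖ(s) ds up to the full-rank
horizon τ. For an indicator covariate, B̂ₖ(t) is the excess cumulative hazard
of that group.

Around the two fitters: ordinal trend tests, Cox-Snell residual
goodness-of-fit with a parametric-bootstrap 45°-line envelope, adjusted
stratum survival curves exp(−(B̂0+B̂ₖ)), attributable-case estimates, a
visit-table → midinterval event-time constructor, and a synthetic
screening-cohort generator with a fully known additive truth (semiannual
visits, four-level exposure, confounders, dropout, per-subject random
substreams). See the methods vignette (`vignettes/additive-hazards.Rmd`)
for models, assumptions and design choices.

## Worked example

```r
library(addhaz)

gen <- simulate_cohort(hpv_scenario(n = 2386, seed = 1))  # known additive truth
fit <- fit_semiparametric(gen$cohort)
summary(fit)
#>                 term     estimate          se      p_value
#> 1     hivcd4=CD4>500  0.029598453 0.005705878 2.132945e-07
#> 2 hivcd4=CD4 200-500  0.075920115 0.007456771 2.401663e-24
#> 3     hivcd4=CD4<200  0.135331840 0.012622839 8.095592e-27
#> 4     smoking=former -0.007895666 0.006390908 2.166620e-01
#> 5    smoking=current  0.009511311 0.006719590 1.569337e-01
```

Each estimate is an excess hazard relative to the reference stratum: the
most immunosuppressed group experiences ≈ 0.135 extra events per woman-year
(the generating truth is 0.1395), i.e. ≈ 14 extra infections per 100
woman-years. The dose-response trend across the four ordered strata:

```r
trend_test(gen$cohort, "hivcd4")   # z = 13.7, p = 1.8e-42
```

Excess cumulative incidence by year 5, from the nonparametric fit:

```r
nfit  <- fit_nonparametric(gen$cohort)
s_ref <- survival_nonparametric(nfit, profile_for_level(gen$cohort, "hivcd4", "HIV-"))
s_low <- survival_nonparametric(nfit, profile_for_level(gen$cohort, "hivcd4", "CD4<200"))
attributable_cases(s_ref, s_low, t = 5, per = 100)
#> [1] 36.5
```

— about 37 extra infections per 100 women by year 5 in the lowest-CD4
stratum, adjusted to reference levels of the other covariates. Model
adequacy via Cox-Snell residuals:

```r
res <- cox_snell_semiparametric(fit, gen$cohort)
gof_envelope(res)$within   # TRUE: residual curve stays inside the 45°-line envelope
```

`run_analysis(gen$cohort, "out/", exposure = "hivcd4")` writes the whole
bundle (effect table, trend test, cumulative regression functions,
residuals + GOF summary, survival curves, attributable cases) as CSVs.

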