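# benchdose

Benchmark dose (BMD) modeling and toxicological risk characterization for
summarized dose–response data, in R.

Toxicological risk assessment increasingly replaces the NOAEL/LOAEL with
the **benchmark dose**: fit a suite of dose–response models to bioassay
incidence or body-weight tables, read off the dose producing a predefined
benchmark response (here 10% extra risk for quantal data, 10% relative
deviation for continuous data), and use the one-sided 95% lower confidence
limit of that dose — the **BMDL** — as the point of departure (POD) for
deriving guidance values. benchdose implements this pipeline for
assessors, regulatory toxicologists and biostatisticians who want it
scriptable, testable and reproducible:

* **Quantal families** (multistage, quantal linear, gamma, Weibull,
  log-logistic, log-probit, logistic, probit, dichotomous Hill), fitted by
  binomial maximum likelihood in restricted and unrestricted form, with
  extra-risk BMD
  `ER(d) = (p(d) − p(0)) / (1 − p(0)) = BMRF` inverted in closed form.
* **Continuous families** (exponential 3/5, Hill, polynomial, power,
  linear) under a constant-variance normal likelihood built from group
  `(n, mean, sd)` sufficient statistics, with relative-deviation BMD
  `|m(d) − m(0)| = BMRF·|m(0)|`.
* **Profile-likelihood BMDL**: the largest dose below the BMD at which the
  constrained maximum log-likelihood has dropped by χ²₁(0.90)/2 ≈ 1.3528
  (one-sided 95%).
* **Viability classification and model recommendation** following the
  standard frequentist decision rules (goodness-of-fit p ≥ 0.10, saturated
  fits, BMD/BMDL collapse below the dosed range; lowest AIC within a
  narrow BMDL range, otherwise lowest BMDL).
* **Risk arithmetic**: uncertainty-factor ledgers, ADI = POD/UF,
  maximum residue levels, per-capita ↔ per-kg conversions, exposure totals
  and margins of exposure — exact, unit-explicit and presentation-rounding
  only.
* **Seeded simulation** of quantal and continuous datasets plus an
  independent grid-scan BMD oracle, so estimators and confidence limits
  are testable against a known truth.

The package ships the summarized isoeugenol gavage-study endpoints (NTP
TR 551: neoplastic liver lesions, trend tumors, nose lesions, body weight)
as worked examples; `isoeugenol_case_study()` runs the whole assessment
end to end.

## Worked example

Fit the unrestricted degree-2 multistage model to the male-mouse
hepatocellular adenoma incidences (24/50, 35/50, 37/50, 33/50 at
0/75/150/300 mg/kg bw/day):

```r
library(benchdose)

d <- isoeugenol_endpoint("adenoma")
fit <- fit_quantal(d, "multistage", degree = 2, restricted = FALSE)
fit
#> <quantal_fit> Multistage Degree 2 (unrestricted)
#>   endpoint: hepatocellular adenoma (male mice, 2 yr)
#>   loglik -125.9078  AIC 257.82  (3 estimated parameters)
#>   GOF p 0.770 (df 1)   BMD 13.05   BMDL 7.959
```

The Pearson goodness-of-fit p-value of 0.77 says the curve is consistent
with the observed incidences; the BMD of 13 mg/kg bw/day is the dose at
10% extra risk over the 48% background, and the BMDL of 8 mg/kg bw/day is
its one-sided 95% profile-likelihood lower bound — the POD of the
assessment. `tidy(fit)`, `glance(fit)`, `augment(fit)` and
`autoplot(fit)` expose parameters, the one-row summary, per-group
residuals and the fitted curve.

Run the whole model suite on the carcinoma endpoint and let the decision
rules pick a model:

```r
suite <- classify_fits(fit_quantal_suite(isoeugenol_endpoint("carcinoma")))
glance(recommend_model(suite))
#> # A tibble: 1 × 7
#>   label                      n_models n_viable recommended rationale   bmd  bmdl
#> 1 hepatocellular carcinoma …       19        9 Multistage… lowest_b…  31.2  18.1
```

Nine of the 19 fitted models are viable; because their BMDLs span more
than a 3-fold range, the unrestricted degree-2 multistage model wins on
the lowest BMDL (BMD 31, BMDL 18 mg/kg bw/day).

Carry the POD through the risk arithmetic (BMDL 8 mg/kg bw/day = 8000
µg/kg bw/day, uncertainty factor 100 × 5):

```r
assess_risk(8000, "bmdl",
            uf_ledger(interspecies_intraspecies = 100, severity = 5),
            exposures = c(europe = 2.35, usa = 1.12),
            daily_food_intake = 0.3, allocation = 0.4)
#> <risk_assessment>
#>   POD (BMDL):          8000 ug/kg bw/day
#>   composite UF:        500
#>   ADI:                 16 ug/kg bw/day
#>   acceptable amount:   960 ug/day (at 60 kg bw)
#>   MRL:                 1280 ug/kg food (40% allocation, 0.3 kg/day)
#>   exposure europe      2.35 ug/kg bw/day  (MOE 3404)
#>   exposure usa         1.12 ug/kg bw/day  (MOE 7143)
```

The ADI of 16 µg/kg bw/day sits well above the estimated total exposures
(2.35 and 1.12 µg/kg bw/day), and the implied fish MRL is 1280 µg/kg.

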