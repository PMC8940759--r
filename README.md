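# gpconv

Arbitrary-precision evaluation of the **gamma-Pareto type I convolution
(GPC)** distribution family and the pharmacokinetic tooling built on it.

Some drugs — metformin after an intravenous bolus is the canonical case —
wash out with a *power-function* tail rather than a terminal exponential:
the concentration falls like `t^-(alpha+1)`, there is no terminal
half-life, and the body burden keeps creeping up under repeated dosing
even while serum peaks barely move. The GPC models this as the
convolution of a gamma density `GD(t; a, b) = e^(-bt)(bt)^a / (t Γ(a))`
with a delayed Pareto type I density `PD(t; α, β) = (α/t)(β/t)^α` for
`t > β`, where `β` is the circulation delay from injection to the
sampling site.

The defining series alternates with terms that grow astronomically large
before converging (at half a year after dosing the largest term is
~10^1392 while the density is ~10^-6), so naive evaluation destroys all
precision. `gpconv` implements the two complementary series-accelerated
algorithms — a short-time primary series with two-pass precision
pre-calculation, and a long-time rearrangement whose confluent
hypergeometric terms terminate under the Kummer transformation — behind
a dispatcher that switches at `t = 4β`, all on GNU MPFR arithmetic under
an explicit precision policy (65 significant digits by default).

For whom: pharmacokineticists and biostatisticians who need the density,
CDF, super-cumulative (integral of the CDF, the key to time-averaged
body burden), and density derivative of the GPC at any time with
controlled precision; plus multidose superposition accounting,
proportional-error (1/C²-weighted) Nelder–Mead fitting, model-based
residual bootstrap CIs, and a synthetic study-design generator.

## Worked example

The dog-1 metformin parameter set (`a = 0.3493`, `b = 0.7318` per hour,
`alpha = 0.2644`, `beta = 25` s; AUC 31.16 mg·h/L, dose 18.248 mg/kg):

```r
library(gpconv)
dog1 <- gpc_params(a = 0.3493, b = 0.7318, alpha = 0.2644, beta_s = 25)
mod  <- gpc_model(dog1, auc = 31.16, dose = 18.248)

gpc_evaluate("pdf", 12, dog1, gpc_policy(30))
#> <gpc_eval> pdf(t = 12 h), long branch, 9 term(s), working 40 digits,
#>   max |term| ~ 1e-8
#> 3.27428265628388165828798698627e-03

mod$cl * 1000 / 60        # clearance, mL/(min kg)
#> [1] 9.760377

interval_stats(mod, dose_regimen(24, 14), 14)
#> <interval 14> conc peak 113.2 (t=312 h) trough 0.1016 mg/L; retained
#> peak 1.974 trough 1.032 mean 1.117; eliminated 12.88 doses
```

Reading: twelve hours after a dose the density is 3.27e-3/h (the long
branch needed 9 terms at 40 working digits). During the 14th daily
dose interval the body still holds 1.117 dose-equivalents on average —
about one full dose parked in tissue — although 12.88 doses' worth has
been eliminated, and the serum trough has risen 2.48-fold while the
peak rose only 0.089%:

```r
acc <- accumulation_summary(mod, dose_regimen(24, 14))
acc$trough_conc_ratio        #> 2.483322
acc$peak_conc_increase_pct   #> 0.08858291
```

Fitting synthetic data back to the model:

```r
d <- generate_synthetic(mod, synth_design(seed = 42))   # 21 samples, 8.6% noise
f <- fit_gpc(d, dose = 18.248, seed = 1)
f
#> <gpc_fit> a=0.3373 b=0.6709 alpha=0.2723 beta=25 s AUC=30.2;
#>   rrms 8.78%, R2 0.98943, CL 10.1 mL/(min*kg)
b <- bootstrap_gpc(d, f, n_reps = 40, seed = 1)
```

A thin command-line front end is installed at
`inst/cli/gpconv.R` (`eval`, `simulate`, `fit`, `multidose`,
`bootstrap`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","gpconv.R",package="gpconv"))')" \
  eval --a 0.3493 --b 0.7318 --alpha 0.2644 --beta-seconds 25 \
  --t-hours 12 --function pdf --digits 30 --diagnostics
```

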