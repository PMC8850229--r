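# kmdregion

Locate the **kinetically derived maximum dose (KMD)** as a bounded
concentration region from toxicokinetic elimination data.

## The problem

Dose-setting for regulatory toxicology studies needs the concentration range
where elimination kinetics begin to saturate: below it elimination is
effectively first order; at and above it the elimination machinery runs near
capacity and different modes of action can switch on. There is no single
concentration where a saturable curve "breaks" — the rate approaches its
asymptote smoothly — so this package reports the KMD as a region
(lower bound, most-likely midpoint, upper bound) with the uncertainty made
explicit, rather than as a point estimate derived from AUC summaries.

## The method

1. **Model.** Blood concentration follows single-compartment saturable
   elimination, `dC/dt = -Vmax*C/(Km + C)` — the system-wide
   Michaelis–Menten rate law (`v = Vmax*S/(Km + S)`) applied to the
   elimination curve's slope. The curve has the exact Lambert-W solution
   `C(t) = Km * W0((C0/Km) * exp((C0 - Vmax*t)/Km))`, evaluated in the log
   domain for numerical robustness.
2. **Inference.** `fit_mm_bayes()` samples the posterior of `(Vmax, Km, σ,
   C0)` under truncated-normal priors on `Vmax`/`Km` and a half-Cauchy prior
   on σ, with a Normal likelihood on the observed concentrations (adaptive
   MCMC, Laplace-seeded proposal, rhat/ESS diagnostics via coda).
   `fit_mm_mle()` is the frequentist counterpart.
3. **Knee detection.** The KMD is the "knee" (point of diminishing returns)
   of the fitted Michaelis–Menten curve, found with the kneedle algorithm
   over a window anchored at the concentrations giving 90% and 95% of Vmax
   (`9*Km` and `19*Km`). For MM curves the knee has the closed form
   `sqrt(Km*(Km + Smax)) - Km`, independent of Vmax.
4. **Region assembly.** `compute_kmd_region()` turns the posterior Km
   summary (2.5% quantile, mean, 97.5% quantile) and the two anchors into
   the lower bound, midpoint and upper bound of the KMD.

A synthetic toxicokinetic generator (`generate_tk_dataset()`) with known
ground truth and configurable noise makes the whole pipeline testable
end-to-end.

## Worked example

Alcohol-like elimination kinetics (`Vmax = 175` mg/dL/h,
`Km = 11.8` mg/dL). With the Km posterior summary from such a fit —
credible interval [11, 13] mg/dL, mean 11.97 mg/dL — and window anchors
computed from Km = 11.8:

```r
library(kmdregion)

conc_at_fraction(0.90, 11.8)   # 106.2  (mg/dL at 90% of Vmax, = 9*Km)
conc_at_fraction(0.95, 11.8)   # 224.2  (mg/dL at 95% of Vmax, = 19*Km)

region <- kmd_region_from_km(km_lower = 11, km_mean = 11.97, km_upper = 13,
                             smax_km = 11.8)
region
#> KMD region (mg/dL)
#>   lower     25  (raw 24.90; Km 11, window [0, 106.2])
#>   midpoint  34  (raw 34.08; Km 11.97, window [0, 165.2])
#>   upper     43  (raw 42.53; Km 13, window [0, 224.2])
```

Read: under these kinetics the KMD plausibly lies between about 25 and
42–43 mg/dL, most likely near 34 mg/dL — doses producing blood
concentrations above that range sit in (or beyond) the saturation
transition. Note the raw upper knee (42.53) rounds to either neighbour; both
raw and rounded values are always reported.

The full pipeline from data:

```r
d   <- default_example_dataset(seed = 1)     # 49 samples, 5% CV noise
fit <- fit_mm_bayes(d)                       # ~7 s; rhat-checked
compute_kmd_region(fit)
```

A command-line interface wraps the same functions
(`simulate`, `fit`, `kmd`, `run` subcommands):

```sh
TOOL=$(Rscript -e 'cat(system.file("cli", "kmd_tool.R", package = "kmdregion"))')
Rscript $TOOL kmd --km-ci 11,13 --km-mean 11.97 --smax-km 11.8 --out kmd.json
```

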