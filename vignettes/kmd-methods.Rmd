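---
title: "Locating the kinetically derived maximum dose as a bounded region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the kinetically derived maximum dose as a bounded region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmdregion)
```

## The problem

Regulatory toxicology studies need a defensible upper bound on dosing: the
concentration range where elimination kinetics begin to saturate. Below that
range elimination is effectively first order; inside and above it the
elimination machinery (enzymes, transporters) runs near capacity, different
modes of action can switch on, and doses on the two sides of the boundary are
not directly comparable. The kinetically derived maximum dose (KMD) is this
transition region. There is no single concentration where a saturable curve
"breaks" — the curve approaches its asymptote smoothly — so `kmdregion`
reports the KMD as a bounded region with a most-likely midpoint, not as a
point estimate.

## The model

Elimination of a chemical by the whole ADME system is treated as one
system-wide saturable process. Blood concentration \(C(t)\) follows

\[
\frac{dC}{dt} = -\,\frac{V_{\max}\, C}{K_m + C},
\]

the Michaelis–Menten rate law applied to the elimination curve's slope:
\(V_{\max}\) (mg/dL per hour) is the capacity-limited maximum elimination
rate and \(K_m\) (mg/dL) the concentration at half-maximal rate. This ODE has
the exact solution

\[
C(t) = K_m\, W_0\!\left(\frac{C_0}{K_m}
        \exp\!\left(\frac{C_0 - V_{\max} t}{K_m}\right)\right),
\]

with \(W_0\) the principal Lambert W branch. The package evaluates this in
the log domain (`lambert_w0_exp()`), because the W argument overflows double
precision whenever \(C_0 \gg K_m\) — exactly the saturated regimes of
interest. A numeric solver (`deSolve::lsoda`, `rtol = atol = 1e-9`) provides
an independent route (`simulate_elimination()`); the two agree to better than
1e-6 relative error, which the test suite verifies over random parameter
sets.

### Bayesian estimation

Given observations \(y_i\) at times \(t_i\),

\[
y_i \sim \mathrm{Normal}\big(C(t_i;\,V_{\max}, K_m, C_0),\ \sigma\big),
\qquad
\sigma \sim \mathrm{HalfCauchy}(1),
\]

with truncated-normal priors (support \((0, \infty)\)) on \(V_{\max}\) and
\(K_m\). The default hyperparameters, `prior_spec(175, 20, 11.8, 3)`, are
weakly-informative values for the packaged alcohol-like example; any
literature-derived block can be supplied, and tighter priors behave as
expected (the prior-only sampling mode exists to check them).

Two estimation choices deserve explanation:

* **The starting concentration is a parameter.** By default
  (`c0_mode = "estimate"`) \(C_0\) gets a weak truncated-normal prior centred
  on the first observation (sd 20% of it). The alternative of anchoring the
  curve exactly at the first observed value (`c0_mode = "fixed"`) looks
  natural for an elimination-only design but is statistically wrong whenever
  that observation carries noise: the single measurement's error propagates
  into \(V_{\max}\) with no accounting. In calibration runs at 5%
  proportional noise, fixing \(C_0\) collapsed the \(V_{\max}\) coverage of
  the 95% credible interval to 5/20 replicates, while estimating it restored
  nominal coverage (18–20/20).
* **The likelihood mean is the concentration curve, not the rate curve.**
  Fitting in concentration space is what an ODE-solver-in-the-likelihood
  procedure does; the Michaelis–Menten expression enters as the model's
  slope function, not as the regression mean.

Sampling is adaptive random-walk Metropolis on log-parameters. Chains start
from a jittered cheap maximum-likelihood estimate (priors may be arbitrarily
weak, so prior centres can sit far from the posterior mass), and the initial
proposal covariance is the Laplace approximation — the inverse curvature of
the log-posterior at that centre — so the sampler is close to well-tuned
even when the posterior is orders of magnitude tighter than the priors.
Warmup then tunes the global scale to ~30% acceptance and re-estimates the
proposal shape from the chain's own history (Haario-type adaptation); the
kernel is frozen for the retained draws. Defaults are 4 chains × (1500
warmup + 2500 draws), seed 2022. A fit is flagged `converged` only when every parameter's
PSRF (rhat, via `coda::gelman.diag`) is ≤ 1.01; `compute_kmd_region()`
refuses non-converged posteriors unless forced. With three to four
parameters and an exact closed-form likelihood mean this sampler reaches
effective sample sizes of several hundred in a few seconds; it is not a
general-purpose replacement for gradient-based samplers on harder
posteriors.

A maximum-likelihood mode (`fit_mm_mle()`, multi-start Nelder–Mead with
\(\sigma\) profiled out) provides the frequentist counterpart; on noise-free
data it recovers the generating parameters to optimizer tolerance.

## Finding the knee

On the fitted Michaelis–Menten curve the KMD is the "point of diminishing
returns": where the rate comes close enough to \(V_{\max}\) that the system
behaves as saturated. The kneedle algorithm finds it by normalizing the curve
to the unit square and maximizing the difference curve
\(d = y_{\mathrm{norm}} - x_{\mathrm{norm}}\) (with the usual sensitivity
threshold, \(S = 1\); for smooth noiseless model curves the thresholded local
maximum and the global argmax coincide).

The knee of a curve with an asymptote is **not** scale-invariant: it depends
on the plotted window. The window is therefore anchored mechanistically, at
the concentration where the rate reaches a stated fraction of \(V_{\max}\).
Solving \(v = f\,V_{\max}\) gives \(S = f K_m/(1-f)\): the 90% anchor is
\(9K_m\) and the 95% anchor \(19K_m\) (`conc_at_fraction()`). The 90–95%
band is used because interval slopes of simulated elimination curves show
near-zero-order (saturated) behaviour from those starting concentrations —
the early-curve slope stays within a few percent of \(-V_{\max}\).

For the Michaelis–Menten curve on \([0, s_{\max}]\) the kneedle construction
has a closed form: the normalized difference curve is maximized at

\[
s^\* = \sqrt{K_m (K_m + s_{\max})} - K_m ,
\]

independent of \(V_{\max}\), which cancels under y-normalization (the
discrete path still accepts a \(V_{\max}\) for interface fidelity; tests
assert its non-effect across three decades). The package verifies the
formula by brute-force grid maximization and uses the discrete kneedle on a
10,001-point grid by default (knee resolution \(\le s_{\max}/10^4\), well
under 1 mg/dL for the worked example; the knee is reported at the grid
argmax, without sub-grid interpolation — the closed form is available when
exactness matters).

## Assembling the region

From a converged posterior, `compute_kmd_region()` builds three knees:

| bound    | Km used              | window edge                      |
|----------|----------------------|----------------------------------|
| lower    | 2.5% posterior quantile  | 90%-of-Vmax anchor           |
| midpoint | posterior mean       | mean of the two anchors          |
| upper    | 97.5% posterior quantile | 95%-of-Vmax anchor           |

The anchors themselves need a \(K_m\); by default the posterior mean is used,
since on real data the truth is unavailable. A `smax_km` override exists for
the case where the anchors should come from an externally known \(K_m\) (the
packaged worked example computes its anchors, 106.2 and 224.2 mg/dL, from
the generating value 11.8 mg/dL). Both raw and integer-rounded bounds are
reported: a raw knee near 42.5 mg/dL can honestly round to either neighbour,
and hiding the raw value would hide that.

```{r example}
region <- kmd_region_from_km(km_lower = 11, km_mean = 11.97, km_upper = 13,
                             smax_km = 11.8)
region
```

## The synthetic generator

`generate_tk_dataset()` produces elimination series from known parameters:
the exact Lambert-W curve plus observation noise (none, additive Gaussian,
or proportional Gaussian; negative draws are truncated at zero rather than
redrawn — a documented simplification that never triggers at the default 5%
CV). The packaged study conditions (`default_example_dataset()`) are
\(V_{\max} = 175\), \(K_m = 11.8\), \(C_0 = 19K_m = 224.2\) mg/dL, 49
samples, proportional noise with CV 5%.

The sampling schedule follows a parameter-free rule: 49 evenly spaced points
across the elimination phase, defined as \([0, t_{99\%}]\) with
\(t_{99\%} = (0.99\,C_0 + K_m \ln 100)/V_{\max}\) from the integrated rate
equation (`elimination_span()`). A fixed calendar window is deliberately not
used: with the example's \(V_{\max}\) the blood is cleared in about 1.6 h,
and a 0–12 h schedule would place ~85% of samples at exactly zero
concentration — observations that carry no kinetic information, yet (having
zero proportional noise) crush the constant-\(\sigma\) likelihood's noise
estimate and destroy interval calibration. A practitioner samples while the
chemical is present; the rule encodes that. For slower kinetics
(\(V_{\max} = 25\), \(K_m = 10.5\)) the same rule spans ~0–9.9 h, an
ordinary TK day.

What the generator does **not** emulate: absorption/distribution phases,
multi-compartment disposition, inter-individual variability, assay limits of
quantification, and non-Gaussian error. Passing recovery tests on this
generator therefore show that the estimation machinery is sound under the
stated single-compartment conditions — not that real TK data, with model
misspecification of those kinds, will yield equally calibrated intervals.
One misspecification is deliberately retained: the generator's default noise
is proportional while the likelihood assumes constant \(\sigma\), so the
recovery tests already demonstrate tolerance to heteroscedasticity of the
magnitude a well-run TK study shows.

## Numerical choices

* ODE tolerances `1e-9` (both relative and absolute): interval slopes are
  meaningful to two decimals, and the closed-form cross-check to `1e-6`.
* Concentrations clamped at zero after integration and after noise.
* Lambert W in the log domain by Newton iteration, to machine precision;
  underflow of the W argument (concentration below ~1e-300 mg/dL) returns 0
  with a warning.
* MCMC parameters sampled on the log scale (Jacobian included); proposal
  adaptation frozen before the retained draws, so the chains are Markov where
  it matters.
* Equal-tailed central 95% credible intervals (2.5%/97.5% quantiles).
* Knee grids: 10,001 points; ties in the difference-curve maximum resolve to
  the first (lowest-concentration) grid index via `which.max`.
* Test-suite problem sizes: recovery experiments use 20 replicates at the
  default sampler settings; the unit-level Bayesian checks run 2 chains ×
  (600 + 800) draws, which is ample for posterior-mean assertions at the
  few-percent level.

## Limitations

* A single saturable compartment: no absorption phase, no parallel
  first-order pathway, no protein-binding submodel. Data with a visible
  distribution phase will fit badly and should be truncated to the
  elimination phase first.
* The constant-\(\sigma\) Gaussian likelihood is a compromise; strongly
  heteroscedastic data beyond the tested range (CV ≫ 10%) would warrant a
  proportional-error likelihood, which the package does not implement.
* The KMD region inherits the 90–95% anchor convention. Other anchor
  fractions are accepted (`fractions =`), but the defaults are the
  convention this methodology is built around.
* rhat ≤ 1.01 is a strict bar; short chains will occasionally flag
  non-convergence on perfectly usable posteriors. Re-run with more draws
  rather than forcing.
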