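Package: kmdregion
Title: Kinetically Derived Maximum Dose Regions from Toxicokinetic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates the kinetically derived maximum dose (KMD) as a bounded
    concentration region rather than a point estimate. Toxicokinetic
    time-concentration elimination data are fit to a single-compartment
    saturable (Michaelis-Menten) elimination model in a Bayesian framework
    (adaptive MCMC with truncated-normal priors on Vmax and Km and a
    half-Cauchy prior on the observation noise), and the knee of the resulting
    system-wide Michaelis-Menten curve is found with the kneedle algorithm,
    anchored at the concentrations giving 90% and 95% of Vmax. Includes a
    synthetic toxicokinetic data generator, a Lambert-W closed form for the
    elimination curve, maximum-likelihood fitting, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    coda,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
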