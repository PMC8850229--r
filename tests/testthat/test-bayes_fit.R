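test_that("prior_spec validates hyperparameters", {
  expect_s3_class(prior_spec(25, 2, 11, 2), "prior_spec")
  expect_error(prior_spec(25, -2, 11, 2), "positive")
  expect_error(prior_spec(25, 2, 11, 2, sigma_scale = 0), "positive")
  expect_error(fit_mm_bayes(noiseless_example(), priors = list(a = 1)))
})

test_that("posterior recovers the truth from effectively noise-free dense data", {
  # CV = 0.1%: dense, nearly exact data (with exactly zero residuals the
  # posterior is improper in sigma, so "noiseless" is tested via the MLE)
  p <- alcohol_params()
  c0 <- conc_at_fraction(0.95, p$km)
  d <- generate_tk_dataset(p, c0,
                           seq(0, elimination_span(p, c0), length.out = 49),
                           noise_model("proportional-gaussian", 0.001),
                           seed = 51)
  fit <- quick_fit(d, seed = 11)
  vm <- fit$summary$mean[fit$summary$parameter == "vmax"]
  km <- fit$summary$mean[fit$summary$parameter == "km"]
  expect_lt(abs(vm - 175) / 175, 0.02)
  expect_lt(abs(km - 11.8) / 11.8, 0.02)
  expect_true(all(fit$summary$ci_lower < fit$summary$mean &
                    fit$summary$mean < fit$summary$ci_upper))
  expect_true(all(fit$draws$vmax > 0 & fit$draws$km > 0 & fit$draws$sigma > 0))
})

test_that("posterior recovers a second regime (vmax=25, km=10.5) from noisy data", {
  p <- mm_params(25, 10.5)
  c0 <- conc_at_fraction(0.95, p$km)
  d <- generate_tk_dataset(p, c0,
                           seq(0, elimination_span(p, c0), length.out = 49),
                           noise_model("proportional-gaussian", 0.05),
                           seed = 2)
  fit <- quick_fit(d, priors = prior_spec(25, 5, 10.5, 3), seed = 12)
  vm <- fit$summary$mean[fit$summary$parameter == "vmax"]
  expect_lt(abs(vm - 25) / 25, 0.05)
})

test_that("with the likelihood disabled the posterior reproduces the prior", {
  priors <- prior_spec(175, 20, 11.8, 3)
  fit <- fit_mm_bayes(noiseless_example(), priors = priors, chains = 2,
                      warmup = 800, draws = 2000, seed = 13,
                      likelihood = FALSE)
  vm <- fit$summary$mean[fit$summary$parameter == "vmax"]
  km <- fit$summary$mean[fit$summary$parameter == "km"]
  # truncation at 0 barely moves these means; MC error a few percent
  expect_lt(abs(vm - 175), 3 * 20 / sqrt(100))
  expect_lt(abs(km - 11.8), 3 * 3 / sqrt(100))
})

test_that("sampling is reproducible under seed and flags short chains", {
  d <- default_example_dataset(seed = 4)
  f1 <- quick_fit(d, seed = 99)
  f2 <- quick_fit(d, seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$summary, f2$summary)

  # absurdly short chains must not be reported as converged
  f3 <- fit_mm_bayes(d, chains = 2, warmup = 40, draws = 40, seed = 1)
  expect_false(f3$converged)
  expect_error(compute_kmd_region(f3), "not converged")
})

test_that("fit preconditions are enforced", {
  p <- alcohol_params()
  short <- generate_tk_dataset(p, 224.2, c(0, 0.25, 0.5))
  expect_error(fit_mm_bayes(short), "at least 5")
  expect_error(fit_mm_mle(short), "at least 5")
  one <- generate_tk_dataset(p, 224.2, 0.5)
  expect_error(fit_mm_mle(one), "at least 5")
})

test_that("MLE recovers truth on clean data, from any reasonable start", {
  d <- noiseless_example()
  m <- fit_mm_mle(d)
  expect_lt(abs(m$params$vmax - 175) / 175, 1e-4)
  expect_lt(abs(m$params$km - 11.8) / 11.8, 1e-4)
  expect_true(m$converged)
  expect_lt(m$sigma, 1e-6)

  # multi-start: an initial guess 10x off lands on the same optimum
  m2 <- fit_mm_mle(d, init = mm_params(1750, 118))
  expect_equal(m2$params$vmax, m$params$vmax, tolerance = 1e-6)
  expect_equal(m2$params$km, m$params$km, tolerance = 1e-6)
})

test_that("MLE and posterior mean agree on low-noise data with weak priors", {
  p <- alcohol_params()
  c0 <- conc_at_fraction(0.95, p$km)
  d <- generate_tk_dataset(p, c0,
                           seq(0, elimination_span(p, c0), length.out = 49),
                           noise_model("proportional-gaussian", 0.005),
                           seed = 21)
  m <- fit_mm_mle(d)
  f <- quick_fit(d, priors = prior_spec(175, 100, 11.8, 15), seed = 22)
  vm <- f$summary$mean[f$summary$parameter == "vmax"]
  km <- f$summary$mean[f$summary$parameter == "km"]
  expect_lt(abs(vm - m$params$vmax) / m$params$vmax, 0.02)
  expect_lt(abs(km - m$params$km) / m$params$km, 0.02)
})

test_that("posterior mean error shrinks as noise shrinks", {
  # weak priors so the data, not prior pull, set the error at every noise
  # level (a truth-centred prior would mask the high-noise error)
  p <- alcohol_params()
  c0 <- conc_at_fraction(0.95, p$km)
  times <- seq(0, elimination_span(p, c0), length.out = 49)
  weak <- prior_spec(175, 100, 11.8, 15)
  err <- function(cv) {
    es <- vapply(1:6, function(s) {
      d <- generate_tk_dataset(p, c0, times,
                               noise_model("proportional-gaussian", cv),
                               seed = 100 + s)
      f <- quick_fit(d, priors = weak, seed = 200 + s)
      km <- f$summary$mean[f$summary$parameter == "km"]
      vm <- f$summary$mean[f$summary$parameter == "vmax"]
      abs(km - 11.8) / 11.8 + abs(vm - 175) / 175
    }, numeric(1))
    mean(es)
  }
  e <- vapply(c(0.10, 0.05, 0.01), err, numeric(1))
  expect_true(e[3] < e[1])
  expect_true(e[2] <= e[1] * 1.5)  # averaged over few replicates; allow slack
})
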