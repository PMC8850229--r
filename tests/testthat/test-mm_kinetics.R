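test_that("mm_rate follows the rate law and its limits", {
  p <- mm_params(25, 10.5)
  expect_equal(mm_rate(0, p), 0)
  expect_equal(mm_rate(p$km, p), p$vmax / 2)     # definition of Km
  expect_equal(mm_rate(199.5, p), 25 * 199.5 / 210)  # 23.75 = 95% of Vmax
  expect_error(mm_rate(-1, p), "non-negative")

  # strictly increasing in s, bounded above by vmax
  s <- seq(0, 1e4, length.out = 2000)
  v <- mm_rate(s, p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < p$vmax))
})

test_that("conc_at_fraction inverts the rate law exactly", {
  expect_equal(conc_at_fraction(0.95, 1), 19)      # [S] = 19 Km
  expect_equal(conc_at_fraction(0.90, 1), 9)       # [S] = 9 Km
  expect_equal(conc_at_fraction(0.95, 11.8), 224.2)
  expect_equal(conc_at_fraction(0.90, 11.8), 106.2)
  expect_equal(conc_at_fraction(0.5, 7), 7)        # half-max at Km

  # scaled by km only: f*km/(1-f) is homogeneous of degree 1 in km
  for (f in c(0.1, 0.37, 0.9, 0.99))
    expect_equal(conc_at_fraction(f, 23) / 23, conc_at_fraction(f, 1))

  expect_error(conc_at_fraction(0, 1), "between 0 and 1")
  expect_error(conc_at_fraction(1, 1), "between 0 and 1")
  expect_error(conc_at_fraction(0.5, -2), "positive")

  # round trip through the rate law
  p <- mm_params(100, 100)
  expect_equal(mm_rate(conc_at_fraction(0.9, 100), p), 90)
})

test_that("simulate_elimination reproduces the printed interval slopes", {
  grid <- seq(0, 12.5, by = 0.5)
  slopes <- function(vmax, km, frac) {
    sim <- simulate_elimination(conc_at_fraction(frac, km),
                                mm_params(vmax, km), grid)
    interval_slopes(sim, 0.5)$slope
  }
  a <- slopes(25, 10.5, 0.95)
  b <- slopes(25, 10.5, 0.90)
  c_ <- slopes(100, 100, 0.95)
  d <- slopes(100, 100, 0.90)

  # frozen reference values for the four designs (2-decimal slope table)
  expect_equal(a[1], -23.71, tolerance = 0.01 / 23.71)
  expect_equal(a[20], -4.65, tolerance = 0.01 / 4.65)   # interval 9.5-10.0 h
  expect_equal(b[1], -22.36, tolerance = 0.01 / 22.36)
  expect_equal(b[12], -1.84, tolerance = 0.01 / 1.84)   # interval 5.5-6.0 h
  expect_equal(c_[1], -94.94, tolerance = 0.01 / 94.94)
  expect_equal(c_[25], -88.45, tolerance = 0.01 / 88.45) # interval 12.0-12.5 h
  expect_equal(d[1], -89.77, tolerance = 0.01 / 89.77)
  expect_equal(d[24], -28.06, tolerance = 0.01 / 28.06) # interval 11.5-12.0 h

  # |slope| decreases monotonically as the curve is depleted
  for (s in list(a, b, c_, d)) expect_true(all(diff(abs(s)) < 1e-6))

  # saturation: the early slope at c0 = 19 Km is within 5.3% of -vmax
  expect_lt(abs(a[1] + 25) / 25, 0.053)
  expect_lt(abs(c_[1] + 100) / 100, 0.053)
})

test_that("simulation edge cases behave physically", {
  p <- mm_params(25, 10.5)
  z <- simulate_elimination(0, p, seq(0, 5, 0.5))
  expect_true(all(z$conc_mg_dl == 0))

  sim <- simulate_elimination(199.5, p, seq(0, 30, 0.5))
  expect_true(all(sim$conc_mg_dl >= 0))
  pos <- sim$conc_mg_dl > 1e-12
  expect_true(all(diff(sim$conc_mg_dl[pos]) < 0))  # strictly decreasing while C > 0

  expect_error(simulate_elimination(100, p, c(0, 1, 1)), "strictly increasing")
  expect_error(interval_slopes(sim, 0.3), "grid")
  flat <- conc_series(seq(0, 2, 0.5), rep(3, 5))
  expect_true(all(interval_slopes(flat, 0.5)$slope == 0))
})

test_that("closed-form Lambert-W curve matches the ODE solver", {
  expect_equal(analytic_concentration(199.5, mm_params(25, 10.5), 0), 199.5)

  # 20 random parameter sets, whole-series agreement to 1e-6 relative
  set.seed(42)
  for (i in 1:20) {
    vmax <- runif(1, 5, 300)
    km <- runif(1, 1, 150)
    c0 <- runif(1, 0.5, 25) * km
    p <- mm_params(vmax, km)
    times <- seq(0, 1.5 * elimination_span(p, c0), length.out = 40)
    num <- simulate_elimination(c0, p, times)$conc_mg_dl
    ana <- analytic_concentration(c0, p, times)
    expect_equal(ana, num, tolerance = 1e-6)
  }
})

test_that("analytic curve approaches first-order decay when c0 << km", {
  p <- mm_params(25, 10.5)
  c0 <- p$km / 1000
  t <- seq(0, 2, 0.1)
  ana <- analytic_concentration(c0, p, t)
  first_order <- c0 * exp(-p$vmax * t / p$km)
  expect_equal(ana, first_order, tolerance = 1e-3)
})

test_that("log-domain Lambert W agrees with the reference implementation", {
  z <- c(-30, -5, -1, 0, 0.5, 2, 10, 100, 500)  # within pracma's range
  expect_equal(lambert_w0_exp(z), pracma::lambertWp(exp(z)), tolerance = 1e-12)
  # and stays finite/consistent where exp(z) overflows: w + log(w) = z
  zbig <- c(1e3, 1e5, 1e8)
  w <- lambert_w0_exp(zbig)
  expect_equal(w + log(w), zbig, tolerance = 1e-12)
})
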