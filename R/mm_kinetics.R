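#' Michaelis-Menten parameter pair
#'
#' Bundles the system-wide maximum elimination rate `Vmax` and half-saturation
#' concentration `Km` describing saturable (protein-mediated) elimination.
#' Internally `Vmax` is a concentration change per hour (mg/dL/h) so that the
#' elimination ODE dC/dt = -Vmax*C/(Km + C) is dimensionally consistent; a
#' display label (e.g. the "mg/kg-hr" convention seen in toxicokinetic
#' reports) can be carried alongside without affecting any computation.
#'
#' @param vmax maximum elimination rate, mg/dL per hour; must be > 0.
#' @param km concentration at half-maximal rate, mg/dL; must be > 0.
#' @param vmax_label display label for the rate units.
#' @return an object of class `mm_params`.
#' @examples
#' mm_params(175, 11.8)
#' @export
mm_params <- function(vmax, km, vmax_label = "mg/dL/h") {
  if (!is.numeric(vmax) || length(vmax) != 1L || !is.finite(vmax) || vmax <= 0)
    stop("`vmax` must be a single positive number", call. = FALSE)
  if (!is.numeric(km) || length(km) != 1L || !is.finite(km) || km <= 0)
    stop("`km` must be a single positive number", call. = FALSE)
  structure(
    list(vmax = as.numeric(vmax), km = as.numeric(km),
         vmax_label = vmax_label, km_label = "mg/dL"),
    class = "mm_params"
  )
}

#' @export
print.mm_params <- function(x, ...) {
  cat("Michaelis-Menten parameters\n")
  cat(sprintf("  Vmax: %g %s\n  Km:   %g %s\n",
              x$vmax, x$vmax_label, x$km, x$km_label))
  invisible(x)
}

#' Michaelis-Menten rate law
#'
#' Evaluates v = Vmax * S / (Km + S), the rate of a saturable protein-mediated
#' process at substrate concentration `s`. This is the (negated) instantaneous
#' slope of the elimination curve at blood concentration `s`.
#'
#' @param s substrate concentration(s), mg/dL; must be >= 0.
#' @param params an [mm_params] object.
#' @return rate(s) in concentration per hour; always in `[0, vmax)`.
#' @examples
#' mm_rate(199.5, mm_params(25, 10.5))  # 23.75, i.e. 95% of Vmax
#' @export
mm_rate <- function(s, params) {
  stopifnot(inherits(params, "mm_params"))
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0))
    stop("`s` must be finite non-negative concentration(s)", call. = FALSE)
  params$vmax * s / (params$km + s)
}

#' Concentration at a stated fraction of Vmax
#'
#' Inverts the Michaelis-Menten rate law: solving v = f * Vmax for S gives
#' S = f * Km / (1 - f). In particular the 95%-of-Vmax concentration is 19*Km
#' and the 90%-of-Vmax concentration is 9*Km; these anchor the evaluation
#' window used for knee detection.
#'
#' @param fraction fraction of Vmax, strictly between 0 and 1.
#' @param km half-saturation concentration, mg/dL; must be > 0.
#' @return concentration in mg/dL at which the rate is `fraction * vmax`.
#' @examples
#' conc_at_fraction(0.95, 11.8)  # 224.2
#' conc_at_fraction(0.90, 11.8)  # 106.2
#' @export
conc_at_fraction <- function(fraction, km) {
  if (!is.numeric(fraction) || any(!is.finite(fraction)) ||
      any(fraction <= 0) || any(fraction >= 1))
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(km) || any(!is.finite(km)) || any(km <= 0))
    stop("`km` must be positive", call. = FALSE)
  fraction * km / (1 - fraction)
}

#' Elimination time-concentration series
#'
#' Light container for an elimination curve: strictly increasing times (hours,
#' first >= 0) and non-negative concentrations (mg/dL) of equal length.
#'
#' @param times numeric vector of hours.
#' @param concentrations numeric vector of mg/dL.
#' @return a `conc_series` object (a data frame with columns `time_h` and
#'   `conc_mg_dl`).
#' @export
conc_series <- function(times, concentrations) {
  if (!is.numeric(times) || length(times) == 0L || any(!is.finite(times)))
    stop("`times` must be non-empty finite numerics", call. = FALSE)
  if (times[1] < 0 || (length(times) > 1 && any(diff(times) <= 0)))
    stop("`times` must be strictly increasing with first element >= 0",
         call. = FALSE)
  if (!is.numeric(concentrations) || length(concentrations) != length(times))
    stop("`concentrations` must match `times` in length", call. = FALSE)
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("`concentrations` must be finite and non-negative", call. = FALSE)
  structure(
    data.frame(time_h = as.numeric(times),
               conc_mg_dl = as.numeric(concentrations)),
    class = c("conc_series", "data.frame")
  )
}

#' Simulate saturable elimination numerically
#'
#' Integrates dC/dt = -Vmax*C/(Km + C) from C(0) = `c0` with a stiff-capable
#' adaptive solver (deSolve `lsoda`, rtol = atol = 1e-9) and returns the
#' solution at the requested times. Concentrations are clamped at zero: the
#' exact solution can never cross zero, but the integrator's tolerance can
#' produce harmless negative round-off in the deeply depleted tail.
#'
#' @param c0 initial concentration, mg/dL; must be >= 0.
#' @param params an [mm_params] object.
#' @param times hours at which to evaluate; strictly increasing, first >= 0.
#' @param rtol,atol solver tolerances.
#' @return a [conc_series].
#' @examples
#' p <- mm_params(25, 10.5)
#' sim <- simulate_elimination(19 * 10.5, p, seq(0, 12.5, 0.5))
#' head(sim)
#' @export
simulate_elimination <- function(c0, params, times, rtol = 1e-9, atol = 1e-9) {
  stopifnot(inherits(params, "mm_params"))
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 < 0)
    stop("`c0` must be a single non-negative number", call. = FALSE)
  if (times[1] < 0 || (length(times) > 1 && any(diff(times) <= 0)))
    stop("`times` must be strictly increasing with first element >= 0",
         call. = FALSE)
  if (c0 == 0)
    return(conc_series(times, rep(0, length(times))))

  rhs <- function(t, y, parms) {
    list(-parms$vmax * y / (parms$km + y))
  }
  t_solve <- if (times[1] > 0) c(0, times) else times
  sol <- try(deSolve::ode(y = c(C = c0), times = t_solve, func = rhs,
                          parms = params, method = "lsoda",
                          rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) != length(t_solve) ||
      any(!is.finite(sol[, "C"])))
    stop("ODE solver failed for vmax=", params$vmax, ", km=", params$km,
         ", c0=", c0, ": ",
         if (inherits(sol, "try-error")) attr(sol, "condition")$message
         else "incomplete or non-finite solution",
         call. = FALSE)
  conc <- pmax(sol[, "C"], 0)
  if (times[1] > 0) conc <- conc[-1]
  conc_series(times, conc)
}

#' Closed-form elimination curve via Lambert W
#'
#' The integrated Michaelis-Menten elimination equation
#' Km*log(C/C0) + (C - C0) = -Vmax*t has the explicit solution
#' C(t) = Km * W0((C0/Km) * exp((C0 - Vmax*t)/Km)), with W0 the principal
#' Lambert W branch. Evaluated in the log domain (see [lambert_w0_exp]), this
#' is exact and fast, and serves both as the oracle for the numeric solver and
#' as the mean function inside the likelihood of [fit_mm_bayes].
#'
#' @param c0 initial concentration, mg/dL; >= 0.
#' @param params an [mm_params] object.
#' @param t time(s) in hours; >= 0.
#' @return concentration(s) at `t`, mg/dL.
#' @examples
#' analytic_concentration(199.5, mm_params(25, 10.5), 0.5)
#' @export
analytic_concentration <- function(c0, params, t) {
  stopifnot(inherits(params, "mm_params"))
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 < 0)
    stop("`c0` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("`t` must be non-negative time(s)", call. = FALSE)
  if (c0 == 0) return(rep(0, length(t)))
  z <- log(c0 / params$km) + (c0 - params$vmax * t) / params$km
  out <- params$km * lambert_w0_exp(z)
  if (any(under <- (z < log(.Machine$double.xmin) - log(params$km)))) {
    warning("Lambert-W argument underflow at late times; concentration set to 0")
    out[under] <- 0
  }
  out
}

#' Mean slopes of an elimination curve over fixed intervals
#'
#' Computes (C(t+dt) - C(t)) / dt for consecutive grid intervals of width
#' `dt`, i.e. the mean elimination slope per interval. On a saturated curve
#' the early slopes sit near -Vmax (near zero-order elimination); as the
#' concentration falls toward Km and below, the slopes decay toward zero
#' (first-order limit).
#'
#' @param series a [conc_series] sampled on a grid commensurate with `dt`.
#' @param dt interval width in hours; must match the sampling grid.
#' @return a data frame with columns `t_start`, `t_end`, `slope`.
#' @examples
#' p <- mm_params(25, 10.5)
#' sim <- simulate_elimination(19 * 10.5, p, seq(0, 12.5, 0.5))
#' head(interval_slopes(sim, 0.5))
#' @export
interval_slopes <- function(series, dt) {
  stopifnot(inherits(series, "conc_series"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  steps <- diff(series$time_h)
  if (any(abs(steps - dt) > 1e-8 * max(1, dt)))
    stop("series is not sampled on a grid of spacing `dt`", call. = FALSE)
  n <- nrow(series)
  data.frame(
    t_start = series$time_h[-n],
    t_end = series$time_h[-1],
    slope = diff(series$conc_mg_dl) / dt
  )
}
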