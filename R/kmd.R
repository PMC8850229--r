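#' Assemble the KMD region from a fitted posterior
#'
#' The kinetically derived maximum dose (KMD) is reported as a bounded
#' concentration region rather than a point. The recipe:
#'
#' * the window anchors are the concentrations at which the rate reaches the
#'   two stated fractions of Vmax: `smax_low = conc_at_fraction(0.90, smax_km)`
#'   and `smax_high = conc_at_fraction(0.95, smax_km)`;
#' * the lower bound is the knee of the MM curve built from the posterior
#'   2.5% quantile of Km over `[0, smax_low]`;
#' * the upper bound is the knee from the 97.5% quantile of Km over
#'   `[0, smax_high]`;
#' * the midpoint takes the posterior mean Km with the mean of the two
#'   anchors as the window edge.
#'
#' The Vmax bounds are carried for provenance but cannot move the knee: the
#' kneedle normalization cancels Vmax exactly.
#'
#' @param posterior an `mm_posterior` from [fit_mm_bayes]; must be converged
#'   (override with `force = TRUE` at your own risk).
#' @param fractions the two Vmax fractions, strictly increasing in (0,1);
#'   default `c(0.90, 0.95)`.
#' @param smax_km the Km used to place the window anchors. Default: the
#'   posterior mean of Km (the truth is unknown on real data). Supplying a
#'   known/true Km reproduces anchor values computed from it.
#' @param n_grid grid size for the discrete kneedle.
#' @param method knee method, as in [mm_knee].
#' @return a `kmd_region`: raw and integer-rounded `lower`, `midpoint`,
#'   `upper` (mg/dL), the anchors, and per-bound provenance.
#' @examples
#' # bypassing the fit with known posterior quantities:
#' r <- kmd_region_from_km(km_lower = 11, km_mean = 11.97, km_upper = 13,
#'                         smax_km = 11.8)
#' r
#' @export
compute_kmd_region <- function(posterior, fractions = c(0.90, 0.95),
                               smax_km = NULL, n_grid = 10001,
                               method = c("discrete-kneedle", "closed-form"),
                               force = FALSE) {
  stopifnot(inherits(posterior, "mm_posterior"))
  if (!posterior$converged && !force)
    stop("posterior has not converged (rhat > 1.01); refusing to compute a ",
         "KMD region. Re-run sampling or pass force = TRUE.", call. = FALSE)
  if (is.null(smax_km)) smax_km <- posterior_stat(posterior, "km", "mean")
  region <- kmd_region_from_km(
    km_lower = posterior_stat(posterior, "km", "ci_lower"),
    km_mean = posterior_stat(posterior, "km", "mean"),
    km_upper = posterior_stat(posterior, "km", "ci_upper"),
    smax_km = smax_km, fractions = fractions, n_grid = n_grid,
    method = method,
    vmax_bounds = c(posterior_stat(posterior, "vmax", "ci_lower"),
                    posterior_stat(posterior, "vmax", "ci_upper")))
  region$posterior_settings <- posterior$settings
  region
}

#' @rdname compute_kmd_region
#' @param km_lower,km_mean,km_upper posterior summary of Km (mg/dL).
#' @param vmax_bounds optional Vmax credible bounds, provenance only.
#' @param force compute even from a non-converged posterior.
#' @export
kmd_region_from_km <- function(km_lower, km_mean, km_upper, smax_km,
                               fractions = c(0.90, 0.95), n_grid = 10001,
                               method = c("discrete-kneedle", "closed-form"),
                               vmax_bounds = NULL) {
  method <- match.arg(method)
  ks <- c(km_lower, km_mean, km_upper, smax_km)
  if (!is.numeric(ks) || any(!is.finite(ks)) || any(ks <= 0))
    stop("all Km inputs must be positive numbers", call. = FALSE)
  if (!(km_lower <= km_mean && km_mean <= km_upper))
    stop("need km_lower <= km_mean <= km_upper", call. = FALSE)
  if (length(fractions) != 2 || any(fractions <= 0) || any(fractions >= 1) ||
      fractions[1] >= fractions[2])
    stop("`fractions` must be two increasing values in (0, 1)", call. = FALSE)

  smax_low <- conc_at_fraction(fractions[1], smax_km)
  smax_high <- conc_at_fraction(fractions[2], smax_km)
  smax_mid <- mean(c(smax_low, smax_high))

  k_lo <- mm_knee(km_lower, smax_low, n_grid = n_grid, method = method,
                  fraction = fractions[1])
  k_mid <- mm_knee(km_mean, smax_mid, n_grid = n_grid, method = method)
  k_hi <- mm_knee(km_upper, smax_high, n_grid = n_grid, method = method,
                  fraction = fractions[2])

  raw <- c(lower = k_lo$knee_x, midpoint = k_mid$knee_x, upper = k_hi$knee_x)
  if (!(raw[1] < raw[2] && raw[2] < raw[3]))
    stop("knee bounds are not ordered; inputs are degenerate", call. = FALSE)

  structure(
    list(lower = unname(round(raw[1])),
         midpoint = unname(round(raw[2])),
         upper = unname(round(raw[3])),
         raw = as.list(raw),
         units = "mg/dL",
         fractions = fractions,
         anchors = list(smax_low = smax_low, smax_high = smax_high,
                        smax_mid = smax_mid, smax_km = smax_km),
         provenance = list(
           lower = list(km = km_lower, smax = smax_low),
           midpoint = list(km = km_mean, smax = smax_mid),
           upper = list(km = km_upper, smax = smax_high),
           vmax_bounds = vmax_bounds,
           method = method, n_grid = n_grid)),
    class = "kmd_region"
  )
}

#' @export
print.kmd_region <- function(x, ...) {
  cat("KMD region (", x$units, ")\n", sep = "")
  cat(sprintf("  lower    %3d  (raw %.2f; Km %.4g, window [0, %.4g])\n",
              x$lower, x$raw$lower, x$provenance$lower$km,
              x$provenance$lower$smax))
  cat(sprintf("  midpoint %3d  (raw %.2f; Km %.4g, window [0, %.4g])\n",
              x$midpoint, x$raw$midpoint, x$provenance$midpoint$km,
              x$provenance$midpoint$smax))
  cat(sprintf("  upper    %3d  (raw %.2f; Km %.4g, window [0, %.4g])\n",
              x$upper, x$raw$upper, x$provenance$upper$km,
              x$provenance$upper$smax))
  invisible(x)
}

#' KMD report with provenance
#'
#' Serializes a KMD region (and, when available, the posterior summary and
#' sampler settings behind it) to a schema-stable list and optionally a JSON
#' file. Both rounded and raw (unrounded) bounds are reported: rounding to
#' whole mg/dL is a presentation convention, and a raw knee near x.5 can
#' legitimately be printed as either neighbour.
#'
#' @param region a `kmd_region`.
#' @param posterior optional `mm_posterior` for provenance.
#' @param file optional path; when given, JSON is written there.
#' @return the report list, invisibly when `file` is given.
#' @export
kmd_report <- function(region, posterior = NULL, file = NULL) {
  stopifnot(inherits(region, "kmd_region"))
  report <- list(
    kmd = list(lower = region$lower, midpoint = region$midpoint,
               upper = region$upper, units = region$units),
    raw = region$raw,
    anchors = region$anchors,
    fractions = region$fractions,
    provenance = region$provenance
  )
  if (!is.null(posterior)) {
    stopifnot(inherits(posterior, "mm_posterior"))
    s <- posterior$summary
    report$posterior <- lapply(seq_len(nrow(s)), function(i) {
      list(mean = s$mean[i], ci95 = c(s$ci_lower[i], s$ci_upper[i]),
           rhat = s$rhat[i], ess = s$ess[i])
    })
    names(report$posterior) <- s$parameter
    report$settings <- posterior$settings
    report$converged <- posterior$converged
  }
  if (!is.null(file)) {
    jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(report))
  }
  report
}

#' Rebuild a KMD region from a serialized report
#'
#' @param source a report list from [kmd_report] or a path to its JSON file.
#' @return a `kmd_region` equal (up to numeric round-trip) to the original.
#' @export
parse_kmd_report <- function(source) {
  report <- if (is.character(source))
    jsonlite::read_json(source, simplifyVector = TRUE)
  else source
  kmd_region_from_km(
    km_lower = report$provenance$lower$km,
    km_mean = report$provenance$midpoint$km,
    km_upper = report$provenance$upper$km,
    smax_km = report$anchors$smax_km,
    fractions = as.numeric(report$fractions),
    n_grid = report$provenance$n_grid,
    method = report$provenance$method,
    vmax_bounds = report$provenance$vmax_bounds)
}
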