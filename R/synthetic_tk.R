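#' Observation-noise model for synthetic toxicokinetic data
#'
#' @param kind one of `"none"`, `"additive-gaussian"` (constant sd in mg/dL)
#'   or `"proportional-gaussian"` (sd = CV * true concentration).
#' @param scale sd in mg/dL (additive) or coefficient of variation
#'   (proportional); ignored for `kind = "none"`. Must be >= 0.
#' @return a `noise_model` object.
#' @examples
#' noise_model("proportional-gaussian", 0.05)
#' @export
noise_model <- function(kind = c("none", "additive-gaussian",
                                 "proportional-gaussian"),
                        scale = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale < 0)
    stop("`scale` must be a single non-negative number", call. = FALSE)
  structure(list(kind = kind, scale = as.numeric(scale)),
            class = "noise_model")
}

apply_noise <- function(conc, noise) {
  noisy <- switch(
    noise$kind,
    "none" = conc,
    "additive-gaussian" = conc + stats::rnorm(length(conc), 0, noise$scale),
    "proportional-gaussian" = conc +
      stats::rnorm(length(conc), 0, noise$scale * conc)
  )
  pmax(noisy, 0)  # physical non-negativity; truncation, not redraw
}

#' Generate a synthetic toxicokinetic dataset
#'
#' Simulates single-compartment saturable elimination from known ground-truth
#' Michaelis-Menten parameters (via the exact Lambert-W curve), adds
#' observation noise, and records the truth and seed so that downstream
#' parameter-recovery analyses can be scored. Negative noisy draws are
#' truncated at zero (rare at the default noise level).
#'
#' @param params an [mm_params] object — the ground truth.
#' @param c0 initial concentration, mg/dL; > 0.
#' @param times sampling schedule in hours; strictly increasing, first >= 0.
#' @param noise a [noise_model].
#' @param seed integer seed; identical seeds give identical datasets. `NULL`
#'   (allowed only for noiseless data) leaves the RNG untouched.
#' @return a `tk_dataset`: list with `series` ([conc_series]), `truth`
#'   (params and c0), `units`, `noise` and `seed`.
#' @examples
#' d <- generate_tk_dataset(mm_params(175, 11.8), 224.2, seq(0, 12, 0.25),
#'                          noise_model("proportional-gaussian", 0.05),
#'                          seed = 1)
#' head(d$series)
#' @export
generate_tk_dataset <- function(params, c0, times,
                                noise = noise_model("none"), seed = NULL) {
  stopifnot(inherits(params, "mm_params"), inherits(noise, "noise_model"))
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 <= 0)
    stop("`c0` must be a single positive number", call. = FALSE)
  if (length(times) == 0L)
    stop("`times` must be non-empty", call. = FALSE)
  if (!is.null(seed)) {
    if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed) ||
        seed != round(seed))
      stop("`seed` must be a single integer", call. = FALSE)
    seed <- as.integer(seed)
  } else if (noise$kind != "none") {
    stop("`seed` is required when noise is not \"none\"", call. = FALSE)
  }

  clean <- analytic_concentration(c0, params, times)
  conc <- if (noise$kind == "none") {
    clean
  } else {
    with_seed(seed, apply_noise(clean, noise))
  }
  structure(
    list(series = conc_series(times, conc),
         truth = list(vmax = params$vmax, km = params$km, c0 = c0),
         units = list(time = "h", conc = "mg/dL"),
         noise = noise,
         seed = seed),
    class = "tk_dataset"
  )
}

# Evaluate `expr` under a temporary RNG state; the caller's state is restored.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Duration of the elimination phase
#'
#' Closed-form time at which the noiseless elimination curve falls to a
#' stated fraction of its starting concentration. Inverting the integrated
#' rate equation Km*log(C/C0) + (C - C0) = -Vmax*t at C = fraction * C0:
#'
#'   t = (C0 * (1 - fraction) + Km * log(1/fraction)) / Vmax.
#'
#' Used to place sampling schedules across the phase where concentration (and
#' hence information about the kinetics) is actually present.
#'
#' @param params an [mm_params] object.
#' @param c0 initial concentration, mg/dL.
#' @param fraction remaining fraction of `c0` defining "eliminated";
#'   default 0.01 (99% eliminated).
#' @return time in hours.
#' @examples
#' elimination_span(mm_params(175, 11.8), 224.2)  # ~1.6 h
#' elimination_span(mm_params(25, 10.5), 199.5)   # ~9.8 h
#' @export
elimination_span <- function(params, c0, fraction = 0.01) {
  stopifnot(inherits(params, "mm_params"))
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0)
    stop("`c0` must be a single positive number", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  (c0 * (1 - fraction) + params$km * log(1 / fraction)) / params$vmax
}

#' The packaged worked-example dataset
#'
#' Alcohol-like elimination kinetics: Vmax = 175 mg/dL/h, Km = 11.8 mg/dL,
#' starting at the 95%-of-Vmax concentration (19 * Km = 224.2 mg/dL), with
#' 49 evenly spaced samples spanning the elimination phase (0 to the
#' 99%-eliminated time, about 1.6 h here; see [elimination_span]) and 5%
#' proportional Gaussian noise. These are the package's reference study
#' conditions for parameter-recovery work. Sampling is restricted to the
#' elimination phase because observations taken after the chemical is gone
#' carry no kinetic information.
#'
#' @param seed integer seed for the noise draws.
#' @param noise a [noise_model]; default 5% proportional Gaussian.
#' @param n_times number of samples.
#' @return a `tk_dataset`.
#' @examples
#' d <- default_example_dataset(seed = 1)
#' d$truth
#' @export
default_example_dataset <- function(seed,
                                    noise = noise_model(
                                      "proportional-gaussian", 0.05),
                                    n_times = 49) {
  params <- mm_params(175, 11.8)
  c0 <- conc_at_fraction(0.95, params$km)
  times <- seq(0, elimination_span(params, c0), length.out = n_times)
  generate_tk_dataset(params, c0, times, noise = noise, seed = seed)
}

#' @export
print.tk_dataset <- function(x, ...) {
  cat(sprintf("Toxicokinetic dataset: %d observations, %g-%g h\n",
              nrow(x$series), min(x$series$time_h), max(x$series$time_h)))
  cat(sprintf("  noise: %s (scale %g)\n", x$noise$kind, x$noise$scale))
  if (!is.null(x$truth))
    cat(sprintf("  truth: Vmax = %g, Km = %g, c0 = %g\n",
                x$truth$vmax, x$truth$km, x$truth$c0))
  invisible(x)
}

#' Write / read a toxicokinetic dataset as CSV
#'
#' The CSV has the fixed header `time_h,conc_mg_dl`. For synthetic datasets a
#' JSON sidecar (`<path>.json`) records the ground truth, noise model and
#' seed, so the CSV alone looks exactly like field data.
#'
#' @param dataset a `tk_dataset`.
#' @param path output CSV path.
#' @param sidecar write the truth/seed sidecar JSON? Default `TRUE` when truth
#'   is present.
#' @return `path`, invisibly.
#' @export
write_tk_csv <- function(dataset, path, sidecar = !is.null(dataset$truth)) {
  stopifnot(inherits(dataset, "tk_dataset"))
  utils::write.csv(as.data.frame(dataset$series)[, c("time_h", "conc_mg_dl")],
                   path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(truth = dataset$truth,
                 noise = list(kind = dataset$noise$kind,
                              scale = dataset$noise$scale),
                 seed = dataset$seed,
                 units = dataset$units)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_tk_csv
#' @export
read_tk_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "conc_mg_dl") %in% names(df)))
    stop("CSV must have header `time_h,conc_mg_dl`", call. = FALSE)
  truth <- NULL; noise <- noise_model("none"); seed <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    truth <- meta$truth
    if (!is.null(meta$noise))
      noise <- noise_model(meta$noise$kind, meta$noise$scale)
    seed <- meta$seed
  }
  structure(
    list(series = conc_series(df$time_h, df$conc_mg_dl),
         truth = truth,
         units = list(time = "h", conc = "mg/dL"),
         noise = noise,
         seed = seed),
    class = "tk_dataset"
  )
}
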