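#' Kneedle knee detection on a discrete curve
#'
#' Finds the "knee" — the point of diminishing returns — of a concave
#' increasing curve. Both axes are min-max normalized to the unit square, the
#' difference curve d = y_norm - x_norm is formed, and the knee is the
#' (thresholded) local maximum of d: the sensitivity parameter `S` sets the
#' threshold T = d_max - S * mean(diff(x_norm)) that d must subsequently fall
#' below for the maximum to count as a knee. For a smooth noiseless concave
#' curve this reduces to the global argmax of the difference curve.
#'
#' Note the knee is not scale-invariant: extending the x window moves it.
#' Callers must state the evaluation window deliberately (here: the
#' concentrations reaching 90% or 95% of Vmax).
#'
#' @param x strictly increasing abscissae (at least 4 points).
#' @param y ordinates, same length as `x`.
#' @param sensitivity the kneedle S parameter (default 1).
#' @return the x-value of the knee.
#' @examples
#' x <- seq(0, 1, length.out = 1001)
#' kneedle(x, sqrt(x))  # 0.25
#' @export
kneedle <- function(x, y, sensitivity = 1) {
  if (length(x) < 4) stop("need at least 4 points", call. = FALSE)
  if (length(y) != length(x)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing", call. = FALSE)
  ry <- max(y) - min(y)
  if (ry <= .Machine$double.eps * max(abs(y), 1))
    stop("flat curve: no knee exists", call. = FALSE)
  xn <- (x - min(x)) / (max(x) - min(x))
  yn <- (y - min(y)) / ry
  d <- yn - xn
  if (max(d) - min(d) < 1e-10)
    stop("degenerate difference curve (straight line): no knee exists",
         call. = FALSE)

  n <- length(d)
  # interior local maxima of the difference curve
  lmx <- which(d[2:(n - 1)] >= d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  if (length(lmx) == 0) stop("no local maximum in difference curve: no knee",
                             call. = FALSE)
  thr_drop <- sensitivity * mean(diff(xn))
  for (i in lmx) {
    thr <- d[i] - thr_drop
    j <- if (i < n) which(d[(i + 1):n] < thr) else integer(0)
    if (length(j) > 0) {
      nxt <- lmx[lmx > i]
      if (length(nxt) == 0 || i + j[1] <= nxt[1]) return(x[i])
    }
  }
  stop("no knee detected at sensitivity ", sensitivity, call. = FALSE)
}

#' Closed-form knee of a Michaelis-Menten curve
#'
#' Continuous limit of the kneedle construction applied to
#' v = Vmax*S/(Km + S) on the window `[0, smax]`: the normalized difference
#' curve is g(S) = (S/(Km+S)) / (smax/(Km+smax)) - S/smax, and setting
#' g'(S) = 0 gives
#'
#'   knee = sqrt(Km * (Km + smax)) - Km.
#'
#' Vmax cancels under the y-normalization, so the knee depends only on Km and
#' on the window edge. (Verified against brute-force dense-grid maximization
#' of the normalized difference curve in the test suite.)
#'
#' @param km half-saturation concentration, mg/dL; > 0.
#' @param smax right edge of the evaluation window, mg/dL; > 0.
#' @return the knee concentration in mg/dL.
#' @examples
#' closed_form_mm_knee(11, 106.2)    # 24.9 -> the worked example's 25
#' closed_form_mm_knee(11.97, 165.2) # 34.1 -> its midpoint 34
#' @export
closed_form_mm_knee <- function(km, smax) {
  if (!is.numeric(km) || any(!is.finite(km)) || any(km <= 0))
    stop("`km` must be positive", call. = FALSE)
  if (!is.numeric(smax) || any(!is.finite(smax)) || any(smax <= 0))
    stop("`smax` must be positive", call. = FALSE)
  sqrt(km * (km + smax)) - km
}

#' Knee of a Michaelis-Menten curve over a stated window
#'
#' Evaluates the MM rate curve on a uniform grid over `[0, smax]` and locates
#' its knee, either by the discrete kneedle algorithm (default; the grid is
#' dense enough that the resolution is smax/(n_grid - 1)) or by the exact
#' closed form. `vmax` is accepted for interface fidelity with rate curves
#' but has no effect on the knee location: it cancels in the normalization.
#'
#' @param km half-saturation concentration, mg/dL.
#' @param smax right edge of the window, mg/dL.
#' @param vmax maximum rate (only sets the reported knee rate `knee_y`).
#' @param n_grid number of grid points for the discrete method.
#' @param method `"discrete-kneedle"` or `"closed-form"`.
#' @param fraction optional Vmax fraction that defined `smax` (metadata).
#' @return a `knee_result` with `knee_x`, `knee_y`, `smax`, `fraction`,
#'   `method`.
#' @examples
#' mm_knee(11, 106.2)
#' @export
mm_knee <- function(km, smax, vmax = 1, n_grid = 10001,
                    method = c("discrete-kneedle", "closed-form"),
                    fraction = NA_real_) {
  method <- match.arg(method)
  if (!is.numeric(km) || length(km) != 1L || km <= 0)
    stop("`km` must be a single positive number", call. = FALSE)
  if (!is.numeric(smax) || length(smax) != 1L || smax <= 0)
    stop("`smax` must be a single positive number", call. = FALSE)
  knee_x <- if (method == "closed-form") {
    closed_form_mm_knee(km, smax)
  } else {
    s <- seq(0, smax, length.out = n_grid)
    kneedle(s, vmax * s / (km + s))
  }
  structure(
    list(knee_x = knee_x,
         knee_y = vmax * knee_x / (km + knee_x),
         smax = smax, fraction = fraction, method = method,
         km = km, vmax = vmax, n_grid = if (method == "closed-form") NA_integer_ else n_grid),
    class = "knee_result"
  )
}

#' @export
print.knee_result <- function(x, ...) {
  cat(sprintf("MM curve knee: %.4g mg/dL (window [0, %.4g], Km = %.4g, %s)\n",
              x$knee_x, x$smax, x$km, x$method))
  invisible(x)
}
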