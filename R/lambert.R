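#' Principal Lambert W of an exponentiated argument
#'
#' Computes `W0(exp(z))`, the principal branch of the Lambert W function
#' evaluated at `exp(z)`, working in the log domain so that very large `z`
#' (where `exp(z)` overflows a double) remains well defined. This is the
#' quantity needed by the integrated Michaelis-Menten elimination curve,
#' where the natural argument `(C0/Km) * exp((C0 - Vmax*t)/Km)` overflows
#' whenever the initial concentration is many multiples of Km.
#'
#' For `w = W0(exp(z))`, `w` solves `w + log(w) = z`. The solver uses a
#' Newton iteration on that equation with an asymptotic starting value;
#' convergence is quadratic and a handful of iterations reach machine
#' precision for any representable `z`.
#'
#' @param z numeric vector; the log of the Lambert W argument.
#' @return numeric vector, `W0(exp(z))`, the same length as `z`.
#' @examples
#' lambert_w0_exp(log(1))            # W0(1) = 0.5671433
#' lambert_w0_exp(1000)              # fine even though exp(1000) overflows
#' @export
lambert_w0_exp <- function(z) {
  stopifnot(is.numeric(z))
  w <- numeric(length(z))
  w[is.na(z)] <- NA_real_
  ok <- !is.na(z)

  # For very negative z, W0(e^z) ~ e^z (1 - e^z + ...); e^z itself is already
  # below machine epsilon relative accuracy of the Newton target, so return it.
  tiny <- ok & (z < -36)
  w[tiny] <- exp(z[tiny])

  act <- ok & !tiny
  if (any(act)) {
    zz <- z[act]
    # starting value: w ~ z - log(z) for large z, else exp(z)/(1 + exp(z)) scale
    w0 <- exp(pmin(zz, 1)) / (1 + exp(pmin(zz, 1)))
    big <- zz > 1
    w0[big] <- zz[big] - log(zz[big])
    w0 <- pmax(w0, 1e-300)
    for (i in 1:50) {
      # Newton on f(w) = w + log(w) - z ; f'(w) = 1 + 1/w
      step <- (w0 + log(w0) - zz) * w0 / (w0 + 1)
      # damp steps that would drive w non-positive
      step <- pmax(step, w0 - 10 * w0)
      w1 <- w0 - step
      w1 <- pmax(w1, w0 * 1e-3)
      if (all(abs(w1 - w0) <= 1e-15 * pmax(w1, 1e-300))) {
        w0 <- w1
        break
      }
      w0 <- w1
    }
    w[act] <- w0
  }
  w
}
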