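#' Prior specification for Michaelis-Menten fitting
#'
#' Truncated-normal priors (support restricted to positive values) on Vmax
#' and Km, and a half-Cauchy prior on the observation noise sd. The defaults
#' are weakly-informative priors for the packaged alcohol-like example;
#' [prior_spec()] accepts any hyperparameters, including tighter
#' literature-derived ones.
#'
#' @param vmax_mean,vmax_sd prior location and scale for Vmax (mg/dL/h).
#' @param km_mean,km_sd prior location and scale for Km (mg/dL).
#' @param sigma_scale half-Cauchy scale for the noise sd (mg/dL).
#' @return a `prior_spec` object.
#' @examples
#' prior_spec(25, 2, 11, 2)        # a tight literature-style prior block
#' default_alcohol_priors()        # the packaged example's priors
#' @export
prior_spec <- function(vmax_mean, vmax_sd, km_mean, km_sd, sigma_scale = 1) {
  vals <- c(vmax_mean = vmax_mean, vmax_sd = vmax_sd,
            km_mean = km_mean, km_sd = km_sd, sigma_scale = sigma_scale)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("all prior hyperparameters must be finite numbers", call. = FALSE)
  if (vmax_sd <= 0 || km_sd <= 0 || sigma_scale <= 0)
    stop("prior scales must be positive", call. = FALSE)
  structure(as.list(vals), class = "prior_spec")
}

#' @rdname prior_spec
#' @export
default_alcohol_priors <- function() prior_spec(175, 20, 11.8, 3, 1)

# log density of Normal(mean, sd) truncated to (0, Inf)
ltnorm <- function(x, mean, sd) {
  ifelse(x <= 0, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           stats::pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

# log density of half-Cauchy(scale) on (0, Inf)
lhalfcauchy <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2) + stats::dcauchy(x, 0, scale, log = TRUE))
}

# Build the log-posterior closure for sampling/optimization on the log scale.
# theta = log(vmax, km, sigma[, c0]); the Jacobian sum(theta) makes the
# density proper with respect to theta.
make_log_post <- function(data, priors, c0_mode, likelihood = TRUE) {
  t_obs <- data$series$time_h - data$series$time_h[1]
  y_obs <- data$series$conc_mg_dl
  c0_fixed <- y_obs[1]
  estimate_c0 <- c0_mode == "estimate"

  function(theta) {
    vmax <- exp(theta[1]); km <- exp(theta[2]); sigma <- exp(theta[3])
    c0 <- if (estimate_c0) exp(theta[4]) else c0_fixed
    if (!all(is.finite(c(vmax, km, sigma, c0)))) return(-Inf)
    lp <- ltnorm(vmax, priors$vmax_mean, priors$vmax_sd) +
      ltnorm(km, priors$km_mean, priors$km_sd) +
      lhalfcauchy(sigma, priors$sigma_scale) +
      sum(theta)
    if (estimate_c0)
      lp <- lp + ltnorm(c0, c0_fixed, 0.2 * c0_fixed + 1e-8)
    if (likelihood) {
      mu <- analytic_concentration(c0, mm_params(vmax, km), t_obs)
      lp <- lp + sum(stats::dnorm(y_obs, mu, sigma, log = TRUE))
    }
    if (!is.finite(lp)) -Inf else lp
  }
}

# One adaptive random-walk Metropolis chain. The proposal starts from a
# supplied shape (typically a Laplace approximation at the posterior mode),
# its global scale is tuned to ~30% acceptance through warmup, and the shape
# is re-estimated from the chain's own history in the second half of warmup
# (Haario-style); the kernel is frozen for the retained draws.
run_chain <- function(log_post, theta0, warmup, draws,
                      chol0 = NULL, scale0 = NULL) {
  d <- length(theta0)
  theta <- theta0
  lp <- log_post(theta)
  if (!is.finite(lp)) stop("initial value has zero posterior density")
  total <- warmup + draws
  out <- matrix(NA_real_, draws, d)
  scale <- if (is.null(scale0)) 0.1 else scale0
  chol_prop <- if (is.null(chol0)) diag(d) else chol0
  cov_mode <- !is.null(chol0)
  warm_store <- matrix(NA_real_, warmup, d)
  accepts <- 0L; block_acc <- 0L

  for (i in seq_len(total)) {
    prop <- theta + scale * as.numeric(chol_prop %*% stats::rnorm(d))
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      theta <- prop; lp <- lp_prop
      accepts <- accepts + 1L; block_acc <- block_acc + 1L
    }
    if (i <= warmup) {
      warm_store[i, ] <- theta
      if (i %% 50 == 0) {
        # keep acceptance near the RWM optimum (~0.3) throughout warmup
        scale <- scale * exp(block_acc / 50 - 0.3)
        block_acc <- 0L
        if (i >= warmup / 2) {
          # Haario phase: proposal shape from the recent warmup history
          cv <- stats::cov(warm_store[max(1, i - 500):i, , drop = FALSE])
          ch <- try(chol(cv + 1e-10 * diag(d)), silent = TRUE)
          if (!inherits(ch, "try-error")) {
            chol_prop <- t(ch)
            if (!cov_mode) {        # re-base the multiplier once on switch
              scale <- 2.38 / sqrt(d)
              cov_mode <- TRUE
            }
          }
        }
      }
    } else {
      out[i - warmup, ] <- theta
    }
  }
  list(draws = out, accept_rate = accepts / total)
}

#' Bayesian estimation of system-wide Vmax and Km
#'
#' Fits the saturable-elimination model to a toxicokinetic dataset. The
#' likelihood is Normal on the observed concentrations, with mean given by
#' the solution of dC/dt = -Vmax*C/(Km + C) at the observation times
#' (evaluated with the exact Lambert-W closed form, so no solver noise enters
#' the posterior). Priors are truncated normals on Vmax and Km and a
#' half-Cauchy on sigma. Sampling is adaptive random-walk Metropolis on the
#' log scale, multiple chains; convergence is declared only when every
#' split-chain PSRF (rhat) is <= 1.01.
#'
#' @param data a `tk_dataset` (see [generate_tk_dataset], [read_tk_csv]);
#'   at least 5 observations.
#' @param priors a [prior_spec]; defaults to [default_alcohol_priors()].
#' @param chains number of MCMC chains.
#' @param warmup,draws warmup and retained iterations per chain.
#' @param seed integer seed controlling initialisation and sampling.
#' @param c0_mode `"estimate"` (default) treats the initial concentration as
#'   a fourth parameter with a weak prior centred on the first observation;
#'   `"fixed"` anchors C(0) exactly at the first observed concentration.
#'   Fixing is only appropriate when the starting concentration is known
#'   without error: anchoring the curve at a noisy observation propagates
#'   that single measurement's error into Vmax with no accounting.
#' @param likelihood set `FALSE` to sample the prior only (sanity checks).
#' @return an `mm_posterior`: draws (with chain index), a summary table
#'   (mean, 2.5% and 97.5% quantiles, rhat, effective sample size per
#'   parameter), a `converged` flag and the settings used.
#' @examples
#' \donttest{
#' d <- default_example_dataset(seed = 1)
#' fit <- fit_mm_bayes(d, chains = 2, warmup = 400, draws = 400, seed = 1)
#' fit$summary
#' }
#' @export
fit_mm_bayes <- function(data, priors = default_alcohol_priors(),
                         chains = 4, warmup = 1500, draws = 2500,
                         seed = 2022, c0_mode = c("estimate", "fixed"),
                         likelihood = TRUE) {
  stopifnot(inherits(data, "tk_dataset"), inherits(priors, "prior_spec"))
  c0_mode <- match.arg(c0_mode)
  if (nrow(data$series) < 5)
    stop("at least 5 observations are required to fit the model",
         call. = FALSE)
  if (chains < 2) stop("at least 2 chains are required for rhat", call. = FALSE)

  log_post <- make_log_post(data, priors, c0_mode, likelihood)
  d <- if (c0_mode == "estimate") 4L else 3L
  par_names <- c("vmax", "km", "sigma", if (d == 4L) "c0")
  y1 <- data$series$conc_mg_dl[1]

  # initialisation centres: a cheap MLE when the likelihood is on (priors may
  # be arbitrarily weak, so prior centres can sit far from the posterior
  # mass); prior centres in prior-only mode
  centre <- if (likelihood) {
    crude <- tryCatch(fit_mm_mle(data, n_starts = 3), error = function(e) NULL)
    if (is.null(crude)) {
      c(priors$vmax_mean, priors$km_mean, 0.02 * mean(data$series$conc_mg_dl), y1)
    } else {
      c(crude$params$vmax, crude$params$km,
        max(crude$sigma, 1e-4 * mean(data$series$conc_mg_dl), 1e-6),
        crude$c0)
    }
  } else {
    c(priors$vmax_mean, priors$km_mean, priors$sigma_scale, y1)
  }

  # Laplace approximation at the centre: the inverse curvature of the
  # log-posterior sets the initial proposal shape, so the sampler starts
  # near-optimal even when the posterior is orders of magnitude tighter than
  # the priors. Warmup adaptation then refines it.
  theta_hat <- log(centre[seq_len(d)])
  chol0 <- NULL
  H <- tryCatch(stats::optimHess(theta_hat, log_post), error = function(e) NULL)
  if (!is.null(H)) {
    S <- tryCatch(solve(-(H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(S) && all(is.finite(S)) && all(diag(S) > 0)) {
      ch <- tryCatch(chol(S + 1e-12 * diag(d)), error = function(e) NULL)
      if (!is.null(ch)) chol0 <- t(ch)
    }
  }

  res <- with_seed(as.integer(seed), {
    lapply(seq_len(chains), function(ch) {
      # overdispersed inits: ~2 posterior sds around the centre when the
      # Laplace shape is available, otherwise a fixed log-scale jitter
      repeat {
        th0 <- if (is.null(chol0)) {
          theta_hat + stats::rnorm(d, 0, 0.3)
        } else {
          theta_hat + 2 * as.numeric(chol0 %*% stats::rnorm(d))
        }
        if (is.finite(log_post(th0))) break
      }
      run_chain(log_post, th0, warmup, draws,
                chol0 = chol0, scale0 = if (is.null(chol0)) NULL
                else 2.38 / sqrt(d))
    })
  })

  # diagnostics on the sampled (log) scale; summaries on the natural scale
  mc <- coda::mcmc.list(lapply(res, function(r)
    coda::mcmc(r$draws, start = warmup + 1)))
  rhat <- tryCatch(
    coda::gelman.diag(mc, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, d))
  ess <- Reduce(`+`, lapply(mc, coda::effectiveSize))

  all_draws <- exp(do.call(rbind, lapply(res, `[[`, "draws")))
  colnames(all_draws) <- par_names
  draws_df <- as.data.frame(all_draws)
  draws_df$.chain <- rep(seq_len(chains), each = draws)

  qs <- apply(all_draws, 2, stats::quantile, probs = c(0.025, 0.975))
  summary <- data.frame(
    parameter = par_names,
    mean = colMeans(all_draws),
    ci_lower = qs[1, ],
    ci_upper = qs[2, ],
    rhat = as.numeric(rhat),
    ess = as.numeric(ess),
    row.names = NULL
  )
  converged <- all(is.finite(summary$rhat)) && all(summary$rhat <= 1.01)

  structure(
    list(draws = draws_df,
         summary = summary,
         converged = converged,
         accept_rates = vapply(res, `[[`, numeric(1), "accept_rate"),
         settings = list(chains = chains, warmup = warmup, draws = draws,
                         seed = as.integer(seed), c0_mode = c0_mode,
                         likelihood = likelihood),
         priors = priors),
    class = "mm_posterior"
  )
}

#' @export
print.mm_posterior <- function(x, digits = 4, ...) {
  cat(sprintf("Michaelis-Menten posterior (%d chains x %d draws)%s\n",
              x$settings$chains, x$settings$draws,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

# convenience accessors used by the KMD assembly
posterior_stat <- function(posterior, parameter, what) {
  row <- posterior$summary[posterior$summary$parameter == parameter, ]
  if (nrow(row) != 1) stop("no such parameter: ", parameter, call. = FALSE)
  row[[what]]
}

#' Maximum-likelihood estimation of Vmax and Km
#'
#' Maximizes the same Normal likelihood as [fit_mm_bayes] (no priors) over
#' (Vmax, Km), with sigma profiled out analytically. Optimization is
#' multi-start Nelder-Mead on the log scale, so an initial guess an order of
#' magnitude off still reaches the same optimum on clean data.
#'
#' @param data a `tk_dataset` with at least 5 observations.
#' @param init optional [mm_params] starting point; defaults to a crude
#'   slope-based guess.
#' @param n_starts number of jittered restarts.
#' @return list with `params` ([mm_params]), `sigma`, `logLik`, `converged`.
#' @examples
#' d <- generate_tk_dataset(mm_params(175, 11.8), 224.2, seq(0, 12, 0.25))
#' fit_mm_mle(d)$params
#' @export
fit_mm_mle <- function(data, init = NULL, n_starts = 5) {
  stopifnot(inherits(data, "tk_dataset"))
  n <- nrow(data$series)
  if (n < 5)
    stop("at least 5 observations are required (model is unidentifiable)",
         call. = FALSE)
  t_obs <- data$series$time_h - data$series$time_h[1]
  y_obs <- data$series$conc_mg_dl

  if (is.null(init)) {
    # early slope ~ -Vmax under saturation; Km ~ a tenth of the start
    v0 <- max(abs((y_obs[2] - y_obs[1]) / (t_obs[2] - t_obs[1])), 1e-3)
    init <- mm_params(v0, max(y_obs[1] / 10, 1e-3))
  }
  stopifnot(inherits(init, "mm_params"))

  # theta = log(vmax, km, c0); c0 is estimated jointly (anchoring it at the
  # noisy first observation would push that measurement's error into vmax).
  # sigma is profiled out: sigma^2 = rss/n, floored at (1e-8)^2 so the
  # objective has a genuine minimum on noise-free data.
  nll <- function(th) {
    p <- exp(th)
    if (!all(is.finite(p))) return(1e10)
    mu <- analytic_concentration(p[3], mm_params(p[1], p[2]), t_obs)
    rss <- sum((y_obs - mu)^2)
    n / 2 * log(max(rss / n, 1e-16)) + n / 2
  }

  starts <- list(log(c(init$vmax, init$km, max(y_obs[1], 1e-3))))
  jit <- with_seed(1L, matrix(stats::rnorm(3 * (n_starts - 1),
                                           0, c(1, 1, 0.1)), ncol = 3,
                              byrow = TRUE))
  for (k in seq_len(n_starts - 1))
    starts[[k + 1]] <- starts[[1]] + jit[k, ]

  best <- NULL
  for (s in starts) {
    fit <- suppressWarnings(stats::optim(s, nll, method = "Nelder-Mead",
                                         control = list(maxit = 5000,
                                                        reltol = 1e-12)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- exp(best$par)
  sigma <- sqrt(mean((y_obs - analytic_concentration(
    p[3], mm_params(p[1], p[2]), t_obs))^2))
  list(params = mm_params(p[1], p[2]),
       c0 = p[3],
       sigma = sigma,
       logLik = -best$value - n / 2 * log(2 * pi),
       converged = best$convergence == 0)
}
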