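#' Fit the multi-component diffusion model to a correlation curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) of the [evaluate_correlation_model()] model against
#' a measured curve. Fractions are constrained to the simplex and times to
#' positivity by an internal stick-breaking / log parameterisation. Starting
#' values come from moments of the curve (amplitude from the small-lag excess,
#' diffusion time from the half-decay lag); five deterministically jittered
#' restarts are run and the best residual norm wins.
#'
#' @param curve Tibble with columns `lag` (seconds) and `G`, e.g. one pair
#'   from [estimate_correlation()].
#' @param n_components Number of diffusion components (1, 2 or 3).
#' @param triplet Include the multiplicative triplet blinking term?
#' @param s_fixed If supplied, the structural parameter is fixed at this
#'   calibrated value rather than fitted.
#' @param weights `"uniform"` (default) or `"lag_bin"` (weights inversely
#'   proportional to the local lag-grid spacing, down-weighting the densely
#'   sampled small-lag region).
#' @return Object of class `fcs_fit` with elements `params`
#'   ([fcs_params()]), `amplitude` (fitted G(0) - 1 = 1/N), `residual_norm`,
#'   `converged`, `degenerate`, `fitted`, `data`. [tidy()] and [glance()]
#'   methods are provided.
#' @export
fit_correlation <- function(curve, n_components = 1, triplet = FALSE,
                            s_fixed = NULL,
                            weights = c("uniform", "lag_bin")) {
  weights <- match.arg(weights)
  stopifnot(is.data.frame(curve), all(c("lag", "G") %in% names(curve)))
  curve <- dplyr::arrange(dplyr::filter(curve, .data$lag > 0), .data$lag)
  lags <- curve$lag
  G <- curve$G
  k <- as.integer(n_components)
  if (!k %in% 1:3) abort("n_components must be 1, 2 or 3")

  n_free <- 1 + k + (k - 1) + (if (is.null(s_fixed)) 1 else 0) +
    (if (triplet) 2 else 0)
  if (length(lags) < 4 * n_free) {
    abort(sprintf("need at least %d points to fit %d free parameters",
                  4 * n_free, n_free))
  }

  if (all(G <= 1)) {
    warn("correlation curve never exceeds 1; returning amplitude-zero result")
    params <- structure(
      list(n_particles = Inf,
           components = tibble(fraction = rep(1 / k, k),
                               tau = rep(stats::median(lags), k)),
           s = if (is.null(s_fixed)) 5 else s_fixed,
           triplet_fraction = NULL, triplet_time = NULL),
      class = "fcs_params")
    return(new_fcs_fit(params, amplitude = 0, residual_norm = NA_real_,
                       converged = TRUE, degenerate = TRUE,
                       fitted = rep(1, length(lags)), data = curve,
                       s_fixed = s_fixed, weights = weights))
  }

  w <- if (weights == "uniform") {
    rep(1, length(lags))
  } else {
    sp <- diff(c(0, lags))
    1 / (sp / min(sp))
  }

  # ---- parameter transform ------------------------------------------------
  # theta = [log N, log tau_1..k, logit stick-breaking fractions (k-1),
  #          log s (if free), logit T, log tau_T (if triplet)]
  unpack <- function(theta) {
    i <- 1
    N <- exp(theta[i]); i <- i + 1
    taus <- exp(theta[i:(i + k - 1)]); i <- i + k
    if (k == 1) {
      fr <- 1
    } else {
      sticks <- stats::plogis(theta[i:(i + k - 2)]); i <- i + k - 1
      fr <- numeric(k)
      rest <- 1
      for (m in seq_len(k - 1)) {
        fr[m] <- rest * sticks[m]
        rest <- rest - fr[m]
      }
      fr[k] <- rest
    }
    s <- if (is.null(s_fixed)) { v <- exp(theta[i]); i <- i + 1; v } else s_fixed
    tf <- tt <- NULL
    if (triplet) {
      tf <- stats::plogis(theta[i]) * 0.999
      tt <- exp(theta[i + 1])
    }
    structure(list(n_particles = N,
                   components = tibble(fraction = fr, tau = taus),
                   s = s, triplet_fraction = tf, triplet_time = tt),
              class = "fcs_params")
  }

  resid_fun <- function(theta) {
    p <- unpack(theta)
    w * (evaluate_correlation_model(p, lags)$G - G)
  }

  # ---- moment-based start -------------------------------------------------
  excess <- G - 1
  A0 <- max(mean(utils::head(excess, 3)), 1e-3)
  half_idx <- which(excess <= A0 / 2)
  tau0 <- if (length(half_idx) > 0) lags[half_idx[1]] else stats::median(lags)
  tau_start <- switch(k,
                      tau0,
                      c(tau0 / 5, tau0 * 5),
                      c(tau0 / 10, tau0, tau0 * 10))
  theta0 <- c(log(1 / A0), log(tau_start))
  # diffusion times are only resolvable inside the measured lag window; the
  # lower bound stops the tau -> 0 ridge where the extrapolated amplitude
  # becomes unconstrained on flat curves
  lower <- c(log(1e-6), rep(log(min(lags)), k))
  upper <- c(log(1e12), rep(log(max(lags) * 10), k))
  if (k > 1) {
    theta0 <- c(theta0, rep(0, k - 1))
    lower <- c(lower, rep(-12, k - 1)); upper <- c(upper, rep(12, k - 1))
  }
  if (is.null(s_fixed)) {
    theta0 <- c(theta0, log(5))
    lower <- c(lower, log(0.5)); upper <- c(upper, log(100))
  }
  if (triplet) {
    theta0 <- c(theta0, stats::qlogis(0.1), log(max(min(lags), 1e-7)))
    lower <- c(lower, -12, log(min(lags) / 100))
    upper <- c(upper, 12, log(max(lags)))
  }
  theta0 <- pmin(pmax(theta0, lower), upper)

  # deterministic jittered restarts; caller's RNG state is untouched
  jitters <- local_rng(20260927L, {
    lapply(1:4, function(i) rnorm(length(theta0), sd = 0.3))
  })
  starts <- c(list(rep(0, length(theta0))), jitters)

  best <- NULL
  for (jit in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(theta0 + jit, lower), upper),
                         fn = resid_fun, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) {
      best <- list(fit = fit, rn = rn)
    }
  }
  if (is.null(best)) {
    warn("all optimizer starts failed; returning non-converged start values")
    p0 <- unpack(theta0)
    return(new_fcs_fit(p0, amplitude = 1 / p0$n_particles,
                       residual_norm = sqrt(sum(resid_fun(theta0)^2)),
                       converged = FALSE, degenerate = FALSE,
                       fitted = evaluate_correlation_model(p0, lags)$G,
                       data = curve, s_fixed = s_fixed, weights = weights))
  }
  # MINPACK info 1-3: ftol/xtol termination; 4: gtol (gradient orthogonal
  # to residual, i.e. a stationary point, typical for near-flat curves)
  converged <- best$fit$info %in% 1:4
  if (!converged) {
    warn(sprintf("fit did not converge (nls.lm info = %d): %s",
                 best$fit$info, best$fit$message))
  }
  params <- unpack(best$fit$par)
  # order components by diffusion time for reportability
  ord <- order(params$components$tau)
  params$components <- params$components[ord, ]
  new_fcs_fit(params, amplitude = 1 / params$n_particles,
              residual_norm = best$rn, converged = converged,
              degenerate = FALSE,
              fitted = evaluate_correlation_model(params, lags)$G,
              data = curve, s_fixed = s_fixed, weights = weights)
}

new_fcs_fit <- function(params, amplitude, residual_norm, converged,
                        degenerate, fitted, data, s_fixed, weights) {
  structure(
    list(params = params, amplitude = amplitude,
         residual_norm = residual_norm, converged = converged,
         degenerate = degenerate, fitted = fitted, data = data,
         s_fixed = s_fixed, weights = weights, n_obs = nrow(data)),
    class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("<fcs_fit>", if (x$degenerate) "(degenerate: amplitude 0)" else "", "\n")
  cat(sprintf("  amplitude G(0)-1 = %.4g, residual norm = %.4g, converged: %s\n",
              x$amplitude, x$residual_norm, x$converged))
  print(x$params)
  invisible(x)
}

#' @rdname fit_correlation
#' @param x An `fcs_fit` object.
#' @param ... Unused.
#' @method tidy fcs_fit
#' @export
tidy.fcs_fit <- function(x, ...) {
  p <- x$params
  k <- nrow(p$components)
  out <- tibble(
    term = c("n_particles", "s",
             paste0("fraction_", seq_len(k)), paste0("tau_", seq_len(k))),
    estimate = c(p$n_particles, p$s, p$components$fraction, p$components$tau))
  if (!is.null(p$triplet_fraction)) {
    out <- dplyr::bind_rows(out, tibble(
      term = c("triplet_fraction", "triplet_time"),
      estimate = c(p$triplet_fraction, p$triplet_time)))
  }
  out
}

#' @rdname fit_correlation
#' @method glance fcs_fit
#' @export
glance.fcs_fit <- function(x, ...) {
  p <- x$params
  tibble(n_particles = p$n_particles, amplitude = x$amplitude,
         tau_d = sum(p$components$fraction * p$components$tau),
         s = p$s, residual_norm = x$residual_norm,
         converged = x$converged, degenerate = x$degenerate,
         n_obs = x$n_obs)
}

# run code under a private RNG seed, restoring the caller's RNG state
local_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
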