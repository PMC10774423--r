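#' Multi-component FCS diffusion-model parameters
#'
#' Container for the parameters of the one- to three-component 3D diffusion
#' model with Gaussian detection volume:
#' \deqn{G(\tau) = 1 + \frac{1}{N} \sum_i F_i
#'   \left(1 + \frac{\tau}{\tau_i}\right)^{-1}
#'   \left(1 + \frac{\tau}{s^2 \tau_i}\right)^{-1/2}}
#' where `N` is the mean particle number in the detection volume, `F_i` and
#' `tau_i` the fraction and diffusion time of component i, and `s = z0/w0`
#' the structural parameter (axial-to-lateral ratio of the confocal volume).
#' An optional triplet blinking term multiplies the diffusion sum by
#' \eqn{1 + \frac{T}{1-T} e^{-\tau/\tau_T}}.
#'
#' @param n_particles Mean particle number N (> 0).
#' @param components Data frame with columns `fraction` and `tau` (seconds);
#'   1 to 3 rows, fractions summing to one.
#' @param s Structural parameter z0/w0 (> 0).
#' @param triplet_fraction,triplet_time Optional triplet parameters
#'   (T in [0, 1), tau_T > 0 seconds); both or neither.
#' @return An object of class `fcs_params`.
#' @export
fcs_params <- function(n_particles, components, s,
                       triplet_fraction = NULL, triplet_time = NULL) {
  components <- as_tibble(components)
  stopifnot(all(c("fraction", "tau") %in% names(components)))
  k <- nrow(components)
  if (k < 1 || k > 3) abort("between 1 and 3 diffusion components required")
  if (abs(sum(components$fraction) - 1) > 1e-9) {
    abort("component fractions must sum to 1 (within 1e-9)")
  }
  if (any(components$fraction < 0) || any(components$fraction > 1)) {
    abort("component fractions must lie in [0, 1]")
  }
  if (!is.numeric(n_particles) || n_particles <= 0) {
    abort("n_particles must be positive")
  }
  if (any(components$tau <= 0)) abort("diffusion times must be positive")
  if (s <= 0) abort("structural parameter s must be positive")
  has_trip <- !is.null(triplet_fraction) || !is.null(triplet_time)
  if (has_trip) {
    if (is.null(triplet_fraction) || is.null(triplet_time)) {
      abort("triplet_fraction and triplet_time must be given together")
    }
    if (triplet_fraction < 0 || triplet_fraction >= 1 || triplet_time <= 0) {
      abort("triplet parameters out of range: T in [0,1), tau_T > 0")
    }
  }
  structure(
    list(n_particles = n_particles, components = components, s = s,
         triplet_fraction = triplet_fraction, triplet_time = triplet_time),
    class = "fcs_params"
  )
}

#' @export
print.fcs_params <- function(x, ...) {
  cat("<fcs_params> N =", format(x$n_particles, digits = 4),
      " s =", format(x$s, digits = 4), "\n")
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  component %d: F = %.4f, tau = %.3g s\n",
                i, x$components$fraction[i], x$components$tau[i]))
  }
  if (!is.null(x$triplet_fraction)) {
    cat(sprintf("  triplet: T = %.3f, tau_T = %.3g s\n",
                x$triplet_fraction, x$triplet_time))
  }
  invisible(x)
}

#' Evaluate the multi-component diffusion correlation model
#'
#' Exact, noise-free evaluation of the model described in [fcs_params()].
#'
#' @param params An [fcs_params()] object.
#' @param lags Lag times in seconds (>= 0).
#' @return Tibble with columns `lag`, `G`.
#' @examples
#' p <- fcs_params(1, data.frame(fraction = 1, tau = 1e-3), s = 5)
#' evaluate_correlation_model(p, 0)  # G(0) = 1 + 1/N = 2
#' @export
evaluate_correlation_model <- function(params, lags) {
  stopifnot(inherits(params, "fcs_params"), all(lags >= 0))
  comp <- params$components
  gsum <- rep(0, length(lags))
  for (i in seq_len(nrow(comp))) {
    gsum <- gsum + comp$fraction[i] /
      ((1 + lags / comp$tau[i]) *
         sqrt(1 + lags / (params$s^2 * comp$tau[i])))
  }
  trip <- 1
  if (!is.null(params$triplet_fraction)) {
    Tf <- params$triplet_fraction
    trip <- 1 + Tf / (1 - Tf) * exp(-lags / params$triplet_time)
  }
  tibble(lag = lags, G = 1 + trip * gsum / params$n_particles)
}
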