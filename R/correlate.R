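#' Quasi-logarithmic lag grid for correlation estimation
#'
#' Builds a multi-tau-style lag grid: every lag is an integer multiple of the
#' sampling interval, linearly spaced over the first octave and thereafter
#' thinned so that each octave carries roughly `points_per_octave` points.
#'
#' @param sample_interval Sampling interval in seconds.
#' @param duration Total trace duration in seconds; lags stay strictly below
#'   half of it so every lag is averaged over at least half the trace.
#' @param points_per_octave Approximate number of lags per factor-of-two in
#'   lag time (default 8).
#' @return Numeric vector of lag times (seconds), strictly increasing.
#' @export
fcs_lag_grid <- function(sample_interval, duration, points_per_octave = 8) {
  stopifnot(sample_interval > 0, duration > 2 * sample_interval)
  max_mult <- floor(duration / (2 * sample_interval))
  mults <- seq_len(min(points_per_octave * 2L, max_mult))
  m <- max(mults)
  while (m < max_mult) {
    step <- max(1, round(m / points_per_octave))
    nxt <- utils::head(seq(m + step, 2 * m, by = step), Inf)
    nxt <- nxt[nxt <= max_mult]
    if (length(nxt) == 0) break
    mults <- c(mults, nxt)
    m <- max(mults)
  }
  unique(mults) * sample_interval
}

# core worker: direct fluctuation estimator on two aligned numeric vectors
correlate_vectors <- function(x, y, dt, lags) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  if (mx <= 0 || my <= 0) {
    abort("degenerate input: trace mean must be positive before correlation")
  }
  dx <- x - mx
  dy <- y - my
  ks <- round(lags / dt)
  if (any(abs(lags / dt - ks) > 1e-6 * pmax(1, ks))) {
    abort("every lag must be an integer multiple of the sample interval")
  }
  if (any(ks < 0) || any(ks >= n)) {
    abort("lags must be non-negative and shorter than the trace duration")
  }
  g <- vapply(ks, function(k) {
    idx <- seq_len(n - k)
    1 + mean(dx[idx] * dy[idx + k]) / (mx * my)
  }, numeric(1))
  g
}

#' Estimate auto- and cross-correlation functions from intensity traces
#'
#' Direct fluctuation-correlation estimator
#' \deqn{G_x(\tau) = 1 + \frac{\langle \delta I_i(t)\,\delta I_j(t+\tau)\rangle}
#'   {\langle I_i\rangle \langle I_j\rangle}}
#' with \eqn{\delta I = I - \langle I\rangle}, averaged over all valid start
#' times. `gg` and `rr` are single-channel auto-correlations, `rg` the
#' red-green cross-correlation.
#'
#' @param traces Tibble with a `time` column (seconds, evenly spaced) and
#'   intensity columns `green` and/or `red` as produced by
#'   [simulate_fccs_traces()].
#' @param pairs Which channel pairs to estimate, subset of
#'   `c("gg", "rr", "rg")`.
#' @param lags Lag times in seconds; each must be an integer multiple of the
#'   sampling interval. Defaults to [fcs_lag_grid()] over the trace.
#' @return Tibble with columns `pair`, `lag`, `G`.
#' @examples
#' tr <- tibble::tibble(time = seq(0, 1, by = 1e-3),
#'                      green = 10 + sin(2 * pi * seq(0, 1, by = 1e-3)))
#' estimate_correlation(tr, pairs = "gg", lags = c(1e-3, 1e-2))
#' @export
estimate_correlation <- function(traces, pairs = c("gg", "rr", "rg"),
                                 lags = NULL) {
  pairs <- match.arg(pairs, several.ok = TRUE)
  stopifnot(is.data.frame(traces), "time" %in% names(traces),
            nrow(traces) >= 2)
  tt <- traces$time
  dts <- diff(tt)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-9 * max(dt, 1e-12))) {
    abort("trace sampling intervals are not uniform")
  }
  if (is.null(lags)) {
    lags <- fcs_lag_grid(dt, length(tt) * dt)
  }
  cols <- list(gg = c("green", "green"), rr = c("red", "red"),
               rg = c("red", "green"))
  purrr::map_dfr(pairs, function(p) {
    ch <- cols[[p]]
    missing_ch <- setdiff(ch, names(traces))
    if (length(missing_ch) > 0) {
      abort(paste0("pair '", p, "' needs trace column(s): ",
                   paste(missing_ch, collapse = ", ")))
    }
    tibble(pair = p, lag = lags,
           G = correlate_vectors(traces[[ch[1]]], traces[[ch[2]]], dt, lags))
  })
}
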