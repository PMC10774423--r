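#' Correlation-curve text I/O
#'
#' Columnar text with header `lag_seconds G_value pair`, full-precision
#' (`%.17g`) so the read/write round trip is bit-exact.
#'
#' @param curves Tibble with columns `pair`, `lag`, `G` (one or more pairs).
#' @param path File path.
#' @return `write_correlation_curves()`: `path` invisibly;
#'   `read_correlation_curves()`: the curves tibble.
#' @export
write_correlation_curves <- function(curves, path) {
  stopifnot(all(c("pair", "lag", "G") %in% names(curves)))
  lines <- c("lag_seconds\tG_value\tpair",
             sprintf("%.17g\t%.17g\t%s", curves$lag, curves$G, curves$pair))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_correlation_curves
#' @export
read_correlation_curves <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tibble(pair = df$pair, lag = df$lag_seconds, G = df$G_value)
}

#' Intensity-trace text I/O
#'
#' Two-channel traces as tab-separated `green`/`red` columns; the time axis
#' is implied by a `# sample_interval:` header line, matching the
#' correlation toolchain's expectation of evenly sampled input.
#'
#' @param traces Tibble with `time`, `green`, `red`.
#' @param path File path.
#' @return `write_traces()`: `path` invisibly; `read_traces()`: the traces
#'   tibble (time reconstructed from the header).
#' @export
write_traces <- function(traces, path) {
  stopifnot(all(c("time", "green", "red") %in% names(traces)))
  dt <- traces$time[2] - traces$time[1]
  lines <- c(sprintf("# sample_interval: %.17g", dt),
             "green\tred",
             sprintf("%.17g\t%.17g", traces$green, traces$red))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1)
  dt <- as.numeric(sub("# sample_interval: ", "", first))
  df <- utils::read.delim(path, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE)
  tibble(time = (seq_len(nrow(df)) - 1) * dt,
         green = df$green, red = df$red)
}
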