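#' Plot a fitted correlation curve
#'
#' Measured points with the fitted model overlaid, log-scaled lag axis.
#'
#' @param object An `fcs_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fcs_fit
#' @export
autoplot.fcs_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$G), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(G(tau)),
                  title = sprintf("N = %.3g, amplitude = %.3g",
                                  object$params$n_particles,
                                  object$amplitude)) +
    ggplot2::theme_minimal()
}

#' Per-residue RMSF profiles, optionally by variant
#'
#' @param rmsf_tbl Tibble with columns `resid`, `rmsf` and optionally
#'   `variant`.
#' @param highlight Optional named list of residue-id vectors shaded as
#'   background regions (e.g. the RIP2-binding loops).
#' @return A ggplot object.
#' @export
plot_rmsf <- function(rmsf_tbl, highlight = NULL) {
  p <- ggplot2::ggplot(rmsf_tbl,
                       ggplot2::aes(x = .data$resid, y = .data$rmsf))
  if (!is.null(highlight)) {
    bands <- purrr::imap_dfr(highlight, function(ids, nm) {
      tibble(name = nm, xmin = min(ids), xmax = max(ids))
    })
    p <- p + ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6)
  }
  if ("variant" %in% names(rmsf_tbl)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$variant))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Variant report overview plot
#'
#' Dot plot of the per-variant metrics (core-RMSD 90th percentile, 166-185
#' occupancy, beta-segment distance, RCA), one panel per metric.
#'
#' @param object A `variant_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variant_report
#' @export
autoplot.variant_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "variant", "rmsd_core_q90",
                  "hbond_166_185_pct", "beta_distance", "rca"),
    -"variant", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$variant, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
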