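#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synchrosqueezed (or wavelet) transform
#'
#' Amplitude heat map on a logarithmic frequency axis.
#'
#' @param object A [synchrosqueeze()] or [compute_wt()] result.
#' @param every_t Thinning factor along time (rasters get large quickly).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swt_transform
#' @export
autoplot.swt_transform <- function(object, every_t = 5L, ...) {
  d <- tidy(object, every_t = every_t)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$freq, fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "time (s)", y = "frequency (Hz)", fill = "|T|",
      title = paste("Synchrosqueezed transform", object$label)
    )
}

#' @rdname autoplot.swt_transform
#' @method autoplot wavelet_transform
#' @export
autoplot.wavelet_transform <- function(object, every_t = 5L, ...) {
  d <- tidy(object, every_t = every_t)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$freq, fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "time (s)", y = "frequency (Hz)", fill = "|W|",
      title = paste("Wavelet transform", object$label)
    )
}

#' Plot an extracted phase/frequency series
#'
#' @param object An [extract_phase_freq()] tibble.
#' @param what `"freq"` (default) or `"phase"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_freq
#' @export
autoplot.phase_freq <- function(object, what = c("freq", "phase"), ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data[[what]])) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "time (s)",
      y = if (what == "freq") "instantaneous frequency (Hz)" else "phase (rad)"
    )
}

#' Plot wavelet phase coherence with its surrogate threshold
#'
#' @param object A [wpc()] result.
#' @param ensemble Optional [intersubject_threshold()] ensemble.
#' @param band_edges Optional band edges drawn as vertical dotted lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coherence_result
#' @export
autoplot.coherence_result <- function(object, ensemble = NULL,
                                      band_edges = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$freq, .data$wpc)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "frequency (Hz)", y = "wavelet phase coherence")
  if (!is.null(ensemble)) {
    thr <- tibble::tibble(freq = ensemble$freqs, threshold = ensemble$threshold)
    p <- p + ggplot2::geom_line(
      data = thr, ggplot2::aes(.data$freq, .data$threshold),
      colour = "grey50", linetype = "dashed"
    )
  }
  if (!is.null(band_edges)) {
    p <- p + ggplot2::geom_vline(
      xintercept = band_edges, linetype = "dotted", colour = "grey70"
    )
  }
  p
}

#' Plot reconstructed coupling-function surfaces
#'
#' Tile maps of `q_h` and `q_r` over the `(phi_h, phi_r)` torus.
#'
#' @param object A [coupling_grid()] result.
#' @param ... Unused.
#' @return A ggplot object faceted by equation.
#' @method autoplot coupling_grid
#' @export
autoplot.coupling_grid <- function(object, ...) {
  long <- function(m, eq) {
    tibble::tibble(
      phi_h = rep(object$phi_h, times = length(object$phi_r)),
      phi_r = rep(object$phi_r, each = length(object$phi_h)),
      q = as.vector(m), equation = eq
    )
  }
  d <- dplyr::bind_rows(long(object$q_h, "q_h"), long(object$q_r, "q_r"))
  ggplot2::ggplot(d, ggplot2::aes(.data$phi_h, .data$phi_r, fill = .data$q)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~equation) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = expression(phi[h]), y = expression(phi[r]),
      fill = "rad/s")
}

#' Plot per-window coupling metrics over time
#'
#' @param object A [coupling_norms()] tibble.
#' @param ... Unused.
#' @return A ggplot of the epsilon norms and directionality versus time.
#' @method autoplot coupling_metrics
#' @export
autoplot.coupling_metrics <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[c("t_mid", "eps_r2h", "eps_h2r", "D")],
    cols = -"t_mid", names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$t_mid, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Age-trend scatter plot for a cohort measure
#'
#' @param result A [run_cohort()] result.
#' @param measure Column of `result$subjects` to plot against age.
#' @return A ggplot with a rank-correlation annotation.
#' @export
plot_age_trend <- function(result, measure = "eps_dir_h") {
  stopifnot(inherits(result, "cohort_result"))
  d <- result$subjects
  tr <- result$trends[result$trends$variable == measure, ]
  lab <- if (nrow(tr) == 1L && is.finite(tr$rho)) {
    sprintf("rho = %.2f, p = %.2g", tr$rho, tr$p)
  } else {
    ""
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data[[measure]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$gender)) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
      colour = "grey30") +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
      label = lab) +
    ggplot2::labs(x = "age (years)", y = measure)
}
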