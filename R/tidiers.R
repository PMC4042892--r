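#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a single-window inference
#'
#' @param x A [infer_window()] result.
#' @param ... Unused.
#' @return A tibble with one row per (equation, term): `equation`
#'   (`"h"`/`"r"`), `term`, `estimate` (rad/s), `std.error` (posterior sd),
#'   `part` (omega/self/direct/indirect).
#' @method tidy window_inference
#' @export
tidy.window_inference <- function(x, ...) {
  K <- length(x$c_h)
  se <- sqrt(pmax(0, diag(x$cov)))
  tibble::tibble(
    equation = rep(c("h", "r"), each = K),
    term = rep(x$basis$label, 2L),
    estimate = c(unname(x$c_h), unname(x$c_r)),
    std.error = unname(se),
    part = c(x$basis$part_h, x$basis$part_r)
  )
}

#' @rdname tidy.window_inference
#' @return `glance()` returns a one-row tibble: inferred noise entries
#'   `E_hh`, `E_hr`, `E_rr`, natural frequencies `f_h`, `f_r` (Hz),
#'   `n_obs`, `n_iter`, `converged`.
#' @method glance window_inference
#' @export
glance.window_inference <- function(x, ...) {
  tibble::tibble(
    E_hh = x$E[1, 1], E_hr = x$E[1, 2], E_rr = x$E[2, 2],
    f_h = x$c_h[["const"]] / (2 * pi), f_r = x$c_r[["const"]] / (2 * pi),
    n_obs = x$n_obs, n_iter = x$n_iter, converged = x$converged
  )
}

#' Tidy an inference sequence
#'
#' @param x An [infer_sequence()] result.
#' @param ... Unused.
#' @return A long tibble: `window`, `t_mid`, `equation`, `term`,
#'   `estimate`, `std.error`, `part`.
#' @method tidy inference_sequence
#' @export
tidy.inference_sequence <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$windows), function(w) {
    d <- tidy(x$windows[[w]])
    d$window <- w
    d$t_mid <- x$t_mid[w]
    d[c("window", "t_mid", "equation", "term", "estimate", "std.error", "part")]
  }))
}

#' @rdname tidy.inference_sequence
#' @return `glance()` returns one row per window with the noise matrix and
#'   convergence diagnostics.
#' @method glance inference_sequence
#' @export
glance.inference_sequence <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$windows), function(w) {
    g <- glance(x$windows[[w]])
    dplyr::bind_cols(tibble::tibble(window = w, t_mid = x$t_mid[w]), g)
  }))
}

#' Summaries of derived-metric objects
#'
#' @param x A [rsa_shape()] result.
#' @param ... Unused.
#' @return The across-window summary (`mean_ba`, `sd_ba`, `gamma`,
#'   `n_excluded`).
#' @method glance rsa_shape
#' @export
glance.rsa_shape <- function(x, ...) {
  attr(x, "summary")
}

#' @rdname glance.rsa_shape
#' @method glance subject_report
#' @export
glance.subject_report <- function(x, ...) {
  glance_subject(x)
}

#' Tidy time--frequency transforms into long tibbles
#'
#' Converts the complex coefficient matrix into a long `(time, freq,
#' amplitude, phase)` tibble, optionally thinned for plotting.
#'
#' @param x A [compute_wt()] or [synchrosqueeze()] result.
#' @param every_t Keep every `every_t`-th time sample.
#' @param ... Unused.
#' @return A tibble with columns `time`, `freq`, `amplitude`, `phase`.
#' @method tidy wavelet_transform
#' @export
tidy.wavelet_transform <- function(x, every_t = 1L, ...) {
  sel <- seq(1L, length(x$times), by = every_t)
  tidy_tf(x$coeffs[, sel, drop = FALSE], x$freqs, x$times[sel])
}

#' @rdname tidy.wavelet_transform
#' @method tidy swt_transform
#' @export
tidy.swt_transform <- function(x, every_t = 1L, ...) {
  sel <- seq(1L, length(x$times), by = every_t)
  tidy_tf(x$coeffs[, sel, drop = FALSE], x$bin_centers, x$times[sel])
}

tidy_tf <- function(coeffs, freqs, times) {
  tibble::tibble(
    time = rep(times, each = length(freqs)),
    freq = rep(freqs, length(times)),
    amplitude = as.vector(Mod(coeffs)),
    phase = as.vector(Arg(coeffs))
  )
}
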