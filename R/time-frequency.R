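#' Continuous Morlet wavelet transform on a log-frequency scale grid
#'
#' Computes the analytic Morlet wavelet transform of a uniformly sampled
#' signal on scales \eqn{a_j = 2^{j/n_v} \cdot (2/f_s)}, i.e. each dyadic
#' interval is divided into `nv` equi-log-spaced bins. The wavelet's central
#' angular frequency is `2*pi`, so scale `a` (seconds) corresponds to the
#' nominal frequency `1/a` Hz and the scale grid spans from the Nyquist
#' frequency downward. Scales are kept only where at least ~8.6 oscillations
#' fit into the record (`a <= T/8.6`), the standard admissibility cap, and
#' are further restricted to `scale_margin` times the requested frequency
#' band to keep the transform economical.
#'
#' The transform uses the L1 ("amplitude") normalization: a unit-amplitude
#' tone at frequency f0 yields `|W| = 1` at the matching scale.
#'
#' @param signal A [uniform_signal()].
#' @param fmin,fmax Frequency band of interest in Hz (`fmin < fmax`).
#' @param nv Voices per octave (default 64).
#' @param scale_margin Factor by which the computed scale range extends
#'   beyond `[fmin, fmax]` on both sides, so that synchrosqueezing can
#'   reassign energy into the band from neighbouring scales.
#' @return An object of class `wavelet_transform`: complex coefficient
#'   matrix `coeffs` (scale x time), `scales` (s), `freqs` (Hz, `1/scales`),
#'   `times` (s), the grid metadata, and per-scale cone-of-influence limits
#'   (`coi_lo`, `coi_hi`, first/last admissible time index per scale, using
#'   +/- 3 Gaussian e-folding widths of wavelet support).
#' @export
#' @examples
#' s <- uniform_signal(cos(2 * pi * seq(0, 60, by = 0.04)), fs = 25)
#' wt <- compute_wt(s, fmin = 0.4, fmax = 2.1)
compute_wt <- function(signal, fmin, fmax, nv = 64L, scale_margin = sqrt(2)) {
  stopifnot(inherits(signal, "uniform_signal"))
  if (!(fmin > 0 && fmax > fmin)) stop("Need 0 < fmin < fmax.", call. = FALSE)
  fs <- signal$fs
  x <- signal$values
  n <- length(x)
  T_rec <- n / fs
  a_cap <- T_rec / 8.6
  if (1 / fmin > a_cap) {
    stop(sprintf(
      "Record too short for fmin = %g Hz: need at least %.1f s (8.6 cycles), have %.1f s.",
      fmin, 8.6 / fmin, T_rec
    ), call. = FALSE)
  }
  omega0 <- 2 * pi
  a0 <- 2 / fs
  a_min <- max(a0, 1 / (fmax * scale_margin))
  a_max <- min(a_cap, scale_margin / fmin)
  j_lo <- max(0L, ceiling(nv * log2(a_min / a0)))
  j_hi <- floor(nv * log2(a_max / a0))
  if (j_hi < j_lo) stop("Empty scale range for the requested band.", call. = FALSE)
  scales <- 2^((j_lo:j_hi) / nv) * a0

  npad <- 2^ceiling(log2(2 * n))
  xf <- stats::fft(c(x, rep(0, npad - n)))
  xi <- 2 * pi * fs * (0:(npad - 1)) / npad
  pos <- seq_len(floor(npad / 2) + 1L)  # non-negative frequencies

  coeffs <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  for (j in seq_along(scales)) {
    psi <- numeric(npad)
    psi[pos] <- 2 * exp(-(scales[j] * xi[pos] - omega0)^2 / 2)
    psi[1L] <- 0  # analytic: no DC
    w <- stats::fft(xf * psi, inverse = TRUE) / npad
    coeffs[j, ] <- w[seq_len(n)]
  }

  times <- signal_times(signal)
  # cone of influence: +/- 3 Gaussian e-folding widths of wavelet support;
  # the envelope exp(-t^2 / (2 a^2)) folds at sqrt(2) a, so the margin is
  # 3 sqrt(2) a (amplitude suppressed to e^-9 beyond it)
  margin <- ceiling(3 * sqrt(2) * scales * fs)
  coi_lo <- pmin(n + 1L, 1L + margin)
  coi_hi <- pmax(0L, n - margin)

  structure(
    list(
      coeffs = coeffs, scales = scales, freqs = 1 / scales, times = times,
      nv = as.integer(nv), omega0 = omega0, fs = fs,
      fmin = fmin, fmax = fmax, scale_margin = scale_margin,
      coi_lo = coi_lo, coi_hi = coi_hi, label = signal$label
    ),
    class = "wavelet_transform"
  )
}

#' @export
print.wavelet_transform <- function(x, ...) {
  cat(sprintf(
    "<wavelet_transform> %s: %d scales (%.3g-%.3g Hz, nv=%d) x %d times @ %g Hz\n",
    if (nzchar(x$label)) x$label else "signal",
    length(x$scales), min(x$freqs), max(x$freqs), x$nv, length(x$times), x$fs
  ))
  invisible(x)
}

#' Cone-of-influence mask of a wavelet transform
#'
#' @param wt A [compute_wt()] result.
#' @return Logical matrix (scale x time); `TRUE` where the wavelet support
#'   lies fully inside the record.
#' @export
wt_coi_mask <- function(wt) {
  nt <- length(wt$times)
  idx <- seq_len(nt)
  t(vapply(seq_along(wt$scales), function(j) {
    idx >= wt$coi_lo[j] & idx <= wt$coi_hi[j]
  }, logical(nt)))
}

#' Instantaneous frequency of each wavelet cell
#'
#' The phase growth rate of every wavelet coefficient, from the central
#' difference of the coefficient argument over time, converted to Hz:
#' `omega_f(a, t_i) = Arg(W(a, t_{i+1}) * Conj(W(a, t_{i-1}))) / (4 pi dt)`.
#' Using the argument of the product wraps the phase difference correctly for
#' components below a quarter of the sampling rate.
#'
#' @param wt A [compute_wt()] result with at least 3 time samples.
#' @param amp_tol Cells with `|W|` below `amp_tol * max|W|` are flagged
#'   undefined (`NA`): their phase carries no information.
#' @return Numeric matrix (scale x time) of instantaneous frequencies in Hz,
#'   `NA` where undefined (record edges and negligible-amplitude cells).
#' @export
instantaneous_wt_freq <- function(wt, amp_tol = 1e-10) {
  stopifnot(inherits(wt, "wavelet_transform"))
  nt <- length(wt$times)
  if (nt < 3L) stop("Need at least 3 time samples.", call. = FALSE)
  dt <- 1 / wt$fs
  W <- wt$coeffs
  omega_f <- matrix(NA_real_, nrow = nrow(W), ncol = nt)
  omega_f[, 2:(nt - 1)] <-
    Arg(W[, 3:nt, drop = FALSE] * Conj(W[, 1:(nt - 2), drop = FALSE])) / (4 * pi * dt)
  a_max <- max(Mod(W))
  if (a_max == 0) {
    omega_f[] <- NA_real_
  } else {
    omega_f[Mod(W) < amp_tol * a_max] <- NA_real_
  }
  omega_f
}

# Morlet admissibility-type constant for the reconstruction formula
# s(t) = Re[(2 / C_psi) * sum_l T(w_l, t) * dw_l], with the package's
# psi_hat(u) = 2 exp(-(u - 2 pi)^2 / 2).
morlet_cpsi <- function(omega0 = 2 * pi) {
  stats::integrate(function(u) 2 * exp(-(u - omega0)^2 / 2) / u,
    lower = 1e-8, upper = omega0 + 40, rel.tol = 1e-10
  )$value
}

#' Synchrosqueeze a wavelet transform
#'
#' Reassigns each wavelet coefficient along the frequency axis to the
#' equi-log-spaced frequency bin containing its instantaneous frequency
#' (see [instantaneous_wt_freq()]), concentrating oscillatory components
#' onto sharp ridges:
#' \deqn{T(\omega_l, t) = \Delta\omega_l^{-1} \sum_{a_k:\ \omega_f(a_k,t) \in
#'   [\omega_l, \omega_{l+1})} W(a_k, t)\, \frac{\ln 2}{n_v}}
#' (`ln 2 / nv` is the log-scale measure `da/a` of the grid). The complex
#' mass `sum_l T dw_l` equals the sum of the reassigned wavelet cells, so a
#' component can be reconstructed from its bins alone via
#' [reconstruct_component()].
#'
#' @param wt A [compute_wt()] result.
#' @param fmin,fmax Frequency range of the output bins (defaults to the
#'   band the transform was computed for).
#' @return An object of class `swt_transform`: complex `coeffs`
#'   (bin x time), `bin_edges`, `bin_centers` (Hz), `times`, the parent
#'   transform's metadata and the reconstruction constant `Cpsi`.
#' @export
synchrosqueeze <- function(wt, fmin = wt$fmin, fmax = wt$fmax) {
  stopifnot(inherits(wt, "wavelet_transform"))
  if (!(fmin > 0 && fmax > fmin)) stop("Need 0 < fmin < fmax.", call. = FALSE)
  nv <- wt$nv
  n_bins <- ceiling(nv * log2(fmax / fmin))
  if (n_bins < 1L) stop("Empty frequency-bin range.", call. = FALSE)
  edges <- fmin * 2^((0:n_bins) / nv)
  centers <- sqrt(edges[-1L] * edges[-(n_bins + 1L)])
  d_omega <- diff(edges)

  omega_f <- instantaneous_wt_freq(wt)
  nt <- length(wt$times)
  tf <- matrix(0 + 0i, nrow = n_bins, ncol = nt)

  ok <- is.finite(omega_f) & omega_f >= fmin & omega_f < edges[n_bins + 1L]
  if (any(ok)) {
    bin <- pmin(n_bins, 1L + floor(nv * log2(omega_f[ok] / fmin)))
    tcol <- col(omega_f)[ok]
    w <- wt$coeffs[ok] * (log(2) / nv)
    # sparseMatrix() accumulates duplicate (i, j) entries: exactly the
    # reassignment sum, done in compiled code
    re <- Matrix::sparseMatrix(i = bin, j = tcol, x = Re(w),
      dims = c(n_bins, nt))
    im <- Matrix::sparseMatrix(i = bin, j = tcol, x = Im(w),
      dims = c(n_bins, nt))
    tf <- complex(real = as.matrix(re), imaginary = as.matrix(im))
    dim(tf) <- c(n_bins, nt)
    tf <- tf / d_omega
  }

  # bin-level cone of influence from the bin's nominal scale 1/f
  n <- nt
  margin <- ceiling(3 * sqrt(2) * wt$fs / centers)
  coi_lo <- pmin(n + 1L, 1L + margin)
  coi_hi <- pmax(0L, n - margin)

  structure(
    list(
      coeffs = tf, bin_edges = edges, bin_centers = centers,
      d_omega = d_omega, times = wt$times, nv = nv, omega0 = wt$omega0,
      fs = wt$fs, Cpsi = morlet_cpsi(wt$omega0),
      coi_lo = coi_lo, coi_hi = coi_hi, label = wt$label,
      parent = list(
        fmin = wt$fmin, fmax = wt$fmax, scale_margin = wt$scale_margin,
        n_scales = length(wt$scales)
      )
    ),
    class = "swt_transform"
  )
}

#' @export
print.swt_transform <- function(x, ...) {
  cat(sprintf(
    "<swt_transform> %s: %d bins (%.3g-%.3g Hz) x %d times @ %g Hz\n",
    if (nzchar(x$label)) x$label else "signal",
    length(x$bin_centers), min(x$bin_centers), max(x$bin_centers),
    length(x$times), x$fs
  ))
  invisible(x)
}

#' Track the support of the main oscillatory component
#'
#' Follows the ridge of one component through a synchrosqueezed transform.
#' At every time step the support is the fixed-width window of frequency
#' bins maximizing a functional that combines (i) the Gaussian-centre-
#' weighted `|T|` mass inside the window, (ii) a penalty suppressing jumps
#' away from the frequency extracted in the previous window, and (iii) a
#' penalty on deviation from the record-wide mean frequency:
#' \deqn{F(i_c, t) = \Big[\sum_{|i - i_c| \le w/2} |T_{i,t}|\,
#'   e^{-(i - i_c)^2 / 2\sigma_g^2}\Big]\,
#'   e^{-\lambda |\log(\omega_{i_c} / \omega_{prev})|}\,
#'   e^{-\kappa |\log(\omega_{i_c} / \bar\omega)|}}
#' with \eqn{\sigma_g} half the window width (edge bins get weight ~0.6).
#' `omega_prev` is the amplitude-weighted mean frequency of the previous
#' window; the chain is initialized at `omega_bar`, the global
#' amplitude-weighted mean, which also anchors the third factor. Ties in the
#' maximization break toward the lower frequency.
#'
#' Recommended penalties: `lambda = 5, kappa = 0` for the ECG component and
#' `lambda = 10, kappa = 10` for respiration, whose frequency wanders more.
#'
#' @param swt A [synchrosqueeze()] result.
#' @param lambda Jump-suppression penalty (dimensionless, >= 0).
#' @param kappa Mean-attraction penalty (dimensionless, >= 0).
#' @param width_bins Total support width in bins (default `nv / 2`); the
#'   effective window is `2 * floor(width_bins / 2) + 1` bins.
#' @param omega_init Frequency (Hz) at which the `omega_prev` chain starts;
#'   defaults to `omega_bar` (no previous window exists at t = 0, and the
#'   global mean is the unbiased anchor). Supply a value to force tracking
#'   of a particular component in a multi-component field.
#' @return An object of class `ridge_support`: tibble with columns `t_idx`,
#'   `i_c` (central bin), `freq_win` (window frequency, Hz), `valid`;
#'   attributes carry the window geometry and `omega_bar`.
#' @export
track_support <- function(swt, lambda = 5, kappa = 0, width_bins = swt$nv / 2,
                          omega_init = NULL) {
  stopifnot(inherits(swt, "swt_transform"))
  nb <- length(swt$bin_centers)
  nt <- length(swt$times)
  if (width_bins > nb) {
    stop("`width_bins` exceeds the number of frequency bins.", call. = FALSE)
  }
  hw <- floor(width_bins / 2)
  cand <- (hw + 1L):(nb - hw)
  ncand <- length(cand)
  f_bins <- swt$bin_centers
  amp <- Mod(swt$coeffs)

  sigma_g <- width_bins / 2
  offs <- -hw:hw
  gauss <- exp(-offs^2 / (2 * sigma_g^2))
  G <- matrix(0, nrow = ncand, ncol = nb)
  B <- matrix(0, nrow = ncand, ncol = nb)
  for (k in seq_along(cand)) {
    G[k, cand[k] + offs] <- gauss
    B[k, cand[k] + offs] <- 1
  }
  S <- G %*% amp            # Gaussian-weighted mass per candidate window
  W0 <- B %*% amp           # plain mass
  W1 <- B %*% (amp * f_bins)
  fwin <- W1 / W0  # amplitude-weighted window frequency
  fwin[W0 <= 0] <- NA_real_

  tot <- sum(amp)
  omega_bar <- if (tot > 0) sum(amp * f_bins) / tot else NA_real_
  lf <- log(f_bins[cand])
  mean_pen <- if (is.na(omega_bar)) rep(1, ncand) else exp(-kappa * abs(lf - log(omega_bar)))

  i_c <- integer(nt)
  freq_win <- rep(NA_real_, nt)
  valid <- logical(nt)
  omega_prev <- if (is.null(omega_init)) omega_bar else omega_init
  for (t in seq_len(nt)) {
    st <- S[, t]
    if (is.na(omega_prev) || max(st) <= 0) {
      i_c[t] <- NA_integer_
      valid[t] <- FALSE
      next
    }
    score <- st * exp(-lambda * abs(lf - log(omega_prev))) * mean_pen
    k <- which.max(score)  # first max = lowest frequency on ties
    i_c[t] <- cand[k]
    freq_win[t] <- fwin[k, t]
    valid[t] <- TRUE
    if (!is.na(fwin[k, t]) && fwin[k, t] > 0) omega_prev <- fwin[k, t]
  }

  out <- tibble::tibble(t_idx = seq_len(nt), i_c = i_c, freq_win = freq_win, valid = valid)
  attr(out, "width_bins") <- width_bins
  attr(out, "hw") <- hw
  attr(out, "lambda") <- lambda
  attr(out, "kappa") <- kappa
  attr(out, "omega_bar") <- omega_bar
  class(out) <- c("ridge_support", class(out))
  out
}

# Sum of complex SWT coefficients (times bin width) and amplitude-weighted
# frequency over the tracked support, vectorized over time.
support_sums <- function(swt, support) {
  hw <- attr(support, "hw")
  nt <- length(swt$times)
  nb <- length(swt$bin_centers)
  z <- complex(length.out = nt)
  a0 <- numeric(nt)
  a1 <- numeric(nt)
  tt <- seq_len(nt)
  ok <- support$valid & !is.na(support$i_c)
  for (off in -hw:hw) {
    rows <- support$i_c + off
    sel <- ok & rows >= 1L & rows <= nb
    idx <- cbind(rows[sel], tt[sel])
    w <- swt$coeffs[idx]
    dw <- swt$d_omega[rows[sel]]
    z[sel] <- z[sel] + w * dw
    a <- Mod(w)
    a0[sel] <- a0[sel] + a
    a1[sel] <- a1[sel] + a * swt$bin_centers[rows[sel]]
  }
  list(z = z, freq = ifelse(a0 > 0, a1 / a0, NA_real_), ok = ok)
}

#' Extract instantaneous phase and frequency from a tracked component
#'
#' The phase is the unwrapped argument of the summed complex synchrosqueezed
#' coefficients over the tracked support; the frequency is the
#' amplitude-weighted mean of the bin frequencies over the same support
#' (more accurate than the ridge centre when the component is non-uniformly
#' broadened). Both are sampled at the parent signal's rate. Times where the
#' support is invalid are filled by linear interpolation and flagged.
#'
#' @param swt A [synchrosqueeze()] result.
#' @param support A [track_support()] result for `swt`.
#' @return A tibble of class `phase_freq` with columns `time` (s), `phase`
#'   (rad, unwrapped), `freq` (Hz), `valid`; attribute `fs`.
#' @export
extract_phase_freq <- function(swt, support) {
  stopifnot(inherits(swt, "swt_transform"), inherits(support, "ridge_support"))
  s <- support_sums(swt, support)
  nt <- length(swt$times)
  ok <- s$ok & Mod(s$z) > 0 & is.finite(s$freq)
  if (!any(ok)) stop("No valid support anywhere: cannot extract a phase.", call. = FALSE)

  raw <- rep(NA_real_, nt)
  raw[ok] <- Arg(s$z[ok])
  freq <- s$freq
  # interpolate gaps (flagged) before unwrapping
  idx <- seq_len(nt)
  if (!all(ok)) {
    raw[!ok] <- stats::approx(idx[ok], raw[ok], xout = idx[!ok], rule = 2)$y
    freq[!ok] <- stats::approx(idx[ok], freq[ok], xout = idx[!ok], rule = 2)$y
  }
  phase <- unwrap_phase(raw)

  out <- tibble::tibble(time = swt$times, phase = phase, freq = freq, valid = ok)
  attr(out, "fs") <- swt$fs
  class(out) <- c("phase_freq", class(out))
  out
}

#' Unwrap a wrapped phase series
#'
#' Standard +/- pi branch correction on successive samples.
#'
#' @param x Phase values in radians.
#' @return Unwrapped phases (no jump between consecutive samples exceeds pi).
#' @export
unwrap_phase <- function(x) {
  d <- diff(x)
  d <- (d + pi) %% (2 * pi) - pi
  cumsum(c(x[1L], d))
}

#' Reconstruct the signal component under a tracked support
#'
#' Inverts the synchrosqueezed transform over the support bins only:
#' `x(t) = Re[(2 / Cpsi) * sum_(support) T(w_l, t) dw_l]`, which isolates the
#' tracked component (e.g. the ECG fundamental) from harmonics and other
#' components.
#'
#' @inheritParams extract_phase_freq
#' @return A [uniform_signal()] with the component waveform.
#' @export
reconstruct_component <- function(swt, support) {
  stopifnot(inherits(swt, "swt_transform"), inherits(support, "ridge_support"))
  s <- support_sums(swt, support)
  x <- Re((2 / swt$Cpsi) * s$z)
  x[!s$ok] <- 0
  uniform_signal(x, fs = swt$fs, t0 = swt$times[1L],
    label = paste0(swt$label, "_component"))
}
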