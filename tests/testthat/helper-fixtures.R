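# Shared fixtures, built in code.

# pure tone signal
tone_signal <- function(f0 = 1, fs = 25, duration = 120, amp = 1, phase0 = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  uniform_signal(amp * cos(2 * pi * f0 * t + phase0), fs = fs, label = "tone")
}

# count sharp positive peaks above a threshold (for R-peak counting)
count_peaks <- function(x, threshold = 0.5) {
  n <- length(x$values)
  v <- x$values
  sum(v[2:(n - 1)] > threshold & v[2:(n - 1)] >= v[1:(n - 2)] &
    v[2:(n - 1)] >= v[3:n])
}

# a window_inference object with prescribed coefficients (bypasses fitting);
# used to probe the metric layer with exactly known inputs
fake_window <- function(c_h = NULL, c_r = NULL, basis = build_basis()) {
  K <- nrow(basis)
  ch <- stats::setNames(rep(0, K), basis$label)
  cr <- stats::setNames(rep(0, K), basis$label)
  if (!is.null(c_h)) ch[names(c_h)] <- c_h
  if (!is.null(c_r)) cr[names(c_r)] <- c_r
  structure(
    list(
      c_h = ch, c_r = cr, coef = c(ch, cr),
      cov = diag(1e-6, 2 * K), E = diag(1e-4, 2),
      n_obs = 500L, h = 0.1, n_iter = 1L, converged = TRUE,
      basis = basis
    ),
    class = "window_inference"
  )
}

# wrap fake windows into an inference_sequence
fake_sequence <- function(windows, window_s = 50) {
  structure(
    list(
      windows = windows,
      t_start = (seq_along(windows) - 1) * window_s,
      t_mid = (seq_along(windows) - 1) * window_s + window_s / 2,
      window_s = window_s, p_w = 20, fs = 10,
      basis = windows[[1L]]$basis
    ),
    class = "inference_sequence"
  )
}

# standard small simulation used by several inference tests
rsa_simulation <- function(duration = 600, seed = 42) {
  simulate_phases(oscillator_spec(
    coeffs_h = coupling_term("sin", 0, 1, 0.5),
    noise_E = diag(0.01, 2), duration = duration, fs_phase = 10, seed = seed
  ))
}
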