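#' Specification of a pair of noisy coupled phase oscillators
#'
#' Defines the ground-truth model from which synthetic cardiorespiratory
#' phase trajectories are drawn:
#' \deqn{\dot\phi_h = \omega_h + q_h(\phi_h, \phi_r) + \xi_h(t)}
#' \deqn{\dot\phi_r = \omega_r + q_r(\phi_h, \phi_r) + \xi_r(t)}
#' where the coupling functions `q` are linear combinations of sin/cos terms
#' (see [coupling_term()]) and `xi` is white Gaussian noise with
#' \eqn{\langle \xi_i(t) \xi_j(\tau) \rangle = \delta(t-\tau) E_{ij}}.
#'
#' @param omega_h,omega_r Natural angular frequencies in rad/s. Defaults put
#'   the cardiac rate at 1.1 Hz and the respiratory rate at 0.25 Hz, inside
#'   the standard analysis bands.
#' @param coeffs_h,coeffs_r Coupling terms for each equation: a data frame
#'   with columns `kind, n, m, value` (rows from [coupling_term()]), or
#'   `NULL` for no coupling.
#' @param noise_E 2x2 symmetric positive semi-definite noise intensity
#'   matrix (rad^2/s); row/column 1 is the heart, 2 the respiration.
#' @param duration Record length in seconds.
#' @param fs_phase Sampling rate of the stored phase series (Hz).
#' @param seed Integer seed making the realization reproducible.
#' @return An object of class `oscillator_spec`.
#' @export
#' @examples
#' spec <- oscillator_spec(coeffs_h = coupling_term("sin", 0, 1, 0.5))
oscillator_spec <- function(omega_h = 2 * pi * 1.1,
                            omega_r = 2 * pi * 0.25,
                            coeffs_h = NULL,
                            coeffs_r = NULL,
                            noise_E = diag(0.01, 2),
                            duration = 300,
                            fs_phase = 50,
                            seed = 1L) {
  if (omega_h <= 0 || omega_r <= 0) {
    stop("Natural frequencies must be positive.", call. = FALSE)
  }
  if (duration * fs_phase < 2) {
    stop("`duration * fs_phase` must be at least 2 samples.", call. = FALSE)
  }
  noise_E <- as.matrix(noise_E)
  if (!all(dim(noise_E) == c(2L, 2L)) || max(abs(noise_E - t(noise_E))) > 1e-12) {
    stop("`noise_E` must be a symmetric 2x2 matrix.", call. = FALSE)
  }
  ev <- eigen(noise_E, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1)) {
    stop("`noise_E` is not positive semi-definite (eigenvalues ",
      paste(signif(ev, 3), collapse = ", "), ").", call. = FALSE)
  }
  check_coeffs <- function(x, nm) {
    if (is.null(x)) return(coupling_term("sin", 0, 1, 0)[0, ])
    x <- tibble::as_tibble(x)
    if (!all(c("kind", "n", "m", "value") %in% names(x))) {
      stop("`", nm, "` needs columns kind, n, m, value (see coupling_term()).",
        call. = FALSE)
    }
    x
  }
  structure(
    list(
      omega_h = omega_h, omega_r = omega_r,
      coeffs_h = check_coeffs(coeffs_h, "coeffs_h"),
      coeffs_r = check_coeffs(coeffs_r, "coeffs_r"),
      noise_E = noise_E, duration = duration,
      fs_phase = fs_phase, seed = as.integer(seed)
    ),
    class = "oscillator_spec"
  )
}

#' @export
print.oscillator_spec <- function(x, ...) {
  cat(sprintf(
    "<oscillator_spec> f_h=%.3g Hz, f_r=%.3g Hz, %d+%d coupling terms, %g s @ %g Hz, seed %d\n",
    x$omega_h / (2 * pi), x$omega_r / (2 * pi),
    nrow(x$coeffs_h), nrow(x$coeffs_r), x$duration, x$fs_phase, x$seed
  ))
  invisible(x)
}

# Matrix square root of a PSD matrix (tolerates semi-definite / zero noise,
# where chol() would fail).
psd_factor <- function(E) {
  e <- eigen(E, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate coupled phase trajectories
#'
#' Integrates the noisy coupled phase-oscillator model of an
#' [oscillator_spec()] with an internal step no larger than
#' `min(1/(20 f_h), 1/fs_phase)` so the fast (cardiac) cycle is well
#' resolved, and returns unwrapped phases sampled at `fs_phase`. Each
#' substep advances the drift by classical RK4 and then adds the Gaussian
#' noise increment `sqrt(dt) * L %*% z` (`L` the symmetric square root of
#' `noise_E`, `z` i.i.d. standard normal) — for additive noise the
#' increment term is exact, and the deterministic part converges at fourth
#' order, so step-halving changes noise-free trajectories only at the
#' 1e-4 rad level or below.
#'
#' @param spec An [oscillator_spec()].
#' @param n_substeps Override the number of internal integrator substeps per
#'   output sample (used e.g. for step-halving convergence checks).
#' @return An object of class `phase_sim`: a list with
#'   \describe{
#'     \item{phases}{tibble with columns `time`, `phi_h`, `phi_r` (rad,
#'       unwrapped),}
#'     \item{spec}{the generating spec (ground truth),}
#'     \item{fs}{the phase sampling rate.}
#'   }
#' @export
#' @examples
#' sim <- simulate_phases(oscillator_spec(duration = 60, fs_phase = 10))
#' head(sim$phases)
simulate_phases <- function(spec, n_substeps = NULL) {
  stopifnot(inherits(spec, "oscillator_spec"))
  f_h <- spec$omega_h / (2 * pi)
  dt_out <- 1 / spec$fs_phase
  n_sub <- max(1L, ceiling(dt_out / (1 / (20 * f_h))))
  if (!is.null(n_substeps)) n_sub <- as.integer(n_substeps)
  dt <- dt_out / n_sub
  n_out <- floor(spec$duration * spec$fs_phase)

  basis_h <- spec$coeffs_h
  basis_r <- spec$coeffs_r
  L <- psd_factor(spec$noise_E)
  noisy <- max(abs(L)) > 0

  # hoist coupling-term columns out of the inner loop
  nh <- basis_h$n; mh <- basis_h$m; vh <- basis_h$value
  sh <- basis_h$kind == "sin"
  nr <- basis_r$n; mr <- basis_r$m; vr <- basis_r$value
  sr <- basis_r$kind == "sin"
  drift <- function(ph, pr) {
    dh <- spec$omega_h
    dr <- spec$omega_r
    if (length(vh)) {
      arg <- nh * ph + mh * pr
      dh <- dh + sum(vh * (sh * sin(arg) + (!sh) * cos(arg)))
    }
    if (length(vr)) {
      arg <- nr * ph + mr * pr
      dr <- dr + sum(vr * (sr * sin(arg) + (!sr) * cos(arg)))
    }
    c(dh, dr)
  }

  set.seed(spec$seed)
  phi <- matrix(NA_real_, nrow = n_out + 1L, ncol = 2L)
  state <- c(0, 0)
  phi[1L, ] <- state
  sq <- sqrt(dt)
  for (i in seq_len(n_out)) {
    if (noisy) {
      z <- matrix(stats::rnorm(2L * n_sub), nrow = 2L)
      dw <- L %*% z * sq
    }
    for (k in seq_len(n_sub)) {
      # RK4 on the drift; the additive Gaussian increment is exact
      k1 <- drift(state[1L], state[2L])
      s2 <- state + dt / 2 * k1
      k2 <- drift(s2[1L], s2[2L])
      s3 <- state + dt / 2 * k2
      k3 <- drift(s3[1L], s3[2L])
      s4 <- state + dt * k3
      k4 <- drift(s4[1L], s4[2L])
      state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (noisy) state <- state + dw[, k]
    }
    phi[i + 1L, ] <- state
  }

  structure(
    list(
      phases = tibble::tibble(
        time = (0:n_out) * dt_out,
        phi_h = phi[, 1L],
        phi_r = phi[, 2L]
      ),
      spec = spec,
      fs = spec$fs_phase
    ),
    class = "phase_sim"
  )
}

#' @export
print.phase_sim <- function(x, ...) {
  cat(sprintf(
    "<phase_sim> %d samples @ %g Hz; final phases (%.1f, %.1f) rad\n",
    nrow(x$phases), x$fs,
    x$phases$phi_h[nrow(x$phases)], x$phases$phi_r[nrow(x$phases)]
  ))
  invisible(x)
}

#' ECG-like and respiration-like periodic waveform templates
#'
#' `ecg_waveform()` builds a 2*pi-periodic template from von-Mises-type bumps
#' `A * exp(kappa * (cos(theta - mu) - 1))`, by default five bumps imitating
#' the P, Q, R, S, T deflections with a dominant sharp R peak at phase 0.
#' `cosine_waveform()` is a plain (quasi-sinusoidal) respiration template.
#'
#' @param bumps Data frame with columns `mu` (bump centre, rad), `A`
#'   (amplitude), `kappa` (concentration; larger = narrower).
#' @return A function of phase `theta` (rad), vectorized, 2*pi-periodic.
#' @export
#' @examples
#' tpl <- ecg_waveform()
#' theta <- seq(0, 2 * pi, length.out = 200)
#' plot(theta, tpl(theta), type = "l")
ecg_waveform <- function(bumps = NULL) {
  if (is.null(bumps)) {
    bumps <- data.frame(
      mu = c(-2.0, -0.35, 0.0, 0.35, 1.6),
      A = c(0.15, -0.10, 1.00, -0.15, 0.30),
      kappa = c(30, 120, 60, 120, 15)
    )
  }
  force(bumps)
  function(theta) {
    out <- numeric(length(theta))
    for (i in seq_len(nrow(bumps))) {
      out <- out + bumps$A[i] * exp(bumps$kappa[i] * (cos(theta - bumps$mu[i]) - 1))
    }
    out
  }
}

#' @rdname ecg_waveform
#' @export
cosine_waveform <- function() {
  function(theta) cos(theta)
}

#' Specification of the measurement model
#'
#' Turns phase trajectories into observable signals: the ECG channel is the
#' ECG template evaluated at the cardiac phase; the respiration channel is
#' the respiration waveform at the respiratory phase plus, optionally, a
#' leaked copy of the ECG template mimicking the direct mechanical influence
#' of heart beats on a respiratory measuring belt. Independent Gaussian
#' amplitude noise is added to both channels.
#'
#' @param fs_signal Output sampling rate (Hz).
#' @param ecg_template,resp_waveform 2*pi-periodic template functions, see
#'   [ecg_waveform()] and [cosine_waveform()].
#' @param artefact_level Fraction of the ECG template amplitude leaked into
#'   the respiration channel (>= 0; 0 disables the artefact).
#' @param amplitude_noise_sd Standard deviation of additive measurement
#'   noise on both channels (template units).
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(fs_signal = 50,
                        ecg_template = ecg_waveform(),
                        resp_waveform = cosine_waveform(),
                        artefact_level = 0,
                        amplitude_noise_sd = 0.01) {
  if (artefact_level < 0) stop("`artefact_level` must be >= 0.", call. = FALSE)
  if (fs_signal <= 0) stop("`fs_signal` must be positive.", call. = FALSE)
  structure(
    list(
      fs_signal = fs_signal, ecg_template = ecg_template,
      resp_waveform = resp_waveform, artefact_level = artefact_level,
      amplitude_noise_sd = amplitude_noise_sd
    ),
    class = "signal_spec"
  )
}

#' Synthesize ECG-like and respiration-like signals from phases
#'
#' @param sim A [simulate_phases()] result.
#' @param spec A [signal_spec()].
#' @param seed Seed for the measurement noise (defaults to the simulation
#'   seed + 1 so phase noise and measurement noise are independent).
#' @return A list with elements `ecg` and `resp`, both [uniform_signal()]s
#'   sampled at `spec$fs_signal`.
#' @export
#' @examples
#' sim <- simulate_phases(oscillator_spec(duration = 30, fs_phase = 50))
#' sig <- synthesize_signals(sim, signal_spec())
synthesize_signals <- function(sim, spec = signal_spec(), seed = NULL) {
  stopifnot(inherits(sim, "phase_sim"), inherits(spec, "signal_spec"))
  f_h <- sim$spec$omega_h / (2 * pi)
  if (spec$fs_signal < 4 * f_h) {
    stop(sprintf(
      "`fs_signal` = %g Hz is below 4x the cardiac frequency (%g Hz): aliasing.",
      spec$fs_signal, f_h
    ), call. = FALSE)
  }
  t_out <- seq(0, max(sim$phases$time), by = 1 / spec$fs_signal)
  ph <- stats::approx(sim$phases$time, sim$phases$phi_h, xout = t_out)$y
  pr <- stats::approx(sim$phases$time, sim$phases$phi_r, xout = t_out)$y

  if (is.null(seed)) seed <- sim$spec$seed + 1L
  set.seed(seed)
  n <- length(t_out)
  ecg_v <- spec$ecg_template(ph %% (2 * pi)) +
    stats::rnorm(n, sd = spec$amplitude_noise_sd)
  resp_v <- spec$resp_waveform(pr %% (2 * pi)) +
    spec$artefact_level * spec$ecg_template(ph %% (2 * pi)) +
    stats::rnorm(n, sd = spec$amplitude_noise_sd)

  list(
    ecg = uniform_signal(ecg_v, fs = spec$fs_signal, label = "ecg"),
    resp = uniform_signal(resp_v, fs = spec$fs_signal, label = "resp")
  )
}

#' Specification of a synthetic cohort
#'
#' Describes an age-graded population of synthetic subjects. Ages are drawn
#' uniformly over `age_range`; each model parameter listed in `trend` is
#' drawn as `base + slope * (age - age_range[1]) + N(0, scatter)`, truncated
#' at zero where negative values would be unphysical. The defaults emulate
#' the qualitative ageing pattern of cardiorespiratory coupling: the direct
#' respiratory modulation of heart rate (RSA) declines with age, the
#' indirect (both-phase) modulation declines more slowly, and the influence
#' of the heart on respiration is age-independent.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param age_range Two ages in years, non-degenerate.
#' @param trend Named list; each element is `list(base=, slope=, scatter=)`
#'   for one of the parameters `rsa_amp` (coefficient of `sin(phi_r)` in the
#'   heart equation, rad/s), `ind_amp` (coefficient of `sin(phi_h + phi_r)`
#'   in the heart equation), `h2r_amp` (coefficient of `sin(phi_h)` in the
#'   respiration equation), `self_h_amp` (coefficient of `sin(phi_h)` in the
#'   heart equation).
#' @param duration,fs_phase,fs_signal,noise_level,artefact_level,amplitude_noise_sd
#'   Per-subject simulation and measurement settings; `noise_level` is the
#'   common diagonal of the phase-noise matrix `E` (rad^2/s).
#' @param freq_jitter_sd Two standard deviations (Hz) of the between-subject
#'   scatter of cardiac and respiratory natural frequencies.
#' @param seed Integer seed; the whole cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100L,
                        age_range = c(16, 90),
                        trend = list(
                          rsa_amp = list(base = 0.5, slope = -0.005, scatter = 0.05),
                          ind_amp = list(base = 0.25, slope = -0.001, scatter = 0.05),
                          h2r_amp = list(base = 0.15, slope = 0, scatter = 0.05),
                          self_h_amp = list(base = 0.10, slope = 0, scatter = 0.03)
                        ),
                        duration = 250,
                        fs_phase = 25,
                        fs_signal = 25,
                        noise_level = 0.01,
                        artefact_level = 0,
                        amplitude_noise_sd = 0.01,
                        freq_jitter_sd = c(0.1, 0.03),
                        seed = 1L) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2.", call. = FALSE)
  if (length(age_range) != 2L || diff(range(age_range)) <= 0) {
    stop("`age_range` must span a non-degenerate interval.", call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), age_range = sort(as.numeric(age_range)),
      trend = trend, duration = duration, fs_phase = fs_phase,
      fs_signal = fs_signal, noise_level = noise_level,
      artefact_level = artefact_level, amplitude_noise_sd = amplitude_noise_sd,
      freq_jitter_sd = freq_jitter_sd, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Draws ages, genders, per-subject model parameters and per-subject seeds
#' from a [cohort_spec()]. The result is bit-reproducible: the same spec
#' always yields the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `cohort` with one row per subject: `subject_id`,
#'   `age`, `gender`, the drawn parameter columns (`rsa_amp`, `ind_amp`,
#'   `h2r_amp`, `self_h_amp`, `f_h`, `f_r`), `seed`, and a list-column
#'   `model` of [oscillator_spec()]s. The generating spec is attached as
#'   attribute `"spec"`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 5, duration = 60))
#' cohort[c("subject_id", "age", "rsa_amp")]
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  gender <- sample(c("male", "female"), n, replace = TRUE)
  draw <- function(tr) {
    pmax(0, tr$base + tr$slope * (age - spec$age_range[1]) +
      stats::rnorm(n, sd = tr$scatter))
  }
  rsa_amp <- draw(spec$trend$rsa_amp)
  ind_amp <- draw(spec$trend$ind_amp)
  h2r_amp <- draw(spec$trend$h2r_amp)
  self_h_amp <- draw(spec$trend$self_h_amp)
  f_h <- pmax(0.7, 1.1 + stats::rnorm(n, sd = spec$freq_jitter_sd[1]))
  f_r <- pmax(0.12, 0.25 + stats::rnorm(n, sd = spec$freq_jitter_sd[2]))
  subj_seed <- sample.int(2^30, n)

  models <- lapply(seq_len(n), function(i) {
    oscillator_spec(
      omega_h = 2 * pi * f_h[i],
      omega_r = 2 * pi * f_r[i],
      coeffs_h = dplyr::bind_rows(
        coupling_term("sin", 0, 1, rsa_amp[i]),
        coupling_term("sin", 1, 1, ind_amp[i]),
        coupling_term("sin", 1, 0, self_h_amp[i])
      ),
      coeffs_r = coupling_term("sin", 1, 0, h2r_amp[i]),
      noise_E = diag(spec$noise_level, 2),
      duration = spec$duration,
      fs_phase = spec$fs_phase,
      seed = subj_seed[i]
    )
  })

  out <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = age, gender = gender,
    rsa_amp = rsa_amp, ind_amp = ind_amp, h2r_amp = h2r_amp,
    self_h_amp = self_h_amp, f_h = f_h, f_r = f_r,
    seed = subj_seed, model = models
  )
  attr(out, "spec") <- spec
  class(out) <- c("cohort", class(out))
  out
}

#' Synthesize the two-channel recording of one cohort subject
#'
#' @param subject One row of a [generate_cohort()] tibble.
#' @param spec The generating [cohort_spec()] (defaults to the attribute
#'   carried by the cohort row's source).
#' @return A list `(ecg, resp, sim)`: the two [uniform_signal()] channels and
#'   the underlying [simulate_phases()] truth.
#' @export
synthesize_subject <- function(subject, spec = NULL) {
  model <- subject$model[[1L]]
  if (is.null(spec)) spec <- attr(subject, "spec")
  stopifnot(inherits(model, "oscillator_spec"))
  fs_signal <- if (!is.null(spec)) spec$fs_signal else model$fs_phase
  artefact <- if (!is.null(spec)) spec$artefact_level else 0
  amp_sd <- if (!is.null(spec)) spec$amplitude_noise_sd else 0.01
  sim <- simulate_phases(model)
  sig <- synthesize_signals(
    sim,
    signal_spec(
      fs_signal = fs_signal, artefact_level = artefact,
      amplitude_noise_sd = amp_sd
    )
  )
  list(ecg = sig$ecg, resp = sig$resp, sim = sim)
}

#' Write a cohort to disk as CSV signals plus a manifest
#'
#' Writes per-subject signal CSVs (see [write_signal_csv()]), a JSON sidecar
#' with each subject's ground-truth parameters, and a `manifest.csv` with
#' columns `subject_id, age, gender, ecg_file, resp_file`.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spec <- attr(cohort, "spec")
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    rec <- synthesize_subject(subj, spec)
    ecg_file <- file.path(dir, paste0(subj$subject_id, "_ecg.csv"))
    resp_file <- file.path(dir, paste0(subj$subject_id, "_resp.csv"))
    write_signal_csv(rec$ecg, ecg_file)
    write_signal_csv(rec$resp, resp_file)
    truth <- subj$model[[1L]]
    jsonlite::write_json(
      list(
        subject_id = subj$subject_id, age = subj$age, gender = subj$gender,
        seed = truth$seed, fs_phase = truth$fs_phase,
        omega_h = truth$omega_h, omega_r = truth$omega_r,
        coeffs_h = truth$coeffs_h, coeffs_r = truth$coeffs_r,
        noise_E = truth$noise_E
      ),
      file.path(dir, paste0(subj$subject_id, "_truth.json")),
      auto_unbox = TRUE, digits = NA
    )
    data.frame(
      subject_id = subj$subject_id, age = subj$age, gender = subj$gender,
      ecg_file = basename(ecg_file), resp_file = basename(resp_file)
    )
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
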