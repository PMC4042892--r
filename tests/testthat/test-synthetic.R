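test_that("zero-noise uncoupled oscillator grows linearly in phase", {
  spec <- oscillator_spec(
    omega_h = 2 * pi * 1.1, noise_E = diag(0, 2),
    duration = 100, fs_phase = 10, seed = 1
  )
  sim <- simulate_phases(spec)
  expect_equal(
    sim$phases$phi_h,
    2 * pi * 1.1 * sim$phases$time,
    tolerance = 1e-6
  )
})

test_that("integrator converges: halving the step changes phases < 1e-4 rad", {
  spec <- oscillator_spec(
    coeffs_h = coupling_term("sin", 0, 1, 0.5),
    coeffs_r = coupling_term("sin", 1, 0, 0.3),
    noise_E = diag(0, 2), duration = 100, fs_phase = 10, seed = 1
  )
  a <- simulate_phases(spec, n_substeps = 4L)
  b <- simulate_phases(spec, n_substeps = 8L)
  expect_lt(max(abs(a$phases$phi_h - b$phases$phi_h)), 1e-4)
  expect_lt(max(abs(a$phases$phi_r - b$phases$phi_r)), 1e-4)
})

test_that("phase-noise variance grows like a Wiener process", {
  # var(phi_h(t) - omega_h t) ~ E_hh * t
  t_end <- 100
  reps <- 100
  dev <- vapply(seq_len(reps), function(r) {
    sim <- simulate_phases(oscillator_spec(
      noise_E = diag(c(0.01, 0), 2), duration = t_end, fs_phase = 10,
      seed = 1000 + r
    ))
    n <- nrow(sim$phases)
    sim$phases$phi_h[n] - 2 * pi * 1.1 * sim$phases$time[n]
  }, numeric(1L))
  v <- stats::var(dev)
  expect_gt(v, 0.01 * t_end * 0.7)
  expect_lt(v, 0.01 * t_end * 1.3)
})

test_that("strong n:m coupling locks the phase difference (Adler dynamics)", {
  # psi = phi_h / 4 - phi_r; d(psi)/dt = -0.4 sin(4 psi) + detuning 0
  sim <- simulate_phases(oscillator_spec(
    omega_h = 4, omega_r = 1,
    coeffs_h = coupling_term("sin", 1, -4, -1.6),
    noise_E = diag(1e-4, 2), duration = 200, fs_phase = 10, seed = 2
  ))
  psi <- sim$phases$phi_h / 4 - sim$phases$phi_r
  after <- sim$phases$time > 20
  # the trajectory starts on the stable branch psi* = 0 and must stay there
  expect_lt(max(abs(psi[after])), 0.5)
})

test_that("phases are monotone when coupling + noise stay below omega", {
  sim <- simulate_phases(oscillator_spec(
    coeffs_h = coupling_term("sin", 0, 1, 0.5),
    noise_E = diag(0.01, 2), duration = 120, fs_phase = 10, seed = 3
  ))
  expect_true(all(diff(sim$phases$phi_h) > 0))
  expect_true(all(diff(sim$phases$phi_r) > 0))
  expect_true(all(is.finite(sim$phases$phi_h)))
})

test_that("non-PSD noise matrices are rejected with a diagnostic", {
  expect_error(
    oscillator_spec(noise_E = matrix(c(0.01, 0.05, 0.05, 0.01), 2)),
    "positive semi-definite"
  )
  expect_error(
    oscillator_spec(noise_E = matrix(c(0.01, 0.02, 0.01, 0.01), 2)),
    "symmetric"
  )
})

test_that("synthesized ECG has one R peak per cardiac cycle", {
  sim <- simulate_phases(oscillator_spec(
    omega_h = 2 * pi * 1.0, noise_E = diag(0, 2),
    duration = 300, fs_phase = 25, seed = 1
  ))
  sig <- synthesize_signals(sim, signal_spec(fs_signal = 25, amplitude_noise_sd = 0.005))
  expect_lte(abs(count_peaks(sig$ecg, 0.5) - 300), 1)
})

test_that("without artefact the respiration channel has no cardiac-band power", {
  sim <- simulate_phases(oscillator_spec(
    noise_E = diag(0.005, 2), duration = 200, fs_phase = 25, seed = 5
  ))
  sig <- synthesize_signals(sim,
    signal_spec(fs_signal = 25, artefact_level = 0, amplitude_noise_sd = 0))
  x <- sig$resp$values - mean(sig$resp$values)
  sp <- Mod(stats::fft(x))^2
  fr <- (seq_along(x) - 1) * sig$resp$fs / length(x)
  in_band <- fr >= 0.4 & fr <= 2.1
  expect_lt(sum(sp[in_band]) / sum(sp[fr > 0 & fr <= sig$resp$fs / 2]), 0.01)
})

test_that("artefact leakage adds exactly the scaled ECG template to respiration", {
  sim <- simulate_phases(oscillator_spec(
    noise_E = diag(0.005, 2), duration = 200, fs_phase = 25, seed = 5
  ))
  spec0 <- signal_spec(fs_signal = 25, artefact_level = 0, amplitude_noise_sd = 0)
  spec2 <- signal_spec(fs_signal = 25, artefact_level = 0.2, amplitude_noise_sd = 0)
  clean <- synthesize_signals(sim, spec0, seed = 9)
  leaked <- synthesize_signals(sim, spec2, seed = 9)
  # same noise seed: the difference is exactly 0.2 * template(phi_h)
  expect_equal(
    leaked$resp$values - clean$resp$values,
    0.2 * clean$ecg$values,
    tolerance = 1e-12
  )
  expect_equal(leaked$ecg$values, clean$ecg$values)
})

test_that("undersampled signal synthesis is rejected", {
  sim <- simulate_phases(oscillator_spec(duration = 10, fs_phase = 25))
  expect_error(
    synthesize_signals(sim, signal_spec(fs_signal = 4)),
    "aliasing"
  )
})

test_that("cohort generation is bit-reproducible and respects trends", {
  spec <- cohort_spec(n_subjects = 100, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$age, b$age)
  expect_identical(a$rsa_amp, b$rsa_amp)
  expect_identical(a$seed, b$seed)

  # default slope -0.005/yr, scatter 0.05: strong negative rank correlation
  tr <- spearman_trend(a$age, a$rsa_amp)
  expect_lt(tr$rho, -0.5)

  # flat trend: correlation indistinguishable from zero
  flat <- cohort_spec(n_subjects = 100, seed = 8)
  flat$trend$rsa_amp$slope <- 0
  c0 <- generate_cohort(flat)
  expect_lt(abs(spearman_trend(c0$age, c0$rsa_amp)$rho), 0.2)
})

test_that("cohort signals round-trip through the CSV interface", {
  cohort <- generate_cohort(cohort_spec(
    n_subjects = 2, duration = 20, fs_phase = 25, seed = 3
  ))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(cohort, dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2L)
  s <- read_signal_csv(file.path(dir, man$ecg_file[1L]))
  rec <- synthesize_subject(cohort[1L, ], attr(cohort, "spec"))
  expect_equal(s$values, rec$ecg$values, tolerance = 1e-6)
  expect_equal(s$fs, rec$ecg$fs)
})
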