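test_that("noise-free constant-frequency phases recover omega exactly", {
  h <- 0.1
  t <- seq(0, 50, by = h)
  b <- build_basis(0, NULL)
  w <- infer_window(2 * pi * 1.1 * t, 2 * pi * 0.25 * t, h, b)
  expect_equal(w$c_h[["const"]], 2 * pi * 1.1, tolerance = 1e-6)
  expect_equal(w$c_r[["const"]], 2 * pi * 0.25, tolerance = 1e-6)
  expect_true(w$converged)
})

test_that("coupling coefficients and noise are recovered from simulation", {
  sim <- rsa_simulation()
  sq <- infer_sequence(sim$phases, window_s = 50, p_w = 20,
    basis = build_basis(), decimate_to = 10)
  expect_length(sq$windows, 12L)

  cs <- vapply(sq$windows, function(w) w$c_h[["sin(r)"]], numeric(1L))
  expect_lt(abs(mean(cs) - 0.5), 0.1)  # within 20% of the true 0.5

  # every truly-zero coupling coefficient averages close to zero
  zero_terms <- setdiff(names(sq$windows[[1L]]$c_h), c("const", "sin(r)"))
  zmeans <- rowMeans(vapply(sq$windows, function(w) w$c_h[zero_terms],
    numeric(length(zero_terms))))
  expect_lt(max(abs(zmeans)), 0.1)

  # inferred noise intensity within a factor 1.5 of the true 0.01
  Es <- vapply(sq$windows, function(w) w$E[1, 1], numeric(1L))
  expect_gt(mean(Es), 0.01 / 1.5)
  expect_lt(mean(Es), 0.01 * 1.5)
})

test_that("posterior covariance stays symmetric PSD and inference is deterministic", {
  sim <- rsa_simulation(duration = 150)
  sq1 <- infer_sequence(sim$phases, basis = build_basis(1, NULL))
  sq2 <- infer_sequence(sim$phases, basis = build_basis(1, NULL))
  for (w in sq1$windows) {
    ev <- eigen(w$cov, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(ev))
  }
  expect_identical(
    vapply(sq1$windows, function(w) w$coef, numeric(18L)),
    vapply(sq2$windows, function(w) w$coef, numeric(18L))
  )
})

test_that("prior propagation reproduces the stated limits", {
  sim <- rsa_simulation(duration = 120)
  b <- build_basis(1, NULL)
  sq <- infer_sequence(sim$phases, window_s = 50, basis = b)
  win <- sq$windows[[1L]]

  # p_w = 0: full propagation, the prior IS the posterior
  p0 <- propagate_prior(win, 0)
  expect_identical(p0$mean, as.numeric(win$coef))
  expect_equal(p0$cov, win$cov)

  # stated inflation rule: prior variance = (1 + p_w^2) x posterior variance
  p20 <- propagate_prior(win, 20)
  expect_equal(diag(p20$cov), (1 + 20^2) * diag(win$cov))
  expect_error(propagate_prior(win, -1), "non-negative")

  # p_w large: indistinguishable from a flat-prior (independent) inference
  h <- 1 / sq$fs
  n_per <- round(50 * sq$fs)
  sel <- (n_per + 1L):(2L * n_per)
  ph <- sim$phases[seq(1L, nrow(sim$phases), by = floor(sim$fs / 10)), ]
  flat <- infer_window(ph$phi_h[sel], ph$phi_r[sel], h, b)
  prior_big <- propagate_prior(win, 1e5)
  carried <- infer_window(ph$phi_h[sel], ph$phi_r[sel], h, b, prior = prior_big)
  rel <- abs(carried$coef - flat$coef) / max(abs(flat$coef))
  expect_lt(max(rel), 0.01)
})

test_that("window bookkeeping: counts, trailing remainder, short records", {
  sim <- rsa_simulation(duration = 600)
  sq <- infer_sequence(sim$phases, window_s = 50)
  expect_length(sq$windows, 12L)
  expect_equal(sq$t_start, seq(0, 550, by = 50))

  expect_error(
    infer_sequence(rsa_simulation(duration = 30)$phases, window_s = 50),
    "shorter than one"
  )
})

test_that("window-to-window scatter shrinks with window length", {
  sim <- rsa_simulation(duration = 800, seed = 9)
  b <- build_basis(1, NULL)
  short <- infer_sequence(sim$phases, window_s = 40, basis = b)
  long <- infer_sequence(sim$phases, window_s = 80, basis = b)
  sd_short <- stats::sd(vapply(short$windows, function(w) w$c_h[["sin(r)"]],
    numeric(1L)))
  sd_long <- stats::sd(vapply(long$windows, function(w) w$c_h[["sin(r)"]],
    numeric(1L)))
  expect_lt(sd_long, sd_short)
})

test_that("a step change in coupling is followed within two windows", {
  # two stationary halves glued together: 0.2 then 0.8 x sin(phi_r)
  a <- simulate_phases(oscillator_spec(
    coeffs_h = coupling_term("sin", 0, 1, 0.2),
    noise_E = diag(0.005, 2), duration = 300, fs_phase = 10, seed = 21
  ))
  b <- simulate_phases(oscillator_spec(
    coeffs_h = coupling_term("sin", 0, 1, 0.8),
    noise_E = diag(0.005, 2), duration = 300, fs_phase = 10, seed = 22
  ))
  glued <- dplyr::bind_rows(
    a$phases,
    tibble::tibble(
      time = b$phases$time + max(a$phases$time) + 0.1,
      phi_h = b$phases$phi_h + max(a$phases$phi_h),
      phi_r = b$phases$phi_r + max(a$phases$phi_r)
    )
  )
  sq <- infer_sequence(glued, window_s = 50, basis = build_basis(1, NULL))
  # gluing shifts the absolute phases, rotating the coupling between the
  # sin and cos terms: compare first-harmonic amplitudes
  amp <- vapply(sq$windows, function(w) {
    sqrt(w$c_h[["sin(r)"]]^2 + w$c_h[["cos(r)"]]^2)
  }, numeric(1L))
  expect_lt(mean(amp[1:5]), 0.45)
  # settled at the new level within two windows of the step (window 7)
  expect_gt(mean(amp[9:12]), 0.55)
})

test_that("tidy and glance expose the fitted model in broom shape", {
  sim <- rsa_simulation(duration = 120)
  sq <- infer_sequence(sim$phases, basis = build_basis(1, NULL))
  td <- tidy(sq)
  expect_true(all(c("window", "equation", "term", "estimate", "std.error",
    "part") %in% names(td)))
  expect_equal(nrow(td), length(sq$windows) * 2L * 9L)
  gl <- glance(sq)
  expect_true(all(c("E_hh", "E_rr", "converged") %in% names(gl)))
  expect_true(all(gl$converged))
})
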