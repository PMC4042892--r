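test_that("uncoupled detuned flow gives a rigid-rotation return map", {
  w <- fake_window(c_h = c(const = 4), c_r = c(const = 1.13))
  mp <- sync_map(w, 4, 1, grid_size = 16)
  shift <- mp$M - mp$psi0
  expect_lt(diff(range(shift)), 1e-3)
  # rotation by the detuning over one sum cycle:
  # d(psi)/d(sigma) = (1 - 1.13) / (1 + 1.13)
  expect_equal(mean(shift), 2 * pi * (1 - 1.13) / (1 + 1.13), tolerance = 1e-3)
  expect_false(as.logical(detect_sync(w, 4, 1, grid_size = 16)))
})

test_that("return map of a locked system has degree 1 and a stable root", {
  # Adler flow: d(psi)/dt = -0.4 sin(4 psi), locked at sin(4 psi*) = 0
  w <- fake_window(
    c_h = c(const = 4, `sin(h-4r)` = -1.6),
    c_r = c(const = 1)
  )
  mp <- sync_map(w, 4, 1, grid_size = 32)
  expect_false(anyNA(mp$M))
  # circle-map degree 1: M(psi + 2 pi) = M(psi) + 2 pi
  b <- cardioresp:::make_sync_batch(list(w), rep(1L, 32), rep(4, 32), rep(1, 32))
  m_shift <- cardioresp:::sync_integrate(b, mp$psi0 + 2 * pi)
  expect_lt(max(abs(m_shift - mp$M - 2 * pi)), 1e-6)

  det <- detect_sync(w, 4, 1, grid_size = 32)
  expect_true(as.logical(det))
  slopes <- attr(det, "slopes")
  roots <- attr(det, "roots")
  expect_true(any(abs(slopes) < 1))
  # roots sit where sin(4 psi) = 0
  expect_lt(max(abs(sin(4 * roots))), 1e-3)
})

test_that("locked simulations are detected and uncoupled ones are not", {
  locked <- simulate_phases(oscillator_spec(
    omega_h = 4, omega_r = 1,
    coeffs_h = coupling_term("sin", 1, -4, -1.6),
    noise_E = diag(0.01, 2), duration = 300, fs_phase = 10, seed = 3
  ))
  sq_l <- infer_sequence(locked$phases, window_s = 50, basis = build_basis())
  st_l <- sync_table(sq_l, ratios = default_sync_ratios()[2, ])
  expect_gte(mean(st_l$synchronized), 0.9)

  uncoupled <- simulate_phases(oscillator_spec(
    omega_h = 4, omega_r = 1.25,
    noise_E = diag(0.01, 2), duration = 300, fs_phase = 10, seed = 4
  ))
  sq_u <- infer_sequence(uncoupled$phases, window_s = 50, basis = build_basis())
  st_u <- sync_table(sq_u, ratios = default_sync_ratios()[2, ])
  expect_lte(mean(st_u$synchronized), 0.1)

  # durations are quantized in window units and sum across ratios
  d <- sync_durations(st_l)
  expect_true(all(d$duration * length(sq_l$windows) ==
    round(d$duration * length(sq_l$windows))))
  expect_equal(
    d$duration[d$ratio == "overall"],
    sum(d$duration[d$ratio != "overall"])
  )
})

test_that("detect_sync agrees with long-integration boundedness of psi", {
  # oracle: integrate the inferred deterministic flow for 100 sum cycles;
  # synchronization <=> psi stays bounded (within a period of its start)
  windows <- list(
    fake_window(c_h = c(const = 4, `sin(h-4r)` = -1.6), c_r = c(const = 1)),
    fake_window(c_h = c(const = 4), c_r = c(const = 1.13)),
    fake_window(c_h = c(const = 4, `sin(h-4r)` = -0.1), c_r = c(const = 1.05)),
    fake_window(c_h = c(const = 4.4, `sin(h-4r)` = -1.0), c_r = c(const = 1))
  )
  for (w in windows) {
    det <- as.logical(detect_sync(w, 4, 1, grid_size = 32))
    flow <- function(ph, pr) {
      v <- evaluate_basis(w$basis, ph, pr)[1L, ]
      c(sum(v * w$c_h), sum(v * w$c_r))
    }
    state <- c(0.3 * 4 / 2, -0.3 / 2)  # psi0 = 0.3 on the sum = 0 section
    dt <- 2 * pi / (200 * (flow(state[1], state[2])[1] / 4 + flow(state[1], state[2])[2]))
    psi <- numeric(20000)
    for (i in seq_len(20000)) {
      k1 <- flow(state[1], state[2])
      k2 <- flow(state[1] + dt / 2 * k1[1], state[2] + dt / 2 * k1[2])
      k3 <- flow(state[1] + dt / 2 * k2[1], state[2] + dt / 2 * k2[2])
      k4 <- flow(state[1] + dt * k3[1], state[2] + dt * k3[2])
      state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      psi[i] <- state[1] / 4 - state[2]
    }
    bounded <- diff(range(psi)) < 2 * pi / 4
    expect_equal(det, bounded)
  }
})

test_that("coupling norms, decomposition and directionality follow their definitions", {
  b <- build_basis()
  # heart-equation coefficients (3, 4) on two phi_r-dependent terms
  w <- fake_window(c_h = c(`sin(r)` = 3, `sin(h+r)` = 4), basis = b)
  nm <- coupling_norms(w)
  expect_equal(nm$eps_r2h, 5)
  expect_equal(nm$eps_h2r, 0)
  expect_equal(nm$D, 1)
  expect_equal(nm$eps_dir_h, 3)  # sin(r) is the direct (RSA) part
  expect_equal(nm$eps_ind_h, 4)  # sin(h+r) is indirect

  # mirror-symmetric coefficients: D = 0
  w2 <- fake_window(
    c_h = c(`sin(r)` = 3, `sin(h+r)` = 4),
    c_r = c(`sin(h)` = 3, `sin(h+r)` = 4), basis = b
  )
  expect_equal(coupling_norms(w2)$D, 0)

  # self and constant terms enter no norm
  w3 <- fake_window(c_h = c(const = 7, `sin(h)` = 2, `cos(2h)` = 1), basis = b)
  nm3 <- coupling_norms(w3)
  expect_equal(nm3$eps_r2h, 0)
  expect_false(nm3$d_defined)
  expect_true(is.na(nm3$D))

  # D is antisymmetric under swapping the oscillator labels
  swapped <- fake_window(
    c_h = c(`sin(r)` = 3, `sin(h+r)` = 4) * 0,
    c_r = c(`sin(h)` = 3, `sin(h+r)` = 4), basis = b
  )
  expect_equal(coupling_norms(swapped)$D, -1)
  # and invariant to overall rescaling
  w4 <- fake_window(
    c_h = c(`sin(r)` = 0.3, `sin(h+r)` = 0.4),
    c_r = c(`sin(h)` = 0.1), basis = b
  )
  w5 <- fake_window(
    c_h = c(`sin(r)` = 3, `sin(h+r)` = 4),
    c_r = c(`sin(h)` = 1), basis = b
  )
  expect_equal(coupling_norms(w4)$D, coupling_norms(w5)$D)
})

test_that("directionality of simulated unidirectional coupling is correctly signed", {
  r2h <- simulate_phases(oscillator_spec(
    coeffs_h = coupling_term("sin", 0, 1, 0.5),
    noise_E = diag(0.01, 2), duration = 600, fs_phase = 10, seed = 5
  ))
  nm <- coupling_norms(infer_sequence(r2h$phases, basis = build_basis()))
  expect_gte(mean(nm$D > 0), 0.95)

  h2r <- simulate_phases(oscillator_spec(
    coeffs_r = coupling_term("sin", 1, 0, 0.5),
    noise_E = diag(0.01, 2), duration = 600, fs_phase = 10, seed = 6
  ))
  nm2 <- coupling_norms(infer_sequence(h2r$phases, basis = build_basis()))
  expect_gte(mean(nm2$D < 0), 0.95)
})

test_that("RSA shape descriptors convert harmonics to amplitude-phase form", {
  b <- build_basis()
  # A sin(phi_r + alpha) + B sin(2 phi_r + beta) with known parameters
  A <- 0.6; alpha <- 0.8; B <- 0.15; beta <- -1.1
  w <- fake_window(c_h = c(
    `sin(r)` = A * cos(alpha), `cos(r)` = A * sin(alpha),
    `sin(2r)` = B * cos(beta), `cos(2r)` = B * sin(beta)
  ), basis = b)
  rs <- rsa_shape(fake_sequence(list(w, w, w)))
  expect_equal(rs$A, rep(A, 3))
  expect_equal(rs$B, rep(B, 3))
  expect_equal(rs$alpha, rep(alpha, 3))
  expect_equal(rs$beta, rep(beta, 3))
  sm <- glance(rs)
  expect_equal(sm$mean_ba, B / A)
  expect_equal(sm$gamma, 1)  # constant harmonic phases: gamma = 1

  # pure first harmonic: B/A stays near zero
  w1 <- fake_window(c_h = c(`sin(r)` = 0.5), basis = b)
  expect_lt(glance(rsa_shape(fake_sequence(list(w1, w1))))$mean_ba, 0.1)

  # random alpha across windows, beta fixed: gamma collapses
  set.seed(8)
  wins <- lapply(stats::runif(100, -pi, pi), function(al) {
    fake_window(c_h = c(
      `sin(r)` = 0.5 * cos(al), `cos(r)` = 0.5 * sin(al), `sin(2r)` = 0.1
    ), basis = b)
  })
  expect_lt(glance(rsa_shape(fake_sequence(wins)))$gamma, 0.2)

  # near-zero first harmonic windows are excluded and counted
  w0 <- fake_window(c_h = c(`sin(2r)` = 0.1), basis = b)
  rs0 <- rsa_shape(fake_sequence(list(w0, w)))
  expect_equal(glance(rs0)$n_excluded, 1L)
})

test_that("coupling-function surfaces evaluate the inferred model on the torus", {
  b <- build_basis()
  w <- fake_window(c_h = c(const = 2 * pi, `sin(r)` = 0.5), basis = b)
  g <- coupling_grid(w, resolution = 32)
  # rows constant in phi_h; each column is 0.5 sin(phi_r); omega excluded
  expect_lt(max(abs(sweep(g$q_h, 2, 0.5 * sin(g$phi_r)))), 1e-12)
  expect_lt(max(abs(g$q_r)), 1e-12)
  # torus mean of any pure sin/cos surface vanishes
  expect_lt(abs(mean(g$q_h)), 1e-12)

  # time-averaged grid equals the grid of time-averaged coefficients
  w2 <- fake_window(c_h = c(const = 2 * pi, `sin(r)` = 0.1, `cos(h+r)` = 0.3),
    basis = b)
  gavg <- coupling_grid(fake_sequence(list(w, w2)), resolution = 32)
  gw <- coupling_grid(w, resolution = 32)
  gw2 <- coupling_grid(w2, resolution = 32)
  expect_equal(gavg$q_h, (gw$q_h + gw2$q_h) / 2, tolerance = 1e-12)
})
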