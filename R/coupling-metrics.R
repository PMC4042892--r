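#' Synchronization return map M(psi) of an inferred window
#'
#' For an `n:m` locking ratio, fixes the slow phase difference
#' `psi = phi_h / n - phi_r / m`, integrates the *deterministic* inferred
#' system (noise off) from the initial condition on the `sum = 0` section
#' until the sum coordinate `phi_h / n + phi_r / m` has advanced by `2 pi`,
#' and records the final `phi_h / n - phi_r / m`. Synchronization
#' corresponds to a stable fixed point of this circle map (see
#' [detect_sync()]).
#'
#' Integration is explicit RK4 on the 2-D flow with a time step of 1/200 of
#' the nominal sum-coordinate cycle; the final crossing of `2 pi` is located
#' by linear interpolation. A trajectory whose sum coordinate stops
#' advancing (derivative sign change), or which has not crossed within
#' `max_cycles` nominal cycles, is indeterminate.
#'
#' @param window A [infer_window()] result.
#' @param n,m Integer locking ratio (`n` cardiac cycles : `m` respiratory).
#' @param grid_size Number of initial `psi` values on `[0, 2 pi)`.
#' @param n_steps Integration steps per sum-coordinate cycle.
#' @return A tibble of class `sync_map` with columns `psi0`, `M`
#'   (final psi, rad; `NA` where that trajectory is indeterminate).
#'   Attribute `indeterminate` is `TRUE` only when the map failed at every
#'   grid point (the whole window is indeterminate);
#'   `frac_indeterminate` gives the failed fraction. Away from the region
#'   explored by the data the inferred flow is prior-dominated and single
#'   trajectories may legitimately fail; root finding simply skips them.
#' @export
sync_map <- function(window, n, m, grid_size = 64L, n_steps = 200L) {
  stopifnot(inherits(window, "window_inference"))
  psi0 <- 2 * pi * (seq_len(grid_size) - 1L) / grid_size
  batch <- make_sync_batch(list(window), rep(1L, grid_size),
    rep(n, grid_size), rep(m, grid_size))
  M <- sync_integrate(batch, psi0, n_steps = n_steps)
  out <- tibble::tibble(psi0 = psi0, M = M)
  attr(out, "indeterminate") <- all(is.na(M))
  attr(out, "frac_indeterminate") <- mean(is.na(M))
  attr(out, "ratio") <- c(n = n, m = m)
  class(out) <- c("sync_map", class(out))
  out
}

# Column batch for the vectorized deterministic flow: every column is one
# trajectory with its own source window (coefficients) and locking ratio.
make_sync_batch <- function(windows, widx, n, m) {
  basis <- windows[[1L]]$basis
  i_sin <- which(basis$kind == "sin")
  i_cos <- which(basis$kind == "cos")
  i_const <- which(basis$kind == "const")
  CH <- vapply(windows, function(w) as.numeric(w$c_h), numeric(nrow(basis)))
  CR <- vapply(windows, function(w) as.numeric(w$c_r), numeric(nrow(basis)))
  CH <- CH[, widx, drop = FALSE]
  CR <- CR[, widx, drop = FALSE]
  list(
    CHS = CH[i_sin, , drop = FALSE], CHC = CH[i_cos, , drop = FALSE],
    ch0 = colSums(CH[i_const, , drop = FALSE]),
    CRS = CR[i_sin, , drop = FALSE], CRC = CR[i_cos, , drop = FALSE],
    cr0 = colSums(CR[i_const, , drop = FALSE]),
    nS = basis$n[i_sin], mS = basis$m[i_sin],
    nC = basis$n[i_cos], mC = basis$m[i_cos],
    n = n, m = m, G = length(widx)
  )
}

# Subset a sync batch to selected columns.
sync_batch_cols <- function(b, j) {
  list(
    CHS = b$CHS[, j, drop = FALSE], CHC = b$CHC[, j, drop = FALSE],
    ch0 = b$ch0[j],
    CRS = b$CRS[, j, drop = FALSE], CRC = b$CRC[, j, drop = FALSE],
    cr0 = b$cr0[j],
    nS = b$nS, mS = b$mS, nC = b$nC, mC = b$mC,
    n = b$n[j], m = b$m[j], G = length(j)
  )
}

# Integrate all columns of a batch from the sum = 0 section (state
# phi_h = n psi0 / 2, phi_r = -m psi0 / 2) to sum = 2 pi.
# Returns final psi per column, NA where indeterminate.
sync_integrate <- function(batch, psi0, n_steps = 200L, max_cycles = 3L) {
  G <- batch$G
  stopifnot(length(psi0) == G)
  b <- batch
  n <- b$n
  m <- b$m
  flow <- function(ph, pr) {
    S <- sin(outer(b$nS, ph) + outer(b$mS, pr))
    C <- cos(outer(b$nC, ph) + outer(b$mC, pr))
    list(
      dh = colSums(b$CHS * S) + colSums(b$CHC * C) + b$ch0,
      dr = colSums(b$CRS * S) + colSums(b$CRC * C) + b$cr0
    )
  }
  ph <- n * psi0 / 2
  pr <- -m * psi0 / 2
  d0 <- flow(ph, pr)
  rate0 <- d0$dh / n + d0$dr / m
  out <- rep(NA_real_, G)
  live <- which(is.finite(rate0) & rate0 > 0)
  if (!length(live)) return(out)

  # work only on still-running trajectories; `live` maps columns to output
  b <- sync_batch_cols(b, live)
  n <- b$n; m <- b$m
  ph <- ph[live]; pr <- pr[live]
  dt <- 2 * pi / (n_steps * rate0[live])
  sigma <- numeric(length(live))

  for (step in seq_len(max_cycles * n_steps)) {
    k1 <- flow(ph, pr)
    k2 <- flow(ph + dt / 2 * k1$dh, pr + dt / 2 * k1$dr)
    k3 <- flow(ph + dt / 2 * k2$dh, pr + dt / 2 * k2$dr)
    k4 <- flow(ph + dt * k3$dh, pr + dt * k3$dr)
    ph_new <- ph + dt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh)
    pr_new <- pr + dt / 6 * (k1$dr + 2 * k2$dr + 2 * k3$dr + k4$dr)
    sig_new <- ph_new / n + pr_new / m

    stalled <- sig_new < sigma
    crossed <- !stalled & sig_new >= 2 * pi
    if (any(crossed)) {
      f <- (2 * pi - sigma[crossed]) / (sig_new[crossed] - sigma[crossed])
      psi_a <- ph[crossed] / n[crossed] - pr[crossed] / m[crossed]
      psi_b <- ph_new[crossed] / n[crossed] - pr_new[crossed] / m[crossed]
      out[live[crossed]] <- psi_a + f * (psi_b - psi_a)
    }
    keep <- !(stalled | crossed)
    if (!any(keep)) return(out)
    if (!all(keep)) {
      kidx <- which(keep)
      b <- sync_batch_cols(b, kidx)
      live <- live[kidx]
      n <- n[kidx]; m <- m[kidx]
      ph <- ph_new[kidx]; pr <- pr_new[kidx]
      sigma <- sig_new[kidx]; dt <- dt[kidx]
    } else {
      ph <- ph_new
      pr <- pr_new
      sigma <- sig_new
    }
  }
  out
}

#' Detect n:m phase synchronization in an inferred window
#'
#' There is (most probably) synchronization at ratio `n:m` if the return map
#' [sync_map()] has a fixed point `M(psi*) = psi*` that is stable,
#' `|dM/dpsi| < 1` at the root. Roots are located by scanning the wrapped
#' displacement `M(psi) - psi` for sign changes between adjacent determinate
#' grid points (ignoring +/- pi branch jumps), refining each by bisection,
#' and checking the slope by central difference.
#'
#' @inheritParams sync_map
#' @param map Optionally a precomputed [sync_map()] for this window/ratio.
#' @param bisect_tol Bisection tolerance on psi (rad).
#' @return A logical scalar with attributes `indeterminate` (`TRUE` when the
#'   map could not be evaluated anywhere; counted as not synchronized),
#'   `roots` (refined fixed points) and `slopes` (dM/dpsi at each root).
#' @export
detect_sync <- function(window, n, m, grid_size = 64L, map = NULL,
                        bisect_tol = 1e-6) {
  if (is.null(map)) map <- sync_map(window, n, m, grid_size = grid_size)
  if (isTRUE(attr(map, "indeterminate"))) {
    out <- FALSE
    attr(out, "indeterminate") <- TRUE
    return(out)
  }
  cand <- sync_candidates(map$psi0, map$M)
  if (!nrow(cand)) {
    out <- FALSE
    attr(out, "indeterminate") <- FALSE
    attr(out, "roots") <- numeric(0)
    attr(out, "slopes") <- numeric(0)
    return(out)
  }
  batch <- make_sync_batch(list(window), rep(1L, nrow(cand)),
    rep(n, nrow(cand)), rep(m, nrow(cand)))
  ref <- sync_refine(batch, cand, bisect_tol)

  ok <- !is.na(ref$slopes)
  out <- any(abs(ref$slopes[ok]) < 1)
  attr(out, "indeterminate") <- FALSE
  attr(out, "roots") <- ref$roots[ok]
  attr(out, "slopes") <- ref$slopes[ok]
  out
}

# Sign-change candidate intervals of the wrapped displacement M(psi) - psi.
sync_candidates <- function(psi0, M) {
  wrap <- function(x) Arg(exp(1i * x))
  d <- wrap(M - psi0)
  g <- length(d)
  nxt <- c(2:g, 1L)
  i <- which(!is.na(d) & !is.na(d[nxt]) &
    sign(d) * sign(d[nxt]) < 0 & abs(d - d[nxt]) < pi)
  dpsi <- psi0[2L] - psi0[1L]
  data.frame(lo = psi0[i], hi = psi0[i] + dpsi, flo = d[i])
}

# Vectorized bisection + slope estimation on a column batch whose columns
# match the rows of `cand`.
sync_refine <- function(batch, cand, bisect_tol = 1e-6, slope_delta = 0.01) {
  wrap <- function(x) Arg(exp(1i * x))
  lo <- cand$lo
  hi <- cand$hi
  flo <- cand$flo
  alive <- rep(TRUE, length(lo))
  while (any(alive & (hi - lo > bisect_tol))) {
    alive <- alive & (hi - lo > bisect_tol)
    mid <- (lo + hi) / 2
    fmid <- wrap(sync_integrate(batch, mid) - mid)
    dead <- alive & is.na(fmid)
    alive[dead] <- FALSE  # keep the current bracket midpoint as estimate
    upd <- alive & !is.na(fmid)
    same <- upd & sign(fmid) == sign(flo)
    oth <- upd & !same
    lo[same] <- mid[same]
    flo[same] <- fmid[same]
    hi[oth] <- mid[oth]
  }
  roots <- (lo + hi) / 2
  k <- length(roots)
  dbl <- sync_batch_cols(batch, rep(seq_len(k), 2L))
  m_pm <- sync_integrate(dbl, c(roots + slope_delta, roots - slope_delta))
  slopes <- (m_pm[seq_len(k)] - m_pm[k + seq_len(k)]) / (2 * slope_delta)
  list(roots = roots, slopes = slopes)
}

#' Synchronization table over an inference sequence
#'
#' Runs the return-map synchronization test for every window and every
#' ratio (all trajectories integrated in one vectorized batch) and
#' summarizes the relative synchronization duration. Durations are
#' quantized in units of the window length: the per-ratio duration is
#' (synchronized windows x window length) / total analysed time, and the
#' overall duration is the sum over ratios.
#'
#' @param seq An [infer_sequence()] result.
#' @param ratios Ratio table as in [default_sync_ratios()].
#' @param grid_size Initial psi grid per window/ratio.
#' @return A tibble of class `sync_table`: one row per window x ratio with
#'   columns `window`, `t_mid`, `ratio`, `n`, `m`, `synchronized`,
#'   `indeterminate`. The per-ratio and overall relative durations are in
#'   attribute `"durations"` (also via [sync_durations()]).
#' @export
sync_table <- function(seq, ratios = default_sync_ratios(), grid_size = 64L) {
  stopifnot(inherits(seq, "inference_sequence"))
  ratios <- tibble::as_tibble(ratios)
  if (!"label" %in% names(ratios)) {
    ratios$label <- paste0(ratios$n, ":", ratios$m)
  }
  W <- length(seq$windows)
  R <- nrow(ratios)
  combos <- expand.grid(w = seq_len(W), r = seq_len(R))
  psi_grid <- 2 * pi * (seq_len(grid_size) - 1L) / grid_size

  # one big batch: columns = combo x psi grid point
  widx <- rep(combos$w, each = grid_size)
  nvec <- rep(ratios$n[combos$r], each = grid_size)
  mvec <- rep(ratios$m[combos$r], each = grid_size)
  psi0 <- rep(psi_grid, nrow(combos))
  batch <- make_sync_batch(seq$windows, widx, nvec, mvec)
  M <- sync_integrate(batch, psi0)

  # per-combo candidate intervals, then one batched refinement
  cand_list <- lapply(seq_len(nrow(combos)), function(k) {
    sel <- ((k - 1L) * grid_size + 1L):(k * grid_size)
    cc <- sync_candidates(psi0[sel], M[sel])
    if (nrow(cc)) cc$combo <- k
    cc
  })
  cand <- dplyr::bind_rows(cand_list)
  synchronized <- rep(FALSE, nrow(combos))
  if (nrow(cand)) {
    rbatch <- make_sync_batch(
      seq$windows, combos$w[cand$combo],
      ratios$n[combos$r[cand$combo]], ratios$m[combos$r[cand$combo]]
    )
    ref <- sync_refine(rbatch, cand)
    hit <- !is.na(ref$slopes) & abs(ref$slopes) < 1
    synchronized[unique(cand$combo[hit])] <- TRUE
  }
  indeterminate <- vapply(seq_len(nrow(combos)), function(k) {
    sel <- ((k - 1L) * grid_size + 1L):(k * grid_size)
    all(is.na(M[sel]))
  }, logical(1L))

  out <- tibble::tibble(
    window = combos$w, t_mid = seq$t_mid[combos$w],
    ratio = ratios$label[combos$r], n = ratios$n[combos$r],
    m = ratios$m[combos$r],
    synchronized = synchronized & !indeterminate,
    indeterminate = indeterminate
  )
  out <- dplyr::arrange(out, .data$window, .data$n, .data$m)
  per_ratio <- out |>
    dplyr::group_by(.data$ratio) |>
    dplyr::summarise(duration = mean(.data$synchronized), .groups = "drop")
  durations <- dplyr::bind_rows(
    per_ratio,
    tibble::tibble(ratio = "overall", duration = sum(per_ratio$duration))
  )
  attr(out, "durations") <- durations
  class(out) <- c("sync_table", class(out))
  out
}

#' @rdname sync_table
#' @param x A `sync_table`.
#' @return `sync_durations()` returns the per-ratio relative durations plus
#'   an `"overall"` row (sum over ratios).
#' @export
sync_durations <- function(x) {
  stopifnot(inherits(x, "sync_table"))
  attr(x, "durations")
}

#' Coupling strengths, decomposition and directionality per window
#'
#' From the inferred coefficients of each window computes the Euclidean
#' norms of designated coefficient subsets:
#' \describe{
#'   \item{`eps_r2h`}{heart-equation coefficients on all terms that depend
#'     on `phi_r` (the direct + indirect influence of respiration on the
#'     heart),}
#'   \item{`eps_h2r`}{respiration-equation coefficients on all terms
#'     depending on `phi_h`,}
#'   \item{`eps_dir_h`, `eps_ind_h`}{the direct (RSA) and indirect parts of
#'     `eps_r2h`; likewise `eps_dir_r`, `eps_ind_r`,}
#'   \item{`D`}{the directionality index
#'     `(eps_r2h - eps_h2r) / (eps_r2h + eps_h2r)` in `[-1, 1]`, positive
#'     when respiration drives the heart more than conversely. Windows with
#'     both strengths below `1e-8` rad/s are flagged undefined.}
#' }
#' Self-interaction and constant terms enter no norm.
#'
#' @param seq An [infer_sequence()] result (or a single [infer_window()]).
#' @return A tibble of class `coupling_metrics`: one row per window with the
#'   columns above plus `window`, `t_mid`, `d_defined`.
#' @export
coupling_norms <- function(seq) {
  if (inherits(seq, "window_inference")) {
    seq <- list(windows = list(seq), t_mid = NA_real_, basis = seq$basis)
  } else {
    stopifnot(inherits(seq, "inference_sequence"))
  }
  basis <- seq$basis
  enorm <- function(x) sqrt(sum(x^2))
  rows <- lapply(seq_along(seq$windows), function(w) {
    win <- seq$windows[[w]]
    dep_r <- basis$m != 0  # terms depending on phi_r
    dep_h <- basis$n != 0
    eps_r2h <- enorm(win$c_h[dep_r])
    eps_h2r <- enorm(win$c_r[dep_h])
    tot <- eps_r2h + eps_h2r
    tibble::tibble(
      window = w, t_mid = seq$t_mid[w],
      eps_r2h = eps_r2h, eps_h2r = eps_h2r,
      eps_dir_h = enorm(win$c_h[basis$part_h == "direct"]),
      eps_ind_h = enorm(win$c_h[basis$part_h == "indirect"]),
      eps_dir_r = enorm(win$c_r[basis$part_r == "direct"]),
      eps_ind_r = enorm(win$c_r[basis$part_r == "indirect"]),
      D = if (tot < 1e-8) NA_real_ else (eps_r2h - eps_h2r) / tot,
      d_defined = tot >= 1e-8
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("coupling_metrics", class(out))
  out
}

#' Shape of the direct (RSA) coupling term
#'
#' Represents the inferred direct modulation of the heart by respiration as
#' a two-harmonic waveform per window,
#' \deqn{d_h(\phi_r, t) = A(t) \sin(\phi_r + \alpha(t)) +
#'   B(t) \sin(2 \phi_r + \beta(t)),}
#' converting the (sin, cos) coefficient pairs of the first and second
#' harmonic to amplitude--phase form (`A = sqrt(c_sin^2 + c_cos^2)`,
#' `alpha = atan2(c_cos, c_sin)`). Shape descriptors:
#' the harmonic-amplitude ratio `B/A` (how non-sinusoidal the RSA waveform
#' is), its across-window mean and standard deviation, and the harmonic
#' phase coherence
#' \deqn{\gamma = \left| \langle e^{i(2\alpha(t) - \beta(t))} \rangle
#'   \right| \in [0, 1],}
#' which is 1 when the two harmonics keep a fixed mutual phase across
#' windows.
#'
#' @param seq An [infer_sequence()] result.
#' @param equation `"h"` (default; harmonics of `phi_r` in the heart
#'   equation, i.e. the RSA term `d_h`) or `"r"` (harmonics of `phi_h` in
#'   the respiration equation, `d_r`).
#' @param a_floor Windows with first-harmonic amplitude below this floor are
#'   excluded from the `B/A` summary (counted in `n_excluded`).
#' @return A tibble of class `rsa_shape`: per window `A`, `B`, `alpha`,
#'   `beta`, `ba`; attribute `"summary"` (also via `glance()`) holds
#'   `mean_ba`, `sd_ba`, `gamma`, `n_excluded`.
#' @export
rsa_shape <- function(seq, equation = c("h", "r"), a_floor = 1e-6) {
  stopifnot(inherits(seq, "inference_sequence"))
  equation <- match.arg(equation)
  basis <- seq$basis
  pick <- function(kind, k) {
    if (equation == "h") {
      which(basis$kind == kind & basis$n == 0 & basis$m == k)
    } else {
      which(basis$kind == kind & basis$n == k & basis$m == 0)
    }
  }
  i_s1 <- pick("sin", 1L); i_c1 <- pick("cos", 1L)
  i_s2 <- pick("sin", 2L); i_c2 <- pick("cos", 2L)
  if (!all(lengths(list(i_s1, i_c1, i_s2, i_c2)) == 1L)) {
    stop("Basis lacks the first/second-harmonic direct terms; use order >= 2.",
      call. = FALSE)
  }
  coefs <- if (equation == "h") {
    lapply(seq$windows, function(w) w$c_h)
  } else {
    lapply(seq$windows, function(w) w$c_r)
  }
  rows <- lapply(seq_along(coefs), function(w) {
    cc <- unname(coefs[[w]])
    A <- sqrt(cc[i_s1]^2 + cc[i_c1]^2)
    B <- sqrt(cc[i_s2]^2 + cc[i_c2]^2)
    tibble::tibble(
      window = w, t_mid = seq$t_mid[w],
      A = A, B = B,
      alpha = atan2(cc[i_c1], cc[i_s1]),
      beta = atan2(cc[i_c2], cc[i_s2]),
      ba = if (A >= a_floor) B / A else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$ba)
  gamma <- Mod(mean(exp(1i * (2 * out$alpha - out$beta))))
  attr(out, "summary") <- tibble::tibble(
    mean_ba = mean(out$ba[ok]),
    sd_ba = stats::sd(out$ba[ok]),
    gamma = gamma,
    n_excluded = sum(!ok),
    equation = equation
  )
  class(out) <- c("rsa_shape", class(out))
  out
}

#' Reconstructed coupling-function surfaces
#'
#' Evaluates the inferred coupling functions `q_h` and `q_r` (all basis
#' terms except the constant) on a uniform `(phi_h, phi_r)` grid over
#' `[0, 2 pi)^2`, either per window or time-averaged over the sequence
#' (the average of the per-window surfaces, which equals the surface of the
#' time-averaged coefficients).
#'
#' @param seq An [infer_sequence()] result or a single [infer_window()].
#' @param resolution Grid points per axis (>= 16).
#' @param average If `TRUE` (default) return the time-averaged surfaces;
#'   otherwise a list of per-window surfaces.
#' @return An object of class `coupling_grid` (or a list of them): list with
#'   `phi_h`, `phi_r` (grid vectors) and matrices `q_h`, `q_r`
#'   (rows index `phi_h`), in rad/s.
#' @export
coupling_grid <- function(seq, resolution = 64L, average = TRUE) {
  if (resolution < 16L) stop("`resolution` must be >= 16.", call. = FALSE)
  if (inherits(seq, "window_inference")) {
    return(coupling_grid_one(seq$c_h, seq$c_r, seq$basis, resolution))
  }
  stopifnot(inherits(seq, "inference_sequence"))
  if (average) {
    c_h <- rowMeans(vapply(seq$windows, function(w) w$c_h,
      numeric(nrow(seq$basis))))
    c_r <- rowMeans(vapply(seq$windows, function(w) w$c_r,
      numeric(nrow(seq$basis))))
    coupling_grid_one(c_h, c_r, seq$basis, resolution)
  } else {
    lapply(seq$windows, function(w) {
      coupling_grid_one(w$c_h, w$c_r, seq$basis, resolution)
    })
  }
}

coupling_grid_one <- function(c_h, c_r, basis, resolution) {
  g <- 2 * pi * (seq_len(resolution) - 1L) / resolution
  grid <- expand.grid(phi_h = g, phi_r = g)
  keep <- basis$kind != "const"
  Phi <- evaluate_basis(basis[keep, ], grid$phi_h, grid$phi_r)
  q_h <- matrix(Phi %*% c_h[keep], nrow = resolution)
  q_r <- matrix(Phi %*% c_r[keep], nrow = resolution)
  structure(
    list(phi_h = g, phi_r = g, q_h = q_h, q_r = q_r),
    class = "coupling_grid"
  )
}

#' @export
print.coupling_grid <- function(x, ...) {
  cat(sprintf(
    "<coupling_grid> %d x %d; range q_h [%.3g, %.3g], q_r [%.3g, %.3g] rad/s\n",
    length(x$phi_h), length(x$phi_r),
    min(x$q_h), max(x$q_h), min(x$q_r), max(x$q_r)
  ))
  invisible(x)
}

#' Write a coupling grid to CSV matrix files with axis headers
#'
#' @param grid A [coupling_grid()] result.
#' @param path_h,path_r Output CSV paths for `q_h` and `q_r`.
#' @return Invisibly, the two paths.
#' @export
write_coupling_grid <- function(grid, path_h, path_r) {
  stopifnot(inherits(grid, "coupling_grid"))
  wr <- function(m, path) {
    d <- as.data.frame(m)
    names(d) <- sprintf("phi_r_%.4f", grid$phi_r)
    d <- cbind(phi_h = grid$phi_h, d)
    utils::write.csv(d, path, row.names = FALSE)
  }
  wr(grid$q_h, path_h)
  wr(grid$q_r, path_r)
  invisible(c(path_h, path_r))
}
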