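#' Wavelet phase coherence between two transforms
#'
#' For each frequency, the modulus of the time-averaged unit phasor of the
#' phase difference between the two wavelet transforms:
#' \deqn{WPC(f) = \left| \langle e^{i(\arg W_A(f,t) - \arg W_B(f,t))}
#'   \rangle_t \right| \in [0, 1].}
#' Amplitudes play no role, so the measure is invariant to any per-channel
#' rescaling. To avoid bias from the frequency-dependent cone of influence,
#' time averaging is restricted, at every frequency, to the admissible
#' interval of the lowest frequency on the grid (the most conservative
#' choice; low-frequency coherence is already biased upward by the small
#' number of cycles in a record, which is why significance must come from
#' surrogates, see [intersubject_threshold()]).
#'
#' @param wtA,wtB [compute_wt()] results on identical frequency and time
#'   grids (same channels lengths and sampling).
#' @return A tibble of class `coherence_result` with columns `freq` (Hz),
#'   `wpc`, `n_effective` (time samples averaged).
#' @export
#' @examples
#' fs <- 20; t <- seq(0, 120 - 1/fs, by = 1/fs)
#' a <- uniform_signal(cos(2 * pi * t), fs)
#' wpc(compute_wt(a, 0.5, 2), compute_wt(a, 0.5, 2))$wpc  # all 1
wpc <- function(wtA, wtB) {
  stopifnot(inherits(wtA, "wavelet_transform"), inherits(wtB, "wavelet_transform"))
  if (length(wtA$freqs) != length(wtB$freqs) ||
    max(abs(log(wtA$freqs / wtB$freqs))) > 1e-8) {
    stop("The two transforms are on different frequency grids.", call. = FALSE)
  }
  if (length(wtA$times) != length(wtB$times)) {
    stop("The two transforms have different time axes.", call. = FALSE)
  }
  # common admissible interval for the lowest frequency
  j_slow <- which.min(wtA$freqs)
  lo <- max(wtA$coi_lo[j_slow], wtB$coi_lo[j_slow])
  hi <- min(wtA$coi_hi[j_slow], wtB$coi_hi[j_slow])
  if (hi <= lo) {
    stop("Record too short: no time interval is admissible at the lowest frequency.",
      call. = FALSE)
  }
  sel <- lo:hi
  P <- wtA$coeffs[, sel, drop = FALSE] * Conj(wtB$coeffs[, sel, drop = FALSE])
  m <- Mod(P)
  nz <- m > 0
  P[nz] <- P[nz] / m[nz]
  P[!nz] <- 0 + 0i
  n_eff <- rowSums(nz)
  s <- rowSums(P)
  out <- tibble::tibble(
    freq = wtA$freqs,
    wpc = ifelse(n_eff > 0, Mod(s) / n_eff, NA_real_),
    n_effective = n_eff
  )
  out <- dplyr::arrange(out, .data$freq)
  class(out) <- c("coherence_result", class(out))
  out
}

#' Intersubject surrogate threshold for wavelet phase coherence
#'
#' Estimates the per-frequency significance level of a genuine WPC by
#' recomputing the coherence on channel pairs taken from *different*
#' subjects, which are necessarily independent while retaining realistic
#' single-channel structure. With cyclic pairing, subject `i`'s first
#' channel is paired with subject `i + 1`'s second channel (mod N), yielding
#' exactly N surrogate values; `pairing = "all"` uses every ordered
#' mismatched pair instead. The threshold is the direct rank-ordered
#' percentile of the surrogate values (no normality assumption).
#'
#' @param wtsA,wtsB Lists (one element per subject, same order) of
#'   [compute_wt()] results for the two channels, all on a common grid.
#' @param percentile Significance percentile (default 95).
#' @param pairing `"cyclic"` (N surrogates) or `"all"` (N(N-1) surrogates).
#' @return An object of class `surrogate_ensemble`: list with `freqs`,
#'   `values` (frequency x surrogate matrix), `threshold` (per-frequency
#'   rank-ordered percentile), `percentile`, `pairing`.
#' @export
intersubject_threshold <- function(wtsA, wtsB, percentile = 95,
                                   pairing = c("cyclic", "all")) {
  pairing <- match.arg(pairing)
  n <- length(wtsA)
  if (length(wtsB) != n) stop("`wtsA` and `wtsB` must have equal length.", call. = FALSE)
  if (n < 2L) stop("Need at least 2 subjects for intersubject surrogates.", call. = FALSE)
  pairs <- if (pairing == "cyclic") {
    cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  } else {
    g <- expand.grid(i = seq_len(n), j = seq_len(n))
    as.matrix(g[g$i != g$j, , drop = FALSE])
  }
  vals <- vapply(
    seq_len(nrow(pairs)),
    function(k) wpc(wtsA[[pairs[k, 1L]]], wtsB[[pairs[k, 2L]]])$wpc,
    numeric(length(wtsA[[1L]]$freqs))
  )
  freqs <- sort(wtsA[[1L]]$freqs)
  thr <- apply(vals, 1L, rank_percentile, p = percentile)
  structure(
    list(
      freqs = freqs, values = vals, threshold = thr,
      percentile = percentile, pairing = pairing, n_subjects = n
    ),
    class = "surrogate_ensemble"
  )
}

# Rank-ordered percentile: the ceiling(p/100 * n)-th order statistic.
rank_percentile <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p / 100 * length(x)))]
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(
    "<surrogate_ensemble> %d surrogate pairs (%s pairing), %d frequencies, %gth percentile\n",
    ncol(x$values), x$pairing, length(x$freqs), x$percentile
  ))
  invisible(x)
}

#' Default physiological frequency bands
#'
#' Band edges (Hz) delimiting, from slow to fast: (V) endothelial,
#' (IV) neurogenic, (III) myogenic, (II) respiratory, (I) cardiac activity.
#' These are configuration defaults, not constants; pass your own edges to
#' [band_summary()] where appropriate.
#'
#' @return Named list with `edges` (length 6, ascending) and `labels`
#'   (length 5, matching the ascending bands: `"V"` slowest ... `"I"`
#'   cardiac).
#' @export
physiological_bands <- function() {
  list(
    edges = c(0.0095, 0.021, 0.052, 0.145, 0.6, 2),
    labels = c("V", "IV", "III", "II", "I")
  )
}

#' Per-band peak coherence and its significance
#'
#' @param result A [wpc()] result.
#' @param ensemble Optional [intersubject_threshold()] ensemble on the same
#'   frequency grid; if omitted, significance flags are `NA`.
#' @param band_edges Ascending band edges in Hz.
#' @param band_labels Labels, one fewer than edges; defaults to the
#'   physiological convention (I cardiac ... V endothelial) when the edges
#'   are the defaults, otherwise to `"band1"`, `"band2"`, ...
#' @return A tibble with one row per band: `band`, `f_lo`, `f_hi`,
#'   `peak_wpc`, `peak_freq`, `threshold` (at the peak frequency),
#'   `significant`.
#' @export
band_summary <- function(result, ensemble = NULL,
                         band_edges = physiological_bands()$edges,
                         band_labels = NULL) {
  stopifnot(inherits(result, "coherence_result"))
  if (is.unsorted(band_edges, strictly = TRUE)) {
    stop("`band_edges` must be strictly increasing.", call. = FALSE)
  }
  nb <- length(band_edges) - 1L
  if (is.null(band_labels)) {
    band_labels <- if (identical(band_edges, physiological_bands()$edges)) {
      physiological_bands()$labels  # ascending edges: V (slowest) ... I (cardiac)
    } else {
      paste0("band", seq_len(nb))
    }
  }
  thr_at <- function(f) {
    if (is.null(ensemble)) return(NA_real_)
    ensemble$threshold[which.min(abs(ensemble$freqs - f))]
  }
  rows <- lapply(seq_len(nb), function(b) {
    sel <- result$freq >= band_edges[b] & result$freq < band_edges[b + 1L] &
      is.finite(result$wpc)
    if (!any(sel)) {
      return(tibble::tibble(
        band = band_labels[b], f_lo = band_edges[b], f_hi = band_edges[b + 1L],
        peak_wpc = NA_real_, peak_freq = NA_real_, threshold = NA_real_,
        significant = NA
      ))
    }
    w <- result$wpc[sel]
    f <- result$freq[sel]
    k <- which.max(w)
    thr <- thr_at(f[k])
    tibble::tibble(
      band = band_labels[b], f_lo = band_edges[b], f_hi = band_edges[b + 1L],
      peak_wpc = w[k], peak_freq = f[k], threshold = thr,
      significant = if (is.na(thr)) NA else w[k] > thr
    )
  })
  dplyr::bind_rows(rows)
}

#' Flag per-frequency significance of a coherence result
#'
#' @inheritParams band_summary
#' @return The coherence tibble with extra columns `threshold` and
#'   `significant`.
#' @export
wpc_significance <- function(result, ensemble) {
  stopifnot(inherits(result, "coherence_result"), inherits(ensemble, "surrogate_ensemble"))
  if (length(ensemble$freqs) != nrow(result) ||
    max(abs(log(ensemble$freqs / result$freq))) > 1e-8) {
    stop("Ensemble and result are on different frequency grids.", call. = FALSE)
  }
  out <- result
  out$threshold <- ensemble$threshold
  out$significant <- out$wpc > out$threshold
  out
}
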