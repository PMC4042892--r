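#' Analysis configuration
#'
#' Collects every tunable constant of the analysis chain in one list, with
#' defaults mirroring the standard settings: 64 voices per octave, analysis
#' bands [0.4, 2.1] Hz (cardiac) and [0.05, 0.7] Hz (respiratory), ridge
#' penalties (lambda, kappa) = (5, 0) for ECG and (10, 10) for respiration,
#' 50-s inference windows with propagation constant 20, the standard
#' synchronization ratio list, and the 95th surrogate percentile.
#'
#' @param nv Voices per octave of all wavelet transforms.
#' @param ecg_band,resp_band Analysis bands in Hz for the cardiac and
#'   respiratory first harmonics.
#' @param lambda_ecg,kappa_ecg,lambda_resp,kappa_resp Ridge-tracking
#'   penalties per channel, see [track_support()].
#' @param width_bins Ridge support width in bins (default `nv / 2`).
#' @param window_s Inference window length in seconds.
#' @param p_w Propagation constant, see [propagate_prior()].
#' @param decimate_to Phase sampling rate used for inference (Hz).
#' @param order Fourier order of the inference basis.
#' @param ratios Synchronization ratio table (see [default_sync_ratios()]),
#'   or `NULL` to skip synchronization analysis.
#' @param sync_grid psi-grid size of the synchronization return map.
#' @param percentile Surrogate significance percentile.
#' @param wpc_band Frequency range (Hz) for wavelet phase coherence; the
#'   default starts at 0.145 Hz so that moderate record lengths admit the
#'   lowest frequency (lower edges need proportionally longer records).
#' @param band_edges Physiological band edges for [band_summary()].
#' @param detrend_window_s,smooth_resp_window_s Preprocessing windows in
#'   seconds, see [preprocess()]; `smooth_resp_window_s = NULL` disables
#'   respiration smoothing.
#' @param scale_margin Scale margin of [compute_wt()].
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(nv = 64L,
                            ecg_band = c(0.4, 2.1),
                            resp_band = c(0.05, 0.7),
                            lambda_ecg = 5, kappa_ecg = 0,
                            lambda_resp = 10, kappa_resp = 10,
                            width_bins = nv / 2,
                            window_s = 50, p_w = 20, decimate_to = 10,
                            order = 2L, ratios = default_sync_ratios(),
                            sync_grid = 64L,
                            percentile = 95,
                            wpc_band = c(0.145, 2),
                            band_edges = physiological_bands()$edges,
                            detrend_window_s = 30,
                            smooth_resp_window_s = NULL,
                            scale_margin = sqrt(2)) {
  out <- as.list(environment())
  class(out) <- "analysis_config"
  out
}

# centred moving average with edge renormalization (partial windows)
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  hw <- (w - 1L) / 2L
  lo <- pmax(0L, seq_len(n) - hw - 1L)
  hi <- pmin(n, seq_len(n) + hw)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Preprocess a raw signal
#'
#' Removes the mean and slow trend by subtracting a centred moving average
#' (window `detrend_window_s`), and optionally applies a short
#' moving-average smoother (e.g. to suppress high-frequency sensor noise on
#' a respiration belt). Both operations are linear filters whose windows are
#' chosen well away from the analysis bands; the applied steps are recorded
#' in the `"log"` attribute.
#'
#' @param signal A [uniform_signal()].
#' @param detrend_window_s Detrending window in seconds (`NULL` to skip).
#' @param smooth_window_s Smoothing window in seconds (`NULL` to skip).
#' @return The preprocessed [uniform_signal()]; attribute `"log"` lists the
#'   operations applied.
#' @export
#' @examples
#' s <- uniform_signal(1:100 / 10 + sin(1:100), fs = 10)
#' p <- preprocess(s, detrend_window_s = 2)
#' attr(p, "log")
preprocess <- function(signal, detrend_window_s = 30, smooth_window_s = NULL) {
  stopifnot(inherits(signal, "uniform_signal"))
  x <- signal$values
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x))
    stop("Signal contains non-finite values at indices: ",
      paste(utils::head(bad, 10L), collapse = ", "),
      if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
      call. = FALSE)
  }
  log <- character(0)
  if (!is.null(smooth_window_s) && smooth_window_s > 0) {
    w <- round(smooth_window_s * signal$fs)
    x <- moving_average(x, w)
    log <- c(log, sprintf("moving-average smoothing, window %.3g s", smooth_window_s))
  }
  if (!is.null(detrend_window_s) && detrend_window_s > 0) {
    w <- round(detrend_window_s * signal$fs)
    x <- x - moving_average(x, w)
    log <- c(log, sprintf("moving-average detrend, window %.3g s", detrend_window_s))
  } else {
    x <- x - mean(x)
    log <- c(log, "mean removal")
  }
  out <- uniform_signal(x, fs = signal$fs, t0 = signal$t0, label = signal$label)
  attr(out, "log") <- log
  out
}

#' Spearman rank correlation with large-sample significance
#'
#' Rank correlation (average ranks on ties) with a two-sided p-value from
#' the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 5`.
#' @param variable Optional name recorded in the output.
#' @return A one-row tibble of class `trend_result`: `variable`, `rho`,
#'   `p`, `n`. Constant input gives `rho = NA` with a warning.
#' @export
#' @examples
#' spearman_trend(1:5, c(2, 1, 4, 3, 5))$rho # 0.8
spearman_trend <- function(x, y, variable = NA_character_) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length.", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("Need at least 5 complete pairs.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Constant input: rank correlation undefined.", call. = FALSE)
    return(tibble_trend(variable, NA_real_, NA_real_, n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    return(tibble_trend(variable, sign(rho), 0, n))
  }
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  tibble_trend(variable, rho, p, n)
}

tibble_trend <- function(variable, rho, p, n) {
  out <- tibble::tibble(variable = variable, rho = rho, p = p, n = n)
  class(out) <- c("trend_result", class(out))
  out
}

#' Run the full analysis chain on one subject
#'
#' Chains every stage for a two-channel recording: preprocessing, Morlet
#' wavelet transform and synchrosqueezing in the cardiac and respiratory
#' bands, adaptive ridge tracking, phase/frequency extraction (IHF and
#' IRF), windowed Bayesian inference of the coupled phase model, coupling
#' norms/directionality, RSA shape, synchronization (if `config$ratios` is
#' not `NULL`), and — unless `coherence = FALSE` — the wavelet transforms
#' of the respiration signal and the IHF over `config$wpc_band` with their
#' phase coherence (plus, for `coherence = "full"`/`TRUE`, the IRF
#' transform and the IRF--IHF coherence).
#'
#' @param ecg,resp [uniform_signal()]s of equal duration and sampling rate.
#' @param config An [analysis_config()].
#' @param coherence `FALSE` for none, `"basic"` for the respiration--IHF
#'   products only (what the cohort analysis needs), `TRUE`/`"full"` to add
#'   the IRF transform and the IRF--IHF coherence.
#' @return An object of class `subject_report`: list with elements
#'   `phase_h`, `phase_r` ([extract_phase_freq()] tibbles), `inference`
#'   ([infer_sequence()]), `norms` ([coupling_norms()]), `rsa`
#'   ([rsa_shape()]), `sync` ([sync_table()] or `NULL`), `coherence`
#'   (list of `wt_resp`, `wt_ihf`, `wt_irf`, `wpc_resp_ihf`, `wpc_irf_ihf`,
#'   or `NULL`), `config`, and a `log` of stages. Use `glance()` for the
#'   one-row summary of all derived measures.
#' @export
run_subject <- function(ecg, resp, config = analysis_config(), coherence = FALSE) {
  stopifnot(inherits(ecg, "uniform_signal"), inherits(resp, "uniform_signal"))
  if (abs(signal_duration(ecg) - signal_duration(resp)) > 1 / min(ecg$fs, resp$fs)) {
    stop("ECG and respiration differ in duration by more than one sample.",
      call. = FALSE)
  }
  if (signal_duration(ecg) < 2 * config$window_s) {
    stop(sprintf("Record shorter than two %g-s windows.", config$window_s),
      call. = FALSE)
  }
  log <- character(0)
  stage <- function(msg) log <<- c(log, msg)

  ecg_p <- preprocess(ecg, config$detrend_window_s)
  resp_p <- preprocess(resp, config$detrend_window_s, config$smooth_resp_window_s)
  stage("preprocess: detrend (+optional respiration smoothing)")

  wt_e <- compute_wt(ecg_p, config$ecg_band[1], config$ecg_band[2],
    nv = config$nv, scale_margin = config$scale_margin)
  swt_e <- synchrosqueeze(wt_e, config$ecg_band[1], config$ecg_band[2])
  sup_e <- track_support(swt_e, config$lambda_ecg, config$kappa_ecg,
    config$width_bins)
  pf_h <- extract_phase_freq(swt_e, sup_e)
  stage(sprintf("cardiac band [%g, %g] Hz: SWT + ridge (lambda=%g, kappa=%g)",
    config$ecg_band[1], config$ecg_band[2], config$lambda_ecg, config$kappa_ecg))

  wt_r <- compute_wt(resp_p, config$resp_band[1], config$resp_band[2],
    nv = config$nv, scale_margin = config$scale_margin)
  swt_r <- synchrosqueeze(wt_r, config$resp_band[1], config$resp_band[2])
  sup_r <- track_support(swt_r, config$lambda_resp, config$kappa_resp,
    config$width_bins)
  pf_r <- extract_phase_freq(swt_r, sup_r)
  stage(sprintf("respiratory band [%g, %g] Hz: SWT + ridge (lambda=%g, kappa=%g)",
    config$resp_band[1], config$resp_band[2], config$lambda_resp, config$kappa_resp))

  phases <- bind_phases(pf_h, pf_r)
  basis <- build_basis(config$order, config$ratios)
  inf <- infer_sequence(phases,
    window_s = config$window_s, p_w = config$p_w,
    basis = basis, decimate_to = config$decimate_to)
  stage(sprintf("inference: %d windows of %g s, p_w=%g, %d basis terms",
    length(inf$windows), config$window_s, config$p_w, nrow(basis)))

  norms <- coupling_norms(inf)
  rsa <- rsa_shape(inf)
  sync <- NULL
  if (!is.null(config$ratios)) {
    sync <- sync_table(inf, config$ratios, grid_size = config$sync_grid)
    stage("synchronization return maps per window and ratio")
  }

  coh <- NULL
  if (!isFALSE(coherence)) {
    full <- isTRUE(coherence) || identical(coherence, "full")
    ihf <- uniform_signal(pf_h$freq, fs = ecg$fs, label = "ihf")
    wt_resp_c <- compute_wt(preprocess(resp, config$detrend_window_s),
      config$wpc_band[1], config$wpc_band[2], nv = config$nv)
    wt_ihf_c <- compute_wt(preprocess(ihf, config$detrend_window_s),
      config$wpc_band[1], config$wpc_band[2], nv = config$nv)
    coh <- list(
      wt_resp = wt_resp_c, wt_ihf = wt_ihf_c,
      wpc_resp_ihf = wpc(wt_resp_c, wt_ihf_c)
    )
    if (full) {
      irf <- uniform_signal(pf_r$freq, fs = resp$fs, label = "irf")
      wt_irf_c <- compute_wt(preprocess(irf, config$detrend_window_s),
        config$wpc_band[1], config$wpc_band[2], nv = config$nv)
      coh$wt_irf <- wt_irf_c
      coh$wpc_irf_ihf <- wpc(wt_irf_c, wt_ihf_c)
    }
    stage(sprintf("coherence products over [%g, %g] Hz%s",
      config$wpc_band[1], config$wpc_band[2],
      if (full) "" else " (respiration-IHF only)"))
  }

  structure(
    list(
      phase_h = pf_h, phase_r = pf_r, inference = inf,
      norms = norms, rsa = rsa, sync = sync, coherence = coh,
      config = config, log = log
    ),
    class = "subject_report"
  )
}

#' @export
print.subject_report <- function(x, ...) {
  cat("<subject_report>\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' Run the analysis over a whole cohort and extract age trends
#'
#' Synthesizes (or accepts) each subject's two-channel recording, runs
#' [run_subject()] on every subject (failures are isolated and reported,
#' the cohort run continues), assembles the per-subject summary table,
#' computes the intersubject surrogate threshold of the respiration--IHF
#' coherence, and regresses every derived measure on age by Spearman rank
#' correlation.
#'
#' Columns of the subject table: frequency statistics (`mean_ihf`,
#' `sd_ihf`, `mean_irf`, `sd_irf`), coupling strengths and decomposition
#' (`eps_r2h`, `eps_h2r`, `eps_dir_h`, `eps_ind_h`, `eps_dir_r`,
#' `eps_ind_r`), directionality (`mean_D`, `sd_D`), RSA shape (`mean_ba`,
#' `sd_ba`, `gamma`), synchronization durations (`sync_<ratio>`,
#' `sync_overall`; only if configured), and coherence peaks
#' (`wpc_resp_peak`, `wpc_resp_sig`, `wpc_cardiac_peak`, `wpc_cardiac_sig`
#' — the band-II and band-I peaks of the respiration--IHF coherence and
#' their significance against the intersubject threshold).
#'
#' @param cohort A [generate_cohort()] tibble, or a list of
#'   `list(ecg=, resp=, age=, subject_id=, gender=)` records.
#' @param config An [analysis_config()].
#' @param coherence Compute cohort coherence products and thresholds?
#' @param progress Print one line per subject?
#' @return An object of class `cohort_result`: list with `subjects`
#'   (per-subject summary tibble), `trends` (Spearman rho/p of each measure
#'   vs age), `ensemble` (the [intersubject_threshold()] object or `NULL`),
#'   `failures` (tibble of subject_id + error message), `config`.
#' @export
run_cohort <- function(cohort, config = analysis_config(), coherence = TRUE,
                       progress = FALSE) {
  recs <- cohort_records(cohort)
  reports <- vector("list", length(recs))
  failures <- list()

  # subjects are processed in a stream: the large wavelet transforms of the
  # coherence stage live only as long as needed to form the cyclic
  # intersubject surrogate (resp_i paired with IHF_{i+1}), then are dropped
  surro <- list()
  prev_resp_wt <- NULL
  first_ihf_wt <- NULL
  first_ok <- NA_integer_
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    res <- tryCatch(
      run_subject(r$ecg, r$resp, config,
        coherence = if (isTRUE(coherence)) "basic" else coherence),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        subject_id = r$subject_id, error = conditionMessage(res)
      )
      reports[[i]] <- NULL
    } else {
      if (coherence) {
        if (!is.null(prev_resp_wt)) {
          surro[[length(surro) + 1L]] <- wpc(prev_resp_wt, res$coherence$wt_ihf)$wpc
        }
        if (is.na(first_ok)) {
          first_ok <- i
          first_ihf_wt <- res$coherence$wt_ihf
        }
        prev_resp_wt <- res$coherence$wt_resp
        # keep only the small per-subject coherence curves
        res$coherence$wt_resp <- NULL
        res$coherence$wt_ihf <- NULL
        res$coherence$wt_irf <- NULL
      }
      reports[[i]] <- res
    }
    if (progress) {
      message(sprintf("[%d/%d] %s %s", i, length(recs), r$subject_id,
        if (inherits(res, "error")) "FAILED" else "ok"))
    }
  }
  ok <- !vapply(reports, is.null, logical(1L))

  ensemble <- NULL
  if (coherence && sum(ok) >= 2L) {
    # close the cycle: last analysed subject's respiration vs first's IHF
    surro[[length(surro) + 1L]] <- wpc(prev_resp_wt, first_ihf_wt)$wpc
    vals <- do.call(cbind, surro)
    freqs <- sort(first_ihf_wt$freqs)
    ensemble <- structure(
      list(
        freqs = freqs, values = vals,
        threshold = apply(vals, 1L, rank_percentile, p = config$percentile),
        percentile = config$percentile, pairing = "cyclic",
        n_subjects = sum(ok)
      ),
      class = "surrogate_ensemble"
    )
  }
  prev_resp_wt <- NULL
  first_ihf_wt <- NULL

  rows <- lapply(which(ok), function(i) {
    g <- glance_subject(reports[[i]], ensemble, config)
    meta <- tibble::tibble(
      subject_id = recs[[i]]$subject_id,
      age = recs[[i]]$age, gender = recs[[i]]$gender
    )
    dplyr::bind_cols(meta, g)
  })
  subjects <- dplyr::bind_rows(rows)

  trends <- NULL
  if (nrow(subjects) >= 5L) {
    measures <- setdiff(
      names(subjects)[vapply(subjects, is.numeric, logical(1L))],
      c("age")
    )
    trends <- dplyr::bind_rows(lapply(measures, function(v) {
      x <- subjects[[v]]
      if (sum(is.finite(x)) < 5L || stats::sd(x[is.finite(x)]) == 0) {
        return(tibble_trend(v, NA_real_, NA_real_, sum(is.finite(x))))
      }
      spearman_trend(subjects$age, x, variable = v)
    }))
  }

  structure(
    list(
      subjects = subjects, trends = trends, ensemble = ensemble,
      failures = dplyr::bind_rows(failures), config = config
    ),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "<cohort_result> %d subjects analysed, %d failed\n",
    nrow(x$subjects), nrow(x$failures)
  ))
  if (!is.null(x$trends)) {
    sig <- x$trends[!is.na(x$trends$p) & x$trends$p < 0.05, ]
    cat(sprintf("%d measures with p < 0.05 age trend\n", nrow(sig)))
  }
  invisible(x)
}

cohort_records <- function(cohort) {
  if (inherits(cohort, "cohort")) {
    spec <- attr(cohort, "spec")
    lapply(seq_len(nrow(cohort)), function(i) {
      subj <- cohort[i, ]
      rec <- synthesize_subject(subj, spec)
      list(
        ecg = rec$ecg, resp = rec$resp,
        age = subj$age, gender = subj$gender, subject_id = subj$subject_id
      )
    })
  } else if (is.list(cohort)) {
    cohort
  } else {
    stop("`cohort` must be a generate_cohort() tibble or a list of records.",
      call. = FALSE)
  }
}

# one-row summary of a subject report (helper behind glance.subject_report)
glance_subject <- function(report, ensemble = NULL, config = report$config) {
  pf_h <- report$phase_h
  pf_r <- report$phase_r
  nm <- report$norms
  rsum <- attr(report$rsa, "summary")
  out <- tibble::tibble(
    n_windows = length(report$inference$windows),
    mean_ihf = mean(pf_h$freq[pf_h$valid]),
    sd_ihf = stats::sd(pf_h$freq[pf_h$valid]),
    mean_irf = mean(pf_r$freq[pf_r$valid]),
    sd_irf = stats::sd(pf_r$freq[pf_r$valid]),
    eps_r2h = mean(nm$eps_r2h), eps_h2r = mean(nm$eps_h2r),
    eps_dir_h = mean(nm$eps_dir_h), eps_ind_h = mean(nm$eps_ind_h),
    eps_dir_r = mean(nm$eps_dir_r), eps_ind_r = mean(nm$eps_ind_r),
    mean_D = mean(nm$D, na.rm = TRUE), sd_D = stats::sd(nm$D, na.rm = TRUE),
    mean_ba = rsum$mean_ba, sd_ba = rsum$sd_ba, gamma = rsum$gamma
  )
  if (!is.null(report$sync)) {
    dur <- sync_durations(report$sync)
    wide <- stats::setNames(
      as.list(dur$duration),
      paste0("sync_", gsub(":", "_", dur$ratio))
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(wide))
  }
  if (!is.null(report$coherence)) {
    bs <- band_summary(report$coherence$wpc_resp_ihf, ensemble,
      band_edges = config$band_edges)
    pick <- function(b, col) {
      v <- bs[[col]][bs$band == b]
      if (length(v)) v else NA
    }
    out$wpc_resp_peak <- pick("II", "peak_wpc")
    out$wpc_resp_sig <- as.numeric(pick("II", "significant"))
    out$wpc_cardiac_peak <- pick("I", "peak_wpc")
    out$wpc_cardiac_sig <- as.numeric(pick("I", "significant"))
    # coherence at the subject's own cardiac frequency: the component of
    # the respiration--IHF coherence locked to this subject's heartbeat,
    # as opposed to the band-wide peak (which can sit on respiratory
    # harmonics k * f_r falling inside the cardiac band)
    # single bin nearest the mean IHF: a windowed maximum would ride the
    # generic low-frequency coherence bias rather than the cardiac line
    w <- report$coherence$wpc_resp_ihf
    k <- which.min(abs(log(w$freq / out$mean_ihf)))
    out$wpc_cardiac_self <- w$wpc[k]
    thr <- if (is.null(ensemble)) NA_real_ else {
      ensemble$threshold[which.min(abs(ensemble$freqs - w$freq[k]))]
    }
    out$wpc_cardiac_self_thr <- thr
    out$wpc_cardiac_self_sig <- as.numeric(w$wpc[k] > thr)
  }
  out
}
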