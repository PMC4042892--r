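#' Uniformly sampled signal
#'
#' Lightweight container for one channel of a uniformly sampled recording.
#' Most functions in the package either take or return one of these; use
#' [tibble::as_tibble()] to get a `(time, value)` data frame for plotting or
#' wrangling.
#'
#' @param values Numeric vector of samples (arbitrary units).
#' @param fs Sampling rate in Hz. Must be positive.
#' @param t0 Time of the first sample in seconds.
#' @param label Optional channel label, e.g. `"ecg"`.
#'
#' @return An object of class `uniform_signal`.
#' @export
#' @examples
#' s <- uniform_signal(sin(2 * pi * seq(0, 10, by = 0.02)), fs = 50)
#' signal_duration(s)
uniform_signal <- function(values, fs, t0 = 0, label = "") {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("`values` must be a numeric vector with at least 2 samples.", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz).", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), fs = fs, t0 = t0, label = as.character(label)),
    class = "uniform_signal"
  )
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf(
    "<uniform_signal> %s: %d samples @ %g Hz (%.1f s)\n",
    if (nzchar(x$label)) x$label else "unlabelled",
    length(x$values), x$fs, signal_duration(x)
  ))
  invisible(x)
}

#' Time axis and duration of a signal
#'
#' @param x A [uniform_signal()].
#' @return `signal_times()` returns the vector of sample times in seconds;
#'   `signal_duration()` the record length in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$t0 + (seq_along(x$values) - 1L) / x$fs
}

#' @rdname signal_times
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  length(x$values) / x$fs
}

#' @method as_tibble uniform_signal
#' @export
as_tibble.uniform_signal <- function(x, ...) {
  tibble::tibble(
    time = signal_times(x),
    value = x$values
  )
}

#' Write / read a signal as two-column CSV
#'
#' The on-disk format is a plain CSV with columns `time_s, value` preceded by
#' a single comment header line `# fs_hz=<fs> label=<label>` so that a file is
#' self-describing.
#'
#' @param x A [uniform_signal()].
#' @param path File path.
#' @return `write_signal_csv()` returns `path` invisibly; `read_signal_csv()`
#'   returns a [uniform_signal()].
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "uniform_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g label=%s", x$fs, x$label), con)
  utils::write.csv(
    data.frame(time_s = signal_times(x), value = x$values),
    con, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# fs_hz=", header)) {
    stop("Not a signal CSV: missing '# fs_hz=' header line.", call. = FALSE)
  }
  fs <- as.numeric(sub("^# fs_hz=([0-9.eE+-]+).*$", "\\1", header))
  label <- sub("^.*label=", "", header)
  d <- utils::read.csv(path, skip = 1L)
  uniform_signal(d$value, fs = fs, t0 = d$time_s[1L], label = label)
}
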