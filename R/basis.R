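#' Fourier basis for coupled phase-oscillator models
#'
#' The right-hand side of each phase equation is modelled as a linear
#' combination of 2-pi-periodic basis functions of the two phases,
#' `sin(n*phi_h + m*phi_r)` and `cos(n*phi_h + m*phi_r)`, plus a constant
#' carrying the natural frequency. `build_basis()` enumerates a full double
#' Fourier series up to `order` (sign-redundant pairs `(n, m)` and
#' `(-n, -m)` are collapsed onto a canonical representative) and appends one
#' sin/cos pair per requested `n:m` synchronization ratio, with argument
#' `m*phi_h - n*phi_r` (the combination that varies slowly when the
#' cardiac-to-respiratory frequency ratio is close to `n/m`).
#'
#' With `order = 2` and the eight default ratios this yields 41 terms per
#' equation: 1 constant + 24 second-order sin/cos terms + 16 ratio terms.
#'
#' Each term is tagged, separately for the heart (`part_h`) and respiration
#' (`part_r`) equations, as one of
#' \describe{
#'   \item{`omega`}{the constant term (natural frequency),}
#'   \item{`self`}{depends only on the equation's own phase,}
#'   \item{`direct`}{depends only on the other oscillator's phase (for the
#'     heart equation this is the RSA term),}
#'   \item{`indirect`}{depends on both phases.}
#' }
#'
#' @param order Maximum harmonic order of the double Fourier series (>= 0).
#' @param ratios Synchronization ratios as a two-column matrix or data frame
#'   with columns `n` (cardiac) and `m` (respiratory), or `NULL` for none.
#'   See [default_sync_ratios()].
#' @return A tibble of class `fourier_basis` with columns
#'   `kind` (`"const"|"sin"|"cos"`), `n`, `m` (integer multipliers of
#'   `phi_h`, `phi_r`), `label`, `part_h`, `part_r`.
#' @export
#' @examples
#' nrow(build_basis())           # 41
#' nrow(build_basis(1, NULL))    # 9
build_basis <- function(order = 2L, ratios = default_sync_ratios()) {
  if (!is.numeric(order) || length(order) != 1L || order < 0) {
    stop("`order` must be a single non-negative integer.", call. = FALSE)
  }
  order <- as.integer(order)

  nm <- expand.grid(n = -order:order, m = -order:order)
  nm <- nm[!(nm$n == 0 & nm$m == 0), , drop = FALSE]
  # canonical representative of the (n, m) ~ (-n, -m) pair
  nm <- nm[nm$n > 0 | (nm$n == 0 & nm$m > 0), , drop = FALSE]
  nm <- nm[order(nm$n, nm$m), , drop = FALSE]

  terms <- tibble::tibble(kind = "const", n = 0L, m = 0L)
  if (nrow(nm) > 0L) {
    terms <- dplyr::bind_rows(
      terms,
      tibble::tibble(
        kind = rep(c("sin", "cos"), nrow(nm)),
        n = rep(as.integer(nm$n), each = 2L),
        m = rep(as.integer(nm$m), each = 2L)
      )
    )
  }

  if (!is.null(ratios)) {
    ratios <- as.data.frame(ratios)
    if (!all(c("n", "m") %in% names(ratios))) {
      stop("`ratios` needs columns `n` and `m`.", call. = FALSE)
    }
    if (anyDuplicated(ratios[c("n", "m")])) {
      stop("Duplicate synchronization ratios supplied.", call. = FALSE)
    }
    rt <- tibble::tibble(
      kind = rep(c("sin", "cos"), nrow(ratios)),
      n = rep(as.integer(ratios$m), each = 2L),   # multiplier of phi_h
      m = rep(as.integer(-ratios$n), each = 2L)   # multiplier of phi_r
    )
    dup <- paste(rt$kind, rt$n, rt$m) %in% paste(terms$kind, terms$n, terms$m)
    if (any(dup)) {
      stop("Ratio terms duplicate Fourier-series terms already in the basis: ",
        paste(rt$n[dup], rt$m[dup], sep = ",", collapse = "; "), call. = FALSE)
    }
    terms <- dplyr::bind_rows(terms, rt)
  }

  terms$label <- term_label(terms$kind, terms$n, terms$m)
  terms$part_h <- term_partition(terms, equation = "h")
  terms$part_r <- term_partition(terms, equation = "r")
  class(terms) <- c("fourier_basis", class(terms))
  terms
}

#' Default cardiorespiratory synchronization ratios
#'
#' The `n:m` locking ratios commonly observed between heartbeat (`n` cycles)
#' and breathing (`m` cycles).
#'
#' @return A tibble with columns `n`, `m` and a `label` such as `"4:1"`.
#' @export
default_sync_ratios <- function() {
  tibble::tibble(
    n = c(3L, 4L, 5L, 6L, 7L, 7L, 9L, 10L),
    m = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L),
    label = c("3:1", "4:1", "5:1", "6:1", "7:1", "7:2", "9:2", "10:3")
  )
}

term_label <- function(kind, n, m) {
  piece <- function(k, sym, first) {
    out <- character(length(k))
    out[k == 0] <- ""
    pos <- k != 0
    coef <- ifelse(abs(k) == 1, "", as.character(abs(k)))
    sgn <- ifelse(k > 0, ifelse(first, "", "+"), "-")
    out[pos] <- paste0(sgn[pos], coef[pos], sym)
    out
  }
  ph <- piece(n, "h", first = TRUE)
  pr <- piece(m, "r", first = n == 0)
  ifelse(kind == "const", "const", paste0(kind, "(", ph, pr, ")"))
}

term_partition <- function(terms, equation = c("h", "r")) {
  equation <- match.arg(equation)
  own <- if (equation == "h") terms$n else terms$m
  other <- if (equation == "h") terms$m else terms$n
  dplyr::case_when(
    terms$kind == "const" ~ "omega",
    other == 0 ~ "self",
    own == 0 ~ "direct",
    TRUE ~ "indirect"
  )
}

#' Evaluate basis functions at given phases
#'
#' @param basis A [build_basis()] object.
#' @param phi_h,phi_r Numeric vectors of heart / respiration phases (rad),
#'   recycled to a common length.
#' @return `evaluate_basis()` returns a numeric matrix with one row per phase
#'   sample and one column per basis term (column names are the term labels).
#'   `basis_deriv()` returns the element-wise partial derivative with respect
#'   to the chosen phase.
#' @export
#' @examples
#' b <- build_basis(1, NULL)
#' evaluate_basis(b, 0, 0)[1, "cos(h)"]  # 1
evaluate_basis <- function(basis, phi_h, phi_r) {
  k <- vctrs_recycle2(phi_h, phi_r)
  arg <- outer(k$a, basis$n) + outer(k$b, basis$m)
  out <- matrix(1, nrow = length(k$a), ncol = nrow(basis))
  is_sin <- basis$kind == "sin"
  is_cos <- basis$kind == "cos"
  out[, is_sin] <- sin(arg[, is_sin, drop = FALSE])
  out[, is_cos] <- cos(arg[, is_cos, drop = FALSE])
  colnames(out) <- basis$label
  out
}

#' @rdname evaluate_basis
#' @param wrt Which phase to differentiate with respect to.
#' @export
basis_deriv <- function(basis, phi_h, phi_r, wrt = c("h", "r")) {
  wrt <- match.arg(wrt)
  k <- vctrs_recycle2(phi_h, phi_r)
  mult <- if (wrt == "h") basis$n else basis$m
  arg <- outer(k$a, basis$n) + outer(k$b, basis$m)
  out <- matrix(0, nrow = length(k$a), ncol = nrow(basis))
  is_sin <- basis$kind == "sin"
  is_cos <- basis$kind == "cos"
  out[, is_sin] <- cos(arg[, is_sin, drop = FALSE])
  out[, is_cos] <- -sin(arg[, is_cos, drop = FALSE])
  out <- sweep(out, 2L, mult, `*`)
  colnames(out) <- basis$label
  out
}

vctrs_recycle2 <- function(a, b) {
  n <- max(length(a), length(b))
  list(a = rep_len(as.numeric(a), n), b = rep_len(as.numeric(b), n))
}

#' One coupling term of the phase model
#'
#' Convenience constructor for ground-truth coupling coefficients used by
#' [oscillator_spec()]: the term `value * kind(n*phi_h + m*phi_r)`.
#'
#' @param kind `"sin"` or `"cos"`.
#' @param n,m Integer multipliers of the heart / respiration phase.
#' @param value Coefficient in rad/s.
#' @return A one-row tibble with columns `kind, n, m, value`; rows can be
#'   combined with [dplyr::bind_rows()].
#' @export
#' @examples
#' # respiratory sinus arrhythmia: 0.5 * sin(phi_r) driving the heart
#' coupling_term("sin", 0, 1, 0.5)
coupling_term <- function(kind, n, m, value) {
  kind <- match.arg(kind, c("sin", "cos"))
  tibble::tibble(kind = kind, n = as.integer(n), m = as.integer(m), value = as.numeric(value))
}
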