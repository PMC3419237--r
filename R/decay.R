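#' Fit first-order radical decay
#'
#' Least-squares fit of `I(t) = I0 * exp(-k t)` to EPR signal intensities.
#' Two time points are solved in closed form; longer series are fitted by
#' nonlinear least squares started from the log-linear regression. An
#' apparent negative decay (intensity rising) clamps `k` to 0 with a
#' warning, since radical regeneration is outside the model.
#'
#' @param times observation times, hours; at least two points, one of which
#'   should be the `t = 0` control (or pass `control_index`).
#' @param intensities signal intensities (e.g. double integrals), same
#'   length as `times`; positive.
#' @param control_index index of the reference observation (default: the
#'   earliest time point).
#' @return Object of class `decay_fit`: `k` (per hour), `t_half` (hours,
#'   `Inf` when `k = 0`), `I0`, `model = "first_order"`, `fitted`.
#' @export
#' @examples
#' fit_decay(c(0, 24), c(1.00, 0.69))   # ~31% loss over 24 h
fit_decay <- function(times, intensities, control_index = which.min(times)) {
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities) || length(times) < 2L)
    stop("need at least two (time, intensity) pairs")
  if (any(!is.finite(times)) || any(times < 0)) stop("negative or non-finite times")
  if (any(intensities <= 0)) stop("intensities must be positive")

  if (length(times) == 2L) {
    i0 <- control_index; i1 <- setdiff(1:2, i0)
    dt <- times[i1] - times[i0]
    if (dt <= 0) stop("the two time points must be distinct")
    k <- log(intensities[i0] / intensities[i1]) / dt
    if (k < 0) {
      warning("intensity increased over time; decay rate clamped to 0")
      k <- 0
    }
    I0 <- intensities[i0] * exp(k * times[i0])
  } else {
    ## log-linear start, then nonlinear refinement on the original scale
    lf <- stats::lm(log(intensities) ~ times)
    k0 <- max(0, -stats::coef(lf)[[2]])
    I00 <- exp(stats::coef(lf)[[1]])
    fit <- try(minpack.lm::nlsLM(
      intensities ~ I0 * exp(-k * times),
      start = list(I0 = I00, k = k0),
      lower = c(I0 = 0, k = 0)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      k <- k0; I0 <- I00
    } else {
      cf <- stats::coef(fit); I0 <- cf[["I0"]]; k <- cf[["k"]]
    }
    if (k == 0 && stats::coef(lf)[[2]] > 0)
      warning("intensity trend is increasing; decay rate clamped to 0")
  }
  structure(list(k = k, t_half = if (k > 0) log(2) / k else Inf,
                 I0 = I0, model = "first_order",
                 fitted = I0 * exp(-k * times)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("First-order radical decay fit\n")
  cat(sprintf("  k = %.4g per hour; half-life = %s\n", x$k,
              if (is.finite(x$t_half)) sprintf("%.3g h", x$t_half) else "infinite"))
  cat(sprintf("  I0 = %.4g\n", x$I0))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(I0 = object$I0, k = object$k)

#' Percent signal change relative to a reference
#'
#' `100 * (I_0 - I_t) / I_0`: positive values are losses.
#'
#' @param I_t intensity at time t.
#' @param I_0 reference intensity (> 0).
#' @return Percent change.
#' @export
#' @examples
#' percent_change(0.69, 1.0)   # 31
percent_change <- function(I_t, I_0) {
  if (any(I_0 <= 0)) stop("reference intensity must be positive")
  100 * (I_0 - I_t) / I_0
}
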