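#' Fit the multi-flip-angle steady-state relaxometry model
#'
#' Estimates the relaxation weighting factor `A = sqrt(T1/T2)` — and from it
#' `T2 = T1 / A^2` — from metabolite amplitudes measured at several
#' preparation flip angles. The flip-angle-0 arm defines the equilibrium
#' amplitude `M0`; every arm is corrected for the short longitudinal recovery
#' during water suppression, converted to the ratio statistic
#' `Rzss = (M0 - Mzss) / sqrt(M0^2 - (M0 - Mzss)^2)`, and `Rzss` is regressed
#' on `X = tan(FA/2)` through the origin with equal weights. The through-origin
#' form has no intercept because `Rzss(0) = 0` exactly; the flip-angle-0 arm
#' contributes the point (0, 0).
#'
#' @param data A data frame with columns `fa_deg` (degrees, must include 0)
#'   and `amplitude` (fitted metabolite amplitudes, arbitrary units). Flip
#'   angles must be distinct.
#' @param t1 Pre-determined longitudinal relaxation time in seconds (e.g. from
#'   [fit_inversion_recovery()]).
#' @param t1_se Standard error of `t1` (seconds), propagated into `T2`.
#' @param ws_delay Water-suppression recovery interval in seconds; see
#'   [correct_ws_recovery()]. Default 0.2 s.
#' @return An object of class `"marzss"`, a list with components
#'   \describe{
#'     \item{coefficients}{named vector `c(A, t2)` (t2 in seconds).}
#'     \item{se}{standard errors of `A` and `t2`.}
#'     \item{r_squared}{uncentered R^2 of the through-origin regression.}
#'     \item{points}{per-arm table: `fa_deg`, `amplitude`, corrected `mzss`,
#'       `x = tan(fa/2)`, `rzss`, `fitted`, `residual`.}
#'     \item{m0, t1, t1_se, ws_delay}{inputs as used.}
#'   }
#' @examples
#' rel <- relaxation_params(t1 = 1.15, t2 = 0.1175)
#' fa <- c(0, 12, 24, 36)
#' amp <- ws_recovery_observe(mzss_fraction(rel, fa), 1, 0.2, rel$t1)
#' fit <- marzss(data.frame(fa_deg = fa, amplitude = amp),
#'               t1 = 1.15, ws_delay = 0.2)
#' coef(fit)["t2"] # recovers 0.1175 s
#' @export
marzss <- function(data, t1, t1_se = 0, ws_delay = 0.2) {
  stopifnot(is.data.frame(data),
            all(c("fa_deg", "amplitude") %in% names(data)),
            t1 > 0, t1_se >= 0, ws_delay >= 0)
  data <- data[order(data$fa_deg), , drop = FALSE]
  if (anyDuplicated(data$fa_deg))
    stop("flip angles must be distinct")
  if (nrow(data) < 2L)
    stop("need at least two flip angles (including 0)")
  if (!any(data$fa_deg == 0))
    stop("a flip-angle-0 arm is required to anchor M0")
  m0 <- data$amplitude[data$fa_deg == 0]
  if (m0 <= 0) stop("the flip-angle-0 amplitude must be positive")

  x <- tan(data$fa_deg * pi / 360)
  nz <- x > 0
  if (sum(nz) < 1L) stop("need at least one non-zero flip angle")
  sxx <- sum(x[nz]^2)

  # the estimator as a function of the raw amplitude vector, so that the
  # uncertainty of the flip-angle-0 reference propagates too
  chain <- function(amp) {
    m0c <- amp[data$fa_deg == 0]
    mz <- correct_ws_recovery(amp, m0c, ws_delay, t1)
    mz[data$fa_deg == 0] <- m0c
    rzss_from_amplitudes(m0c, mz)
  }
  rzss <- chain(data$amplitude)
  mzss <- correct_ws_recovery(data$amplitude, m0, ws_delay, t1)
  mzss[data$fa_deg == 0] <- m0
  A <- sum(x[nz] * rzss[nz]) / sxx
  fitted <- A * x
  resid <- rzss - fitted

  # Delta-method standard error under equal per-arm amplitude noise (the
  # acquisition adds the same noise at every flip angle): the noise scale is
  # estimated from the ratio residuals mapped back to amplitude units, then
  # propagated through the full estimator — including the shared M0 reference,
  # which residual-based regression formulas would miss.
  A_se <- 0
  if (sum(nz) > 1L) {
    n_arm <- nrow(data)
    eps <- 1e-6 * max(m0, 1e-12)
    A_of <- function(amp) sum(x[nz] * suppressWarnings(chain(amp))[nz]) / sxx
    grad <- vapply(seq_len(n_arm), function(j) {
      d <- data$amplitude
      d[j] <- d[j] + eps
      (A_of(d) - A) / eps
    }, numeric(1))
    drda <- vapply(which(nz), function(j) {
      d <- data$amplitude
      d[j] <- d[j] + eps
      (suppressWarnings(chain(d))[j] - rzss[j]) / eps
    }, numeric(1))
    sigma_a <- sqrt(sum((resid[nz] / drda)^2) / (sum(nz) - 1L))
    A_se <- sigma_a * sqrt(sum(grad^2))
  }
  # uncentered R^2: regression is through the origin
  r2 <- if (sum(rzss^2) > 0) 1 - sum(resid^2) / sum(rzss^2) else NA_real_
  t2 <- t2_from_t1_A(t1, A, t1_se, A_se)

  structure(list(
    coefficients = c(A = A, t2 = unname(t2["t2"])),
    se = c(A = A_se, t2 = unname(t2["se"])),
    r_squared = r2,
    points = data.frame(fa_deg = data$fa_deg, amplitude = data$amplitude,
                        mzss = mzss, x = x, rzss = rzss,
                        fitted = fitted, residual = resid),
    m0 = m0, t1 = t1, t1_se = t1_se, ws_delay = ws_delay,
    call = match.call()
  ), class = "marzss")
}

#' @export
print.marzss <- function(x, digits = 4, ...) {
  cat("Multi-flip-angle steady-state T2 fit\n")
  cat(sprintf("  arms: FA = %s deg\n",
              paste(format(x$points$fa_deg), collapse = ", ")))
  cat(sprintf("  A  = %.*f (SE %.2g)\n", digits, x$coefficients["A"],
              x$se["A"]))
  cat(sprintf("  T2 = %.1f ms (SE %.2g ms), T1 = %.3f s (given)\n",
              1000 * x$coefficients["t2"], 1000 * x$se["t2"], x$t1))
  cat(sprintf("  R^2 (through origin) = %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
summary.marzss <- function(object, ...) {
  structure(list(fit = object), class = "summary.marzss")
}

#' @export
print.summary.marzss <- function(x, ...) {
  print(x$fit)
  cat("\nPer-arm amplitudes and ratio statistic:\n")
  print(x$fit$points, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
coef.marzss <- function(object, ...) object$coefficients

#' @export
residuals.marzss <- function(object, ...) object$points$residual

#' Predicted steady-state amplitudes from a fitted model
#'
#' @param object A fitted [marzss()] object.
#' @param fa_deg Flip angles (degrees) at which to predict.
#' @param type `"amplitude"` (observed scale, including water-suppression
#'   recovery), `"mzss"` (steady-state fraction times M0) or `"rzss"`.
#' @param ... Unused.
#' @export
predict.marzss <- function(object, fa_deg = object$points$fa_deg,
                           type = c("amplitude", "mzss", "rzss"), ...) {
  type <- match.arg(type)
  A <- object$coefficients["A"]
  frac <- mzss_fraction(unname(A), fa_deg)
  switch(type,
    amplitude = ws_recovery_observe(object$m0 * frac, object$m0,
                                    object$ws_delay, object$t1),
    mzss = object$m0 * frac,
    rzss = unname(A) * tan(fa_deg * pi / 360))
}

#' Simulate amplitude sets from a fitted model
#'
#' Draws replicate multi-flip-angle amplitude vectors from the fitted model
#' with i.i.d. Gaussian amplitude noise, for parametric-bootstrap style use.
#'
#' @param object A fitted [marzss()] object.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param sd Amplitude noise standard deviation; defaults to the RMS amplitude
#'   residual implied by the Rzss residuals.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of amplitudes, rows matching
#'   `object$points$fa_deg`.
#' @export
simulate.marzss <- function(object, nsim = 1, seed = NULL, sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  if (is.null(sd)) {
    nz <- object$points$x > 0
    sd <- if (sum(nz) > 1)
      stats::sd(object$points$amplitude[nz] - mu[nz]) else 0
  }
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "fa_deg") <- object$points$fa_deg
  out
}

#' @export
plot.marzss <- function(x, ...) {
  p <- x$points
  graphics::plot(p$x, p$rzss, xlab = "tan(FA / 2)",
                 ylab = expression(R[zss]), pch = 19, ...)
  graphics::abline(0, x$coefficients["A"], lty = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "A = %.3f, T2 = %.1f ms, R2 = %.3f",
    x$coefficients["A"], 1000 * x$coefficients["t2"], x$r_squared))
  invisible(x)
}

#' Estimate the weighting factor A from an amplitude series
#'
#' Lower-level interface to the through-origin regression used by [marzss()]:
#' takes already-corrected steady-state amplitudes (or a prepared
#' `(x, rzss)` table) and returns the slope and its standard error.
#'
#' @param fa_deg Flip angles in degrees (must include 0 or `m0` given).
#' @param amplitude Steady-state amplitudes (already corrected for
#'   water-suppression recovery).
#' @param m0 Equilibrium amplitude; defaults to the amplitude at `fa_deg == 0`.
#' @return Named vector `c(A, se)`.
#' @export
estimate_A <- function(fa_deg, amplitude, m0 = NULL) {
  stopifnot(length(fa_deg) == length(amplitude), length(fa_deg) >= 2)
  if (anyDuplicated(fa_deg)) stop("flip angles must be distinct")
  if (is.null(m0)) {
    if (!any(fa_deg == 0)) stop("m0 must be given when no fa = 0 point exists")
    m0 <- amplitude[fa_deg == 0]
  }
  x <- tan(fa_deg * pi / 360)
  if (all(x == 0)) stop("all flip angles are zero")
  rzss <- rzss_from_amplitudes(m0, amplitude)
  nz <- x > 0
  sxx <- sum(x[nz]^2)
  A <- sum(x[nz] * rzss[nz]) / sxx
  resid <- rzss[nz] - A * x[nz]
  se <- if (sum(nz) > 1) sqrt(sum(resid^2) / (sum(nz) - 1) / sxx) else 0
  c(A = A, se = se)
}
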