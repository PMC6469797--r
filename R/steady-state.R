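#' Relaxation parameters for one resonance pool
#'
#' Bundles the longitudinal and transverse relaxation times of a single
#' (mono-exponential) pool and the derived relaxation weighting factor
#' `A = sqrt(T1/T2)` that governs the RF-driven steady state.
#'
#' @param t1 Longitudinal relaxation time in seconds (> 0).
#' @param t2 Transverse relaxation time in seconds (> 0).
#' @return An object of class `"relaxation_params"`: a list with elements
#'   `t1`, `t2` (seconds) and `A` (dimensionless, `sqrt(t1/t2)`).
#' @examples
#' relaxation_params(t1 = 1.15, t2 = 0.1175)
#' @export
relaxation_params <- function(t1, t2) {
  stopifnot(is.numeric(t1), length(t1) == 1L, is.finite(t1),
            is.numeric(t2), length(t2) == 1L, is.finite(t2))
  if (t1 <= 0 || t2 <= 0)
    stop("t1 and t2 must be positive (seconds)")
  structure(list(t1 = t1, t2 = t2, A = sqrt(t1 / t2)),
            class = "relaxation_params")
}

#' @export
print.relaxation_params <- function(x, ...) {
  cat(sprintf("Relaxation: T1 = %.4g s, T2 = %.4g s, A = sqrt(T1/T2) = %.4f\n",
              x$t1, x$t2, x$A))
  invisible(x)
}

as_relaxation <- function(x) {
  if (inherits(x, "relaxation_params")) return(x)
  if (is.list(x) && all(c("t1", "t2") %in% names(x)))
    return(relaxation_params(x$t1, x$t2))
  stop("expected a relaxation_params object or a list with t1 and t2")
}

#' Closed-form RF-driven longitudinal steady state
#'
#' Fraction of thermal-equilibrium magnetization remaining after a long train
#' of identical RF pulses with interleaved spoiler gradients has driven the
#' longitudinal magnetization into steady state:
#' \deqn{M_{zss}/M_0 = 1 - \frac{A X}{\sqrt{1 + A^2 X^2}},}
#' with \eqn{A = \sqrt{T_1/T_2}} and \eqn{X = \tan(\mathrm{FA}/2)}. Under this
#' form the amplitude-ratio statistic [rzss_from_amplitudes()] is exactly
#' linear in `X` with slope `A`, which is what makes the multi-flip-angle
#' regression work.
#'
#' @param relax A [relaxation_params()] object (or list with `t1`, `t2`), or a
#'   bare numeric `A` value.
#' @param fa_deg Flip angle(s) in degrees, in \[0, 90\].
#' @return Steady-state fraction(s) `Mzss/M0` in (0, 1\].
#' @examples
#' mzss_fraction(relaxation_params(1.15, 0.1175), fa_deg = c(0, 12, 24, 36))
#' @export
mzss_fraction <- function(relax, fa_deg) {
  A <- if (is.numeric(relax)) relax else as_relaxation(relax)$A
  stopifnot(is.numeric(A), length(A) == 1L, A > 0)
  if (any(fa_deg < 0 | fa_deg > 90))
    stop("flip angle must lie in [0, 90] degrees")
  x <- tan(fa_deg * pi / 360)
  1 - A * x / sqrt(1 + (A * x)^2)
}

#' Amplitude-ratio statistic of the steady-state method
#'
#' Converts an equilibrium amplitude `m0` (the flip-angle-0 measurement) and a
#' steady-state amplitude `mzss` into the ratio statistic
#' \deqn{R_{zss} = \frac{M_0 - M_{zss}}{\sqrt{M_0^2 - (M_0 - M_{zss})^2}},}
#' which equals `A * tan(FA/2)` exactly when `mzss` follows the closed-form
#' steady state. Scale-invariant in `m0`.
#'
#' Noise can push a measured `mzss` slightly above `m0`; such values are
#' clipped to `m0 * (1 - 1e-6)`... i.e. to an Rzss of essentially 0, with a
#' warning, rather than producing NaN.
#'
#' @param m0 Equilibrium amplitude (> 0).
#' @param mzss Steady-state amplitude(s), 0 < mzss (values > m0 are clipped).
#' @return Non-negative `Rzss` value(s).
#' @export
rzss_from_amplitudes <- function(m0, mzss) {
  stopifnot(is.numeric(m0), length(m0) == 1L, m0 > 0, is.numeric(mzss))
  if (any(mzss <= 0))
    stop("steady-state amplitude must be positive")
  if (any(mzss > m0)) {
    warning("amplitude(s) above the M0 reference; clipping (noise-driven)")
    mzss <- pmin(mzss, m0 * (1 - 1e-6))
  }
  d <- m0 - mzss
  d / sqrt(m0^2 - d^2)
}

#' Water-suppression recovery correction
#'
#' The water-suppression module sits between the steady-state preparation
#' train and the readout, so the longitudinal magnetization recovers towards
#' equilibrium for a short delay before being sampled:
#' `M_obs = M0 - (M0 - Mzss) * exp(-ws_delay / T1)`. This function inverts
#' that recovery to return the steady-state amplitude at the end of the train.
#'
#' @param observed Observed (post-recovery) amplitude(s).
#' @param m0 Equilibrium amplitude.
#' @param ws_delay Recovery interval in seconds (>= 0). The default water
#'   suppression block of nine 9 ms pulses with 12 ms delays and 1.2 ms
#'   spoilers lasts about 0.2 s.
#' @param t1 Longitudinal relaxation time in seconds.
#' @return Corrected steady-state amplitude(s).
#' @seealso [ws_recovery_observe()] for the forward model.
#' @export
correct_ws_recovery <- function(observed, m0, ws_delay, t1) {
  stopifnot(ws_delay >= 0, t1 > 0, m0 > 0)
  if (ws_delay == 0) return(observed)
  mzss <- m0 - (m0 - observed) * exp(ws_delay / t1)
  if (any(mzss <= 0))
    stop("water-suppression correction yields non-positive amplitude; ",
         "inputs inconsistent with the recovery model")
  mzss
}

#' Forward water-suppression recovery
#'
#' Forward counterpart of [correct_ws_recovery()]: the amplitude observed
#' after the magnetization has recovered for `ws_delay` seconds.
#'
#' @inheritParams correct_ws_recovery
#' @param mzss Steady-state amplitude(s) at the end of the preparation train.
#' @return Observed amplitude(s).
#' @export
ws_recovery_observe <- function(mzss, m0, ws_delay, t1) {
  stopifnot(ws_delay >= 0, t1 > 0, m0 > 0)
  m0 - (m0 - mzss) * exp(-ws_delay / t1)
}

#' Transverse relaxation time from T1 and the weighting factor
#'
#' `T2 = T1 / A^2`, with first-order (delta-method) uncertainty propagation:
#' the relative variance of T2 is the relative variance of T1 plus four times
#' that of A.
#'
#' @param t1 Longitudinal relaxation time (seconds).
#' @param A Relaxation weighting factor (> 0).
#' @param t1_se,A_se Optional standard errors (default 0).
#' @return Named numeric vector with `t2` and `se` (seconds).
#' @export
t2_from_t1_A <- function(t1, A, t1_se = 0, A_se = 0) {
  stopifnot(t1 > 0, A > 0, t1_se >= 0, A_se >= 0)
  t2 <- t1 / A^2
  rel <- sqrt((t1_se / t1)^2 + (2 * A_se / A)^2)
  c(t2 = t2, se = t2 * rel)
}
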