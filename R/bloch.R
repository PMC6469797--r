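#' Interleaved RF-and-gradient pulse train description
#'
#' The preparation train that drives longitudinal magnetization to its
#' T1/T2-weighted steady state: identical RF pulses of flip angle `fa_deg`
#' applied every `interpulse_delay` seconds, each followed by a spoiler
#' gradient lobe that dephases transverse magnetization across the voxel.
#'
#' @param fa_deg Flip angle of each pulse, degrees.
#' @param pulse_duration RF pulse duration, seconds (default 4 ms).
#' @param interpulse_delay Pulse repetition period of the train, seconds
#'   (default 10 ms, interpreted as the full pulse-to-pulse period).
#' @param n_pulses Number of pulses, or `NULL` for "until the horizon".
#' @param gradient_amplitude Spoiler amplitude, mT/m (default 2).
#' @param gradient_duration Spoiler duration, seconds (default 5 ms).
#' @param voxel_size Voxel extent along the gradient, m (default 0.02).
#' @param recovery_delay Delay between readout and the next train, seconds.
#' @return An object of class `"ipfg_train"`.
#' @export
ipfg_train <- function(fa_deg, pulse_duration = 0.004,
                       interpulse_delay = 0.010, n_pulses = NULL,
                       gradient_amplitude = 2, gradient_duration = 0.005,
                       voxel_size = 0.02, recovery_delay = 0) {
  stopifnot(fa_deg >= 0, fa_deg <= 90, pulse_duration > 0,
            interpulse_delay > 0, gradient_duration > 0,
            gradient_duration <= interpulse_delay,
            gradient_amplitude >= 0, voxel_size > 0, recovery_delay >= 0)
  if (!is.null(n_pulses)) stopifnot(n_pulses >= 1)
  structure(list(fa_deg = fa_deg, pulse_duration = pulse_duration,
                 interpulse_delay = interpulse_delay, n_pulses = n_pulses,
                 gradient_amplitude = gradient_amplitude,
                 gradient_duration = gradient_duration,
                 voxel_size = voxel_size, recovery_delay = recovery_delay),
            class = "ipfg_train")
}

# gradient phase cycles across the voxel per lobe: gamma * G * tau * L
gradient_cycles <- function(train) {
  gamma_hz_per_t <- 42.577478518e6
  gamma_hz_per_t * train$gradient_amplitude * 1e-3 *
    train$gradient_duration * train$voxel_size
}

#' Isochromat phases representing gradient spoiling
#'
#' Per-period dephasing angles across the ensemble. The spoiler lobe imparts
#' several full phase cycles across the voxel (about 8.5 for 2 mT/m over 5 ms
#' and a 2 cm voxel, checked here); only the phase modulo 2 pi matters within
#' a period, so the ensemble samples one cycle uniformly (midpoint rule),
#' which avoids aliasing between the cycle count and the ensemble size.
#'
#' @param train An [ipfg_train()]; an error is thrown if its gradient is too
#'   weak to impart at least one full cycle across the voxel.
#' @param n_isochromats Ensemble size (default 128; >= 64 recommended).
#' @return Numeric vector of per-period phases, radians, spanning one cycle.
#' @export
isochromat_phases <- function(train, n_isochromats = 128) {
  stopifnot(n_isochromats >= 2)
  if (gradient_cycles(train) < 1)
    stop("gradient imparts less than one phase cycle across the voxel; ",
         "spoiling would be ineffective")
  2 * pi * (seq_len(n_isochromats) - 0.5) / n_isochromats
}

#' Bloch simulation of the preparation train
#'
#' Evolves an ensemble of isochromats through the pulse train: each period is
#' an instantaneous rotation by the nominal flip angle followed by free
#' evolution with T1/T2 relaxation and the gradient-imposed, position-dependent
#' phase. The trajectory is the ensemble-averaged longitudinal magnetization
#' sampled at the end of each period. Transverse magnetization is dephased, not
#' destroyed, so the plateau depends on T2 as well as T1 — the effect the
#' multi-flip-angle method exploits.
#'
#' @param train An [ipfg_train()].
#' @param relax A [relaxation_params()] object.
#' @param initial_mz Starting longitudinal fraction (1 = thermal equilibrium).
#' @param horizon Maximum simulated time, seconds (used when the train does
#'   not fix `n_pulses`).
#' @param n_isochromats Ensemble size.
#' @return A data frame of class `"mz_trajectory"` with columns `time`
#'   (seconds, end of each period) and `mz` (fraction of M0), plus attributes
#'   `steady_state_value` and `steady_state_time` (first time the per-period
#'   change drops, and stays, below 0.1% of M0; `NA` if never).
#' @export
simulate_ipfg <- function(train, relax, initial_mz = 1, horizon = 20,
                          n_isochromats = 128) {
  relax <- as_relaxation(relax)
  stopifnot(abs(initial_mz) <= 1, horizon > 0)
  tau <- train$interpulse_delay
  n <- if (!is.null(train$n_pulses)) train$n_pulses else ceiling(horizon / tau)
  alpha <- train$fa_deg * pi / 180
  phases <- isochromat_phases(train, n_isochromats)
  e1 <- exp(-tau / relax$t1)
  e2 <- exp(-tau / relax$t2)
  rot <- exp(1i * phases) * e2
  ca <- cos(alpha); sa <- sin(alpha)

  mz <- rep(initial_mz, n_isochromats)
  mxy <- complex(real = rep(0, n_isochromats))
  traj <- numeric(n)
  for (k in seq_len(n)) {
    # hard pulse about x: My' = My cos a + Mz sin a; Mz' = Mz cos a - My sin a
    my <- Im(mxy)
    my_new <- my * ca + mz * sa
    mz <- mz * ca - my * sa
    mxy <- complex(real = Re(mxy), imaginary = my_new)
    # free evolution: gradient phase + T2 decay; T1 recovery
    mxy <- mxy * rot
    mz <- 1 + (mz - 1) * e1
    traj[k] <- mean(mz)
  }
  times <- tau * seq_len(n)
  d <- abs(diff(c(initial_mz, traj)))
  below <- d < 1e-3
  ss_idx <- if (all(!below)) NA_integer_ else {
    last_bad <- max(c(0L, which(!below)))
    if (last_bad >= n) NA_integer_ else last_bad + 1L
  }
  out <- data.frame(time = times, mz = traj)
  attr(out, "steady_state_value") <- traj[n]
  attr(out, "steady_state_time") <-
    if (is.na(ss_idx)) NA_real_ else times[ss_idx]
  class(out) <- c("mz_trajectory", "data.frame")
  out
}

#' Minimum repetition time for reaching the RF-driven steady state
#'
#' Simulates the train from thermal equilibrium and returns the earliest time
#' at which the per-period change of the ensemble-averaged Mz falls — and
#' stays — below `tol` of M0 (0.1% by default).
#'
#' @param train An [ipfg_train()] (its `n_pulses` is ignored; the horizon
#'   governs).
#' @param relax A [relaxation_params()] object.
#' @param tol Per-period change criterion as a fraction of M0.
#' @param horizon Simulation horizon in seconds; an error is thrown if the
#'   criterion is never met within it.
#' @param initial_mz Starting longitudinal fraction (default equilibrium).
#' @param ... Passed to [simulate_ipfg()].
#' @return Named vector `c(tr_min, tr_min_grid)`: the raw criterion time and
#'   its value rounded up to a 0.5 s protocol grid.
#' @export
find_tr_min <- function(train, relax, tol = 0.001, horizon = 20,
                        initial_mz = 1, ...) {
  stopifnot(tol > 0)
  tr <- simulate_ipfg(train, relax, initial_mz = initial_mz,
                      horizon = horizon, ...)
  d <- abs(diff(c(initial_mz, tr$mz)))
  below <- d < tol
  if (!any(below) || !below[length(below)])
    stop("steady state not reached within the horizon")
  last_bad <- max(c(0L, which(!below)))
  raw <- if (last_bad == 0L) 0 else tr$time[last_bad + 1L]
  c(tr_min = raw, tr_min_grid = ceiling(raw / 0.5) * 0.5)
}

#' Long-horizon numeric steady state of the train
#'
#' @inheritParams find_tr_min
#' @return Plateau value of Mz/M0.
#' @export
steady_state_numeric <- function(train, relax, horizon = 20, ...) {
  tr <- simulate_ipfg(train, relax, initial_mz = 1, horizon = horizon, ...)
  if (is.na(attr(tr, "steady_state_time")))
    stop("steady state not reached within the horizon")
  attr(tr, "steady_state_value")
}

#' Per-flip-angle repetition-time schedule
#'
#' For each flip angle, the repetition time is the time needed for the
#' longitudinal magnetization — destroyed by the readout excitation, so
#' starting from Mz = 0 — to come back within `tol` of that arm's steady
#' state (equilibrium for the flip-angle-0 arm), plus any fixed readout
#' overhead, rounded up to a 0.5 s protocol grid. Larger flip angles pin the
#' steady state further from equilibrium and reach it sooner, so the schedule
#' is non-increasing in flip angle.
#'
#' @param fas Flip angles in degrees.
#' @param relax A [relaxation_params()] object.
#' @param readout_overhead Fixed per-scan overhead in seconds (default 0).
#' @param tol Closeness-to-steady-state criterion, fraction of M0.
#' @param template An [ipfg_train()] supplying the train timing (flip angle is
#'   overridden per entry).
#' @param ... Passed to [simulate_ipfg()].
#' @return Data frame with columns `fa_deg` and `tr` (seconds).
#' @export
design_tr_schedule <- function(fas, relax, readout_overhead = 0, tol = 0.001,
                               template = ipfg_train(0), ...) {
  stopifnot(length(fas) >= 1, readout_overhead >= 0, tol > 0)
  relax <- as_relaxation(relax)
  tr <- vapply(fas, function(fa) {
    if (fa == 0) {
      # pure T1 recovery from saturation to within tol of equilibrium
      t_ss <- relax$t1 * log(1 / tol)
    } else {
      train <- template
      train$fa_deg <- fa
      train$n_pulses <- NULL
      sim <- simulate_ipfg(train, relax, initial_mz = 0, ...)
      ss <- attr(sim, "steady_state_value")
      ok <- which(abs(sim$mz - ss) < tol)
      # earliest period from which the trajectory stays within tol
      stay <- ok[ok > max(c(0L, which(abs(sim$mz - ss) >= tol)))]
      if (!length(stay)) stop("steady state not reached within the horizon")
      t_ss <- sim$time[stay[1L]]
    }
    ceiling((t_ss + readout_overhead) / 0.5) * 0.5
  }, numeric(1))
  data.frame(fa_deg = fas, tr = tr)
}
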