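#' Total duration of a protocol
#'
#' Sum over arms of `n_averages * tr`.
#'
#' @param protocol List of [protocol_arm()] objects (may be empty).
#' @return Seconds.
#' @examples
#' total_duration(default_protocol()) # 424 s, about 7 minutes
#' @export
total_duration <- function(protocol) {
  if (!length(protocol)) return(0)
  sum(vapply(protocol, function(a) a$n_averages * a$tr, numeric(1)))
}

#' Monte Carlo configuration
#'
#' @param n_reps Replicates per condition (default 100).
#' @param fa_grid Flip angles swept (default 50 levels spanning 20 to 70
#'   degrees; each flip angle corresponds to one signal-to-noise level since
#'   the noise is held fixed while the steady-state signal shrinks).
#' @param n_averages Averages per synthesized measurement (default 16).
#' @param seed Base seed.
#' @return An object of class `"mc_config"`.
#' @export
mc_config <- function(n_reps = 100, fa_grid = seq(20, 70, length.out = 50),
                      n_averages = 16, seed = 1) {
  stopifnot(n_reps >= 2, length(fa_grid) >= 1, n_averages >= 1)
  structure(list(n_reps = n_reps, fa_grid = fa_grid,
                 n_averages = n_averages, seed = seed),
            class = "mc_config")
}

# synthesize one arm, average, preprocess and fit; returns Glu amplitude + ANR
fit_one_arm <- function(basis, truth, arm, seed, preproc, config,
                        metabolite = "Glu") {
  syn <- synthesize_arm(basis, truth, arm, seed = seed)
  avg <- syn$fids[[1]]
  avg$samples <- Reduce(`+`, lapply(syn$fids, `[[`, "samples")) / arm$n_averages
  sp <- preprocess(avg, preproc)
  fit <- fit_spectrum(sp, basis, config)
  c(amplitude = unname(fit$amplitudes[metabolite]),
    se = unname(fit$se[metabolite]),
    anr = amplitude_to_noise(fit, sp, metabolite))
}

#' Monte Carlo sweep of fitted amplitude accuracy vs flip angle
#'
#' For each flip angle on the grid, synthesizes `n_reps` noisy measurements
#' (noise level fixed across flip angles, signal attenuated by the steady
#' state), fits each with the linear-combination model, and records the mean,
#' standard deviation and deviation-from-truth of the fitted glutamate
#' amplitude and its amplitude-to-noise ratio.
#'
#' @param config An [mc_config()].
#' @param truth A [ground_truth()] with the operating noise `sigma` set (see
#'   [calibrate_noise_sigma()]).
#' @param basis A [build_basis()] basis set.
#' @param preproc A [preproc_spec()].
#' @param fitcfg A [fit_config()].
#' @return Data frame of class `"mc_result"`: one row per flip angle with
#'   `fa_deg`, `truth_amplitude`, `mean_amplitude`, `sd_amplitude`,
#'   `deviation` (relative, mean vs truth), `mean_anr`, `sd_anr`, `n_fail`.
#' @export
run_mc <- function(config, truth, basis, preproc = preproc_spec(),
                   fitcfg = fit_config()) {
  rows <- lapply(seq_along(config$fa_grid), function(i) {
    fa <- config$fa_grid[i]
    arm <- protocol_arm(fa, tr = 10, n_averages = config$n_averages)
    tru <- truth$concentrations[["Glu"]] * arm_attenuation(truth, fa)[["Glu"]]
    reps <- vapply(seq_len(config$n_reps), function(r) {
      seed <- (config$seed * 100000L + i * 1000L + r) %% .Machine$integer.max
      tryCatch(fit_one_arm(basis, truth, arm, seed, preproc, fitcfg),
               error = function(e) c(amplitude = NA_real_, se = NA_real_,
                                     anr = NA_real_))
    }, numeric(3))
    amp <- reps["amplitude", ]
    data.frame(fa_deg = fa, truth_amplitude = tru,
               mean_amplitude = mean(amp, na.rm = TRUE),
               sd_amplitude = stats::sd(amp, na.rm = TRUE),
               deviation = mean(amp, na.rm = TRUE) / tru - 1,
               mean_anr = mean(reps["anr", ], na.rm = TRUE),
               sd_anr = stats::sd(reps["anr", ], na.rm = TRUE),
               n_fail = sum(is.na(amp)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mc_result", "data.frame")
  out
}

#' Amplitude-to-noise contour over flip angle and averages
#'
#' The ratio follows the steady-state attenuation and the square-root-of-
#' averages law, anchored at the calibrated operating point: by default the
#' glutamate amplitude-to-noise ratio is `anchor_anr` at the anchor flip angle
#' and average count, and scales as
#' `anr(fa, n) = anchor * (att(fa) / att(anchor_fa)) * sqrt(n / anchor_n)`,
#' where `att` is the observed steady-state attenuation.
#'
#' @param fa_range Flip angles (degrees).
#' @param averages_range Average counts.
#' @param truth A [ground_truth()].
#' @param anchor_anr,anchor_fa,anchor_n The calibration anchor (defaults 5,
#'   36 degrees, 16 averages).
#' @param metabolite Metabolite whose relaxation sets the attenuation.
#' @return Data frame with `fa_deg`, `n_averages`, `anr` (one row per grid
#'   point).
#' @export
anr_contour <- function(fa_range = seq(20, 70, by = 1),
                        averages_range = 2^(0:7), truth = ground_truth(),
                        anchor_anr = 5, anchor_fa = 36, anchor_n = 16,
                        metabolite = "Glu") {
  stopifnot(length(fa_range) >= 1, length(averages_range) >= 1)
  rel <- truth$relaxation[[metabolite]]
  att <- function(fa) ws_recovery_observe(mzss_fraction(rel, fa), 1,
                                          truth$ws_delay, rel$t1)
  att0 <- att(anchor_fa)
  grid <- expand.grid(fa_deg = fa_range, n_averages = averages_range)
  grid$anr <- anchor_anr * vapply(grid$fa_deg, att, numeric(1)) / att0 *
    sqrt(grid$n_averages / anchor_n)
  grid
}

#' Largest usable flip angle at a reliability threshold
#'
#' The last (largest) flip angle whose amplitude-to-noise ratio stays at or
#' above the threshold for the given number of averages — the "furthest from
#' zero" arm of the multi-flip-angle design.
#'
#' @param contour Output of [anr_contour()].
#' @param threshold Minimum acceptable ratio (default 5).
#' @param n_averages Average count to read the contour at.
#' @return The selected flip angle in degrees, or `NA` (with a warning) if no
#'   grid point satisfies the threshold.
#' @export
select_max_fa <- function(contour, threshold = 5, n_averages = 16) {
  sub <- contour[contour$n_averages == n_averages, ]
  if (!nrow(sub)) stop("contour does not cover the requested average count")
  ok <- sub$fa_deg[sub$anr >= threshold - 1e-12]
  if (!length(ok)) {
    warning("no flip angle reaches the threshold: design infeasible")
    return(NA_real_)
  }
  max(ok)
}

#' Full-chain Monte Carlo comparison of two protocols
#'
#' Runs the complete estimation chain (synthesize -> average -> preprocess ->
#' fit -> ratio regression -> T2) for each protocol over seeded replicates and
#' reports the relative root-mean-square error of T2, plus per-protocol
#' durations. T1 is held at its true value so the comparison isolates the
#' acquisition design.
#'
#' @param p_a,p_b Two protocols (lists of [protocol_arm()]).
#' @param truth A [ground_truth()] with noise set.
#' @param basis A [build_basis()] basis set.
#' @param n_reps Replicates (default 50).
#' @param seed Base seed.
#' @param preproc,fitcfg Preprocessing and fit settings.
#' @return Data frame with one row per protocol: `duration_s`,
#'   `rel_rmse_t2`, `median_rel_err_t2`, `n_fail`.
#' @export
compare_protocols <- function(p_a, p_b, truth, basis, n_reps = 50, seed = 1,
                              preproc = preproc_spec(), fitcfg = fit_config()) {
  t2_true <- truth$relaxation$Glu$t2
  one <- function(protocol, tag) {
    errs <- vapply(seq_len(n_reps), function(r) {
      study <- generate_study(protocol, truth, basis,
                              seed = (seed + 7919L * r) %% 2147483647L)
      est <- tryCatch(
        estimate_t2_study(study, basis, t1 = truth$relaxation$Glu$t1,
                          preproc = preproc, fitcfg = fitcfg),
        error = function(e) NULL)
      if (is.null(est)) return(NA_real_)
      coef(est$fit)[["t2"]] / t2_true - 1
    }, numeric(1))
    data.frame(protocol = tag,
               duration_s = total_duration(protocol),
               rel_rmse_t2 = sqrt(mean(errs^2, na.rm = TRUE)),
               median_rel_err_t2 = stats::median(abs(errs), na.rm = TRUE),
               n_fail = sum(is.na(errs)))
  }
  rbind(one(p_a, "A"), one(p_b, "B"))
}
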