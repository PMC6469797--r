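#' One acquisition arm of a multi-flip-angle protocol
#'
#' @param fa_deg Preparation flip angle, degrees.
#' @param tr Repetition time, seconds.
#' @param n_averages Number of signal averages (default 16).
#' @param n_pulses Number of preparation pulses in the train (default: fills
#'   the TR minus a 1 s readout allowance at the 10 ms period, matching the
#'   750/700/550/350 pulse counts of the reference protocol).
#' @return An object of class `"protocol_arm"`.
#' @export
protocol_arm <- function(fa_deg, tr, n_averages = 16, n_pulses = NULL) {
  stopifnot(fa_deg >= 0, fa_deg <= 90, tr > 0, n_averages >= 1)
  if (is.null(n_pulses)) n_pulses <- max(0L, round((tr - 1) / 0.010))
  structure(list(fa_deg = fa_deg, tr = tr, n_averages = n_averages,
                 n_pulses = n_pulses),
            class = "protocol_arm")
}

#' The reference four-flip-angle protocol
#'
#' Flip angles 0, 12, 24 and 36 degrees with per-arm repetition times
#' 8.5, 7.5, 6.0 and 4.5 s, 16 averages each, and trains of 750, 700, 550 and
#' 350 pulses — about 7 minutes in total.
#'
#' @return List of four [protocol_arm()] objects.
#' @export
default_protocol <- function() {
  Map(protocol_arm,
      fa_deg = c(0, 12, 24, 36), tr = c(8.5, 7.5, 6.0, 4.5),
      n_averages = 16, n_pulses = c(750, 700, 550, 350))
}

#' Ground truth for synthetic studies
#'
#' Defines everything the generator needs: per-metabolite concentrations
#' (arbitrary millimolar-like units) and relaxation times, the target
#' lineshape, the smooth baseline, the complex noise level and the
#' water-suppression recovery delay. Defaults mimic a healthy medial-frontal
#' voxel at 7 T: glutamate carries T1 = 1.15 s and T2 = 117.5 ms; the other
#' metabolites carry literature-plausible placeholder relaxation times.
#'
#' @param concentrations Named numeric vector (subset of the basis names).
#' @param relaxation Named list of [relaxation_params()].
#' @param lineshape `c(lorentzian_hz, gaussian_hz)` target broadening applied
#'   to the noiseless signal (FWHM, Hz).
#' @param sigma Complex-noise standard deviation per FID sample per average
#'   (same units as the summed metabolite FID). Use
#'   [calibrate_noise_sigma()] to pin it to an amplitude-to-noise operating
#'   point.
#' @param baseline_scale Peak amplitude of the smooth baseline as a fraction
#'   of the tallest metabolite peak (default 0.05, a gentle rolling baseline).
#' @param ws_delay Water-suppression recovery delay, seconds.
#' @param water_amp Amplitude of the unsuppressed water reference.
#' @param eddy_rad Amplitude (radians) of an optional injected eddy-current
#'   phase transient, `phi(t) = eddy_rad * exp(-t / eddy_tau)`; default 0.
#' @param eddy_tau Decay constant of the injected phase, seconds.
#' @return An object of class `"ground_truth"`.
#' @export
ground_truth <- function(
    concentrations = c(NAA = 12, NAAG = 1.5, tCr = 8, tCho = 1.5, Asp = 2.5,
                       Glu = 9, Gln = 3, GSH = 2, GABA = 1.5, mI = 6),
    relaxation = list(
      NAA = relaxation_params(1.70, 0.150),
      NAAG = relaxation_params(1.60, 0.130),
      tCr = relaxation_params(1.65, 0.125),
      tCho = relaxation_params(1.25, 0.160),
      Asp = relaxation_params(1.40, 0.110),
      Glu = relaxation_params(1.15, 0.1175),
      Gln = relaxation_params(1.20, 0.110),
      GSH = relaxation_params(1.10, 0.100),
      GABA = relaxation_params(1.30, 0.100),
      mI = relaxation_params(1.10, 0.130)),
    lineshape = c(lorentzian_hz = 5, gaussian_hz = 5),
    sigma = 0, baseline_scale = 0.05, ws_delay = 0.2,
    water_amp = 150, eddy_rad = 0, eddy_tau = 0.05) {
  stopifnot(all(concentrations >= 0), sigma >= 0, ws_delay >= 0,
            baseline_scale >= 0, all(lineshape >= 0), water_amp >= 0,
            eddy_tau > 0)
  if (!all(names(concentrations) %in% names(relaxation)))
    stop("every metabolite needs relaxation parameters")
  structure(list(concentrations = concentrations, relaxation = relaxation,
                 lineshape = lineshape, sigma = sigma,
                 baseline_scale = baseline_scale, ws_delay = ws_delay,
                 water_amp = water_amp, eddy_rad = eddy_rad,
                 eddy_tau = eddy_tau),
            class = "ground_truth")
}

# per-metabolite observed steady-state attenuation (including WS recovery)
arm_attenuation <- function(truth, fa_deg) {
  vapply(names(truth$concentrations), function(m) {
    rel <- truth$relaxation[[m]]
    ws_recovery_observe(mzss_fraction(rel, fa_deg), 1, truth$ws_delay, rel$t1)
  }, numeric(1))
}

# fixed smooth baseline shape: cubic spline through preset control points,
# returned as a time-domain FID on the acquisition grid
baseline_fid <- function(seq, scale) {
  if (scale == 0) return(complex(length.out = seq$n_points))
  n <- seq$n_points
  sw <- 1 / seq$dwell
  # shifted-order frequency axis as produced by preprocess()
  half <- ceiling(n / 2)
  freq <- (seq_len(n) - 1 - n + half) / (n * seq$dwell)
  ppm <- seq$ref_ppm + freq / seq$b0_mhz
  knots_ppm <- seq(min(ppm), max(ppm), length.out = 9)
  ctrl <- c(0.0, 0.15, -0.2, 0.55, 1.0, 0.35, -0.25, 0.1, 0.0)
  shape <- stats::spline(knots_ppm, ctrl, xout = ppm, method = "natural")$y
  s_shifted <- scale * shape + 0i
  # undo the fftshift, then inverse transform to the time domain
  idx <- c((half + 1):n, 1:half)
  s_unshifted <- numeric(n) + 0i
  s_unshifted[idx] <- s_shifted
  stats::fft(s_unshifted, inverse = TRUE) / n
}

# noiseless summed metabolite FID for one arm (target lineshape applied)
noiseless_arm_fid <- function(basis, truth, fa_deg) {
  mets <- names(truth$concentrations)
  missing <- setdiff(mets, names(basis$fids))
  if (length(missing))
    stop("metabolite(s) missing from basis: ", paste(missing, collapse = ", "))
  att <- arm_attenuation(truth, fa_deg)
  seq <- basis$seq
  times <- seq$dwell * (seq_len(seq$n_points) - 1)
  w <- apodization_weights(times, truth$lineshape[["lorentzian_hz"]],
                           truth$lineshape[["gaussian_hz"]])
  total <- complex(length.out = seq$n_points)
  for (m in mets)
    total <- total + truth$concentrations[[m]] * att[[m]] * basis$fids[[m]]$samples
  total * w
}

# tallest real peak of the noiseless fa = 0 spectrum, used to scale the baseline
reference_peak_height <- function(basis, truth) {
  fid0 <- new_fid(noiseless_arm_fid(basis, truth, 0), basis$seq)
  sp <- preprocess(fid0, preproc_spec(zero_fill_factor = 1,
                                      lorentzian_hz = 0, gaussian_hz = 0))
  max(Re(sp$intensity))
}

#' Synthesize one protocol arm
#'
#' Builds the per-average metabolite FIDs for one flip-angle arm: each basis
#' metabolite is scaled by its concentration and its steady-state attenuation
#' (including water-suppression recovery), the sum is broadened to the target
#' lineshape, a fixed smooth baseline is added, an optional eddy-current phase
#' transient is applied, and i.i.d. complex Gaussian noise of standard
#' deviation `truth$sigma` is added per average. An unsuppressed water FID
#' (same eddy phase, no noise by default) accompanies the arm.
#'
#' @param basis A [build_basis()] basis set covering the truth's metabolites.
#' @param truth A [ground_truth()].
#' @param arm A [protocol_arm()].
#' @param seed Integer seed (reproducible noise).
#' @return List with `fids` (list of per-average `simulated_fid`), `water`
#'   (one `simulated_fid`), `arm`, and `noiseless` (the clean arm FID).
#' @export
synthesize_arm <- function(basis, truth, arm, seed = 1) {
  stopifnot(inherits(arm, "protocol_arm"))
  seq <- basis$seq
  clean <- noiseless_arm_fid(basis, truth, arm$fa_deg)
  bl_scale <- truth$baseline_scale * reference_peak_height(basis, truth)
  clean <- clean + baseline_fid(seq, bl_scale)
  times <- seq$dwell * (seq_len(seq$n_points) - 1)
  eddy <- exp(1i * truth$eddy_rad * exp(-times / truth$eddy_tau))
  clean_e <- clean * eddy

  set.seed(seed)
  fids <- lapply(seq_len(arm$n_averages), function(i) {
    noise <- complex(real = stats::rnorm(seq$n_points, 0, truth$sigma),
                     imaginary = stats::rnorm(seq$n_points, 0, truth$sigma))
    new_fid(clean_e + noise, seq)
  })
  water <- truth$water_amp * exp(-pi * 10 * times) * eddy
  list(fids = fids, water = new_fid(water, seq), arm = arm,
       noiseless = new_fid(clean, seq))
}

#' Generate a complete synthetic multi-flip-angle study
#'
#' @param protocol List of [protocol_arm()] objects (default:
#'   [default_protocol()], i.e. flip angles 0/12/24/36 degrees with 16
#'   averages each).
#' @param truth A [ground_truth()].
#' @param basis A basis set from [build_basis()].
#' @param seed Integer seed; per-arm seeds are derived from it, so two studies
#'   with the same seed are identical and two seeds differ only in noise.
#' @return An object of class `"synthetic_study"`: list of per-arm outputs of
#'   [synthesize_arm()] plus the embedded `truth` and `protocol`.
#' @export
generate_study <- function(protocol = default_protocol(), truth = ground_truth(),
                           basis, seed = 1) {
  if (!length(protocol)) stop("empty protocol")
  arms <- lapply(seq_along(protocol), function(i)
    synthesize_arm(basis, truth, protocol[[i]], seed = seed * 1000L + i))
  structure(list(arms = arms, truth = truth, protocol = protocol,
                 seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  fas <- vapply(x$protocol, `[[`, numeric(1), "fa_deg")
  cat(sprintf("Synthetic study: %d arms (FA %s deg), sigma = %.3g, seed %d\n",
              length(x$arms), paste(fas, collapse = "/"), x$truth$sigma,
              x$seed))
  invisible(x)
}

#' Synthetic inversion-recovery series
#'
#' Amplitudes `a + b * exp(-TI / T1)` at the requested inversion times, with
#' optional Gaussian noise. The default models perfect inversion (`b = -2a`)
#' of the glutamate pool.
#'
#' @param truth A [ground_truth()] (supplies Glu T1) or a numeric T1 value.
#' @param inversion_times Seconds, strictly increasing. Default: the standard
#'   nine-point list 0.255 to 5.025 s.
#' @param a Equilibrium amplitude.
#' @param b Inversion amplitude (default `-2 * a`).
#' @param sigma Amplitude noise SD.
#' @param seed Integer seed.
#' @return Data frame with `ti` (s) and `amplitude`.
#' @export
make_ir_series <- function(truth = ground_truth(),
                           inversion_times = c(0.255, 0.355, 0.455, 0.655,
                                               1.225, 1.825, 2.825, 3.825,
                                               5.025),
                           a = 1, b = -2 * a, sigma = 0, seed = 1) {
  stopifnot(all(inversion_times > 0), !is.unsorted(inversion_times,
                                                   strictly = TRUE))
  t1 <- if (is.numeric(truth)) truth else truth$relaxation$Glu$t1
  amp <- a + b * exp(-inversion_times / t1)
  if (sigma > 0) {
    set.seed(seed)
    amp <- amp + stats::rnorm(length(amp), 0, sigma)
  }
  data.frame(ti = inversion_times, amplitude = amp)
}

#' Calibrate the noise level to an amplitude-to-noise operating point
#'
#' Chooses the per-sample complex noise standard deviation so that the
#' glutamate amplitude-to-noise ratio — tallest real point of the broadened
#' glutamate component divided by the spectral noise SD after preprocessing
#' and averaging — equals `anr` at the stated flip angle and average count
#' (default: ANR 5 at 36 degrees with 16 averages). The spectral noise SD per
#' unit time-domain sigma is exact: `sqrt(sum(w^2)) / sqrt(n_averages)` with
#' `w` the apodization weights (first point halved).
#'
#' @param truth A [ground_truth()].
#' @param basis A [build_basis()] basis set.
#' @param anr Target amplitude-to-noise ratio.
#' @param fa_deg,n_averages Operating point.
#' @param preproc The [preproc_spec()] the fitting pipeline will use.
#' @param metabolite Which metabolite anchors the calibration.
#' @param window ppm window in which the peak height is measured.
#' @return The calibrated sigma (scalar).
#' @export
calibrate_noise_sigma <- function(truth, basis, anr = 5, fa_deg = 36,
                                  n_averages = 16, preproc = preproc_spec(),
                                  metabolite = "Glu",
                                  window = c(1.8, 4.2)) {
  stopifnot(anr > 0)
  seq <- basis$seq
  rel <- truth$relaxation[[metabolite]]
  att <- ws_recovery_observe(mzss_fraction(rel, fa_deg), 1, truth$ws_delay,
                             rel$t1)
  times <- seq$dwell * (seq_len(seq$n_points) - 1)
  wtruth <- apodization_weights(times, truth$lineshape[["lorentzian_hz"]],
                                truth$lineshape[["gaussian_hz"]])
  fid <- new_fid(truth$concentrations[[metabolite]] * att *
                   basis$fids[[metabolite]]$samples * wtruth, seq)
  sp <- preprocess(fid, preproc)
  peak <- max(Re(sp$intensity[ppm_window(sp, window[1], window[2])]))
  w <- apodization_weights(times, preproc$lorentzian_hz, preproc$gaussian_hz)
  w[1] <- w[1] / 2
  noise_per_sigma <- sqrt(sum(w^2)) / sqrt(n_averages)
  peak / (anr * noise_per_sigma)
}
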