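test_that("plain transform preserves energy and zero-fill densifies the grid", {
  set.seed(8)
  fid <- list(samples = complex(real = rnorm(256), imaginary = rnorm(256)),
              dwell = 1e-3, b0_mhz = 297.2, ref_ppm = 4.7)
  sp <- preprocess(fid, preproc_spec(zero_fill_factor = 1, lorentzian_hz = 0,
                                     gaussian_hz = 0))
  x <- fid$samples
  x[1] <- x[1] / 2   # documented first-point convention
  expect_equal(sum(Mod(sp$intensity)^2), 256 * sum(Mod(x)^2),
               tolerance = 1e-10)
  sp8 <- preprocess(fid, preproc_spec(zero_fill_factor = 8, lorentzian_hz = 0,
                                      gaussian_hz = 0))
  expect_length(sp8$intensity, 8 * 256)
  expect_error(preprocess(list(samples = complex(0), dwell = 1e-3,
                               b0_mhz = 297.2, ref_ppm = 4.7)), "empty")
})

test_that("zero-filling leaves peak positions unchanged", {
  sq <- sequence_spec()
  fid <- simulate_press(spin_system("s", 3.2), sq)
  p1 <- preprocess(fid, preproc_spec(zero_fill_factor = 1, lorentzian_hz = 3,
                                     gaussian_hz = 0))
  p8 <- preprocess(fid, preproc_spec(zero_fill_factor = 8, lorentzian_hz = 3,
                                     gaussian_hz = 0))
  pk1 <- p1$ppm[which.max(Re(p1$intensity))]
  pk8 <- p8$ppm[which.max(Re(p8$intensity))]
  expect_lt(abs(pk1 - pk8), 1 / (2048 * sq$dwell) / 297.2)  # one coarse point
})

test_that("reference apodization yields the analytic Voigt linewidth", {
  # zero-width singlet apodized with 3 Hz Lorentz + 3 Hz Gauss: FWHM from the
  # standard Voigt approximation 0.5346 L + sqrt(0.2166 L^2 + G^2)
  sq <- sequence_spec(n_points = 8192)   # long acquisition: no truncation
  fid <- simulate_press(spin_system("s", 3.0), sq)
  sp <- preprocess(fid, preproc_spec(zero_fill_factor = 4, lorentzian_hz = 3,
                                     gaussian_hz = 3))
  y <- Re(sp$intensity)
  half <- max(y) / 2
  above <- which(y >= half)
  fwhm_hz <- (sp$ppm[max(above)] - sp$ppm[min(above)]) * sq$b0_mhz
  voigt <- 0.5346 * 3 + sqrt(0.2166 * 9 + 9)
  expect_equal(fwhm_hz, voigt, tolerance = 0.05)
})

test_that("eddy-current correction inverts an injected phase transient", {
  basis <- default_basis()
  truth_clean <- ground_truth()
  truth_eddy <- ground_truth(eddy_rad = 1.2, eddy_tau = 0.08)
  arm <- protocol_arm(0, 8.5, n_averages = 1)
  clean <- synthesize_arm(basis, truth_clean, arm, seed = 1)
  dirty <- synthesize_arm(basis, truth_eddy, arm, seed = 1)
  fixed <- eddy_current_correct(dirty$fids[[1]], dirty$water)
  ref <- clean$fids[[1]]$samples
  expect_gt(max(Mod(dirty$fids[[1]]$samples - ref)), 1)
  expect_lt(max(Mod(fixed$samples - ref)) / max(Mod(ref)), 1e-8)
  # identity for a phase-flat reference, hence idempotent afterwards
  again <- eddy_current_correct(fixed, clean$water)
  expect_lt(max(Mod(again$samples - fixed$samples)) / max(Mod(ref)), 1e-8)
  bad <- dirty$water
  bad$samples <- bad$samples[-1]
  expect_error(eddy_current_correct(dirty$fids[[1]], bad), "grid")
})

test_that("noiseless fits recover amplitudes to a fraction of a percent", {
  basis <- default_basis()
  truth <- ground_truth()
  arm <- protocol_arm(0, 8.5, n_averages = 1)
  syn <- synthesize_arm(basis, truth, arm, seed = 7)
  sp <- preprocess(syn$fids[[1]])
  fit <- fit_spectrum(sp, basis)
  expected <- truth$concentrations * marzss:::arm_attenuation(truth, 0)
  expect_true(all(abs(fit$amplitudes / expected - 1) < 0.005))
  expect_true(fit$converged)
  # single-basis synthetic with amplitude 1
  b1 <- build_basis(spin_system_library("NAA"))
  f1 <- b1$fids$NAA
  times <- f1$dwell * (seq_len(f1$n_points) - 1)
  f1$samples <- f1$samples * marzss:::apodization_weights(times, 4, 4)
  fit1 <- fit_spectrum(preprocess(f1), b1)
  expect_equal(unname(fit1$amplitudes), 1, tolerance = 1e-3)
  expect_lt(unname(fit1$se), 1e-3)
})

test_that("fitted amplitude is linear in concentration", {
  basis <- default_basis()
  t1x <- ground_truth()
  t2x <- ground_truth(concentrations = 2 * t1x$concentrations)
  arm <- protocol_arm(0, 8.5, n_averages = 1)
  f1 <- fit_spectrum(preprocess(synthesize_arm(basis, t1x, arm)$fids[[1]]),
                     basis)
  f2 <- fit_spectrum(preprocess(synthesize_arm(basis, t2x, arm)$fids[[1]]),
                     basis)
  expect_equal(unname(f2$amplitudes / f1$amplitudes),
               rep(2, length(f1$amplitudes)), tolerance = 1e-3)
})

test_that("a known zero-order phase is absorbed by the phase parameter", {
  basis <- default_basis()
  truth <- ground_truth()
  arm <- protocol_arm(0, 8.5, n_averages = 1)
  syn <- synthesize_arm(basis, truth, arm, seed = 7)
  rot <- syn$fids[[1]]
  rot$samples <- rot$samples * exp(1i * pi / 6)
  fit0 <- fit_spectrum(preprocess(syn$fids[[1]]), basis)
  fit30 <- fit_spectrum(preprocess(rot), basis)
  expect_equal(fit30$theta[["phi0"]] - fit0$theta[["phi0"]], pi / 6,
               tolerance = 0.01)
  expect_true(all(abs(fit30$amplitudes / fit0$amplitudes - 1) < 1e-3))
})

test_that("the spline baseline does not absorb the glutamate signal", {
  basis <- default_basis()
  truth <- ground_truth()
  arm <- protocol_arm(0, 8.5, n_averages = 1)
  sp <- preprocess(synthesize_arm(basis, truth, arm)$fids[[1]])
  fit_all <- fit_spectrum(sp, basis)
  fit_noglu <- fit_spectrum(sp, basis,
                            metabolites = setdiff(names(basis$fids), "Glu"))
  win <- function(f) f$window_ppm >= 2.2 & f$window_ppm <= 2.5
  e_all <- sum(Mod(fit_all$residual[win(fit_all)])^2)
  e_noglu <- sum(Mod(fit_noglu$residual[win(fit_noglu)])^2)
  expect_gt(e_noglu, 10 * e_all)
})

test_that("amplitude-to-noise hits the calibrated operating point", {
  basis <- default_basis()
  truth <- calibrated_truth()
  # calibration anchor is exact by construction: true Glu component peak over
  # the analytic spectral noise SD equals 5
  seqd <- basis$seq
  rel <- truth$relaxation$Glu
  att <- ws_recovery_observe(mzss_fraction(rel, 36), 1, truth$ws_delay,
                             rel$t1)
  times <- seqd$dwell * (seq_len(seqd$n_points) - 1)
  gfid <- basis$fids$Glu
  gfid$samples <- truth$concentrations[["Glu"]] * att * gfid$samples *
    marzss:::apodization_weights(times, truth$lineshape[["lorentzian_hz"]],
                                 truth$lineshape[["gaussian_hz"]])
  gsp <- preprocess(gfid)
  peak <- max(Re(gsp$intensity[marzss:::ppm_window(gsp, 1.8, 4.2)]))
  w <- marzss:::apodization_weights(times, 3, 3)
  w[1] <- w[1] / 2
  expect_equal(peak / (truth$sigma * sqrt(sum(w^2)) / 4), 5,
               tolerance = 1e-9)
  # the measured ratio scatters (and inflates slightly) around the anchor:
  # estimator deviations at the reliability threshold
  arm <- protocol_arm(36, 4.5, n_averages = 16)
  anr <- vapply(1:6, function(s) {
    syn <- synthesize_arm(basis, truth, arm, seed = 300 + s)
    sp <- preprocess(average_arm(syn))
    amplitude_to_noise(fit_spectrum(sp, basis), sp)
  }, numeric(1))
  expect_gt(mean(anr), 4)
  expect_lt(mean(anr), 6.5)
  # noiseless, baseline-free data: ratio is flagged infinite
  syn0 <- synthesize_arm(basis, ground_truth(baseline_scale = 0),
                         protocol_arm(36, 4.5, n_averages = 1))
  sp0 <- preprocess(syn0$fids[[1]])
  expect_identical(amplitude_to_noise(fit_spectrum(sp0, basis), sp0), Inf)
  expect_error(amplitude_to_noise(fit_spectrum(sp0, basis), sp0,
                                  noise_window = c(2, 3)), "overlaps")
})

test_that("doubling the averages four-fold doubles the measured ratio", {
  basis <- default_basis()
  truth <- calibrated_truth()
  anr_for <- function(n, seed) {
    syn <- synthesize_arm(basis, truth, protocol_arm(36, 4.5, n_averages = n),
                          seed = seed)
    sp <- preprocess(average_arm(syn))
    amplitude_to_noise(fit_spectrum(sp, basis), sp)
  }
  r16 <- mean(vapply(1:3, function(s) anr_for(16, 400 + s), numeric(1)))
  r64 <- mean(vapply(1:3, function(s) anr_for(64, 400 + s), numeric(1)))
  expect_equal(r64 / r16, 2, tolerance = 0.2)
})
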