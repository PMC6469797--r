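#' Inversion-recovery T1 fit
#'
#' Three-parameter exponential fit `S(TI) = a + b * exp(-TI / t1)` by
#' Levenberg-Marquardt nonlinear least squares, with the standard error of T1
#' taken from the fit covariance. Signed amplitudes are expected; for
#' magnitude data restore polarity first (`abs = TRUE` flips the early-TI
#' points by the best two-segment polarity).
#'
#' @param series Data frame with columns `ti` (seconds) and `amplitude`, or
#'   the output of [make_ir_series()].
#' @param abs Set `TRUE` when amplitudes are magnitudes (polarity restored by
#'   minimizing the fit RSS over the inversion point).
#' @return List with `t1`, `se`, coefficients `a` and `b`, and the `nls` fit
#'   object.
#' @export
fit_inversion_recovery <- function(series, abs = FALSE) {
  stopifnot(all(c("ti", "amplitude") %in% names(series)), nrow(series) >= 3)
  fit_signed <- function(amp) {
    df <- data.frame(ti = series$ti, amp = amp)
    a0 <- max(amp)
    b0 <- min(amp) - a0
    t10 <- stats::median(series$ti) / log(2)
    minpack.lm::nlsLM(amp ~ a + b * exp(-ti / t1), data = df,
                      start = list(a = a0, b = b0, t1 = t10),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  if (abs) {
    fits <- lapply(seq_len(nrow(series)), function(k) {
      amp <- series$amplitude
      if (k > 1) amp[1:(k - 1)] <- -amp[1:(k - 1)]
      tryCatch(fit_signed(amp), error = function(e) NULL)
    })
    rss <- vapply(fits, function(f) if (is.null(f)) Inf else
      sum(stats::residuals(f)^2), numeric(1))
    fit <- fits[[which.min(rss)]]
  } else {
    fit <- fit_signed(series$amplitude)
  }
  co <- summary(fit)$coefficients
  t1 <- co["t1", "Estimate"]
  if (t1 < 0.05 || t1 > 10)
    warning("fitted T1 outside the physiological range (0.05-10 s)")
  list(t1 = t1, se = co["t1", "Std. Error"],
       a = co["a", "Estimate"], b = co["b", "Estimate"], fit = fit)
}

#' Estimate T2 from a multi-flip-angle study
#'
#' The full estimation chain: average each arm's FIDs, optionally correct eddy
#' currents against the arm's water reference, preprocess, fit the
#' linear-combination model, then feed the per-arm metabolite amplitudes into
#' the steady-state ratio regression ([marzss()]) with the pre-determined T1.
#'
#' @param study A [generate_study()] object, or any list with `arms` (each arm
#'   a list of `fids`, `water` and a `protocol_arm`).
#' @param basis The basis set used for fitting.
#' @param t1 Pre-determined longitudinal relaxation time, seconds.
#' @param t1_se Its standard error.
#' @param metabolite Metabolite whose T2 is estimated (default `"Glu"`).
#' @param ws_delay Water-suppression recovery delay passed to [marzss()]
#'   (default: the study truth's value if embedded, else 0.2 s).
#' @param eddy_correct Apply [eddy_current_correct()] per arm.
#' @param preproc,fitcfg Preprocessing and fit settings.
#' @return List of class `"t2_report"`: the [marzss()] `fit`, per-arm
#'   amplitude table `arms`, the `lc_fits`, and echoed inputs.
#' @export
estimate_t2_study <- function(study, basis, t1, t1_se = 0, metabolite = "Glu",
                              ws_delay = NULL, eddy_correct = FALSE,
                              preproc = preproc_spec(), fitcfg = fit_config()) {
  stopifnot(t1 > 0)
  if (is.null(ws_delay))
    ws_delay <- if (!is.null(study$truth)) study$truth$ws_delay else 0.2
  fas <- vapply(study$arms, function(a) a$arm$fa_deg, numeric(1))
  if (!any(fas == 0)) stop("study lacks a flip-angle-0 arm (M0 anchor)")

  start <- NULL   # later arms warm-start from the first arm's lineshape/phase
  lc_fits <- vector("list", length(study$arms))
  for (i in seq_along(study$arms)) {
    a <- study$arms[[i]]
    avg <- a$fids[[1]]
    avg$samples <- Reduce(`+`, lapply(a$fids, `[[`, "samples")) /
      length(a$fids)
    if (eddy_correct) avg <- eddy_current_correct(avg, a$water)
    sp <- preprocess(avg, preproc)
    fit <- fit_spectrum(sp, basis, fitcfg, start = start)
    if (i == 1L) start <- unname(fit$theta)
    lc_fits[[i]] <- list(fit = fit, spectrum = sp)
  }
  flagged <- !vapply(lc_fits, function(x) x$fit$converged, logical(1))
  if (any(flagged))
    warning("spectral fit flagged non-convergence in arm(s): ",
            paste(which(flagged), collapse = ", "))

  amp <- vapply(lc_fits, function(x) x$fit$amplitudes[[metabolite]],
                numeric(1))
  se <- vapply(lc_fits, function(x) x$fit$se[[metabolite]], numeric(1))
  anr <- vapply(seq_along(lc_fits), function(i)
    amplitude_to_noise(lc_fits[[i]]$fit, lc_fits[[i]]$spectrum, metabolite),
    numeric(1))
  fit <- marzss(data.frame(fa_deg = fas, amplitude = amp),
                t1 = t1, t1_se = t1_se, ws_delay = ws_delay)
  structure(list(fit = fit,
                 arms = data.frame(fa_deg = fas, amplitude = amp,
                                   amplitude_se = se, anr = anr),
                 lc_fits = lapply(lc_fits, `[[`, "fit"),
                 metabolite = metabolite, t1 = t1, t1_se = t1_se,
                 ws_delay = ws_delay),
            class = "t2_report")
}

#' @export
print.t2_report <- function(x, ...) {
  cat(sprintf("T2 study report (%s)\n", x$metabolite))
  print(x$fit)
  cat("\nPer-arm fitted amplitudes:\n")
  print(x$arms, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a T2 report
#'
#' Writes the study summary as JSON (machine-readable) and, optionally, the
#' per-arm table as CSV. Times are reported in seconds and milliseconds with
#' labeled units.
#'
#' @param x A `t2_report` (or a list of them).
#' @param json_path Output JSON path (`NULL` to skip).
#' @param csv_path Output CSV path for the per-arm table (`NULL` to skip).
#' @return The summary list, invisibly.
#' @export
write_t2_report <- function(x, json_path = NULL, csv_path = NULL) {
  reports <- if (inherits(x, "t2_report")) list(x) else x
  summarize <- function(r) {
    co <- coef(r$fit)
    list(metabolite = r$metabolite,
         t1_s = r$t1, t1_se_s = r$t1_se,
         A = unname(co["A"]), A_se = unname(r$fit$se["A"]),
         t2_s = unname(co["t2"]), t2_se_s = unname(r$fit$se["t2"]),
         t2_ms = 1000 * unname(co["t2"]),
         r_squared = r$fit$r_squared,
         ws_delay_s = r$ws_delay,
         arms = r$arms)
  }
  out <- lapply(reports, summarize)
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(csv_path)) {
    tabs <- do.call(rbind, lapply(seq_along(reports), function(i) {
      cbind(report = i, reports[[i]]$arms)
    }))
    utils::write.csv(tabs, csv_path, row.names = FALSE)
  }
  invisible(out)
}

#' Write and read the plain-text study container
#'
#' A synthetic study is stored as a directory: a JSON manifest (protocol,
#' ground truth scalars, grid metadata) plus one CSV per FID with `re`/`im`
#' columns. The container is self-describing and diff-friendly.
#'
#' @param study A [generate_study()] result.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  seqd <- list(dwell = study$arms[[1]]$fids[[1]]$dwell,
               n_points = study$arms[[1]]$fids[[1]]$n_points,
               b0_mhz = study$arms[[1]]$fids[[1]]$b0_mhz,
               ref_ppm = study$arms[[1]]$fids[[1]]$ref_ppm)
  manifest <- list(
    format = "marzss-study-v1", grid = seqd, seed = study$seed,
    arms = lapply(seq_along(study$arms), function(i) {
      a <- study$arms[[i]]$arm
      list(index = i, fa_deg = a$fa_deg, tr = a$tr,
           n_averages = a$n_averages, n_pulses = a$n_pulses)
    }))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(study$arms)) {
    arm <- study$arms[[i]]
    for (j in seq_along(arm$fids)) {
      utils::write.csv(data.frame(re = Re(arm$fids[[j]]$samples),
                                  im = Im(arm$fids[[j]]$samples)),
                       file.path(path, sprintf("arm%02d_avg%02d.csv", i, j)),
                       row.names = FALSE)
    }
    utils::write.csv(data.frame(re = Re(arm$water$samples),
                                im = Im(arm$water$samples)),
                     file.path(path, sprintf("arm%02d_water.csv", i)),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_study
#' @param path Directory written by [write_study()].
#' @return For `read_study()`: a study-shaped list usable by
#'   [estimate_t2_study()].
#' @export
read_study <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "marzss-study-v1"))
    stop("not a recognized study container")
  g <- manifest$grid
  seqd <- list(dwell = g$dwell, b0_mhz = g$b0_mhz, ref_ppm = g$ref_ppm)
  load_fid <- function(f) {
    d <- utils::read.csv(f)
    structure(list(samples = complex(real = d$re, imaginary = d$im),
                   dwell = seqd$dwell, n_points = nrow(d),
                   b0_mhz = seqd$b0_mhz, ref_ppm = seqd$ref_ppm),
              class = "simulated_fid")
  }
  arms <- lapply(seq_len(nrow(manifest$arms)), function(i) {
    m <- manifest$arms[i, ]
    fids <- lapply(seq_len(m$n_averages), function(j)
      load_fid(file.path(path, sprintf("arm%02d_avg%02d.csv", i, j))))
    list(fids = fids,
         water = load_fid(file.path(path, sprintf("arm%02d_water.csv", i))),
         arm = protocol_arm(m$fa_deg, m$tr, m$n_averages, m$n_pulses))
  })
  list(arms = arms, seed = manifest$seed)
}
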