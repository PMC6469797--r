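# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# the full ten-metabolite basis on the default readout (built once, ~6 s)
default_basis <- function() {
  if (is.null(.fixtures$basis))
    .fixtures$basis <- build_basis()
  .fixtures$basis
}

# ground truth with noise calibrated to the ANR = 5 (36 deg / 16 avg) anchor
calibrated_truth <- function() {
  if (is.null(.fixtures$truth)) {
    t0 <- ground_truth()
    .fixtures$truth <- ground_truth(
      sigma = calibrate_noise_sigma(t0, default_basis()))
  }
  .fixtures$truth
}

glu_relax <- function() relaxation_params(t1 = 1.15, t2 = 0.1175)

# average the FIDs of one synthesized arm
average_arm <- function(arm_out) {
  avg <- arm_out$fids[[1]]
  avg$samples <- Reduce(`+`, lapply(arm_out$fids, `[[`, "samples")) /
    length(arm_out$fids)
  avg
}

# independent dense matrix exponential (scaled 24-term Taylor series), used
# as an oracle against the eigendecomposition-based propagators
expm_taylor <- function(M) {
  k <- max(0L, ceiling(log2(max(1, max(abs(M))))) + 4L)
  A <- M / 2^k
  out <- diag(nrow(M)) + 0i
  term <- out
  for (j in 1:24) {
    term <- term %*% A / j
    out <- out + term
  }
  for (j in seq_len(k)) out <- out %*% out
  out
}

# locate local maxima of the real channel of a spectrum within a ppm window
real_peaks <- function(spectrum, lo, hi, n = 2) {
  w <- which(spectrum$ppm >= lo & spectrum$ppm <= hi)
  v <- Re(spectrum$intensity[w])
  cand <- which(diff(sign(diff(v))) == -2) + 1
  idx <- w[cand[order(v[cand], decreasing = TRUE)][seq_len(n)]]
  spectrum$ppm[idx]
}
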