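---
title: "Steady-state metabolite T2 relaxometry: model, design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state metabolite T2 relaxometry: model, design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(marzss)
```

## The model

A train of identical RF pulses of flip angle FA, each followed by a spoiler
gradient, drives the longitudinal magnetization of a pool with relaxation
times T1 and T2 from thermal equilibrium `M0` into a steady state. The
closed-form steady state implemented by `mzss_fraction()` is

$$\frac{M_{zss}}{M_0} \;=\; 1 - \frac{AX}{\sqrt{1 + A^2X^2}},
\qquad A = \sqrt{T_1/T_2},\; X = \tan(\mathrm{FA}/2),\; 0 \le \mathrm{FA} \le 90^\circ .$$

This square-root form is the unique algebraic form under which the ratio
statistic

$$R_{zss} = \frac{M_0 - M_{zss}}{\sqrt{M_0^2 - (M_0 - M_{zss})^2}}$$

is *exactly* linear in $X$ with slope $A$ (substitute and simplify; the
package asserts the identity to $10^{-10}$ over a dense $(A, \mathrm{FA})$
grid). That exact linearity is the entire point of the method: amplitudes
measured at a few flip angles give $A$ by a through-origin linear regression,
and with $T_1$ measured once by inversion recovery,

$$T_2 = T_1 / A^2 .$$

Assumptions worth keeping in mind:

* **Mono-exponential relaxation.** Tissue voxels mix compartments; the
  regression fits a phenomenological single exponential. Using more than two
  flip angles with equal weights guards against bias from mild
  multi-exponential behavior, which is why the regression is equal-weight and
  through the origin (the flip-angle-0 arm defines $M_0$ and contributes the
  exact point $(0, 0)$).
* **Uncoupled-pool closed form.** The closed form ignores J couplings during
  the train. The package's density-matrix simulator quantifies the
  consequences (below).
* **Water-suppression recovery.** The water-suppression block between the
  train and the readout lets $M_z$ recover for `ws_delay` seconds;
  `correct_ws_recovery()` inverts
  $M_{obs} = M_0 - (M_0 - M_{zss})e^{-\mathrm{ws\_delay}/T_1}$. The default
  `ws_delay = 0.2` s is the duration of the standard suppression block (nine
  9 ms pulses, 12 ms inter-pulse delays, 1.2 ms spoilers, about 0.19–0.20 s);
  it is configurable because vendor implementations differ.

## Bloch simulation of the preparation train

`simulate_ipfg()` evolves an ensemble of isochromats through
pulse–precession–relaxation periods. Numerical choices:

* **Hard pulses.** The nominal flip is applied instantaneously; relaxation
  during the 4 ms pulse is neglected (4 ms ≪ T2). Steady-state behavior at
  these flip angles is insensitive to pulse shape.
* **Period.** The train period is 10 ms pulse-to-pulse. (With 750 pulses in
  the longest arm, a 14 ms period would exceed the arm's repetition time, so
  the quoted inter-pulse delay is read as the full period.)
* **Spoiling.** The 2 mT/m × 5 ms spoiler imparts ≈ 8.5 phase cycles across a
  2 cm voxel — comfortably past full spoiling. Only the phase modulo $2\pi$
  matters within a period, so the ensemble samples one cycle uniformly
  (midpoint rule, default 128 isochromats; the plateau changes by
  < 0.01% of M0 on doubling). Sampling several literal cycles instead
  aliases whenever the ensemble size divides the cycle count.
* **Transverse magnetization is dephased, not destroyed**, so the plateau
  depends on T2 — the mechanism the method measures. In the rapid-pulsing
  regime (period ≤ T2/10) the numeric plateau agrees with the closed form
  within 1% of M0 across $A \in [1, 6]$, FA ∈ [5°, 70°].

`find_tr_min()` reports the first time the per-period change of the
ensemble-averaged $M_z$ falls (and stays) below 0.1% of $M_0$. Two starting
conditions matter:

* From **thermal equilibrium**, the 36° train settles in ≈ 1.0 s, well inside
  the 4.5 s repetition time of that arm. The time is *not* monotone in FA
  from this start (small flip angles begin close to their own steady state).
* From the **post-readout saturated state** ($M_z = 0$) — the condition that
  actually recurs inside a protocol — the settle time decreases
  monotonically with FA. `design_tr_schedule()` uses this condition and
  rounds up to a 0.5 s protocol grid; for the flip-angle-0 arm it reduces to
  pure T1 recovery, $T_1\ln(1/\mathrm{tol})$. For T1 = 1.15 s this yields the
  non-increasing schedule 8.0 / 6.5 / 5.0 / 3.5 s for 0/12/24/36°; the
  reference protocol's published 8.5 / 7.5 / 6.0 / 4.5 s entries are
  consistent upper bounds (the rounding margin used there is not specified,
  so only the bound at 36° and the monotonicity are asserted).

## Density-matrix simulation and the basis set

`simulate_press()` evolves each metabolite's coupled spin system (full
isotropic J Hamiltonian, so strong-coupling distortions at 7 T appear
automatically) through an ideal 90x–180y–180y double echo with TE1 = 69 ms,
TE2 = 37 ms — a timing chosen to concentrate the glutamate C4 multiplet near
2.35 ppm. Localization gradients, shaped pulses and relaxation during the
readout are not modeled; relaxation enters as post hoc lineshape weighting.
Shifts and couplings come from the standard published tabulations; NAAG, GSH
and choline are reduced to their dominant observed proton groups (documented
in `spin_system_library()`), which keeps every Hilbert space at ≤ 6 spins.
FIDs are normalized so one proton gives unit amplitude; a basis set
(`build_basis()`) shares grid and field across members by construction.

`simulate_ipfg_coupled()` runs the full train on a coupled system with a
single-T1/T2 relaxation model per period and the same spoiling ensemble as
the Bloch simulator. With all J set to zero it reproduces the Bloch result to
machine precision. **With glutamate's real couplings the steady state falls
about 13% below the uncoupled closed form at 36°** (about 9% after projecting
the subsequent PRESS readout onto the equilibrium response, the quantity a
shape-matched fit reports), which propagates to a T2 underestimate of roughly
14–19% in a design with 98 ms ground truth. Scalar evolution during the train
is therefore a genuine, quantifiable negative bias of the technique for
strongly coupled spins — consistent with steady-state glutamate T2 estimates
sitting at the lower end of the multi-echo-time literature range — and the
package reports both the raw and readout-projected attenuations so users can
assess it for their own spin systems.

## The synthetic study generator

`generate_study()` emulates a four-arm study: per-arm, per-average FIDs built
from the basis, each metabolite scaled by concentration × steady-state
attenuation × water-suppression recovery, broadened to a target lineshape
(default 5 Hz Lorentz + 5 Hz Gauss; with the 3 + 3 Hz analysis apodization
this lands near typical in vivo 7 T linewidths of 12–14 Hz), plus a fixed
gentle spline baseline (default peak 5% of the tallest metabolite peak), an
optional eddy-current phase transient, an unsuppressed water reference, and
i.i.d. complex Gaussian noise per average. Defaults mimic a healthy
medial-frontal voxel: glutamate T1 = 1.15 s, T2 = 117.5 ms; the other nine
metabolites carry literature-plausible placeholder relaxation times (only
glutamate's values matter to the headline analyses). The noise level is not a
free dial: `calibrate_noise_sigma()` pins it so the glutamate
amplitude-to-noise ratio (tallest real point of the broadened glutamate
component over the analytic spectral noise SD) equals 5 at 36° with 16
averages — the published operating point of the protocol.

What the generator does **not** emulate: multi-channel reception (data are
single-channel), frequency drift, motion, macromolecule signals, and measured
in vivo baselines. Passing tests therefore demonstrate correctness of the
estimation chain under the stated signal model, not robustness to every
in vivo artifact.

## Linear-combination fitting

`fit_spectrum()` models the preprocessed complex spectrum in a window
(default 1.8–4.2 ppm) as non-negative basis amplitudes, a global extra
Lorentz/Gauss broadening pair, zero- and first-order phase, and a cubic
B-spline baseline (knot spacing 0.15 ppm, light second-difference penalty,
independent real/imaginary channels). Numerical choices:

* **Variable projection.** For each trial of the four nonlinear parameters,
  amplitudes and baseline are solved exactly: the penalized baseline is
  eliminated through a QR factorization and the amplitudes obtained by
  non-negative least squares (Lawson–Hanson, with an unconstrained fast
  path). The outer search is bounded quasi-Newton with a four-point
  zero-order-phase multi-start.
* **Information-complete subgrid.** Zero-filled spectral points are
  trigonometric interpolates of the plain-transform bins, so the fit uses
  every `zero_fill_factor`-th point; the model then needs only a 2048-point
  transform per evaluation. Peak heights for amplitude-to-noise ratios are
  evaluated once on the fine grid.
* **First-point halving** before the transform (the t = 0 sample is shared
  between both half-lines), applied identically to data and model.
* **Noise statistics.** Apodization correlates spectral noise across bins, so
  ordinary least squares here is unbiased but its nominal amplitude standard
  errors are indicative. A generalized-least-squares variant with the exact
  apodization covariance achieved the same replicate scatter while degrading
  noiseless fidelity (whitening amplifies late-FID baseline/model mismatch),
  so the plain solve is kept. `amplitude_to_noise()` measures the noise SD on
  the information-complete subgrid for the same reason.

On noiseless ten-metabolite data the fit recovers all amplitudes to ≤ 0.5%
(typically ≤ 0.05%); amplitudes are linear in concentration and invariant to
injected zero-order phase.

## Estimation chain, uncertainty, and what precision to expect

`estimate_t2_study()` averages each arm's FIDs, optionally applies the
water-reference eddy-current correction, preprocesses (zero-fill ×8, 3 Hz
Lorentz + 3 Hz Gauss), fits the linear-combination model per arm (later arms
warm-start from the flip-angle-0 arm's lineshape), corrects the
water-suppression recovery, and feeds the amplitudes into `marzss()`. T1
comes from `fit_inversion_recovery()` — a three-parameter signed exponential
(`a + b exp(-TI/T1)`) by Levenberg–Marquardt, with optional polarity
restoration for magnitude data.

The `marzss()` standard error is a delta-method propagation under equal
per-arm amplitude noise: the noise scale is estimated from the ratio
residuals mapped back to amplitude units and pushed through the full
estimator *including the shared M0 reference* — a residual-only regression
formula misses the coherent M0 error and under-covers by about a factor of
two. In a 4000-replicate simulation the mean reported SE matches the
empirical scatter of A within 2%. R² is the uncentered (through-origin)
definition.

Precision at the published operating point deserves honesty: with the
glutamate amplitude-to-noise ratio at 5 (36°, 16 averages), the per-replicate
scatter of the 36°-arm amplitude is about 20% — an information limit given
metabolite overlap, reproduced identically by generalized least squares — and
the equal-weight ratio regression then yields a median per-replicate relative
T2 error of roughly 30% (the through-origin R² stays near 0.97, matching the
in vivo regime). Single-study T2 values at this operating point are
correspondingly uncertain; protocol-level conclusions (which design is more
accurate, which flip angle is still reliable) rest on Monte Carlo means
across replicates, where deviations of the *mean* are at the few-percent
level. This is also why the contour tool anchors the largest usable flip
angle at ratio ≥ 5: below it, fitted-amplitude deviations inflate rapidly.

## Monte Carlo protocol tools

`run_mc()` holds the noise fixed while sweeping flip angle (each flip angle
is one signal-to-noise level) and records mean, SD and deviation-from-truth
of the fitted glutamate amplitude over seeded replicates. `anr_contour()` is
analytic — attenuation × √averages, anchored at the calibrated operating
point — and `select_max_fa()` picks the largest flip angle above a
reliability threshold (36° at ratio 5 with 16 averages, by construction of
the anchor). `compare_protocols()` runs the full chain under two protocols at
matched total duration and reports relative RMS and median T2 errors; the
variable-TR four-arm protocol (424 s) beats a fixed-8.5 s-TR protocol
truncated to the same duration (12 averages per arm), since the shortened
repetition times buy more averages per unit time. The study sizes used by the
shipped checks (20–25 replicates for directional comparisons, 100 replicates
for the headline recovery study) were chosen to make the directional effects
statistically unambiguous at fixed seeds.

## Known limitations

* The closed form treats each metabolite as an uncoupled pool; the
  density-matrix simulator shows a real scalar-evolution bias for glutamate
  (above). No correction is applied — the package quantifies, rather than
  absorbs, the effect.
* Single-channel data; no coil-combination, B1 mapping or segmentation
  machinery (tissue fractions, if any, are metadata).
* The spline baseline and global two-parameter broadening are simplifications
  of vendor fitting packages; per-metabolite broadening is available as a
  future extension point but is off by default since the generator uses a
  global lineshape.
* Amplitude SEs from the spectral fit are indicative (correlated spectral
  noise); the T2 uncertainty is driven by the ratio-regression delta method,
  which is validated, and by the T1 SE, which propagates one-for-one into T2.
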