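---
title: "Single-scan water content mapping: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-scan water content mapping: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(watermap)
```

# The measurement model

A spoiled gradient-echo acquisition with repetition time far above tissue T1
(TR = 10 s against T1 ≤ 2 s for white and gray matter at 3 T) removes T1
weighting: the signal extrapolated to echo time zero is the equilibrium
magnetization density M0 — proportional to the voxel's MR-visible water —
multiplied only by the transmit and receive field profiles. The per-echo
forward model used throughout this package is

$$M(TE) = M_0 \, f(TR, T_1, \alpha_{eff})\, \sin(\alpha_{eff})\, B_1^-\,
\mathrm{sinc}\!\left(\tfrac{\gamma}{2} g_z \Delta z\, TE\right) e^{-TE/T_2^*},$$

with the steady-state factor
$f = (1 - E_1)/(1 - \cos\alpha_{eff} \cdot E_1)$, $E_1 = e^{-TR/T_1}$, and
the unnormalized $\mathrm{sinc}(x) = \sin(x)/x$ in radians. Under this
convention the through-slice dephasing null falls at full dephasing
$\gamma g_z \Delta z\, TE = 2\pi$, which is the only reading consistent with
the half-argument inside the sinc. Phase evolves as
$\varphi_0 + \gamma\, \Delta B_0\, TE$ with a TE-independent receive phase
offset $\varphi_0$.

Assumptions inherited from the acquisition concept:

* mono-exponential magnitude decay (single water compartment per voxel);
* through-slice field inhomogeneity representable by a constant per-voxel
  gradient $g_z$ (first-order model; the in-plane gradients are estimated and
  reported but not corrected, since only the slice direction dephases within
  the excited slab);
* multiplicative, spatially smooth combined transmit/receive inhomogeneity;
* CSF is 100% water with a field-independent T1 of 4.3 s, so its intensity
  mode can serve as an internal calibration standard once its residual
  steady-state saturation (factor 0.93 at TR 10 s, effective flip 72°) is
  accounted for.

# Pipeline stages and the parameters that matter

## Decay fitting (`fit_volume`)

Background gradients come from wrapped forward phase differences divided by
$\gamma \Delta x_i TE$, averaged over echoes whose magnitude is at least half
the first echo's. Two modes exist:

* `phi0_subtract = TRUE` (default): the first echo's phase is subtracted
  voxel-wise and TE is replaced by TE − TE₁. This removes the receive phase
  offset exactly; with a smooth nonzero $\varphi_0$ the literal per-echo
  form shows a deterministic $1/TE$-weighted contamination (the tests verify
  the closed form of that bias), which is why subtraction is the default.
  The literal form is retained as a fidelity mode.
* Edge voxels copy their inner neighbour's gradient; no 3D phase unwrapping
  is attempted — per-difference wrapping to (−π, π] suffices for the small
  per-voxel phase steps the method assumes.

Echo selection keeps the largest echo prefix with
$\gamma |g_z| \Delta z\, TE \le 0.8\pi$ (at most the configured maximum); at
least 3 echoes are required for a valid fit. The fit itself is weighted
least squares on log-signal — intensity² weights by default, the standard
maximum-likelihood approximation for log-transformed data with additive
noise — with T2* capped to [1, 2000] ms (capped voxels flagged). A
Nelder-Mead nonlinear refinement is available behind `refine = "nls"` and
agrees with the log-linear route to well under 0.1% on noiseless data.
Δz is the excited slice thickness (1.5 mm), not including any slice gap:
dephasing accrues across the excited magnetization only.

For CSF-calibrated studies the full echo train should enter the fit — the
Monte-Carlo test shows the 32-echo fit of the slowly decaying CSF signal
(T2* ≈ 200 ms) more than halves the T2* error against a 12-echo subset at
SNR 97 — whereas tissue T2* can be fit on a reduced subset (`max_echoes`).

## Bias-field removal (`segment_and_debias`)

The TE = 0 map is modeled as a K-class Gaussian mixture (default
`n_classes = 4`: WM, GM, CSF and a spare class for non-brain/degraded
voxels) multiplied by the exponential of a 3D DCT expansion (default
`basis_order = 4` components per axis). EM alternates responsibilities,
class moments, and one damped Gauss–Newton step on the log-bias
coefficients; a step is accepted only if the penalized mixture
log-likelihood does not decrease, so the objective trace is monotone (a
property test asserts it). The DC component is removed and the basis
mean-centred over the fit region, fixing the gauge at unit geometric mean
field. Convergence: relative log-likelihood change below `tol = 1e-6`,
`max_iter = 200`; class variances floored at 1e-6 × data variance.

Design choices that proved load-bearing during development:

* **Fit-region erosion** (`erode_fit = 1`). Voxels on object surfaces carry
  corrupted decay fits (their gradient estimates borrow phase from
  signal-free neighbours); left in, they smear the WM class by several
  standard deviations and cap the exclusive tissue posteriors below the
  0.98 rule. The mixture and field are therefore fit on a 6-neighbourhood
  eroded foreground and evaluated everywhere.
* **Deterministic quantile initialization, restarts opt-in**
  (`n_restarts = 1`). Likelihood-ranked k-means++ restarts were implemented
  and measured: on smooth concentric anatomy, degenerate labelings in which
  the field absorbs GM/CSF contrast attain *higher* likelihood than the
  correct solution, so best-likelihood restart selection actively harms
  recovery. The quantile start is robust across coil realizations at the
  field amplitudes this model class can identify.
* **Class labeling by proton-density pattern.** The highest-mean class is
  CSF; WM and GM are the classes closest to the expected relative means
  (69/93 and 83/93 of the saturated-CSF intensity). Rank order alone
  mislabels whenever the spare class settles between two tissue modes.
* **Tissue-conditional posteriors.** The exclusive ≥ 0.98 mask rule and the
  CSF calibration threshold are applied to posteriors renormalized over the
  three tissue classes. An atlas-driven segmentation keeps non-tissue
  classes spatially away from the brain, so tissue posteriors sum to ~1
  there; an intensity-only mixture has no spatial information and any spare
  class overlaps the tissue range, capping raw posteriors below any fixed
  high-confidence cut.
* **Two passes** (`seg_passes = 2`). A second segmentation of the corrected
  image removes most residual field curvature (log-field correlation with
  truth typically rises from ~0.98 to ~0.999) and mirrors the two-run
  practice of the original processing.
* **Regularization** (`bias_reg = 0.1`). A bending-energy-style penalty
  proportional to $(k_x^2+k_y^2+k_z^2)^2$, scaled relative to the
  Gauss–Newton Hessian, discourages high-order field curvature. The original
  processing chain's exact basis cutoff and regularization are not reported;
  these defaults are chosen for the synthetic field class and exposed in
  configuration.

## Calibration (`csf_mode`, `calibrate_map`)

Voxels with tissue-conditional CSF posterior above 0.98 (≥ 100 required)
enter a 128-bin histogram over the central 99% of their intensity range; the
mode — parabolic interpolation through the maximal bin — is mapped to
`ss_factor × 100%` (93% at 3 T; an explicit override of 1.0 reproduces the
1.5 T full-relaxation convention). The mode, not the mean, is used because
the full CSF distribution is broad and asymmetric while the ventricle-like
peak is narrow. One printed statement equates the CSF mode with "94% after
correction"; the factor 0.93 used throughout is implemented and the 94%
print treated as rounding. Values above 120% are clipped for display with
the count recorded. An optional flag re-divides CSF-class voxels by the
steady-state factor for display near 100%; it is off by default to keep the
map globally linear. Binning is benign: 64- versus 128-bin calibration moves
tissue means by under 0.3 percent units in the tests.

## Statistics (`tissue_statistics`, `voxelwise_retest`, `oedema_mask`)

Per-class histograms use 64 bins over 40–110% by default; "width" is the
FWHM of a least-squares Gaussian fit to the histogram
(FWHM = 2√(2 ln 2) σ), consistent with how tissue distributions are usually
summarized in this literature. Retest analysis takes pre-aligned grids only
— **no image registration is performed anywhere in this package** — and
summarizes the voxel-wise SD map by its mean and its histogram mode (the
same interpolated-mode estimator as the calibration). The oedema rule flags
voxels above mean(WM) + 1.5·SD(WM).

# The synthetic phantoms: what they emulate, what they do not

`make_brain_phantom` builds nested ellipsoids — WM core, GM shell, CSF rim
and ventricles — with water 69/83/100%, T1 0.9/1.4/4.3 s, T2*
50.0/55.7/200 ms, optional within-class Gaussian jitter of water content
(the values behind the reported tissue widths: jitter SD ≈ 1.2 gives a WM
FWHM ≈ 2.8). `make_revolver_phantom` builds a water-filled cylinder with 10
tubes at 10–100% water and tube T1 below 3 s. Smooth multiplicative fields
are exponentials of random low-order DCT expansions (the model class the
corrector assumes — a Gaussian-blob mode exists to test mismatch), with the
log-field SD set by `log_sd` (default 0.05, i.e. ~5% fields). B0 comes as a
constant through-slice ramp or a localized hotspot; noise enters as
independent Gaussians on the real and imaginary channels (Rician magnitude,
faithful at low SNR), with `noise_sd_for_snr()` translating a target
first-echo tissue SNR (mode of signal / noise SD — 97 and 52 are the 3 T
and 1.5 T regimes) into the generator's noise fraction. Defaults: 64×64×24
voxels at 2×2×1.5 mm (desk scale, keeping the acquisition's slice
thickness); heavier multi-run tests use 48×48×16 to stay within test-time
budgets.

A green phantom test therefore establishes: correctness of the physics
forward/inverse algebra, unbiasedness of the gradient estimator, recovery
of fields from the assumed smooth class, calibration linearity, and noise
propagation. It does **not** establish performance on real anatomy:
convoluted cortex, partial-volume voxels, flow, motion, chemical shift and
k-space artifacts are all absent, and the concentric phantom geometry is in
fact *harder* than real anatomy for an intensity-only bias model (its
anatomy is itself low-order smooth).

# Known limitations

* **Field-amplitude identifiability.** With GM→CSF contrast of only ~11%,
  intensity-only joint segmentation/bias estimation becomes non-identifiable
  once the field variation approaches that scale (measured here: ~12%
  log-SD fields break it; ~5% fields are recovered with log-field
  correlation ≥ 0.98). The original method leans on atlas priors in exactly
  this regime; registration is deliberately out of scope here.
* **Smooth pathology.** A disease process producing genuinely smooth
  water-content gradients is indistinguishable from bias field by this
  model class; flagged, not resolved (untestable without clinical data).
* **Low SNR masks.** At SNR ≈ 52 the exclusive 0.98 rule yields sparser,
  recomposed masks; the calibration threshold is exposed
  (`csf_prob_threshold`) and cross-SNR comparisons in the tests are made on
  fixed ground-truth voxel sets so mask recomposition is not conflated with
  map error.
* **First-order dephasing only.** Voxels near strong susceptibility
  gradients keep a residual error after sinc correction; they are the
  dominant contributors to retest variability in the real acquisition and
  are flagged via `echoes_used`/`valid` rather than corrected beyond first
  order.
* **Printed-value discrepancies.** The design-table caption value "10.5 s"
  for the 0.5% saturation level differs from the closed form
  −2·ln(0.005) = 10.597 s; the implementation follows the formula. The SNR
  per unit time definition assumes 1/√TR scaling (fixed readout) and is
  used only for ranking TR choices, where the optimum lands between 9 and
  10 s.
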