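# watermap

Quantitative brain water-content mapping from a single long-TR multi-echo
gradient-echo (mGRE) scan.

## The problem

The water content of a voxel — the fraction of its volume occupied by
MR-visible water, in percent — is tightly regulated in healthy brain
(WM ≈ 69%, GM ≈ 83%, CSF ≈ 100%) and rises by only a few percent units in
oedema, stroke and tumors, so a clinically useful map must be accurate and
precise at the 1% level. A spoiled gradient-echo acquisition with TR ≫ T1
(here TR = 10 s, α = 90°) removes T1 weighting, so the signal extrapolated
to TE = 0 is proportional to water content times the transmit (B1+) and
receive (B1−) field profiles:

```
M(TE) = M0 · f(TR, T1, α_eff) · sin(α_eff) · B1− · sinc(γ/2 · g_z · Δz · TE) · e^(−TE/T2*)
```

with `f = (1 − E1) / (1 − cos α_eff · E1)`, `E1 = exp(−TR/T1)` the
steady-state factor, `α_eff = 0.8 · α_nom` the scanner-calibrated effective
flip angle, and the unnormalized sinc describing through-slice dephasing by a
background gradient `g_z` across the excited slice of thickness `Δz`.

The package implements the full single-scan pipeline:

1. **Decay fit** — per-voxel background gradients from the multi-echo phase
   (Δφ / (γ·Δx·TE), φ0-subtracted), echo selection under the
   `γ·|g_z|·Δz·TE ≤ 0.8π` dephasing rule, sinc correction, and weighted
   log-linear mono-exponential fitting for S0 and T2*.
2. **Bias removal** — joint Gaussian-mixture segmentation (WM/GM/CSF
   [+ non-brain]) with a multiplicative bias field modeled as the exponential
   of a low-order 3D cosine (DCT) expansion, estimated by EM with interleaved
   damped Gauss–Newton field updates; run in two passes.
3. **Calibration** — the histogram mode of high-confidence CSF intensities is
   an internal standard: it maps to `0.93 × 100%` at 3 T (the CSF
   steady-state factor for T1 = 4.3 s), so unsaturated tissue of true water
   content W reads W.
4. **Statistics** — per-tissue histograms with Gaussian-fit FWHM, the GM/WM
   ratio, voxel-wise test–retest summaries, the oedema threshold rule
   `mean(WM) + 1.5·SD(WM)`, and standard KS/ANOVA distribution comparisons.
5. **Phantoms** — a synthetic brain (nested ellipsoids, known water/T1/T2*,
   smooth bias fields, B0 gradients, Rician noise) and a 10-tube "revolver"
   ladder, with complete ground truth, so every stage is testable without
   scanner data.

I/O is NIfTI-1 (magnitude/phase 4D volumes) plus a JSON acquisition sidecar.

## Worked example

Simulate a 3 T brain acquisition at first-echo SNR 97 with smooth coil
fields, then run the full pipeline:

```r
library(watermap)
p <- acq_protocol(tr_s = 10, flip_deg = 90, cal_factor = 0.8, n_echoes = 12,
                  voxel_mm = c(2, 2, 1.5))
spec <- phantom_spec("brain", grid_shape = c(48, 48, 16),
                     jitter_sd = c(WM = 1.2, GM = 2.1),
                     bias_transmit = field_spec("dct", log_sd = 0.05, seed = 11),
                     bias_receive  = field_spec("dct", log_sd = 0.05, seed = 12))
truth  <- make_brain_phantom(spec)
series <- simulate_echo_series(truth, p,
                               noise_sd = noise_sd_for_snr(truth, p, 97),
                               seed = 7)
res <- map_water(series, seg_seed = 1)
print(res$map)
print(res$stats)
```

prints

```
water map: 48x48x16 voxels, CSF mode 887.8 -> scale 0.1048 %/unit (ss factor 0.930)
 class     mean        sd gaussian_fit_mean gaussian_fit_fwhm n_voxels
    WM 69.03156 1.3111499          69.01306          3.132221     3208
    GM 83.61374 2.9241749          83.20670          6.104104     5499
   CSF 92.94999 0.4919986          92.94764          1.386662     3007
mean(GM)/mean(WM) = 1.211
```

The CSF intensity mode (887.8 units) anchors the scale: CSF-class voxels read
93% (their signal is genuinely T1-saturated by the factor 0.93), and the
recovered tissue means match the phantom's ground truth (WM 69, GM 83) to a
few tenths of a percent unit; the calibration-independent GM/WM ratio is
1.21. `cmd_protocol(list())` prints the protocol-design table (maximum flip
angle and relative SNR per unit time per TR; saturation at 90° is 0.674% at
TR = 10 s, the 1% level is reached at TR = 9.2 s).

A file-level CLI covers the same flow:

```sh
Rscript inst/cli/watermap simulate --out_dir sim --grid 48,48,16 --snr 97 --seed 7
Rscript inst/cli/watermap map --magnitude sim/mgre_mag.nii.gz \
    --phase sim/mgre_phase.nii.gz --protocol sim/mgre_protocol.json --out_dir sim/out
```

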