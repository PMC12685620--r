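# apextrack

Markerless, diaphragm-based tumor tracking for rotational dual-kV imaging
during volumetric modulated arc therapy (VMAT), with a deterministic
synthetic phantom for end-to-end validation.

## Who this is for

Medical-physics and image-guided-radiotherapy researchers who want a
self-contained, testable implementation of the full markerless
real-time-tracking chain: stereo kV projection geometry, template-based
diaphragm-apex detection, apex-to-tumor offset modelling, and
external-surrogate prediction — without access to clinical fluoroscopy.

## What it computes

* **Geometry** — perspective projection and ray back-projection for two
  orthogonal kV imagers on a rotating O-ring gantry (SAD 1000 mm,
  SID 2000 mm, 0.2 mm isocenter pixel size by default), triangulation by
  the skew-ray midpoint rule, epipolar lines, and lateral-region
  classification (gantry angles 50–130 and 230–310 degrees).
* **Imaging** — the preprocessing chain for kV frames (fiducial inpainting
  from a 5–10 px annulus, log compression + density inversion,
  75 × 205 px resolution matching with bilinear restoration) and exhaustive
  zero-mean normalized cross-correlation (NCC) matching of 299 × 199 px
  angle-indexed diaphragm templates, with the search window constrained by
  the previous frame (±10 px horizontally, ±50 px vertically) or, in
  lateral views, by the epipolar line of the paired detection (±15 px).
* **Motion models** — breathing-extrema detection; offset-vector scenarios
  `S_no` (tumor observed directly), `S_con` (constant end-expiratory
  offset) and `S_var` (offset linear in the surrogate between
  end-expiration and end-inspiration):

  `s(p) = s_in + (s_ex − s_in)(p − p_in)/(p_ex − p_in)`

  and the quadratic surrogate correlation model ("4DM"), fitted per
  direction by closed-form least squares:

  `F(p) = a p² + b p + c + d ṗ² + e ṗ`
* **Evaluation** — signed mean ± SD, E90/E95 percentile errors (linear
  interpolation between closest ranks), reduction ratio `R = 1 − E90_SI/A`,
  asynchrony residuals and surrogate–tumor Pearson correlations.
* **Phantom** — a seeded generator for the surrogate signal
  (`sin^(2n)` breathing waveform, drift, cardiac pulsation, noise, pauses /
  deep breaths / amplitude shifts), coupled apex/tumor/marker trajectories
  with controllable phase-dependent asynchrony and hysteresis lag, and
  analytically rendered projection frames and template banks.

## Worked example

A 70 s session (351 frames at 0.2 s) on the asynchronous phantom
(phase-dependent apex–tumor asynchrony 6.1 mm, hysteresis lag 0.3 s),
with noise-free apex input:

```r
library(apextrack)
cfg <- session_config(
  anatomy = anatomy_config(asynchrony_SI_amplitude_mm = 6.1,
                           hysteresis_lag_s = 0.3),
  tracking = "truth", seed = 1)
res <- run_session(cfg)
print(res)
```

prints (abridged to the SI direction):

```
Session: 351 frames, 70.0 s, scenarios: S_no, S_con, S_var, tracking: truth
 scenario direction    mean_mm   sd_mm  e90_mm  e95_mm  A_mm      R
     S_no        SI  0.0063116 0.15363 0.20139 0.29620 9.988 0.9798
    S_con        SI -2.4611129 3.99478 9.28980 9.34804 9.988 0.0699
    S_var        SI  0.5169793 2.61949 4.56683 4.88070 9.988 0.5428
```

Reading: with the tumor directly observable (`S_no`) the 4DM predicts the
evaluation window almost perfectly; a constant offset vector (`S_con`)
leaves most of the 6.1 mm phase-dependent asynchrony plus the lag as error
(SI E90 9.3 mm); the phase-dependent offset (`S_var`) removes the
asynchrony and halves that error (4.6 mm), the residual being the
hysteresis lag that an offset affine in the surrogate cannot represent.
`A` is the session's peak-to-peak SI pseudo-tumor excursion and `R` the
fraction of it removed by tracking. Setting `tracking = "image"` runs the
same session through frame rendering, preprocessing, NCC matching and
triangulation instead (about 4 minutes on one CPU; median 3D apex error on
the clean phantom is ~0.2 mm).

## Command line

```sh
Rscript inst/cli/apextrack.R run-session --seed 1 --tracking truth --out out/
Rscript inst/cli/apextrack.R simulate --seed 1 --frames --out phantom/
```

Artifacts are CSV (signal, ground truth, apex track, predictions, error
summaries), JSON (offset + 4DM models) and 16-bit PGM frames.
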