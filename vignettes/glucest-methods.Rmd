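---
title: "GluCEST analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GluCEST analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucest)
```

## The forward model

Saturation transfer is modelled with the Bloch-McConnell equations for a
star exchange topology: bulk water plus solute pools (glutamate amine at
+3 ppm, optionally creatine at +1.9 ppm) that each exchange protons with
water. For pool $i$ with offset $\Delta_i$ from the saturation frequency,
relaxation rates $R_{1i}, R_{2i}$, and exchange rate $k_i$ (solute to
water; the reverse rate is $k_i f_i$ with $f_i$ the proton fraction
relative to water), the magnetization obeys a linear ODE system driven by
the saturation amplitude $\omega_1 = 2\pi\,\gamma B_1$. During a constant
pulse the system is linear time-invariant, so each segment is propagated by
one matrix exponential of the augmented $(3n{+}1)$ generator — the exact
solution, not a discretisation. The independent check in the test suite is
a fixed-step RK4 integrator written directly from the componentwise
equations; the two agree to ~1e-12, far inside the 1e-4 gate.

The default saturation scheme is four 250 ms square pulses with sub-10 µs
gaps at 250 Hz peak B1. Gaps below 0.1 ms are folded into continuous-wave
saturation of the total duration (1 s); longer gaps are simulated as
alternating saturation/free-precession propagators. An 8 s recovery delay
justifies starting each offset from thermal equilibrium.

Z-spectra are reported as $Z(\Delta\omega) = M_{sat}/M_0 \in [0,1]$, and
the contrast is the asymmetry
$\mathrm{MTR_{asym}} = 100\,(Z(-\Delta\omega) - Z(+\Delta\omega)) /
Z(-\Delta\omega)$ evaluated at 3 ppm. Positive offsets are downfield of
water, so an amine pool at +3 ppm gives positive contrast.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| water T1 / T2 | 1.8 / 0.05 | s | typical brain parenchyma at 9.4 T |
| glutamate shift | +3 | ppm | amine proton resonance |
| glutamate exchange rate | 5500 | s⁻¹ | literature-typical fast amine exchange |
| protons per glutamate | 3 | — | amine group content |
| glutamate T1 / T2 | 1.0 / 0.008 | s | short-T2 labile protons |
| creatine pool | +1.9 ppm, 950 s⁻¹, 4 H | — | optional background species |
| peak B1 | 250 (5.87 µT) | Hz | the acquisition's stated amplitude |
| offsets | ±2.5 … ±3.5 (step 0.25) | ppm | the imaging ladder; 0…±5 step 0.2 for asymmetry plots |
| Hz per ppm | 400.2 | Hz | 9.4 T proton frequency; overridable everywhere |
| TE list | 3.5, 4.0, 4.5 | ms | B0 mapping echoes (ΔTE = 0.5 ms ⇒ 1 kHz Nyquist) |
| flip angles | 30 / 60 | ° | double-angle pair |
| B1 plausibility band | 0.5–1.5 | — | beyond it the linear correction is meaningless; pixels flagged invalid |
| model-selection α | 0.01 | — | the study's significance level |

None of the pool parameters are printed in the source study; they are
field-typical values chosen once, and every generator accepts overrides.
At these parameters the simulated contrast is percent-scale (≈7–10 % for
10–15 mM glutamate with the creatine background) rather than the in vivo
≈23–26 %, which also includes semisolid MT and other amides; absolute
in vivo contrast is not a target of the simulator.

A consequence worth knowing: with fast exchange (5500 s⁻¹) at 250 Hz B1
the asymmetry curve is broad and its maximum sits slightly upfield of
3 ppm (around 2–2.5 ppm). The tests therefore check curve shape (3 ppm on
the high shoulder, dominating 1 and 5 ppm) rather than an exact peak
location.

## What the synthetic data emulate — and what they do not

The phantom generator emulates: per-pixel z-spectra from region-wise pool
sets (a control-like striatum at 12.3 mM glutamate, a lesioned one at
14.4 mM, creatine-bearing tissue elsewhere), smooth B0 fields (default
±0.3 ppm) and B1 fields (default 0.85–1.15), Rician magnitude noise
(Gaussian on the complex channels), and the companion acquisitions: GRE
phase evolving as $2\pi B_0 TE$ plus a receiver phase, wrapped to
$(-\pi,\pi]$, and flip-angle magnitudes following $\sin(\alpha\,s_{B1})$.
The cohort generator draws [Glu] per group (12.3 ± 1.0, 14.4 ± 1.1 mM;
n = 16/19), places true GluCEST on the line 1.31 %/mM · [Glu] + 6.81 %,
and adds Gaussian scan noise.

It does not emulate: k-space/readout effects, slice profiles, motion,
semisolid magnetization transfer or rNOE pools, partial volume, or
anatomical geometry. A green test therefore establishes correctness of the
processing chain against its own stated forward model — not in vivo
fidelity of the absolute contrast level.

The cohort noise SD default is **derived, not assumed**: for a single line
with predictor variance $\mathrm{Var}(x)$ (here the two-group mixture
variance, 2.208 mM²), $R^2 = b^2\mathrm{Var}(x) / (b^2\mathrm{Var}(x) +
\sigma^2)$, so the printed $R^2 = 0.86$ implies $\sigma \approx 0.79\,\%$
(`calibration_noise_sd()`). The printed within-group GluCEST SD (0.8 %) is
actually *smaller* than slope × within-group [Glu] SD (≈1.31 %), which a
noise-free linear law cannot produce with independent errors; the
generator exposes an `error_correlation` mode for correlated per-animal
errors, but the independent-error model with the derived σ is the default
because the true error structure is unknown.

## Numerical and design choices

* **B0 mapping.** Phase is unwrapped temporally (successive inter-echo
  differences wrapped to $(-\pi,\pi]$, then accumulated), which is exact
  for |B0| below $1/(2\Delta TE)$ = 1 kHz; a raster 2-D spatial unwrap is
  available behind `spatial_unwrap = TRUE` for fields that wrap spatially.
  Ordinary least squares of phase on TE is the default; magnitude-squared
  weighting sits behind `weighted = TRUE` (the original work does not say
  which it used).
* **B1 mapping.** The double-angle estimator
  $\alpha = \arccos(S_{2\alpha}/2S_\alpha)$ is adopted; it is the standard
  estimator consistent with a 30°/60° pair, and it exactly inverts the
  generator's sine law at zero noise. Pixels outside the arccos domain are
  flagged invalid rather than clipped.
* **B0 correction.** Natural cubic spline interpolation of each pixel's
  z-spectrum *within each same-sign limb* (the ladder leaves the water dip
  unsampled, so interpolation never crosses it), resampled at the acquired
  offsets shifted by the pixel's B0 in ppm. Shifts that push a sample
  outside its limb yield NA — no extrapolation — and the pixel is flagged
  invalid if ±3 ppm become unavailable.
* **B1 correction.** Applied to the contrast map (division by the relative
  B1), not to raw spectra, matching the "linear correction as a ratio of
  actual to expected B1" description. The correction is first-order; the
  tests hold region means to 5 % relative under a 0.85–1.15 field.
* **Pipeline order** is fixed and logged: assemble → B0-correct →
  asymmetry → B1-correct. (Whether the original pipeline B1-corrected
  before or after the asymmetry is not stated; this order is the package's
  convention and is recorded in the processing log.)
* **Model selection.** Sequential nested F-tests at α = 0.01: full
  interaction vs common-slope, then common-slope vs single line, choosing
  the simplest non-rejected model. On noise-free data the F statistic is
  0/0; a simpler model whose RSS is below $10^{-10}$ of the total sum of
  squares is accepted outright, making the noiseless recovery well-defined.
* **Fit method.** Ordinary least squares is primary even though both axes
  carry measurement error (the study tabulates errors but does not state an
  error-weighted fit; its printed slope 1.31 is close to but not equal to
  the two-group-mean slope ≈1.38, which OLS on scattered subjects
  reproduces naturally). A Deming errors-in-variables option
  (`method = "deming"`, variance ratio from the tabulated errors) is
  provided for sensitivity analysis.
* **Background split.** `GluCEST_average` is the subject-weighted grand
  mean over both groups — with 16 + 19 subjects and the printed group means
  this reproduces the ≈27 % / ≈73 % split; equal-group weighting would not.
  The split is invariant under rescaling all GluCEST values.
* **Inter-animal CV aggregation.** Inter-animal CV is computed per session
  across subjects and then averaged over sessions (the "mean ± SD over 3
  values" form of the reported number); per-subject CVs across sessions
  give the intra-animal figure. Both vectors are returned so either
  convention can be inspected.
* **CV caveat.** With only between-session noise, the simulated
  inter-animal CV also absorbs true between-subject spread, so it lands
  higher than the reported 3.3 % unless subjects are drawn from one
  homogeneous group, as in the study's reproducibility arm.
* **NIfTI I/O** is a minimal built-in NIfTI-1 float32/int reader-writer
  (uncompressed single-file `.nii`, little-endian) because no NIfTI package
  is assumed; it round-trips everything the pipeline writes and the header
  fields are covered by byte-level tests.

## Scaling of the shipped checks

The acceptance-style phantom checks in the test suite run on a 16 × 24 grid
(the generator's cost is one matrix exponential per pixel × offset) so the
whole suite stays under half a minute; the same code scales to the default
32 × 32 grid in a couple of seconds per run. The R² reproduction uses 200
replicate cohorts, matching its stated replicate count.

## Known limitations

* No semisolid MT or rNOE pools: background in the simulator comes from
  creatine only, so the phantom's intercept-based background share is
  smaller than the in vivo ≈27 %.
* The linear B1 correction is first-order; strongly non-uniform transmit
  fields (outside 0.5–1.5) are flagged, not corrected.
* Temporal unwrapping assumes |B0| < 1 kHz at ΔTE = 0.5 ms; stronger
  gradients need the spatial unwrap flag or closer echoes.
* Star exchange topology (all solutes exchange with water only); no
  solute-solute exchange.
* Magnitude images at very low SNR acquire a Rician floor that biases Z
  upward; the pipeline does not debias it.
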