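# glucest

Glutamate chemical exchange saturation transfer (GluCEST) MRI analysis in R:
a Bloch-McConnell z-spectrum simulator with known ground truth, B0/B1
field-map reconstruction, corrected MTRasym contrast maps, ROI and
test-retest statistics, and the GluCEST-vs-[Glu] calibration with
background decomposition.

## The problem

GluCEST images brain glutamate indirectly: a frequency-selective pulse
saturates the glutamate amine protons resonating **+3 ppm** downfield of
water, and chemical exchange carries that saturation into the water signal.
The contrast is the asymmetry of the z-spectrum about water,

```
GluCEST_asym(Δω = 3 ppm) = 100 × [ M_sat(−3 ppm) − M_sat(+3 ppm) ] / M_sat(−3 ppm)
```

Two practical questions decide whether GluCEST is usable as a biomarker:

1. **Field inhomogeneity.** Static (B0) and transmit (B1) field errors shift
   and scale the saturation, biasing the asymmetry. The pipeline maps B0 by
   a linear fit of multi-echo gradient-echo phase against TE (after
   unwrapping) and B1 by the double-angle method from 30°/60° preparation
   images, then resamples each pixel's z-spectrum to the true water frame
   and rescales the contrast linearly by the relative B1.
2. **Specificity.** Other amine/amide protons (creatine, macromolecules)
   also contribute. Regressing per-animal GluCEST (%) on ¹H-MRS glutamate
   concentration [Glu] (mM) gives a calibration line; its intercept is the
   contrast that would remain at zero glutamate, so the **non-glutamate
   background fraction** is

```
background (%) = 100 × GluCEST_at[Glu]=0 / mean(GluCEST)
```

Everything is exercised on synthetic data with known ground truth: pool
exchange models integrated through the saturation scheme (4 × 250 ms square
pulses at 250 Hz peak B1, duty cycle 100%), smooth B0/B1 corruption fields,
Rician magnitude noise, and two-group cohorts on a known calibration line.

## Worked example

```r
library(glucest)

# z-spectrum of a 12.3 mM glutamate voxel under the default scheme
z <- simulate_zspectrum(list(water_pool(), glutamate_pool(12.3)),
                        saturation_scheme())
round(z, 4)
#>  -3.50  -3.25  -3.00  -2.75  -2.50   2.50   2.75   3.00   3.25   3.50
#> 0.6196 0.5775 0.5298 0.4762 0.4167 0.3806 0.4379 0.4913 0.5404 0.5851
```

The downfield (+) limb sits below the upfield (−) limb: that asymmetry is
the glutamate signal, here `100*(0.5298-0.4913)/0.5298` ≈ 7.3 %.

```r
res <- run_pipeline(pipeline_config(seed = 1))
res$roi[, c("roi", "glucest_mean", "glucest_sd", "n_pixels")]
#>                roi glucest_mean glucest_sd n_pixels
#> 1 striatum-control     9.013155  0.5650675       36
#> 2  striatum-lesion    10.043042  0.4451520       36
res$fit
#> <calibration_fit> GluCEST (%) = 1.318 x [Glu] (mM) + 6.693; R^2 = 0.972; model = single_line
res$background
#> <background_estimate> background 27.4% / glutamate 72.6% of mean GluCEST 24.46% (intercept 6.69%)
res$reproducibility
#> <reproducibility_report> intra-subject CV 3.3 +/- 1.7 %; inter-subject CV 9.3 +/- 1.0 %
```

The phantom's two striatum-like regions (12.3 vs 14.4 mM glutamate) remain
separated after B0/B1 corruption and correction; the simulated 35-subject
cohort recovers its generating line (slope ≈ 1.31 %/mM, intercept ≈ 6.8 %)
and splits the signal into ≈27 % background and ≈73 % glutamate.

A command-line driver wraps the stages (`simulate`, `fieldmap`, `glucest`,
`quantify`, `calibrate`, `run`):

```sh
Rscript inst/scripts/glucest run --config cfg.json --out out/
```

Outputs are NIfTI maps, CSV tables, and JSON fit/provenance records.

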