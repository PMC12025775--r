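# tearllt

Estimation of tear-film **lipid layer thickness (LLT)** from the interference
colors recorded by a Placido-disk tear-film analyzer, plus the pre/post
two-group statistical stage used in dry-eye treatment studies.

The lipid film on the tear surface is tens of nanometres thick, so white light
reflected from it shows thin-film interference colors: the color of each pixel
encodes the local film thickness. The package implements the device-style
estimation pipeline:

1. **Frame selection.** From a lipid-layer video, the analysis frame is the
   one captured 0.5 s after the end of the second natural blink. Blinks are
   detected as contiguous runs of frames whose mean intensity drops below a
   fraction of the sequence's baseline intensity.
2. **Region of interest.** Only the lower half of the cornea is analyzed
   (the upper half is routinely obscured by lashes and lids): pixels inside a
   configured corneal circle and strictly below its center row.
3. **Nearest-color classification.** Each ROI pixel *(r, g, b)* is assigned
   the thickness of the lookup-table entry *(R, G, B)* minimising the
   Euclidean distance
   *d = sqrt((r − R)² + (g − G)² + (b − B)²)*,
   with ties broken toward the smaller thickness. No segmentation is applied.
4. **Calibration.** The mean classified thickness is mapped through the fixed
   affine calibration *LLT = 0.6 × raw + 10* (nm).
5. **Sectioning.** The ROI is split at the horizontal midline of its bounding
   box; the absolute difference between the calibrated upper- and
   lower-section LLTs is the *vertical difference*, a measure of lipid
   distribution.

The lookup table can be loaded from CSV (`thickness_nm,red,green,blue`) or
generated from first principles: the two-beam normal-incidence reflectance of
a lipid film (n = 1.48) on water (n = 1.336),
*R(λ) = r₁² + r₂² + 2 r₁ r₂ cos(4π n T / λ)*, integrated against the CIE 1931
color-matching functions under an equal-energy illuminant. The same forward
model renders synthetic interferograms with known ground truth, so every
stage is testable without clinical data. A cohort simulator draws per-eye
(pre, post) dry-eye parameters (OSDI, NIBUT, NITMH, redness, LLT, vertical
difference, meibography) from bivariate normals parameterised by published
two-arm summary statistics (treatment n = 94, control n = 91), and
`summarize_study()` reproduces the statistical stage: Kolmogorov–Smirnov
normality screening, within-group paired t tests, and between-group
independent t tests on change scores, at α = 0.05.

## Worked example

```r
library(tearllt)

# lookup table: load the bundled synthetic 0-160 nm table (or build one)
tab <- load_reference_table(
  system.file("extdata", "lookup_synthetic.csv", package = "tearllt"))

# synthetic eye: thickness rising from 80 nm (top) to 120 nm (bottom),
# rendered through the same table with channel noise
field <- generate_thickness_field(c(64, 64), "vertical_gradient",
                                  list(top = 80, bottom = 120),
                                  grid_range = c(0, 160))
img <- render_interferogram(field, tab, noise_sd = 6, seed = 42)

fit <- estimate_llt(img, tab, roi_spec(31.5, 20, 30))
fit
#> Lipid layer thickness estimate
#>   calibrated LLT: 70.27 nm (raw mean 100.45 nm over 1380 pixels)
#>   sections: upper 68.24 nm, lower 73.11 nm, vertical difference 4.87 nm
```

The ROI covers the lower cornea, where the gradient field averages close to
100 nm raw; calibration maps that to ~70 nm, and the downward-increasing
thickness shows up as a positive vertical difference.

```r
co <- generate_cohort(study_cohort_params(), seed = 11,
                      parameters = c("llt", "nibut_avg"))
summarize_study(co)
#> Pre/post study report (student independent test, alpha = 0.05)
#>
#>  parameter   group  n           pre          post        p p_change
#>  nibut_avg  CsA-CE 94  10.38 ± 3.70  13.02 ± 4.95 <0.001 *    0.002
#>  nibut_avg control 91  12.07 ± 4.54  12.44 ± 5.43    0.501    0.002
#>        llt  CsA-CE 94 69.89 ± 23.23 84.75 ± 22.21 <0.001 *    0.004
#>        llt control 91 77.10 ± 28.16 81.48 ± 24.22    0.123    0.004
#>
#>   * within-group paired t significant at p < 0.05
```

The simulated treatment arm shows the expected pattern: a significant
within-group LLT increase for the treated eyes, none for the controls, and a
significant between-group difference in the change scores.

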