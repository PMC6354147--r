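# secmorph

Section-plane sensitivity of two-dimensional bone-graft morphometry, as a
fully reproducible in-silico study.

## The problem

After socket-preservation grafting, healing is quantified by morphometry on
a single 2D section — percent **bone**, **graft** (residual hydroxyapatite
particles) and **noncalcified** area inside a 4 × 4 mm region of interest.
Whether that number means much depends on how sensitive it is to the exact
cutting plane. This package replicates a study design that measures that
sensitivity: match a virtual micro-CT section to a reference (histology)
image, then move the plane by ±4 pixels (±79 µm at 19.75 µm pixel pitch)
parallel to itself and rotate it ±10° about the vertical in-plane axis,
and quantify how the morphometric values change.

Agreement between two measurement series \(x, y\) is summarized by Lin's
concordance correlation coefficient

```
CCC = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)
```

with a 95 % CI (inverse-tanh transform, asymptotic SE), the mean paired
difference ± SD, Bland–Altman limits of agreement (bias ± 1.96 SD), and an
ICC(A,1) comparator. The real specimens are unavailable, so the pipeline
works on synthetic three-phase microstructure phantoms (thresholded
Gaussian random field bone + hard-sphere graft particles) and reproduces
the design and its qualitative finding — high concordance at the matched
plane, degraded concordance at every offset/rotated plane — not the
original coefficient values.

It is aimed at researchers in trabecular/graft morphometry who want a
tested reference implementation of the agreement statistics and a sandbox
for section-plane sensitivity questions.

## Worked example

```r
library(secmorph)

report <- run_study(study_config(seed = 42L))   # 16 synthetic specimens
print(report$table_bone[, c("reference", "comparator", "ccc",
                            "ci_lower", "ci_upper", "mean_diff", "sd_diff")],
      digits = 3)
```

```
 reference comparator   ccc ci_lower ci_upper mean_diff sd_diff
        HM   original 0.995    0.990    0.998     0.232   0.508
        HM   offset+4 0.653    0.279    0.855     2.086   5.062
        HM   offset-4 0.735    0.462    0.880    -0.058   5.137
        HM     rot+10 0.319   -0.113    0.650    -2.736   8.491
        HM     rot-10 0.575    0.291    0.766    -5.428   3.771
  original   offset+4 0.659    0.276    0.862     1.854   5.231
  original   offset-4 0.751    0.471    0.894    -0.290   5.087
  original     rot+10 0.329   -0.113    0.662    -2.968   8.586
  original     rot-10 0.568    0.279    0.763    -5.659   3.923
```

Reading the table: the first block compares the histology-proxy
measurement of percent bone area against the original (matched-plane)
virtual section and its four plane variants; the second block compares the
original section against its variants. At the matched plane the
concordance is near-perfect (CCC 0.995, mean difference 0.23 ± 0.51
percentage points); moving the plane 79 µm or rotating it 10° drops the
CCC to 0.32–0.75 and inflates the difference SD roughly tenfold — the
section plane materially changes what a single 2D image measures.
`report$table_graft` shows the same pattern for percent graft area, and
`report$bland_altman` holds the per-comparison difference-vs-mean point
sets.

The numbered scripts under `analysis/` run the full narrative: phantom
generation (`01`), planted-plane recovery by the formalized trial-and-error
search (`02`), the 16-specimen study above (`03`), and the offset/rotation
sensitivity sweep (`04`), each writing its tables under `results/`.

## Package layout

* `R/` — phantom generator, section-plane geometry and extraction,
  luminance-threshold segmentation, percent-area morphometry and overlap
  rates, plane search, agreement statistics, study pipeline, TIFF/PNG/JSON
  I/O.
* `vignettes/section-plane-sensitivity.Rmd` — models, conventions,
  parameter choices and limitations.
* `analysis/` — the numbered study drivers; `tests/testthat/` — the test
  suite, including study-level acceptance tests.
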