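---
title: "Section-plane sensitivity of 2D bone-graft morphometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Section-plane sensitivity of 2D bone-graft morphometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secmorph)
```

## The question

Two-dimensional morphometry of grafted bone — percent bone, graft and
noncalcified area measured on a single histologic or tomographic section —
implicitly assumes that the chosen section plane is representative. This
package replicates, entirely in silico, a study design that probes that
assumption: match a virtual tomographic section to a reference (histology)
image, then move the section plane by ±4 pixels (±79 µm at a 19.75 µm
pixel pitch) parallel to itself and rotate it ±10° about the vertical
in-plane axis as seen from the occlusal view, and quantify how much the
morphometric values change. Agreement is summarized with Lin's concordance
correlation coefficient (CCC)

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

the mean paired difference ± its SD, and Bland–Altman limits of agreement
$\text{bias} \pm 1.96\,\mathrm{SD}$. The expected signature is high
concordance at the matched plane and visibly degraded concordance at every
offset and rotated plane.

The original specimens (16 grafted beagle-mandible biopsies) are physical
objects we cannot access; the pipeline therefore reproduces the *design*
and the *ordinal pattern* of the study on synthetic specimens, never its
printed coefficient values.

## Synthetic specimens

`generate_phase_volume()` builds a three-phase label volume on an isotropic
grid (default 19.75 µm/voxel, the reconstructed pixel pitch the design
assumes):

* **Bone** is a thresholded Gaussian random field: white noise smoothed
  with a Gaussian kernel of width `correlation_length` (default 60 µm ≈ 3
  voxels, giving trabecula-like structures a few voxels across), cut at
  the empirical quantile that realizes the target bone fraction. This is
  the simplest stationary, spatially correlated binary microstructure
  whose sensitivity to plane shifts is controlled by a single length
  scale. Smoothing uses periodic FFT convolution; the wrap-around boundary
  is irrelevant at the scales measured.
* **Graft** particles are hard spheres (radius ~ N(55, 15²) µm, truncated
  at one voxel) rejection-sampled into non-bone space until the target
  fraction is approached; placement fails loudly, naming the realized
  fraction, if the target is unreachable. Sphere radii around 55 µm keep
  the default 15 % graft fraction reachable inside the pore space of a
  30 % bone phantom — the source design gives no quantitative particle
  size or packing, so these defaults are chosen for testability, not
  biological fidelity.
* **Noncalcified tissue** is everything else.

`render_grayscale()` maps phases to grayscale means (defaults 50 / 160 /
230: residual hydroxyapatite is slightly *denser* than mineralized bone,
so the narrow contrast gap sits between bone and graft, with soft tissue
far darker), adds Gaussian noise (default SD 10) and an optional Gaussian
blur. `make_histology_proxy()` stands in for the stained physical section:
the phase volume sectioned at the nominal plane perturbed by a configurable
offset/tilt, with a fraction of pixel labels flipped (default 5 %).
Label-flip noise — rather than intensity noise — models inter-modality
disagreement directly at the level where the measurement happens, since
the histology measurement is itself a segmentation.

What the phantom does **not** emulate: anisotropic or plate-like trabecular
architecture, partial-volume blur at phase boundaries, histologic shrinkage
and tearing, staining variability, CT artefacts (beam hardening, rings).
Passing tests therefore demonstrate the pipeline's internal correctness
and the geometric sensitivity effect, not agreement magnitudes for real
tissue.

## Geometry

A `section_plane` is an origin (rectangle center), an orthonormal
right-handed frame $(u, v, n = u \times v)$, a pixel pitch and an extent.
Voxel $(i,j,k)$ (0-based) is centered at `origin + (i,j,k)·spacing`; this
voxel-center convention makes axis-aligned extraction reproduce the raw
array slice bit-for-bit, which anchors the geometry tests. Parallel offsets
move along $+n$ (buccal = '+'); rotations pivot about the in-plane vertical
axis $v$ through the image center, clockwise from the occlusal view
(looking along $-v$) being '+'. The rotation pivots about the image center
because a rotation "seen from the occlusal view" that keeps the displayed
image centered must do so; the pivot location is the one genuinely open
reading of the design and is recorded in provenance. Offset and rotated
variants are always derived independently from the original plane, never
chained.

Extraction samples pixel $(a,b)$ at
`origin + (a-(n_u-1)/2)·pitch·u + (b-(n_v-1)/2)·pitch·v`, trilinearly for
grayscale and nearest-neighbor for labels. Out-of-volume samples are
masked invalid, never zero-filled — zero-filling would masquerade as
noncalcified tissue and bias percent areas. Histology slice thickness
(tens of µm) is not modeled as a projection; sections are ideal planes.

## Segmentation and morphometry

Sections are partitioned by two luminance thresholds (dark → noncalcified,
middle → bone, bright → graft by default, configurable). The thresholds
default to the three-class Otsu solution — maximizing between-class
variance on a 256-bin histogram of the valid pixels, computed per image
because threshold selection in the emulated workflow was per image. Manual
override masks (`apply_manual_override()`) replace automatic labels where
provided, mirroring the manual demarcation of ambiguous boundaries. No
morphological cleanup is applied by default.

Percent areas are exact pixel-count ratios over valid pixels inside a
centered region of interest (default 4 × 4 mm, clipped to the image; the
default 64³ study phantom is 1.26 mm across, so the ROI is effectively the
whole section — a 256³ `phantom_spec_full_roi()` preset fits the full ROI).
The ROI is fixed in plane coordinates (centered), not re-selected per
variant, and that choice is recorded in each result's provenance.
`concordance_area_rate()` computes per-phase Jaccard/Dice overlap of two
superimposed maps — spatial agreement that equal cumulative areas do not
imply; phases absent from both maps are reported as undefined (`NA`) and
excluded from averages rather than scored 0 or 1.

At a noise SD equal to ¼ of the minimum inter-phase gap, the optimal
threshold sits about 2σ from the adjacent phase means, so roughly
Φ(−2) ≈ 2.3 % of each adjacent phase's pixels cross the boundary; with
bone and graft jointly holding ~45 % of pixels the expected pixel accuracy
is ≈ 98.8–99.0 %, a useful calibration point for how hard that noise level
actually is.

## Plane matching

`search_best_plane()` formalizes the by-eye "trial and error" selection of
the tomographic section most similar to the reference image: a coarse grid
over up to five plane parameters (offset along the normal, tilts about
$u$ and $v$, in-plane rotation, in-plane translation along $u$) followed
by Nelder–Mead refinement of the free parameters from the best grid point
(200-iteration cap). The default similarity is mean per-phase Dice over
the phases present in the reference — the comparison object in the
emulated workflow is a demarcated (segmented) image, so a label-overlap
score is the faithful objective; mutual information is available for
grayscale references. Every evaluation is logged, and the reported score
is reproducible by independently re-extracting and re-scoring the best
plane.

## The study pipeline

`run_study()` executes the whole design per specimen: generate a phantom
(bone target ~ U(0.20, 0.40), graft ~ U(0.08, 0.18) per specimen — the
source design reports no per-specimen values, so these ranges supply the
between-specimen variance that any correlation-type agreement statistic
needs to be meaningful); take the central mesiodistal plane; build the
histology proxy; fix the original section (the known plane in fast mode,
the search result otherwise — both modes share all downstream code, and
fast mode exists because the search is the costly stage); derive the ±4 px
and ±10° variants; segment and measure all six images; then assemble the
two 9-row agreement tables (reference = histology proxy, 5 rows;
reference = original section, 4 rows) for bone and graft, with Bland–
Altman point sets. The difference sign convention is reference minus
comparator, recorded in every row.

Seeding: specimen $i$ of a study with master seed $m$ uses phantom seed
$m + 10i$, with sub-streams $+0$ (bone field and spheres), $+1$ (rendering
noise), $+2$ (proxy label flips), $+3$ (fraction targets). Everything
downstream is deterministic, so every table is recomputable from the
config and master seed alone.

## Statistics

The CCC point estimate uses 1/n moment estimators (the defining
convention); its CI uses the inverse-hyperbolic-tangent transform with the
asymptotic standard error, assumed two-sided 95 %. The mean difference
uses the sample SD (n−1). Bland–Altman limits use the conventional 1.96
multiplier. The ICC comparator is ICC(A,1) — two-way, absolute agreement,
single measure — implemented from the mean-squares decomposition and
documented as the statistic the concordance coefficient is preferred over
(the ICC presumes equal marginal distributions; the CCC separates
inaccuracy from imprecision). Degenerate inputs: two constant series are
an error; one constant series returns CCC 0 with a degeneracy flag.

Simulation checks at n = 16 put the transformed CI's empirical coverage
near 95 % (the asymptotic method is only approximate at that n; the
tolerance in tests is accordingly wide, 90–99 %).

## Problem sizes and replication settings

The test and analysis scale is: 64³ phantoms for study-level experiments
(16 specimens per study, 20 replicate studies), 8-specimen studies × 20
replicates for the offset sweep ({1, 2, 4, 8} pixels), 20 seeds for the
planted-plane recovery (±6 px / ±15° bounds) and segmentation-accuracy
replicates, and 500 simulated studies for CI coverage — sizes chosen so
the full suite replicates the qualitative findings in minutes on one CPU.
Smaller 24³–48³ phantoms back the unit-level property tests.

## Known limitations

* Agreement magnitudes depend on the assumed between-specimen variance
  ranges and the 5 % proxy label-flip rate; only the ordinal pattern
  (matched plane best, perturbed planes worse, disagreement growing with
  offset) is design-driven.
* The Gaussian-field phantom's slice-fraction variance grows with
  correlation length, so *absolute* between-plane differences grow with
  smoothness even as *relative* agreement (concordance) improves; tests
  assert the scale-free version.
* Planes are ideal (zero thickness); no deformable histology-to-volume
  registration is attempted, so specimen distortion is out of scope.
* `ccc()` returns the asymptotic CI only; no hypothesis tests comparing
  CCCs between rows are provided.
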