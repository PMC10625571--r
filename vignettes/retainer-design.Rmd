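---
title: "From basilar-view photograph to printed nostril retainer: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From basilar-view photograph to printed nostril retainer: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nariform)
```

## The problem

A nostril retainer is a two-pronged splint worn in the nares after
cleft-lip-nose repair; each prong (crus) props one nostril open while the
columella sits in the gap between them. A retainer that is too small fails
to resist cartilage collapse, one that is too large distends the repaired
aperture. Because cleft deformities are often asymmetric, an off-the-shelf
symmetric device can fit one nostril and not the other, and because the
device must be re-sized every few weeks as a child grows, fitting visits
dominate the cost of care. The pipeline in this package replaces the
fitting visit with a single calibrated photograph: the basilar (worm's-eye)
view shows both nostril apertures and the columella in one plane, a green
sticker of known size supplies the scale, and the measured dimensions
drive a parametric, per-nostril reshaping of a printable retainer model.

## Calibration model and its assumptions

A square sticker of physical side $S$ (3 or 5 mm; centimetre sizes are
converted to mm once, at configuration time — every internal length in
this package is mm or px) appears in the photograph with side $L$ px, so
the scale is $S/L$ mm/px. The package supports two routes to $L$:

* **drawn calibrator** — the user draws a line spanning one side of the
  square; $L$ is its euclidean length. The line is taken to span a *side*,
  not the diagonal; diagonal spans are deliberately unsupported, since
  supporting both silently would make a 41% scale error undetectable.
* **automatic detection** — pixels are classified in HSV space (hue
  90–150°, saturation ≥ 0.4, value ≥ 0.3; all config-exposed), connected
  components are labelled with 4-connectivity so diagonal leaks cannot
  bridge the marker to green reflections, and the largest component is
  summarised. Its side estimate is the mean of the bounding-box width and
  height, which tolerates one-pixel boundary raggedness; the raw pixel
  count backs a square-ness check (side must be within 25% of
  $\sqrt{\text{area}}$), and a second candidate at ≥ 50% of the largest
  raises an ambiguity error rather than guessing.

The single geometric assumption is that the photograph is taken parallel
to the sticker plane. No perspective or lens-distortion correction is
applied; out-of-plane tilt foreshortens all lengths by the cosine of the
tilt angle and is the main accuracy caveat for real photographs. Pixel
`(c, r)` (zero-based, origin top-left, y down) has its centre at
`(c + 0.5, r + 0.5)`; centroids and annotation endpoints live on this
continuous grid.

## Measurement

Annotation lines (width and height per nostril, columella) are free
segments, not axis projections: patients' heads are never perfectly
aligned, and the aperture dimensions of interest are the maxima seen in
the basilar view, so the full euclidean length is the right quantity and
is invariant to head roll. Sides are anatomical (patient's left/right) and
recorded explicitly in the annotation file rather than inferred from image
position. Measurements are taken in triplicate and averaged
(`average_replicates()` enforces the count; the default of 3 is the
measurement protocol, and a config switch exists for general use).
Values outside (0, 50) mm raise an error — a value like 86 mm is almost
always a 3 mm sticker configured as 5 mm, not an 86 mm nostril.

## Retainer template and reshaping

No published dimensions exist for the retainer itself, so the template
geometry is this package's own, shaped after the commercial two-crura
silicone retainers and unilateral conformer designs used in post-operative
care, and every dimension is a parameter:

| parameter | default | meaning |
|---|---|---|
| `nominal_width_mm` | 8.6 | outer crus cross-section, width axis |
| `nominal_height_mm` | 12.5 | outer crus cross-section, height axis |
| `nominal_columella_mm` | 6.8 | gap between inner crus surfaces |
| `wall_mm` | 1.5 | tube wall thickness |
| `depth_mm` | 12 | crus length along insertion axis |
| `bridge_mm` | 2 | bridge-bar cross-section |
| `segments` | 48 | angular resolution |

The width/height/columella defaults are healthy-adult means, so the
no-input template is an "average" adult retainer. Each crus is a hollow
elliptical tube closed at the superior end by a rounded cap (height =
`wall_mm`, so apex thickness equals the wall) and sealed at the inferior
end by an annular rim face; the bridge is a separate closed box embedded
one wall-thickness into each crus. The mesh is therefore a union of three
closed, outward-oriented solids — printable slicers union overlapping
closed shells natively, and keeping the solids separate avoids boolean
surgery on the mesh while preserving the every-edge-in-two-faces
invariant that `validate_mesh()` enforces.

Reshaping applies $f_x = w/W$, $f_y = h/H$ to each crus's vertices about
that crus's own axis. Per-axis, per-side factors are the only reading of
"rescaling to the patient" consistent with asymmetric deformities; a side
without measurements keeps factors of exactly 1, which is what makes the
unilateral case safe. The columella measurement moves the crura
symmetrically apart (the mid-sagittal plane stays at $x = 0$) — scaling
the gap rather than the crura is an interpretation, documented here, and
the symmetric choice keeps the device centred. Overcorrection is additive
(mm offsets to the targets before factor computation) because surgeons
prescribe overcorrection in millimetres, not ratios. After every reshape
the mesh is re-validated; a broken manifold is an error, never a warning.

### Numerical choices

* `segments` must be a multiple of 4 so the extreme-axis vertices exist at
  every resolution: the outer bounding box of a crus then equals the
  target dimensions exactly (to 1e-6 mm in the tests) regardless of
  resolution.
* STL export is binary by default with a constant 80-byte header — output
  bytes are a pure function of the mesh, so runs are reproducible and
  diffable. ASCII is available for inspection.
* STL import welds vertices by *exact* float32 equality. Epsilon welding
  can silently fuse the two sides of a 1.5 mm wall on coarse meshes;
  exact welding cannot, and the meshes this package writes always
  round-trip correctly under it.
* STL carries no units; a JSON sidecar declares `1 unit = 1 mm`.

## Agreement statistics

Caliper-vs-program validation uses three procedures. Bland–Altman: bias
$\bar d$ and limits $\bar d \pm 1.96\,s_d$ with the sample SD ($n-1$); the
1.96 multiplier is a fixed convention (config-overridable), not a normal
quantile recomputed at runtime. ICC: the form is ICC(2,1) — two-way random
effects, absolute agreement, single measures — the standard choice when
raters are a random sample; ICC(3,1) is available as an option. The
confidence interval is the standard F-based (Shrout–Fleiss) interval and
is labelled as such in output, with Satterthwaite degrees of freedom.
Reliability bands are left-closed at the boundaries (0.5 → moderate,
0.75 → good, 0.9 → excellent), a convention this package fixes because
the verbal definitions ("below", "between", "over") leave the boundary
points ambiguous. Paired comparison: a Shapiro–Wilk test on the paired
differences at α = 0.05 gates between the paired t-test and the Wilcoxon
signed-rank test; all-zero differences return p = 1 by convention. The
gate and both α levels are config-exposed.

Degenerate inputs are handled explicitly: a constant rating matrix has an
undefined ANOVA ratio and returns ICC = 1 flagged `degenerate`; a zero
residual mean square (perfect agreement with varying subjects) collapses
the CI onto the estimate.

## What the synthetic generator emulates — and what it does not

`render_basilar()` draws a flat skin-tone background, an axis-aligned
green square (side rounded to whole pixels and recorded), and two dark
ellipses separated by a background-coloured columella strip, with the
ideal annotation set and every true dimension carried alongside. It
emulates exactly the features the pipeline consumes: colour contrast for
the HSV classifier, pixel quantisation of the marker, sub-pixel line
geometry, and in-plane aperture roll. It does not emulate skin texture,
shading, specular reflections, partial occlusion, lens distortion or
perspective. Tests passing on synthetic images therefore demonstrate the
*geometric* correctness of calibration, measurement and mesh generation,
and the correct propagation of annotation error — not robustness of
marker detection to real-world lighting, which only real photographs can
show. Anti-aliasing is off by default so pixel counts are exact; an AA
switch exists to stress sub-pixel robustness.

Human drawing error is modelled as i.i.d. Gaussian jitter of every
annotation endpoint (default studies use 2 px SD). Camera tilt is not
modelled projectively; its first-order effect on lengths is a uniform
cosine scale factor, which the jitter study absorbs into scale variation.
Default colours (skin 224/172/140, nostril 40/20/20, marker 0/200/0) are
chosen to be unambiguous under the default HSV gate.

The rater simulator generates `value[i,j] = mean + subject_i + bias_j +
noise_ij`; its implied ICC(2,1) uses the population variance of the
supplied rater biases, which is the rater variance component those biases
realise.

## Study sizes used in the tests

The test-suite and acceptance studies use sizes chosen to make Monte-Carlo
noise small relative to the tolerances they check: 200 synthetic
photographs for the end-to-end error study (scales 0.05–0.2 mm/px,
cleft-cohort aperture distributions, 2 px jitter), 10⁴ pairs for
Bland–Altman coverage, 200 subjects × 2 raters for ICC recovery (±0.05),
10⁶ draws for the endpoint-jitter oracle, and 1,000 null replicates for
the paired-test type-I error (±0.02). All are seeded; generators restore
the caller's RNG state.

## Known limitations

* No perspective correction: accuracy on real photographs depends on the
  camera being parallel to the sticker plane.
* The HSV green gate is tuned for a saturated sticker; green clothing or
  strong colour casts can produce ambiguous detections (which raise
  errors rather than mis-calibrate).
* The template is an idealised elliptical-tube device; it does not fit
  free-form 3D scans or CT surfaces, and no printability analysis
  (supports, overhangs, material) is performed.
* Vertex welding on import is exact-match only; third-party STLs with
  near-duplicate vertices are preserved as-is, which can legitimately
  fail the watertightness report.
* The agreement module reproduces procedures, not cohort findings: real
  participant data are not distributable, so reliability values computed
  here describe synthetic datasets with known variance components.
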