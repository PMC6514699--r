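---
title: "Measuring leaf geometry with a dynamic bounding-rectangle reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring leaf geometry with a dynamic bounding-rectangle reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafrect)
```

## The measurement model

`leafrect` measures the length, width, perimeter and area of a flattened
leaf photographed inside a rectangular calibration plate.  The plate carries
a black rectangular frame whose four sides are parallel to the plate edges;
millimetre tick marks are engraved along the frame's upper and left borders.
The leaf is clamped flat inside the frame, clear of the tick rows, with its
elongation axis as parallel as possible to the plate sides.

Three ideas carry the method:

1. **Projective self-calibration from the frame corners.**  A hand-held
   camera views the plate from an arbitrary distance and tilt, so the plate
   appears as a general convex quadrilateral.  Because all content lies in
   the plate plane, the distortion is exactly a planar homography with eight
   degrees of freedom,
   \[
   u = \frac{Ax + By + C}{Gx + Hy + 1}, \qquad
   v = \frac{Dx + Ey + F}{Gx + Hy + 1},
   \]
   and the four detected frame corners paired with the four corners of a
   *virtual* frontal plate determine $A,\dots,H$ exactly (8 equations, 8
   unknowns).  The image is then resampled onto the virtual plate grid by
   inverse mapping with bilinear interpolation, so every output pixel is
   filled — forward mapping would leave holes where source pixels land
   between grid positions.

2. **Physical scale from the tick marks.**  On the rectified image the tick
   pitch is nominally known (the rectification scale times the 1-mm tick
   spacing), but the actual recovered pitch is re-measured from the median
   adjacent-tick spacing, so the reported millimetres come from the engraved
   ruler, not from assumptions about the camera.  The leaf's axis-aligned
   bounding rectangle (the *positive circumscribed rectangle*, corners
   $A = (X_{\min}, Y_{\min})$, $B = (X_{\max}, Y_{\max})$) is projected onto
   both rulers; its physical length is the number of tick pitches between
   the ticks inside the span plus the sub-tick fractions from each rectangle
   edge to its nearest inner tick, converted at the local pixels-per-mm.

3. **The bounding rectangle as a dynamic reference object.**  Areas and
   perimeters come from pixel-count ratios against that rectangle:
   \[
   S = S_r \frac{P_t}{P_{rt}}, \quad S_r = L_r W_r, \qquad
   C = C_r \frac{P_c}{P_{ct}}, \quad C_r = 2 (L_r + W_r),
   \]
   with $P_t$ the pixels enclosed by the leaf's outermost contour, $P_c$ the
   pixels on that contour, and $P_{rt}$, $P_{ct}$ the interior and boundary
   pixel counts of the rectangle.  Because the reference always has nearly
   the same pixel count as the leaf, the physical weight of a pixel is the
   same on both sides of the ratio; a leaf that *is* an axis-aligned
   rectangle is measured against itself and the ratio is exact.  Counting
   only the outermost contour makes the area estimate insensitive to
   interior holes (lesions, wormholes): they are filled before counting.

## Pipeline and parameters

`measure(image, config)` runs: grayscale → smoothing → binarization →
corner detection → homography → rectification → re-binarization → contour
extraction → tick reading → the ratio formulas.  The `leafrect_config()`
parameters that matter:

* `preprocess$gray_weights` (default ITU-R BT.601 `0.299, 0.587, 0.114`):
  the weighted-average grayscale conversion.
* `preprocess$gauss_sigma` (px, default 1): smoothing before thresholding.
  A literal 1 × 1 smoothing kernel is the identity, which `gauss_sigma = 0`
  reproduces; the default of 1 px is the smallest kernel that actually
  suppresses sensor noise.
* `preprocess$threshold_method` (default `"otsu"`): global Otsu threshold on
  the 8-bit histogram, foreground = dark (leaf, frame, ticks on the light
  plate).  Ties on an empty histogram plateau resolve to the smallest
  maximizing threshold.  A `"fixed"` threshold is available.
* `plate$width_mm`, `plate$height_mm` (default 120 × 90): outer frame
  dimensions; `plate$px_per_mm` (default 10) and `plate$margin_mm`
  (default 5) set the rectified grid.  The margin keeps the frame contour
  away from the image border, where contour tracing and dilation behave
  poorly; it only changes the rectified canvas, never the measured scale,
  which comes from the ticks.
* `ticks$kernel_base = 49` at `ticks$kernel_ref_width = 3264`: broken ticks
  are reconnected by dilating with a one-pixel-wide directional structuring
  element — 1 × k for the vertical ticks of the top ruler, k × 1 for the
  horizontal ticks of the left ruler — so fragments of one tick merge while
  neighbouring ticks never do.  The length 49 px is calibrated to ~3264-px
  captures and scales linearly with image width (minimum 3, forced odd).
* `calibration$method`: `"contour"` (Douglas–Peucker with a tolerance
  schedule starting at 1% of the contour perimeter, growing ×1.5 to at most
  10%, plus iterative total-least-squares edge refinement) or `"hough"`
  (accumulator over the contour points, four dominant lines, intersections).
  Contour approximation is the default: Hough parameters are notoriously
  image-dependent, which is exactly why a parameter-free geometric reduction
  is preferred here.

### Numerical choices

* **Convolution borders**: mirror (symmetric) padding, which conserves the
  image mean exactly for the normalized Gaussian kernel.
* **Corner sub-pixel refinement**: Douglas–Peucker vertices are pixel
  positions and sit up to tens of pixels along an edge from the true corner
  at coarse tolerances.  Each side is therefore re-fitted by total least
  squares on the contour pixels (corner neighbourhoods excluded), iterating
  with capture bands of 20, 5 and 3 px, and the fitted lines are shifted
  half a pixel outward — boundary-pixel *centres* lie about half a pixel
  inside the continuous region edge — before intersecting.  This keeps the
  ground-truth corner reprojection below 1 px up to 45° tilt.
* **Tick lattice consensus**: engraved ticks sit on an exact 1-mm lattice,
  so recovered centroids are validated against it.  The anchor with maximal
  lattice-consistent support wins; off-lattice centroids (partially washed
  or laterally merged ticks) are discarded; fragments in one lattice slot
  are averaged; the pitch is re-estimated by least squares over slot
  indices; and on a rectified image the pitch must agree with the nominal
  `px_per_mm × tick_spacing` within 30%, which prevents the fit from locking
  onto a multiple of the true pitch when many ticks are lost.  Fewer than
  three consistent ticks on a border is an error, not a guess.
* **Pixel-extent conventions**: the rectangle's pixel extents are
  `max − min` (its height is `Ymax − Ymin`); interior counts use
  `max − min + 1` (pixel-area semantics).  Physical lengths always come from
  the ticks, so this off-by-one never reaches the reported millimetres.
* **Connectivity**: components are 4-connected (EBImage labelling), boundary
  traces 8-connected; `P_c` counts distinct traced pixels.
* **Tie-breaks**: a rectangle edge within 0.5 px of a tick centre counts the
  tick and contributes a zero end fraction.  Tick positions are taken at
  stroke centroids (configurable in principle; inner endpoints would differ
  by a constant that cancels between the two ends).

## The synthetic scene generator

`scene_spec()`/`render_scene()` stand in for the physical clamp plate and a
phone camera.  The scene — light plate, black frame (default 120 × 90 mm,
3 mm bars), 1-mm ticks (3 mm long, 0.3 mm wide) on the upper and left inner
borders, dark silhouette — is drawn in plate coordinates at 0.05 mm
resolution, pushed through the projective camera implied by the distance and
tilt (rotation about the plate's horizontal centreline; a full 6-DOF pose is
out of scope), sampled at 2 × 2 supersamples per output pixel (×4
supersampling, then box downsampling) with bilinear interpolation, and
optionally degraded: Gaussian blur, additive Gaussian sensor noise, and a
soft dark band around the silhouette that mimics the edge shadow cast by a
leaf's thickness (the mechanism that biases real-leaf areas upward).
Distances below 235 mm add 0.2 px of blur per mm of approach — a stated
stand-in for close-range defocus, not a physical camera model.  The focal
length is fixed so a frontal plate at 240 mm fills 85% of the image width;
the default image width of 1600 px keeps the full test suite fast, while
phone-class captures (3264–4608 px) are reachable via `image_width_px`.

Regular test shapes (square 50 mm, rectangle 60 × 40 mm, circle ⌀60 mm,
isosceles triangle 60 × 60 mm) carry analytic ground truth; the circle is
rendered as a 16384-gon (sagitta ≪ 10⁻³ mm).  Leaf silhouettes are smooth
closed curves — cardioid (heart, cucumber-like), ellipse (oval, soybean),
serrated ellipse (tomato), tapered high-aspect lens (slender, rice) — with a
seeded low-order radial perturbation (default 4%) so every seed gives an
individual leaf; their truth is integrated from the ≥ 16k-vertex polygon.
Leaves are scaled to a requested area and centred in the tick-free frame
interior.  A slender (aspect ≈ 8) leaf of 40 cm² would be over 21 cm long
and fit no plausible clamp plate, so panels use 10–16 cm² for the slender
template and up to 80 cm² for the broad templates on a 160 × 120 mm plate —
plate dimensions are configuration, and the tick-derived scale makes the
measurements independent of them.

What the generator does **not** emulate: lens (radial) distortion, specular
highlights, texture and venation, uneven illumination, partially curled
leaves.  Passing the synthetic suites therefore validates the geometry and
the estimator chain, not robustness to real-world segmentation failures.

## Expected accuracy, and a known estimator bias

On noiseless frontal renders the full pipeline recovers the reference-shape
areas, lengths and widths to a few tenths of a percent, and stays within
about 0.5% across 0–45° tilt with blur and noise (the acceptance script
reproduces these numbers).  Two caveats:

* **Perimeters of non-rectangular shapes are biased low.**  The ratio
  $C = C_r \, P_c / P_{ct}$ compares boundary *pixel counts*, and the count
  of an 8-connected digital boundary is not proportional to its Euclidean
  length: a digital disc of radius $r$ has about $4\sqrt2\,r$ boundary
  pixels against a true circumference of $2\pi r$, while the axis-aligned
  reference rectangle's count matches its true perimeter.  The ratio is
  exact only when the leaf's boundary orientation statistics match the
  rectangle's; for a circle the estimate is low by a factor
  $\tfrac{4\sqrt2}{2\pi} \cdot \tfrac{\pi}{4} \approx 0.90$ (−10%) at every
  resolution, and about −8% for the test triangle.  This is a property of
  the estimator itself, reproduced faithfully here; no orientation-corrected
  length estimator is substituted.
* **Resolution floors.**  Reading a 1-mm ruler requires the pitch to stay
  comfortably above the blur scale on the compressed side of a tilted view;
  at 800-px captures and 45° tilt ticks begin to merge, which the lattice
  consensus tolerates but which marks the practical lower bound.  The
  default 1600 px — half of the lowest phone-class resolution — is
  comfortable across the full tested range.

## Design choices that were genuinely open

* The printed form of the transformation's third row (`1 = Gx + Hy + 1`)
  would force $G = H = 0$ and contradict the eight solved parameters; the
  standard projective denominator $Gx + Hy + 1$ is used.
* "Largest contour = frame" is implemented as *largest enclosed area*
  (outer contour, holes filled): a large leaf can contain more raw pixels
  than the thin frame ring, but nothing inside the frame can enclose more
  area than the ring does.  The same ranking orders the leaf as the
  second-largest contour, which also keeps strongly serrated leaves (long
  boundaries, modest area) from outranking anything.
* The outer boundary of the black frame defines the calibration points, and
  the virtual plate reproduces that outer rectangle.
* Tick positions are measured at stroke centroids.
* The phrase "subtracting one of the number of tick marks" is read as
  $(n-1)$ pitches between $n$ ticks — the only dimensionally consistent
  interpretation — generalized to lattice-interval counting between the
  outermost inner ticks so that an occasional lost tick cannot shift the
  result by a millimetre.

## Limitations

The rectangle is axis-aligned by assumption: a leaf whose elongation axis is
not parallel to the plate sides gets an oversized reference rectangle, the
main error source for slender leaves (rotated-rectangle extraction is future
work).  Perimeter ratios inherit the digital-boundary bias above.  Scenes
with multiple leaves, midrib/vein analysis and lesion quantification are out
of scope.
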