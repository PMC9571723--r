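---
title: "Methods: pond water-color identification in aquacolor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pond water-color identification in aquacolor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquacolor)
```

`aquacolor` estimates the representative water color of an aquaculture pond
from a fixed-camera image containing a 24-block reference checkerboard.
This vignette documents the model, the numerical choices, and what the
synthetic test bed does and does not establish.

## Color model and correction

All color math runs in CIE Lab. RGB channels are scaled to $[0,1]$ and
multiplied by the fixed sRGB/D65 transfer matrix to get XYZ; Lab follows
with the piecewise compression $f(v) = v^{1/3}$ for $v > 0.008856$ and
$f(v) = 7.787037\,v + 16/116$ otherwise, against the white point
$(X_n, Y_n, Z_n) = (0.9515, 1, 1.0886)$. Two deliberate choices:

* **Lightness is $L = 116 f(Y/Y_n) - 16$.** The $-16$ term is required for
  black to map to $L = 0$ given that $f$ carries the $16/116$ offset; the
  package uses the standard CIE form.
* **No gamma linearization.** The camera response is treated as linear;
  the matrix is applied to raw scaled channels. Since the correction matrix
  is estimated *and* applied in the same spaces, a monotone channel
  nonlinearity would be partially absorbed by the fit; handling it
  explicitly is out of scope.

The inverse path picks the compression branch by the threshold f-value
$f(0.008856) \approx 0.2069$ and clamps to gamut only at the final 8-bit
RGB stage, so intermediate out-of-gamut Lab values survive the round trip.

The correction model is a purely linear $3\times3$ matrix $M$ on Lab
column vectors — no affine offset — estimated from the 24 measured/reference
block pairs via the stacked $72\times9$ block-diagonal system and the
normal-equation pseudo-inverse. Consequences worth knowing:

* linear Lab distortions are inverted *exactly* (24 consistent equation
  triples, 9 unknowns), which the test suite exercises to $10^{-6}$;
* least-squares optimality guarantees the corrected blocks never fit worse
  than the uncorrected ones in the stacked 2-norm;
* rank deficiency (all blocks measuring alike, e.g. a fully occluded
  board) is detected via the QR rank and reported as an estimation error
  rather than producing a garbage matrix.

The reported residual is the RMS Lab distance of corrected blocks from
their references; with 8-bit quantization alone it sits around 0.2–0.4 Lab
units, so values well above ~2 indicate a localization or segmentation
problem upstream.

## Board localization

The board carries four square fiducial markers (6×6 modules: black border,
4×4 payload) at its corners, ids 0–3 at top-left, top-right, bottom-right,
bottom-left. The 50-id dictionary is generated deterministically: 16-bit
payloads are scanned in a fixed order and accepted when all rotations stay
at Hamming distance ≥ 4 from each other and from every accepted code, so
identity and orientation are unambiguous and renderer and detector always
agree. Detection thresholds the luma image (Otsu, with two fixed fallback
levels), labels dark 8-connected components, fits a quadrilateral to each
candidate (farthest-pair diagonal, farthest-from-diagonal points, then
total-least-squares line fits to the hull edges intersected for sub-pixel
corners), and decodes the payload over all four rotations; only exact
dictionary matches survive, which makes false positives from dark water or
equipment regions a non-issue in practice.

The image→ROI homography is estimated by the normalized DLT from up to 16
marker-corner correspondences (any 3 of the 4 markers suffice); collinear
or near-degenerate configurations are rejected by the second-smallest
singular value of the design matrix. Block colors are measured on the
canonical 200×200 warp as the mean over the central 50% × 50% window of
each cell — the margin absorbs cell-border bleed and sub-pixel corner error.
The 4×6 grid order is row-major in the board's reading order; this
ordering is a fixed convention of the layout object and is property-tested
by rendering each cell a unique color.

## Candidate patch extraction and the fuzzy score

Patches are squares of side $w = W/20$ (rounded to an even pixel count so
integer centers give integer corners), sampled uniformly in the lower
two-thirds of the frame. The upper third is excluded because distant water
is reflection-dominated. Patches covering any non-water mask label are
rejected before scoring: the mask, not the FIS, handles waterwheels,
boards and other equipment; the FIS handles graded proximity to foam and
texture.

The score $q \in [0,1]$ comes from a 25-rule Mamdani system on

* $p_1$: minimum Euclidean distance (pixels) from the patch boundary
  pixels to any foam contour pixel, clamped to $[0, L_1]$ where $L_1$ is
  the diagonal of the lower two-thirds of the frame. With no foam present
  $p_1 = L_1$ (maximal), and any overlap gives 0. Boundary-to-contour
  distance was chosen over center-to-contour because the failure mode that
  matters is foam *entering* the crop.
* $p_2$: population standard deviation (divisor $w^2$) of the patch's
  BT.601 gray levels — a flatness measure.

Each antecedent has five fuzzy sets (VS, S, M, L, VL) with peaks at
$(0, 25, 50, 75, 100)$ pixels for $p_1$ and $(0, 45, 90, 135, 180)$ gray
levels for $p_2$: shoulders at the domain ends, triangles between adjacent
peaks. The consequent universe $[0,1]$ uses the same shape family with
peaks at $0, 0.25, 0.5, 0.75, 1$. Inference is min conjunction, max
aggregation, and center-of-gravity defuzzification by the midpoint rule on
1001 points; the rule strengths sharing a consequent term are collapsed by
max first, which is algebraically identical and keeps the inner loop at
five terms. Against an independent fine-grid (10⁴-point) centroid oracle
the implementation agrees to better than $10^{-3}$.

Two properties deserve explicit statement:

* The defuzzified surface is monotone across the antecedent *peak lattice*
  (the inputs where a single set fires fully) and globally ordered — the
  best corner is (far, flat) and the worst is (near, rough).
* Strict monotonicity along arbitrary grid lines does **not** hold for
  this inference scheme: wherever two adjacent antecedent sets map to the
  same consequent term (e.g. both L and VL of $p_1$ map to VL at low
  $p_2$), the max-aggregated strength of that term dips to 0.5 at the
  membership crossover while other terms stay put, and the clipped end-set
  centroid depends on clip height, producing ripples of up to ~0.013 in
  $q$. This is intrinsic to max–min–centroid inference with shared
  consequents, not an implementation artifact; alternative consequent
  shapes were prototyped and do not remove it. The ripple is far below the
  acceptance threshold $T = 0.5$'s decision margin in practice.

The operating point — collect $N = 11$ candidates above $T = 0.5$, keep the
top $N_1 = 5$ — is the calibrated default. Ties in ranking break by larger
$p_1$, then sampling order, making runs reproducible under a fixed seed.
The sampling loop is capped at $1000\,N$ attempts; exhaustion (e.g. an
all-foam frame) raises a structured error carrying the attempt count and
best degree seen. A lookup table over integer $(p_1, p_2)$ replaces direct
inference when enabled; it is computed with the same arithmetic on the
reduced unique-membership grid, so it equals direct inference exactly at
every table point, and nearest-integer lookup differs from direct
inference by at most the local table gradient.

## Classification and voting

The default classifier is deterministic nearest-centroid: the patch's mean
Lab color against 19 palette centroids, probabilities as a softmax of
negative distances, and rejection to "unknown" beyond a per-code tolerance
radius (default 30 Lab units). The regulation behind the 19 codes fixes
names, not colorimetry, so the shipped centroids are hand-assigned values
consistent with the names and fully overridable (YAML palette files;
`fit_palette()` re-estimates centroids from labeled patches). A compact
trainable alternative — a single-hidden-layer softmax network on mean-Lab
and Lab-spread features, fitted with `nnet` — stands in for a full
deep-network classifier at desk scale; the reference full-scale
architecture (a ResNet-50 extractor with a 2048→1000→100→19 softmax head
and its training hyperparameters) is kept as a documented specification
object, not instantiated, since no deep-learning runtime is a package
dependency.

The vote over the five classified patches is: strict majority; else unique
mode; else the code of the highest-confidence patch, with exact-confidence
ties broken by the lexicographically smallest code so the result is
deterministic and permutation-invariant.

## The synthetic test bed

`render_scene()` draws a water field at a chosen palette code with a
smooth Lab gradient (default amplitude 4 L units), a striped waterwheel
rectangle, bright elliptical foam blobs placed disjointly in the lower
two-thirds (default 3 blobs, semi-axes 6–14 px), and the checkerboard
rendered in board coordinates and placed by a homography (default: an
upper-left similarity at about half the frame height). The whole frame
then passes through a chosen invertible 3×3 Lab distortion and i.i.d.
Gaussian channel noise (default SD 2), and is quantized to 8 bits.
Rendering is nearest-neighbor, so the paired class mask is exact to the
pixel, and everything is bit-reproducible from the spec's seed. Default
frame size is 480 × 360; the end-to-end suite runs 20 such scenes across
all 19 codes with random mild distortions.

What this emulates: known reference colors under a global linear color
distortion, sensor noise, spatial color drift, and occluding objects with
exact masks. What it does not: nonlinear camera response, sun glint and
specular reflection, wave texture, mask errors from a real segmenter,
print/fade deviations of a physical board, and atmospheric effects. Tests
passing on synthetic scenes therefore validate the algorithmic chain —
localization, exact inversion of linear distortions, FIS behavior, voting —
not field robustness, which depends on segmentation quality and on how
well a linear Lab map approximates real illumination changes.

`make_patch_dataset()` generates class-balanced water patches (centroid
color, random-direction lightness gradient up to 3 L units, Gaussian
channel noise SD 8) used to measure classifier accuracy at 200 patches per
class with a 20% holdout; at these noise levels the classes remain
separable by construction, so the measured accuracy is a correctness check
of the classification path, not evidence about field data.

## Degenerate inputs and error taxonomy

Stage failures raise classed conditions (`localization_error`,
`extraction_error`, `estimation_error`, `extraction_exhausted`), and
`run_pipeline()` converts them into a structured report tagged with the
failing stage instead of a partial answer; batch mode records the error
and continues. Empty masks, boards without four detectable corner markers,
rank-deficient block measurements, and frames with no acceptable water
area all land in this taxonomy deliberately.
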