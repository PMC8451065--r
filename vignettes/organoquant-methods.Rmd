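---
title: "Methods: segmentation and quantification of single-organoid images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and quantification of single-organoid images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoquant)
```

organoquant analyses 2D multi-channel images that each contain a single
organoid: the first channel (typically bright-field) drives segmentation,
the remaining channels are fluorescence. The pipeline has two stages — a
machine-learning segmentation stage and a quantification stage — and this
vignette explains the models behind both, the tunable parameters, the
synthetic data used for validation, and the numerical choices made where the
design was genuinely open.

## Three-class pixel segmentation

Organoids in culture are surrounded by debris and delaminating cells, and
their defocused boundary is the most reliable visual cue. Pixels are
therefore classified into **three** classes — background, organoid proper
and organoid **edge** — rather than two. Training labels come from binary
masks of a few representative images: the mask is dilated and eroded by
`edge_width` pixels and the band between the two becomes the edge class, the
eroded interior organoid proper, everything else background.

`edge_width` defaults to 2 px. The final classifier mask includes the edge
class by construction (foreground = organoid ∪ edge), so it is dilated
relative to the true object by roughly the half-band; a band matched to the
visible rim width keeps that bias small while still giving the classifier
enough edge pixels to learn from. Users segmenting images with broader
out-of-focus rims should raise it.

### Features

Per pixel, "ilastik-mode" features are computed at filter widths
σ = 1, 2, 5, 15 px: Gaussian smoothing, Laplacian of Gaussian and Gaussian
gradient magnitude at each width (12 features), plus a difference of
Gaussians for each of the 6 width pairs — 18 features in total, following
the count law `3k + k(k−1)/2` for `k` widths. The decomposition into
{smoothing, LoG, gradient magnitude} × widths + DoG pairs is the unique
natural composition consistent with 18 features at the default widths; the
raw image is not included as a separate feature. Filters pad image borders
by replication. "Daisy mode" appends dense DAISY-style texture descriptors:
rectified directional image gradients are Gaussian-pooled at a central scale
(σ = 2.5) and a ring scale (σ = 5) and the ring maps sampled at 6 points of
radius 8 px around each pixel, for 4 orientations — 28 extra features with
the defaults. All features are standardised (training-set mean and scale,
stored with the model and reapplied at prediction); the MLP optimisation is
unstable without this.

Images can be downscaled by `resize_factor` before feature extraction to
save time; probability maps computed at reduced scale are upscaled back
bilinearly and renormalised before mask derivation.

### Classifiers

Two model kinds are supported, mirroring the choice between a classical and
a deep classifier:

* **Multinomial logistic regression** via `nnet::multinom()`.
* **Multilayer perceptron** with exactly two hidden layers (default
  100 and 50 ReLU units, softmax output), trained full-batch with Adam
  (learning rate 0.01, up to 250 iterations, loss-change tolerance 1e-8).
  No installed package provides a two-hidden-layer network, so the package
  implements this compact MLP directly; at tens of features and a few
  classes a full-batch fit is fast and, importantly, exactly reproducible
  under a fixed seed.

Training pixels are a random 50% of the image by default; an extraction
probability `bias` ≥ 1 oversamples foreground classes when the organoid
occupies a small part of the frame (selection probabilities renormalised so
the expected pixel count is unchanged). Edge pixels get twice the training
weight of the other classes (configurable): they are the scarcest class and
carry most of the boundary information.

### From probabilities to masks

Two masks are derived from the class-probability maps:

* the **classifier mask** — per-pixel argmax, foreground = organoid ∪ edge
  (ties to the lowest class index, except organoid proper is preferred over
  edge);
* the **watershed mask** — priority flooding of the edge-probability
  topography from two seeds, the centre of mass of the organoid-proper map
  and the image border; the foreground is the interior seed's catchment
  basin, whose boundary locks onto the edge-probability ridge.

Post-processing fills holes, removes objects below `min_size` (default
100 px²), optionally dilates, and keeps only the largest connected
component; any additional object — including partial neighbours touching
the image border — is discarded, while the largest object itself is kept
even when it touches the border. The order (fill, size filter, dilation,
largest-object selection) is fixed; an empty result is flagged rather than
raised as an error so batch runs continue.

Model persistence is plain CSV (configuration, per-feature normalisation,
long-format weights written with 17 significant digits), so a reloaded
model reproduces predictions bit-identically.

## Morphometrics

Basic descriptors: area (pixel count), perimeter (length of the subpixel
0.5 iso-contour of the lightly smoothed mask, traced by marching squares),
form factor `4πA/P²` (1 for a circle — the standard circularity convention),
and eccentricity, axis lengths and orientation from the moment-matched
ellipse. Second moments carry the 1/12 px² pixel-variance correction so a
solid rectangle of side L has variance exactly L²/12.

### Midline extraction and straightening

Shape changes of elongated organoids (curving of the body axis) are
quantified on a computationally straightened frame. The midline is obtained
by Guo–Hall thinning of the mask; thinning runs off the medial ridge near
the poles (corner bisectors at blunt ends, side branches), so the longest
geodesic path through the skeleton graph is kept and its terminal segments
are pruned where the interior radius (distance transform) climbs steeply
along the path (≥ 0.35 px/px, searched within two interior radii of each
end) — on the true ridge that slope is near zero, on an off-ridge branch it
approaches 0.7. The pruned path is spline-smoothed, extended from both ends
along the mean terminal tangent until it crosses the mask boundary, and
resampled to 1 px spacing. Near-round masks whose skeleton collapses to a
few pixels fall back to the principal axis through the skeleton centre. The
pole with the lower column index is index 0; profile orientation is fixed
downstream by the fluorescence convention.

The meshgrid attaches to each midline point a segment orthogonal to the
local tangent, sampled at 1 px steps to a half-width equal to the maximum
of the distance transform plus 2 px (or a given width). Straightening maps
output pixel (i, j) to bilinear interpolation of the input at orthogonal j
of midline point i; masks are interpolated and re-thresholded at 0.5.
Straightened descriptors report major axis = number of foreground rows
(anteroposterior length) and minor axis = mean foreground width.

Area is conserved to first order because the Jacobian of the unbending map,
1 − κ·offset, integrates to 1 across each symmetric orthogonal; tests bound
the error at 5% for curvature × width ≤ 0.32.

## LOCO-EFA shape spectra

The outline (closed, counterclockwise, uniformly resampled) is decomposed
into classical elliptical Fourier coefficients (Kuhl–Giardina, arclength
parametrised; default N = 50 harmonics or half the contour points minus
one, whichever is smaller). Each harmonic n is rewritten as two
counter-rotating circular motions with complex amplitudes
`c⁺ₙ = ((aₙ+dₙ) + i(cₙ−bₙ))/2` (frequency +n) and
`c⁻ₙ = ((aₙ−dₙ) + i(cₙ+bₙ))/2` (frequency −n). Relative to the fundamental
rotation, frequencies +(l+1) and −(l−1) both modulate the outline radius
with l lobes, which motivates the lobe amplitude

L_l = | c⁺_{l+1} e^{−iζ₁} + conj(c⁻_{l−1}) e^{+iζ₁} |,  ζ₁ = Arg c⁺₁,

with L₁ combining the fundamental circle |c⁺₁| and the 1-lobe component
|c⁺₂| in quadrature, and L₀ ≡ 0 so the spectrum is translation invariant.
A circle of radius R gives L₁ = R; a p-lobed flower r = R(1 + ε cos pθ)
gives L_p ≈ εR (exact to first order in ε — the arclength parametrisation
moves a few percent of the amplitude into neighbouring modes at ε = 0.2);
the spectrum is invariant under rotation, translation and
starting-point shifts and exactly linear in scale — properties the test
suite asserts to machine precision on analytic contours.

Cumulative coverage is **power**-based, `Σ_{m≤l} L_m² / Σ L_m²`, and the
coverage cutoff is the smallest mode reaching the threshold (default 95%).
Whether "describing 95% of the shape" should be amplitude- or
power-cumulative is open; power was chosen because reconstruction error is
quadratic in the omitted amplitudes, and the threshold is a parameter.

## Fluorescence quantification

Per channel: background = median intensity outside the 5 px-dilated mask
(median rather than mean, to resist debris); average = mean
background-subtracted intensity over the mask. Profiles (all
background-subtracted, mean per bin; mean vs median per bin is
configurable-by-edit, mean matches the linearity properties tested):

* **AP profile** — per straightened row, mean over foreground columns;
  coordinates are normalised arclength bin midpoints in [0, 1]. The profile
  is flipped if needed so its maximum lies in the posterior half, matching
  the convention that the marker pole defines the posterior; the flip is
  recorded.
* **Mediolateral profile** — per straightened column, coordinate 0 at the
  midline.
* **Angular profile** — mask pixels binned by angle about the mask centroid
  (default 90 bins of 4°), circularly rotated so the brightest bin sits at
  angle 0 (with an even bin count the peak lands on the bin centre nearest
  0, half a bin width away); the original peak direction is kept as an
  attribute.
* **Radial profile** — binned by normalised depth, distance transform over
  its maximum (default 20 bins), 0 = boundary, 1 = deepest interior.

### Decay-length fitting

Axial marker gradients are modelled as the steady state of a 1D point
source confined at x₀ in a domain [0, L] with zero-flux (impermeable)
boundaries: λ²A″ = A away from the source, A′(0) = A′(L) = 0, which forces
the piecewise-cosh profile

A(x) = A₀ cosh(x/λ)/cosh(x₀/λ) for x ≤ x₀, and
A(x) = A₀ cosh((L−x)/λ)/cosh((L−x₀)/λ) for x ≥ x₀.

x₀ is fixed at the profile maximum rather than fitted (the source position
is the position of highest expression); A₀ is profiled out in closed form,
leaving a 1D least-squares problem in λ solved by Brent search on log λ over
[0.005 L, 50 L] with a narrow refinement pass so that a noise-free model
profile is recovered to machine precision. Fits with λ ≥ 10 L are flagged
`unconstrained` (the profile is too flat to measure a decay). Simulated
profiles at 2% noise recover λ with a median error well under 5% across
λ/L ∈ {0.1, 0.2, 0.3}.

## Synthetic data and what it can show

The generator renders organoid silhouettes — disks, rotated ellipses,
p-lobed flowers and bent bars (capsules with an arc spine) — with a
bright-field-like appearance: textured interior, a dark rim straddling the
object boundary as a defocused edge does, uneven multiplicative
illumination, additive Gaussian noise, and debris specks outside the object
(possibly touching the border). Fluorescence channels follow prescribed
patterns: uniform, an angular pole (von-Mises-like bright spot at a known
angle), an axial cosh gradient with known λ and x₀, or a bright shell.
Every true parameter (analytic area, centerline, pole angle, decay length)
is emitted as metadata, so each analysis step can be tested against ground
truth without any external data.

Default study conditions: a 192 × 192 px canvas with objects as large as it
comfortably holds (disk r = 58, ellipse 66 × 44, flower r = 52 with
ε = 0.2, bent bar 120 × 40 with curvature 0.006 /px). Real organoid images
at 10× are hundreds of pixels across while the edge band stays a few
pixels; keeping the band-to-object ratio realistic matters because the
classifier mask carries an edge-band-sized halo. Datasets generated at
other canvas sizes scale the shape parameters proportionally. End-to-end
validation trains on 3 images and evaluates Jaccard distance on 20 unseen
ones — sizes chosen to complete quickly on a single CPU while matching the
train-small/apply-broadly workflow.

What passing these tests does **not** show: real bright-field texture is
far richer (halos, internal structure, container walls), illumination
artefacts are not simple tilts, and real masks have annotation uncertainty.
The synthetic suite validates the machinery — that the models learn what
the features expose, that geometry and spectra are computed correctly —
not that the defaults are optimal for any particular microscope.

## Degenerate inputs and tie-breaks

Empty masks raise errors in descriptors and labelling; an empty
post-processing result is flagged, not raised. Argmax ties go to the lowest
class index except organoid-proper over edge. Watershed flooding breaks
elevation ties by insertion order, making it deterministic. Masks too thin
to skeletonise raise a midline error; near-round skeletons fall back to the
principal axis. The Jaccard distance of two empty masks is defined as 0;
precision of an all-background prediction is NA with an `undefined` flag.

## Known limitations

Only 2D images (z-stacks should be projected upstream); one organoid per
image (multi-object images go through the labelled-mask import/split path);
no branching midlines — multi-armed shapes are better served by the LOCO
spectrum; no photobleaching or flat-field correction (delegated to
preprocessing); `xls` export is tab-separated text rather than a binary
spreadsheet. The MLP is full-batch and in-memory, sized for single images
and small training sets, not for training on thousands of images.
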