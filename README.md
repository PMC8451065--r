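# organoquant

Segmentation and quantification of single-organoid 2D microscopy images:
gastruloids, pescoids, brain and intestinal organoids imaged one object per
frame, bright-field plus optional fluorescence channels. The package is
aimed at labs that image organoids in multi-well plates and want
reproducible, scriptable morphometrics and fluorescence profiles without a
GUI in the loop.

## What it does

**Segmentation.** Pixels of the first channel are classified into three
classes — background, organoid proper and organoid *edge* — by a
multinomial logistic regression or a two-hidden-layer multilayer
perceptron, trained on a handful of annotated images. Features are
ilastik-style filter banks (Gaussian, Laplacian of Gaussian, gradient
magnitude at σ = 1, 2, 5, 15 px, plus differences of Gaussians: 18 features
per pixel; the count follows 3k + k(k−1)/2 for k widths), optionally
extended with dense DAISY texture descriptors. Masks come either from the
per-pixel argmax (foreground = organoid ∪ edge) or from a seeded watershed
that floods the edge-probability map from the organoid's centre of mass
against the image border; morphological post-processing keeps a single
clean object.

**Morphometrics.** Area, perimeter (subpixel outline), form factor
4πA/P², moment-ellipse eccentricity and axes; skeleton-based midline
extraction with tangential extension to the poles; computational
straightening of images along the midline's orthogonal meshgrid; and
lobe-contribution elliptical Fourier analysis (LOCO-EFA) of the outline —
per-mode lobe amplitudes L_n with the smallest mode covering 95% of the
shape power. A circle concentrates at L_1; a p-lobed shape peaks at L_p.

**Fluorescence.** Background (median outside the dilated mask),
background-subtracted averages, and profiles along the anteroposterior,
mediolateral, angular and radial directions. Axial gradients are fitted
with the steady-state point-source model under zero-flux boundaries,

    A(x) = A0·cosh(x/λ)/cosh(x0/λ)         x ≤ x0
    A(x) = A0·cosh((L−x)/λ)/cosh((L−x0)/λ)  x ≥ x0

with the source x0 fixed at the profile maximum and the decay length λ
estimated by least squares.

**Benchmarking.** Jaccard distance (|XOR| / (|XOR| + |AND|)), precision and
accuracy against ground-truth masks, plus a synthetic-image generator
(lobed and bent organoid silhouettes with bright-field texture, debris,
uneven illumination, and fluorescence channels with known pole angles and
decay lengths) so the whole pipeline is testable offline.

## Worked example

Generate a small synthetic dataset (first three images are the training
set) with a posterior marker gradient, run the pipeline, and inspect one
record:

```r
library(organoquant)

dir <- file.path(tempdir(), "demo")
generate_dataset(6, dir, seed = 7,
                 fluorescence = list(bra = list(pattern = "axial_gradient",
                                                lambda_frac = 0.2,
                                                x0_frac = 0.9)))
res <- run_pipeline(dir, model_kind = "logistic", seed = 1)
rec <- res$records[["img_004"]]
```

Output for `img_004` (a bent, elongated shape):

```
area 6871 px^2 | perimeter 381.5 px | form factor 0.593 | eccentricity 0.954
LOCO cutoff mode: 2 ; L[1..6] = 50.6, 29.5, 3.28, 1.02, 0.0245, 0.0333
straightened length 164 px, width 41.9 px
ch1: background 0.1004, average 0.1242
decay fit: lambda/L = 0.217 (generated with 0.2), x0/L = 0.899
Jaccard distance vs ground truth: 0.118
```

Reading this: the form factor 0.59 and eccentricity 0.95 flag an elongated,
non-circular object; the LOCO spectrum is dominated by L_1 (size) and L_2
(elongation) with 95% of the shape power reached by mode 2 — no higher
lobes. Straightening unbends the object to 164 px (the generator's
pole-to-pole length is 160 px; the segmented mask carries a small edge
halo). The fitted decay length 0.217 and source position 0.899 recover the
generating values (0.2 and 0.9) on the segmented, straightened mask, and
the mask itself is within Jaccard distance 0.12 of the ground truth.
Quantification lands in `<dir>/result_segmentation/` as JSON and CSV,
per-group summaries in `summary.csv`; `kymograph()` stacks per-timepoint
profiles into a time × position matrix.

A thin command-line front end over the same functions is included at
`inst/cli/oq.R` (`synth`, `run`, `eval` subcommands).

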