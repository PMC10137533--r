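---
title: "Methods: handcrafted-descriptor CAD for melanoma/nevus classification"
author: "dermaCAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: handcrafted-descriptor CAD for melanoma/nevus classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dermaCAD implements a classical computer-aided-diagnosis (CAD) pipeline for
pigmented skin lesions: clean the photograph, segment the lesion, describe
its texture and shape with handcrafted local descriptors, and classify it as
melanoma (+1) or nevus (-1) under cross-validation. This vignette explains
the models and the design decisions behind each stage; the README shows a
worked example.

## Preprocessing

Images are converted to grayscale with BT.601 luminance weights
(0.299, 0.587, 0.114) and resized to a uniform 150 x 150 pixels by bilinear
resampling with pixel-centre alignment. Two artifact filters follow.

*Median filtering* (default window 5 x 5) suppresses impulsive
salt-and-pepper noise while keeping edges. The window size is a package
default: small enough to preserve lesion-border contrast, large enough to
remove the roughly 1% corrupted pixels the generator emulates. A 3 x 3
window under-cleans dense impulse noise; larger windows blur texture the
descriptors need.

*Hair removal* builds on the bottom-hat transform, closing(I) - I with a
flat disk (default radius 5 px). The closing fills any dark structure
narrower than the disk, so the difference lights up exactly the thin dark
hairs (1-3 px) while being zero on flat regions. Pixels with response above
a threshold (default 30 intensity levels, about half the hair/skin contrast)
form the hair mask, dilated by one pixel to catch anti-aliased stroke edges.
Masked pixels are replaced by the median of non-hair pixels in a growing
window (5, 7, 9, ...): a deterministic, dependency-free local inpainting.
A hair mask covering more than half the image signals a degenerate
threshold; the image is returned unchanged with a warning rather than
half-destroyed. Everywhere in the package, out-of-frame neighbours take the
replicated edge value, so all neighbourhood operators are defined on the
full pixel grid.

## Segmentation

Pigmented lesions are darker than the surrounding skin, so each RGB plane is
thresholded with Otsu's criterion (exhaustive search of the 256-bin
histogram for the cut maximizing between-class variance; ties break toward
the smaller cut) and the darker side taken as lesion. The three binary
planes are fused by per-pixel majority vote — the robust middle ground
between union (noise-prone) and intersection (undersegmenting); both
alternatives remain selectable. Cleanup is a fixed chain: morphological
opening (disk radius 3) removes blobs that cannot contain the disk;
iterative binary median smoothing with decreasing windows (7, 5, 3) smooths
the border and fills pinholes; an iterated open-close filter (disk radius 2,
at most 5 passes or until a fixed point) repairs remaining specks and holes;
a size filter deletes 8-connected components below 5% of the image area.
The largest surviving component is the lesion, and its closed boundary is
traced with the Moore-neighbour algorithm, reported counterclockwise from
the topmost-then-leftmost boundary pixel. On a binary mask, edge detection
and exact boundary tracing coincide, which is how the contour step is
realized. The whole module is deterministic.

## Descriptors

**LBP.** At each interior pixel the 8 neighbours of the 3 x 3 square ring
are compared with the centre: code = sum of s(g_p - g_c) 2^p with s(x) = 1
for x >= 0 (so exact ties set the bit). The histogram over all coded pixels
(border of width R excluded) is the 256-bin descriptor. Because the code
depends only on signs of differences, the descriptor is invariant to
monotonic intensity scaling. A circular neighbourhood with bilinear
sampling is available, but the square ring is the default, matching the
classic square-mask formulation.

**N-LBP.** The neighbourhood grows to the 24 pixels of the 5 x 5 ring
(raster bit order), giving a 2^24 = 16,777,216 code space. Histograms are
stored sparsely — a 150 x 150 image codes at most 146 x 146 = 21,316 pixels —
and assembled into a sparse sample x code matrix over the codes observed in
the dataset. Because the classifier cannot digest millions of columns, a
variance filter (fitted on training rows only, default top 4096 non-constant
columns) stands in for the unspecified feature-selection step; it is
deliberately simple and documented as a stand-in.

**HOG / CS-HOG.** Central-difference gradients (edge replicated) yield
magnitude and orientation, folded to [0, 180). Per cell (8 x 8 px for HOG,
2 x 2 px for CS-HOG) a 9-bin orientation histogram is accumulated with
magnitude-weighted linear soft binning between the two nearest bin centres;
blocks of 2 x 2 cells at stride 1 are L2-normalized (epsilon 1e-6) and
concatenated — the Dalal-Triggs defaults, since only the cell sizes are
prescribed. Images are cropped, not padded, to a multiple of the cell size:
padding would inject artificial gradients. Soft binning conserves gradient
weight before normalization, and every block vector has norm at most 1;
both properties are tested.

## Classifiers

All three models share one contract: features in, labels in {-1, +1} out,
with a zero decision score mapping to +1 (melanoma) — the safety-first
direction for a diagnostic tool.

**Gentle AdaBoost** boosts regression stumps fit by weighted least squares:
with labels in {-1, +1}, the WLS-optimal response in each region is the
weighted mean of the labels there, i.e. the weighted class-probability
difference, automatically in [-1, 1] with no extra shrinkage. The search is
exhaustive over all features and all thresholds between consecutive sorted
values (ties: lowest feature, then lowest threshold), so training is
deterministic. Weights start at 1/N and update as
w_i <- w_i exp(-y_i f_m(x_i)), renormalized each round; M defaults to 100.
One consequence worth stating: a sum of single-feature stumps is an
additive model, so point sets that are not additively separable (the
classic 4-point XOR) cannot reach zero training error with any number of
rounds — the four XOR margin inequalities sum to a contradiction. Tests
document this boundary of the model class.

**kNN** stores the training matrix as given (no internal normalization; an
explicit z-scaling would have to be fitted on training folds) and predicts
the majority label of the k = 5 nearest samples in Euclidean distance.
Distance ties at the k-th position break by lower training index; vote ties
by the nearest neighbour's label — both rules make prediction fully
deterministic.

**SVM** is a soft-margin RBF machine, sign(sum_i alpha_i y_i k(x_i, x) + b)
with k(x, x') = exp(-gamma ||x - x'||^2); the quadratic program is delegated
to the libsvm solver in e1071, with C = 1 and
gamma = 1 / (d x mean feature variance) as defaults (the classic scale
heuristic; no hyperparameter values are prescribed).

## Evaluation

The positive class is melanoma. Class imbalance is handled by random
over-sampling: minority rows are replicated (seeded, with replacement) until
counts balance — 70/100 becomes 100/100 by appending exactly 30 replicas.
By default over-sampling happens inside the training folds only; replicating
before the split would place copies of a training row into test folds and
inflate every statistic. Because some published protocols balance the whole
dataset before splitting, a `replicateFirst` flag reproduces that order
explicitly. Cross-validation is stratified 10-fold (seeded shuffle within
class, round-robin deal, spill-over rotated so fold sizes differ by at most
one). Fold confusion matrices are pooled (micro-averaged) — stable for
small folds — and per-fold reports are kept. The five statistics AC, SE,
SP, PPV, NPV are the standard percentage ratios of the pooled counts; any
zero-denominator ratio is reported as NA, never as 0 or 100.

## The synthetic generator

Every stage is tested without external data using a seeded generator that
emulates small clinical lesion photographs: one darker, roughly elliptical
lesion (semi-axes 0.15-0.35 of the 150 px side; mean levels 70 lesion / 180
skin, with a fixed small RGB tint of +/-8 around the gray base) on lighter
skin; a radial border perturbation from smoothed periodic harmonics
(amplitude 0.3 of the radius for melanoma, 0.05 for nevus); lesion texture
as a spatially correlated Gaussian field (white noise smoothed with a
Gaussian kernel, correlation length 1.5 px) rescaled to SD 30 (melanoma) or
8 (nevus), with skin texture at SD 5; 0-8 anti-aliased curved hair strokes
of width 1-3 px at intensity 30; and 1% salt-and-pepper pixels, applied
last, after the ground-truth mask is frozen. Correlated texture matters:
pigment structure in real lesions is blotchy at supra-pixel scale, and a
sign-based descriptor like LBP is blind to the amplitude of independent
per-pixel noise, which would make the texture classes undetectable by
construction. Per-sample seeds derive deterministically from the master
seed, so datasets are reproducible and order-independent.

What the generator does *not* emulate: real pigment-network morphology,
colour variegation, vignettes, rulers, air bubbles, illumination gradients.
Passing the synthetic benchmarks therefore demonstrates that the pipeline's
machinery works end to end and separates texture/border classes of the
stated strength — not clinical performance on real dermoscopy archives.

## Problem sizes and numerical choices

The shipped benchmarks use 20 seeded samples for segmentation quality
(mean IoU >= 0.80 with hairs and impulse noise; >= 0.95 clean) and a
120-sample (60/60) dataset for the cross-validated pipeline — the same
order of size as the 170-image archive the method was designed around, and
comfortably reproducible on one CPU. Determinism is enforced throughout:
seeded RNG confined with an internal with-seed helper, exhaustive
deterministic stump search, tie rules stated for Otsu, kNN and all sign
decisions, and reruns of the pipeline with one configuration are
byte-identical including the JSON report.
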