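---
title: "BI-RADS mass classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BI-RADS mass classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biradsCAD)
```

This vignette is the package's account of its science: what each stage
models, which parameters matter and why their defaults were chosen, what the
synthetic phantoms do and do not emulate, and where the method's genuine
weaknesses lie. It states no empirical result that the test suite does not
itself compute.

## The classification problem

Radiologists describe mammographic masses with the BI-RADS lexicon — shape
(round … irregular), margin (circumscribed … spiculated) and density (fat
containing … high) — and assign an assessment category that drives patient
management: B-2 benign, B-3 probably benign, B-4 suspicious, B-5 highly
suggestive of malignancy. The package quantifies those three descriptor
families into 130 numeric features per segmented mass and learns the
category with a small neural network, with a genetic algorithm choosing the
feature subset.

## Segmentation model

Region growing accretes the 8-connected component of pixels with grey level
`>= t` around the ROI center pixel. The homogeneity rule (grey level at or
above threshold) encodes the assumption that masses are hyperintense
relative to surrounding tissue — true after histogram equalization for the
lesion-centered crops the pipeline operates on. Because no single `t`
suits every mass, candidates are grown at `nThresholds = 16` values evenly
spaced over the ROI's grey range; candidates are nested in `t`, so the
family forms a monotone sequence from over- to under-segmentation.
Candidate choice is a proxy for the expert-in-the-loop step: the mask whose
equivalent-circle radius is nearest the annotated approximate radius wins,
ties going to the larger mask (over-segmentation preserves margin
information that under-segmentation destroys). An `interactive` strategy
exposes the choice to a human through a pluggable `chooser`. No contour
refinement operator is provided: how an expert "refines" a contour is not
specifiable, so the hook ends at candidate selection.

Boundaries come from Moore neighbour tracing (clockwise, from the
topmost-leftmost pixel, Jacob's stopping criterion). Holes are filled first
so the boundary is a single closed loop. One deliberate deviation from the
obvious contract: pixels on one-pixel-wide spurs are *revisited* by the
trace and retained, because deduplicating them would break the
8-connectivity of the sequence; all downstream consumers (resampling,
waveform anchoring, refilling) are indifferent to the repeats.

## Feature families

**Shape (ids 1–9).** The contour is resampled to `nPoints = 128`
arc-length-uniform points. Continuity is the variance of consecutive-point
spacing; curvature the mean squared second difference; irregularity the
count of resampled points whose turning angle exceeds `tau = pi/12`.
`tau` was fixed at 15° once: large enough to ignore the small angular
jitter of near-straight digital arcs, small enough to count every visually
salient direction change. A caveat discovered during development and kept
on the record: a *digital* boundary has a staircase noise floor — a
radius-16 disc already yields an irregularity count near 50-60 at this
sampling density — so the measure discriminates high-frequency spiculation
(where tests show it strictly increasing in perturbation amplitude) but not
gentle low-order undulation, which hides below the floor. Difference area
is the convex-hull pixel count minus the mask pixel count, both true lattice
counts (hull membership via point-in-polygon with boundary inclusion). The
"variation" profile is the Feret diameter at 180 angles over `[0, pi)`;
its mean/variance/skewness/kurtosis use population moments (kurtosis
non-excess, zero-variance inputs reporting skewness and kurtosis 0), and
its entropy is the Shannon entropy in bits of the extent sequence
normalized to a probability vector — `log2(180)` for a perfect disc.

**Margin (ids 12–32).** 32 waveforms of 64 bilinear samples at 1 px
spacing, anchored at the contour points nearest rays cast from the mass
centroid every `pi/16`, oriented radially (a robust approximation of the
margin normal), with sample 33 on the anchor — 32 samples inside, 32
outside; samples beyond the ROI take the nearest border value. The
edge-probability vector is the normalized absolute first difference of the
3-sample-smoothed waveform. This is a deliberately transparent stand-in
for wavelet-based edge evidence: it preserves the defining property (mass
concentrated where the intensity transition is abrupt), is exactly
shift-invariant under global grey offsets, and has clean analytic test
cases (a step concentrates the mass at the margin; a constant waveform
degrades to the uniform vector with 6 bits of entropy). Ties in the
argmax resolve towards the margin, then outward. Kurtosis, entropy and the
signed index of the maximum (negative inside, positive outside) are then
summarized by mean/max/min/sd/variance/skewness/kurtosis across the 32
waveforms, descriptor-major.

**Density (ids 33–130).** Grey levels are quantized to 64 bins (min–max of
the ROI; 64 keeps co-occurrence matrices well populated for the 50–130 px
ROIs the pipeline sees). The co-occurrence matrix at displacement
`(round(d sin a), round(d cos a))` is symmetrized and normalized, and the
14 classical Haralick descriptors are computed — entropies in bits, the
exponential in the second information measure of correlation taken over
natural-log entropies as is conventional, the maximal correlation
coefficient as the square root of the second-largest eigenvalue of the Q
matrix, and degenerate marginals reporting correlation and MCC 0. Two
readings of the distance set are possible ("0, 1, 2, 3, L/2" versus "each
d in [1, L/2]"); the package uses all integers `1..floor(L/2)` because
`d = 0` is degenerate and the seven-statistics-over-distance step is only
meaningful with a full distance axis. Angles are not a reported axis:
descriptors are averaged over the 8 angles at each distance, which is the
unique aggregation yielding the printed 14 × 7 = 98 layout. The GLCM
covers the full square ROI rather than the mask, since BI-RADS density is
judged against the surrounding tissue.

**Normalization.** Min–max scaling learned on the training split only;
held-out values are clamped to `[0, 1]` and constant features map to 0.
Fitting the scaler before the split would leak evaluation data into
training, so the pipeline never does it.

## Genetic feature selection

Chromosomes are length-`L` sequences of distinct feature ids, so every
individual is a valid subset of exactly `L` features. One GA run per
subset size; `L = 1` and `L = F` are handled exhaustively. Within a run:
elitism copies the best two chromosomes; parents are drawn by roulette
wheel on raw fitness; crossover uses `K = L − 1` points (children
alternate parental genes positionally) with probability 1; mutation
repairs duplicate ids with uniform draws from the absent ids and resets
each gene with probability `Pm = 0.01`; the run stops after `stagnationX`
generations without improvement (default 10). Fitness values are memoised
per order-insensitive subset, so the classifier trains at most once per
distinct subset per run.

The population/generation schedule is open in the method's description
beyond "a multiple of 4" that "decreases slowly" with `L`; the defaults
`pop = max(20, 4⌈(F − L + 4)/4⌉)` and `maxGenerations = max(15, 60 − L/3)`
honor both constraints at desk scale and are fully overridable. Sweep ties
across sizes resolve to the smaller subset (parsimony).

**A documented weakness.** The positional crossover cannot combine two ids
that occupy the same gene position in their carriers, so once the
population converges positionally, a missing informative id can enter a
near-optimal chromosome only through mutation or duplicate-repair draws —
events of probability on the order of 1/F per replacement. In controlled
recovery experiments (130 features, 3 complementary informative features at
effect size 2, fitness = network validation accuracy averaged over two
inner splits), the sweep's global best recovered the exact planted triple
only in a minority of seeded runs at desk-scale schedules; the
corresponding acceptance test reports the honest recovery count and is
expected to fail its ≥ 4/5 bar. The operator set explores *small* subsets
poorly; selection among larger subsets, where informative ids are abundant
in the initial population, is much less brittle.

## Classifier

One hidden layer, logistic hidden units, 4 softmax outputs, cross-entropy
objective; hidden width `H = min(⌊4 + 0.75 I⌋, 2I − 1)`, which is 101, 38
and 1 hidden units at 130, 46 and 1 inputs. The fit is nnet's quasi-Newton
optimization of that objective with weight decay (defaults `maxit = 200`,
`decay = 1e-3`, both exposed); random weight initialization is seeded, so
training is bit-reproducible. GA fitness is accuracy on an inner stratified
75/25 validation split carved from the training table — never the held-out
test set, which would leak selection information. The evaluation protocol
is a stratified 60/40 split (125 cases per class give exactly 75/50),
per-class one-vs-rest sensitivity and specificity, and micro-averaged
PPV/NPV/MCC over the pooled one-vs-rest counts. For any single-label
multi-class confusion matrix the pooled false positives equal the pooled
false negatives, so micro PPV always equals overall accuracy — a useful
internal consistency check that the test suite asserts on random matrices.

## Synthetic phantoms and tables

`makePhantom()` draws a star-convex boundary `r(phi) = radius +
Σ a_k cos(k phi + phase_k)`, fills it over a 60-grey background raised by
`interiorContrast`, blurs the edge with a Gaussian of `blurSigma`, and adds
Gaussian noise — one controllable axis per BI-RADS descriptor family
(irregularity, margin sharpness, density), with category archetypes B2→B5
mapping monotonically onto amplitude and blur. Defaults (radius 16 px,
amplitudes 0.5–5 px, blur 0.5–2.2 px, contrast 80–125, noise sd 4) were
chosen once as a regime where the four archetypes are separable but not
trivially so at the 61×61 px scale. Phantoms are fully determined by their
spec and seed. What they do *not* emulate: fibroglandular texture,
pectoral muscle and artifacts, non-star-convex (e.g. multi-focal) masses,
and scanner noise characteristics — so green phantom tests demonstrate the
pipeline's internal correctness and sensitivity to its descriptor axes,
not clinical performance.

`makeFeatureTable()` builds labeled 130-column tables where informative
features carry a one-vs-rest class shift (feature `i` shifts one class,
cycling B3/B4/B5/B2, by `classEffectSize` standard deviations) and all
other features are standard noise. The one-vs-rest design makes each
informative feature *necessary*: with three of them, no strict subset
separates all four classes, so the informative set is an identifiable
ground truth for selection experiments. (Under a monotone per-class shift
a single feature nearly saturates accuracy and recovery of the triple is
unfalsifiable.)

## Problem sizes and determinism

The test suite runs everything at desk scale, chosen as the package's own
defaults for tests: 16–32 px phantom radii, 16–32 grey quantization levels
in pipeline tests, a 120-phantom cohort for the end-to-end check, GA
sweeps over subset sizes 1–10 (toy) and 1–4/1–5 (recovery), and 200–400
row synthetic tables. Every stochastic step — phantom synthesis, table
generation, splits, GA, weight initialization — takes an explicit seed,
and reports embed the resolved configuration, so reruns are bit-identical.

## Known limitations

* Clinical accuracy claims are out of reach by design: no clinical mammograms, no
  radiologist in the loop; the 84.5 % reference accuracy is reproduced only
  as arithmetic on the reference confusion matrix.
* The irregularity count has a digitization noise floor (above) and should
  be read comparatively, not absolutely.
* The edge-probability vector is a gradient-based stand-in, not a wavelet
  reconstruction; absolute margin-feature values are not comparable to
  wavelet-based implementations, though orderings (sharp vs blurred) are.
* The GA's positional crossover limits exploration at small subset sizes;
  see the documented weakness above.
* Age and pixel spacing are taken as given metadata; no DICOM parsing.
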