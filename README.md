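# biradsCAD

Computer-aided diagnosis of mammographic masses: an R package that assigns a
segmented breast mass to one of the four BI-RADS assessment categories —
B-2 (benign), B-3 (probably benign), B-4 (suspicious) and B-5 (highly
suggestive of malignancy). It is aimed at medical-image-analysis researchers
who want a tested, fully reproducible reference implementation of a classical
handcrafted-feature CAD pipeline, exercisable end to end on synthetic lesion
phantoms without any clinical image data.

## The method

The pipeline mirrors clinical CAD practice in five stages:

1. **Preprocessing** — the region of interest (ROI) around the reported
   lesion center is cropped and contrast-enhanced by histogram equalization
   (`cropROI()`, `equalizeHistogram()`).
2. **Segmentation** — seeded region growing from the ROI center over a sweep
   of grey-level thresholds spanning `[min, max]` of the ROI; the candidate
   whose equivalent-circle radius `sqrt(area / pi)` best matches the
   annotated approximate radius is selected (an interactive hook stands in
   for expert refinement), holes are filled, and the boundary is traced by
   Moore neighbour tracing (`generateCandidates()`, `selectCandidate()`,
   `extractContour()`).
3. **Feature extraction** — 130 handcrafted BI-RADS descriptors per mass:
   - *shape* (ids 1–9): boundary continuity, curvature and irregularity from
     the resampled contour; convex-hull difference area; and the moments and
     entropy of the angular Feret-extent ("variation") profile;
   - *additional* (ids 10–11): mass size in mm² and patient age in years;
   - *margin* (ids 12–32): 32 intensity waveforms of length 64 sampled
     perpendicular to the margin (one every π/16) are reduced to
     edge-probability vectors; kurtosis, entropy and index-of-maximum of each
     are summarized by 7 statistics across waveforms (3 × 7 = 21);
   - *density* (ids 33–130): the 14 Haralick descriptors of the grey-level
     co-occurrence matrix, averaged over 8 angles at each displacement
     distance `d ∈ 1..⌊L/2⌋` and summarized by the same 7 statistics over
     distance (14 × 7 = 98).
   Features are min–max normalized, `d_norm = (d − d_min)/(d_max − d_min)`,
   with the extrema learned on the training split only.
4. **Feature selection** — a modified genetic algorithm whose chromosomes
   are fixed-length sequences of *distinct integer feature ids* (not
   bitmasks). Selection combines elitism (best 2 copied unchanged) with
   roulette-wheel sampling `P(c_i) = f(c_i)/Σf(c_j)`; crossover uses
   `K = L − 1` points, so children alternate parental genes position by
   position; mutation repairs duplicated ids with random absent ones and
   resets each gene with probability 0.01. The GA runs once per subset size
   `L` (exhaustively for `L = 1` and `L = F`), and the global best across
   sizes is selected (`runGA()`, `gaSweep()`).
5. **Classification** — a one-hidden-layer neural network with 4 softmax
   outputs and hidden width `H = min(⌊4 + 0.75 I⌋, 2I − 1)` for `I` inputs;
   its validation accuracy on an inner 75/25 split of the training data is
   the GA fitness. Evaluation uses a stratified 60/40 train/test split, the
   4×4 confusion matrix, per-class sensitivity/specificity, and
   micro-averaged PPV/NPV/MCC pooled over one-vs-rest counts
   (`trainBPN()`, `metricsReport()`).

Deterministic lesion phantoms with known ground-truth masks emulate the
three BI-RADS descriptor axes — boundary irregularity, margin sharpness and
interior density (`makePhantom()`) — and `runAll()` chains everything into a
single seeded, reproducible run.

## Worked example

```r
library(biradsCAD)

ph  <- makePhantom(phantomSpec("B4", seed = 21))
ph$roi
#> ROIImage 61x61 px, 0.050 mm/px, grey range [45, 183], source 'phantom-B4-seed21'

seg <- segmentROI(ph$roi, targetRadius = ph$radiusPx)
diceCoefficient(seg$mask, ph$mask)
#> [1] 0.968

feats <- extractFeatures(seg$roi, seg$mask, ph$ageYears,
                         contour = seg$contour, glcmCfg = glcmConfig(levels = 32))
round(feats[c(3, 4, 10, 11, 19, 40)], 3)
#>          irregularity       difference_area             mass_size
#>                64.000                29.000                 1.890
#>           patient_age   margin_entropy_mean density_contrast_mean
#>                65.000                 5.296               144.790
```

The segmentation recovers the planted mass almost exactly (Dice 0.97); the
130-entry feature vector reports, e.g., a 1.89 mm² mass in a 65-year-old
synthetic case, with the margin's mean edge-position entropy (5.3 bits of a
possible 6 — an ill-defined margin) and the mean GLCM contrast over
distances.

Evaluating a reference 200-case confusion matrix:

```r
cm <- matrix(c(47, 2, 1, 0,  3, 41, 4, 2,  2, 5, 36, 7,  0, 3, 2, 45),
             4, 4, byrow = TRUE,
             dimnames = list(actual    = c("B2", "B3", "B4", "B5"),
                             predicted = c("B2", "B3", "B4", "B5")))
metricsReport(cm)
#> Accuracy: 84.5%
#>   B2: sensitivity 94.0%, specificity 96.7%
#>   ...
#> Micro PPV 84.5%, NPV 94.8%, MCC 79.3%
```

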