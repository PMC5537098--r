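---
title: "From quantitative CT lesion features to visual semantic terms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From quantitative CT lesion features to visual semantic terms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmap)
```

## The problem

Radiologists describe liver lesions on contrast CT with *visual semantic
terms* (VSTs) — controlled-vocabulary observations such as "thin rim",
"solitary lesion" or "water density".  lesionmap implements a pipeline
that (i) computes a fixed 496-dimensional quantitative feature vector
from a 2-D CT slice and a lesion region of interest, (ii) learns, per
term, a small feature subset whose Gaussian-kernel SVM best predicts the
term under fivefold cross-validation, and (iii) emits the learned
feature-to-term mapping explicitly, so the basis of each prediction is
inspectable rather than buried in a black-box classifier.

## The feature bank

The 495 traditional dimensions are grouped into five blocks: intensity
(6), texture (376 = 12 co-occurrence + 32 Gabor + 324 Daubechies + 1
Haar + 7 run-length), shape (20), histogram (32 = 12 LBP + 20 bins) and
edge (61 = 60 contour-sharpness profiles + 1 gradient-entropy value).
The 496th dimension is the number of lesions elsewhere in the liver that
resemble the primary lesion (next section).

The block totals are fixed, but each family admits many internal
configurations; the ones used here are deliberate, documented choices
(`feature_config()`), not reconstructions of any particular prior
implementation:

* **Co-occurrence (12)** — contrast, correlation and energy of a
  symmetric co-occurrence matrix at distance 1 and offsets 0/45/90/135
  degrees, on 32 gray levels quantised over the lesion's own range.
  Degenerate (constant) lesions give contrast 0, energy 1 and
  correlation defined as 0.
* **Gabor (32)** — carrier wavelengths 3, 4, 6 and 8 px, four
  orientations, Gaussian envelope sigma = 0.56 wavelength; mean and
  population sd of the quadrature response magnitude over the mask.
* **Daubechies (324)** — 3-level periodic db4 decomposition of the
  lesion bounding box resampled to 64 x 64; each of the 9 detail
  subbands is pooled on a 6 x 6 spatial grid of RMS energies
  (9 x 36 = 324).  The pooled layout keeps the count fixed regardless
  of lesion size.
* **Haar (1)** — total detail energy of a 1-level Haar decomposition of
  the same patch.
* **Run length (7)** — SRE, LRE, GLN, RLN, RP, LGRE, HGRE on 16 gray
  levels, runs along image rows, broken at the mask boundary.
* **Shape (20)** — compactness 4&pi;A/P&sup2; (perimeter from the traced
  contour polygon), moment-ellipse eccentricity, roughness
  (perimeter / convex-hull perimeter), the local area integral
  invariant — the fraction of a disc centred on the contour that lies
  inside the mask — averaged over the contour at radii 2..16 px, and
  mean/sd of the centroid-to-contour radial distance.
* **Histogram (32)** — proportions of uniform LBP(8,1) patterns by
  number of set bits plus non-uniform proportion and code mean/sd,
  computed only on pixels whose full 8-neighbourhood lies inside the
  mask; and 20 equal-width bins over a configurable HU window (default
  [-200, 400]) with out-of-window pixels clamped into the end bins so
  counts always sum to the lesion area.
* **Edge (61)** — 60 radial profiles at equally spaced angles crossing
  the contour (&plusmn;4 px at 0.5 px steps, bilinear interpolation);
  each contributes its maximum finite-difference slope.  On a digital
  disk these values agree only up to the anisotropy of bilinear
  sampling (diagonal rays see a wider transition), which is why the
  symmetry test uses a generous relative tolerance.  The 61st value is
  the entropy of gradient magnitudes on the one-pixel contour band.
* **Intensity (6)** — median, entropy of integer-rounded values,
  proportion of pixels above a threshold (by default the image's own
  within-class-variance optimum, overridable), and mean lesion-vs-ring
  intensity differences for rings from dilations of 2, 4 and 8 px.
  Dyadic ring radii are a convention; nothing downstream depends on the
  exact choice.

Matrices are z-scored per column with the **population** sd (divide by
N); constant columns map to 0.  The training-time statistics are stored
and re-applied verbatim at prediction time — prediction never re-fits
normalisation.

## Counting similar lesions

The multiplicity feature asks: how many other spots in the liver look
like the primary lesion?  The pipeline is:

1. **Balance weight.**  The fraction of primary-lesion pixels within
   one population sd of the lesion mean decides the weight
   &lambda; &isin; {0.75, 0.15}: homogeneous lesions (fraction &ge;
   0.68, the Gaussian value, boundary inclusive) weight the class-mean
   contrast; heterogeneous lesions weight the within-class spread.
2. **Threshold.**  J(&lambda;, T) = (1 &minus; &lambda;)&sigma;~w~(T)
   &minus; &lambda;|m~l~(T) &minus; m~b~(T)| is evaluated on every
   candidate threshold (by default all integers between the crop
   region's 1st and 99th percentiles) and minimised exhaustively; ties
   break toward the smallest T, and a threshold that empties a class is
   skipped via an infinite sentinel.  &sigma;~w~ is the square root of
   the probability-weighted within-class variance.  The lesion-side
   class is the side of T on which the user-masked lesion mean lies.
3. **Clusters.**  The thresholded lesion-side pixels are labelled by
   4-connected flood fill; components under `min_cluster_px` (default
   9) are dropped; the rest are ordered by their topmost-leftmost
   pixel.
4. **Signatures.**  Each cluster is summarised by &alpha; =
   &radic;(&Delta;mean&sup2; + &Delta;sd&sup2;), comparing pixels inside
   the cluster with a two-pixel outer ring, and &beta; &ge; 1, the
   major/minor axis ratio of its second-moment ellipse (minor axis
   floored at 1 px).  &alpha; folds the two first-order contrasts into
   one scalar so the similarity metric below stays two-dimensional; the
   definition is isolated in `cluster_signature()` and can be swapped.
5. **Decision.**  A cluster is counted when its Euclidean distance to
   the primary's signature in (&alpha;, &beta;) space is at most
   `similarity_threshold` (default 10, configuration-exposed — the
   acceptance radius is empirical by nature).  Clusters overlapping the
   primary mask are never counted.

Choices worth knowing: the crop region defaults to the liver mask when
given, otherwise to the primary bounding box expanded by 4 x its
diagonal; the primary lesion itself is excluded from the count; and at
low contrast-to-noise the J objective genuinely prefers extreme-tail
thresholds (the contrast term grows monotonically as T recedes into a
tail) — with realistic portal-venous contrast (&ge; 40 HU) the
&sigma;~w~ term dominates and the full-lesion split wins, which is the
regime the phantoms emulate.

## Selecting features per term

Each term is a binary annotation a &isin; {1, &minus;1}.  Features are
ranked once by the plug-in mutual information I(f; a) = H(f) + H(a)
&minus; H(f, a) in bits, estimated after equal-frequency discretisation
into 8 bins (ties to the lower bin; a constant column gets a single
code and zero information).  Eight bins are a robustness choice after
z-scoring; the ranking only needs the relative order.  Ties in
relevance break toward the earlier column.

Selection starts from the top-ranked feature and makes one pass down
the ranking: a candidate joins the selected set **iff** adding it
strictly increases the pooled fivefold cross-validated accuracy
&tau; = (TP + TN)/N of a Gaussian-kernel SVM (cost 1, kernel width
1/d over the d active features, fixed — nothing is tuned).  Folds are
stratified by class so imbalanced terms cannot produce single-class
folds, and a fresh seeded fold assignment is drawn at each evaluation,
mirroring repeated random subsampling; everything is reproducible from
the master seed.  Accepted features are never revisited — the greedy
scheme's known limitation.

Selected features get a 0-5 *ranking value*: relevance rescaled
linearly so the most relevant selected feature scores 5 and the least
scores 1 (all 5 on ties); unselected features score 0, meaning "not
mapped".

### What the accuracy gate does and does not control

The gate is honest per evaluation — on label-independent data the CV
accuracy of a *fixed* feature sits at chance (mean 0.50, range
0.43-0.57 over 20 seeds in the shipped acceptance run).  But the
ranking step consults the labels over the whole dataset before CV, so
on an all-noise 200 x 50 matrix the *top-ranked* column is spuriously
correlated in held-out folds too (mean &tau; &asymp; 0.55), and the
strict-improvement rule then retains further lucky candidates: the
final &tau; averages &asymp; 0.63.  This selection-before-validation
bias is a property of the procedure itself, and the package reports it
rather than masking it; treat the final &tau; as an optimistic training
diagnostic, not an unbiased error estimate.  An outer validation split
is the remedy when one is affordable.

## The end-to-end annotator

`vst_train()` z-scores the cohort matrix, keeps the terms whose
occurrence lies in the inclusive 20-75% band (rarer terms starve the
positive class; near-universal terms starve the negative), runs the
selector once per retained term, and refits each term's SVM on its
selected columns.  The bundle stores the vocabulary, per-term models
and traces, the normalisation statistics and the multiplicity
configuration, under a format version that `load_bundle()` refuses to
cross.  `predict()` emits hard present/absent decisions per term — the
underlying models are hard classifiers, and no probability calibration
is attempted.

## What the phantoms emulate — and what they do not

All tests and the acceptance run operate on synthetic phantoms, since
the clinical cohort behind the method is not redistributable.  The
generators emulate the study conditions: portal-venous-phase contrast,
with enhanced parenchyma near 110 HU inside an elliptical "liver",
extrahepatic background near -100 HU, hypodense elliptical lesions
(cyst-like means below ~18 HU, soft-tissue means 45-65 HU, i.e.
lesion-parenchyma contrast of roughly 40-110 HU), mild speckle texture
and Gaussian noise of 1.5-2 HU.  Satellite lesions are planted at fixed
angular slots with seed-drawn geometry; "dissimilar" satellites are
thin streaks whose axis-ratio signature lies far outside the acceptance
radius.  Cohorts of 40 phantoms carry three independent binary
attributes, each driving one term (hypodensity, elongation,
multiplicity) plus an always-present term that the occurrence filter
must remove.

What passing these tests shows: the dimensional contract, the oracle
identities, planted-truth recovery at realistic contrast, monotone
properties, and bit-level determinism of the full train/persist/predict
loop.  What it does not show: performance on real CT, where lesion
texture, partial-volume boundaries, enhancement heterogeneity,
anatomy-driven false candidates (vessels, bile ducts) and annotation
noise are far richer than any phantom here.  Accuracy on clinical data
can only be established on a clinical cohort, and no such claim is made
by this package's tests.

## Problem sizes and numerical conventions

Test and acceptance runs use 192 px phantoms (96-160 px in the cheaper
module tests), 40-sample cohorts, 200 x 50 selection matrices with 20
seed replicates, 1,000 sampled joint tables for the mutual-information
oracle and 100 phantoms for the threshold oracle; these sizes make the
planted effects decisive while a full run stays in the minutes range on
one core.  Conventions fixed throughout: (row, col) pixel coordinates;
population sd everywhere a spread is computed; entropies in bits;
intensities as HU-like signed 16-bit integers (slices round-trip
through 16-bit TIFF with a +32768 offset); 4-connectivity for
components; inclusive boundaries for the 0.68 homogeneity rule and the
20-75% occurrence band; smallest-T and earliest-column tie-breaks;
mutual information clamped at 0 against round-off.

## A worked run

```{r example, eval = FALSE}
ph <- similar_lesion_phantom(n_similar = 3, seed = 7)
res <- count_similar_lesions(ph$image)
res$count          # 3 on this phantom
glance(res)        # count, T*, lambda, candidate clusters

co <- phantom_cohort(40, seed = 7)
feats <- extract_cohort_features(co$images)
bundle <- vst_train(feats, co$annotations, seed = 7)
mapping_report(bundle)
autoplot(mapping_report(bundle))
predict(bundle, co$images[[1]])
```

The chunk is not evaluated at build time (a full cohort extraction
takes a few minutes); `README.md` shows the printed output of the same
run, and `scripts/acceptance.R` recomputes every headline quantity from
scratch.
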