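---
title: "Virtual-cell consensus segmentation of H&E tissue: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-cell consensus segmentation of H&E tissue: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcellseg)
```

`vcellseg` labels the tissue compartments of an H&E-stained brightfield image
— epithelium versus stroma — without training data. This vignette is the
package's own account of the underlying models, the parameters that matter,
the numerical conventions, and what the synthetic test bed does and does not
establish about real slides.

## The imaging model

H&E staining is subtractive: haematoxylin (nucleic acids, blue-violet) and
eosin (protein-rich cytoplasm and extracellular matrix, pink) absorb light
according to the Beer–Lambert law. A background-corrected 8-bit RGB pixel
with transmittance $v_c$ in channel $c$ has optical density
$OD_c = -\log(v_c/255)$, and the densities $d_s$ of the three stain
components (haematoxylin, eosin, a residual direction) satisfy the linear
model $OD = M^\top d$ with $M$ the matrix of unit stain absorbance vectors.
`deconvolve()` solves this system per pixel, clips negative densities to
zero, and stores the per-stain transmittances $255 e^{-d_s}$ as the stain
image.

Choices made here:

* **Stain vectors.** The slide scanner's true dye spectra are unknown, so the
  default basis is the standard published H&E deconvolution basis
  (`default_he_vectors()`); the residual direction is the normalised cross
  product of the haematoxylin and eosin directions, hence exactly orthogonal
  to both. Users with calibrated vectors can override them via the
  `stain_vectors` config entry; estimating vectors from the image itself
  (Macenko-style) is deliberately out of scope.
* **Saturated pixels.** A transmittance floor of `eps = 1` grey level bounds
  the optical density of fully dark pixels ($OD \le \log 255 \approx 5.54$).
  The floor, rather than an additive offset inside the logarithm, keeps
  white pixels at exactly zero density and leaves all other pixels unbiased;
  the forward/inverse round trip then agrees to within 8-bit quantisation
  (about 1% mean relative error on the recovered densities, checked in the
  test suite).
* **Precision.** All internal arithmetic is double precision; channels are
  quantised to 8 bits only when a stain image is materialised (the
  `quantise` argument), matching the 8-bit stain image the rest of the
  pipeline consumes.

## Morphological segmentation into virtual cells

The stained-tissue mask is the per-pixel minimum of the haematoxylin and
eosin transmittances, thresholded with Huang's fuzzy-entropy criterion
(256-bin histogram; the threshold minimising the summed Shannon entropy of
the fuzzy memberships, ties resolved toward the lower threshold; foreground
is the set of pixels at or below it). The residual channel plays no role in
masking.

Nuclear seeds are dark basins of the haematoxylin channel. The h-concave
transform $HMIN_h(I) - I$ is positive exactly inside intensity basins and
equals $\min(\text{depth}, h)$ at a basin bottom. Two conventions needed
fixing:

* **Border handling.** The image frame is treated as an outlet: water
  escaping past the border is lost. Without this, a completely flat image —
  or any frame whose global minimum's catchment spans the frame — would be
  reported as one giant basin, which is the literal behaviour of
  reconstruction-by-erosion but useless as a nucleus detector. On realistic
  images, whose frame-touching background is the brightest region, the
  convention changes nothing. It is implemented by padding the reconstruction
  with a one-pixel flood-source ring.
* **Support threshold.** Any strictly positive h-concave response counts as
  basin support. Because every basin responds at any $h \ge 1$, raising $h$
  does not *remove* shallow basins; it *merges* nearby basins into common
  lakes, so the number of seed components is non-increasing in $h$ (a
  property test). Small noise basins are instead removed by the binary
  opening by reconstruction: `e` erosions with a 3×3 square structuring
  element followed by reconstruction-by-dilation, which deletes components
  that vanish under the erosions while leaving every survivor's shape
  pixel-for-pixel intact. A consequence worth knowing: a component must
  contain a 7×7 solid square to survive `e = 3`, so nuclei thinner than
  about 8–9 px across their minor axis are discarded — at typical 0.37 µm/px
  TMA resolution real nuclei are comfortably wider.

Defaults are `h = 30` grey levels and `e = 3` erosions, the method's
published operating point. Larger `h` merges detail (under-segmentation);
smaller `h` fragments tissue into noise basins (over-segmentation).

The watershed step floods the haematoxylin channel from the seed components
imposed as minima (priority-flood with first-in-first-out tie-breaking, so
results are deterministic), restricted to the tissue mask. No watershed-line
pixels are produced: the virtual cells exactly tile the mask, one v-cell per
seed, and each seed keeps its v-cell's id. The flooding surface is not
dictated by the method's description — dark nuclei as basins of the
haematoxylin image is the consistent reading and the default
(`watershed_mode = "intensity"`); a pure geodesic-influence-zone mode
(`"distance"`, flat landscape) is available for comparison. Mask islands
containing no seed (rare, but possible with fragmented masks) are assigned to
the nearest labelled region by a second breadth-first pass rather than left
unlabelled, because downstream feature extraction requires a complete
partition. Connectivity is 8-connected throughout; label 0 is background.

## The 63-descriptor feature table

`build_feature_table()` returns one row per v-cell: 11 colour statistics on
each stain channel over the v-cell's pixels (computed on the 8-bit
transmittance values; mode and Shannon entropy — in bits — use the 256-bin
histogram; variance and sd are sample statistics; skewness and excess
kurtosis are population moment ratios, reported as 0 for constant regions),
22 v-cell shape descriptors and 8 descriptors of the enclosed nucleus.

Geometric conventions, all on pixel centres:

* the **perimeter** is the length of the Moore-traced boundary polygon, with
  diagonal steps weighted $\sqrt 2$. This overestimates the perimeter of a
  smooth disc by a few percent, so circularity of a large digital disc is
  about 0.9, not 1.0 — tolerances in the tests reflect that;
* the **convex hull** is taken over pixel centres; `chullArea` is the count
  of pixel centres inside or on the hull polygon, so solidity is exactly 1
  and concavity exactly 0 for convex digital regions (the tests verify the
  count against Pick's theorem);
* **feret** is the maximum caliper over hull vertices and **breadth** the
  maximal extent perpendicular to the feret axis; **MinR** is the distance
  from the centre of mass to the nearest boundary pixel and **MaxR** to the
  farthest region pixel;
* one-pixel regions take perimeter 4 and area 1, and every ratio with a zero
  denominator is reported as 0 rather than NaN, so degenerate regions cannot
  poison the clustering.

The 63-column set is fixed; no feature selection is re-run. Features are
z-standardised per column before clustering (`standardize_features()`, also
applied internally by `generate_ensemble()`): the table mixes pixels,
intensities and dimensionless ratios, and distance-based clusterers would
otherwise be dominated by the large-magnitude columns. Zero-spread columns
standardise to 0 and are dropped inside the Gaussian-mixture clusterer, where
they would make the M-step singular.

## Ensemble generation, selection and consensus

The ensemble crosses five clustering strategies, all with $k = 2$:

| algorithm | runs | parameters |
|---|---|---|
| k-means | 10 | random-start count per run drawn uniformly from [10, 200]; best start by within-cluster sum of squares |
| EM (diagonal Gaussian mixture) | 10 | same random-start counts; candidates scored by one M+E step, EM from the best (≤ 100 iterations, 1e-6 log-likelihood tolerance) |
| unsupervised LVQ | 4 | learning rates 0.05, 0.07, 0.09, 0.1; 100 epochs; rate decays linearly to 0 |
| density-based reassignment (MDB) | 1 | k-means base, per-feature normal densities, variance floored at 1e-6 of the global feature variance; posterior ties go to the lower cluster index |
| agglomerative hierarchical | 6 | complete and average linkage × Euclidean, Manhattan, Minkowski (p = 3) |

— 31 partitions in total. The "mean" hierarchical link is read as average
linkage, and the Minkowski exponent is set to 3 to make the run distinct
from the Euclidean one; the LVQ epoch count and the EM initialisation scheme
are this package's choices where the published description is silent. A
single master seed drives every run, so ensembles are bit-reproducible.

**Selection.** Each member's diversity is its average Rand index against all
other members of the original ensemble (Rand index: the fraction of object
pairs on which two partitions agree). Members outside the inclusive window
`[D1, D2] = [0.5, 0.9]` are rejected: too dissimilar members drag the
consensus toward noise, and near-duplicates add no information. A rejected
stochastic member is re-run with a fresh seed up to 5 times, each candidate
screened against the *original* ensemble (excluding the replaced slot, so the
averaging denominator is unchanged); hierarchical members are deterministic
and are removed without replacement. An ensemble of mutually identical
partitions therefore empties — by design, since consensus over duplicates is
pointless — and the package raises an error rather than proceeding.

**Evidence accumulation (EAC).** The co-association matrix
$M_{ij} = m_{ij}/\dot C$ counts how often the selected members group v-cells
$i$ and $j$ together. $1 - M$ is clustered hierarchically (average linkage by
default; complete available) and cut at two clusters. This route is
quadratic in the number of v-cells.

**Voting.** Cluster labels are arbitrary, so members are first aligned to a
reference partition — chosen as the member with the highest ensemble
similarity, the most consensual anchor — by rendering each cluster as its
v-cell pixel set and matching clusters of maximal Jaccard overlap; with
$k = 2$ this reduces to either keeping or swapping the labels. The overlap is
computed by area-weighted set arithmetic over v-cell ids, which is exactly
equal to rasterising the clusters and counting pixels (a conformance test
keeps a rasterising mode honest) but avoids image-sized temporaries. The
consensus label of each v-cell is then the majority across members; a vote
tie takes the label of the member with the highest ensemble similarity, and a
residual tie (equal votes *and* equal similarity) takes the lower label.
Everything here is linear in the number of v-cells.

## Evaluation

Pixel-level annotations (0 background, 1 epithelium, 2 stroma) are
transferred to v-cells by majority pixel class, ties resolved by the fixed
priority epithelium > stroma > background. The two consensus clusters are
mapped onto the classes by maximal pixel overlap before scoring, so a global
label swap cannot hurt. Reported measures: Rand index on v-cell pairs;
precision, recall and F1 with epithelium positive, counted over v-cells
(the clustering's unit of analysis); and the Jaccard index of the epithelium
maps, computed pixel-wise (area-weighted over v-cells, which is exact because
classes are constant within a v-cell). Background v-cells are excluded from
all counts. With multiple images, reports are averaged per image without
weighting.

## The synthetic test bed

`generate_tissue_image()` renders a circular tissue core on a bright
background, split by a wavy vertical boundary into an epithelium compartment
(denser, rounder nuclei: 16 per 10⁴ px², equivalent radius 5–6.5 px, axis
ratio ≤ 1.25) and a stroma compartment (sparser, elongated nuclei: 7 per 10⁴
px², radius 6–7.5 px, axis ratio 1.5–1.9, stronger eosin uptake: cytoplasm
eosin OD 0.6 versus 0.35, haematoxylin OD 0.12 versus 0.25). Nuclei
(haematoxylin OD ≈ 1.0) are placed by dart-throwing with a minimum-spacing
constraint so no two seeds can merge, and are sized to survive the `e = 3`
opening at the default geometry. Per-stain density fields go through the
forward Beer–Lambert model to 8-bit RGB with Gaussian noise (sd 2 grey
levels). All randomness flows from one spec seed; images are bit-identical
across runs.

What the generator emulates: two compartments separable by stain and
morphology statistics; nuclei as the only deep haematoxylin basins; a bright
background that crops and thresholds cleanly. What it does not emulate:
touching and overlapping nuclei (the method does not claim to split them),
staining gradients and batch variability, tissue folds, out-of-focus regions,
texture. Passing the end-to-end tests therefore shows the machinery is
correct and the consensus logic robust to ensemble noise — not that the
default parameters transfer to any particular scanner or laboratory.

One behaviour the generator exposed and the documentation should state: when
an entire compartment's cytoplasm takes up enough haematoxylin to sit within
`h` grey levels of the background, that whole compartment is itself a basin
and yields one giant "seed". This is the mathematically correct output of the
transform, and real H&E nuclei are far deeper than cytoplasm, but it means
"no nuclei implies no seeds" only holds when haematoxylin uptake is
nucleus-specific.

## Problem sizes and budgets

The test suite exercises unit fixtures at 64–256 px and two full-scale runs:
the default 512×512 core (≥ 200 nuclei) through the complete pipeline, and a
planted-feature recovery experiment (500 objects, 63 dimensions, 10σ
centroid separation, 30% of the 31 ensemble members replaced by random
partitions) in which both consensus routes must reach a Rand index of at
least 0.95 against the planted labels. These sizes were chosen so the whole
suite runs in a couple of minutes on one CPU while still covering the
regimes that matter (hundreds of v-cells, full ensemble grid).

## Known limitations

* $k$ is fixed at 2; multi-class consensus (the bipartite-matching
  generalisation of the alignment) is out of scope.
* Merged or occluded nuclei produce a single v-cell; no splitting is
  attempted.
* Stain vectors are assumed, not estimated; strongly miscalibrated vectors
  degrade both the mask and the colour features.
* The diversity window `[0.5, 0.9]` presumes a moderately noisy ensemble; on
  trivially separable data all members agree and selection (correctly)
  refuses to produce an ensemble of duplicates.
* Evaluation counts v-cells, not pixels, for precision/recall/F1; with very
  uneven v-cell sizes the two conventions can differ.
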