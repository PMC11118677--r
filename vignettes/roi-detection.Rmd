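---
title: "Patch-based ROI detection in melanocytic tumor slides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based ROI detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Diagnosing a melanocytic skin tumor starts from a pathologist's reading
of an H&E-stained whole-slide image (WSI): is the lesion a benign nevus
or a melanoma, and where is the diagnostically relevant region (ROI)?
Slide archives typically carry a slide-level diagnosis, and *partial*
ROI annotations: a slide often contains several slices of the same
tissue, and the pathologist outlines the tumor on some slices only.
patchROI implements a weakly-supervised framework that learns from this
partial information and produces, for an unseen slide, (i) a slide-level
melanoma/nevus call and (ii) a predicted ROI on the patch grid, with
overlap, boundary and heatmap visualizations.

# The procedure

1. **Tiling.** Each slide is cut into non-overlapping 256 × 256 px
   patches at the working magnification (nominally 20×). Partial edge
   tiles are dropped: grids are `floor(h/256) × floor(w/256)`, indexed
   row-major. All boxes are half-open in 0-based pixel coordinates, so
   tiling arithmetic is exact.
2. **Tissue filtering.** A pixel is tissue when its HSV saturation
   exceeds `s_min = 0.05` and its brightness is below `v_max = 0.95`
   (stained tissue is colorful, glass is bright and gray). Patches with
   tissue fraction below `min_fraction = 0.25` are not extracted. The
   thresholds are configuration keys; the defaults are conventional
   values for H&E tiles.
3. **Labeling from partial annotations.** A patch is *inside* an
   annotation iff its center point lies in any annotated polygon
   (points exactly on an edge count as inside, so labels are
   deterministic). Inside patches receive the slide label; designated
   "other-source" zones provide the third class; everything else stays
   unlabeled and is never trained on, because an unlabeled tissue patch
   may be unannotated tumor. "Other" patches are balanced per slide to
   the annotated-patch count.
4. **Patch classifier.** A pluggable three-class classifier returns a
   simplex score triple (melanoma, nevus, other) per patch; class order
   is fixed globally. The default is a single-hidden-layer softmax
   network over 24 per-patch color/texture summaries (below). A
   ground-truth oracle classifier with a tunable error rate serves as a
   test double, and heavyweight convolutional backbones can implement
   the same `fitClassifier`/`predictScores` interface.
5. **Slide call and ROI.** Ignoring patches whose argmax is "other",
   the slide is classified by majority vote between melanoma- and
   nevus-voting patches. All n extracted patches are then ranked by the
   winning class's score, and the top `k = round(n·β)` patches become
   the predicted ROI, where the annotated ratio β is the fraction of
   extracted patches inside the annotated region. At evaluation time β
   comes from the test slide's own annotations — exactly the
   evaluation protocol this framework reproduces, with the information
   leak made explicit; for annotation-free inference the command-line
   tool accepts a user-supplied β.
6. **Evaluation.** Three metrics: three-class patch accuracy on
   labeled test patches, slide-level accuracy, and per-slide
   intersection-over-union on the patch grid,
   `IoU = |A∩B| / |A∪B|`, averaged unweighted; both A (annotated) and
   B (predicted) live on the same tissue-filtered patch set. `IoU = 1`
   when both sets are empty.

## Numerical conventions

* Vote ties go to melanoma with an explicit `tie_flag` — the
  clinically conservative choice when the counts give no direction.
* `k = round(n·β)` rounds half away from zero, so `n = 10, β = 0.25`
  selects 3 patches; score ties are broken by row-major patch index,
  making the selection stable and permutation-invariant.
* Polygon membership is the even-odd (ray-casting) rule with
  edge-inclusive boundaries.
* All randomness (training shuffles, initialization, augmentation,
  oracle flips, cohort generation) is derived from explicit seeds; the
  oracle's per-patch error draws are hashes of (seed, slide, row, col),
  so they are independent of batch order and nested across increasing
  error rates, which makes degradation monotone by construction.

# Preprocessing choices

**Color normalization.** Two methods sit behind the normalizer
interface. The classical channel-statistics transfer maps each
channel's tissue mean/sd in the perceptual lαβ (log-LMS rotation) space
onto a reference slide; it is exact for pure channel-gain differences
and is the method the `fitColorNormalizer`/`applyColorNormalization`
pair implements. The pipeline default, however, is *white-point
standardization*: estimate the glass background color from bright
desaturated pixels and rescale channels so it maps to pure white. The
reason is composition sensitivity: global channel statistics shift with
a slide's tumor burden, so statistics transfer can *introduce*
class-correlated shifts between slides whose tumor content differs,
while the glass background is tissue-independent. On synthetic cohorts
with class-dependent tumor darkness this difference is large enough to
change patch accuracy materially (the package's tests exercise both
paths). When normalizing patches, the image-side statistics are always
computed once per slide — normalizing a patch against its own
statistics would erase the very color differences that carry the class
signal.

**Augmentation.** Reflective 8 px padding followed by a random crop
back to 256 × 256, a horizontal flip with probability 0.5, and optional
per-channel standardization with fixed constants (0.5/0.5). Two
augmented copies per labeled patch are added at training time.

**Features.** The default classifier sees 24 per-patch statistics:
RGB means and standard deviations, saturation mean/sd, brightness
quantiles (5/25/50%), tissue fraction, and color/brightness summaries
on two concentric windows (half and one-sixteenth of the side).
Brightness is summarized by quantiles rather than a thresholded
dark-pixel count: quantiles respond continuously to nuclear density and
pigmentation, where a hard cutoff can flip for an entire slide under a
small stain-gain shift. The central windows exist because patch class
is defined by the patch *center*: a patch whose center sits just
outside the tumor boundary can still be half tumor by area.

# The classifier

The default is deliberately small: features → 16 tanh units → softmax,
trained by mini-batch SGD with momentum (defaults: 10 epochs, batch 32,
learning rate 0.05, momentum 0.9) on the three-class cross-entropy,
returning the per-epoch loss trajectory. The step size suits a shallow
network on standardized low-dimensional features. Training errors out
if any class is absent, is bit-reproducible given the seed, and
checkpoints restore bit-identical scores. The framework's claims do not
depend on this particular backbone; it is the desk-scale stand-in
behind the same interface a convolutional model would implement.

# The synthetic cohort generator

Real melanocytic-tumor archives are not redistributable, so the
package ships a generator whose output has the *structure* the method
needs: two visually distinct tumor classes, background/stroma tissue,
multiple slices per slide with only some slices annotated, slide-level
labels, and Aperio-ImageScope-style XML polygon exports.

Per slide: a white glass background; one to three elliptical tissue
slices with pink stroma; one star-shaped tumor polygon per slice, dark
and nucleus-dense for melanoma, lighter and less dense for nevus
(brightness and nuclear density are exactly the cues reported to drive
melanocytic classification); per-pixel Gaussian color noise; and a
per-slide stain gain/offset jitter emulating scanning-session
variability. Each tumor slice is annotated with probability 0.6
(independently, with no forced minimum, so a slide can have no exported
annotations at all); the full polygon set is kept as ground truth, and
ground-truth masks are written alongside. Tumors are centered on the
patch-grid center nearest their slice anchor, so every tumor contains
at least one patch center and every slide has tumor-voting patches.

The generator also exports per-slide *other-source zone* polygons —
small discs whose patch centers are verified (against the full ground
truth) to lie outside every tumor polygon, including near-boundary
stroma. These formalize the manual step of picking safe non-tumor
example regions; without them, unannotated tumor would contaminate the
"other" class by construction, which is precisely the failure mode the
partial-annotation design exists to avoid. The zones deliberately
include stroma close to the tumor edge so the classifier must learn the
center rule at the boundary, not merely a tissue/background split.

Default scale: 20 slides of 3072 × 2304 px (a 12 × 9 grid of 256 px
patches), class balance 86:74, split 80/20 into 16 training and 4 test
slides; this yields on the order of 500–600 training instances after
balancing and augmentation, enough to fit the default classifier in
seconds while keeping whole-cohort generation around two minutes on one
CPU. All sizes are configurable.

**What passing tests do and do not show.** The generator produces a
*learnable but honest* cohort: classes differ in color and texture with
within-class noise, annotations are partial, slides differ in stain.
It does not model nuclear morphology, pigment granularity, scanner
artifacts, tissue folds, or the ambiguous lesions that make real
melanocytic diagnosis hard. Passing the end-to-end criteria shows the
*framework* — labeling, learning, voting, ranking, IoU — is correct and
stable under its stated assumptions; it says nothing about clinical
performance on real slides.

# Visualization

The overlap map alpha-blends a transparent blue over everything except
the selected ROI patches, so the untinted fraction equals β. The
boundary map clusters ROI patch centers with OPTICS (implemented in the
package: reachability ordering with core distance at `min_samples = 5`,
clusters extracted at `max_eps = 3 × patch size`) and draws the exact
rectilinear outer boundary of the largest cluster's patch-square union;
the outline is traced on grid edges (shared edges cancel, remaining
directed edges form loops, the largest-area loop is the outer boundary)
and can be exported back into the annotation XML dialect. The heatmap
renders each patch's winning-class score through a blue→red ramp as
uniform patch blocks, unsmoothed. OPTICS parameters are configurable;
the defaults keep 8-connected patches in one cluster while separating
distinct tissue slices. Patch centers (not pixels) are clustered — the
framework is patch-based throughout.

# Known limitations

* β at test time uses the test slide's own annotations, as the
  evaluation protocol dictates; annotation-free deployment needs a
  user-supplied or estimated β.
* The tissue-filtered patch set is the denominator for both β and the
  ranking; slides whose annotations sit in sub-threshold tissue can
  have β = 0 (then both A and the ROI are empty and IoU is 1 by
  convention).
* The boundary map outlines only the largest OPTICS cluster; multifocal
  ROIs are visible in the overlap map and heatmap but not outlined.
* The default classifier is color/texture-based; it cannot represent
  morphology and will fail on cohorts where class-conditional color is
  uninformative. It is the interface, not the contribution.
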