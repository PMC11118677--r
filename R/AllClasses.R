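## Central S4 classes. Images are numeric arrays h x w x 3 in [0, 1]
## (the png package convention); pixel coordinates are 0-based with the
## x axis along columns and y along rows, so a slide occupies
## [0, width) x [0, height) and all boxes are half-open.

CLASS_ORDER <- c("melanoma", "nevus", "other")

#' AnnotationRegion: one polygon ROI annotation
#'
#' A closed polygon annotation at working magnification. Vertices are
#' 0-based pixel coordinates, ordered; the last vertex implicitly
#' connects back to the first. At least 3 vertices are required and all
#' coordinates must be finite and non-negative.
#'
#' @slot region_id character identifier.
#' @slot vertices numeric matrix with columns `x`, `y`.
#' @slot label_hint optional free-text label carried through the XML.
#' @export
setClass("AnnotationRegion",
  representation(region_id = "character",
                 vertices = "matrix",
                 label_hint = "character"))

setValidity("AnnotationRegion", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L)
    return("vertices must be a numeric matrix with two columns (x, y)")
  if (nrow(v) < 3L)
    return(sprintf("region '%s' has fewer than 3 vertices", object@region_id))
  if (!all(is.finite(v)))
    return("vertex coordinates must be finite")
  if (any(v < 0))
    return("vertex coordinates must be >= 0")
  TRUE
})

#' Create an annotation region
#'
#' @param region_id identifier (coerced to character).
#' @param vertices two-column numeric matrix (or coercible) of `x`, `y`
#'   pixel coordinates at working magnification, 0-based.
#' @param label_hint optional free text.
#' @return an [AnnotationRegion-class] object.
#' @examples
#' annotationRegion("r1", cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' @export
annotationRegion <- function(region_id, vertices, label_hint = NA_character_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  new("AnnotationRegion", region_id = as.character(region_id),
      vertices = vertices, label_hint = as.character(label_hint))
}

#' @rdname accessors
#' @export
setMethod("vertices", "AnnotationRegion", function(x) x@vertices)

setMethod("show", "AnnotationRegion", function(object) {
  cat(sprintf("AnnotationRegion '%s': %d vertices, bbox [%.0f,%.0f]x[%.0f,%.0f]\n",
              object@region_id, nrow(object@vertices),
              min(object@vertices[, 1]), max(object@vertices[, 1]),
              min(object@vertices[, 2]), max(object@vertices[, 2])))
})

#' SlideRecord: one whole-slide image with label and annotations
#'
#' Holds either an in-memory raster (`image`) or a path to a PNG/TIFF
#' (`image_path`), slide dimensions at working magnification, the
#' slide-level diagnosis, and the polygon annotations exported for the
#' slide (which may cover only some tissue slices).
#'
#' @slot slide_id character identifier.
#' @slot image in-memory raster array (h x w x 3) or `NULL`.
#' @slot image_path path to the raster on disk, or `NA`.
#' @slot width_px,height_px slide dimensions in pixels.
#' @slot slide_label `"melanoma"`, `"nevus"`, or `"unknown"` (inference
#'   time only).
#' @slot regions list of [AnnotationRegion-class] (the exported, possibly
#'   partial annotations).
#' @slot magnification nominal objective power (default 20).
#' @export
setClass("SlideRecord",
  representation(slide_id = "character", image = "ANY",
                 image_path = "character", width_px = "numeric",
                 height_px = "numeric", slide_label = "character",
                 regions = "list", magnification = "numeric"))

setValidity("SlideRecord", function(object) {
  if (object@width_px <= 0 || object@height_px <= 0)
    return("slide dimensions must be positive")
  if (!object@slide_label %in% c(CLASS_ORDER[1:2], "unknown"))
    return("slide_label must be 'melanoma', 'nevus' or 'unknown'")
  for (r in object@regions) {
    if (!is(r, "AnnotationRegion")) return("regions must be AnnotationRegion objects")
    v <- r@vertices
    if (any(v[, 1] >= object@width_px) || any(v[, 2] >= object@height_px))
      return(sprintf("region '%s' has vertices outside the slide bounds",
                     r@region_id))
  }
  TRUE
})

#' Create a slide record
#'
#' @param slide_id identifier.
#' @param image in-memory raster array (h x w x 3, values in `[0,1]`), or
#'   `NULL` when `image_path` is given.
#' @param image_path path to a PNG raster on disk.
#' @param width_px,height_px dimensions; inferred from `image` if omitted.
#' @param slide_label `"melanoma"`, `"nevus"` or `"unknown"`.
#' @param regions list of [AnnotationRegion-class].
#' @param magnification nominal objective power.
#' @return a [SlideRecord-class] object.
#' @export
slideRecord <- function(slide_id, image = NULL, image_path = NA_character_,
                        width_px = NULL, height_px = NULL,
                        slide_label = "unknown", regions = list(),
                        magnification = 20) {
  if (is.null(width_px)) {
    if (is.null(image)) stop("either image or explicit dimensions are required")
    width_px <- dim(image)[2]
    height_px <- dim(image)[1]
  }
  new("SlideRecord", slide_id = as.character(slide_id), image = image,
      image_path = as.character(image_path), width_px = width_px,
      height_px = height_px, slide_label = slide_label,
      regions = regions, magnification = magnification)
}

#' @rdname accessors
#' @export
setMethod("slideId", "SlideRecord", function(x) x@slide_id)

#' @rdname accessors
#' @export
setMethod("slideLabel", "SlideRecord", function(x) x@slide_label)

#' @rdname accessors
#' @export
setMethod("regions", "SlideRecord", function(x) x@regions)

setMethod("show", "SlideRecord", function(object) {
  cat(sprintf("SlideRecord '%s': %dx%d px at %gx, label=%s, %d annotated region(s)\n",
              object@slide_id, object@width_px, object@height_px,
              object@magnification, object@slide_label,
              length(object@regions)))
})

#' Load the raster of a slide
#'
#' Returns the in-memory raster if present, otherwise reads the PNG at
#' `image_path`.
#'
#' @param slide a [SlideRecord-class].
#' @return numeric array h x w x 3 in `[0, 1]`.
#' @export
slideRaster <- function(slide) {
  stopifnot(is(slide, "SlideRecord"))
  if (!is.null(slide@image)) return(slide@image)
  if (is.na(slide@image_path))
    stop(sprintf("slide '%s' has neither an in-memory raster nor an image path",
                 slide@slide_id))
  img <- png::readPNG(slide@image_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' PatchSet: the tiling of one slide into grid patches
#'
#' The non-overlapping patch grid of a slide together with a per-patch
#' table (`row`, `col` are 0-based grid positions; `x0,y0,x1,y1` the
#' half-open pixel bounding box; `tissue_fraction`; `label` one of
#' melanoma/nevus/other/unlabeled). Partial edge patches are dropped, so
#' `n_rows = floor(height/patch_size)` and likewise for columns.
#'
#' @slot slide_id slide identifier.
#' @slot patch_size patch side length in pixels.
#' @slot n_rows,n_cols grid dimensions.
#' @slot patches the per-patch data frame.
#' @export
setClass("PatchSet",
  representation(slide_id = "character", patch_size = "integer",
                 n_rows = "integer", n_cols = "integer",
                 patches = "data.frame"))

setValidity("PatchSet", function(object) {
  p <- object@patches
  need <- c("row", "col", "x0", "y0", "x1", "y1", "tissue_fraction", "label")
  if (!all(need %in% names(p))) return("patch table is missing required columns")
  if (nrow(p) > 0) {
    if (any(p$x1 - p$x0 != object@patch_size) ||
        any(p$y1 - p$y0 != object@patch_size))
      return("patch bounding boxes must have side length patch_size")
    bad <- !p$label %in% c(CLASS_ORDER, "unlabeled")
    if (any(bad)) return("patch labels must be melanoma/nevus/other/unlabeled")
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("patchTable", "PatchSet", function(x) x@patches)

#' @rdname accessors
#' @export
setMethod("nPatches", "PatchSet", function(x) nrow(x@patches))

#' @rdname accessors
#' @export
setMethod("slideId", "PatchSet", function(x) x@slide_id)

setMethod("show", "PatchSet", function(object) {
  lab <- table(factor(object@patches$label, c(CLASS_ORDER, "unlabeled")))
  cat(sprintf("PatchSet '%s': %dx%d grid of %d px patches, %d kept (%s)\n",
              object@slide_id, object@n_rows, object@n_cols,
              object@patch_size, nrow(object@patches),
              paste(sprintf("%s=%d", names(lab), lab), collapse = ", ")))
})

#' Virtual parent class of all patch classifiers
#'
#' A patch classifier maps a patch to a simplex-constrained score triple
#' over (melanoma, nevus, other). Concrete classes: the trainable
#' [softmaxNetClassifier()] and the ground-truth [oracleClassifier()]
#' test double. Heavier backbones can be plugged in by subclassing and
#' providing `fitClassifier` / `predictScores` methods.
#'
#' @export
setClass("PatchClassifier", representation("VIRTUAL"))

#' SoftmaxNetClassifier: seeded shallow neural network
#'
#' A single-hidden-layer (tanh) network with a softmax head trained by
#' mini-batch SGD with momentum on cross-entropy, over per-patch summary
#' features (see [patchFeatures()]). Fully deterministic given the
#' training seed.
#'
#' @slot hidden hidden-layer width.
#' @slot W1,b1,W2,b2 network parameters.
#' @slot feat_center,feat_scale feature standardization constants.
#' @slot feature_names expected feature column order.
#' @slot trained logical.
#' @slot loss per-epoch mean training cross-entropy.
#' @slot config training configuration used.
#' @export
setClass("SoftmaxNetClassifier", contains = "PatchClassifier",
  representation(hidden = "integer", W1 = "matrix", b1 = "numeric",
                 W2 = "matrix", b2 = "numeric", feat_center = "numeric",
                 feat_scale = "numeric", feature_names = "character",
                 trained = "logical", loss = "numeric", config = "list"))

#' @rdname accessors
#' @export
setMethod("isTrained", "SoftmaxNetClassifier", function(x) x@trained)

#' @rdname accessors
#' @export
setMethod("lossTrajectory", "SoftmaxNetClassifier", function(x) x@loss)

setMethod("show", "SoftmaxNetClassifier", function(object) {
  cat(sprintf("SoftmaxNetClassifier: %d hidden units, %s\n", object@hidden,
              if (object@trained)
                sprintf("trained (%d epochs, final loss %.4f)",
                        length(object@loss), utils::tail(object@loss, 1))
              else "untrained"))
})

#' OracleClassifier: ground-truth test double
#'
#' Returns the one-hot score triple of each patch's true class, looked up
#' from ground truth, optionally corrupted: with probability `epsilon`
#' the prediction is flipped to one of the two other classes. Flips are a
#' deterministic function of (seed, slide_id, row, col), so predictions
#' are independent of batch composition and order, and the flipped sets
#' are nested across increasing `epsilon`.
#'
#' @slot truth environment mapping "slide|row|col" to the true class.
#' @slot epsilon flip probability in `[0, 1]`.
#' @slot seed integer seed for the per-patch flip draws.
#' @export
setClass("OracleClassifier", contains = "PatchClassifier",
  representation(truth = "environment", epsilon = "numeric",
                 seed = "integer"))

setMethod("show", "OracleClassifier", function(object) {
  cat(sprintf("OracleClassifier: %d patches known, epsilon=%g\n",
              length(ls(object@truth)), object@epsilon))
})

#' ColorNormalizer: Reinhard-style channel-statistics transfer
#'
#' Stores per-channel mean and standard deviation of a reference image's
#' tissue pixels in the perceptual l-alpha-beta (log-LMS rotation) color
#' space. Applying the normalizer shifts/scales each channel of an input
#' image to the reference statistics. Must be fitted exactly once before
#' use.
#'
#' @slot ref_mean,ref_sd reference channel statistics (length 3 each).
#' @slot s_min,v_max HSV tissue-detection thresholds used when fitting.
#' @slot fitted logical.
#' @export
setClass("ColorNormalizer",
  representation(ref_mean = "numeric", ref_sd = "numeric",
                 s_min = "numeric", v_max = "numeric", fitted = "logical"))

setValidity("ColorNormalizer", function(object) {
  if (object@fitted && any(object@ref_sd <= 0))
    return("reference channel standard deviations must be positive")
  TRUE
})

setMethod("show", "ColorNormalizer", function(object) {
  if (object@fitted)
    cat(sprintf("ColorNormalizer (lalphabeta): ref mean [%s], sd [%s]\n",
                paste(sprintf("%.3f", object@ref_mean), collapse = ", "),
                paste(sprintf("%.3f", object@ref_sd), collapse = ", ")))
  else cat("ColorNormalizer: unfitted\n")
})

#' SlidePrediction: slide-level result of the detection stage
#'
#' Majority-vote label, per-class vote counts, annotated ratio beta, the
#' ranking of all patches by the winning-class score, and the selected
#' top-`round(n*beta)` ROI patch set (a prefix of the ranking).
#'
#' @slot slide_id slide identifier.
#' @slot predicted_label `"melanoma"` or `"nevus"`.
#' @slot vote_counts named counts of per-patch argmax (melanoma, nevus,
#'   other).
#' @slot beta annotated ratio in `[0, 1]`.
#' @slot ranked_patches integer indices (into the scored patch table) in
#'   descending winning-class score order.
#' @slot roi_patches prefix of `ranked_patches` of length `round(n*beta)`.
#' @slot tie_flag `TRUE` when the melanoma/nevus vote was tied (melanoma
#'   is then returned).
#' @export
setClass("SlidePrediction",
  representation(slide_id = "character", predicted_label = "character",
                 vote_counts = "numeric", beta = "numeric",
                 ranked_patches = "integer", roi_patches = "integer",
                 tie_flag = "logical"))

setValidity("SlidePrediction", function(object) {
  if (!object@predicted_label %in% CLASS_ORDER[1:2])
    return("predicted_label must be melanoma or nevus")
  if (object@beta < 0 || object@beta > 1) return("beta must lie in [0, 1]")
  k <- length(object@roi_patches)
  if (k > 0 && !identical(object@roi_patches, object@ranked_patches[seq_len(k)]))
    return("roi_patches must be a prefix of ranked_patches")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("slideId", "SlidePrediction", function(x) x@slide_id)

#' @rdname accessors
#' @export
setMethod("roiPatches", "SlidePrediction", function(x) x@roi_patches)

setMethod("show", "SlidePrediction", function(object) {
  cat(sprintf(
    "SlidePrediction '%s': %s%s (votes mel=%d nev=%d oth=%d), beta=%.3f, |ROI|=%d\n",
    object@slide_id, object@predicted_label,
    if (object@tie_flag) " [tie]" else "",
    object@vote_counts[1], object@vote_counts[2], object@vote_counts[3],
    object@beta, length(object@roi_patches)))
})

#' EvalReport: cohort evaluation metrics
#'
#' Patch-level three-class accuracy, slide-level accuracy, per-slide
#' patch-grid IoU (each slide evaluated at its own annotated ratio beta)
#' and their unweighted mean.
#'
#' @slot patch_accuracy fraction of labeled test patches whose argmax
#'   matches the true class.
#' @slot slide_accuracy fraction of test slides classified correctly.
#' @slot per_slide_iou named numeric vector of per-slide IoU.
#' @slot mean_iou unweighted mean of `per_slide_iou`.
#' @slot per_slide data frame with one row per slide (label, votes, beta,
#'   k, iou).
#' @export
setClass("EvalReport",
  representation(patch_accuracy = "numeric", slide_accuracy = "numeric",
                 per_slide_iou = "numeric", mean_iou = "numeric",
                 per_slide = "data.frame"))

setValidity("EvalReport", function(object) {
  v <- c(object@patch_accuracy, object@slide_accuracy,
         object@per_slide_iou, object@mean_iou)
  if (any(v < -1e-12 | v > 1 + 1e-12)) return("all metrics must lie in [0, 1]")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("meanIoU", "EvalReport", function(x) x@mean_iou)

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  patch accuracy: %.4f\n", object@patch_accuracy))
  cat(sprintf("  slide accuracy: %.4f\n", object@slide_accuracy))
  cat(sprintf("  mean IoU:       %.4f over %d slide(s)\n", object@mean_iou,
              length(object@per_slide_iou)))
})

#' CohortSpec: parameters of the synthetic slide generator
#'
#' Describes a synthetic cohort of H&E-like slides: two visually distinct
#' tumor classes (melanoma dark/dense, nevus light), white background,
#' elliptical tissue slices with pink stroma texture, one star-shaped
#' tumor polygon per slice, and partial annotation (each tumor slice is
#' exported to XML independently with probability `annotation_coverage`).
#' The seed fully determines the cohort.
#'
#' @slot n_slides number of slides.
#' @slot class_balance unnormalized melanoma:nevus weights.
#' @slot slide_width,slide_height slide size in pixels.
#' @slot patch_size patch side length (used to align tumors to the grid).
#' @slot slices_range min/max tissue slices per slide.
#' @slot tumor_radius_range base tumor polygon radii in pixels.
#' @slot annotation_coverage probability a tumor slice is annotated.
#' @slot noise_sd per-pixel Gaussian color noise.
#' @slot stain_sd per-slide stain gain/offset jitter.
#' @slot colors named list of base RGB colors (background, stroma, nevus,
#'   melanoma, nuclei).
#' @slot nuclei_density named per-patch-area nuclei disc counts.
#' @slot seed integer seed.
#' @export
setClass("CohortSpec",
  representation(n_slides = "integer", class_balance = "numeric",
                 slide_width = "integer", slide_height = "integer",
                 patch_size = "integer", slices_range = "integer",
                 tumor_radius_range = "numeric",
                 annotation_coverage = "numeric", noise_sd = "numeric",
                 stain_sd = "numeric", colors = "list",
                 nuclei_density = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@n_slides < 2L) return("n_slides must be >= 2")
  if (object@annotation_coverage <= 0 || object@annotation_coverage > 1)
    return("annotation_coverage must lie in (0, 1]")
  bal <- object@class_balance
  n_mel <- round(object@n_slides * bal[1] / sum(bal))
  if (n_mel < 1 || n_mel > object@n_slides - 1)
    return("class balance must give at least one slide per class")
  if (min(object@slide_width, object@slide_height) <
      4L * object@tumor_radius_range[2])
    return("slide size too small for the requested tumor region sizes")
  TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d slides (%dx%d px, patch %d), coverage=%.2f, seed=%d\n",
    object@n_slides, object@slide_width, object@slide_height,
    object@patch_size, object@annotation_coverage, object@seed))
})
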