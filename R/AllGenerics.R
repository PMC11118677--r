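#' @import methods
NULL

#' Fit a patch classifier
#'
#' Train a three-class (melanoma, nevus, other) patch classifier on a
#' feature matrix. The class order is fixed globally as
#' `c("melanoma", "nevus", "other")` in all score vectors and files.
#'
#' @param object a [PatchClassifier-class] instance.
#' @param x numeric feature matrix, one row per training patch.
#' @param y character or factor vector of patch labels; every one of the
#'   three classes must be present.
#' @param config a [trainConfig()] list controlling epochs, batch size,
#'   learning rate and seed.
#' @param ... passed to methods.
#' @return the trained classifier (with a stored training-loss trajectory,
#'   see [lossTrajectory()]).
#' @export
setGeneric("fitClassifier", function(object, x, y, config = trainConfig(), ...)
  standardGeneric("fitClassifier"))

#' Predict per-patch class scores
#'
#' Returns a simplex-constrained score triple (melanoma, nevus, other) for
#' each patch. For the feature-based classifier `newdata` is a feature
#' matrix (or a single patch raster, from which features are computed);
#' for the oracle classifier `newdata` is a data frame with `slide_id`,
#' `row`, `col` identifying patches with known ground truth.
#'
#' @param object a trained [PatchClassifier-class].
#' @param newdata patches to score (see Details above).
#' @param ... passed to methods.
#' @return numeric matrix with columns `p_melanoma`, `p_nevus`, `p_other`,
#'   each row summing to 1.
#' @export
setGeneric("predictScores", function(object, newdata, ...)
  standardGeneric("predictScores"))

#' @rdname accessors
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))

#' @rdname accessors
#' @export
setGeneric("slideLabel", function(x) standardGeneric("slideLabel"))

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("patchTable", function(x) standardGeneric("patchTable"))

#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname accessors
#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))

#' @rdname accessors
#' @export
setGeneric("lossTrajectory", function(x) standardGeneric("lossTrajectory"))

#' @rdname accessors
#' @export
setGeneric("roiPatches", function(x) standardGeneric("roiPatches"))

#' @rdname accessors
#' @export
setGeneric("meanIoU", function(x) standardGeneric("meanIoU"))
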