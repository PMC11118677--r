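## The quantitative core: slide classification by majority vote over
## patch predictions, annotated ratio beta, top-(n*beta) ROI selection
## by winning-class score, and patch-grid IoU evaluation.

scoreCols <- c("p_melanoma", "p_nevus", "p_other")

argmaxClass <- function(scores) {
  CLASS_ORDER[max.col(as.matrix(scores), ties.method = "first")]
}

#' Classify a slide by majority vote
#'
#' Each patch votes for its argmax class; patches predicted "other" are
#' ignored, and the slide is melanoma when melanoma-voting patches
#' outnumber nevus-voting patches, nevus in the opposite case. A tied
#' vote returns melanoma (the clinically conservative default) with
#' `tie_flag` set.
#'
#' @param scores matrix or data frame of per-patch score triples
#'   (columns `p_melanoma`, `p_nevus`, `p_other`).
#' @return list with `label`, `vote_counts` (named, melanoma/nevus/
#'   other) and `tie_flag`.
#' @examples
#' s <- rbind(c(.8, .1, .1), c(.1, .8, .1), c(.7, .2, .1))
#' colnames(s) <- c("p_melanoma", "p_nevus", "p_other")
#' classifySlide(s)$label  # "melanoma"
#' @export
classifySlide <- function(scores) {
  scores <- as.matrix(as.data.frame(scores)[, scoreCols])
  cls <- argmaxClass(scores)
  counts <- c(melanoma = sum(cls == "melanoma"), nevus = sum(cls == "nevus"),
              other = sum(cls == "other"))
  if (counts["melanoma"] + counts["nevus"] == 0)
    stop("no tumor-voting patches: every patch argmax is 'other'")
  tie <- counts["melanoma"] == counts["nevus"]
  label <- if (counts["melanoma"] >= counts["nevus"]) "melanoma" else "nevus"
  list(label = label, vote_counts = counts, tie_flag = unname(tie))
}

#' Annotated ratio
#'
#' `beta = A_p / C_p`: the number of extracted patches inside the
#' annotated region divided by the total number of patches extracted
#' from the slide.
#'
#' @param n_annotated_patches patches inside the annotated region.
#' @param n_total_patches total extracted patches (> 0).
#' @return beta in `[0, 1]`.
#' @examples
#' computeBeta(20, 100)  # 0.2: the top 20% of patches form the ROI
#' @export
computeBeta <- function(n_annotated_patches, n_total_patches) {
  if (n_total_patches <= 0) stop("n_total_patches must be positive")
  if (n_annotated_patches < 0 || n_annotated_patches > n_total_patches)
    stop("n_annotated_patches must lie in [0, n_total_patches]")
  n_annotated_patches / n_total_patches
}

#' Select the top n-beta patches as the ROI
#'
#' The `k = round(n * beta)` highest-scoring patches (rounding half away
#' from zero) form the predicted ROI, where `n` is the number of scored
#' patches and the score is the winning class's predicted probability.
#' All patches participate in the ranking (including other-argmax
#' patches); score ties are broken by ascending patch index, i.e.
#' row-major grid order, making selection stable.
#'
#' @param winning_scores numeric vector of winning-class scores for all
#'   `n` patches.
#' @param beta annotated ratio in `[0, 1]`.
#' @return list with `roi` (integer indices of the selected patches, in
#'   descending score order), `ranked` (all indices ranked) and `k`.
#' @export
selectROI <- function(winning_scores, beta) {
  if (is.na(beta) || beta < 0 || beta > 1)
    stop("beta must lie in [0, 1]")
  n <- length(winning_scores)
  k <- as.integer(roundHalfUp(n * beta))
  ranked <- order(-winning_scores, seq_len(n))
  list(roi = ranked[seq_len(k)], ranked = as.integer(ranked), k = k)
}

#' Patch-grid intersection over union
#'
#' `IoU = |A intersect B| / |A union B|` over patch positions of one
#' slide's grid, comparing the annotated patch set with the predicted
#' ROI patch set. Defined as 1 when both sets are empty (perfect
#' agreement on "no ROI").
#'
#' @param a,b patch sets: integer vectors of patch indices, or
#'   data frames with `row` and `col` columns (and optionally
#'   `slide_id`, which must then be constant and identical across the
#'   two sets).
#' @return IoU in `[0, 1]`.
#' @examples
#' computeIoU(1:10, 6:15)  # 5/15
#' @export
computeIoU <- function(a, b) {
  as_keys <- function(x) {
    if (is.data.frame(x)) {
      if ("slide_id" %in% names(x) && length(unique(x$slide_id)) > 1L)
        stop("patch set mixes patches from different slides")
      paste(x$row, x$col, sep = "|")
    } else as.character(x)
  }
  if (is.data.frame(a) && is.data.frame(b) &&
      all(c("slide_id") %in% names(a)) && all(c("slide_id") %in% names(b)) &&
      nrow(a) && nrow(b) &&
      !identical(unique(a$slide_id), unique(b$slide_id)))
    stop("patch sets come from different slides")
  ka <- unique(as_keys(a)); kb <- unique(as_keys(b))
  uni <- length(union(ka, kb))
  if (uni == 0L) return(1)
  length(intersect(ka, kb)) / uni
}

#' Slide-level prediction with ROI selection
#'
#' Runs the full detection stage for one slide: majority vote over the
#' patch score triples, ranking of all patches by the winning-class
#' score, and selection of the top `round(n*beta)` patches as the ROI.
#'
#' @param slide_id slide identifier.
#' @param scores data frame or matrix of score triples for all `n`
#'   extracted patches of the slide.
#' @param beta annotated ratio (at evaluation time, from the test
#'   slide's own annotations; for annotation-free inference supply a
#'   chosen value).
#' @return a [SlidePrediction-class].
#' @export
predictSlide <- function(slide_id, scores, beta) {
  scores <- as.matrix(as.data.frame(scores)[, scoreCols])
  vote <- classifySlide(scores)
  win_col <- if (vote$label == "melanoma") "p_melanoma" else "p_nevus"
  sel <- selectROI(scores[, win_col], beta)
  new("SlidePrediction", slide_id = as.character(slide_id),
      predicted_label = vote$label, vote_counts = vote$vote_counts,
      beta = beta, ranked_patches = sel$ranked, roi_patches = sel$roi,
      tie_flag = vote$tie_flag)
}

#' Evaluate a cohort of test slides
#'
#' Computes the three reported metrics: three-class patch accuracy over
#' labeled test patches, slide-level accuracy, and per-slide patch IoU
#' using each slide's own annotated ratio beta, averaged unweighted.
#' Beta and the annotated patch set A come from the ground-truth
#' annotations of each test slide (restricted to extracted patches, the
#' same tissue filter as extraction).
#'
#' @param scores data frame with columns `slide_id`, `row`, `col` and
#'   the three score columns, covering every extracted patch of every
#'   test slide.
#' @param truth data frame with columns `slide_id`, `row`, `col`,
#'   `true_class` (melanoma/nevus/other) and `in_roi` (logical, center
#'   inside a ground-truth tumor polygon).
#' @param slide_labels named character vector: true slide label per
#'   slide_id.
#' @return an [EvalReport-class].
#' @export
evaluateCohort <- function(scores, truth, slide_labels) {
  slides <- unique(scores$slide_id)
  missing <- setdiff(slides, intersect(unique(truth$slide_id),
                                       names(slide_labels)))
  if (length(missing))
    stop(sprintf("slide(s) missing ground truth: %s",
                 paste(missing, collapse = ", ")))
  key <- function(d) patchKey(d$slide_id, d$row, d$col)
  truth_idx <- match(key(scores), key(truth))
  if (anyNA(truth_idx))
    stop("some scored patches have no ground-truth record")
  true_class <- truth$true_class[truth_idx]
  in_roi <- truth$in_roi[truth_idx]
  pred_class <- argmaxClass(scores[, scoreCols])
  patch_accuracy <- mean(pred_class == true_class)

  per_slide <- lapply(slides, function(sid) {
    si <- scores$slide_id == sid
    sc <- scores[si, , drop = FALSE]
    beta <- computeBeta(sum(in_roi[si]), sum(si))
    pred <- predictSlide(sid, sc, beta)
    a_set <- paste(sc$row[in_roi[si]], sc$col[in_roi[si]], sep = "|")
    b_set <- paste(sc$row[pred@roi_patches], sc$col[pred@roi_patches],
                   sep = "|")
    iou <- computeIoU(a_set, b_set)
    data.frame(slide_id = sid, true_label = unname(slide_labels[sid]),
               predicted_label = pred@predicted_label,
               n_mel = unname(pred@vote_counts["melanoma"]),
               n_nev = unname(pred@vote_counts["nevus"]),
               n_oth = unname(pred@vote_counts["other"]),
               beta = beta, k = length(pred@roi_patches), iou = iou,
               tie = pred@tie_flag, stringsAsFactors = FALSE)
  })
  per_slide <- do.call(rbind, per_slide)
  iou <- stats::setNames(per_slide$iou, per_slide$slide_id)
  new("EvalReport",
      patch_accuracy = patch_accuracy,
      slide_accuracy = mean(per_slide$predicted_label == per_slide$true_label),
      per_slide_iou = iou, mean_iou = mean(iou), per_slide = per_slide)
}

#' Write an evaluation report
#'
#' Writes the machine-readable JSON report and the per-slide prediction
#' table (tab-separated) for an [EvalReport-class].
#'
#' @param report an [EvalReport-class].
#' @param json_path path for the JSON summary (optional).
#' @param table_path path for the per-slide TSV (optional).
#' @return the report, invisibly.
#' @export
writeEvalReport <- function(report, json_path = NULL, table_path = NULL) {
  stopifnot(is(report, "EvalReport"))
  if (!is.null(json_path))
    jsonlite::write_json(list(
      patch_accuracy = report@patch_accuracy,
      slide_accuracy = report@slide_accuracy,
      mean_iou = report@mean_iou,
      per_slide_iou = as.list(report@per_slide_iou)),
      json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(table_path))
    utils::write.table(report@per_slide, table_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(report)
}
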