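## End-to-end pipeline stages. Each stage reads its inputs from the run
## directory and writes its artifacts there, so stages can run in one
## call (runPipeline) or as separate shell invocations; all randomness
## derives from the configuration seed.

subsetPatchSet <- function(ps, keep) {
  p <- ps@patches[keep, , drop = FALSE]
  rownames(p) <- NULL
  initialize(ps, patches = p)
}

#' Load a generated cohort from disk
#'
#' Rebuilds the cohort structure written by [generateCohort()] from the
#' manifest, slide PNG paths, partial annotation XML and full
#' ground-truth XML. Rasters stay on disk and are loaded per slide on
#' demand.
#'
#' @param data_dir directory written by `generateCohort(spec, dir)`.
#' @return cohort list (`spec` is `NULL`; `slides`, `truth`,
#'   `manifest`).
#' @export
loadCohort <- function(data_dir) {
  man_path <- file.path(data_dir, "manifest.tsv")
  if (!file.exists(man_path))
    stop(sprintf("missing cohort manifest: %s", man_path))
  manifest <- utils::read.delim(man_path, stringsAsFactors = FALSE)
  slides <- list(); truth <- list(); zones <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$slide_id[i]
    ann <- parseAnnotationXML(file.path(data_dir, "annotations",
                                        paste0(sid, ".xml")))
    zone_path <- file.path(data_dir, "annotations", paste0(sid, "_other.xml"))
    zones[[sid]] <- if (file.exists(zone_path))
      parseAnnotationXML(zone_path) else list()
    all_reg <- parseAnnotationXML(file.path(data_dir, "truth",
                                            paste0(sid, ".xml")))
    slides[[sid]] <- slideRecord(
      sid, image_path = file.path(data_dir, "slides", paste0(sid, ".png")),
      width_px = manifest$width_px[i], height_px = manifest$height_px[i],
      slide_label = manifest$label[i], regions = ann)
    ann_ids <- vapply(ann, function(r) r@region_id, character(1))
    truth[[sid]] <- list(
      slide_id = sid, label = manifest$label[i], regions = all_reg,
      annotated = vapply(all_reg, function(r) r@region_id %in% ann_ids,
                         logical(1)))
  }
  list(spec = NULL, slides = slides, truth = truth, other_zones = zones,
       manifest = manifest)
}

# tile + tissue-filter one slide; returns the extracted PatchSet
extractedPatches <- function(slide, raster, config) {
  grid <- tileSlide(slide, config$patch$size)
  grid <- patchTissueFractions(grid, raster, config$tissue$s_min,
                               config$tissue$v_max)
  subsetPatchSet(grid, grid@patches$tissue_fraction >=
                   config$tissue$min_fraction)
}

# fit the reference-side normalizer state (only the Reinhard method
# needs a reference slide)
cohortNormalizer <- function(train, config) {
  if (!identical(config$colornorm$method, "reinhard")) return(NULL)
  ref_id <- config$colornorm$reference %||% train$manifest$slide_id[1]
  ref <- train$slides[[ref_id]]
  if (is.null(ref)) stop(sprintf("reference slide '%s' not in training set",
                                 ref_id))
  fitColorNormalizer(slideRaster(ref), config$tissue$s_min,
                     config$tissue$v_max)
}

# slide-level color transform applied to every patch of one slide
slideTransform <- function(raster, config, normalizer = NULL) {
  method <- config$colornorm$method %||% "whitepoint"
  switch(method,
    none = NULL,
    whitepoint = {
      wp <- estimateWhitePoint(raster, stride = 7L)
      if (is.null(wp)) NULL else function(px) applyWhitePoint(px, wp)
    },
    reinhard = {
      stats <- labTissueStats(raster, normalizer@s_min, normalizer@v_max,
                              stride = 7L)
      function(px) applyColorNormalization(normalizer, px,
                                           image_stats = stats)
    },
    stop(sprintf("unknown color-normalization method '%s'", method)))
}

#' Assemble training data from a training cohort
#'
#' For every training slide: tile, tissue-filter, label patches from the
#' partial annotations (slide-label inside annotated polygons, "other"
#' from the configured other-source zone, balanced), color-normalize,
#' augment, and compute features.
#'
#' @param train training cohort subset.
#' @param config pipeline configuration.
#' @param normalizer optional fitted [ColorNormalizer-class] (needed
#'   only for the Reinhard normalization method).
#' @return list with `features` (matrix), `labels` (character),
#'   `slide_ids` (character, per feature row), `patches` (per-slide
#'   list of labeled [PatchSet-class]).
#' @export
cohortTrainingData <- function(train, config = pipelineConfig(),
                               normalizer = NULL) {
  feats <- list(); labels <- list(); psets <- list()
  for (i in seq_along(train$slides)) {
    slide <- train$slides[[i]]
    # per-slide seed offset derived from the slide id, so a slide's
    # augmented features do not depend on which cohort subset it is in
    soff <- (sum(utf8ToInt(slide@slide_id)) * 131L) %% 100003L
    raster <- slideRaster(slide)
    ext <- extractedPatches(slide, raster, config)
    # prefer explicit other-source zone polygons shipped with the cohort
    # (the formalized manual "other" selection); fall back to the
    # configured rule
    zones <- train$other_zones[[slide@slide_id]]
    oz <- if (!is.null(zones) && length(zones))
      list(mode = "polygons", polygons = zones) else config$other_zone
    lab <- labelPatches(ext, slide,
                        min_tissue_fraction = config$tissue$min_fraction,
                        other_zone = oz,
                        balance_other = TRUE, seed = config$seed + soff)
    keep <- lab@patches$label %in% CLASS_ORDER
    lab <- subsetPatchSet(lab, keep)
    psets[[slide@slide_id]] <- lab
    if (nPatches(lab) == 0L) next
    fm <- patchFeatureMatrix(raster, lab,
                             transform = slideTransform(raster, config,
                                                        normalizer),
                             n_aug = config$augment$n_aug,
                             aug_seed = config$seed + soff,
                             pad = config$augment$pad,
                             flip_p = config$augment$flip_p)
    feats[[slide@slide_id]] <- fm$features
    labels[[slide@slide_id]] <- lab@patches$label[fm$index]
  }
  list(features = do.call(rbind, feats),
       labels = unlist(labels, use.names = FALSE),
       slide_ids = rep(names(feats), vapply(feats, nrow, integer(1))),
       patches = psets)
}

#' Assemble test data from a test cohort
#'
#' For every test slide: tile, tissue-filter, compute features for all
#' extracted patches, and derive per-patch ground truth from the full
#' ground-truth polygons.
#'
#' @param test test cohort subset (with ground truth).
#' @param config pipeline configuration.
#' @param normalizer optional fitted [ColorNormalizer-class].
#' @param features compute the feature matrix (disable for
#'   oracle-classifier runs, which need only patch identities).
#' @return list with `keys` (data frame slide_id/row/col), `features`
#'   (matrix or `NULL`), `truth` (data frame with `true_class`,
#'   `in_roi`), `patches` (per-slide extracted [PatchSet-class]).
#' @export
cohortTestData <- function(test, config = pipelineConfig(),
                           normalizer = NULL, features = TRUE) {
  keys <- list(); feats <- list(); truths <- list(); psets <- list()
  for (slide in test$slides) {
    raster <- if (features || is.null(slide@image)) slideRaster(slide) else
      slide@image
    ext <- extractedPatches(slide, raster, config)
    psets[[slide@slide_id]] <- ext
    tr <- test$truth[[slide@slide_id]]
    if (is.null(tr))
      stop(sprintf("slide '%s' has no ground truth", slide@slide_id))
    truths[[slide@slide_id]] <- patchTruth(ext, tr)
    keys[[slide@slide_id]] <- data.frame(
      slide_id = slide@slide_id, row = ext@patches$row,
      col = ext@patches$col, stringsAsFactors = FALSE)
    if (features) {
      fm <- patchFeatureMatrix(raster, ext,
                               transform = slideTransform(raster, config,
                                                          normalizer),
                               n_aug = 0L)
      feats[[slide@slide_id]] <- fm$features
    }
  }
  list(keys = do.call(rbind, c(keys, list(make.row.names = FALSE))),
       features = if (features) do.call(rbind, feats) else NULL,
       truth = do.call(rbind, c(truths, list(make.row.names = FALSE))),
       patches = psets)
}

#' Evaluate a cohort with the ground-truth oracle classifier
#'
#' Runs the full detection stage with the epsilon-oracle classifier in
#' place of a trained model: per-patch one-hot (possibly flipped)
#' scores, majority vote, top-n-beta selection and IoU. With
#' `epsilon = 0` this measures the framework's ceiling (only
#' grid-quantization losses); increasing `epsilon` degrades the result
#' monotonically.
#'
#' @param cohort cohort (or test subset) with ground truth.
#' @param epsilon oracle error rate.
#' @param config pipeline configuration.
#' @param oracle_seed seed of the oracle's flip draws.
#' @return an [EvalReport-class].
#' @export
oracleEvaluate <- function(cohort, epsilon = 0, config = pipelineConfig(),
                           oracle_seed = 1L) {
  td <- cohortTestData(cohort, config, features = FALSE)
  oracle <- oracleClassifier(td$truth, epsilon = epsilon, seed = oracle_seed)
  scores <- cbind(td$keys,
                  as.data.frame(predictScores(oracle, td$keys)))
  evaluateCohort(scores, td$truth, cohortLabels(cohort))
}

#' Run the full pipeline
#'
#' synth -> extract -> train -> predict -> evaluate (-> visualize) on a
#' synthetic cohort, writing every stage artifact under
#' `config$out_dir`. Fully reproducible from configuration + seed.
#'
#' @param config pipeline configuration (see [pipelineConfig()]).
#' @param visualize also render the three visualization maps for each
#'   test slide (default `FALSE`).
#' @return list with `report` ([EvalReport-class]), `classifier`,
#'   `split`, and artifact paths.
#' @export
runPipeline <- function(config = pipelineConfig(), visualize = FALSE) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  writePipelineConfig(config, file.path(out, "config.yaml"))

  spec_args <- list(n_slides = config$synth$n_slides,
                    slide_width = config$synth$slide_width,
                    slide_height = config$synth$slide_height,
                    patch_size = config$patch$size,
                    annotation_coverage = config$synth$annotation_coverage,
                    seed = config$seed)
  if (!is.null(config$synth$tumor_radius_range))
    spec_args$tumor_radius_range <- config$synth$tumor_radius_range
  spec <- do.call(cohortSpec, spec_args)
  cohort <- generateCohort(spec, dir = file.path(out, "data"))

  split <- trainTestSplit(cohort, config$split$train_fraction,
                          seed = config$seed)
  utils::write.table(
    data.frame(slide_id = c(split$train$manifest$slide_id,
                            split$test$manifest$slide_id),
               split = rep(c("train", "test"),
                           c(nrow(split$train$manifest),
                             nrow(split$test$manifest)))),
    file.path(out, "split.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  normalizer <- cohortNormalizer(split$train, config)
  tr <- cohortTrainingData(split$train, config, normalizer)
  writePatchManifest(tr$patches, file.path(out, "patches_train.tsv"))

  clf <- fitClassifier(softmaxNetClassifier(config$train$hidden),
                       tr$features, tr$labels,
                       config = trainConfig(
                         epochs = config$train$epochs,
                         batch_size = config$train$batch_size,
                         learning_rate = config$train$learning_rate,
                         momentum = config$train$momentum,
                         hidden = config$train$hidden,
                         seed = config$seed))
  saveClassifier(clf, file.path(out, "classifier.rds"))

  te <- cohortTestData(split$test, config, normalizer)
  scores <- cbind(te$keys, as.data.frame(predictScores(clf, te$features)))
  writeScoreTable(scores, file.path(out, "scores.tsv"))
  utils::write.table(te$truth, file.path(out, "truth_test.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  report <- evaluateCohort(scores, te$truth, cohortLabels(split$test))
  writeEvalReport(report, json_path = file.path(out, "report.json"),
                  table_path = file.path(out, "per_slide.tsv"))

  if (visualize) {
    vis_dir <- file.path(out, "vis")
    dir.create(vis_dir, showWarnings = FALSE)
    for (sid in names(split$test$slides))
      visualizeSlide(split$test$slides[[sid]],
                     scores[scores$slide_id == sid, , drop = FALSE],
                     te$patches[[sid]], report, config, vis_dir)
  }
  list(report = report, classifier = clf, split = split,
       out_dir = out, scores = scores, truth = te$truth)
}

# render and write the three maps + predicted-ROI XML for one slide
visualizeSlide <- function(slide, slide_scores, patch_set, report, config,
                           vis_dir) {
  raster <- slideRaster(slide)
  ps <- patch_set@patch_size
  beta <- report@per_slide$beta[report@per_slide$slide_id == slide@slide_id]
  pred <- predictSlide(slide@slide_id, slide_scores, beta)
  roi <- patch_set@patches[pred@roi_patches, , drop = FALSE]
  png::writePNG(overlapMap(raster, roi),
                file.path(vis_dir, paste0(slide@slide_id, "_overlap.png")))
  if (nrow(roi)) {
    bm <- boundaryMap(raster, roi, ps,
                      min_samples = config$optics$min_samples,
                      max_eps = config$optics$max_eps_factor * ps)
    png::writePNG(bm$raster,
                  file.path(vis_dir, paste0(slide@slide_id, "_boundary.png")))
    writeAnnotationXML(list(outlineAsRegion(bm$outline)),
                       file.path(vis_dir, paste0(slide@slide_id,
                                                 "_predicted_roi.xml")))
  }
  win <- if (pred@predicted_label == "melanoma") "p_melanoma" else "p_nevus"
  hm <- scoreHeatmap(patch_set@n_rows, patch_set@n_cols, ps,
                     data.frame(row = patch_set@patches$row,
                                col = patch_set@patches$col,
                                score = slide_scores[[win]]))
  png::writePNG(hm, file.path(vis_dir, paste0(slide@slide_id, "_heatmap.png")))
  invisible(pred)
}
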