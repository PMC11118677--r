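# The synthetic cohort generator: determinism, partial annotation,
# class-conditional appearance, splits.

test_that("generation is byte-identical for a fixed spec and seed", {
  spec <- cohortSpec(n_slides = 2L, slide_width = 1536L,
                     slide_height = 1280L, tumor_radius_range = c(160, 220),
                     seed = 77L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generateCohort(spec, dir = d1)
  generateCohort(spec, dir = d2)
  for (f in c("slides/S001.png", "annotations/S001.xml", "truth/S001.xml",
              "masks/S001.png", "manifest.tsv"))
    expect_identical(readBin(file.path(d1, f), "raw", 5e7),
                     readBin(file.path(d2, f), "raw", 5e7),
                     label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("full coverage exports every ground-truth polygon", {
  spec <- cohortSpec(n_slides = 2L, slide_width = 1536L,
                     slide_height = 1280L, tumor_radius_range = c(160, 220),
                     annotation_coverage = 1, seed = 5L)
  cohort <- generateCohort(spec)
  for (sid in names(cohort$slides)) {
    expect_true(all(cohort$truth[[sid]]$annotated))
    expect_identical(length(regions(cohort$slides[[sid]])),
                     length(cohort$truth[[sid]]$regions))
  }
})

test_that("the annotated slice fraction sits in the binomial band", {
  cohort <- smallCohort()  # 20 slides, coverage 0.6
  n_slices <- sum(cohort$manifest$n_slices)
  n_ann <- sum(cohort$manifest$n_annotated)
  expect_gte(n_ann / n_slices, 0.4)
  expect_lte(n_ann / n_slices, 0.8)
})

test_that("exported XML reparses to the annotated polygon subset", {
  cohort <- smallCohort()
  dir <- file.path(tempdir(), "patchroi-small-cohort")
  for (sid in cohort$manifest$slide_id[1:5]) {
    regs <- parseAnnotationXML(file.path(dir, "annotations",
                                         paste0(sid, ".xml")))
    expect_length(regs, sum(cohort$truth[[sid]]$annotated))
    all_regs <- parseAnnotationXML(file.path(dir, "truth",
                                             paste0(sid, ".xml")))
    expect_length(all_regs, length(cohort$truth[[sid]]$regions))
    # annotated polygons are a subset of the ground truth, id for id
    ann_ids <- vapply(regs, function(r) r@region_id, character(1))
    truth_ids <- vapply(all_regs, function(r) r@region_id, character(1))
    expect_true(all(ann_ids %in% truth_ids))
  }
})

test_that("melanoma tumor tissue is darker than nevus tumor tissue", {
  cohort <- smallCohort()
  lum <- function(sid) {
    slide <- cohort$slides[[sid]]
    raster <- slideRaster(slide)
    tr <- cohort$truth[[sid]]
    g <- tileSlide(slide, 256)
    truth <- patchTruth(patchTissueFractions(g, raster), tr)
    tumor <- truth[truth$in_roi, ]
    vals <- vapply(seq_len(nrow(tumor)), function(i) {
      p <- patchTable(g)[patchTable(g)$row == tumor$row[i] &
                         patchTable(g)$col == tumor$col[i], ]
      px <- extractPatchPixels(raster, p)
      mean(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
    }, numeric(1))
    mean(vals)
  }
  mel <- cohort$manifest$slide_id[cohort$manifest$label == "melanoma"][1:2]
  nev <- cohort$manifest$slide_id[cohort$manifest$label == "nevus"][1:2]
  expect_lt(mean(vapply(mel, lum, numeric(1))),
            mean(vapply(nev, lum, numeric(1))) - 0.05)
})

test_that("patch ground truth follows the center-in-polygon rule", {
  cohort <- smallCohort()
  sid <- cohort$manifest$slide_id[1]
  slide <- cohort$slides[[sid]]
  g <- patchTissueFractions(tileSlide(slide, 256), slideRaster(slide))
  truth <- patchTruth(g, cohort$truth[[sid]])
  ctr <- patchROI:::patchCenters(patchTable(g), 256)
  inside <- patchROI:::pointInAnyRegion(cohort$truth[[sid]]$regions,
                                        ctr[, 1], ctr[, 2])
  expect_identical(truth$in_roi, inside)
  expect_true(all(truth$true_class[truth$in_roi] == cohort$truth[[sid]]$label))
  expect_true(all(truth$true_class[!truth$in_roi] == "other"))
})

# lightweight cohort stub: split logic needs only labels and ids
stubCohort <- function(n_mel, n_nev) {
  ids <- sprintf("S%03d", seq_len(n_mel + n_nev))
  labels <- rep(c("melanoma", "nevus"), c(n_mel, n_nev))
  list(spec = NULL,
       slides = stats::setNames(as.list(ids), ids),
       truth = stats::setNames(as.list(labels), ids),
       other_zones = stats::setNames(vector("list", length(ids)), ids),
       manifest = data.frame(slide_id = ids, label = labels,
                             stringsAsFactors = FALSE))
}

test_that("train/test split is stratified and deterministic", {
  sp <- trainTestSplit(stubCohort(6, 4), 0.8, seed = 3L)
  expect_identical(nrow(sp$train$manifest), 8L)
  expect_identical(nrow(sp$test$manifest), 2L)
  sp2 <- trainTestSplit(stubCohort(6, 4), 0.8, seed = 3L)
  expect_identical(sp$train$manifest$slide_id, sp2$train$manifest$slide_id)

  sp3 <- trainTestSplit(stubCohort(12, 8), 0.75, seed = 1L)
  tab <- table(sp3$train$manifest$label)
  expect_identical(as.integer(tab[["melanoma"]]), 9L)
  expect_identical(as.integer(tab[["nevus"]]), 6L)
  # the paper-scale split shape: 20 slides at 86:74 -> 16 train, 4 test
  sp4 <- trainTestSplit(stubCohort(11, 9), 0.8, seed = 1L)
  expect_identical(nrow(sp4$train$manifest), 16L)
  expect_identical(nrow(sp4$test$manifest), 4L)
  expect_error(trainTestSplit(stubCohort(1, 9), 0.8), "fewer than 2")
  # the train subset drops ground truth, the test subset keeps it
  cohort <- smallCohort()
  sp5 <- trainTestSplit(cohort, 0.8, seed = 1L)
  expect_true(all(vapply(sp5$train$truth, is.null, logical(1))))
  expect_false(any(vapply(sp5$test$truth, is.null, logical(1))))
})

test_that("training subsampling is stratified with stable sizes", {
  train <- trainTestSplit(stubCohort(12, 8), 0.75, seed = 1L)$train
  expect_identical(subsampleTraining(train, 1), train)
  half <- subsampleTraining(train, 0.5, seed = 2L)
  expect_identical(nrow(half$manifest), 8L)
  tab <- table(half$manifest$label)
  expect_identical(as.integer(tab[["melanoma"]]), 5L)  # round(0.5 * 9)
  expect_identical(as.integer(tab[["nevus"]]), 3L)
  sizes <- vapply(1:10, function(s)
    nrow(subsampleTraining(train, 0.5, seed = s)$manifest), integer(1))
  expect_true(all(sizes == 8L))
  picks <- vapply(1:10, function(s)
    paste(sort(subsampleTraining(train, 0.5, seed = s)$manifest$slide_id),
          collapse = ","), character(1))
  expect_gt(length(unique(picks)), 1L)
  expect_error(subsampleTraining(train, 0.05), "leaves no")
})

test_that("slide size must accommodate the tumor size range", {
  expect_error(cohortSpec(slide_width = 800L, slide_height = 600L),
               "too small")
})
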