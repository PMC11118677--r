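# Majority vote, annotated ratio, top-n-beta selection, IoU.

scoresFrom <- function(n_mel, n_nev, n_oth) {
  one_hot <- function(k, j) {
    m <- matrix(0.05, k, 3)
    m[, j] <- 0.9
    m
  }
  s <- rbind(one_hot(n_mel, 1), one_hot(n_nev, 2), one_hot(n_oth, 3))
  colnames(s) <- c("p_melanoma", "p_nevus", "p_other")
  s[sample(nrow(s)), , drop = FALSE]
}

test_that("majority vote ignores other and breaks ties toward melanoma", {
  set.seed(77)
  v <- classifySlide(scoresFrom(10, 3, 40))
  expect_identical(v$label, "melanoma")
  expect_equal(unname(v$vote_counts), c(10, 3, 40))
  expect_false(v$tie_flag)
  expect_identical(classifySlide(scoresFrom(0, 1, 0))$label, "nevus")
  tie <- classifySlide(scoresFrom(5, 5, 2))
  expect_identical(tie$label, "melanoma")
  expect_true(tie$tie_flag)
  expect_error(classifySlide(scoresFrom(0, 0, 7)), "no tumor-voting")
  # invariance under patch order permutation
  s <- scoresFrom(8, 12, 5)
  expect_identical(classifySlide(s), classifySlide(s[rev(seq_len(25)), ]))
})

test_that("the annotated ratio is an exact patch-count ratio", {
  expect_equal(computeBeta(20, 100), 0.2)
  expect_equal(computeBeta(0, 50), 0)
  expect_equal(computeBeta(50, 50), 1)
  expect_error(computeBeta(1, 0), "positive")
  expect_error(computeBeta(-1, 10), "\\[0, n_total_patches\\]")
  expect_error(computeBeta(11, 10), "\\[0, n_total_patches\\]")
})

test_that("beta = 0.2 selects exactly the top 20% of patches", {
  set.seed(50)
  s <- sample(seq(0.01, 0.99, length.out = 100))  # distinct scores
  sel <- selectROI(s, 0.2)
  expect_length(sel$roi, 20L)
  expect_setequal(sel$roi, order(s, decreasing = TRUE)[1:20])
  expect_length(selectROI(s, 0)$roi, 0L)
  expect_error(selectROI(s, 1.2), "beta")
})

test_that("ties and rounding follow the stable row-major rule", {
  sel <- selectROI(rep(0.5, 10), 0.25)
  expect_identical(sel$k, 3L)          # round(2.5) half away from zero
  expect_identical(sel$roi, 1:3)       # smallest row-major indices win
})

test_that("selection agrees with a brute-force sort oracle", {
  set.seed(60)
  for (i in seq_len(1000)) {
    n <- sample(1:50, 1)
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    beta <- runif(1)
    sel <- selectROI(s, beta)
    k <- floor(n * beta + 0.5)
    r <- rank(-s, ties.method = "first")  # independent ranking route
    expect_identical(sel$k, as.integer(k))
    expect_setequal(sel$roi, which(r <= k))
    # the ROI is a prefix of the full ranking
    expect_identical(sel$roi, sel$ranked[seq_len(k)])
  }
})

test_that("|ROI| is non-decreasing in beta for fixed scores", {
  set.seed(61)
  s <- runif(40)
  ks <- vapply(seq(0, 1, by = 0.05), function(b) length(selectROI(s, b)$roi),
               integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("patch IoU matches set enumeration and is symmetric", {
  expect_equal(computeIoU(1:10, 1:10), 1)
  expect_equal(computeIoU(1:5, 6:10), 0)
  expect_equal(computeIoU(1:10, 6:15), 5 / 15)
  expect_equal(computeIoU(integer(), integer()), 1)  # no ROI, agreed
  expect_equal(computeIoU(integer(), 1:3), 0)
  set.seed(62)
  for (i in 1:50) {
    a <- sample(100, sample(20, 1))
    b <- sample(100, sample(20, 1))
    iou <- computeIoU(a, b)
    expect_identical(iou, computeIoU(b, a))
    expect_gte(iou, 0); expect_lte(iou, 1)
    expect_equal(iou, length(intersect(a, b)) / length(union(a, b)))
  }
  expect_error(computeIoU(data.frame(slide_id = "a", row = 0, col = 0),
                          data.frame(slide_id = "b", row = 0, col = 0)),
               "different slides")
})

# a small synthetic cohort of score tables with known structure
fixtureCohort <- function(invert_slide = NULL) {
  slides <- c("A", "B", "C", "D")
  labels <- c(A = "melanoma", B = "melanoma", C = "nevus", D = "nevus")
  scores <- NULL; truth <- NULL
  set.seed(17)
  for (sid in slides) {
    n <- 20L
    in_roi <- c(rep(TRUE, 5L), rep(FALSE, 15L))
    cls <- ifelse(in_roi, labels[[sid]], "other")
    s <- matrix(0.03, n, 3)
    ci <- match(cls, c("melanoma", "nevus", "other"))
    s[cbind(seq_len(n), ci)] <- 0.9
    s <- s + matrix(runif(n * 3, 0, 0.02), n, 3)
    s <- s / rowSums(s)
    if (identical(sid, invert_slide))
      s <- s[, c(2, 1, 3)]  # swap melanoma and nevus scores
    colnames(s) <- c("p_melanoma", "p_nevus", "p_other")
    scores <- rbind(scores, cbind(
      data.frame(slide_id = sid, row = 0L, col = seq_len(n) - 1L),
      as.data.frame(s)))
    truth <- rbind(truth, data.frame(
      slide_id = sid, row = 0L, col = seq_len(n) - 1L,
      true_class = cls, in_roi = in_roi, stringsAsFactors = FALSE))
  }
  list(scores = scores, truth = truth, labels = labels)
}

test_that("cohort evaluation reproduces constructed outcomes", {
  f <- fixtureCohort()
  rep <- evaluateCohort(f$scores, f$truth, f$labels)
  expect_equal(rep@patch_accuracy, 1)
  expect_equal(rep@slide_accuracy, 1)
  expect_equal(unname(rep@per_slide_iou), rep(1, 4))
  expect_equal(meanIoU(rep), 1)
  expect_equal(rep@per_slide$beta, rep(0.25, 4))

  # one slide constructed with inverted tumor scores: 3 of 4 correct
  f2 <- fixtureCohort(invert_slide = "B")
  rep2 <- evaluateCohort(f2$scores, f2$truth, f2$labels)
  expect_equal(rep2@slide_accuracy, 0.75)

  # missing ground truth is reported with the slide id
  expect_error(evaluateCohort(f$scores, f$truth[f$truth$slide_id != "C", ],
                              f$labels), "C")
})

test_that("evaluation is invariant to patch order within slides", {
  f <- fixtureCohort()
  idx <- sample(nrow(f$scores))
  rep1 <- evaluateCohort(f$scores, f$truth, f$labels)
  rep2 <- evaluateCohort(f$scores[idx, ], f$truth, f$labels)
  expect_equal(rep1@patch_accuracy, rep2@patch_accuracy)
  expect_equal(rep1@per_slide_iou[sort(names(rep1@per_slide_iou))],
               rep2@per_slide_iou[sort(names(rep2@per_slide_iou))])
})

test_that("slide prediction assembles vote, ranking and ROI", {
  f <- fixtureCohort()
  sc <- f$scores[f$scores$slide_id == "A", ]
  pred <- predictSlide("A", sc, beta = 0.25)
  expect_identical(pred@predicted_label, "melanoma")
  expect_length(roiPatches(pred), 5L)
  expect_identical(roiPatches(pred), pred@ranked_patches[1:5])
  rep <- evaluateCohort(f$scores, f$truth, f$labels)
  path <- tempfile(fileext = ".json")
  writeEvalReport(rep, json_path = path)
  back <- jsonlite::read_json(path)
  expect_equal(back$slide_accuracy, 1)
})
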