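# The trainable softmax-net classifier and the ground-truth oracle.

# trivially separable patches: three solid colors with slight noise
separableData <- function(n_per = 10L, seed = 1L) {
  cols <- list(melanoma = c(0.4, 0.25, 0.4), nevus = c(0.8, 0.6, 0.75),
               other = c(0.92, 0.78, 0.84))
  feats <- NULL; labels <- character()
  k <- 0L
  for (cls in names(cols)) for (i in seq_len(n_per)) {
    k <- k + 1L
    feats <- rbind(feats, patchFeatures(
      solidPatch(cols[[cls]], 32, noise = 0.03, seed = seed * 1000L + k)))
    labels <- c(labels, cls)
  }
  list(x = feats, y = labels)
}

test_that("the default net overfits trivially separable patches", {
  d <- separableData()
  clf <- fitClassifier(softmaxNetClassifier(), d$x, d$y,
                       trainConfig(epochs = 20L, seed = 5L))
  expect_true(isTrained(clf))
  expect_length(lossTrajectory(clf), 20L)
  scores <- predictScores(clf, d$x)
  pred <- c("melanoma", "nevus", "other")[max.col(scores)]
  expect_identical(pred, d$y)  # training accuracy 1.0
  # loss decreases overall
  expect_lt(tail(lossTrajectory(clf), 1), lossTrajectory(clf)[1])
})

test_that("training is deterministic given the seed", {
  d <- separableData()
  c1 <- fitClassifier(softmaxNetClassifier(), d$x, d$y,
                      trainConfig(epochs = 5L, seed = 9L))
  c2 <- fitClassifier(softmaxNetClassifier(), d$x, d$y,
                      trainConfig(epochs = 5L, seed = 9L))
  expect_identical(lossTrajectory(c1), lossTrajectory(c2))
  expect_identical(predictScores(c1, d$x), predictScores(c2, d$x))
})

test_that("randomly permuted labels give chance-level accuracy at epoch 1", {
  d <- separableData(n_per = 40L)
  set.seed(123)
  y_perm <- sample(d$y)
  clf <- fitClassifier(softmaxNetClassifier(), d$x, y_perm,
                       trainConfig(epochs = 1L, seed = 3L))
  acc <- mean(c("melanoma", "nevus", "other")[
    max.col(predictScores(clf, d$x))] == y_perm)
  expect_gte(acc, 1 / 3 - 0.15)
  expect_lte(acc, 1 / 3 + 0.15)
})

test_that("training validates its inputs", {
  d <- separableData(n_per = 4L)
  keep <- d$y != "nevus"
  expect_error(fitClassifier(softmaxNetClassifier(), d$x[keep, ], d$y[keep]),
               "nevus")
  expect_error(predictScores(softmaxNetClassifier(), d$x), "not been trained")
})

test_that("scores are a simplex and independent of batch composition", {
  d <- separableData()
  clf <- fitClassifier(softmaxNetClassifier(), d$x, d$y,
                       trainConfig(epochs = 5L, seed = 2L))
  s <- predictScores(clf, d$x)
  expect_identical(colnames(s), c("p_melanoma", "p_nevus", "p_other"))
  expect_true(all(s >= 0))
  expect_equal(rowSums(s), rep(1, nrow(s)), tolerance = 1e-6)
  # permuting the batch permutes the rows and nothing else
  idx <- sample(nrow(d$x))
  expect_equal(predictScores(clf, d$x[idx, ]), s[idx, ])
  # a single raster patch can be scored directly
  s1 <- predictScores(clf, solidPatch(c(0.4, 0.25, 0.4), 32, 0.03, seed = 1))
  expect_equal(sum(s1), 1, tolerance = 1e-6)
})

test_that("classifier checkpoints restore bit-identical scores", {
  d <- separableData()
  clf <- fitClassifier(softmaxNetClassifier(), d$x, d$y,
                       trainConfig(epochs = 5L, seed = 4L))
  path <- tempfile(fileext = ".rds")
  saveClassifier(clf, path)
  back <- loadClassifier(path)
  expect_identical(predictScores(back, d$x), predictScores(clf, d$x))
  expect_error(loadClassifier({p <- tempfile(); saveRDS(list(a = 1), p); p}),
               "checkpoint")
})

oracleTruth <- function(n) {
  data.frame(slide_id = "s1", row = (seq_len(n) - 1L) %/% 100L,
             col = (seq_len(n) - 1L) %% 100L,
             true_class = rep(c("melanoma", "nevus", "other"),
                              length.out = n),
             stringsAsFactors = FALSE)
}

test_that("oracle classifier returns the exact truth at epsilon 0", {
  tr <- oracleTruth(60)
  oc <- oracleClassifier(tr, epsilon = 0)
  s <- predictScores(oc, tr)
  expect_true(all(rowSums(s) == 1))
  pred <- c("melanoma", "nevus", "other")[max.col(s)]
  expect_identical(pred, tr$true_class)
  expect_error(predictScores(oc, data.frame(slide_id = "zz", row = 0,
                                            col = 0)), "outside known")
})

test_that("oracle error rate is calibrated and order-invariant", {
  tr <- oracleTruth(10000)
  oc1 <- oracleClassifier(tr, epsilon = 1, seed = 2L)
  pred1 <- c("melanoma", "nevus", "other")[max.col(predictScores(oc1, tr))]
  expect_true(all(pred1 != tr$true_class))

  oc <- oracleClassifier(tr, epsilon = 0.2, seed = 2L)
  pred <- c("melanoma", "nevus", "other")[max.col(predictScores(oc, tr))]
  err <- mean(pred != tr$true_class)
  expect_gte(err, 0.185)
  expect_lte(err, 0.215)
  # same patch gets the same prediction regardless of batch order
  idx <- sample(nrow(tr))
  s_perm <- predictScores(oc, tr[idx, ])
  expect_identical(s_perm, predictScores(oc, tr)[idx, ])
  # flipped sets are nested across increasing epsilon
  oc_small <- oracleClassifier(tr, epsilon = 0.1, seed = 2L)
  pred_small <- c("melanoma", "nevus", "other")[
    max.col(predictScores(oc_small, tr))]
  flipped_small <- pred_small != tr$true_class
  flipped_large <- pred != tr$true_class
  expect_true(all(!flipped_small | flipped_large))
})
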