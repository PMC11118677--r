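## The pluggable three-class patch classifier: a trainable shallow
## softmax network over patch features, and a ground-truth oracle test
## double. Class order is fixed globally as (melanoma, nevus, other).

#' Training configuration
#'
#' @param epochs number of passes over the training data (>= 1).
#' @param batch_size mini-batch size.
#' @param learning_rate SGD step size.
#' @param momentum SGD momentum coefficient.
#' @param hidden hidden-layer width of the default network.
#' @param seed integer seed fixing all stochastic behavior (weight
#'   initialization and batch shuffling).
#' @return a named list.
#' @export
trainConfig <- function(epochs = 10L, batch_size = 32L, learning_rate = 0.05,
                        momentum = 0.9, hidden = 16L, seed = 1L) {
  stopifnot(epochs >= 1L)
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       learning_rate = learning_rate, momentum = momentum,
       hidden = as.integer(hidden), seed = as.integer(seed))
}

#' Create an untrained default patch classifier
#'
#' A single-hidden-layer tanh network with a softmax head over the
#' [patchFeatures()] summary statistics, trained with mini-batch SGD
#' plus momentum on the three-class cross-entropy. Deliberately small:
#' the pluggable [PatchClassifier-class] interface admits heavyweight
#' convolutional backbones, but the default trains in seconds on a
#' single CPU.
#'
#' @param hidden hidden-layer width (default 16).
#' @return an untrained [SoftmaxNetClassifier-class].
#' @export
softmaxNetClassifier <- function(hidden = 16L) {
  new("SoftmaxNetClassifier", hidden = as.integer(hidden),
      W1 = matrix(0, 0, 0), b1 = numeric(), W2 = matrix(0, 0, 0),
      b2 = numeric(), feat_center = numeric(), feat_scale = numeric(),
      feature_names = character(), trained = FALSE, loss = numeric(),
      config = list())
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' @rdname fitClassifier
#' @export
setMethod("fitClassifier", "SoftmaxNetClassifier",
          function(object, x, y, config = trainConfig(), ...) {
  x <- as.matrix(x)
  y <- as.character(y)
  missing_cls <- setdiff(CLASS_ORDER, unique(y))
  if (length(missing_cls))
    stop(sprintf("training data is missing class(es): %s",
                 paste(missing_cls, collapse = ", ")))
  if (any(!y %in% CLASS_ORDER))
    stop("labels must be melanoma, nevus or other")
  n <- nrow(x); d <- ncol(x); h <- object@hidden
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale <= 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, `/`)
  yi <- match(y, CLASS_ORDER)
  Y <- matrix(0, n, 3L)
  Y[cbind(seq_len(n), yi)] <- 1

  lr <- config$learning_rate; mom <- config$momentum
  bs <- min(config$batch_size, n)
  losses <- numeric(config$epochs)
  state <- withSeed(config$seed, {
    W1 <- matrix(stats::rnorm(d * h, sd = 1 / sqrt(d)), d, h)
    b1 <- numeric(h)
    W2 <- matrix(stats::rnorm(h * 3L, sd = 1 / sqrt(h)), h, 3L)
    b2 <- numeric(3L)
    vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- b2
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- xs[idx, , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        m <- length(idx)
        hid <- tanh(sweep(xb %*% W1, 2, b1, `+`))
        prob <- softmaxRows(sweep(hid %*% W2, 2, b2, `+`))
        ep_loss <- ep_loss - sum(yb * log(pmax(prob, 1e-12)))
        dz2 <- (prob - yb) / m
        gW2 <- t(hid) %*% dz2
        gb2 <- colSums(dz2)
        dh <- (dz2 %*% t(W2)) * (1 - hid^2)
        gW1 <- t(xb) %*% dh
        gb1 <- colSums(dh)
        vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
        vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
        vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
        vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
      }
      losses[ep] <- ep_loss / n
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, losses = losses)
  })
  initialize(object, W1 = state$W1, b1 = state$b1, W2 = state$W2,
             b2 = state$b2, feat_center = center, feat_scale = scale,
             feature_names = colnames(x) %||% character(),
             trained = TRUE, loss = state$losses, config = config)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

scoreMatrix <- function(p) {
  colnames(p) <- c("p_melanoma", "p_nevus", "p_other")
  p
}

#' @rdname predictScores
#' @export
setMethod("predictScores", "SoftmaxNetClassifier",
          function(object, newdata, ...) {
  if (!object@trained) stop("classifier has not been trained")
  if (is.array(newdata) && length(dim(newdata)) == 3L)
    newdata <- matrix(patchFeatures(newdata), nrow = 1,
                      dimnames = list(NULL, PATCH_FEATURES))
  x <- as.matrix(newdata)
  if (length(object@feature_names) && !is.null(colnames(x)))
    x <- x[, object@feature_names, drop = FALSE]
  xs <- sweep(sweep(x, 2, object@feat_center), 2, object@feat_scale, `/`)
  hid <- tanh(sweep(xs %*% object@W1, 2, object@b1, `+`))
  scoreMatrix(softmaxRows(sweep(hid %*% object@W2, 2, object@b2, `+`)))
})

patchKey <- function(slide_id, row, col) paste(slide_id, row, col, sep = "|")

#' Ground-truth oracle classifier
#'
#' A test double that bypasses learning: it returns the one-hot score
#' triple of each queried patch's true class, looked up from ground
#' truth, with an optional error rate. With probability `epsilon` the
#' prediction is flipped to one of the two other classes. Flips are
#' deterministic functions of (seed, patch identity): the same patch is
#' flipped or not regardless of batch order, and the set of flipped
#' patches at a smaller `epsilon` is contained in the set at a larger
#' one, so pipeline quality degrades monotonically in `epsilon`.
#'
#' @param truth data frame with columns `slide_id`, `row`, `col`,
#'   `true_class` (melanoma/nevus/other).
#' @param epsilon flip probability in `[0, 1]` (default 0).
#' @param seed integer seed for the flip draws.
#' @return an [OracleClassifier-class].
#' @export
oracleClassifier <- function(truth, epsilon = 0, seed = 1L) {
  stopifnot(all(c("slide_id", "row", "col", "true_class") %in% names(truth)),
            epsilon >= 0, epsilon <= 1)
  env <- new.env(parent = emptyenv())
  keys <- patchKey(truth$slide_id, truth$row, truth$col)
  for (i in seq_along(keys)) assign(keys[i], truth$true_class[i], envir = env)
  new("OracleClassifier", truth = env, epsilon = epsilon,
      seed = as.integer(seed))
}

#' @rdname predictScores
#' @export
setMethod("predictScores", "OracleClassifier", function(object, newdata, ...) {
  stopifnot(all(c("slide_id", "row", "col") %in% names(newdata)))
  keys <- patchKey(newdata$slide_id, newdata$row, newdata$col)
  known <- vapply(keys, exists, logical(1), envir = object@truth,
                  USE.NAMES = FALSE)
  if (any(!known))
    stop(sprintf("patch(es) outside known ground truth: %s",
                 paste(utils::head(keys[!known], 5), collapse = ", ")))
  cls <- vapply(keys, get, character(1), envir = object@truth,
                USE.NAMES = FALSE)
  ci <- match(cls, CLASS_ORDER)
  if (object@epsilon > 0) {
    u <- hashUnit(keys, salt = object@seed)
    flip <- u < object@epsilon
    pick <- 1L + (hashUnit(keys, salt = object@seed + 1L) >= 0.5)  # 1 or 2
    other <- matrix(c(2L, 3L, 1L, 3L, 1L, 2L), nrow = 3, byrow = TRUE)
    ci[flip] <- other[cbind(ci[flip], pick[flip])]
  }
  p <- matrix(0, length(ci), 3L)
  p[cbind(seq_along(ci), ci)] <- 1
  scoreMatrix(p)
})

#' Save / load a classifier
#'
#' Checkpoints are self-describing RDS files carrying a format tag and
#' version; loading restores an object giving bit-identical scores.
#'
#' @param classifier a [PatchClassifier-class].
#' @param path checkpoint file path.
#' @return `loadClassifier` returns the restored classifier.
#' @export
saveClassifier <- function(classifier, path) {
  stopifnot(is(classifier, "PatchClassifier"))
  saveRDS(list(format = "patchROI-classifier", version = 1L,
               class = class(classifier), object = classifier), path)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "patchROI-classifier"))
    stop("not a patchROI classifier checkpoint")
  x$object
}

#' Write a per-patch score table
#'
#' Tab-separated text: slide_id, row, col, p_melanoma, p_nevus, p_other.
#'
#' @param scores data frame with those columns.
#' @param path output file.
#' @export
writeScoreTable <- function(scores, path) {
  need <- c("slide_id", "row", "col", "p_melanoma", "p_nevus", "p_other")
  stopifnot(all(need %in% names(scores)))
  utils::write.table(scores[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(scores)
}
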