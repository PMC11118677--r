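## Per-patch summary features for the default classifier: color moments
## in RGB and HSV plus darkness and tissue fractions. Melanocytic tumor
## appearance is driven by stain color and nuclear density, so low-order
## color statistics carry most of the class signal at patch scale.

PATCH_FEATURES <- c("mean_r", "mean_g", "mean_b", "sd_r", "sd_g", "sd_b",
                    "mean_s", "sd_s", "v_q05", "v_q25", "v_q50",
                    "tissue_fraction",
                    "mid_mean_r", "mid_mean_g", "mid_mean_b",
                    "mid_mean_s", "mid_v_q25", "mid_v_q50",
                    "ctr_mean_r", "ctr_mean_g", "ctr_mean_b",
                    "ctr_mean_s", "ctr_v_q25", "ctr_v_q50")

windowStats <- function(patch_rgb, frac) {
  d <- dim(patch_rgb)
  half <- c(max(1, round(d[1] * frac / 2)), max(1, round(d[2] * frac / 2)))
  mid <- c(d[1] / 2, d[2] / 2)
  ri <- max(1L, floor(mid[1] - half[1] + 1)):min(d[1], ceiling(mid[1] + half[1]))
  ci <- max(1L, floor(mid[2] - half[2] + 1)):min(d[2], ceiling(mid[2] + half[2]))
  win <- patch_rgb[ri, ci, , drop = FALSE]
  r <- as.vector(win[, , 1]); g <- as.vector(win[, , 2])
  b <- as.vector(win[, , 3])
  hsv <- grDevices::rgb2hsv(r = r, g = g, b = b, maxColorValue = 1)
  c(mean(r), mean(g), mean(b), mean(hsv[2, ]),
    stats::quantile(hsv[3, ], c(0.25, 0.5), names = FALSE))
}

#' Summary features of one patch
#'
#' Twenty-four per-patch statistics: mean and standard deviation of
#' each RGB channel, mean/sd of HSV saturation, brightness (HSV value)
#' quantiles and the tissue fraction over the whole patch, plus color
#' and brightness summaries recomputed on two concentric central
#' windows (half and one-sixteenth of each side). Darkness is summarized
#' by brightness quantiles rather than a thresholded dark-pixel count:
#' quantiles respond continuously to nuclear density and pigmentation
#' and are robust to small per-slide stain gain shifts, which can push
#' a hard darkness threshold across an entire class. The central-window
#' features matter because patch class is defined by the patch
#' *center*: a patch whose center sits just outside a tumor region can
#' still contain a lot of tumor at its edges, and whole-patch means
#' alone would mislabel it.
#'
#' @param patch_rgb RGB raster in `[0, 1]`.
#' @param s_min,v_max tissue thresholds (see [tissueFraction()]).
#' @return named numeric vector of length 24.
#' @export
patchFeatures <- function(patch_rgb, s_min = 0.05, v_max = 0.95) {
  checkRaster(patch_rgb, "patch")
  r <- as.vector(patch_rgb[, , 1])
  g <- as.vector(patch_rgb[, , 2])
  b <- as.vector(patch_rgb[, , 3])
  hsv <- grDevices::rgb2hsv(r = r, g = g, b = b, maxColorValue = 1)
  s <- hsv[2, ]; v <- hsv[3, ]
  out <- c(mean(r), mean(g), mean(b), stats::sd(r), stats::sd(g), stats::sd(b),
           mean(s), stats::sd(s),
           stats::quantile(v, c(0.05, 0.25, 0.5), names = FALSE),
           mean(s > s_min & v < v_max),
           windowStats(patch_rgb, 0.5), windowStats(patch_rgb, 0.0625))
  names(out) <- PATCH_FEATURES
  out
}

#' Feature matrix for a set of patches
#'
#' Extracts each patch of a [PatchSet-class] from the slide raster,
#' optionally color-normalizes it, optionally adds augmented copies
#' (seeded), and computes [patchFeatures()] for every instance.
#'
#' @param raster slide raster.
#' @param patch_set a [PatchSet-class] of extracted patches.
#' @param transform optional per-patch normalization function
#'   (raster in, raster out), typically a slide-level color transform
#'   built by the pipeline.
#' @param n_aug number of additional augmented copies per patch
#'   (default 0; used at training time).
#' @param aug_seed base seed for augmentation.
#' @param pad,flip_p augmentation parameters (see [augmentPatch()]).
#' @return list with `features` (numeric matrix, one row per instance)
#'   and `index` (integer vector mapping instances back to patch-table
#'   rows).
#' @export
patchFeatureMatrix <- function(raster, patch_set, transform = NULL,
                               n_aug = 0L, aug_seed = 1L, pad = 8L,
                               flip_p = 0.5) {
  stopifnot(is(patch_set, "PatchSet"))
  p <- patch_set@patches
  n <- nrow(p)
  feats <- matrix(NA_real_, n * (1L + n_aug), length(PATCH_FEATURES),
                  dimnames = list(NULL, PATCH_FEATURES))
  index <- integer(n * (1L + n_aug))
  k <- 0L
  for (i in seq_len(n)) {
    px <- extractPatchPixels(raster, p[i, ])
    if (!is.null(transform)) px <- transform(px)
    k <- k + 1L
    feats[k, ] <- patchFeatures(px)
    index[k] <- i
    for (a in seq_len(n_aug)) {
      aug <- augmentPatch(px, seed = aug_seed + 131L * i + a, pad = pad,
                          flip_p = flip_p, standardize = FALSE)
      k <- k + 1L
      feats[k, ] <- patchFeatures(aug)
      index[k] <- i
    }
  }
  list(features = feats, index = index)
}
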