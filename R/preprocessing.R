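## Tissue detection, Reinhard-style color normalization in the Ruderman
## l-alpha-beta space, and training-time augmentation.

#' Fraction of tissue pixels in a patch
#'
#' A pixel counts as tissue when its HSV saturation exceeds `s_min` and
#' its brightness (value) is below `v_max`: stained tissue is colorful
#' and not glare-white, while glass background is desaturated and
#' bright.
#'
#' @param patch_rgb RGB raster array (h x w x 3, values in `[0,1]`).
#' @param s_min minimum saturation (default 0.05).
#' @param v_max maximum brightness (default 0.95).
#' @return fraction in `[0, 1]`.
#' @examples
#' white <- array(1, c(16, 16, 3))
#' tissueFraction(white)  # 0
#' @export
tissueFraction <- function(patch_rgb, s_min = 0.05, v_max = 0.95) {
  checkRaster(patch_rgb, "patch")
  hsv <- rasterHSV(patch_rgb)
  mean(hsv$s > s_min & hsv$v < v_max)
}

## sRGB (linear-light assumed at desk scale) <-> LMS <-> l-alpha-beta.
## Fixed matrices of the classical channel-statistics transfer method.
.RGB2LMS <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.LMS2RGB <- solve(.RGB2LMS)
.LMS2LAB <- matrix(c(1/sqrt(3), 1/sqrt(3), 1/sqrt(3),
                     1/sqrt(6), 1/sqrt(6), -2/sqrt(6),
                     1/sqrt(2), -1/sqrt(2), 0), 3, 3, byrow = TRUE)
.LAB2LMS <- solve(.LMS2LAB)

# pixels: N x 3 RGB in [0,1] -> N x 3 l-alpha-beta
rgbToLab <- function(px) {
  lms <- px %*% t(.RGB2LMS)
  lms[lms < 1 / 255] <- 1 / 255  # avoid log(0) on pure black
  log10(lms) %*% t(.LMS2LAB)
}

labToRgb <- function(lab) {
  lms <- 10^(lab %*% t(.LAB2LMS))
  clip01(lms %*% t(.LMS2RGB))
}

#' Fit a color normalizer to a reference image
#'
#' Computes per-channel mean and standard deviation of the reference
#' image's tissue pixels in the perceptual l-alpha-beta space. Slides
#' normalized against this reference share its global stain statistics.
#'
#' @param reference_rgb RGB raster of the reference image.
#' @param s_min,v_max tissue-detection thresholds (see
#'   [tissueFraction()]).
#' @return a fitted [ColorNormalizer-class].
#' @export
fitColorNormalizer <- function(reference_rgb, s_min = 0.05, v_max = 0.95) {
  checkRaster(reference_rgb, "reference image")
  hsv <- rasterHSV(reference_rgb)
  mask <- hsv$s > s_min & hsv$v < v_max
  if (!any(mask)) stop("reference image contains no tissue pixels")
  px <- cbind(as.vector(reference_rgb[, , 1])[mask],
              as.vector(reference_rgb[, , 2])[mask],
              as.vector(reference_rgb[, , 3])[mask])
  lab <- rgbToLab(px)
  sds <- apply(lab, 2, stats::sd)
  if (any(sds <= 0))
    stop("reference tissue is constant-color; channel standard deviation is zero")
  new("ColorNormalizer", ref_mean = colMeans(lab), ref_sd = sds,
      s_min = s_min, v_max = v_max, fitted = TRUE)
}

#' Tissue color statistics of an image
#'
#' Per-channel mean and standard deviation of an image's tissue pixels
#' in the l-alpha-beta space, optionally on a strided pixel subsample
#' for large rasters. These are the image-side statistics of the
#' normalization transfer; when normalizing patches cut from one slide,
#' compute them once on the whole slide so that every patch undergoes
#' the same slide-level transform (normalizing each patch against its
#' own statistics would erase the patch-to-patch color differences that
#' carry the class signal).
#'
#' @param image_rgb RGB raster.
#' @param s_min,v_max tissue thresholds.
#' @param stride keep every `stride`-th pixel (default 1 = all).
#' @return list with `mean` and `sd` (length-3 each), or `NULL` when
#'   the image has no tissue pixels.
#' @export
labTissueStats <- function(image_rgb, s_min = 0.05, v_max = 0.95,
                           stride = 1L) {
  checkRaster(image_rgb, "image")
  px <- cbind(as.vector(image_rgb[, , 1]), as.vector(image_rgb[, , 2]),
              as.vector(image_rgb[, , 3]))
  if (stride > 1L) px <- px[seq(1L, nrow(px), by = stride), , drop = FALSE]
  hsv <- grDevices::rgb2hsv(r = px[, 1], g = px[, 2], b = px[, 3],
                            maxColorValue = 1)
  mask <- hsv[2, ] > s_min & hsv[3, ] < v_max
  if (!any(mask)) return(NULL)
  lab <- rgbToLab(px[mask, , drop = FALSE])
  sds <- apply(lab, 2, stats::sd)
  sds[sds <= 0] <- 1
  list(mean = colMeans(lab), sd = sds)
}

#' Apply color normalization to an image
#'
#' Shifts and scales each l-alpha-beta channel of the input so its
#' tissue-pixel statistics match the fitted reference, then converts
#' back to RGB with clipping to `[0, 1]`. By default the image-side
#' statistics are computed from the input itself; pass `image_stats`
#' (from [labTissueStats()] on the whole slide) when normalizing
#' individual patches of a slide. Images without tissue pixels are
#' returned unchanged (there is nothing to normalize against).
#'
#' @param state a fitted [ColorNormalizer-class].
#' @param image_rgb RGB raster.
#' @param image_stats optional precomputed image-side statistics.
#' @return normalized RGB raster of the same dimensions.
#' @export
applyColorNormalization <- function(state, image_rgb, image_stats = NULL) {
  stopifnot(is(state, "ColorNormalizer"))
  if (!state@fitted) stop("color normalizer has not been fitted")
  checkRaster(image_rgb, "image")
  if (is.null(image_stats))
    image_stats <- labTissueStats(image_rgb, state@s_min, state@v_max)
  if (is.null(image_stats)) return(image_rgb)
  d <- dim(image_rgb)
  px <- cbind(as.vector(image_rgb[, , 1]), as.vector(image_rgb[, , 2]),
              as.vector(image_rgb[, , 3]))
  lab <- rgbToLab(px)
  lab <- sweep(lab, 2, image_stats$mean)
  lab <- sweep(lab, 2, state@ref_sd / image_stats$sd, `*`)
  lab <- sweep(lab, 2, state@ref_mean, `+`)
  array(labToRgb(lab), d[1:3])
}

#' White-point (luminosity) standardization
#'
#' Estimates the color of the glass background (bright, desaturated
#' pixels) and rescales each channel so that the background maps to
#' pure white. Because every slide's background is tissue-independent,
#' this corrects scanner/stain gain differences without the
#' composition sensitivity of global channel-statistics transfer:
#' a slide's global color statistics shift with its tumor burden, its
#' background does not.
#'
#' @param image_rgb RGB raster.
#' @param s_max maximum saturation of background pixels (default 0.12).
#' @param v_min minimum brightness of background pixels (default 0.85).
#' @param stride pixel subsampling stride for the estimate.
#' @return length-3 white-point estimate, or `NULL` when the image has
#'   no background pixels.
#' @export
estimateWhitePoint <- function(image_rgb, s_max = 0.12, v_min = 0.85,
                               stride = 1L) {
  checkRaster(image_rgb, "image")
  px <- cbind(as.vector(image_rgb[, , 1]), as.vector(image_rgb[, , 2]),
              as.vector(image_rgb[, , 3]))
  if (stride > 1L) px <- px[seq(1L, nrow(px), by = stride), , drop = FALSE]
  hsv <- grDevices::rgb2hsv(r = px[, 1], g = px[, 2], b = px[, 3],
                            maxColorValue = 1)
  mask <- hsv[2, ] <= s_max & hsv[3, ] >= v_min
  if (!any(mask)) return(NULL)
  wp <- colMeans(px[mask, , drop = FALSE])
  pmax(wp, 0.2)  # guard against degenerate estimates
}

#' @rdname estimateWhitePoint
#' @param white_point estimate from `estimateWhitePoint`.
#' @export
applyWhitePoint <- function(image_rgb, white_point) {
  checkRaster(image_rgb, "image")
  if (is.null(white_point)) return(image_rgb)
  for (ch in 1:3) image_rgb[, , ch] <- image_rgb[, , ch] / white_point[ch]
  clip01(image_rgb)
}

#' Flip a patch horizontally
#'
#' @param patch_rgb RGB raster.
#' @return the mirrored raster.
#' @export
flipHorizontal <- function(patch_rgb) {
  checkRaster(patch_rgb, "patch")
  patch_rgb[, rev(seq_len(dim(patch_rgb)[2])), , drop = FALSE]
}

# Reflective padding of a raster by `pad` pixels on every side.
padReflect <- function(img, pad) {
  if (pad == 0) return(img)
  d <- dim(img)
  ri <- c(rev(seq_len(pad) + 1L), seq_len(d[1]), d[1] - seq_len(pad))
  ci <- c(rev(seq_len(pad) + 1L), seq_len(d[2]), d[2] - seq_len(pad))
  img[ri, ci, , drop = FALSE]
}

#' Augment a training patch
#'
#' Training-time augmentation pipeline: reflective pad then random crop
#' back to the original size, horizontal flip with probability
#' `flip_p`, and optional per-channel standardization with fixed
#' constants. Fully determined by `seed`.
#'
#' @param patch_rgb RGB raster.
#' @param seed integer seed controlling the crop offset and flip draw.
#' @param pad reflective padding in pixels (default 8).
#' @param flip_p horizontal-flip probability (default 0.5).
#' @param standardize when `TRUE` (default) the output is
#'   `(x - center) / scale` per channel and no longer lies in `[0,1]`.
#' @param center,scale standardization constants (defaults 0.5 / 0.5).
#' @return the augmented patch.
#' @export
augmentPatch <- function(patch_rgb, seed, pad = 8L, flip_p = 0.5,
                         standardize = TRUE, center = 0.5, scale = 0.5) {
  checkRaster(patch_rgb, "patch")
  d <- dim(patch_rgb)
  out <- withSeed(seed, {
    padded <- padReflect(patch_rgb, pad)
    dy <- sample.int(2L * pad + 1L, 1L) - 1L
    dx <- sample.int(2L * pad + 1L, 1L) - 1L
    crop <- padded[dy + seq_len(d[1]), dx + seq_len(d[2]), , drop = FALSE]
    if (stats::runif(1) < flip_p) crop <- flipHorizontal(crop)
    crop
  })
  if (standardize) out <- (out - center) / scale
  out
}
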