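## Tiling slides into non-overlapping patches and assigning the
## three-class training labels from partial annotations.

#' Tile a slide into a non-overlapping patch grid
#'
#' Covers the slide with non-overlapping `patch_size` x `patch_size`
#' patches in row-major order; partial edge patches are dropped, so the
#' grid is `floor(height/patch_size)` x `floor(width/patch_size)`.
#'
#' @param slide a [SlideRecord-class].
#' @param patch_size patch side length in pixels (default 256).
#' @return a [PatchSet-class] with all grid patches, tissue fraction
#'   `NA` and label `"unlabeled"`.
#' @examples
#' s <- slideRecord("s", width_px = 1024, height_px = 768)
#' nPatches(tileSlide(s))  # 12
#' @export
tileSlide <- function(slide, patch_size = 256L) {
  stopifnot(is(slide, "SlideRecord"))
  patch_size <- as.integer(patch_size)
  n_rows <- as.integer(slide@height_px %/% patch_size)
  n_cols <- as.integer(slide@width_px %/% patch_size)
  if (n_rows < 1L || n_cols < 1L)
    stop(sprintf("slide '%s' (%dx%d) is smaller than one %d px patch",
                 slide@slide_id, slide@width_px, slide@height_px, patch_size))
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  patches <- data.frame(
    row = row, col = col,
    x0 = col * patch_size, y0 = row * patch_size,
    x1 = (col + 1L) * patch_size, y1 = (row + 1L) * patch_size,
    tissue_fraction = NA_real_, label = "unlabeled",
    stringsAsFactors = FALSE)
  new("PatchSet", slide_id = slide@slide_id, patch_size = patch_size,
      n_rows = n_rows, n_cols = n_cols, patches = patches)
}

#' Compute tissue fractions for every patch of a grid
#'
#' Fills the `tissue_fraction` column of a patch grid from the slide
#' raster using the HSV tissue rule of [tissueFraction()], computed for
#' all patches in one pass over the raster.
#'
#' @param grid a [PatchSet-class] from [tileSlide()].
#' @param raster the slide raster (h x w x 3).
#' @param s_min,v_max tissue thresholds.
#' @return the grid with tissue fractions filled in.
#' @export
patchTissueFractions <- function(grid, raster, s_min = 0.05, v_max = 0.95) {
  stopifnot(is(grid, "PatchSet"))
  checkRaster(raster, "slide raster")
  hsv <- rasterHSV(raster)
  tissue <- (hsv$s > s_min & hsv$v < v_max) * 1
  ps <- grid@patch_size
  frac <- blockSums(tissue, ps, grid@n_rows, grid@n_cols) / (ps * ps)
  p <- grid@patches
  p$tissue_fraction <- frac[cbind(p$row + 1L, p$col + 1L)]
  initialize(grid, patches = p)
}

patchCenters <- function(patches, patch_size) {
  cbind(x = patches$x0 + patch_size / 2, y = patches$y0 + patch_size / 2)
}

#' Assign three-class training labels to patches
#'
#' Implements the partial-annotation labeling rule: a patch is "inside"
#' an annotated region iff its center point is inside any region
#' polygon. Inside tissue patches receive the slide-level label
#' (melanoma or nevus); tissue patches outside the annotations that fall
#' in a designated other-source zone are labeled `"other"`; remaining
#' tissue patches stay `"unlabeled"` and are never used for training
#' (unannotated tumor must not silently become "other").
#' Patches below the tissue threshold are excluded from the result.
#'
#' The other-source zone formalizes the manual selection of non-tumor
#' example regions. Modes:
#' \describe{
#'   \item{`margin`}{tissue at distance > `margin` px (default 512) from
#'     every annotated polygon. When the slide carries no annotations
#'     the zone is empty (there is nothing to keep a safe distance
#'     from).}
#'   \item{`polygons`}{explicit zone polygons
#'     ([AnnotationRegion-class] list) supplied by the caller.}
#'   \item{`none`}{no other patches.}
#' }
#'
#' @param grid a [PatchSet-class] with tissue fractions filled in (see
#'   [patchTissueFractions()]).
#' @param slide the [SlideRecord-class]; its `slide_label` must be
#'   melanoma or nevus and its `regions` are the annotated polygons.
#' @param min_tissue_fraction minimum tissue fraction for a patch to be
#'   extracted (default 0.25).
#' @param other_zone list describing the other-source zone, e.g.
#'   `list(mode = "margin", margin = 512)` (default) or
#'   `list(mode = "polygons", polygons = <list>)`.
#' @param balance_other subsample "other" patches down to the number of
#'   annotated (slide-label) patches (default `TRUE`).
#' @param seed seed for the balancing subsample.
#' @return a [PatchSet-class] containing only extracted (tissue)
#'   patches, labeled melanoma/nevus/other/unlabeled.
#' @export
labelPatches <- function(grid, slide, min_tissue_fraction = 0.25,
                         other_zone = list(mode = "margin", margin = 512),
                         balance_other = TRUE, seed = 1L) {
  stopifnot(is(grid, "PatchSet"), is(slide, "SlideRecord"))
  if (!slide@slide_label %in% c("melanoma", "nevus"))
    stop(sprintf("slide '%s' has label '%s'; training-time labeling needs melanoma or nevus",
                 slide@slide_id, slide@slide_label))
  p <- grid@patches
  if (anyNA(p$tissue_fraction))
    stop("tissue fractions must be computed before labeling (patchTissueFractions)")
  p <- p[p$tissue_fraction >= min_tissue_fraction, , drop = FALSE]
  ctr <- patchCenters(p, grid@patch_size)
  inside <- if (length(slide@regions))
    pointInAnyRegion(slide@regions, ctr[, "x"], ctr[, "y"]) else
    logical(nrow(p))
  p$label <- "unlabeled"
  p$label[inside] <- slide@slide_label

  mode <- if (is.null(other_zone$mode)) "margin" else other_zone$mode
  in_zone <- switch(mode,
    margin = {
      if (length(slide@regions) == 0L) logical(nrow(p)) else {
        margin <- if (is.null(other_zone$margin)) 512 else other_zone$margin
        dmin <- rep(Inf, nrow(p))
        for (r in slide@regions)
          dmin <- pmin(dmin, distanceToRegion(r, ctr[, "x"], ctr[, "y"]))
        dmin > margin
      }
    },
    polygons = pointInAnyRegion(other_zone$polygons, ctr[, "x"], ctr[, "y"]),
    none = logical(nrow(p)),
    stop(sprintf("unknown other-zone mode '%s'", mode)))
  p$label[!inside & in_zone] <- "other"

  if (balance_other) {
    oth <- which(p$label == "other")
    n_keep <- sum(inside)
    if (length(oth) > n_keep) {
      drop <- withSeed(seed, sample(oth, length(oth) - n_keep))
      p$label[drop] <- "unlabeled"
    }
  }
  rownames(p) <- NULL
  initialize(grid, patches = p)
}

#' Extract the pixels of one patch
#'
#' Exact crop of a patch bounding box from the slide raster, no
#' resampling.
#'
#' @param slide a [SlideRecord-class] (or a raster array).
#' @param patch one row of a patch table (list or data.frame row with
#'   `x0`, `y0`, `x1`, `y1`), or a numeric vector `c(x0, y0, x1, y1)`.
#' @return RGB raster of the patch.
#' @export
extractPatchPixels <- function(slide, patch) {
  raster <- if (is(slide, "SlideRecord")) slideRaster(slide) else
    checkRaster(slide, "slide")
  if (is.numeric(patch) && length(patch) == 4L)
    patch <- list(x0 = patch[1], y0 = patch[2], x1 = patch[3], y1 = patch[4])
  d <- dim(raster)
  if (patch$x0 < 0 || patch$y0 < 0 || patch$x1 > d[2] || patch$y1 > d[1])
    stop(sprintf("patch bbox [%g,%g)x[%g,%g) is outside the %dx%d slide",
                 patch$x0, patch$x1, patch$y0, patch$y1, d[2], d[1]))
  raster[(patch$y0 + 1):patch$y1, (patch$x0 + 1):patch$x1, , drop = FALSE]
}

#' Write a patch manifest
#'
#' Tab-separated text with one extracted patch per line:
#' slide_id, row, col, x0, y0, x1, y1, tissue_fraction, label.
#'
#' @param patch_sets a [PatchSet-class] or list of them.
#' @param path output file.
#' @return the manifest data frame, invisibly.
#' @export
writePatchManifest <- function(patch_sets, path) {
  if (is(patch_sets, "PatchSet")) patch_sets <- list(patch_sets)
  cols <- c("row", "col", "x0", "y0", "x1", "y1", "tissue_fraction", "label")
  rows <- lapply(patch_sets, function(ps) {
    if (nrow(ps@patches) == 0L) return(NULL)
    cbind(slide_id = ps@slide_id, ps@patches[, cols])
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest))
    manifest <- cbind(data.frame(slide_id = character()),
                      stats::setNames(rep(list(numeric()), length(cols)),
                                      cols))
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
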