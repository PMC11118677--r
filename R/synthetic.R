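## Deterministic synthetic cohorts emulating the structure of an H&E
## melanocytic-tumor slide archive: white glass background, 1-3
## elliptical tissue slices per slide with pink stroma texture and
## scattered dark nuclei, one star-shaped tumor polygon per slice whose
## color depends on the slide class (melanoma dark and nucleus-dense,
## nevus light), slide-level labels, and partial annotation: each tumor
## slice is exported to ImageScope XML independently with probability
## annotation_coverage, while the full ground truth keeps every polygon.

#' Create a synthetic cohort specification
#'
#' Defaults describe the desk-scale study conditions: 20 slides of
#' 3072 x 2304 px (a 12 x 9 grid of 256 px patches), melanoma:nevus
#' balance 86:74, 1-3 tissue slices per slide, one tumor region per
#' slice, and 60% of tumor slices annotated. Each tumor polygon is
#' centered on the patch-grid center nearest its slice anchor, so every
#' tumor region contains at least one patch center and every slide
#' yields tumor-voting patches.
#'
#' @param n_slides number of slides (default 20).
#' @param class_balance melanoma:nevus weights (default `c(86, 74)`).
#' @param slide_width,slide_height slide pixels (default 3072 x 2304).
#' @param patch_size patch side length (default 256).
#' @param slices_range min/max tissue slices per slide (default 1:3).
#' @param tumor_radius_range base tumor radii in px (default 280-380).
#' @param annotation_coverage per-slice annotation probability
#'   (default 0.6).
#' @param noise_sd per-pixel Gaussian color noise (default 0.03).
#' @param stain_sd per-slide stain gain/offset jitter (default 0.04).
#' @param seed integer seed; fully determines the cohort (default 1).
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(n_slides = 20L, class_balance = c(86, 74),
                       slide_width = 3072L, slide_height = 2304L,
                       patch_size = 256L, slices_range = c(1L, 3L),
                       tumor_radius_range = c(280, 380),
                       annotation_coverage = 0.6, noise_sd = 0.03,
                       stain_sd = 0.04, seed = 1L) {
  colors <- list(background = c(0.97, 0.96, 0.97),
                 stroma = c(0.93, 0.76, 0.83),
                 nevus = c(0.80, 0.62, 0.74),
                 melanoma = c(0.46, 0.31, 0.45),
                 nuclei = c(0.26, 0.16, 0.36))
  # per-patch-area (256^2 px) disc counts; tumor is nucleus-dense
  # (roughly 8% pixel coverage for nevus, 18% for melanoma, 1% stroma)
  nuclei_density <- c(stroma = 25, nevus = 190, melanoma = 430)
  new("CohortSpec", n_slides = as.integer(n_slides),
      class_balance = as.numeric(class_balance),
      slide_width = as.integer(slide_width),
      slide_height = as.integer(slide_height),
      patch_size = as.integer(patch_size),
      slices_range = as.integer(slices_range),
      tumor_radius_range = as.numeric(tumor_radius_range),
      annotation_coverage = annotation_coverage, noise_sd = noise_sd,
      stain_sd = stain_sd, colors = colors,
      nuclei_density = nuclei_density, seed = as.integer(seed))
}

# star-shaped tumor polygon centered on a patch-grid center
starPolygon <- function(cx, cy, rx, ry, n_vertices = 14L, wobble = 0.12) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  k <- stats::runif(n_vertices, 1 - wobble, 1 + wobble)
  cbind(x = cx + rx * k * cos(theta), y = cy + ry * k * sin(theta))
}

generateSlide <- function(spec, slide_id, label, slide_seed) {
  w <- spec@slide_width; h <- spec@slide_height; ps <- spec@patch_size
  withSeed(slide_seed, {
    n_slices <- sample(seq(spec@slices_range[1], spec@slices_range[2]), 1L)
    anchors <- list(c(0.27, 0.36), c(0.73, 0.36), c(0.50, 0.68))
    anchors <- anchors[sample.int(3L)][seq_len(n_slices)]

    # grid of patch centers (for snapping tumors onto the patch grid)
    gx <- (seq_len(w %/% ps) - 0.5) * ps
    gy <- (seq_len(h %/% ps) - 0.5) * ps

    slices <- lapply(anchors, function(an) {
      a <- stats::runif(1, 0.20, 0.23) * w
      b <- stats::runif(1, 0.24, 0.27) * h
      tcx <- gx[which.min(abs(gx - an[1] * w))]
      tcy <- gy[which.min(abs(gy - an[2] * h))]
      cx <- tcx + stats::runif(1, -25, 25)
      cy <- tcy + stats::runif(1, -25, 25)
      # keep the tumor polygon (center snapped to the grid, +-12% radial
      # wobble) strictly inside the slice ellipse
      rmax <- (min(a, b) - 30) / 1.12
      rx <- min(stats::runif(1, spec@tumor_radius_range[1],
                             spec@tumor_radius_range[2]), rmax)
      ry <- min(stats::runif(1, spec@tumor_radius_range[1],
                             spec@tumor_radius_range[2]), rmax)
      poly <- starPolygon(tcx, tcy, rx, ry)
      poly[, 1] <- pmin(pmax(poly[, 1], 0), w - 1)
      poly[, 2] <- pmin(pmax(poly[, 2], 0), h - 1)
      list(cx = cx, cy = cy, a = a, b = b, poly = poly)
    })

    # class mask: 0 background, 1 stroma, 2 tumor
    mask <- matrix(0L, h, w)
    px_x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    px_y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
    for (sl in slices) {
      inside <- ((px_x - sl$cx) / sl$a)^2 + ((px_y - sl$cy) / sl$b)^2 <= 1
      mask[inside] <- 1L
    }
    for (sl in slices) {
      bb <- c(floor(min(sl$poly[, 1])), ceiling(max(sl$poly[, 1])),
              floor(min(sl$poly[, 2])), ceiling(max(sl$poly[, 2])))
      cols <- max(1L, bb[1]):min(w, bb[2])
      rows <- max(1L, bb[3]):min(h, bb[4])
      subx <- rep(cols - 0.5, each = length(rows))
      suby <- rep(rows - 0.5, times = length(cols))
      hit <- pointsInPolygon(subx, suby, sl$poly)
      idx <- cbind(rep(rows, times = length(cols))[hit],
                   rep(cols, each = length(rows))[hit])
      mask[idx] <- 2L
    }

    tumor_color <- spec@colors[[label]]
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      base <- matrix(spec@colors$background[ch], h, w)
      base[mask == 1L] <- spec@colors$stroma[ch]
      base[mask == 2L] <- tumor_color[ch]
      img[, , ch] <- base + matrix(stats::rnorm(h * w, sd = spec@noise_sd), h, w)
    }

    # nuclei discs with class-dependent density (per patch-area counts),
    # drawn by radius group with one vectorized index assignment each
    addNuclei <- function(img, idx_pool, density, area) {
      n_discs <- round(area / (ps * ps) * density)
      if (n_discs < 1L || !length(idx_pool)) return(img)
      centers <- idx_pool[sample.int(length(idx_pool),
                                     min(n_discs, length(idx_pool)))]
      cy <- (centers - 1L) %% h + 1L
      cx <- (centers - 1L) %/% h + 1L
      radii <- sample(2:4, length(centers), replace = TRUE)
      for (R in 2:4) {
        sel <- radii == R
        if (!any(sel)) next
        offs <- which(outer((-R:R)^2, (-R:R)^2, `+`) <= R^2, arr.ind = TRUE)
        offs <- offs - (R + 1L)
        py <- rep(cy[sel], each = nrow(offs)) + offs[, 1]
        px <- rep(cx[sel], each = nrow(offs)) + offs[, 2]
        ok <- py >= 1L & py <= h & px >= 1L & px <= w
        for (ch in 1:3)
          img[cbind(py[ok], px[ok], ch)] <- spec@colors$nuclei[ch]
      }
      img
    }
    stroma_idx <- which(mask == 1L)
    tumor_idx <- which(mask == 2L)
    img <- addNuclei(img, stroma_idx, spec@nuclei_density["stroma"],
                     length(stroma_idx))
    img <- addNuclei(img, tumor_idx, spec@nuclei_density[label],
                     length(tumor_idx))

    # per-slide stain jitter: slides from "different scanning sessions"
    gain <- exp(stats::rnorm(3, sd = spec@stain_sd))
    offset <- stats::rnorm(3, sd = spec@stain_sd / 2)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * gain[ch] + offset[ch]
    img <- clip01(img)

    regions_all <- lapply(seq_along(slices), function(i)
      annotationRegion(sprintf("%s-t%d", slide_id, i), slices[[i]]$poly,
                       label_hint = label))
    annotated <- stats::runif(length(slices)) < spec@annotation_coverage

    # other-source zones: discs of definitely-non-tumor stroma, placed on
    # patch-grid centers well inside a slice and clear of *every* tumor
    # polygon (annotated or not). This emulates the manual selection of
    # "other" example regions; without it, unannotated tumor would leak
    # into the "other" class.
    ctr_x <- rep(gx, times = length(gy))
    ctr_y <- rep(gy, each = length(gx))
    safe <- rep(FALSE, length(ctr_x))
    for (sl in slices)
      safe <- safe | (((ctr_x - sl$cx) / (0.92 * sl$a))^2 +
                      ((ctr_y - sl$cy) / (0.92 * sl$b))^2 <= 1)
    # a zone disc only ever captures its own grid center (disc radius <
    # grid spacing), so the center must clear every tumor polygon, with
    # a small safety band; near-boundary stroma is deliberately kept --
    # the classifier has to learn the center rule at the tumor edge
    dmin <- rep(Inf, length(ctr_x))
    for (r in regions_all)
      dmin <- pmin(dmin, distanceToRegion(r, ctr_x, ctr_y))
    zone_r <- 60
    safe <- safe & dmin > 25
    idx <- which(safe)
    if (length(idx) > 12L) idx <- sort(sample(idx, 12L))
    theta <- seq(0, 2 * pi, length.out = 17L)[-17L]
    other_zones <- lapply(seq_along(idx), function(k) {
      cx <- ctr_x[idx[k]]; cy <- ctr_y[idx[k]]
      annotationRegion(sprintf("%s-oz%d", slide_id, k),
                       cbind(pmin(pmax(cx + zone_r * cos(theta), 0), w - 1),
                             pmin(pmax(cy + zone_r * sin(theta), 0), h - 1)),
                       label_hint = "other")
    })

    list(image = img, mask = mask, regions_all = regions_all,
         annotated = annotated, other_zones = other_zones)
  })
}

#' Generate a synthetic cohort
#'
#' Generates `spec@n_slides` slides with labels, rasters, partial XML
#' annotations and full ground truth, fully determined by `spec@seed`.
#' With `dir` given, writes per-slide PNG rasters
#' (`slides/<id>.png`), annotation XML for the annotated subset
#' (`annotations/<id>.xml`), other-source zone polygons
#' (`annotations/<id>_other.xml`), full ground-truth XML
#' (`truth/<id>.xml`),
#' ground-truth class masks (`masks/<id>.png`, gray levels
#' 0, 1/3, 2/3 for background/stroma/tumor) and a tab-separated cohort
#' manifest; slide records then reference the PNG paths instead of
#' holding rasters in memory.
#'
#' @param spec a [CohortSpec-class].
#' @param dir output directory, or `NULL` to keep rasters in memory.
#' @param write_masks write ground-truth mask PNGs (default `TRUE`).
#' @return list with `spec`, `slides` (list of [SlideRecord-class],
#'   carrying only the annotated regions), `truth` (per slide: label,
#'   all region polygons, annotated flags), `other_zones` (per slide:
#'   non-tumor example-zone polygons) and `manifest` (data frame).
#' @export
generateCohort <- function(spec, dir = NULL, write_masks = TRUE) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n_mel <- as.integer(round(spec@n_slides * spec@class_balance[1] /
                            sum(spec@class_balance)))
  labels <- rep(c("melanoma", "nevus"), c(n_mel, spec@n_slides - n_mel))
  ids <- sprintf("S%03d", seq_len(spec@n_slides))
  if (!is.null(dir)) {
    for (d in c("slides", "annotations", "truth",
                if (write_masks) "masks"))
      dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  slides <- vector("list", spec@n_slides)
  truth <- vector("list", spec@n_slides)
  other_zones <- vector("list", spec@n_slides)
  for (i in seq_len(spec@n_slides)) {
    g <- generateSlide(spec, ids[i], labels[i],
                       slide_seed = (spec@seed %% 65011) * 33003L + 977L * i)
    ann_regions <- g$regions_all[g$annotated]
    other_zones[[i]] <- g$other_zones
    if (!is.null(dir)) {
      img_path <- file.path(dir, "slides", paste0(ids[i], ".png"))
      png::writePNG(g$image, img_path)
      writeAnnotationXML(ann_regions,
                         file.path(dir, "annotations", paste0(ids[i], ".xml")))
      writeAnnotationXML(g$other_zones,
                         file.path(dir, "annotations",
                                   paste0(ids[i], "_other.xml")))
      writeAnnotationXML(g$regions_all,
                         file.path(dir, "truth", paste0(ids[i], ".xml")))
      if (write_masks)
        png::writePNG(g$mask / 3, file.path(dir, "masks", paste0(ids[i], ".png")))
      slides[[i]] <- slideRecord(ids[i], image = NULL, image_path = img_path,
                                 width_px = spec@slide_width,
                                 height_px = spec@slide_height,
                                 slide_label = labels[i],
                                 regions = ann_regions)
    } else {
      slides[[i]] <- slideRecord(ids[i], image = g$image,
                                 slide_label = labels[i],
                                 regions = ann_regions)
    }
    truth[[i]] <- list(slide_id = ids[i], label = labels[i],
                       regions = g$regions_all, annotated = g$annotated)
  }
  names(slides) <- ids
  names(truth) <- ids
  names(other_zones) <- ids
  manifest <- data.frame(
    slide_id = ids, label = labels,
    width_px = spec@slide_width, height_px = spec@slide_height,
    n_slices = vapply(truth, function(t) length(t$regions), integer(1)),
    n_annotated = vapply(truth, function(t) sum(t$annotated), integer(1)),
    stringsAsFactors = FALSE)
  if (!is.null(dir))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  list(spec = spec, slides = slides, truth = truth,
       other_zones = other_zones, manifest = manifest)
}

cohortSubset <- function(cohort, ids, keep_truth = TRUE) {
  list(spec = cohort$spec, slides = cohort$slides[ids],
       truth = if (keep_truth) cohort$truth[ids] else
         stats::setNames(vector("list", length(ids)), ids),
       other_zones = cohort$other_zones[ids],
       manifest = cohort$manifest[match(ids, cohort$manifest$slide_id), ,
                                  drop = FALSE])
}

cohortLabels <- function(cohort)
  stats::setNames(cohort$manifest$label, cohort$manifest$slide_id)

#' Stratified train/test split of a cohort
#'
#' Splits slides into training and test sets, stratified by slide
#' label, deterministic given `seed`. The test set keeps its full
#' ground truth for evaluation; the training set carries only the
#' partial XML annotations (its ground-truth entries are dropped,
#' mirroring the information available on real archives).
#'
#' @param cohort result of [generateCohort()].
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.8).
#' @param seed split seed.
#' @return list with `train` and `test` cohort subsets.
#' @export
trainTestSplit <- function(cohort, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- cohortLabels(cohort)
  train_ids <- character()
  for (cls in c("melanoma", "nevus")) {
    ids <- names(labels)[labels == cls]
    if (length(ids) < 2L)
      stop(sprintf("class '%s' has fewer than 2 slides; cannot split", cls))
    n_train <- roundHalfUp(train_fraction * length(ids))
    n_train <- min(max(n_train, 1L), length(ids) - 1L)
    train_ids <- c(train_ids,
                   withSeed(seed + match(cls, CLASS_ORDER),
                            sample(ids, n_train)))
  }
  all_ids <- cohort$manifest$slide_id
  train_ids <- all_ids[all_ids %in% train_ids]
  test_ids <- setdiff(all_ids, train_ids)
  list(train = cohortSubset(cohort, train_ids, keep_truth = FALSE),
       test = cohortSubset(cohort, test_ids, keep_truth = TRUE))
}

#' Stratified subsample of a training set
#'
#' Draws a class-stratified random subset of the training slides, used
#' to study robustness against shrinking training data.
#'
#' @param train training cohort subset from [trainTestSplit()].
#' @param fraction fraction of each class to keep (in `(0, 1]`).
#' @param seed subsample seed.
#' @return a reduced training cohort subset.
#' @export
subsampleTraining <- function(train, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(train)
  labels <- cohortLabels(train)
  keep_ids <- character()
  for (cls in c("melanoma", "nevus")) {
    ids <- names(labels)[labels == cls]
    n_keep <- roundHalfUp(fraction * length(ids))
    if (n_keep < 1L)
      stop(sprintf("subsample leaves no '%s' training slides", cls))
    keep_ids <- c(keep_ids,
                  withSeed(seed + 7L * match(cls, CLASS_ORDER),
                           sample(ids, n_keep)))
  }
  all_ids <- train$manifest$slide_id
  cohortSubset(train, all_ids[all_ids %in% keep_ids], keep_truth = FALSE)
}

#' Ground-truth patch classes for a slide
#'
#' Derives the per-patch ground truth used by the oracle classifier and
#' the evaluation: a patch whose center lies inside any ground-truth
#' tumor polygon has the slide's class (and `in_roi = TRUE`); every
#' other extracted tissue patch is `"other"`.
#'
#' @param patch_set extracted patches of the slide ([PatchSet-class]).
#' @param truth the slide's ground-truth entry (label + regions), as
#'   produced by [generateCohort()].
#' @return data frame with `slide_id`, `row`, `col`, `true_class`,
#'   `in_roi`.
#' @export
patchTruth <- function(patch_set, truth) {
  p <- patch_set@patches
  ctr <- patchCenters(p, patch_set@patch_size)
  inside <- if (length(truth$regions))
    pointInAnyRegion(truth$regions, ctr[, "x"], ctr[, "y"]) else
    logical(nrow(p))
  data.frame(slide_id = patch_set@slide_id, row = p$row, col = p$col,
             true_class = ifelse(inside, truth$label, "other"),
             in_roi = inside, stringsAsFactors = FALSE)
}
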