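## The three visualization maps: overlap (blue-masked non-ROI), boundary
## (outline of the largest OPTICS cluster of ROI patches) and heatmap
## (blue-to-red winning-class scores per patch).

#' Overlap map
#'
#' Shows the ROI patches unmodified and alpha-blends every other pixel
#' with a transparent blue mask; the fraction of un-tinted area equals
#' the annotated ratio beta by construction of the ROI selection.
#'
#' @param raster slide raster (h x w x 3).
#' @param roi_patches data frame of ROI patches (`x0`, `y0`, `x1`,
#'   `y1` pixel boxes).
#' @param alpha mask opacity (default 0.4).
#' @param color mask RGB color (default blue).
#' @return the blended raster.
#' @export
overlapMap <- function(raster, roi_patches, alpha = 0.4,
                       color = c(0, 0, 1)) {
  checkRaster(raster, "slide raster")
  d <- dim(raster)
  keep <- matrix(FALSE, d[1], d[2])
  if (!is.null(roi_patches) && nrow(roi_patches))
    for (i in seq_len(nrow(roi_patches)))
      keep[(roi_patches$y0[i] + 1):roi_patches$y1[i],
           (roi_patches$x0[i] + 1):roi_patches$x1[i]] <- TRUE
  out <- raster
  for (ch in 1:3) {
    m <- out[, , ch]
    m[!keep] <- (1 - alpha) * m[!keep] + alpha * color[ch]
    out[, , ch] <- m
  }
  out
}

# Outer boundary polygon(s) of a union of grid cells. Cells are given as
# 0-based (row, col); returns loops as matrices of (x, y) grid-corner
# coordinates in pixels (vertices lie on patch-grid edges). Shared edges
# of adjacent cells cancel; the remaining directed edges form closed
# loops. The loop with the largest absolute shoelace area is the outer
# boundary.
traceCellBoundary <- function(cells, patch_size) {
  stopifnot(nrow(cells) > 0)
  ekey <- function(x1, y1, x2, y2) paste(x1, y1, x2, y2, sep = ",")
  edges <- new.env(parent = emptyenv())
  add_edge <- function(x1, y1, x2, y2) {
    rk <- ekey(x2, y2, x1, y1)
    if (exists(rk, envir = edges, inherits = FALSE))
      rm(list = rk, envir = edges)
    else assign(ekey(x1, y1, x2, y2), c(x1, y1, x2, y2), envir = edges)
  }
  for (i in seq_len(nrow(cells))) {
    c0 <- cells$col[i]; r0 <- cells$row[i]
    add_edge(c0,     r0,     c0 + 1, r0)      # top, left to right
    add_edge(c0 + 1, r0,     c0 + 1, r0 + 1)  # right, downward
    add_edge(c0 + 1, r0 + 1, c0,     r0 + 1)  # bottom, right to left
    add_edge(c0,     r0 + 1, c0,     r0)      # left, upward
  }
  remaining <- as.list(edges)
  # successor lookup by start vertex
  starts <- vapply(remaining, function(e) paste(e[1], e[2], sep = ","),
                   character(1))
  by_start <- split(names(remaining), starts)
  used <- new.env(parent = emptyenv())
  loops <- list()
  for (k in names(remaining)) {
    if (exists(k, envir = used, inherits = FALSE)) next
    loop <- list()
    cur <- k
    repeat {
      e <- remaining[[cur]]
      assign(cur, TRUE, envir = used)
      loop[[length(loop) + 1L]] <- e[1:2]
      nxt_key <- paste(e[3], e[4], sep = ",")
      cands <- by_start[[nxt_key]]
      cands <- cands[!vapply(cands, exists, logical(1), envir = used,
                             USE.NAMES = FALSE)]
      if (!length(cands)) break
      if (length(cands) > 1L) {
        # degree-4 vertex (diagonally touching cells): prefer the edge
        # turning left relative to the incoming direction, keeping the
        # traversal on the same side of the union
        din <- c(e[3] - e[1], e[4] - e[2])
        turn <- vapply(cands, function(ck) {
          ce <- remaining[[ck]]
          dout <- c(ce[3] - ce[1], ce[4] - ce[2])
          din[1] * dout[2] - din[2] * dout[1]
        }, numeric(1))
        cands <- cands[order(turn)]
      }
      cur <- cands[[1]]
    }
    loops[[length(loops) + 1L]] <- do.call(rbind, loop) * patch_size
  }
  areas <- vapply(loops, function(v) {
    x <- v[, 1]; y <- v[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  list(outer = loops[[which.max(areas)]], loops = loops)
}

drawPolyline <- function(raster, verts, color = c(0, 0.8, 0), width = 3L) {
  d <- dim(raster)
  closed <- rbind(verts, verts[1, ])
  half <- (width - 1L) %/% 2L
  for (i in seq_len(nrow(verts))) {
    a <- closed[i, ]; b <- closed[i + 1, ]
    len <- max(abs(b - a))
    t <- seq(0, 1, length.out = max(2L, ceiling(len) + 1L))
    xs <- round(a[1] + t * (b[1] - a[1]))
    ys <- round(a[2] + t * (b[2] - a[2]))
    for (dx in -half:half) for (dy in -half:half) {
      px <- pmin(pmax(xs + dx, 0L), d[2] - 1L)
      py <- pmin(pmax(ys + dy, 0L), d[1] - 1L)
      for (ch in 1:3) raster[cbind(py + 1L, px + 1L, ch)] <- color[ch]
    }
  }
  raster
}

#' Boundary map
#'
#' Clusters the ROI (highlighted) patches with OPTICS, takes the
#' cluster with the most patches, and draws the exact rectilinear outer
#' boundary of the union of that cluster's patch squares on the slide
#' raster. The outline vertices lie on patch-grid edges.
#'
#' @param raster slide raster.
#' @param roi_patches data frame of ROI patches (`row`, `col`, `x0`,
#'   `y0`, `x1`, `y1`).
#' @param patch_size patch side length in pixels.
#' @param min_samples,max_eps OPTICS parameters (defaults 5 and
#'   `3 * patch_size`).
#' @param color,width outline color and stroke width in pixels.
#' @return list with `raster` (outline drawn), `outline` (matrix of
#'   polygon vertices in pixels) and `cluster_patches` (the largest
#'   cluster's patch rows).
#' @export
boundaryMap <- function(raster, roi_patches, patch_size,
                        min_samples = 5L, max_eps = 3 * patch_size,
                        color = c(0, 0.8, 0), width = 3L) {
  checkRaster(raster, "slide raster")
  stopifnot(nrow(roi_patches) > 0)
  in_big <- largestRoiCluster(roi_patches, patch_size,
                              min_samples = min_samples, max_eps = max_eps)
  cl <- roi_patches[in_big, , drop = FALSE]
  tr <- traceCellBoundary(cl, patch_size)
  list(raster = drawPolyline(raster, tr$outer, color = color, width = width),
       outline = tr$outer, cluster_patches = cl)
}

#' Export a boundary outline as an annotation region
#'
#' Converts a traced outline into an [AnnotationRegion-class] so that
#' predicted ROIs can be written to ImageScope XML and viewed alongside
#' the pathologist's annotations.
#'
#' @param outline vertex matrix from [boundaryMap()].
#' @param region_id identifier for the exported region.
#' @return an [AnnotationRegion-class].
#' @export
outlineAsRegion <- function(outline, region_id = "predicted-roi") {
  annotationRegion(region_id, outline, label_hint = "predicted ROI")
}

#' Score heatmap
#'
#' Renders the per-patch winning-class scores on the slide grid through
#' a blue-to-red colormap: red marks patches with high predicted
#' scores, blue patches with low scores. Each patch is drawn as a
#' uniform square; no smoothing.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param patch_size patch side length in pixels.
#' @param scores data frame with `row`, `col`, `score` (in `[0, 1]`;
#'   grid patches without a score render as score 0).
#' @return raster of size `(n_rows*patch_size) x (n_cols*patch_size)`.
#' @export
scoreHeatmap <- function(n_rows, n_cols, patch_size, scores) {
  if (any(scores$score < 0 | scores$score > 1))
    stop("scores must lie in [0, 1]")
  grid <- matrix(0, n_rows, n_cols)
  grid[cbind(scores$row + 1L, scores$col + 1L)] <- scores$score
  ramp <- grDevices::colorRamp(c("blue", "red"))
  cols <- ramp(as.vector(grid)) / 255
  h <- n_rows * patch_size; w <- n_cols * patch_size
  out <- array(0, c(h, w, 3))
  ones <- matrix(1, patch_size, patch_size)
  for (ch in 1:3)
    out[, , ch] <- kronecker(matrix(cols[, ch], n_rows, n_cols), ones)
  out
}
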