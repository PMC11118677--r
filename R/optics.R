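## OPTICS density-based clustering for patch centers. Written for the
## small point sets of a patch grid (hundreds of points), using the
## full O(n^2) distance matrix and DBSCAN-style cluster extraction at
## the max_eps threshold.

#' OPTICS clustering of 2-D points
#'
#' Computes the OPTICS reachability ordering (core distance = distance
#' to the `min_samples`-th nearest neighbor counting the point itself)
#' and extracts clusters by cutting reachability at `max_eps`,
#' equivalent to DBSCAN at that radius but with the OPTICS ordering.
#'
#' @param points numeric matrix with two columns (x, y).
#' @param min_samples minimum neighborhood size for a core point
#'   (default 5).
#' @param max_eps maximum reachability radius (default `Inf`).
#' @return list with `order` (visit order), `reachability` (aligned to
#'   `order`, `Inf` for cluster starts), `cluster` (integer labels per
#'   input point, 0 = noise).
#' @export
opticsCluster <- function(points, min_samples = 5L, max_eps = Inf) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(list(order = integer(), reachability = numeric(),
                           cluster = integer()))
  D <- as.matrix(stats::dist(points))
  core <- apply(D, 1, function(d) sort(d)[min(min_samples, n)])
  core[core > max_eps] <- Inf

  order_out <- integer(n)
  reach_out <- numeric(n)
  reach <- rep(Inf, n)
  processed <- logical(n)
  pos <- 0L
  for (start in seq_len(n)) {
    if (processed[start]) next
    # seed a new component with the unprocessed point of smallest index
    current <- start
    reach[current] <- Inf
    repeat {
      processed[current] <- TRUE
      pos <- pos + 1L
      order_out[pos] <- current
      reach_out[pos] <- reach[current]
      if (is.finite(core[current])) {
        nb <- which(!processed & D[current, ] <= max_eps)
        if (length(nb)) {
          newreach <- pmax(core[current], D[current, nb])
          upd <- newreach < reach[nb]
          reach[nb[upd]] <- newreach[upd]
        }
      }
      cand <- which(!processed & is.finite(reach))
      if (!length(cand)) break
      current <- cand[which.min(reach[cand])]
    }
  }

  cluster <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    p <- order_out[i]
    if (reach_out[i] > max_eps) {
      if (is.finite(core[p])) {
        cid <- cid + 1L
        cluster[p] <- cid
      } else cluster[p] <- 0L  # noise
    } else cluster[p] <- cid
  }
  list(order = order_out, reachability = reach_out, cluster = cluster)
}

#' Largest OPTICS cluster of ROI patches
#'
#' Clusters ROI patch centers with [opticsCluster()] and returns the
#' patch-table rows of the cluster containing the most patches. With
#' fewer ROI patches than `min_samples` every patch is kept as a single
#' cluster (with a warning).
#'
#' @param roi_patches data frame of ROI patches with `row`, `col`.
#' @param patch_size patch side length in pixels.
#' @param min_samples OPTICS core-point neighborhood size (default 5).
#' @param max_eps maximum reachability radius in pixels (default
#'   `3 * patch_size`).
#' @return logical vector marking the rows of `roi_patches` in the
#'   largest cluster.
#' @export
largestRoiCluster <- function(roi_patches, patch_size, min_samples = 5L,
                              max_eps = 3 * patch_size) {
  n <- nrow(roi_patches)
  if (n < min_samples) {
    warning(sprintf(
      "only %d ROI patch(es) with min_samples=%d: keeping all as one cluster",
      n, min_samples))
    return(rep(TRUE, n))
  }
  ctr <- cbind((roi_patches$col + 0.5) * patch_size,
               (roi_patches$row + 0.5) * patch_size)
  cl <- opticsCluster(ctr, min_samples = min_samples, max_eps = max_eps)
  labs <- cl$cluster
  if (all(labs == 0L)) return(rep(TRUE, n))  # all noise: keep everything
  tab <- table(labs[labs > 0L])
  best <- as.integer(names(tab)[which.max(tab)])
  labs == best
}
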