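# Tiling and the three-class labeling rules.

test_that("tiling drops partial edge patches and indexes row-major", {
  g <- tileSlide(slideRecord("a", width_px = 1024, height_px = 768), 256)
  expect_identical(c(g@n_rows, g@n_cols), c(3L, 4L))
  expect_identical(nPatches(g), 12L)
  p <- patchTable(g)
  expect_identical(p$row[1:5], c(0L, 0L, 0L, 0L, 1L))  # row-major order
  g2 <- tileSlide(slideRecord("b", width_px = 1000, height_px = 1000), 256)
  expect_identical(nPatches(g2), 9L)
  g3 <- tileSlide(slideRecord("c", width_px = 256, height_px = 256), 256)
  expect_identical(nPatches(g3), 1L)
  expect_equal(unlist(patchTable(g3)[1, c("x0", "y0", "x1", "y1")]),
               c(x0 = 0, y0 = 0, x1 = 256, y1 = 256))
  expect_error(tileSlide(slideRecord("d", width_px = 200, height_px = 500),
                         256), "smaller")
})

test_that("patches partition the grid area", {
  g <- tileSlide(slideRecord("a", width_px = 1024, height_px = 768), 256)
  p <- patchTable(g)
  # pairwise disjoint (half-open boxes): identical corners never repeat
  expect_identical(anyDuplicated(p[, c("x0", "y0")]), 0L)
  expect_equal(sum((p$x1 - p$x0) * (p$y1 - p$y0)),
               g@n_rows * g@n_cols * 256^2)
})

pinkSlide <- function(id, w, h, label = "melanoma", regions = list()) {
  img <- solidPatch(c(0.85, 0.55, 0.65), 1)[1, 1, ]
  raster <- array(rep(img, each = h * w), c(h, w, 3))
  slideRecord(id, image = raster, slide_label = label, regions = regions)
}

tissueGrid <- function(slide, ps = 256) {
  g <- tileSlide(slide, ps)
  patchTissueFractions(g, slideRaster(slide))
}

test_that("labeling follows the partial-annotation rules", {
  # annotation covering the whole slide: every patch gets the slide label
  s <- pinkSlide("s", 1024, 768, "nevus",
                 list(rectRegion("all", 0, 0, 1023, 767)))
  lab <- labelPatches(tissueGrid(s), s)
  expect_true(all(patchTable(lab)$label == "nevus"))

  # no annotations, margin rule: nothing to anchor on, all unlabeled
  s2 <- pinkSlide("s2", 1024, 768, "melanoma")
  lab2 <- labelPatches(tissueGrid(s2), s2)
  expect_true(all(patchTable(lab2)$label == "unlabeled"))

  # unknown slide label is rejected for training-time labeling
  s3 <- pinkSlide("s3", 512, 512, "melanoma")
  s3@slide_label <- "unknown"
  expect_error(labelPatches(tissueGrid(s3), s3), "unknown")
})

test_that("rectangular annotation labels exactly the covered columns", {
  # 3x4 grid; annotation covers columns 0-1, explicit other-zone covers
  # the remaining area
  s <- pinkSlide("r", 1024, 768, "melanoma",
                 list(rectRegion("roi", 0, 0, 512, 767)))
  lab <- labelPatches(tissueGrid(s), s,
                      other_zone = list(mode = "polygons",
                                        polygons = list(
                                          rectRegion("oz", 513, 0, 1023, 767))))
  tab <- table(patchTable(lab)$label)
  expect_identical(as.integer(tab[["melanoma"]]), 6L)
  expect_identical(as.integer(tab[["other"]]), 6L)
})

test_that("labeling is invariant to region order and monotone in size", {
  set.seed(21)
  for (rep in 1:10) {
    regs <- list(randomStar("a", 300, 300, 150),
                 randomStar("b", 700, 450, 180))
    s <- pinkSlide("m", 1024, 768, "melanoma", regs)
    g <- tissueGrid(s)
    l1 <- patchTable(labelPatches(g, s))$label
    s_rev <- pinkSlide("m", 1024, 768, "melanoma", rev(regs))
    l2 <- patchTable(labelPatches(g, s_rev))$label
    expect_identical(l1, l2)

    # shrink both polygons toward their centroids: never more tumor patches
    shrink <- lapply(regs, function(r) {
      v <- vertices(r)
      c0 <- colMeans(v)
      annotationRegion(r@region_id,
                       sweep(sweep(v, 2, c0) * 0.7, 2, c0, `+`))
    })
    s_small <- pinkSlide("m", 1024, 768, "melanoma", shrink)
    l3 <- patchTable(labelPatches(g, s_small))$label
    expect_lte(sum(l3 == "melanoma"), sum(l1 == "melanoma"))
  }
})

test_that("patch pixel extraction is an exact crop", {
  const <- pinkSlide("c", 512, 512)
  p <- list(x0 = 256, y0 = 0, x1 = 512, y1 = 256)
  crop <- extractPatchPixels(const, p)
  expect_identical(dim(crop), c(256L, 256L, 3L))
  expect_equal(length(unique(as.vector(crop))), 3L)  # constant per channel

  # checkerboard with 256 px squares: every patch is uniform
  h <- 512L; w <- 768L
  board <- array(0, c(h, w, 3))
  for (ch in 1:3)
    board[, , ch] <- outer(seq_len(h) - 1L, seq_len(w) - 1L,
                           function(i, j) ((i %/% 256) + (j %/% 256)) %% 2)
  bs <- slideRecord("b", image = board, slide_label = "melanoma")
  g <- tileSlide(bs, 256)
  for (i in seq_len(nPatches(g))) {
    px <- extractPatchPixels(bs, patchTable(g)[i, ])
    expect_length(unique(as.vector(px)), 1L)
  }
  # crop then re-insert leaves the slide unchanged
  patch <- extractPatchPixels(bs, patchTable(g)[2, ])
  board2 <- board
  board2[1:256, 257:512, ] <- patch
  expect_identical(board2, board)
  expect_error(extractPatchPixels(bs, c(600, 0, 856, 256)), "outside")
})

test_that("block tissue fractions agree with the per-patch computation", {
  set.seed(14)
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  s <- slideRecord("t", image = img, slide_label = "nevus")
  g <- patchTissueFractions(tileSlide(s, 256), img)
  p <- patchTable(g)
  for (i in seq_len(nrow(p)))
    expect_equal(p$tissue_fraction[i],
                 tissueFraction(extractPatchPixels(img, p[i, ])))
})

test_that("patch manifests round-trip through the TSV format", {
  s <- pinkSlide("m1", 512, 512, "melanoma",
                 list(rectRegion("r", 0, 0, 511, 511)))
  lab <- labelPatches(tissueGrid(s), s)
  path <- tempfile(fileext = ".tsv")
  writePatchManifest(lab, path)
  back <- read.delim(path)
  expect_identical(nrow(back), nPatches(lab))
  expect_identical(back$label, patchTable(lab)$label)
  expect_identical(back$slide_id, rep("m1", nPatches(lab)))
})
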