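## Internal helpers: local RNG scoping, deterministic per-key hashing,
## raster checks and block statistics.

# Run code under a temporary RNG state; the caller's stream is untouched.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic uniform in [0,1) from a string key and an integer salt.
# Order-invariant per-patch randomness (oracle flips) relies on this.
hashUnit <- function(key, salt = 0L) {
  m <- 2147483647
  vapply(key, function(k) {
    h <- (as.numeric(salt) %% m + 17) %% m
    for (b in utf8ToInt(k)) h <- (h * 131 + b) %% m
    # one extra scramble round to decorrelate similar keys
    h <- (h * 48271) %% m
    h / m
  }, numeric(1), USE.NAMES = FALSE)
}

checkRaster <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop(sprintf("%s must be an h x w x 3 RGB array", what))
  if (dim(img)[1] == 0L || dim(img)[2] == 0L)
    stop(sprintf("%s is empty", what))
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Sum of each patch_size x patch_size block of a matrix, for the first
# n_rows*patch_size rows and n_cols*patch_size columns. Returns an
# n_rows x n_cols matrix.
blockSums <- function(m, patch_size, n_rows, n_cols) {
  m <- m[seq_len(n_rows * patch_size), seq_len(n_cols * patch_size), drop = FALSE]
  a <- array(m, c(patch_size, n_rows, patch_size * n_cols))
  s <- colSums(a)                                   # n_rows x (ps*n_cols)
  a2 <- array(t(s), c(patch_size, n_cols, n_rows))  # sum over column blocks
  t(colSums(a2))                                    # n_rows x n_cols
}

# HSV channels of a raster as a list of h x w matrices.
rasterHSV <- function(img) {
  d <- dim(img)
  hsv <- grDevices::rgb2hsv(r = as.vector(img[, , 1]),
                            g = as.vector(img[, , 2]),
                            b = as.vector(img[, , 3]), maxColorValue = 1)
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# Round half away from zero (base round() is banker's rounding).
roundHalfUp <- function(x) floor(x + 0.5)
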