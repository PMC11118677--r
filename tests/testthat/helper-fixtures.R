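# Shared fixtures: tiny rasters built in code, and memoised synthetic
# cohorts (generated once per test run, reused across files).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# solid-color raster with optional Gaussian noise
solidPatch <- function(color, n = 32L, noise = 0, seed = NULL) {
  img <- array(rep(color, each = n * n), c(n, n, 3))
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- pmin(pmax(img + array(rnorm(n * n * 3, sd = noise),
                                 c(n, n, 3)), 0), 1)
  }
  img
}

# square annotation region [x0,x1] x [y0,y1]
rectRegion <- function(id, x0, y0, x1, y1) {
  annotationRegion(id, cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}

# random simple (star-shaped) polygon around a center
randomStar <- function(id, cx, cy, r, n = 10L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  k <- runif(n, 0.7, 1.3)
  annotationRegion(id, cbind(cx + r * k * cos(th), cy + r * k * sin(th)))
}

# small-slide cohort for structural synthetic-data tests (fast)
smallCohortSpec <- function(seed = 11L, n_slides = 20L,
                            annotation_coverage = 0.6)
  cohortSpec(n_slides = n_slides, slide_width = 1536L, slide_height = 1280L,
             tumor_radius_range = c(160, 220),
             annotation_coverage = annotation_coverage, seed = seed)

smallCohort <- function() memo("small_cohort", {
  dir <- file.path(tempdir(), "patchroi-small-cohort")
  generateCohort(smallCohortSpec(), dir = dir)
})

# the default desk-scale cohort shared by the end-to-end tests
defaultCohort <- function() memo("default_cohort", {
  dir <- file.path(tempdir(), "patchroi-default-cohort")
  generateCohort(cohortSpec(seed = 42L), dir = dir)
})

defaultSplit <- function() memo("default_split",
  trainTestSplit(defaultCohort(), 0.8, seed = 42L))

# patch identities + ground truth for all extracted patches of the
# default cohort (no features; used with the oracle classifier)
defaultCohortTestData <- function() memo("default_td",
  cohortTestData(defaultCohort(), pipelineConfig(seed = 42L),
                 features = FALSE))

# training features for the full default training set
defaultTrainData <- function() memo("default_train",
  cohortTrainingData(defaultSplit()$train, pipelineConfig(seed = 42L)))

# test features for the default test set
defaultTestData <- function() memo("default_test",
  cohortTestData(defaultSplit()$test, pipelineConfig(seed = 42L)))
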