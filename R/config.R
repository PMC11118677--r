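## Pipeline configuration: a nested list of every tunable, round-tripped
## losslessly through YAML. Every run logs the fully resolved
## configuration next to its artifacts.

#' Default pipeline configuration
#'
#' Returns the fully resolved configuration for the end-to-end
#' pipeline. Any subset of keys can be overridden via `...` (named
#' nested lists) or a YAML file ([readPipelineConfig()]).
#'
#' @param seed master seed; stage seeds derive from it.
#' @param out_dir pipeline output directory.
#' @return nested named list.
#' @export
pipelineConfig <- function(seed = 1L, out_dir = "patchroi-run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synth = list(n_slides = 20L, slide_width = 3072L, slide_height = 2304L,
                 annotation_coverage = 0.6),
    patch = list(size = 256L),
    tissue = list(s_min = 0.05, v_max = 0.95, min_fraction = 0.25),
    other_zone = list(mode = "margin", margin = 512),
    # colornorm$reference (a slide id) may be added for the reinhard
    # method; it defaults to the first training slide when absent
    colornorm = list(method = "whitepoint"),
    augment = list(pad = 8L, flip_p = 0.5, n_aug = 2L),
    train = list(epochs = 10L, batch_size = 32L, learning_rate = 0.05,
                 momentum = 0.9, hidden = 16L),
    split = list(train_fraction = 0.8),
    optics = list(min_samples = 5L, max_eps_factor = 3))
}

mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]]))
      base[[k]] <- mergeConfig(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of the configuration; values missing from the file
#' fall back to [pipelineConfig()] defaults.
#'
#' @param path YAML file path.
#' @param config configuration list to write.
#' @return `readPipelineConfig` returns the merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  mergeConfig(pipelineConfig(), yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
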