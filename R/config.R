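#' Pipeline configuration
#'
#' Every tunable of the CAD pipeline in one validated object. Defaults are
#' the pipeline's reference operating point: sigmoid `alpha = 400`,
#' `beta = 600`; skull growing from 30% of the maximum intensity; radius-10
#' VOI dilation; likelihood binarized strictly above 0.5; the strict >30%
#' overlap rule; 128-voxel blocks; batch size 1 and Adam at learning rate
#' 5e-4. Unknown keys are rejected.
#'
#' @param ... key = value overrides of the defaults listed below.
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # preprocessing
    bias_iterations = 50L, bias_levels = 3L,
    sigmoid_alpha = 400, sigmoid_beta = 600,
    # step one
    skull_lower_fraction = 0.30, skull_smooth_radius = 2,
    n_seed_components = 5L, connectivity = 26L, voi_radius = 10,
    # augmentation
    augment = TRUE, augment_variance = 4.0, augment_max_kernel_width = 32L,
    intensity_filter = "equalize",
    # network / training
    block_size = 128L, depth = 4L, base_filters = 16L,
    deep_supervision_levels = NA_integer_,
    batch_size = 1L, learning_rate = 5e-4, max_epochs = 200L,
    early_stop_patience = 10L,
    # detection / evaluation
    likelihood_threshold = 0.5, min_component_size = 5L,
    overlap_rule = 0.30,
    # phantom cohorts (run-all)
    phantom_size = 64L, n_train = 20L, n_test = 8L,
    seed = 1L)
  ov <- list(...)
  if (length(ov) == 1 && is.list(ov[[1]]) && is.null(names(ov)))
    ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, ov)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop(sprintf("invalid config value for `%s`: %s", key, what),
                  call. = FALSE)
  }
  chk(cfg$sigmoid_alpha > 0, "sigmoid_alpha", "must be > 0")
  chk(cfg$skull_lower_fraction > 0 && cfg$skull_lower_fraction <= 1,
      "skull_lower_fraction", "must be in (0, 1]")
  chk(cfg$voi_radius >= 0, "voi_radius", "must be >= 0")
  chk(cfg$skull_smooth_radius >= 0, "skull_smooth_radius", "must be >= 0")
  chk(cfg$connectivity %in% c(6, 18, 26), "connectivity", "must be 6/18/26")
  chk(cfg$likelihood_threshold >= 0 && cfg$likelihood_threshold <= 1,
      "likelihood_threshold", "must be in [0, 1]")
  chk(cfg$overlap_rule >= 0 && cfg$overlap_rule < 1, "overlap_rule",
      "must be in [0, 1)")
  chk(cfg$learning_rate > 0, "learning_rate", "must be > 0")
  chk(cfg$block_size >= 8, "block_size", "must be >= 8")
  chk(cfg$min_component_size >= 1, "min_component_size", "must be >= 1")
  chk(cfg$augment_variance >= 0, "augment_variance", "must be >= 0")
  chk(cfg$n_seed_components >= 1, "n_seed_components", "must be >= 1")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path YAML file of key: value overrides.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k,
                                  paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}

#' Network configuration implied by a pipeline configuration
#'
#' @param cfg a [pipeline_config()].
#' @return A [network_config()].
#' @export
net_config_from <- function(cfg) {
  ds <- cfg$deep_supervision_levels
  network_config(input_size = cfg$block_size, depth = cfg$depth,
                 base_filters = cfg$base_filters,
                 deep_supervision_levels = if (is.na(ds)) NULL else ds)
}
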