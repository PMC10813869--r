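# Run configuration: one YAML file (or defaults) fanned out to the module
# constructors, validated before any work starts.

#' Default run configuration
#'
#' Returns the default configuration tree used by the command-line entry
#' points: a small CPU-sized phantom cohort and network (patch side 32),
#' standard LSGAN Adam settings, and the default loss weights and SSIM
#' parameters. Every field can be overridden from a YAML file via
#' [read_run_config()].
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    phantom = list(width_n = 64L, side_p = 32L, n_teeth = 6L,
                   vertical_offset_mm = 2, noise_sd = 0.05),
    counts = list(buccal_mesial = 2L, middle_mesial = 1L, lingual_mesial = 1L,
                  control = 1L),
    network = list(patch_side = 32L, base_channels = 8L, n_levels = 2L),
    training = list(learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                    steps = 200L, batch_size = 1L, d_updates_per_g = 1L,
                    patch_stride = NULL),
    weights = list(lambda1 = 0.1, lambda2 = 10, lambda3 = 10),
    evaluation = list(window = 7L, data_range = 2, K1 = 0.01, K2 = 0.03,
                      roi_dilate = 2L),
    reconstruction = list(stride = NULL),
    cv = list(k = 15L)
  )
}

#' Read and validate a run configuration
#'
#' Merges a YAML configuration file over [default_run_config()] and
#' validates every section against the owning module's constructor
#' (phantom spec, network config, training config, loss weights) before
#' any work starts. A `--seed`-style override replaces the master seed.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param seed Optional master seed override.
#' @return Validated configuration list with an attached `objects` element
#'   holding the constructed configs.
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("read_run_config: no such file: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Configuration list to validate.
#' @export
validate_run_config <- function(cfg) {
  phantom_defaults <- do.call(phantom_spec, c(cfg$phantom, list(seed = cfg$seed)))
  net <- do.call(generator_config, c(cfg$network, list(seed = derive_seed(cfg$seed, 1L))))
  weights <- do.call(loss_weights, cfg$weights)
  training <- do.call(train_config,
                      c(cfg$training,
                        list(weights = weights, seed = derive_seed(cfg$seed, 2L))))
  if (phantom_defaults$side_p != net$patch_side) {
    stop("config: phantom side_p must equal network patch_side", call. = FALSE)
  }
  counts <- unlist(cfg$counts)
  if (any(counts < 0)) stop("config: counts must be >= 0", call. = FALSE)
  cfg$objects <- list(phantom_defaults = phantom_defaults, net = net,
                      weights = weights, training = training)
  cfg
}
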