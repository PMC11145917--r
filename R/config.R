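#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their documented defaults.
#' Units: micrometres for lengths, cubic micrometres for volumes.
#'
#' @return nested named list (class `pipeline_config`).
#' @export
default_config <- function() {
  structure(list(
    tile = list(
      core_shape = c(48L, 48L, 48L),   # core tile; with halo 8 the model input is 64^3
      halo = 8L
    ),
    volume = list(
      voxel_size = c(3.5, 1, 1)        # (dz, dy, dx) um
    ),
    mask_generation = list(
      k_thresh = 3,                    # threshold = mean + k * SD
      spot_radius_um = 3,              # rendered spot ellipsoid radius
      min_separation_um = 8            # peak non-maximum suppression distance
    ),
    model = list(
      in_channels = 1L,
      num_classes = 2L,
      embed_dim = 32L,
      token_patch = c(2L, 2L, 2L),
      window = c(4L, 4L, 4L),
      depths = c(2L, 2L, 6L, 2L),
      heads = NULL,                    # NULL = stage_dim / 16, at least 1
      dilation_rates = c(1L, 2L, 3L),
      conv_channels = 4L,              # channels per dilated branch
      fused_channels = 8L,
      mlp_ratio = 4,
      dropout = 0,
      hybrid = TRUE                    # FALSE = ablated variant without conv front-end
    ),
    train = list(
      patch_shape = c(32L, 32L, 32L),  # training patch size (divisibility contract)
      epochs = 20L,
      lr = 1e-4,
      batch_size = 8L,
      val_frac = 0.2,
      weight_decay = 0.01
    ),
    filters = list(
      af_overlap_frac = 0.5,           # autofluorescence overlap fraction theta
      soma_volume_um3_min = 50,
      soma_volume_um3_max = 5000,
      intensity_k = 3
    ),
    stats = list(
      fc_cut = 1.4,
      q_cut = 0.05,
      cv_ddof = 1L,
      epsilon = 0.5,                   # pseudo-count guarding zero-mean fold changes
      zscore_baseline = "pooled",      # or "control"
      welch = FALSE
    ),
    phantom = list(
      shape = c(64L, 128L, 128L),
      n_cells = 80L,
      cell_radius_um = c(2, 4),
      cell_peak_intensity = c(300, 600),
      background_level = 100,
      noise_sd = 5,
      n_vessels = 4L,
      vessel_radius_um = 3,
      vessel_intensity = 300,
      autofl_bleed_frac = 0.6
    ),
    atlas = list(
      n_superregions = 2L,
      n_children_per = 2L,
      with_layers = FALSE,
      n_layers = 3L
    ),
    groups = list(
      names = c("ctrl", "stress"),
      n_per_group = 6L,
      baseline_mean = 100,
      effect_factor = 2,
      effect_frac = 0.2,
      sigma = 0.25
    ),
    seeds = list(global = 1L)
  ), class = "pipeline_config")
}

config_ranges <- function() {
  list(
    "tile.halo" = c(0, Inf),
    "mask_generation.k_thresh" = c(0, Inf),
    "mask_generation.spot_radius_um" = c(1e-6, Inf),
    "mask_generation.min_separation_um" = c(1e-6, Inf),
    "model.mlp_ratio" = c(1, 16),
    "model.dropout" = c(0, 1),
    "train.lr" = c(1e-8, 1),
    "train.val_frac" = c(0, 0.9),
    "filters.af_overlap_frac" = c(1e-9, 1),
    "filters.soma_volume_um3_min" = c(1e-9, Inf),
    "filters.intensity_k" = c(0, Inf),
    "stats.fc_cut" = c(0, Inf),
    "stats.q_cut" = c(0, 1),
    "stats.epsilon" = c(1e-12, Inf),
    "phantom.autofl_bleed_frac" = c(0, 1),
    "phantom.noise_sd" = c(0, Inf),
    "groups.sigma" = c(0, Inf)
  )
}

merge_config <- function(base, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.null(user[[key]])) next   # explicit null = keep the default
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) stop("config key ", full, " must be a mapping")
      base[[key]] <- merge_config(base[[key]], user[[key]], c(path, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks every documented numeric range plus structural constraints
#' (4 encoder stages, divisible token patch, positive shapes).
#'
#' @param cfg a config list as returned by [default_config()] / [load_config()].
#' @return `cfg`, invisibly, or an error naming the offending key.
#' @export
validate_config <- function(cfg) {
  for (key in names(config_ranges())) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    rng <- config_ranges()[[key]]
    if (!is.null(val) && (any(!is.finite(val)) || any(val < rng[1]) || any(val > rng[2])))
      stop("config value out of range: ", key, " must lie in [",
           rng[1], ", ", rng[2], "]")
  }
  if (length(cfg$model$depths) != 4L || any(cfg$model$depths < 1L))
    stop("config value out of range: model.depths must be 4 positive integers")
  if (any(cfg$tile$core_shape < 1L))
    stop("config value out of range: tile.core_shape")
  if (cfg$filters$soma_volume_um3_min >= cfg$filters$soma_volume_um3_max)
    stop("config value out of range: soma volume bounds must satisfy min < max")
  if (!cfg$stats$zscore_baseline %in% c("pooled", "control"))
    stop("config value out of range: stats.zscore_baseline")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Absent keys take the documented defaults; unknown keys are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file. An empty document yields the
#'   full default configuration.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  cfg <- normalize_config_types(cfg)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

normalize_config_types <- function(cfg) {
  ints <- list(c("tile", "core_shape"), c("tile", "halo"),
               c("model", "depths"), c("model", "token_patch"),
               c("model", "window"), c("model", "embed_dim"),
               c("train", "epochs"), c("train", "batch_size"),
               c("phantom", "shape"), c("phantom", "n_cells"),
               c("phantom", "n_vessels"), c("groups", "n_per_group"))
  for (p in ints) {
    v <- cfg[[p[1]]][[p[2]]]
    if (!is.null(v)) cfg[[p[1]]][[p[2]]] <- as.integer(v)
  }
  cfg
}

#' Save a configuration to YAML or JSON
#'
#' @param cfg a `pipeline_config`.
#' @param path output path; format chosen by extension.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
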