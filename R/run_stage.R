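#' Run one pipeline stage in a workspace
#'
#' Stages communicate through fixed workspace subdirectories:
#' \describe{
#'   \item{simulate}{`raw/` dual-channel phantom TIFFs, `truth/` ground
#'     truth, `atlas/` toy annotation + ontology, `counts/group_counts.csv`
#'     synthetic cohort table.}
#'   \item{make-masks}{`trainset/` spot-mask training patches + index CSV.}
#'   \item{train}{`model/checkpoint.rds`, `model/metrics.csv`.}
#'   \item{predict}{`pred/mask_signal.tif`, `pred/mask_autofl.tif`.}
#'   \item{postprocess}{`cells/cells.csv`, `cells/filter_report.json`.}
#'   \item{quantify}{`quant/region_counts.csv`, `quant/hemisphere_counts.csv`.}
#'   \item{stats}{`stats/region_stats.csv`, `stats/zscores.csv`,
#'     `stats/correlation.csv`.}
#' }
#' Each stage writes a JSON report (`reports/<stage>.json`) with input and
#' output hashes and timing. Missing prerequisite artifacts are an error
#' naming the missing file. With fixed seeds every stage is reproducible.
#'
#' @param stage one of `simulate`, `make-masks`, `train`, `predict`,
#'   `postprocess`, `quantify`, `stats`.
#' @param config a `pipeline_config` (see [default_config()]).
#' @param workspace workspace directory (created if absent).
#' @param verbose log progress to stderr.
#' @return the stage report, invisibly.
#' @export
run_stage <- function(stage, config = default_config(), workspace,
                      verbose = FALSE) {
  stages <- c("simulate", "make-masks", "train", "predict", "postprocess",
              "quantify", "stats")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; expected one of ",
         paste(stages, collapse = ", "))
  validate_config(config)
  dir.create(workspace, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(...) if (verbose) message("[", stage, "] ", ...)
  t0 <- Sys.time()
  fn <- switch(stage,
               "simulate" = stage_simulate, "make-masks" = stage_make_masks,
               "train" = stage_train, "predict" = stage_predict,
               "postprocess" = stage_postprocess, "quantify" = stage_quantify,
               "stats" = stage_stats)
  io <- fn(config, workspace, log_)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report <- list(stage = stage, elapsed_s = elapsed,
                 inputs = hash_files(io$inputs), outputs = hash_files(io$outputs))
  dir.create(file.path(workspace, "reports"), showWarnings = FALSE)
  jsonlite::write_json(report,
                       file.path(workspace, "reports", paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

hash_files <- function(paths) {
  if (length(paths) == 0) return(structure(list(), names = character(0)))
  as.list(tools::md5sum(paths))
}

ws_path <- function(workspace, ...) file.path(workspace, ...)

require_artifact <- function(path, what) {
  if (!file.exists(path)) stop(what, " not found: ", path)
  path
}

model_config_from <- function(config) {
  m <- config$model
  hswin3d_config(embed_dim = m$embed_dim, token_patch = m$token_patch,
                 window = m$window, depths = m$depths, heads = m$heads,
                 dilation_rates = m$dilation_rates,
                 conv_channels = m$conv_channels,
                 fused_channels = m$fused_channels, mlp_ratio = m$mlp_ratio,
                 dropout = m$dropout, num_classes = m$num_classes,
                 in_channels = m$in_channels, hybrid = m$hybrid,
                 seed = config$seeds$global)
}

stage_simulate <- function(config, workspace, log_) {
  for (d in c("raw", "truth", "atlas", "counts"))
    dir.create(ws_path(workspace, d), showWarnings = FALSE)
  ph <- config$phantom
  spec <- phantom_spec(shape = ph$shape, voxel_size = config$volume$voxel_size,
                       n_cells = ph$n_cells, cell_radius_um = ph$cell_radius_um,
                       cell_peak_intensity = ph$cell_peak_intensity,
                       background_level = ph$background_level,
                       noise_sd = ph$noise_sd, n_vessels = ph$n_vessels,
                       vessel_radius_um = ph$vessel_radius_um,
                       vessel_intensity = ph$vessel_intensity,
                       autofl_bleed_frac = ph$autofl_bleed_frac,
                       seed = config$seeds$global)
  log_("generating phantom ", paste(ph$shape, collapse = "x"))
  sample <- generate_phantom(spec)
  write_volume(sample$signal, ws_path(workspace, "raw", "signal.tif"))
  write_volume(sample$autofl, ws_path(workspace, "raw", "autofl.tif"))
  write_volume(sample$truth_vessel_mask,
               ws_path(workspace, "truth", "vessel_mask.tif"))
  utils::write.csv(sample$truth_cells,
                   ws_path(workspace, "truth", "cells.csv"), row.names = FALSE)
  # toy atlas on the same grid as the phantom (identity-aligned for the demo)
  at <- config$atlas
  atlas <- generate_toy_atlas(shape = ph$shape,
                              n_superregions = at$n_superregions,
                              n_children_per = at$n_children_per,
                              with_layers = at$with_layers,
                              n_layers = at$n_layers,
                              voxel_size = config$volume$voxel_size,
                              seed = config$seeds$global)
  write_atlas(atlas, ws_path(workspace, "atlas", "annotation.tif"),
              ws_path(workspace, "atlas", "ontology.json"))
  # synthetic cohort counts over the atlas leaves for the statistics stage
  gr <- config$groups
  leaves <- sort(setdiff(unique(as.vector(atlas$annotation)), 0L))
  n_eff <- max(1L, round(gr$effect_frac * length(leaves)))
  effects <- stats::setNames(rep(gr$effect_factor, n_eff),
                             as.character(leaves[seq_len(n_eff)]))
  design <- group_design(groups = gr$names, n_per_group = gr$n_per_group,
                         regions = leaves, baseline_mean = gr$baseline_mean,
                         effects = stats::setNames(
                           rep(list(effects), length(gr$names) - 1L),
                           gr$names[-1]),
                         sigma = gr$sigma, seed = config$seeds$global + 1L)
  cohort <- generate_group_counts(design)
  utils::write.csv(cohort, ws_path(workspace, "counts", "group_counts.csv"),
                   row.names = FALSE)
  list(inputs = character(0),
       outputs = c(ws_path(workspace, "raw", c("signal.tif", "autofl.tif")),
                   ws_path(workspace, "truth", c("cells.csv", "vessel_mask.tif")),
                   ws_path(workspace, "atlas", c("annotation.tif", "ontology.json")),
                   ws_path(workspace, "counts", "group_counts.csv")))
}

stage_make_masks <- function(config, workspace, log_) {
  sig_path <- require_artifact(ws_path(workspace, "raw", "signal.tif"),
                               "raw signal volume")
  dir.create(ws_path(workspace, "trainset"), showWarnings = FALSE)
  vol <- read_volume(sig_path, "signal", config$volume$voxel_size)
  ts <- build_training_set(list(vol), config,
                           core_shape = config$train$patch_shape)
  log_(length(ts$pairs), " training pairs, positive fraction ",
       signif(ts$positive_fraction, 3))
  saveRDS(ts$pairs, ws_path(workspace, "trainset", "pairs.rds"))
  utils::write.csv(ts$index, ws_path(workspace, "trainset", "index.csv"),
                   row.names = FALSE)
  list(inputs = sig_path,
       outputs = ws_path(workspace, "trainset", c("pairs.rds", "index.csv")))
}

stage_train <- function(config, workspace, log_) {
  pairs_path <- require_artifact(ws_path(workspace, "trainset", "pairs.rds"),
                                 "training set")
  dir.create(ws_path(workspace, "model"), showWarnings = FALSE)
  pairs <- readRDS(pairs_path)
  model <- build_model(model_config_from(config))
  tr <- config$train
  rep_ <- train_model(model, pairs, epochs = tr$epochs, lr = tr$lr,
                      batch_size = tr$batch_size, val_frac = tr$val_frac,
                      seed = config$seeds$global, weight_decay = tr$weight_decay,
                      verbose = FALSE)
  log_("best val Dice ", signif(rep_$best_val_dice, 4))
  save_checkpoint(model, ws_path(workspace, "model", "checkpoint.rds"))
  utils::write.csv(rep_$history, ws_path(workspace, "model", "metrics.csv"),
                   row.names = FALSE)
  list(inputs = pairs_path,
       outputs = ws_path(workspace, "model", c("checkpoint.rds", "metrics.csv")))
}

stage_predict <- function(config, workspace, log_) {
  ck_path <- require_artifact(ws_path(workspace, "model", "checkpoint.rds"),
                              "model checkpoint")
  sig_path <- require_artifact(ws_path(workspace, "raw", "signal.tif"),
                               "raw signal volume")
  af_path <- require_artifact(ws_path(workspace, "raw", "autofl.tif"),
                              "raw autofluorescence volume")
  dir.create(ws_path(workspace, "pred"), showWarnings = FALSE)
  model <- load_checkpoint(ck_path)
  vs <- config$volume$voxel_size
  # one single-channel model applied independently to both channels
  for (ch in c("signal", "autofl")) {
    vol <- read_volume(if (ch == "signal") sig_path else af_path,
                       ifelse(ch == "signal", "signal", "autofluorescence"), vs)
    # oversized cores fall back to a single reflect-padded tile per axis,
    # so the model input stays at core + 2*halo and meets the divisibility
    # contract even for thin volumes
    mask <- segment_volume(model, vol, config$tile$core_shape,
                           config$tile$halo)
    write_volume(mask, ws_path(workspace, "pred", paste0("mask_", ch, ".tif")))
    log_("segmented ", ch, ": ", sum(mask$data), " positive voxels")
  }
  list(inputs = c(ck_path, sig_path, af_path),
       outputs = ws_path(workspace, "pred",
                         c("mask_signal.tif", "mask_autofl.tif")))
}

stage_postprocess <- function(config, workspace, log_) {
  m_sig <- require_artifact(ws_path(workspace, "pred", "mask_signal.tif"),
                            "signal mask")
  m_af <- require_artifact(ws_path(workspace, "pred", "mask_autofl.tif"),
                           "autofluorescence mask")
  sig_path <- require_artifact(ws_path(workspace, "raw", "signal.tif"),
                               "raw signal volume")
  dir.create(ws_path(workspace, "cells"), showWarnings = FALSE)
  vs <- config$volume$voxel_size
  raw <- read_volume(sig_path, "signal", vs)
  cfos <- mask_volume(read_volume(m_sig, voxel_size = vs)$data, vs)
  af <- mask_volume(read_volume(m_af, voxel_size = vs)$data, vs)
  fc <- apply_filter_chain(cfos, af, raw, config)
  cells <- extract_cells(fc$mask, raw)
  log_(nrow(cells), " cells after filtering (",
       fc$report$components_before, " components before)")
  utils::write.csv(cells, ws_path(workspace, "cells", "cells.csv"),
                   row.names = FALSE)
  rep_ <- fc$report
  rep_$details <- lapply(rep_$details, function(d) d)
  jsonlite::write_json(unclass(rep_),
                       ws_path(workspace, "cells", "filter_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  list(inputs = c(m_sig, m_af, sig_path),
       outputs = ws_path(workspace, "cells",
                         c("cells.csv", "filter_report.json")))
}

stage_quantify <- function(config, workspace, log_) {
  cells_path <- require_artifact(ws_path(workspace, "cells", "cells.csv"),
                                 "cell table")
  ann_path <- require_artifact(ws_path(workspace, "atlas", "annotation.tif"),
                               "atlas annotation")
  ont_path <- require_artifact(ws_path(workspace, "atlas", "ontology.json"),
                               "atlas ontology")
  dir.create(ws_path(workspace, "quant"), showWarnings = FALSE)
  cells <- utils::read.csv(cells_path)
  atlas <- read_atlas(ann_path, ont_path)
  # identity-aligned demo atlas: um -> atlas voxel is a pure scaling
  T <- make_affine(scale = 1 / atlas$voxel_size)
  cells <- map_cells_to_atlas(cells, T, atlas)
  level <- max(atlas$ontology$level[is.na(atlas$ontology$layer)])
  counts <- counts_by_level(cells, atlas, level)
  hemi <- hemisphere_counts(cells, atlas, level)
  utils::write.csv(counts, ws_path(workspace, "quant", "region_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(hemi, ws_path(workspace, "quant", "hemisphere_counts.csv"),
                   row.names = FALSE)
  log_(sum(counts$count), " cells assigned at level ", level)
  list(inputs = c(cells_path, ann_path, ont_path),
       outputs = ws_path(workspace, "quant",
                         c("region_counts.csv", "hemisphere_counts.csv")))
}

stage_stats <- function(config, workspace, log_) {
  counts_path <- require_artifact(ws_path(workspace, "counts",
                                          "group_counts.csv"),
                                  "cohort count table")
  dir.create(ws_path(workspace, "stats"), showWarnings = FALSE)
  cohort <- utils::read.csv(counts_path)
  st <- config$stats
  gs <- unique(cohort$group)
  stats_tab <- region_group_stats(cohort, gs[2], gs[1], fc_cut = st$fc_cut,
                                  q_cut = st$q_cut, epsilon = st$epsilon,
                                  welch = st$welch)
  mat <- stats::xtabs(count ~ animal + region, data = cohort)
  z <- relative_zscore(as.matrix(mat), baseline = st$zscore_baseline,
                       control_rows = which(rownames(mat) %in%
                                              cohort$animal[cohort$group == gs[1]]))
  cm <- correlation_map(as.matrix(mat)[rownames(mat) %in%
                                         cohort$animal[cohort$group == gs[2]], ,
                                       drop = FALSE])
  utils::write.csv(stats_tab, ws_path(workspace, "stats", "region_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(as.matrix(z)),
                   ws_path(workspace, "stats", "zscores.csv"))
  utils::write.csv(as.data.frame(cm$rho),
                   ws_path(workspace, "stats", "correlation.csv"))
  log_(sum(stats_tab$significance_class != "ns"), " significant regions")
  list(inputs = counts_path,
       outputs = ws_path(workspace, "stats",
                         c("region_stats.csv", "zscores.csv", "correlation.csv")))
}

#' Run the full pipeline end to end
#'
#' Convenience wrapper executing all seven stages in order.
#'
#' @inheritParams run_stage
#' @return named list of stage reports.
#' @export
run_pipeline <- function(config = default_config(), workspace,
                         verbose = FALSE) {
  stages <- c("simulate", "make-masks", "train", "predict", "postprocess",
              "quantify", "stats")
  reports <- lapply(stages, run_stage, config = config,
                    workspace = workspace, verbose = verbose)
  names(reports) <- stages
  invisible(reports)
}
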