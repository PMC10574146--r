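#' Desk-scale run configuration
#'
#' Reads the versioned toy configuration shipped with the package and
#' builds the parameter objects for a full pipeline run: scene simulator,
#' season shift, network spec, training, probe, and sweep grids. All
#' stage seeds derive from the single `seed` argument.
#'
#' @param seed Global seed.
#' @param path Optional path to an alternative YAML configuration.
#' @return An `mtpi_config` list.
#' @export
mtpi_toy_config <- function(seed = 1L, path = NULL) {
  path <- path %||% system.file("extdata", "config", "toy_default.yaml",
                                package = "mtpi")
  cfg <- yaml::read_yaml(path)
  seed <- as.integer(seed)
  sp <- scene_params(height = cfg$scene$size, width = cfg$scene$size,
                     class_mix = unlist(cfg$scene$class_mix),
                     blob_scale = cfg$scene$blob_scale,
                     seed = seed)
  shift <- season_shift(
    hue_shift = cfg$shift$hue_shift,
    brightness_gain = cfg$shift$brightness_gain,
    saturation_gain = cfg$shift$saturation_gain,
    texture_contrast_gain = cfg$shift$texture_contrast_gain,
    per_class_flags = unlist(cfg$shift$per_class_flags))
  spec <- net_spec(depth = cfg$net$depth,
                   channels = unlist(cfg$net$channels),
                   residual = cfg$net$residual,
                   input_size = cfg$scene$size,
                   seed = derive_seed(seed, 11L))
  pretrain <- train_config(
    max_iterations = cfg$train$pretrain_iterations,
    batch_size = cfg$train$batch_size,
    learning_rate = cfg$train$learning_rate,
    momentum = cfg$train$momentum,
    validation_cadence = cfg$train$validation_cadence,
    conv_tol = cfg$train$pretrain_conv_tol,
    conv_window = cfg$train$pretrain_conv_window,
    seed = derive_seed(seed, 12L))
  transfer <- train_config(
    max_iterations = cfg$train$transfer_iterations,
    batch_size = cfg$train$batch_size,
    learning_rate = cfg$train$learning_rate,
    momentum = cfg$train$momentum,
    validation_cadence = cfg$train$validation_cadence,
    conv_tol = cfg$train$transfer_conv_tol,
    conv_window = cfg$train$conv_window,
    seed = derive_seed(seed, 13L))
  probe <- probe_config(calibration_n = cfg$probe$calibration_n,
                        eval_n = cfg$probe$eval_n,
                        rule = cfg$probe$rule,
                        seed = derive_seed(seed, 14L))
  structure(
    list(seed = seed, scene = sp, shift = shift, spec = spec,
         n_source = cfg$scene$n_source, n_target = cfg$scene$n_target,
         pretrain = pretrain, transfer = transfer, probe = probe,
         nlevel = cfg$tpi$nlevel, tpi_form = cfg$tpi$form,
         tds_fractions = unlist(cfg$sweep$tds_fractions),
         sweep_seeds = cfg$sweep$n_seeds,
         sweep_conv_tol = cfg$sweep$conv_tol,
         sweep_max_iterations = cfg$sweep$max_iterations,
         raw = cfg),
    class = "mtpi_config"
  )
}

#' Pre-train a network on source-domain scenes
#'
#' Generates a source survey, splits it 4:1:1 into train/validation/test,
#' derives inverse-frequency class weights, trains the network, and
#' evaluates it on the held-out test split.
#'
#' @param config An [mtpi_toy_config()].
#' @return A list with `net`, `trace`, `splits`, `report` (test metrics),
#'   `tds_pre` (training-set size), and `ls_pre` (total parameters).
#' @export
run_pretrain <- function(config = mtpi_toy_config()) {
  survey <- generate_survey(config$scene, n_scenes = config$n_source,
                            seed = derive_seed(config$seed, 1L))
  splits <- split_dataset(survey, seed = derive_seed(config$seed, 2L))
  net <- build_net(config$spec)
  cfg <- config$pretrain
  cfg$class_weights <- class_weights(splits$train)
  fit <- train_net(net, splits$train, cfg,
                   val_scenes = utils::head(splits$validation$scene, 8L))
  report <- scenes_metric_report(fit$net, splits$test)
  list(net = fit$net, trace = fit$trace, splits = splits, report = report,
       tds_pre = nrow(splits$train),
       ls_pre = ls_at(layer_sizes(fit$net), 0L))
}

#' Generate the shifted target survey for a configuration
#'
#' @param config An [mtpi_toy_config()].
#' @param n_scenes Override for the number of target scenes.
#' @return A survey tibble in the target domain.
#' @export
target_survey <- function(config, n_scenes = config$n_target) {
  generate_survey(config$scene, n_scenes = n_scenes, shift = config$shift,
                  seed = derive_seed(config$seed, 3L))
}

#' Scan transfer points and solve the MTPI condition
#'
#' Computes a TPI curve per dataset, averages them, selects TP0 at the
#' maximum of the averaged curve, and applies the linear sample-size rule
#' to obtain TDS0.
#'
#' @param net A pre-trained `seg_net`.
#' @param surveys Named list of scene sets (e.g. source and target).
#' @param probe A [probe_config()].
#' @param nlevel Cost levels.
#' @param form Cost-level form, see [tpi_tp()].
#' @param tds_pre,ls_pre Pre-training bookkeeping for [tds_rule()].
#' @param available Transfer samples available for TDS0 capping.
#' @return A list with `curves`, `average`, `tp0`, and `condition`.
#' @export
run_scan <- function(net, surveys, probe = probe_config(), nlevel = 10L,
                     form = "fraction", tds_pre, ls_pre, available = Inf) {
  curves <- lapply(names(surveys), function(nm) {
    tpi_curve(net, surveys[[nm]], probe, nlevel, form, dataset = nm)
  })
  names(curves) <- names(surveys)
  avg <- if (length(curves) > 1L) average_curves(curves) else curves[[1L]]
  tp0 <- select_tp0(avg)
  cond <- tds_rule(ls_at(layer_sizes(net), tp0), tds_pre, ls_pre,
                   available = available, tp0 = tp0)
  list(curves = curves, average = avg, tp0 = tp0, condition = cond)
}

#' Transfer a pre-trained network under an MTPI condition
#'
#' Freezes layers 1..TP0, draws TDS0 transfer samples from the target
#' training split (seeded), retrains, and evaluates on target test scenes.
#'
#' @param net Pre-trained `seg_net`.
#' @param target_train Target-domain training scenes.
#' @param target_test Target-domain evaluation scenes.
#' @param condition An `mtpi_condition` (or a list with `tp0`, `tds0`).
#' @param config A [train_config()].
#' @param seed Seed for the transfer-sample draw.
#' @return A list with `net`, `trace`, `report`, `tds_used`, `tp_used`,
#'   `trainable`.
#' @export
run_transfer <- function(net, target_train, target_test, condition,
                         config = train_config(), seed = 1L) {
  scenes <- as_scene_list(target_train)
  tds <- min(condition$tds0, length(scenes))
  if (tds < condition$tds0) {
    warn("fewer target samples than TDS0; using all available.")
  }
  take <- with_seed(seed, sample.int(length(scenes), tds))
  frozen <- freeze(net, condition$tp0)
  fit <- train_net(frozen, scenes[take], config)
  report <- scenes_metric_report(fit$net, target_test)
  list(net = fit$net, trace = fit$trace, report = report,
       tds_used = tds, tp_used = condition$tp0,
       trainable = trainable_params(frozen))
}

#' Sweep transfer points and transfer dataset sizes
#'
#' The validation harness around a solved MTPI condition: retrains one
#' cell per (grid value, seed), recording iterations-to-convergence and
#' final target WKs. The TP sweep fixes TDS = TDS0; the TDS sweep fixes
#' TP = TP0.
#'
#' @param net Pre-trained `seg_net`.
#' @param target_train,target_test Target-domain scene sets.
#' @param condition An `mtpi_condition`.
#' @param config A [train_config()] for the cells.
#' @param tp_grid,tds_grid Grid values; defaults scale the full-scale
#'   protocol down around the condition.
#' @param seeds Seeds (one run per grid cell per seed).
#' @return A tibble with columns `sweep`, `tp`, `tds`, `seed`,
#'   `iterations`, `converged_at`, `wks`.
#' @export
run_sweep <- function(net, target_train, target_test, condition,
                      config = train_config(),
                      tp_grid = NULL, tds_grid = NULL, seeds = 1:3) {
  T <- length(net$convs)
  scenes <- as_scene_list(target_train)
  avail <- length(scenes)
  tp_grid <- tp_grid %||% sort(unique(pmax(pmin(
    c(condition$tp0, condition$tp0 - 1L, condition$tp0 + 1L, 0L, -1L), T),
    -1L)))
  tds_grid <- tds_grid %||% sort(unique(pmax(1L, pmin(avail, round(
    condition$tds0 * c(0.1, 0.25, 0.5, 1, 2))))))
  rows <- list()
  run_cell <- function(sweep, tp, tds, seed) {
    if (tds > avail) {
      warn(sprintf("TDS = %d exceeds available data (%d); cell skipped.",
                   tds, avail))
      return(NULL)
    }
    take <- with_seed(derive_seed(seed, 100L + tds), sample.int(avail, tds))
    cfg <- config
    cfg$seed <- derive_seed(seed, 17L)
    fit <- train_net(freeze(net, tp), scenes[take], cfg)
    rep <- scenes_metric_report(fit$net, target_test)
    tibble(sweep = sweep, tp = tp, tds = tds, seed = seed,
           iterations = fit$trace$iterations,
           converged_at = fit$trace$converged_at,
           wks = rep$WKs)
  }
  for (seed in seeds) {
    for (tp in tp_grid) {
      rows[[length(rows) + 1L]] <- run_cell("tp", tp, condition$tds0, seed)
    }
    for (tds in tds_grid) {
      rows[[length(rows) + 1L]] <-
        run_cell("tds", condition$tp0, tds, seed)
    }
  }
  bind_rows(rows)
}

#' End-to-end MTPI pipeline at desk scale
#'
#' Pre-trains on source scenes, screens source and shifted target scenes,
#' scans the TPI curve to solve (TP0, TDS0), transfers under the condition,
#' and compares against full fine-tuning (TP = 0, all target training
#' data).
#'
#' @param seed Global seed.
#' @param config An [mtpi_toy_config()]; built from `seed` if missing.
#' @param sweep Also run the TP/TDS sweep harness.
#' @return A list with all stage outputs and a `summary` tibble.
#' @export
mtpi_pipeline <- function(seed = 1L, config = NULL, sweep = FALSE) {
  config <- config %||% mtpi_toy_config(seed)
  pre <- run_pretrain(config)
  tgt <- target_survey(config)
  tsplits <- split_dataset(tgt, seed = derive_seed(config$seed, 4L))
  screen_src <- screen_dataset(pre$net, pre$splits$test)
  screen_tgt <- screen_dataset(pre$net, tsplits$test)
  scan <- run_scan(
    pre$net,
    list(source = pre$splits$validation, target = tsplits$validation),
    probe = config$probe, nlevel = config$nlevel, form = config$tpi_form,
    tds_pre = pre$tds_pre, ls_pre = pre$ls_pre,
    available = nrow(tsplits$train))
  transfer <- run_transfer(pre$net, tsplits$train, tsplits$test,
                           scan$condition, config$transfer,
                           seed = derive_seed(config$seed, 5L))
  full_cfg <- config$transfer
  full_cfg$seed <- derive_seed(config$seed, 6L)
  full <- train_net(freeze(pre$net, 0L), tsplits$train, full_cfg)
  full_report <- scenes_metric_report(full$net, tsplits$test)
  sweep_tbl <- if (sweep) {
    sweep_cfg <- config$transfer
    sweep_cfg$conv_tol <- config$sweep_conv_tol %||% 0.005
    sweep_cfg$max_iterations <- as.integer(
      config$sweep_max_iterations %||% sweep_cfg$max_iterations)
    run_sweep(pre$net, tsplits$train, tsplits$test, scan$condition,
              sweep_cfg,
              tds_grid = sort(unique(pmax(1L, pmin(nrow(tsplits$train),
                round(scan$condition$tds0 * config$tds_fractions))))),
              seeds = seq_len(config$sweep_seeds))
  } else {
    NULL
  }
  summary <- tibble(
    source_wks = screen_src$WKs,
    target_wks_before = screen_tgt$WKs,
    tp0 = scan$tp0,
    tds0 = scan$condition$tds0,
    transfer_wks = transfer$report$WKs,
    full_finetune_wks = full_report$WKs,
    trainable_fraction = transfer$trainable / pre$ls_pre,
    data_fraction = transfer$tds_used / nrow(tsplits$train),
    transfer_iterations = transfer$trace$converged_at,
    full_iterations = full$trace$converged_at
  )
  list(config = config, pretrain = pre, target_splits = tsplits,
       screen_source = screen_src, screen_target = screen_tgt,
       scan = scan, transfer = transfer,
       full = list(trace = full$trace, report = full_report),
       sweep = sweep_tbl, summary = summary)
}
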