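#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list.  Unknown keys, a missing seed, or
#' out-of-range values are rejected before any computation; all defaults are
#' resolved and echoed in the returned object.
#'
#' @param config path to a YAML file, or a list.
#' @return a list of class `run_config` with fully constructed parameter
#'   blocks (`cohort`, `effects`, `scene`, `gel`, `segmentation`, `stats`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    stop_if(!file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stop_if(!is.list(config), "config must be a YAML file or a list")

  allowed_top <- c("seed", "cohort", "effects", "scene", "gel", "segmentation", "stats")
  unknown <- setdiff(names(config), allowed_top)
  stop_if(length(unknown) > 0, "unknown config key(s): %s", paste(unknown, collapse = ", "))
  stop_if(is.null(config$seed), "config must set an explicit seed")
  stop_if(!is.numeric(config$seed) || config$seed != round(config$seed),
          "seed must be an integer")

  check_block <- function(block, fn, drop = character()) {
    ok <- setdiff(names(formals(fn)), drop)
    unknown <- setdiff(names(block), ok)
    stop_if(length(unknown) > 0, "unknown config key(s): %s",
            paste(unknown, collapse = ", "))
    block
  }
  cohort_block <- check_block(config$cohort %||% list(), cohort_params)
  effects_block <- check_block(config$effects %||% list(), effect_params, drop = "cohort")
  scene_block <- check_block(config$scene %||% list(), tissue_scene_params,
                             drop = c("post_layout", "release_time", "n_frames",
                                      "frame_interval", "seed"))
  gel_block <- check_block(config$gel %||% list(), gel_scene_params,
                           drop = c("lanes", "polarity", "seed"))
  seg_block <- check_block(config$segmentation %||% list(), seg_config)
  stats_block <- config$stats %||% list()
  unknown <- setdiff(names(stats_block), c("alpha", "exclude_outliers"))
  stop_if(length(unknown) > 0, "unknown config key(s): %s", paste(unknown, collapse = ", "))
  exclude <- stats_block$exclude_outliers %||% "sensitivity"
  stop_if(!exclude %in% c("never", "sensitivity"),
          "stats$exclude_outliers must be 'never' or 'sensitivity'")

  cohort_block$seed <- cohort_block$seed %||% derive_seed(config$seed, "cohort")
  cohort <- do.call(cohort_params, cohort_block)
  effects <- do.call(effect_params, c(effects_block, list(cohort = cohort)))
  scene_defaults <- scene_block
  ## construct a trial scene so out-of-range values fail at validation time
  do.call(tissue_scene_params, scene_defaults)
  segmentation <- do.call(seg_config, seg_block)

  structure(list(seed = as.integer(config$seed),
                 cohort = cohort, effects = effects,
                 scene_defaults = scene_defaults,
                 gel_defaults = gel_block,
                 segmentation = segmentation,
                 stats = list(alpha = stats_block$alpha %||% 0.05,
                              exclude_outliers = exclude)),
            class = "run_config")
}

demo_gel_scene <- function(lanes, polarity, gel_defaults, seed) {
  do.call(gel_scene_params,
          c(list(lanes = lanes, polarity = polarity, seed = seed), gel_defaults))
}

## quantify one multi-target gel; returns per-lane rows of band measurements
quantify_demo_gel <- function(gel, targets, config = densito_config()) {
  lay <- gel$layout
  ladder_rows <- migration_row(lay$ladder_weights, lay$migration_calibration)
  map <- calibrate_migration(ladder_rows, lay$ladder_weights)
  sample_ids <- setdiff(names(lay$lane_cols), "ladder")
  out <- list()
  for (id in sample_ids) {
    for (tg in names(targets)) {
      out[[length(out) + 1L]] <- quantify_band(
        gel$image, lay$lane_cols[[id]], targets[[tg]], map,
        polarity = lay$polarity, all_lane_cols = lay$lane_cols,
        target = tg, lane = id, config = config)
    }
  }
  do.call(rbind, out)
}

#' Run the full synthetic demonstration pipeline
#'
#' Cohort generation, per-tendon read-outs, endpoint (0 h / 48 h) brightfield
#' rendering, segmentation with fallback, compaction read-outs, blot and
#' zymograph rendering and densitometry, the loading-control outlier rule,
#' and the per-read-out regression table.  Every tabular artifact is written
#' as CSV; reruns with the same configuration are byte-identical.
#'
#' @param config a [validate_config()] result, a YAML path, or a list.
#' @param out_dir output directory (created; existing files overwritten).
#' @return the output directory, invisibly; artifacts: `cohort.csv`,
#'   `readouts_true.csv`, `compaction.csv`, `bands.csv`, `merged.csv`,
#'   `table2.csv`, `table2.txt`, `qq_pairs.csv`, `manifest.json`, `run.log`,
#'   and per-tendon image stacks under `stacks/`.
#' @export
run_demo <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "stacks"), showWarnings = FALSE)
  log_lines <- character()
  logmsg <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  wcsv <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
    logmsg("wrote %s (%d rows)", name, nrow(df))
  }

  ## stage 1: cohort and ground-truth read-outs -----------------------------
  logmsg("stage cohort: n_patients=%d seed=%d", cfg$cohort$n_patients, cfg$cohort$seed)
  cohort <- generate_cohort(cfg$cohort)
  readouts <- generate_readouts(cohort, cfg$effects,
                                seed = derive_seed(cfg$seed, "readouts"))
  wcsv(cohort, "cohort.csv")
  wcsv(readouts, "readouts_true.csv")

  ## stage 2: endpoint imaging + segmentation + compaction ------------------
  logmsg("stage imaging: %d tendons, endpoint (0/48 h) acquisition", nrow(readouts))
  base_scene <- cfg$scene_defaults
  compaction <- list()
  for (i in seq_len(nrow(readouts))) {
    rel_frac <- clamp(readouts$relative_area_pct[i] / 100, 0.08, 0.92)
    scene_args <- c(base_scene, list(
      n_frames = 2L, frame_interval = 48,
      release_time = if (readouts$intact[i] == 0) readouts$release_time_h[i],
      seed = derive_seed(cfg$seed, paste0("scene", readouts$tendon_id[i]))))
    scene_args$initial_area <- scene_args$initial_area %||%
      formals(tissue_scene_params)$initial_area
    scene_args$plateau_area <- scene_args$initial_area * rel_frac
    ## decay law exactly attains the target 48 h ratio in the plateau limit;
    ## use a rate fast enough that A(48) is within rounding of the plateau
    scene_args$compaction_rate <- 0.25
    scene <- do.call(tissue_scene_params, scene_args)
    rt <- render_timelapse(scene)
    stack_path <- file.path(out_dir, "stacks",
                            sprintf("tendon_%02d.tif", readouts$tendon_id[i]))
    write_image_stack(rt$frames, stack_path, scene$pixel_size, rt$times)
    f0 <- image_frame(rt$frames[[1]], scene$pixel_size, rt$times[1])
    f1 <- image_frame(rt$frames[[2]], scene$pixel_size, rt$times[2])
    ser <- endpoint_series(f0, f1, cfg$segmentation)
    ser$tendon_id <- readouts$tendon_id[i]
    cls <- classify_release(ser, attr(ser, "masks"), scene$post_layout)
    rel_pct <- tryCatch(relative_area(ser), error = function(e) NA_real_)
    compaction[[i]] <- data.frame(
      tendon_id = readouts$tendon_id[i],
      relative_area_pct = rel_pct,
      status = cls$status,
      release_time_h = cls$release_time_h,
      strategy_0h = attr(ser, "strategies")[1],
      strategy_48h = attr(ser, "strategies")[2])
  }
  compaction <- do.call(rbind, compaction)
  wcsv(compaction, "compaction.csv")

  ## stage 3: gels + densitometry -------------------------------------------
  intact_idx <- which(readouts$intact == 1)
  logmsg("stage gels: %d intact tendons on blots and zymographs", length(intact_idx))
  gel_cfg <- densito_config()
  zym_scale <- 20      # zymograph loading concentrates the MMP2 signal
  bands_all <- list()
  meas <- data.frame(tendon_id = readouts$tendon_id[intact_idx],
                     tnmd_tubulin = NA_real_, asma_tubulin = NA_real_,
                     active_mmp2_au = NA_real_, mmp2_active_fraction = NA_real_,
                     tubulin_au = NA_real_, tubulin_outlier = NA)
  groups <- split(intact_idx, ceiling(seq_along(intact_idx) / 12))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    blot_lanes <- lapply(idx, function(i) {
      tub <- readouts$tubulin_au[i]
      list(id = readouts$tendon_id[i],
           bands = data.frame(
             kda = c(37, 42, 50.5, 54),
             amount = c(readouts$tnmd_tubulin[i] * tub,
                        readouts$asma_tubulin[i] * tub,
                        tub / 2, tub / 2)))
    })
    zym_lanes <- lapply(idx, function(i) {
      act <- readouts$active_mmp2_au[i] * zym_scale
      frac <- readouts$mmp2_active_fraction[i]
      pro <- if (frac > 0) act * (1 / frac - 1) else readouts$active_mmp2_au[i] * zym_scale
      list(id = readouts$tendon_id[i],
           bands = data.frame(kda = c(62, 72), amount = c(act, pro)))
    })
    blot <- render_gel(demo_gel_scene(blot_lanes, "bright", cfg$gel_defaults,
                                      derive_seed(cfg$seed, paste0("blot", gi))))
    zym <- render_gel(demo_gel_scene(zym_lanes, "bright", cfg$gel_defaults,
                                     derive_seed(cfg$seed, paste0("zym", gi))))
    bm_blot <- quantify_demo_gel(blot, list(tenomodulin = 37, aSMA = 42,
                                            tubulin = c(50, 55)), gel_cfg)
    bm_zym <- quantify_demo_gel(zym, list(active_mmp2 = 62, pro_mmp2 = 72,
                                          mmp9 = 92), gel_cfg)
    bands_all[[length(bands_all) + 1L]] <- rbind(bm_blot, bm_zym)

    ## per-unit-amount response, internally calibrated from the marker lane
    lay <- zym$layout
    map <- calibrate_migration(migration_row(lay$ladder_weights,
                                             lay$migration_calibration),
                               lay$ladder_weights)
    ladder62 <- quantify_band(zym$image, lay$lane_cols[["ladder"]],
                              lay$ladder_weights[which.min(abs(lay$ladder_weights - 62))],
                              map, polarity = lay$polarity,
                              all_lane_cols = lay$lane_cols,
                              target = "marker", lane = "ladder", config = gel_cfg)
    per_unit <- ladder62$corrected_intensity / zym$params$ladder_amount

    for (i in idx) {
      id <- readouts$tendon_id[i]
      row <- which(meas$tendon_id == id)
      b <- function(df, tg) df[df$lane == as.character(id) & df$target == tg, ]
      tub <- b(bm_blot, "tubulin")
      meas$tnmd_tubulin[row] <- housekeeping_ratio(b(bm_blot, "tenomodulin"), tub)
      meas$asma_tubulin[row] <- housekeeping_ratio(b(bm_blot, "aSMA"), tub)
      meas$tubulin_au[row] <- tub$corrected_intensity
      act <- b(bm_zym, "active_mmp2"); pro <- b(bm_zym, "pro_mmp2")
      meas$active_mmp2_au[row] <- act$corrected_intensity / per_unit / zym_scale
      meas$mmp2_active_fraction[row] <- mmp2_active_fraction(act, pro)
    }
  }
  bands_all <- do.call(rbind, bands_all)
  wcsv(bands_all, "bands.csv")

  ## stage 4: loading-control outlier rule ----------------------------------
  meas$tubulin_outlier <- as.logical(loading_outliers(meas$tubulin_au))
  logmsg("stage loading-control: %d outlier(s) flagged", sum(meas$tubulin_outlier))

  ## stage 5: merge + regression layer --------------------------------------
  merged <- merge(readouts[, c("patient_id", "tendon_id", "age_y", "gender",
                               "tendon", "pro_collagen_ng_ml")],
                  compaction[, c("tendon_id", "relative_area_pct", "status")],
                  by = "tendon_id")
  merged <- merge(merged, meas, by = "tendon_id", all.x = TRUE)
  merged$intact <- as.numeric(merged$status == "intact")
  merged <- merged[order(merged$tendon_id), ]
  wcsv(merged, "merged.csv")

  logit_fit <- tryCatch(fit_logistic(model_input(merged, "intact", binary = TRUE)),
                        error = function(e) {
                          logmsg("logistic fit refused: %s", conditionMessage(e))
                          NULL
                        })
  fits <- list(
    fit_linear(model_input(merged, "relative_area_pct")),
    fit_linear(model_input(merged, "pro_collagen_ng_ml")),
    fit_linear(model_input(merged, "tnmd_tubulin")),
    fit_linear(model_input(merged, "asma_tubulin")),
    fit_linear(model_input(merged, "active_mmp2_au")),
    fit_linear(model_input(merged, "mmp2_active_fraction")))
  if (!is.null(logit_fit)) fits <- c(list(logit_fit), fits)
  if (cfg$stats$exclude_outliers == "sensitivity") {
    keep <- merged[is.na(merged$tubulin_outlier) | !merged$tubulin_outlier, ]
    fits <- c(fits, list(
      fit_linear(model_input(keep, "pro_collagen_ng_ml"), variant = "no-outliers")))
  }
  tab <- results_table(fits)
  wcsv(tab, "table2.csv")
  writeLines(attr(tab, "text"), file.path(out_dir, "table2.txt"))

  qq <- qq_normality(resid(lm(relative_area_pct ~ age_y, data = merged)))
  wcsv(qq$pairs, "qq_pairs.csv")
  logmsg("stage stats: %d model rows, qq correlation %.4f",
         nrow(tab), qq$correlation)

  ## manifest of artifact hashes --------------------------------------------
  files <- sort(c(list.files(out_dir, pattern = "\\.(csv|txt)$", full.names = TRUE),
                  list.files(file.path(out_dir, "stacks"), full.names = TRUE)))
  manifest <- lapply(files, function(f) unname(tools::md5sum(f)))
  names(manifest) <- sub(paste0("^", out_dir, "/?"), "", files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
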