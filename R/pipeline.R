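# End-to-end pipeline: simulate -> preprocess -> (augment) -> train ->
# ensemble -> measure -> compare -> stats, with a deterministic artifact
# layout and per-stage seeds so each stage can be reproduced independently.
# Completed stages are skipped on re-run (the stage's stored configuration
# must match) unless `force = TRUE`.

#' Default pipeline configuration
#'
#' A desk-scale configuration: a small phantom cohort on a coarse grid,
#' consecutive K-fold cross-validation with one small 3D V-Net per fold,
#' probability-averaging ensembling, morphometry of the ensemble
#' predictions against the phantom ground truth, and paired statistics on
#' the per-subject measurements.
#'
#' @param output_dir artifact directory.
#' @param seed master seed; per-stage seeds are derived as seed + offset.
#' @return nested configuration list (can be serialized as one YAML file).
#' @export
pipeline_config <- function(output_dir = "scapseg_run", seed = 1) {
  list(
    output_dir = output_dir,
    seed = seed,
    cohort = list(n = 6, shape = c(48, 48, 48), spacing = c(2.75, 2.75, 2.75),
                  noise_sd = 0.02, bias_amplitude = 0.1),
    preprocess = list(crop_rows = 0, crop_cols = 0),
    augment = list(enabled = FALSE, copies = 2, prob = 0.3),
    train = list(k = 2, n_channels = 4, n_levels = 1, convs_per_level = 1,
                 bottom_convs = 1, kernel_size = 3, learning_rate = 0.005,
                 max_iterations = 200, validate_every = 25, patience = 8,
                 stop_dsc = NULL),
    ensemble = list(threshold = 0.70)
  )
}

.stage_done <- function(dir, stage, cfg) {
  f <- file.path(dir, paste0(".", stage, ".done.json"))
  if (!file.exists(f)) return(FALSE)
  identical(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10),
            jsonlite::toJSON(jsonlite::read_json(f, simplifyVector = TRUE),
                             auto_unbox = TRUE, digits = 10))
}

.stage_mark <- function(dir, stage, cfg) {
  jsonlite::write_json(cfg, file.path(dir, paste0(".", stage, ".done.json")),
                       auto_unbox = TRUE, digits = 10)
}

.log_line <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full phantom-to-statistics pipeline
#'
#' Stages: (1) simulate a phantom cohort; (2) preprocess (crop, validation
#' normalization); (3) optional augmentation of the training pairs;
#' (4) train one 3D model per cross-validation fold; (5) DSC-gated
#' ensembling; (6) ensemble prediction + morphometry of predicted and
#' ground-truth masks; (7) trial-mean comparison table and paired
#' statistics. Artifacts land under `config$output_dir`; the run log is
#' JSON-lines. Two runs with identical configuration and seed produce
#' identical measurement tables.
#'
#' @param config a [pipeline_config()] list or path to a YAML file.
#' @param force re-run stages even when up to date.
#' @param verbose print progress.
#' @return invisibly, a list with the artifact paths and the in-memory
#'   results (records, ensemble, measurements, comparison, stats).
#' @export
run_pipeline <- function(config = pipeline_config(), force = FALSE,
                         verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out, "pipeline.log.jsonl"), open = "a")
  on.exit(close(logf))
  seed <- config$seed %||% 1

  # -- stage 1: simulate -----------------------------------------------------
  cohort_dir <- file.path(out, "cohort")
  if (force || !.stage_done(out, "simulate", config$cohort)) {
    cohort <- generate_cohort(config$cohort$n,
                              shape = config$cohort$shape,
                              spacing = config$cohort$spacing,
                              noise_sd = config$cohort$noise_sd,
                              bias_amplitude = config$cohort$bias_amplitude,
                              seed = seed + 11, dir = cohort_dir)
    .stage_mark(out, "simulate", config$cohort)
    .log_line(logf, "simulate", n = config$cohort$n, seed = seed + 11)
  } else {
    cohort <- .read_cohort(cohort_dir, config$cohort$n)
    .log_line(logf, "simulate", skipped = TRUE)
  }
  if (verbose) message("cohort ready (", length(cohort), " phantoms)")

  # -- stage 2: preprocess ---------------------------------------------------
  cs <- crop_spec(config$preprocess$crop_rows %||% 0,
                  config$preprocess$crop_cols %||% 0)
  pairs <- lapply(cohort, function(s) {
    v <- crop_volume(s$volume, cs)
    m <- crop_volume(s$mask, cs)
    list(volume = normalize_volume(v, normalization_spec("validation")),
         mask = m)
  })
  .log_line(logf, "preprocess", crop = c(cs$n_rows, cs$n_cols))

  # -- stage 3+4: cross-validation training ----------------------------------
  k <- config$train$k
  split <- kfold_split(seq_along(pairs), k)
  records_path <- file.path(out, "models", "records.json")
  dir.create(file.path(out, "models"), showWarnings = FALSE)
  vcfg <- vnet_config(dims = 3, n_channels = config$train$n_channels,
                      n_levels = config$train$n_levels,
                      convs_per_level = rep(config$train$convs_per_level,
                                            config$train$n_levels),
                      bottom_convs = config$train$bottom_convs,
                      kernel_size = config$train$kernel_size,
                      learning_rate = config$train$learning_rate)
  tcfg <- train_config(max_iterations = config$train$max_iterations,
                       validate_every = config$train$validate_every,
                       patience = config$train$patience,
                       stop_dsc = config$train$stop_dsc)
  records <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- split$folds[[f]]
    tr <- pairs[fold$train_ids]
    va <- pairs[fold$val_ids]
    if (isTRUE(config$augment$enabled)) {
      tr <- augment_dataset(tr, augment_spec(
        per_transform_prob = config$augment$prob,
        copies_per_original = config$augment$copies,
        seed = seed + 300 + f))
    }
    model <- build_model(vcfg, seed = seed + 100 + f)
    tcfg$seed <- seed + 200 + f
    records[[f]] <- train_model(model, tr, va, tcfg,
                                model_id = sprintf("3D-fold%d", f - 1),
                                verbose = verbose)
    .log_line(logf, "train", fold = f - 1,
              val_dsc = records[[f]]$val_dsc,
              iterations = records[[f]]$iterations_run)
  }
  jsonlite::write_json(
    lapply(records, function(r) list(model_id = r$model_id,
                                     val_dsc = r$val_dsc,
                                     iterations = r$iterations_run)),
    records_path, auto_unbox = TRUE, digits = NA)

  # -- stage 5: ensemble -----------------------------------------------------
  ens <- build_ensemble(records, threshold = config$ensemble$threshold)
  .log_line(logf, "ensemble", members = length(ens$members),
            excluded = attr(ens, "excluded"))

  # -- stage 6: measure ------------------------------------------------------
  meas_dir <- file.path(out, "measurements")
  dir.create(meas_dir, showWarnings = FALSE)
  mnames <- c("glenoid_height", "glenoid_width", "retroversion",
              "inclination_angle", "critical_shoulder_angle", "rsa_angle")
  rows <- list()
  for (i in seq_along(pairs)) {
    pm <- ensemble_predict(ens, pairs[[i]]$volume)
    pred_mask <- binarize(pm, 0.5)
    pred_fine <- binarize(.upsample_probmap(pm, 2L), 0.5)
    pred_m <- tryCatch(measure_mask(pred_fine), error = function(e) NULL)
    true_m <- cohort[[i]]$truth$measurements
    dsc <- dice_coefficient(pred_mask, pairs[[i]]$mask)
    for (nm in mnames) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = i, measurement = nm, dsc = dsc,
        predicted = if (is.null(pred_m)) NA_real_ else pred_m[[nm]],
        truth = true_m[[nm]], stringsAsFactors = FALSE)
    }
  }
  meas <- do.call(rbind, rows)
  meas_csv <- file.path(meas_dir, "measurements.csv")
  utils::write.csv(meas, meas_csv, row.names = FALSE)
  .log_line(logf, "measure", subjects = length(pairs), table = meas_csv)

  # -- stage 7: compare + stats ----------------------------------------------
  # per measurement: predicted-vs-truth trial means over the subjects whose
  # predicted mask was measurable (NA row when none was)
  comp <- do.call(rbind, lapply(mnames, function(nm) {
    sel <- meas$measurement == nm & !is.na(meas$predicted)
    allm <- meas$measurement == nm
    if (any(sel)) {
      cm <- compare_measurements(list(x = meas$predicted[sel]),
                                 list(x = meas$truth[sel]))
      data.frame(measurement = nm, n_measured = sum(sel),
                 mean_predicted = cm$mean_a, mean_truth = cm$mean_b,
                 mean_difference = cm$mean_difference,
                 mean_difference_2dp = cm$mean_difference_2dp,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(measurement = nm, n_measured = 0L,
                 mean_predicted = NA_real_, mean_truth = mean(meas$truth[allm]),
                 mean_difference = NA_real_, mean_difference_2dp = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }))
  comp_csv <- file.path(meas_dir, "comparison.csv")
  utils::write.csv(comp, comp_csv, row.names = FALSE)
  stats_rows <- lapply(mnames, function(nm) {
    sel <- meas$measurement == nm & !is.na(meas$predicted)
    if (sum(sel) < 3) return(NULL)
    r <- gated_paired_compare(meas$predicted[sel], meas$truth[sel])
    data.frame(measurement = nm, test = r$test_used %||% NA,
               statistic = r$statistic %||% NA_real_,
               p_value = r$p_value %||% NA_real_,
               significant = isTRUE(r$significant), stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, stats_rows)
  if (is.null(stats_df))
    stats_df <- data.frame(measurement = character(0), test = character(0),
                           statistic = numeric(0), p_value = numeric(0),
                           significant = logical(0))
  stats_csv <- file.path(out, "stats", "paired_tests.csv")
  dir.create(file.path(out, "stats"), showWarnings = FALSE)
  utils::write.csv(stats_df, stats_csv, row.names = FALSE)
  .log_line(logf, "stats", table = stats_csv)

  invisible(list(records = records, ensemble = ens, measurements = meas,
                 comparison = comp, stats = stats_df,
                 paths = list(cohort = cohort_dir, records = records_path,
                              measurements = meas_csv, comparison = comp_csv,
                              stats = stats_csv)))
}

# Trilinear upsampling of a probability map by an integer factor; gives
# sub-voxel surfaces before binarization so morphometry works on masks
# predicted at coarse training resolutions.
.upsample_probmap <- function(p, factor = 2L) {
  arr <- .grid_data(p)
  sp <- .grid_spacing(p)
  d <- dim(arr)
  d2 <- d * factor
  src <- sweep(.coord_grid(d2), 2, (d - 1) / pmax(d2 - 1, 1), `*`)
  as_probmap(array(pmin(1, pmax(0, cpp_resample(arr, d, src, FALSE, 0))), d2),
             sp * (d - 1) / pmax(d2 - 1, 1))
}

.read_cohort <- function(dir, n) {
  truths <- jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  lapply(seq_len(n), function(i) {
    id <- sprintf("phantom_%03d", i)
    tr <- truths[[id]]
    lms <- tr$landmarks
    lmo <- structure(lapply(lms, as.numeric), class = "scap_landmarks")
    list(volume = read_volume(file.path(dir, paste0(id, "_image.nii.gz"))),
         mask = read_volume(file.path(dir, paste0(id, "_mask.nii.gz")),
                            as = "mask"),
         truth = list(landmarks = lmo,
                      measurements = structure(as.list(tr$measurements),
                                               class = "scap_measurements")))
  })
}
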