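#' Pipeline run configuration
#'
#' Parameters of the end-to-end desk run: acquire (simulate) -> subtract ->
#' QC -> crop -> identify -> count -> warn. Defaults are smoke-scale so a
#' full run finishes in seconds; stage blocks accept the same arguments as
#' the corresponding module functions.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param n_frames frames of the simulated capture sequence.
#' @param frame_size capture frame size, px.
#' @param n_per_class images per class of the training set.
#' @param image_size training image side, px.
#' @param classifier `"svm"` (fast, feature-based) or `"resnet"`.
#' @param epochs training epochs when `classifier = "resnet"`.
#' @param pso_iterations PSO iterations when `classifier = "svm"`.
#' @param n_days,base_count,daily_growth simulated count series.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_frames = 80L, frame_size = c(120L, 120L),
                       n_per_class = 30L, image_size = 32L,
                       classifier = c("svm", "resnet"), epochs = 5L,
                       pso_iterations = 5L, n_days = 14L, base_count = 8L,
                       daily_growth = 1.25) {
  classifier <- match.arg(classifier)
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 frame_size = as.integer(frame_size),
                 n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size), classifier = classifier,
                 epochs = as.integer(epochs),
                 pso_iterations = as.integer(pso_iterations),
                 n_days = as.integer(n_days), base_count = base_count,
                 daily_growth = daily_growth),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

stage_done <- function(run_dir, stage) {
  file.exists(file.path(run_dir, paste0(stage, ".done")))
}

mark_done <- function(run_dir, stage) {
  writeLines(format(Sys.time(), tz = "UTC"),
             file.path(run_dir, paste0(stage, ".done")))
}

#' Run the full monitoring pipeline
#'
#' Executes every stage into `run_dir`, writing a manifest (config hash,
#' seed, package version, stage completion) and per-stage outputs. Stages
#' whose done-marker already exists are skipped, so deleting one stage's
#' marker and output re-runs only that stage; identical configs produce
#' identical manifests.
#'
#' @param config a [run_config()].
#' @param run_dir output directory.
#' @return `run_dir`, invisibly; outputs include a QC ledger CSV, a trained
#'   classifier evaluation JSON and the outbreak warning report JSON.
#' @export
run_pipeline <- function(config = run_config(), run_dir = tempfile("pestrun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  if (!stage_done(run_dir, "simulate")) {
    traj <- parabolic_trajectory(config$n_frames, config$frame_size)
    spec <- scene_spec(frame_size = config$frame_size, trajectory = traj)
    seqn <- render_sequence(spec, config$n_frames, seed = seed)
    write_sequence(seqn, file.path(run_dir, "frames"))
    series <- make_count_series(count_series_spec(
      config$n_days, config$base_count, config$daily_growth,
      noise = 1, seed = seed))
    write_count_series(series, file.path(run_dir, "counts.csv"))
    mark_done(run_dir, "simulate")
  }

  if (!stage_done(run_dir, "subtract")) {
    traj <- parabolic_trajectory(config$n_frames, config$frame_size)
    spec <- scene_spec(frame_size = config$frame_size, trajectory = traj)
    seqn <- render_sequence(spec, config$n_frames, seed = seed)
    res <- subtract(seqn, bg_config(burn_in = min(30L, config$n_frames %/% 3L)))
    qc <- qc_sequence(seqn, res)
    utils::write.csv(qc, file.path(run_dir, "qc_ledger.csv"), row.names = FALSE)
    mark_done(run_dir, "subtract")
  }

  if (!stage_done(run_dir, "identify")) {
    ds <- make_insect_dataset(default_class_specs(), config$n_per_class,
                              config$image_size, seed = seed + 1L,
                              provenance = "dataset1")
    ds <- split_dataset(ds, c(7, 1.5, 1.5), seed = seed + 2L)
    if (config$classifier == "svm") {
      feats <- dataset_features(ds)
      X <- as.matrix(feats[, feature_names()])
      sel <- select_features(X, feats$label, seed = seed + 3L)
      keep <- if (length(sel$selected)) sel$selected else seq_len(ncol(X))
      tr <- ds$split == "train"
      te <- ds$split == "test"
      fit <- train_pso_svm(scale(X[tr, keep, drop = FALSE]), feats$label[tr],
                           svm_config(swarm = 10L,
                                      iterations = config$pso_iterations,
                                      cv_folds = 5L),
                           seed = seed + 4L)
      ctr <- attr(scale(X[tr, keep, drop = FALSE]), "scaled:center")
      scl <- attr(scale(X[tr, keep, drop = FALSE]), "scaled:scale")
      pred <- as.integer(as.character(
        predict(fit, scale(X[te, keep, drop = FALSE], ctr, scl))))
      report <- evaluate_predictions(feats$label[te], pred,
                                     length(ds$class_names))
    } else {
      model <- build_resnet_v2(n_classes = length(ds$class_names),
                               input_size = config$image_size,
                               seed = seed + 3L)
      model <- train_resnet(model, ds,
                            train_config(epochs = config$epochs),
                            seed = seed + 4L)
      report <- evaluate_model(model, ds, "test")
    }
    write_eval_report(report, file.path(run_dir, "identification.json"),
                      file.path(run_dir, "identification.csv"))
    mark_done(run_dir, "identify")
  }

  if (!stage_done(run_dir, "forecast")) {
    series <- read_count_series(file.path(run_dir, "counts.csv"))
    report <- analyze_counts(series)
    write_warning_report(report, file.path(run_dir, "warning.json"))
    mark_done(run_dir, "forecast")
  }

  manifest <- list(config = unclass(config), config_hash = config_hash(config),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("pestwatch")),
                   stages = c("simulate", "subtract", "identify", "forecast"))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(run_dir)
}
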