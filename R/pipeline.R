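#' Default pipeline configuration
#'
#' Nested configuration covering every stage, with defaults matching the
#' study conditions: 25-65 degC heating over 480 s, 1 Hz trace, 30 fps
#' imaging, 64-pixel ROI, 3x3 mean filter, 16 gray/gradient levels, lag-5
#' gray-temperature gradient, k = 5 periods, Adam at lr 0.001 with weight
#' decay 1e-5 for up to 1000 epochs, and a 7:3 experiment-level split.
#'
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    run = list(seed = 0L, out = "runs", run_id = "run", write_frames = FALSE),
    simulate = list(n_experiments = 4L, T0 = 25, Tmax = 65, tau = 120, duration = 480,
                    sample_rate = 1, trace_noise_sd = 0.05, base_mean = 70,
                    avgl_slope = 0.5,
                    sub_periods = list(c(6, 0.8), c(20, 1.0), c(48, 1.2)),
                    speckle_scale = 1, frame_rate = 30, roi_size = 64L,
                    pattern_amp = 12),
    preprocess = list(kernel = 3L, target_rate = 1),
    features = list(N = 16L, M = 16L, lag = 5L),
    model = list(k_periods = 5L, embed_dim = 16L, n_blocks = 2L,
                 n_heads = 2L, local_kernel = 3L, window_length = 96L,
                 dropout = 0.1, kv_pool = 4L),
    train = list(lr = 0.001, weight_decay = 1e-5, epochs = 1000L,
                 split_ratio = 0.7, batch_size = 32L, patience = 50L,
                 stride = 24L, val_fraction = 0.2, use_temp_grad = FALSE),
    evaluate = list(stride = 1L, band_edges = c(30, 45)),
    render = list(curves = FALSE)
  ), class = "pipeline_config")
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) {
      stop("unknown config key: ", paste0(path, nm), call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) {
        stop("config key ", paste0(path, nm), " must be a section",
             call. = FALSE)
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or accepts a nested list), injects defaults for
#' missing keys, rejects unknown keys, and checks value constraints before
#' any stage runs.
#'
#' @param config Path to a YAML file, a nested list, or `NULL` for pure
#'   defaults.
#' @param seed Optional seed override.
#' @return A normalized `pipeline_config`.
#' @export
validate_config <- function(config = NULL, seed = NULL) {
  cfg <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    if (inherits(config, "pipeline_config")) config <- unclass(config)
    cfg <- merge_config(unclass(cfg), config)
    class(cfg) <- "pipeline_config"
  }
  if (!is.null(seed)) cfg$run$seed <- as.integer(seed)
  if (cfg$model$k_periods < 1) stop("model.k_periods must be >= 1",
                                    call. = FALSE)
  if (cfg$simulate$n_experiments < 2) stop("simulate.n_experiments must be >= 2 (the split needs both sides)",
                               call. = FALSE)
  if (cfg$train$split_ratio <= 0 || cfg$train$split_ratio >= 1) {
    stop("train.split_ratio must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$features$N < 2 || cfg$features$M < 2) {
    stop("features.N and features.M must be >= 2", call. = FALSE)
  }
  if (cfg$preprocess$kernel %% 2 != 1) {
    stop("preprocess.kernel must be odd", call. = FALSE)
  }
  cfg
}

# hash of the scientific configuration: output locations are excluded so two
# runs of one protocol hash identically wherever they are written
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$run$out <- NULL
  cfg$run$run_id <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write / read a temperature trace CSV (`time_s,temp_C`)
#'
#' @param trace A [temperature_trace()].
#' @param path CSV path.
#' @return `path` (write) or a [temperature_trace()] (read).
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times, temp_C = trace$temps),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "temp_C") %in% names(df))) {
    stop("trace CSV must have columns time_s,temp_C", call. = FALSE)
  }
  temperature_trace(df$time_s, df$temp_C)
}

#' Write / read a feature series CSV
#'
#' Columns: `time_s`, `temp_C` (if supplied), then one column per channel.
#'
#' @param fs A [feature_series()].
#' @param path CSV path.
#' @param temps Optional matching temperatures.
#' @return `path` (write) or a list with `features` and `temps` (read).
#' @export
write_features_csv <- function(fs, path, temps = NULL) {
  df <- data.frame(time_s = fs$times)
  if (!is.null(temps)) df$temp_C <- temps
  df <- cbind(df, as.data.frame(fs$channels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  temps <- if ("temp_C" %in% names(df)) df$temp_C
  ch <- as.matrix(df[, setdiff(names(df), c("time_s", "temp_C")),
                     drop = FALSE])
  list(features = feature_series(df$time_s, ch), temps = temps)
}

#' Save / load a model checkpoint
#'
#' The weights go to an RDS file; a JSON sidecar (same path plus `.json`)
#' records the configuration, channel names, normalization statistics and
#' seed for inspection without loading the weights.
#'
#' @param model A trained model.
#' @param path Checkpoint path (e.g. `checkpoint.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(class = class(model)[1], cfg = unclass(model$cfg),
               channels = model$channels,
               norm = lapply(model$norm, unname),
               seed = model$train_cfg$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

stage_checksums <- function(files) {
  files <- sort(files[file.exists(files)])
  sums <- tools::md5sum(files)
  names(sums) <- basename(names(sums))
  as.list(sums)
}

#' Run the full pipeline
#'
#' simulate -> preprocess/features -> split -> train -> evaluate
#' (-> render), writing stage outputs under a run-id-scoped directory and a
#' manifest with the config hash, seeds, package version and per-stage
#' output checksums. Rerunning with an identical configuration reproduces
#' the manifest checksums.
#'
#' @param config A `pipeline_config`, YAML path or nested list
#'   (see [validate_config()]).
#' @param seed Optional seed override.
#' @return The run directory path, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config = NULL, seed = NULL) {
  cfg <- validate_config(config, seed)
  run_dir <- file.path(cfg$run$out, cfg$run$run_id)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$run$seed,
                   package_version = as.character(utils::packageVersion("ustherm")),
                   stages = list())
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate
  sim_dir <- file.path(run_dir, "simulate")
  dir.create(sim_dir, showWarnings = FALSE)
  exps <- stage("simulate", function() {
    s <- cfg$simulate
    heat <- heating_model(s$T0, s$Tmax, s$tau, s$duration, s$sample_rate)
    tex <- texture_model(s$base_mean, s$avgl_slope, s$sub_periods,
                         s$speckle_scale, s$frame_rate, s$roi_size,
                         s$pattern_amp)
    ex <- make_experiment_set(s$n_experiments, heat, tex, seed = cfg$run$seed,
                              trace_noise_sd = s$trace_noise_sd)
    for (i in seq_along(ex)) {
      write_trace_csv(ex[[i]]$trace,
                      file.path(sim_dir, sprintf("trace_%03d.csv", i)))
      meta <- list(seed = ex[[i]]$seed,
                   injected_periods = ex[[i]]$injected_periods,
                   heating = unclass(ex[[i]]$params$heating),
                   texture = unclass(ex[[i]]$params$texture))
      jsonlite::write_json(meta,
                           file.path(sim_dir, sprintf("meta_%03d.json", i)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      if (isTRUE(cfg$run$write_frames)) {
        write_frames(ex[[i]]$frames,
                     file.path(sim_dir, sprintf("frames_%03d", i)))
      }
    }
    ex
  })
  manifest$stages$simulate <-
    stage_checksums(list.files(sim_dir, recursive = TRUE, full.names = TRUE))

  # -- preprocess + features
  feat_dir <- file.path(run_dir, "features")
  dir.create(feat_dir, showWarnings = FALSE)
  feats <- stage("features", function() {
    fx <- dataset_features(exps, kernel = cfg$preprocess$kernel,
                           N = cfg$features$N, M = cfg$features$M,
                           lag = cfg$features$lag)
    for (i in seq_along(fx)) {
      write_features_csv(fx[[i]]$features,
                         file.path(feat_dir, sprintf("features_%03d.csv", i)),
                         temps = fx[[i]]$temps)
    }
    fx
  })
  manifest$stages$features <-
    stage_checksums(list.files(feat_dir, full.names = TRUE))

  # -- split + train
  train_dir <- file.path(run_dir, "train")
  dir.create(train_dir, showWarnings = FALSE)
  trained <- stage("train", function() {
    split <- split_experiments(feats, ratio = cfg$train$split_ratio,
                               seed = cfg$run$seed)
    tc <- train_config(lr = cfg$train$lr,
                       weight_decay = cfg$train$weight_decay,
                       epochs = cfg$train$epochs,
                       split_ratio = cfg$train$split_ratio,
                       batch_size = cfg$train$batch_size,
                       patience = cfg$train$patience,
                       stride = cfg$train$stride,
                       val_fraction = cfg$train$val_fraction,
                       use_temp_grad = cfg$train$use_temp_grad,
                       seed = cfg$run$seed)
    mc <- model_config(channels = default_model_channels(tc$use_temp_grad),
                       k_periods = cfg$model$k_periods,
                       embed_dim = cfg$model$embed_dim,
                       n_blocks = cfg$model$n_blocks,
                       n_heads = cfg$model$n_heads,
                       local_kernel = cfg$model$local_kernel,
                       window_length = cfg$model$window_length,
                       dropout = cfg$model$dropout,
                       kv_pool = cfg$model$kv_pool,
                       seed = cfg$run$seed + 1L)
    model <- train_temporal_model(split$train, mc, tc)
    save_model(model, file.path(train_dir, "checkpoint.rds"))
    utils::write.csv(model$history, file.path(train_dir, "history.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(train_idx = split$train_idx, test_idx = split$test_idx),
      file.path(train_dir, "split.json"), auto_unbox = FALSE
    )
    list(model = model, split = split)
  })
  manifest$stages$train <-
    stage_checksums(list.files(train_dir, full.names = TRUE))

  # -- evaluate
  eval_dir <- file.path(run_dir, "evaluate")
  dir.create(eval_dir, showWarnings = FALSE)
  report <- stage("evaluate", function() {
    rep <- evaluate(trained$model, trained$split$test,
                    stride = cfg$evaluate$stride,
                    band_edges = cfg$evaluate$band_edges)
    jsonlite::write_json(
      list(metrics = list(mse = rep$mse, rmse = rep$rmse, mae = rep$mae),
           per_band = rep$per_band, per_experiment = rep$per_experiment,
           split = list(train_idx = trained$split$train_idx,
                        test_idx = trained$split$test_idx),
           config_hash = manifest$config_hash, seed = cfg$run$seed),
      file.path(eval_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, dataframe = "rows"
    )
    rep
  })
  manifest$stages$evaluate <-
    stage_checksums(list.files(eval_dir, full.names = TRUE))

  # -- render (optional)
  if (isTRUE(cfg$render$curves)) {
    rend_dir <- file.path(run_dir, "render")
    stage("render", function() render_prediction_curves(report, rend_dir))
    manifest$stages$render <-
      stage_checksums(list.files(rend_dir, full.names = TRUE))
  }

  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(run_dir)
}
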