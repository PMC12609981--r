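#' Read and validate a run configuration
#'
#' Parses a YAML run configuration with nested blocks `synth`, `denoise`,
#' `features`, `window`, `model`, `train`, `loss` and `paths`, merging each
#' block over the package defaults; every block is validated by its own
#' constructor. Unknown top-level keys are an error so typos cannot silently
#' disable options.
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return A named list of validated configuration objects plus `paths`,
#'   `seed` and `hr_range_bpm`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("synth", "denoise", "features", "window", "model", "train",
             "loss", "paths", "seed", "deterministic")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("read_run_config: unknown config block(s): ",
         paste(bad, collapse = ", "))
  build <- function(ctor, block) do.call(ctor, raw[[block]] %||% list())
  seed <- as.integer(raw$seed %||% 1L)
  # plain MSE unless a loss block explicitly enables the composite terms
  loss <- if (is.null(raw$loss)) loss_config(0, 0, 0)
          else build(loss_config, "loss")
  win <- build(window_spec, "window")
  train_args <- raw$train %||% list()
  train_args$window <- win
  train_args$loss <- loss
  if (is.null(train_args$seed)) train_args$seed <- seed
  synth_args <- raw$synth %||% list()
  if (is.null(synth_args$seed)) synth_args$seed <- seed
  list(seed = seed,
       synth = do.call(synth_config, synth_args),
       denoise = build(denoise_config, "denoise"),
       hr_range_bpm = unlist(raw$features$hr_range_bpm %||% c(40, 180)),
       window = win,
       model = build(model_config, "model"),
       train = do.call(train_config, train_args),
       loss = loss,
       paths = modifyList(list(out_dir = "pulsecast-run"),
                          raw$paths %||% list()))
}

#' Serialize a run configuration back to YAML
#'
#' `read_run_config(write_run_config(cfg, path))` round-trips the
#' configuration.
#'
#' @param config A [read_run_config()] result.
#' @param path Destination YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  plain <- list(
    seed = config$seed,
    synth = unclass(config$synth),
    denoise = unclass(config$denoise),
    features = list(hr_range_bpm = as.numeric(config$hr_range_bpm)),
    window = unclass(config$window),
    model = unclass(config$model),
    train = unclass(config$train)[c("epochs", "batch_size", "lr",
                                    "weight_decay", "seed", "folds")],
    loss = unclass(config$loss),
    paths = config$paths)
  yaml::write_yaml(plain, path)
  invisible(path)
}

stage_path <- function(config, ...) file.path(config$paths$out_dir, ...)

write_provenance <- function(config, stage, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, seed = config$seed,
           package_version = as.character(utils::packageVersion("pulsecast")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      extra),
    stage_path(config, paste0(stage, ".provenance.json")),
    auto_unbox = TRUE, digits = NA)
}

#' Run the processing pipeline end to end
#'
#' Executes the requested stages in canonical order: `simulate` writes a
#' paired synthetic record; `denoise` cleans the source trace; `featurize`
#' builds the 7-channel feature matrix; `train` fits CBAnet on the training
#' block and saves a checkpoint plus normalizer; `evaluate` runs held-out
#' sliding-window inference and writes `report.json` with RMSE/MAE/R-squared
#' and Bland-Altman fields. Each stage checks that its prerequisite artifacts
#' exist and writes a provenance sidecar (seed, package version).
#'
#' @param config A [read_run_config()] result.
#' @param stages Character subset of
#'   `c("simulate", "denoise", "featurize", "train", "evaluate")`.
#' @param verbose Print stage progress.
#' @return Invisibly, a list of per-stage outputs (the evaluation report when
#'   `evaluate` ran).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "denoise", "featurize",
                                    "train", "evaluate"),
                         verbose = TRUE) {
  order_all <- c("simulate", "denoise", "featurize", "train", "evaluate")
  stages <- order_all[order_all %in% match.arg(stages, order_all,
                                               several.ok = TRUE)]
  dir.create(config$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  src_csv <- stage_path(config, "source.csv")
  tgt_csv <- stage_path(config, "target.csv")
  clean_csv <- stage_path(config, "source_clean.csv")
  feat_csv <- stage_path(config, "features.csv")
  ckpt <- stage_path(config, "model.rds")
  norm_json <- stage_path(config, "normalizer.json")

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    ds <- make_dataset(config$synth, n_records = 1L)
    write_trace(ds$records[[1]]$source, src_csv)
    write_trace(ds$records[[1]]$target, tgt_csv)
    jsonlite::write_json(ds$manifest, stage_path(config, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_provenance(config, "simulate")
    say("simulate: wrote %s (%.1f s)", src_csv, proc.time()[3] - t0)
  }

  if ("denoise" %in% stages) {
    if (!file.exists(src_csv))
      stop("run_pipeline: denoise needs ", src_csv, " (run simulate first)")
    t0 <- proc.time()[3]
    tr <- read_trace(src_csv)
    write_trace(denoise_pipeline(tr, config$denoise), clean_csv)
    write_provenance(config, "denoise")
    say("denoise: wrote %s (%.1f s)", clean_csv, proc.time()[3] - t0)
  }

  if ("featurize" %in% stages) {
    if (!file.exists(src_csv) && !file.exists(clean_csv))
      stop("run_pipeline: featurize needs ", src_csv, " (run simulate first)")
    t0 <- proc.time()[3]
    # prefer the denoised trace when the denoise stage has run
    tr <- read_trace(if (file.exists(clean_csv)) clean_csv else src_csv)
    fm <- build_feature_matrix(tr, hr_range_bpm = config$hr_range_bpm)
    write_feature_matrix(fm, feat_csv)
    write_provenance(config, "featurize")
    say("featurize: wrote %s (%.1f s)", feat_csv, proc.time()[3] - t0)
  }

  if ("train" %in% stages) {
    if (!file.exists(feat_csv) || !file.exists(tgt_csv))
      stop("run_pipeline: train needs ", feat_csv, " and ", tgt_csv)
    t0 <- proc.time()[3]
    feats <- as.matrix(read.csv(feat_csv))
    feats <- feats[, seq_len(config$model$in_channels), drop = FALSE]
    tgt <- read_trace(tgt_csv)
    split <- split_record(nrow(feats), n_val = 0L, train_frac = 0.8)
    norm <- fit_normalizer(feats[split$train, , drop = FALSE],
                           tgt$samples[split$train])
    nx <- normalize_data(norm, x = feats[split$train, , drop = FALSE])
    ny <- normalize_data(norm, y = tgt$samples[split$train])
    wx <- make_windows(nx, config$window)
    wy <- make_windows(ny, config$window)
    set.seed(config$train$seed)
    model <- init_cbanet(config$model)
    fit <- train_cbanet(model, wx$windows, wy$windows, config$train)
    save_cbanet(fit$model, ckpt)
    jsonlite::write_json(unclass(norm), norm_json, auto_unbox = TRUE,
                         digits = NA)
    write.csv(data.frame(epoch = seq_along(fit$history),
                         loss = as.numeric(fit$history),
                         attr(fit$history, "terms")),
              stage_path(config, "loss_history.csv"), row.names = FALSE)
    write_provenance(config, "train",
                     list(final_loss = tail(as.numeric(fit$history), 1)))
    say("train: %d epochs, final loss %.5f (%.1f s)",
        config$train$epochs, tail(as.numeric(fit$history), 1),
        proc.time()[3] - t0)
    out$history <- fit$history
  }

  if ("evaluate" %in% stages) {
    if (!file.exists(ckpt))
      stop("run_pipeline: evaluate needs a checkpoint at ", ckpt,
           " (run train first)")
    t0 <- proc.time()[3]
    model <- load_cbanet(ckpt)
    nj <- jsonlite::read_json(norm_json, simplifyVector = TRUE)
    norm <- structure(nj, class = "normalizer")
    feats <- as.matrix(read.csv(feat_csv))
    feats <- feats[, seq_len(model$config$in_channels), drop = FALSE]
    src <- read_trace(src_csv)
    tgt <- read_trace(tgt_csv)
    split <- split_record(nrow(feats), n_val = 0L, train_frac = 0.8)
    te <- split$test
    held <- paired_record(
      signal_trace(src$samples[te], src$fs, src$label, src$units),
      signal_trace(tgt$samples[te], tgt$fs, tgt$label, tgt$units))
    ev <- evaluate_pipeline(model, held, norm, config$window,
                            features = feats[te, , drop = FALSE])
    report <- list(rmse = ev$report$rmse, mae = ev$report$mae,
                   r2 = ev$report$r2,
                   bland_altman = list(bias = ev$bland_altman$bias,
                                       sd = ev$bland_altman$sd,
                                       loa_low = ev$bland_altman$loa_low,
                                       loa_high = ev$bland_altman$loa_high))
    jsonlite::write_json(report, stage_path(config, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_provenance(config, "evaluate")
    say("evaluate: RMSE %.4f  MAE %.4f  R2 %.4f", report$rmse, report$mae,
        report$r2)
    out$report <- report
  }
  invisible(out)
}
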