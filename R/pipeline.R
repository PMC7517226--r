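# End-to-end pipeline driver. One config (R list or YAML file) fixes every
# stage -- simulate (optional), plan, extract, train, fuse, evaluate -- and
# one global seed, from which every downstream seed is derived, so a run is
# reproducible byte for byte. Stage outputs are cached under
# <out_dir>/cache and reused on resume.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulate = NULL,
    audio_dir = NULL, labels = NULL, segments = NULL,
    exclude = character(),
    crop = list(S = 4, test_cap = 89L),
    stft = list(win_ms = 64, hop_ms = 32, nfft = 1024L),
    cnn = list(),
    ensemble = list(M = 50L, method = 1L),
    cv = list(n_folds = 0L),
    resume = TRUE
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

#' Assemble and validate a pipeline configuration
#'
#' @param config A named list or the path to a YAML file. Recognized keys:
#'   `seed`, `out_dir`, `simulate` (a [synth_config()] argument list, or
#'   absent to use an existing corpus), `audio_dir`, `labels`, `segments`,
#'   `exclude`, `crop` (`S`, `test_cap`), `stft` (`win_ms`, `hop_ms`,
#'   `nfft`), `cnn` ([cnn_config()] arguments), `ensemble` (`M`, `method`),
#'   `cv` (`n_folds`), `resume`. Unspecified keys take the canonical
#'   defaults.
#' @return A validated config list of class `pipeline_config`. Schema
#'   violations error before any computation.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  # YAML 1.1 reads an unquoted key `N` as the boolean FALSE; undo that
  if (!is.null(config$cnn) && "FALSE" %in% names(config$cnn)) {
    names(config$cnn)[names(config$cnn) == "FALSE"] <- "N"
  }
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.null(cfg$out_dir)) stop("config: out_dir is required")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$labels) || !file.exists(cfg$labels)) {
      stop("config: no simulate block and no existing label CSV")
    }
    if (is.null(cfg$audio_dir) || !dir.exists(cfg$audio_dir)) {
      stop("config: no simulate block and no existing audio_dir")
    }
  }
  stopifnot(cfg$crop$S > 0, cfg$crop$test_cap >= 1,
            cfg$ensemble$M >= 1, cfg$ensemble$method %in% 1:3)
  cfg$cnn <- do.call(cnn_config, cfg$cnn)
  class(cfg) <- "pipeline_config"
  cfg
}

cache_stage <- function(dir, name, resume, builder) {
  path <- file.path(dir, paste0(name, ".rds"))
  if (resume && file.exists(path)) return(readRDS(path))
  value <- builder()
  saveRDS(value, path)
  value
}

#' Run the full pipeline
#'
#' Executes simulate (when configured), corpus loading, sampling-plan
#' optimization and materialization, feature extraction, ensemble training,
#' fusion and evaluation; writes the crop manifest, per-sample prediction
#' table, fused speaker decisions, metrics and seed provenance under
#' `out_dir`. All randomness derives from `config$seed`, so the same
#' config yields byte-identical manifests and metrics.
#'
#' @param config A [pipeline_config()], a plain list, or a YAML path.
#' @return Invisibly, a list with `plan`, `metrics`, `fused`, `config` and
#'   the output file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(file.path(cfg$out_dir, "cache"), recursive = TRUE,
             showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)

  if (!is.null(cfg$simulate)) {
    corpus_dir <- file.path(cfg$out_dir, "corpus")
    if (!(cfg$resume && file.exists(file.path(corpus_dir, "labels.csv")))) {
      logf("stage simulate: generating synthetic corpus")
      sim_args <- cfg$simulate
      sim_args$seed <- derive_seed(cfg$seed, "simulate")
      generate_corpus(do.call(synth_config, sim_args), corpus_dir)
    } else {
      logf("stage simulate: reusing cached corpus")
    }
    cfg$audio_dir <- file.path(corpus_dir, "audio")
    cfg$labels <- file.path(corpus_dir, "labels.csv")
    cfg$segments <- file.path(corpus_dir, "segments.csv")
  }

  logf("stage plan: loading roster and planning crops")
  roster <- load_roster(cfg$labels, exclude = cfg$exclude)
  annotation <- if (!is.null(cfg$segments)) load_segments(cfg$segments)
  loader <- audio_loader_dir(cfg$audio_dir, annotation = annotation)
  cache <- file.path(cfg$out_dir, "cache")

  recordings <- cache_stage(cache, "recordings", cfg$resume, function() {
    recs <- lapply(roster$speaker_id, loader)
    names(recs) <- roster$speaker_id
    recs
  })
  durations <- vapply(recordings, function(r) r$duration, numeric(1L))

  plan_seed <- derive_seed(cfg$seed, "plan")
  plan <- materialize_plan(roster, durations, S = cfg$crop$S,
                           seed = plan_seed)
  test_manifest <- crop_test_speakers(roster, durations,
                                      c_cap = cfg$crop$test_cap,
                                      S = cfg$crop$S)
  manifest <- rbind(plan$manifest, test_manifest)
  manifest_path <- file.path(cfg$out_dir, "crop_manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  logf("stage plan: c=%d k=%d total=%d train samples, %d test samples",
       plan$c, plan$k, plan$total, nrow(test_manifest))

  mem_loader <- audio_loader_memory(recordings)
  feats <- cache_stage(cache, "features", cfg$resume, function() {
    logf("stage extract: computing log-spectrograms")
    list(
      train = extract_features(mem_loader, plan$manifest, S = cfg$crop$S,
                               win_ms = cfg$stft$win_ms,
                               hop_ms = cfg$stft$hop_ms,
                               nfft = cfg$stft$nfft),
      test = if (nrow(test_manifest) > 0L) {
        extract_features(mem_loader, test_manifest, S = cfg$crop$S,
                         win_ms = cfg$stft$win_ms,
                         hop_ms = cfg$stft$hop_ms, nfft = cfg$stft$nfft)
      }
    )
  })
  if (is.null(feats$test)) stop("no test speakers: nothing to evaluate")

  ens <- ensemble_config(M = cfg$ensemble$M, method = cfg$ensemble$method,
                         tie_seed = derive_seed(cfg$seed, "tie"),
                         base_seed = derive_seed(cfg$seed, "ensemble"))

  if (cfg$cv$n_folds >= 2L) {
    logf("stage train/fuse: %d-fold cross-validation, M=%d method %d",
         cfg$cv$n_folds, ens$M, ens$method)
    cv <- cache_stage(cache, "crossval", cfg$resume, function() {
      crossval_evaluate(feats$train, feats$test, roster, cfg$cnn, ens,
                        n_folds = cfg$cv$n_folds,
                        seed = derive_seed(cfg$seed, "cv"))
    })
    predictions <- cv$predictions
    metrics <- cv$metrics
    fused <- predictions[, c("speaker_id", "pred")]
    names(fused) <- c("speaker_id", "final_label")
  } else {
    logf("stage train: M=%d machines", ens$M)
    models <- cache_stage(cache, "models", cfg$resume, function() {
      train_ensemble(feats$train, cnn = cfg$cnn, ens = ens)
    })
    logf("stage predict/fuse: method %d", ens$method)
    tbl <- predict_table(models, feats$test)
    utils::write.csv(tbl, file.path(cfg$out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    fused <- fuse_predictions(tbl, ens$method, ens$tie_seed)
    names(fused)[names(fused) == "label"] <- "final_label"
    truth <- test_manifest$label[!duplicated(test_manifest$speaker_id)]
    names(truth) <- unique(test_manifest$speaker_id)
    metrics <- per_class_metrics(truth[fused$speaker_id],
                                 fused$final_label)
    predictions <- data.frame(speaker_id = fused$speaker_id,
                              true = unname(truth[fused$speaker_id]),
                              pred = fused$final_label)
  }
  utils::write.csv(fused, file.path(cfg$out_dir, "fusion.csv"),
                   row.names = FALSE, quote = FALSE)

  metrics_path <- file.path(cfg$out_dir, "metrics.json")
  jsonlite::write_json(
    list(accuracy = metrics$accuracy,
         f1 = list(depressed = metrics$depressed$f1,
                   nondepressed = metrics$nondepressed$f1),
         precision = list(depressed = metrics$depressed$precision,
                          nondepressed = metrics$nondepressed$precision),
         recall = list(depressed = metrics$depressed$recall,
                       nondepressed = metrics$nondepressed$recall),
         plan = list(c = plan$c, k = plan$k, total = plan$total)),
    metrics_path, auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(
    list(global_seed = cfg$seed,
         plan_seed = plan_seed,
         machine_seeds = ens$seeds, tie_seed = ens$tie_seed),
    file.path(cfg$out_dir, "seeds.json"), auto_unbox = TRUE, digits = NA)
  logf("done: accuracy %.3f F1(dep) %.3f F1(non) %.3f", metrics$accuracy,
       metrics$depressed$f1, metrics$nondepressed$f1)

  invisible(list(plan = plan, metrics = metrics, fused = fused,
                 predictions = predictions, config = cfg,
                 paths = list(manifest = manifest_path,
                              metrics = metrics_path)))
}

#' Sweep one architecture parameter across pipeline runs
#'
#' Re-runs the pipeline for each value of a swept parameter (the max-pool
#' kernel length, or the filter/hidden widths jointly) and collects one
#' metrics row per configuration, mirroring the layout of a hyperparameter
#' comparison table.
#'
#' @param config Base pipeline config (list, YAML path or
#'   [pipeline_config()]).
#' @param param `"pool_k"` or `"N_n4"`.
#' @param values For `pool_k`, an integer vector (e.g. `c(1, 3, 5, 7)`);
#'   for `N_n4`, a list of `c(N, n4)` pairs.
#' @return `data.frame` with one row per configuration: the swept value,
#'   accuracy and per-class F1/precision/recall (`_dep` / `_non`
#'   suffixes). Also written to `<out_dir>/sweep.csv`.
#' @export
run_sweep <- function(config, param = c("pool_k", "N_n4"), values) {
  param <- match.arg(param)
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  base_out <- cfg$out_dir
  rows <- lapply(seq_along(values), function(i) {
    v <- values[[i]]
    sub <- cfg
    if (param == "pool_k") {
      sub$cnn$pool_k <- as.integer(v)
      tag <- paste0("pool_k_", v)
    } else {
      sub$cnn$N <- as.integer(v[1L]); sub$cnn$n4 <- as.integer(v[2L])
      tag <- paste0("N", v[1L], "_n4", v[2L])
    }
    sub$out_dir <- file.path(base_out, tag)
    m <- run_pipeline(sub)$metrics
    data.frame(value = tag, accuracy = m$accuracy,
               f1_dep = m$depressed$f1, f1_non = m$nondepressed$f1,
               precision_dep = m$depressed$precision,
               precision_non = m$nondepressed$precision,
               recall_dep = m$depressed$recall,
               recall_non = m$nondepressed$recall,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dir.create(base_out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, file.path(base_out, "sweep.csv"),
                   row.names = FALSE, quote = FALSE)
  out
}
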