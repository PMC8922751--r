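# End-to-end pipeline driver and the per-stage manifest contract. The
# command-line front-end (inst/cli/convmotif.R) is a thin wrapper over
# these functions.

# Stable hash of a configuration object: md5 of its canonical JSON.
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Write a stage manifest
#'
#' Every pipeline stage directory carries a `manifest.json` sufficient to
#' re-run it: the stage name, seed, configuration hash, and md5 checksums
#' of its input files. Re-running a deterministic stage with identical
#' inputs reproduces an identical manifest.
#'
#' @param dir stage output directory.
#' @param stage stage name.
#' @param seed integer seed the stage ran under.
#' @param config the stage's configuration object (hashed, not embedded).
#' @param inputs character vector of input file paths to checksum.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, stage, seed, config, inputs = character(0)) {
  man <- list(stage = stage, seed = seed,
              config_hash = config_hash(config),
              inputs = as.list(tools::md5sum(inputs)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Smoke-level driver wiring the stages together on synthetic data:
#' simulate -> train (cross-validated) -> interpret (kernel transformation)
#' -> export MEME -> scan -> occurrence profiles -> SVM validation. Each
#' stage writes its artifacts and a manifest under `outdir/<stage>/`.
#'
#' @param cfg a [synth_config] describing the dataset.
#' @param model_cfg a [model_config].
#' @param outdir output directory.
#' @param reference_lib optional [motif_library] to match transformed
#'   motifs against (common/specific calling is skipped when `NULL`).
#' @param q_threshold scanner q cutoff.
#' @return List with the fitted `cv`, transformed `motifs` per fold, the
#'   `common` call (when a reference library was given), scanner `hits`,
#'   `profiles`, and the SVM `metrics`.
#' @export
run_pipeline <- function(cfg, model_cfg, outdir, reference_lib = NULL,
                         q_threshold = 0.1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sim_dir <- file.path(outdir, "simulate")
  ds <- simulate_dataset(cfg)
  paths <- write_dataset(ds, sim_dir)
  write_manifest(sim_dir, "simulate", cfg$seed, cfg)

  train_dir <- file.path(outdir, "train")
  dir.create(train_dir, showWarnings = FALSE)
  splits <- split_train(ds$labels, seed = model_cfg$seed)
  cv <- cnn_cv(ds$sequences, ds$labels, model_cfg, splits = splits)
  metrics <- data.frame(
    fold = seq_along(cv$folds),
    accuracy = vapply(cv$folds, `[[`, numeric(1), "accuracy"),
    auroc = vapply(cv$folds, `[[`, numeric(1), "auroc"))
  utils::write.table(metrics, file.path(train_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (f in cv$folds) {
    if (!is.null(f$roc)) {
      utils::write.table(f$roc,
                         file.path(train_dir,
                                   sprintf("roc_fold%d.tsv", f$fold)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    export_kernels(f$model,
                   file.path(train_dir, sprintf("kernels_fold%d.json",
                                                f$fold)))
  }
  write_manifest(train_dir, "train", model_cfg$seed, model_cfg,
                 unname(paths["fasta"]))

  int_dir <- file.path(outdir, "interpret")
  dir.create(int_dir, showWarnings = FALSE)
  fold_libs <- lapply(cv$folds, function(f)
    transform_model(f$model, fold = f$fold))
  all_pwms <- unlist(lapply(fold_libs, function(l) l$pwms),
                     recursive = FALSE)
  lib <- motif_library(all_pwms, source = "transformed")
  write_meme(lib, file.path(int_dir, "transformed_motifs.meme"))
  common <- NULL
  if (!is.null(reference_lib)) {
    per_fold <- lapply(fold_libs, function(l)
      match_library(l, reference_lib)$match)
    common <- call_common(per_fold)
  }
  write_manifest(int_dir, "interpret", model_cfg$seed, model_cfg)

  scan_dir <- file.path(outdir, "scan")
  dir.create(scan_dir, showWarnings = FALSE)
  scan_lib <- if (!is.null(reference_lib)) reference_lib else lib
  hits <- scan_motifs(scan_lib, ds$sequences, q_threshold = q_threshold)
  write_hits_tsv(hits, file.path(scan_dir, "hits.tsv"))
  profiles <- lapply(stats::setNames(nm = unique(hits$motif)), function(m)
    occurrence_profile(hits[hits$motif == m, ], ds$labels,
                       window_length = cfg$window_length))
  write_manifest(scan_dir, "scan", cfg$seed,
                 list(q_threshold = q_threshold),
                 file.path(int_dir, "transformed_motifs.meme"))

  svm_dir <- file.path(outdir, "svm")
  dir.create(svm_dir, showWarnings = FALSE)
  X <- feature_matrix(hits, names(ds$labels))
  train_idx <- setdiff(seq_along(ds$labels), splits$test_idx)
  svm_metrics <- svm_evaluate(X, ds$labels, train_idx, splits$test_idx,
                              seed = model_cfg$seed)
  write_metrics_tsv(
    data.frame(motif_set = scan_lib$source,
               accuracy = svm_metrics$accuracy,
               precision = svm_metrics$precision,
               recall = svm_metrics$recall, f1 = svm_metrics$f1),
    file.path(svm_dir, "svm_metrics.tsv"))
  write_manifest(svm_dir, "svm", model_cfg$seed,
                 list(q_threshold = q_threshold),
                 file.path(scan_dir, "hits.tsv"))

  list(dataset = ds, cv = cv, motifs = fold_libs, common = common,
       hits = hits, profiles = profiles, svm = svm_metrics)
}
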