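## End-to-end orchestration: one config describes a run
## (dataset -> featurize -> first-level OOF -> meta -> evaluate -> report).

#' Build and validate a run configuration
#'
#' @param dataset Either a path to a bioassay CSV/TSV, a `bioassay_dataset`,
#'   or a [synthetic_assay_config()].
#' @param models List of `learner_spec`s, or `"all"` for the thirteen
#'   defaults.
#' @param combiner Meta-learner (see [train_meta()]); `"UNIFORM"` gives
#'   plain averaging.
#' @param repeats Repeated experiments (default 1).
#' @param master_seed Integer master seed.
#' @param output_dir Report directory (created if missing); `NULL` skips
#'   writing.
#' @param train_fraction,k Split parameters.
#' @param bagging `NULL`, or a list with `n_bags` to bag every first-level
#'   learner.
#' @param fingerprint_backend `"chemmineob"` or `"rdkit"`.
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return A validated `run_config`.
#' @export
run_config <- function(dataset, models = "all", combiner = "SVM",
                       repeats = 1, master_seed = 1, output_dir = NULL,
                       train_fraction = 0.75, k = 5, bagging = NULL,
                       fingerprint_backend = "chemmineob", quiet = TRUE) {
  if (identical(models, "all")) models <- all_default_specs(master_seed)
  if (!length(models)) stop_qsar("no models configured",
                                 class = "qsar_config_error")
  for (m in models)
    if (!inherits(m, "learner_spec"))
      stop_qsar("models must be learner_spec objects",
                class = "qsar_config_error")
  combiner <- match.arg(combiner, c("SVM", "LOGISTIC", "OLS", "RF", "GBM",
                                    "NN", "UNIFORM"))
  if (repeats < 1) stop_qsar("repeats must be >= 1",
                             class = "qsar_config_error")
  structure(list(dataset = dataset, models = models, combiner = combiner,
                 repeats = as.integer(repeats),
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir, train_fraction = train_fraction,
                 k = as.integer(k), bagging = bagging,
                 fingerprint_backend = fingerprint_backend, quiet = quiet),
            class = "run_config")
}

#' @noRd
resolve_dataset <- function(dataset) {
  if (inherits(dataset, "bioassay_dataset")) return(dataset)
  if (inherits(dataset, "synthetic_assay_config"))
    return(generate_synthetic_assay(dataset))
  if (is.character(dataset) && length(dataset) == 1) {
    fmt <- if (grepl("\\.tsv$", dataset)) "tsv" else "csv"
    return(read_bioassay(dataset, format = fmt))
  }
  stop_qsar("unsupported dataset specification", class = "qsar_config_error")
}

#' Run the full two-level pipeline from one configuration
#'
#' Stages, in order: resolve and clean the dataset, featurize every needed
#' representation, run the repeated split/OOF/meta/evaluate protocol, and
#' (optionally) write a report bundle: the AUC table (TSV), the last
#' repeat's OOF matrix (TSV), importance vector (JSON), test predictions
#' (TSV), and a manifest (JSON: seeds, config fingerprint, package version)
#' sufficient to re-run deterministically.
#'
#' @param cfg A [run_config()].
#' @return A `pipeline_result`: list with `experiment`
#'   (see [run_experiment()]), `importance` (linear combiners), `ensemble`
#'   (last repeat's fitted ensemble), `dataset`, and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!cfg$quiet) message(sprintf(...))
  stage <- "dataset"
  res <- tryCatch({
    ds <- resolve_dataset(cfg$dataset)
    ds <- deduplicate_bioassay(ds)
    say("dataset: %d compounds (%s)", nrow(ds), assay_id(ds))

    stage <- "featurize"
    reps <- unique(vapply(cfg$models, function(s) s$representation,
                          character(1)))
    features <- stats::setNames(lapply(reps, function(r)
      featurize_dataset(ds, r, backend = cfg$fingerprint_backend)), reps)
    say("featurized: %s", paste(reps, collapse = ", "))

    stage <- "experiment"
    exp <- run_experiment(ds, cfg$models, combiner = cfg$combiner,
                          repeats = cfg$repeats,
                          master_seed = cfg$master_seed,
                          train_fraction = cfg$train_fraction, k = cfg$k,
                          features = features,
                          n_bags = cfg$bagging$n_bags)

    stage <- "interpret"
    plan <- split_train_test(ds, cfg$train_fraction, cfg$k,
                             seed = derive_seed(cfg$master_seed, "repeat",
                                                cfg$repeats))
    ens <- train_ensemble(cfg$models, features, ds$label, plan,
                          combiner = cfg$combiner,
                          seed = derive_seed(cfg$master_seed, "meta",
                                             cfg$repeats),
                          n_bags = cfg$bagging$n_bags)
    imp <- if (cfg$combiner %in% c("SVM", "LOGISTIC", "OLS", "UNIFORM"))
      model_importance(ens$meta) else NULL

    manifest <- list(
      package_version = as.character(utils::packageVersion("qsarstack")),
      assay_id = assay_id(ds), n_compounds = nrow(ds),
      master_seed = cfg$master_seed, repeats = cfg$repeats,
      combiner = cfg$combiner,
      models = vapply(cfg$models, spec_label, character(1)),
      train_fraction = cfg$train_fraction, k = cfg$k,
      fingerprint_backend = cfg$fingerprint_backend)

    out <- structure(list(experiment = exp, importance = imp, ensemble = ens,
                          dataset = ds, features = features,
                          manifest = manifest),
                     class = "pipeline_result")
    if (!is.null(cfg$output_dir)) write_report(out, cfg$output_dir)
    out
  }, qsarstack_error = function(e) {
    stop_qsar("pipeline failed at stage '%s': %s", stage,
              conditionMessage(e), class = "qsar_pipeline_error")
  })
  res
}

#' @noRd
write_report <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(model = names(res$experiment$mean),
               mean_auc = unname(res$experiment$mean),
               sd_auc = unname(res$experiment$sd)),
    file.path(dir, "auc_table.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(res$ensemble$oof$P, file.path(dir, "oof_matrix.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$importance))
    jsonlite::write_json(as.list(res$importance),
                         file.path(dir, "importance.json"),
                         auto_unbox = TRUE, digits = NA)
  pr <- predict(res$ensemble, res$features)
  utils::write.table(
    data.frame(index = res$ensemble$plan$test_indices,
               probability = pr$probability),
    file.path(dir, "test_predictions.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %s, %d repeat(s), combiner %s>\n",
              x$manifest$assay_id, x$manifest$repeats, x$manifest$combiner))
  print(x$experiment)
  if (!is.null(x$importance)) {
    cat("Model importance:\n")
    print(round(x$importance, 3))
  }
  invisible(x)
}

#' Write a synthetic assay to a dataset CSV
#'
#' Companion to the command-line `synth` subcommand: materializes a
#' generated assay in the standard input format (`cid`, `smiles`,
#' `outcome`).
#'
#' @param cfg A [synthetic_assay_config()].
#' @param path Output CSV path.
#' @return Invisibly, the generated `bioassay_dataset`.
#' @export
write_synthetic_assay <- function(cfg, path) {
  ds <- generate_synthetic_assay(cfg)
  utils::write.csv(
    data.frame(cid = ds$compound_id, smiles = ds$smiles,
               outcome = ifelse(ds$label == 1, "Active", "Inactive")),
    path, row.names = FALSE, quote = FALSE)
  invisible(ds)
}
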