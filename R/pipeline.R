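## Config-driven runs: load the three inputs, build integrated
## similarities, predict, evaluate, and write outputs plus a manifest
## sufficient to reproduce the run. These functions back the
## `wbnproj` command-line script (inst/scripts/wbnproj).

.DEFAULT_CONFIG <- list(
  delta = 0.5, beta = -0.1,
  bandwidth_prime_m = 1, bandwidth_prime_d = 1,
  bandwidth_form = "divide",
  drop_isolated = FALSE,
  k = 5L, repeats = 10L, seed = 1L,
  betas = seq(-0.9, 0, by = 0.1),
  outdir = "."
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list) and
#' fills defaults. Recognized keys: `associations`, `functional_similarity`,
#' `dags` (input paths; the first is required), `delta`, `beta`,
#' `bandwidth_prime_m`, `bandwidth_prime_d`, `bandwidth_form`,
#' `drop_isolated`, `k`, `repeats`, `seed`, `betas`, `outdir`.
#'
#' @param config path to a YAML file, or a named list.
#' @return The completed configuration list.
#' @export
loadRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a named list")
  cfg <- modifyList(.DEFAULT_CONFIG, config)
  if (is.null(cfg$associations))
    stop("config is missing the required key 'associations'")
  for (key in c("associations", "functional_similarity", "dags")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("file not found: ", cfg[[key]], " (config key '", key, "')")
  }
  if (!(cfg$beta > -1 && cfg$beta <= 0)) stop("beta must lie in (-1, 0]")
  if (!(cfg$delta > 0 && cfg$delta <= 1)) stop("delta must lie in (0, 1]")
  if (!cfg$bandwidth_form %in% c("divide", "multiply"))
    stop("bandwidth_form must be 'divide' or 'multiply'")
  cfg
}

.loadInputs <- function(cfg) {
  assoc <- readAssociationTable(cfg$associations)
  if (isTRUE(cfg$drop_isolated)) assoc <- dropIsolated(assoc)
  fs <- if (!is.null(cfg$functional_similarity))
    readSimilarityMatrix(cfg$functional_similarity, kind = "functional")
  dags <- if (!is.null(cfg$dags)) readDiseaseDAGs(cfg$dags)
  list(assoc = assoc, fs = fs, dags = dags)
}

.integratedPair <- function(assoc, fs, dags, cfg) {
  ms <- if (is.null(fs)) {
    gipKernel(assoc, "mirna", cfg$bandwidth_prime_m, cfg$bandwidth_form)
  } else {
    integratedMirnaSimilarity(assoc, fs, cfg$bandwidth_prime_m,
                              cfg$bandwidth_form)
  }
  ds <- if (is.null(dags)) {
    gipKernel(assoc, "disease", cfg$bandwidth_prime_d, cfg$bandwidth_form)
  } else {
    integratedDiseaseSimilarity(assoc, dags, cfg$delta,
                                cfg$bandwidth_prime_d, cfg$bandwidth_form)
  }
  list(ms = ms, ds = ds)
}

.writeManifest <- function(cfg, outdir, extra = list()) {
  inputs <- Filter(Negate(is.null),
                   cfg[c("associations", "functional_similarity", "dags")])
  manifest <- c(list(
    package = "wbnproj",
    version = as.character(packageVersion("wbnproj")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[setdiff(names(cfg), "outdir")],
    input_md5 = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), character(1)))),
    extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the prediction pipeline from a configuration
#'
#' Loads the inputs, computes the integrated similarities, runs the
#' projection, and writes the final score matrix, the ranked per-disease
#' predictions, and a manifest (parameters, input checksums, package
#' version) to the output directory.
#'
#' @param config YAML path or named list (see [loadRunConfig()]).
#' @return Invisibly, a list with the final [ScoreMatrix-class] and the
#'   paths written.
#' @export
runPredict <- function(config) {
  cfg <- loadRunConfig(config)
  inp <- .loadInputs(cfg)
  sim <- .integratedPair(inp$assoc, inp$fs, inp$dags, cfg)
  scores <- predictScores(inp$assoc, sim$ms, sim$ds, beta = cfg$beta)
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(scores = file.path(outdir, "scores.tsv"),
             predictions = file.path(outdir, "ranked_predictions.tsv"))
  writeScoreMatrix(scores, paths[["scores"]])
  writeRankedPredictions(scores, inp$assoc, paths[["predictions"]])
  .writeManifest(cfg, outdir, list(command = "predict"))
  invisible(list(scores = scores, paths = paths))
}

#' Run a cross-validation protocol from a configuration
#'
#' @param config YAML path or named list (see [loadRunConfig()]).
#' @param protocol `"loocv"`, `"kfold"` or `"beta-sweep"`.
#' @return Invisibly, the [CVResult-class] (or sweep list) plus paths.
#'   Writes per-record TSV, a JSON summary (`auc`, `auc_mean`,
#'   `auc_sd`, `seed`, parameters), ROC points, and the manifest.
#' @export
runEvaluate <- function(config, protocol = c("loocv", "kfold",
                                             "beta-sweep")) {
  protocol <- match.arg(protocol)
  cfg <- loadRunConfig(config)
  inp <- .loadInputs(cfg)
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (protocol == "beta-sweep") {
    sweep <- betaSweep(inp$assoc, inp$fs, inp$dags, betas = cfg$betas,
                       protocol = "kfold", k = cfg$k,
                       repeats = cfg$repeats, seed = cfg$seed,
                       delta = cfg$delta,
                       bandwidthPrime = cfg$bandwidth_prime_d,
                       bandwidthForm = cfg$bandwidth_form)
    path <- file.path(outdir, "beta_sweep.tsv")
    write.table(sweep$table, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      list(protocol = protocol, best_beta = sweep$bestBeta,
           seed = cfg$seed),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
    .writeManifest(cfg, outdir, list(command = "evaluate",
                                     protocol = protocol))
    return(invisible(list(result = sweep, paths = path)))
  }
  res <- if (protocol == "loocv") {
    loocv(inp$assoc, inp$fs, inp$dags, beta = cfg$beta, delta = cfg$delta,
          bandwidthPrime = cfg$bandwidth_prime_d,
          bandwidthForm = cfg$bandwidth_form)
  } else {
    kfoldCV(inp$assoc, inp$fs, inp$dags, k = cfg$k, repeats = cfg$repeats,
            seed = cfg$seed, beta = cfg$beta, delta = cfg$delta,
            bandwidthPrime = cfg$bandwidth_prime_d,
            bandwidthForm = cfg$bandwidth_form)
  }
  paths <- c(records = file.path(outdir, "cv_records.tsv"),
             roc = file.path(outdir, "roc_points.tsv"),
             summary = file.path(outdir, "summary.json"))
  write.table(res@records, paths[["records"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cvRoc(res), paths[["roc"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(protocol = res@protocol, auc = res@auc,
         auc_mean = res@aucMean, auc_sd = res@aucSd,
         n_records = nrow(res@records), n_failed = nrow(res@failed),
         seed = res@seed,
         params = cfg[c("beta", "delta", "bandwidth_form", "k", "repeats")]),
    paths[["summary"]], auto_unbox = TRUE, digits = NA)
  .writeManifest(cfg, outdir, list(command = "evaluate",
                                   protocol = protocol))
  invisible(list(result = res, paths = paths))
}

#' Generate and write a synthetic dataset from a specification
#'
#' @param spec YAML path or named list with any of the
#'   [generateDataset()] arguments (`nm`, `nd`, `n_blocks`, `p_within`,
#'   `p_between`, `fs_signal`, `dag_depth`, `seed`).
#' @param outdir output directory.
#' @return Invisibly, the dataset list plus the written paths.
#' @export
runSynth <- function(spec = list(), outdir = ".") {
  if (is.character(spec)) {
    if (!file.exists(spec)) stop("spec file not found: ", spec)
    spec <- yaml::read_yaml(spec)
  }
  args <- list(nm = spec$nm, nd = spec$nd, nBlocks = spec$n_blocks,
               pWithin = spec$p_within, pBetween = spec$p_between,
               fsSignal = spec$fs_signal, dagDepth = spec$dag_depth,
               seed = spec$seed)
  args <- Filter(Negate(is.null), args)
  ds <- do.call(generateDataset, args)
  paths <- writeDataset(ds, outdir)
  invisible(list(dataset = ds, paths = paths))
}
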