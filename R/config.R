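# Orchestration: config validation and the five pipeline stages
# (simulate / build-graph / train / evaluate / interpret).

.CONFIG_DEFAULTS <- list(
  alpha = 0.05, radius = 2, n_bits = 1024,
  batch_size = 64, epochs = 50, learning_rate = 0.001,
  strategy = "pair_kfold", k = 5, seed = 1,
  ic_scale = "ln", divisor = "availability",
  runs = 10, top_k = 20, n_select = 10,
  n_cells = 250, n_genes = 150, n_proteins = 60, n_pathways = 15, n_drugs = 8,
  edge_density_gp = 0.05, edge_density_pk = 0.25, edge_density_kd = 0.35,
  n_driver_genes = 10, signal_strength = 4, noise_sd = 0.5,
  n_cancer_types = 6)

.CONFIG_PATH_KEYS <- c("data_dir", "graph_dir", "model_path")
.CONFIG_KEYS <- c(names(.CONFIG_DEFAULTS), .CONFIG_PATH_KEYS, "out_dir")

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; applies the reference defaults
#' (batch size 64, 50 epochs, learning rate 0.001, 1024 fingerprint bits,
#' pathway cutoff 0.05, 5 folds), and reports every problem — unknown keys and
#' missing input paths — in a single error.
#'
#' @param config YAML file path or named list.
#' @param requirePaths character vector of path keys that must exist for the
#'   intended command (e.g. \code{"data_dir"} for training).
#' @return the normalized configuration: a named list with class
#'   \code{"RunConfig"}. Re-validating the result is the identity.
#' @export
validateConfig <- function(config = list(), requirePaths = character()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stopf("config must be a file path or a named list")
  config <- config[!vapply(config, is.null, TRUE)]
  class(config) <- NULL

  problems <- character()
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, config)
  for (key in union(requirePaths, intersect(.CONFIG_PATH_KEYS, names(config)))) {
    if (is.null(cfg[[key]]))
      problems <- c(problems, sprintf("missing required path '%s'", key))
    else if (!file.exists(cfg[[key]]))
      problems <- c(problems, sprintf("path '%s' does not exist: %s",
                                      key, cfg[[key]]))
  }
  if (!cfg$strategy %in% c("pair_kfold", "lodo", "loclo", "loco"))
    problems <- c(problems, sprintf("unknown strategy '%s'", cfg$strategy))
  if (length(problems))
    stopf("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  structure(cfg, class = "RunConfig")
}

.asTrainConfig <- function(cfg) {
  trainConfig(batchSize = cfg$batch_size, epochs = cfg$epochs,
              learningRate = cfg$learning_rate, seed = cfg$seed)
}

.writeManifest <- function(outDir, cfg, command, inputs, outputs,
                           status = "complete") {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = command, status = status,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("maskDRP")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(outputs),
    config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.bundlePaths <- function(dir) {
  file.path(dir, c(sprintf("omics_%s.csv", c("ge", "cnv", "mut", "prot")),
                   "gp_edges.tsv", "pk_edges.tsv", "kd_edges.tsv",
                   "drugs.csv", "responses.csv", "cancer_types.csv"))
}

.planFromConfig <- function(cfg, responses) {
  switch(cfg$strategy,
    pair_kfold = splitPairKFold(responses, k = cfg$k, seed = cfg$seed),
    lodo = splitLODO(responses),
    loclo = splitLOCLO(responses),
    loco = splitLOCO(responses))
}

#' Run one pipeline stage
#'
#' Executes the module chain for one of the five commands and writes a
#' machine-readable run manifest (input checksums, seed, versions, outputs)
#' into the output directory. Errors during a stage are re-signalled with the
#' stage name, and a partial manifest with \code{status = "failed"} is left
#' behind.
#'
#' Commands: \describe{
#'   \item{simulate}{generate a synthetic study into \code{out_dir}.}
#'   \item{build-graph}{read annotation tables from \code{data_dir}, filter
#'     pathways at \code{alpha}, prune, and export masks.}
#'   \item{train}{train on the full response table of \code{data_dir}; writes a
#'     model checkpoint and loss history.}
#'   \item{evaluate}{cross-validated metrics under \code{strategy}; writes a
#'     tidy per-fold CSV.}
#'   \item{interpret}{multi-run importance analysis of a trained checkpoint;
#'     writes per-entity score and aggregation CSVs.}
#' }
#'
#' @param cfg a \code{RunConfig} from [validateConfig()] (or a raw list/path,
#'   validated on the fly).
#' @param command one of \code{"simulate"}, \code{"build-graph"},
#'   \code{"train"}, \code{"evaluate"}, \code{"interpret"}.
#' @return invisibly, a list of stage artifacts (paths and key objects).
#' @export
runPipeline <- function(cfg, command = c("simulate", "build-graph", "train",
                                         "evaluate", "interpret")) {
  command <- match.arg(command)
  needs <- switch(command, simulate = character(),
                  `build-graph` = "data_dir", train = "data_dir",
                  evaluate = "data_dir", interpret = c("data_dir", "model_path"))
  if (!inherits(cfg, "RunConfig")) cfg <- validateConfig(cfg, requirePaths = needs)
  if (is.null(cfg$out_dir)) stopf("config needs 'out_dir'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      .writeManifest(cfg$out_dir, cfg, command, character(),
                     list(), status = "failed")
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  out <- switch(command,
    simulate = run("simulate", {
      spec <- syntheticSpec(
        nCells = cfg$n_cells, nGenes = cfg$n_genes, nProteins = cfg$n_proteins,
        nPathways = cfg$n_pathways, nDrugs = cfg$n_drugs,
        edgeDensityGP = cfg$edge_density_gp, edgeDensityPK = cfg$edge_density_pk,
        edgeDensityKD = cfg$edge_density_kd, nDriverGenes = cfg$n_driver_genes,
        signalStrength = cfg$signal_strength, noiseSd = cfg$noise_sd,
        fingerprintBits = cfg$n_bits, nCancerTypes = cfg$n_cancer_types,
        seed = cfg$seed)
      bundle <- simulateDataset(spec, cfg$out_dir)
      logMsg("simulate: wrote %d response records for %d cells x %d drugs",
             nrow(bundle$responses), spec@nCells, spec@nDrugs)
      .writeManifest(cfg$out_dir, cfg, command, character(),
                     as.list(.bundlePaths(cfg$out_dir)))
      list(bundle = bundle)
    }),
    `build-graph` = run("build-graph", {
      bundle <- readBundle(cfg$data_dir, radius = cfg$radius, nBits = cfg$n_bits,
                           icScale = cfg$ic_scale)
      h <- filterSignificantPathways(bundle$hierarchy, cfg$alpha)
      h <- pruneHierarchy(h)
      masks <- masksFromHierarchy(h)
      paths <- writeMasksCsv(masks, cfg$out_dir)
      .writeManifest(cfg$out_dir, cfg, command, .bundlePaths(cfg$data_dir),
                     as.list(paths))
      list(hierarchy = h, masks = masks, paths = paths)
    }),
    train = run("train", {
      bundle <- readBundle(cfg$data_dir, radius = cfg$radius, nBits = cfg$n_bits,
                           icScale = cfg$ic_scale)
      integrated <- integrateOmics(lapply(bundle$omics, minmaxScale),
                                   divisor = cfg$divisor)
      h <- filterSignificantPathways(bundle$hierarchy, cfg$alpha)
      h <- pruneHierarchy(.restrictGenes(h, featureIds(integrated)))
      masks <- masksFromHierarchy(h)
      tc <- .asTrainConfig(cfg)
      net <- initNetwork(masks, nBits = cfg$n_bits, config = tc, hierarchy = h)
      fit <- trainNetwork(net, integrated, bundle$drugs, bundle$responses, tc)
      modelPath <- file.path(cfg$out_dir, "model.rds")
      saveNetwork(fit$network, modelPath)
      histPath <- file.path(cfg$out_dir, "history.csv")
      utils::write.csv(fit$history, histPath, row.names = FALSE)
      .writeManifest(cfg$out_dir, cfg, command, .bundlePaths(cfg$data_dir),
                     list(model = modelPath, history = histPath))
      list(network = fit$network, history = fit$history, model_path = modelPath)
    }),
    evaluate = run("evaluate", {
      bundle <- readBundle(cfg$data_dir, radius = cfg$radius, nBits = cfg$n_bits,
                           icScale = cfg$ic_scale)
      plan <- .planFromConfig(cfg, bundle$responses)
      res <- runExperiment(bundle$omics, bundle$hierarchy, bundle$drugs,
                           bundle$responses, plan, .asTrainConfig(cfg),
                           alpha = cfg$alpha, divisor = cfg$divisor)
      metricsPath <- file.path(cfg$out_dir, "metrics.csv")
      utils::write.csv(res, metricsPath, row.names = FALSE)
      summaryPath <- file.path(cfg$out_dir, "metrics_summary.csv")
      utils::write.csv(attr(res, "summary"), summaryPath, row.names = FALSE)
      .writeManifest(cfg$out_dir, cfg, command, .bundlePaths(cfg$data_dir),
                     list(metrics = metricsPath, summary = summaryPath))
      list(metrics = res)
    }),
    interpret = run("interpret", {
      bundle <- readBundle(cfg$data_dir, radius = cfg$radius, nBits = cfg$n_bits,
                           icScale = cfg$ic_scale)
      integrated <- integrateOmics(lapply(bundle$omics, minmaxScale),
                                   divisor = cfg$divisor)
      ref <- loadNetwork(cfg$model_path)
      masks <- ref@masks; names(masks) <- c("gp", "pk", "kd")
      reports <- lapply(seq_len(cfg$runs), function(r) {
        tc <- trainConfig(batchSize = cfg$batch_size, epochs = cfg$epochs,
                          learningRate = cfg$learning_rate,
                          seed = childSeed(cfg$seed, sprintf("run%d", r)))
        net <- initNetwork(masks, nBits = cfg$n_bits, config = tc)
        fit <- trainNetwork(net, integrated, bundle$drugs, bundle$responses, tc)
        geneImportanceReport(fit$network, integrated, bundle$drugs,
                             bundle$responses, seed = tc@seed, runId = r)
      })
      agg <- aggregateRuns(reports, topK = cfg$top_k, nSelect = cfg$n_select)
      tidy <- do.call(rbind, lapply(reports, function(r) {
        s <- importanceScores(r)
        sc <- setdiff(names(s), "entity_id")
        data.frame(level = r@level,
                   entity_id = rep(s$entity_id, times = length(sc)),
                   score_name = rep(sc, each = nrow(s)),
                   value = unname(unlist(s[sc])),
                   run_id = r@runId, row.names = NULL)
      }))
      scorePath <- file.path(cfg$out_dir, "importance.csv")
      utils::write.csv(tidy, scorePath, row.names = FALSE)
      aggPath <- file.path(cfg$out_dir, "importance_top.csv")
      utils::write.csv(agg, aggPath, row.names = FALSE)
      .writeManifest(cfg$out_dir, cfg, command,
                     c(.bundlePaths(cfg$data_dir), cfg$model_path),
                     list(importance = scorePath, top = aggPath))
      list(reports = reports, aggregated = agg)
    }))
  invisible(out)
}
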