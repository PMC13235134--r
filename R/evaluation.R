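.newPlan <- function(strategy, folds, seed = NA_integer_) {
  plan <- methods::new("SplitPlan", strategy = strategy, folds = folds,
                       seed = as.integer(seed))
  methods::validObject(plan)
  plan
}

#' Random k-fold split over (cell line, drug) pairs
#'
#' Seeded random partition of the response records into k folds with no
#' restriction on drugs or cell lines: a pair is in exactly one of training or
#' testing, but the same drug or cell line may appear on both sides.
#'
#' @param records response data.frame (one row per pair).
#' @param k number of folds (>= 2); default 5.
#' @param seed integer seed.
#' @return a [SplitPlan-class].
#' @export
splitPairKFold <- function(records, k = 5, seed = 1) {
  n <- nrow(records)
  if (k < 2) stopf("k must be >= 2")
  if (k > n) stopf("k = %d exceeds the number of records (%d)", k, n)
  assign <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  folds <- lapply(seq_len(k), function(i) {
    test <- which(assign == i)
    list(fold_id = sprintf("fold%d", i), train = which(assign != i), test = test)
  })
  .newPlan("pair_kfold", folds, seed)
}

.groupSplit <- function(records, groups, strategy, what) {
  ug <- unique(groups)
  if (length(ug) < 2) stopf("need at least 2 distinct %s for %s", what, strategy)
  folds <- lapply(ug, function(g) {
    list(fold_id = as.character(g),
         train = which(groups != g), test = which(groups == g))
  })
  .newPlan(strategy, folds)
}

#' Leave-one-drug-out split
#'
#' One fold per drug; the fold's test set is exactly that drug's records, so no
#' information about the held-out drug is seen in training.
#'
#' @param records response data.frame with a \code{drug_id} column.
#' @return a [SplitPlan-class].
#' @export
splitLODO <- function(records) {
  .groupSplit(records, records$drug_id, "lodo", "drugs")
}

#' Leave-one-cell-line-out split
#'
#' One fold per cell line, symmetric to [splitLODO()].
#'
#' @param records response data.frame with a \code{cell_id} column.
#' @return a [SplitPlan-class].
#' @export
splitLOCLO <- function(records) {
  .groupSplit(records, records$cell_id, "loclo", "cell lines")
}

#' Leave-one-cancer-type-out split
#'
#' One fold per cancer type; all cell lines of the held-out type are excluded
#' from training.
#'
#' @param records response data.frame with a \code{cell_id} column (and
#'   optionally \code{cancer_type}).
#' @param cancerMap named character vector mapping cell IDs to cancer types;
#'   defaults to the records' \code{cancer_type} column.
#' @return a [SplitPlan-class].
#' @export
splitLOCO <- function(records, cancerMap = NULL) {
  if (is.null(cancerMap)) {
    if (is.null(records$cancer_type))
      stopf("provide cancerMap or a cancer_type column")
    types <- records$cancer_type
  } else {
    unmapped <- setdiff(unique(records$cell_id), names(cancerMap))
    if (length(unmapped))
      stopf("unmapped cell line(s): %s", paste(unmapped, collapse = ", "))
    types <- unname(cancerMap[records$cell_id])
  }
  .groupSplit(records, types, "loco", "cancer types")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the chance that a
#' random positive outranks a random negative, with ties counted one half
#' (implemented through midranks).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels lengths differ")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stopf("AUC is undefined: only one class present")
  r <- rank(scores)
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step rule: records are ranked by decreasing score and the
#' area is the sum over positive ranks of precision-at-rank times the recall
#' increment (average precision).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return AUPR in (0, 1].
#' @export
auprScore <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels lengths differ")
  nPos <- sum(labels == 1)
  if (nPos == 0) stopf("AUPR is undefined: no positive labels")
  ord <- order(-scores)
  hits <- labels[ord] == 1
  prec <- cumsum(hits) / seq_along(hits)
  sum(prec[hits]) / nPos
}

.accuracyScore <- function(scores, labels, threshold = 0.5) {
  mean(as.integer(scores >= threshold) == labels)
}

# Restrict a hierarchy's gene level to a universe (drops genes + their edges;
# leaves it unpruned).
.restrictGenes <- function(h, geneUniverse) {
  h@genes <- intersect(h@genes, geneUniverse)
  h@edgesGP <- h@edgesGP[h@edgesGP$gene %in% h@genes, , drop = FALSE]
  h@pruned <- FALSE
  h
}

#' Run one cross-validation experiment end to end
#'
#' For each fold of the plan: min-max scale each omics layer, integrate them
#' (optionally restricted to \code{omicsSubset} kinds), filter pathways at
#' \code{alpha}, re-prune the hierarchy against the integrated gene universe,
#' build masks, train a fresh network on the fold's training records (each fold
#' gets its own seed substream derived from the config seed), predict the test
#' records and score them. Preprocessing is deterministic, so it is computed
#' once outside the fold loop.
#'
#' Folds whose test set contains a single class are reported with \code{NA}
#' metrics rather than dropped.
#'
#' @param omics list of [OmicsMatrix-class] layers.
#' @param hierarchy an unpruned [BioHierarchy-class].
#' @param drugs a [DrugSet-class].
#' @param responses response data.frame (\code{cell_id}, \code{drug_id},
#'   \code{label}, optionally \code{cancer_type}).
#' @param plan a [SplitPlan-class] over \code{responses} row order.
#' @param config a [TrainConfig-class].
#' @param omicsSubset optional character vector of omics kinds to integrate
#'   (ablation switch); \code{NULL} keeps all layers.
#' @param alpha pathway significance cutoff (1 disables filtering).
#' @param divisor integration divisor mode, see [integrateOmics()].
#' @return data.frame with one row per fold (\code{strategy}, \code{fold_id},
#'   \code{n_train}, \code{n_test}, \code{auc}, \code{aupr}, \code{accuracy});
#'   the across-fold mean and sample standard deviation are attached via
#'   [experimentSummary()].
#' @export
runExperiment <- function(omics, hierarchy, drugs, responses, plan,
                          config = trainConfig(), omicsSubset = NULL,
                          alpha = 0.05, divisor = "availability") {
  stopifnot(is(plan, "SplitPlan"))
  kinds <- vapply(omics, omicsKind, character(1))
  if (!is.null(omicsSubset)) {
    bad <- setdiff(omicsSubset, kinds)
    if (length(bad)) stopf("unknown omics kind(s): %s", paste(bad, collapse = ", "))
    omics <- omics[kinds %in% omicsSubset]
  }
  integrated <- integrateOmics(lapply(omics, minmaxScale), divisor = divisor)
  h <- filterSignificantPathways(hierarchy, alpha)
  h <- pruneHierarchy(.restrictGenes(h, featureIds(integrated)))
  masks <- masksFromHierarchy(h)
  nBits <- ncol(fingerprints(drugs))

  rows <- lapply(plan@folds, function(fold) {
    foldCfg <- trainConfig(batchSize = config@batchSize, epochs = config@epochs,
                           learningRate = config@learningRate,
                           seed = childSeed(config@seed, fold$fold_id),
                           initScheme = config@initScheme)
    net <- initNetwork(masks, nBits = nBits, config = foldCfg, hierarchy = h)
    fit <- tryCatch(
      trainNetwork(net, integrated, drugs, responses[fold$train, , drop = FALSE],
                   foldCfg),
      error = function(e) stopf("fold %s: %s", fold$fold_id, conditionMessage(e)))
    test <- responses[fold$test, , drop = FALSE]
    p <- predictResponse(fit$network, test, integrated, drugs)
    oneClass <- length(unique(test$label)) < 2
    data.frame(
      strategy = plan@strategy, fold_id = fold$fold_id,
      n_train = length(fold$train), n_test = length(fold$test),
      auc = if (oneClass) NA_real_ else aucScore(p, test$label),
      aupr = if (sum(test$label) == 0) NA_real_ else auprScore(p, test$label),
      accuracy = .accuracyScore(p, test$label),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "summary") <- experimentSummary(res)
  res
}

#' Across-fold mean and standard deviation of the experiment metrics
#'
#' Uses the sample standard deviation; undefined-metric folds (\code{NA}) are
#' excluded from the summary but remain in the per-fold table.
#'
#' @param results per-fold data.frame from [runExperiment()].
#' @return data.frame with columns \code{metric}, \code{mean}, \code{sd},
#'   \code{n_folds}.
#' @export
experimentSummary <- function(results) {
  do.call(rbind, lapply(c("auc", "aupr", "accuracy"), function(m) {
    v <- results[[m]][!is.na(results[[m]])]
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v),
               n_folds = length(v), stringsAsFactors = FALSE)
  }))
}

#' Omics ablation harness
#'
#' Re-runs the full pipeline once per configuration: each single-omics layer,
#' each leave-one-omics-out subset, and all layers together, mirroring the
#' systematic removal design. The hierarchy is re-pruned against each reduced
#' gene universe.
#'
#' @param omics,hierarchy,drugs,responses,plan,config,alpha as in
#'   [runExperiment()].
#' @param configurations optional named list of omics-kind subsets; the default
#'   covers gene expression alone, every leave-one-out triple and the full set.
#' @return data.frame with one row per (configuration, fold) plus a
#'   \code{configuration} column; per-configuration summaries are attached as
#'   attribute \code{"summary"}.
#' @export
ablationStudy <- function(omics, hierarchy, drugs, responses, plan,
                          config = trainConfig(), alpha = 0.05,
                          configurations = NULL) {
  kinds <- vapply(omics, omicsKind, character(1))
  if (is.null(configurations)) {
    configurations <- c(
      list(only_GE = "GE"),
      stats::setNames(lapply(kinds, function(k) setdiff(kinds, k)),
                      paste0("without_", kinds)),
      list(all_omics = kinds))
  }
  out <- lapply(names(configurations), function(nm) {
    res <- runExperiment(omics, hierarchy, drugs, responses, plan, config,
                         omicsSubset = configurations[[nm]], alpha = alpha)
    cbind(configuration = nm, res, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(names(configurations), function(nm) {
    cbind(configuration = nm,
          experimentSummary(res[res$configuration == nm, , drop = FALSE]),
          stringsAsFactors = FALSE)
  }))
  attr(res, "summary") <- summ
  res
}
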