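#' Gene-layer input matrix for a set of response records
#'
#' Extracts the integrated feature rows for the records' cell lines, restricted
#' to the network's gene order — the \code{x} matrix every gene-level
#' importance score is defined over.
#'
#' @param net a [MaskedNetwork-class].
#' @param features an [IntegratedCellFeatures-class].
#' @param responses response data.frame (\code{cell_id}, \code{drug_id},
#'   \code{label}).
#' @return numeric matrix, one row per record, columns in network gene order.
#' @export
geneInputs <- function(net, features, responses) {
  if (nrow(responses) == 0L) stopf("empty test set")
  genes <- net@nodeOrders$genes
  miss <- setdiff(genes, featureIds(features))
  if (length(miss)) stopf("feature matrix lacks network gene(s): %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  featureValues(features)[responses$cell_id, genes, drop = FALSE]
}

#' Gradient-based gene importance
#'
#' Mean absolute partial derivative of the per-sample loss with respect to each
#' gene input, averaged over the test samples. Fingerprint bits are not scored:
#' importance is reported for the biological input layer only.
#'
#' @param net a trained [MaskedNetwork-class].
#' @param features an [IntegratedCellFeatures-class].
#' @param drugs a [DrugSet-class].
#' @param responses labelled test records.
#' @return named nonnegative vector, one score per network gene.
#' @export
gradientImportance <- function(net, features, drugs, responses) {
  if (nrow(responses) == 0L) stopf("empty test set")
  batch <- .resolveBatch(net, responses, features, drugs)
  G <- .inputGradients(net, batch$X, batch$FP, batch$y)
  stats::setNames(colMeans(abs(G)), net@nodeOrders$genes)
}

#' Activation (magnitude) importance
#'
#' Mean absolute input value per feature; model-independent.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @return named nonnegative vector of per-feature scores.
#' @export
activationImportance <- function(x) {
  if (is.null(dim(x)) || nrow(x) == 0L) stopf("empty test set")
  colMeans(abs(x))
}

#' Variance importance
#'
#' Unbiased (N-1 divisor) sample variance per feature.
#'
#' @param x numeric matrix with at least two rows.
#' @return named nonnegative vector of per-feature scores.
#' @export
varianceImportance <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 2L) stopf("need at least 2 samples")
  apply(x, 2, stats::var)
}

#' Permutation importance
#'
#' For each gene, its column of the test inputs is shuffled (seeded), the mean
#' loss is recomputed, and the score is the increase over the baseline loss,
#' clipped at zero and averaged over \code{nRepeats} shuffles. The error metric
#' is the same binary cross-entropy the model is trained on.
#'
#' @param net a trained [MaskedNetwork-class].
#' @param features an [IntegratedCellFeatures-class].
#' @param drugs a [DrugSet-class].
#' @param responses labelled test records (at least 2).
#' @param nRepeats number of shuffles per gene; default 5.
#' @param seed integer seed for the shuffles.
#' @return named nonnegative vector, one score per network gene.
#' @export
permutationImportance <- function(net, features, drugs, responses,
                                  nRepeats = 5, seed = 1) {
  if (nrow(responses) < 2L) stopf("need at least 2 test samples")
  batch <- .resolveBatch(net, responses, features, drugs)
  base <- bceLoss(.forwardBatch(net, batch$X, batch$FP)$prob, batch$y)
  nGenes <- ncol(batch$X)
  scores <- withSeed(seed, {
    s <- numeric(nGenes)
    for (r in seq_len(nRepeats)) {
      for (i in seq_len(nGenes)) {
        Xp <- batch$X
        Xp[, i] <- Xp[sample.int(nrow(Xp)), i]
        permLoss <- bceLoss(.forwardBatch(net, Xp, batch$FP)$prob, batch$y)
        s[i] <- s[i] + max(0, permLoss - base)
      }
    }
    s / nRepeats
  })
  stats::setNames(scores, net@nodeOrders$genes)
}

#' Combine the four gene-importance scores
#'
#' The four component scores live on incommensurable scales, so each vector is
#' min-max normalized to [0, 1] across genes before averaging (raw-scale
#' averaging, which lets the variance term dominate, is available with
#' \code{normalize = FALSE}).
#'
#' @param grad,act,var,perm aligned per-gene score vectors.
#' @param normalize min-max normalize each component first (default TRUE).
#' @return named per-gene combined score.
#' @export
combinedImportance <- function(grad, act, var, perm, normalize = TRUE) {
  n <- length(grad)
  if (length(act) != n || length(var) != n || length(perm) != n)
    stopf("the four score vectors must have equal length")
  comps <- list(grad, act, var, perm)
  if (normalize) {
    comps <- lapply(comps, function(s) {
      rng <- max(s) - min(s)
      if (rng > 0) (s - min(s)) / rng else rep(0, length(s))
    })
  }
  out <- (comps[[1]] + comps[[2]] + comps[[3]] + comps[[4]]) / 4
  names(out) <- names(grad)
  out
}

#' Mean absolute activation per node of a hidden layer
#'
#' Extracts the intermediate activations of the protein, pathway or drug layer
#' over the test samples and averages their absolute values per node.
#'
#' @param net a trained [MaskedNetwork-class].
#' @param features an [IntegratedCellFeatures-class].
#' @param drugs a [DrugSet-class].
#' @param responses test records.
#' @param level \code{"protein"}, \code{"pathway"} or \code{"drug"}.
#' @return named nonnegative vector, one score per node of the chosen layer.
#' @export
layerImportance <- function(net, features, drugs, responses,
                            level = c("protein", "pathway", "drug")) {
  level <- match.arg(level)
  if (nrow(responses) == 0L) stopf("empty test set")
  batch <- .resolveBatch(net, responses, features, drugs)
  fw <- .forwardBatch(net, batch$X, batch$FP)
  act <- switch(level, protein = fw$H1, pathway = fw$H2, drug = fw$H3)
  ids <- switch(level, protein = net@nodeOrders$proteins,
                pathway = net@nodeOrders$pathways, drug = net@nodeOrders$drugs)
  stats::setNames(colMeans(abs(act)), ids)
}

#' Full gene-level importance report
#'
#' Computes the four component scores and their combination for one trained
#' model and test set.
#'
#' @param net a trained [MaskedNetwork-class].
#' @param features an [IntegratedCellFeatures-class].
#' @param drugs a [DrugSet-class].
#' @param responses labelled test records.
#' @param nRepeats,seed permutation-importance settings.
#' @param runId integer run identifier.
#' @return an [ImportanceReport-class] at gene level with score columns
#'   \code{grad}, \code{act}, \code{var}, \code{perm}, \code{combined}.
#' @export
geneImportanceReport <- function(net, features, drugs, responses,
                                 nRepeats = 5, seed = 1, runId = 1L) {
  x <- geneInputs(net, features, responses)
  grad <- gradientImportance(net, features, drugs, responses)
  act <- activationImportance(x)
  vr <- varianceImportance(x)
  perm <- permutationImportance(net, features, drugs, responses,
                                nRepeats = nRepeats, seed = seed)
  methods::new("ImportanceReport",
    level = "gene", entityIds = net@nodeOrders$genes,
    scores = data.frame(grad = unname(grad), act = unname(act),
                        var = unname(vr), perm = unname(perm),
                        combined = unname(combinedImportance(grad, act, vr, perm))),
    nSamples = nrow(responses), runId = as.integer(runId))
}

#' Layer-level importance report
#'
#' @param net,features,drugs,responses as in [layerImportance()].
#' @param level \code{"protein"}, \code{"pathway"} or \code{"drug"}.
#' @param runId integer run identifier.
#' @return an [ImportanceReport-class] with a single \code{layer} score column.
#' @export
layerImportanceReport <- function(net, features, drugs, responses, level,
                                  runId = 1L) {
  s <- layerImportance(net, features, drugs, responses, level)
  methods::new("ImportanceReport",
    level = level, entityIds = names(s),
    scores = data.frame(layer = unname(s)),
    nSamples = nrow(responses), runId = as.integer(runId))
}

#' Aggregate importance reports across independent runs
#'
#' Within each run the top \code{topK} entities by score are selected; the
#' selections are pooled and the \code{nSelect} most frequently occurring
#' entities are returned, ranked by frequency, with ties broken by mean score
#' across runs and then by entity ID.
#'
#' @param reports list of [ImportanceReport-class] objects sharing one level
#'   and entity universe.
#' @param topK entities taken per run (default 20).
#' @param nSelect entities returned overall (default 10).
#' @param scoreColumn score used for ranking; defaults to \code{combined} at
#'   gene level and \code{layer} elsewhere.
#' @return data.frame with columns \code{entity_id}, \code{frequency},
#'   \code{mean_score}, ordered by rank.
#' @export
aggregateRuns <- function(reports, topK = 20, nSelect = 10, scoreColumn = NULL) {
  if (!length(reports)) stopf("empty report list")
  lv <- unique(vapply(reports, function(r) r@level, character(1)))
  if (length(lv) != 1L) stopf("reports mix levels: %s", paste(lv, collapse = ", "))
  universe <- reports[[1]]@entityIds
  if (!all(vapply(reports, function(r) setequal(r@entityIds, universe), TRUE)))
    stopf("reports do not share one entity universe")
  if (is.null(scoreColumn)) scoreColumn <- if (lv == "gene") "combined" else "layer"

  picks <- lapply(reports, function(r) {
    s <- r@scores[[scoreColumn]]
    if (is.null(s)) stopf("report lacks score column '%s'", scoreColumn)
    ord <- order(-s, r@entityIds, method = "radix")
    r@entityIds[ord[seq_len(min(topK, length(ord)))]]
  })
  freq <- table(factor(unlist(picks), levels = universe))
  meanScore <- rowMeans(vapply(reports, function(r) {
    stats::setNames(r@scores[[scoreColumn]], r@entityIds)[universe]
  }, numeric(length(universe))))
  keep <- names(freq)[freq > 0]
  ord <- order(-as.numeric(freq[keep]), -meanScore[keep], keep, method = "radix")
  sel <- keep[ord][seq_len(min(nSelect, length(keep)))]
  data.frame(entity_id = sel, frequency = as.integer(freq[sel]),
             mean_score = unname(meanScore[sel]), stringsAsFactors = FALSE)
}
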