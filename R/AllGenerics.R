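#' @title Accessors for maskDRP classes
#' @description Small accessor generics so downstream code never touches slots
#'   directly.
#' @param x an object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x, ...) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("pathwayIds", function(x, ...) standardGeneric("pathwayIds"))
#' @rdname accessors
#' @export
setGeneric("drugIds", function(x, ...) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x, ...) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x, ...) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("omicsKind", function(x, ...) standardGeneric("omicsKind"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x, ...) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x, level, ...) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("isPruned", function(x) standardGeneric("isPruned"))
#' @rdname accessors
#' @export
setGeneric("maxConc", function(x, ...) standardGeneric("maxConc"))
#' @rdname accessors
#' @export
setGeneric("fingerprints", function(x, ...) standardGeneric("fingerprints"))
#' @rdname accessors
#' @export
setGeneric("importanceScores", function(x, ...) standardGeneric("importanceScores"))

#' @rdname accessors
setMethod("geneIds", "BioHierarchy", function(x, ...) x@genes)
#' @rdname accessors
setMethod("proteinIds", "BioHierarchy", function(x, ...) x@proteins)
#' @rdname accessors
setMethod("pathwayIds", "BioHierarchy", function(x, ...) x@pathways)
#' @rdname accessors
setMethod("drugIds", "BioHierarchy", function(x, ...) x@drugs)
#' @rdname accessors
setMethod("isPruned", "BioHierarchy", function(x) x@pruned)

#' @rdname accessors
#' @param level for \code{edgeTable}: \code{"gp"}, \code{"pk"} or \code{"kd"}.
setMethod("edgeTable", "BioHierarchy", function(x, level = c("gp", "pk", "kd"), ...) {
  switch(match.arg(level), gp = x@edgesGP, pk = x@edgesPK, kd = x@edgesKD)
})

#' @rdname accessors
setMethod("cellIds", "OmicsMatrix", function(x, ...) rownames(x@values))
#' @rdname accessors
setMethod("featureIds", "OmicsMatrix", function(x, ...) colnames(x@values))
#' @rdname accessors
setMethod("featureValues", "OmicsMatrix", function(x, ...) x@values)
#' @rdname accessors
setMethod("omicsKind", "OmicsMatrix", function(x, ...) x@kind)

#' @rdname accessors
setMethod("cellIds", "IntegratedCellFeatures", function(x, ...) rownames(x@values))
#' @rdname accessors
setMethod("featureIds", "IntegratedCellFeatures", function(x, ...) colnames(x@values))
#' @rdname accessors
setMethod("featureValues", "IntegratedCellFeatures", function(x, ...) x@values)

#' @rdname accessors
setMethod("maskMatrix", "LayerMask", function(x, ...) x@mask)

#' @rdname accessors
setMethod("drugIds", "DrugSet", function(x, ...) x@drugIds)
#' @rdname accessors
setMethod("maxConc", "DrugSet", function(x, ...) {
  stats::setNames(x@maxConc, x@drugIds)
})
#' @rdname accessors
setMethod("fingerprints", "DrugSet", function(x, ...) {
  fp <- x@fingerprints
  rownames(fp) <- x@drugIds
  fp
})

#' @rdname accessors
setMethod("importanceScores", "ImportanceReport", function(x, ...) {
  cbind(data.frame(entity_id = x@entityIds, stringsAsFactors = FALSE), x@scores)
})

setMethod("show", "BioHierarchy", function(object) {
  cat(sprintf(
    "BioHierarchy (%s)\n  %d genes -> %d protein complexes -> %d pathways -> %d drugs\n",
    if (object@pruned) "pruned" else "unpruned",
    length(object@genes), length(object@proteins),
    length(object@pathways), length(object@drugs)))
  cat(sprintf("  edges: %d gene-protein, %d protein-pathway, %d pathway-drug\n",
              nrow(object@edgesGP), nrow(object@edgesPK), nrow(object@edgesKD)))
})

setMethod("show", "LayerMask", function(object) {
  cat(sprintf("LayerMask %d x %d, %d active connections (density %.3f)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              mean(object@mask)))
})

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix [%s]: %d cell lines x %d features\n",
              object@kind, nrow(object@values), ncol(object@values)))
})

setMethod("show", "IntegratedCellFeatures", function(object) {
  multi <- sum(lengths(object@provenance) > 1L)
  cat(sprintf(
    "IntegratedCellFeatures: %d cell lines x %d unique features (%d multi-omics)\n",
    nrow(object@values), ncol(object@values), multi))
})

setMethod("show", "DrugSet", function(object) {
  cat(sprintf("DrugSet: %d drugs, %d fingerprint bits\n",
              length(object@drugIds), ncol(object@fingerprints)))
})

setMethod("show", "MaskedNetwork", function(object) {
  dims <- vapply(object@masks, function(m) dim(m@mask), integer(2))
  cat("MaskedNetwork\n")
  cat(sprintf("  gene(%d) -> protein(%d) -> pathway(%d) -> drug(%d) ++ %d fp bits -> 1\n",
              dims[1, 1], dims[2, 1], dims[2, 2], dims[1, 3], object@nBits))
  cat(sprintf("  active connections: %s; trainable parameters: %d\n",
              paste(vapply(object@masks, function(m) sum(m@mask), numeric(1)),
                    collapse = " / "),
              parameterCount(object)))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan [%s]: %d folds, test sizes %s\n", object@strategy,
              length(object@folds),
              paste(utils::head(vapply(object@folds, function(f) length(f$test),
                                       integer(1)), 10), collapse = ", ")))
})

setMethod("show", "ImportanceReport", function(object) {
  cat(sprintf("ImportanceReport [%s level]: %d entities, %d test samples, run %d\n",
              object@level, length(object@entityIds), object@nSamples, object@runId))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d cells, %d genes, %d proteins, %d pathways, %d drugs (seed %d)\n",
    object@nCells, object@nGenes, object@nProteins, object@nPathways,
    object@nDrugs, object@seed))
  cat(sprintf("  drivers: %d, signal %.2f, noise sd %.2f, %d fp bits\n",
              object@nDriverGenes, object@signalStrength, object@noiseSd,
              object@fingerprintBits))
})
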