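#' Build the four-level biological hierarchy from annotation edge tables
#'
#' Assembles the unpruned gene -> protein complex -> pathway -> drug structure
#' from three edge lists, restricted to the supplied gene and drug universes.
#' Edges whose endpoints fall outside the universes (or outside the node sets
#' induced by the surviving edges) are dropped with a logged count; edge lists
#' are deduplicated, keeping the first occurrence.
#'
#' @param gpEdges data.frame with columns \code{gene_id}, \code{protein_id} and
#'   optionally \code{score} (PPI interaction score; defaults to 1).
#' @param pkEdges data.frame with columns \code{protein_id}, \code{pathway_id},
#'   \code{p_value} (enrichment p-value) and optionally \code{combined_score}
#'   (defaults to 1).
#' @param kdEdges data.frame with columns \code{pathway_id}, \code{drug_id}.
#' @param geneUniverse character vector of admissible gene IDs (normally the
#'   integrated multi-omics feature list); its order fixes the gene node order.
#' @param drugUniverse character vector of admissible drug IDs; fixes the drug
#'   node order.
#' @param minScore optional PPI score cutoff for gene-protein edges; the default
#'   \code{-Inf} keeps all provided edges.
#' @return an unpruned [BioHierarchy-class].
#' @examples
#' h <- buildHierarchy(
#'   data.frame(gene_id = "g1", protein_id = "p1"),
#'   data.frame(protein_id = "p1", pathway_id = "k1", p_value = 0.01),
#'   data.frame(pathway_id = "k1", drug_id = "d1"),
#'   geneUniverse = "g1", drugUniverse = "d1")
#' @export
buildHierarchy <- function(gpEdges, pkEdges, kdEdges, geneUniverse, drugUniverse,
                           minScore = -Inf) {
  .needCols <- function(df, cols, what) {
    if (nrow(df) == 0L) stopf("empty %s edge table", what)
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stopf("%s edge table lacks column(s): %s", what, paste(miss, collapse = ", "))
  }
  .needCols(gpEdges, c("gene_id", "protein_id"), "gene-protein")
  .needCols(pkEdges, c("protein_id", "pathway_id", "p_value"), "protein-pathway")
  .needCols(kdEdges, c("pathway_id", "drug_id"), "pathway-drug")

  if (is.null(gpEdges$score)) gpEdges$score <- 1
  if (is.null(pkEdges$combined_score)) pkEdges$combined_score <- 1

  n0 <- nrow(gpEdges)
  gp <- gpEdges[gpEdges$gene_id %in% geneUniverse & gpEdges$score >= minScore, ,
                drop = FALSE]
  kd <- kdEdges[kdEdges$drug_id %in% drugUniverse, , drop = FALSE]
  dropped <- (n0 - nrow(gp)) + (nrow(kdEdges) - nrow(kd))
  if (dropped > 0L)
    logMsg("buildHierarchy: dropped %d edge(s) outside the gene/drug universes",
           dropped)

  gp <- gp[!duplicated(gp[c("gene_id", "protein_id")]), , drop = FALSE]
  pk <- pkEdges[!duplicated(pkEdges[c("protein_id", "pathway_id")]), , drop = FALSE]
  kd <- kd[!duplicated(kd[c("pathway_id", "drug_id")]), , drop = FALSE]

  genes    <- intersect(geneUniverse, unique(gp$gene_id))
  proteins <- unique(c(gp$protein_id, pk$protein_id))
  pathways <- unique(c(pk$pathway_id, kd$pathway_id))
  drugs    <- intersect(drugUniverse, unique(kd$drug_id))

  methods::new("BioHierarchy",
    genes = genes, proteins = proteins, pathways = pathways, drugs = drugs,
    edgesGP = data.frame(gene = gp$gene_id, protein = gp$protein_id,
                         score = gp$score, stringsAsFactors = FALSE),
    edgesPK = data.frame(protein = pk$protein_id, pathway = pk$pathway_id,
                         p_value = pk$p_value,
                         combined_score = pk$combined_score,
                         stringsAsFactors = FALSE),
    edgesKD = data.frame(pathway = kd$pathway_id, drug = kd$drug_id,
                         stringsAsFactors = FALSE),
    pruned = FALSE)
}

#' Keep only significantly enriched pathways
#'
#' A pathway is retained iff its enrichment p-value is less than or equal to
#' \code{alpha} (the boundary is inclusive). Incident protein->pathway and
#' pathway->drug edges of removed pathways are dropped; combined enrichment
#' scores of survivors are retained as edge attributes.
#'
#' The per-pathway p-value is taken as the minimum over that pathway's
#' protein->pathway edge p-values (a pathway is significant if any membership
#' call is).
#'
#' @param hierarchy a [BioHierarchy-class].
#' @param alpha significance cutoff in (0, 1]; default 0.05.
#' @return the filtered [BioHierarchy-class].
#' @export
filterSignificantPathways <- function(hierarchy, alpha = 0.05) {
  stopifnot(is(hierarchy, "BioHierarchy"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stopf("alpha must be a single probability")
  pk <- hierarchy@edgesPK
  if (any(is.na(pk$p_value))) {
    bad <- unique(pk$pathway[is.na(pk$p_value)])
    stopf("missing p-value for pathway(s): %s", paste(bad, collapse = ", "))
  }
  noEdge <- setdiff(hierarchy@pathways, pk$pathway)
  if (length(noEdge))
    stopf("missing p-value for pathway(s): %s", paste(noEdge, collapse = ", "))

  pvals <- tapply(pk$p_value, pk$pathway, min)
  keep <- names(pvals)[pvals <= alpha]
  keep <- intersect(hierarchy@pathways, keep)  # preserve stored order
  if (length(keep) == 0L)
    stopf("no pathway passes the significance cutoff alpha = %g", alpha)

  h <- hierarchy
  h@pathways <- keep
  h@edgesPK <- pk[pk$pathway %in% keep, , drop = FALSE]
  h@edgesKD <- hierarchy@edgesKD[hierarchy@edgesKD$pathway %in% keep, , drop = FALSE]
  h@pruned <- FALSE
  methods::validObject(h)
  h
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability \eqn{P[X \ge overlap]} for
#' \eqn{X \sim Hypergeometric(universe, pathwaySize, proteinSetSize)}: the
#' chance of drawing at least \code{overlap} pathway members when sampling
#' \code{proteinSetSize} proteins without replacement from a universe containing
#' \code{pathwaySize} members. A self-contained stand-in for an external
#' enrichment service when annotation tables come without p-values.
#'
#' @param proteinSetSize number of proteins in the query set.
#' @param pathwaySize number of universe proteins annotated to the pathway.
#' @param overlap observed intersection size.
#' @param universe total number of proteins.
#' @return the upper-tail p-value.
#' @examples
#' overrepresentationPvalue(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
overrepresentationPvalue <- function(proteinSetSize, pathwaySize, overlap, universe) {
  args <- c(proteinSetSize, pathwaySize, overlap, universe)
  if (any(!is.finite(args)) || any(args < 0) || any(args != round(args)))
    stopf("all counts must be nonnegative integers")
  if (overlap > min(proteinSetSize, pathwaySize) ||
      max(proteinSetSize, pathwaySize) > universe)
    stopf("inconsistent counts: need overlap <= min(set, pathway) <= universe")
  if (overlap == 0) return(1.0)
  stats::phyper(overlap - 1, pathwaySize, universe - pathwaySize,
                proteinSetSize, lower.tail = FALSE)
}

# One forward sweep: drop nodes lacking a downstream edge (genes w/o protein,
# proteins w/o pathway, pathways w/o drug, drugs w/o pathway), then restrict
# edges to surviving nodes. Repeating to a fixed point also realises backward
# pruning: removing a downstream node strips edges, which disconnects upstream
# nodes on the next sweep.
.pruneSweep <- function(h) {
  genes    <- intersect(h@genes, h@edgesGP$gene)
  proteins <- intersect(h@proteins, intersect(h@edgesGP$protein, h@edgesPK$protein))
  pathways <- intersect(h@pathways, intersect(h@edgesPK$pathway, h@edgesKD$pathway))
  drugs    <- intersect(h@drugs, h@edgesKD$drug)

  h@edgesGP <- h@edgesGP[h@edgesGP$gene %in% genes &
                         h@edgesGP$protein %in% proteins, , drop = FALSE]
  h@edgesPK <- h@edgesPK[h@edgesPK$protein %in% proteins &
                         h@edgesPK$pathway %in% pathways, , drop = FALSE]
  h@edgesKD <- h@edgesKD[h@edgesKD$pathway %in% pathways &
                         h@edgesKD$drug %in% drugs, , drop = FALSE]
  h@genes <- genes; h@proteins <- proteins
  h@pathways <- pathways; h@drugs <- drugs
  h
}

#' Prune the hierarchy to a fully connected gene-to-drug structure
#'
#' Forward pruning removes genes without protein edges, proteins without
#' pathway edges, pathways without drug edges, and (symmetrically) drugs
#' without pathway edges. Because removals can strand upstream and downstream
#' neighbours, the sweep is iterated to a fixed point, which realises backward
#' pruning. On return every remaining node lies on at least one full
#' gene -> protein -> pathway -> drug path; the operation is idempotent.
#'
#' @param hierarchy a [BioHierarchy-class].
#' @return the pruned [BioHierarchy-class] (\code{isPruned(x)} is \code{TRUE}).
#' @export
pruneHierarchy <- function(hierarchy) {
  stopifnot(is(hierarchy, "BioHierarchy"))
  h <- hierarchy
  repeat {
    sizes <- c(length(h@genes), length(h@proteins), length(h@pathways),
               length(h@drugs))
    h <- .pruneSweep(h)
    if (identical(sizes, c(length(h@genes), length(h@proteins),
                           length(h@pathways), length(h@drugs)))) break
  }
  if (length(h@genes) == 0L || length(h@drugs) == 0L)
    stopf("pruning removed every gene-to-drug path; the hierarchy is empty")
  if (!identical(h@genes, hierarchy@genes) ||
      !identical(h@proteins, hierarchy@proteins) ||
      !identical(h@pathways, hierarchy@pathways) ||
      !identical(h@drugs, hierarchy@drugs))
    logMsg("pruneHierarchy: %d -> %d genes, %d -> %d proteins, %d -> %d pathways, %d -> %d drugs",
           length(hierarchy@genes), length(h@genes),
           length(hierarchy@proteins), length(h@proteins),
           length(hierarchy@pathways), length(h@pathways),
           length(hierarchy@drugs), length(h@drugs))
  h@pruned <- TRUE
  methods::validObject(h)
  h
}

.edgeMask <- function(src, tgt, from, to) {
  m <- matrix(0, length(src), length(tgt), dimnames = list(src, tgt))
  m[cbind(match(from, src), match(to, tgt))] <- 1
  dimnames(m) <- NULL
  methods::new("LayerMask", sourceIds = src, targetIds = tgt, mask = m)
}

#' Derive the three binary layer masks from a pruned hierarchy
#'
#' Mask entry (i, j) is 1 iff the corresponding edge exists; row and column
#' orders equal the hierarchy's stored node orders, which downstream feature
#' matrices and network layers index by construction.
#'
#' @param hierarchy a pruned [BioHierarchy-class].
#' @return named list with [LayerMask-class] elements \code{gp} (gene ->
#'   protein), \code{pk} (protein -> pathway) and \code{kd} (pathway -> drug).
#' @export
masksFromHierarchy <- function(hierarchy) {
  stopifnot(is(hierarchy, "BioHierarchy"))
  if (!hierarchy@pruned)
    stopf("masksFromHierarchy requires a pruned hierarchy (all-zero rows/columns otherwise); call pruneHierarchy() first")
  out <- list(
    gp = .edgeMask(hierarchy@genes, hierarchy@proteins,
                   hierarchy@edgesGP$gene, hierarchy@edgesGP$protein),
    pk = .edgeMask(hierarchy@proteins, hierarchy@pathways,
                   hierarchy@edgesPK$protein, hierarchy@edgesPK$pathway),
    kd = .edgeMask(hierarchy@pathways, hierarchy@drugs,
                   hierarchy@edgesKD$pathway, hierarchy@edgesKD$drug))
  for (m in out) {
    mk <- m@mask
    if (any(rowSums(mk) == 0) || any(colSums(mk) == 0))
      stopf("internal error: all-zero mask row/column after pruning")
  }
  out
}

# Per-pathway minimum enrichment p-value and maximum combined score, in the
# hierarchy's pathway order (used by the synthetic generator and exports).
.pathwayStats <- function(h) {
  pk <- h@edgesPK
  data.frame(
    pathway = h@pathways,
    p_value = as.numeric(tapply(pk$p_value, pk$pathway, min)[h@pathways]),
    combined_score = as.numeric(tapply(pk$combined_score, pk$pathway, max)[h@pathways]),
    stringsAsFactors = FALSE)
}
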