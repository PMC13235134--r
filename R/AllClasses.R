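#' @import methods
NULL

#' Four-level biological hierarchy
#'
#' Holds the gene, protein-complex, pathway and drug node lists together with the
#' three edge sets connecting consecutive levels. Genes connect to protein
#' complexes through PPI-derived edges (with interaction scores), protein
#' complexes to pathways through membership edges (with enrichment p-values and
#' combined scores), and pathways to drugs through binary target indicators.
#' Node order is significant: it is the single source of truth for the row and
#' column order of every downstream layer mask and feature matrix.
#'
#' @slot genes,proteins,pathways,drugs ordered, duplicate-free node ID vectors.
#' @slot edgesGP data.frame with columns \code{gene}, \code{protein}, \code{score}.
#' @slot edgesPK data.frame with columns \code{protein}, \code{pathway},
#'   \code{p_value}, \code{combined_score}.
#' @slot edgesKD data.frame with columns \code{pathway}, \code{drug}.
#' @slot pruned logical; \code{TRUE} once [pruneHierarchy()] has reduced the
#'   structure so that every node lies on a full gene-to-drug path.
#' @seealso [buildHierarchy()], [pruneHierarchy()], [masksFromHierarchy()]
#' @export
setClass("BioHierarchy",
  representation(
    genes = "character", proteins = "character",
    pathways = "character", drugs = "character",
    edgesGP = "data.frame", edgesPK = "data.frame", edgesKD = "data.frame",
    pruned = "logical"
  ),
  prototype(pruned = FALSE)
)

setValidity("BioHierarchy", function(object) {
  msgs <- character()
  for (lvl in c("genes", "proteins", "pathways", "drugs")) {
    ids <- slot(object, lvl)
    if (anyDuplicated(ids)) msgs <- c(msgs, sprintf("duplicate IDs in '%s'", lvl))
  }
  chk <- function(df, cols, a, b, name) {
    if (!all(cols %in% names(df))) {
      return(sprintf("edge table '%s' lacks columns %s", name,
                     paste(setdiff(cols, names(df)), collapse = ", ")))
    }
    bad <- !(df[[cols[1]]] %in% a) | !(df[[cols[2]]] %in% b)
    if (any(bad)) sprintf("%d edge(s) in '%s' reference unknown nodes", sum(bad), name)
  }
  msgs <- c(msgs,
    chk(object@edgesGP, c("gene", "protein"), object@genes, object@proteins, "edgesGP"),
    chk(object@edgesPK, c("protein", "pathway"), object@proteins, object@pathways, "edgesPK"),
    chk(object@edgesKD, c("pathway", "drug"), object@pathways, object@drugs, "edgesKD"))
  if (length(msgs)) msgs else TRUE
})

#' Binary connectivity mask between two consecutive layers
#'
#' A \code{|source| x |target|} 0/1 matrix whose entry (i, j) is 1 iff source
#' node i is biologically connected to target node j. Applied as a Hadamard
#' factor to the corresponding weight matrix so that only annotated connections
#' carry signal or gradient.
#'
#' @slot sourceIds,targetIds ordered node IDs labelling rows and columns.
#' @slot mask numeric 0/1 matrix of shape \code{length(sourceIds) x length(targetIds)}.
#' @export
setClass("LayerMask",
  representation(sourceIds = "character", targetIds = "character", mask = "matrix")
)

setValidity("LayerMask", function(object) {
  m <- object@mask
  if (!is.numeric(m)) return("mask must be numeric")
  if (nrow(m) != length(object@sourceIds) || ncol(m) != length(object@targetIds))
    return("mask shape does not match ID lists")
  if (!all(m %in% c(0, 1))) return("mask entries must be 0 or 1")
  TRUE
})

#' One omics layer: cell lines x features
#'
#' Cell IDs are row names and feature IDs column names of \code{values}; the
#' \code{kind} tag records which omics the matrix carries (gene expression,
#' copy-number variation, mutation VAF, or protein expression).
#'
#' @slot values numeric matrix (cells x features) with full dimnames.
#' @slot kind one of \code{"GE"}, \code{"CNV"}, \code{"MUT"}, \code{"PROT"}.
#' @export
setClass("OmicsMatrix", representation(values = "matrix", kind = "character"))

setValidity("OmicsMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry cell IDs as rownames and feature IDs as colnames")
  if (anyDuplicated(rownames(v))) return("duplicate cell IDs")
  if (anyDuplicated(colnames(v))) return("duplicate feature IDs")
  if (length(object@kind) != 1L || !object@kind %in% c("GE", "CNV", "MUT", "PROT"))
    return("kind must be one of GE, CNV, MUT, PROT")
  TRUE
})

#' Integrated multi-omics cell-line features
#'
#' One row per cell line and one column per unique feature ID across all input
#' omics; each value is the availability-weighted average of the omics layers
#' containing that feature. \code{provenance} records, per feature, which omics
#' kinds contributed.
#'
#' @slot values numeric matrix (cells x unique features) with dimnames.
#' @slot provenance named list mapping each feature ID to a character vector of
#'   contributing omics kinds (never empty).
#' @seealso [integrateOmics()]
#' @export
setClass("IntegratedCellFeatures",
  representation(values = "matrix", provenance = "list"))

setValidity("IntegratedCellFeatures", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v))) return("values must have dimnames")
  if (!setequal(names(object@provenance), colnames(v)))
    return("provenance names must match feature IDs")
  if (any(lengths(object@provenance) == 0L)) return("empty provenance entry")
  TRUE
})

#' Drug panel with SMILES, screening concentrations and fingerprints
#'
#' @slot drugIds ordered drug IDs.
#' @slot smiles per-drug SMILES string (canonicalized).
#' @slot maxConc per-drug maximum screening concentration, on the same scale as
#'   \code{exp(ln IC50)}; strictly positive.
#' @slot fingerprints binary matrix (drugs x bits) of hashed circular
#'   (Morgan/ECFP) fingerprints; identical bit length across drugs.
#' @seealso [drugSetFromTable()], [morganFingerprint()]
#' @export
setClass("DrugSet",
  representation(drugIds = "character", smiles = "character",
                 maxConc = "numeric", fingerprints = "matrix"))

setValidity("DrugSet", function(object) {
  n <- length(object@drugIds)
  if (anyDuplicated(object@drugIds)) return("duplicate drug IDs")
  if (length(object@smiles) != n || length(object@maxConc) != n ||
      nrow(object@fingerprints) != n)
    return("slot lengths disagree with number of drugs")
  if (any(!is.finite(object@maxConc)) || any(object@maxConc <= 0))
    return("maxConc must be positive and finite")
  if (!all(object@fingerprints %in% c(0, 1))) return("fingerprints must be 0/1")
  TRUE
})

#' Masked feedforward network over the biological hierarchy
#'
#' Three hidden layers (protein complex, pathway, drug) whose weight matrices
#' are Hadamard-multiplied with binary layer masks in every forward pass, so a
#' masked-out weight never carries signal and never receives gradient. The drug
#' layer output is concatenated with the sample's drug fingerprint before a
#' single sigmoid output unit.
#'
#' @slot masks list of three [LayerMask-class] objects (gene->protein,
#'   protein->pathway, pathway->drug).
#' @slot weights list of three numeric matrices, shaped like the masks.
#' @slot biases list of three numeric vectors (target-layer sizes).
#' @slot outputWeights numeric vector of length \code{n_drugs + nBits}.
#' @slot outputBias numeric scalar.
#' @slot nodeOrders named list with elements \code{genes}, \code{proteins},
#'   \code{pathways}, \code{drugs} fixing all index orders.
#' @slot nBits fingerprint length expected at the concatenation step.
#' @seealso [initNetwork()], [trainNetwork()], [forwardPass()]
#' @export
setClass("MaskedNetwork",
  representation(masks = "list", weights = "list", biases = "list",
                 outputWeights = "numeric", outputBias = "numeric",
                 nodeOrders = "list", nBits = "integer"))

setValidity("MaskedNetwork", function(object) {
  if (length(object@masks) != 3L || length(object@weights) != 3L ||
      length(object@biases) != 3L)
    return("need exactly three masked layers")
  for (l in 1:3) {
    mk <- object@masks[[l]]@mask
    if (!identical(dim(mk), dim(object@weights[[l]])))
      return(sprintf("layer %d: weight and mask shapes disagree", l))
    if (length(object@biases[[l]]) != ncol(mk))
      return(sprintf("layer %d: bias length mismatch", l))
  }
  nDrugs <- ncol(object@masks[[3]]@mask)
  if (length(object@outputWeights) != nDrugs + object@nBits)
    return("outputWeights length must be n_drugs + nBits")
  TRUE
})

#' Cross-validation split plan
#'
#' @slot strategy one of \code{"pair_kfold"}, \code{"lodo"}, \code{"loclo"},
#'   \code{"loco"}.
#' @slot folds list of folds, each a list with \code{fold_id} (character),
#'   \code{train} and \code{test} (integer indices into the fixed response
#'   record ordering). Test sets partition the records; train and test are
#'   disjoint within a fold.
#' @slot seed integer seed (used by \code{pair_kfold} only; \code{NA} otherwise).
#' @export
setClass("SplitPlan",
  representation(strategy = "character", folds = "list", seed = "integer"))

setValidity("SplitPlan", function(object) {
  if (!object@strategy %in% c("pair_kfold", "lodo", "loclo", "loco"))
    return("unknown strategy")
  for (f in object@folds) {
    if (length(intersect(f$train, f$test)))
      return(sprintf("fold %s: train/test overlap", f$fold_id))
  }
  tests <- unlist(lapply(object@folds, `[[`, "test"))
  if (anyDuplicated(tests)) return("test sets are not disjoint across folds")
  TRUE
})

#' Per-entity feature-importance report
#'
#' At gene level the \code{scores} table carries the four component scores
#' (\code{grad}, \code{act}, \code{var}, \code{perm}) and their \code{combined}
#' average; at protein/pathway/drug level a single \code{layer} activation
#' score. Entity order matches the network's node order.
#'
#' @slot level one of \code{"gene"}, \code{"protein"}, \code{"pathway"}, \code{"drug"}.
#' @slot entityIds ordered entity IDs.
#' @slot scores data.frame of nonnegative finite scores, one row per entity.
#' @slot nSamples number of test samples the scores were computed over.
#' @slot runId integer run identifier (for multi-run aggregation).
#' @seealso [combinedImportance()], [aggregateRuns()]
#' @export
setClass("ImportanceReport",
  representation(level = "character", entityIds = "character",
                 scores = "data.frame", nSamples = "integer", runId = "integer"))

setValidity("ImportanceReport", function(object) {
  if (!object@level %in% c("gene", "protein", "pathway", "drug"))
    return("invalid level")
  if (nrow(object@scores) != length(object@entityIds))
    return("scores rows must match entityIds")
  vals <- unlist(object@scores)
  if (any(!is.finite(vals)) || any(vals < 0))
    return("scores must be finite and >= 0")
  TRUE
})

#' Specification of a synthetic drug-response study
#'
#' Defines the size, wiring densities, planted-signal parameters and seed of a
#' generated dataset. The defaults describe the package's reference synthetic
#' study: 250 cell lines x 8 drugs (2000 response pairs), 150 genes routed
#' through 60 protein complexes and 15 pathways, 10 driver genes, and a
#' resistant:sensitive class ratio of roughly 2:1.
#'
#' @slot nCells,nGenes,nProteins,nPathways,nDrugs level sizes (all >= 1).
#' @slot edgeDensityGP,edgeDensityPK,edgeDensityKD independent edge probabilities
#'   in (0, 1] for the three inter-level edge sets.
#' @slot nDriverGenes number of genes wired into the planted response mechanism
#'   (<= nGenes).
#' @slot signalStrength logit-scale effect size multiplying the summed driver
#'   signal (>= 0; 0 means labels are independent of driver values).
#' @slot noiseSd standard deviation of the Gaussian noise added to the latent
#'   response score (>= 0).
#' @slot fingerprintBits fingerprint length for generated drugs.
#' @slot nCancerTypes number of cancer types assigned to cell lines.
#' @slot seed integer master seed; every generator derives its own named
#'   substream from it, so identical spec + seed gives bit-identical output.
#' @seealso [syntheticSpec()], [generateHierarchy()], [simulateDataset()]
#' @export
setClass("SyntheticSpec",
  representation(
    nCells = "integer", nGenes = "integer", nProteins = "integer",
    nPathways = "integer", nDrugs = "integer",
    edgeDensityGP = "numeric", edgeDensityPK = "numeric", edgeDensityKD = "numeric",
    nDriverGenes = "integer", signalStrength = "numeric", noiseSd = "numeric",
    fingerprintBits = "integer", nCancerTypes = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  cnt <- c(nCells = object@nCells, nGenes = object@nGenes,
           nProteins = object@nProteins, nPathways = object@nPathways,
           nDrugs = object@nDrugs, fingerprintBits = object@fingerprintBits,
           nCancerTypes = object@nCancerTypes)
  if (any(cnt < 1L)) msgs <- c(msgs, sprintf(
    "counts must be >= 1 (offending: %s)", paste(names(cnt)[cnt < 1L], collapse = ", ")))
  dens <- c(object@edgeDensityGP, object@edgeDensityPK, object@edgeDensityKD)
  if (any(dens <= 0 | dens > 1)) msgs <- c(msgs, "edge densities must lie in (0, 1]")
  if (object@nDriverGenes > object@nGenes)
    msgs <- c(msgs, "nDriverGenes must not exceed nGenes")
  if (object@nDriverGenes < 1L) msgs <- c(msgs, "nDriverGenes must be >= 1")
  if (object@signalStrength < 0) msgs <- c(msgs, "signalStrength must be >= 0")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Training hyperparameters
#'
#' Defaults mirror the reference training setup: mini-batch size 64, 50 epochs,
#' Adam with learning rate 0.001.
#'
#' @slot batchSize mini-batch size (>= 1).
#' @slot epochs number of passes over the training data (>= 1).
#' @slot learningRate Adam step size.
#' @slot seed integer seed for weight initialization and epoch shuffling.
#' @slot initScheme \code{"glorot"} (uniform Glorot on unmasked positions) or
#'   \code{"glorot_enrichment"} (protein->pathway weights additionally scaled by
#'   the stored combined enrichment scores).
#' @seealso [trainConfig()]
#' @export
setClass("TrainConfig",
  representation(batchSize = "integer", epochs = "integer",
                 learningRate = "numeric", seed = "integer",
                 initScheme = "character"))

setValidity("TrainConfig", function(object) {
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (!is.finite(object@learningRate) || object@learningRate < 0)
    return("learningRate must be finite and >= 0")
  if (!object@initScheme %in% c("glorot", "glorot_enrichment"))
    return("unknown initScheme")
  TRUE
})
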