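# Pool of valid drug-like SMILES the generator samples from. Small, common
# molecules and marketed drugs; all parse under the cheminformatics backend.
.SMILES_POOL <- c(
  "CC(=O)Oc1ccccc1C(=O)O",                     # aspirin
  "CC(=O)Nc1ccc(O)cc1",                        # paracetamol
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",                # caffeine
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",                # ibuprofen
  "OC(=O)c1ccccc1O",                           # salicylic acid
  "Clc1ccccc1",                                # chlorobenzene
  "c1ccc2c(c1)cccc2",                          # naphthalene
  "CCN(CC)CCNC(=O)c1ccc(N)cc1",                # procainamide
  "CN1CCC[C@H]1c1cccnc1",                      # nicotine
  "NC(=O)c1ccc[nH]1",                          # pyrrole amide
  "OCC(O)CO",                                  # glycerol
  "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",             # melatonin
  "Nc1ccc(cc1)S(=O)(=O)Nc1ncccn1",             # sulfadiazine
  "CN(C)CCOC(c1ccccc1)c1ccccc1",               # diphenhydramine
  "OC(=O)CC(O)(CC(=O)O)C(=O)O",                # citric acid
  "C1CCNCC1",                                  # piperidine
  "c1ccncc1",                                  # pyridine
  "CC(N)Cc1ccccc1",                            # amphetamine
  "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",            # atenolol
  "CSCCC(N)C(=O)O",                            # methionine
  "NC(Cc1ccc(O)cc1)C(=O)O",                    # tyrosine
  "OC(=O)c1cc(O)c(O)c(O)c1",                   # gallic acid
  "CCOC(=O)c1ccccc1",                          # ethyl benzoate
  "Oc1ccc(cc1)C=Cc1cc(O)cc(O)c1",              # resveratrol
  "CN1C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1",        # atropine
  "Clc1ccc(cc1)C(c1ccccc1)N1CCN(CCOCCO)CC1",   # hydroxyzine
  "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O",            # estradiol
  "OCC1OC(O)C(O)C(O)C1O",                      # glucose
  "NCCc1c[nH]cn1",                             # histamine
  "NCCc1ccc(O)c(O)c1",                         # dopamine
  "CNC(C)Cc1ccccc1",                           # methamphetamine
  "OC(=O)c1ccc(O)cc1",                         # 4-hydroxybenzoic acid
  "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",             # salbutamol
  "Cc1ccc(cc1)S(=O)(=O)N",                     # tosylamide
  "O=C1NC(=O)NC(=O)C1",                        # barbituric acid
  "c1ccc(cc1)c1ccccc1",                        # biphenyl
  "OCCN1CCN(CCCN2c3ccccc3Sc3ccc(Cl)cc23)CC1",  # perphenazine-like
  "CC(C)(C)c1ccc(O)cc1",                       # 4-tert-butylphenol
  "COc1ccc2cc(ccc2c1)C(C)C(=O)O",              # naproxen
  "NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O",        # hydrochlorothiazide
  "OC(CCN(C)C)(c1ccccc1)c1ccccc1",             # diphenyl aminopropanol
  "COc1cc2c(cc1OC)C(=O)C(CC2)CC1CCN(Cc2ccccc2)CC1", # donepezil-like
  "CCn1cc(C(=O)O)c(=O)c2ccc(C)nc12",           # nalidixic acid
  "CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O", # penicillin G
  "CN1CCCC1CCO",                               # aminoalcohol
  "Oc1ccc2[nH]cc(CCN)c2c1",                    # serotonin
  "CC(CS)C(=O)N1CCCC1C(=O)O",                  # captopril
  "NC1CCCCC1"                                  # cyclohexylamine
)

#' Create a synthetic study specification
#'
#' The defaults are the package's reference synthetic study: 250 cell lines
#' and 8 drugs (2000 response pairs), 150 genes wired through 60 protein
#' complexes and 15 pathways, 10 planted driver genes, a logit-scale driver
#' effect of 4 with Gaussian noise sd 0.5, and 1024-bit fingerprints. Per-drug
#' response thresholds are placed so that about one third of pairs come out
#' sensitive (a roughly 2:1 resistant:sensitive ratio).
#'
#' @param nCells,nGenes,nProteins,nPathways,nDrugs level sizes.
#' @param edgeDensityGP,edgeDensityPK,edgeDensityKD edge probabilities in (0, 1].
#' @param nDriverGenes number of planted driver genes.
#' @param signalStrength logit-scale driver effect size (0 disconnects labels
#'   from drivers).
#' @param noiseSd latent-score noise standard deviation.
#' @param fingerprintBits fingerprint length.
#' @param nCancerTypes number of cancer types assigned to cell lines.
#' @param seed master seed; all generators derive named substreams from it.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nCells = 250, nGenes = 150, nProteins = 60,
                          nPathways = 15, nDrugs = 8,
                          edgeDensityGP = 0.05, edgeDensityPK = 0.25,
                          edgeDensityKD = 0.35, nDriverGenes = 10,
                          signalStrength = 4, noiseSd = 0.5,
                          fingerprintBits = 1024, nCancerTypes = 6, seed = 1) {
  methods::new("SyntheticSpec",
    nCells = as.integer(nCells), nGenes = as.integer(nGenes),
    nProteins = as.integer(nProteins), nPathways = as.integer(nPathways),
    nDrugs = as.integer(nDrugs),
    edgeDensityGP = edgeDensityGP, edgeDensityPK = edgeDensityPK,
    edgeDensityKD = edgeDensityKD, nDriverGenes = as.integer(nDriverGenes),
    signalStrength = signalStrength, noiseSd = noiseSd,
    fingerprintBits = as.integer(fingerprintBits),
    nCancerTypes = as.integer(nCancerTypes), seed = as.integer(seed))
}

.specGeneIds <- function(spec) sprintf("g%04d", seq_len(spec@nGenes))
.specProteinIds <- function(spec) sprintf("p%03d", seq_len(spec@nProteins))
.specPathwayIds <- function(spec) sprintf("k%02d", seq_len(spec@nPathways))
.specDrugIds <- function(spec) sprintf("d%02d", seq_len(spec@nDrugs))
.specCellIds <- function(spec) sprintf("c%04d", seq_len(spec@nCells))

#' Planted driver genes of a synthetic spec
#'
#' A pure function of the spec (drawn from its own seed substream), so the
#' ground truth is recoverable without carrying extra state.
#'
#' @param spec a [SyntheticSpec-class].
#' @return character vector of driver gene IDs.
#' @export
driverGenes <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  withSeed(childSeed(spec@seed, "drivers"),
           sort(sample(.specGeneIds(spec), spec@nDriverGenes)))
}

# All (source, target) pairs drawn independently at the given density.
.randomEdges <- function(src, tgt, density) {
  pairs <- expand.grid(from = src, to = tgt, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  pairs[stats::runif(nrow(pairs)) < density, , drop = FALSE]
}

#' Generate a planted biological hierarchy
#'
#' Wires genes, protein complexes, pathways and drugs with independent random
#' edges at the spec's densities, draws pathway enrichment p-values (about
#' three quarters significant at the conventional 0.05 cutoff) and combined
#' scores, then repairs connectivity so that every planted driver gene lies on
#' at least one gene -> protein -> pathway -> drug path routed through a
#' significant pathway. Non-driver nodes keep their purely random wiring, so
#' pruning has genuine work to do. Edge lists are deduplicated; the result is
#' unpruned and covers all spec nodes (including any isolated ones).
#'
#' @param spec a [SyntheticSpec-class].
#' @return an unpruned [BioHierarchy-class].
#' @export
generateHierarchy <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  methods::validObject(spec)
  genes <- .specGeneIds(spec); prots <- .specProteinIds(spec)
  paths <- .specPathwayIds(spec); drugs <- .specDrugIds(spec)
  drivers <- driverGenes(spec)

  withSeed(childSeed(spec@seed, "hierarchy"), {
    gp <- .randomEdges(genes, prots, spec@edgeDensityGP)
    pk <- .randomEdges(prots, paths, spec@edgeDensityPK)
    kd <- .randomEdges(paths, drugs, spec@edgeDensityKD)

    sig <- stats::runif(spec@nPathways) < 0.75
    pvals <- ifelse(sig, stats::runif(spec@nPathways, 0, 0.05),
                         stats::runif(spec@nPathways, 0.06, 0.9))
    names(pvals) <- paths
    if (!any(pvals <= 0.05)) pvals[1] <- 0.025  # keep the cutoff attainable
    cscore <- stats::runif(spec@nPathways, 0.5, 2) * -log10(pmax(pvals, 1e-4))
    names(cscore) <- paths

    sigPaths <- paths[pvals <= 0.05]
    # pathway -> drug: make sure at least one significant pathway targets a drug
    if (!any(kd$from %in% sigPaths))
      kd <- rbind(kd, data.frame(from = sigPaths[1], to = drugs[1]))

    # protein reaches a drug iff it joins a significant, drug-targeting pathway
    reachPaths <- intersect(sigPaths, unique(kd$from))
    protReaches <- function() unique(pk$from[pk$to %in% reachPaths])
    if (length(protReaches()) == 0L) {
      pk <- rbind(pk, data.frame(from = prots[1], to = reachPaths[1]))
    }
    for (g in drivers) {
      ok <- protReaches()
      hasPath <- any(gp$from == g & gp$to %in% ok)
      if (!hasPath)
        gp <- rbind(gp, data.frame(from = g, to = sample(ok, 1)))
    }

    gp <- gp[!duplicated(gp), , drop = FALSE]
    pk <- pk[!duplicated(pk), , drop = FALSE]
    kd <- kd[!duplicated(kd), , drop = FALSE]

    methods::new("BioHierarchy",
      genes = genes, proteins = prots, pathways = paths, drugs = drugs,
      edgesGP = data.frame(gene = gp$from, protein = gp$to,
                           score = round(stats::runif(nrow(gp), 0.4, 1), 3),
                           stringsAsFactors = FALSE),
      edgesPK = data.frame(protein = pk$from, pathway = pk$to,
                           p_value = unname(pvals[pk$to]),
                           combined_score = round(unname(cscore[pk$to]), 4),
                           stringsAsFactors = FALSE),
      edgesKD = data.frame(pathway = kd$from, drug = kd$to,
                           stringsAsFactors = FALSE),
      pruned = FALSE)
  })
}

#' Generate the four synthetic omics layers
#'
#' Emits gene expression (Normal(0,1) over all genes), copy-number variation
#' (discrete \{0..4\}/4 centred on two copies), mutation VAF (Beta(2,5), values
#' in [0,1]) and protein expression (Normal(0,1)), over overlapping but
#' non-identical gene sets. Membership in the CNV, MUT and PROT layers is
#' sampled at the same rates for driver and non-driver genes, so drivers are
#' not distributionally distinguishable by their availability profile; each
#' driver is then guaranteed a second layer beyond gene expression, which
#' spreads the planted signal across omics. One non-driver gene is forced to
#' be expression-only so the single-source integration path is always
#' exercised. Protein features reuse their gene's ID, matching the verbatim-ID
#' integration contract.
#'
#' @param spec a [SyntheticSpec-class].
#' @param hierarchy the hierarchy generated from the same spec (fixes the gene
#'   universe).
#' @return named list of four [OmicsMatrix-class] objects (\code{GE},
#'   \code{CNV}, \code{MUT}, \code{PROT}).
#' @export
generateOmics <- function(spec, hierarchy) {
  stopifnot(is(spec, "SyntheticSpec"), is(hierarchy, "BioHierarchy"))
  genes <- .specGeneIds(spec)
  cells <- .specCellIds(spec)
  drivers <- driverGenes(spec)
  nondriver <- setdiff(genes, drivers)

  withSeed(childSeed(spec@seed, "omics"), {
    soleGE <- if (length(nondriver)) nondriver[length(nondriver)] else character()
    pickable <- setdiff(genes, soleGE)
    member <- function(frac) {
      n <- round(length(pickable) * frac)
      if (n > 0) sort(sample(pickable, n)) else character()
    }
    gCnv <- member(0.6); gMut <- member(0.5); gProt <- member(0.4)
    # every driver is measured beyond GE in at least one more layer
    for (g in drivers) {
      if (!g %in% c(gCnv, gMut, gProt)) {
        pickLayer <- sample(3, 1)
        if (pickLayer == 1) gCnv <- sort(c(gCnv, g))
        else if (pickLayer == 2) gMut <- sort(c(gMut, g))
        else gProt <- sort(c(gProt, g))
      }
    }

    rmat <- function(ids, draw) {
      m <- matrix(draw(length(cells) * length(ids)), length(cells), length(ids),
                  dimnames = list(cells, ids))
      m
    }
    list(
      GE = omicsMatrix(rmat(genes, function(n) stats::rnorm(n)), "GE"),
      CNV = omicsMatrix(rmat(gCnv, function(n)
        sample(0:4, n, replace = TRUE,
               prob = c(0.05, 0.2, 0.5, 0.2, 0.05)) / 4), "CNV"),
      MUT = omicsMatrix(rmat(gMut, function(n) stats::rbeta(n, 2, 5)), "MUT"),
      PROT = omicsMatrix(rmat(gProt, function(n) stats::rnorm(n)), "PROT"))
  })
}

#' Generate a synthetic drug panel
#'
#' Samples distinct drug-like SMILES from a built-in pool, assigns maximum
#' screening concentrations uniformly in [1, 10] (arbitrary concentration
#' units; ln IC50 values are emitted on the same scale), and fingerprints every
#' drug at the spec's bit length.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [DrugSet-class].
#' @export
generateDrugs <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (spec@nDrugs > length(.SMILES_POOL))
    stopf("at most %d synthetic drugs are supported", length(.SMILES_POOL))
  withSeed(childSeed(spec@seed, "drugset"), {
    smiles <- sample(.SMILES_POOL, spec@nDrugs)
    maxConc <- round(stats::runif(spec@nDrugs, 1, 10), 3)
    drugSetFromTable(
      data.frame(drug_id = .specDrugIds(spec), smiles = smiles,
                 max_conc = maxConc, stringsAsFactors = FALSE),
      radius = 2, nBits = spec@fingerprintBits)
  })
}

# Driver x drug reachability through significant pathways (the paths a
# conventionally filtered network can exploit).
.driverReach <- function(hierarchy, drivers, alpha = 0.05) {
  pv <- tapply(hierarchy@edgesPK$p_value, hierarchy@edgesPK$pathway, min)
  sigPaths <- names(pv)[pv <= alpha]
  kd <- hierarchy@edgesKD[hierarchy@edgesKD$pathway %in% sigPaths, , drop = FALSE]
  pk <- hierarchy@edgesPK[hierarchy@edgesPK$pathway %in% sigPaths, , drop = FALSE]
  out <- matrix(FALSE, length(drivers), length(hierarchy@drugs),
                dimnames = list(drivers, hierarchy@drugs))
  for (d in unique(kd$drug)) {
    pathsD <- kd$pathway[kd$drug == d]
    protsD <- unique(pk$protein[pk$pathway %in% pathsD])
    gp <- hierarchy@edgesGP
    genesD <- unique(gp$gene[gp$protein %in% protsD])
    out[, d] <- drivers %in% genesD
  }
  out
}

#' Generate responses from the planted mechanism
#'
#' For every (cell line, drug) pair a latent sensitivity score is formed:
#' \code{signalStrength} times the sum of the cell's integrated (min-max
#' scaled, availability-averaged) values over the driver genes that reach the
#' drug through the hierarchy, plus a drug-specific fingerprint-bit term, plus
#' Gaussian noise of sd \code{noiseSd}. The per-drug sensitivity cutoff is the
#' upper-third quantile of that drug's scores (planting a roughly 2:1
#' resistant:sensitive ratio), and ln IC50 is emitted as
#' \code{log(maxConc) - (score - cutoff)}, so binarizing ln IC50 against the
#' stored maximum screening concentration reproduces the planted labels
#' exactly. Cells also receive a cancer-type assignment.
#'
#' @param spec a [SyntheticSpec-class].
#' @param hierarchy,omics,drugs outputs of the matching generators.
#' @return data.frame with columns \code{cell_id}, \code{drug_id},
#'   \code{ln_ic50}, \code{label}, \code{cancer_type}; the planted driver IDs
#'   and the latent score matrix are attached as attributes \code{"drivers"}
#'   and \code{"latent"}.
#' @export
generateResponses <- function(spec, hierarchy, omics, drugs) {
  stopifnot(is(spec, "SyntheticSpec"), is(hierarchy, "BioHierarchy"),
            is(drugs, "DrugSet"))
  cells <- .specCellIds(spec)
  drugIdsV <- drugIds(drugs)
  drivers <- driverGenes(spec)
  integrated <- integrateOmics(lapply(omics, minmaxScale))
  Fmat <- featureValues(integrated)[cells, , drop = FALSE]
  reach <- .driverReach(hierarchy, drivers)
  fp <- fingerprints(drugs)
  mc <- maxConc(drugs)

  withSeed(childSeed(spec@seed, "responses"), {
    nBeta <- min(16L, ncol(fp))
    betaPos <- sample.int(ncol(fp), nBeta)
    beta <- stats::rnorm(nBeta, 0, 0.3)
    fpTerm <- as.numeric(fp[, betaPos, drop = FALSE] %*% beta)
    names(fpTerm) <- drugIdsV

    latent <- matrix(0, length(cells), length(drugIdsV),
                     dimnames = list(cells, drugIdsV))
    for (d in drugIdsV) {
      dg <- drivers[reach[, d]]
      drive <- if (length(dg)) rowSums(Fmat[, dg, drop = FALSE]) else 0
      latent[, d] <- spec@signalStrength * drive + fpTerm[d] +
        stats::rnorm(length(cells), 0, spec@noiseSd)
    }
    cutoffs <- apply(latent, 2, stats::quantile, probs = 2 / 3, names = FALSE)
    cancer <- sample(sprintf("T%02d", seq_len(spec@nCancerTypes)),
                     length(cells), replace = TRUE)
    names(cancer) <- cells

    res <- do.call(rbind, lapply(seq_along(drugIdsV), function(j) {
      d <- drugIdsV[j]
      ln <- log(mc[d]) - (latent[, d] - cutoffs[j])
      data.frame(cell_id = cells, drug_id = d, ln_ic50 = unname(ln),
                 label = binarizeResponse(unname(ln), mc[[d]]),
                 cancer_type = unname(cancer[cells]),
                 stringsAsFactors = FALSE)
    }))
    rownames(res) <- NULL
    attr(res, "drivers") <- drivers
    attr(res, "latent") <- latent
    res
  })
}

#' Generate a complete synthetic study
#'
#' Runs all generators for one spec and optionally writes the dataset in the
#' same delimited formats the real-data readers consume: per-omics CSVs (cells
#' x features), annotation edge TSVs, a drug table CSV (\code{drug_id},
#' \code{smiles}, \code{max_conc}), a response CSV and a cancer-type map CSV.
#'
#' @param spec a [SyntheticSpec-class].
#' @param outDir optional output directory (created if needed).
#' @return (invisibly when writing) a list with elements \code{spec},
#'   \code{hierarchy}, \code{omics}, \code{drugs}, \code{responses}.
#' @export
simulateDataset <- function(spec, outDir = NULL) {
  hierarchy <- generateHierarchy(spec)
  omics <- generateOmics(spec, hierarchy)
  drugs <- generateDrugs(spec)
  responses <- generateResponses(spec, hierarchy, omics, drugs)
  bundle <- list(spec = spec, hierarchy = hierarchy, omics = omics,
                 drugs = drugs, responses = responses)
  if (!is.null(outDir)) {
    writeBundle(bundle, outDir)
    return(invisible(bundle))
  }
  bundle
}
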