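# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written with a different algorithmic route than the
# implementation they check (breadth-first search instead of iterated sweeps,
# explicit loops instead of matrix algebra).

# ---- toy hierarchy builders -------------------------------------------------

chainHierarchy <- function() {
  buildHierarchy(
    data.frame(gene_id = "g1", protein_id = "p1"),
    data.frame(protein_id = "p1", pathway_id = "k1", p_value = 0.01),
    data.frame(pathway_id = "k1", drug_id = "d1"),
    geneUniverse = "g1", drugUniverse = "d1")
}

# Random layered hierarchy with no connectivity guarantees (pruning must cope).
randomHierarchy <- function(nG = 8, nP = 5, nK = 4, nD = 3, p = 0.3) {
  genes <- paste0("g", seq_len(nG)); prots <- paste0("p", seq_len(nP))
  paths <- paste0("k", seq_len(nK)); drugs <- paste0("d", seq_len(nD))
  pick <- function(a, b) {
    all <- expand.grid(x = a, y = b, stringsAsFactors = FALSE)
    all[runif(nrow(all)) < p, , drop = FALSE]
  }
  gp <- pick(genes, prots); pk <- pick(prots, paths); kd <- pick(paths, drugs)
  # guarantee one full chain so pruning never empties the graph
  gp <- unique(rbind(gp, data.frame(x = genes[1], y = prots[1])))
  pk <- unique(rbind(pk, data.frame(x = prots[1], y = paths[1])))
  kd <- unique(rbind(kd, data.frame(x = paths[1], y = drugs[1])))
  new("BioHierarchy",
      genes = genes, proteins = prots, pathways = paths, drugs = drugs,
      edgesGP = data.frame(gene = gp$x, protein = gp$y, score = 1),
      edgesPK = data.frame(protein = pk$x, pathway = pk$y, p_value = 0.01,
                           combined_score = 1),
      edgesKD = data.frame(pathway = kd$x, drug = kd$y),
      pruned = FALSE)
}

# ---- reachability oracle (breadth-first search over emitted edge lists) -----

# Adjacency as a named list of successor / predecessor vectors.
.bfs <- function(starts, adj) {
  seen <- unique(starts); frontier <- seen
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

# Nodes of each level lying on at least one full gene -> drug path.
pathNodesOracle <- function(h) {
  fwd <- split(c(h@edgesGP$protein, h@edgesPK$pathway, h@edgesKD$drug),
               c(h@edgesGP$gene, h@edgesPK$protein, h@edgesKD$pathway))
  bwd <- split(c(h@edgesGP$gene, h@edgesPK$protein, h@edgesKD$pathway),
               c(h@edgesGP$protein, h@edgesPK$pathway, h@edgesKD$drug))
  downFromGenes <- .bfs(h@genes, fwd)     # genes + everything genes reach
  upFromDrugs <- .bfs(h@drugs, bwd)       # drugs + everything reaching drugs
  onPath <- intersect(downFromGenes, upFromDrugs)
  list(genes = intersect(h@genes, onPath),
       proteins = intersect(h@proteins, onPath),
       pathways = intersect(h@pathways, onPath),
       drugs = intersect(h@drugs, onPath))
}

driversReachDrugOracle <- function(h, drivers) {
  fwd <- split(c(h@edgesGP$protein, h@edgesPK$pathway, h@edgesKD$drug),
               c(h@edgesGP$gene, h@edgesPK$protein, h@edgesKD$pathway))
  vapply(drivers, function(g) any(.bfs(g, fwd) %in% h@drugs), logical(1))
}

# ---- dense forward oracle ---------------------------------------------------

# Independent evaluation of the masked network: computes (M * W)^T x with
# explicit per-node loops, column-vector convention.
denseForwardOracle <- function(net, x, fp) {
  act <- x
  for (l in 1:3) {
    Wm <- net@masks[[l]]@mask * net@weights[[l]]
    nxt <- numeric(ncol(Wm))
    for (j in seq_len(ncol(Wm))) {
      s <- net@biases[[l]][j]
      for (i in seq_len(nrow(Wm))) s <- s + Wm[i, j] * act[i]
      nxt[j] <- max(s, 0)
    }
    act <- nxt
  }
  z <- net@outputBias
  cat_vec <- c(act, fp)
  for (i in seq_along(cat_vec)) z <- z + cat_vec[i] * net@outputWeights[i]
  1 / (1 + exp(-z))
}

# Small random network (random masks with no all-zero guarantee needed for the
# forward pass itself).
randomSmallNetwork <- function(sizes = c(6, 4, 3, 2), nBits = 5) {
  mk <- function(a, b) {
    m <- matrix(rbinom(a * b, 1, 0.6), a, b)
    new("LayerMask", sourceIds = paste0("s", seq_len(a)),
        targetIds = paste0("t", seq_len(b)), mask = m)
  }
  masks <- list(mk(sizes[1], sizes[2]), mk(sizes[2], sizes[3]),
                mk(sizes[3], sizes[4]))
  masks[[2]]@sourceIds <- masks[[1]]@targetIds
  masks[[3]]@sourceIds <- masks[[2]]@targetIds
  net <- initNetwork(masks, nBits = nBits,
                     config = trainConfig(seed = sample.int(1e6, 1)))
  # randomize biases so the oracle exercises them
  net@biases <- lapply(net@biases, function(b) rnorm(length(b), 0, 0.3))
  net@outputBias <- rnorm(1, 0, 0.3)
  net
}

# ---- metric oracles ---------------------------------------------------------

aucBruteForce <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

bceElementwise <- function(probs, labels, clip = 1e-7) {
  s <- 0
  for (i in seq_along(probs)) {
    p <- min(max(probs[i], clip), 1 - clip)
    s <- s + labels[i] * log(p) + (1 - labels[i]) * log(1 - p)
  }
  -s / length(probs)
}

# ---- shared small study fixture --------------------------------------------

# One modest synthetic study reused across network/evaluation tests (cached).
.fixtureEnv <- new.env()
smallStudy <- function() {
  if (is.null(.fixtureEnv$study)) {
    spec <- syntheticSpec(nCells = 60, nGenes = 50, nProteins = 20,
                          nPathways = 8, nDrugs = 5, nDriverGenes = 6,
                          signalStrength = 6, noiseSd = 0.2,
                          fingerprintBits = 64, nCancerTypes = 4, seed = 42)
    .fixtureEnv$study <- simulateDataset(spec)
  }
  .fixtureEnv$study
}

# Integrated features + pruned masks + network inputs for the small study.
smallModelParts <- function(epochs = 10, seed = 42) {
  if (is.null(.fixtureEnv$parts)) {
    b <- smallStudy()
    integrated <- integrateOmics(lapply(b$omics, minmaxScale))
    h <- filterSignificantPathways(b$hierarchy, 0.05)
    h <- pruneHierarchy(maskDRP:::.restrictGenes(h, featureIds(integrated)))
    .fixtureEnv$parts <- list(bundle = b, integrated = integrated, hierarchy = h,
                              masks = masksFromHierarchy(h))
  }
  .fixtureEnv$parts
}
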