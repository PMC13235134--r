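#' Training configuration
#'
#' @param batchSize mini-batch size; default 64.
#' @param epochs training epochs; default 50.
#' @param learningRate Adam learning rate; default 0.001.
#' @param seed integer seed driving weight initialization and epoch shuffling.
#' @param initScheme \code{"glorot"} or \code{"glorot_enrichment"} (see
#'   [TrainConfig-class]).
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(batchSize = 64, epochs = 50, learningRate = 0.001,
                        seed = 1, initScheme = "glorot") {
  methods::new("TrainConfig",
    batchSize = as.integer(batchSize), epochs = as.integer(epochs),
    learningRate = as.numeric(learningRate), seed = as.integer(seed),
    initScheme = initScheme)
}

#' Initialize a masked network from layer masks
#'
#' Weights on unmasked positions are drawn Glorot-uniform
#' (\eqn{U(\pm\sqrt{6/(fan_{in}+fan_{out})})}) from the configured seed; masked
#' positions are initialized to exactly zero and, because their gradient is
#' identically zero under the Hadamard forward pass, remain zero forever.
#' Biases start at zero. With \code{initScheme = "glorot_enrichment"} the
#' protein->pathway initial weights are additionally scaled by the stored
#' combined enrichment scores (normalized to mean 1 over present edges), which
#' requires \code{hierarchy}.
#'
#' @param masks named list of three [LayerMask-class] objects (\code{gp},
#'   \code{pk}, \code{kd}) as produced by [masksFromHierarchy()].
#' @param nBits fingerprint length concatenated at the drug layer.
#' @param config a [TrainConfig-class].
#' @param hierarchy the source [BioHierarchy-class]; only needed for the
#'   enrichment-scaled initialization.
#' @return an untrained [MaskedNetwork-class].
#' @export
initNetwork <- function(masks, nBits = 1024, config = trainConfig(),
                        hierarchy = NULL) {
  stopifnot(length(masks) == 3L)
  masks <- unname(masks)
  junctions <- c("gene->protein / protein->pathway",
                 "protein->pathway / pathway->drug")
  for (l in 1:2) {
    if (!identical(masks[[l]]@targetIds, masks[[l + 1]]@sourceIds))
      stopf("incompatible mask chain at junction %s", junctions[l])
  }
  nBits <- as.integer(nBits)
  nDrugs <- length(masks[[3]]@targetIds)

  glorot <- function(nIn, nOut) {
    lim <- sqrt(6 / (nIn + nOut))
    matrix(stats::runif(nIn * nOut, -lim, lim), nIn, nOut)
  }
  params <- withSeed(childSeed(config@seed, "init"), {
    W <- lapply(masks, function(m)
      glorot(nrow(m@mask), ncol(m@mask)) * m@mask)
    wOut <- stats::runif(nDrugs + nBits,
                         -sqrt(6 / (nDrugs + nBits + 1)),
                          sqrt(6 / (nDrugs + nBits + 1)))
    list(W = W, wOut = wOut)
  })
  if (config@initScheme == "glorot_enrichment") {
    if (is.null(hierarchy))
      stopf("initScheme 'glorot_enrichment' requires the hierarchy")
    pk <- hierarchy@edgesPK
    S <- matrix(0, nrow(masks[[2]]@mask), ncol(masks[[2]]@mask))
    idx <- cbind(match(pk$protein, masks[[2]]@sourceIds),
                 match(pk$pathway, masks[[2]]@targetIds))
    ok <- stats::complete.cases(idx)
    S[idx[ok, , drop = FALSE]] <- pk$combined_score[ok]
    if (any(S > 0)) S <- S / mean(S[S > 0])
    params$W[[2]] <- params$W[[2]] * S
  }
  net <- methods::new("MaskedNetwork",
    masks = masks, weights = params$W,
    biases = lapply(masks, function(m) numeric(ncol(m@mask))),
    outputWeights = params$wOut, outputBias = 0,
    nodeOrders = list(genes = masks[[1]]@sourceIds,
                      proteins = masks[[1]]@targetIds,
                      pathways = masks[[2]]@targetIds,
                      drugs = masks[[3]]@targetIds),
    nBits = nBits)
  methods::validObject(net)
  net
}

#' Count trainable parameters of a masked network
#'
#' Only unmasked weight positions are trainable: the count is the sum of mask
#' entries plus all biases, the output weight vector and the output bias. It is
#' strictly below the dense network of identical layer sizes whenever any mask
#' entry is zero.
#'
#' @param net a [MaskedNetwork-class].
#' @return integer parameter count.
#' @export
parameterCount <- function(net) {
  stopifnot(is(net, "MaskedNetwork"))
  as.integer(sum(vapply(net@masks, function(m) sum(m@mask), numeric(1))) +
             sum(lengths(net@biases)) + length(net@outputWeights) + 1L)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Batched forward pass. X: samples x genes; FP: samples x nBits.
# Returns all intermediate activations for backprop and layer importance.
.forwardBatch <- function(net, X, FP) {
  We <- lapply(1:3, function(l) net@masks[[l]]@mask * net@weights[[l]])
  A1 <- sweep(X  %*% We[[1]], 2, net@biases[[1]], "+"); H1 <- pmax(A1, 0)
  A2 <- sweep(H1 %*% We[[2]], 2, net@biases[[2]], "+"); H2 <- pmax(A2, 0)
  A3 <- sweep(H2 %*% We[[3]], 2, net@biases[[3]], "+"); H3 <- pmax(A3, 0)
  C <- cbind(H3, FP)
  z <- drop(C %*% net@outputWeights) + net@outputBias
  list(We = We, A1 = A1, H1 = H1, A2 = A2, H2 = H2, A3 = A3, H3 = H3,
       C = C, prob = .sigmoid(z))
}

# Gradients of the mean BCE loss over the batch. Parameter gradients are
# Hadamard-masked, so masked positions receive exactly zero gradient.
.backwardBatch <- function(net, fw, X, y) {
  n <- length(y)
  dz <- (fw$prob - y) / n
  gwOut <- drop(crossprod(fw$C, dz))
  gbOut <- sum(dz)
  dC <- tcrossprod(dz, net@outputWeights)
  nDrugs <- ncol(fw$H3)
  dA3 <- dC[, seq_len(nDrugs), drop = FALSE] * (fw$A3 > 0)
  gW3 <- crossprod(fw$H2, dA3) * net@masks[[3]]@mask
  gb3 <- colSums(dA3)
  dA2 <- (dA3 %*% t(fw$We[[3]])) * (fw$A2 > 0)
  gW2 <- crossprod(fw$H1, dA2) * net@masks[[2]]@mask
  gb2 <- colSums(dA2)
  dA1 <- (dA2 %*% t(fw$We[[2]])) * (fw$A1 > 0)
  gW1 <- crossprod(X, dA1) * net@masks[[1]]@mask
  gb1 <- colSums(dA1)
  list(W = list(gW1, gW2, gW3), b = list(gb1, gb2, gb3),
       wOut = gwOut, bOut = gbOut)
}

# Per-sample gradient of the per-sample BCE loss w.r.t. each input gene
# (no 1/N averaging): rows are samples, columns genes.
.inputGradients <- function(net, X, FP, y) {
  fw <- .forwardBatch(net, X, FP)
  dz <- fw$prob - y
  dC <- tcrossprod(dz, net@outputWeights)
  nDrugs <- ncol(fw$H3)
  dA3 <- dC[, seq_len(nDrugs), drop = FALSE] * (fw$A3 > 0)
  dA2 <- (dA3 %*% t(fw$We[[3]])) * (fw$A2 > 0)
  dA1 <- (dA2 %*% t(fw$We[[2]])) * (fw$A1 > 0)
  dA1 %*% t(fw$We[[1]])
}

#' Forward pass for one sample
#'
#' Three masked ReLU layers, concatenation of the drug-layer activations with
#' the sample's fingerprint, and a single sigmoid output unit.
#'
#' @param net a [MaskedNetwork-class].
#' @param cellFeatures numeric vector of length \code{length(nodeOrders$genes)},
#'   in the network's gene order.
#' @param fingerprint binary vector of length \code{nBits}.
#' @return predicted sensitivity probability in (0, 1).
#' @export
forwardPass <- function(net, cellFeatures, fingerprint) {
  stopifnot(is(net, "MaskedNetwork"))
  if (length(cellFeatures) != length(net@nodeOrders$genes))
    stopf("cellFeatures length %d != gene layer size %d",
          length(cellFeatures), length(net@nodeOrders$genes))
  if (length(fingerprint) != net@nBits)
    stopf("fingerprint length %d != configured nBits %d",
          length(fingerprint), net@nBits)
  fw <- .forwardBatch(net, matrix(cellFeatures, 1), matrix(fingerprint, 1))
  unname(fw$prob)
}

#' Mean binary cross-entropy loss
#'
#' Probabilities are clipped into \code{[clip, 1 - clip]} before taking logs so
#' saturated predictions cannot produce infinities.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 labels, same length.
#' @param clip clipping constant; default \code{1e-7}.
#' @return nonnegative scalar loss.
#' @export
bceLoss <- function(probs, labels, clip = 1e-7) {
  if (length(probs) == 0L) stopf("empty input to bceLoss")
  if (length(probs) != length(labels)) stopf("probs and labels lengths differ")
  p <- pmin(pmax(probs, clip), 1 - clip)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# Resolve (cell_id, drug_id) records against the feature matrix and drug set;
# returns aligned X, FP, y. Errors list every unresolvable ID.
.resolveBatch <- function(net, responses, features, drugs) {
  genes <- net@nodeOrders$genes
  missG <- setdiff(genes, featureIds(features))
  if (length(missG))
    stopf("feature matrix lacks %d network gene(s), e.g. %s",
          length(missG), paste(utils::head(missG, 5), collapse = ", "))
  badC <- setdiff(unique(responses$cell_id), cellIds(features))
  badD <- setdiff(unique(responses$drug_id), drugIds(drugs))
  if (length(badC) || length(badD))
    stopf("unresolvable IDs: %s",
          paste(c(badC, badD), collapse = ", "))
  fp <- fingerprints(drugs)
  if (ncol(fp) != net@nBits)
    stopf("drug fingerprints have %d bits but the network expects %d",
          ncol(fp), net@nBits)
  X <- featureValues(features)[responses$cell_id, genes, drop = FALSE]
  FP <- fp[responses$drug_id, , drop = FALSE]
  dimnames(X) <- NULL; dimnames(FP) <- NULL  # keep parameter tensors unnamed
  list(X = X, FP = FP, y = responses$label)
}

#' Train a masked network with mini-batch Adam
#'
#' Minimizes the mean binary cross-entropy with the Adam optimizer
#' (\eqn{\beta_1 = 0.9}, \eqn{\beta_2 = 0.999}, \eqn{\epsilon = 10^{-8}}).
#' Epoch shuffling is seeded from the training configuration. Masked-out
#' weights receive exactly zero gradient (the mask is a Hadamard factor of the
#' forward pass), so they stay at their initial value of zero through any
#' number of updates.
#'
#' @param net an initialized [MaskedNetwork-class].
#' @param features an [IntegratedCellFeatures-class] covering the network's
#'   genes.
#' @param drugs a [DrugSet-class] covering all drugs in \code{responses}.
#' @param responses data.frame with columns \code{cell_id}, \code{drug_id},
#'   \code{label}.
#' @param config a [TrainConfig-class].
#' @return list with elements \code{network} (the trained
#'   [MaskedNetwork-class]) and \code{history} (data.frame of per-epoch mean
#'   training loss).
#' @export
trainNetwork <- function(net, features, drugs, responses, config = trainConfig()) {
  stopifnot(is(net, "MaskedNetwork"), is(config, "TrainConfig"))
  batch <- .resolveBatch(net, responses, features, drugs)
  X <- batch$X; FP <- batch$FP; y <- batch$y
  n <- nrow(X)

  # Adam state per parameter tensor
  zero <- function(x) x * 0
  mW <- lapply(net@weights, zero); vW <- mW
  mB <- lapply(net@biases, zero);  vB <- mB
  mO <- zero(net@outputWeights);   vO <- mO
  mOb <- 0; vOb <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config@learningRate
  step <- 0L
  history <- numeric(config@epochs)

  withSeed(childSeed(config@seed, "train"), {
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config@batchSize)
      for (s in starts) {
        idx <- ord[s:min(s + config@batchSize - 1L, n)]
        fw <- .forwardBatch(net, X[idx, , drop = FALSE], FP[idx, , drop = FALSE])
        g <- .backwardBatch(net, fw, X[idx, , drop = FALSE], y[idx])
        step <- step + 1L
        c1 <- 1 - b1^step; c2 <- 1 - b2^step
        adam <- function(par, m, v, grad) {
          m <- b1 * m + (1 - b1) * grad
          v <- b2 * v + (1 - b2) * grad^2
          list(par = par - lr * (m / c1) / (sqrt(v / c2) + eps), m = m, v = v)
        }
        for (l in 1:3) {
          up <- adam(net@weights[[l]], mW[[l]], vW[[l]], g$W[[l]])
          net@weights[[l]] <- up$par; mW[[l]] <- up$m; vW[[l]] <- up$v
          up <- adam(net@biases[[l]], mB[[l]], vB[[l]], g$b[[l]])
          net@biases[[l]] <- up$par; mB[[l]] <- up$m; vB[[l]] <- up$v
        }
        up <- adam(net@outputWeights, mO, vO, g$wOut)
        net@outputWeights <- up$par; mO <- up$m; vO <- up$v
        up <- adam(net@outputBias, mOb, vOb, g$bOut)
        net@outputBias <- up$par; mOb <- up$m; vOb <- up$v
      }
      history[epoch] <- bceLoss(.forwardBatch(net, X, FP)$prob, y)
    }
  })
  list(network = net, history = data.frame(epoch = seq_len(config@epochs),
                                           loss = history))
}

#' Predict sensitivity probabilities for (cell line, drug) pairs
#'
#' Batched forward pass; the output order matches the input pair order and is
#' invariant to how the pairs are partitioned into batches.
#'
#' @param net a [MaskedNetwork-class].
#' @param pairs data.frame with columns \code{cell_id}, \code{drug_id}.
#' @param features an [IntegratedCellFeatures-class].
#' @param drugs a [DrugSet-class].
#' @return numeric vector of probabilities, one per pair.
#' @export
predictResponse <- function(net, pairs, features, drugs) {
  stopifnot(is(net, "MaskedNetwork"))
  pairs$label <- 0L  # unused by the forward pass
  batch <- .resolveBatch(net, pairs, features, drugs)
  unname(.forwardBatch(net, batch$X, batch$FP)$prob)
}
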