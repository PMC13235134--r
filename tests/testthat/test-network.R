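chainMasks <- function() {
  mk <- function(a, b, src, tgt)
    new("LayerMask", sourceIds = src, targetIds = tgt,
        mask = matrix(1, a, b))
  list(mk(1, 1, "g1", "p1"), mk(1, 1, "p1", "k1"), mk(1, 1, "k1", "d1"))
}

test_that("network initialization respects shapes, masks and seeds", {
  net <- initNetwork(chainMasks(), nBits = 4, config = trainConfig(seed = 3))
  expect_length(net@outputWeights, 1 + 4)  # 1 drug node + 4 fingerprint bits

  # same seed twice => identical parameters
  net2 <- initNetwork(chainMasks(), nBits = 4, config = trainConfig(seed = 3))
  expect_identical(net@weights, net2@weights)
  expect_identical(net@outputWeights, net2@outputWeights)

  # reference-architecture shapes: 837 x 812, 812 x 51, 51 x 69 with 1024 bits
  set.seed(10)
  mk <- function(a, b) {
    m <- matrix(rbinom(a * b, 1, 0.02), a, b)
    m[cbind(seq_len(a), sample.int(b, a, replace = TRUE))] <- 1  # no empty rows
    new("LayerMask", sourceIds = sprintf("s%d", seq_len(a)),
        targetIds = sprintf("t%d", seq_len(b)), mask = m)
  }
  big <- list(mk(837, 812), mk(812, 51), mk(51, 69))
  big[[2]]@sourceIds <- big[[1]]@targetIds
  big[[3]]@sourceIds <- big[[2]]@targetIds
  bigNet <- initNetwork(big, nBits = 1024)
  expect_length(bigNet@outputWeights, 69 + 1024)
  # masked positions start (and stay) at exactly zero
  for (l in 1:3)
    expect_true(all(bigNet@weights[[l]][bigNet@masks[[l]]@mask == 0] == 0))

  badChain <- chainMasks()
  badChain[[2]]@sourceIds <- "px"
  expect_error(initNetwork(badChain, 4), "junction gene->protein")
})

test_that("the forward pass computes (M*W)^T x with ReLU and sigmoid", {
  # hand example: one 2x2 layer, mask [[1,0],[0,1]], weights [[.5,.9],[.3,.2]]
  mk <- function(src, tgt)
    new("LayerMask", sourceIds = src, targetIds = tgt,
        mask = matrix(c(1, 0, 0, 1), 2))
  net <- initNetwork(list(mk(c("g1", "g2"), c("p1", "p2")),
                          mk(c("p1", "p2"), c("k1", "k2")),
                          mk(c("k1", "k2"), c("d1", "d2"))), nBits = 2)
  net@weights[[1]] <- matrix(c(0.5, 0.3, 0.9, 0.2), 2)
  fw <- maskDRP:::.forwardBatch(net, matrix(c(1, 1), 1), matrix(0, 1, 2))
  expect_equal(unname(fw$H1[1, ]), c(0.5, 0.2))

  # all-zero input and biases: every hidden activation 0, output sigmoid(0)=.5
  z <- initNetwork(chainMasks(), nBits = 3)
  expect_equal(forwardPass(z, 0, c(0, 0, 0)), 0.5)

  # Hadamard contract: arbitrary values in masked-out positions change nothing
  set.seed(21)
  rnet <- randomSmallNetwork()
  x <- rnorm(6); fp <- rbinom(5, 1, 0.5)
  p0 <- forwardPass(rnet, x, fp)
  for (l in 1:3) {
    w <- rnet@weights[[l]]
    w[rnet@masks[[l]]@mask == 0] <- 1e6
    rnet@weights[[l]] <- w
  }
  expect_identical(forwardPass(rnet, x, fp), p0)

  expect_error(forwardPass(z, c(0, 0), c(0, 0, 0)), "length")
  expect_error(forwardPass(z, 0, 0), "fingerprint")
})

test_that("masked forward equals the dense loop oracle on 100 random networks", {
  set.seed(123)
  worst <- 0
  for (i in 1:100) {
    net <- randomSmallNetwork(sizes = sample(2:7, 4, replace = TRUE),
                              nBits = sample(3:8, 1))
    x <- rnorm(length(net@nodeOrders$genes))
    fp <- rbinom(net@nBits, 1, 0.5)
    dev <- abs(forwardPass(net, x, fp) - denseForwardOracle(net, x, fp))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-6)
})

test_that("binary cross-entropy matches closed forms and a loop oracle", {
  expect_lt(bceLoss(1 - 1e-9, 1), 1e-6)
  expect_equal(bceLoss(c(0.5, 0.5), c(0, 1)), log(2), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(50); y <- rbinom(50, 1, 0.5)
    expect_equal(bceLoss(p, y), bceElementwise(p, y), tolerance = 1e-12)
  }
  expect_error(bceLoss(numeric(), numeric()), "empty")
  expect_error(bceLoss(0.5, c(1, 0)), "lengths")
})

test_that("training follows the Adam update rule and freezes masked weights", {
  parts <- smallModelParts()
  b <- parts$bundle

  # learning rate 0: parameters unchanged, loss history flat
  net0 <- initNetwork(parts$masks, nBits = 64,
                      config = trainConfig(seed = 1))
  fit0 <- trainNetwork(net0, parts$integrated, b$drugs, b$responses,
                       trainConfig(epochs = 3, learningRate = 0, seed = 1))
  expect_identical(fit0$network@weights, net0@weights)
  expect_equal(diff(fit0$history$loss), c(0, 0), tolerance = 1e-15)

  # single Adam step on a 1-node chain reproduces the hand-derived update
  masks1 <- chainMasks()
  net1 <- initNetwork(masks1, nBits = 1, config = trainConfig(seed = 2))
  feats <- new("IntegratedCellFeatures",
               values = matrix(0.7, 1, 1, dimnames = list("c1", "g1")),
               provenance = list(g1 = "GE"))
  ds <- new("DrugSet", drugIds = "d1", smiles = "C", maxConc = 1,
            fingerprints = matrix(1, 1, 1))
  resp <- data.frame(cell_id = "c1", drug_id = "d1", label = 1L)
  lr <- 0.01
  fit1 <- trainNetwork(net1, feats, ds, resp,
                       trainConfig(batchSize = 1, epochs = 1,
                                   learningRate = lr, seed = 2))
  # independent scalar chain rule: h1=relu(w1 x), h2=relu(w2 h1), h3=relu(w3 h2)
  # z = wo1 h3 + wo2 fp, p = sigmoid(z); dL/dz = p - y
  w1 <- net1@weights[[1]][1, 1]; w2 <- net1@weights[[2]][1, 1]
  w3 <- net1@weights[[3]][1, 1]; wo <- net1@outputWeights
  x <- 0.7; fp1 <- 1
  h1 <- max(w1 * x, 0); h2 <- max(w2 * h1, 0); h3 <- max(w3 * h2, 0)
  p <- 1 / (1 + exp(-(wo[1] * h3 + wo[2] * fp1)))
  dz <- p - 1
  g <- list(w1 = dz * wo[1] * (h3 > 0) * w3 * (h2 > 0) * w2 * (h1 > 0) * x,
            wo1 = dz * h3, wo2 = dz * fp1, bo = dz)
  adam1 <- function(par, grad) {
    m <- 0.1 * grad; v <- 0.001 * grad^2          # first-step moments
    par - lr * (m / 0.1) / (sqrt(v / 0.001) + 1e-8)
  }
  expect_equal(fit1$network@weights[[1]][1, 1], adam1(w1, g$w1), tolerance = 1e-10)
  expect_equal(fit1$network@outputWeights,
               adam1(wo, c(g$wo1, g$wo2)), tolerance = 1e-10)
  expect_equal(fit1$network@outputBias, adam1(0, g$bo), tolerance = 1e-10)

  # determinism: same config twice gives identical parameters
  netA <- initNetwork(parts$masks, nBits = 64, config = trainConfig(seed = 5))
  fitA <- trainNetwork(netA, parts$integrated, b$drugs, b$responses,
                       trainConfig(epochs = 2, seed = 5))
  fitB <- trainNetwork(netA, parts$integrated, b$drugs, b$responses,
                       trainConfig(epochs = 2, seed = 5))
  expect_identical(fitA$network@weights, fitB$network@weights)

  # easy planted data: loss strictly decreases over the first epochs
  expect_true(all(diff(fitA$history$loss) < 0))

  # masked weights remain exactly zero after training
  for (l in 1:3)
    expect_true(all(fitA$network@weights[[l]][parts$masks[[l]]@mask == 0] == 0))

  expect_error(
    trainNetwork(netA, parts$integrated, b$drugs,
                 data.frame(cell_id = "nope", drug_id = "d01", label = 1L),
                 trainConfig(epochs = 1)),
    "nope")
})

test_that("prediction is order-preserving, batch-invariant and matches forward()", {
  parts <- smallModelParts()
  b <- parts$bundle
  net <- initNetwork(parts$masks, nBits = 64, config = trainConfig(seed = 9))
  fit <- trainNetwork(net, parts$integrated, b$drugs,
                      b$responses[1:120, ], trainConfig(epochs = 3, seed = 9))
  net <- fit$network

  pairs <- b$responses[sample.int(nrow(b$responses), 20), c("cell_id", "drug_id")]
  p <- predictResponse(net, pairs, parts$integrated, b$drugs)
  expect_true(all(p > 0 & p < 1))

  # duplicated pair gives identical probabilities
  dup <- rbind(pairs[1, ], pairs[1, ])
  pd <- predictResponse(net, dup, parts$integrated, b$drugs)
  expect_identical(pd[1], pd[2])

  # partition invariance
  pSplit <- c(predictResponse(net, pairs[1:7, ], parts$integrated, b$drugs),
              predictResponse(net, pairs[8:20, ], parts$integrated, b$drugs))
  expect_equal(pSplit, p, tolerance = 1e-15)

  # matches the one-at-a-time forward pass
  fpMat <- fingerprints(b$drugs)
  X <- featureValues(parts$integrated)
  for (i in seq_len(nrow(pairs))) {
    one <- forwardPass(net, X[pairs$cell_id[i], net@nodeOrders$genes],
                       fpMat[pairs$drug_id[i], ])
    expect_equal(p[i], one, tolerance = 1e-12)
  }
})

test_that("effective parameter count is below the dense equivalent", {
  parts <- smallModelParts()
  net <- initNetwork(parts$masks, nBits = 64)
  dims <- vapply(net@masks, function(m) dim(m@mask), integer(2))
  dense <- sum(dims[1, ] * dims[2, ]) + sum(dims[2, ]) +
    length(net@outputWeights) + 1
  expect_equal(parameterCount(net),
               sum(vapply(net@masks, function(m) sum(m@mask), numeric(1))) +
                 sum(dims[2, ]) + length(net@outputWeights) + 1)
  expect_lt(parameterCount(net), dense)
})
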