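# Trained small model shared by the importance tests.
trainedSmall <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      parts <- smallModelParts()
      b <- parts$bundle
      net <- initNetwork(parts$masks, nBits = 64,
                         config = trainConfig(seed = 11))
      fit <- trainNetwork(net, parts$integrated, b$drugs,
                          b$responses[1:200, ],
                          trainConfig(epochs = 8, seed = 11))
      cache <<- list(net = fit$network, parts = parts,
                     test = b$responses[201:300, ])
    }
    cache
  }
})

test_that("activation and variance importance match their textbook oracles", {
  x <- cbind(zero = c(0, 0, 0, 0), sym = c(-1, 1, -1, 1),
             r1 = c(0.2, 0.8, 0.5, 0.1))
  act <- activationImportance(x)
  expect_equal(unname(act["zero"]), 0)
  expect_equal(unname(act["sym"]), 1)
  vr <- varianceImportance(x)
  expect_equal(unname(vr["zero"]), 0)
  expect_equal(unname(varianceImportance(cbind(a = c(0, 1)))["a"]), 0.5)

  set.seed(31)
  xr <- matrix(rnorm(200), 20)
  colnames(xr) <- sprintf("f%d", 1:10)
  expect_equal(unname(activationImportance(xr)),
               apply(xr, 2, function(col) mean(abs(col))), tolerance = 1e-12,
               ignore_attr = TRUE)
  twoPass <- apply(xr, 2, function(col) sum((col - mean(col))^2) / (nrow(xr) - 1))
  expect_equal(unname(varianceImportance(xr)), unname(twoPass), tolerance = 1e-12)
  expect_error(varianceImportance(xr[1, , drop = FALSE]), "at least 2")
})

test_that("analytic input gradients agree with central finite differences", {
  set.seed(55)
  for (rep in 1:10) {
    net <- randomSmallNetwork(sizes = c(5, 4, 3, 2), nBits = 4)
    X <- matrix(rnorm(3 * 5), 3)
    FP <- matrix(rbinom(12, 1, 0.5), 3)
    y <- rbinom(3, 1, 0.5)
    G <- maskDRP:::.inputGradients(net, X, FP, y)
    eps <- 1e-5
    for (j in sample(5, 2)) for (i in 1:3) {
      up <- X; up[i, j] <- up[i, j] + eps
      dn <- X; dn[i, j] <- dn[i, j] - eps
      lossAt <- function(M) {
        p <- maskDRP:::.forwardBatch(net, M[i, , drop = FALSE],
                                     FP[i, , drop = FALSE])$prob
        bceLoss(p, y[i])
      }
      expect_equal(G[i, j], (lossAt(up) - lossAt(dn)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("gradient importance averages |dL/dx| over the test set", {
  tr <- trainedSmall()
  g <- gradientImportance(tr$net, tr$parts$integrated,
                          tr$parts$bundle$drugs, tr$test)
  expect_length(g, length(tr$net@nodeOrders$genes))
  expect_true(all(is.finite(g) & g >= 0))
  # direct average over per-sample gradients
  batch <- maskDRP:::.resolveBatch(tr$net, tr$test, tr$parts$integrated,
                                   tr$parts$bundle$drugs)
  G <- maskDRP:::.inputGradients(tr$net, batch$X, batch$FP, batch$y)
  expect_equal(unname(g), unname(colMeans(abs(G))), tolerance = 1e-12)
  expect_error(gradientImportance(tr$net, tr$parts$integrated,
                                  tr$parts$bundle$drugs, tr$test[0, ]),
               "empty")
})

test_that("permutation importance is zero for inert features and seeded", {
  tr <- trainedSmall()
  # constant column: shuffling changes nothing, so the score is exactly 0
  feats <- tr$parts$integrated
  v <- featureValues(feats)
  v[, tr$net@nodeOrders$genes[1]] <- 0.5
  constFeats <- new("IntegratedCellFeatures", values = v,
                    provenance = feats@provenance)
  s <- permutationImportance(tr$net, constFeats, tr$parts$bundle$drugs,
                             tr$test, nRepeats = 2, seed = 4)
  expect_equal(unname(s[1]), 0)
  s2 <- permutationImportance(tr$net, constFeats, tr$parts$bundle$drugs,
                              tr$test, nRepeats = 2, seed = 4)
  expect_identical(s, s2)
  expect_true(all(s >= 0))
})

test_that("combined importance min-max normalizes each component first", {
  grad <- c(a = 0, b = 5, c = 10)
  act <- c(a = 1, b = 2, c = 3)
  vr <- c(a = 0.1, b = 0.2, c = 0.3)
  perm <- c(a = 0, b = 50, c = 100)
  comb <- combinedImportance(grad, act, vr, perm)
  expect_equal(unname(comb), c(0, 0.5, 1))  # maximal in all four => 1
  # element-wise oracle on random vectors
  set.seed(12)
  g <- runif(8); a <- runif(8); v <- runif(8); p <- runif(8)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  expect_equal(combinedImportance(g, a, v, p),
               (mm(g) + mm(a) + mm(v) + mm(p)) / 4, tolerance = 1e-12)
  # raw-scale averaging behind the flag
  expect_equal(combinedImportance(g, a, v, p, normalize = FALSE),
               (g + a + v + p) / 4, tolerance = 1e-12)
  expect_error(combinedImportance(g, a, v, p[-1]), "equal length")
})

test_that("layer importance is the mean absolute activation per node", {
  tr <- trainedSmall()
  for (lvl in c("protein", "pathway", "drug")) {
    s <- layerImportance(tr$net, tr$parts$integrated, tr$parts$bundle$drugs,
                         tr$test, lvl)
    expect_length(s, length(tr$net@nodeOrders[[paste0(lvl, "s")]]))
    expect_true(all(s >= 0))
    # direct per-node loop oracle
    batch <- maskDRP:::.resolveBatch(tr$net, tr$test, tr$parts$integrated,
                                     tr$parts$bundle$drugs)
    fw <- maskDRP:::.forwardBatch(tr$net, batch$X, batch$FP)
    H <- switch(lvl, protein = fw$H1, pathway = fw$H2, drug = fw$H3)
    direct <- vapply(seq_len(ncol(H)), function(k) mean(abs(H[, k])), numeric(1))
    expect_equal(unname(s), direct, tolerance = 1e-12)
  }
  # zero input with zero biases: all activations zero
  z <- initNetwork(list(
    new("LayerMask", sourceIds = "g1", targetIds = "p1", mask = matrix(1)),
    new("LayerMask", sourceIds = "p1", targetIds = "k1", mask = matrix(1)),
    new("LayerMask", sourceIds = "k1", targetIds = "d1", mask = matrix(1))),
    nBits = 2)
  fw0 <- maskDRP:::.forwardBatch(z, matrix(0, 1, 1), matrix(0, 1, 2))
  expect_equal(unname(fw0$H2[1, ]), 0)
})

test_that("cross-run aggregation reproduces a hand enumeration", {
  mkReport <- function(scores, run) {
    new("ImportanceReport", level = "gene", entityIds = names(scores),
        scores = data.frame(combined = unname(scores)),
        nSamples = 10L, runId = as.integer(run))
  }
  # hand-written 3-run example over 5 genes, top 2 per run:
  # run1 -> {gA, gB}; run2 -> {gA, gC}; run3 -> {gA, gB}
  r1 <- mkReport(c(gA = 0.9, gB = 0.8, gC = 0.1, gD = 0.0, gE = 0.0), 1)
  r2 <- mkReport(c(gA = 0.7, gB = 0.2, gC = 0.9, gD = 0.1, gE = 0.0), 2)
  r3 <- mkReport(c(gA = 0.6, gB = 0.9, gC = 0.2, gD = 0.0, gE = 0.1), 3)
  agg <- aggregateRuns(list(r1, r2, r3), topK = 2, nSelect = 3)
  expect_identical(agg$entity_id, c("gA", "gB", "gC"))
  expect_identical(agg$frequency, c(3L, 2L, 1L))

  # single run: simply its top n
  agg1 <- aggregateRuns(list(r1), topK = 3, nSelect = 2)
  expect_identical(agg1$entity_id, c("gA", "gB"))

  # an entity in every run's top-k ranks first with frequency = run count
  expect_equal(agg$frequency[1], 3L)
  # frequency ties broken by mean score: gB (mean .633) over gC (mean .4)
  expect_error(aggregateRuns(list()), "empty")
  bad <- mkReport(c(gX = 1), 1)
  expect_error(aggregateRuns(list(r1, bad)), "universe")
})
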