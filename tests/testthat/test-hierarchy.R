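test_that("buildHierarchy assembles toy tables and drops out-of-universe edges", {
  h <- chainHierarchy()
  expect_equal(length(geneIds(h)) + length(proteinIds(h)) +
               length(pathwayIds(h)) + length(drugIds(h)), 4L)
  expect_equal(nrow(edgeTable(h, "gp")) + nrow(edgeTable(h, "pk")) +
               nrow(edgeTable(h, "kd")), 3L)

  # an edge referencing an unknown gene is dropped, hierarchy unchanged
  h2 <- buildHierarchy(
    data.frame(gene_id = c("g1", "gX"), protein_id = c("p1", "p1")),
    data.frame(protein_id = "p1", pathway_id = "k1", p_value = 0.01),
    data.frame(pathway_id = "k1", drug_id = "d1"),
    geneUniverse = "g1", drugUniverse = "d1")
  expect_equal(geneIds(h2), "g1")
  expect_equal(nrow(edgeTable(h2, "gp")), 1L)

  # hand-enumerated counts on a 3-gene / 2-protein / 2-pathway / 2-drug toy
  h3 <- buildHierarchy(
    data.frame(gene_id = c("g1", "g2", "g3", "g3"),
               protein_id = c("p1", "p1", "p2", "p1")),
    data.frame(protein_id = c("p1", "p2"), pathway_id = c("k1", "k2"),
               p_value = c(0.01, 0.02)),
    data.frame(pathway_id = c("k1", "k2", "k2"), drug_id = c("d1", "d1", "d2")),
    geneUniverse = c("g1", "g2", "g3"), drugUniverse = c("d1", "d2"))
  expect_equal(length(geneIds(h3)), 3L)
  expect_equal(length(proteinIds(h3)), 2L)
  expect_equal(length(pathwayIds(h3)), 2L)
  expect_equal(length(drugIds(h3)), 2L)
  expect_equal(nrow(edgeTable(h3, "gp")), 4L)
  expect_equal(nrow(edgeTable(h3, "kd")), 3L)

  expect_error(buildHierarchy(
    data.frame(gene_id = character(), protein_id = character()),
    data.frame(protein_id = "p1", pathway_id = "k1", p_value = 0.01),
    data.frame(pathway_id = "k1", drug_id = "d1"),
    "g1", "d1"), "gene-protein")
})

test_that("pathway significance filtering keeps the 0.05 boundary inclusive", {
  h <- buildHierarchy(
    data.frame(gene_id = c("g1", "g1", "g1"), protein_id = c("p1", "p2", "p3")),
    data.frame(protein_id = c("p1", "p2", "p3"),
               pathway_id = c("k1", "k2", "k3"),
               p_value = c(0.01, 0.05, 0.06)),
    data.frame(pathway_id = c("k1", "k2", "k3"), drug_id = "d1"),
    geneUniverse = "g1", drugUniverse = "d1")
  kept <- filterSignificantPathways(h, 0.05)
  expect_setequal(pathwayIds(kept), c("k1", "k2"))

  expect_equal(pathwayIds(filterSignificantPathways(h, 1.0)),
               pathwayIds(h))  # alpha = 1 is the identity
  expect_error(filterSignificantPathways(h, 0), "no pathway passes")

  hNA <- h
  hNA@edgesPK$p_value[2] <- NA
  expect_error(filterSignificantPathways(hNA, 0.05), "k2")
})

test_that("over-representation p-value matches exact combinatorics", {
  expect_identical(overrepresentationPvalue(5, 5, 0, 10), 1.0)
  expect_equal(overrepresentationPvalue(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  # brute-force tail sum oracle at the floored expected overlap
  bruteTail <- function(setSize, pathSize, ov, uni) {
    sum(vapply(ov:min(setSize, pathSize), function(k)
      choose(pathSize, k) * choose(uni - pathSize, setSize - k), numeric(1))) /
      choose(uni, setSize)
  }
  ovExp <- floor(6 * 10 / 30)  # E[X] = setSize * pathSize / universe
  p <- overrepresentationPvalue(6, 10, ovExp, 30)
  expect_equal(p, bruteTail(6, 10, ovExp, 30), tolerance = 1e-12)
  expect_gte(p, 0.3)
  expect_error(overrepresentationPvalue(5, 5, 6, 10), "inconsistent")
})

test_that("pruning removes off-path nodes and matches the BFS oracle", {
  # isolated gene g2 disappears, the chain survives
  h <- buildHierarchy(
    data.frame(gene_id = "g1", protein_id = "p1"),
    data.frame(protein_id = "p1", pathway_id = "k1", p_value = 0.01),
    data.frame(pathway_id = "k1", drug_id = "d1"),
    geneUniverse = c("g1", "g2"), drugUniverse = "d1")
  p <- pruneHierarchy(h)
  expect_equal(geneIds(p), "g1")
  expect_true(isPruned(p))

  # p2 has no pathway: removed forward; g3 (only wired to p2) removed backward
  h2 <- new("BioHierarchy",
    genes = c("g1", "g3"), proteins = c("p1", "p2"),
    pathways = "k1", drugs = "d1",
    edgesGP = data.frame(gene = c("g1", "g3"), protein = c("p1", "p2"),
                         score = 1),
    edgesPK = data.frame(protein = "p1", pathway = "k1", p_value = 0.01,
                         combined_score = 1),
    edgesKD = data.frame(pathway = "k1", drug = "d1"), pruned = FALSE)
  p2 <- pruneHierarchy(h2)
  expect_equal(geneIds(p2), "g1")
  expect_equal(proteinIds(p2), "p1")

  # fully disconnected graph errors out explicitly
  h3 <- new("BioHierarchy",
    genes = "g1", proteins = "p1", pathways = "k1", drugs = "d1",
    edgesGP = data.frame(gene = "g1", protein = "p1", score = 1),
    edgesPK = data.frame(protein = character(), pathway = character(),
                         p_value = numeric(), combined_score = numeric()),
    edgesKD = data.frame(pathway = "k1", drug = "d1"), pruned = FALSE)
  expect_error(pruneHierarchy(h3), "empty")

  # oracle equivalence + idempotence over 50 random hierarchies
  set.seed(501)
  for (i in 1:50) {
    h <- randomHierarchy()
    pr <- pruneHierarchy(h)
    oracle <- pathNodesOracle(h)
    expect_identical(sort(geneIds(pr)), sort(oracle$genes))
    expect_identical(sort(proteinIds(pr)), sort(oracle$proteins))
    expect_identical(sort(pathwayIds(pr)), sort(oracle$pathways))
    expect_identical(sort(drugIds(pr)), sort(oracle$drugs))
    pr2 <- pruneHierarchy(pr)
    expect_identical(geneIds(pr2), geneIds(pr))
    expect_identical(edgeTable(pr2, "gp"), edgeTable(pr, "gp"))
  }
})

test_that("layer masks mirror the edge sets in stored node order", {
  p <- pruneHierarchy(chainHierarchy())
  masks <- masksFromHierarchy(p)
  for (m in masks) expect_equal(maskMatrix(m), matrix(1, 1, 1))

  # complete bipartite gene-protein wiring gives an all-ones mask
  h <- buildHierarchy(
    data.frame(gene_id = rep(c("g1", "g2"), each = 2),
               protein_id = rep(c("p1", "p2"), 2)),
    data.frame(protein_id = c("p1", "p2"), pathway_id = "k1",
               p_value = 0.01),
    data.frame(pathway_id = "k1", drug_id = "d1"),
    geneUniverse = c("g1", "g2"), drugUniverse = "d1")
  masks2 <- masksFromHierarchy(pruneHierarchy(h))
  expect_equal(maskMatrix(masks2$gp), matrix(1, 2, 2))

  # density and edge-count bijection + order stability on random hierarchies
  set.seed(77)
  for (i in 1:10) {
    pr <- pruneHierarchy(randomHierarchy(10, 6, 4, 3, 0.35))
    mk <- masksFromHierarchy(pr)
    expect_equal(sum(maskMatrix(mk$gp)), nrow(edgeTable(pr, "gp")))
    expect_equal(sum(maskMatrix(mk$pk)), nrow(edgeTable(pr, "pk")))
    expect_equal(sum(maskMatrix(mk$kd)), nrow(edgeTable(pr, "kd")))
    expect_equal(mean(maskMatrix(mk$gp)),
                 nrow(edgeTable(pr, "gp")) /
                   (length(geneIds(pr)) * length(proteinIds(pr))))
    expect_identical(mk$gp@sourceIds, geneIds(pr))
    expect_identical(mk$kd@targetIds, drugIds(pr))
    expect_false(any(rowSums(maskMatrix(mk$gp)) == 0))
    expect_false(any(colSums(maskMatrix(mk$kd)) == 0))
  }

  expect_error(masksFromHierarchy(chainHierarchy()), "pruned")
})
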