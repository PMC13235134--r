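# Delimited-table readers and writers for the formats the pipeline consumes:
# omics CSVs (cells x features), annotation edge TSVs, drug and response CSVs,
# mask exports and model checkpoints.

#' Read one omics layer from CSV
#'
#' Expects cell IDs in the first column and feature IDs as the header.
#' Duplicate (cell, feature) measurements — duplicated row or column labels —
#' are mean-aggregated.
#'
#' @param path CSV file.
#' @param kind omics kind tag (\code{"GE"}, \code{"CNV"}, \code{"MUT"},
#'   \code{"PROT"}).
#' @return an [OmicsMatrix-class].
#' @export
readOmicsCsv <- function(path, kind) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cellsRaw <- as.character(df[[1]])
  featsRaw <- names(df)[-1]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(cellsRaw, featsRaw)  # subsetting mangles duplicates
  if (anyDuplicated(cellsRaw)) {
    m <- rowsum(m, cellsRaw, reorder = FALSE) /
      as.vector(table(cellsRaw)[unique(cellsRaw)])
    rownames(m) <- unique(cellsRaw)
  }
  if (anyDuplicated(colnames(m))) {
    t_agg <- rowsum(t(m), colnames(m), reorder = FALSE) /
      as.vector(table(colnames(m))[unique(colnames(m))])
    m <- t(t_agg)
  }
  omicsMatrix(m, kind)
}

#' Write one omics layer to CSV
#'
#' @param m an [OmicsMatrix-class].
#' @param path output CSV file.
#' @export
writeOmicsCsv <- function(m, path) {
  df <- data.frame(cell_id = cellIds(m), featureValues(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read the three annotation edge tables
#'
#' Tab-separated files with headers: gene-protein (\code{gene_id},
#' \code{protein_id}, optional \code{score}), protein-pathway
#' (\code{protein_id}, \code{pathway_id}, \code{p_value}, optional
#' \code{combined_score}) and pathway-drug (\code{pathway_id}, \code{drug_id}).
#'
#' @param gpPath,pkPath,kdPath file paths.
#' @return named list of three data.frames (\code{gp}, \code{pk}, \code{kd}).
#' @export
readEdgeTables <- function(gpPath, pkPath, kdPath) {
  rd <- function(p) utils::read.delim(p, stringsAsFactors = FALSE)
  list(gp = rd(gpPath), pk = rd(pkPath), kd = rd(kdPath))
}

#' Write a bundle of synthetic study tables
#'
#' Emits the same delimited formats the readers consume: one CSV per omics
#' layer, three annotation edge TSVs, the drug table, the response table and
#' the cell-line to cancer-type map.
#'
#' @param bundle list as returned by [simulateDataset()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outDir, f)
  paths <- character()
  for (m in bundle$omics) {
    f <- p(sprintf("omics_%s.csv", tolower(omicsKind(m))))
    writeOmicsCsv(m, f); paths <- c(paths, f)
  }
  h <- bundle$hierarchy
  utils::write.table(
    data.frame(gene_id = h@edgesGP$gene, protein_id = h@edgesGP$protein,
               score = h@edgesGP$score),
    p("gp_edges.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(protein_id = h@edgesPK$protein, pathway_id = h@edgesPK$pathway,
               p_value = h@edgesPK$p_value,
               combined_score = h@edgesPK$combined_score),
    p("pk_edges.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(pathway_id = h@edgesKD$pathway, drug_id = h@edgesKD$drug),
    p("kd_edges.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  d <- bundle$drugs
  utils::write.csv(
    data.frame(drug_id = drugIds(d), smiles = d@smiles,
               max_conc = unname(maxConc(d))),
    p("drugs.csv"), row.names = FALSE)
  utils::write.csv(
    bundle$responses[c("cell_id", "drug_id", "ln_ic50")],
    p("responses.csv"), row.names = FALSE)
  cmap <- unique(bundle$responses[c("cell_id", "cancer_type")])
  utils::write.csv(cmap, p("cancer_types.csv"), row.names = FALSE)
  invisible(c(paths, p(c("gp_edges.tsv", "pk_edges.tsv", "kd_edges.tsv",
                         "drugs.csv", "responses.csv", "cancer_types.csv"))))
}

#' Read a study bundle from a directory
#'
#' Counterpart of [writeBundle()]: loads the omics CSVs, annotation TSVs, drug
#' table, responses and cancer-type map; builds the [DrugSet-class] (with
#' fingerprints) and the unpruned [BioHierarchy-class]; and labels the
#' responses by binarizing ln IC50 against each drug's maximum screening
#' concentration.
#'
#' @param dir directory written by [writeBundle()] (or hand-assembled in the
#'   same layout).
#' @param radius,nBits fingerprint parameters.
#' @param icScale \code{"ln"} or \code{"log10"}, see [binarizeResponse()].
#' @return list with elements \code{omics}, \code{hierarchy}, \code{drugs},
#'   \code{responses}.
#' @export
readBundle <- function(dir, radius = 2, nBits = 1024, icScale = "ln") {
  p <- function(f) file.path(dir, f)
  kinds <- c("GE", "CNV", "MUT", "PROT")
  files <- p(sprintf("omics_%s.csv", tolower(kinds)))
  present <- file.exists(files)
  if (!any(present)) stopf("no omics_*.csv found in %s", dir)
  omics <- Map(readOmicsCsv, files[present], kinds[present])
  names(omics) <- kinds[present]

  drugTab <- utils::read.csv(p("drugs.csv"), stringsAsFactors = FALSE)
  drugs <- drugSetFromTable(drugTab, radius = radius, nBits = nBits)

  edges <- readEdgeTables(p("gp_edges.tsv"), p("pk_edges.tsv"), p("kd_edges.tsv"))
  geneUniverse <- unique(unlist(lapply(omics, featureIds)))
  hierarchy <- buildHierarchy(edges$gp, edges$pk, edges$kd,
                              geneUniverse = geneUniverse,
                              drugUniverse = drugIds(drugs))

  responses <- utils::read.csv(p("responses.csv"), stringsAsFactors = FALSE)
  mc <- maxConc(drugs)
  bad <- setdiff(unique(responses$drug_id), names(mc))
  if (length(bad)) stopf("responses reference unknown drug(s): %s",
                         paste(bad, collapse = ", "))
  responses$label <- binarizeResponse(responses$ln_ic50,
                                      unname(mc[responses$drug_id]),
                                      scale = icScale)
  cmapFile <- p("cancer_types.csv")
  if (file.exists(cmapFile)) {
    cmap <- utils::read.csv(cmapFile, stringsAsFactors = FALSE)
    responses$cancer_type <- cmap$cancer_type[match(responses$cell_id,
                                                    cmap$cell_id)]
  }
  list(omics = omics, hierarchy = hierarchy, drugs = drugs,
       responses = responses)
}

#' Export layer masks as dense CSVs with node-order sidecars
#'
#' @param masks named list from [masksFromHierarchy()].
#' @param outDir output directory.
#' @return invisibly, the written paths.
#' @export
writeMasksCsv <- function(masks, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(masks)) {
    m <- masks[[nm]]
    f <- file.path(outDir, sprintf("mask_%s.csv", nm))
    mm <- maskMatrix(m)
    dimnames(mm) <- list(m@sourceIds, m@targetIds)
    utils::write.csv(mm, f)
    o <- file.path(outDir, sprintf("mask_%s_order.csv", nm))
    n <- max(length(m@sourceIds), length(m@targetIds))
    utils::write.csv(data.frame(
      source_id = c(m@sourceIds, rep("", n - length(m@sourceIds))),
      target_id = c(m@targetIds, rep("", n - length(m@targetIds)))),
      o, row.names = FALSE)
    paths <- c(paths, f, o)
  }
  invisible(paths)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds masks, weights, biases, node orders and the fingerprint
#' length; the round-trip is exact.
#'
#' @param net a [MaskedNetwork-class].
#' @param path checkpoint file.
#' @return \code{loadNetwork} returns the restored [MaskedNetwork-class].
#' @export
saveNetwork <- function(net, path) {
  stopifnot(is(net, "MaskedNetwork"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  net <- readRDS(path)
  if (!is(net, "MaskedNetwork")) stopf("'%s' is not a model checkpoint", path)
  methods::validObject(net)
  net
}
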