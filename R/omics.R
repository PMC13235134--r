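#' Construct an OmicsMatrix
#'
#' Duplicate (cell, feature) measurements are not representable in a matrix;
#' use [readOmicsCsv()] for tables that may carry duplicates (they are
#' mean-aggregated there).
#'
#' @param values numeric matrix, cells in rows, features in columns, full
#'   dimnames.
#' @param kind one of \code{"GE"}, \code{"CNV"}, \code{"MUT"}, \code{"PROT"}.
#' @return an [OmicsMatrix-class].
#' @export
omicsMatrix <- function(values, kind) {
  methods::new("OmicsMatrix", values = values, kind = kind)
}

#' Two-stage variance filter
#'
#' First drops the \code{dropLowFraction} of features with the lowest variance,
#' then keeps only the \code{keepTopFraction} of the survivors with the highest
#' variance — the order used for expression preprocessing (drop the low-variance
#' half, then keep the top quarter by variance). Ties are broken by feature-ID
#' lexicographic order, so the result is deterministic.
#'
#' @param m an [OmicsMatrix-class].
#' @param dropLowFraction fraction in [0, 1] of lowest-variance features to drop
#'   in stage one.
#' @param keepTopFraction fraction in [0, 1] of highest-variance survivors to
#'   keep in stage two.
#' @return the filtered [OmicsMatrix-class].
#' @export
varianceFilter <- function(m, dropLowFraction = 0.5, keepTopFraction = 0.25) {
  stopifnot(is(m, "OmicsMatrix"))
  if (dropLowFraction < 0 || dropLowFraction > 1 ||
      keepTopFraction < 0 || keepTopFraction > 1)
    stopf("fractions must lie in [0, 1]")
  v <- m@values
  vars <- apply(v, 2, stats::var)
  # order by variance, ties by feature ID (C locale for stability)
  ord <- order(vars, colnames(v), method = "radix")
  nDrop <- floor(ncol(v) * dropLowFraction)
  stage1 <- ord[seq_len(ncol(v) - nDrop) + nDrop]
  nKeep <- ceiling(length(stage1) * keepTopFraction)
  if (nKeep == 0L) stopf("variance filter removed every feature")
  keep <- stage1[seq(length(stage1) - nKeep + 1L, length(stage1))]
  keep <- sort(keep)  # preserve original column order
  omicsMatrix(v[, keep, drop = FALSE], m@kind)
}

#' Drop features dominated by zeros
#'
#' A feature is removed iff its fraction of exactly-zero values strictly
#' exceeds \code{maxZeroFraction} ("more than" the cutoff); a feature sitting
#' exactly on the boundary is retained.
#'
#' @param m an [OmicsMatrix-class].
#' @param maxZeroFraction tolerated zero fraction in [0, 1]; default 0.05.
#' @return the filtered [OmicsMatrix-class].
#' @export
zeroFractionFilter <- function(m, maxZeroFraction = 0.05) {
  stopifnot(is(m, "OmicsMatrix"))
  if (maxZeroFraction < 0 || maxZeroFraction > 1)
    stopf("maxZeroFraction must lie in [0, 1]")
  v <- m@values
  zf <- colMeans(v == 0)
  keep <- zf <= maxZeroFraction
  if (!any(keep)) stopf("zero-fraction filter removed every feature")
  omicsMatrix(v[, keep, drop = FALSE], m@kind)
}

#' Per-feature min-max scaling to [0, 1]
#'
#' Each feature is mapped to \code{(x - min) / (max - min)}. Constant features
#' (max == min) map to 0: they carry no information, and 0 is the conservative
#' choice for the downstream ReLU layers.
#'
#' @param m an [OmicsMatrix-class].
#' @return the scaled [OmicsMatrix-class].
#' @export
minmaxScale <- function(m) {
  stopifnot(is(m, "OmicsMatrix"))
  v <- m@values
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  rng <- hi - lo
  scaled <- sweep(v, 2, lo, "-")
  pos <- rng > 0
  scaled[, pos] <- sweep(scaled[, pos, drop = FALSE], 2, rng[pos], "/")
  scaled[, !pos] <- 0
  omicsMatrix(scaled, m@kind)
}

#' Integrate omics layers by availability-weighted averaging
#'
#' Builds one feature matrix over the union of feature IDs across layers. For a
#' feature present in \eqn{|M|} of the supplied omics, its integrated value is
#' the sum of its per-omics values divided by the availability divisor: by
#' default \eqn{|M|} itself (a true average over the omics that measured the
#' feature), or the constant total number of supplied layers with
#' \code{divisor = "constant"} (which shrinks features measured in few layers).
#' Feature IDs are matched verbatim across layers; no symbol mapping is
#' attempted.
#'
#' Cell lines are intersected across layers (with a logged count when rows are
#' dropped); feature order is first-seen order across the layer list, but the
#' integrated values themselves are invariant to permuting the input list.
#'
#' @param matrices list of [OmicsMatrix-class] objects (distinct kinds).
#' @param divisor \code{"availability"} (default) or \code{"constant"}.
#' @return an [IntegratedCellFeatures-class].
#' @export
integrateOmics <- function(matrices, divisor = c("availability", "constant")) {
  divisor <- match.arg(divisor)
  if (!length(matrices) || !all(vapply(matrices, is, TRUE, "OmicsMatrix")))
    stopf("matrices must be a non-empty list of OmicsMatrix objects")
  kinds <- vapply(matrices, omicsKind, character(1))
  if (anyDuplicated(kinds)) stopf("duplicate omics kinds: %s",
                                  paste(kinds[duplicated(kinds)], collapse = ", "))

  cellSets <- lapply(matrices, cellIds)
  cells <- Reduce(intersect, cellSets)
  if (length(cells) == 0L) stopf("no cell line is shared across all omics layers")
  if (any(lengths(cellSets) != length(cells)))
    logMsg("integrateOmics: restricted to %d shared cell line(s)", length(cells))

  feats <- unique(unlist(lapply(matrices, featureIds)))
  total <- matrix(0, length(cells), length(feats), dimnames = list(cells, feats))
  avail <- matrix(0L, length(cells), length(feats))
  prov <- stats::setNames(vector("list", length(feats)), feats)
  for (m in matrices) {
    f <- featureIds(m)
    total[, f] <- total[, f] + featureValues(m)[cells, f, drop = FALSE]
    avail[, match(f, feats)] <- avail[, match(f, feats)] + 1L
    for (id in f) prov[[id]] <- c(prov[[id]], omicsKind(m))
  }
  div <- if (divisor == "availability") avail else length(matrices)
  methods::new("IntegratedCellFeatures", values = total / div, provenance = prov)
}
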