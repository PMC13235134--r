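#' Canonicalize SMILES strings
#'
#' Round-trips each SMILES through the cheminformatics backend's canonical
#' writer, so equivalent spellings of one molecule map to one string (and hence
#' to one fingerprint). Unparsable input yields an error naming the offender.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional identifiers used in error messages (defaults to the
#'   SMILES themselves).
#' @return character vector of canonical SMILES.
#' @export
canonicalSmiles <- function(smiles, ids = smiles) {
  stopifnot(length(smiles) == length(ids))
  out <- character(length(smiles))
  for (i in seq_along(smiles)) {
    smi <- smiles[i]
    if (is.na(smi) || !nzchar(trimws(smi)))
      stopf("empty SMILES for '%s'", ids[i])
    can <- trimws(ChemmineOB::convertFormat("SMILES", "CAN", source = smi))
    if (!nzchar(can)) stopf("unparsable SMILES for '%s': %s", ids[i], smi)
    out[i] <- can
  }
  out
}

#' Morgan (extended-connectivity) fingerprints from SMILES
#'
#' Computes hashed circular fingerprints: each atom's neighbourhood up to
#' \code{radius} bonds is hashed (the ECFP\eqn{2r} scheme; radius 2 is the
#' usual ECFP4), and the resulting identifiers are folded to \code{nBits}
#' positions by modular OR. SMILES are canonicalized first, so equivalent
#' spellings of one molecule produce bit-identical fingerprints, and the
#' computation is deterministic across sessions.
#'
#' @param smiles character vector of SMILES strings.
#' @param radius neighbourhood radius in bonds (0-5); default 2 (ECFP4).
#' @param nBits fingerprint length; conventional choices are 512, 1024 (default)
#'   or 2048.
#' @param ids optional identifiers for error messages.
#' @return binary matrix of shape \code{length(smiles) x nBits}, rownames
#'   \code{ids}.
#' @examples
#' \donttest{
#' fp <- morganFingerprint(c(methane = "C", ethane = "CC"), nBits = 512)
#' }
#' @export
morganFingerprint <- function(smiles, radius = 2, nBits = 1024, ids = names(smiles)) {
  if (!is.numeric(radius) || radius != round(radius) || radius < 0 || radius > 5)
    stopf("radius must be an integer in 0..5")
  if (!is.numeric(nBits) || nBits < 1 || nBits != round(nBits))
    stopf("nBits must be a positive integer")
  if (is.null(ids)) ids <- smiles
  can <- canonicalSmiles(smiles, ids)
  fpType <- paste0("ECFP", 2L * radius)
  out <- matrix(0, length(can), nBits, dimnames = list(ids, NULL))
  for (i in seq_along(can)) {
    mols <- ChemmineOB::forEachMol("SMILES", paste0(can[i], "\n"), identity)
    raw <- as.numeric(ChemmineOB::fingerprint_OB(mols, fpType))
    set <- which(raw > 0) - 1L           # 0-based hashed positions
    out[i, unique(set %% nBits) + 1L] <- 1
  }
  out
}

#' Build a DrugSet from a drug table
#'
#' Expects columns \code{drug_id}, \code{smiles}, \code{max_conc}. Drugs with a
#' missing or empty SMILES are dropped with a logged count; an unparsable
#' SMILES is an error naming the drug. SMILES are stored canonicalized and
#' fingerprinted.
#'
#' @param drugTable data.frame with columns \code{drug_id}, \code{smiles},
#'   \code{max_conc}.
#' @param radius,nBits fingerprint parameters, see [morganFingerprint()].
#' @return a [DrugSet-class].
#' @export
drugSetFromTable <- function(drugTable, radius = 2, nBits = 1024) {
  need <- c("drug_id", "smiles", "max_conc")
  miss <- setdiff(need, names(drugTable))
  if (length(miss)) stopf("drug table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(drugTable$drug_id)) stopf("duplicate drug IDs in drug table")
  has <- !is.na(drugTable$smiles) & nzchar(trimws(drugTable$smiles))
  if (any(!has))
    logMsg("drugSetFromTable: dropped %d drug(s) without a SMILES string", sum(!has))
  tab <- drugTable[has, , drop = FALSE]
  if (nrow(tab) == 0L) stopf("no drug with a SMILES string remains")
  can <- canonicalSmiles(tab$smiles, tab$drug_id)
  fp <- morganFingerprint(can, radius = radius, nBits = nBits, ids = tab$drug_id)
  methods::new("DrugSet",
    drugIds = as.character(tab$drug_id), smiles = can,
    maxConc = as.numeric(tab$max_conc), fingerprints = fp)
}

#' Binarize ln IC50 against the maximum screening concentration
#'
#' A (cell line, drug) pair is labelled sensitive (1) iff
#' \code{exp(lnIC50) <= maxConc}; the boundary case is sensitive. Pairs whose
#' IC50 exceeds the highest concentration actually screened are resistant (0).
#'
#' @param lnIC50 numeric vector of natural-log IC50 values. For log10-scale
#'   inputs set \code{scale = "log10"}; values are converted to natural log
#'   before thresholding.
#' @param maxConc positive numeric vector (recycled) of per-drug maximum
#'   screening concentrations, on the same concentration scale as
#'   \code{exp(lnIC50)}.
#' @param scale \code{"ln"} (default) or \code{"log10"}.
#' @return integer vector of 0/1 labels.
#' @export
binarizeResponse <- function(lnIC50, maxConc, scale = c("ln", "log10")) {
  scale <- match.arg(scale)
  if (any(!is.finite(lnIC50))) stopf("lnIC50 contains non-finite values")
  if (any(!is.finite(maxConc)) || any(maxConc <= 0))
    stopf("maxConc must be positive and finite")
  if (scale == "log10") lnIC50 <- lnIC50 * log(10)
  as.integer(exp(lnIC50) <= maxConc)
}
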