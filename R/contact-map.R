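#' @include AllClasses.R
NULL

#' Compute a CA contact map
#'
#' A residue pair (i, j) is in contact iff |i - j| >= \code{minSeparation}
#' and the CA-CA distance is at most \code{cutoff} (inclusive boundary).
#' The defaults (8 Angstrom cutoff, separation 1) reproduce the map
#' parameters under which chirality information is lost: a model and its
#' exact mirror image generate identical contact maps.
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param cutoff distance cutoff in Angstroms.
#' @param minSeparation minimum sequence separation |i - j|.
#' @return a \linkS4class{ContactMap}.
#' @export
computeContactMap <- function(model, cutoff = 8.0, minSeparation = 1L) {
  ca <- caCoords(model)
  if (!all(is.finite(ca))) stop("missing CA coordinates")
  dm <- as.matrix(stats::dist(ca))
  sep <- abs(row(dm) - col(dm))
  contacts <- dm <= cutoff & sep >= minSeparation
  diag(contacts) <- FALSE
  new("ContactMap", contacts = unname(contacts), cutoff = cutoff,
      minSeparation = as.integer(minSeparation))
}

#' Normalized contact-map difference
#'
#' The number of upper-triangle cells where the two maps disagree, divided
#' by the number of upper-triangle contacts in the reference map. Zero iff
#' the maps are identical. The normalization is reference-based, so
#' \code{contactMapDiff(a, b)} and \code{contactMapDiff(b, a)} generally
#' differ.
#'
#' @param modelMap,referenceMap \linkS4class{ContactMap}s with equal size
#'   and parameters.
#' @return numeric(1) >= 0 (fraction; multiply by 100 for percent).
#' @export
contactMapDiff <- function(modelMap, referenceMap) {
  if (nResidues(modelMap) != nResidues(referenceMap))
    stop("contact maps have different sizes")
  if (modelMap@cutoff != referenceMap@cutoff ||
      modelMap@minSeparation != referenceMap@minSeparation)
    stop("contact maps were computed with different parameters")
  up <- upper.tri(referenceMap@contacts)
  disagree <- sum(modelMap@contacts[up] != referenceMap@contacts[up])
  nref <- sum(referenceMap@contacts[up])
  if (nref == 0) {
    if (disagree == 0) return(0)
    warning("reference map has no contacts; diff is infinite")
    return(Inf)
  }
  disagree / nref
}

#' Read/write contact maps as plain text
#'
#' \code{writeContactMap} serializes either a dense 0/1 matrix (one row per
#' line, space-separated) or a sparse pair list (lines "i j", 1-based,
#' i < j). \code{readContactMap} reads either format back; for the sparse
#' format the residue count must be supplied.
#'
#' @param map a \linkS4class{ContactMap}.
#' @param path file path.
#' @param format \code{"matrix"} or \code{"pairs"}.
#' @param n residue count (required when reading \code{"pairs"}).
#' @param cutoff,minSeparation parameters to record on the map read back.
#' @return \code{readContactMap}: a \linkS4class{ContactMap}.
#' @export
writeContactMap <- function(map, path, format = c("matrix", "pairs")) {
  format <- match.arg(format)
  m <- map@contacts
  if (format == "matrix") {
    writeLines(apply(m * 1L, 1, paste, collapse = " "), path)
  } else {
    idx <- which(m & upper.tri(m), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    writeLines(sprintf("%d %d", idx[, 1], idx[, 2]), path)
  }
  invisible(path)
}

#' @rdname writeContactMap
#' @export
readContactMap <- function(path, format = c("matrix", "pairs"), n = NULL,
                           cutoff = 8.0, minSeparation = 1L) {
  format <- match.arg(format)
  if (format == "matrix") {
    rows <- strsplit(trimws(readLines(path)), "\\s+")
    rows <- rows[lengths(rows) > 0]
    m <- do.call(rbind, lapply(rows, as.integer))
    if (nrow(m) != ncol(m)) stop("matrix file is not square")
    contacts <- m == 1L
  } else {
    if (is.null(n)) stop("n is required to read a sparse pair list")
    contacts <- matrix(FALSE, n, n)
    lns <- trimws(readLines(path))
    lns <- lns[nzchar(lns)]
    if (length(lns)) {
      ij <- do.call(rbind, lapply(strsplit(lns, "\\s+"), as.integer))
      if (any(ij[, 1] >= ij[, 2]) || any(ij < 1) || any(ij > n))
        stop("invalid pair list (need 1 <= i < j <= n)")
      contacts[ij] <- TRUE
      contacts[ij[, c(2, 1), drop = FALSE]] <- TRUE
    }
  }
  new("ContactMap", contacts = unname(contacts), cutoff = cutoff,
      minSeparation = as.integer(minSeparation))
}
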