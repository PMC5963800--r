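#' @include AllClasses.R
NULL

#' Accessors for backbone models and ensembles
#'
#' @param x a \linkS4class{BackboneModel}, \linkS4class{DomainEnsemble} or
#'   \linkS4class{ContactMap}.
#' @param atom one of \code{"N"}, \code{"CA"}, \code{"C"}, \code{"O"}.
#' @return \code{nResidues}: integer residue count. \code{modelId},
#'   \code{domainId}: character identifiers. \code{modelSequence}: the
#'   one-letter sequence. \code{atomCoords}: n x 3 coordinate matrix for one
#'   atom type; \code{caCoords} is shorthand for the CA atoms.
#'   \code{models}, \code{referenceModel}, \code{orientationTruth}: ensemble
#'   components. \code{contactMatrix}: the logical contact matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("domainId", function(x) standardGeneric("domainId"))
#' @rdname accessors
#' @export
setGeneric("modelSequence", function(x) standardGeneric("modelSequence"))
#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x, atom = "CA") standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname accessors
#' @export
setGeneric("models", function(x) standardGeneric("models"))
#' @rdname accessors
#' @export
setGeneric("referenceModel", function(x) standardGeneric("referenceModel"))
#' @rdname accessors
#' @export
setGeneric("orientationTruth", function(x) standardGeneric("orientationTruth"))
#' @rdname accessors
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))

#' @rdname accessors
setMethod("nResidues", "BackboneModel", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("modelId", "BackboneModel", function(x) x@modelId)
#' @rdname accessors
setMethod("domainId", "BackboneModel", function(x) x@domainId)
#' @rdname accessors
setMethod("domainId", "DomainEnsemble", function(x) x@domainId)
#' @rdname accessors
setMethod("modelSequence", "BackboneModel", function(x) x@sequence)
#' @rdname accessors
setMethod("atomCoords", "BackboneModel", function(x, atom = "CA") {
  atom <- match.arg(atom, BACKBONE_ATOMS)
  m <- x@coords[, atom, , drop = FALSE]
  dim(m) <- c(dim(x@coords)[1], 3L)
  colnames(m) <- c("x", "y", "z")
  m
})
#' @rdname accessors
setMethod("caCoords", "BackboneModel", function(x) atomCoords(x, "CA"))
#' @rdname accessors
setMethod("models", "DomainEnsemble", function(x) x@models)
#' @rdname accessors
setMethod("referenceModel", "DomainEnsemble", function(x) x@reference)
#' @rdname accessors
setMethod("orientationTruth", "DomainEnsemble", function(x) x@truth)
#' @rdname accessors
setMethod("contactMatrix", "ContactMap", function(x) x@contacts)
#' @rdname accessors
setMethod("nResidues", "ContactMap", function(x) nrow(x@contacts))

setMethod("show", "BackboneModel", function(object) {
  cat(sprintf("BackboneModel '%s' (domain '%s'): %d residues\n",
              object@modelId, object@domainId, nResidues(object)))
  cat(sprintf("  sequence: %s%s\n",
              paste(utils::head(object@sequence, 30), collapse = ""),
              if (nResidues(object) > 30) "..." else ""))
})

setMethod("show", "DomainEnsemble", function(object) {
  cat(sprintf("DomainEnsemble '%s': %d models of %d residues\n",
              object@domainId, length(object@models),
              nResidues(object@reference)))
  if (length(object@truth))
    cat(sprintf("  truth: %d native / %d mirror\n",
                sum(object@truth == "native"),
                sum(object@truth == "mirror")))
  else cat("  truth: unknown\n")
})

setMethod("show", "RamaDensityGrid", function(object) {
  cat(sprintf(
    "RamaDensityGrid: %g-degree bins, classes: %s\n  thresholds: favored >= %g, allowed >= %g\n",
    object@binWidth, paste(names(object@density), collapse = ", "),
    object@favoredThreshold, object@allowedThreshold))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf(
    "ContactMap: %d residues, %d contacts (cutoff %g A, min separation %d)\n",
    nrow(object@contacts), sum(object@contacts[upper.tri(object@contacts)]),
    object@cutoff, object@minSeparation))
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition: rmsd = %.4f A (proper rotation, det = %+.6f)\n",
              object@rmsd, det(object@rotation)))
})

setMethod("show", "EnergyConfig", function(object) {
  cat("EnergyConfig:\n")
  cat(sprintf("  coulomb: C = %g, eps(r) = r, cutoff %g A, min dist %g A\n",
              object@coulombConstant, object@coulombCutoff,
              object@coulombMinDist))
  cat(sprintf("  LJ: cutoff %g A; bonded exclusion < %d bonds\n",
              object@ljCutoff, object@minBondSeparation))
})
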