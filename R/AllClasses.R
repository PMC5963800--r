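#' @import methods
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Backbone protein model
#'
#' Holds one backbone-only structural model: an ordered chain of residues,
#' each carrying the four backbone heavy atoms N, CA, C and O. Residues are
#' indexed sequentially 1..n regardless of author numbering in the source
#' file, because all downstream analysis (dihedrals, contact maps, bonded
#' exclusions) works on sequence separation.
#'
#' @slot modelId character(1) identifier of the model.
#' @slot domainId character(1) identifier of the domain the model belongs to.
#' @slot sequence character vector of one-letter amino-acid codes, one per
#'   residue.
#' @slot coords numeric array of dimension \code{c(n, 4, 3)}; second
#'   dimension named \code{N, CA, C, O}; third dimension x, y, z in
#'   Angstroms.
#'
#' @aliases BackboneModel-class
#' @exportClass BackboneModel
setClass("BackboneModel",
  representation(
    modelId  = "character",
    domainId = "character",
    sequence = "character",
    coords   = "array"
  )
)

setValidity("BackboneModel", function(object) {
  d <- dim(object@coords)
  msgs <- character()
  if (length(d) != 3L || d[2] != 4L || d[3] != 3L)
    msgs <- c(msgs, "coords must be an n x 4 x 3 array")
  else {
    n <- d[1]
    if (n < 3L) msgs <- c(msgs, "a model needs at least 3 residues")
    if (length(object@sequence) != n)
      msgs <- c(msgs, "sequence length must equal residue count")
    if (!identical(dimnames(object@coords)[[2]], BACKBONE_ATOMS))
      msgs <- c(msgs, "atom dimension must be named N, CA, C, O")
    if (!all(is.finite(object@coords)))
      msgs <- c(msgs, "all coordinates must be finite")
  }
  if (length(object@modelId) != 1L || length(object@domainId) != 1L)
    msgs <- c(msgs, "modelId and domainId must be length-1 character")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BackboneModel
#'
#' @param modelId,domainId identifiers.
#' @param sequence character vector of one-letter codes.
#' @param coords n x 4 x 3 numeric array (atoms N, CA, C, O).
#' @return A \linkS4class{BackboneModel}.
#' @export
BackboneModel <- function(modelId, domainId, sequence, coords) {
  dimnames(coords) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"))
  new("BackboneModel", modelId = as.character(modelId),
      domainId = as.character(domainId),
      sequence = as.character(sequence), coords = coords)
}

#' Ensemble of candidate models for one domain
#'
#' The per-domain unit of analysis: a reference backbone plus the set of
#' candidate models, optionally with known ground-truth orientation labels
#' (\code{"native"} or \code{"mirror"}) for each model.
#'
#' @slot domainId character(1).
#' @slot reference a \linkS4class{BackboneModel} (may be absent: a
#'   zero-length list slot is not allowed, use \code{hasReference}).
#' @slot models list of \linkS4class{BackboneModel}.
#' @slot truth character vector of per-model orientation labels, or
#'   length 0 when unknown.
#'
#' @aliases DomainEnsemble-class
#' @exportClass DomainEnsemble
setClass("DomainEnsemble",
  representation(
    domainId  = "character",
    reference = "BackboneModel",
    models    = "list",
    truth     = "character"
  )
)

setValidity("DomainEnsemble", function(object) {
  msgs <- character()
  if (!all(vapply(object@models, is, logical(1), "BackboneModel")))
    msgs <- c(msgs, "models must all be BackboneModel objects")
  else {
    nref <- nResidues(object@reference)
    ns <- vapply(object@models, nResidues, integer(1))
    if (any(ns != nref))
      msgs <- c(msgs, "all models must length-match the reference")
  }
  if (length(object@truth) &&
      (length(object@truth) != length(object@models) ||
       !all(object@truth %in% c("native", "mirror"))))
    msgs <- c(msgs, "truth must label every model 'native' or 'mirror'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DomainEnsemble
#'
#' @param domainId character(1).
#' @param reference reference \linkS4class{BackboneModel}.
#' @param models list of models.
#' @param truth optional character vector of per-model labels.
#' @return A \linkS4class{DomainEnsemble}.
#' @export
DomainEnsemble <- function(domainId, reference, models,
                           truth = character(0)) {
  new("DomainEnsemble", domainId = as.character(domainId),
      reference = reference, models = models,
      truth = as.character(truth))
}

#' Ramachandran occupancy density grid
#'
#' Binned (phi, psi) occupancy densities per residue class. Densities are
#' probability mass per bin: each class matrix sums to 1. The classification
#' thresholds (favored >= 0.02, allowed >= 0.0005, else outlier) act
#' directly on these per-bin masses.
#'
#' @slot binWidth numeric(1), bin width in degrees; the grid is
#'   (360/binWidth) x (360/binWidth), rows = phi bins, cols = psi bins,
#'   bin centers at -180 + binWidth/2, ...
#' @slot density named list of per-class matrices.
#' @slot favoredThreshold,allowedThreshold numeric(1) classification
#'   thresholds on per-bin mass.
#'
#' @aliases RamaDensityGrid-class
#' @exportClass RamaDensityGrid
setClass("RamaDensityGrid",
  representation(
    binWidth         = "numeric",
    density          = "list",
    favoredThreshold = "numeric",
    allowedThreshold = "numeric"
  ),
  prototype(favoredThreshold = 0.02, allowedThreshold = 5e-4)
)

setValidity("RamaDensityGrid", function(object) {
  msgs <- character()
  nb <- 360 / object@binWidth
  if (nb != round(nb)) msgs <- c(msgs, "binWidth must divide 360")
  if (!length(object@density) || is.null(names(object@density)))
    msgs <- c(msgs, "density must be a non-empty named list")
  else for (cl in names(object@density)) {
    m <- object@density[[cl]]
    if (!is.matrix(m) || any(dim(m) != nb))
      msgs <- c(msgs, sprintf("class '%s': matrix must be %d x %d", cl, nb, nb))
    else {
      if (any(m < 0)) msgs <- c(msgs, sprintf("class '%s': negative density", cl))
      if (abs(sum(m) - 1) > 1e-9)
        msgs <- c(msgs, sprintf("class '%s': mass must sum to 1", cl))
    }
  }
  if (!(object@favoredThreshold > object@allowedThreshold &&
        object@allowedThreshold > 0))
    msgs <- c(msgs, "need favoredThreshold > allowedThreshold > 0")
  if (length(msgs)) msgs else TRUE
})

#' Configuration for the simplified energy terms
#'
#' Parameters of the nonbonded and knowledge-based scoring terms. Defaults
#' are generic heavy-atom values (no hydrogens: backbone models carry none):
#' CHARMM-like partial charges summing to ~0 per residue, uniform
#' Lennard-Jones well depth, a distance-dependent dielectric eps(r) = r for
#' the Coulomb term, and a bonded exclusion of pairs fewer than 4 covalent
#' bonds apart.
#'
#' @slot charges,ljRadius,ljEpsilon named numeric, per atom name.
#' @slot coulombConstant numeric(1), kcal*A/(mol*e^2).
#' @slot coulombCutoff,coulombMinDist,ljCutoff numeric(1), Angstroms.
#' @slot minBondSeparation integer(1): pairs closer than this many covalent
#'   bonds are excluded from nonbonded sums.
#' @slot weights named numeric, per-term weights for the total score.
#'
#' @aliases EnergyConfig-class
#' @exportClass EnergyConfig
setClass("EnergyConfig",
  representation(
    charges           = "numeric",
    ljRadius          = "numeric",
    ljEpsilon         = "numeric",
    coulombConstant   = "numeric",
    coulombCutoff     = "numeric",
    coulombMinDist    = "numeric",
    ljCutoff          = "numeric",
    minBondSeparation = "integer",
    weights           = "numeric"
  )
)

setValidity("EnergyConfig", function(object) {
  msgs <- character()
  if (!(object@coulombCutoff > object@coulombMinDist &&
        object@coulombMinDist > 0))
    msgs <- c(msgs, "need coulombCutoff > coulombMinDist > 0")
  if (object@ljCutoff <= 0) msgs <- c(msgs, "ljCutoff must be positive")
  if (!all(is.finite(object@weights)))
    msgs <- c(msgs, "weights must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Default energy configuration
#'
#' @param charges,ljRadius,ljEpsilon named numeric vectors per atom name.
#' @param coulombConstant Coulomb prefactor in kcal*A/(mol*e^2).
#' @param coulombCutoff,coulombMinDist,ljCutoff distances in Angstroms.
#' @param minBondSeparation minimum covalent-bond separation for a pair to
#'   enter the nonbonded sums.
#' @param weights per-term weights used for the total.
#' @return An \linkS4class{EnergyConfig}.
#' @export
energyConfig <- function(charges = c(N = -0.47, CA = 0.07, C = 0.51, O = -0.51),
                         ljRadius = c(N = 1.75, CA = 2.00, C = 2.00, O = 1.55),
                         ljEpsilon = c(N = 0.10, CA = 0.10, C = 0.10, O = 0.10),
                         coulombConstant = 322.0637,
                         coulombCutoff = 5.5, coulombMinDist = 1.45,
                         ljCutoff = 6.0, minBondSeparation = 4L,
                         weights = c(fa_atr = 1, fa_rep = 1, hack_elec = 1,
                                     rama = 1, p_aa_pp = 1)) {
  new("EnergyConfig", charges = charges, ljRadius = ljRadius,
      ljEpsilon = ljEpsilon, coulombConstant = coulombConstant,
      coulombCutoff = coulombCutoff, coulombMinDist = coulombMinDist,
      ljCutoff = ljCutoff, minBondSeparation = as.integer(minBondSeparation),
      weights = weights)
}

#' Residue contact map
#'
#' Symmetric boolean matrix marking residue pairs whose CA atoms lie within
#' a distance cutoff, subject to a minimum sequence separation.
#'
#' @slot contacts logical n x n matrix, symmetric, FALSE diagonal.
#' @slot cutoff numeric(1) distance cutoff in Angstroms.
#' @slot minSeparation integer(1) minimum |i - j| for a contact.
#'
#' @aliases ContactMap-class
#' @exportClass ContactMap
setClass("ContactMap",
  representation(
    contacts      = "matrix",
    cutoff        = "numeric",
    minSeparation = "integer"
  )
)

setValidity("ContactMap", function(object) {
  m <- object@contacts
  msgs <- character()
  if (!is.logical(m) || nrow(m) != ncol(m))
    msgs <- c(msgs, "contacts must be a square logical matrix")
  else {
    if (any(diag(m))) msgs <- c(msgs, "diagonal must be FALSE")
    if (!isSymmetric(unname(m * 1))) msgs <- c(msgs, "matrix must be symmetric")
    sep <- abs(row(m) - col(m))
    if (any(m & sep < object@minSeparation))
      msgs <- c(msgs, "contacts violate the minimum separation")
  }
  if (length(msgs)) msgs else TRUE
})

#' Rigid-body superposition result
#'
#' A proper rotation (determinant +1), a translation and the resulting
#' RMSD. The transform maps mobile coordinates x to R x + t.
#'
#' @slot rotation 3 x 3 proper rotation matrix.
#' @slot translation numeric(3) in Angstroms.
#' @slot rmsd numeric(1) >= 0.
#'
#' @aliases Superposition-class
#' @exportClass Superposition
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric")
)

setValidity("Superposition", function(object) {
  R <- object@rotation
  msgs <- character()
  if (any(dim(R) != 3L)) msgs <- c(msgs, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      msgs <- c(msgs, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-9)
      msgs <- c(msgs, "rotation must be proper (det +1)")
  }
  if (object@rmsd < 0) msgs <- c(msgs, "rmsd must be >= 0")
  if (length(msgs)) msgs else TRUE
})
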