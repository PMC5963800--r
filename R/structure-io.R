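#' @include AllClasses.R
NULL

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Read backbone models from a PDB file
#'
#' Parses ATOM records (via \pkg{bio3d}), retaining only the backbone heavy
#' atoms N, CA, C and O, and returns one \linkS4class{BackboneModel} per
#' MODEL record (or a single model when none are present). Residues are
#' renumbered sequentially from 1. Completeness is enforced the way curation
#' of reconstruction ensembles demands it: a residue missing a backbone
#' atom strictly inside the chain is a validation error, while incomplete
#' terminal residues are trimmed (reduction of the chain). Hetero residues
#' and non-standard amino acids are rejected. The first alternate location
#' encountered is kept.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier to restrict to.
#' @return list of \linkS4class{BackboneModel}.
#' @export
readPDBBackbone <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || !nrow(at)) stop("no ATOM records in ", path)
  keep <- at$type == "ATOM"
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!any(keep)) stop("no ATOM records", if (!is.null(chain))
    paste0(" for chain ", chain) else "", " in ", path)
  het <- keep & !(at$resid %in% STANDARD_AA3)
  if (any(het))
    stop("non-standard or hetero residue '", at$resid[which(het)[1]],
         "' at author position ", at$resno[which(het)[1]])
  keep <- keep & at$elety %in% BACKBONE_ATOMS
  idx <- which(keep)
  at <- at[idx, , drop = FALSE]
  reskey <- paste(at$chain, at$resno, at$insert %||% "")
  # first altloc encountered per residue/atom
  firstalt <- !duplicated(paste(reskey, at$elety))
  at <- at[firstalt, , drop = FALSE]
  idx <- idx[firstalt]
  reskey <- reskey[firstalt]
  resf <- factor(reskey, levels = unique(reskey))
  nres <- nlevels(resf)
  if (nres < 1) stop("no residues in ", path)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nmodels <- nrow(xyz)
  base <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)

  # residue atom presence is model-independent (shared ATOM table)
  bygroups <- split(seq_len(nrow(at)), resf)
  present <- t(vapply(bygroups, function(i)
    BACKBONE_ATOMS %in% at$elety[i], logical(4)))
  complete <- rowSums(present) == 4L
  lo <- 1L; hi <- nres
  while (lo <= hi && !complete[lo]) lo <- lo + 1L
  while (hi >= lo && !complete[hi]) hi <- hi - 1L
  if (hi - lo + 1L < 3L)
    stop("fewer than 3 complete residues after terminal trimming in ", path)
  if (!all(complete[lo:hi])) {
    bad <- lo:hi
    bad <- bad[!complete[bad]][1]
    miss <- BACKBONE_ATOMS[!present[bad, ]][1]
    stop("residue ", bad - lo + 1L, " (author ",
         levels(resf)[bad], ") is missing backbone atom ", miss)
  }
  kept <- lo:hi
  n <- length(kept)
  seq1 <- vapply(bygroups[kept], function(i)
    bio3d::aa321(at$resid[i][1]), character(1))

  lapply(seq_len(nmodels), function(m) {
    co <- array(NA_real_, c(n, 4, 3),
                dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
    xm <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    for (r in seq_len(n)) {
      rows <- bygroups[[kept[r]]]
      for (j in rows)
        co[r, at$elety[j], ] <- xm[idx[j], ]
    }
    if (!all(is.finite(co)))
      stop("non-finite coordinates in model ", m, " of ", path)
    BackboneModel(
      modelId = if (nmodels > 1) sprintf("%s_m%d", base, m) else base,
      domainId = base, sequence = seq1, coords = co)
  })
}

#' Write a backbone model as PDB
#'
#' Writes standard fixed-width ATOM records (atoms N, CA, C, O per residue,
#' chain A, sequential numbering). Coordinates whose magnitude does not fit
#' the PDB 8.3 field (>= 10000 Angstroms) raise an error rather than being
#' truncated silently.
#'
#' @param model a valid \linkS4class{BackboneModel}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePDB <- function(model, path) {
  if (!is(model, "BackboneModel")) stop("model must be a BackboneModel")
  validObject(model)
  if (max(abs(model@coords)) >= 1e4)
    stop("coordinate magnitude exceeds the PDB field width (|x| >= 10000)")
  n <- nResidues(model)
  resid3 <- vapply(model@sequence, bio3d::aa123, character(1))
  xyz <- matrix(aperm(model@coords, c(3, 2, 1)), nrow = 3)  # 3 x (4n)
  tryCatch(
    suppressWarnings(bio3d::write.pdb(
      file = path,
      xyz = as.numeric(xyz),
      elety = rep(BACKBONE_ATOMS, n),
      resid = rep(resid3, each = 4),
      resno = rep(seq_len(n), each = 4),
      chain = rep("A", 4 * n),
      o = rep(1, 4 * n), b = rep(0, 4 * n))),
    error = function(e) stop("cannot write PDB to '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}
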