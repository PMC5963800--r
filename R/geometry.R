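#' @include AllClasses.R
NULL

#' Torsion angle between four points
#'
#' IUPAC sign convention: looking along p2 -> p3, a clockwise rotation of
#' the far bond relative to the near bond is positive. Result in degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric(3) coordinates in Angstroms.
#' @return numeric(1) angle in degrees.
#' @examples
#' dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0))  # cis: 0
#' dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0))  # trans: 180
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("degenerate geometry: coincident consecutive points")
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("degenerate geometry: collinear points")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  wrapAngle(atan2(y, x) * 180 / pi)
}

#' Backbone dihedral series of a model
#'
#' phi(i) from C(i-1), N(i), CA(i), C(i); psi(i) from N(i), CA(i), C(i),
#' N(i+1); omega(i) from CA(i-1), C(i-1), N(i), CA(i). Angles undefined at
#' the respective termini are NA.
#'
#' @param model a \linkS4class{BackboneModel}.
#' @return data.frame with columns \code{residue}, \code{aa}, \code{phi},
#'   \code{psi}, \code{omega} (degrees).
#' @export
backboneDihedrals <- function(model) {
  n <- nResidues(model)
  N <- atomCoords(model, "N"); CA <- atomCoords(model, "CA")
  C <- atomCoords(model, "C")
  phi <- psi <- omg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ok <- function(expr, what) tryCatch(expr, error = function(e)
      stop(sprintf("degenerate geometry at residue %d (%s): %s",
                   i, what, conditionMessage(e))))
    if (i > 1) {
      phi[i] <- ok(dihedralAngle(C[i - 1, ], N[i, ], CA[i, ], C[i, ]), "phi")
      omg[i] <- ok(dihedralAngle(CA[i - 1, ], C[i - 1, ], N[i, ], CA[i, ]),
                   "omega")
    }
    if (i < n)
      psi[i] <- ok(dihedralAngle(N[i, ], CA[i, ], C[i, ], N[i + 1, ]), "psi")
  }
  data.frame(residue = seq_len(n), aa = modelSequence(model),
             phi = phi, psi = psi, omega = omg)
}

#' Mirror reflection of a model
#'
#' Reflects every coordinate through the plane x = 0. Any single mirror
#' plane differs from any other by a proper rotation, which superposition
#' absorbs, so the choice of plane is immaterial.
#'
#' @param model a \linkS4class{BackboneModel}.
#' @return the reflected \linkS4class{BackboneModel}.
#' @export
mirrorReflect <- function(model) {
  co <- model@coords
  co[, , 1] <- -co[, , 1]
  BackboneModel(model@modelId, model@domainId, model@sequence, co)
}

#' Proper-rotation (Kabsch) superposition
#'
#' Least-RMSD rigid superposition of \code{mobile} onto \code{target},
#' restricted to proper rotations: if the optimal orthogonal matrix has
#' determinant -1, the sign of the smallest singular direction is flipped.
#' Because reflections are forbidden, the mirror image of a chiral point
#' set keeps a strictly positive RMSD -- the property that makes RMSD a
#' chirality detector.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3.
#' @return a \linkS4class{Superposition}; the transform maps mobile points
#'   x to \code{rotation \%*\% x + translation}.
#' @export
kabschSuperpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3 || ncol(target) != 3)
    stop("mobile and target must be equal-length n x 3 matrices")
  if (nrow(mobile) < 3) stop("at least 3 points are required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  if (svd(P, nu = 0, nv = 0)$d[2] < 1e-8 ||
      svd(Q, nu = 0, nv = 0)$d[2] < 1e-8)
    stop("degenerate geometry: all points collinear")
  s <- svd(crossprod(P, Q))  # t(P) %*% Q = U D V'
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  new("Superposition", rotation = R, translation = as.numeric(ct - R %*% cm),
      rmsd = rmsd)
}

#' Fraction of positive phi torsions
#'
#' The positive-phi ratio: count(phi > 0) / count(defined phi). Near 0 for
#' natively oriented (right-handed) folds, near 1 for their mirror images.
#'
#' @param x a \linkS4class{BackboneModel} or a data.frame with a
#'   \code{phi} column (as from \code{\link{backboneDihedrals}}).
#' @return numeric(1) in [0, 1].
#' @export
phiPlusRatio <- function(x) {
  if (is(x, "BackboneModel")) x <- backboneDihedrals(x)
  phi <- x$phi[!is.na(x$phi)]
  if (!length(phi)) stop("no defined phi angles")
  mean(phi > 0)
}

#' Assign native/mirror orientation by double superposition
#'
#' Superposes the model's CA trace onto the reference and onto the
#' reference's mirror image; the lower RMSD decides the orientation label.
#' Ties (achievable only for achiral traces) are labeled native with a
#' warning.
#'
#' @param model,reference \linkS4class{BackboneModel}s with equal residue
#'   counts.
#' @param atoms \code{"CA"} (default) superposes CA atoms only;
#'   \code{"backbone"} uses all four backbone atoms.
#' @return list with \code{label} (\code{"native"} or \code{"mirror"}),
#'   \code{rmsdToReference} and \code{rmsdToMirrorReference}.
#' @export
assignOrientation <- function(model, reference, atoms = c("CA", "backbone")) {
  atoms <- match.arg(atoms)
  if (nResidues(model) != nResidues(reference))
    stop("model and reference must have equal residue counts")
  getco <- function(m) {
    if (atoms == "CA") caCoords(m)
    else do.call(rbind, lapply(BACKBONE_ATOMS, function(a) atomCoords(m, a)))
  }
  mo <- getco(model)
  r1 <- kabschSuperpose(mo, getco(reference))@rmsd
  r2 <- kabschSuperpose(mo, getco(mirrorReflect(reference)))@rmsd
  if (r1 == r2) {
    warning("RMSD tie between reference and its mirror; labeling native")
    label <- "native"
  } else label <- if (r1 < r2) "native" else "mirror"
  list(label = label, rmsdToReference = r1, rmsdToMirrorReference = r2)
}
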