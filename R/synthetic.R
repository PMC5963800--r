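#' @include AllClasses.R geometry.R utils.R
NULL

# Ideal backbone internal coordinates (Angstroms / degrees).
BOND_N_CA <- 1.458; BOND_CA_C <- 1.525; BOND_C_N <- 1.329; BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2; ANGLE_CA_C_N <- 116.2; ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8

# Canonical torsions per secondary-structure code.
SS_TORSIONS <- list(H = c(phi = -57, psi = -47),
                    E = c(phi = -139, psi = 135))

# Fixed table of allowed coil torsions; loops draw uniformly from it so
# generated coils stay in populated Ramachandran regions.
COIL_TORSIONS <- matrix(c(
   -60, -40,  -70, -45,  -60, -30, -120, 120,
  -130, 135, -100, 130, -110, 140, -140, 130,
   -75, 150,  -70, 140,  -80, 150,  -65, 145),
  ncol = 2, byrow = TRUE, dimnames = list(NULL, c("phi", "psi")))

# Place atom D given positions A, B, C, the C-D bond length, the B-C-D
# bond angle and the A-B-C-D torsion (degrees). Standard internal-to-
# Cartesian (NeRF) construction.
placeAtom <- function(a, b, c_, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- c_ - b; bc <- bc / vnorm(bc)
  n <- cross3(b - a, bc); n <- n / vnorm(n)
  m <- cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  c_ + cbind(bc, m, n) %*% d2
}

#' Build an idealized backbone from a secondary-structure string
#'
#' Constructs a chain by sequential placement from ideal internal
#' coordinates (bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329 A; angles
#' N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees; omega = 180). Torsions
#' per code: \code{H} (alpha helix) phi/psi = -57/-47, \code{E} (extended
#' strand) -139/135, \code{L} drawn per-residue from a fixed table of
#' allowed coil values using the seed. The carbonyl O is placed in the
#' peptide plane opposite the next residue's N.
#'
#' @param ss secondary-structure string over \{H, E, L\}.
#' @param sequence optional one-letter sequence (default poly-alanine).
#' @param seed integer seed (used only for L torsion draws).
#' @param modelId,domainId identifiers for the resulting model.
#' @return a \linkS4class{BackboneModel}.
#' @export
buildBackbone <- function(ss, sequence = NULL, seed = 1L,
                          modelId = "ref", domainId = "synthetic") {
  codes <- strsplit(ss, "")[[1]]
  n <- length(codes)
  if (n < 3) stop("need at least 3 residues")
  if (!all(codes %in% c("H", "E", "L")))
    stop("invalid secondary-structure code: ",
         setdiff(codes, c("H", "E", "L"))[1])
  if (is.null(sequence)) sequence <- rep("A", n)
  if (is.character(sequence) && length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  if (length(sequence) != n)
    stop("sequence length must match the secondary-structure string")
  tors <- withSeed(seed, t(vapply(codes, function(cd) {
    if (cd == "L") COIL_TORSIONS[sample.int(nrow(COIL_TORSIONS), 1), ]
    else SS_TORSIONS[[cd]]
  }, numeric(2))))
  colnames(tors) <- c("phi", "psi")

  co <- array(NA_real_, c(n, 4, 3),
              dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
  co[1, "N", ] <- c(0, 0, 0)
  co[1, "CA", ] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  co[1, "C", ] <- co[1, "CA", ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      co[i + 1, "N", ] <- placeAtom(co[i, "N", ], co[i, "CA", ], co[i, "C", ],
                                    BOND_C_N, ANGLE_CA_C_N, tors[i, "psi"])
      co[i + 1, "CA", ] <- placeAtom(co[i, "CA", ], co[i, "C", ],
                                     co[i + 1, "N", ],
                                     BOND_N_CA, ANGLE_C_N_CA, 180)
      co[i + 1, "C", ] <- placeAtom(co[i, "C", ], co[i + 1, "N", ],
                                    co[i + 1, "CA", ],
                                    BOND_CA_C, ANGLE_N_CA_C,
                                    tors[i + 1, "phi"])
    }
    # carbonyl O opposite the next N in the peptide plane
    co[i, "O", ] <- placeAtom(co[i, "N", ], co[i, "CA", ], co[i, "C", ],
                              BOND_C_O, ANGLE_CA_C_O,
                              wrapAngle(tors[i, "psi"] - 180))
  }
  BackboneModel(modelId, domainId, sequence, co)
}

#' Add Gaussian coordinate noise to a model
#'
#' Adds iid Gaussian displacement (sd = \code{noiseSd} per coordinate) to
#' every atom; deterministic per seed. This is the difficulty knob of the
#' synthetic benchmark: small noise gives well-separated native/mirror
#' RMSD distributions, large noise makes them overlap.
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param noiseSd noise standard deviation in Angstroms (>= 0).
#' @param seed integer seed.
#' @return the perturbed \linkS4class{BackboneModel}.
#' @export
perturbModel <- function(model, noiseSd, seed = 1L) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  co <- model@coords
  if (noiseSd > 0)
    co <- co + withSeed(seed, array(stats::rnorm(length(co), 0, noiseSd),
                                    dim(co)))
  BackboneModel(model@modelId, model@domainId, model@sequence, co)
}

#' Generate a synthetic domain ensemble
#'
#' Emulates a reconstruction ensemble: a reference backbone built from the
#' secondary-structure string, and \code{nModels} candidate models each of
#' which is, with probability \code{mirrorFraction}, the mirror reflection
#' of the reference, then perturbed with Gaussian coordinate noise. Noise
#' is applied after reflection, so mirror models are not exact reflections
#' of any native model -- as in real reconstruction ensembles, where
#' distance-dependent energy terms can therefore carry signal. The true
#' orientation of every model is recorded.
#'
#' @param ss secondary-structure string.
#' @param sequence optional one-letter sequence (default poly-alanine).
#' @param nModels number of models.
#' @param mirrorFraction probability a model is generated mirrored.
#' @param noiseSd coordinate noise sd in Angstroms.
#' @param seed integer master seed.
#' @param domainId domain identifier.
#' @return a \linkS4class{DomainEnsemble} with truth labels.
#' @export
makeEnsemble <- function(ss, sequence = NULL, nModels = 100,
                         mirrorFraction = 0.5, noiseSd = 0.5, seed = 1L,
                         domainId = "synthetic") {
  stopifnot(nModels >= 1, mirrorFraction >= 0, mirrorFraction <= 1,
            noiseSd >= 0)
  ref <- buildBackbone(ss, sequence, seed = deriveSeed(seed, 0),
                       modelId = paste0(domainId, "_ref"),
                       domainId = domainId)
  refM <- mirrorReflect(ref)
  out <- withSeed(deriveSeed(seed, 1), {
    flips <- stats::runif(nModels) < mirrorFraction
    mods <- vector("list", nModels)
    for (i in seq_len(nModels)) {
      base <- if (flips[i]) refM else ref
      co <- base@coords +
        array(stats::rnorm(length(base@coords), 0, noiseSd),
              dim(base@coords))
      mods[[i]] <- BackboneModel(sprintf("%s_m%03d", domainId, i),
                                 domainId, base@sequence, co)
    }
    list(mods = mods, flips = flips)
  })
  DomainEnsemble(domainId, ref, out$mods,
                 truth = ifelse(out$flips, "mirror", "native"))
}

#' Simulate energy-term feature vectors for clustering tests
#'
#' Draws native rows from N(0, sigma^2 I) and mirror rows from
#' N(delta, sigma^2 I), isolating the clustering stage from the scoring
#' stage: the separation delta/sigma controls the attainable accuracy
#' (Bayes rate Phi(|delta| / (2 sigma)) per dimension).
#'
#' @param nNative,nMirror group sizes (>= 1).
#' @param delta numeric vector of per-term mean shifts (names become
#'   feature names).
#' @param sigma common standard deviation (> 0).
#' @param seed integer seed.
#' @return list with \code{features} (matrix) and \code{truth}
#'   (character vector).
#' @export
simulateEtFeatures <- function(nNative, nMirror, delta, sigma = 1, seed = 1L) {
  stopifnot(nNative >= 1, nMirror >= 1, sigma > 0)
  d <- length(delta)
  if (is.null(names(delta))) names(delta) <- paste0("et", seq_len(d))
  x <- withSeed(seed, {
    xn <- matrix(stats::rnorm(nNative * d, 0, sigma), nNative, d)
    xm <- matrix(stats::rnorm(nMirror * d, 0, sigma), nMirror, d)
    rbind(xn, sweep(xm, 2, delta, "+"))
  })
  colnames(x) <- names(delta)
  list(features = x,
       truth = c(rep("native", nNative), rep("mirror", nMirror)))
}

#' Seeded multi-domain synthetic benchmark
#'
#' A corpus of synthetic domain ensembles cycling through helix-rich,
#' sheet-rich and mixed secondary-structure layouts (grouped accordingly),
#' each with \code{nModels} models at roughly 50 percent mirror fraction.
#' Deterministic given the master seed; used by the worked examples and
#' the end-to-end evaluation.
#'
#' @param nDomains number of domains.
#' @param nModels models per domain.
#' @param noiseSd coordinate noise sd in Angstroms.
#' @param length0 approximate domain length in residues.
#' @param seed master seed.
#' @return list with \code{ensembles} (list of
#'   \linkS4class{DomainEnsemble}) and \code{grouping} (named character
#'   vector domainId -> group).
#' @export
makeDemoBenchmark <- function(nDomains = 20, nModels = 100, noiseSd = 0.5,
                              length0 = 40, seed = 1L) {
  layouts <- c(
    `helix-rich` = paste0("LL", strrep("H", length0 - 4), "LL"),
    `sheet-rich` = paste0("L", strrep("E", (length0 - 4) %/% 2), "LL",
                          strrep("E", length0 - 4 - (length0 - 4) %/% 2),
                          "L"),
    mixed = paste0("L", strrep("H", (length0 - 4) %/% 2), "LL",
                   strrep("E", length0 - 4 - (length0 - 4) %/% 2), "L"))
  ensembles <- vector("list", nDomains)
  grouping <- character(nDomains)
  ids <- sprintf("dom%02d", seq_len(nDomains))
  for (k in seq_len(nDomains)) {
    g <- names(layouts)[(k - 1) %% length(layouts) + 1]
    ensembles[[k]] <- makeEnsemble(layouts[[g]], nModels = nModels,
                                   mirrorFraction = 0.5, noiseSd = noiseSd,
                                   seed = deriveSeed(seed, 100 + k),
                                   domainId = ids[k])
    grouping[k] <- g
  }
  names(grouping) <- ids
  list(ensembles = ensembles, grouping = grouping)
}
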