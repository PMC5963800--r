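#' @include AllClasses.R ramachandran.R
NULL

ENERGY_TERMS <- c("fa_atr", "fa_rep", "hack_elec", "rama", "p_aa_pp")

# Flat atom table for a model: residue index, atom name, coordinates,
# and the backbone-graph position used for closed-form bond separation.
# Chain atoms N, CA, C sit at consecutive integer positions
# 3(i-1), 3(i-1)+1, 3(i-1)+2; O hangs one bond off its C.
atomTable <- function(model) {
  n <- nResidues(model)
  res <- rep(seq_len(n), each = 4)
  atom <- rep(BACKBONE_ATOMS, n)
  co <- matrix(aperm(model@coords, c(2, 1, 3)), ncol = 3)  # (4n) x 3
  t0 <- 3 * (res - 1) + match(atom, c("N", "CA", "C"), nomatch = 0L) - 1L
  isO <- atom == "O"
  t0[isO] <- 3 * (res[isO] - 1) + 2L  # O attaches to C
  data.frame(res = res, atom = atom, t = t0, isO = isO,
             x = co[, 1], y = co[, 2], z = co[, 3])
}

#' Covalent bond separation between two backbone atoms
#'
#' Number of covalent bonds on the shortest path through the backbone graph
#' N(i)-CA(i)-C(i)-N(i+1), with O bonded to its C. Used to exclude bonded
#' (1-2, 1-3, 1-4) pairs from the nonbonded energy sums.
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param resA,resB residue indices (1-based).
#' @param atomA,atomB atom names in N, CA, C, O.
#' @return integer bond count >= 0.
#' @export
bondSeparation <- function(model, resA, atomA, resB, atomB) {
  n <- nResidues(model)
  chk <- function(r, a) {
    if (r < 1 || r > n || !(a %in% BACKBONE_ATOMS))
      stop("atom ", a, " of residue ", r, " is not in the model")
  }
  chk(resA, atomA); chk(resB, atomB)
  tpos <- function(r, a) {
    if (a == "O") list(t = 3 * (r - 1) + 2, o = 1L)
    else list(t = 3 * (r - 1) + match(a, c("N", "CA", "C")) - 1, o = 0L)
  }
  a <- tpos(resA, atomA); b <- tpos(resB, atomB)
  if (resA == resB && atomA == atomB) return(0L)
  as.integer(abs(a$t - b$t) + a$o + b$o)
}

# Pairwise matrices shared by the nonbonded terms: distances and bond
# separations between all 4n atoms.
pairGeometry <- function(model) {
  at <- atomTable(model)
  dm <- as.matrix(stats::dist(at[, c("x", "y", "z")]))
  sep <- abs(outer(at$t, at$t, "-")) + outer(at$isO, at$isO, "+")
  list(at = at, dist = dm, sep = sep)
}

#' Coulomb electrostatic energy (hack_elec analog)
#'
#' Screened Coulomb sum over nonbonded atom pairs with a
#' distance-dependent dielectric eps(r) = r, so each pair contributes
#' C q_i q_j / r^2, with r clamped below at \code{coulombMinDist}. Each
#' pair term is shifted by its value at \code{coulombCutoff} so the
#' potential goes continuously to zero there; pairs beyond the cutoff or
#' closer than \code{minBondSeparation} covalent bonds are excluded.
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param config an \linkS4class{EnergyConfig}.
#' @return numeric(1) energy (score units).
#' @export
coulombEnergy <- function(model, config = energyConfig()) {
  pg <- pairGeometry(model)
  q <- config@charges[pg$at$atom]
  if (any(is.na(q)))
    stop("no partial charge configured for atom ",
         pg$at$atom[which(is.na(q))[1]])
  elig <- pg$sep >= config@minBondSeparation & pg$dist <= config@coulombCutoff
  elig[lower.tri(elig, diag = TRUE)] <- FALSE
  if (!any(elig)) return(0)
  r <- pmax(pg$dist[elig], config@coulombMinDist)
  qq <- outer(q, q)[elig]
  C <- config@coulombConstant
  sum(C * qq / r^2 - C * qq / config@coulombCutoff^2)
}

#' Split Lennard-Jones energies (fa_atr / fa_rep analogs)
#'
#' 12-6 potential with pair parameters r_min = r_i + r_j and
#' eps_pair = sqrt(eps_i eps_j), split at its minimum: for r >= r_min a
#' pair contributes LJ(r) to the attractive component and nothing to the
#' repulsive one; for r < r_min it contributes -eps_pair to the attractive
#' component and LJ(r) + eps_pair to the repulsive one, so both components
#' are continuous and fa_rep >= 0, fa_atr <= 0 always hold. The same
#' bonded exclusion applies; pairs beyond \code{ljCutoff} are ignored.
#'
#' @inheritParams coulombEnergy
#' @return list with \code{fa_atr} (<= 0) and \code{fa_rep} (>= 0).
#' @export
ljEnergies <- function(model, config = energyConfig()) {
  pg <- pairGeometry(model)
  rad <- config@ljRadius[pg$at$atom]
  eps <- config@ljEpsilon[pg$at$atom]
  if (any(is.na(rad)) || any(is.na(eps)))
    stop("missing LJ radius or epsilon for atom ",
         pg$at$atom[which(is.na(rad) | is.na(eps))[1]])
  elig <- pg$sep >= config@minBondSeparation & pg$dist <= config@ljCutoff
  elig[lower.tri(elig, diag = TRUE)] <- FALSE
  if (!any(elig)) return(list(fa_atr = 0, fa_rep = 0))
  r <- pg$dist[elig]
  rmin <- outer(rad, rad, "+")[elig]
  ep <- sqrt(outer(eps, eps))[elig]
  s6 <- (rmin / r)^6
  lj <- ep * (s6^2 - 2 * s6)
  below <- r < rmin
  atr <- sum(ifelse(below, -ep, lj))
  rep_ <- sum(ifelse(below, lj + ep, 0))
  list(fa_atr = atr, fa_rep = rep_)
}

#' Ramachandran preference energy (rama analog)
#'
#' Sum over scored residues (phi and psi both defined) of
#' -ln(p + floor), where p is the class-specific per-bin occupancy mass at
#' the residue's (phi, psi) and the floor avoids -ln 0 for empty bins.
#' Lower values mean torsions in better-populated regions; mirror-image
#' folds, whose torsions land in sparsely populated sign-flipped regions,
#' score higher.
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param grid a \linkS4class{RamaDensityGrid}.
#' @param floor additive floor inside the logarithm.
#' @return numeric(1) energy.
#' @export
ramaEnergy <- function(model, grid, floor = 1e-6) {
  dh <- backboneDihedrals(model)
  sc <- !is.na(dh$phi) & !is.na(dh$psi)
  if (!any(sc)) stop("no residues with both phi and psi defined")
  cls <- residueRamaClass(modelSequence(model))[sc]
  p <- lookupDensity(grid, cls, dh$phi[sc], dh$psi[sc])
  sum(-log(p + floor))
}

#' Default amino-acid-to-class mapping for the conditional torsion term
#'
#' Maps each of the 20 standard amino acids to the Ramachandran class whose
#' density models its torsion preferences: G to glycine, P to proline, all
#' others to general.
#'
#' @return named character vector (one-letter code to class name).
#' @export
aaClassMapping <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  cls <- rep("general", length(aa))
  cls[aa == "G"] <- "glycine"
  cls[aa == "P"] <- "proline"
  stats::setNames(cls, aa)
}

#' Amino-acid-conditional torsion probability energy (p_aa_pp analog)
#'
#' Sum over scored residues of -ln(P(aa | phi, psi) + floor), with
#' P(aa | phi, psi) = w_aa p_aa(phi, psi) / sum_b w_b p_b(phi, psi), where
#' p_aa is the density of the class mapped to amino acid aa and w are
#' amino-acid priors (uniform by default). The sum in the denominator runs
#' over every amino acid in the mapping.
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param grid a \linkS4class{RamaDensityGrid} supplying the per-class
#'   densities.
#' @param mapping named character vector amino acid -> grid class.
#' @param priors optional named numeric amino-acid priors (uniform if NULL).
#' @param floor additive floor inside the logarithm.
#' @return numeric(1) energy.
#' @export
pAaPpEnergy <- function(model, grid, mapping = aaClassMapping(),
                        priors = NULL, floor = 1e-6) {
  dh <- backboneDihedrals(model)
  sc <- which(!is.na(dh$phi) & !is.na(dh$psi))
  if (!length(sc)) stop("no residues with both phi and psi defined")
  aa <- modelSequence(model)[sc]
  if (!all(aa %in% names(mapping)))
    stop("amino acid '", setdiff(aa, names(mapping))[1],
         "' is absent from the grid family mapping")
  if (is.null(priors))
    priors <- stats::setNames(rep(1 / length(mapping), length(mapping)),
                              names(mapping))
  if (!all(names(mapping) %in% names(priors)))
    stop("priors must cover every amino acid in the mapping")
  # per-residue density under each family member's class
  densByAa <- vapply(names(mapping), function(b)
    priors[[b]] * lookupDensity(grid, mapping[[b]], dh$phi[sc], dh$psi[sc]),
    numeric(length(sc)))
  densByAa <- matrix(densByAa, nrow = length(sc),
                     dimnames = list(NULL, names(mapping)))
  denom <- rowSums(densByAa)
  pcond <- densByAa[cbind(seq_along(sc), match(aa, names(mapping)))] / denom
  pcond[denom == 0] <- 0
  sum(-log(pcond + floor))
}

#' Energy profile of a model
#'
#' Computes the enabled energy terms and their weighted total for one
#' model. The default term set is the implemented five-term subset; the
#' total is the weighted sum of the enabled terms (weights from the
#' config, default 1 each).
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param config an \linkS4class{EnergyConfig}.
#' @param grid a \linkS4class{RamaDensityGrid}.
#' @param terms character vector of term names to compute (subset of
#'   \code{fa_atr, fa_rep, hack_elec, rama, p_aa_pp}).
#' @param mapping,priors passed to \code{\link{pAaPpEnergy}}.
#' @return one-row data.frame: model_id, domain_id, one column per term,
#'   total.
#' @export
energyProfile <- function(model, config = energyConfig(),
                          grid = buildSurrogateGrid(),
                          terms = ENERGY_TERMS,
                          mapping = aaClassMapping(), priors = NULL) {
  terms <- match.arg(terms, ENERGY_TERMS, several.ok = TRUE)
  vals <- numeric(0)
  if (any(c("fa_atr", "fa_rep") %in% terms)) {
    lj <- ljEnergies(model, config)
    if ("fa_atr" %in% terms) vals["fa_atr"] <- lj$fa_atr
    if ("fa_rep" %in% terms) vals["fa_rep"] <- lj$fa_rep
  }
  if ("hack_elec" %in% terms)
    vals["hack_elec"] <- coulombEnergy(model, config)
  if ("rama" %in% terms) vals["rama"] <- ramaEnergy(model, grid)
  if ("p_aa_pp" %in% terms)
    vals["p_aa_pp"] <- pAaPpEnergy(model, grid, mapping, priors)
  w <- config@weights[names(vals)]
  w[is.na(w)] <- 1
  out <- data.frame(model_id = modelId(model), domain_id = domainId(model))
  for (t in names(vals)) out[[t]] <- vals[[t]]
  out$total <- sum(w * vals)
  out
}

#' Energy profiles for a whole ensemble
#'
#' @param x a \linkS4class{DomainEnsemble} or a list of
#'   \linkS4class{BackboneModel}s.
#' @inheritParams energyProfile
#' @return data.frame, one row per model (energy-profile table schema:
#'   model_id, domain_id, term columns, total).
#' @export
energyProfiles <- function(x, config = energyConfig(),
                           grid = buildSurrogateGrid(),
                           terms = ENERGY_TERMS,
                           mapping = aaClassMapping(), priors = NULL) {
  mods <- if (is(x, "DomainEnsemble")) models(x) else x
  do.call(rbind, lapply(mods, energyProfile, config = config, grid = grid,
                        terms = terms, mapping = mapping, priors = priors))
}

#' Read/write energy-profile tables as TSV
#'
#' The TSV schema (model_id, domain_id, one column per term, total) is also
#' the import path for externally computed energy terms: a table produced
#' by a full-featured scoring package can be read here and fed directly to
#' the statistics and clustering stages.
#'
#' @param profiles data.frame as returned by \code{\link{energyProfiles}}.
#' @param path file path.
#' @return \code{readEnergyProfiles}: the data.frame.
#' @export
writeEnergyProfiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnergyProfiles
#' @export
readEnergyProfiles <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("model_id", "domain_id") %in% names(df)))
    stop("energy-profile table must have model_id and domain_id columns")
  df
}
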