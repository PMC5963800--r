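#' @include AllClasses.R
NULL

#' Build the surrogate Ramachandran density grid
#'
#' A deterministic stand-in for an empirical occupancy grid, built as a
#' wrapped bivariate Gaussian mixture per residue class and discretized to
#' the grid (probability mass per bin, summing to 1 per class). The
#' general class carries a right-handed-helix mode at (-63, -43) with
#' weight 0.50, a sheet mode at (-120, 130) with weight 0.40, a left-handed
#' helix mode at (57, 47) with weight 0.05 and a polyproline-II mode at
#' (-75, 150) with weight 0.05, all with a common 15-degree sd. The glycine
#' class adds a mirror-symmetric copy of every mode (so its density obeys
#' p(phi, psi) = p(-phi, -psi)); proline is restricted around phi = -63;
#' pre-proline is the general mixture with an extra (-130, 75) mode.
#'
#' With the default 10-degree bins, an ideal right-handed helix residue
#' falls in a favored bin (mass about 0.03 >= 0.02) while its mirror falls
#' in an allowed bin and mirrored sheet falls among outliers, so the
#' favored/allowed/outlier thresholds act on this surrogate the way they
#' act on empirical occupancy grids.
#'
#' @param binWidth bin width in degrees (must divide 360).
#' @param modeSd common mode standard deviation in degrees.
#' @param components optional named list of per-class data.frames with
#'   columns \code{phi}, \code{psi}, \code{w} overriding the defaults.
#'   Weights not summing to 1 are renormalized with a warning.
#' @param favoredThreshold,allowedThreshold classification thresholds.
#' @return a \linkS4class{RamaDensityGrid}.
#' @export
buildSurrogateGrid <- function(binWidth = 10, modeSd = 15,
                               components = NULL,
                               favoredThreshold = 0.02,
                               allowedThreshold = 5e-4) {
  general <- data.frame(
    phi = c(-63, -120, 57, -75), psi = c(-43, 130, 47, 150),
    w = c(0.50, 0.40, 0.05, 0.05))
  if (is.null(components)) {
    glycine <- rbind(general, transform(general, phi = -phi, psi = -psi))
    glycine$w <- glycine$w / 2
    proline <- data.frame(phi = c(-63, -63), psi = c(-35, 145),
                          w = c(0.5, 0.5))
    preproline <- rbind(transform(general, w = w * 0.9),
                        data.frame(phi = -130, psi = 75, w = 0.1))
    components <- list(general = general, glycine = glycine,
                       proline = proline, `pre-proline` = preproline)
  }
  dens <- lapply(components, function(modes) {
    if (any(modes$w <= 0)) stop("mixture weights must be positive")
    if (abs(sum(modes$w) - 1) > 1e-6) {
      warning("mixture weights do not sum to 1; renormalizing")
    }
    modes$w <- modes$w / sum(modes$w)
    centers <- binCenters(binWidth)
    m <- matrix(0, length(centers), length(centers))
    for (k in seq_len(nrow(modes))) {
      dphi <- wrappedDnorm(centers, modes$phi[k], modeSd)
      dpsi <- wrappedDnorm(centers, modes$psi[k], modeSd)
      m <- m + modes$w[k] * outer(dphi, dpsi)
    }
    m / sum(m)
  })
  new("RamaDensityGrid", binWidth = binWidth, density = dens,
      favoredThreshold = favoredThreshold,
      allowedThreshold = allowedThreshold)
}

binCenters <- function(binWidth) seq(-180 + binWidth / 2, 180 - binWidth / 2,
                                     by = binWidth)

# Gaussian density on the circle (degrees), wrapped over +/- one turn;
# ample for sd << 360.
wrappedDnorm <- function(x, mu, sd) {
  stats::dnorm(x, mu, sd) + stats::dnorm(x, mu - 360, sd) +
    stats::dnorm(x, mu + 360, sd)
}

#' Load a Ramachandran density grid from a tabular file
#'
#' Expects a header \code{class,phi,psi,density} (comma- or tab-separated),
#' angles at bin centers in degrees. Bins absent from the file are filled
#' with zero and each class is renormalized to unit mass, so sparse files
#' covering only the populated regions are valid input. An empirical grid
#' (e.g. one derived from a curated reference set of structures) supplied
#' this way replaces the surrogate everywhere.
#'
#' @param path file path.
#' @return a \linkS4class{RamaDensityGrid}.
#' @export
loadDensityGrid <- function(path) {
  if (!file.exists(path)) stop("cannot read density grid: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed density-grid file: ",
                             conditionMessage(e)))
  need <- c("class", "phi", "psi", "density")
  if (!all(need %in% names(df)))
    stop("density-grid file must have columns class, phi, psi, density")
  bad <- which(!is.finite(df$phi) | !is.finite(df$psi) |
                 !is.finite(df$density))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  if (any(df$density < 0)) {
    i <- which(df$density < 0)[1]
    stop("negative density at line ", i + 1L, " of ", path)
  }
  centers <- sort(unique(c(df$phi, df$psi)))
  binWidth <- 360 / length(binGuess(centers))
  nb <- 360 / binWidth
  dens <- list()
  for (cl in unique(df$class)) {
    sub <- df[df$class == cl, , drop = FALSE]
    key <- paste(sub$phi, sub$psi)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop("duplicate bin (", d, ") for class '", cl, "'")
    }
    m <- matrix(0, nb, nb)
    i <- binIndex(sub$phi, binWidth)
    j <- binIndex(sub$psi, binWidth)
    m[cbind(i, j)] <- sub$density
    if (sum(m) <= 0) stop("class '", cl, "' has zero total density")
    dens[[cl]] <- m / sum(m)
  }
  new("RamaDensityGrid", binWidth = binWidth, density = dens)
}

# Infer the bin lattice from observed bin centers: the smallest positive
# spacing is the bin width.
binGuess <- function(centers) {
  if (length(centers) < 2) stop("cannot infer bin width from a single bin")
  bw <- min(diff(centers))
  if (360 / bw != round(360 / bw))
    stop("bin centers are not on a lattice dividing 360 degrees")
  seq_len(360 / bw)
}

# Nearest-bin index with wrapping at +/- 180 degrees.
binIndex <- function(angle, binWidth) {
  i <- floor((wrapAngle(angle) + 180) / binWidth) + 1L
  n <- as.integer(360 / binWidth)
  ((as.integer(i) - 1L) %% n) + 1L
}

#' Look up per-bin occupancy mass
#'
#' Nearest-bin lookup (no interpolation), wrapping at +/-180 degrees.
#'
#' @param grid a \linkS4class{RamaDensityGrid}.
#' @param class residue class name; a class absent from the grid falls back
#'   to \code{"general"} when present (single-class grids are allowed).
#' @param phi,psi angles in degrees (vectorized).
#' @return numeric vector of per-bin masses.
#' @export
lookupDensity <- function(grid, class, phi, psi) {
  if (length(class) == 1) class <- rep(class, length(phi))
  cls <- ifelse(class %in% names(grid@density), class,
                if ("general" %in% names(grid@density)) "general"
                else names(grid@density)[1])
  i <- binIndex(phi, grid@binWidth)
  j <- binIndex(psi, grid@binWidth)
  vapply(seq_along(phi), function(k) grid@density[[cls[k]]][i[k], j[k]],
         numeric(1))
}

#' Classify occupancy values into Ramachandran regions
#'
#' favored if p >= 0.02; allowed if 0.0005 <= p < 0.02; outlier if
#' p < 0.0005 (both thresholds inclusive on the favorable side, and
#' configurable through the grid).
#'
#' @param p non-negative occupancy value(s).
#' @param favoredThreshold,allowedThreshold thresholds on per-bin mass.
#' @return character vector in \{"favored", "allowed", "outlier"\}.
#' @export
classifyResidue <- function(p, favoredThreshold = 0.02,
                            allowedThreshold = 5e-4) {
  if (any(p < 0)) stop("occupancy values must be non-negative")
  ifelse(p >= favoredThreshold, "favored",
         ifelse(p >= allowedThreshold, "allowed", "outlier"))
}

#' Residue class for Ramachandran lookup
#'
#' Glycine and proline get their own classes, a residue immediately
#' preceding a proline is "pre-proline", everything else is "general"
#' (the four-class convention of empirical Ramachandran reference grids).
#'
#' @param sequence character vector of one-letter codes.
#' @return character vector of class names.
#' @export
residueRamaClass <- function(sequence) {
  n <- length(sequence)
  cls <- rep("general", n)
  pre <- c(sequence[-1] == "P", FALSE)
  cls[pre] <- "pre-proline"
  cls[sequence == "G"] <- "glycine"
  cls[sequence == "P"] <- "proline"
  cls
}

#' Ramachandran region occupancy of a model
#'
#' Scores every residue with both phi and psi defined: looks up its
#' class-specific per-bin occupancy mass and classifies it as favored,
#' allowed or outlier. Returns the fractions over scored residues (which
#' partition: they sum to 1).
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param grid a \linkS4class{RamaDensityGrid}.
#' @return list with \code{favored}, \code{allowed}, \code{outlier}
#'   fractions, \code{nScored}, and per-residue \code{detail} data.frame.
#' @export
regionOccupancy <- function(model, grid) {
  dh <- backboneDihedrals(model)
  sc <- !is.na(dh$phi) & !is.na(dh$psi)
  if (!any(sc)) stop("no residues with both phi and psi defined")
  cls <- residueRamaClass(modelSequence(model))[sc]
  p <- lookupDensity(grid, cls, dh$phi[sc], dh$psi[sc])
  region <- classifyResidue(p, grid@favoredThreshold, grid@allowedThreshold)
  n <- sum(sc)
  list(favored = sum(region == "favored") / n,
       allowed = sum(region == "allowed") / n,
       outlier = sum(region == "outlier") / n,
       nScored = n,
       detail = data.frame(residue = dh$residue[sc], aa = dh$aa[sc],
                           class = cls, phi = dh$phi[sc], psi = dh$psi[sc],
                           density = p, region = region))
}
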