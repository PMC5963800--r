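# Shared fixtures, all generated in code.

idealHelix <- function(n = 12, seed = 1) buildBackbone(strrep("H", n),
                                                       seed = seed)

mixedModel <- function(seed = 1)
  buildBackbone("LHHHHHHHHHHLLEEEEEEEEL", seed = seed)

# A model with hand-placed coordinates (atoms N/C/O parked near their CA so
# validity holds); used where exact CA distances matter.
modelFromCa <- function(ca, sequence = rep("A", nrow(ca))) {
  n <- nrow(ca)
  co <- array(0, c(n, 4, 3))
  for (a in 1:4) co[, a, ] <- ca + (a - 2) * 0.1
  co[, 2, ] <- ca
  BackboneModel("manual", "manual", sequence, co)
}

# Minimal fixed-width PDB ATOM lines for a poly-ALA chain; `drop` removes
# the atom records named "res:atom" (e.g. "2:O").
polyAlaPdbLines <- function(n = 3, drop = character(0)) {
  lines <- character(0)
  serial <- 0
  for (r in seq_len(n)) {
    for (a in c("N", "CA", "C", "O")) {
      if (paste0(r, ":", a) %in% drop) next
      serial <- serial + 1
      x <- r * 3.8 + ifelse(a == "N", 0, ifelse(a == "CA", 1, 2))
      y <- ifelse(a == "O", 1.2, 0)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%4s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, a, "ALA", r, x, y, 0, substr(a, 1, 1)))
    }
  }
  lines
}

writeTempPdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  path
}

# Direct-arithmetic oracle for the confusion-table metrics, written from
# the printed formulas with the documented zero conventions.
metricOracle <- function(tp, tn, fp, fn) {
  z <- function(num, den) if (den == 0) 0 else num / den
  list(acc = (tp + tn) / (tp + tn + fp + fn),
       sn = z(tp, tp + fn),
       spc = z(tn, tn + fp),
       mcc = {
         f <- c(tp + fp, tp + fn, tn + fp, tn + fn)
         if (any(f == 0)) 0 else (tp * tn - fp * fn) / sqrt(prod(f))
       },
       f1 = {
         sn <- z(tp, tp + fn); pr <- z(tp, tp + fp)
         if (sn == 0 || pr == 0) 0 else 2 / (1 / sn + 1 / pr)
       })
}

binCentersT <- function(bw) seq(-180 + bw / 2, 180 - bw / 2, by = bw)

# Wrap into (-180, 180], identifying 180 with -180 (for torsion sums and
# differences modulo a full turn).
wrapAngleT <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

# Random proper rotation matrix.
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
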