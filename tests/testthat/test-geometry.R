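test_that("dihedral angle matches planar cases and the vector-algebra oracle", {
  expect_equal(dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)), 0)
  expect_equal(dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0)), 180)
  # +/-90 case: sign fixed by an independent cross-product argument.
  # b2 = (0,1,0), b3 = (0,0,1): the far bond rotates clockwise (viewed
  # along b2) from the near-bond normal, giving +90 under the IUPAC rule.
  expect_equal(dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1)), 90)
  expect_equal(dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,-1)), -90)
})

test_that("dihedral angles agree with an independent implementation", {
  # bio3d's torsion routine as external oracle on random tetrads
  set.seed(11)
  for (k in 1:25) {
    pts <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    ours <- tryCatch(dihedralAngle(pts[1,], pts[2,], pts[3,], pts[4,]),
                     error = function(e) NA)
    if (is.na(ours)) next
    oracle <- bio3d::torsion.xyz(as.numeric(t(pts)), atm.inc = 4)
    expect_equal(wrapAngleT(ours - oracle), 0, tolerance = 1e-6)
  }
})

test_that("degenerate dihedral geometry raises an error", {
  expect_error(dihedralAngle(c(0,0,0), c(0,0,0), c(1,0,0), c(1,1,0)),
               "degenerate")
  expect_error(dihedralAngle(c(0,0,0), c(1,0,0), c(2,0,0), c(3,1,0)),
               "degenerate")
})

test_that("builder and analyzer are inverse for canonical torsions", {
  h <- buildBackbone(strrep("H", 10))
  dh <- backboneDihedrals(h)
  expect_equal(dh$phi[2:10], rep(-57, 9), tolerance = 1e-6)
  expect_equal(dh$psi[1:9], rep(-47, 9), tolerance = 1e-6)
  expect_equal(dh$omega[2:10], rep(180, 9), tolerance = 1e-6)
  e <- buildBackbone(strrep("E", 6))
  dhe <- backboneDihedrals(e)
  expect_equal(dhe$phi[2:6], rep(-139, 5), tolerance = 1e-6)
  expect_equal(dhe$psi[1:5], rep(135, 5), tolerance = 1e-6)
})

test_that("terminal torsions are undefined", {
  m <- idealHelix(3)
  dh <- backboneDihedrals(m)
  expect_true(is.na(dh$phi[1]) && is.na(dh$omega[1]))
  expect_true(is.na(dh$psi[3]))
  expect_false(anyNA(dh$phi[-1]))
})

test_that("mirror reflection is an exact involution that negates torsions", {
  for (seed in 1:5) {
    m <- perturbModel(mixedModel(seed), 0.3, seed = seed)
    mm <- mirrorReflect(m)
    expect_identical(mirrorReflect(mm)@coords, m@coords)
    d1 <- backboneDihedrals(m); d2 <- backboneDihedrals(mm)
    for (col in c("phi", "psi", "omega")) {
      a <- d1[[col]]; b <- d2[[col]]
      ok <- !is.na(a)
      expect_lt(max(abs(wrapAngleT(a[ok] + b[ok]))), 1e-6)
    }
    expect_equal(phiPlusRatio(mm), 1 - phiPlusRatio(m))
  }
})

test_that("positive-phi ratio counts signs directly", {
  h <- idealHelix(10)
  expect_equal(phiPlusRatio(h), 0)
  expect_equal(phiPlusRatio(mirrorReflect(h)), 1)
  df <- data.frame(phi = c(-57, 57, -57, 57, NA))
  expect_equal(phiPlusRatio(df), 0.5)
})

test_that("kabsch recovers rigid motions exactly and stays proper", {
  ca <- caCoords(mixedModel())
  s0 <- kabschSuperpose(ca, ca)
  expect_lt(s0@rmsd, 1e-9)
  set.seed(5)
  for (k in 1:10) {
    R <- randomRotation()
    tgt <- sweep(ca %*% t(R), 2, stats::rnorm(3, sd = 5), "+")
    s <- kabschSuperpose(ca, tgt)
    expect_lt(s@rmsd, 1e-9)
    expect_equal(det(s@rotation), 1, tolerance = 1e-9)
    # transform really maps mobile onto target
    moved <- sweep(ca %*% t(s@rotation), 2, s@translation, "+")
    expect_lt(max(abs(moved - tgt)), 1e-6)
  }
})

test_that("a chiral set keeps positive RMSD against its mirror", {
  pts <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))
  mir <- pts; mir[, 1] <- -mir[, 1]
  s <- kabschSuperpose(pts, mir)
  expect_gt(s@rmsd, 0.1)
  # brute-force oracle: no sampled proper rotation does better
  set.seed(21)
  cp <- sweep(pts, 2, colMeans(pts)); cm <- sweep(mir, 2, colMeans(mir))
  best <- min(vapply(1:2000, function(i) {
    R <- randomRotation()
    sqrt(mean(rowSums((cp %*% t(R) - cm)^2)))
  }, numeric(1)))
  expect_lte(s@rmsd, best + 1e-9)
})

test_that("kabsch agrees with an independent superposition implementation", {
  set.seed(9)
  for (k in 1:5) {
    a <- matrix(stats::rnorm(30, sd = 4), 10, 3)
    b <- matrix(stats::rnorm(30, sd = 4), 10, 3)
    ours <- kabschSuperpose(a, b)@rmsd
    fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(b)),
                                           mobile = as.numeric(t(a))))
    oracle <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - b)^2)))
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("returned superposition is optimal over random rotations", {
  set.seed(33)
  a <- matrix(stats::rnorm(24, sd = 3), 8, 3)
  b <- matrix(stats::rnorm(24, sd = 3), 8, 3)
  s <- kabschSuperpose(a, b)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  rmsds <- vapply(1:1000, function(i) {
    R <- randomRotation()
    sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
  }, numeric(1))
  expect_true(all(s@rmsd <= rmsds + 1e-12))
})

test_that("kabsch rejects bad input", {
  expect_error(kabschSuperpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  expect_error(kabschSuperpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               "equal-length")
  lin <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(lin, lin), "collinear")
})

test_that("the choice of reflection plane is immaterial", {
  m <- mixedModel()
  refX <- mirrorReflect(m)
  coY <- m@coords; coY[, , 2] <- -coY[, , 2]
  refY <- BackboneModel("y", "d", modelSequence(m), coY)
  expect_lt(kabschSuperpose(caCoords(refX), caCoords(refY))@rmsd, 1e-9)
})

test_that("orientation assignment follows the lower-RMSD rule", {
  ref <- idealHelix(30)
  self <- assignOrientation(ref, ref)
  expect_equal(self$label, "native")
  expect_lt(self$rmsdToReference, 1e-9)
  mir <- assignOrientation(mirrorReflect(ref), ref)
  expect_equal(mir$label, "mirror")
  expect_lt(mir$rmsdToMirrorReference, 1e-9)
  expect_error(assignOrientation(idealHelix(10), ref), "equal residue")
})

test_that("small noise never flips the orientation of a chiral helix", {
  ref <- idealHelix(30)
  labels <- vapply(1:100, function(s)
    assignOrientation(perturbModel(ref, 0.3, seed = s), ref)$label,
    character(1))
  expect_true(all(labels == "native"))
})

test_that("native and mirror RMSD populations are symmetric", {
  ens <- makeEnsemble("LHHHHHHHHHHLLEEEEEEEEL", nModels = 80,
                      noiseSd = 0.8, seed = 4, domainId = "sym")
  ref <- referenceModel(ens); tr <- orientationTruth(ens)
  r1 <- r2 <- numeric(0)
  for (i in seq_along(models(ens))) {
    o <- assignOrientation(models(ens)[[i]], ref)
    if (tr[i] == "native") r1 <- c(r1, o$rmsdToReference)
    else r2 <- c(r2, o$rmsdToMirrorReference)
  }
  se <- sqrt(stats::var(r1) / length(r1) + stats::var(r2) / length(r2))
  expect_lt(abs(mean(r1) - mean(r2)), 2 * se + 1e-12)
})
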