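# Independent brute-force oracle for the nonbonded terms: explicit double
# loop over atoms using bondSeparation and the per-pair closed forms.
bruteNonbonded <- function(model, cfg) {
  n <- nResidues(model)
  atoms <- expand.grid(res = seq_len(n), atom = c("N", "CA", "C", "O"),
                       stringsAsFactors = FALSE)
  coul <- 0; atr <- 0; rep_ <- 0
  for (i in seq_len(nrow(atoms) - 1)) for (j in (i + 1):nrow(atoms)) {
    ai <- atoms[i, ]; aj <- atoms[j, ]
    bs <- bondSeparation(model, ai$res, ai$atom, aj$res, aj$atom)
    if (bs < cfg@minBondSeparation) next
    pi_ <- model@coords[ai$res, ai$atom, ]
    pj <- model@coords[aj$res, aj$atom, ]
    r <- sqrt(sum((pi_ - pj)^2))
    if (r <= cfg@coulombCutoff) {
      rc <- max(r, cfg@coulombMinDist)
      qq <- cfg@charges[[ai$atom]] * cfg@charges[[aj$atom]]
      coul <- coul + cfg@coulombConstant * qq *
        (1 / rc^2 - 1 / cfg@coulombCutoff^2)
    }
    if (r <= cfg@ljCutoff) {
      rmin <- cfg@ljRadius[[ai$atom]] + cfg@ljRadius[[aj$atom]]
      ep <- sqrt(cfg@ljEpsilon[[ai$atom]] * cfg@ljEpsilon[[aj$atom]])
      lj <- ep * ((rmin / r)^12 - 2 * (rmin / r)^6)
      if (r < rmin) { atr <- atr - ep; rep_ <- rep_ + lj + ep }
      else atr <- atr + lj
    }
  }
  list(coul = coul, atr = atr, rep = rep_)
}

test_that("bond separation counts covalent bonds along the backbone", {
  m <- idealHelix(5)
  expect_equal(bondSeparation(m, 1, "N", 1, "CA"), 1L)
  expect_equal(bondSeparation(m, 1, "C", 2, "N"), 1L)
  expect_equal(bondSeparation(m, 1, "CA", 2, "CA"), 3L)
  expect_equal(bondSeparation(m, 1, "C", 1, "O"), 1L)
  expect_equal(bondSeparation(m, 1, "O", 2, "O"), 5L)
  expect_equal(bondSeparation(m, 2, "CA", 2, "CA"), 0L)
  expect_error(bondSeparation(m, 9, "N", 1, "CA"), "not in the model")
})

test_that("bond separation matches shortest paths in the bond graph", {
  n <- 4
  m <- idealHelix(n)
  # build the covalent graph independently with igraph
  vnames <- as.vector(outer(c("N", "CA", "C", "O"), seq_len(n),
                            function(a, r) paste0(a, r)))
  edges <- c()
  for (r in seq_len(n)) {
    edges <- c(edges, paste0("N", r), paste0("CA", r),
               paste0("CA", r), paste0("C", r),
               paste0("C", r), paste0("O", r))
    if (r < n) edges <- c(edges, paste0("C", r), paste0("N", r + 1))
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  dm <- igraph::distances(g)
  for (r1 in seq_len(n)) for (a1 in c("N", "CA", "C", "O"))
    for (r2 in seq_len(n)) for (a2 in c("N", "CA", "C", "O"))
      expect_equal(bondSeparation(m, r1, a1, r2, a2),
                   as.integer(dm[paste0(a1, r1), paste0(a2, r2)]))
})

test_that("nonbonded energies equal the brute-force double loop", {
  cfg <- energyConfig()
  for (seed in 1:3) {
    m <- perturbModel(buildBackbone(strrep("H", 8), seed = seed), 0.3,
                      seed = seed)
    oracle <- bruteNonbonded(m, cfg)
    expect_equal(coulombEnergy(m, cfg), oracle$coul, tolerance = 1e-9)
    lj <- ljEnergies(m, cfg)
    expect_equal(lj$fa_atr, oracle$atr, tolerance = 1e-9)
    expect_equal(lj$fa_rep, oracle$rep, tolerance = 1e-9)
  }
})

test_that("a chain with every pair bonded or beyond cutoff sums to zero", {
  # residues 40 A apart: all cross-residue pairs exceed both cutoffs and
  # all within/adjacent-residue pairs are excluded as bonded
  m <- modelFromCa(rbind(c(0, 0, 0), c(40, 0, 0), c(80, 0, 0)))
  cfg <- energyConfig()
  oracle <- bruteNonbonded(m, cfg)
  expect_equal(oracle$coul, 0)  # confirms the sum really is empty
  expect_equal(coulombEnergy(m, cfg), 0)
  lj <- ljEnergies(m, cfg)
  expect_equal(lj$fa_atr, 0)
  expect_equal(lj$fa_rep, 0)
})

test_that("LJ split signs and bounds hold on arbitrary models", {
  cfg <- energyConfig()
  for (seed in 1:4) {
    m <- perturbModel(mixedModel(seed), 0.8, seed = seed)
    lj <- ljEnergies(m, cfg)
    expect_gte(lj$fa_rep, 0)
    expect_lte(lj$fa_atr, 0)
  }
})

test_that("distance-based terms are invariant under exact reflection", {
  cfg <- energyConfig()
  m <- perturbModel(mixedModel(), 0.4, seed = 6)
  mm <- mirrorReflect(m)
  expect_equal(coulombEnergy(mm, cfg), coulombEnergy(m, cfg),
               tolerance = 1e-9)
  expect_equal(ljEnergies(mm, cfg), ljEnergies(m, cfg), tolerance = 1e-9)
})

test_that("missing parameters raise configuration errors", {
  m <- idealHelix(5)
  cfg <- energyConfig(charges = c(N = -0.47, CA = 0.07, C = 0.51))
  expect_error(coulombEnergy(m, cfg), "charge")
  cfg2 <- energyConfig(ljRadius = c(N = 1.75))
  expect_error(ljEnergies(m, cfg2), "radius")
})

test_that("rama energy prefers populated torsion regions", {
  g <- buildSurrogateGrid()
  h <- idealHelix(15)
  expect_lt(ramaEnergy(h, g), ramaEnergy(mirrorReflect(h), g))
  # uniform grid: energy depends only on length
  nb <- as.integer(360 / g@binWidth)
  uni <- new("RamaDensityGrid", binWidth = g@binWidth,
             density = list(general = matrix(1 / nb^2, nb, nb)))
  e1 <- ramaEnergy(h, uni)
  e2 <- ramaEnergy(perturbModel(h, 2, seed = 1), uni)
  expect_equal(e1, e2, tolerance = 1e-9)
  expect_equal(e1, -13 * log(1 / nb^2 + 1e-6), tolerance = 1e-9)
})

test_that("rama energy decreases when a residue moves to a denser bin", {
  g <- buildSurrogateGrid()
  h <- idealHelix(15)
  mm <- mirrorReflect(h)
  # move one interior residue of the mirror from (57,47) toward nothing:
  # compare summed -log densities directly
  dh <- backboneDihedrals(h); dm <- backboneDihedrals(mm)
  sc <- !is.na(dh$phi) & !is.na(dh$psi)
  pNative <- lookupDensity(g, "general", dh$phi[sc], dh$psi[sc])
  pMirror <- lookupDensity(g, "general", dm$phi[sc], dm$psi[sc])
  expect_true(all(pNative > pMirror))
})

test_that("conditional torsion probability follows the Bayes formula", {
  g <- buildSurrogateGrid()
  # two-member family with identical grids: P = 0.5 everywhere
  nb <- as.integer(360 / g@binWidth)
  same <- new("RamaDensityGrid", binWidth = g@binWidth,
              density = list(X = g@density$general, Y = g@density$general))
  m <- idealHelix(10)
  e <- pAaPpEnergy(m, same, mapping = c(A = "X", B = "Y"))
  expect_equal(e, 8 * -log(0.5 + 1e-6), tolerance = 1e-9)

  # separated family: helix-mode amino acid scores lower on a helix
  helixOnly <- buildSurrogateGrid(components = list(
    H = data.frame(phi = -63, psi = -43, w = 1),
    S = data.frame(phi = -120, psi = 130, w = 1)))
  polyH <- pAaPpEnergy(m, helixOnly, mapping = c(A = "H", B = "S"))
  mB <- BackboneModel("b", "d", rep("B", 10), m@coords)
  polyB <- pAaPpEnergy(mB, helixOnly, mapping = c(A = "H", B = "S"))
  expect_lt(polyH, polyB)

  # brute-force per-residue Bayes oracle on an arbitrary model
  m5 <- perturbModel(buildBackbone("HELHH", sequence = "AGPAV"), 0.2,
                     seed = 3)
  mapping <- aaClassMapping()
  dh <- backboneDihedrals(m5)
  sc <- which(!is.na(dh$phi) & !is.na(dh$psi))
  expected <- 0
  for (i in sc) {
    dens <- vapply(names(mapping), function(b)
      lookupDensity(g, mapping[[b]], dh$phi[i], dh$psi[i]), numeric(1))
    p <- dens[[dh$aa[i]]] / sum(dens)   # uniform priors cancel
    expected <- expected - log(p + 1e-6)
  }
  expect_equal(pAaPpEnergy(m5, g), expected, tolerance = 1e-9)
})

test_that("energy profiles are weighted sums of their terms", {
  m <- perturbModel(mixedModel(), 0.3, seed = 9)
  cfg <- energyConfig()
  p <- energyProfile(m, cfg)
  terms <- c("fa_atr", "fa_rep", "hack_elec", "rama", "p_aa_pp")
  expect_equal(p$total, sum(unlist(p[terms])), tolerance = 1e-9)
  # zero weight removes a term's influence; doubling weights doubles total
  cfg0 <- energyConfig(weights = c(fa_atr = 0, fa_rep = 1, hack_elec = 1,
                                   rama = 1, p_aa_pp = 1))
  p0 <- energyProfile(m, cfg0)
  expect_equal(p0$total, sum(unlist(p[c("fa_rep", "hack_elec", "rama",
                                        "p_aa_pp")])), tolerance = 1e-9)
  cfg2 <- energyConfig(weights = c(fa_atr = 2, fa_rep = 2, hack_elec = 2,
                                   rama = 2, p_aa_pp = 2))
  expect_equal(energyProfile(m, cfg2)$total, 2 * p$total, tolerance = 1e-9)
})

test_that("profile tables round-trip through TSV", {
  ens <- makeEnsemble(strrep("H", 10), nModels = 4, noiseSd = 0.3, seed = 2)
  pr <- energyProfiles(ens)
  expect_equal(nrow(pr), 4)
  path <- tempfile(fileext = ".tsv")
  writeEnergyProfiles(pr, path)
  back <- readEnergyProfiles(path)
  expect_equal(back$total, pr$total, tolerance = 1e-12)
  expect_equal(back$model_id, pr$model_id)
})
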