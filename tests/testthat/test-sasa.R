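# Shrake-Rupley SASA engine

test_that("an isolated atom reproduces the closed-form sphere area", {
  s <- toyStructure("C", c(0, 0, 0), element = "C")
  r <- vdwRadii()[["C"]] + 1.4
  exact <- 4 * pi * r^2
  got <- shrakeRupley(s, nPoints = 960)
  expect_lt(abs(got - exact) / exact, 0.005)
  # Fibonacci weights are exactly uniform, so the value is exact here
  expect_equal(got, exact, tolerance = 1e-9)
  # far-apart atoms are exactly additive
  s2 <- toyStructure(c("C", "C"), c(0, 0, 0, 100, 0, 0), element = "C")
  expect_equal(sum(shrakeRupley(s2)), 2 * exact, tolerance = 1e-9)
})

test_that("two overlapping spheres match the analytic spherical-cap formula", {
  rC <- vdwRadii()[["C"]] + 1.4
  rN <- vdwRadii()[["N"]] + 1.4
  for (d in c(2.0, 3.0, 4.5, 6.0)) {
    s <- toyStructure(c("C", "N"), c(0, 0, 0, d, 0, 0),
                      element = c("C", "N"))
    got <- shrakeRupley(s, nPoints = 3840)
    capA <- 2 * pi * rC * (rC - (d^2 + rC^2 - rN^2) / (2 * d))
    capB <- 2 * pi * rN * (rN - (d^2 + rN^2 - rC^2) / (2 * d))
    exactA <- 4 * pi * rC^2 - max(0, capA)
    exactB <- 4 * pi * rN^2 - max(0, capB)
    expect_lt(abs(got[1] - exactA) / exactA, 0.02)
    expect_lt(abs(got[2] - exactB) / exactB, 0.02)
  }
})

test_that("the engine agrees with a Monte-Carlo surface oracle within 3 sigma", {
  pep <- buildPeptide("FDL", backbone = "extended", resnoStart = 1L)
  a <- atomData(pep)
  radii <- vdwRadii()[a$element]
  mc <- mcSASA(getCoords(pep), radii, npts = 4000, seed = 3)
  got <- shrakeRupley(pep, nPoints = 3840)  # fine lattice: MC error dominates
  # per-atom bound at 4 sigma: ~24 atoms are tested jointly, so a 3-sigma
  # per-atom bound would false-alarm for ~6 % of oracle draws
  for (i in seq_len(nAtoms(pep)))
    expect_lt(abs(got[i] - mc$sasa[i]), 4 * mc$se[i] + 0.5)
  # and the summed profile is a 3-sigma-level comparison
  seTot <- sqrt(sum(mc$se^2))
  expect_lt(abs(sum(got) - sum(mc$sasa)), 3 * seTot + 2)
})

test_that("point-set refinement converges on the p53N fixture", {
  pep <- p53nHelix()
  s960 <- sum(shrakeRupley(pep, nPoints = 960))
  s3840 <- sum(shrakeRupley(pep, nPoints = 3840))
  expect_lt(abs(s960 - s3840) / s3840, 0.02)
})

test_that("adding atoms never increases any existing atom's SASA", {
  set.seed(7)
  pep <- buildPeptide("SDL", backbone = "extended", resnoStart = 1L)
  base <- shrakeRupley(pep)
  for (k in 1:5) {
    extra <- toyStructure("C", rnorm(3, sd = 4), element = "C",
                          resno = 900L + k)
    comb <- .Structure(rbind(atomData(pep), atomData(extra)),
                       rbind(getCoords(pep), getCoords(extra)))
    grown <- shrakeRupley(comb)[seq_len(nAtoms(pep))]
    expect_true(all(grown <= base + 1e-9))
  }
})

test_that("per-residue profiles sum atoms exactly and split side chains", {
  pep <- p53nHelix()
  perAtom <- shrakeRupley(pep)
  prof <- residueSASA(pep)
  expect_equal(sum(prof$sasaTotal), sum(perAtom, na.rm = TRUE),
               tolerance = 1e-9)
  expect_true(all(prof$sasaSideChain <= prof$sasaTotal + 1e-9))
  expect_true(all(prof$sasaTotal > 0))  # an extended/helical 13-mer cannot bury a residue fully
  a <- atomData(pep)
  i19 <- a$resno == 19 & !(a$name %in% c("N", "CA", "C", "O", "OXT"))
  expect_equal(prof$sasaSideChain[prof$resno == 19],
               sum(perAtom[i19]), tolerance = 1e-9)
  # empty selection warns and returns an empty profile
  expect_warning(p0 <- residueSASA(pep, selection = list(chains = "A",
                                                         atomNames = "XX")),
                 "empty selection")
  expect_equal(nrow(p0), 0L)
})

test_that("a caged residue loses essentially all SASA as the cage closes", {
  pep <- p53nHelix()
  free <- residueSASA(pep)
  sparse <- buildSyntheticComplex(pep, 22, pointsPerAtom = 8L)
  dense <- buildSyntheticComplex(pep, 22, pointsPerAtom = 60L)
  s22 <- function(x) {
    p <- residueSASA(x)
    p$sasaSideChain[p$chain == "A" & p$resno == 22]
  }
  expect_gt(s22(pep), 30)
  expect_lt(s22(dense), s22(sparse))
  expect_lt(s22(dense), 5)
})

test_that("ensemble SASA means and sds behave and coil exceeds helix for core residues", {
  pep <- p53nHelix()
  ens <- rigidCopies(pep, 3L)
  es <- ensembleSASA(ens)
  expect_true(all(es$summary$sdTotal < 1e-9))  # identical conformers
  expect_equal(es$summary$meanTotal, residueSASA(pep)$sasaTotal,
               tolerance = 1e-9)
  # rotated rigid copies: means agree to lattice resolution (~1 A^2)
  ensR <- rigidCopies(pep, 3L, rotate = TRUE, seed = 9)
  esR <- ensembleSASA(ensR)
  expect_lt(max(abs(esR$summary$meanTotal - es$summary$meanTotal)), 3)
  # 2-frame ensemble mean is the arithmetic average of the frame profiles
  two <- .Ensemble(atomData(pep), getCoords(ens)[1:2, , , drop = FALSE])
  es2 <- ensembleSASA(two)
  pr1 <- residueSASA(frameStructure(two, 1))$sasaTotal
  pr2 <- residueSASA(frameStructure(two, 2))$sasaTotal
  expect_equal(es2$summary$meanTotal, (pr1 + pr2) / 2, tolerance = 1e-9)
  # helix buries the core relative to coil for interior residues
  simH <- sampleEnsemble(generatorSpec(nFrames = 4, backbone = "helix",
                                       seed = 15))
  simC <- sampleEnsemble(generatorSpec(nFrames = 4, backbone = "coil",
                                       seed = 16))
  mh <- ensembleSASA(simH$ensemble)$summary
  mc <- ensembleSASA(simC$ensemble)$summary
  core <- mh$resno >= 20 & mh$resno <= 26
  expect_gt(mean(mc$meanTotal[core]), mean(mh$meanTotal[core]))
})
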