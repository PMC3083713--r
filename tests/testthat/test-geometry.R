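# Torsion angles, Kabsch superposition, RMSD series

test_that("planar reference torsions and the sign convention are exact", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(dihedral(p1, p2, p3, c(1, 1, 0)), 0)
  expect_equal(dihedral(p1, p2, p3, c(1, -1, 0)), 180)
  expect_equal(dihedral(p1, p2, p3, c(1, 0, 1)), 90)
  expect_error(dihedral(p1, p2, p3, c(2, 0, 0)), "degenerate")
})

test_that("torsion matches a rotation-construction oracle on random quadruples", {
  # build p4 by rotating the cis position about the p2->p3 axis by a known
  # angle; the returned torsion must equal that angle (sign included)
  set.seed(11)
  for (k in 1:1000) {
    p1 <- rnorm(3); p2 <- rnorm(3); p3 <- rnorm(3)
    while (sqrt(sum((p3 - p2)^2)) < 0.3) p3 <- rnorm(3)
    axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
    # cis direction: component of (p1 - p2) perpendicular to the axis
    v <- (p1 - p2) - sum((p1 - p2) * axis) * axis
    if (sqrt(sum(v^2)) < 1e-3) next
    v <- v / sqrt(sum(v^2))
    theta <- runif(1, -179.9, 179.9)
    th <- theta * pi / 180
    # Rodrigues rotation of v about the p2->p3 axis. A right-handed
    # rotation by +theta appears clockwise when viewed from p2 toward p3,
    # which is the IUPAC-positive sense, so the torsion must equal theta.
    w <- v * cos(th) + IDPAnchor:::.cross(axis, v) * sin(th) +
      axis * sum(axis * v) * (1 - cos(th))
    p4 <- p3 + w + axis * 0.7
    expect_equal(dihedral(p1, p2, p3, p4), theta, tolerance = 1e-8)
  }
})

test_that("torsion is invariant under rigid motion and flips sign under mirror", {
  set.seed(21)
  for (k in 1:50) {
    pts <- matrix(rnorm(12), 4, 3)
    ref <- tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                    error = function(e) NA)
    if (is.na(ref)) next
    R <- randomRotation(); tr <- rnorm(3, sd = 10)
    q <- pts %*% t(R) + matrix(tr, 4, 3, byrow = TRUE)
    expect_equal(dihedral(q[1, ], q[2, ], q[3, ], q[4, ]), ref,
                 tolerance = 1e-8)
    m <- pts; m[, 3] <- -m[, 3]  # mirror
    got <- dihedral(m[1, ], m[2, ], m[3, ], m[4, ])
    expect_equal(abs(got), abs(ref), tolerance = 1e-8)
    if (abs(abs(ref) - 180) > 1e-6 && abs(ref) > 1e-6)
      expect_equal(got, -ref, tolerance = 1e-8)
  }
})

test_that("chi angles of the bound-like Phe19 conformer read back exactly", {
  pep <- p53nHelix(chi = list(`19` = c(177, 71)))
  chi <- chiAngles(pep, 19)
  expect_equal(unname(chi["chi1"]), 177, tolerance = 1e-6)
  expect_equal(unname(chi["chi2"]), 71, tolerance = 1e-6)
  # leucine at exactly -60
  pep2 <- buildPeptide("ALA", backbone = "extended", resnoStart = 1L,
                       chi = list(`2` = c(-60, 180)))
  expect_equal(unname(chiAngles(pep2, 2)["chi1"]), -60, tolerance = 1e-6)
  # alanine has no chi atoms: explicit missing, not zero
  expect_true(all(is.na(chiAngles(pep2, 1))))
})

test_that("superposition is exact on rigid copies and matches the quaternion oracle", {
  set.seed(31)
  A <- matrix(rnorm(45), 15, 3)
  s <- superpose(A, A)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)
  for (k in 1:100) {
    n <- sample(4:30, 1)
    A <- matrix(rnorm(3 * n), n, 3)
    B <- matrix(rnorm(3 * n), n, 3)
    expect_equal(superpose(A, B)$rmsd, quaternionRMSD(A, B),
                 tolerance = 1e-8)
    # rigid copies superpose to zero and rotations stay proper
    R <- randomRotation()
    A2 <- A %*% t(R) + matrix(rnorm(3), n, 3, byrow = TRUE)
    fit <- superpose(A2, A)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  }
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("optimal RMSD never exceeds the unfitted RMSD and is symmetric", {
  set.seed(41)
  for (k in 1:20) {
    A <- matrix(rnorm(30), 10, 3); B <- matrix(rnorm(30), 10, 3)
    direct <- sqrt(mean(rowSums((A - B)^2)))
    opt <- superpose(A, B)$rmsd
    expect_lte(opt, direct + 1e-12)
    expect_equal(opt, superpose(B, A)$rmsd, tolerance = 1e-9)
  }
})

test_that("backbone RMSD series is zero on rigid copies and steps at a construction switch", {
  ref <- p53nHelix()
  ens <- rigidCopies(ref, 5L, rotate = TRUE, seed = 5)
  rs <- backboneRMSDSeries(ens, ref, c(19, 26))
  expect_true(all(rs < 1e-8))
  # helix then coil: the series steps up at the construction switch frame
  spec <- generatorSpec(nFrames = 40,
                        backbone = c(rep("helix", 20), rep("coil", 20)),
                        seed = 13)
  sim <- sampleEnsemble(spec)
  rs2 <- backboneRMSDSeries(sim$ensemble, ref, c(19, 26))
  expect_lt(max(rs2[1:20]), 1.5)
  expect_gt(min(rs2[21:40]), 2.0)
  # Gaussian noise: mean RMSD close to the direct per-frame computation
  pepN <- rigidCopies(ref, 10L)
  co <- getCoords(pepN)
  set.seed(77); co <- co + rnorm(length(co), sd = 0.3)
  ensN <- .Ensemble(atomData(ref), co)
  rsN <- backboneRMSDSeries(ensN, ref, c(19, 26))
  a <- atomData(ref)
  idx <- which(a$resno >= 19 & a$resno <= 26 &
                 a$name %in% c("N", "CA", "C", "O"))
  direct <- vapply(1:10, function(f)
    superpose(co[f, idx, ], getCoords(ref)[idx, ])$rmsd, numeric(1))
  expect_equal(rsN, direct, tolerance = 1e-10)
  expect_error(backboneRMSDSeries(ensN, selectAtoms(ref, resnoRange = c(17, 20)),
                                  c(19, 26)),
               "reference lacks")
})
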