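# Rotamer regions, populations, joint statistics, transitions

test_that("circular interval membership matches a brute-force 1-degree grid", {
  cfg <- defaultRegionConfig()
  rs <- cfg$regions[["19"]]
  grid <- seq(-179.5, 179.5, by = 1)
  bruteLabel <- function(x) {
    inIv <- function(lo, hi) ((x - lo) %% 360) < ((hi - lo) %% 360)
    for (r in seq_len(nrow(rs)))
      if (inIv(rs$chi1Lo[r], rs$chi1Hi[r])) return(rs$label[r])
    "unassigned"
  }
  got <- classifyFrames(data.frame(chi1 = grid, chi2 = NA), rs)
  expect_identical(got, vapply(grid, bruteLabel, character(1)))
  # boundary frames classify deterministically into the half-open side
  expect_equal(classifyFrames(data.frame(chi1 = 120, chi2 = NA), rs)[1], "A")
  expect_equal(classifyFrames(data.frame(chi1 = 0, chi2 = NA), rs)[1], "C")
  # the literature chi1 of bound Phe19 falls in region A
  expect_equal(classifyFrames(data.frame(chi1 = 177, chi2 = NA), rs)[1], "A")
})

test_that("overlapping regions are rejected at construction", {
  expect_error(regionSet(c("A", "B"), c(0, 100), c(120, 200)), "overlap")
  expect_error(regionSet("A", 0, 360), "empty/full")
  # wrapped intervals that do not overlap are fine
  expect_s3_class(regionSet(c("A", "B"), c(120, -120), c(-120, 0)),
                  "regionSet")
  # 2-D regions with identical chi1 but disjoint chi2 coexist
  expect_s3_class(regionSet(c("1", "2"), c(120, 120), c(-120, -120),
                            c(0, -180), c(180, 0)), "regionSet")
})

test_that("Phe chi2 is symmetry-folded into [-90, 90) before classification", {
  expect_equal(foldSymmetricChi2(150), -30)
  expect_equal(foldSymmetricChi2(-150), 30)
  expect_equal(foldSymmetricChi2(71), 71)
  expect_equal(foldSymmetricChi2(90), -90)
  pep <- p53nHelix(chi = list(`19` = c(60, 150)))
  ens <- rigidCopies(pep, 2L)
  chi <- extractChiSeries(ens, 19)
  expect_equal(chi$chi2, c(-30, -30), tolerance = 1e-6)
  # Trp is not folded (indole is asymmetric)
  pepW <- p53nHelix(chi = list(`23` = c(60, 150)))
  chiW <- extractChiSeries(rigidCopies(pepW, 1L), 23)
  expect_equal(chiW$chi2, 150, tolerance = 1e-6)
  expect_error(extractChiSeries(rigidCopies(buildPeptide("AGA",
    backbone = "extended", resnoStart = 1L), 1L), 1), "unsupported")
})

test_that("populations equal a direct recount and carry binomial errors", {
  labels <- c(rep("A", 30), rep("B", 15), rep("unassigned", 5))
  p <- statePopulation(labels, "A")
  expect_equal(p$fraction, 30 / 50)
  expect_equal(p$n, 50L)
  expect_equal(p$se, sqrt(0.6 * 0.4 / 50))
  expect_equal(statePopulation(rep("A", 10), "A")$fraction, 1)
  # partition + unassigned sums exactly to 1
  tot <- sum(vapply(c("A", "B", "unassigned"),
                    function(l) statePopulation(labels, l)$fraction,
                    numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
  expect_error(statePopulation(rep(NA_character_, 3), "A"), "no assigned")
  # bound-reference matching uses circular distance on both angles
  br <- boundReference(19, "p53N-MDM2", chi1 = 177, chi2 = 71,
                       tolerance = 40)
  chi <- data.frame(chi1 = c(177, 150, -170, 100, NA),
                    chi2 = c(71, 60, 85, 71, 71))
  pb <- statePopulation(chi, br)
  expect_equal(pb$count, 3L)   # 177/71, 150/60 and -170/85 match (wrap)
  expect_equal(pb$n, 4L)       # the NA frame leaves the denominator
})

test_that("generator targets are recovered within binomial error", {
  cfg <- defaultRegionConfig()
  phe <- data.frame(label = c("A", "B", "C"), chi1 = c(177, -65, 60),
                    chi2 = c(71, -80, 90), prob = c(0.595, 0.25, 0.1))
  spec <- generatorSpec(nFrames = 2000, backbone = "helix",
                        rotamerStates = list(`19` = phe), seed = 101)
  ss <- sampleStateSeries(spec)
  truth <- mean(ss$states[, "19"] == "A")
  se <- sqrt(0.595 * 0.405 / 2000)
  expect_lt(abs(truth - 0.595), 3 * se)
  # and the full coordinate path agrees with the ground truth labels
  spec2 <- generatorSpec(nFrames = 150, backbone = "helix",
                         rotamerStates = list(`19` = phe), seed = 102)
  sim <- sampleEnsemble(spec2)
  lab <- classifyFrames(extractChiSeries(sim$ensemble, 19),
                        cfg$regions[["19"]])
  gt <- sim$groundTruth$states[, "19"]
  expect_true(all(lab[gt != "free"] == gt[gt != "free"]))
})

test_that("population recovery holds across seeded replicates (property)", {
  # statistical layer only: 200 replicates x 4 target levels at n = 2000
  probs <- c(0.05, 0.2, 0.5, 0.8)
  fails <- 0L; total <- 0L
  for (seed in 1:50) {
    for (p0 in probs) {
      st <- data.frame(label = "A", chi1 = 177, chi2 = 71, prob = p0)
      ss <- sampleStateSeries(generatorSpec(nFrames = 2000,
                                            rotamerStates = list(`19` = st),
                                            seed = 7000 + seed * 7 +
                                              round(p0 * 100)))
      phat <- mean(ss$states[, "19"] == "A")
      total <- total + 1L
      if (abs(phat - p0) >= 3 * sqrt(p0 * (1 - p0) / 2000))
        fails <- fails + 1L
    }
  }
  expect_gte(1 - fails / total, 0.99 - 0.03)  # 3-se rule holds ~99.7%
})

test_that("joint populations reproduce marginals exactly and obey Frechet bounds", {
  set.seed(202)
  labs <- function(n, opts) sample(opts, n, replace = TRUE)
  l1 <- labs(500, c("A", "B", "C", "unassigned"))
  l2 <- labs(500, as.character(1:6))
  m <- jointPopulation(l1, l2)
  expect_equal(sum(m), 1, tolerance = 1e-12)
  marg1 <- rowSums(m)
  for (lab in rownames(m))
    expect_equal(unname(marg1[lab]), statePopulation(l1, lab)$fraction,
                 tolerance = 1e-12)
  marg2 <- colSums(m)
  for (lab in colnames(m))
    expect_equal(unname(marg2[lab]), statePopulation(l2, lab)$fraction,
                 tolerance = 1e-12)
  for (i in rownames(m)) for (j in colnames(m))
    expect_lte(m[i, j], min(marg1[i], marg2[j]) + 1e-12)
  # perfectly correlated series: P(A,1) = P(A) = P(1)
  lc <- ifelse(l1 == "A", "1", "2")
  mc <- jointPopulation(l1, lc)
  expect_equal(mc["A", "1"], unname(rowSums(mc)["A"]), tolerance = 1e-12)
  expect_error(jointPopulation(l1, l2[-1]), "length")
})

test_that("coupled generation reproduces a target joint population", {
  phe <- data.frame(label = c("A", "B", "C"), chi1 = c(177, -65, 60),
                    chi2 = c(71, -80, 90), prob = c(0.595, 0.25, 0.1))
  trp <- data.frame(label = as.character(1:6),
                    chi1 = c(180, 180, -65, -65, 60, 60),
                    chi2 = c(90, -90, 95, -95, 90, -90),
                    prob = c(0.624, 0.07, 0.1, 0.07, 0.06, 0.05))
  spec <- generatorSpec(nFrames = 4000, backbone = "helix",
                        rotamerStates = list(`19` = phe, `23` = trp),
                        couple = list(resnoA = 19, resnoB = 23,
                                      labelA = "A", labelB = "1",
                                      pJoint = 0.51),
                        seed = 303)
  ss <- sampleStateSeries(spec)
  pJoint <- mean(ss$states[, "19"] == "A" & ss$states[, "23"] == "1")
  expect_lt(abs(pJoint - 0.51), 3 * sqrt(0.51 * 0.49 / 4000))
  pA <- mean(ss$states[, "19"] == "A")
  expect_lt(abs(pA - 0.595), 3 * sqrt(0.595 * 0.405 / 4000))
  pB <- mean(ss$states[, "23"] == "1")
  expect_lt(abs(pB - 0.624), 3 * sqrt(0.624 * 0.376 / 4000))
  expect_error(generatorSpec(nFrames = 10, rotamerStates = list(`19` = phe),
                             couple = list(resnoA = 19, resnoB = 23,
                                           labelA = "A", labelB = "1",
                                           pJoint = 0.9), seed = 1) |>
                 sampleStateSeries(), "unreachable|state tables")
})

test_that("transition counting is exact and debouncing matches a run-length oracle", {
  expect_equal(countTransitions(c("A", "A", "B", "A", "B")), 3L)
  expect_equal(countTransitions(rep("A", 100)), 0L)
  expect_equal(countTransitions(character(0)), 0L)
  # independent run-length oracle
  oracle <- function(labels, minDwell) {
    r <- rle(labels)
    v <- r$values[r$lengths >= minDwell]
    if (length(v) == 0) return(0L)
    sum(v[-1] != v[-length(v)])
  }
  set.seed(404)
  for (k in 1:30) {
    n <- sample(50:400, 1)
    lab <- sample(c("A", "B"), n, replace = TRUE, prob = c(0.6, 0.4))
    for (dw in c(1L, 2L, 3L, 5L))
      expect_equal(countTransitions(lab, dw), oracle(lab, dw))
  }
  # two-state series with known switch count: exact recovery at dwell 1
  set.seed(405)
  for (k in 1:20) {
    switches <- sample(5:40, 1)
    runs <- sample(3:20, switches + 1, replace = TRUE)
    lab <- unlist(lapply(seq_along(runs), function(i)
      rep(c("helix", "coil")[1 + i %% 2], runs[i])))
    expect_equal(countTransitions(lab, 1L), switches)
    # relabeling and time reversal leave the count unchanged
    expect_equal(countTransitions(rev(lab), 1L), switches)
    expect_equal(countTransitions(chartr("hc", "xy", lab), 1L), switches)
  }
})

test_that("library comparison flags the Phe19 preference reversal", {
  lib <- rotamerLibraryReference()
  expect_equal(lib$libraryPct[lib$resno == 19 & lib$role == "anchor-type"],
               31.71)
  pops <- data.frame(resno = c(19, 19, 23, 23),
                     role = rep(c("anchor-type", "non-anchor"), 2),
                     fraction = c(0.595, 0.122, 0.624, 0.053))
  cmp <- compareWithLibrary(pops, lib)
  # library prefers the non-anchor Phe19 rotamer; the helix state reverses it
  expect_true(cmp$reversed[cmp$resno == 19])
  expect_false(cmp$reversed[cmp$resno == 23])
  expect_equal(cmp$libraryNonAnchor[cmp$resno == 19], 0.4708)
  # identical table and reference -> zero differences
  pops2 <- data.frame(resno = 19, role = c("anchor-type", "non-anchor"),
                      fraction = c(0.3171, 0.4708))
  cmp2 <- compareWithLibrary(pops2, lib)
  expect_equal(cmp2$deltaAnchor, 0, tolerance = 1e-12)
  expect_equal(cmp2$deltaNonAnchor, 0, tolerance = 1e-12)
  # constructed offsets come back exactly
  pops3 <- data.frame(resno = 19, role = c("anchor-type", "non-anchor"),
                      fraction = c(0.3171 + 0.1, 0.4708 - 0.2))
  cmp3 <- compareWithLibrary(pops3, lib)
  expect_equal(cmp3$deltaAnchor, 0.1, tolerance = 1e-12)
  expect_equal(cmp3$deltaNonAnchor, -0.2, tolerance = 1e-12)
})
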