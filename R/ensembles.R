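## Synthetic conformational ensembles with known ground truth: two-state
## (helix/coil) backbone switching with geometric dwell times, per-residue
## rotamer states drawn per dwell segment from target populations, angular
## jitter around state centres, optional Gaussian coordinate noise.
## These ensembles emulate the statistical structure of MD trajectories of
## an unbound disordered peptide; they carry no physics.

#' Specification for a synthetic peptide ensemble
#'
#' @param sequence one-letter sequence (default p53N, ETFSDLWKLLPEN,
#'   residues 17-29).
#' @param nFrames number of frames (>= 1).
#' @param backbone either \code{"helix"} or \code{"coil"} for a single
#'   state throughout, a per-frame character vector of those labels, or a
#'   list \code{list(initial =, dwellHelix =, dwellCoil =)} giving mean
#'   dwell times in frames for a two-state switching schedule with
#'   geometric dwell-time distribution.
#' @param rotamerStates named list: resno (as character) -> data.frame with
#'   columns \code{label}, \code{chi1}, \code{chi2} (state centres, deg;
#'   chi2 NA for 1-chi residues) and \code{prob}. Probabilities must sum to
#'   <= 1; the remainder is sampled uniformly over chi space ("free"
#'   frames). States are redrawn independently per residue per backbone
#'   dwell segment. Optionally a data.frame may carry an attribute-free
#'   extra column \code{prob2} ignored here.
#' @param couple optional list \code{list(resnoA =, resnoB =, labelA =,
#'   labelB =, pJoint =)} forcing the joint probability of (labelA, labelB)
#'   for two residues to \code{pJoint} while keeping other draws
#'   independent; used to emulate correlated two-residue states.
#' @param rotamerDwellFrames mean dwell (frames) of the side-chain state
#'   process. 1 (default) redraws states independently every frame, so
#'   frame counts are binomial; larger values hold states over
#'   geometric-dwell segments (redrawn at backbone switches too), for
#'   kinetics-style analyses such as transition counting.
#' @param jitterDeg half-width of the uniform angular jitter added around
#'   each state centre (default 10 deg).
#' @param noiseSd isotropic Gaussian coordinate noise added last (A,
#'   default 0).
#' @param dt ns per frame (default 0.1).
#' @param seed integer RNG seed (mandatory: ensembles are reproducible).
#' @param resnoStart author number of the first residue (default 17).
#' @return object of class \code{generatorSpec} (a validated list).
#' @export
generatorSpec <- function(sequence = "ETFSDLWKLLPEN", nFrames = 100L,
                          backbone = "helix", rotamerStates = list(),
                          couple = NULL, rotamerDwellFrames = 1,
                          jitterDeg = 10, noiseSd = 0,
                          dt = 0.1, seed, resnoStart = 17L) {
  if (missing(seed)) stop("a seed is mandatory for ensemble generation")
  stopifnot(nFrames >= 1L, jitterDeg >= 0, noiseSd >= 0, dt > 0,
            rotamerDwellFrames >= 1)
  for (rn in names(rotamerStates)) {
    st <- rotamerStates[[rn]]
    if (!all(c("label", "chi1", "prob") %in% names(st)))
      stop("rotamer state table for residue ", rn,
           " needs columns label, chi1, prob (chi2 optional)")
    if (sum(st$prob) > 1 + 1e-9)
      stop("rotamer state probabilities for residue ", rn, " exceed 1")
  }
  out <- list(sequence = sequence, nFrames = as.integer(nFrames),
              backbone = backbone, rotamerStates = rotamerStates,
              couple = couple, rotamerDwellFrames = rotamerDwellFrames,
              jitterDeg = jitterDeg, noiseSd = noiseSd,
              dt = dt, seed = as.integer(seed),
              resnoStart = as.integer(resnoStart))
  class(out) <- "generatorSpec"
  out
}

# geometric two-state switching schedule; returns per-frame labels
.backboneSchedule <- function(backbone, nFrames) {
  if (is.character(backbone) && length(backbone) == 1L)
    return(rep(backbone, nFrames))
  if (is.character(backbone)) {
    if (length(backbone) != nFrames)
      stop("per-frame backbone vector has wrong length")
    return(backbone)
  }
  state <- backbone$initial
  out <- character(0)
  while (length(out) < nFrames) {
    mean <- if (state == "helix") backbone$dwellHelix else backbone$dwellCoil
    dwell <- 1L + stats::rgeom(1L, prob = 1 / mean)
    out <- c(out, rep(state, dwell))
    state <- if (state == "helix") "coil" else "helix"
  }
  out[seq_len(nFrames)]
}

# phi/psi per backbone state: helix = alpha basin, coil = PPII/beta-like
.backboneAngles <- function(state, n, jitterDeg) {
  jit <- function(k) stats::runif(k, -jitterDeg, jitterDeg)
  if (state == "helix") list(phi = -57 + jit(n), psi = -47 + jit(n))
  else list(phi = stats::runif(n, -150, -70), psi = stats::runif(n, 110, 170))
}

#' Sample the discrete state series of a generator spec (no coordinates)
#'
#' Draws only the statistical layer of [sampleEnsemble()]: the backbone
#' schedule, per-residue rotamer state labels per dwell segment, and the
#' exact chi angles (centre + jitter). Useful when an analysis needs many
#' replicates of the state statistics without 3-D coordinates.
#'
#' @param spec a [generatorSpec()].
#' @return list with \code{backbone} (per-frame labels), \code{states}
#'   (frames x residues character matrix of rotamer labels; "free" for
#'   unassigned draws), \code{chi} (named list: resno -> data.frame chi1,
#'   chi2), and \code{switchFrames} (first frame of each backbone dwell
#'   segment after the first).
#' @export
sampleStateSeries <- function(spec) {
  stopifnot(inherits(spec, "generatorSpec"))
  set.seed(spec$seed)
  nf <- spec$nFrames
  bb <- .backboneSchedule(spec$backbone, nf)
  r <- rle(bb)
  segStart <- cumsum(c(1L, utils::head(r$lengths, -1L)))
  # side-chain state segmentation: backbone switches always start a new
  # segment; within a backbone run, states persist for geometric dwells of
  # mean rotamerDwellFrames (1 = redraw every frame)
  if (spec$rotamerDwellFrames <= 1) {
    segId <- seq_len(nf)
  } else {
    breaks <- rep(FALSE, nf)
    breaks[segStart] <- TRUE
    breaks[1L] <- TRUE
    p <- 1 / spec$rotamerDwellFrames
    breaks <- breaks | (stats::runif(nf) < p)
    segId <- cumsum(breaks)
  }
  r <- list(lengths = rle(segId)$lengths, values = unique(segId))
  resnos <- names(spec$rotamerStates)
  states <- matrix("free", nrow = nf, ncol = length(resnos),
                   dimnames = list(NULL, resnos))
  chi <- list()
  nSeg <- length(r$lengths)
  # joint coupling of two residues: draw per segment one of four pair
  # categories (both in target, A only, B only, neither) so that the joint
  # probability is exactly pJoint while marginals stay at the spec targets
  cp <- spec$couple
  coupledLab <- NULL
  if (!is.null(cp)) {
    rnA <- as.character(cp$resnoA); rnB <- as.character(cp$resnoB)
    stA <- spec$rotamerStates[[rnA]]; stB <- spec$rotamerStates[[rnB]]
    if (is.null(stA) || is.null(stB))
      stop("coupled residues must have rotamer state tables")
    pA <- stA$prob[stA$label == cp$labelA]
    pB <- stB$prob[stB$label == cp$labelB]
    pj <- cp$pJoint
    if (length(pA) != 1L || length(pB) != 1L)
      stop("coupling labels not found in state tables")
    if (pj > min(pA, pB) + 1e-9 || 1 - pA - pB + pj < -1e-9)
      stop("unreachable joint probability for the requested marginals")
    drawOther <- function(st, target) {
      rest <- st$label != target
      opts <- c(st$label[rest], "free")
      probs <- c(st$prob[rest], 1 - sum(st$prob))
      if (sum(probs) <= 0) return("free")
      sample(opts, 1L, prob = probs)
    }
    coupledLab <- matrix(NA_character_, nrow = nSeg, ncol = 2L,
                         dimnames = list(NULL, c(rnA, rnB)))
    for (s in seq_len(nSeg)) {
      cat4 <- sample(c("both", "Aonly", "Bonly", "neither"), 1L,
                     prob = c(pj, pA - pj, pB - pj, 1 - pA - pB + pj))
      coupledLab[s, 1L] <- if (cat4 %in% c("both", "Aonly")) cp$labelA else
        drawOther(stA, cp$labelA)
      coupledLab[s, 2L] <- if (cat4 %in% c("both", "Bonly")) cp$labelB else
        drawOther(stB, cp$labelB)
    }
  }
  for (k in seq_along(resnos)) {
    rn <- resnos[k]
    st <- spec$rotamerStates[[rn]]
    pFree <- 1 - sum(st$prob)
    if (!is.null(coupledLab) && rn %in% colnames(coupledLab)) {
      labSeg <- coupledLab[, rn]
    } else {
      labSeg <- vapply(seq_len(nSeg), function(s)
        sample(c(st$label, "free"), 1L, prob = c(st$prob, pFree)),
        character(1))
    }
    states[, k] <- labSeg[segId]
    cc <- matrix(NA_real_, nrow = nf, ncol = 2L)
    for (f in seq_len(nf)) {
      lab <- states[f, k]
      if (lab == "free") {
        cc[f, ] <- c(stats::runif(1, -180, 180), stats::runif(1, -180, 180))
      } else {
        row <- st[st$label == lab, , drop = FALSE]
        cc[f, 1] <- row$chi1 + stats::runif(1, -spec$jitterDeg, spec$jitterDeg)
        c2 <- if ("chi2" %in% names(row)) row$chi2 else NA_real_
        cc[f, 2] <- if (is.na(c2)) NA_real_ else
          c2 + stats::runif(1, -spec$jitterDeg, spec$jitterDeg)
      }
    }
    cc[, 1] <- .wrap180(cc[, 1])
    cc[, 2] <- .wrap180(cc[, 2])
    chi[[rn]] <- data.frame(chi1 = cc[, 1], chi2 = cc[, 2])
  }
  list(backbone = bb, states = states, chi = chi,
       switchFrames = segStart[-1L])
}

.wrap180 <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[!is.na(out) & out <= -180] <- 180
  out
}

#' Generate a synthetic peptide ensemble with ground truth
#'
#' Draws the state series of \code{spec} (see [sampleStateSeries()]),
#' builds every frame with the ideal-geometry constructor
#' ([buildPeptide()]) at the drawn backbone and side-chain angles, and
#' finally adds isotropic Gaussian coordinate noise. Fully reproducible
#' from the seed (R's default Mersenne-Twister RNG; recorded in the
#' ground-truth attributes).
#'
#' @param spec a [generatorSpec()].
#' @return list with \code{ensemble} (an \linkS4class{Ensemble}) and
#'   \code{groundTruth} (the [sampleStateSeries()] list plus \code{spec}
#'   and \code{rng}).
#' @export
sampleEnsemble <- function(spec) {
  gt <- sampleStateSeries(spec)   # seeds the RNG itself
  nf <- spec$nFrames
  seq1 <- strsplit(toupper(spec$sequence), "")[[1]]
  n <- length(seq1)
  resnos <- seq.int(spec$resnoStart, length.out = n)
  coords <- NULL
  for (f in seq_len(nf)) {
    st <- gt$backbone[f]
    ang <- .backboneAngles(st, n, spec$jitterDeg)
    chi <- list()
    for (rn in names(gt$chi)) {
      v <- as.numeric(gt$chi[[rn]][f, ])
      chi[[rn]] <- v[!is.na(v)]
    }
    s <- buildPeptide(spec$sequence, backbone = ang, chi = chi,
                      resnoStart = spec$resnoStart)
    if (is.null(coords))
      coords <- array(NA_real_, dim = c(nf, nAtoms(s), 3L))
    coords[f, , ] <- s@xyz
    if (f == 1L) atoms <- atomData(s)
  }
  if (spec$noiseSd > 0)
    coords <- coords + stats::rnorm(length(coords), sd = spec$noiseSd)
  gt$spec <- spec
  gt$rng <- RNGkind()[1L]
  list(ensemble = Ensemble(atoms, coords, dt = spec$dt,
                           label = sprintf("synthetic-seed%d", spec$seed)),
       groundTruth = gt)
}

#' Write the ground-truth sidecar table of a synthetic ensemble
#'
#' Tab-separated: frame, backbone state, then per tracked residue its state
#' label and exact chi1/chi2.
#' @param groundTruth the \code{groundTruth} element of [sampleEnsemble()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  df <- data.frame(frame = seq_along(groundTruth$backbone),
                   backbone = groundTruth$backbone)
  for (rn in colnames(groundTruth$states)) {
    df[[paste0("state_", rn)]] <- groundTruth$states[, rn]
    df[[paste0("chi1_", rn)]] <- round(groundTruth$chi[[rn]]$chi1, 3)
    df[[paste0("chi2_", rn)]] <- round(groundTruth$chi[[rn]]$chi2, 3)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a synthetic two-chain complex burying chosen residues
#'
#' Surrounds the side chains of the named peptide residues with a rigid
#' cage of dummy carbon atoms (chain "Z") so that those side chains are
#' essentially fully occluded while other residues stay exposed. The cage
#' is a fixture for anchor-classification: by construction the pocket
#' residues are the anchors.
#'
#' @param peptide a \linkS4class{Structure} (single chain).
#' @param pocketResnos integer residue numbers to bury.
#' @param shellRadius distance from each buried atom to its cage shell
#'   (default 4.0 A).
#' @param pointsPerAtom cage atoms per buried atom before pruning
#'   (default 40).
#' @param clearance cage atoms closer than this to any non-pocket residue
#'   atom are removed so that only pocket residues are occluded
#'   (default 4.5 A).
#' @return a two-chain \linkS4class{Structure}: peptide plus cage chain
#'   "Z" (residue name DUM).
#' @export
buildSyntheticComplex <- function(peptide, pocketResnos, shellRadius = 4.0,
                                  pointsPerAtom = 40L, clearance = 4.5) {
  a <- atomData(peptide)
  missing <- setdiff(pocketResnos, unique(a$resno))
  if (length(missing) > 0L)
    stop("pocket residue(s) absent from peptide: ",
         paste(missing, collapse = ", "))
  sideMask <- !(a$name %in% .BACKBONE) & a$element != "H"
  target <- which(a$resno %in% pocketResnos & sideMask)
  if (length(target) == 0L) return(peptide)
  other <- peptide@xyz[-target, , drop = FALSE]
  shell <- fibonacciSphere(as.integer(pointsPerAtom)) * shellRadius
  cage <- do.call(rbind, lapply(target, function(i)
    sweep(shell, 2L, peptide@xyz[i, ], "+")))
  # prune: keep cage atoms clear of non-pocket atoms, and thin duplicates
  keep <- rep(TRUE, nrow(cage))
  for (k in seq_len(nrow(cage))) {
    d2 <- (other[, 1] - cage[k, 1])^2 + (other[, 2] - cage[k, 2])^2 +
      (other[, 3] - cage[k, 3])^2
    if (min(d2) < clearance^2) keep[k] <- FALSE
  }
  cage <- cage[keep, , drop = FALSE]
  if (nrow(cage) > 1L) {
    thin <- rep(TRUE, nrow(cage))
    for (k in 2:nrow(cage)) {
      prev <- cage[seq_len(k - 1L), , drop = FALSE][thin[seq_len(k - 1L)], ,
                                                    drop = FALSE]
      d2 <- (prev[, 1] - cage[k, 1])^2 + (prev[, 2] - cage[k, 2])^2 +
        (prev[, 3] - cage[k, 3])^2
      if (length(d2) > 0L && min(d2) < 1.2^2) thin[k] <- FALSE
    }
    cage <- cage[thin, , drop = FALSE]
  }
  nC <- nrow(cage)
  cageAtoms <- data.frame(name = "C", resname = "DUM", chain = "Z",
                          resno = seq_len(nC) + 1000L, element = "C",
                          stringsAsFactors = FALSE)
  Structure(rbind(a, cageAtoms), rbind(peptide@xyz, cage))
}
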