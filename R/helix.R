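## Simplified helix assignment and unfolding-time detection. Full DSSP
## (electrostatic H-bond energies) is deliberately not re-implemented: the
## analysis only needs a helix/not-helix call over a short residue window,
## for which two standard criteria suffice: an alpha-basin phi/psi run of
## >= 4 residues, or the O(i)->N(i+4) hydrogen-bond distance proxy.

.ALPHA_PHI <- c(-100, -30)
.ALPHA_PSI <- c(-80, -5)

.phiPsiStructure <- function(structure, chain, resnos) {
  a <- atomData(structure)
  idx <- function(rn, nm) {
    i <- which(a$chain == chain & a$resno == rn & a$name == nm)
    if (length(i) == 1L) i else NA_integer_
  }
  n <- length(resnos)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    rn <- resnos[k]
    iC0 <- idx(rn - 1L, "C"); iN <- idx(rn, "N"); iCA <- idx(rn, "CA")
    iC <- idx(rn, "C"); iN1 <- idx(rn + 1L, "N")
    x <- structure@xyz
    if (!anyNA(c(iC0, iN, iCA, iC)))
      phi[k] <- dihedral(x[iC0, ], x[iN, ], x[iCA, ], x[iC, ])
    if (!anyNA(c(iN, iCA, iC, iN1)))
      psi[k] <- dihedral(x[iN, ], x[iCA, ], x[iC, ], x[iN1, ])
  }
  list(phi = phi, psi = psi)
}

.helixFlagsStructure <- function(structure, chain, resnos) {
  n <- length(resnos)
  pp <- .phiPsiStructure(structure, chain, resnos)
  basin <- !is.na(pp$phi) & !is.na(pp$psi) &
    pp$phi >= .ALPHA_PHI[1] & pp$phi <= .ALPHA_PHI[2] &
    pp$psi >= .ALPHA_PSI[1] & pp$psi <= .ALPHA_PSI[2]
  flags <- rep(FALSE, n)
  # criterion (a): >= 4 consecutive alpha-basin residues
  r <- rle(basin)
  ends <- cumsum(r$lengths)
  for (s in seq_along(r$lengths))
    if (r$values[s] && r$lengths[s] >= 4L)
      flags[(ends[s] - r$lengths[s] + 1L):ends[s]] <- TRUE
  # criterion (b): O(i) -> N(i+4) distance < 3.5 A marks i..i+4
  a <- atomData(structure)
  for (k in seq_len(n)) {
    if (k + 4L > n) break
    iO <- which(a$chain == chain & a$resno == resnos[k] & a$name == "O")
    iN <- which(a$chain == chain & a$resno == resnos[k + 4L] & a$name == "N")
    if (length(iO) == 1L && length(iN) == 1L) {
      d <- sqrt(sum((structure@xyz[iO, ] - structure@xyz[iN, ])^2))
      if (d < 3.5) flags[k:(k + 4L)] <- TRUE
    }
  }
  flags
}

#' Helix assignment over a residue window
#'
#' Flags a residue as helical when it belongs to a run of >= 4 consecutive
#' residues inside the alpha basin (phi in [-100, -30], psi in [-80, -5])
#' or is spanned by an O(i)->N(i+4) hydrogen-bond proxy (< 3.5 A). The
#' per-frame helix fraction is the mean flag over the window.
#'
#' @param x a \linkS4class{Structure} or \linkS4class{Ensemble}.
#' @param window length-2 residue range (default c(18, 26), the p53N
#'   transient-helix window Thr18-Leu26).
#' @param chain chain id (default: sole chain).
#' @return list: \code{flags} (frames x residues logical matrix; one row
#'   for a Structure), \code{fraction} (per-frame helix fraction),
#'   \code{resnos}, \code{window}.
#' @export
assignHelix <- function(x, window = c(18L, 26L), chain = NULL) {
  if (diff(window) + 1L < 4L)
    stop("helix window must span at least 4 residues (i, i+4 pattern)")
  a <- atomData(x)
  if (is.null(chain)) {
    ch <- unique(a$chain)
    if (length(ch) > 1L) stop("multiple chains present; specify `chain`")
    chain <- ch
  }
  resnos <- sort(unique(a$resno[a$chain == chain &
                                  a$resno >= window[1] &
                                  a$resno <= window[2]]))
  if (length(resnos) == 0L) stop("window contains no residues")
  frames <- if (is(x, "Ensemble"))
    lapply(seq_len(nFrames(x)), function(f) frameStructure(x, f))
  else list(x)
  flags <- t(vapply(frames, .helixFlagsStructure, logical(length(resnos)),
                    chain = chain, resnos = resnos))
  dimnames(flags) <- list(NULL, as.character(resnos))
  list(flags = flags, fraction = rowMeans(flags), resnos = resnos,
       window = window)
}

#' Detect the helix unfolding time of a trajectory
#'
#' The unfolding time tau_u is the time of the first frame at which the
#' backbone RMSD (over the helical window, against the supplied reference
#' helix) exceeds \code{rmsdThreshold} \emph{and} the helix fraction falls
#' below \code{helixFractionThreshold}, with both conditions sustained for
#' at least \code{dwell} consecutive frames (single-frame spikes are
#' ignored). Trajectories that never satisfy the criterion are reported
#' as not unfolded. All criteria are echoed in the result.
#'
#' @param ensemble an \linkS4class{Ensemble} with a time step.
#' @param refHelix reference helical \linkS4class{Structure}.
#' @param rmsdThreshold backbone RMSD threshold, A (default 2.5).
#' @param helixFractionThreshold helix-fraction threshold (default 0.25).
#' @param dwell sustained-frames requirement (default 10).
#' @param rmsdWindow residue window for RMSD (default c(19, 26),
#'   Phe19-Leu26).
#' @param helixWindow residue window for helix content (default c(18, 26)).
#' @param chain chain id (default: sole chain).
#' @return list of class \code{unfoldingResult}: \code{unfolded},
#'   \code{tauNs} (NA when not unfolded), \code{frame}, \code{criteria},
#'   \code{rmsdSeries}, \code{helixFractionSeries}.
#' @export
detectUnfolding <- function(ensemble, refHelix, rmsdThreshold = 2.5,
                            helixFractionThreshold = 0.25, dwell = 10L,
                            rmsdWindow = c(19L, 26L),
                            helixWindow = c(18L, 26L), chain = NULL) {
  if (rmsdThreshold <= 0 || helixFractionThreshold <= 0 || dwell < 1L)
    stop("thresholds must be positive and dwell >= 1")
  rmsd <- backboneRMSDSeries(ensemble, refHelix, rmsdWindow, chain = chain)
  hel <- assignHelix(ensemble, window = helixWindow, chain = chain)$fraction
  cond <- rmsd > rmsdThreshold & hel < helixFractionThreshold
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  frame <- NA_integer_
  for (s in seq_along(r$lengths)) {
    if (r$values[s] && r$lengths[s] >= dwell) {
      frame <- ends[s] - r$lengths[s] + 1L
      break
    }
  }
  dt <- timeStep(ensemble)
  out <- list(
    unfolded = !is.na(frame),
    tauNs = if (!is.na(frame) && !is.na(dt)) (frame - 1L) * dt else NA_real_,
    frame = frame,
    criteria = list(rmsdThreshold = rmsdThreshold,
                    helixFractionThreshold = helixFractionThreshold,
                    dwell = as.integer(dwell), rmsdWindow = rmsdWindow,
                    helixWindow = helixWindow),
    rmsdSeries = rmsd, helixFractionSeries = hel)
  class(out) <- c("unfoldingResult", "list")
  out
}

#' Partition ensemble frames into helix-state and disordered-state sets
#'
#' Frames before the unfolding time (minus an equilibration prefix) form
#' the helix state; frames from the unfolding time plus a margin onward
#' form the disordered state. A whole-trajectory label ("helix" or
#' "disordered") may be supplied instead for trajectories that never
#' unfold or that start disordered.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param unfolding an \code{unfoldingResult} from [detectUnfolding()], or
#'   NULL when \code{label} is given.
#' @param label optional whole-trajectory state label.
#' @param equilibrationNs prefix excluded from the helix state (default 1).
#' @param marginNs gap after tau_u excluded from the disordered state
#'   (default 0).
#' @return list: \code{helixFrames}, \code{disorderedFrames} (integer
#'   indices), \code{margins}.
#' @export
partitionStates <- function(ensemble, unfolding = NULL, label = NULL,
                            equilibrationNs = 1, marginNs = 0) {
  nf <- nFrames(ensemble)
  dt <- timeStep(ensemble)
  eqFrames <- if (!is.na(dt)) as.integer(ceiling(equilibrationNs / dt)) else 0L
  if (!is.null(label)) {
    label <- match.arg(label, c("helix", "disordered"))
    idx <- seq_len(nf)
    idx <- idx[idx > eqFrames | label == "disordered"]
    return(list(helixFrames = if (label == "helix") idx else integer(0),
                disorderedFrames = if (label == "disordered") idx else
                  integer(0),
                margins = list(equilibrationNs = equilibrationNs,
                               marginNs = marginNs)))
  }
  if (is.null(unfolding) || !isTRUE(unfolding$unfolded))
    stop("unfolding time undefined and no whole-trajectory label supplied")
  tauFrame <- unfolding$frame
  marginFrames <- if (!is.na(dt)) as.integer(ceiling(marginNs / dt)) else 0L
  helix <- seq_len(nf)[seq_len(nf) > eqFrames & seq_len(nf) < tauFrame]
  dis <- seq_len(nf)[seq_len(nf) >= tauFrame + marginFrames]
  list(helixFrames = helix, disorderedFrames = dis,
       margins = list(equilibrationNs = equilibrationNs,
                      marginNs = marginNs))
}

#' Summarise unfolding times per trajectory group
#'
#' Arithmetic mean and sample standard deviation of the defined unfolding
#' times within each group; not-unfolded trajectories are excluded from
#' the statistics and counted.
#'
#' @param tauNs numeric unfolding times in ns (NA = not unfolded).
#' @param groups character group labels, same length.
#' @return data.frame: group, n, nUnfolded, meanNs, sdNs.
#' @export
summarizeUnfolding <- function(tauNs, groups) {
  stopifnot(length(tauNs) == length(groups))
  if (all(is.na(tauNs)))
    stop("no trajectory unfolded in any group; nothing to summarise")
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    v <- tauNs[groups == g]
    def <- v[!is.na(v)]
    data.frame(group = g, n = length(v), nUnfolded = length(def),
               meanNs = if (length(def) > 0L) mean(def) else NA_real_,
               sdNs = if (length(def) > 1L) stats::sd(def) else
                 if (length(def) == 1L) 0 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
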