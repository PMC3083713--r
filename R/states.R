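## Rotamer-region definition and population analysis: circular chi1 (or
## chi1 x chi2) regions, bound-like conformation matching by circular
## distance, joint two-residue statistics, transition counting.

#' Circular angular distance in degrees
#' @param a,b angles in degrees.
#' @return smallest absolute angular separation, in [0, 180].
#' @export
circularDistance <- function(a, b) {
  d <- abs(((a - b + 180) %% 360) - 180)
  d
}

# membership of x in circular half-open interval [lo, hi); lo > hi wraps
# through 180/-180. Width (hi - lo) mod 360; a full circle is not allowed.
.inInterval <- function(x, lo, hi) {
  width <- (hi - lo) %% 360
  if (width == 0) stop("empty or full circular interval [", lo, ", ", hi, ")")
  ((x - lo) %% 360) < width
}

#' Define a rotamer region set
#'
#' A region set is a data.frame of named, pairwise-disjoint circular
#' regions in chi1 (1-D) or chi1 x chi2 (2-D rectangles) space for one
#' residue. Intervals are half-open [lo, hi) degrees and may wrap through
#' 180/-180; frames on a boundary therefore classify deterministically,
#' and evaluation in lower-label-first order makes the tie rule explicit.
#'
#' @param labels character region labels (e.g. \code{c("A","B","C")} or
#'   \code{as.character(1:6)}).
#' @param chi1Lo,chi1Hi numeric vectors of interval bounds (degrees).
#' @param chi2Lo,chi2Hi optional chi2 bounds for 2-D regions (NA for 1-D).
#' @return data.frame of class \code{regionSet}.
#' @export
regionSet <- function(labels, chi1Lo, chi1Hi, chi2Lo = NA_real_,
                      chi2Hi = NA_real_) {
  rs <- data.frame(label = as.character(labels), chi1Lo = chi1Lo,
                   chi1Hi = chi1Hi, chi2Lo = chi2Lo, chi2Hi = chi2Hi,
                   stringsAsFactors = FALSE)
  rs <- rs[order(rs$label), , drop = FALSE]
  rownames(rs) <- NULL
  .validateRegions(rs)
  class(rs) <- c("regionSet", "data.frame")
  rs
}

.overlap1d <- function(lo1, hi1, lo2, hi2) {
  w1 <- (hi1 - lo1) %% 360; w2 <- (hi2 - lo2) %% 360
  ((lo2 - lo1) %% 360) < w1 || ((lo1 - lo2) %% 360) < w2
}

.validateRegions <- function(rs) {
  if (anyDuplicated(rs$label)) stop("duplicated region labels")
  n <- nrow(rs)
  if (n < 1L) stop("region set is empty")
  twoD <- !is.na(rs$chi2Lo)
  if (any(twoD) && !all(twoD))
    stop("regions of one set must be all 1-D or all 2-D")
  for (i in seq_len(n)) {
    if ((rs$chi1Hi[i] - rs$chi1Lo[i]) %% 360 == 0)
      stop("region ", rs$label[i], " has an empty/full chi1 interval")
    for (j in seq_len(i - 1L)) {
      o1 <- .overlap1d(rs$chi1Lo[i], rs$chi1Hi[i], rs$chi1Lo[j], rs$chi1Hi[j])
      o2 <- if (all(twoD))
        .overlap1d(rs$chi2Lo[i], rs$chi2Hi[i], rs$chi2Lo[j], rs$chi2Hi[j])
      else TRUE
      if (o1 && o2)
        stop("regions ", rs$label[j], " and ", rs$label[i], " overlap")
    }
  }
  invisible(rs)
}

#' Fold an angle into [-90, 90) for two-fold symmetric side chains
#'
#' Phe and Tyr chi2 is 180-degree periodic (ring flip symmetry); all chi2
#' values of those residues are mapped into [-90, 90) before any region
#' test or population count.
#' @param x angles in degrees.
#' @return folded angles in [-90, 90).
#' @export
foldSymmetricChi2 <- function(x) ((x + 90) %% 180) - 90

#' Extract a per-frame chi1/chi2 series from an ensemble
#'
#' Computes chi1 and chi2 of one residue for every frame (vectorised
#' torsion evaluation). Frames with missing atoms yield NA and are
#' excluded from downstream denominators. For Phe and Tyr the chi2 values
#' are symmetry-folded into [-90, 90) (see [foldSymmetricChi2()]).
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param resno author residue number.
#' @param chain chain id (default: sole chain).
#' @return data.frame with columns frame, chi1, chi2 (degrees).
#' @export
extractChiSeries <- function(ensemble, resno, chain = NULL) {
  a <- atomData(ensemble)
  if (is.null(chain)) {
    ch <- unique(a$chain)
    if (length(ch) > 1L) stop("multiple chains present; specify `chain`")
    chain <- ch
  }
  sel <- a$chain == chain & a$resno == resno
  if (!any(sel)) stop("residue ", chain, ":", resno, " not found")
  resname <- a$resname[sel][1L]
  g <- .CHI1_ATOM[resname]
  if (is.na(g))
    stop("residue type ", resname, " has no chi angles (unsupported)")
  d <- .CHI2_ATOM[resname]
  idx <- function(nm) {
    i <- which(sel & a$name == nm)
    if (length(i) == 1L) i else NA_integer_
  }
  iN <- idx("N"); iCA <- idx("CA"); iCB <- idx("CB"); iG <- idx(g)
  nf <- nFrames(ensemble)
  chi1 <- rep(NA_real_, nf); chi2 <- rep(NA_real_, nf)
  co <- ensemble@coords
  atomFrames <- function(i) {
    m <- co[, i, , drop = FALSE]
    dim(m) <- c(nf, 3L)
    m
  }
  if (!anyNA(c(iN, iCA, iCB, iG))) {
    chi1 <- .dihedralRows(atomFrames(iN), atomFrames(iCA),
                          atomFrames(iCB), atomFrames(iG))
    if (!is.na(d)) {
      iD <- idx(d)
      if (!is.na(iD))
        chi2 <- .dihedralRows(atomFrames(iCA), atomFrames(iCB),
                              atomFrames(iG), atomFrames(iD))
    }
  } else {
    warning("residue ", chain, ":", resno,
            " is missing chi-defining atoms; series is all-NA")
  }
  if (resname %in% c("PHE", "TYR")) chi2 <- foldSymmetricChi2(chi2)
  data.frame(frame = seq_len(nf), chi1 = chi1, chi2 = chi2)
}

#' Classify frames of a chi series into rotamer regions
#'
#' Assigns each frame the label of the region containing its angles, or
#' "unassigned" when none matches or an angle is NA. Regions are tested in
#' label order (lower label wins a boundary tie; intervals are half-open
#' so true ties cannot occur within one set).
#'
#' @param chiSeries data.frame from [extractChiSeries()] (columns chi1 and,
#'   for 2-D sets, chi2).
#' @param regions a [regionSet()].
#' @return character vector of per-frame labels; NA-angle frames get
#'   NA (missing), distinct from "unassigned" (sampled but outside all
#'   regions).
#' @export
classifyFrames <- function(chiSeries, regions) {
  .validateRegions(regions)
  twoD <- !is.na(regions$chi2Lo[1L])
  n <- nrow(chiSeries)
  out <- rep("unassigned", n)
  miss <- is.na(chiSeries$chi1) | (twoD & is.na(chiSeries$chi2))
  out[miss] <- NA_character_
  for (r in seq_len(nrow(regions))) {
    hit <- !miss & out == "unassigned" &
      .inInterval(chiSeries$chi1, regions$chi1Lo[r], regions$chi1Hi[r])
    if (twoD)
      hit <- hit & .inInterval(chiSeries$chi2, regions$chi2Lo[r],
                               regions$chi2Hi[r])
    out[hit] <- regions$label[r]
  }
  out
}

#' Bound-reference side-chain conformation
#'
#' Records the chi1/chi2 of a residue in a specific complex, the matching
#' tolerance, and whether the conformation is the anchor-type one (the
#' residue is an anchor in that complex) or the non-anchor alternative.
#'
#' @param resno residue number; @param complexLabel e.g. "p53N-MDM2".
#' @param chi1,chi2 reference angles, degrees (chi2 NA for 1-chi matches).
#' @param tolerance per-angle circular matching tolerance, degrees
#'   (default 40; every report echoes it).
#' @param role "anchor-type" or "non-anchor".
#' @return list of class \code{boundReference}.
#' @export
boundReference <- function(resno, complexLabel, chi1, chi2 = NA_real_,
                           tolerance = 40, role = c("anchor-type",
                                                    "non-anchor")) {
  role <- match.arg(role)
  if (tolerance <= 0) stop("tolerance must be > 0")
  out <- list(resno = as.integer(resno), complexLabel = complexLabel,
              chi1 = chi1, chi2 = chi2, tolerance = tolerance, role = role)
  class(out) <- "boundReference"
  out
}

#' Fraction of frames matching a region label or a bound reference
#'
#' For a region label: matching frames / non-missing frames (unassigned
#' frames stay in the denominator, so fractions over the disjoint
#' partition plus "unassigned" sum to 1). For a bound reference: frames
#' whose chi1 (and chi2 when defined) lie within the circular tolerance
#' of the reference, over all non-missing frames. The binomial standard
#' error sqrt(p(1-p)/n) is attached.
#'
#' @param x per-frame labels (character, for region targets) or a chi
#'   series data.frame (for bound references).
#' @param target a region label (character scalar) or a
#'   [boundReference()].
#' @return list: fraction, se, count, n (denominator).
#' @export
statePopulation <- function(x, target) {
  if (inherits(target, "boundReference")) {
    stopifnot(is.data.frame(x))
    ok <- !is.na(x$chi1)
    if (!is.na(target$chi2)) ok <- ok & !is.na(x$chi2)
    n <- sum(ok)
    if (n == 0L) stop("no frames with defined chi angles")
    match1 <- circularDistance(x$chi1[ok], target$chi1) <= target$tolerance
    match <- if (is.na(target$chi2)) match1 else
      match1 & circularDistance(x$chi2[ok], target$chi2) <= target$tolerance
    count <- sum(match)
  } else {
    stopifnot(is.character(x) || is.factor(x))
    lab <- as.character(x)
    n <- sum(!is.na(lab))
    if (n == 0L) stop("no assigned frames")
    count <- sum(lab == target, na.rm = TRUE)
  }
  p <- count / n
  list(fraction = p, se = sqrt(p * (1 - p) / n), count = count, n = n)
}

#' Joint population matrix of two residues' region labels
#'
#' Pairwise fractions over frame-aligned label series, including the
#' "unassigned" category; marginals are recoverable exactly by summation
#' over one axis. Frames missing in either series are dropped from the
#' common denominator.
#'
#' @param labels1,labels2 per-frame label vectors of equal length.
#' @param labelOrder1,labelOrder2 optional label orderings for the matrix
#'   dimensions (default: sorted observed labels plus "unassigned").
#' @return matrix of fractions with attribute \code{n} (frames used).
#' @export
jointPopulation <- function(labels1, labels2, labelOrder1 = NULL,
                            labelOrder2 = NULL) {
  if (length(labels1) != length(labels2))
    stop("label series have different lengths (frame alignment lost)")
  ok <- !is.na(labels1) & !is.na(labels2)
  l1 <- as.character(labels1[ok]); l2 <- as.character(labels2[ok])
  n <- length(l1)
  if (n == 0L) stop("no frames with both residues assigned")
  ord1 <- labelOrder1 %||% sort(unique(l1))
  ord2 <- labelOrder2 %||% sort(unique(l2))
  tab <- table(factor(l1, levels = ord1), factor(l2, levels = ord2))
  m <- unclass(tab) / n
  attr(m, "n") <- n
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count state transitions in a label series, with debouncing
#'
#' With \code{minDwell = 1} this is the raw count of label changes between
#' consecutive frames. With \code{minDwell > 1}, runs shorter than
#' \code{minDwell} frames are discarded first (flickers do not count as
#' excursions), adjacent equal runs are merged, and the remaining label
#' changes are counted.
#'
#' @param labels character vector (NA frames are dropped first).
#' @param minDwell minimum run length, frames (default 1).
#' @return integer transition count (0 for empty/constant input).
#' @export
countTransitions <- function(labels, minDwell = 1L) {
  lab <- as.character(labels[!is.na(labels)])
  if (length(lab) < 2L) return(0L)
  r <- rle(lab)
  if (minDwell > 1L) {
    keep <- r$lengths >= minDwell
    if (!any(keep)) return(0L)
    v <- r$values[keep]
    v <- v[c(TRUE, v[-1L] != v[-length(v)])]  # merge adjacent equals
  } else {
    v <- r$values
  }
  length(v) - 1L
}

#' Compare state populations with a rotamer-library reference
#'
#' Side-by-side fractions of the anchor-type and non-anchor bound-like
#' conformations per residue, from an ensemble-state population table and
#' a backbone-independent rotamer-library reference, flagging residues
#' whose preference (anchor-type vs non-anchor) is reversed between the
#' library and the ensemble state.
#'
#' @param populations data.frame with columns resno, role ("anchor-type"/
#'   "non-anchor"), fraction (0..1).
#' @param library data.frame with columns resno, role, libraryFraction
#'   (0..1), as from [rotamerLibraryReference()].
#' @return data.frame per residue: anchor-type and non-anchor fractions in
#'   ensemble and library, their differences, and \code{reversed}.
#' @export
compareWithLibrary <- function(populations, library) {
  need <- c("resno", "role", "fraction")
  if (!all(need %in% names(populations)))
    stop("populations needs columns: ", paste(need, collapse = ", "))
  res <- sort(unique(populations$resno))
  pick <- function(df, rn, role, col) {
    v <- df[[col]][df$resno == rn & df$role == role]
    if (length(v) != 1L)
      stop("no unique ", role, " entry for residue ", rn,
           " in ", deparse(substitute(df)))
    v
  }
  out <- do.call(rbind, lapply(res, function(rn) {
    ea <- pick(populations, rn, "anchor-type", "fraction")
    en <- pick(populations, rn, "non-anchor", "fraction")
    la <- pick(library, rn, "anchor-type", "libraryFraction")
    ln <- pick(library, rn, "non-anchor", "libraryFraction")
    data.frame(resno = rn, ensembleAnchor = ea, ensembleNonAnchor = en,
               libraryAnchor = la, libraryNonAnchor = ln,
               deltaAnchor = ea - la, deltaNonAnchor = en - ln,
               reversed = sign(ea - en) != sign(la - ln) &
                 (ea != en) & (la != ln))
  }))
  rownames(out) <- NULL
  out
}
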