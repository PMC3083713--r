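## Geometric primitives: torsion angles, Kabsch superposition, RMSD series.
## Angles are in degrees throughout, range (-180, 180], IUPAC sign
## convention (positive = clockwise looking from atom 2 toward atom 3).

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion (dihedral) angle of four points
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees, range (-180, 180].
#' @details Errors on degenerate geometry (zero-length bond or exactly
#'   collinear triple), where the torsion is undefined.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  ln1 <- sqrt(sum(n1^2)); ln2 <- sqrt(sum(n2^2)); lb2 <- sqrt(sum(b2^2))
  if (lb2 < 1e-10 || ln1 < 1e-10 || ln2 < 1e-10)
    stop("degenerate geometry: collinear or coincident points")
  m1 <- .cross(n1, b2 / lb2)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Vectorised torsion over matrices of points (one row per observation).
# Returns NA where geometry is degenerate instead of erroring.
.dihedralRows <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  crossRows <- function(A, B)
    cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
          A[, 3] * B[, 1] - A[, 1] * B[, 3],
          A[, 1] * B[, 2] - A[, 2] * B[, 1])
  n1 <- crossRows(b1, b2); n2 <- crossRows(b2, b3)
  lb2 <- sqrt(rowSums(b2^2))
  m1 <- crossRows(n1, b2 / lb2)
  ang <- -atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  bad <- lb2 < 1e-10 | sqrt(rowSums(n1^2)) < 1e-10 |
    sqrt(rowSums(n2^2)) < 1e-10
  ang[bad] <- NA_real_
  ang
}

# chi-defining atom names per residue type; chi2 uses CD1 for Phe/Trp/Leu
# (and Ile), OD1/OE-type atoms for the acids/amides, CD for Glu/Gln/Lys/
# Arg/Pro, SD for Met, ND1 for His.
.CHI1_ATOM <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
                GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
                MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
                TRP = "CG", TYR = "CG", VAL = "CG1")
.CHI2_ATOM <- c(ARG = "CD", ASN = "OD1", ASP = "OD1", GLN = "CD", GLU = "CD",
                HIS = "ND1", ILE = "CD1", LEU = "CD1", LYS = "CD",
                MET = "SD", PHE = "CD1", PRO = "CD", TRP = "CD1",
                TYR = "CD1")

#' Side-chain chi1/chi2 angles of one residue
#'
#' chi1 is the N-CA-CB-(gamma atom) torsion, chi2 the CA-CB-(gamma)-(delta)
#' torsion with the delta atom taken as CD1 for Phe, Trp and Leu. Residues
#' without the required atoms (Gly, Ala, or incomplete side chains) return
#' NA for the undefined angle; missingness is explicit, never reported as 0.
#'
#' @param structure a \linkS4class{Structure}.
#' @param resno author residue number.
#' @param chain chain id (default: the only chain present).
#' @return named numeric vector \code{c(chi1 = , chi2 = )}, degrees, with
#'   NA for undefined angles.
#' @export
chiAngles <- function(structure, resno, chain = NULL) {
  a <- atomData(structure)
  if (is.null(chain)) {
    ch <- unique(a$chain)
    if (length(ch) > 1L) stop("multiple chains present; specify `chain`")
    chain <- ch
  }
  sel <- a$chain == chain & a$resno == resno
  if (!any(sel)) stop("residue ", chain, ":", resno, " not found")
  resname <- a$resname[sel][1L]
  coord <- function(nm) {
    i <- which(sel & a$name == nm)
    if (length(i) != 1L) return(NULL)
    structure@xyz[i, ]
  }
  g <- .CHI1_ATOM[resname]; d <- .CHI2_ATOM[resname]
  out <- c(chi1 = NA_real_, chi2 = NA_real_)
  if (is.na(g)) return(out)
  pN <- coord("N"); pCA <- coord("CA"); pCB <- coord("CB"); pG <- coord(g)
  if (!is.null(pN) && !is.null(pCA) && !is.null(pCB) && !is.null(pG)) {
    out["chi1"] <- dihedral(pN, pCA, pCB, pG)
    if (!is.na(d)) {
      pD <- coord(d)
      if (!is.null(pD)) out["chi2"] <- dihedral(pCA, pCB, pG, pD)
    }
  }
  out
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of \code{mobile} onto \code{ref} over all
#' proper rotations and translations, unweighted by default. Reflections
#' are rejected (determinant forced to +1).
#'
#' @param mobile,ref n x 3 coordinate matrices, n >= 3.
#' @param weights optional non-negative per-point weights.
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (applied as \code{ref ~ mobile \%*\% t(R) + t}), and \code{rmsd} (A).
#' @export
superpose <- function(mobile, ref, weights = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (nrow(mobile) != nrow(ref)) stop("point counts differ")
  if (nrow(mobile) < 3L) stop("superposition needs at least 3 points")
  n <- nrow(mobile)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) stop("invalid weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(ref * w)
  M <- sweep(mobile, 2L, cm); Rf <- sweep(ref, 2L, cr)
  if (max(rowSums(M^2)) < 1e-20 || max(rowSums(Rf^2)) < 1e-20)
    stop("degenerate point spread")
  H <- t(M * w) %*% Rf
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  fitted <- M %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Rf)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

#' Per-frame backbone RMSD of an ensemble against a fixed reference
#'
#' For each frame, the backbone atoms of the given residue window are
#' least-squares superposed on the same atoms of the reference structure
#' and the minimised RMSD is reported. Atoms are matched by
#' (chain, resno, name); hydrogens are never part of the default backbone
#' set.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param ref a \linkS4class{Structure} containing the window.
#' @param resnoRange length-2 residue window (e.g. \code{c(19, 26)} for the
#'   p53N helical region Phe19-Leu26).
#' @param atomNames backbone atom names (default N, CA, C, O).
#' @param chain chain id in the ensemble (default: sole chain).
#' @param refChain chain id in the reference (default: same as chain).
#' @return numeric vector of per-frame RMSD (Angstrom).
#' @export
backboneRMSDSeries <- function(ensemble, ref, resnoRange,
                               atomNames = c("N", "CA", "C", "O"),
                               chain = NULL, refChain = NULL) {
  a <- atomData(ensemble)
  if (is.null(chain)) {
    ch <- unique(a$chain)
    if (length(ch) > 1L) stop("multiple chains in ensemble; specify `chain`")
    chain <- ch
  }
  if (is.null(refChain)) {
    rch <- unique(atomData(ref)$chain)
    refChain <- if (length(rch) == 1L) rch else chain
  }
  sel <- a$chain == chain & a$resno >= resnoRange[1] &
    a$resno <= resnoRange[2] & a$name %in% atomNames
  if (!any(sel)) stop("window matches no atoms in ensemble")
  key <- paste(a$resno[sel], a$name[sel])
  ra <- atomData(ref)
  rsel <- ra$chain == refChain & ra$resno >= resnoRange[1] &
    ra$resno <= resnoRange[2] & ra$name %in% atomNames
  rkey <- paste(ra$resno[rsel], ra$name[rsel])
  ord <- match(key, rkey)
  if (anyNA(ord)) {
    missing <- key[is.na(ord)][1L]
    stop("reference lacks backbone atom (resno name): ", missing)
  }
  refXYZ <- ref@xyz[which(rsel)[ord], , drop = FALSE]
  idx <- which(sel)
  vapply(seq_len(nFrames(ensemble)), function(f) {
    superpose(ensemble@coords[f, idx, , drop = TRUE], refXYZ)$rmsd
  }, numeric(1))
}
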