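## Ideal-geometry peptide builder. Heavy atoms only, fixed standard bond
## lengths/angles (Engh-Huber-like values in one table), requested
## phi/psi/chi torsions reproduced exactly on readback. Geometry only -
## no sterics, no energies.

.AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")

# Place atom D bonded to C given reference atoms A-B-C, bond length |C-D|,
# bond angle B-C-D (deg) and torsion A-B-C-D (deg), such that
# dihedral(A, B, C, D) returns exactly `torsion`.
.placeAtom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Side-chain templates: per residue type, an ordered list of heavy atoms
# with NeRF references and torsion specification. Torsion spec is either a
# fixed number (deg) or list(chi = k, offset = deg) meaning chi_k + offset.
# chi1 = N-CA-CB-G, chi2 = CA-CB-G-D (D = CD1 for Phe/Trp/Leu).
.sc <- function(name, a, b, c, bond, angle, tor)
  list(name = name, refs = c(a, b, c), bond = bond, angle = angle, tor = tor)
.chi <- function(k, offset = 0) list(chi = k, offset = offset)

.SIDECHAINS <- list(
  ALA = list(),
  GLY = NULL,  # no CB at all
  SER = list(.sc("OG", "N", "CA", "CB", 1.417, 110.8, .chi(1))),
  THR = list(.sc("OG1", "N", "CA", "CB", 1.433, 109.6, .chi(1)),
             .sc("CG2", "N", "CA", "CB", 1.521, 110.5, .chi(1, -120))),
  CYS = list(.sc("SG", "N", "CA", "CB", 1.808, 114.4, .chi(1))),
  ASP = list(.sc("CG", "N", "CA", "CB", 1.516, 112.6, .chi(1)),
             .sc("OD1", "CA", "CB", "CG", 1.249, 118.4, .chi(2)),
             .sc("OD2", "CA", "CB", "CG", 1.249, 118.4, .chi(2, 180))),
  ASN = list(.sc("CG", "N", "CA", "CB", 1.516, 112.6, .chi(1)),
             .sc("OD1", "CA", "CB", "CG", 1.231, 120.8, .chi(2)),
             .sc("ND2", "CA", "CB", "CG", 1.328, 116.4, .chi(2, 180))),
  GLU = list(.sc("CG", "N", "CA", "CB", 1.520, 114.1, .chi(1)),
             .sc("CD", "CA", "CB", "CG", 1.516, 112.6, .chi(2)),
             .sc("OE1", "CB", "CG", "CD", 1.249, 118.4, .chi(3)),
             .sc("OE2", "CB", "CG", "CD", 1.249, 118.4, .chi(3, 180))),
  GLN = list(.sc("CG", "N", "CA", "CB", 1.520, 114.1, .chi(1)),
             .sc("CD", "CA", "CB", "CG", 1.516, 112.6, .chi(2)),
             .sc("OE1", "CB", "CG", "CD", 1.231, 120.8, .chi(3)),
             .sc("NE2", "CB", "CG", "CD", 1.328, 116.4, .chi(3, 180))),
  LEU = list(.sc("CG", "N", "CA", "CB", 1.530, 116.3, .chi(1)),
             .sc("CD1", "CA", "CB", "CG", 1.521, 110.7, .chi(2)),
             .sc("CD2", "CA", "CB", "CG", 1.521, 110.7, .chi(2, 122))),
  LYS = list(.sc("CG", "N", "CA", "CB", 1.520, 114.1, .chi(1)),
             .sc("CD", "CA", "CB", "CG", 1.520, 111.3, .chi(2)),
             .sc("CE", "CB", "CG", "CD", 1.520, 111.3, .chi(3)),
             .sc("NZ", "CG", "CD", "CE", 1.489, 111.9, .chi(4))),
  PHE = list(.sc("CG", "N", "CA", "CB", 1.502, 113.8, .chi(1)),
             .sc("CD1", "CA", "CB", "CG", 1.384, 120.7, .chi(2)),
             .sc("CD2", "CA", "CB", "CG", 1.384, 120.7, .chi(2, 180)),
             .sc("CE1", "CB", "CG", "CD1", 1.382, 120.7, 180),
             .sc("CE2", "CB", "CG", "CD2", 1.382, 120.7, 180),
             .sc("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0)),
  TRP = list(.sc("CG", "N", "CA", "CB", 1.498, 113.6, .chi(1)),
             .sc("CD1", "CA", "CB", "CG", 1.365, 126.9, .chi(2)),
             .sc("CD2", "CA", "CB", "CG", 1.433, 126.6, .chi(2, 180)),
             .sc("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
             .sc("CE2", "CG", "CD1", "NE1", 1.370, 109.0, 0),
             .sc("CE3", "CB", "CG", "CD2", 1.398, 133.9, 180),
             .sc("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180),
             .sc("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 180),
             .sc("CH2", "CE3", "CZ3", "CZ2", 1.368, 121.1, 0)),
  PRO = list(.sc("CG", "N", "CA", "CB", 1.492, 104.5, .chi(1)),
             .sc("CD", "CA", "CB", "CG", 1.503, 106.1, .chi(2))),
  VAL = list(.sc("CG1", "N", "CA", "CB", 1.521, 110.5, .chi(1)),
             .sc("CG2", "N", "CA", "CB", 1.521, 110.5, .chi(1, 122))),
  ILE = list(.sc("CG1", "N", "CA", "CB", 1.530, 110.4, .chi(1)),
             .sc("CG2", "N", "CA", "CB", 1.521, 110.5, .chi(1, -122)),
             .sc("CD1", "CA", "CB", "CG1", 1.513, 113.8, .chi(2))),
  MET = list(.sc("CG", "N", "CA", "CB", 1.520, 114.1, .chi(1)),
             .sc("SD", "CA", "CB", "CG", 1.803, 112.7, .chi(2)),
             .sc("CE", "CB", "CG", "SD", 1.791, 100.9, .chi(3))),
  HIS = list(.sc("CG", "N", "CA", "CB", 1.497, 113.8, .chi(1)),
             .sc("ND1", "CA", "CB", "CG", 1.371, 122.7, .chi(2)),
             .sc("CD2", "CA", "CB", "CG", 1.356, 131.1, .chi(2, 180)),
             .sc("CE1", "CB", "CG", "ND1", 1.319, 109.3, 180),
             .sc("NE2", "CG", "ND1", "CE1", 1.374, 111.7, 0)),
  TYR = list(.sc("CG", "N", "CA", "CB", 1.512, 113.9, .chi(1)),
             .sc("CD1", "CA", "CB", "CG", 1.389, 120.8, .chi(2)),
             .sc("CD2", "CA", "CB", "CG", 1.389, 120.8, .chi(2, 180)),
             .sc("CE1", "CB", "CG", "CD1", 1.382, 121.1, 180),
             .sc("CE2", "CB", "CG", "CD2", 1.382, 121.1, 180),
             .sc("CZ", "CG", "CD1", "CE1", 1.378, 119.6, 0),
             .sc("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180)))

# default chi angles per residue type (trans-dominant rotamers)
.DEFAULT_CHI <- list(SER = -65, THR = -60, CYS = -65, ASP = c(-70, -15),
                     ASN = c(-65, -20), GLU = c(-67, 180, -10),
                     GLN = c(-67, 180, -10), LEU = c(-65, 175),
                     LYS = c(-67, 180, 180, 180), PHE = c(-65, 90),
                     TRP = c(-65, 95), PRO = c(28, -35),
                     VAL = 175, ILE = c(-65, 170), MET = c(-65, 180, 75),
                     HIS = c(-65, -70), TYR = c(-65, 90))

.elementOf <- function(name) substr(sub("^[0-9]*", "", name), 1L, 1L)

#' Build a peptide from internal coordinates
#'
#' Constructs an all-heavy-atom peptide with fixed ideal bond lengths and
#' angles, placing atoms by the natural-extension (NeRF) rule so that every
#' requested phi, psi and chi torsion is reproduced exactly when read back
#' with [dihedral()]/[chiAngles()]. The default sequence is the p53
#' transactivation peptide p53N (Glu17-Asn29, ETFSDLWKLLPEN).
#'
#' @param sequence one-letter amino-acid sequence.
#' @param backbone \code{"helix"} (phi -57, psi -47), \code{"extended"}
#'   (phi -120, psi +120), or a data.frame/list with numeric \code{phi} and
#'   \code{psi} vectors (degrees, one per residue; phi of the first and psi
#'   of the last residue are undefined and ignored).
#' @param chi named list: author resno (as character) -> numeric vector of
#'   chi angles (degrees). Unlisted residues get standard rotamer defaults.
#' @param resnoStart author number of the first residue (default 17, the
#'   p53 numbering of Glu17).
#' @param chain chain id (default "A").
#' @return a \linkS4class{Structure}.
#' @examples
#' pep <- buildPeptide("ETFSDLWKLLPEN", backbone = "helix",
#'                     chi = list(`19` = c(177, 71)))
#' chiAngles(pep, 19)  # c(chi1 = 177, chi2 = 71)
#' @export
buildPeptide <- function(sequence = "ETFSDLWKLLPEN", backbone = "helix",
                         chi = list(), resnoStart = 17L, chain = "A") {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (!all(seq1 %in% names(.AA3)))
    stop("unknown residue letter(s): ",
         paste(unique(seq1[!seq1 %in% names(.AA3)]), collapse = ", "))
  n <- length(seq1)
  res3 <- .AA3[seq1]
  if (identical(backbone, "helix")) {
    phi <- rep(-57, n); psi <- rep(-47, n)
  } else if (identical(backbone, "extended")) {
    phi <- rep(-120, n); psi <- rep(120, n)
  } else {
    phi <- as.numeric(backbone$phi); psi <- as.numeric(backbone$psi)
    if (length(phi) != n || length(psi) != n)
      stop("backbone phi/psi must have one value per residue")
  }
  resno <- seq.int(resnoStart, length.out = n)

  # pass 1: backbone N/CA/C chained by psi(i-1), omega = 180, phi(i)
  pos <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1L) {
      ang <- 111.2 * pi / 180
      pos[[i]] <- list(N = c(0, 0, 0), CA = c(1.458, 0, 0),
                       C = c(1.458, 0, 0) + 1.525 * c(-cos(ang), sin(ang), 0))
    } else {
      prev <- pos[[i - 1L]]
      N <- .placeAtom(prev$N, prev$CA, prev$C, 1.329, 116.2, psi[i - 1L])
      CA <- .placeAtom(prev$CA, prev$C, N, 1.458, 121.7, 180)  # trans omega
      C <- .placeAtom(prev$C, N, CA, 1.525, 111.2, phi[i])
      pos[[i]] <- list(N = N, CA = CA, C = C)
    }
  }

  # pass 2: carbonyl O, CB and side chains, emitted residue-major
  names_ <- character(0); resn_ <- character(0); rno_ <- integer(0)
  xyz_ <- matrix(numeric(0), ncol = 3L)
  for (i in seq_len(n)) {
    p <- pos[[i]]
    # carbonyl O: torsion N-CA-C-O = psi(i) + 180
    p$O <- .placeAtom(p$N, p$CA, p$C, 1.231, 120.8, psi[i] + 180)
    # CB by improper torsion C-N-CA-CB (L-configuration)
    if (res3[i] != "GLY")
      p$CB <- .placeAtom(p$C, p$N, p$CA, 1.530, 110.4, 122.6)
    tmpl <- .SIDECHAINS[[res3[i]]]
    chiReq <- chi[[as.character(resno[i])]]
    chiDef <- .DEFAULT_CHI[[res3[i]]]
    chiUse <- if (is.null(chiDef)) numeric(0) else chiDef
    if (!is.null(chiReq)) chiUse[seq_along(chiReq)] <- chiReq
    if (!is.null(tmpl)) {
      for (at in tmpl) {
        tor <- at$tor
        if (is.list(tor)) {
          if (tor$chi > length(chiUse))
            stop("residue ", res3[i], " ", resno[i], ": chi", tor$chi,
                 " required but not specified")
          tor <- chiUse[tor$chi] + tor$offset
        }
        p[[at$name]] <- .placeAtom(p[[at$refs[1]]], p[[at$refs[2]]],
                                   p[[at$refs[3]]], at$bond, at$angle, tor)
      }
    }
    ord <- intersect(c("N", "CA", "C", "O", "CB",
                       vapply(tmpl, `[[`, "", "name")), names(p))
    for (nm in ord) {
      names_ <- c(names_, nm); resn_ <- c(resn_, res3[i])
      rno_ <- c(rno_, resno[i]); xyz_ <- rbind(xyz_, p[[nm]])
    }
  }
  atoms <- data.frame(name = names_, resname = resn_,
                      chain = chain, resno = rno_,
                      element = .elementOf(names_), stringsAsFactors = FALSE)
  Structure(atoms, xyz_)
}
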