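## Shrake-Rupley solvent-accessible surface area. Deterministic Fibonacci
## point lattice (no RNG), NACCESS-style element radii, probe 1.4 A.
## Hydrogens are excluded both as surface atoms and as occluders, the
## NACCESS convention.

#' van der Waals radii used by the SASA engine
#'
#' NACCESS-style element radii (Chothia-type): C 1.87, N 1.65, O 1.40,
#' S 1.85, P 1.80 Angstrom. Atom names resolve through their element
#' symbol; an unknown element is an error naming the atom.
#' @return named numeric vector of radii (Angstrom).
#' @export
vdwRadii <- function() {
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80, H = 1.00)
}

.atomRadii <- function(atoms) {
  r <- vdwRadii()[atoms$element]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1L]
    stop("no van der Waals radius for atom ", atoms$name[bad],
         " (element '", atoms$element[bad], "') in residue ",
         atoms$resname[bad], " ", atoms$resno[bad])
  }
  unname(r)
}

#' Deterministic unit-sphere point lattice
#'
#' Fibonacci (golden-angle) lattice of n nearly uniform points on the unit
#' sphere. Deterministic: the same n always yields the same points.
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Distributes \code{nPoints} test points on each atom's probe-expanded
#' sphere (radius r + probe) and counts points not inside any neighbour's
#' expanded sphere: SASA = exposed fraction x 4 pi (r + probe)^2.
#'
#' @param structure a \linkS4class{Structure}.
#' @param probeRadius solvent probe radius in Angstrom (default 1.4).
#' @param nPoints test points per atom (default 960; >= 60 required).
#' @param includeHydrogens include hydrogens as surface atoms and
#'   occluders (default FALSE, the NACCESS convention).
#' @return numeric vector of per-atom SASA (Angstrom^2) aligned with
#'   \code{atomData(structure)}; hydrogens get NA when excluded.
#' @export
shrakeRupley <- function(structure, probeRadius = 1.4, nPoints = 960L,
                         includeHydrogens = FALSE) {
  if (probeRadius < 0) stop("probe radius must be >= 0")
  if (nPoints < 60L) stop("nPoints must be >= 60")
  atoms <- atomData(structure)
  out <- rep(NA_real_, nrow(atoms))
  use <- if (includeHydrogens) rep(TRUE, nrow(atoms)) else
    atoms$element != "H"
  if (!any(use)) return(out)
  xyz <- structure@xyz[use, , drop = FALSE]
  rad <- .atomRadii(atoms[use, , drop = FALSE]) + probeRadius
  m <- nrow(xyz)
  pts <- fibonacciSphere(as.integer(nPoints))
  sasa <- numeric(m)
  # neighbour lists from squared distances (m is at most a few thousand)
  for (i in seq_len(m)) {
    di2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nbr <- which(di2 < (rad + rad[i])^2 & seq_len(m) != i)
    if (length(nbr) == 0L) {
      sasa[i] <- 4 * pi * rad[i]^2
      next
    }
    P <- pts * rad[i]
    P[, 1] <- P[, 1] + xyz[i, 1]
    P[, 2] <- P[, 2] + xyz[i, 2]
    P[, 3] <- P[, 3] + xyz[i, 3]
    exposed <- rep(TRUE, nPoints)
    # closest neighbours first: they bury the most points
    nbr <- nbr[order(di2[nbr])]
    for (j in nbr) {
      if (!any(exposed)) break
      idx <- which(exposed)
      d2 <- (P[idx, 1] - xyz[j, 1])^2 + (P[idx, 2] - xyz[j, 2])^2 +
        (P[idx, 3] - xyz[j, 3])^2
      exposed[idx[d2 < rad[j]^2]] <- FALSE
    }
    sasa[i] <- sum(exposed) / nPoints * 4 * pi * rad[i]^2
  }
  out[use] <- sasa
  out
}

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Per-residue SASA profile of a structure
#'
#' Sums per-atom Shrake-Rupley SASA within each residue; the side-chain
#' column excludes backbone atoms (N, CA, C, O, OXT).
#'
#' @inheritParams shrakeRupley
#' @param selection optional list passed to [selectAtoms()] (elements
#'   \code{chains}, \code{resnoRange}, \code{atomNames}) restricting which
#'   atoms are profiled; occlusion is still computed in the context of the
#'   full structure.
#' @return data.frame: chain, resno, resname, sasaTotal, sasaSideChain
#'   (Angstrom^2), one row per residue in structure order.
#' @export
residueSASA <- function(structure, selection = NULL, probeRadius = 1.4,
                        nPoints = 960L) {
  atoms <- atomData(structure)
  perAtom <- shrakeRupley(structure, probeRadius = probeRadius,
                          nPoints = nPoints)
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(selection)) {
    if (!is.null(selection$chains))
      keep <- keep & atoms$chain %in% selection$chains
    if (!is.null(selection$resnoRange))
      keep <- keep & atoms$resno >= selection$resnoRange[1] &
        atoms$resno <= selection$resnoRange[2]
    if (!is.null(selection$atomNames))
      keep <- keep & atoms$name %in% selection$atomNames
    if (!any(keep)) {
      warning("empty selection: returning empty SASA profile")
      return(data.frame(chain = character(), resno = integer(),
                        resname = character(), sasaTotal = numeric(),
                        sasaSideChain = numeric()))
    }
  }
  a <- atoms[keep, , drop = FALSE]
  s <- perAtom[keep]
  s[is.na(s)] <- 0  # hydrogens contribute nothing
  key <- paste(a$chain, a$resno)
  first <- !duplicated(key)
  tot <- tapply(s, key, sum)
  side <- tapply(s * !(a$name %in% .BACKBONE), key, sum)
  ord <- key[first]
  data.frame(chain = a$chain[first], resno = a$resno[first],
             resname = a$resname[first],
             sasaTotal = as.numeric(tot[ord]),
             sasaSideChain = as.numeric(side[ord]),
             stringsAsFactors = FALSE)
}

#' SASA of a peptide extracted from its complex
#'
#' Removes everything but the peptide selection from a complex and
#' recomputes per-residue SASA of the remaining peptide in its complexed
#' conformation ("unbound-from-complex" reference).
#'
#' @param complex a \linkS4class{Structure} containing peptide and target.
#' @param peptideChains chain id(s) of the peptide.
#' @param resnoRange optional residue window within the peptide chains.
#' @inheritParams shrakeRupley
#' @return per-residue SASA profile (see [residueSASA()]).
#' @export
unboundSASAFromComplex <- function(complex, peptideChains,
                                   resnoRange = NULL, probeRadius = 1.4,
                                   nPoints = 960L) {
  pep <- selectAtoms(complex, chains = peptideChains,
                     resnoRange = resnoRange)
  if (nAtoms(pep) == nAtoms(complex))
    warning("peptide selection equals the whole complex; nothing removed")
  residueSASA(pep, probeRadius = probeRadius, nPoints = nPoints)
}

#' Per-residue SASA over an ensemble
#'
#' Computes the per-residue SASA profile of every frame and its mean and
#' standard deviation per residue.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param selection optional selection list (see [residueSASA()]).
#' @inheritParams shrakeRupley
#' @return list with \code{summary} (chain, resno, resname, meanTotal,
#'   sdTotal, meanSideChain, sdSideChain) and \code{perFrame} (list of two
#'   frames x residues matrices, \code{total} and \code{sideChain}).
#' @export
ensembleSASA <- function(ensemble, selection = NULL, probeRadius = 1.4,
                         nPoints = 960L) {
  nf <- nFrames(ensemble)
  profiles <- lapply(seq_len(nf), function(f)
    residueSASA(frameStructure(ensemble, f), selection = selection,
                probeRadius = probeRadius, nPoints = nPoints))
  tot <- do.call(rbind, lapply(profiles, `[[`, "sasaTotal"))
  side <- do.call(rbind, lapply(profiles, `[[`, "sasaSideChain"))
  p1 <- profiles[[1L]]
  sdv <- function(m) if (nrow(m) > 1L) apply(m, 2L, stats::sd) else
    rep(0, ncol(m))
  summary <- data.frame(chain = p1$chain, resno = p1$resno,
                        resname = p1$resname,
                        meanTotal = colMeans(tot), sdTotal = sdv(tot),
                        meanSideChain = colMeans(side),
                        sdSideChain = sdv(side),
                        stringsAsFactors = FALSE)
  list(summary = summary, perFrame = list(total = tot, sideChain = side))
}
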