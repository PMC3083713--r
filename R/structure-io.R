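## PDB reading/writing is delegated to bio3d; this layer converts to the
## package's Structure/Ensemble containers and enforces the parsing policy
## (altloc 'A'-or-blank kept, author residue numbering, line-level checks).

.guessElement <- function(name) {
  # PDB v3 atom names: element is the leading alphabetic character(s) after
  # any digits; for standard amino-acid heavy atoms a single letter suffices.
  core <- sub("^[0-9']*", "", name)
  first <- toupper(substr(core, 1L, 1L))
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, first)
}

.prescanPDB <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  if (any(isAtom)) {
    bad <- which(isAtom & nchar(lines) < 54L)
    if (length(bad) == 0L) {
      coordTxt <- substr(lines[isAtom], 31L, 54L)
      xyz <- suppressWarnings(cbind(as.numeric(substr(coordTxt, 1L, 8L)),
                                    as.numeric(substr(coordTxt, 9L, 16L)),
                                    as.numeric(substr(coordTxt, 17L, 24L))))
      badc <- which(!stats::complete.cases(xyz))
      if (length(badc) > 0L) bad <- which(isAtom)[badc[1L]]
    } else {
      bad <- bad[1L]
    }
    if (length(bad) == 1L && !is.na(bad))
      stop("malformed ATOM/HETATM record at line ", bad, " of ", path)
  }
  sum(isAtom)
}

.bio3dToAtoms <- function(atom) {
  element <- atom$elesy
  noEl <- is.na(element) | !nzchar(trimws(element))
  element[noEl] <- .guessElement(atom$elety[noEl])
  chain <- atom$chain
  chain[is.na(chain) | !nzchar(chain)] <- " "
  data.frame(name = atom$elety, resname = atom$resid, chain = chain,
             resno = as.integer(atom$resno), element = trimws(element),
             stringsAsFactors = FALSE)
}

#' Read a PDB coordinate file
#'
#' Parses single- or multi-model PDB files (fixed-column v3). Multi-model
#' files yield an \linkS4class{Ensemble} in MODEL order when
#' \code{modelPolicy = "all"}, otherwise the first model as a
#' \linkS4class{Structure}. Alternate locations other than 'A' or blank are
#' dropped; hydrogens are retained in the structure (downstream SASA and
#' RMSD exclude them by default).
#'
#' @param path path to a PDB file.
#' @param modelPolicy \code{"first"} or \code{"all"}.
#' @param dt optional time per frame in ns, attached to ensembles.
#' @return a \linkS4class{Structure} or \linkS4class{Ensemble}.
#' @export
readPDB <- function(path, modelPolicy = c("first", "all"), dt = numeric(0)) {
  modelPolicy <- match.arg(modelPolicy)
  if (!file.exists(path)) stop("file not found: ", path)
  nAtomLines <- .prescanPDB(path)
  if (nAtomLines == 0L) stop("no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, multi = (modelPolicy == "all"), verbose = FALSE)
  keep <- is.na(pdb$atom$alt) | pdb$atom$alt %in% c("", "A")
  atoms <- .bio3dToAtoms(pdb$atom[keep, , drop = FALSE])
  xyzIdx <- as.vector(rbind(3L * which(keep) - 2L, 3L * which(keep) - 1L,
                            3L * which(keep)))
  if (modelPolicy == "first") {
    xyz <- matrix(pdb$xyz[1L, xyzIdx], ncol = 3L, byrow = TRUE)
    return(Structure(atoms, xyz))
  }
  xyzMat <- pdb$xyz[, xyzIdx, drop = FALSE]
  nf <- nrow(xyzMat)
  coords <- array(NA_real_, dim = c(nf, nrow(atoms), 3L))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyzMat[f, ], ncol = 3L, byrow = TRUE)
  Ensemble(atoms, coords, dt = dt, label = basename(path))
}

#' Write a Structure or Ensemble to a PDB file
#'
#' Emits standard fixed-column PDB; ensembles become MODEL/ENDMDL blocks.
#'
#' @param x a \linkS4class{Structure} or \linkS4class{Ensemble}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(x, path) {
  atoms <- atomData(x)
  if (nrow(atoms) == 0L) stop("cannot write an empty structure")
  if (is(x, "Ensemble")) {
    nf <- nFrames(x)
    xyzMat <- matrix(NA_real_, nrow = nf, ncol = 3L * nAtoms(x))
    for (f in seq_len(nf))
      xyzMat[f, ] <- as.vector(t(x@coords[f, , , drop = TRUE]))
  } else {
    xyzMat <- matrix(as.vector(t(x@xyz)), nrow = 1L)
  }
  if (any(abs(xyzMat) > 9999.999))
    stop("coordinate magnitude exceeds PDB fixed-column field width")
  chain <- atoms$chain
  chain[chain == " "] <- ""
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyzMat, type = "ATOM",
    resno = atoms$resno, resid = atoms$resname, chain = chain,
    elety = atoms$name, elesy = atoms$element,
    eleno = seq_len(nrow(atoms))))
  invisible(path)
}

#' Select atoms by chain, residue range and/or atom name
#'
#' Returns a sub-structure (or sub-ensemble) preserving atom order. An
#' empty result is allowed but warned about; an unknown chain id is an
#' error, since it usually means a mistyped selection.
#'
#' @param x a \linkS4class{Structure} or \linkS4class{Ensemble}.
#' @param chains character vector of chain ids, or NULL for all.
#' @param resnoRange length-2 integer range (author numbering), or NULL.
#' @param atomNames character vector of atom names, or NULL.
#' @param hydrogens keep hydrogens (default TRUE; SASA/RMSD drop them
#'   themselves).
#' @return object of the same class as \code{x}.
#' @export
selectAtoms <- function(x, chains = NULL, resnoRange = NULL,
                        atomNames = NULL, hydrogens = TRUE) {
  atoms <- atomData(x)
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chains)) {
    unknown <- setdiff(chains, unique(atoms$chain))
    if (length(unknown) > 0L)
      stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
    keep <- keep & atoms$chain %in% chains
  }
  if (!is.null(resnoRange)) {
    stopifnot(length(resnoRange) == 2L)
    keep <- keep & atoms$resno >= resnoRange[1] & atoms$resno <= resnoRange[2]
  }
  if (!is.null(atomNames)) keep <- keep & atoms$name %in% atomNames
  if (!hydrogens) keep <- keep & atoms$element != "H"
  if (!any(keep)) warning("selection matches no atoms")
  idx <- which(keep)
  if (is(x, "Ensemble"))
    Ensemble(atoms[idx, , drop = FALSE],
             x@coords[, idx, , drop = FALSE], dt = x@dt, label = x@label)
  else
    Structure(atoms[idx, , drop = FALSE], x@xyz[idx, , drop = FALSE],
              modelId = x@modelId)
}

#' Residue table of a structure
#'
#' One row per residue in atom order: chain, resno, resname.
#' @param x a \linkS4class{Structure} or \linkS4class{Ensemble}.
#' @return data.frame with columns chain, resno, resname.
#' @export
residueTable <- function(x) {
  a <- atomData(x)
  key <- paste(a$chain, a$resno)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             resname = a$resname[first], stringsAsFactors = FALSE)
}
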