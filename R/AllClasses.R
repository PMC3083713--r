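#' @import methods
NULL

#' Single-conformer molecular structure
#'
#' A \code{Structure} holds one conformer: an atom table (names, residue
#' identifiers, chain identifiers, elements) and a matching n x 3 coordinate
#' matrix in Angstrom. Residue numbering is always the author numbering of
#' the source file (p53 numbering 17-29 for the p53N peptide); nothing is
#' re-indexed, and all downstream reports key on (chain, resno).
#'
#' @slot atoms data.frame with columns \code{name} (PDB v3 atom name),
#'   \code{resname} (3-letter residue code), \code{chain} (single character),
#'   \code{resno} (integer author residue number), \code{element} (symbol).
#' @slot xyz numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @slot modelId integer model number (1 for single-model files).
#'
#' @seealso [readPDB()], [selectAtoms()], [buildPeptide()]
#' @export
setClass("Structure",
  representation(atoms = "data.frame", xyz = "matrix", modelId = "integer"),
  prototype(
    atoms = data.frame(name = character(), resname = character(),
                       chain = character(), resno = integer(),
                       element = character(), stringsAsFactors = FALSE),
    xyz = matrix(numeric(), ncol = 3L), modelId = 1L))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("name", "resname", "chain", "resno", "element")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (ncol(object@xyz) != 3L) return("xyz must have 3 columns")
  if (nrow(a) != nrow(object@xyz)) return("atoms and xyz row counts differ")
  if (nrow(a) > 0L) {
    if (any(!is.finite(object@xyz))) return("coordinates must be finite")
    if (any(!nzchar(a$name))) return("atom names must be non-empty")
    key <- paste(a$chain, a$resno, a$name)
    if (anyDuplicated(key))
      return(paste("duplicated (chain, resno, atom name) key:",
                   key[duplicated(key)][1L]))
  }
  TRUE
})

#' Ordered conformational ensemble sharing one topology
#'
#' An \code{Ensemble} is an ordered sequence of conformers of the same
#' molecule: one atom table plus a frames x atoms x 3 coordinate array.
#' An optional time step \code{dt} (ns per frame) attaches a time axis, with
#' frame 1 at t = 0. Ensembles stand in for MD trajectories of the unbound
#' peptide.
#'
#' @slot atoms shared atom table (see \linkS4class{Structure}).
#' @slot coords numeric array, dim = c(nFrames, nAtoms, 3), Angstrom.
#' @slot dt numeric(1) ns per frame, or numeric(0) when no time axis.
#' @slot label free-text ensemble label (e.g. a trajectory name).
#'
#' @seealso [readPDB()] with \code{modelPolicy = "all"}, [sampleEnsemble()]
#' @export
setClass("Ensemble",
  representation(atoms = "data.frame", coords = "array",
                 dt = "numeric", label = "character"),
  prototype(dt = numeric(0), label = NA_character_))

setValidity("Ensemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (d[1] < 1L) return("ensemble must contain at least one frame")
  if (d[2] != nrow(object@atoms))
    return("coords atom dimension does not match atoms table")
  if (any(!is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@dt) > 1L) return("dt must be a single value or empty")
  if (length(object@dt) == 1L && (!is.finite(object@dt) || object@dt <= 0))
    return("dt must be > 0 when present")
  TRUE
})

Structure <- function(atoms, xyz, modelId = 1L) {
  atoms$resno <- as.integer(atoms$resno)
  new("Structure", atoms = atoms,
      xyz = matrix(as.numeric(xyz), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z"))),
      modelId = as.integer(modelId))
}

Ensemble <- function(atoms, coords, dt = numeric(0), label = NA_character_) {
  atoms$resno <- as.integer(atoms$resno)
  new("Ensemble", atoms = atoms, coords = coords, dt = as.numeric(dt),
      label = as.character(label))
}

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      "chains:", paste(sort(unique(a$chain)), collapse = " "), "\n")
  if (nrow(a) > 0L) {
    rng <- range(a$resno)
    cat("  residue numbers", rng[1], "-", rng[2],
        " model", object@modelId, "\n")
  }
  invisible(object)
})

setMethod("show", "Ensemble", function(object) {
  d <- dim(object@coords)
  cat("Ensemble:", d[1], "frames x", d[2], "atoms")
  if (length(object@dt) == 1L) cat(", dt =", object@dt, "ns")
  if (!is.na(object@label)) cat(", label:", object@label)
  cat("\n")
  invisible(object)
})
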