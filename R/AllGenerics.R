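#' Accessors for Structure and Ensemble objects
#'
#' \code{atomData} returns the atom table; \code{getCoords} the coordinates
#' (matrix for a \code{Structure}, frames x atoms x 3 array for an
#' \code{Ensemble}); \code{nAtoms} and \code{nFrames} the obvious counts;
#' \code{frameStructure} extracts one frame of an ensemble as a
#' \code{Structure}; \code{timeStep} the ns-per-frame spacing (or NA).
#'
#' @param x a \linkS4class{Structure} or \linkS4class{Ensemble}.
#' @param i frame index (1-based).
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))
#' @rdname accessors
#' @export
setGeneric("getCoords", function(x) standardGeneric("getCoords"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameStructure", function(x, i) standardGeneric("frameStructure"))
#' @rdname accessors
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))

#' @rdname accessors
#' @export
setMethod("atomData", "Structure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atomData", "Ensemble", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("getCoords", "Structure", function(x) x@xyz)
#' @rdname accessors
#' @export
setMethod("getCoords", "Ensemble", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Ensemble", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("nFrames", "Structure", function(x) 1L)
#' @rdname accessors
#' @export
setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[1])
#' @rdname accessors
#' @export
setMethod("frameStructure", "Ensemble", function(x, i) {
  i <- as.integer(i)
  if (i < 1L || i > nFrames(x))
    stop("frame index ", i, " out of range 1..", nFrames(x))
  Structure(x@atoms, x@coords[i, , , drop = TRUE], modelId = i)
})
#' @rdname accessors
#' @export
setMethod("timeStep", "Ensemble",
          function(x) if (length(x@dt) == 1L) x@dt else NA_real_)

#' Time axis of an ensemble
#'
#' Frame times in ns, with frame 1 at t = 0. Requires a time step.
#' @param x an \linkS4class{Ensemble} with \code{dt} set.
#' @return numeric vector of length \code{nFrames(x)}.
#' @export
frameTimes <- function(x) {
  dt <- timeStep(x)
  if (is.na(dt)) stop("ensemble has no time step (dt)")
  (seq_len(nFrames(x)) - 1L) * dt
}
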