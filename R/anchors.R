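## Anchor-residue classification: a residue is an anchor when it is
## solvent-exposed in the unbound reference and essentially fully buried
## (SASA <= 15 A^2) in the complex.

#' Classify anchor residues from bound and unbound SASA profiles
#'
#' A residue is flagged as an anchor when its bound SASA is at most
#' \code{buriedThreshold} (default 15 Angstrom^2) \emph{and} its unbound
#' SASA is at least \code{exposedThreshold} (default 30 Angstrom^2). The
#' two-sided rule encodes the anchor concept: exposed before binding,
#' deeply buried after. The burial cutoff is the literature value; the
#' exposure cutoff is this package's operationalisation of "exposed to
#' solvent" and is always echoed in the report.
#'
#' @param boundProfile per-residue SASA of the peptide within the complex
#'   (from [residueSASA()] on the complex, restricted to the peptide).
#' @param unboundProfile per-residue SASA of the unbound reference: either
#'   the complex-minus-partner conformation ([unboundSASAFromComplex()])
#'   or an ensemble mean ([ensembleSASA()] summary renamed to
#'   sasaTotal/sasaSideChain).
#' @param buriedThreshold bound-state burial cutoff, Angstrom^2.
#' @param exposedThreshold unbound-state exposure cutoff, Angstrom^2.
#' @param measure \code{"total"} (per-residue all-atom SASA, default) or
#'   \code{"sideChain"}.
#' @return data.frame sorted by decreasing deltaSASA with columns chain,
#'   resno, resname, sasaBound, sasaUnbound, deltaSASA, isAnchor;
#'   thresholds and measure attached as attributes \code{thresholds}.
#' @export
classifyAnchors <- function(boundProfile, unboundProfile,
                            buriedThreshold = 15, exposedThreshold = 30,
                            measure = c("total", "sideChain")) {
  measure <- match.arg(measure)
  col <- if (measure == "total") "sasaTotal" else "sasaSideChain"
  if (!all(c("chain", "resno", col) %in% names(boundProfile)) ||
      !all(c("chain", "resno", col) %in% names(unboundProfile)))
    stop("profiles must have chain, resno and ", col, " columns")
  bk <- paste(boundProfile$chain, boundProfile$resno)
  uk <- paste(unboundProfile$chain, unboundProfile$resno)
  if (!setequal(bk, uk))
    stop("bound and unbound profiles cover different residues: ",
         paste(union(setdiff(bk, uk), setdiff(uk, bk)), collapse = ", "))
  m <- match(bk, uk)
  rep <- data.frame(chain = boundProfile$chain, resno = boundProfile$resno,
                    resname = boundProfile$resname,
                    sasaBound = boundProfile[[col]],
                    sasaUnbound = unboundProfile[[col]][m],
                    stringsAsFactors = FALSE)
  rep$deltaSASA <- rep$sasaUnbound - rep$sasaBound
  rep$isAnchor <- rep$sasaBound <= buriedThreshold &
    rep$sasaUnbound >= exposedThreshold
  rep <- rep[order(-rep$deltaSASA), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "thresholds") <- list(buriedThreshold = buriedThreshold,
                                  exposedThreshold = exposedThreshold,
                                  measure = measure)
  rep
}

#' Anchor residue numbers from an anchor report
#' @param report output of [classifyAnchors()].
#' @return sorted integer vector of anchor residue numbers.
#' @export
anchorResidues <- function(report) sort(report$resno[report$isAnchor])
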