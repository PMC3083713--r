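## Accessors for the packaged reference tables: rotamer-library
## populations of the p53N bound-like conformations, the reference
## unfolding-time table, and the default region/bound-reference
## configuration.

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "IDPAnchor")
  if (!nzchar(path)) stop("packaged data file not found: ", name)
  path
}

#' Rotamer-library reference populations for the p53N anchor residues
#'
#' Backbone-independent rotamer-library populations of the anchor-type and
#' non-anchor bound-like conformations of Phe19, Leu22, Trp23 and Leu26,
#' shipped as packaged data. The "<" qualifier marks an upper bound; its
#' numeric value is used as-is in comparisons.
#'
#' @return data.frame: resno, resname, role, libraryPct, qualifier,
#'   libraryFraction (= libraryPct / 100).
#' @export
rotamerLibraryReference <- function() {
  df <- utils::read.delim(.extdata("rotamer_library_reference.tsv"),
                          comment.char = "#", stringsAsFactors = FALSE)
  df$qualifier[is.na(df$qualifier)] <- ""
  df$libraryFraction <- df$libraryPct / 100
  df
}

#' Reference unfolding-time table for the p53N trajectories
#'
#' Trajectory labels, groups (MDM2-helix, Taz2-helix, disordered),
#' durations and unfolding times (ns) of the reference p53N MD study,
#' shipped as packaged data for the summary worked example.
#'
#' @return data.frame: trajectory, group, durationNs, unfoldingTimeNs.
#' @export
referenceUnfoldingTimes <- function() {
  utils::read.delim(.extdata("p53n_unfolding_times.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Load a region/bound-reference configuration file
#'
#' Reads the YAML schema shipped as
#' \code{inst/extdata/p53n_regions.yaml}: a per-residue map of circular
#' rotamer regions (chi1, optionally chi1 x chi2), a list of bound
#' reference conformations and the global matching tolerance.
#'
#' @param path YAML file path (default: the packaged p53N configuration).
#' @return list with \code{regions} (named list of [regionSet()]s keyed by
#'   resno), \code{boundReferences} (named list of [boundReference()]s
#'   keyed by "resno:complex") and \code{tolerance}.
#' @export
loadRegionConfig <- function(path = .extdata("p53n_regions.yaml")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions)) stop("config has no `regions` block")
  tol <- cfg$tolerance %||% 40
  regions <- lapply(cfg$regions, function(r) {
    labels <- as.character(r$labels)
    chi1 <- do.call(rbind, lapply(labels, function(l) unlist(r$chi1[[l]])))
    if (!is.null(r$chi2)) {
      chi2 <- do.call(rbind, lapply(labels, function(l) unlist(r$chi2[[l]])))
      regionSet(labels, chi1[, 1], chi1[, 2], chi2[, 1], chi2[, 2])
    } else {
      regionSet(labels, chi1[, 1], chi1[, 2])
    }
  })
  refs <- list()
  for (b in cfg$boundReferences %||% list()) {
    br <- boundReference(b$resno, b$complex, b$chi1,
                         b$chi2 %||% NA_real_, tolerance = tol,
                         role = b$role)
    br$synthetic <- isTRUE(b$synthetic)
    refs[[paste0(b$resno, ":", b$complex)]] <- br
  }
  list(regions = regions, boundReferences = refs, tolerance = tol)
}

#' Default p53N region/bound-reference configuration
#' @return see [loadRegionConfig()].
#' @export
defaultRegionConfig <- function() loadRegionConfig()
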