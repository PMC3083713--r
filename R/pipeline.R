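## End-to-end pipeline commands. Each command writes tab-separated result
## files whose first lines echo the package version, a configuration hash
## and every threshold used, so any output can be reproduced from its own
## header. Results go to files; progress goes to stderr.

.pkgVersion <- function() {
  as.character(utils::packageVersion("IDPAnchor"))
}

.writeHeader <- function(con, config) {
  cat(sprintf("# IDPAnchor %s\n", .pkgVersion()), file = con)
  cat(sprintf("# configHash: %s\n", rlang::hash(config)), file = con)
  for (k in sort(names(config))) {
    v <- config[[k]]
    if (is.list(v)) v <- paste(unlist(v), collapse = ",")
    cat(sprintf("# %s: %s\n", k, paste(v, collapse = ",")), file = con)
  }
}

.writeResultTable <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  .writeHeader(con, config)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.msg <- function(...) message("[IDPAnchor] ", ...)

#' Anchor-classification pipeline command
#'
#' Reads a complex PDB, computes per-residue SASA of the peptide within
#' the complex (bound) and of the peptide alone in the same conformation
#' (unbound-from-complex), classifies anchors and writes the report.
#'
#' @param complexPdb path to the complex PDB file.
#' @param peptideChains chain id(s) of the peptide.
#' @param outFile output path for the anchor report (TSV).
#' @param buriedThreshold,exposedThreshold,measure see [classifyAnchors()].
#' @param probeRadius,nPoints see [shrakeRupley()].
#' @return the anchor report data.frame, invisibly.
#' @export
runAnchorAnalysis <- function(complexPdb, peptideChains, outFile,
                              buriedThreshold = 15, exposedThreshold = 30,
                              measure = "total", probeRadius = 1.4,
                              nPoints = 960L) {
  config <- list(command = "anchors", input = complexPdb,
                 peptideChains = peptideChains,
                 buriedThreshold = buriedThreshold,
                 exposedThreshold = exposedThreshold, measure = measure,
                 probeRadius = probeRadius, nPoints = nPoints)
  complex <- readPDB(complexPdb)
  .msg("read ", nAtoms(complex), " atoms from ", complexPdb)
  boundAll <- residueSASA(complex, probeRadius = probeRadius,
                          nPoints = nPoints)
  bound <- boundAll[boundAll$chain %in% peptideChains, , drop = FALSE]
  unbound <- unboundSASAFromComplex(complex, peptideChains,
                                    probeRadius = probeRadius,
                                    nPoints = nPoints)
  rep <- classifyAnchors(bound, unbound, buriedThreshold = buriedThreshold,
                         exposedThreshold = exposedThreshold,
                         measure = measure)
  .writeResultTable(rep, outFile, config)
  .msg("anchors: ", paste(anchorResidues(rep), collapse = ", "))
  invisible(rep)
}

#' Rotamer-population pipeline command
#'
#' Extracts chi series for every residue with a region set in the
#' configuration, classifies frames, and writes region populations plus
#' bound-like populations per bound reference.
#'
#' @param ensemblePdb multi-model PDB of the unbound ensemble.
#' @param outFile output TSV path.
#' @param configFile region/bound-reference YAML
#'   (default: packaged p53N configuration).
#' @param state ensemble-state label recorded in the output
#'   ("helix" or "disordered").
#' @param frames optional integer frame subset (e.g. from
#'   [partitionStates()]).
#' @param dt ns per frame for the ensemble (optional).
#' @return data.frame of populations, invisibly.
#' @export
runPopulationAnalysis <- function(ensemblePdb, outFile,
                                  configFile = NULL,
                                  state = c("helix", "disordered"),
                                  frames = NULL, dt = numeric(0)) {
  state <- match.arg(state)
  cfg <- if (is.null(configFile)) defaultRegionConfig() else
    loadRegionConfig(configFile)
  config <- list(command = "populations", input = ensemblePdb,
                 configFile = configFile %||% "packaged-p53N",
                 state = state, tolerance = cfg$tolerance,
                 frames = if (is.null(frames)) "all" else length(frames))
  ens <- readPDB(ensemblePdb, modelPolicy = "all", dt = dt)
  if (nFrames(ens) < 1L) stop("empty ensemble")
  if (!is.null(frames)) {
    ens <- Ensemble(atomData(ens),
                    ens@coords[frames, , , drop = FALSE], dt = ens@dt,
                    label = ens@label)
  }
  rows <- list()
  for (rn in names(cfg$regions)) {
    chi <- extractChiSeries(ens, as.integer(rn))
    labels <- classifyFrames(chi, cfg$regions[[rn]])
    for (lab in c(cfg$regions[[rn]]$label, "unassigned")) {
      p <- statePopulation(labels, lab)
      rows[[length(rows) + 1L]] <-
        data.frame(resno = as.integer(rn), state = state,
                   target = paste0("region:", lab), role = "",
                   fraction = p$fraction, se = p$se, count = p$count,
                   n = p$n, stringsAsFactors = FALSE)
    }
  }
  for (key in names(cfg$boundReferences)) {
    br <- cfg$boundReferences[[key]]
    chi <- extractChiSeries(ens, br$resno)
    p <- statePopulation(chi, br)
    rows[[length(rows) + 1L]] <-
      data.frame(resno = br$resno, state = state,
                 target = paste0("bound:", br$complexLabel),
                 role = br$role, fraction = p$fraction, se = p$se,
                 count = p$count, n = p$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  .writeResultTable(out, outFile, config)
  invisible(out)
}

#' Joint two-residue population pipeline command
#'
#' Classifies two residues against their region sets and writes the full
#' joint label matrix (including "unassigned") in long format.
#'
#' @inheritParams runPopulationAnalysis
#' @param resnoA,resnoB the two residues (must have region sets).
#' @return the joint matrix, invisibly.
#' @export
runJointAnalysis <- function(ensemblePdb, resnoA, resnoB, outFile,
                             configFile = NULL, frames = NULL) {
  cfg <- if (is.null(configFile)) defaultRegionConfig() else
    loadRegionConfig(configFile)
  config <- list(command = "joint", input = ensemblePdb,
                 resnoA = resnoA, resnoB = resnoB,
                 configFile = configFile %||% "packaged-p53N")
  ens <- readPDB(ensemblePdb, modelPolicy = "all")
  if (!is.null(frames))
    ens <- Ensemble(atomData(ens), ens@coords[frames, , , drop = FALSE],
                    dt = ens@dt, label = ens@label)
  rsA <- cfg$regions[[as.character(resnoA)]]
  rsB <- cfg$regions[[as.character(resnoB)]]
  if (is.null(rsA) || is.null(rsB))
    stop("both residues need region sets in the configuration")
  labA <- classifyFrames(extractChiSeries(ens, resnoA), rsA)
  labB <- classifyFrames(extractChiSeries(ens, resnoB), rsB)
  m <- jointPopulation(labA, labB,
                       labelOrder1 = c(rsA$label, "unassigned"),
                       labelOrder2 = c(rsB$label, "unassigned"))
  long <- expand.grid(labelA = rownames(m), labelB = colnames(m),
                      stringsAsFactors = FALSE)
  long$fraction <- as.vector(m)
  .writeResultTable(long, outFile, config)
  invisible(m)
}

#' Helix-unfolding pipeline command
#'
#' @param ensemblePdb multi-model PDB trajectory of the peptide.
#' @param refPdb reference helix structure PDB.
#' @param outFile output TSV path.
#' @param dt ns per frame (required to report tau in ns).
#' @inheritParams detectUnfolding
#' @return the \code{unfoldingResult}, invisibly.
#' @export
runUnfoldingAnalysis <- function(ensemblePdb, refPdb, outFile, dt,
                                 rmsdThreshold = 2.5,
                                 helixFractionThreshold = 0.25,
                                 dwell = 10L) {
  config <- list(command = "unfold", input = ensemblePdb, ref = refPdb,
                 dt = dt, rmsdThreshold = rmsdThreshold,
                 helixFractionThreshold = helixFractionThreshold,
                 dwell = dwell)
  ens <- readPDB(ensemblePdb, modelPolicy = "all", dt = dt)
  ref <- readPDB(refPdb)
  res <- detectUnfolding(ens, ref, rmsdThreshold = rmsdThreshold,
                         helixFractionThreshold = helixFractionThreshold,
                         dwell = dwell)
  df <- data.frame(frame = seq_along(res$rmsdSeries),
                   timeNs = frameTimes(ens),
                   rmsd = round(res$rmsdSeries, 4),
                   helixFraction = round(res$helixFractionSeries, 4))
  config$unfolded <- res$unfolded
  config$tauNs <- res$tauNs
  .writeResultTable(df, outFile, config)
  .msg(if (res$unfolded) paste0("unfolded at ", res$tauNs, " ns") else
    "not unfolded")
  invisible(res)
}

#' Ensemble-simulation pipeline command
#'
#' Generates a synthetic ensemble from a [generatorSpec()] and writes the
#' multi-model PDB plus the tab-separated ground-truth sidecar
#' (same path with extension .truth.tsv).
#'
#' @param spec a [generatorSpec()].
#' @param outPdb output PDB path.
#' @return list from [sampleEnsemble()], invisibly.
#' @export
runSimulation <- function(spec, outPdb) {
  sim <- sampleEnsemble(spec)
  writePDB(sim$ensemble, outPdb)
  writeGroundTruth(sim$groundTruth,
                   sub("\\.pdb$", ".truth.tsv", outPdb))
  .msg("wrote ", nFrames(sim$ensemble), " frames to ", outPdb)
  invisible(sim)
}
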