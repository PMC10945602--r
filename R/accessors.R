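#' @describeIn chromoMC-generics number of nucleosome cores in a topology.
#' @export
setMethod("nCores", "FiberTopology", function(x) x@nCores)

#' @describeIn chromoMC-generics number of cores in a configuration.
#' @export
setMethod("nCores", "Configuration", function(x) nrow(x@coreXYZ))

#' @describeIn chromoMC-generics total linker-bead count of a topology.
#' @export
setMethod("linkerBeadCount", "FiberTopology", function(x) sum(x@linkerBeads))

#' @describeIn chromoMC-generics TF-bindable flags per linker bead.
#' @export
setMethod("tfBindable", "FiberTopology", function(x) x@tfBindable)

#' @describeIn chromoMC-generics LH occupancy as a density (LH/nucleosome).
#' @export
setMethod("lhDensity", "FiberTopology", function(x) mean(x@lhOccupied))

#' @describeIn chromoMC-generics acetylation flags per core.
#' @export
setMethod("acetylated", "FiberTopology", function(x) x@acetylated)

#' @describeIn chromoMC-generics saved frames of a trajectory.
#' @export
setMethod("frames", "Trajectory", function(x) x@frames)

#' @describeIn chromoMC-generics pooled frames of an ensemble.
#' @export
setMethod("frames", "ChromatinEnsemble", function(x) x@frames)

#' @describeIn chromoMC-generics frame count of a trajectory.
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@frames))

#' @describeIn chromoMC-generics frame count of an ensemble.
#' @export
setMethod("nFrames", "ChromatinEnsemble", function(x) length(x@frames))

#' @describeIn chromoMC-generics frame count of a contact map.
#' @export
setMethod("nFrames", "ContactMap", function(x) x@nFrames)

#' @describeIn chromoMC-generics the topology a trajectory sampled.
#' @export
setMethod("fiberTopology", "Trajectory", function(x) x@topology)

#' @describeIn chromoMC-generics the topology of an ensemble.
#' @export
setMethod("fiberTopology", "ChromatinEnsemble", function(x) x@topology)

#' @describeIn chromoMC-generics raw count matrix (or frequencies with
#'   \code{normalized = TRUE}).
#' @export
setMethod("contactMatrix", "ContactMap", function(x, normalized = FALSE) {
  if (normalized && !x@normalized) return(x@matrix / max(1, x@nFrames))
  x@matrix
})

#' @describeIn chromoMC-generics active restraint pairs of a RestraintSet.
#' @export
setMethod("activeRestraints", "RestraintSet", function(x) x@pairs)

#' Total of an energy breakdown
#' @param x an \linkS4class{EnergyBreakdown}.
#' @return the summed total energy, kcal/mol.
#' @export
energyTotal <- function(x) {
  stopifnot(is(x, "EnergyBreakdown"))
  sum(x@components)
}

#' Components of an energy breakdown
#' @param x an \linkS4class{EnergyBreakdown}.
#' @return named numeric vector (ES..ETF).
#' @export
energyComponents <- function(x) {
  stopifnot(is(x, "EnergyBreakdown"))
  x@components
}

setMethod("show", "FiberTopology", function(object) {
  cat(sprintf("FiberTopology: %d cores, %d linker runs (%d beads)\n",
              object@nCores, length(object@runAfterCore),
              sum(object@linkerBeads)))
  cat(sprintf("  NRL %.0f bp | region %.0f bp | NFR runs: %d\n",
              object@nrlBp, object@regionBp, nrow(object@nfrSpans)))
  cat(sprintf("  LH density %.2f | acetylated cores %d | TF-bindable beads %d\n",
              mean(object@lhOccupied), sum(object@acetylated),
              sum(object@tfBindable)))
})

setMethod("show", "Configuration", function(object) {
  cat(sprintf("Configuration: %d cores, %d linker beads, %d tail beads, %d LH beads\n",
              nrow(object@coreXYZ), nrow(object@linkerXYZ),
              nrow(object@tailXYZ), nrow(object@lhXYZ)))
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat("EnergyBreakdown (kcal/mol):\n")
  print(round(object@components, 4))
  cat(sprintf("  total: %.4f\n", sum(object@components)))
})

setMethod("show", "RestraintSet", function(object) {
  cat(sprintf("RestraintSet: %d active restraint(s), k = %.1f, l0 = %.1f nm\n",
              nrow(object@pairs), object@params@k, object@params@l0))
})

setMethod("show", "Trajectory", function(object) {
  acc <- object@acceptance
  rate <- ifelse(acc[, 1] > 0, acc[, 2] / acc[, 1], NA_real_)
  cat(sprintf("Trajectory: %d frames (%g steps, save every %g), seed %g, twist %+g deg\n",
              length(object@frames), object@nSteps, object@saveEvery,
              object@seed, object@twistOffsetDeg))
  cat("  acceptance:", paste(sprintf("%s %.2f", rownames(acc), rate),
                             collapse = ", "), "\n")
})

setMethod("show", "ChromatinEnsemble", function(object) {
  cat(sprintf("ChromatinEnsemble: %d frames pooled from %d replica(s)\n",
              length(object@frames), length(unique(object@provenance$replica))))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d x %d (%s resolution), %g frames, cutoff %.1f nm\n",
              nrow(object@matrix), ncol(object@matrix), object@resolution,
              object@nFrames, object@cutoffNm))
})

setMethod("show", "MicrodomainSet", function(object) {
  k <- length(setdiff(unique(object@labels), 0L))
  cat(sprintf("MicrodomainSet: %d cluster(s), %d noise nucleosome(s) (eps %.2f, minPoints %d)\n",
              k, sum(object@labels == 0L), object@eps, object@minPoints))
})

setMethod("show", "PromoterGeometry", function(object) {
  cat(sprintf("PromoterGeometry (alpha %.0f): area %.1f +/- %.1f nm^2, volume %.1f +/- %.1f nm^3\n",
              object@alpha, object@areaMean, object@areaSd,
              object@volumeMean, object@volumeSd))
})

#' Number of detected microdomains
#' @param x a \linkS4class{MicrodomainSet}.
#' @return count of clusters (noise excluded).
#' @export
nMicrodomains <- function(x) {
  stopifnot(is(x, "MicrodomainSet"))
  length(setdiff(unique(x@labels), 0L))
}

#' Cluster labels of a microdomain set
#' @param x a \linkS4class{MicrodomainSet}.
#' @return integer label per nucleosome, 0 for noise.
#' @export
microdomainLabels <- function(x) {
  stopifnot(is(x, "MicrodomainSet"))
  x@labels
}
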