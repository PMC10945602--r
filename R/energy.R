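# User-facing energy operations. All terms are evaluated by the same C++
# kernel used by the sampler; these wrappers slice the breakdown.

.restraintSiteMatrix <- function(restraints, model) {
  if (is.null(restraints) || nrow(restraints@pairs) == 0)
    return(matrix(integer(), 0, 2))
  p <- restraints@pairs
  if (any(p < 1L) || any(p > length(model$linkerSites)))
    stop("invalid argument: restraint bead index out of range")
  matrix(model$linkerSites[p], ncol = 2)
}

.energyVector <- function(config, topology, ff, restraints = NULL) {
  model <- .beadModel(topology, ff, config@twistOffsetDeg)
  X <- .flattenConfiguration(config, model)
  rp <- if (is.null(restraints)) restraintParams() else restraints@params
  .cppTotalEnergy(model$cpp, .coordsVector(X), config@twistDeg * pi / 180,
                  config@tailFolded, .restraintSiteMatrix(restraints, model),
                  rp@k, rp@l0)
}

#' Total potential energy with breakdown
#'
#' Evaluates all components of the potential: linker-DNA stretching, bending,
#' and twisting (ES, EB, ET), histone-tail and LH stretching/bending (EtS,
#' EtB, ElhS, ElhB), excluded volume (EV), screened electrostatics (EC), and
#' the TF-restraint term (ETF). The total equals the component sum.
#'
#' @param config a \linkS4class{Configuration}.
#' @param topology the matching \linkS4class{FiberTopology}.
#' @param ff a \linkS4class{ForceField}.
#' @param restraints optional \linkS4class{RestraintSet}.
#' @param ... unused.
#' @return an \linkS4class{EnergyBreakdown} (kcal/mol).
#' @export
setMethod("totalEnergy", "Configuration",
  function(config, topology, ff = defaultForceField(), restraints = NULL, ...) {
    e <- .energyVector(config, topology, ff, restraints)
    new("EnergyBreakdown", components = e[seq_len(10)])
  })

#' Linker-DNA elastic energy
#'
#' Harmonic stretching about the equilibrium bond length, bending about
#' collinearity, and twisting about the registry's equilibrium (the replica's
#' global twist offset). Each term is >= 0 and zero at the reference geometry.
#'
#' @inheritParams totalEnergy,Configuration-method
#' @return named numeric c(ES, EB, ET), kcal/mol.
#' @export
dnaElasticEnergy <- function(config, topology, ff = defaultForceField()) {
  e <- .energyVector(config, topology, ff)
  e[c("ES", "EB", "ET")]
}

#' Histone-tail and LH elastic energy
#'
#' Harmonic stretching/bending of the tail and LH bead chains about their
#' reference geometry. Tails of acetylated cores use the folded reference
#' geometry and constants scaled by the acetylation stiffness multiplier
#' (default 100).
#'
#' @inheritParams totalEnergy,Configuration-method
#' @return named numeric c(EtS, EtB, ElhS, ElhB), kcal/mol.
#' @export
tailLhEnergy <- function(config, topology, ff = defaultForceField()) {
  e <- .energyVector(config, topology, ff)
  e[c("EtS", "EtB", "ElhS", "ElhB")]
}

#' Screened electrostatic energy
#'
#' Pairwise Debye-Hueckel energy q_i q_j exp(-r/lambda_D) / (eps' r) over all
#' non-bonded, non-same-nucleosome charged site pairs, truncated at the
#' interaction cutoff.
#'
#' @inheritParams totalEnergy,Configuration-method
#' @return EC in kcal/mol.
#' @export
electrostaticEnergy <- function(config, topology, ff = defaultForceField()) {
  unname(.energyVector(config, topology, ff)["EC"])
}

#' Excluded-volume energy
#'
#' Purely repulsive shifted-truncated 12-6 potential with per-species
#' effective diameters: zero at and beyond contact, steeply repulsive as beads
#' overlap.
#'
#' @inheritParams totalEnergy,Configuration-method
#' @return EV in kcal/mol.
#' @export
excludedVolumeEnergy <- function(config, topology, ff = defaultForceField()) {
  unname(.energyVector(config, topology, ff)["EV"])
}

#' TF-restraint energy
#'
#' Sum over active restraints of k (l - l0)^2, where l is the distance between
#' the restrained linker beads.
#'
#' @param restraints a \linkS4class{RestraintSet}.
#' @param config a \linkS4class{Configuration}.
#' @param topology the matching \linkS4class{FiberTopology}.
#' @param ff a \linkS4class{ForceField}.
#' @return energy in kcal/mol (0 for an empty set).
#' @export
tfRestraintEnergy <- function(restraints, config, topology,
                              ff = defaultForceField()) {
  if (nrow(restraints@pairs) == 0) return(0)
  model <- .beadModel(topology, ff, config@twistOffsetDeg)
  X <- .flattenConfiguration(config, model)
  sm <- .restraintSiteMatrix(restraints, model)
  d <- sqrt(rowSums((X[sm[, 1], , drop = FALSE] - X[sm[, 2], , drop = FALSE])^2))
  sum(restraints@params@k * (d - restraints@params@l0)^2)
}

#' Update the dynamic restraint set
#'
#' Applies the engagement/release rules: active pairs farther apart than the
#' capture radius are released; unengaged TF-bindable bead pairs within the
#' capture radius and separated by at least the minimum bead separation are
#' engaged, nearest pair first, with at most one restraint per bead (a
#' bivalent heterotetramer bridges exactly two loci). Deterministic given the
#' configuration.
#'
#' @param config a \linkS4class{Configuration}.
#' @param topology the matching \linkS4class{FiberTopology}.
#' @param current the current \linkS4class{RestraintSet}.
#' @param params \linkS4class{RestraintParams} (defaults to those of
#'   \code{current}).
#' @param ff a \linkS4class{ForceField}.
#' @return the updated \linkS4class{RestraintSet}.
#' @export
updateRestraints <- function(config, topology, current = restraintSet(),
                             params = current@params, ff = defaultForceField()) {
  model <- .beadModel(topology, ff, config@twistOffsetDeg)
  X <- .flattenConfiguration(config, model)
  sm <- .restraintSiteMatrix(current, model)
  out <- .cppUpdateRestraints(model$cpp, .coordsVector(X), sm,
                              params@k, params@l0, params@captureRadius,
                              params@minBeadSeparation)
  beadPairs <- matrix(match(out, model$linkerSites), ncol = 2)
  restraintSet(beadPairs, params)
}

#' Metropolis acceptance rule
#'
#' @param deltaE energy change, kcal/mol.
#' @param temperature K.
#' @param rngDraw a uniform draw in [0, 1).
#' @return TRUE iff \code{rngDraw < min(1, exp(-deltaE / kB T))}.
#' @export
metropolisAccept <- function(deltaE, temperature, rngDraw) {
  if (temperature <= 0) stop("temperature must be > 0")
  rngDraw < min(1, exp(-deltaE / .kBT(temperature)))
}
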