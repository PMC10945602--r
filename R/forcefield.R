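# Force-field and restraint-parameter constructors.

#' Default force field
#'
#' Constants for the mesoscale energy model. DNA elasticity follows a combined
#' worm-like chain and bead model at ~9 bp (3.06 nm) per bead: the bending
#' constant derives from a 50 nm persistence length and the twisting constant
#' from a 75 nm torsional persistence length. Charges are effective (salt-
#' renormalized) values on linker DNA (negative), histone tails (positive),
#' LH beads (strongly positive, mimicking the basic C-terminal domain), and
#' the core surface (net negative, spread over \code{nCoreCharges} sites on
#' the core cylinder). Electrostatics are Debye-Hueckel screened Coulomb with
#' the Debye length set by the monovalent salt concentration; excluded volume
#' is a purely repulsive shifted-truncated 12-6 potential, zero at contact.
#'
#' @param ... named overrides for any slot of \linkS4class{ForceField}.
#' @return a \linkS4class{ForceField}.
#' @examples
#' ff <- defaultForceField(monovalentSalt = 0.10)
#' @export
defaultForceField <- function(...) {
  defaults <- list(
    dnaStretchConst = 30,       # kcal/mol/nm^2 (bond-length sd ~0.1 nm)
    dnaBendConst = 4.76,        # 50 nm persistence: Lp*kBT/(2*l0) at 293 K
    dnaTwistConst = 7.14,       # 75 nm torsional persistence
    dnaBondLength = 3.06,       # 9 bp * 0.34 nm/bp
    tailStretchConst = 10,
    tailBendConst = 2,
    lhStretchConst = 10,
    lhBendConst = 2,
    acetylStiffnessMultiplier = 100,
    evStrength = 0.35,
    evDiameterCore = 11,        # matches the 5.5 nm core radius
    evDiameterLinker = 2.4,
    evDiameterTail = 1.8,
    evDiameterLh = 2.2,
    coreCharge = -40,           # total effective core surface charge, e
    linkerBeadCharge = -4,      # effective (salt-renormalized) per 9 bp bead
    tailBeadCharge = 1,
    lhBeadCharges = c(3, 4, 4), # globular head + C-terminal domain beads
    nCoreCharges = 12L,
    dielectric = 80,
    temperature = 293,
    monovalentSalt = 0.15,
    interactionCutoff = 12,
    coreRadius = 5.5,
    coreHalfHeight = 2.75,
    tailsPerCore = 4L,
    tailBeadsPerChain = 3L,
    lhBeadsPerChain = 3L,
    tailBondLength = 1.5,
    foldedTailBondLength = 0.8,
    lhBondLength = 1.8)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(c(defaults, list(zigzagWedgeDeg = 0))))
  unknown <- setdiff(unknown, "zigzagWedgeDeg")
  if (length(unknown))
    stop("unknown force-field parameter(s): ", paste(unknown, collapse = ", "))
  defaults$zigzagWedgeDeg <- 150
  defaults[names(overrides)] <- overrides
  int <- c("nCoreCharges", "tailsPerCore", "tailBeadsPerChain", "lhBeadsPerChain")
  for (k in int) defaults[[k]] <- as.integer(defaults[[k]])
  do.call(new, c(list("ForceField"), defaults))
}

#' Debye screening length
#'
#' @param ff a \linkS4class{ForceField}.
#' @return Debye length in nm (0.304/sqrt(I) for monovalent salt I in mol/L).
#' @export
debyeLength <- function(ff) 0.304 / sqrt(ff@monovalentSalt)

#' TF-restraint parameters
#'
#' Defaults: spring constant 20 kcal/mol/nm^2, rest length 13 nm (the
#' distance between the two DNA duplexes in the bound heterotetramer
#' structure), capture/release radius 20 nm, and a minimum chain separation of
#' 30 linker beads between restrained loci.
#'
#' @param k spring constant, kcal/mol/nm^2.
#' @param l0 rest length, nm.
#' @param captureRadius engagement/release distance, nm.
#' @param minBeadSeparation minimum bead separation along the chain.
#' @return a \linkS4class{RestraintParams}.
#' @export
restraintParams <- function(k = 20, l0 = 13, captureRadius = 20,
                            minBeadSeparation = 30L) {
  new("RestraintParams", k = k, l0 = l0, captureRadius = captureRadius,
      minBeadSeparation = as.integer(minBeadSeparation))
}

#' Construct a restraint set
#'
#' @param pairs m x 2 matrix of linker-bead indices (global chain order).
#' @param params a \linkS4class{RestraintParams}.
#' @return a \linkS4class{RestraintSet}.
#' @export
restraintSet <- function(pairs = matrix(integer(), 0, 2),
                         params = restraintParams()) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0)
    pairs <- t(apply(pairs, 1, sort))
  new("RestraintSet", pairs = pairs, params = params)
}
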