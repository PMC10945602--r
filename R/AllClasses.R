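#' Fiber topology
#'
#' Static description of a chromatin fiber: nucleosome cores, linker-DNA bead
#' runs (~9 bp per bead), nucleosome-free regions (NFRs, represented as
#' extended free-DNA bead runs), linker-histone occupancy, histone-tail
#' acetylation flags, and TF-bindable marks on linker beads.
#'
#' @slot nCores number of nucleosome cores.
#' @slot runAfterCore for each linker run, the index of the core it follows
#'   (0 = run precedes the first core; \code{nCores} = run trails the fiber).
#' @slot linkerBeads beads per linker run.
#' @slot linkerBp DNA length of each run in bp (including NFR extensions).
#' @slot nfrSpans data.frame with columns \code{run} and \code{bp}: runs that
#'   contain an NFR extension and the NFR length merged into them.
#' @slot lhOccupied logical per core: linker histone bound.
#' @slot acetylated logical per core: histone tails acetylated.
#' @slot tfBindable logical per linker bead (chain order): TF can bind.
#' @slot tfRegions data.frame with columns \code{start}, \code{end}
#'   (nucleosome indices) when marks were applied as region patterns.
#' @slot nrlBp nucleosome repeat length in bp.
#' @slot regionBp genomic length of the modeled region in bp.
#' @slot coreBp nCores x 2 matrix of 0-based half-open genomic core footprints.
#' @slot beadBp M x 2 matrix of genomic footprints of linker beads.
#' @export
setClass("FiberTopology",
  representation(
    nCores = "integer",
    runAfterCore = "integer",
    linkerBeads = "integer",
    linkerBp = "numeric",
    nfrSpans = "data.frame",
    lhOccupied = "logical",
    acetylated = "logical",
    tfBindable = "logical",
    tfRegions = "data.frame",
    nrlBp = "numeric",
    regionBp = "numeric",
    coreBp = "matrix",
    beadBp = "matrix"))

setValidity("FiberTopology", function(object) {
  msg <- character()
  n <- object@nCores
  if (length(n) != 1L || is.na(n) || n < 1L)
    msg <- c(msg, "nCores must be a single integer >= 1")
  nRuns <- length(object@runAfterCore)
  if (length(object@linkerBeads) != nRuns || length(object@linkerBp) != nRuns)
    msg <- c(msg, "linkerBeads/linkerBp must match the number of runs")
  if (nRuns > 0 && any(object@linkerBeads < 1L))
    msg <- c(msg, "every linker run must have at least one bead")
  if (n >= 1L) {
    internal <- sort(object@runAfterCore[object@runAfterCore >= 1L &
                                         object@runAfterCore <= n - 1L])
    if (!identical(internal, seq_len(max(0L, n - 1L))))
      msg <- c(msg, "exactly one linker run is required between consecutive cores")
    if (any(object@runAfterCore < 0L) || any(object@runAfterCore > n))
      msg <- c(msg, "runAfterCore out of range")
    if (sum(object@runAfterCore == 0L) > 1L || sum(object@runAfterCore == n) > 1L)
      msg <- c(msg, "at most one terminal run at each fiber end")
  }
  if (length(object@lhOccupied) != n || length(object@acetylated) != n)
    msg <- c(msg, "lhOccupied/acetylated must have one flag per core")
  if (length(object@tfBindable) != sum(object@linkerBeads))
    msg <- c(msg, "tfBindable must have one flag per linker bead")
  if (nrow(object@coreBp) != n)
    msg <- c(msg, "coreBp must have one row per core")
  if (nrow(object@beadBp) != sum(object@linkerBeads))
    msg <- c(msg, "beadBp must have one row per linker bead")
  if (length(msg)) msg else TRUE
})

#' TF binding-pattern specification
#'
#' One of the four enumerated binding-region patterns for a 50-nucleosome
#' fiber, or a custom pattern (regions of consecutive nucleosomes whose linker
#' DNA is marked TF-bindable).
#'
#' @slot patternId 1-4 for the enumerated patterns, NA for custom patterns.
#' @slot regionCount number of binding regions.
#' @slot regionSpan nucleosomes covered by each region.
#' @slot placement one of "evenly", "ends", "middle", "near-ends".
#' @export
setClass("TFTopologySpec",
  representation(patternId = "integer", regionCount = "integer",
                 regionSpan = "integer", placement = "character"))

setValidity("TFTopologySpec", function(object) {
  canonical <- list(
    `1` = list(count = 5L, span = 5L, placement = "evenly"),
    `2` = list(count = 2L, span = 15L, placement = "ends"),
    `3` = list(count = 1L, span = 15L, placement = "middle"),
    `4` = list(count = 2L, span = 5L, placement = "near-ends"))
  msg <- character()
  if (!object@placement %in% c("evenly", "ends", "middle", "near-ends"))
    msg <- c(msg, "unknown placement rule")
  if (!is.na(object@patternId)) {
    if (!object@patternId %in% 1:4) {
      msg <- c(msg, "patternId must be 1, 2, 3, 4, or NA")
    } else {
      ref <- canonical[[as.character(object@patternId)]]
      if (object@regionCount != ref$count || object@regionSpan != ref$span ||
          object@placement != ref$placement)
        msg <- c(msg, "parameters do not match the enumerated pattern")
    }
  }
  if (object@regionCount < 1L || object@regionSpan < 1L)
    msg <- c(msg, "regionCount and regionSpan must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Force-field parameters
#'
#' Energy constants, geometry, and electrostatics of the mesoscale model.
#' Energies are kcal/mol, lengths nm, angles radians internally (degrees at
#' user-facing interfaces), temperature K, salt mol/L. Harmonic terms use the
#' convention E = k (x - x0)^2.
#'
#' @slot dnaStretchConst,dnaBendConst,dnaTwistConst linker-DNA elastic
#'   constants (kcal/mol/nm^2 resp. kcal/mol/rad^2).
#' @slot dnaBondLength equilibrium linker bond length, nm (~9 bp).
#' @slot tailStretchConst,tailBendConst histone-tail chain constants.
#' @slot lhStretchConst,lhBendConst linker-histone chain constants.
#' @slot acetylStiffnessMultiplier multiplier applied to tail constants of
#'   acetylated cores (default 100).
#' @slot evStrength excluded-volume energy scale, kcal/mol.
#' @slot evDiameterCore,evDiameterLinker,evDiameterTail,evDiameterLh effective
#'   bead diameters, nm.
#' @slot coreCharge total core surface charge (e), spread over
#'   \code{nCoreCharges} sites on the core cylinder surface.
#' @slot linkerBeadCharge,tailBeadCharge charge per bead (e).
#' @slot lhBeadCharges charges of the LH bead chain (e).
#' @slot nCoreCharges surface charge sites per core.
#' @slot dielectric relative solvent permittivity.
#' @slot temperature K.
#' @slot monovalentSalt mol/L; sets the Debye length.
#' @slot interactionCutoff nonbonded cutoff, nm.
#' @slot coreRadius nucleosome core radius, nm.
#' @slot coreHalfHeight half-height of the core cylinder, nm.
#' @slot tailsPerCore,tailBeadsPerChain,lhBeadsPerChain chain resolution.
#' @slot tailBondLength,foldedTailBondLength,lhBondLength bond lengths, nm.
#' @slot zigzagWedgeDeg wedge angle of the ideal two-start zigzag used for
#'   initial structures and attachment geometry, degrees.
#' @export
setClass("ForceField",
  representation(
    dnaStretchConst = "numeric", dnaBendConst = "numeric",
    dnaTwistConst = "numeric", dnaBondLength = "numeric",
    tailStretchConst = "numeric", tailBendConst = "numeric",
    lhStretchConst = "numeric", lhBendConst = "numeric",
    acetylStiffnessMultiplier = "numeric",
    evStrength = "numeric",
    evDiameterCore = "numeric", evDiameterLinker = "numeric",
    evDiameterTail = "numeric", evDiameterLh = "numeric",
    coreCharge = "numeric", linkerBeadCharge = "numeric",
    tailBeadCharge = "numeric", lhBeadCharges = "numeric",
    nCoreCharges = "integer",
    dielectric = "numeric", temperature = "numeric",
    monovalentSalt = "numeric", interactionCutoff = "numeric",
    coreRadius = "numeric", coreHalfHeight = "numeric",
    tailsPerCore = "integer", tailBeadsPerChain = "integer",
    lhBeadsPerChain = "integer",
    tailBondLength = "numeric", foldedTailBondLength = "numeric",
    lhBondLength = "numeric", zigzagWedgeDeg = "numeric"))

setValidity("ForceField", function(object) {
  msg <- character()
  stiff <- c(object@dnaStretchConst, object@dnaBendConst, object@dnaTwistConst,
             object@tailStretchConst, object@tailBendConst,
             object@lhStretchConst, object@lhBendConst, object@evStrength)
  if (any(stiff < 0)) msg <- c(msg, "stiffness constants must be >= 0")
  if (object@monovalentSalt <= 0) msg <- c(msg, "monovalentSalt must be > 0")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@acetylStiffnessMultiplier <= 0)
    msg <- c(msg, "acetylStiffnessMultiplier must be > 0")
  if (length(msg)) msg else TRUE
})

#' Harmonic TF-restraint parameters
#'
#' @slot k spring constant, kcal/mol/nm^2 (default 20).
#' @slot l0 rest length, nm (default 13).
#' @slot captureRadius engagement/release distance, nm (default 20).
#' @slot minBeadSeparation minimum separation along the linker-bead chain
#'   (default 30 beads).
#' @export
setClass("RestraintParams",
  representation(k = "numeric", l0 = "numeric", captureRadius = "numeric",
                 minBeadSeparation = "integer"))

setValidity("RestraintParams", function(object) {
  msg <- character()
  if (object@k <= 0) msg <- c(msg, "k must be > 0")
  if (object@l0 >= object@captureRadius)
    msg <- c(msg, "l0 must be smaller than captureRadius")
  if (object@minBeadSeparation < 1L)
    msg <- c(msg, "minBeadSeparation must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Active TF restraints
#'
#' The currently engaged harmonic bead-pair restraints. Pairs index linker
#' beads along the fiber chain (1..M); each bead holds at most one restraint
#' (one bivalent heterotetramer bridges exactly two loci).
#'
#' @slot pairs m x 2 integer matrix of linker-bead indices (i < j per row).
#' @slot params the \linkS4class{RestraintParams} in force.
#' @export
setClass("RestraintSet",
  representation(pairs = "matrix", params = "RestraintParams"))

setValidity("RestraintSet", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (nrow(p) > 0) {
    if (any(p[, 1] >= p[, 2])) return("pairs must satisfy i < j")
    beads <- as.vector(p)
    if (anyDuplicated(beads)) return("a bead may hold at most one restraint")
    if (any(abs(p[, 2] - p[, 1]) < object@params@minBeadSeparation))
      return("pairs violate the minimum bead separation")
  }
  TRUE
})

#' One geometric state of a fiber
#'
#' @slot coreXYZ nCores x 3 core centres, nm.
#' @slot coreFrames 3 x 3 x nCores orthonormal orientation triads (columns are
#'   the body axes in lab coordinates).
#' @slot linkerXYZ,tailXYZ,lhXYZ bead coordinates, nm (model site order).
#' @slot twistDeg per-linker-run twist registry, degrees.
#' @slot twistOffsetDeg the replica's global twist offset (the registry's
#'   equilibrium), degrees.
#' @slot tailFolded logical per core: tails currently in the folded reference
#'   geometry.
#' @export
setClass("Configuration",
  representation(coreXYZ = "matrix", coreFrames = "array",
                 linkerXYZ = "matrix", tailXYZ = "matrix", lhXYZ = "matrix",
                 twistDeg = "numeric", twistOffsetDeg = "numeric",
                 tailFolded = "logical"))

setValidity("Configuration", function(object) {
  msg <- character()
  nC <- nrow(object@coreXYZ)
  d <- dim(object@coreFrames)
  if (length(d) != 3L || d[1] != 3L || d[2] != 3L || d[3] != nC)
    msg <- c(msg, "coreFrames must be a 3 x 3 x nCores array")
  else {
    for (c in seq_len(nC)) {
      F <- object@coreFrames[, , c]
      if (max(abs(crossprod(F) - diag(3))) > 1e-9) {
        msg <- c(msg, "core frames must be orthonormal (1e-9)")
        break
      }
    }
  }
  if (length(object@tailFolded) != nC)
    msg <- c(msg, "tailFolded must have one flag per core")
  if (length(msg)) msg else TRUE
})

#' Energy breakdown
#'
#' Components of the total potential energy: linker-DNA stretching, bending,
#' twisting (ES, EB, ET); histone-tail stretching/bending (EtS, EtB); LH
#' stretching/bending (ElhS, ElhB); excluded volume (EV); screened
#' electrostatics (EC); and the TF-restraint term (ETF). kcal/mol.
#'
#' @slot components named numeric vector of the ten components.
#' @export
setClass("EnergyBreakdown", representation(components = "numeric"))

setValidity("EnergyBreakdown", function(object) {
  nm <- c("ES","EB","ET","EtS","EtB","ElhS","ElhB","EV","EC","ETF")
  if (!identical(names(object@components), nm))
    return("components must be named ES..ETF in canonical order")
  TRUE
})

#' Monte Carlo move set
#'
#' @slot weights named selection weights for the move kinds
#'   \code{pivot}, \code{linker}, \code{core}, \code{lh}, \code{tail}.
#' @slot ampLinkerNm,ampCoreNm,ampLhNm maximum bead/core displacements, nm.
#' @slot rotCoreDeg,pivotDeg maximum rotation amplitudes, degrees.
#' @slot nTrials Rosenbluth trial directions for tail regrowth.
#' @slot refreshEvery full restraint-refresh cadence, steps.
#' @export
setClass("MoveSet",
  representation(weights = "numeric", ampLinkerNm = "numeric",
                 ampCoreNm = "numeric", rotCoreDeg = "numeric",
                 ampLhNm = "numeric", pivotDeg = "numeric",
                 nTrials = "integer", refreshEvery = "numeric"))

setValidity("MoveSet", function(object) {
  nm <- c("pivot", "linker", "core", "lh", "tail")
  if (!identical(names(object@weights), nm))
    return("weights must be named pivot/linker/core/lh/tail")
  if (any(object@weights < 0) || sum(object@weights) <= 0)
    return("weights must be non-negative and not all zero")
  amps <- c(object@ampLinkerNm, object@ampCoreNm, object@ampLhNm,
            object@rotCoreDeg, object@pivotDeg)
  if (any(amps <= 0)) return("move amplitudes must be > 0")
  if (object@nTrials < 1L) return("nTrials must be >= 1")
  TRUE
})

#' Replica plan
#'
#' @slot nReplicas number of independent replicas.
#' @slot nSteps MC steps per replica.
#' @slot saveEvery steps between saved frames.
#' @slot seeds one RNG seed per replica (distinct).
#' @slot twistOffsetsDeg per-replica global twist offsets, cycling through
#'   0, +12, -12 degrees.
#' @export
setClass("ReplicaPlan",
  representation(nReplicas = "integer", nSteps = "numeric",
                 saveEvery = "numeric", seeds = "numeric",
                 twistOffsetsDeg = "numeric"))

setValidity("ReplicaPlan", function(object) {
  msg <- character()
  if (object@nSteps %% object@saveEvery != 0)
    msg <- c(msg, "nSteps must be a multiple of saveEvery")
  if (length(object@seeds) != object@nReplicas)
    msg <- c(msg, "one seed per replica required")
  if (anyDuplicated(object@seeds)) msg <- c(msg, "seeds must be distinct")
  if (length(object@twistOffsetsDeg) != object@nReplicas)
    msg <- c(msg, "one twist offset per replica required")
  if (length(msg)) msg else TRUE
})

#' Saved frames of one replica
#'
#' @slot topology the simulated \linkS4class{FiberTopology}.
#' @slot forceField,restraintParams parameters the replica ran under.
#' @slot initial the starting \linkS4class{Configuration} (frame 0; metadata,
#'   not counted among saved frames).
#' @slot frames list of \linkS4class{Configuration}, ordered by step.
#' @slot restraints list of m x 2 linker-bead-index matrices per frame.
#' @slot energies frame x component matrix (ES..ETF, total).
#' @slot seed,twistOffsetDeg replica metadata.
#' @slot nSteps,saveEvery schedule; frame count = nSteps / saveEvery.
#' @slot acceptance 5 x 2 matrix (tried, accepted) per move kind.
#' @slot events restraint engagement/release log (step, i, j, engaged).
#' @export
setClass("Trajectory",
  representation(topology = "FiberTopology", forceField = "ForceField",
                 restraintParams = "RestraintParams",
                 initial = "Configuration", frames = "list",
                 restraints = "list", energies = "matrix",
                 seed = "numeric", twistOffsetDeg = "numeric",
                 nSteps = "numeric", saveEvery = "numeric",
                 acceptance = "matrix", events = "data.frame"))

setValidity("Trajectory", function(object) {
  msg <- character()
  expected <- object@nSteps / object@saveEvery
  if (length(object@frames) != expected)
    msg <- c(msg, "frame count must equal nSteps / saveEvery")
  if (length(object@restraints) != length(object@frames))
    msg <- c(msg, "one restraint snapshot per frame required")
  if (length(msg)) msg else TRUE
})

#' Pooled analysis ensemble
#'
#' Frames pooled across replicas (typically the final segment of each
#' trajectory), with per-frame provenance.
#'
#' @slot topology the shared \linkS4class{FiberTopology}.
#' @slot forceField force field shared by the pooled replicas.
#' @slot frames list of \linkS4class{Configuration}.
#' @slot restraints list of m x 2 linker-bead-index matrices per frame.
#' @slot provenance data.frame with columns \code{replica}, \code{step},
#'   \code{seed}, \code{twistOffsetDeg}.
#' @export
setClass("ChromatinEnsemble",
  representation(topology = "FiberTopology", forceField = "ForceField",
                 frames = "list", restraints = "list",
                 provenance = "data.frame"))

#' Contact map
#'
#' Symmetric interaction-count matrix at nucleosome or bp resolution. Counts
#' are per-frame binary contacts accumulated over frames; contact frequency is
#' counts normalized by the frame count.
#'
#' @slot matrix symmetric non-negative count matrix.
#' @slot resolution "nucleosome" or "bp".
#' @slot cutoffNm element-to-element surface gap defining a contact (default 2).
#' @slot nFrames frames accumulated.
#' @slot binBp bin width for bp-resolution maps (NA for nucleosome maps).
#' @slot normalized whether \code{matrix} already holds frequencies.
#' @export
setClass("ContactMap",
  representation(matrix = "matrix", resolution = "character",
                 cutoffNm = "numeric", nFrames = "numeric", binBp = "numeric",
                 normalized = "logical"))

setValidity("ContactMap", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("contact matrix must be square")
  if (any(m < 0)) return("contact matrix must be non-negative")
  if (max(abs(m - t(m))) > 1e-9) return("contact matrix must be symmetric")
  TRUE
})

#' Contact-decay profile
#'
#' I(k), the interaction mass at nucleosome offset k, normalized so that the
#' profile sums to one.
#'
#' @slot values I(k) for k = 1..NC-1.
#' @slot normalization the off-diagonal interaction mass used as denominator.
#' @export
setClass("ContactDecay",
  representation(values = "numeric", normalization = "numeric"))

#' DBSCAN microdomain labels
#'
#' @slot labels cluster label per nucleosome (0 = noise).
#' @slot eps DBSCAN search radius on the inverse-frequency distance matrix.
#' @slot minPoints DBSCAN core-point threshold.
#' @export
setClass("MicrodomainSet",
  representation(labels = "integer", eps = "numeric", minPoints = "integer"))

#' Alpha-shape promoter geometry
#'
#' @slot areaMean,areaSd projected (x, y) alpha-shape area, nm^2.
#' @slot volumeMean,volumeSd alpha-shape volume, nm^3.
#' @slot alpha alpha radius, nm.
#' @slot coreIndices nucleosome indices used as vertices.
#' @slot perFrame per-frame area/volume table.
#' @export
setClass("PromoterGeometry",
  representation(areaMean = "numeric", areaSd = "numeric",
                 volumeMean = "numeric", volumeSd = "numeric",
                 alpha = "numeric", coreIndices = "integer",
                 perFrame = "data.frame"))

#' Convergence report
#'
#' Per-frame series of the convergence monitors: total energy, end-to-end
#' distance, sedimentation coefficient, and mean nucleosome triplet angle.
#'
#' @slot series data.frame with columns \code{step}, \code{energy},
#'   \code{endToEnd}, \code{sedimentation}, \code{tripletAngle}.
#' @export
setClass("ConvergenceReport", representation(series = "data.frame"))

#' Validated run configuration
#'
#' @slot system,forcefield,restraints,mc,analysis,output validated sections of
#'   the structured-text run configuration, with defaults applied.
#' @export
setClass("RunConfig",
  representation(system = "list", forcefield = "list", restraints = "list",
                 mc = "list", analysis = "list", output = "list"))
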