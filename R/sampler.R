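# Replica sampling: move-set defaults, replica plans, and the runReplica /
# runEnsemble drivers around the C++ Metropolis kernel.

#' Default Monte Carlo move set
#'
#' Selection weights are proportional to component counts (linker beads,
#' cores, LH beads, tail chains) with a global-pivot probability of 0.2 (0 for
#' single-nucleosome fibers). Amplitudes default to values giving roughly
#' 30-50 percent acceptance on 25-50 nucleosome fibers; all are configurable.
#'
#' @param topology the \linkS4class{FiberTopology} to be sampled.
#' @param ff the \linkS4class{ForceField} in use.
#' @param pivotWeight probability mass of the global pivot move.
#' @param ampLinkerNm,ampCoreNm,ampLhNm maximum displacements, nm.
#' @param rotCoreDeg,pivotDeg maximum rotations, degrees.
#' @param nTrials Rosenbluth trial count for tail regrowth.
#' @param refreshEvery full restraint-refresh cadence, steps.
#' @return a \linkS4class{MoveSet}.
#' @export
defaultMoveSet <- function(topology, ff = defaultForceField(),
                           pivotWeight = 0.2, ampLinkerNm = 0.5,
                           ampCoreNm = 0.6, rotCoreDeg = 12, ampLhNm = 0.6,
                           pivotDeg = 30, nTrials = 8L, refreshEvery = 1000) {
  nLinker <- sum(topology@linkerBeads)
  nLh <- sum(topology@lhOccupied) * ff@lhBeadsPerChain
  nTail <- topology@nCores * ff@tailsPerCore
  counts <- c(linker = nLinker, core = topology@nCores, lh = nLh, tail = nTail)
  local <- counts / sum(counts) * (1 - pivotWeight)
  pv <- if (topology@nCores >= 2 && nLinker > 0) pivotWeight else 0
  w <- c(pivot = pv, local[c("linker", "core", "lh", "tail")])
  names(w) <- c("pivot", "linker", "core", "lh", "tail")
  new("MoveSet", weights = w, ampLinkerNm = ampLinkerNm, ampCoreNm = ampCoreNm,
      rotCoreDeg = rotCoreDeg, ampLhNm = ampLhNm, pivotDeg = pivotDeg,
      nTrials = as.integer(nTrials), refreshEvery = refreshEvery)
}

#' Replica plan
#'
#' Seeds default to \code{seedBase + 0..(n-1)}; twist offsets cycle through
#' 0, +12, -12 degrees across replicas.
#'
#' @param nReplicas number of replicas.
#' @param nSteps MC steps per replica.
#' @param saveEvery steps between saved frames (default 100,000).
#' @param seedBase base RNG seed.
#' @param seeds explicit per-replica seeds (overrides seedBase).
#' @param twistOffsetsDeg explicit per-replica twist offsets.
#' @return a \linkS4class{ReplicaPlan}.
#' @export
replicaPlan <- function(nReplicas, nSteps, saveEvery = 100000, seedBase = 1,
                        seeds = NULL, twistOffsetsDeg = NULL) {
  if (is.null(seeds)) seeds <- seedBase + seq_len(nReplicas) - 1
  if (is.null(twistOffsetsDeg))
    twistOffsetsDeg <- c(0, 12, -12)[(seq_len(nReplicas) - 1) %% 3 + 1]
  new("ReplicaPlan", nReplicas = as.integer(nReplicas), nSteps = nSteps,
      saveEvery = saveEvery, seeds = seeds,
      twistOffsetsDeg = twistOffsetsDeg)
}

#' Run one Monte Carlo replica
#'
#' Executes \code{nSteps} Metropolis move attempts (global pivot, local
#' bead/core moves, LH translations, Rosenbluth tail regrowth), maintains the
#' dynamic TF-restraint set (per-bead updates after accepted moves that
#' displace bindable beads, plus a periodic full refresh), and saves a frame
#' every \code{saveEvery} steps. Runs are bitwise reproducible for a fixed
#' seed. Spatial moves use the full energy in the acceptance rule; the
#' restraint term is part of the total.
#'
#' @param topology a \linkS4class{FiberTopology}.
#' @param ff a \linkS4class{ForceField}.
#' @param rp \linkS4class{RestraintParams}.
#' @param nSteps MC steps (multiple of \code{saveEvery}).
#' @param saveEvery frame cadence in steps.
#' @param seed replica RNG seed.
#' @param twistOffsetDeg global twist offset (0, +12, -12).
#' @param moveSet a \linkS4class{MoveSet}; defaults to
#'   \code{defaultMoveSet(topology, ff)}.
#' @param initial starting \linkS4class{Configuration}; defaults to the ideal
#'   zigzag.
#' @return a \linkS4class{Trajectory}.
#' @export
runReplica <- function(topology, ff = defaultForceField(),
                       rp = restraintParams(), nSteps = 1e6,
                       saveEvery = 1e5, seed = 1, twistOffsetDeg = 0,
                       moveSet = NULL, initial = NULL) {
  if (nSteps %% saveEvery != 0)
    stop("nSteps must be a multiple of saveEvery")
  if (is.null(moveSet)) moveSet <- defaultMoveSet(topology, ff)
  if (is.null(initial))
    initial <- initialConfiguration(topology, ff, twistOffsetDeg)
  model <- .beadModel(topology, ff, twistOffsetDeg)
  X <- .flattenConfiguration(initial, model)
  mc <- list(nSteps = nSteps, saveEvery = saveEvery, seed = seed,
             weights = unname(moveSet@weights),
             ampLinker = moveSet@ampLinkerNm, ampCore = moveSet@ampCoreNm,
             rotCore = moveSet@rotCoreDeg * pi / 180,
             ampLh = moveSet@ampLhNm, ampPivot = moveSet@pivotDeg * pi / 180,
             nTrials = moveSet@nTrials, refreshEvery = moveSet@refreshEvery)
  res <- .cppRunReplica(model$cpp, .coordsVector(X),
                        .framesMatrix(initial@coreFrames),
                        initial@twistDeg * pi / 180, initial@tailFolded,
                        matrix(integer(), 0, 2),
                        c(rp@k, rp@l0, rp@captureRadius, rp@minBeadSeparation),
                        mc)
  nF <- length(res$frameCoords)
  frames <- vector("list", nF)
  restraints <- vector("list", nF)
  for (f in seq_len(nF)) {
    frames[[f]] <- .unflattenConfiguration(res$frameCoords[[f]],
                                           .framesArray(res$frameFrames[[f]]),
                                           model, initial)
    rm <- res$frameRestraints[[f]]
    restraints[[f]] <- if (nrow(rm))
      matrix(match(rm, model$linkerSites), ncol = 2)
    else matrix(integer(), 0, 2)
  }
  energies <- res$frameEnergy
  colnames(energies) <- c("ES","EB","ET","EtS","EtB","ElhS","ElhB","EV","EC",
                          "ETF","total")
  acceptance <- res$acceptance
  dimnames(acceptance) <- list(c("pivot","linker","core","lh","tail"),
                               c("tried", "accepted"))
  events <- res$events
  if (nrow(events)) {
    events$i <- match(events$i, model$linkerSites)
    events$j <- match(events$j, model$linkerSites)
  }
  new("Trajectory", topology = topology, forceField = ff,
      restraintParams = rp, initial = initial, frames = frames,
      restraints = restraints, energies = energies, seed = seed,
      twistOffsetDeg = twistOffsetDeg, nSteps = nSteps, saveEvery = saveEvery,
      acceptance = acceptance, events = events)
}

#' Run an ensemble of independent replicas
#'
#' Each replica gets its own seed and a twist offset cycling through 0, +12,
#' -12 degrees; replicas are independent, so results per replica are
#' identical whether run sequentially or not.
#'
#' @param topology a \linkS4class{FiberTopology}.
#' @param ff a \linkS4class{ForceField}.
#' @param rp \linkS4class{RestraintParams}.
#' @param plan a \linkS4class{ReplicaPlan}.
#' @param moveSet optional shared \linkS4class{MoveSet}.
#' @return list of \linkS4class{Trajectory}, one per replica.
#' @export
runEnsemble <- function(topology, ff = defaultForceField(),
                        rp = restraintParams(), plan, moveSet = NULL) {
  stopifnot(is(plan, "ReplicaPlan"))
  lapply(seq_len(plan@nReplicas), function(i)
    runReplica(topology, ff, rp, nSteps = plan@nSteps,
               saveEvery = plan@saveEvery, seed = plan@seeds[i],
               twistOffsetDeg = plan@twistOffsetsDeg[i], moveSet = moveSet))
}
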