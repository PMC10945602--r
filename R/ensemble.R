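# Ensemble assembly and restraint-occupancy summaries.

#' Pool the tails of replicas into an analysis ensemble
#'
#' Takes the final \code{tailSteps} MC steps of each trajectory (e.g. the last
#' 10,000,000 steps at a save interval of 100,000 gives 100 frames per
#' replica; 10 replicas give a 1000-structure ensemble, 20 replicas 2000) and
#' pools them with per-frame provenance.
#'
#' @param trajectories list of \linkS4class{Trajectory} sharing one topology.
#' @param tailSteps MC steps from the end of each trajectory to keep
#'   (multiple of the save interval).
#' @return a \linkS4class{ChromatinEnsemble}.
#' @export
assembleAnalysisEnsemble <- function(trajectories, tailSteps) {
  stopifnot(length(trajectories) >= 1,
            all(vapply(trajectories, is, logical(1), "Trajectory")))
  frames <- list(); restraints <- list(); prov <- list()
  for (r in seq_along(trajectories)) {
    tr <- trajectories[[r]]
    if (tailSteps %% tr@saveEvery != 0)
      stop("invalid argument: tailSteps must be a multiple of the save interval")
    keep <- tailSteps / tr@saveEvery
    nF <- length(tr@frames)
    if (keep > nF)
      stop("invalid argument: tail longer than the trajectory")
    idx <- seq.int(nF - keep + 1L, nF)
    frames <- c(frames, tr@frames[idx])
    restraints <- c(restraints, tr@restraints[idx])
    prov[[r]] <- data.frame(replica = r, step = idx * tr@saveEvery,
                            seed = tr@seed, twistOffsetDeg = tr@twistOffsetDeg)
  }
  new("ChromatinEnsemble", topology = trajectories[[1]]@topology,
      forceField = trajectories[[1]]@forceField, frames = frames,
      restraints = restraints, provenance = do.call(rbind, prov))
}

#' Realized (effective) TF concentration
#'
#' Per replica: the fraction of TF-bindable linker beads participating in at
#' least one active restraint, averaged over the analysed frames; the
#' ensemble value is the mean over replicas. Captures the difference between
#' nominal bindable marks and restraints that actually engage (e.g. rigid
#' LH-compacted fibers engage far fewer).
#'
#' @param trajectories list of \linkS4class{Trajectory}.
#' @param tailSteps restrict to the final tailSteps of each replica
#'   (default: all saved frames).
#' @return list with \code{ensemblePercent} and \code{replicaPercent}.
#' @export
effectiveTfConcentration <- function(trajectories, tailSteps = NULL) {
  stopifnot(length(trajectories) >= 1)
  nBind <- sum(tfBindable(trajectories[[1]]@topology))
  if (nBind == 0) return(list(ensemblePercent = NA_real_,
                              replicaPercent = rep(NA_real_, length(trajectories))))
  per <- vapply(trajectories, function(tr) {
    idx <- seq_along(tr@frames)
    if (!is.null(tailSteps)) {
      keep <- tailSteps / tr@saveEvery
      idx <- utils::tail(idx, keep)
    }
    engaged <- vapply(tr@restraints[idx], function(p) length(unique(as.vector(p))),
                      numeric(1))
    mean(engaged) / nBind * 100
  }, numeric(1))
  list(ensemblePercent = mean(per), replicaPercent = per)
}

#' Restraint engagement rate
#'
#' Mean fraction of TF-bindable beads engaged in a restraint, over the saved
#' frames of each trajectory.
#'
#' @param trajectories list of \linkS4class{Trajectory}.
#' @return numeric vector, one rate in [0, 1] per trajectory.
#' @export
restraintEngagementRate <- function(trajectories) {
  nBind <- sum(tfBindable(trajectories[[1]]@topology))
  vapply(trajectories, function(tr) {
    if (nBind == 0) return(NA_real_)
    mean(vapply(tr@restraints, function(p)
      length(unique(as.vector(p))) / nBind, numeric(1)))
  }, numeric(1))
}
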