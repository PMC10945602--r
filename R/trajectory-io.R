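# Trajectory store: single-file container per replica with an explicit schema
# version and a payload checksum, so truncated or foreign files raise
# integrity errors instead of being silently mis-read.

.TRAJECTORY_STORE_VERSION <- 1L

.trajectoryChecksum <- function(trajectory) {
  s <- 0
  for (f in trajectory@frames)
    s <- s + sum(f@coreXYZ) + sum(f@linkerXYZ) + sum(f@tailXYZ) + sum(f@lhXYZ)
  signif(s + sum(trajectory@energies), 12)
}

#' Write a trajectory to a single-file store
#'
#' Positions (float64 nm), restraint logs, energies, and replica metadata
#' (seed, twist offset, acceptance) round-trip losslessly.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param path output file.
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  payload <- list(version = .TRAJECTORY_STORE_VERSION,
                  checksum = .trajectoryChecksum(trajectory),
                  trajectory = trajectory)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a trajectory store
#'
#' @param path file written by \code{\link{writeTrajectory}}.
#' @return the stored \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("integrity error: trajectory store unreadable (", conditionMessage(e), ")"))
  if (!is.list(payload) || is.null(payload$version))
    stop("integrity error: not a trajectory store")
  if (!identical(payload$version, .TRAJECTORY_STORE_VERSION))
    stop("unsupported trajectory store version: ", payload$version)
  tr <- payload$trajectory
  if (!identical(.trajectoryChecksum(tr), payload$checksum))
    stop("integrity error: checksum mismatch")
  tr
}

#' Export a configuration as PDB bead records
#'
#' One ATOM record per bead. Chain identifiers separate component classes
#' (C cores, D linker DNA, T tails, L linker histones); the bead class is
#' also encoded in the atom-name field. Intended for coarse visualization.
#'
#' @param config a \linkS4class{Configuration}.
#' @param topology the matching \linkS4class{FiberTopology}.
#' @param path output PDB file.
#' @param ff a \linkS4class{ForceField}.
#' @export
exportPDB <- function(config, topology, path, ff = defaultForceField()) {
  rec <- function(serial, name, chain, resid, xyz) {
    # PDB coordinates are Angstrom-styled; we write nm values directly and
    # note the unit in a REMARK
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.2f%8.2f%8.2f  1.00  0.00",
            serial %% 100000, name, "BEA", chain, resid %% 10000,
            xyz[1], xyz[2], xyz[3])
  }
  lines <- c("REMARK   coarse-grained chromatin beads; coordinates in nm")
  serial <- 0L
  add <- function(xyzs, name, chain) {
    for (i in seq_len(nrow(xyzs))) {
      serial <<- serial + 1L
      lines <<- c(lines, rec(serial, name, chain, i, xyzs[i, ]))
    }
  }
  add(config@coreXYZ, "CORE", "C")
  if (nrow(config@linkerXYZ)) add(config@linkerXYZ, "DNA", "D")
  if (nrow(config@tailXYZ)) add(config@tailXYZ, "TAIL", "T")
  if (nrow(config@lhXYZ)) add(config@lhXYZ, "LH", "L")
  writeLines(c(lines, "END"), path)
  invisible(path)
}
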