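# R-level Monte Carlo move operations. These construct single proposals for
# inspection and testing; the production sampling loop lives in the C++
# kernel behind runReplica() and uses the same geometric rules.

#' Global pivot proposal
#'
#' Chooses a pivot linker bead uniformly at random, determines the fiber end
#' with fewer cores, and rigidly rotates that end about a random axis through
#' the pivot bead (cores, their rigid surface sites, tails, and LH beads all
#' rotate together; intra-segment geometry is preserved exactly).
#'
#' @param config a \linkS4class{Configuration}.
#' @param topology the matching \linkS4class{FiberTopology}.
#' @param amplitudeDeg maximum rotation angle, degrees; the angle is drawn
#'   uniformly in (-amplitude, +amplitude).
#' @param seed RNG seed for pivot bead, axis, and angle.
#' @param ff a \linkS4class{ForceField}.
#' @return the proposed \linkS4class{Configuration}.
#' @export
globalPivot <- function(config, topology, amplitudeDeg = 60, seed = 1,
                        ff = defaultForceField()) {
  if (topology@nCores < 2) stop("pivot requires a fiber with >= 2 cores")
  model <- .beadModel(topology, ff, config@twistOffsetDeg)
  draw <- .withSeed(seed, {
    p <- sample(length(model$linkerSites), 1L)
    axis <- stats::rnorm(3)
    angle <- runif(1, -amplitudeDeg, amplitudeDeg) * pi / 180
    list(p = p, axis = axis / sqrt(sum(axis^2)), angle = angle)
  })
  pivotSite <- model$linkerSites[draw$p]
  X <- .flattenConfiguration(config, model)
  chainPos <- model$cpp$chainPos
  pPos <- chainPos[pivotSite]
  coresBefore <- sum(chainPos[model$coreSite] < pPos)
  moveBefore <- coresBefore <= topology@nCores - coresBefore
  moved <- if (moveBefore) which(chainPos < pPos) else which(chainPos > pPos)
  R <- .rotationAbout(draw$axis, draw$angle)
  piv <- X[pivotSite, ]
  X[moved, ] <- sweep(sweep(X[moved, , drop = FALSE], 2, piv) %*% t(R), 2,
                      piv, `+`)
  framesMat <- .framesMatrix(config@coreFrames)
  for (c in seq_len(topology@nCores)) {
    if (model$coreSite[c] %in% moved) {
      F <- matrix(framesMat[c, ], 3, 3, byrow = TRUE)
      framesMat[c, ] <- as.numeric(t(R %*% F))
    }
  }
  .unflattenConfiguration(X, .framesArray(framesMat), model, config)
}

#' Local move proposal
#'
#' Displaces a single bead (linker, tail, or LH) uniformly inside a sphere of
#' the given amplitude, or applies a random translation/rotation to one core
#' unit (centre, surface sites, attachments, tails, and LH move rigidly; the
#' orientation triad stays orthonormal).
#'
#' @param config a \linkS4class{Configuration}.
#' @param topology the matching \linkS4class{FiberTopology}.
#' @param target list with \code{kind} ("linker", "tail", "lh", or "core")
#'   and \code{index} (bead index within that class, or core index).
#' @param amplitudeNm maximum displacement, nm.
#' @param rotateDeg for core targets: maximum rotation, degrees (0 =
#'   translation only).
#' @param seed RNG seed.
#' @param ff a \linkS4class{ForceField}.
#' @return the proposed \linkS4class{Configuration}.
#' @export
localMove <- function(config, topology, target, amplitudeNm = 1, rotateDeg = 0,
                      seed = 1, ff = defaultForceField()) {
  model <- .beadModel(topology, ff, config@twistOffsetDeg)
  X <- .flattenConfiguration(config, model)
  framesMat <- .framesMatrix(config@coreFrames)
  draw <- .withSeed(seed, {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    r <- runif(1)^(1/3) * amplitudeNm
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, -rotateDeg, rotateDeg) * pi / 180
    list(disp = v * r, axis = ax, angle = th)
  })
  if (target$kind == "core") {
    c <- target$index
    kids <- c(model$coreSite[c], which(model$parent == c))
    kids <- unique(kids)
    if (rotateDeg > 0) {
      R <- .rotationAbout(draw$axis, draw$angle)
      ctr <- X[model$coreSite[c], ]
      X[kids, ] <- sweep(sweep(X[kids, , drop = FALSE], 2, ctr) %*% t(R), 2,
                         ctr, `+`)
      F <- matrix(framesMat[c, ], 3, 3, byrow = TRUE)
      framesMat[c, ] <- as.numeric(t(R %*% F))
    } else {
      X[kids, ] <- sweep(X[kids, , drop = FALSE], 2, draw$disp, `+`)
    }
  } else {
    pool <- switch(target$kind, linker = model$linkerSites,
                   tail = model$tailBeadSites, lh = model$lhBeadSites,
                   stop("unknown move target kind"))
    s <- pool[target$index]
    X[s, ] <- X[s, ] + draw$disp
  }
  .unflattenConfiguration(X, .framesArray(framesMat), model, config)
}

#' Rosenbluth tail-regrowth proposal
#'
#' Rebuilds one histone-tail chain bead by bead, choosing among
#' \code{trialCount} trial directions per bead with Boltzmann weights
#' (configurational-bias Monte Carlo). Bond lengths and bead counts are
#' preserved; the returned log weight ratio log(W_new/W_old) feeds the
#' acceptance rule. With \code{trialCount = 1} the scheme reduces to plain
#' Metropolis on the regrown energy.
#'
#' @param config a \linkS4class{Configuration}.
#' @param topology the matching \linkS4class{FiberTopology}.
#' @param tailId tail-chain index (1-based, core-major order).
#' @param trialCount trial directions per bead (>= 1).
#' @param seed RNG seed.
#' @param ff a \linkS4class{ForceField}.
#' @return list with \code{configuration} (the proposal) and
#'   \code{logWeightRatio}.
#' @export
tailRegrowth <- function(config, topology, tailId, trialCount = 8, seed = 1,
                         ff = defaultForceField()) {
  stopifnot(trialCount >= 1)
  model <- .beadModel(topology, ff, config@twistOffsetDeg)
  X <- .flattenConfiguration(config, model)
  res <- .cppRegrowTail(model$cpp, .coordsVector(X), config@tailFolded,
                        as.integer(tailId), as.integer(trialCount),
                        as.numeric(seed))
  X[res$beadSites + 1L, ] <- res$newPositions  # C++ site indices are 0-based
  list(configuration = .unflattenConfiguration(X, config@coreFrames, model, config),
       logWeightRatio = res$logWeightRatio)
}

#' Tail-state swap move
#'
#' Proposes replacing one core's tail coordinates with the alternative
#' reference geometry (folded vs extended), in the core's current frame, and
#' accepts via the Metropolis rule on the local electrostatic energy change of
#' the swapped tail beads. A double swap returns the original geometry.
#'
#' @param config a \linkS4class{Configuration}.
#' @param topology the matching \linkS4class{FiberTopology}.
#' @param coreId core index.
#' @param seed RNG seed for the acceptance draw.
#' @param ff a \linkS4class{ForceField}.
#' @return the resulting \linkS4class{Configuration}; attribute
#'   \code{"accepted"} records the Metropolis outcome.
#' @export
swapTailState <- function(config, topology, coreId, seed = 1,
                          ff = defaultForceField()) {
  model <- .beadModel(topology, ff, config@twistOffsetDeg)
  X <- .flattenConfiguration(config, model)
  folded <- config@tailFolded
  target <- !folded[coreId]
  sites <- model$tailBeadSites[model$parent[model$tailBeadSites] == coreId]
  F <- config@coreFrames[, , coreId]
  ctr <- config@coreXYZ[coreId, ]
  newPos <- t(vapply(sites, function(s) {
    loc <- if (target) model$tailLocalFolded[[as.character(s)]]
           else model$tailLocalWild[[as.character(s)]]
    ctr + as.numeric(F %*% loc)
  }, numeric(3)))
  # local electrostatic change of the swapped beads (same-core pairs excluded)
  lambda <- debyeLength(ff)
  kc <- 332.0637 / ff@dielectric
  others <- which(model$cpp$interacting &
                  (is.na(model$parent) | model$parent != coreId))
  others <- setdiff(others, sites)
  ecOf <- function(pos, s) {
    d <- sqrt(rowSums(sweep(X[others, , drop = FALSE], 2, pos)^2))
    q <- model$cpp$charge[s] * model$cpp$charge[others]
    keep <- d <= ff@interactionCutoff & d > 1e-9 & q != 0
    sum(kc * q[keep] * exp(-d[keep] / lambda) / d[keep])
  }
  dE <- 0
  for (i in seq_along(sites)) {
    dE <- dE + ecOf(newPos[i, ], sites[i]) - ecOf(X[sites[i], ], sites[i])
  }
  accepted <- .withSeed(seed,
    metropolisAccept(dE, ff@temperature, runif(1)))
  if (accepted) {
    X[sites, ] <- newPos
    folded[coreId] <- target
  }
  out <- .unflattenConfiguration(X, config@coreFrames, model, config)
  out@tailFolded <- folded
  attr(out, "accepted") <- accepted
  out
}
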