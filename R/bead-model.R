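# Flat bead-model construction: converts a FiberTopology + ForceField into the
# site/bond/angle tables consumed by the C++ energy and MC kernels, plus the
# index maps used to convert between Configuration objects and flat coordinate
# arrays.
#
# Site types: 0 linker bead, 1 core centre, 2 core surface charge, 3 tail bead,
# 4 LH bead, 5 attachment point (rigid, non-interacting).

.beadModel <- function(topology, ff, twistOffsetDeg = 0) {
  nC <- topology@nCores
  nRuns <- length(topology@runAfterCore)
  nS <- ff@nCoreCharges
  nt <- ff@tailsPerCore
  nb <- ff@tailBeadsPerChain
  nlh <- ff@lhBeadsPerChain
  Ra <- ff@coreRadius
  hh <- ff@coreHalfHeight
  # two-start zigzag: the wedge rotation alternates sign along the fiber, so
  # entry-attachment locals (and the LH dyad direction) depend on core parity
  wedge <- ff@zigzagWedgeDeg * pi / 180
  aExit <- c(Ra, 0, 0)
  wedgeSign <- function(c) if (c %% 2 == 1) 1 else -1  # run exiting core c
  aEntryFor <- function(c) { # entry local of core c (run exits core c - 1)
    A <- .rotationZ(wedgeSign(c - 1) * wedge)
    as.numeric(-Ra * (t(A) %*% c(1, 0, 0)))
  }

  # surface charge locals: two staggered rings on the core cylinder, kept
  # strictly inside the excluded-volume envelope so no approaching bead can
  # fall into an unscreened point-charge well
  surfLocal <- matrix(0, nS, 3)
  half <- nS %/% 2
  rRing <- 0.75 * Ra
  for (i in seq_len(nS)) {
    ring <- if (i <= half) 0L else 1L
    idxInRing <- if (ring == 0L) i - 1L else i - half - 1L
    nRing <- if (ring == 0L) half else nS - half
    ang <- 2 * pi * idxInRing / max(1L, nRing) + ring * pi / max(1L, nRing)
    z <- if (nS > 1) (if (ring == 0L) -0.5 else 0.5) * hh else 0
    surfLocal[i, ] <- c(rRing * cos(ang), rRing * sin(ang), z)
  }
  # tail attachment directions, kept off the linker entry/exit (+x) sector
  tailDir <- matrix(0, max(1L, nt), 3)
  tailZ <- numeric(max(1L, nt))
  for (t in seq_len(nt)) {
    phi <- (2 * pi * (t - 0.5) / nt) + pi / 2
    tailDir[t, ] <- c(cos(phi), sin(phi), 0)
    tailZ[t] <- 0.8 * hh * (if (t %% 2 == 0) 1 else -1)
  }
  # LH sits on the dyad bisector between the entry and exit linker arms
  bisFor <- function(c) {
    b <- c(1, 0, 0) + aEntryFor(c) / Ra
    b / sqrt(sum(b^2))
  }

  type <- integer(0); parent <- integer(0); group <- integer(0)
  charge <- numeric(0); radius <- numeric(0); interacting <- logical(0)
  bindSite <- logical(0)
  localRows <- list(); rigid <- logical(0)
  coreSite <- integer(nC)
  tailChains <- list(); tailAttachV <- integer(0); tailCoreV <- integer(0)
  lhBeadSites <- integer(0); lhAttachV <- integer(0)
  tailBeadSites <- integer(0)
  exitSite <- integer(nC); entrySite <- integer(nC)
  tailLocalWild <- list(); tailLocalFolded <- list()  # per site row
  lhLocal <- list()

  addSite <- function(ty, par, grp, q, r, inter, loc) {
    type <<- c(type, ty); parent <<- c(parent, par); group <<- c(group, grp)
    charge <<- c(charge, q); radius <<- c(radius, r)
    interacting <<- c(interacting, inter)
    bindSite <<- c(bindSite, FALSE)
    localRows[[length(localRows) + 1L]] <<- if (is.null(loc)) NA else loc
    rigid <<- c(rigid, !is.null(loc))
    length(type)
  }

  qSurf <- ff@coreCharge / nS
  for (c in seq_len(nC)) {
    coreSite[c] <- addSite(1L, c, c, 0, ff@evDiameterCore / 2, TRUE, c(0, 0, 0))
    for (i in seq_len(nS))
      addSite(2L, c, c, qSurf, 0, qSurf != 0, surfLocal[i, ])
    exitSite[c] <- addSite(5L, c, c, 0, 0, FALSE, aExit)
    entrySite[c] <- addSite(5L, c, c, 0, 0, FALSE, aEntryFor(c))
    acet <- topology@acetylated[c]
    for (t in seq_len(nt)) {
      attLoc <- Ra * tailDir[t, ] + c(0, 0, tailZ[t])
      att <- addSite(5L, c, c, 0, 0, FALSE, attLoc)
      beads <- integer(nb)
      for (j in seq_len(nb)) {
        locW <- (Ra + j * ff@tailBondLength) * tailDir[t, ] + c(0, 0, tailZ[t])
        locF <- (Ra + j * ff@foldedTailBondLength) * tailDir[t, ] + c(0, 0, tailZ[t])
        s <- addSite(3L, c, c, ff@tailBeadCharge, ff@evDiameterTail / 2, TRUE, NULL)
        tailLocalWild[[as.character(s)]] <- locW
        tailLocalFolded[[as.character(s)]] <- locF
        beads[j] <- s
        tailBeadSites <- c(tailBeadSites, s)
      }
      tailChains[[length(tailChains) + 1L]] <- beads
      tailAttachV <- c(tailAttachV, att)
      tailCoreV <- c(tailCoreV, c)
    }
    if (topology@lhOccupied[c]) {
      bis <- bisFor(c)
      att <- addSite(5L, c, c, 0, 0, FALSE, Ra * bis)
      qs <- rep_len(ff@lhBeadCharges, nlh)
      for (j in seq_len(nlh)) {
        s <- addSite(4L, c, c, qs[j], ff@evDiameterLh / 2, TRUE, NULL)
        lhLocal[[as.character(s)]] <- (Ra + j * ff@lhBondLength) * bis
        lhBeadSites <- c(lhBeadSites, s)
      }
      lhAttachV <- c(lhAttachV, att)
    }
  }
  lhCores <- which(topology@lhOccupied)

  # linker runs, chain order
  linkerSites <- integer(0)
  runSites <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    k <- topology@linkerBeads[r]
    after <- topology@runAfterCore[r]
    upstream <- if (after == 0L) 1L else after
    downstream <- if (after == nC) nC else after + 1L
    beads <- integer(k)
    for (b in seq_len(k)) {
      grp <- if (b <= ceiling(k / 2)) upstream else downstream
      if (after == 0L) grp <- 1L
      if (after == nC) grp <- nC
      s <- addSite(0L, NA_integer_, grp, ff@linkerBeadCharge,
                   ff@evDiameterLinker / 2, TRUE, NULL)
      beads[b] <- s
    }
    runSites[[r]] <- beads
    linkerSites <- c(linkerSites, beads)
  }
  N <- length(type)
  bindSite[linkerSites] <- topology@tfBindable

  # chain positions along the fiber
  chainPos <- integer(N)
  pos <- 0L
  runIdx <- 1L
  for (c in 0:nC) {
    if (runIdx <= nRuns && topology@runAfterCore[runIdx] == c) {
      for (s in runSites[[runIdx]]) { pos <- pos + 1L; chainPos[s] <- pos }
      runIdx <- runIdx + 1L
    }
    if (c < nC) {
      pos <- pos + 1L
      cs <- coreSite[c + 1L]
      chainPos[cs] <- pos
      kids <- which(parent == c + 1L)
      chainPos[kids] <- pos
    }
  }
  linkerIndex <- rep(NA_integer_, N)
  linkerIndex[linkerSites] <- seq_along(linkerSites)

  # ---- bonds and angles ----
  bI <- integer(0); bJ <- integer(0); bCls <- integer(0); bCore <- integer(0)
  bK <- numeric(0); bL0 <- numeric(0); bL0f <- numeric(0)
  addBond <- function(i, j, cls, k, l0, l0f = l0, core = NA_integer_) {
    bI <<- c(bI, i); bJ <<- c(bJ, j); bCls <<- c(bCls, cls)
    bK <<- c(bK, k); bL0 <<- c(bL0, l0); bL0f <<- c(bL0f, l0f)
    bCore <<- c(bCore, core)
  }
  aI <- integer(0); aJ <- integer(0); aK <- integer(0); aCls <- integer(0)
  aG <- numeric(0); aTh0 <- numeric(0)
  addAngle <- function(i, j, k, cls, g, th0 = 0) {
    aI <<- c(aI, i); aJ <<- c(aJ, j); aK <<- c(aK, k); aCls <<- c(aCls, cls)
    aG <<- c(aG, g); aTh0 <<- c(aTh0, th0)
  }

  for (r in seq_len(nRuns)) {
    after <- topology@runAfterCore[r]
    beads <- runSites[[r]]
    path <- c(if (after >= 1L) exitSite[after],
              beads,
              if (after <= nC - 1L) entrySite[after + 1L])
    for (i in seq_len(length(path) - 1L))
      addBond(path[i], path[i + 1L], 0L, ff@dnaStretchConst, ff@dnaBondLength)
    if (length(path) >= 3L)
      for (i in 2:(length(path) - 1L))
        if (path[i] %in% beads)
          addAngle(path[i - 1L], path[i], path[i + 1L], 0L, ff@dnaBendConst)
  }
  for (tc in seq_along(tailChains)) {
    c <- tailCoreV[tc]
    mult <- if (topology@acetylated[c]) ff@acetylStiffnessMultiplier else 1
    path <- c(tailAttachV[tc], tailChains[[tc]])
    for (i in seq_len(length(path) - 1L))
      addBond(path[i], path[i + 1L], 1L, ff@tailStretchConst * mult,
              ff@tailBondLength, ff@foldedTailBondLength, core = c)
    if (length(path) >= 3L)
      for (i in 2:(length(path) - 1L))
        addAngle(path[i - 1L], path[i], path[i + 1L], 1L, ff@tailBendConst * mult)
  }
  if (length(lhCores)) {
    for (li in seq_along(lhCores)) {
      beads <- lhBeadSites[((li - 1L) * nlh + 1L):(li * nlh)]
      path <- c(lhAttachV[li], beads)
      for (i in seq_len(length(path) - 1L))
        addBond(path[i], path[i + 1L], 2L, ff@lhStretchConst, ff@lhBondLength)
      if (length(path) >= 3L)
        for (i in 2:(length(path) - 1L))
          addAngle(path[i - 1L], path[i], path[i + 1L], 2L, ff@lhBendConst)
    }
  }

  localMat <- matrix(NA_real_, N, 3)
  for (s in seq_len(N))
    if (length(localRows[[s]]) == 3L) localMat[s, ] <- localRows[[s]]

  cpp <- list(
    nSites = N, nCores = nC, nRuns = nRuns,
    type = as.integer(type), parent = as.integer(parent),
    group = as.integer(group), chainPos = as.integer(chainPos),
    linkerIndex = as.integer(linkerIndex),
    charge = charge, radius = radius,
    interacting = interacting, bindable = bindSite,
    bonds = list(i = bI, j = bJ, cls = bCls, core = bCore,
                 k = bK, l0 = bL0, l0folded = bL0f),
    angles = list(i = aI, j = aJ, k = aK, cls = aCls, g = aG, theta0 = aTh0),
    coreSite = coreSite,
    tails = tailChains, tailAttach = tailAttachV, tailCore = tailCoreV,
    twistS = ff@dnaTwistConst,
    twistEq = rep(twistOffsetDeg * pi / 180, nRuns),
    kev = ff@evStrength, kc = 332.0637 / ff@dielectric,
    debyeLength = debyeLength(ff), rcut = ff@interactionCutoff,
    kBT = .kBT(ff@temperature))

  list(cpp = cpp, nSites = N, nCores = nC, nRuns = nRuns,
       coreSite = coreSite, exitSite = exitSite, entrySite = entrySite,
       linkerSites = linkerSites, runSites = runSites,
       tailBeadSites = tailBeadSites, lhBeadSites = lhBeadSites,
       tailChains = tailChains, tailAttach = tailAttachV, tailCore = tailCoreV,
       lhAttach = lhAttachV, lhCores = lhCores,
       local = localMat, rigid = rigid, parent = parent, type = type,
       group = group,
       tailLocalWild = tailLocalWild, tailLocalFolded = tailLocalFolded,
       lhLocal = lhLocal,
       twistOffsetDeg = twistOffsetDeg, ff = ff)
}

# Configuration -> flat N x 3 coordinate matrix (site order)
.flattenConfiguration <- function(config, model) {
  N <- model$nSites
  X <- matrix(0, N, 3)
  X[model$coreSite, ] <- config@coreXYZ
  for (c in seq_len(model$nCores)) {
    F <- config@coreFrames[, , c]
    kids <- which(model$parent == c & model$rigid)
    kids <- setdiff(kids, model$coreSite[c])
    for (s in kids)
      X[s, ] <- config@coreXYZ[c, ] + as.numeric(F %*% model$local[s, ])
  }
  if (length(model$linkerSites)) X[model$linkerSites, ] <- config@linkerXYZ
  if (length(model$tailBeadSites)) X[model$tailBeadSites, ] <- config@tailXYZ
  if (length(model$lhBeadSites)) X[model$lhBeadSites, ] <- config@lhXYZ
  X
}

.unflattenConfiguration <- function(X, coreFrames, model, template) {
  new("Configuration",
      coreXYZ = X[model$coreSite, , drop = FALSE],
      coreFrames = coreFrames,
      linkerXYZ = X[model$linkerSites, , drop = FALSE],
      tailXYZ = X[model$tailBeadSites, , drop = FALSE],
      lhXYZ = X[model$lhBeadSites, , drop = FALSE],
      twistDeg = template@twistDeg,
      twistOffsetDeg = template@twistOffsetDeg,
      tailFolded = template@tailFolded)
}

# row-major flattening used at the C++ boundary
.coordsVector <- function(X) as.numeric(t(X))
.framesMatrix <- function(coreFrames) {
  nC <- dim(coreFrames)[3]
  out <- matrix(0, nC, 9)
  for (c in seq_len(nC)) out[c, ] <- as.numeric(t(coreFrames[, , c]))
  out
}
.framesArray <- function(framesMat) {
  nC <- nrow(framesMat)
  arr <- array(0, c(3, 3, nC))
  for (c in seq_len(nC)) arr[, , c] <- matrix(framesMat[c, ], 3, 3, byrow = TRUE)
  arr
}

#' Initial ideal-zigzag configuration
#'
#' Builds the starting structure for a topology: cores propagated along an
#' ideal two-start zigzag (wedge angle from the force field), straight linker
#' bead runs at the equilibrium bond length, tails and LH chains at their
#' reference geometry. All bonded energies are exactly zero in this structure.
#' The replica's global twist offset rotates each successive core frame about
#' the preceding linker axis, giving twist-offset replicas distinct folds.
#'
#' @param topology a \linkS4class{FiberTopology}.
#' @param ff a \linkS4class{ForceField}.
#' @param twistOffsetDeg global twist offset in degrees (0, +12, -12).
#' @return a \linkS4class{Configuration}.
#' @export
initialConfiguration <- function(topology, ff = defaultForceField(),
                                 twistOffsetDeg = 0) {
  model <- .beadModel(topology, ff, twistOffsetDeg)
  nC <- topology@nCores
  nRuns <- length(topology@runAfterCore)
  l0 <- ff@dnaBondLength
  Ra <- ff@coreRadius
  wedge <- ff@zigzagWedgeDeg * pi / 180
  wedgeFor <- function(c) .rotationZ((if (c %% 2 == 1) 1 else -1) * wedge)
  offRad <- twistOffsetDeg * pi / 180

  coreXYZ <- matrix(0, nC, 3)
  coreFrames <- array(0, c(3, 3, nC))
  coreFrames[, , 1] <- diag(3)
  linkerXYZ <- matrix(0, length(model$linkerSites), 3)
  runAfter <- topology@runAfterCore

  rowOf <- function(sites) match(sites, model$linkerSites)
  aEntry <- model$local[model$entrySite[1], ]

  # leading free-DNA run (enters core 1)
  lead <- which(runAfter == 0L)
  if (length(lead)) {
    beads <- model$runSites[[lead]]
    entry <- coreXYZ[1, ] + as.numeric(coreFrames[, , 1] %*% aEntry)
    u <- as.numeric(coreFrames[, , 1] %*% aEntry); u <- u / sqrt(sum(u^2))
    k <- length(beads)
    for (j in seq_len(k))
      linkerXYZ[rowOf(beads[j]), ] <- entry + (k - j + 1L) * l0 * u
  }
  for (c in seq_len(nC - 1L)) {
    Fc <- coreFrames[, , c]
    d <- as.numeric(Fc %*% c(1, 0, 0))
    run <- which(runAfter == c)
    beads <- model$runSites[[run]]
    k <- length(beads)
    exitP <- coreXYZ[c, ] + Ra * d
    for (j in seq_len(k))
      linkerXYZ[rowOf(beads[j]), ] <- exitP + j * l0 * d
    entryP <- exitP + (k + 1L) * l0 * d
    Fn <- .rotationAbout(d, offRad) %*% Fc %*% wedgeFor(c)
    coreFrames[, , c + 1L] <- Fn
    coreXYZ[c + 1L, ] <- entryP - as.numeric(Fn %*%
      model$local[model$entrySite[c + 1L], ])
  }
  trail <- which(runAfter == nC)
  if (length(trail)) {
    Fc <- coreFrames[, , nC]
    d <- as.numeric(Fc %*% c(1, 0, 0))
    beads <- model$runSites[[trail]]
    exitP <- coreXYZ[nC, ] + Ra * d
    for (j in seq_along(beads))
      linkerXYZ[rowOf(beads[j]), ] <- exitP + j * l0 * d
  }

  tailXYZ <- matrix(0, length(model$tailBeadSites), 3)
  folded <- topology@acetylated
  for (i in seq_along(model$tailBeadSites)) {
    s <- model$tailBeadSites[i]
    c <- model$parent[s]
    loc <- if (folded[c]) model$tailLocalFolded[[as.character(s)]]
           else model$tailLocalWild[[as.character(s)]]
    tailXYZ[i, ] <- coreXYZ[c, ] + as.numeric(coreFrames[, , c] %*% loc)
  }
  lhXYZ <- matrix(0, length(model$lhBeadSites), 3)
  for (i in seq_along(model$lhBeadSites)) {
    s <- model$lhBeadSites[i]
    c <- model$parent[s]
    lhXYZ[i, ] <- coreXYZ[c, ] +
      as.numeric(coreFrames[, , c] %*% model$lhLocal[[as.character(s)]])
  }
  new("Configuration", coreXYZ = coreXYZ, coreFrames = coreFrames,
      linkerXYZ = linkerXYZ, tailXYZ = tailXYZ, lhXYZ = lhXYZ,
      twistDeg = rep(twistOffsetDeg, nRuns),
      twistOffsetDeg = twistOffsetDeg, tailFolded = folded)
}
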