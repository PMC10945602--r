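# Gene-locus fiber builder: tiles a genomic region with nucleosomes around
# nucleosome-free regions (NFRs), draws linker lengths from a distribution,
# and annotates LH occupancy and TF-bindable beads from genomic tracks.

.validateIntervals <- function(iv, regionBp, what) {
  if (!nrow(iv)) return(invisible())
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (any(iv[, 1] < 0) || any(iv[, 2] > regionBp))
    stop("invalid argument: ", what, " track outside [0, region)")
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
    stop("invalid argument: overlapping ", what, " intervals")
  invisible()
}

.overlaps <- function(s, e, iv) {
  if (!nrow(iv)) return(FALSE)
  any(iv[, 1] < e & iv[, 2] > s)
}

#' Build a gene-locus fiber from genomic tracks
#'
#' NFR intervals become runs of free linker-DNA beads with no nucleosome; the
#' remaining sequence is tiled with cores whose count derives from the
#' nucleosome repeat length (or is pinned via \code{targetCores}); linker
#' lengths are drawn from the given distribution and rescaled so each
#' inter-NFR segment is filled exactly; LH and TF flags are set on cores and
#' beads whose genomic footprint overlaps the respective track.
#'
#' @param regionBp region length, bp (coordinates are region-relative,
#'   0-based half-open).
#' @param nfrTrack NFR intervals: a \code{GRanges} track or 2-column matrix.
#' @param nrlBp nucleosome repeat length, bp (> 147).
#' @param linkerDistribution named fractions per linker bp class.
#' @param lhTrack LH ChIP-like intervals, or a numeric density (random,
#'   seeded placement).
#' @param tfTrack TF-binding intervals (or NULL).
#' @param seed RNG seed for linker draws (and LH placement in density mode).
#' @param targetCores pin the core count (e.g. 129) instead of deriving it
#'   from the NRL.
#' @return a \linkS4class{FiberTopology} with genomic footprints.
#' @export
buildGeneFiber <- function(regionBp, nfrTrack, nrlBp,
                           linkerDistribution = mESCLinkerDistribution(),
                           lhTrack = 0, tfTrack = NULL, seed = 1,
                           targetCores = NULL) {
  if (nrlBp <= 147) stop("invalid argument: nrlBp must exceed 147")
  if (abs(sum(linkerDistribution) - 1) > 1e-9)
    stop("invalid argument: linker distribution fractions must sum to 1")
  nfr <- .trackIntervals(nfrTrack)
  nfr <- nfr[order(nfr[, 1]), , drop = FALSE]
  .validateIntervals(nfr, regionBp, "NFR")
  tfIv <- .trackIntervals(tfTrack)
  if (nrow(tfIv)) {
    tfIv[, 2] <- pmin(tfIv[, 2], regionBp)  # clip at the region end
    .validateIntervals(tfIv, regionBp, "TF")
  }
  lhIsTrack <- !(is.numeric(lhTrack) && length(lhTrack) == 1L)
  lhIv <- if (lhIsTrack) .trackIntervals(lhTrack) else matrix(numeric(), 0, 2)
  if (nrow(lhIv)) {
    if (any(lhIv[, 1] < 0) || any(lhIv[, 2] > regionBp))
      stop("invalid argument: LH track outside [0, region)")
  }

  # complement of the NFRs: segments to tile with nucleosomes
  bounds <- c(0, as.vector(t(nfr)), regionBp)
  segs <- matrix(bounds, ncol = 2, byrow = TRUE)
  segs <- segs[segs[, 2] > segs[, 1], , drop = FALSE]
  segLen <- segs[, 2] - segs[, 1]
  totalL <- sum(segLen)
  nCores <- if (is.null(targetCores)) as.integer(round(totalL / nrlBp))
            else as.integer(targetCores)
  if (nCores < 1) stop("invalid argument: region too short for one nucleosome")

  # largest-remainder allocation of cores to segments, capacity-capped
  quota <- segLen * nCores / totalL
  m <- floor(quota)
  rem <- nCores - sum(m)
  if (rem > 0) {
    ord <- order(quota - m, decreasing = TRUE)
    m[ord[seq_len(rem)]] <- m[ord[seq_len(rem)]] + 1
  }
  cap <- pmax(0, floor((segLen + 9) / (147 + 9)))
  over <- which(m > cap)
  while (length(over)) {
    excess <- sum(m[over] - cap[over])
    m[over] <- cap[over]
    slack <- which(m < cap)
    if (!length(slack) && excess > 0)
      stop("invalid argument: cores do not fit between the NFRs")
    ord <- slack[order(segLen[slack], decreasing = TRUE)]
    i <- 1
    while (excess > 0) {
      s <- ord[(i - 1) %% length(ord) + 1]
      if (m[s] < cap[s]) { m[s] <- m[s] + 1; excess <- excess - 1 }
      i <- i + 1
    }
    over <- which(m > cap)
  }
  if (sum(m) != nCores) stop("internal error: core allocation mismatch")

  # per-segment linker lengths (drawn, then rescaled to fill the segment) and
  # free-DNA padding for segments with < 2 cores
  bps <- as.numeric(names(linkerDistribution))
  segLinkers <- vector("list", length(segLen))
  prePad <- numeric(length(segLen))
  postPad <- numeric(length(segLen))
  .withSeed(seed, {
    for (s in seq_along(segLen)) {
      if (m[s] == 0) { prePad[s] <- segLen[s]; next }
      free <- segLen[s] - 147 * m[s]
      if (m[s] == 1) {
        prePad[s] <- floor(free / 2); postPad[s] <- free - prePad[s]
        next
      }
      nl <- m[s] - 1
      draw <- bps[sample.int(length(bps), nl, replace = TRUE,
                             prob = linkerDistribution)]
      l <- pmax(9, round(draw * free / sum(draw)))
      drift <- free - sum(l)
      # absorb rounding drift, keeping every linker >= 9 bp
      i <- 1
      while (drift != 0) {
        step <- sign(drift)
        if (l[i] + step >= 9) { l[i] <- l[i] + step; drift <- drift - step }
        i <- i %% nl + 1
      }
      segLinkers[[s]] <- l
    }
  })

  # assemble runs in genomic order; inter-segment runs merge padding + NFR bp
  runAfter <- integer(0); runBp <- numeric(0); nfrOfRun <- numeric(0)
  coreCount <- 0L
  pendingBp <- 0; pendingNfr <- 0
  nfrIdx <- 1
  for (s in seq_along(segLen)) {
    pendingBp <- pendingBp + prePad[s]
    if (m[s] > 0) {
      for (c in seq_len(m[s])) {
        if (coreCount > 0L || pendingBp > 0) {
          runAfter <- c(runAfter, coreCount)
          runBp <- c(runBp, pendingBp)
          nfrOfRun <- c(nfrOfRun, pendingNfr)
        }
        pendingBp <- 0; pendingNfr <- 0
        coreCount <- coreCount + 1L
        if (c < m[s]) pendingBp <- segLinkers[[s]][c]
      }
      pendingBp <- pendingBp + postPad[s]
    }
    if (s < length(segLen)) { # the NFR between segment s and s+1
      w <- nfr[nfrIdx, 2] - nfr[nfrIdx, 1]
      pendingBp <- pendingBp + w
      pendingNfr <- pendingNfr + w
      nfrIdx <- nfrIdx + 1
    }
  }
  if (pendingBp > 0) {
    runAfter <- c(runAfter, coreCount)
    runBp <- c(runBp, pendingBp)
    nfrOfRun <- c(nfrOfRun, pendingNfr)
  }
  # runs between consecutive cores are mandatory even at zero drawn bp
  stopifnot(coreCount == nCores)

  beads <- vapply(runBp, .linkerBeadsFor, integer(1))
  nfrSpans <- data.frame(run = which(nfrOfRun > 0), bp = nfrOfRun[nfrOfRun > 0])
  topo <- .newTopology(nCores, runAfter, beads, runBp, nfrSpans = nfrSpans,
                       nrlBp = nrlBp)

  # annotate from tracks via genomic footprints
  if (lhIsTrack) {
    occ <- vapply(seq_len(nCores), function(c)
      .overlaps(topo@coreBp[c, 1], topo@coreBp[c, 2], lhIv), logical(1))
    topo@lhOccupied <- occ
  } else if (lhTrack > 0) {
    topo <- placeLinkerHistones(topo, lhTrack, mode = "random", seed = seed + 1)
  }
  if (nrow(tfIv)) {
    marks <- vapply(seq_len(sum(beads)), function(b)
      .overlaps(topo@beadBp[b, 1], topo@beadBp[b, 2], tfIv), logical(1))
    topo@tfBindable <- marks
  }
  validObject(topo)
  topo
}
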