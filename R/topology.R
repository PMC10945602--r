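# Fiber topology builders: uniform, life-like, and annotation operations.
# Linker DNA is discretized at ~9 bp per bead: beads = round(bp / 9), min 1.

.DNA_BP_PER_BEAD <- 9

.emptyNfr <- function() data.frame(run = integer(), bp = numeric())

# construct a FiberTopology; runs are canonicalized to chain order and genomic
# footprints (0-based half-open) are derived by walking the chain
.newTopology <- function(nCores, runAfterCore, linkerBeads, linkerBp,
                         nfrSpans = .emptyNfr(), lhOccupied = NULL,
                         acetylated = NULL, tfBindable = NULL,
                         tfRegions = NULL, nrlBp = NA_real_,
                         coreBp = NULL, beadBp = NULL, regionBp = NULL) {
  ord <- order(runAfterCore)
  runAfterCore <- as.integer(runAfterCore[ord])
  linkerBeads <- as.integer(linkerBeads[ord])
  linkerBp <- as.numeric(linkerBp[ord])
  if (nrow(nfrSpans) > 0)
    nfrSpans$run <- match(nfrSpans$run, ord)
  nCores <- as.integer(nCores)
  M <- sum(linkerBeads)
  if (is.null(lhOccupied)) lhOccupied <- rep(FALSE, nCores)
  if (is.null(acetylated)) acetylated <- rep(FALSE, nCores)
  if (is.null(tfBindable)) tfBindable <- rep(FALSE, M)
  if (is.null(tfRegions))
    tfRegions <- data.frame(start = integer(), end = integer())
  if (is.null(coreBp) || is.null(beadBp)) {
    coreBp <- matrix(0, nCores, 2)
    beadBp <- matrix(0, max(1L, M), 2)[seq_len(M), , drop = FALSE]
    pos <- 0
    runIdx <- 1L
    beadIdx <- 1L
    nRuns <- length(runAfterCore)
    for (c in 0:nCores) {
      if (runIdx <= nRuns && runAfterCore[runIdx] == c) {
        nb <- linkerBeads[runIdx]
        per <- linkerBp[runIdx] / nb
        for (b in seq_len(nb)) {
          beadBp[beadIdx, ] <- c(pos, pos + per)
          pos <- pos + per
          beadIdx <- beadIdx + 1L
        }
        runIdx <- runIdx + 1L
      }
      if (c < nCores) {
        coreBp[c + 1L, ] <- c(pos, pos + 147)
        pos <- pos + 147
      }
    }
    if (is.null(regionBp)) regionBp <- pos
  }
  if (is.null(regionBp)) regionBp <- max(coreBp[, 2], if (M) beadBp[, 2] else 0)
  new("FiberTopology", nCores = nCores, runAfterCore = runAfterCore,
      linkerBeads = linkerBeads, linkerBp = linkerBp, nfrSpans = nfrSpans,
      lhOccupied = lhOccupied, acetylated = acetylated,
      tfBindable = tfBindable, tfRegions = tfRegions, nrlBp = as.numeric(nrlBp),
      regionBp = as.numeric(regionBp), coreBp = coreBp, beadBp = beadBp)
}

# first bead index (chain order) of each run
.runBeadOffsets <- function(topology) {
  c(0L, cumsum(topology@linkerBeads))[seq_along(topology@linkerBeads)]
}

.linkerBeadsFor <- function(bp) max(1L, as.integer(round(bp / .DNA_BP_PER_BEAD)))

#' Build a uniform fiber
#'
#' A fiber of \code{nCores} nucleosomes with identical linker-DNA lengths.
#' Each linker is discretized to \code{round(linkerBp / 9)} beads (minimum 1).
#' The result carries no LH, no acetylation, and no TF marks.
#'
#' @param nCores number of nucleosomes (>= 1).
#' @param linkerBp linker DNA length in bp (e.g. 26, 44, 62).
#' @param nrlBp optional nucleosome repeat length annotation; defaults to
#'   \code{147 + linkerBp}.
#' @return a \linkS4class{FiberTopology}.
#' @examples
#' fib <- buildUniformFiber(50, 26)
#' nCores(fib)
#' @export
buildUniformFiber <- function(nCores, linkerBp, nrlBp = 147 + linkerBp) {
  if (length(nCores) != 1L || !is.finite(nCores) || nCores < 1)
    stop("invalid argument: nCores must be a positive integer")
  if (length(linkerBp) != 1L || !is.finite(linkerBp) || linkerBp <= 0)
    stop("invalid argument: linkerBp must be positive")
  nCores <- as.integer(nCores)
  nRuns <- nCores - 1L
  nb <- .linkerBeadsFor(linkerBp)
  .newTopology(nCores,
               runAfterCore = seq_len(nRuns),
               linkerBeads = rep(nb, nRuns),
               linkerBp = rep(as.numeric(linkerBp), nRuns),
               nrlBp = nrlBp)
}

#' Linker-length distribution of mouse embryonic stem cells
#'
#' Fractions per linker-length class used for life-like fibers:
#' 30\% 26 bp, 17\% 35 bp, 15\% 44 bp, 13\% 53 bp, 9\% 62 bp, 7\% 70 bp,
#' 9\% 80 bp.
#'
#' @return named numeric vector of fractions (names are bp values).
#' @export
mESCLinkerDistribution <- function() {
  c(`26` = 0.30, `35` = 0.17, `44` = 0.15, `53` = 0.13,
    `62` = 0.09, `70` = 0.07, `80` = 0.09)
}

#' Build a life-like fiber
#'
#' Linker lengths are drawn per linker from a discrete distribution of bp
#' classes (default: the mESC distribution), reproducibly for a given seed.
#'
#' @param nCores number of nucleosomes.
#' @param linkerDistribution named numeric vector of fractions; names are
#'   linker lengths in bp. Must sum to 1 (tolerance 1e-9).
#' @param seed RNG seed for the per-linker draws.
#' @param nrlBp optional NRL annotation; defaults to 147 + mean linker.
#' @return a \linkS4class{FiberTopology}.
#' @export
buildLifelikeFiber <- function(nCores, linkerDistribution = mESCLinkerDistribution(),
                               seed, nrlBp = NULL) {
  if (abs(sum(linkerDistribution) - 1) > 1e-9)
    stop("invalid argument: linker distribution fractions must sum to 1")
  if (is.null(names(linkerDistribution)))
    stop("invalid argument: linker distribution must be named by bp")
  nCores <- as.integer(nCores)
  if (nCores < 1L) stop("invalid argument: nCores must be >= 1")
  bps <- as.numeric(names(linkerDistribution))
  nRuns <- nCores - 1L
  draws <- if (nRuns > 0)
    .withSeed(seed, bps[sample.int(length(bps), nRuns, replace = TRUE,
                                   prob = linkerDistribution)])
  else numeric()
  if (is.null(nrlBp)) nrlBp <- 147 + sum(bps * linkerDistribution)
  .newTopology(nCores,
               runAfterCore = seq_len(nRuns),
               linkerBeads = vapply(draws, .linkerBeadsFor, integer(1)),
               linkerBp = draws,
               nrlBp = nrlBp)
}

#' TF binding-pattern specification
#'
#' The four enumerated patterns for 50-nucleosome fibers are: pattern 1 —
#' five equally distributed regions of 5 consecutive nucleosomes; pattern 2 —
#' two regions of 15 nucleosomes at the fiber ends; pattern 3 — one region of
#' 15 nucleosomes in the middle; pattern 4 — two regions of 5 nucleosomes near
#' the ends. Custom patterns pass \code{patternId = NA} with explicit
#' parameters.
#'
#' @param patternId 1-4, or NA for a custom pattern.
#' @param regionCount,regionSpan,placement required for custom patterns.
#' @return a \linkS4class{TFTopologySpec}.
#' @export
tfTopologySpec <- function(patternId = NA, regionCount = NULL,
                           regionSpan = NULL, placement = NULL) {
  canonical <- list(
    `1` = list(count = 5L, span = 5L, placement = "evenly"),
    `2` = list(count = 2L, span = 15L, placement = "ends"),
    `3` = list(count = 1L, span = 15L, placement = "middle"),
    `4` = list(count = 2L, span = 5L, placement = "near-ends"))
  if (!is.na(patternId)) {
    ref <- canonical[[as.character(as.integer(patternId))]]
    if (is.null(ref)) stop("invalid argument: patternId must be 1..4 or NA")
    regionCount <- ref$count; regionSpan <- ref$span; placement <- ref$placement
  }
  new("TFTopologySpec", patternId = as.integer(patternId),
      regionCount = as.integer(regionCount), regionSpan = as.integer(regionSpan),
      placement = placement)
}

# nucleosome regions (start, end inclusive) implied by a TFTopologySpec
.tfRegions <- function(spec, nCores) {
  count <- spec@regionCount; span <- spec@regionSpan
  n <- nCores
  starts <- switch(spec@placement,
    evenly = {
      block <- n / count
      vapply(seq_len(count), function(i)
        as.integer(round((i - 0.5) * block - span / 2)) + 1L, integer(1))
    },
    ends = c(1L, n - span + 1L),
    middle = as.integer(floor((n - span) / 2)) + 1L,
    `near-ends` = {
      gap <- as.integer(round(n * 0.1))
      c(gap + 1L, n - gap - span + 1L)
    })
  regions <- data.frame(start = starts, end = starts + span - 1L)
  if (any(regions$start < 1L) || any(regions$end > n) ||
      nrow(regions) > 1 && any(diff(regions$start) <= span))
    stop("invalid argument: TF pattern does not fit the fiber length")
  regions
}

#' Mark TF-bindable linker DNA by binding-region pattern
#'
#' Sets \code{tfBindable} to TRUE exactly on linker beads whose run connects
#' consecutive nucleosomes inside a binding region; all other beads are FALSE.
#'
#' @param topology a \linkS4class{FiberTopology}.
#' @param spec a \linkS4class{TFTopologySpec}.
#' @return the annotated topology.
#' @export
applyTfTopology <- function(topology, spec) {
  stopifnot(is(topology, "FiberTopology"), is(spec, "TFTopologySpec"))
  regions <- .tfRegions(spec, topology@nCores)
  marks <- rep(FALSE, sum(topology@linkerBeads))
  offsets <- .runBeadOffsets(topology)
  for (r in seq_len(nrow(regions))) {
    runs <- which(topology@runAfterCore >= regions$start[r] &
                  topology@runAfterCore <= regions$end[r] - 1L)
    for (run in runs)
      marks[offsets[run] + seq_len(topology@linkerBeads[run])] <- TRUE
  }
  topology@tfBindable <- marks
  topology@tfRegions <- regions
  validObject(topology)
  topology
}

#' Mark TF-bindable linker beads at a bulk concentration
#'
#' Marks \code{floor(percent/100 * M)} of the M linker beads, chosen uniformly
#' at random with the given seed. Sampling is nested: for a fixed seed, the
#' marked set at a lower percentage is a subset of the set at a higher one.
#'
#' @param topology a \linkS4class{FiberTopology}.
#' @param percent TF concentration, 0-100 (percentage of linker beads).
#' @param seed RNG seed.
#' @return the annotated topology.
#' @export
setTfConcentration <- function(topology, percent, seed = 1) {
  stopifnot(is(topology, "FiberTopology"))
  if (!is.finite(percent) || percent < 0 || percent > 100)
    stop("invalid argument: percent must be in [0, 100]")
  M <- sum(topology@linkerBeads)
  nMark <- as.integer(floor(percent / 100 * M))
  perm <- .withSeed(seed, sample.int(M))
  marks <- rep(FALSE, M)
  if (nMark > 0) marks[perm[seq_len(nMark)]] <- TRUE
  topology@tfBindable <- marks
  topology@tfRegions <- data.frame(start = integer(), end = integer())
  topology
}

#' Place linker histones
#'
#' Flags \code{floor(density * nCores)} cores as LH-occupied. Placement is
#' uniform (evenly spaced), random (seeded), or explicit (a list of core
#' indices).
#'
#' @param topology a \linkS4class{FiberTopology}.
#' @param density LH per nucleosome, 0-1. Ignored in explicit mode.
#' @param mode "uniform", "random", or "explicit".
#' @param positions core indices for explicit mode.
#' @param seed RNG seed for random mode.
#' @return the annotated topology.
#' @export
placeLinkerHistones <- function(topology, density,
                                mode = c("uniform", "random", "explicit"),
                                positions = NULL, seed = 1) {
  stopifnot(is(topology, "FiberTopology"))
  mode <- match.arg(mode)
  n <- topology@nCores
  occ <- rep(FALSE, n)
  if (mode == "explicit") {
    if (is.null(positions))
      stop("invalid argument: explicit mode requires positions")
    if (any(positions < 1 | positions > n))
      stop("invalid argument: LH positions out of range")
    occ[as.integer(positions)] <- TRUE
  } else {
    if (!is.finite(density) || density < 0 || density > 1)
      stop("invalid argument: density must be in [0, 1]")
    nLh <- as.integer(floor(density * n))
    if (nLh > 0) {
      idx <- if (mode == "uniform")
        as.integer(floor((seq_len(nLh) - 1L) * n / nLh)) + 1L
      else .withSeed(seed, sample.int(n, nLh))
      occ[idx] <- TRUE
    }
  }
  topology@lhOccupied <- occ
  topology
}

#' Mark histone-acetylation islands
#'
#' Sets the acetylation flag exactly for cores inside the given 1-based
#' inclusive index ranges (e.g. the four islands 6-11, 17-22, 28-33, 39-44).
#'
#' @param topology a \linkS4class{FiberTopology}.
#' @param islands list of \code{c(start, end)} core-index ranges (or an
#'   n x 2 matrix).
#' @return the annotated topology.
#' @export
markAcetylation <- function(topology, islands) {
  stopifnot(is(topology, "FiberTopology"))
  if (is.matrix(islands))
    islands <- lapply(seq_len(nrow(islands)), function(i) islands[i, ])
  flags <- rep(FALSE, topology@nCores)
  for (isl in islands) {
    if (length(isl) != 2L || isl[1] < 1 || isl[2] > topology@nCores ||
        isl[1] > isl[2])
      stop("invalid argument: acetylation island out of range")
    flags[seq.int(isl[1], isl[2])] <- TRUE
  }
  topology@acetylated <- flags
  topology
}

#' Four-island acetylation preset
#'
#' The canonical four 6-nucleosome acetylation islands at nucleosomes 6-11,
#' 17-22, 28-33, and 39-44 of a 50-nucleosome fiber.
#'
#' @return list of core-index ranges.
#' @export
acetylationIslands50 <- function() {
  list(c(6L, 11L), c(17L, 22L), c(28L, 33L), c(39L, 44L))
}
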