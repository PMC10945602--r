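# Single-configuration and per-trajectory observables: fiber axis and packing
# ratio, sedimentation coefficient, radius of gyration, convergence monitors.

#' Fiber axis and length
#'
#' Defines the fiber axis by cubic smoothing splines fitted independently to
#' the nucleosome x, y, and z coordinates against the core index, and
#' measures the axis arc length by dense piecewise-linear quadrature. The
#' default effective degrees of freedom (one per three cores, at least 4)
#' keep the axis of an ideal zigzag between the two nucleosome stacks instead
#' of threading through every core; fibers with fewer than 5 cores fall back
#' to the polyline through the cores.
#'
#' @param config a \linkS4class{Configuration} (or core-coordinate matrix).
#' @param df effective degrees of freedom of the smoothing spline.
#' @param densify sampling points per core for the arc-length quadrature.
#' @return list with \code{axis} (matrix of points along the axis) and
#'   \code{length} (arc length Fl, nm).
#' @export
fiberAxis <- function(config, df = NULL, densify = 20) {
  xyz <- if (is(config, "Configuration")) config@coreXYZ else config
  n <- nrow(xyz)
  if (n < 2) stop("fiber axis undefined for a single core")
  if (n < 5) {
    seglen <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                            xyz[-n, , drop = FALSE])^2))
    return(list(axis = xyz, length = sum(seglen)))
  }
  if (is.null(df)) df <- max(4, ceiling(n / 3))
  df <- min(df, n)
  t <- seq_len(n)
  tt <- seq(1, n, length.out = n * densify)
  ax <- vapply(1:3, function(d) {
    fit <- stats::smooth.spline(t, xyz[, d], df = df)
    stats::predict(fit, tt)$y
  }, numeric(length(tt)))
  seglen <- sqrt(rowSums((ax[-1, , drop = FALSE] -
                          ax[-nrow(ax), , drop = FALSE])^2))
  list(axis = ax, length = sum(seglen))
}

#' @describeIn chromoMC-generics fiber packing ratio of one configuration:
#'   nucleosomes per 11 nm of fiber-axis length, 11 * NC / Fl.
#' @export
setMethod("packingRatio", "Configuration", function(x, ...) {
  11 * nrow(x@coreXYZ) / fiberAxis(x, ...)$length
})

#' @describeIn chromoMC-generics mean packing ratio over the frames of a
#'   trajectory.
#' @export
setMethod("packingRatio", "Trajectory", function(x, ...) {
  mean(vapply(x@frames, function(f) packingRatio(f, ...), numeric(1)))
})

#' @describeIn chromoMC-generics per-frame packing ratios of an ensemble.
#' @export
setMethod("packingRatio", "ChromatinEnsemble", function(x, ...) {
  vapply(x@frames, function(f) packingRatio(f, ...), numeric(1))
})

.sedimentation <- function(coreXYZ, rho, S0 = 11.1, S1 = 12, R1 = 5.5) {
  nc <- nrow(coreXYZ)
  pref <- (S1 - S0) * rho + S0
  if (nc == 1) return(pref)
  D <- as.matrix(stats::dist(coreXYZ))
  off <- D[upper.tri(D)]
  if (any(off < 1e-9)) stop("singular geometry: coincident nucleosome cores")
  # ordered-pair double sum over i != j
  pref * (1 + (R1 / nc) * 2 * sum(1 / off))
}

#' @describeIn chromoMC-generics sedimentation coefficient S20,w of one
#'   configuration (Svedberg), from the Kirkwood-type double sum over
#'   internucleosome distances with the mononucleosome anchors S0 = 11.1 S
#'   (no LH) and S1 = 12 S (with LH) and nucleosome radius R1 = 5.5 nm:
#'   \code{((S1-S0) rho + S0) (1 + R1/NC sum_i sum_j 1/Rij)}, ordered pairs
#'   i != j.
#' @param rho linker-histone density, 0-1.
#' @export
setMethod("sedimentationCoefficient", "Configuration",
  function(x, rho = 0, ...) .sedimentation(x@coreXYZ, rho))

#' @describeIn chromoMC-generics mean sedimentation coefficient over the
#'   frames of a trajectory; rho defaults to the topology's LH density.
#' @export
setMethod("sedimentationCoefficient", "Trajectory", function(x, rho = NULL, ...) {
  if (is.null(rho)) rho <- lhDensity(x@topology)
  mean(vapply(x@frames, function(f) .sedimentation(f@coreXYZ, rho), numeric(1)))
})

#' @describeIn chromoMC-generics per-frame sedimentation coefficients of an
#'   ensemble.
#' @export
setMethod("sedimentationCoefficient", "ChromatinEnsemble",
  function(x, rho = NULL, ...) {
    if (is.null(rho)) rho <- lhDensity(x@topology)
    vapply(x@frames, function(f) .sedimentation(f@coreXYZ, rho), numeric(1))
  })

#' @describeIn chromoMC-generics radius of gyration of one configuration:
#'   root-mean-square core distance from the core centroid, nm.
#' @export
setMethod("radiusOfGyration", "Configuration", function(x, ...) {
  xyz <- x@coreXYZ
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
})

#' @describeIn chromoMC-generics mean radius of gyration over a trajectory.
#' @export
setMethod("radiusOfGyration", "Trajectory", function(x, ...) {
  mean(vapply(x@frames, radiusOfGyration, numeric(1)))
})

#' @describeIn chromoMC-generics per-frame radii of gyration of an ensemble.
#' @export
setMethod("radiusOfGyration", "ChromatinEnsemble", function(x, ...) {
  vapply(x@frames, radiusOfGyration, numeric(1))
})

.tripletAngles <- function(coreXYZ) {
  n <- nrow(coreXYZ)
  if (n < 3) return(numeric())
  vapply(2:(n - 1), function(i) {
    u <- coreXYZ[i - 1, ] - coreXYZ[i, ]
    v <- coreXYZ[i + 1, ] - coreXYZ[i, ]
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(max(-1, min(1, cosang))) * 180 / pi
  }, numeric(1))
}

#' Convergence report
#'
#' Per-frame convergence monitors of a trajectory: total energy, end-to-end
#' distance (first to last core), sedimentation coefficient, and the mean
#' nucleosome triplet angle (angle at core i formed by the centres of cores
#' i-1, i, i+1; 180 degrees for a straight fiber).
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @return a \linkS4class{ConvergenceReport}.
#' @export
convergenceReport <- function(trajectory) {
  stopifnot(is(trajectory, "Trajectory"))
  if (length(trajectory@frames) < 1) stop("trajectory has no frames")
  rho <- lhDensity(trajectory@topology)
  rows <- lapply(seq_along(trajectory@frames), function(f) {
    cfg <- trajectory@frames[[f]]
    xyz <- cfg@coreXYZ
    data.frame(
      step = f * trajectory@saveEvery,
      energy = trajectory@energies[f, "total"],
      endToEnd = sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2)),
      sedimentation = .sedimentation(xyz, rho),
      tripletAngle = if (nrow(xyz) >= 3) mean(.tripletAngles(xyz)) else NA_real_)
  })
  new("ConvergenceReport", series = do.call(rbind, rows))
}

#' Contact-map matrix density
#'
#' Fraction of strictly positive entries above the diagonal.
#'
#' @param map a \linkS4class{ContactMap}.
#' @return fraction in [0, 1].
#' @export
matrixDensity <- function(map) {
  stopifnot(is(map, "ContactMap"))
  m <- map@matrix
  up <- m[upper.tri(m)]
  if (!length(up)) return(0)
  mean(up > 0)
}

#' Contact-decay profile
#'
#' Collapses a nucleosome-resolution interaction matrix into I(k), the
#' interaction mass at offset |i - j| = k, normalized by the total
#' off-diagonal interaction mass so that sum_k I(k) = 1.
#'
#' @param map a nucleosome-resolution \linkS4class{ContactMap}.
#' @return a \linkS4class{ContactDecay}.
#' @export
contactDecay <- function(map) {
  stopifnot(is(map, "ContactMap"))
  if (map@resolution != "nucleosome")
    stop("contact decay requires a nucleosome-resolution map")
  m <- map@matrix
  nc <- nrow(m)
  sums <- vapply(seq_len(nc - 1), function(k) {
    i <- seq_len(nc - k)
    sum(m[cbind(i, i + k)])
  }, numeric(1))
  norm <- sum(sums)
  if (norm <= 0) stop("undefined normalization: contact map has no off-diagonal mass")
  new("ContactDecay", values = setNames(sums / norm, seq_len(nc - 1)),
      normalization = norm)
}
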