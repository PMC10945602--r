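# Alpha-shape promoter geometry. The 3D alpha complex is computed by brute
# force (the vertex sets are small: a handful of promoter nucleosomes):
# a tetrahedron of the Delaunay triangulation belongs to the alpha shape when
# its circumradius is below alpha; the Delaunay property is checked directly
# via the empty-circumsphere criterion. A deterministic micro-jitter breaks
# cospherical degeneracies (e.g. points on a cube). The 2D projected area
# works the same way with triangles and circumcircles.

.alphaJitter <- function(p, scale = 1e-7) {
  n <- nrow(p)
  span <- max(apply(p, 2, function(v) diff(range(v))), 1)
  phi <- (sqrt(5) - 1) / 2
  j <- outer(seq_len(n), seq_len(ncol(p)), function(i, d)
    (((i * phi * d + 0.123 * d) %% 1) - 0.5))
  p + span * scale * j
}

.circumsphere <- function(v) { # rows: 4 points -> list(center, radius) or NULL
  a <- v[1, ]
  M <- rbind(v[2, ] - a, v[3, ] - a, v[4, ] - a)
  rhs <- 0.5 * rowSums(M^2)
  det <- det(M)
  if (abs(det) < 1e-12) return(NULL)
  ctr <- a + solve(M, rhs)
  list(center = ctr, radius = sqrt(sum((ctr - a)^2)))
}

.circumcircle <- function(v) { # rows: 3 points in 2D
  a <- v[1, ]
  M <- rbind(v[2, ] - a, v[3, ] - a)
  rhs <- 0.5 * rowSums(M^2)
  det <- det(M)
  if (abs(det) < 1e-12) return(NULL)
  ctr <- a + solve(M, rhs)
  list(center = ctr, radius = sqrt(sum((ctr - a)^2)))
}

#' Alpha-shape volume of a 3D point set
#'
#' Sum of the volumes of Delaunay tetrahedra whose circumradius is below
#' \code{alpha}. For alpha larger than the point-set extent this equals the
#' convex-hull volume; it never exceeds it.
#'
#' @param points n x 3 coordinate matrix (n >= 4, non-coplanar).
#' @param alpha alpha radius, nm.
#' @return volume in nm^3.
#' @export
alphaShapeVolume <- function(points, alpha = 100) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("degenerate geometry: need >= 4 vertices")
  sv <- svd(sweep(points, 2, colMeans(points)))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: vertices are coplanar")
  p <- .alphaJitter(points)
  n <- nrow(p)
  combs <- utils::combn(n, 4)
  vol <- 0
  any_valid <- FALSE
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    cs <- .circumsphere(p[idx, ])
    if (is.null(cs)) next
    others <- setdiff(seq_len(n), idx)
    if (length(others)) {
      d <- sqrt(colSums((t(p[others, , drop = FALSE]) - cs$center)^2))
      if (any(d < cs$radius * (1 - 1e-9))) next  # not Delaunay
    }
    any_valid <- TRUE
    if (cs$radius < alpha) {
      M <- rbind(p[idx[2], ] - p[idx[1], ],
                 p[idx[3], ] - p[idx[1], ],
                 p[idx[4], ] - p[idx[1], ])
      vol <- vol + abs(det(M)) / 6
    }
  }
  if (!any_valid) stop("degenerate geometry: vertices are coplanar")
  vol
}

#' Alpha-shape area of a 2D point set
#'
#' Sum of the areas of Delaunay triangles whose circumradius is below
#' \code{alpha}.
#'
#' @param points n x 2 coordinate matrix (n >= 3, non-collinear).
#' @param alpha alpha radius, nm.
#' @return area in nm^2.
#' @export
alphaShapeArea <- function(points, alpha = 100) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(points) < 3) stop("degenerate geometry: need >= 3 vertices")
  sv <- svd(sweep(points, 2, colMeans(points)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: vertices are collinear")
  p <- .alphaJitter(points)
  n <- nrow(p)
  combs <- utils::combn(n, 3)
  area <- 0
  any_valid <- FALSE
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    cc <- .circumcircle(p[idx, ])
    if (is.null(cc)) next
    others <- setdiff(seq_len(n), idx)
    if (length(others)) {
      d <- sqrt(colSums((t(p[others, , drop = FALSE]) - cc$center)^2))
      if (any(d < cc$radius * (1 - 1e-9))) next
    }
    any_valid <- TRUE
    if (cc$radius < alpha) {
      M <- rbind(p[idx[2], ] - p[idx[1], ], p[idx[3], ] - p[idx[1], ])
      area <- area + abs(det(M)) / 2
    }
  }
  if (!any_valid) stop("degenerate geometry: vertices are collinear")
  area
}

#' Promoter alpha-shape geometry over an ensemble
#'
#' For each frame, computes the alpha-shape volume of the selected nucleosome
#' centres (x, y, z) and the alpha-shape area of their (x, y) projection —
#' a loose bounding envelope (alpha = 100) quantifying how open or occluded
#' the promoter region is — and reports ensemble mean and standard deviation.
#'
#' @param x a \linkS4class{ChromatinEnsemble}, \linkS4class{Trajectory}, or
#'   list of \linkS4class{Configuration}.
#' @param coreIndices nucleosome indices used as vertices (e.g. 123:129).
#' @param alpha alpha radius, nm.
#' @return a \linkS4class{PromoterGeometry}.
#' @export
promoterGeometry <- function(x, coreIndices, alpha = 100) {
  frameList <- if (is(x, "Trajectory") || is(x, "ChromatinEnsemble")) frames(x)
               else x
  if (!length(frameList)) stop("invalid argument: no frames")
  coreIndices <- as.integer(coreIndices)
  perFrame <- do.call(rbind, lapply(seq_along(frameList), function(f) {
    xyz <- frameList[[f]]@coreXYZ[coreIndices, , drop = FALSE]
    data.frame(frame = f,
               area = alphaShapeArea(xyz[, 1:2], alpha),
               volume = alphaShapeVolume(xyz, alpha))
  }))
  new("PromoterGeometry",
      areaMean = mean(perFrame$area), areaSd = stats::sd(perFrame$area),
      volumeMean = mean(perFrame$volume), volumeSd = stats::sd(perFrame$volume),
      alpha = alpha, coreIndices = coreIndices, perFrame = perFrame)
}
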