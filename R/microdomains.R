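# Microdomain detection: DBSCAN on the inverse-contact-frequency distance
# matrix (d = 1/frequency). No clustering package in the dependency set
# provides DBSCAN, so the algorithm is implemented here (standard queue-based
# region growing on a precomputed distance matrix).

# DBSCAN on a symmetric distance matrix; labels: 0 = noise, 1..k clusters.
# A point is a core point when its eps-neighborhood (self included) holds at
# least minPts points.
.dbscanDistance <- function(D, eps, minPts) {
  n <- nrow(D)
  labels <- rep(0L, n)
  expanded <- rep(FALSE, n)
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nbrs) >= minPts
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    expanded[i] <- TRUE
    queue <- i
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      for (q in nbrs[[j]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q] && !expanded[q]) {
            expanded[q] <- TRUE
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

#' Convert a contact map to a DBSCAN distance matrix
#'
#' d = 1 / frequency per entry; zero-frequency entries are capped at 10x the
#' largest finite distance (DBSCAN needs finite entries, and the cap exceeds
#' any plausible search radius). The diagonal is 0.
#'
#' @param map a nucleosome-resolution \linkS4class{ContactMap}.
#' @param normalized use frequencies (counts / frames) instead of raw counts.
#' @return symmetric distance matrix.
#' @export
contactDistanceMatrix <- function(map, normalized = TRUE) {
  stopifnot(is(map, "ContactMap"))
  m <- if (normalized) contactMatrix(map, normalized = TRUE) else map@matrix
  D <- ifelse(m > 0, 1 / m, NA_real_)
  finite <- D[is.finite(D)]
  cap <- if (length(finite)) 10 * max(finite) else 1
  D[!is.finite(D)] <- cap
  diag(D) <- 0
  D
}

#' Detect microdomains by DBSCAN
#'
#' Converts the nucleosome-resolution interaction matrix to a distance matrix
#' (d = 1/frequency) and clusters nucleosomes with DBSCAN. The published
#' search radii are eps = 3 for 62 bp fibers, 2 for 44 bp and life-like
#' fibers, and 1.4 for 26 bp fibers, always with minpoints = 5.
#'
#' @param map a nucleosome-resolution \linkS4class{ContactMap}.
#' @param eps DBSCAN search radius on the inverse-frequency distances.
#' @param minPoints DBSCAN core-point threshold (default 5).
#' @param normalized cluster on frequencies rather than raw counts.
#' @return a \linkS4class{MicrodomainSet}.
#' @export
detectMicrodomains <- function(map, eps, minPoints = 5L, normalized = TRUE) {
  if (map@resolution != "nucleosome")
    stop("microdomain detection requires a nucleosome-resolution map")
  D <- contactDistanceMatrix(map, normalized = normalized)
  labels <- .dbscanDistance(D, eps, as.integer(minPoints))
  new("MicrodomainSet", labels = labels, eps = eps,
      minPoints = as.integer(minPoints))
}
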