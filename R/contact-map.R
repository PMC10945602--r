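# Simulated contact maps: per-frame binary contacts between nucleosomes (or
# genomic bins), accumulated over frames. Two nucleosomes are in contact when
# any element of one (core, linker DNA, tails, LH) comes within the cutoff of
# any element of the other, measured surface-to-surface (centre distance minus
# both excluded-volume radii).

# element table shared by all frames of one topology/force field
.contactElements <- function(topology, ff, resolution, binBp) {
  model <- .beadModel(topology, ff)
  elems <- which(model$cpp$radius > 0)
  radius <- model$cpp$radius[elems]
  if (resolution == "nucleosome") {
    bin <- model$group[elems]
    nBins <- topology@nCores
  } else {
    mid <- numeric(length(elems))
    for (k in seq_along(elems)) {
      s <- elems[k]
      ty <- model$type[s]
      mid[k] <- if (ty == 0) {
        row <- match(s, model$linkerSites)
        mean(topology@beadBp[row, ])
      } else {
        mean(topology@coreBp[model$parent[s], ])
      }
    }
    nBins <- max(1L, as.integer(ceiling(topology@regionBp / binBp)))
    bin <- pmin(nBins, as.integer(floor(mid / binBp)) + 1L)
    if (any(mid >= topology@regionBp)) bin[mid >= topology@regionBp] <- nBins
  }
  list(model = model, elems = elems, radius = radius, bin = bin, nBins = nBins)
}

.contactCountsForFrames <- function(frameList, topology, ff, cutoff,
                                    resolution, binBp) {
  el <- .contactElements(topology, ff, resolution, binBp)
  mats <- lapply(frameList, function(cfg) {
    X <- .flattenConfiguration(cfg, el$model)
    X[el$elems, , drop = FALSE]
  })
  .cppContactCounts(mats, as.integer(el$bin), el$radius,
                    as.integer(el$nBins), cutoff)
}

#' @describeIn chromoMC-generics contact map of a trajectory's saved frames.
#' @param cutoff surface-to-surface contact cutoff, nm (default 2).
#' @param resolution "nucleosome" or "bp".
#' @param binBp bin width for bp-resolution maps.
#' @param ff force field (bead radii and element assignment); defaults to the
#'   trajectory's.
#' @export
setMethod("contactMap", "Trajectory",
  function(x, cutoff = 2, resolution = c("nucleosome", "bp"), binBp = 200,
           ff = NULL, ...) {
    resolution <- match.arg(resolution)
    if (is.null(ff)) ff <- x@forceField
    if (length(x@frames) == 0) stop("invalid argument: no frames")
    counts <- .contactCountsForFrames(x@frames, x@topology, ff, cutoff,
                                      resolution, binBp)
    new("ContactMap", matrix = counts, resolution = resolution,
        cutoffNm = cutoff, nFrames = length(x@frames),
        binBp = if (resolution == "bp") binBp else NA_real_,
        normalized = FALSE)
  })

#' @describeIn chromoMC-generics contact map of a pooled ensemble.
#' @export
setMethod("contactMap", "ChromatinEnsemble",
  function(x, cutoff = 2, resolution = c("nucleosome", "bp"), binBp = 200,
           ff = NULL, ...) {
    resolution <- match.arg(resolution)
    if (is.null(ff)) ff <- x@forceField
    if (length(x@frames) == 0) stop("invalid argument: no frames")
    counts <- .contactCountsForFrames(x@frames, x@topology, ff, cutoff,
                                      resolution, binBp)
    new("ContactMap", matrix = counts, resolution = resolution,
        cutoffNm = cutoff, nFrames = length(x@frames),
        binBp = if (resolution == "bp") binBp else NA_real_,
        normalized = FALSE)
  })

#' @describeIn chromoMC-generics contact map of an explicit frame list
#'   (\code{topology} required).
#' @param topology the \linkS4class{FiberTopology} shared by the frames.
#' @export
setMethod("contactMap", "list",
  function(x, topology, cutoff = 2, resolution = c("nucleosome", "bp"),
           binBp = 200, ff = defaultForceField(), ...) {
    resolution <- match.arg(resolution)
    if (length(x) == 0) stop("invalid argument: empty frame list")
    counts <- .contactCountsForFrames(x, topology, ff, cutoff, resolution, binBp)
    new("ContactMap", matrix = counts, resolution = resolution,
        cutoffNm = cutoff, nFrames = length(x),
        binBp = if (resolution == "bp") binBp else NA_real_,
        normalized = FALSE)
  })

#' Ensemble (summed) contact map
#'
#' Elementwise sum of single-trajectory contact maps; the population-level
#' analogue of Hi-C maps, where microdomains appear that single trajectories
#' do not show. Frame counts accumulate in the metadata.
#'
#' @param maps list of \linkS4class{ContactMap} with identical shape,
#'   resolution, and cutoff.
#' @param normalizePerTrajectory divide each map by its own frame count before
#'   summing (so trajectories with different lengths weigh equally).
#' @return a \linkS4class{ContactMap}.
#' @export
ensembleContactMap <- function(maps, normalizePerTrajectory = FALSE) {
  stopifnot(length(maps) >= 1, all(vapply(maps, is, logical(1), "ContactMap")))
  ref <- maps[[1]]
  for (m in maps) {
    if (!identical(dim(m@matrix), dim(ref@matrix)) ||
        m@resolution != ref@resolution)
      stop("invalid argument: contact maps have mismatching shape or resolution")
  }
  acc <- matrix(0, nrow(ref@matrix), ncol(ref@matrix))
  for (m in maps) {
    add <- if (normalizePerTrajectory) m@matrix / max(1, m@nFrames) else m@matrix
    acc <- acc + add
  }
  new("ContactMap", matrix = acc, resolution = ref@resolution,
      cutoffNm = ref@cutoffNm, nFrames = sum(vapply(maps, nFrames, numeric(1))),
      binBp = ref@binBp, normalized = normalizePerTrajectory)
}

#' Write a contact map as TSV
#'
#' Dense tab-separated matrix with header comments recording resolution,
#' frame count, and cutoff.
#'
#' @param map a \linkS4class{ContactMap}.
#' @param path output file.
#' @export
writeContactMap <- function(map, path) {
  stopifnot(is(map, "ContactMap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# resolution: %s", map@resolution),
               sprintf("# frames: %g", map@nFrames),
               sprintf("# cutoff_nm: %g", map@cutoffNm),
               sprintf("# bin_bp: %g", map@binBp),
               sprintf("# normalized: %s", map@normalized)), con)
  utils::write.table(map@matrix, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a contact map written by \code{writeContactMap}
#'
#' @param path TSV file.
#' @return a \linkS4class{ContactMap}.
#' @export
readContactMap <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  m <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)],
                                   sep = "\t"))
  dimnames(m) <- NULL
  num <- function(v) if (identical(v, "NA")) NA_real_ else as.numeric(v)
  new("ContactMap", matrix = m, resolution = get("resolution"),
      cutoffNm = num(get("cutoff_nm")), nFrames = num(get("frames")),
      binBp = num(get("bin_bp")),
      normalized = as.logical(get("normalized")))
}
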