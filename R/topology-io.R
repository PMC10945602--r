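# Versioned structured-text serialization of FiberTopology. Numbers are
# written with 17 significant digits so round-trips are bitwise exact.

.TOPOLOGY_FORMAT_VERSION <- 1L

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write a topology as structured text
#'
#' Versioned key/value document listing all fields of the topology;
#' round-trips bitwise via \code{\link{readTopology}}.
#'
#' @param topology a \linkS4class{FiberTopology}.
#' @param path output file.
#' @export
writeTopology <- function(topology, path) {
  stopifnot(is(topology, "FiberTopology"))
  num <- function(v) paste(.fmtNum(v), collapse = ",")
  ints <- function(v) paste(v, collapse = ",")
  lg <- function(v) paste(as.integer(v), collapse = ",")
  lines <- c(
    sprintf("format_version: %d", .TOPOLOGY_FORMAT_VERSION),
    sprintf("n_cores: %d", topology@nCores),
    sprintf("run_after_core: %s", ints(topology@runAfterCore)),
    sprintf("linker_beads: %s", ints(topology@linkerBeads)),
    sprintf("linker_bp: %s", num(topology@linkerBp)),
    sprintf("nfr_runs: %s", ints(topology@nfrSpans$run)),
    sprintf("nfr_bp: %s", num(topology@nfrSpans$bp)),
    sprintf("lh_occupied: %s", lg(topology@lhOccupied)),
    sprintf("acetylated: %s", lg(topology@acetylated)),
    sprintf("tf_bindable: %s", lg(topology@tfBindable)),
    sprintf("tf_region_start: %s", ints(topology@tfRegions$start)),
    sprintf("tf_region_end: %s", ints(topology@tfRegions$end)),
    sprintf("nrl_bp: %s", .fmtNum(topology@nrlBp)),
    sprintf("region_bp: %s", .fmtNum(topology@regionBp)),
    sprintf("core_bp: %s", num(as.vector(topology@coreBp))),
    sprintf("bead_bp: %s", num(as.vector(topology@beadBp))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a structured-text topology
#'
#' @param path file written by \code{\link{writeTopology}}.
#' @return the \linkS4class{FiberTopology}.
#' @export
readTopology <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
  get <- function(key) vals[match(key, keys)]
  splitNum <- function(s) if (is.na(s) || s == "") numeric() else
    as.numeric(strsplit(s, ",")[[1]])
  splitInt <- function(s) as.integer(splitNum(s))
  ver <- splitInt(get("format_version"))
  if (!identical(ver, .TOPOLOGY_FORMAT_VERSION))
    stop("unsupported topology format version: ", ver)
  n <- splitInt(get("n_cores"))
  M <- sum(splitInt(get("linker_beads")))
  new("FiberTopology",
      nCores = n,
      runAfterCore = splitInt(get("run_after_core")),
      linkerBeads = splitInt(get("linker_beads")),
      linkerBp = splitNum(get("linker_bp")),
      nfrSpans = data.frame(run = splitInt(get("nfr_runs")),
                            bp = splitNum(get("nfr_bp"))),
      lhOccupied = as.logical(splitInt(get("lh_occupied"))),
      acetylated = as.logical(splitInt(get("acetylated"))),
      tfBindable = if (M) as.logical(splitInt(get("tf_bindable")))
                   else logical(),
      tfRegions = data.frame(start = splitInt(get("tf_region_start")),
                             end = splitInt(get("tf_region_end"))),
      nrlBp = splitNum(get("nrl_bp")),
      regionBp = splitNum(get("region_bp")),
      coreBp = matrix(splitNum(get("core_bp")), ncol = 2),
      beadBp = matrix(splitNum(get("bead_bp")), ncol = 2))
}
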