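# Genomic tracks. Tracks are GRanges on a single region with 0-based
# half-open coordinates at the file level (BED convention); GRanges uses
# 1-based closed internally and rtracklayer converts on import/export.

#' Build a genomic track
#'
#' @param start,end 0-based half-open interval coordinates (bp).
#' @param label interval names.
#' @param seqname region name.
#' @return a \code{GRanges} track, sorted, with names in \code{name}.
#' @export
genomicTrack <- function(start, end, label = NULL, seqname = "region") {
  if (any(start < 0)) stop("invalid argument: negative coordinates")
  if (any(end <= start)) stop("invalid argument: intervals need start < end")
  gr <- GenomicRanges::GRanges(seqname,
                               IRanges::IRanges(start = start + 1L, end = end))
  if (!is.null(label)) gr$name <- label
  GenomicRanges::sort(gr)
}

# 0-based half-open (start, end) matrix of a track
.trackIntervals <- function(track) {
  if (is.null(track)) return(matrix(numeric(), 0, 2))
  if (is.matrix(track) || is.data.frame(track)) {
    m <- as.matrix(track[, 1:2, drop = FALSE])
    dimnames(m) <- NULL
    return(m)
  }
  cbind(GenomicRanges::start(track) - 1L, GenomicRanges::end(track))
}

#' Read a BED track
#'
#' Tab-separated BED (chrom, start, end, name), 0-based half-open.
#'
#' @param path BED file.
#' @return a \code{GRanges} track.
#' @export
readTrack <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write a BED track
#'
#' @param track a \code{GRanges} track.
#' @param path output BED file.
#' @export
writeTrack <- function(track, path) {
  rtracklayer::export(track, path, format = "BED")
  invisible(path)
}
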