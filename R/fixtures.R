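# Offline fixtures. The Eed-locus tracks are SYNTHETIC stand-ins assembled
# from published summary statistics (region span, NFR count and sizes, the
# two TF ChIP intervals, LH density), not processed sequencing data: NFR
# positions within the region are a deterministic design choice. The TF
# intervals are the reported mm9 ChIP regions made region-relative (region
# chr7:97,103,164-97,129,486; TF region 1 clipped at the region end).

.EED_REGION_BP <- 26322          # 97,129,486 - 97,103,164
.EED_OFFSET <- 97103164
.EED_TARGET_CORES <- 129L
.EED_NRL_BP <- 189

.eedNfrTrack <- function() {
  # two long (~350 bp) promoter-proximal NFRs and five short (~200 bp) ones
  genomicTrack(start = c(3000, 6500, 10000, 13500, 17000, 20400, 24650),
               end   = c(3200, 6700, 10200, 13700, 17200, 20750, 25000),
               label = paste0("NFR", c(3:7, 2, 1)),
               seqname = "Eed_region")
}

.eedTfTrack <- function() {
  # ChIP intervals 97,124,070-97,124,896 and 97,128,221-97,129,793 (clipped)
  genomicTrack(start = c(97124070, 97128221) - .EED_OFFSET,
               end = pmin(c(97124896, 97129793) - .EED_OFFSET, .EED_REGION_BP),
               label = c("TF_region_2", "TF_region_1"),
               seqname = "Eed_region")
}

.eedLhTrack <- function() {
  # ChIP-like LH peaks synthesized to occupy 47 of 129 cores (density 0.364,
  # matching the reported 0.37): the middle 50 bp of evenly spaced cores of
  # the LH-free topology
  base <- buildGeneFiber(.EED_REGION_BP, .eedNfrTrack(), .EED_NRL_BP,
                         lhTrack = 0, tfTrack = NULL, seed = 1903,
                         targetCores = .EED_TARGET_CORES)
  nLh <- 47L
  cores <- floor((seq_len(nLh) - 1L) * .EED_TARGET_CORES / nLh) + 1L
  mid <- rowMeans(base@coreBp[cores, , drop = FALSE])
  genomicTrack(start = round(mid - 25), end = round(mid + 25),
               label = paste0("LH_peak", seq_len(nLh)), seqname = "Eed_region")
}

#' Build a named fixture system
#'
#' Named offline fixtures reproducing the study systems:
#' \describe{
#'   \item{eed_wt}{129-core Eed-locus fiber (NRL 189 bp, 7 NFR runs, LH
#'     density ~0.37 from the synthetic LH track), no TF marks.}
#'   \item{eed_tf}{eed_wt plus the two TF-binding regions.}
#'   \item{eed_lh08}{Eed fiber with LH density 0.8 (randomly placed).}
#'   \item{eed_lh08_tf}{LH density 0.8 plus TF regions.}
#'   \item{uniform_topology1..4}{50-nucleosome, 44 bp uniform fiber with TF
#'     binding pattern 1-4.}
#'   \item{lifelike}{50-nucleosome fiber with mESC linker distribution.}
#' }
#'
#' @param name fixture name.
#' @param seed RNG seed for the stochastic parts (linker draws, random LH).
#' @return list with \code{topology}, \code{tracks} (list of GRanges), and
#'   \code{description}.
#' @export
makeFixture <- function(name, seed = 1903) {
  eed <- function(lh, tf) {
    tracks <- list(nfr = .eedNfrTrack(),
                   tf = if (tf) .eedTfTrack() else NULL,
                   lh = if (identical(lh, "track")) .eedLhTrack() else NULL)
    topo <- buildGeneFiber(.EED_REGION_BP, tracks$nfr, .EED_NRL_BP,
                           lhTrack = if (identical(lh, "track")) tracks$lh else lh,
                           tfTrack = tracks$tf, seed = seed,
                           targetCores = .EED_TARGET_CORES)
    list(topology = topo, tracks = tracks[!vapply(tracks, is.null, logical(1))])
  }
  out <- switch(name,
    eed_wt = c(eed("track", FALSE),
               description = "Eed locus, LH density ~0.37, no TF"),
    eed_tf = c(eed("track", TRUE),
               description = "Eed locus, LH density ~0.37, two TF regions"),
    eed_lh08 = c(eed(0.8, FALSE),
                 description = "Eed locus, LH density 0.8, no TF"),
    eed_lh08_tf = c(eed(0.8, TRUE),
                    description = "Eed locus, LH density 0.8, two TF regions"),
    lifelike = list(topology = buildLifelikeFiber(50, seed = seed),
                    tracks = list(),
                    description = "50-nucleosome life-like fiber (mESC linkers)"),
    {
      m <- regmatches(name, regexec("^uniform_topology([1-4])$", name))[[1]]
      if (length(m) != 2) stop("invalid argument: unknown fixture '", name, "'")
      pat <- as.integer(m[2])
      list(topology = applyTfTopology(buildUniformFiber(50, 44),
                                      tfTopologySpec(pat)),
           tracks = list(),
           description = sprintf("50-nucleosome 44 bp fiber, TF topology %d", pat))
    })
  out
}

#' Paths of the shipped synthetic Eed BED tracks
#'
#' The package ships the synthetic Eed-locus tracks as BED files under
#' \code{inst/extdata} (files carry "synthetic" in their names); this helper
#' returns their installed paths.
#'
#' @return named character vector (nfr, tf, lh).
#' @export
eedTrackFiles <- function() {
  c(nfr = system.file("extdata", "eed_nfr_synthetic.bed", package = "chromoMC"),
    tf = system.file("extdata", "eed_tf_synthetic.bed", package = "chromoMC"),
    lh = system.file("extdata", "eed_lh_synthetic.bed", package = "chromoMC"))
}
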