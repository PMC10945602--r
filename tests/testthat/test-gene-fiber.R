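# Gene-locus builder and genomic tracks

test_that("the Eed-like fixture reproduces the documented construction", {
  fx <- makeFixture("eed_tf")
  topo <- fx$topology
  expect_equal(nCores(topo), 129L)
  expect_equal(nrow(topo@nfrSpans), 7L)
  expect_equal(topo@regionBp, 26322)
  # the two ChIP intervals produce exactly two TF-bindable bead blocks
  blocks <- rle(tfBindable(topo))
  expect_equal(sum(blocks$values), 2L)
  expect_gt(sum(tfBindable(topo)), 0L)
  # NFR runs are long free-DNA runs (~200 / ~350 bp -> >= 22 beads)
  nfrBeads <- topo@linkerBeads[topo@nfrSpans$run]
  expect_true(all(nfrBeads >= 20L))

  wt <- makeFixture("eed_wt")$topology
  expect_equal(sum(tfBindable(wt)), 0L)
  expect_equal(sum(wt@lhOccupied), 47L)      # density ~0.37
  expect_equal(round(lhDensity(wt), 2), 0.36)

  lh08 <- makeFixture("eed_lh08")$topology
  expect_equal(sum(lh08@lhOccupied), 103L)   # floor(0.8 * 129)
})

test_that("a gene fiber without NFRs equals the uniform builder", {
  n <- 12L
  region <- n * 189
  topo <- buildGeneFiber(region, matrix(numeric(), 0, 2), nrlBp = 189,
                         linkerDistribution = c(`42` = 1.0), seed = 5)
  ref <- buildUniformFiber(n, 42)
  expect_equal(nCores(topo), n)
  expect_equal(length(topo@runAfterCore), length(ref@runAfterCore))
  expect_identical(topo@linkerBeads, ref@linkerBeads)
})

test_that("gene-fiber footprints tile the region exactly", {
  fx <- makeFixture("eed_wt")$topology
  covered <- sum(fx@coreBp[, 2] - fx@coreBp[, 1]) +
    sum(fx@beadBp[, 2] - fx@beadBp[, 1])
  expect_equal(covered, fx@regionBp, tolerance = 1e-9)
  # footprints are ordered and non-overlapping
  allBp <- rbind(fx@coreBp, fx@beadBp)
  allBp <- allBp[order(allBp[, 1]), ]
  expect_true(all(diff(allBp[, 1]) > 0))
  expect_true(all(allBp[-1, 1] - allBp[-nrow(allBp), 2] > -1e-9))
})

test_that("gene-fiber input validation rejects bad tracks", {
  nfrOverlap <- matrix(c(100, 300, 200, 400), 2, 2, byrow = TRUE)
  expect_error(buildGeneFiber(5000, nfrOverlap, 189, seed = 1), "overlapping")
  nfrOutside <- matrix(c(4000, 6000), 1, 2)
  expect_error(buildGeneFiber(5000, nfrOutside, 189, seed = 1), "outside")
  expect_error(buildGeneFiber(5000, matrix(numeric(), 0, 2), 140, seed = 1),
               "nrlBp")
})

test_that("BED tracks round-trip through the reader/writer", {
  tr <- genomicTrack(start = c(10, 500), end = c(200, 900),
                     label = c("a", "b"), seqname = "chrT")
  path <- tempfile(fileext = ".bed")
  writeTrack(tr, path)
  back <- readTrack(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(tr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(tr))
  expect_equal(back$name, tr$name)
  # 0-based half-open on disk
  raw <- read.table(path, sep = "\t")
  expect_equal(raw$V2, c(10, 500))
  expect_equal(raw$V3, c(200, 900))
  expect_error(genomicTrack(10, 10), "invalid")
  expect_error(genomicTrack(-5, 10), "invalid")
})

test_that("shipped synthetic Eed tracks load and match the fixture", {
  files <- eedTrackFiles()
  expect_true(all(file.exists(files)))
  tf <- readTrack(files["tf"])
  expect_equal(length(tf), 2L)
  expect_equal(GenomicRanges::start(tf) - 1L, c(20906L, 25057L))
  nfr <- readTrack(files["nfr"])
  expect_equal(length(nfr), 7L)
})
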