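# Contact maps: the 2 nm surface-gap criterion, symmetry, ensemble summation

# two-core fiber with no tails and the linker bead parked far away, so the
# only possible contact is core-core (surfaces touch at centre distance 11)
twoCoreConfig <- function(centreDist) {
  ff <- slimForceField()
  fib <- buildUniformFiber(2, 9)
  cfg <- initialConfiguration(fib, ff)
  cfg@coreXYZ[1, ] <- c(0, 0, 0)
  cfg@coreXYZ[2, ] <- c(centreDist, 0, 0)
  cfg@linkerXYZ[1, ] <- c(1e5, 0, 0)
  list(fib = fib, ff = ff, cfg = cfg)
}

test_that("contacts follow the surface-to-surface 2 nm criterion", {
  near <- twoCoreConfig(11 + 1.9)   # gap 1.9 nm -> contact
  m1 <- contactMap(list(near$cfg), topology = near$fib, ff = near$ff)
  expect_equal(contactMatrix(m1)[1, 2], 1)
  far <- twoCoreConfig(11 + 2.1)    # gap 2.1 nm -> no contact
  m2 <- contactMap(list(far$cfg), topology = far$fib, ff = far$ff)
  expect_equal(contactMatrix(m2)[1, 2], 0)
  expect_identical(contactMatrix(m1), t(contactMatrix(m1)))
})

test_that("per-frame contacts are binary and accumulate over frames", {
  near <- twoCoreConfig(12)
  m <- contactMap(rep(list(near$cfg), 7), topology = near$fib, ff = near$ff)
  expect_equal(contactMatrix(m)[1, 2], 7)     # one indicator per frame
  expect_equal(nFrames(m), 7)
  expect_equal(contactMatrix(m, normalized = TRUE)[1, 2], 1)
})

test_that("ensemble maps are elementwise sums", {
  set.seed(5)
  mk <- function(m, frames = 10) new("ContactMap", matrix = m,
    resolution = "nucleosome", cutoffNm = 2, nFrames = frames,
    binBp = NA_real_, normalized = FALSE)
  r1 <- matrix(rpois(36, 3), 6, 6); r1 <- r1 + t(r1)
  r2 <- matrix(rpois(36, 3), 6, 6); r2 <- r2 + t(r2)
  ens <- ensembleContactMap(list(mk(r1), mk(r2)))
  expect_equal(contactMatrix(ens), r1 + r2)
  expect_equal(nFrames(ens), 20)
  ten <- ensembleContactMap(rep(list(mk(r1)), 10))
  expect_equal(contactMatrix(ten), 10 * r1)
  expect_equal(contactMatrix(ensembleContactMap(list(mk(r1)))), r1)
  expect_error(ensembleContactMap(list(mk(r1), mk(matrix(0, 4, 4)))),
               "mismatch")
})

test_that("map construction distributes over frame-set concatenation", {
  fib <- buildUniformFiber(6, 26)
  ff <- slimForceField()
  tr <- runReplica(fib, ff, nSteps = 6000, saveEvery = 1000, seed = 9)
  a <- contactMap(tr@frames[1:3], topology = fib, ff = ff)
  b <- contactMap(tr@frames[4:6], topology = fib, ff = ff)
  ab <- contactMap(tr@frames, topology = fib, ff = ff)
  expect_equal(contactMatrix(ab), contactMatrix(a) + contactMatrix(b))
})

test_that("bp-resolution maps bin elements by genomic position", {
  near <- twoCoreConfig(12)
  m <- contactMap(list(near$cfg), topology = near$fib, ff = near$ff,
                  resolution = "bp", binBp = 100)
  expect_equal(nrow(contactMatrix(m)),
               ceiling(near$fib@regionBp / 100))
  expect_identical(contactMatrix(m), t(contactMatrix(m)))
  # the two cores occupy distinct bins and touch
  expect_gt(sum(contactMatrix(m)), 0)
})

test_that("contact maps survive the TSV round trip", {
  near <- twoCoreConfig(12)
  m <- contactMap(rep(list(near$cfg), 3), topology = near$fib, ff = near$ff)
  path <- tempfile(fileext = ".tsv")
  writeContactMap(m, path)
  back <- readContactMap(path)
  expect_equal(contactMatrix(back), contactMatrix(m))
  expect_equal(back@resolution, m@resolution)
  expect_equal(back@nFrames, m@nFrames)
  expect_equal(back@cutoffNm, m@cutoffNm)
})
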