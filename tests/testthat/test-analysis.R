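# Observables: fiber axis, packing ratio, sedimentation, Rg, decay profiles,
# matrix density, convergence monitors, ensemble assembly

mkConfig <- function(coreXYZ) {
  n <- nrow(coreXYZ)
  new("Configuration", coreXYZ = coreXYZ,
      coreFrames = array(rep(diag(3), n), c(3, 3, n)),
      linkerXYZ = matrix(0, 0, 3), tailXYZ = matrix(0, 0, 3),
      lhXYZ = matrix(0, 0, 3), twistDeg = numeric(), twistOffsetDeg = 0,
      tailFolded = rep(FALSE, n))
}

test_that("the fiber axis recovers straight and circular reference lengths", {
  straight <- mkConfig(cbind(5 * (0:49), 0, 0))
  fl <- fiberAxis(straight)$length
  expect_equal(fl, 245, tolerance = 1e-3)          # 49 gaps x 5 nm
  # rigid rotation leaves the length unchanged
  R <- chromoMC:::.rotationAbout(c(1, 1, 2), 1.1)
  rot <- mkConfig(straight@coreXYZ %*% t(R))
  expect_equal(fiberAxis(rot)$length, fl, tolerance = 1e-6)
  # cores on a circle: length within 2% of the arc through them (an open
  # chain of n points spans (n-1)/n of the circumference)
  Rc <- 40; n <- 24
  th <- 2 * pi * (seq_len(n) - 1) / n
  circ <- mkConfig(cbind(Rc * cos(th), Rc * sin(th), 0))
  arc <- 2 * pi * Rc * (n - 1) / n
  expect_lt(abs(fiberAxis(circ)$length - arc) / arc, 0.02)
  expect_error(fiberAxis(mkConfig(matrix(0, 1, 3))), "single core")
})

test_that("packing ratio is 11 NC / Fl", {
  # 50 collinear cores with Fl = 275 nm -> Pr = 2
  cfg <- mkConfig(cbind(275 / 49 * (0:49), 0, 0))
  expect_equal(packingRatio(cfg), 2, tolerance = 1e-3)
  # doubling the fiber length halves the packing ratio
  cfg2 <- mkConfig(cbind(2 * 275 / 49 * (0:49), 0, 0))
  expect_equal(packingRatio(cfg2), 1, tolerance = 1e-3)
  cfg4 <- mkConfig(cbind(137.5 / 49 * (0:49), 0, 0))
  expect_equal(packingRatio(cfg4), 4, tolerance = 1e-3)
})

test_that("sedimentation coefficients match the Kirkwood-type closed forms", {
  one <- mkConfig(matrix(c(3, -2, 7), 1, 3))
  expect_equal(sedimentationCoefficient(one, rho = 0), 11.1)
  expect_equal(sedimentationCoefficient(one, rho = 1), 12)
  two <- mkConfig(matrix(c(0, 0, 0, 11, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(sedimentationCoefficient(two, rho = 0),
               11.1 * (1 + (5.5 / 2) * (2 / 11)))   # 16.65 S
  # strictly decreasing under uniform dilation
  set.seed(8)
  base <- matrix(rnorm(30, sd = 20), 10, 3)
  vals <- vapply(c(0.8, 1, 1.3, 1.9, 2.5), function(s)
    sedimentationCoefficient(mkConfig(base * s), rho = 0), numeric(1))
  expect_true(all(diff(vals) < 0))
  overlap <- mkConfig(matrix(0, 2, 3))
  expect_error(sedimentationCoefficient(overlap), "singular")
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radiusOfGyration(mkConfig(matrix(1:3, 1, 3))), 0)
  two <- mkConfig(matrix(c(0, 0, 0, 6, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(radiusOfGyration(two), 3)               # d/2
  a <- 4
  sq <- mkConfig(matrix(c(0, 0, 0, a, 0, 0, a, a, 0, 0, a, 0), 4, 3,
                        byrow = TRUE))
  expect_equal(radiusOfGyration(sq), a / sqrt(2))
})

test_that("observables are invariant under rigid transforms of every frame", {
  fib <- buildUniformFiber(12, 44)
  cfg <- initialConfiguration(fib)
  R <- chromoMC:::.rotationAbout(c(2, -1, 1), 0.7)
  mv <- function(m) sweep(m %*% t(R), 2, c(8, -5, 11), `+`)
  cfg2 <- cfg
  cfg2@coreXYZ <- mv(cfg@coreXYZ)
  cfg2@linkerXYZ <- mv(cfg@linkerXYZ)
  cfg2@tailXYZ <- mv(cfg@tailXYZ)
  for (c in seq_len(12)) cfg2@coreFrames[, , c] <- R %*% cfg@coreFrames[, , c]
  expect_equal(radiusOfGyration(cfg2), radiusOfGyration(cfg), tolerance = 1e-9)
  expect_equal(sedimentationCoefficient(cfg2), sedimentationCoefficient(cfg),
               tolerance = 1e-9)
  expect_equal(packingRatio(cfg2), packingRatio(cfg), tolerance = 1e-6)
})

test_that("contact decay normalizes to one and matches hand-computed values", {
  mk <- function(m) new("ContactMap", matrix = m, resolution = "nucleosome",
                        cutoffNm = 2, nFrames = 1, binBp = NA_real_,
                        normalized = FALSE)
  m3 <- matrix(1, 3, 3); diag(m3) <- 0
  cd <- contactDecay(mk(m3))
  expect_equal(unname(cd@values), c(2/3, 1/3))
  band <- matrix(0, 5, 5)
  for (i in 1:4) band[i, i + 1] <- band[i + 1, i] <- 2
  cd2 <- contactDecay(mk(band))
  expect_equal(unname(cd2@values), c(1, 0, 0, 0))
  set.seed(3)
  r <- matrix(runif(49), 7, 7); r <- r + t(r); diag(r) <- 0
  expect_equal(sum(contactDecay(mk(r))@values), 1, tolerance = 1e-12)
  expect_error(contactDecay(mk(matrix(0, 4, 4))), "normalization")
})

test_that("matrix density counts strictly positive upper-triangle entries", {
  mk <- function(m) new("ContactMap", matrix = m, resolution = "nucleosome",
                        cutoffNm = 2, nFrames = 1, binBp = NA_real_,
                        normalized = FALSE)
  expect_equal(matrixDensity(mk(matrix(0, 6, 6))), 0)
  expect_equal(matrixDensity(mk(matrix(1, 6, 6))), 1)
  m <- matrix(0, 15, 15)
  picks <- cbind(c(1, 2, 3, 4, 5, 6, 7, 1, 2, 3), c(8, 9, 10, 11, 12, 13, 14, 15, 14, 13))
  m[picks] <- 5; m[picks[, 2:1]] <- 5
  expect_equal(matrixDensity(mk(m)), 10 / choose(15, 2))
})

test_that("convergence reports track energy, size, and local geometry", {
  fib <- buildUniformFiber(6, 44)
  tr <- runReplica(fib, nSteps = 3000, saveEvery = 1000, seed = 3)
  rep <- convergenceReport(tr)
  expect_equal(nrow(rep@series), 3L)
  expect_identical(colnames(rep@series),
                   c("step", "energy", "endToEnd", "sedimentation",
                     "tripletAngle"))
  straight <- mkConfig(cbind(6 * (0:9), 0, 0))
  expect_equal(mean(chromoMC:::.tripletAngles(straight@coreXYZ)), 180,
               tolerance = 1e-9)
  two <- mkConfig(matrix(c(0, 0, 0, 0, 8, 0), 2, 3, byrow = TRUE))
  expect_equal(sqrt(sum((two@coreXYZ[2, ] - two@coreXYZ[1, ])^2)), 8)
})

test_that("ensemble assembly pools the stated frame counts with provenance", {
  fib <- buildUniformFiber(2, 44)
  ff <- slimForceField()
  trs10 <- lapply(1:10, function(s)
    mockTrajectory(fib, ff, nSteps = 5e7, saveEvery = 1e5, seed = s))
  ens <- assembleAnalysisEnsemble(trs10, tailSteps = 1e7)
  expect_equal(nFrames(ens), 1000L)
  expect_equal(nrow(ens@provenance), 1000L)
  expect_equal(length(unique(ens@provenance$replica)), 10L)

  trs20 <- lapply(1:20, function(s)
    mockTrajectory(fib, ff, nSteps = 7e7, saveEvery = 1e5, seed = s))
  expect_equal(nFrames(assembleAnalysisEnsemble(trs20, 1e7)), 2000L)

  tr1 <- mockTrajectory(fib, ff, nSteps = 1e6, saveEvery = 1e5, seed = 1)
  expect_equal(nFrames(assembleAnalysisEnsemble(list(tr1), 1e5)), 1L)
  expect_error(assembleAnalysisEnsemble(list(tr1), 2e6), "tail longer")
  expect_error(assembleAnalysisEnsemble(list(tr1), 1.5e5), "multiple")
})

test_that("effective TF concentration averages replica occupancies", {
  fib <- setTfConcentration(buildUniformFiber(12, 62), 100, 1)  # 77 beads
  nb <- sum(tfBindable(fib))
  ff <- slimForceField()
  mkTr <- function(nEngagedBeads) {
    pairs <- if (nEngagedBeads > 0)
      cbind(seq_len(nEngagedBeads / 2), seq_len(nEngagedBeads / 2) + 30L)
    else matrix(integer(), 0, 2)
    mockTrajectory(fib, ff, nSteps = 1000, saveEvery = 500, seed = 1,
                   engagedPairsPerFrame = pairs)
  }
  # replica occupancies 50%, 0%, 10% of bindable beads (hand-built logs)
  half <- round(nb * 0.5 / 2) * 2
  tenth <- round(nb * 0.1 / 2) * 2
  trajs <- c(replicate(4, mkTr(half), simplify = FALSE),
             replicate(4, mkTr(0), simplify = FALSE),
             replicate(2, mkTr(tenth), simplify = FALSE))
  res <- effectiveTfConcentration(trajs)
  manual <- mean(c(rep(half / nb, 4), rep(0, 4), rep(tenth / nb, 2))) * 100
  expect_equal(res$ensemblePercent, manual, tolerance = 1e-9)
  # no bindable beads -> not-applicable marker
  plain <- buildUniformFiber(12, 62)
  trP <- mockTrajectory(plain, ff, 1000, 500)
  expect_true(is.na(effectiveTfConcentration(list(trP))$ensemblePercent))
})
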