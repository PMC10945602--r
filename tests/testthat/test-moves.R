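# Monte Carlo move proposals (R-level operations)

kBT293 <- 0.0019872041 * 293

test_that("the Metropolis rule matches its closed forms", {
  expect_true(metropolisAccept(0, 293, 0.999999))        # exp(0) = 1
  expect_true(metropolisAccept(-5, 293, 0.999999))
  dE <- kBT293 * log(2)                                  # acceptance exactly 1/2
  expect_true(metropolisAccept(dE, 293, 0.4999))
  expect_false(metropolisAccept(dE, 293, 0.5001))
  expect_false(metropolisAccept(1e8, 293, 1e-12))        # limit: reject
  expect_error(metropolisAccept(1, -5, 0.5), "temperature")
})

test_that("global pivot is a rigid transform of the shorter end", {
  fib <- buildUniformFiber(9, 44)
  ff <- slimForceField()
  cfg <- initialConfiguration(fib, ff)
  prop <- globalPivot(cfg, fib, amplitudeDeg = 40, seed = 6, ff = ff)
  moved <- which(rowSums(abs(prop@coreXYZ - cfg@coreXYZ)) > 1e-12)
  kept <- setdiff(seq_len(9), moved)
  expect_gt(length(moved), 0)
  expect_gt(length(kept), 0)
  # the side with fewer cores rotates
  expect_lte(length(moved), length(kept))
  # intra-segment pairwise distances preserved to 1e-9
  for (grp in list(moved, kept)) {
    if (length(grp) < 2) next
    before <- dist(cfg@coreXYZ[grp, , drop = FALSE])
    after <- dist(prop@coreXYZ[grp, , drop = FALSE])
    expect_equal(as.numeric(after), as.numeric(before), tolerance = 1e-9)
  }
  # frames stay orthonormal
  for (c in seq_len(9))
    expect_equal(crossprod(prop@coreFrames[, , c]), diag(3), tolerance = 1e-9)
  # zero amplitude leaves the configuration unchanged
  same <- globalPivot(cfg, fib, amplitudeDeg = 0, seed = 6, ff = ff)
  expect_equal(same@coreXYZ, cfg@coreXYZ, tolerance = 1e-12)
})

test_that("local moves respect their amplitude and triad orthonormality", {
  fib <- buildUniformFiber(5, 44)
  ff <- slimForceField()
  cfg <- initialConfiguration(fib, ff)
  for (s in 1:5) {
    prop <- localMove(cfg, fib, list(kind = "linker", index = 3L),
                      amplitudeNm = 0.7, seed = s, ff = ff)
    shift <- sqrt(sum((prop@linkerXYZ[3, ] - cfg@linkerXYZ[3, ])^2))
    expect_lte(shift, 0.7 + 1e-12)
    expect_equal(prop@linkerXYZ[-3, ], cfg@linkerXYZ[-3, ])
  }
  rot <- localMove(cfg, fib, list(kind = "core", index = 2L),
                   amplitudeNm = 0, rotateDeg = 25, seed = 2, ff = ff)
  expect_equal(crossprod(rot@coreFrames[, , 2]), diag(3), tolerance = 1e-9)
  expect_equal(rot@coreXYZ[2, ], cfg@coreXYZ[2, ], tolerance = 1e-12)
})

test_that("tail regrowth preserves bead counts and bond lengths", {
  ff <- defaultForceField(tailsPerCore = 2L, tailBeadsPerChain = 3L)
  fib <- buildUniformFiber(3, 44)
  cfg <- initialConfiguration(fib, ff)
  model <- chromoMC:::.beadModel(fib, ff)
  bondSpectrum <- function(cf, tailId) {
    chain <- model$tailChains[[tailId]]
    rows <- match(chain, model$tailBeadSites)
    X <- chromoMC:::.flattenConfiguration(cf, model)
    att <- X[model$tailAttach[tailId], ]
    pts <- rbind(att, cf@tailXYZ[rows, ])
    sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  }
  for (trialCount in c(1L, 8L)) {
    res <- tailRegrowth(cfg, fib, tailId = 2L, trialCount = trialCount, seed = 5,
                        ff = ff)
    expect_equal(dim(res$configuration@tailXYZ), dim(cfg@tailXYZ))
    expect_equal(bondSpectrum(res$configuration, 2L), bondSpectrum(cfg, 2L),
                 tolerance = 1e-9)
    expect_true(is.finite(res$logWeightRatio))
    # other tails untouched
    others <- setdiff(seq_len(nrow(cfg@tailXYZ)),
                      match(model$tailChains[[2]], model$tailBeadSites))
    expect_equal(res$configuration@tailXYZ[others, ], cfg@tailXYZ[others, ])
  }
})

test_that("tail-state swaps are involutive and accept identical geometry", {
  # make the folded and extended references identical: dE = 0, always accepted
  ffSame <- defaultForceField(tailsPerCore = 1L, tailBeadsPerChain = 2L,
                              foldedTailBondLength = 1.5)
  fib <- buildUniformFiber(2, 44)
  cfg <- initialConfiguration(fib, ffSame)
  once <- swapTailState(cfg, fib, coreId = 1L, seed = 3, ff = ffSame)
  expect_true(attr(once, "accepted"))
  expect_equal(once@tailXYZ, cfg@tailXYZ, tolerance = 1e-12)
  expect_true(once@tailFolded[1])
  # distinct geometries: a double swap restores the original coordinates
  ff <- defaultForceField(tailsPerCore = 1L, tailBeadsPerChain = 2L)
  cfg <- initialConfiguration(fib, ff)
  one <- swapTailState(cfg, fib, coreId = 1L, seed = 3, ff = ff)
  if (attr(one, "accepted")) {
    expect_false(isTRUE(all.equal(one@tailXYZ, cfg@tailXYZ)))
    two <- swapTailState(one, fib, coreId = 1L, seed = 4, ff = ff)
    if (attr(two, "accepted"))
      expect_equal(two@tailXYZ, cfg@tailXYZ, tolerance = 1e-9)
  }
})
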