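# Fiber topology builders and annotation operations

test_that("uniform fibers discretize linkers at ~9 bp per bead", {
  fib <- buildUniformFiber(50, 26)
  expect_equal(length(fib@runAfterCore), 49L)
  expect_true(all(fib@linkerBeads == 3L))        # round(26/9) = 3
  expect_true(all(fib@linkerBp == 26))
  expect_equal(sum(fib@lhOccupied), 0L)
  expect_equal(sum(fib@acetylated), 0L)
  expect_equal(sum(fib@tfBindable), 0L)

  expect_true(all(buildUniformFiber(50, 62)@linkerBeads == 7L))  # round(62/9)
  expect_true(all(buildUniformFiber(50, 44)@linkerBeads == 5L))

  single <- buildUniformFiber(1, 44)
  expect_equal(length(single@runAfterCore), 0L)
  expect_equal(length(single@tfBindable), 0L)

  expect_error(buildUniformFiber(0, 26), "invalid")
  expect_error(buildUniformFiber(10, -5), "invalid")
})

test_that("bead accounting holds on every builder output", {
  ffs <- list(buildUniformFiber(20, 44),
              buildLifelikeFiber(20, seed = 4),
              makeFixture("eed_wt")$topology)
  for (fib in ffs) {
    expect_equal(length(fib@tfBindable), sum(fib@linkerBeads))
    expect_equal(length(fib@lhOccupied), fib@nCores)
    expect_equal(nrow(fib@beadBp), sum(fib@linkerBeads))
    expect_true(all(fib@linkerBeads >= 1L))
  }
})

test_that("life-like fibers draw linkers from the mESC distribution", {
  expect_equal(sum(mESCLinkerDistribution()), 1)

  # degenerate distribution reproduces the uniform fiber
  degen <- buildLifelikeFiber(50, c(`26` = 1.0), seed = 11)
  expect_identical(degen@linkerBeads, buildUniformFiber(50, 26)@linkerBeads)
  expect_identical(degen@linkerBp, buildUniformFiber(50, 26)@linkerBp)

  # identical seeds give bitwise-identical topologies
  a <- buildLifelikeFiber(50, seed = 42)
  b <- buildLifelikeFiber(50, seed = 42)
  expect_identical(a@linkerBp, b@linkerBp)
  expect_false(identical(a@linkerBp, buildLifelikeFiber(50, seed = 43)@linkerBp))

  # law of large numbers: class frequencies within +/- 0.02 at 10,000 linkers
  big <- buildLifelikeFiber(10001, seed = 7)
  freq <- table(factor(big@linkerBp, levels = names(mESCLinkerDistribution())))
  freq <- as.numeric(freq) / sum(freq)
  expect_true(all(abs(freq - unname(mESCLinkerDistribution())) <= 0.02))

  expect_error(buildLifelikeFiber(50, c(`26` = 0.9), seed = 1), "sum to 1")
})

test_that("TF binding patterns mark the stated regions", {
  fib <- buildUniformFiber(50, 44)

  p1 <- applyTfTopology(fib, tfTopologySpec(1))
  expect_equal(nrow(p1@tfRegions), 5L)
  expect_true(all(p1@tfRegions$end - p1@tfRegions$start + 1L == 5L))
  # marked nucleosomes = region_count x region_span (pattern coverage)
  marked1 <- sum(p1@tfRegions$end - p1@tfRegions$start + 1L)
  expect_equal(marked1, 25L)

  p2 <- applyTfTopology(fib, tfTopologySpec(2))
  expect_equal(p2@tfRegions$start, c(1L, 36L))
  expect_equal(p2@tfRegions$end, c(15L, 50L))
  expect_equal(sum(p2@tfRegions$end - p2@tfRegions$start + 1L), 30L)

  p3 <- applyTfTopology(fib, tfTopologySpec(3))
  expect_equal(nrow(p3@tfRegions), 1L)
  expect_equal(p3@tfRegions$end - p3@tfRegions$start + 1L, 15L)
  # centred in the fiber
  expect_lte(abs((p3@tfRegions$start + p3@tfRegions$end) / 2 - 25.5), 1)

  for (pat in 1:4) {
    sp <- tfTopologySpec(pat)
    pp <- applyTfTopology(fib, sp)
    expect_equal(sum(pp@tfRegions$end - pp@tfRegions$start + 1L),
                 sp@regionCount * sp@regionSpan)
    # marks fall only on runs inside regions
    offsets <- c(0L, cumsum(pp@linkerBeads))
    markedRuns <- which(vapply(seq_along(pp@linkerBeads), function(r)
      any(pp@tfBindable[(offsets[r] + 1):offsets[r + 1]]), logical(1)))
    inRegion <- unlist(lapply(seq_len(nrow(pp@tfRegions)), function(k)
      seq(pp@tfRegions$start[k], pp@tfRegions$end[k] - 1L)))
    expect_setequal(pp@runAfterCore[markedRuns], inRegion)
  }

  expect_error(applyTfTopology(buildUniformFiber(10, 44), tfTopologySpec(2)),
               "does not fit")
  expect_error(tfTopologySpec(7), "patternId")
})

test_that("TF concentration marking floors, nests, and reproduces", {
  fib <- buildUniformFiber(50, 26)  # 147 linker beads
  expect_equal(sum(tfBindable(setTfConcentration(fib, 100, 1))), 147L)
  expect_equal(sum(tfBindable(setTfConcentration(fib, 0, 1))), 0L)
  expect_equal(sum(tfBindable(setTfConcentration(fib, 25, 1))), 36L) # floor(36.75)

  # nested and monotone for a fixed seed
  prev <- rep(FALSE, 147)
  for (pct in c(0, 10, 25, 50, 75, 100)) {
    cur <- tfBindable(setTfConcentration(fib, pct, seed = 9))
    expect_true(all(cur[prev]))
    expect_gte(sum(cur), sum(prev))
    prev <- cur
  }
  expect_identical(tfBindable(setTfConcentration(fib, 50, seed = 3)),
                   tfBindable(setTfConcentration(fib, 50, seed = 3)))
  expect_error(setTfConcentration(fib, 101, 1), "invalid")
})

test_that("linker histone placement follows the floor rule", {
  expect_equal(sum(placeLinkerHistones(buildUniformFiber(50, 44), 1)@lhOccupied), 50L)
  f129 <- buildUniformFiber(129, 44)
  expect_equal(sum(placeLinkerHistones(f129, 0.8, "random", seed = 2)@lhOccupied),
               103L)  # floor(103.2)
  pos <- c(3L, 17L, 90L)
  expl <- placeLinkerHistones(f129, 0.37, "explicit", positions = pos)
  expect_identical(which(expl@lhOccupied), pos)
  expect_error(placeLinkerHistones(f129, 1.2), "invalid")
  expect_error(placeLinkerHistones(f129, 0.5, "explicit"), "positions")
})

test_that("acetylation islands flag exactly the covered cores", {
  fib <- buildUniformFiber(50, 44)
  isl <- markAcetylation(fib, acetylationIslands50())
  expect_equal(sum(isl@acetylated), 24L)   # four 6-nucleosome islands
  expect_true(all(isl@acetylated[6:11]))
  expect_false(any(isl@acetylated[c(1:5, 12:16, 45:50)]))
  expect_equal(sum(markAcetylation(fib, list())@acetylated), 0L)
  expect_equal(sum(markAcetylation(fib, list(c(1, 50)))@acetylated), 50L)
  expect_error(markAcetylation(fib, list(c(45, 55))), "invalid")
})

test_that("topology text serialization round-trips bitwise", {
  fib <- makeFixture("eed_tf")$topology
  path <- tempfile(fileext = ".topo")
  writeTopology(fib, path)
  back <- readTopology(path)
  for (sl in slotNames("FiberTopology"))
    expect_identical(slot(back, sl), slot(fib, sl), label = sl)
})
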