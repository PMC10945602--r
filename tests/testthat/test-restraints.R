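# Dynamic restraint engagement/release rules

rp <- restraintParams()

# a 12-core 62 bp fiber gives 77 linker beads; all bindable
bindFib <- setTfConcentration(buildUniformFiber(12, 62), 100, 1)
slimFF <- slimForceField()

# place selected linker beads at controlled positions, everything else far
spreadConfig <- function(pairsAt = list()) {
  cfg <- initialConfiguration(bindFib, slimFF)
  # park all linker beads on a distant, well-separated line
  n <- nrow(cfg@linkerXYZ)
  cfg@linkerXYZ <- cbind(1e4 + 100 * seq_len(n), 0, 0)
  for (p in pairsAt) {
    cfg@linkerXYZ[p$i, ] <- c(p$at, 0, 0)
    cfg@linkerXYZ[p$j, ] <- c(p$at + p$dist, 0, 0)
  }
  cfg
}

test_that("eligible pairs engage within the capture radius", {
  cfg <- spreadConfig(list(list(i = 10L, j = 50L, at = 0, dist = 15)))
  rs <- updateRestraints(cfg, bindFib, restraintSet(params = rp), rp, slimFF)
  expect_equal(nrow(activeRestraints(rs)), 1L)
  expect_equal(activeRestraints(rs)[1, ], c(10L, 50L))
})

test_that("pairs closer than 30 beads along the chain are refused", {
  cfg <- spreadConfig(list(list(i = 10L, j = 30L, at = 0, dist = 5)))
  rs <- updateRestraints(cfg, bindFib, restraintSet(params = rp), rp, slimFF)
  expect_equal(nrow(activeRestraints(rs)), 0L)
})

test_that("engaged pairs separating beyond 20 nm are released", {
  engaged <- restraintSet(matrix(c(10L, 50L), 1, 2), rp)
  cfg <- spreadConfig(list(list(i = 10L, j = 50L, at = 0, dist = 25)))
  rs <- updateRestraints(cfg, bindFib, engaged, rp, slimFF)
  expect_equal(nrow(activeRestraints(rs)), 0L)
})

test_that("each bead holds at most one restraint, nearest pair first", {
  # bead 40 sits between beads 1 and 77; 40-77 is the closer admissible pair
  cfg <- spreadConfig(list())
  cfg@linkerXYZ[1, ] <- c(0, 0, 0)
  cfg@linkerXYZ[40, ] <- c(15, 0, 0)
  cfg@linkerXYZ[77, ] <- c(25, 0, 0)   # 10 nm from bead 40
  rs <- updateRestraints(cfg, bindFib, restraintSet(params = rp), rp, slimFF)
  p <- activeRestraints(rs)
  expect_equal(nrow(p), 1L)            # bead 1 is left unpartnered (> 20 nm)
  expect_equal(p[1, ], c(40L, 77L))
})

test_that("restraint-set invariants hold on randomized configurations", {
  for (seedv in 1:25) {
    cfg <- initialConfiguration(bindFib, slimFF)
    set.seed(seedv)
    cfg@linkerXYZ <- matrix(runif(length(cfg@linkerXYZ), 0, 55), ncol = 3)
    rs <- updateRestraints(cfg, bindFib, restraintSet(params = rp), rp, slimFF)
    p <- activeRestraints(rs)
    if (nrow(p) == 0) next
    expect_false(anyDuplicated(as.vector(p)) > 0)
    expect_true(all(abs(p[, 1] - p[, 2]) >= rp@minBeadSeparation))
    d <- sqrt(rowSums((cfg@linkerXYZ[p[, 1], , drop = FALSE] -
                       cfg@linkerXYZ[p[, 2], , drop = FALSE])^2))
    expect_true(all(d <= rp@captureRadius))
    # updates are deterministic given the configuration
    rs2 <- updateRestraints(cfg, bindFib, restraintSet(params = rp), rp, slimFF)
    expect_identical(activeRestraints(rs2), p)
  }
})

test_that("restraint-set validity enforces the bivalent-tetramer rule", {
  expect_error(restraintSet(matrix(c(1L, 40L, 40L, 77L), 2, 2, byrow = TRUE)),
               "at most one")
  expect_error(restraintSet(matrix(c(1L, 10L), 1, 2)), "separation")
})
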