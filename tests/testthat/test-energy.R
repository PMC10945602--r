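# Energy model: harmonic terms, screened electrostatics, excluded volume,
# restraints, and oracle equivalence against a brute-force double loop

kBT293 <- 0.0019872041 * 293

test_that("all harmonic terms vanish at the reference geometry", {
  fib <- placeLinkerHistones(buildUniformFiber(6, 44), 0.5)
  ff <- defaultForceField()
  cfg <- initialConfiguration(fib, ff)
  e <- energyComponents(totalEnergy(cfg, fib, ff))
  expect_equal(unname(e[c("ES","EB","ET","EtS","EtB","ElhS","ElhB")]),
               rep(0, 7), tolerance = 1e-12)
  expect_equal(unname(e["ETF"]), 0)
})

test_that("stretching a single bond is harmonic in the displacement", {
  fib <- buildUniformFiber(2, 9)   # one 1-bead linker
  ff <- slimForceField()
  cfg <- initialConfiguration(fib, ff)
  d <- (cfg@coreXYZ[2, ] - cfg@coreXYZ[1, ])
  d <- d / sqrt(sum(d^2))
  for (delta in c(0.1, 0.25, -0.2)) {
    cfg2 <- cfg
    cfg2@coreXYZ[2, ] <- cfg@coreXYZ[2, ] + delta * d
    el <- dnaElasticEnergy(cfg2, fib, ff)
    expect_equal(unname(el["ES"]), ff@dnaStretchConst * delta^2,
                 tolerance = 1e-8)
    expect_lt(unname(el["EB"]), 1e-9)  # axial displacement keeps collinearity
  }
})

test_that("bending a collinear triplet is harmonic in the angle", {
  fib <- buildUniformFiber(2, 27)  # 3-bead linker: interior angles exist
  ff <- slimForceField()
  cfg <- initialConfiguration(fib, ff)
  axis <- cfg@coreXYZ[2, ] - cfg@coreXYZ[1, ]
  axis <- axis / sqrt(sum(axis^2))
  perp <- c(-axis[2], axis[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  h <- 0.12
  cfg2 <- cfg
  cfg2@linkerXYZ[2, ] <- cfg@linkerXYZ[2, ] + h * perp
  # expected: sum of g*theta^2 over the three interior vertices of the
  # exit -> b1 -> b2 -> b3 -> entry path, from explicit geometry
  model <- chromoMC:::.beadModel(fib, ff)
  exitP <- cfg@coreXYZ[1, ] +
    as.numeric(cfg@coreFrames[, , 1] %*% model$local[model$exitSite[1], ])
  entryP <- cfg@coreXYZ[2, ] +
    as.numeric(cfg@coreFrames[, , 2] %*% model$local[model$entrySite[2], ])
  path <- rbind(exitP, cfg2@linkerXYZ, entryP)
  expected <- 0
  for (v in 2:4) {
    u1 <- path[v - 1, ] - path[v, ]; u2 <- path[v + 1, ] - path[v, ]
    th <- pi - acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2)))
    expected <- expected + ff@dnaBendConst * th^2
  }
  el <- dnaElasticEnergy(cfg2, fib, ff)
  expect_equal(unname(el["EB"]), expected, tolerance = 1e-9)
  expect_gt(expected, 0)
})

test_that("acetylated tails cost 100x the wildtype distortion energy", {
  ff <- defaultForceField(tailsPerCore = 1L, tailBeadsPerChain = 2L)
  wt <- buildUniformFiber(2, 44)
  ac <- markAcetylation(buildUniformFiber(2, 44), list(c(1, 2)))
  cw <- initialConfiguration(wt, ff)
  ca <- initialConfiguration(ac, ff)
  # displace the terminal tail bead of core 1 along its bond direction
  displace <- function(cfg, topo) {
    model <- chromoMC:::.beadModel(topo, ff)
    chain <- model$tailChains[[1]]
    rows <- match(chain, model$tailBeadSites)
    dirv <- cfg@tailXYZ[rows[2], ] - cfg@tailXYZ[rows[1], ]
    dirv <- dirv / sqrt(sum(dirv^2))
    cfg@tailXYZ[rows[2], ] <- cfg@tailXYZ[rows[2], ] + 0.2 * dirv
    cfg
  }
  ew <- tailLhEnergy(displace(cw, wt), wt, ff)
  ea <- tailLhEnergy(displace(ca, ac), ac, ff)
  expect_gt(ew["EtS"], 0)
  expect_equal(unname(ea["EtS"] / ew["EtS"]), 100, tolerance = 1e-6)
})

test_that("fibers without LH have zero LH terms", {
  fib <- buildUniformFiber(4, 44)
  e <- tailLhEnergy(initialConfiguration(fib), fib)
  expect_equal(unname(e[c("ElhS", "ElhB")]), c(0, 0))
})

test_that("screened Coulomb pair energy follows the closed form", {
  lambda <- 0.785
  kc <- 332.0637 / 80
  place <- function(r) matrix(c(0, 0, 0, r, 0, 0), 2, 3, byrow = TRUE)
  # zero charge partner -> zero energy
  e0 <- toyEnergy(toyModel(2, charges = c(5, 0), lambda = lambda), place(2))
  expect_equal(unname(e0["EC"]), 0)
  # at r = lambda_D the unscreened value is attenuated by exactly e^-1
  e1 <- toyEnergy(toyModel(2, charges = c(1, 1), lambda = lambda), place(lambda))
  expect_equal(unname(e1["EC"]), kc / lambda * exp(-1), tolerance = 1e-12)
  # bilinearity: doubling one charge doubles the pair energy
  e2 <- toyEnergy(toyModel(2, charges = c(2, 1), lambda = lambda), place(lambda))
  expect_equal(unname(e2["EC"]), 2 * unname(e1["EC"]), tolerance = 1e-12)
})

test_that("excluded volume is zero at contact and steep inside", {
  place <- function(r) matrix(c(0, 0, 0, r, 0, 0), 2, 3, byrow = TRUE)
  radii <- c(1.2, 1.2)  # contact at 2.4
  m <- toyModel(2, radii = radii)
  expect_equal(unname(toyEnergy(m, place(3))["EV"]), 0)
  expect_equal(unname(toyEnergy(m, place(2.4))["EV"]), 0, tolerance = 1e-10)
  inside <- unname(toyEnergy(m, place(1.2))["EV"])
  expect_gt(inside, kBT293)  # far above thermal energy at half contact
})

test_that("restraint energy is quadratic and even about the rest length", {
  fib <- setTfConcentration(buildUniformFiber(12, 62), 100, 1)
  ff <- slimForceField()
  cfg <- initialConfiguration(fib, ff)
  rp <- restraintParams()   # k = 20, l0 = 13
  setPair <- function(cfg, i, j, dist) {
    cfg@linkerXYZ[j, ] <- cfg@linkerXYZ[i, ] + c(dist, 0, 0)
    cfg
  }
  rs <- restraintSet(matrix(c(1L, 40L), 1, 2), rp)
  expect_equal(tfRestraintEnergy(rs, setPair(cfg, 1, 40, 13), fib, ff), 0)
  expect_equal(tfRestraintEnergy(rs, setPair(cfg, 1, 40, 14), fib, ff), 20)
  expect_equal(tfRestraintEnergy(rs, setPair(cfg, 1, 40, 12), fib, ff), 20)
  # even function of (l - l0), probed numerically
  for (d in c(0.5, 2, 4.7)) {
    up <- tfRestraintEnergy(rs, setPair(cfg, 1, 40, 13 + d), fib, ff)
    dn <- tfRestraintEnergy(rs, setPair(cfg, 1, 40, 13 - d), fib, ff)
    expect_equal(up, dn, tolerance = 1e-9)
    expect_equal(up, 20 * d^2, tolerance = 1e-9)
  }
  expect_equal(tfRestraintEnergy(restraintSet(), cfg, fib, ff), 0)
})

test_that("the breakdown total equals the component sum and is deterministic", {
  fib <- placeLinkerHistones(buildUniformFiber(5, 53), 0.6)
  ff <- defaultForceField()
  cfg <- initialConfiguration(fib, ff)
  cfg@linkerXYZ <- cfg@linkerXYZ + 0.05 * matrix(sin(seq_len(length(cfg@linkerXYZ))),
                                                 ncol = 3)
  e1 <- totalEnergy(cfg, fib, ff)
  e2 <- totalEnergy(cfg, fib, ff)
  expect_identical(energyComponents(e1), energyComponents(e2))
  expect_equal(energyTotal(e1), sum(energyComponents(e1)), tolerance = 1e-12)
})

test_that("adding a restraint away from rest length raises the total", {
  fib <- setTfConcentration(buildUniformFiber(12, 62), 100, 1)
  ff <- slimForceField()
  cfg <- initialConfiguration(fib, ff)
  base <- energyTotal(totalEnergy(cfg, fib, ff))
  rs <- restraintSet(matrix(c(1L, 50L), 1, 2))
  with <- energyTotal(totalEnergy(cfg, fib, ff, rs))
  expect_gt(with, base)
})

test_that("energy components match an independent brute-force double loop", {
  ff <- defaultForceField(tailsPerCore = 2L, tailBeadsPerChain = 2L,
                          nCoreCharges = 4L)
  fib <- placeLinkerHistones(
    markAcetylation(setTfConcentration(buildUniformFiber(8, 44), 60, 2),
                    list(c(2, 3))), 0.6)
  cfg <- initialConfiguration(fib, ff)
  set.seed(31)
  cfg@linkerXYZ <- cfg@linkerXYZ + matrix(rnorm(length(cfg@linkerXYZ), sd = 0.3),
                                          ncol = 3)
  cfg@tailXYZ <- cfg@tailXYZ + matrix(rnorm(length(cfg@tailXYZ), sd = 0.3),
                                      ncol = 3)
  cfg@lhXYZ <- cfg@lhXYZ + matrix(rnorm(length(cfg@lhXYZ), sd = 0.2), ncol = 3)
  rs <- restraintSet(matrix(c(2L, 33L), 1, 2))
  got <- energyComponents(totalEnergy(cfg, fib, ff, rs))
  want <- bruteForceEnergy(fib, ff, cfg, rs)
  for (comp in names(want))
    expect_equal(unname(got[comp]), unname(want[comp]), tolerance = 1e-9,
                 label = comp)
})

test_that("all energy terms are invariant under rigid-body transforms", {
  fib <- placeLinkerHistones(buildUniformFiber(4, 62), 0.5)
  ff <- defaultForceField()
  cfg <- initialConfiguration(fib, ff)
  e0 <- energyComponents(totalEnergy(cfg, fib, ff))
  R <- chromoMC:::.rotationAbout(c(1, 2, 3), 0.83)
  shift <- c(14, -3, 7)
  rot <- function(m) sweep(m %*% t(R), 2, shift, `+`)
  cfg2 <- cfg
  cfg2@coreXYZ <- rot(cfg@coreXYZ)
  cfg2@linkerXYZ <- rot(cfg@linkerXYZ)
  cfg2@tailXYZ <- rot(cfg@tailXYZ)
  cfg2@lhXYZ <- rot(cfg@lhXYZ)
  for (c in seq_len(nCores(fib)))
    cfg2@coreFrames[, , c] <- R %*% cfg@coreFrames[, , c]
  e1 <- energyComponents(totalEnergy(cfg2, fib, ff))
  expect_equal(e1, e0, tolerance = 1e-9)
})
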