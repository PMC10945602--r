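# shared helpers: light force fields, handcrafted toy bead models for the
# C++ kernel, naive reference implementations used as independent oracles

# small force field without tails/LH chatter, for geometry-focused tests
slimForceField <- function(...) {
  defaultForceField(tailsPerCore = 0L, nCoreCharges = 2L, coreCharge = 0,
                    linkerBeadCharge = 0, tailBeadCharge = 0, ...)
}

# a minimal hand-built cpp model: n free beads with given charges/radii and
# optional bonds (harmonic k, l0); used to probe single energy terms in
# isolation of the fiber machinery
toyModel <- function(n, charges = rep(0, n), radii = rep(0, n),
                     bonds = NULL, kBT = 0.5824 , kev = 0.35,
                     kc = 332.0637 / 80, lambda = 0.785, rcut = 1e6) {
  if (is.null(bonds))
    bonds <- list(i = integer(), j = integer(), cls = integer(),
                  core = integer(), k = numeric(), l0 = numeric(),
                  l0folded = numeric())
  list(nSites = n, nCores = 1L, nRuns = 0L,
       type = rep(0L, n), parent = rep(NA_integer_, n), group = rep(1L, n),
       chainPos = seq_len(n), linkerIndex = seq_len(n),
       charge = charges, radius = radii,
       interacting = rep(TRUE, n), bindable = rep(FALSE, n),
       bonds = bonds,
       angles = list(i = integer(), j = integer(), k = integer(),
                     cls = integer(), g = numeric(), theta0 = numeric()),
       coreSite = 1L, tails = list(), tailAttach = integer(),
       tailCore = integer(), twistS = 0, twistEq = numeric(),
       kev = kev, kc = kc, debyeLength = lambda, rcut = rcut, kBT = kBT)
}

toyEnergy <- function(model, positions) {
  chromoMC:::.cppTotalEnergy(model, as.numeric(t(positions)), numeric(0),
                             FALSE, matrix(integer(), 0, 2), 20, 13)
}

# independent brute-force evaluation of the full potential from the model
# tables (R double loops; no shared code with the C++ kernel)
bruteForceEnergy <- function(topology, ff, config, restraints = NULL) {
  model <- chromoMC:::.beadModel(topology, ff, config@twistOffsetDeg)
  X <- chromoMC:::.flattenConfiguration(config, model)
  cpp <- model$cpp
  folded <- config@tailFolded
  E <- setNames(numeric(10),
                c("ES","EB","ET","EtS","EtB","ElhS","ElhB","EV","EC","ETF"))
  compB <- c("ES", "EtS", "ElhS")
  for (b in seq_along(cpp$bonds$i)) {
    i <- cpp$bonds$i[b]; j <- cpp$bonds$j[b]
    l0 <- cpp$bonds$l0[b]
    bc <- cpp$bonds$core[b]
    if (!is.na(bc) && folded[bc]) l0 <- cpp$bonds$l0folded[b]
    d <- sqrt(sum((X[i, ] - X[j, ])^2))
    E[compB[cpp$bonds$cls[b] + 1]] <- E[compB[cpp$bonds$cls[b] + 1]] +
      cpp$bonds$k[b] * (d - l0)^2
  }
  compA <- c("EB", "EtB", "ElhB")
  for (a in seq_along(cpp$angles$i)) {
    u <- X[cpp$angles$i[a], ] - X[cpp$angles$j[a], ]
    v <- X[cpp$angles$k[a], ] - X[cpp$angles$j[a], ]
    th <- pi - acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    E[compA[cpp$angles$cls[a] + 1]] <- E[compA[cpp$angles$cls[a] + 1]] +
      cpp$angles$g[a] * (th - cpp$angles$theta0[a])^2
  }
  tw <- config@twistDeg * pi / 180
  E["ET"] <- sum(cpp$twistS * (tw - cpp$twistEq)^2)
  bondedPairs <- paste(pmin(cpp$bonds$i, cpp$bonds$j),
                       pmax(cpp$bonds$i, cpp$bonds$j))
  inter <- which(cpp$interacting)
  for (ii in seq_along(inter)) {
    for (jj in seq_len(ii - 1L)) {
      i <- inter[ii]; j <- inter[jj]
      pi_ <- cpp$parent[i]; pj <- cpp$parent[j]
      if (!is.na(pi_) && !is.na(pj) && pi_ == pj) next
      if (paste(min(i, j), max(i, j)) %in% bondedPairs) next
      r <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (r > cpp$rcut) next
      if (cpp$radius[i] > 0 && cpp$radius[j] > 0) {
        sig <- cpp$radius[i] + cpp$radius[j]
        if (r < sig) {
          s6 <- (sig / r)^6
          E["EV"] <- E["EV"] + cpp$kev * (s6^2 - 2 * s6 + 1)
        }
      }
      qq <- cpp$charge[i] * cpp$charge[j]
      if (qq != 0)
        E["EC"] <- E["EC"] + cpp$kc * qq * exp(-r / cpp$debyeLength) / r
    }
  }
  if (!is.null(restraints) && nrow(restraints@pairs)) {
    sm <- matrix(model$linkerSites[restraints@pairs], ncol = 2)
    for (r in seq_len(nrow(sm))) {
      d <- sqrt(sum((X[sm[r, 1], ] - X[sm[r, 2], ])^2))
      E["ETF"] <- E["ETF"] + restraints@params@k * (d - restraints@params@l0)^2
    }
  }
  E
}

# naive reference DBSCAN (repeat-scan label merging; independent of the
# package's queue-based implementation)
naiveDbscan <- function(D, eps, minPts) {
  n <- nrow(D)
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= minPts, logical(1))
  labels <- rep(0L, n)
  cl <- 0L
  for (i in which(core)) {
    if (labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    repeat {
      grew <- FALSE
      for (j in which(core & labels == cl)) {
        nb <- which(D[j, ] <= eps)
        newCore <- nb[core[nb] & labels[nb] == 0L]
        if (length(newCore)) { labels[newCore] <- cl; grew <- TRUE }
      }
      if (!grew) break
    }
  }
  # border points join the cluster of the nearest core point within eps
  for (i in which(!core & labels == 0L)) {
    nb <- which(D[i, ] <= eps & core)
    if (length(nb)) labels[i] <- labels[nb[which.min(D[i, nb])]]
  }
  labels
}

# partitions equal up to label permutation (noise must match exactly)
samePartition <- function(a, b) {
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ok <- a != 0L
  if (!any(ok)) return(TRUE)
  identical(outer(a[ok], a[ok], "=="), outer(b[ok], b[ok], "=="))
}

# minimal Trajectory for bookkeeping tests (frames share one configuration)
mockTrajectory <- function(topology, ff, nSteps, saveEvery, seed = 1,
                           engagedPairsPerFrame = NULL) {
  cfg <- initialConfiguration(topology, ff)
  nF <- nSteps / saveEvery
  restr <- if (is.null(engagedPairsPerFrame))
    replicate(nF, matrix(integer(), 0, 2), simplify = FALSE)
  else replicate(nF, engagedPairsPerFrame, simplify = FALSE)
  en <- matrix(0, nF, 11,
               dimnames = list(NULL, c("ES","EB","ET","EtS","EtB","ElhS",
                                       "ElhB","EV","EC","ETF","total")))
  acc <- matrix(c(rep(10, 5), rep(5, 5)), 5, 2,
                dimnames = list(c("pivot","linker","core","lh","tail"),
                                c("tried", "accepted")))
  new("Trajectory", topology = topology, forceField = ff,
      restraintParams = restraintParams(), initial = cfg,
      frames = replicate(nF, cfg, simplify = FALSE),
      restraints = restr, energies = en, seed = seed, twistOffsetDeg = 0,
      nSteps = nSteps, saveEvery = saveEvery, acceptance = acc,
      events = data.frame(step = numeric(), i = integer(), j = integer(),
                          engaged = integer()))
}
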