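# Structured run configuration (YAML). Strict schema: unknown keys are
# rejected, defaults are applied, and constraint violations name the key.

.CONFIG_SCHEMA_VERSION <- 1L

.configDefaults <- function() {
  list(
    schema_version = .CONFIG_SCHEMA_VERSION,
    system = list(builder = "uniform", n_cores = 50L, linker_bp = 44,
                  seed = 1L, fixture = NULL, region_bp = NULL, nrl_bp = NULL,
                  nfr_bed = NULL, lh_bed = NULL, tf_bed = NULL,
                  target_cores = NULL,
                  tf = list(pattern = NULL, concentration = NULL, seed = 1L),
                  lh = list(density = 0, mode = "uniform", seed = 1L),
                  acetylation = list(islands = list())),
    forcefield = list(),
    restraints = list(k = 20, l0 = 13, capture_radius = 20,
                      min_bead_separation = 30L),
    mc = list(replicas = 10L, steps = 5e7, save_every = 1e5, seed_base = 1L),
    analysis = list(ops = c("packing", "sed", "rg", "map"),
                    ensemble_tail_steps = 1e7, eps = 2, minpoints = 5L,
                    alpha = 100, promoter_cores = NULL, cutoff_nm = 2),
    output = list(dir = "chromoMC_out"))
}

# recursive default merge; unlike modifyList it replaces unnamed lists
# (e.g. lists of island ranges) instead of silently dropping them
.mergeConfig <- function(def, new) {
  for (k in names(new)) {
    named <- function(x) is.list(x) && length(x) && !is.null(names(x)) &&
      all(nzchar(names(x)))
    def[[k]] <- if (named(def[[k]]) && named(new[[k]]))
      .mergeConfig(def[[k]], new[[k]])
    else new[[k]]
  }
  def
}

.checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("config error in '", where, "': unknown key(s) ",
         paste(unknown, collapse = ", "))
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, applies documented
#' defaults, and validates constraints (positive sizes, percentages in range,
#' known builders). Force-field overrides are validated against the
#' \linkS4class{ForceField} slots.
#'
#' @param path YAML file.
#' @return a validated \linkS4class{RunConfig}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  def <- .configDefaults()
  .checkKeys(raw, names(def), "top level")
  if (!is.null(raw$schema_version) &&
      raw$schema_version != .CONFIG_SCHEMA_VERSION)
    stop("config error: unsupported schema_version ", raw$schema_version)
  merged <- def
  for (sec in intersect(names(raw), names(def))) {
    if (sec == "schema_version") next
    .checkKeys(raw[[sec]], names(def[[sec]]), sec)
    merged[[sec]] <- .mergeConfig(def[[sec]], raw[[sec]])
  }
  sys <- merged$system
  if (!sys$builder %in% c("uniform", "lifelike", "gene", "fixture"))
    stop("config error in 'system.builder': unknown builder '", sys$builder, "'")
  if (sys$builder %in% c("uniform", "lifelike") &&
      (!is.numeric(sys$n_cores) || sys$n_cores < 1))
    stop("config error in 'system.n_cores': must be a positive integer")
  if (sys$builder == "uniform" &&
      (!is.numeric(sys$linker_bp) || sys$linker_bp <= 0))
    stop("config error in 'system.linker_bp': must be positive")
  if (!is.null(sys$tf$concentration) &&
      (sys$tf$concentration < 0 || sys$tf$concentration > 100))
    stop("config error in 'system.tf.concentration': must be in [0, 100]")
  if (sys$lh$density < 0 || sys$lh$density > 1)
    stop("config error in 'system.lh.density': must be in [0, 1]")
  ffKeys <- slotNames("ForceField")
  .checkKeys(merged$forcefield, ffKeys, "forcefield")
  rs <- merged$restraints
  if (rs$k <= 0) stop("config error in 'restraints.k': must be > 0")
  if (rs$l0 >= rs$capture_radius)
    stop("config error in 'restraints.l0': must be below capture_radius")
  mc <- merged$mc
  if (mc$steps %% mc$save_every != 0)
    stop("config error in 'mc.steps': must be a multiple of mc.save_every")
  new("RunConfig", system = merged$system, forcefield = merged$forcefield,
      restraints = merged$restraints, mc = merged$mc,
      analysis = merged$analysis, output = merged$output)
}

#' Materialize the objects described by a run configuration
#'
#' @param config a \linkS4class{RunConfig}.
#' @return list with \code{topology}, \code{forceField},
#'   \code{restraintParams}, and \code{plan}.
#' @export
configToSystem <- function(config) {
  stopifnot(is(config, "RunConfig"))
  sys <- config@system
  topo <- switch(sys$builder,
    uniform = buildUniformFiber(sys$n_cores, sys$linker_bp),
    lifelike = buildLifelikeFiber(sys$n_cores, seed = sys$seed),
    fixture = makeFixture(sys$fixture, seed = sys$seed)$topology,
    gene = buildGeneFiber(sys$region_bp,
                          readTrack(sys$nfr_bed),
                          nrlBp = if (is.null(sys$nrl_bp)) 189 else sys$nrl_bp,
                          lhTrack = if (is.null(sys$lh_bed)) sys$lh$density
                                    else readTrack(sys$lh_bed),
                          tfTrack = if (is.null(sys$tf_bed)) NULL
                                    else readTrack(sys$tf_bed),
                          seed = sys$seed, targetCores = sys$target_cores))
  if (!is.null(sys$tf$pattern))
    topo <- applyTfTopology(topo, tfTopologySpec(sys$tf$pattern))
  if (!is.null(sys$tf$concentration))
    topo <- setTfConcentration(topo, sys$tf$concentration, seed = sys$tf$seed)
  if (sys$builder != "gene" && sys$lh$density > 0)
    topo <- placeLinkerHistones(topo, sys$lh$density, mode = sys$lh$mode,
                                seed = sys$lh$seed)
  if (length(sys$acetylation$islands))
    topo <- markAcetylation(topo, sys$acetylation$islands)
  ff <- do.call(defaultForceField, config@forcefield)
  rp <- restraintParams(k = config@restraints$k, l0 = config@restraints$l0,
                        captureRadius = config@restraints$capture_radius,
                        minBeadSeparation = config@restraints$min_bead_separation)
  plan <- replicaPlan(config@mc$replicas, config@mc$steps,
                      config@mc$save_every, seedBase = config@mc$seed_base)
  list(topology = topo, forceField = ff, restraintParams = rp, plan = plan)
}
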