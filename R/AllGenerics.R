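#' @name chromoMC-generics
#' @title Generics for chromoMC containers
#' @description Accessor and analysis generics shared across the package's
#'   S4 containers.
#' @param x,object a chromoMC object.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname chromoMC-generics
#' @export
setGeneric("nCores", function(x) standardGeneric("nCores"))

#' @rdname chromoMC-generics
#' @export
setGeneric("linkerBeadCount", function(x) standardGeneric("linkerBeadCount"))

#' @rdname chromoMC-generics
#' @export
setGeneric("tfBindable", function(x) standardGeneric("tfBindable"))

#' @rdname chromoMC-generics
#' @export
setGeneric("lhDensity", function(x) standardGeneric("lhDensity"))

#' @rdname chromoMC-generics
#' @export
setGeneric("acetylated", function(x) standardGeneric("acetylated"))

#' @rdname chromoMC-generics
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname chromoMC-generics
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname chromoMC-generics
#' @export
setGeneric("fiberTopology", function(x) standardGeneric("fiberTopology"))

#' @rdname chromoMC-generics
#' @export
setGeneric("contactMatrix", function(x, ...) standardGeneric("contactMatrix"))

#' @rdname chromoMC-generics
#' @export
setGeneric("activeRestraints", function(x, ...) standardGeneric("activeRestraints"))

#' @rdname chromoMC-generics
#' @export
setGeneric("totalEnergy", function(config, topology, ff, restraints = NULL, ...)
  standardGeneric("totalEnergy"))

#' @rdname chromoMC-generics
#' @export
setGeneric("contactMap", function(x, ...) standardGeneric("contactMap"))

#' @rdname chromoMC-generics
#' @export
setGeneric("packingRatio", function(x, ...) standardGeneric("packingRatio"))

#' @rdname chromoMC-generics
#' @export
setGeneric("radiusOfGyration", function(x, ...) standardGeneric("radiusOfGyration"))

#' @rdname chromoMC-generics
#' @export
setGeneric("sedimentationCoefficient", function(x, ...)
  standardGeneric("sedimentationCoefficient"))
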