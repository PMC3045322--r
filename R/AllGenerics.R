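#' @name gsmvault-generics
#' @title Generics for model containers
#' @description Accessor and operation generics for [MetabolicModel-class],
#'   [ModelStore-class] and [ModelComparison-class] objects.
#' @param object,x An object.
#' @param ... Method-specific arguments.
NULL

#' @rdname gsmvault-generics
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))

#' @rdname gsmvault-generics
#' @export
setGeneric("organism", function(object) standardGeneric("organism"))

#' @rdname gsmvault-generics
#' @export
setGeneric("versionLabel", function(object) standardGeneric("versionLabel"))

#' @rdname gsmvault-generics
#' @export
setGeneric("compartments", function(object, ...) standardGeneric("compartments"))

#' @rdname gsmvault-generics
#' @export
setGeneric("metabolites", function(object, ...) standardGeneric("metabolites"))

#' @rdname gsmvault-generics
#' @export
setGeneric("reactions", function(object, ...) standardGeneric("reactions"))

#' @rdname gsmvault-generics
#' @export
setGeneric("genes", function(object, ...) standardGeneric("genes"))

#' @rdname gsmvault-generics
#' @export
setGeneric("subsystems", function(object) standardGeneric("subsystems"))
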