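## Generics. Implementations live in the module files; documentation is on
## the methods' surface functions.

#' @rdname registerType
#' @export
setGeneric("registerType", function(registry, descriptor)
  standardGeneric("registerType"))

#' @rdname subsumes
#' @export
setGeneric("subsumes", function(registry, ancestor, descendant)
  standardGeneric("subsumes"))

#' @rdname lookupType
#' @export
setGeneric("lookupType", function(registry, typeName)
  standardGeneric("lookupType"))

#' @rdname validateInstance
#' @export
setGeneric("validateInstance", function(registry, instance)
  standardGeneric("validateInstance"))

#' @rdname schemaStats
#' @export
setGeneric("schemaStats", function(registry) standardGeneric("schemaStats"))

#' @rdname dumpSchema
#' @export
setGeneric("dumpSchema", function(registry, path)
  standardGeneric("dumpSchema"))

#' @rdname addAnnotation
#' @export
setGeneric("addAnnotation", function(store, typeName, begin = NA, end = NA,
                                     features = list())
  standardGeneric("addAnnotation"))

#' @rdname getByType
#' @export
setGeneric("getByType", function(store, typeName, includeSubtypes = TRUE)
  standardGeneric("getByType"))

#' @rdname selectCovered
#' @export
setGeneric("selectCovered", function(store, typeName, begin, end)
  standardGeneric("selectCovered"))

#' @rdname serializeStore
#' @export
setGeneric("serializeStore", function(store) standardGeneric("serializeStore"))

#' @rdname validateStore
#' @export
setGeneric("validateStore", function(store) standardGeneric("validateStore"))

#' @rdname resolveDocument
#' @export
setGeneric("resolveDocument", function(store, config = bridgeConfig())
  standardGeneric("resolveDocument"))

#' @rdname buildCorefChains
#' @export
setGeneric("buildCorefChains", function(store)
  standardGeneric("buildCorefChains"))

#' @rdname writeCetypeXml
#' @export
setGeneric("writeCetypeXml", function(model) standardGeneric("writeCetypeXml"))

#' @rdname generateStore
#' @export
setGeneric("generateStore", function(spec) standardGeneric("generateStore"))
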