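## schema_registry: the meta level. Types are registered one at a time into
## a single-inheritance forest; subsumption, instance validation and the
## conformance statistics all read off the registered descriptors.

#' Construct a feature descriptor
#'
#' @param name Feature name (identifier).
#' @param range Feature range; see [FeatureDescriptor-class].
#' @param declaringType Qualified name of the declaring type (filled in by
#'   [typeDescriptor()] when omitted).
#' @param reconstructed Flag for reconstructed inventory slots.
#' @return A [FeatureDescriptor-class] object.
#' @export
#' @examples
#' featureDescriptor("severity", "ref:refsem.Severity")
featureDescriptor <- function(name, range, declaringType = NA_character_,
                              reconstructed = FALSE) {
  new("FeatureDescriptor", name = name, range = range,
      declaringType = declaringType, reconstructed = reconstructed)
}

#' Construct a type descriptor
#'
#' @param qualifiedName Qualified type name, `"<namespace>.<Name>"`.
#' @param supertype Qualified supertype name or a root marker
#'   (`"SPAN_ROOT"`/`"TOP"`).
#' @param features List of [FeatureDescriptor-class] (their `declaringType`
#'   is stamped with `qualifiedName`).
#' @param spanned Whether instances carry a text span. Defaults to the
#'   supertype's spanned-ness when that can be inferred from the root
#'   markers (`SPAN_ROOT` implies `TRUE`, `TOP` implies `FALSE`); it is
#'   checked against the supertype at registration.
#' @param reconstructed Flag for reconstructed inventory slots.
#' @return A [TypeDescriptor-class] object.
#' @export
#' @examples
#' typeDescriptor("refsem.SignSymptom", "refsem.Event", spanned = FALSE)
typeDescriptor <- function(qualifiedName, supertype, features = list(),
                           spanned = NA, reconstructed = FALSE) {
  if (is.na(spanned))
    spanned <- switch(supertype, SPAN_ROOT = TRUE, TOP = FALSE,
                      NA)  # non-root supertypes: resolved at registration
  features <- lapply(features, function(f) {
    f@declaringType <- qualifiedName
    validObject(f)
    f
  })
  new("TypeDescriptor",
      qualifiedName = qualifiedName,
      namespace = sub("\\..*$", "", qualifiedName),
      supertype = supertype,
      spanned = spanned,
      features = features,
      reconstructed = reconstructed)
}

#' Create an empty schema registry
#'
#' @return An empty [SchemaRegistry-class].
#' @export
schemaRegistry <- function() new("SchemaRegistry")

#' Register an annotation type
#'
#' Adds one [TypeDescriptor-class] to the registry. The supertype must
#' already be registered (or be a root marker), the qualified name must be
#' new, the namespace must be one of the seven, and the declared spanned-ness
#' must agree with the supertype's: the single-inheritance tree keeps spanned
#' and unspanned types in separate subtrees. The direct-subtype index of the
#' supertype is updated.
#'
#' @param registry A [SchemaRegistry-class].
#' @param descriptor A [TypeDescriptor-class].
#' @return The updated registry.
#' @export
#' @examples
#' reg <- schemaRegistry()
#' reg <- registerType(reg, typeDescriptor("refsem.Element", "TOP"))
#' reg <- registerType(reg, typeDescriptor("refsem.Event", "refsem.Element"))
setMethod("registerType", "SchemaRegistry", function(registry, descriptor) {
  stopifnot(is(descriptor, "TypeDescriptor"))
  validObject(descriptor)
  qn <- descriptor@qualifiedName
  if (!descriptor@namespace %in% clinNamespaces())
    stop(sprintf("schema error: unknown namespace '%s' for type '%s'",
                 descriptor@namespace, qn))
  if (!is.null(registry@types[[qn]]))
    stop(sprintf("schema error: duplicate type name '%s'", qn))
  st <- descriptor@supertype
  if (st %in% .root_markers()) {
    expected <- identical(st, SPAN_ROOT)
  } else {
    std <- registry@types[[st]]
    if (is.null(std))
      stop(sprintf("schema error: unknown supertype '%s' for type '%s'",
                   st, qn))
    expected <- std@spanned
  }
  if (is.na(descriptor@spanned)) descriptor@spanned <- expected
  if (!identical(descriptor@spanned, expected))
    stop(sprintf(
      "schema error: type '%s' declares spanned=%s but its supertype chain implies %s",
      qn, descriptor@spanned, expected))
  ## inherited features must not be re-declared
  inherited <- names(.collect_features(registry, st))
  clash <- intersect(vapply(descriptor@features, function(f) f@name,
                            character(1)), inherited)
  if (length(clash))
    stop(sprintf("schema error: type '%s' re-declares inherited feature(s): %s",
                 qn, paste(clash, collapse = ", ")))
  registry@types[[qn]] <- descriptor
  registry@typeOrder <- c(registry@typeOrder, qn)
  registry@children[[st]] <- c(registry@children[[st]], qn)
  if (is.null(registry@children[[qn]])) registry@children[[qn]] <- character()
  registry
})

#' Look up a registered type
#'
#' @param registry A [SchemaRegistry-class].
#' @param typeName Qualified type name.
#' @return The [TypeDescriptor-class]; error if unregistered.
#' @export
setMethod("lookupType", "SchemaRegistry", function(registry, typeName) {
  td <- registry@types[[typeName]]
  if (is.null(td))
    stop(sprintf("unknown type '%s'", typeName))
  td
})

## Supertype chain from a type up to (excluding) the root marker.
.ancestors <- function(registry, typeName) {
  out <- character()
  cur <- typeName
  repeat {
    td <- registry@types[[cur]]
    if (is.null(td)) stop(sprintf("unknown type '%s'", cur))
    st <- td@supertype
    if (st %in% .root_markers()) return(out)
    out <- c(out, st)
    cur <- st
  }
}

## All features visible on a type (own + inherited), named by feature name.
## `typeName` may be a root marker (empty result).
.collect_features <- function(registry, typeName) {
  if (typeName %in% .root_markers()) return(list())
  chain <- c(typeName, .ancestors(registry, typeName))
  out <- list()
  for (tn in rev(chain)) {        # supertype features first
    for (f in registry@types[[tn]]@features) out[[f@name]] <- f
  }
  out
}

#' All transitive subtypes of a type
#'
#' @param registry A [SchemaRegistry-class].
#' @param typeName Qualified type name (or a root marker).
#' @param includeSelf Include `typeName` itself (default `TRUE`; root
#'   markers are never included).
#' @return Character vector of qualified names.
#' @export
subtypesOf <- function(registry, typeName, includeSelf = TRUE) {
  if (!typeName %in% .root_markers()) lookupType(registry, typeName)
  out <- character()
  frontier <- typeName
  while (length(frontier)) {
    kids <- unlist(registry@children[frontier], use.names = FALSE)
    out <- c(out, kids)
    frontier <- kids
  }
  if (includeSelf && !typeName %in% .root_markers()) out <- c(typeName, out)
  out
}

#' Type subsumption
#'
#' `TRUE` iff `descendant` equals `ancestor` or `ancestor` lies on the
#' supertype chain of `descendant`. Subsumption is reflexive, transitive and
#' antisymmetric (a partial order): defining a subtype is the idiomatic way
#' to subset annotations, and the store indices rely on it.
#'
#' @param registry A [SchemaRegistry-class].
#' @param ancestor,descendant Qualified type names (both must be registered).
#' @return Logical scalar.
#' @export
#' @examples
#' reg <- defaultRegistry()
#' subsumes(reg, "textsem.IdentifiedAnnotation", "textsem.EventMention")
#' subsumes(reg, "refsem.Entity", "refsem.Event")  # siblings: FALSE
setMethod("subsumes", "SchemaRegistry", function(registry, ancestor,
                                                 descendant) {
  lookupType(registry, ancestor)
  if (identical(ancestor, descendant)) {
    lookupType(registry, descendant)
    return(TRUE)
  }
  ancestor %in% .ancestors(registry, descendant)
})

## Does `value` fit `range`? Reference targets are checked at store level.
.value_fits_range <- function(value, range) {
  switch(range,
    boolean = is.logical(value) && length(value) == 1L && !is.na(value),
    integer = (is.integer(value) ||
                 (is.numeric(value) && all(value == trunc(value)))) &&
              length(value) == 1L && !is.na(value),
    float = is.numeric(value) && length(value) == 1L && !is.na(value),
    string = is.character(value) && length(value) == 1L && !is.na(value),
    stringarray = is.character(value) && !anyNA(value),
    {
      if (startsWith(range, "ref:"))
        isClinRef(value) && length(value) == 1L
      else if (startsWith(range, "refarray:"))
        isClinRef(value)
      else FALSE
    })
}

#' Validate an instance against the schema
#'
#' Checks one [AnnotationInstance-class] against the registry: the type must
#' be registered; a span must be present iff the type is spanned; every
#' feature must be declared on the type or an ancestor; values must match the
#' declared ranges; the four shared attribute types
#' (`refsem.Severity`, `refsem.Course`, `refsem.BodySide`,
#' `refsem.BodyLaterality`) must hold values from their documented value
#' sets, concept identifiers must match their pattern constraints, and
#' `refsem.Date` fields must form a valid calendar date when all set.
#' Violations are returned, never raised.
#'
#' @param registry A [SchemaRegistry-class].
#' @param instance An [AnnotationInstance-class].
#' @return Character vector of violations; empty when valid.
#' @export
#' @examples
#' reg <- defaultRegistry()
#' sev <- annotationInstance("refsem.Severity", features = list(value = "severe"))
#' validateInstance(reg, sev)  # character(0)
setMethod("validateInstance", c("SchemaRegistry", "AnnotationInstance"),
          function(registry, instance) {
  violations <- character()
  td <- registry@types[[instance@typeName]]
  if (is.null(td))
    return(sprintf("unknown type '%s'", instance@typeName))
  has_span <- !is.na(instance@begin) && !is.na(instance@end)
  if (td@spanned && !has_span)
    violations <- c(violations,
      sprintf("type '%s' is spanned but instance has no begin/end offsets",
              td@qualifiedName))
  if (!td@spanned && has_span)
    violations <- c(violations,
      sprintf("type '%s' is unspanned but instance carries begin/end offsets",
              td@qualifiedName))
  declared <- .collect_features(registry, instance@typeName)
  for (fname in names(instance@features)) {
    fd <- declared[[fname]]
    value <- instance@features[[fname]]
    if (is.null(fd)) {
      violations <- c(violations,
        sprintf("feature '%s' is not declared on '%s' or its ancestors",
                fname, instance@typeName))
      next
    }
    if (!.value_fits_range(value, fd@range))
      violations <- c(violations,
        sprintf("feature '%s' value does not match range '%s'",
                fname, fd@range))
  }
  violations <- c(violations,
                  .check_value_constraints(registry, instance))
  violations
})

## Constants-file driven constraints: closed value sets on the four shared
## attributes, regex-constrained identifier features, calendar-valid dates.
.check_value_constraints <- function(registry, instance) {
  cons <- clinConstants()
  violations <- character()
  tn <- instance@typeName
  chain <- c(tn, tryCatch(.ancestors(registry, tn), error = function(e) character()))
  for (vt in intersect(chain, names(cons$valueSets))) {
    allowed <- cons$valueSets[[vt]]
    v <- instance@features[["value"]]
    if (!is.null(v) && is.character(v) && !all(v %in% allowed))
      violations <- c(violations,
        sprintf("value '%s' outside the %s value set {%s}",
                paste(setdiff(v, allowed), collapse = ", "), vt,
                paste(allowed, collapse = ", ")))
  }
  for (pt in intersect(chain, names(cons$patterns))) {
    pats <- cons$patterns[[pt]]
    for (fname in names(pats)) {
      v <- instance@features[[fname]]
      if (!is.null(v) && is.character(v) && !all(grepl(pats[[fname]], v)))
        violations <- c(violations,
          sprintf("feature '%s' value '%s' does not match pattern %s",
                  fname, paste(v, collapse = ","), pats[[fname]]))
    }
  }
  if (tn == "refsem.Date") {
    f <- instance@features
    if (!is.null(f$day) && !is.null(f$month) && !is.null(f$year)) {
      d <- tryCatch(as.Date(sprintf("%04d-%02d-%02d", f$year, f$month,
                                    f$day)),
                    error = function(e) NA)
      if (is.na(d))
        violations <- c(violations,
          sprintf("day/month/year %d/%d/%d is not a valid calendar date",
                  f$day, f$month, f$year))
    }
  }
  violations
}

#' Per-namespace schema statistics
#'
#' Counts types and declared features per namespace. A feature counts once,
#' at the type that declares it; inherited features are never double-counted
#' (the only convention under which the per-namespace budgets are additive).
#' On the shipped normative schema the totals are 100 types and 207 declared
#' features across the 7 namespaces, 2.07 features per type.
#'
#' @param registry A [SchemaRegistry-class].
#' @return A `data.frame` with columns `namespace`, `types`, `features`, one
#'   row per namespace.
#' @export
#' @examples
#' stats <- schemaStats(defaultRegistry())
#' sum(stats$types)     # 100
#' sum(stats$features)  # 207
setMethod("schemaStats", "SchemaRegistry", function(registry) {
  ns_order <- c("structured", "syntax", "refsem", "textsem", "textspan",
                "util", "relation")
  ns <- vapply(registry@types, function(td) td@namespace, character(1))
  nf <- vapply(registry@types, function(td) length(td@features), integer(1))
  data.frame(
    namespace = ns_order,
    types = vapply(ns_order, function(n) sum(ns == n), integer(1)),
    features = vapply(ns_order, function(n) sum(nf[ns == n]), integer(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
})

## ---- schema descriptor file (JSON lines, one type per line) ----

.descriptor_to_json <- function(td) {
  feats <- lapply(td@features, function(f) {
    x <- list(name = f@name, range = f@range)
    if (isTRUE(f@reconstructed)) x$reconstructed <- TRUE
    x
  })
  x <- list(name = td@qualifiedName, namespace = td@namespace,
            supertype = td@supertype, spanned = td@spanned,
            features = feats)
  if (isTRUE(td@reconstructed)) x$reconstructed <- TRUE
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

#' Write a registry to a schema descriptor file
#'
#' The descriptor dialect is line-oriented JSON: one type object per line,
#' `{"name", "namespace", "supertype", "spanned", "features": [...]}`, in
#' registration order. `dumpSchema` followed by [loadSchema()] is the
#' identity, and the output of `dumpSchema` is the canonical form (stable key
#' and line order), so equal registries produce byte-identical files.
#'
#' @param registry A [SchemaRegistry-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
setMethod("dumpSchema", "SchemaRegistry", function(registry, path) {
  lines <- vapply(registry@typeOrder, function(qn)
    .descriptor_to_json(registry@types[[qn]]), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
})

.descriptor_from_json <- function(x, line) {
  required <- c("name", "namespace", "supertype", "spanned")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("schema parse error at line %d: missing field(s) %s",
                 line, paste(missing, collapse = ", ")))
  feats <- lapply(x$features, function(f)
    featureDescriptor(f$name, f$range,
                      reconstructed = isTRUE(f$reconstructed)))
  typeDescriptor(x$name, x$supertype, features = feats,
                 spanned = isTRUE(x$spanned),
                 reconstructed = isTRUE(x$reconstructed))
}

#' Load a schema descriptor file
#'
#' Reads a line-oriented JSON schema descriptor file (see [dumpSchema()]) and
#' registers every type in file order. Parse errors report the offending
#' line number; semantic errors (duplicate names, unknown supertypes or
#' namespaces, cyclic inheritance — impossible to register because a
#' supertype must precede its subtypes) are raised as in [registerType()].
#' After loading, every feature's reference range must resolve to a
#' registered type (or root marker).
#'
#' @param path Path to a schema descriptor file.
#' @return A [SchemaRegistry-class].
#' @export
loadSchema <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  registry <- schemaRegistry()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    x <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("schema parse error at line %d: %s", i,
                                 conditionMessage(e))))
    registry <- registerType(registry, .descriptor_from_json(x, i))
  }
  .check_reference_ranges(registry)
  registry
}

.check_reference_ranges <- function(registry) {
  for (td in registry@types) {
    for (f in td@features) {
      target <- .range_target(f@range)
      if (is.na(target) || target %in% .root_markers()) next
      if (is.null(registry@types[[target]]))
        stop(sprintf(
          "schema error: feature '%s' of '%s' references unregistered type '%s'",
          f@name, td@qualifiedName, target))
    }
  }
  invisible(registry)
}

## ---- shipped normative schema and constants (cached per session) ----

.clintypes_cache <- new.env(parent = emptyenv())

#' Path to the shipped normative schema file
#' @return File path of the packaged schema descriptor file.
#' @export
schemaPath <- function() {
  system.file("extdata", "schema", "clintypes-schema.jsonl",
              package = "clintypes", mustWork = TRUE)
}

#' The shipped normative registry
#'
#' Loads (and caches) the packaged 100-type inventory across the seven
#' namespaces. This is the registry every store uses unless another is given.
#'
#' @return A [SchemaRegistry-class].
#' @export
#' @examples
#' reg <- defaultRegistry()
#' length(reg@types)  # 100
defaultRegistry <- function() {
  if (is.null(.clintypes_cache$registry))
    .clintypes_cache$registry <- loadSchema(schemaPath())
  .clintypes_cache$registry
}

#' The shipped constants table
#'
#' The constants file augments the type system with the documented value sets
#' of the shared attribute types, identifier pattern constraints, the typeID
#' semantic-group codes, the temporal/degree relation category vocabulary,
#' the category-to-relation-type lifting map, and the model file names of the
#' packaged Clinical Element Models.
#'
#' @return Named list, parsed from the packaged constants JSON.
#' @export
clinConstants <- function() {
  if (is.null(.clintypes_cache$constants)) {
    path <- system.file("extdata", "schema", "constants.json",
                        package = "clintypes", mustWork = TRUE)
    .clintypes_cache$constants <- jsonlite::fromJSON(path,
                                                     simplifyVector = TRUE,
                                                     simplifyDataFrame = FALSE)
  }
  .clintypes_cache$constants
}

#' @describeIn SchemaRegistry-class Compact registry summary.
#' @param object A `SchemaRegistry`.
#' @export
setMethod("show", "SchemaRegistry", function(object) {
  st <- schemaStats(object)
  cat(sprintf("SchemaRegistry with %d types / %d declared features\n",
              sum(st$types), sum(st$features)))
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-10s %3d types %3d features\n", st$namespace[i],
                st$types[i], st$features[i]))
  invisible(object)
})
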