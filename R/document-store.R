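## annotation_store: the per-document container. Functional updates — every
## mutating operation returns a new store; ids are assigned monotonically
## and never reused, and there is no deletion.

#' Create an empty document store
#'
#' @param text Document text (offsets are 0-based, half-open, over Unicode
#'   code points).
#' @param metadata Named list of document metadata; put the ISO 8601
#'   document date under `"documentDate"` if relative times are to be
#'   normalized.
#' @param registry Schema registry to validate against; defaults to the
#'   shipped normative registry.
#' @return A [DocumentStore-class].
#' @export
#' @examples
#' store <- documentStore("Cough noted.", metadata = list(documentDate = "2006-09-03"))
documentStore <- function(text = "", metadata = list(),
                          registry = defaultRegistry()) {
  new("DocumentStore", text = text, metadata = metadata,
      registry = registry)
}

#' Construct a free-standing annotation instance
#'
#' Builds an [AnnotationInstance-class] not yet attached to a store (its id
#' is `NA`). [addAnnotation()] is the usual entry point; this constructor is
#' for validation and default-construction workflows.
#'
#' @param typeName Qualified type name.
#' @param begin,end Character offsets for spanned types; leave `NA` for
#'   unspanned types.
#' @param features Named list of feature values.
#' @param id Instance id (assigned by the store; `NA` by default).
#' @return An [AnnotationInstance-class].
#' @export
annotationInstance <- function(typeName, begin = NA, end = NA,
                               features = list(), id = NA_integer_) {
  new("AnnotationInstance", id = as.integer(id), typeName = typeName,
      begin = as.integer(begin), end = as.integer(end),
      features = features)
}

## ---- accessors ----

#' Document text of a store
#' @param store A [DocumentStore-class].
#' @return The document string.
#' @export
docText <- function(store) store@text

#' Document metadata of a store
#' @param store A [DocumentStore-class].
#' @return Named list of metadata.
#' @export
storeMetadata <- function(store) store@metadata

#' Id of the most recently added instance
#' @param store A [DocumentStore-class].
#' @return Integer id (0 when the store is empty).
#' @export
lastId <- function(store) store@lastId

#' Retrieve one instance by id
#' @param store A [DocumentStore-class].
#' @param id Integer instance id.
#' @return The [AnnotationInstance-class]; error for unknown ids.
#' @export
instanceById <- function(store, id) {
  inst <- store@instances[[as.character(id)]]
  if (is.null(inst)) stop(sprintf("no instance with id %s", id))
  inst
}

#' All instance ids in insertion order
#' @param store A [DocumentStore-class].
#' @return Integer vector of ids.
#' @export
instanceIds <- function(store) store@order

#' Add an annotation to a store
#'
#' Constructs an instance of `typeName` — defaults first (see
#' [makeDefault()]), then the supplied `features` on top — assigns the next
#' id, validates it against the store's registry and text, and indexes it
#' under its type and every ancestor type. Validation violations are raised
#' as an error listing them.
#'
#' @param store A [DocumentStore-class].
#' @param typeName Qualified type name.
#' @param begin,end Character offsets (spanned types only).
#' @param features Named list of feature values; [clinRef()] values must
#'   reference instances already in the store.
#' @return The updated store; the new instance's id is `lastId(store)`.
#' @export
#' @examples
#' store <- documentStore("severe cough")
#' store <- addAnnotation(store, "textsem.EventMention", 7, 12)
#' lastId(store)
setMethod("addAnnotation", "DocumentStore",
          function(store, typeName, begin = NA, end = NA,
                   features = list()) {
  id <- store@lastId + 1L
  inst <- makeDefault(typeName, registry = store@registry)
  inst@id <- id
  inst@begin <- as.integer(begin)
  inst@end <- as.integer(end)
  for (fname in names(features)) inst@features[[fname]] <- features[[fname]]
  validObject(inst)
  violations <- c(validateInstance(store@registry, inst),
                  .check_in_store(store, inst))
  if (length(violations))
    stop(sprintf("cannot add '%s' instance:\n%s", typeName,
                 paste0("  - ", violations, collapse = "\n")))
  store@instances[[as.character(id)]] <- inst
  store@order <- c(store@order, id)
  store@lastId <- id
  store
})

## Store-level checks that validateInstance cannot do alone: span bounds
## against the text, reference resolution and reference target typing.
.check_in_store <- function(store, inst) {
  violations <- character()
  if (!is.na(inst@begin) && !is.na(inst@end) &&
      inst@end > nchar(store@text))
    violations <- c(violations,
      sprintf("span [%d,%d) exceeds document length %d", inst@begin,
              inst@end, nchar(store@text)))
  declared <- .collect_features(store@registry, inst@typeName)
  for (fname in names(inst@features)) {
    v <- inst@features[[fname]]
    if (!isClinRef(v)) next
    fd <- declared[[fname]]
    target <- if (!is.null(fd)) .range_target(fd@range) else NA_character_
    for (rid in unclass(v)) {
      ref <- store@instances[[as.character(rid)]]
      if (is.null(ref)) {
        violations <- c(violations,
          sprintf("feature '%s' references missing id %d (dangling reference)",
                  fname, rid))
        next
      }
      if (is.na(target) || target == TOP) next
      ok <- if (target == SPAN_ROOT)
        lookupType(store@registry, ref@typeName)@spanned
      else
        subsumes(store@registry, target, ref@typeName)
      if (!ok)
        violations <- c(violations,
          sprintf("feature '%s' must reference '%s' but id %d is a '%s'",
                  fname, target, rid, ref@typeName))
    }
  }
  violations
}

## Order spanned instances by (begin, end, id); unspanned by id.
.order_instances <- function(insts) {
  if (!length(insts)) return(insts)
  spanned <- vapply(insts, function(x) !is.na(x@begin), logical(1))
  sp <- insts[spanned]
  un <- insts[!spanned]
  if (length(sp)) {
    b <- vapply(sp, function(x) x@begin, integer(1))
    e <- vapply(sp, function(x) x@end, integer(1))
    i <- vapply(sp, function(x) x@id, integer(1))
    sp <- sp[order(b, e, i)]
  }
  if (length(un)) {
    i <- vapply(un, function(x) x@id, integer(1))
    un <- un[order(i)]
  }
  c(sp, un)
}

#' Retrieve instances by type
#'
#' Returns the instances of a type — and, with `includeSubtypes`, of all its
#' descendants, the subsumption-aware index that makes subtyping an
#' efficient way to subset annotations. Spanned results are ordered by
#' `(begin, end, id)`, unspanned results by id (spanned before unspanned
#' when a query mixes both).
#'
#' @param store A [DocumentStore-class].
#' @param typeName Qualified type name (must be registered).
#' @param includeSubtypes Include instances of descendant types (default
#'   `TRUE`).
#' @return List of [AnnotationInstance-class].
#' @export
setMethod("getByType", "DocumentStore",
          function(store, typeName, includeSubtypes = TRUE) {
  lookupType(store@registry, typeName)
  wanted <- if (includeSubtypes) subtypesOf(store@registry, typeName)
            else typeName
  insts <- store@instances[vapply(store@instances,
                                  function(x) x@typeName %in% wanted,
                                  logical(1))]
  .order_instances(unname(insts))
})

#' Select annotations covered by a window
#'
#' Returns the spanned instances of the (subsumed) type lying fully inside
#' the half-open window `[begin, end)`.
#'
#' @param store A [DocumentStore-class].
#' @param typeName Qualified type name.
#' @param begin,end Window offsets, `0 <= begin <= end <= nchar(text)`.
#' @return List of [AnnotationInstance-class], ordered by `(begin, end, id)`.
#' @export
setMethod("selectCovered", "DocumentStore",
          function(store, typeName, begin, end) {
  begin <- as.integer(begin); end <- as.integer(end)
  if (is.na(begin) || is.na(end) || begin < 0L || begin > end ||
      end > nchar(store@text))
    stop(sprintf("window [%s,%s) out of range for text of length %d",
                 begin, end, nchar(store@text)))
  insts <- getByType(store, typeName, includeSubtypes = TRUE)
  Filter(function(x) !is.na(x@begin) && x@begin >= begin && x@end <= end,
         insts)
})

#' Validate a whole store
#'
#' Runs [validateInstance()] on every instance plus the store-level checks:
#' spans within the text, every id-reference resolving to an instance of the
#' declared target type, and `util.ProbabilityDistribution` values parsing
#' as probabilities in `[0, 1]`.
#'
#' @param store A [DocumentStore-class].
#' @return Character vector of violations; empty when the store validates.
#' @export
setMethod("validateStore", "DocumentStore", function(store) {
  violations <- character()
  for (inst in store@instances) {
    v <- c(validateInstance(store@registry, inst),
           .check_in_store(store, inst))
    if (length(v))
      violations <- c(violations,
                      sprintf("instance %d (%s): %s", inst@id,
                              inst@typeName, v))
  }
  for (inst in store@instances) {
    if (inst@typeName != "util.ProbabilityDistribution") next
    for (pid in unclass(inst@features$pairs %||% clinRef(integer()))) {
      pair <- store@instances[[as.character(pid)]]
      if (is.null(pair)) next
      p <- suppressWarnings(as.numeric(pair@features$value))
      if (is.na(p) || p < 0 || p > 1)
        violations <- c(violations,
          sprintf("instance %d: probability value '%s' not in [0, 1]",
                  inst@id, pair@features$value))
    }
  }
  violations
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- canonical JSON serialization ----

.feature_to_json <- function(value, range) {
  if (isClinRef(value)) {
    refs <- lapply(unclass(value), function(i) list("$ref" = i))
    if (!is.na(range) && startsWith(range, "ref:")) return(refs[[1L]])
    return(refs)
  }
  if (!is.na(range) && range == "stringarray") return(as.list(value))
  if (is.character(value) && length(value) > 1L) return(as.list(value))
  value
}

.instance_to_json <- function(inst, declared) {
  x <- list(id = inst@id, type = inst@typeName)
  if (!is.na(inst@begin)) { x$begin <- inst@begin; x$end <- inst@end }
  feats <- inst@features
  if (length(feats)) feats <- feats[order(names(feats))]
  x$features <- lapply(stats::setNames(names(feats), names(feats)),
    function(fname) {
      fd <- declared[[fname]]
      .feature_to_json(feats[[fname]], if (is.null(fd)) NA_character_
                       else fd@range)
    })
  x
}

#' Serialize a store to the document JSON dialect
#'
#' Produces the canonical JSON form of a store:
#' `{"text", "metadata", "annotations": [...]}` with metadata keys sorted,
#' annotations in id order, feature maps sorted by name, and references as
#' `{"$ref": id}`. The serialization is canonical, so equal stores produce
#' byte-identical output, and [deserializeStore()] inverts it exactly.
#'
#' @param store A [DocumentStore-class] (must validate).
#' @return A single JSON string.
#' @export
setMethod("serializeStore", "DocumentStore", function(store) {
  violations <- validateStore(store)
  if (length(violations))
    stop(sprintf("store does not validate:\n%s",
                 paste0("  - ", violations, collapse = "\n")))
  meta <- store@metadata
  if (length(meta)) meta <- meta[order(names(meta))]
  ids <- sort(store@order)
  anns <- lapply(ids, function(id) {
    inst <- store@instances[[as.character(id)]]
    .instance_to_json(inst, .collect_features(store@registry,
                                              inst@typeName))
  })
  doc <- list(text = store@text,
              metadata = if (length(meta)) meta else structure(list(),
                                                               names = character()),
              annotations = anns)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null"))
})

.feature_from_json <- function(value, range) {
  if (is.list(value)) {
    if (!is.null(value[["$ref"]])) return(clinRef(value[["$ref"]]))
    if (length(value) &&
        all(vapply(value, function(v) is.list(v) && !is.null(v[["$ref"]]),
                   logical(1))))
      return(clinRef(vapply(value, function(v) as.integer(v[["$ref"]]),
                            integer(1))))
    if (!length(value)) {
      if (!is.na(range) && startsWith(range, "refarray"))
        return(clinRef(integer()))
      return(character())
    }
    return(vapply(value, as.character, character(1)))
  }
  if (is.na(range)) return(value)
  switch(range,
    integer = as.integer(value),
    float = as.numeric(value),
    boolean = as.logical(value),
    string = as.character(value),
    stringarray = as.character(value),
    value)
}

#' Deserialize a document JSON dialect string
#'
#' Inverse of [serializeStore()]. The parsed store is fully validated:
#' malformed JSON, dangling `$ref` references and schema violations are all
#' raised as errors.
#'
#' @param json A JSON string (or a file path to one via [readLines()] by the
#'   caller).
#' @param registry Registry to validate against; defaults to the shipped
#'   normative registry.
#' @return A [DocumentStore-class].
#' @export
deserializeStore <- function(json, registry = defaultRegistry()) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(doc$text)) stop("document JSON lacks a 'text' field")
  store <- new("DocumentStore", text = doc$text,
               metadata = lapply(doc$metadata %||% list(), identity),
               registry = registry)
  anns <- doc$annotations %||% list()
  ids <- vapply(anns, function(a) as.integer(a$id), integer(1))
  if (anyDuplicated(ids)) stop("duplicate annotation ids in document JSON")
  insts <- list()
  for (a in anns) {
    declared <- .collect_features(registry, a$type)
    feats <- lapply(stats::setNames(names(a$features %||% list()),
                                    names(a$features %||% list())),
      function(fname) {
        fd <- declared[[fname]]
        .feature_from_json(a$features[[fname]],
                           if (is.null(fd)) NA_character_ else fd@range)
      })
    insts[[as.character(a$id)]] <-
      annotationInstance(a$type, begin = a$begin %||% NA,
                         end = a$end %||% NA, features = feats,
                         id = a$id)
  }
  store@instances <- insts
  store@order <- ids
  store@lastId <- if (length(ids)) max(ids) else 0L
  violations <- validateStore(store)
  if (length(violations))
    stop(sprintf("document JSON does not validate:\n%s",
                 paste0("  - ", violations, collapse = "\n")))
  store
}

#' @describeIn DocumentStore-class Compact store summary.
#' @param object A `DocumentStore`.
#' @export
setMethod("show", "DocumentStore", function(object) {
  preview <- object@text
  if (nchar(preview) > 60) preview <- paste0(substr(preview, 1, 57), "...")
  cat(sprintf("DocumentStore: %d chars, %d annotations\n",
              nchar(object@text), length(object@instances)))
  cat(sprintf("  text: \"%s\"\n", preview))
  if (length(object@instances)) {
    tys <- table(vapply(object@instances, function(x) x@typeName,
                        character(1)))
    for (tn in names(tys)) cat(sprintf("  %3d x %s\n", tys[[tn]], tn))
  }
  invisible(object)
})

#' @describeIn AnnotationInstance-class One-line instance rendering.
#' @param object An `AnnotationInstance`.
#' @export
setMethod("show", "AnnotationInstance", function(object) {
  span <- if (is.na(object@begin)) "" else
    sprintf(" [%d,%d)", object@begin, object@end)
  feats <- vapply(names(object@features), function(fname) {
    v <- object@features[[fname]]
    repr <- if (isClinRef(v))
      paste0("@", paste(unclass(v), collapse = ",@"))
    else paste(format(v), collapse = ",")
    paste0(fname, "=", repr)
  }, character(1))
  cat(sprintf("<%s#%s%s %s>\n", object@typeName,
              ifelse(is.na(object@id), "?", object@id), span,
              paste(feats, collapse = " ")))
  invisible(object)
})
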