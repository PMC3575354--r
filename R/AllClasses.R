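## Core S4 classes for the clinical annotation type system.
##
## Two meta-levels coexist: the *schema* level (FeatureDescriptor,
## TypeDescriptor, SchemaRegistry) describes what annotation types exist and
## what features they may carry; the *instance* level (AnnotationInstance,
## DocumentStore) holds the typed markup of one clinical document.

#' The seven annotation namespaces
#'
#' The type inventory is partitioned into exactly seven namespaces:
#' structured document data, utility types, text spans, syntax, textual
#' semantics (spanned mentions), referential semantics (unspanned
#' document-level elements), and relations. The set is closed: registering a
#' type under any other namespace is an error.
#'
#' @return Character vector of the seven namespace names.
#' @export
#' @examples
#' clinNamespaces()
clinNamespaces <- function() {
  c("structured", "util", "textspan", "syntax", "textsem", "refsem",
    "relation")
}

## Root markers for the two inheritance trees: spanned textual annotations
## hang off SPAN_ROOT; unspanned document-level objects hang off TOP.
SPAN_ROOT <- "SPAN_ROOT"
TOP <- "TOP"

.root_markers <- function() c(SPAN_ROOT, TOP)

## Legal feature ranges. Reference ranges carry their target type after a
## colon, e.g. "ref:refsem.Time" or "refarray:util.Pair"; the pseudo-targets
## SPAN_ROOT and TOP mean "any spanned annotation" / "any instance".
.primitive_ranges <- c("boolean", "integer", "float", "string", "stringarray")

.range_ok <- function(range) {
  if (range %in% .primitive_ranges) return(TRUE)
  grepl("^(ref|refarray):[A-Za-z_][A-Za-z0-9_.]*$", range)
}

.range_target <- function(range) {
  if (!grepl(":", range, fixed = TRUE)) return(NA_character_)
  sub("^[a-z]+:", "", range)
}

#' @title FeatureDescriptor: one declared feature of an annotation type
#' @description A feature (attribute) declaration: its name, its value range
#'   (primitive, string array, or a reference to instances of a target type)
#'   and the qualified name of the type that declares it. Inherited features
#'   are never re-declared on subtypes. Features reconstructed to complete
#'   the inventory (rather than named in its normative description) carry
#'   `reconstructed = TRUE`.
#' @slot name Feature name, unique within its declaring type.
#' @slot range One of `"boolean"`, `"integer"`, `"float"`, `"string"`,
#'   `"stringarray"`, `"ref:<type>"`, `"refarray:<type>"`.
#' @slot declaringType Qualified name of the declaring type.
#' @slot reconstructed Logical flag for reconstructed inventory slots.
#' @exportClass FeatureDescriptor
setClass("FeatureDescriptor",
  representation(
    name = "character",
    range = "character",
    declaringType = "character",
    reconstructed = "logical"
  ),
  prototype(reconstructed = FALSE)
)

setValidity("FeatureDescriptor", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name) ||
      !grepl("^[A-Za-z_$][A-Za-z0-9_$]*$", object@name))
    msgs <- c(msgs, "feature name must be a single identifier string")
  if (length(object@range) != 1L || !.range_ok(object@range))
    msgs <- c(msgs, sprintf("invalid feature range '%s'",
                            paste(object@range, collapse = ",")))
  if (length(msgs)) msgs else TRUE
})

#' @title TypeDescriptor: one annotation type in the schema
#' @description Schema entry for one annotation type: its qualified
#'   `namespace.Name`, its single supertype (or the `SPAN_ROOT`/`TOP` root
#'   marker), whether its instances carry a text span, and its declared
#'   (non-inherited) features in declaration order.
#' @slot qualifiedName Qualified type name, `"<namespace>.<Name>"`.
#' @slot namespace One of the seven namespaces, see [clinNamespaces()].
#' @slot supertype Qualified supertype name, or `"SPAN_ROOT"`/`"TOP"`.
#' @slot spanned `TRUE` iff the type descends from the span root; spanned
#'   instances carry `begin`/`end` character offsets.
#' @slot features List of [FeatureDescriptor-class] objects.
#' @slot reconstructed Logical flag for reconstructed inventory slots.
#' @exportClass TypeDescriptor
setClass("TypeDescriptor",
  representation(
    qualifiedName = "character",
    namespace = "character",
    supertype = "character",
    spanned = "logical",
    features = "list",
    reconstructed = "logical"
  ),
  prototype(features = list(), reconstructed = FALSE)
)

setValidity("TypeDescriptor", function(object) {
  msgs <- character()
  if (length(object@qualifiedName) != 1L ||
      !grepl("^[a-z]+\\.[A-Za-z][A-Za-z0-9]*$", object@qualifiedName))
    msgs <- c(msgs, "qualifiedName must look like '<namespace>.<Name>'")
  if (length(object@namespace) != 1L ||
      !object@namespace %in% clinNamespaces())
    msgs <- c(msgs, sprintf("unknown namespace '%s'",
                            paste(object@namespace, collapse = ",")))
  if (length(object@qualifiedName) == 1L && length(object@namespace) == 1L &&
      !startsWith(object@qualifiedName, paste0(object@namespace, ".")))
    msgs <- c(msgs, "qualifiedName must live inside its namespace")
  if (length(object@supertype) != 1L || !nzchar(object@supertype))
    msgs <- c(msgs, "exactly one supertype (or root marker) is required")
  if (!all(vapply(object@features, inherits, logical(1),
                  "FeatureDescriptor")))
    msgs <- c(msgs, "features must all be FeatureDescriptor objects")
  fn <- vapply(object@features, function(f) f@name, character(1))
  if (anyDuplicated(fn))
    msgs <- c(msgs, sprintf("duplicate feature name(s): %s",
                            paste(unique(fn[duplicated(fn)]),
                                  collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @title SchemaRegistry: the type inventory
#' @description Holds the registered [TypeDescriptor-class] objects, keyed by
#'   qualified name, together with a direct-subtype index maintained on
#'   registration. The supertype graph is a single-inheritance forest rooted
#'   at the two markers `SPAN_ROOT` (spanned annotations) and `TOP`
#'   (unspanned objects).
#' @slot types Named list of [TypeDescriptor-class], keyed by qualified name.
#' @slot typeOrder Character vector of qualified names in registration
#'   order (the canonical dump order).
#' @slot children Named list mapping a type (or root marker) to the
#'   qualified names of its direct subtypes.
#' @exportClass SchemaRegistry
setClass("SchemaRegistry",
  representation(
    types = "list",
    typeOrder = "character",
    children = "list"
  ),
  prototype(
    types = list(),
    typeOrder = character(),
    children = structure(list(character(), character()),
                         names = c("SPAN_ROOT", "TOP"))
  )
)

setValidity("SchemaRegistry", function(object) {
  msgs <- character()
  if (!identical(sort(names(object@types)), sort(object@typeOrder)))
    msgs <- c(msgs, "typeOrder must enumerate exactly the registered types")
  for (td in object@types) {
    st <- td@supertype
    if (!st %in% .root_markers() && is.null(object@types[[st]]))
      msgs <- c(msgs, sprintf("supertype '%s' of '%s' is not registered",
                              st, td@qualifiedName))
  }
  if (length(msgs)) msgs else TRUE
})

#' @title AnnotationInstance: one typed object in a document
#' @description A single annotation: a document-unique integer id, a
#'   qualified type name, optional `begin`/`end` character offsets (0-based,
#'   half-open, present iff the type is spanned) and a named feature map.
#'   Feature values are primitives, [clinRef()] id-references, or arrays
#'   thereof.
#' @slot id Document-unique integer id (`NA` until added to a store).
#' @slot typeName Qualified type name.
#' @slot begin,end 0-based half-open character offsets over Unicode code
#'   points, or `NA` for unspanned types.
#' @slot features Named list of feature values.
#' @exportClass AnnotationInstance
setClass("AnnotationInstance",
  representation(
    id = "integer",
    typeName = "character",
    begin = "integer",
    end = "integer",
    features = "list"
  ),
  prototype(id = NA_integer_, begin = NA_integer_, end = NA_integer_,
            features = list())
)

setValidity("AnnotationInstance", function(object) {
  msgs <- character()
  if (length(object@typeName) != 1L || !nzchar(object@typeName))
    msgs <- c(msgs, "typeName is required")
  if (!is.na(object@begin) && !is.na(object@end)) {
    if (object@begin < 0L) msgs <- c(msgs, "begin must be >= 0")
    if (object@begin > object@end)
      msgs <- c(msgs, sprintf("begin (%d) must be <= end (%d)",
                              object@begin, object@end))
  } else if (xor(is.na(object@begin), is.na(object@end))) {
    msgs <- c(msgs, "begin and end must be set together")
  }
  if (length(object@features) &&
      (is.null(names(object@features)) || any(!nzchar(names(object@features)))))
    msgs <- c(msgs, "features must be a named list")
  if (length(msgs)) msgs else TRUE
})

#' @title DocumentStore: per-document annotation container
#' @description The per-document container (the analysis-structure analog):
#'   the document text, document metadata (including the document date under
#'   `"documentDate"`), and the typed annotation instances with their
#'   subsumption-aware retrieval operations. Stores are build-once: ids are
#'   assigned monotonically and never reused, and deletion is unsupported.
#' @slot text The document text.
#' @slot metadata Named list of document metadata; the document date is an
#'   ISO 8601 string under key `"documentDate"`.
#' @slot instances Named list of [AnnotationInstance-class], keyed by id.
#' @slot order Integer ids in insertion order.
#' @slot registry The [SchemaRegistry-class] the store validates against.
#' @slot lastId Most recently assigned id (0 when empty).
#' @exportClass DocumentStore
setClass("DocumentStore",
  representation(
    text = "character",
    metadata = "list",
    instances = "list",
    order = "integer",
    registry = "SchemaRegistry",
    lastId = "integer"
  ),
  prototype(text = "", metadata = list(), instances = list(),
            order = integer(), lastId = 0L)
)

setValidity("DocumentStore", function(object) {
  msgs <- character()
  if (length(object@text) != 1L)
    msgs <- c(msgs, "text must be a single string")
  ids <- names(object@instances)
  if (!identical(sort(as.integer(ids)), sort(object@order)))
    msgs <- c(msgs, "instance names and insertion order disagree")
  if (length(msgs)) msgs else TRUE
})

#' @title CorefChain: one coreference chain of mentions
#' @description An ordered set of mention ids (document order) that refer to
#'   the same underlying real-world instance. Chains partition the mentions
#'   of a document; mentions that do not corefer form singleton chains.
#' @slot mentionIds Integer mention ids in document order.
#' @exportClass CorefChain
setClass("CorefChain", representation(mentionIds = "integer"))

#' @title BridgeConfig: configuration of the resolution bridge
#' @description Controls how the mention-to-element bridge resolves feature
#'   conflicts between coreferring mentions, which relative-date patterns are
#'   enabled, and which metadata key carries the document date.
#' @slot conflictPolicy `"last-mention-wins"` (default) or `"error"`.
#' @slot dateGrammar Enabled relative-time pattern names, a subset of
#'   `c("ago", "yesterday", "today")`.
#' @slot documentDateKey Metadata key of the ISO document date.
#' @exportClass BridgeConfig
setClass("BridgeConfig",
  representation(
    conflictPolicy = "character",
    dateGrammar = "character",
    documentDateKey = "character"
  ),
  prototype(conflictPolicy = "last-mention-wins",
            dateGrammar = c("ago", "yesterday", "today"),
            documentDateKey = "documentDate")
)

setValidity("BridgeConfig", function(object) {
  msgs <- character()
  if (length(object@conflictPolicy) != 1L ||
      !object@conflictPolicy %in% c("last-mention-wins", "error"))
    msgs <- c(msgs,
              "conflictPolicy must be 'last-mention-wins' or 'error'")
  if (!all(object@dateGrammar %in% c("ago", "yesterday", "today")))
    msgs <- c(msgs, "unknown dateGrammar pattern")
  if (length(msgs)) msgs else TRUE
})

#' @title CetypeModel: a parsed Clinical Element Model definition
#' @description One `cetype` model: its kind and name, the coded key, the
#'   value-choice data domain and coded type (e.g. `cwe` coded-with-
#'   extensions, `pq` physical quantity), and the ordered qualifier,
#'   modifier, and attribution declarations each with a cardinality string
#'   (`"0-1"`, `"0-M"`, ...).
#' @slot kind Model kind, e.g. `"statement"`.
#' @slot name Model name, e.g. `"CoughAssert"`.
#' @slot keyCode Coded key, e.g. `"Assertion_KEY_ECID"`.
#' @slot dataDomain Value-choice domain, e.g. `"CoughType_VALUESET_ECID"`.
#' @slot dataType Value-choice coded type, e.g. `"cwe"`.
#' @slot quals,mods,atts Data frames with columns `name`, `type`, `card`.
#' @exportClass CetypeModel
setClass("CetypeModel",
  representation(
    kind = "character",
    name = "character",
    keyCode = "character",
    dataDomain = "character",
    dataType = "character",
    quals = "data.frame",
    mods = "data.frame",
    atts = "data.frame"
  )
)

.empty_cem_slots <- function() {
  data.frame(name = character(), type = character(), card = character(),
             stringsAsFactors = FALSE)
}

setValidity("CetypeModel", function(object) {
  msgs <- character()
  for (slotname in c("quals", "mods", "atts")) {
    df <- slot(object, slotname)
    if (!identical(names(df), c("name", "type", "card"))) {
      msgs <- c(msgs, sprintf("%s must have columns name/type/card", slotname))
      next
    }
    bad <- !grepl("^[0-9]+-([0-9]+|M)$", df$card)
    if (any(bad))
      msgs <- c(msgs, sprintf("bad cardinality '%s' in %s",
                              df$card[bad][1L], slotname))
    if (anyDuplicated(df$name))
      msgs <- c(msgs, sprintf("duplicate %s name(s): %s", slotname,
                              paste(unique(df$name[duplicated(df$name)]),
                                    collapse = ", ")))
  }
  nm <- c(object@quals$name, object@mods$name, object@atts$name)
  if (anyDuplicated(nm))
    msgs <- c(msgs, "qualifier/modifier/attribution names must be unique")
  if (length(msgs)) msgs else TRUE
})

#' @title CemInstance: one Clinical Element Model instance
#' @description A populated clinical element: the model it instantiates, its
#'   key, its data value, and value maps for qualifiers, modifiers and
#'   attributions. Multiplicity must respect the model's cardinalities.
#' @slot modelName Name of the [CetypeModel-class] instantiated.
#' @slot keyCode Coded key copied from the model.
#' @slot dataValue The value-choice value (e.g. a concept code).
#' @slot quals,mods,atts Named lists of character value vectors.
#' @exportClass CemInstance
setClass("CemInstance",
  representation(
    modelName = "character",
    keyCode = "character",
    dataValue = "character",
    quals = "list",
    mods = "list",
    atts = "list"
  ),
  prototype(dataValue = NA_character_, quals = list(), mods = list(),
            atts = list())
)

#' @title FixtureSpec: parameters of the synthetic document generator
#' @description Parameters controlling [generateStore()]: the random seed,
#'   document shape, the probabilities of coreference, negation, and relative
#'   dates, and the concept vocabulary. Generation is a pure function of the
#'   spec (including its seed).
#' @slot seed Integer random seed.
#' @slot nSentences,nMentionsPerSentence Document shape.
#' @slot corefRate,negationRate,relativeDateRate Probabilities in [0, 1].
#' @slot vocabulary Data frame with columns `code`, `tui`, `surface`.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(
    seed = "integer",
    nSentences = "integer",
    nMentionsPerSentence = "integer",
    corefRate = "numeric",
    negationRate = "numeric",
    relativeDateRate = "numeric",
    vocabulary = "data.frame"
  )
)

setValidity("FixtureSpec", function(object) {
  msgs <- character()
  probs <- c(coref = object@corefRate, negation = object@negationRate,
             relativeDate = object@relativeDateRate)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    msgs <- c(msgs, sprintf("rate(s) outside [0, 1]: %s",
                            paste(names(probs)[bad], collapse = ", ")))
  if (object@nSentences < 1L || object@nMentionsPerSentence < 1L)
    msgs <- c(msgs, "document shape parameters must be >= 1")
  if (!all(c("code", "tui", "surface") %in% names(object@vocabulary)))
    msgs <- c(msgs, "vocabulary needs columns code, tui, surface")
  if (length(msgs)) msgs else TRUE
})

#' Create an id-reference feature value
#'
#' Feature values that point at other instances in the same store are
#' represented as `clinRef` objects: integer id vectors with class
#' `"clinRef"`. A length-1 `clinRef` fills a `ref:` feature; any length fills
#' a `refarray:` feature. In the document JSON dialect a reference serializes
#' as `{"$ref": id}`.
#'
#' @param ids Integer instance id(s).
#' @return An integer vector of class `"clinRef"`.
#' @export
#' @examples
#' clinRef(3L)
#' clinRef(c(1L, 4L))
clinRef <- function(ids) {
  ids <- as.integer(ids)
  if (anyNA(ids)) stop("clinRef ids must be non-missing integers")
  structure(ids, class = "clinRef")
}

#' Test for an id-reference value
#' @param x Object to test.
#' @return `TRUE` iff `x` is a [clinRef()] value.
#' @export
isClinRef <- function(x) inherits(x, "clinRef")

#' @export
print.clinRef <- function(x, ...) {
  cat("<clinRef:", paste(unclass(x), collapse = ","), ">\n")
  invisible(x)
}
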