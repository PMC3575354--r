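## domain_model: the normative inventory lives in the shipped schema file;
## this file exposes its conventions — documented defaults, the constants
## value sets, and the core Clinical Element Model types.

#' The six core Clinical Element Model types
#'
#' Anatomical sites, diseases/disorders, labs, medications, procedures, and
#' signs/symptoms: the six referential-semantic element types that carry a
#' full clinical attribute template. `refsem.AnatomicalSite` is an Entity
#' (non-temporal); the other five are Events.
#'
#' @return Character vector of six qualified type names.
#' @export
#' @examples
#' coreCemTypes()
coreCemTypes <- function() {
  unlist(clinConstants()$coreCems, use.names = FALSE)
}

#' The typeID semantic-group code table
#'
#' The paper-level semantic groups (drugs, disorders, ...) are stored on
#' mentions as integer `typeID` codes. The codes themselves are a documented
#' convention shipped in the constants file; each mapped code names the core
#' CEM type a mention chain of that group resolves to.
#'
#' @return Data frame with columns `typeID`, `group`, `elementType`
#'   (`NA` for the unmapped "unknown" code).
#' @export
typeIdTable <- function() {
  tab <- clinConstants()$typeIds
  data.frame(
    typeID = vapply(tab, function(x) as.integer(x$code), integer(1)),
    group = vapply(tab, function(x) x$group, character(1)),
    elementType = vapply(tab, function(x) x$elementType %||% NA_character_,
                         character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Documented value set of an attribute type
#'
#' Returns the constants-file value set for one of the four shared attribute
#' types (`refsem.Severity`, `refsem.Course`, `refsem.BodySide`,
#' `refsem.BodyLaterality`). These sets are deliberately *not* enforced when
#' linking attributes to elements — hard-coded value sets hamper downstream
#' development — but [validateInstance()] enforces them on the attribute
#' instances themselves.
#'
#' @param attributeTypeName Qualified attribute type name.
#' @param registry Registry the type must be registered in.
#' @return Character vector of allowed values.
#' @export
#' @examples
#' allowedValues("refsem.Severity")
#' allowedValues("refsem.BodySide")
allowedValues <- function(attributeTypeName, registry = defaultRegistry()) {
  lookupType(registry, attributeTypeName)
  vs <- clinConstants()$valueSets[[attributeTypeName]]
  if (is.null(vs))
    stop(sprintf("no documented value set for '%s'", attributeTypeName))
  vs
}

## Documented defaults: an unqualified mention or element is affirmed
## (polarity 1), certain (uncertainty 0), unconditional, non-generic, about
## the patient; value-set attributes start "unmarked".
.feature_default <- function(typeName, fd, registry) {
  cons <- clinConstants()
  defaults <- cons$featureDefaults
  if (!is.null(defaults[[fd@name]])) {
    v <- defaults[[fd@name]]
    return(switch(fd@range,
                  integer = as.integer(v),
                  boolean = as.logical(v),
                  float = as.numeric(v),
                  as.character(v)))
  }
  if (fd@name == "value" && fd@range == "string") {
    chain <- c(typeName, .ancestors(registry, typeName))
    for (vt in intersect(chain, names(cons$valueSets)))
      if ("unmarked" %in% cons$valueSets[[vt]]) return("unmarked")
  }
  NULL
}

#' Construct an instance with documented defaults
#'
#' Builds a free-standing [AnnotationInstance-class] of the given type with
#' the documented default feature values filled in: `polarity = 1`,
#' `uncertainty = 0`, `conditional = FALSE`, `generic = FALSE`,
#' `subject = "patient"` wherever those features are declared, and
#' `value = "unmarked"` on the shared value-set attribute types. All other
#' features are left unset.
#'
#' @param typeName Qualified type name (must be registered).
#' @param registry Registry to resolve the type in.
#' @return An [AnnotationInstance-class] with `NA` id and no span.
#' @export
#' @examples
#' makeDefault("textsem.EventMention")@features$polarity  # 1
#' makeDefault("refsem.Severity")@features$value          # "unmarked"
makeDefault <- function(typeName, registry = defaultRegistry()) {
  lookupType(registry, typeName)
  feats <- list()
  for (fd in .collect_features(registry, typeName)) {
    v <- .feature_default(typeName, fd, registry)
    if (!is.null(v)) feats[[fd@name]] <- v
  }
  annotationInstance(typeName, features = feats)
}

## Internal: update one feature of an existing instance, with validation.
.set_feature <- function(store, id, fname, value) {
  inst <- instanceById(store, id)
  inst@features[[fname]] <- value
  violations <- c(validateInstance(store@registry, inst),
                  .check_in_store(store, inst))
  if (length(violations))
    stop(sprintf("cannot set feature '%s' on instance %d:\n%s", fname, id,
                 paste0("  - ", violations, collapse = "\n")))
  store@instances[[as.character(id)]] <- inst
  store
}
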