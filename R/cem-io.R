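## cem_io: the cetype XML dialect. A cetype model declares a clinical
## element: kind + name, a coded key, a value choice (data domain + coded
## type such as cwe or pq), and qualifier / modifier / attribution entries
## with cardinalities. The internal refsem model flattens the qualifier /
## modifier / attribution trichotomy into plain features; the shipped model
## files restore the classification on export.

#' Parse a cetype XML model
#'
#' Reads one `<cetype>` document. Element order within the qualifier,
#' modifier and attribution lists is preserved; unknown child elements and
#' malformed cardinality strings are errors.
#'
#' @param xml A cetype XML string, or a file path to one.
#' @return A [CetypeModel-class].
#' @export
#' @examples
#' m <- parseCetypeXml(cemModelPath("CoughAssert"))
#' m@keyCode
parseCetypeXml <- function(xml) {
  doc <- xml2::read_xml(xml)
  if (xml2::xml_name(doc) != "cetype")
    stop(sprintf("expected a <cetype> root, found <%s>", xml2::xml_name(doc)))
  kind <- xml2::xml_attr(doc, "kind")
  name <- xml2::xml_attr(doc, "name")
  if (is.na(kind) || is.na(name))
    stop("<cetype> requires 'kind' and 'name' attributes")
  keyCode <- NA_character_
  dataDomain <- NA_character_
  dataType <- NA_character_
  slots <- list(qual = .empty_cem_slots(), mod = .empty_cem_slots(),
                att = .empty_cem_slots())
  for (child in xml2::xml_children(doc)) {
    tag <- xml2::xml_name(child)
    if (tag == "key") {
      keyCode <- xml2::xml_attr(child, "code")
    } else if (tag == "data") {
      dataDomain <- xml2::xml_attr(child, "domain")
      dataType <- xml2::xml_attr(child, "type")
    } else if (tag %in% names(slots)) {
      card <- xml2::xml_attr(child, "card")
      if (is.na(card) || !grepl("^[0-9]+-([0-9]+|M)$", card))
        stop(sprintf("bad cardinality '%s' on <%s name=\"%s\">", card, tag,
                     xml2::xml_attr(child, "name")))
      slots[[tag]] <- rbind(slots[[tag]], data.frame(
        name = xml2::xml_attr(child, "name"),
        type = xml2::xml_attr(child, "type"),
        card = card, stringsAsFactors = FALSE))
    } else {
      stop(sprintf("unknown element <%s> in cetype '%s'", tag, name))
    }
  }
  if (is.na(keyCode)) stop(sprintf("cetype '%s' lacks a <key>", name))
  new("CetypeModel", kind = kind, name = name, keyCode = keyCode,
      dataDomain = dataDomain, dataType = dataType,
      quals = slots$qual, mods = slots$mod, atts = slots$att)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Write a cetype XML model
#'
#' Emits the canonical textual form of a model: attribute order
#' `kind, name, xmlns` on the root and `card, name, type` on entries,
#' self-closing child elements, one per line. The output is bit-stable:
#' `parseCetypeXml(writeCetypeXml(m))` recovers `m` exactly, and writing the
#' same model twice yields byte-identical text. Models with duplicate entry
#' names are refused.
#'
#' @param model A [CetypeModel-class].
#' @return A single XML string.
#' @export
setMethod("writeCetypeXml", "CetypeModel", function(model) {
  validObject(model)
  lines <- c(
    sprintf('<cetype kind="%s" name="%s" xmlns="">',
            .xml_escape(model@kind), .xml_escape(model@name)),
    sprintf('  <key code="%s" />', .xml_escape(model@keyCode)))
  if (!is.na(model@dataDomain))
    lines <- c(lines, sprintf('  <data domain="%s" type="%s" />',
                              .xml_escape(model@dataDomain),
                              .xml_escape(model@dataType)))
  for (tag in c("qual", "mod", "att")) {
    df <- slot(model, c(qual = "quals", mod = "mods", att = "atts")[[tag]])
    for (i in seq_len(nrow(df)))
      lines <- c(lines, sprintf('  <%s card="%s" name="%s" type="%s" />',
                                tag, .xml_escape(df$card[i]),
                                .xml_escape(df$name[i]),
                                .xml_escape(df$type[i])))
  }
  paste0(paste(c(lines, "</cetype>"), collapse = "\n"), "\n")
})

#' Path to a shipped cetype model file
#'
#' The package ships one cetype model per core CEM (seeded from the
#' sign/symptom pattern) plus the cough assertion model.
#'
#' @param name Model name, e.g. `"CoughAssert"` or `"MedicationAssert"`.
#' @return File path.
#' @export
cemModelPath <- function(name) {
  system.file("extdata", "cem", paste0(name, ".xml"), package = "clintypes",
              mustWork = TRUE)
}

#' The shipped cetype model for a core CEM type
#'
#' @param typeName Qualified core CEM type name, e.g. `"refsem.SignSymptom"`.
#' @return A [CetypeModel-class].
#' @export
cemModelFor <- function(typeName) {
  fname <- clinConstants()$cemModels[[typeName]]
  if (is.null(fname))
    stop(sprintf("no shipped cetype model for '%s'", typeName))
  parseCetypeXml(system.file("extdata", "cem", fname, package = "clintypes",
                             mustWork = TRUE))
}

#' Construct a CEM instance
#'
#' @param modelName,keyCode Model identification.
#' @param dataValue The value-choice value.
#' @param quals,mods,atts Named lists of character value vectors.
#' @return A [CemInstance-class].
#' @export
cemInstance <- function(modelName, keyCode, dataValue = NA_character_,
                        quals = list(), mods = list(), atts = list()) {
  new("CemInstance", modelName = modelName, keyCode = keyCode,
      dataValue = dataValue, quals = quals, mods = mods, atts = atts)
}

.card_bounds <- function(card) {
  parts <- strsplit(card, "-", fixed = TRUE)[[1]]
  c(lo = as.integer(parts[1]),
    hi = if (parts[2] == "M") NA_integer_ else as.integer(parts[2]))
}

#' Check a CEM instance against its model's cardinalities
#'
#' Verifies that every populated qualifier/modifier/attribution is declared
#' by the model and that value multiplicities respect the declared
#' cardinality strings (`"0-1"`: at most one; `"0-M"`: any number; ...).
#'
#' @param instance A [CemInstance-class].
#' @param model The [CetypeModel-class] it instantiates.
#' @return Character vector of violations; empty when conformant.
#' @export
checkCemCardinality <- function(instance, model) {
  violations <- character()
  for (tag in c("quals", "mods", "atts")) {
    df <- slot(model, tag)
    values <- slot(instance, tag)
    unknown <- setdiff(names(values), df$name)
    if (length(unknown))
      violations <- c(violations,
        sprintf("%s '%s' not declared by model '%s'",
                sub("s$", "", tag), unknown, model@name))
    for (i in seq_len(nrow(df))) {
      n <- length(values[[df$name[i]]] %||% character())
      b <- .card_bounds(df$card[i])
      if (n < b[["lo"]] || (!is.na(b[["hi"]]) && n > b[["hi"]]))
        violations <- c(violations,
          sprintf("%s '%s' has %d value(s), cardinality %s",
                  sub("s$", "", tag), df$name[i], n, df$card[i]))
    }
  }
  violations
}

## Deref an element's attribute slot to the attribute's string value.
.attr_value <- function(store, el, slotName) {
  r <- el@features[[slotName]]
  if (is.null(r)) return(NULL)
  instanceById(store, unclass(r)[1L])@features$value
}

#' Export a resolved element as a CEM instance
#'
#' Maps a resolved core-CEM element onto a cetype model: the element's
#' disambiguated concept code becomes the data value; same-named attribute
#' slots (severity, course, ...) fill the corresponding qualifiers; negated
#' polarity sets the `negationInd` modifier (reversing the asserted value),
#' uncertainty sets the `uncertainty` modifier, and the subject fills the
#' `subject` modifier. Attributions (observed / reportedReceived /
#' verified) record the context of an action and are not recoverable from
#' the element, so they are left unpopulated. Cardinality violations and
#' model/type mismatches are errors.
#'
#' @param store A [DocumentStore-class] holding the element.
#' @param elementId Id of a core-CEM element instance.
#' @param model A [CetypeModel-class]; defaults to the shipped model for the
#'   element's type.
#' @return A [CemInstance-class].
#' @export
#' @examples
#' resolved <- resolveDocument(workedExampleStore())
#' cough <- getByType(resolved, "refsem.SignSymptom", FALSE)[[1]]
#' elementToCem(resolved, cough@id)
elementToCem <- function(store, elementId, model = NULL) {
  el <- instanceById(store, elementId)
  if (!el@typeName %in% coreCemTypes())
    stop(sprintf("'%s' is not a core CEM type", el@typeName))
  if (is.null(model)) model <- cemModelFor(el@typeName)
  declaredType <- clinConstants()$cemModelTypes[[model@name]]
  if (!is.null(declaredType) && declaredType != el@typeName)
    stop(sprintf("model '%s' describes %s, not %s", model@name,
                 declaredType, el@typeName))
  dataValue <- NA_character_
  cr <- el@features$ontologyConcept
  if (!is.null(cr))
    dataValue <- instanceById(store, unclass(cr)[1L])@features$code %||%
      NA_character_
  quals <- list()
  for (qn in model@quals$name) {
    v <- .attr_value(store, el, qn)
    if (!is.null(v)) quals[[qn]] <- v
  }
  mods <- list()
  if ("subject" %in% model@mods$name && !is.null(el@features$subject))
    mods$subject <- el@features$subject
  if ("negationInd" %in% model@mods$name &&
      identical(as.integer(el@features$polarity %||% 1L), -1L))
    mods$negationInd <- "true"
  if ("uncertainty" %in% model@mods$name &&
      identical(as.integer(el@features$uncertainty %||% 0L), 1L))
    mods$uncertainty <- "true"
  inst <- cemInstance(model@name, model@keyCode, dataValue = dataValue,
                      quals = quals, mods = mods)
  violations <- checkCemCardinality(inst, model)
  if (length(violations))
    stop(sprintf("CEM cardinality violation(s):\n%s",
                 paste0("  - ", violations, collapse = "\n")))
  inst
}

#' Render a CEM instance as XML
#'
#' The instance dialect mirrors the model's entry names:
#' `<ceinst model="...">` with a `<data value=""/>` child and one
#' `<qual/mod/att name="" value=""/>` element per populated value, in model
#' order. This instance dialect is defined by this package (the model
#' dialect defines no instance serialization).
#'
#' @param instance A [CemInstance-class].
#' @param model The [CetypeModel-class] it instantiates (supplies entry
#'   order and the trichotomy).
#' @return A single XML string.
#' @export
cemInstanceXml <- function(instance, model) {
  violations <- checkCemCardinality(instance, model)
  if (length(violations))
    stop(sprintf("CEM cardinality violation(s):\n%s",
                 paste0("  - ", violations, collapse = "\n")))
  lines <- sprintf('<ceinst model="%s" key="%s">',
                   .xml_escape(instance@modelName),
                   .xml_escape(instance@keyCode))
  if (!is.na(instance@dataValue))
    lines <- c(lines, sprintf('  <data value="%s" />',
                              .xml_escape(instance@dataValue)))
  for (tag in c("qual", "mod", "att")) {
    sl <- c(qual = "quals", mod = "mods", att = "atts")[[tag]]
    df <- slot(model, sl)
    values <- slot(instance, sl)
    for (nm in df$name)
      for (v in values[[nm]] %||% character())
        lines <- c(lines, sprintf('  <%s name="%s" value="%s" />', tag,
                                  .xml_escape(nm), .xml_escape(v)))
  }
  paste0(paste(c(lines, "</ceinst>"), collapse = "\n"), "\n")
}

#' @describeIn CetypeModel-class Compact model summary.
#' @param object A `CetypeModel`.
#' @export
setMethod("show", "CetypeModel", function(object) {
  cat(sprintf("CetypeModel '%s' (kind %s): key %s, data %s [%s]\n",
              object@name, object@kind, object@keyCode, object@dataDomain,
              object@dataType))
  cat(sprintf("  %d qualifier(s), %d modifier(s), %d attribution(s)\n",
              nrow(object@quals), nrow(object@mods), nrow(object@atts)))
  invisible(object)
})

#' @describeIn CemInstance-class Compact instance summary.
#' @param object A `CemInstance`.
#' @export
setMethod("show", "CemInstance", function(object) {
  cat(sprintf("CemInstance of '%s': data value %s\n", object@modelName,
              object@dataValue))
  for (tag in c("quals", "mods", "atts")) {
    values <- slot(object, tag)
    for (nm in names(values))
      cat(sprintf("  %s %s = %s\n", sub("s$", "", tag), nm,
                  paste(values[[nm]], collapse = ", ")))
  }
  invisible(object)
})
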