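## semantic_bridge: the shallow-to-deep transformation. Coreferring spanned
## mentions (textsem) are resolved into unspanned document-level elements
## (refsem): chains become elements, concept hypothesis arrays are
## disambiguated to a single concept, context flags are merged, relative
## times are normalized against the document date, modifiers become element
## attributes, and text relations are lifted to element relations.

#' Configure the resolution bridge
#'
#' @param conflictPolicy How feature conflicts between coreferring mentions
#'   are resolved: `"last-mention-wins"` (default; clinical narrative tends
#'   to refine earlier statements) or `"error"`.
#' @param dateGrammar Enabled relative-time patterns, a subset of
#'   `c("ago", "yesterday", "today")`.
#' @param documentDateKey Metadata key holding the ISO 8601 document date.
#' @return A [BridgeConfig-class].
#' @export
bridgeConfig <- function(conflictPolicy = c("last-mention-wins", "error"),
                         dateGrammar = c("ago", "yesterday", "today"),
                         documentDateKey = "documentDate") {
  conflictPolicy <- match.arg(conflictPolicy)
  new("BridgeConfig", conflictPolicy = conflictPolicy,
      dateGrammar = dateGrammar, documentDateKey = documentDateKey)
}

#' Construct a coreference chain
#' @param mentionIds Integer mention ids in document order.
#' @return A [CorefChain-class].
#' @export
corefChain <- function(mentionIds) new("CorefChain",
                                       mentionIds = as.integer(mentionIds))

## Deref a RelationArgument reference down to the wrapped annotation id.
.argument_mention <- function(store, relArgRef) {
  ra <- instanceById(store, unclass(relArgRef)[1L])
  arg <- ra@features$argument
  if (is.null(arg)) stop(sprintf("RelationArgument %d has no argument", ra@id))
  unclass(arg)[1L]
}

#' Build coreference chains
#'
#' Computes the connected components of the coreference graph: nodes are the
#' entity/event mentions of the document, edges the
#' `relation.CoreferenceRelation` instances (via their `RelationArgument`
#' wrappers). Mentions not participating in any coreference relation form
#' singleton chains, so the chains partition the mentions. Chains are
#' ordered by their first mention's `begin` offset; mentions within a chain
#' are in document order.
#'
#' @param store A [DocumentStore-class].
#' @return List of [CorefChain-class].
#' @export
setMethod("buildCorefChains", "DocumentStore", function(store) {
  mentions <- c(getByType(store, "textsem.EntityMention", TRUE),
                getByType(store, "textsem.EventMention", TRUE))
  ids <- vapply(mentions, function(x) x@id, integer(1))
  corefs <- getByType(store, "relation.CoreferenceRelation", TRUE)
  edges <- matrix(integer(), ncol = 2)
  for (rel in corefs) {
    m1 <- .argument_mention(store, rel@features$arg1)
    m2 <- .argument_mention(store, rel@features$arg2)
    for (m in c(m1, m2)) {
      tn <- instanceById(store, m)@typeName
      if (!subsumes(store@registry, "textsem.IdentifiedAnnotation", tn))
        stop(sprintf(
          "coreference argument %d is a '%s', not an IdentifiedAnnotation",
          m, tn))
    }
    ids <- union(ids, c(m1, m2))
    edges <- rbind(edges, c(m1, m2))
  }
  if (!length(ids)) return(list())
  ## union-find over mention ids
  parent <- stats::setNames(ids, as.character(ids))
  find <- function(x) {
    k <- as.character(x)
    while (parent[[k]] != x) { x <- parent[[k]]; k <- as.character(x) }
    x
  }
  if (nrow(edges))
    for (i in seq_len(nrow(edges))) {
      r1 <- find(edges[i, 1]); r2 <- find(edges[i, 2])
      if (r1 != r2) parent[[as.character(r2)]] <- r1
    }
  roots <- vapply(ids, find, integer(1))
  groups <- split(ids, roots)
  pos <- function(id) {
    inst <- instanceById(store, id)
    if (is.na(inst@begin)) .Machine$integer.max else inst@begin
  }
  chains <- lapply(groups, function(g) {
    g <- g[order(vapply(g, pos, integer(1)), g)]
    corefChain(g)
  })
  first <- vapply(chains, function(ch) pos(ch@mentionIds[1L]), integer(1))
  firstId <- vapply(chains, function(ch) ch@mentionIds[1L], integer(1))
  unname(chains[order(first, firstId)])
})

#' Choose the element type of a chain
#'
#' Maps a coreference chain to the referential-semantic type its element
#' should have, via the mentions' `typeID` semantic-group code (see
#' [typeIdTable()]). Event-mention chains resolve to one of the five event
#' core CEMs (or plain `refsem.Event` for unmapped codes); entity-mention
#' chains resolve to `refsem.AnatomicalSite` or plain `refsem.Entity`.
#' Chains mixing entity and event mentions are an error; mentions of a chain
#' disagreeing on `typeID` are resolved per the conflict policy.
#'
#' @param chain A [CorefChain-class].
#' @param store A [DocumentStore-class].
#' @param config A [BridgeConfig-class].
#' @return A qualified `refsem` type name.
#' @export
selectElementType <- function(chain, store, config = bridgeConfig()) {
  insts <- lapply(chain@mentionIds, instanceById, store = store)
  isEvent <- vapply(insts, function(x)
    subsumes(store@registry, "textsem.EventMention", x@typeName), logical(1))
  isEntity <- vapply(insts, function(x)
    subsumes(store@registry, "textsem.EntityMention", x@typeName), logical(1))
  if (any(isEvent) && any(isEntity))
    stop("chain mixes EntityMention and EventMention mentions")
  if (!all(isEvent | isEntity))
    stop("chain contains mentions that are neither entity nor event mentions")
  tids <- vapply(insts, function(x)
    as.integer(x@features$typeID %||% 0L), integer(1))
  tid <- .merge_one(tids, insts, "typeID", config)
  tab <- typeIdTable()
  mapped <- tab$elementType[match(tid, tab$typeID)]
  if (all(isEvent)) {
    ev <- mapped[!is.na(mapped)]
    if (length(ev) &&
        subsumes(store@registry, "refsem.Event", ev)) return(ev)
    return("refsem.Event")
  }
  if (!is.na(mapped) && mapped == "refsem.AnatomicalSite")
    return("refsem.AnatomicalSite")
  "refsem.Entity"
}

#' Disambiguate a chain's ontology concept
#'
#' Each mention carries a ranked hypothesis array
#' (`ontologyConceptArr`); the element gets the single concept appearing in
#' every nonempty array with the best (lowest) rank-sum. Ties are broken
#' lexicographically by concept code; when no concept is common to all
#' nonempty arrays, the first mention's top-ranked concept is used. With all
#' arrays empty the concept is left unset (`NA`).
#'
#' @param chain A [CorefChain-class].
#' @param store A [DocumentStore-class].
#' @return The chosen `refsem.OntologyConcept` instance id, or
#'   `NA_integer_`.
#' @export
disambiguateConcept <- function(chain, store) {
  insts <- lapply(chain@mentionIds, instanceById, store = store)
  arrs <- lapply(insts, function(x)
    unclass(x@features$ontologyConceptArr %||% clinRef(integer())))
  codes <- lapply(arrs, function(a)
    vapply(a, function(cid) instanceById(store, cid)@features$code %||%
             NA_character_, character(1)))
  nonempty <- which(lengths(codes) > 0L)
  if (!length(nonempty)) return(NA_integer_)
  common <- Reduce(intersect, codes[nonempty])
  if (length(common)) {
    ranksum <- vapply(common, function(code)
      sum(vapply(codes[nonempty], function(cs) match(code, cs), integer(1))),
      integer(1))
    best <- common[ranksum == min(ranksum)]
    chosen <- sort(best)[1L]
  } else {
    chosen <- codes[[nonempty[1L]]][1L]
  }
  for (i in nonempty)
    if (chosen %in% codes[[i]])
      return(arrs[[i]][match(chosen, codes[[i]])])
  NA_integer_
}

## Resolve one feature across the chain: unanimous passes through,
## conflicts per policy (last-mention-wins = greatest begin, tie greatest
## id; error = raise naming the feature).
.merge_one <- function(values, insts, fname, config) {
  uniq <- unique(values)
  if (length(uniq) == 1L) return(uniq[[1L]])
  if (config@conflictPolicy == "error")
    stop(sprintf("conflicting '%s' values across coreferring mentions: %s",
                 fname, paste(format(values), collapse = " vs ")))
  b <- vapply(insts, function(x)
    if (is.na(x@begin)) -1L else x@begin, integer(1))
  i <- vapply(insts, function(x) x@id, integer(1))
  values[order(b, i)][[length(values)]]
}

#' Merge context flags across a chain
#'
#' Aggregates the five context features of coreferring mentions — polarity,
#' conditional, uncertainty, generic, subject — into the values the resolved
#' element carries. Unanimous values pass through; conflicts are resolved by
#' the configured policy (`"last-mention-wins"`: the value of the mention
#' with the greatest `begin`; `"error"`: raise, naming the conflicting
#' feature).
#'
#' @param chain A [CorefChain-class] (nonempty).
#' @param store A [DocumentStore-class].
#' @param config A [BridgeConfig-class].
#' @return Named list with elements `polarity`, `conditional`,
#'   `uncertainty`, `generic`, `subject`.
#' @export
mergeContextFlags <- function(chain, store, config = bridgeConfig()) {
  stopifnot(length(chain@mentionIds) > 0L)
  insts <- lapply(chain@mentionIds, instanceById, store = store)
  defaults <- list(polarity = 1L, conditional = FALSE, uncertainty = 0L,
                   generic = FALSE, subject = "patient")
  out <- list()
  for (fname in names(defaults)) {
    values <- lapply(insts, function(x)
      x@features[[fname]] %||% defaults[[fname]])
    out[[fname]] <- .merge_one(values, insts, fname, config)
  }
  out
}

.days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  nxt <- if (month == 12L) as.Date(sprintf("%04d-01-01", year + 1L))
         else as.Date(sprintf("%04d-%02d-01", year, month + 1L))
  as.integer(nxt - first)
}

.shift_months <- function(date, nMonths) {
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  total <- y * 12L + (m - 1L) - nMonths
  y2 <- total %/% 12L
  m2 <- total %% 12L + 1L
  d2 <- min(d, .days_in_month(y2, m2))
  list(day = d2, month = m2, year = y2)
}

#' Normalize a relative time expression against the document date
#'
#' Grounds a relative phrase — `"<N> (day|week|month|year)s? ago"`,
#' `"yesterday"`, `"today"` — to calendar day/month/year integers by
#' subtracting from the document date. Month and year subtraction clamps the
#' day to the target month's length (e.g. two months before March 31 is
#' January 31, but one month before is February 28/29). Phrases outside the
#' grammar are deliberately left unnormalized: the function returns `NULL`
#' rather than guessing.
#'
#' @param phrase Time expression string (case-insensitive, surrounding
#'   whitespace ignored).
#' @param documentDate The document date, as a `Date` or an ISO 8601 string.
#' @param config A [BridgeConfig-class]; its `dateGrammar` selects the
#'   enabled patterns.
#' @return `list(day =, month =, year =)`, or `NULL` when the phrase does
#'   not match the grammar.
#' @export
#' @examples
#' normalizeRelativeDate("2 days ago", "2006-09-03")  # 2006-09-01
#' normalizeRelativeDate("next Tuesday", "2006-09-03")  # NULL
normalizeRelativeDate <- function(phrase, documentDate,
                                  config = bridgeConfig()) {
  D <- tryCatch(as.Date(documentDate), error = function(e) NA)
  if (is.na(D)) stop("documentDate is not a valid date")
  p <- tolower(trimws(phrase))
  asfields <- function(date) list(day = as.integer(format(date, "%d")),
                                  month = as.integer(format(date, "%m")),
                                  year = as.integer(format(date, "%Y")))
  if (p == "today" && "today" %in% config@dateGrammar) return(asfields(D))
  if (p == "yesterday" && "yesterday" %in% config@dateGrammar)
    return(asfields(D - 1L))
  if ("ago" %in% config@dateGrammar) {
    m <- regmatches(p, regexec("^([0-9]+) (day|week|month|year)s? ago$", p))[[1]]
    if (length(m) == 3L) {
      n <- as.integer(m[2L])
      return(switch(m[3L],
        day = asfields(D - n),
        week = asfields(D - 7L * n),
        month = .shift_months(D, n),
        year = .shift_months(D, 12L * n)))
    }
  }
  NULL
}

#' Attach a normalized modifier to an element
#'
#' Takes a `textsem.Modifier` that has been normalized to a
#' `refsem.Attribute` and stores that attribute in the matching slot of the
#' element: the element type's (possibly inherited) feature whose reference
#' range covers the attribute's type — e.g. a `refsem.Severity` fills the
#' `severity` slot of a sign/symptom. Attribute kinds not declared for the
#' element's type are an error (a medication strength cannot attach to a
#' procedure).
#'
#' @param store A [DocumentStore-class].
#' @param modifierId Id of the `textsem.Modifier` (its `normalized` feature
#'   must be set).
#' @param elementId Id of the target `refsem.Element` instance.
#' @return The updated store.
#' @export
attachModifier <- function(store, modifierId, elementId) {
  mod <- instanceById(store, modifierId)
  if (!subsumes(store@registry, "textsem.Modifier", mod@typeName))
    stop(sprintf("instance %d is not a textsem.Modifier", modifierId))
  normRef <- mod@features$normalized
  if (is.null(normRef))
    stop(sprintf("Modifier %d has not been normalized to an Attribute",
                 modifierId))
  attrId <- unclass(normRef)[1L]
  attrType <- instanceById(store, attrId)@typeName
  el <- instanceById(store, elementId)
  slotName <- NULL
  for (fd in .collect_features(store@registry, el@typeName)) {
    target <- .range_target(fd@range)
    if (is.na(target) || !startsWith(fd@range, "ref:")) next
    if (!target %in% .root_markers() &&
        subsumes(store@registry, "refsem.Attribute", target) &&
        subsumes(store@registry, target, attrType)) {
      slotName <- fd@name
      break
    }
  }
  if (is.null(slotName))
    stop(sprintf("attribute kind '%s' is not declared for element type '%s'",
                 attrType, el@typeName))
  store <- .set_feature(store, elementId, slotName, clinRef(attrId))
  .set_feature(store, modifierId, "normalized", clinRef(attrId))
}

#' Lift a text relation to an element relation
#'
#' Converts a spanned `relation.BinaryTextRelation` between two mentions
#' into an unspanned element relation between the mentions' resolved
#' elements. The relation's `category` selects the concrete type (degreeOf,
#' affects, locationOf, resultOf, manifestationOf map to the named UMLS
#' relation types; anything else becomes a generic
#' `relation.ElementRelation`); polarity and uncertainty are copied exactly
#' — a negated text relation lifts to a negated element relation.
#'
#' @param store A [DocumentStore-class].
#' @param relationId Id of the text relation.
#' @param elementMap Named integer vector mapping mention id (as name) to
#'   element id.
#' @return The updated store; the new relation's id is `lastId(store)`.
#' @export
liftRelation <- function(store, relationId, elementMap) {
  rel <- instanceById(store, relationId)
  m1 <- .argument_mention(store, rel@features$arg1)
  m2 <- .argument_mention(store, rel@features$arg2)
  e1 <- elementMap[as.character(m1)]
  e2 <- elementMap[as.character(m2)]
  if (is.na(e1) || is.na(e2))
    stop(sprintf(
      "text relation %d has an argument whose mention maps to no element",
      relationId))
  category <- rel@features$category %||% NA_character_
  lifted <- clinConstants()$liftMap[[category]] %||% "relation.ElementRelation"
  addAnnotation(store, lifted, features = list(
    category = category,
    polarity = as.integer(rel@features$polarity %||% 1L),
    uncertainty = as.integer(rel@features$uncertainty %||% 0L),
    arg1 = clinRef(e1), arg2 = clinRef(e2)))
}

## TimeMention handling: ground the phrase, materialize refsem.Time (ISO
## normalizedForm) + refsem.Date, and point the mention at both.
.normalize_time_mentions <- function(store, config) {
  tms <- getByType(store, "textsem.TimeMention", TRUE)
  map <- list()
  if (!length(tms)) return(list(store = store, map = map))
  docDate <- store@metadata[[config@documentDateKey]]
  if (is.null(docDate))
    stop(sprintf("document date missing from metadata key '%s' but TimeMentions are present",
                 config@documentDateKey))
  for (tm in tms) {
    phrase <- substr(store@text, tm@begin + 1L, tm@end)
    norm <- normalizeRelativeDate(phrase, docDate, config)
    if (is.null(norm)) next       # outside the grammar: leave unnormalized
    store <- addAnnotation(store, "refsem.Date", features = list(
      day = norm$day, month = norm$month, year = norm$year))
    dateId <- lastId(store)
    store <- addAnnotation(store, "refsem.Time", features = list(
      normalizedForm = sprintf("%04d-%02d-%02d", norm$year, norm$month,
                               norm$day)))
    timeId <- lastId(store)
    store <- .set_feature(store, tm@id, "time", clinRef(timeId))
    store <- .set_feature(store, tm@id, "date", clinRef(dateId))
    map[[as.character(tm@id)]] <- list(timeId = timeId, dateId = dateId)
  }
  list(store = store, map = map)
}

## A BinaryTextRelation between a TimeMention and an event mention with a
## temporal category sets the element's startTime (or startDate) slot.
.apply_temporal <- function(store, rel, elementMap, timeMap) {
  m1 <- .argument_mention(store, rel@features$arg1)
  m2 <- .argument_mention(store, rel@features$arg2)
  isTime <- function(m)
    subsumes(store@registry, "textsem.TimeMention",
             instanceById(store, m)@typeName)
  tmId <- if (isTime(m1)) m1 else if (isTime(m2)) m2 else return(store)
  evId <- if (tmId == m1) m2 else m1
  eid <- elementMap[as.character(evId)]
  tinfo <- timeMap[[as.character(tmId)]]
  if (is.na(eid) || is.null(tinfo)) return(store)
  el <- instanceById(store, eid)
  feats <- .collect_features(store@registry, el@typeName)
  if (!is.null(feats[["startTime"]]))
    return(.set_feature(store, eid, "startTime", clinRef(tinfo$timeId)))
  if (!is.null(feats[["startDate"]]))
    return(.set_feature(store, eid, "startDate", clinRef(tinfo$dateId)))
  store
}

#' Resolve a document's text semantics into referential semantics
#'
#' The full shallow-to-deep bridge. Starting from a store holding the
#' textual-semantic layer (mentions, modifiers, time mentions, text
#' relations), it:
#' \enumerate{
#'   \item normalizes every `textsem.TimeMention` matching the relative-date
#'     grammar into `refsem.Time`/`refsem.Date` instances, grounded against
#'     the document date;
#'   \item builds coreference chains ([buildCorefChains()]) and creates one
#'     `refsem` element per chain — type via [selectElementType()], single
#'     disambiguated concept via [disambiguateConcept()], merged context
#'     flags via [mergeContextFlags()] — with `mention` back-pointers and
#'     bidirectional `EventMention:event` / `EntityMention:entity` links;
#'   \item applies temporal text relations (categories `"startTime"`,
#'     `"TIMEX-of"`) as `startTime`/`startDate` slots on the elements;
#'   \item attaches modifier degree relations as element attributes
#'     ([attachModifier()]);
#'   \item lifts the remaining binary text relations between resolved
#'     mentions to element relations ([liftRelation()]).
#' }
#' The operation is idempotent: a store already carrying a referential layer
#' is returned unchanged. The output store still validates.
#'
#' @param store A [DocumentStore-class].
#' @param config A [BridgeConfig-class].
#' @return The augmented store.
#' @export
#' @examples
#' resolved <- resolveDocument(workedExampleStore())
#' getByType(resolved, "refsem.SignSymptom", FALSE)
setMethod("resolveDocument", "DocumentStore",
          function(store, config = bridgeConfig()) {
  if (length(getByType(store, "refsem.Element", TRUE)))
    return(store)                 # already resolved: no-op
  chains <- buildCorefChains(store)
  tm <- .normalize_time_mentions(store, config)
  store <- tm$store
  elementMap <- integer()
  for (chain in chains) {
    etype <- selectElementType(chain, store, config)
    conceptId <- disambiguateConcept(chain, store)
    flags <- mergeContextFlags(chain, store, config)
    feats <- c(flags, list(mention = clinRef(chain@mentionIds)))
    if (!is.na(conceptId)) feats$ontologyConcept <- clinRef(conceptId)
    store <- addAnnotation(store, etype, features = feats)
    eid <- lastId(store)
    isEvent <- subsumes(store@registry, "refsem.Event", etype)
    backSlot <- if (isEvent) "event" else "entity"
    for (m in chain@mentionIds) {
      mtn <- instanceById(store, m)@typeName
      slotOk <- if (isEvent)
        subsumes(store@registry, "textsem.EventMention", mtn)
      else subsumes(store@registry, "textsem.EntityMention", mtn)
      if (slotOk) store <- .set_feature(store, m, backSlot, clinRef(eid))
      elementMap[as.character(m)] <- eid
    }
  }
  cons <- clinConstants()
  consumed <- integer()
  btrs <- getByType(store, "relation.BinaryTextRelation", TRUE)
  for (rel in btrs) {
    if (subsumes(store@registry, "relation.CoreferenceRelation",
                 rel@typeName)) next
    category <- rel@features$category %||% NA_character_
    if (!is.na(category) && category %in% cons$temporalCategories) {
      store <- .apply_temporal(store, rel, elementMap, tm$map)
      consumed <- c(consumed, rel@id)
    }
  }
  for (rel in btrs) {
    category <- rel@features$category %||% NA_character_
    if (is.na(category) || !category %in% cons$degreeCategories) next
    m1 <- .argument_mention(store, rel@features$arg1)
    m2 <- .argument_mention(store, rel@features$arg2)
    isMod <- function(m)
      subsumes(store@registry, "textsem.Modifier",
               instanceById(store, m)@typeName)
    modId <- if (isMod(m1)) m1 else if (isMod(m2)) m2 else next
    target <- if (modId == m1) m2 else m1
    eid <- elementMap[as.character(target)]
    if (is.na(eid)) next
    store <- attachModifier(store, modId, eid)
    consumed <- c(consumed, rel@id)
  }
  for (rel in btrs) {
    if (rel@id %in% consumed) next
    if (subsumes(store@registry, "relation.CoreferenceRelation",
                 rel@typeName)) next
    m1 <- .argument_mention(store, rel@features$arg1)
    m2 <- .argument_mention(store, rel@features$arg2)
    if (is.na(elementMap[as.character(m1)]) ||
        is.na(elementMap[as.character(m2)])) next
    store <- liftRelation(store, rel@id, elementMap)
  }
  store
})
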