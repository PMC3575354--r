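## fixtures_cli (data half): the packaged worked example and the randomized
## synthetic-document generator. Both build stores purely through the public
## store API, so every fixture is schema-valid by construction.

## Small helper: add a RelationArgument wrapping a mention, return its id.
.wrap_arg <- function(store, mentionId) {
  addAnnotation(store, "relation.RelationArgument",
                features = list(argument = clinRef(mentionId)))
}

#' The packaged worked-example store
#'
#' Builds the two-sentence chief-complaint document
#' `"Chief complaint: severe cough and fever. Cough started 2 days ago, no
#' expectoration."` with its shallow semantic layer: four event mentions
#' (`cough` \[24,29), `fever` \[34,39), `Cough` \[41,46), `expectoration`
#' \[70,83)), the `severe` modifier \[17,23) normalized to a
#' `refsem.Severity`, the `2 days ago` time mention \[55,65), a coreference
#' relation linking the two cough mentions, a temporal relation attaching
#' the time to `Cough`, a degree relation attaching `severe` to `cough`, and
#' a negated manifestation relation between `Cough` and `expectoration`.
#' The document date is 2006-09-03, so `"2 days ago"` normalizes to
#' 2006-09-01.
#'
#' @return A schema-valid [DocumentStore-class] (textual layer only; run
#'   [resolveDocument()] for the referential layer).
#' @export
#' @examples
#' store <- workedExampleStore()
#' validateStore(store)   # character(0)
workedExampleStore <- function() {
  txt <- paste0("Chief complaint: severe cough and fever. ",
                "Cough started 2 days ago, no expectoration.")
  store <- documentStore(txt, metadata = list(documentDate = "2006-09-03"))
  store <- addAnnotation(store, "textspan.Sentence", 0, 40,
                         list(sentenceNumber = 0L))
  store <- addAnnotation(store, "textspan.Sentence", 41, 84,
                         list(sentenceNumber = 1L))
  mkConcept <- function(store, cui) {
    addAnnotation(store, "refsem.UMLSConcept", features = list(
      code = cui, codingScheme = "UMLS", cui = cui, tui = "T184"))
  }
  mkMention <- function(store, begin, end, conceptId, polarity = 1L) {
    addAnnotation(store, "textsem.EventMention", begin, end, list(
      typeID = 3L, polarity = polarity,
      ontologyConceptArr = clinRef(conceptId)))
  }
  store <- mkConcept(store, "C0010200"); coughC1 <- lastId(store)
  store <- mkMention(store, 24, 29, coughC1); cough1 <- lastId(store)
  store <- mkConcept(store, "C0015967"); feverC <- lastId(store)
  store <- mkMention(store, 34, 39, feverC); fever <- lastId(store)
  store <- mkConcept(store, "C0010200"); coughC2 <- lastId(store)
  store <- mkMention(store, 41, 46, coughC2); cough2 <- lastId(store)
  store <- mkConcept(store, "C0034642"); expC <- lastId(store)
  store <- mkMention(store, 70, 83, expC, polarity = -1L)
  expect <- lastId(store)
  ## "severe" modifier, pre-normalized to a Severity attribute
  store <- addAnnotation(store, "refsem.Severity",
                         features = list(value = "severe"))
  sev <- lastId(store)
  store <- addAnnotation(store, "textsem.Modifier", 17, 23,
                         list(normalized = clinRef(sev)))
  severe <- lastId(store)
  store <- addAnnotation(store, "textsem.TimeMention", 55, 65)
  when <- lastId(store)
  rel <- function(store, type, m1, m2, features = list()) {
    store <- .wrap_arg(store, m1); a1 <- lastId(store)
    store <- .wrap_arg(store, m2); a2 <- lastId(store)
    addAnnotation(store, type,
                  features = c(list(arg1 = clinRef(a1),
                                    arg2 = clinRef(a2)), features))
  }
  store <- rel(store, "relation.CoreferenceRelation", cough1, cough2)
  store <- rel(store, "relation.BinaryTextRelation", cough2, when,
               list(category = "startTime"))
  store <- rel(store, "relation.BinaryTextRelation", severe, cough1,
               list(category = "degreeOf"))
  store <- rel(store, "relation.UMLSRelation", cough2, expect,
               list(category = "manifestationOf", polarity = -1L))
  store
}

#' Path to the packaged worked-example document JSON
#' @return File path of the serialized worked example.
#' @export
workedExamplePath <- function() {
  system.file("extdata", "worked-example.json", package = "clintypes",
              mustWork = TRUE)
}

.default_vocabulary <- function() {
  data.frame(
    code = c("C0010200", "C0015967", "C0030193", "C0034642", "C0018681",
             "C0027497"),
    tui = "T184",
    surface = c("cough", "fever", "pain", "expectoration", "headache",
                "nausea"),
    stringsAsFactors = FALSE)
}

#' Parameters for the synthetic document generator
#'
#' Defaults describe a short clinical note: five sentences of two
#' sign/symptom mentions each, with roughly a third of repeat mentions
#' coreferring, a modest negation rate typical of problem-list narrative,
#' and an occasional relative date. The vocabulary is a small illustrative
#' concept table (including the pain concept C0030193/T184).
#'
#' @param seed Integer random seed; generation is a pure function of the
#'   spec including this seed.
#' @param nSentences,nMentionsPerSentence Document shape.
#' @param corefRate Probability that a repeated concept mention corefers
#'   with its first mention.
#' @param negationRate Probability that a mention is negated.
#' @param relativeDateRate Probability that a sentence carries a relative
#'   date attached to its first mention.
#' @param vocabulary Data frame with columns `code`, `tui`, `surface`.
#' @return A [FixtureSpec-class].
#' @export
fixtureSpec <- function(seed = 1L, nSentences = 5L,
                        nMentionsPerSentence = 2L, corefRate = 0.3,
                        negationRate = 0.15, relativeDateRate = 0.2,
                        vocabulary = .default_vocabulary()) {
  new("FixtureSpec", seed = as.integer(seed),
      nSentences = as.integer(nSentences),
      nMentionsPerSentence = as.integer(nMentionsPerSentence),
      corefRate = corefRate, negationRate = negationRate,
      relativeDateRate = relativeDateRate, vocabulary = vocabulary)
}

#' Generate a random synthetic clinical document store
#'
#' Emits a schema-valid store of templated sentences ("Patient reports
#' cough and fever." / "Patient denies nausea ..."), each mention an
#' `textsem.EventMention` with its own `refsem.UMLSConcept` hypothesis.
#' Negated mentions are written with "no"/"denies" wording and polarity -1.
#' Repeat mentions of a concept corefer with the first mention with
#' probability `corefRate`; sentences gain a `"<N> days ago"` time mention
#' wired to their first mention with probability `relativeDateRate`.
#' The same spec (including its seed) always yields a byte-identical
#' serialization; the caller's RNG state is left untouched. Coreference
#' links are only ever created between same-concept mentions.
#'
#' @param spec A [FixtureSpec-class].
#' @return A [DocumentStore-class].
#' @export
#' @examples
#' store <- generateStore(fixtureSpec(seed = 42))
#' length(buildCorefChains(store))
setMethod("generateStore", "FixtureSpec", function(spec) {
  validObject(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec@seed)
  vocab <- spec@vocabulary
  pieces <- character()
  pos <- 0L
  mentions <- list()   # list(begin, end, code, polarity, sentence)
  dates <- list()      # list(begin, end, sentence)
  emit <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  for (s in seq_len(spec@nSentences)) {
    rows <- sample.int(nrow(vocab), spec@nMentionsPerSentence,
                       replace = FALSE)
    neg <- stats::runif(length(rows)) < spec@negationRate
    emit(if (neg[1L]) "Patient denies " else "Patient reports ")
    for (k in seq_along(rows)) {
      if (k > 1L) emit(if (neg[k]) " and no " else " and ")
      surf <- vocab$surface[rows[k]]
      mentions[[length(mentions) + 1L]] <-
        list(begin = pos, end = pos + nchar(surf),
             code = vocab$code[rows[k]],
             polarity = if (neg[k]) -1L else 1L, sentence = s)
      emit(surf)
    }
    if (stats::runif(1) < spec@relativeDateRate) {
      emit(" starting ")
      phrase <- sprintf("%d days ago", sample.int(30L, 1L))
      dates[[length(dates) + 1L]] <-
        list(begin = pos, end = pos + nchar(phrase), sentence = s)
      emit(phrase)
    }
    emit(". ")
  }
  text <- sub(" $", "", paste(pieces, collapse = ""))
  store <- documentStore(text, metadata = list(documentDate = "2010-06-15"))
  mentionIds <- integer(length(mentions))
  firstByCode <- list()
  corefPairs <- list()
  for (i in seq_along(mentions)) {
    m <- mentions[[i]]
    store <- addAnnotation(store, "refsem.UMLSConcept", features = list(
      code = m$code, codingScheme = "UMLS", cui = m$code,
      tui = vocab$tui[match(m$code, vocab$code)]))
    cid <- lastId(store)
    store <- addAnnotation(store, "textsem.EventMention", m$begin, m$end,
                           list(typeID = 3L, polarity = m$polarity,
                                ontologyConceptArr = clinRef(cid)))
    mentionIds[i] <- lastId(store)
    prev <- firstByCode[[m$code]]
    if (is.null(prev)) {
      firstByCode[[m$code]] <- mentionIds[i]
    } else if (stats::runif(1) < spec@corefRate) {
      corefPairs[[length(corefPairs) + 1L]] <- c(prev, mentionIds[i])
    }
  }
  for (pair in corefPairs) {
    store <- .wrap_arg(store, pair[1L]); a1 <- lastId(store)
    store <- .wrap_arg(store, pair[2L]); a2 <- lastId(store)
    store <- addAnnotation(store, "relation.CoreferenceRelation",
                           features = list(arg1 = clinRef(a1),
                                           arg2 = clinRef(a2)))
  }
  sentenceFirst <- vapply(seq_len(spec@nSentences), function(s) {
    hit <- which(vapply(mentions, function(m) m$sentence == s, logical(1)))
    if (length(hit)) mentionIds[hit[1L]] else NA_integer_
  }, integer(1))
  for (d in dates) {
    store <- addAnnotation(store, "textsem.TimeMention", d$begin, d$end)
    tmId <- lastId(store)
    target <- sentenceFirst[d$sentence]
    if (is.na(target)) next
    store <- .wrap_arg(store, target); a1 <- lastId(store)
    store <- .wrap_arg(store, tmId); a2 <- lastId(store)
    store <- addAnnotation(store, "relation.BinaryTextRelation",
                           features = list(arg1 = clinRef(a1),
                                           arg2 = clinRef(a2),
                                           category = "startTime"))
  }
  store
})
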