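test_that("coreference chains partition the worked example's mentions", {
  store <- workedExampleStore()
  chains <- buildCorefChains(store)
  expect_length(chains, 3)
  surf <- lapply(chains, function(ch)
    vapply(ch@mentionIds, function(id) {
      m <- instanceById(store, id)
      substr(worked_text, m@begin + 1, m@end)
    }, character(1)))
  expect_identical(surf[[1]], c("cough", "Cough"))
  expect_identical(surf[[2]], "fever")
  expect_identical(surf[[3]], "expectoration")
})

test_that("chaining is transitive and matches the closure oracle on random graphs", {
  ## explicit transitivity: (m1,m2),(m2,m3) collapse to one chain
  g <- mention_graph_store(3, list(c(1, 2), c(2, 3)))
  chains <- buildCorefChains(g$store)
  expect_length(chains, 1)
  expect_setequal(chains[[1]]@mentionIds, g$mentionIds)
  ## random graphs up to 50 mentions vs boolean matrix closure
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:50, 1)
    nEdges <- sample(0:(n %/% 2), 1)
    pairs <- replicate(nEdges, sample.int(n, 2), simplify = FALSE)
    g <- mention_graph_store(n, pairs)
    got <- lapply(buildCorefChains(g$store), function(ch)
      sort(ch@mentionIds))
    want <- closure_chains(g$mentionIds,
                           lapply(pairs, function(p) g$mentionIds[p]))
    expect_identical(sort(vapply(got, paste, "", collapse = ",")),
                     sort(vapply(want, paste, "", collapse = ",")),
                     info = sprintf("seed %d", seed))
  }
})

test_that("chaining agrees with igraph connected components", {
  skip_if_not_installed("igraph")
  set.seed(99)
  n <- 40
  pairs <- replicate(15, sample.int(n, 2), simplify = FALSE)
  g <- mention_graph_store(n, pairs)
  got <- lapply(buildCorefChains(g$store), function(ch) sort(ch@mentionIds))
  ig <- igraph::graph_from_edgelist(
    do.call(rbind, lapply(pairs, function(p)
      match(g$mentionIds[p], g$mentionIds))), directed = FALSE)
  ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  comp <- igraph::components(ig)$membership
  want <- lapply(split(g$mentionIds, comp), sort)
  expect_identical(sort(vapply(got, paste, "", collapse = ",")),
                   sort(vapply(unname(want), paste, "", collapse = ",")))
})

test_that("coreference over non-mention annotations is refused", {
  store <- documentStore("a sentence here")
  store <- addAnnotation(store, "textspan.Sentence", 0, 5,
                         list(sentenceNumber = 0L))
  s1 <- lastId(store)
  store <- addAnnotation(store, "textsem.EventMention", 2, 10,
                         list(typeID = 3L))
  m1 <- lastId(store)
  store <- addAnnotation(store, "relation.RelationArgument",
                         features = list(argument = clinRef(s1)))
  a1 <- lastId(store)
  store <- addAnnotation(store, "relation.RelationArgument",
                         features = list(argument = clinRef(m1)))
  a2 <- lastId(store)
  store <- addAnnotation(store, "relation.CoreferenceRelation",
                         features = list(arg1 = clinRef(a1),
                                         arg2 = clinRef(a2)))
  expect_error(buildCorefChains(store), "not an IdentifiedAnnotation")
})

test_that("chains map to element types via typeID semantic groups", {
  store <- workedExampleStore()
  chains <- buildCorefChains(store)
  expect_identical(selectElementType(chains[[1]], store),
                   "refsem.SignSymptom")
  ## an entity mention with an anatomical-site code becomes an AnatomicalSite
  st2 <- documentStore("left lung")
  st2 <- addAnnotation(st2, "textsem.EntityMention", 5, 9,
                       list(typeID = 6L))
  ch <- corefChain(lastId(st2))
  expect_identical(selectElementType(ch, st2), "refsem.AnatomicalSite")
  ## unmapped codes fall back to the generic element kinds
  st2 <- addAnnotation(st2, "textsem.EntityMention", 0, 4,
                       list(typeID = 0L))
  expect_identical(selectElementType(corefChain(lastId(st2)), st2),
                   "refsem.Entity")
  st2 <- addAnnotation(st2, "textsem.EventMention", 0, 4,
                       list(typeID = 0L))
  expect_identical(selectElementType(corefChain(lastId(st2)), st2),
                   "refsem.Event")
  ## mixed entity/event chains are an error
  mixed <- corefChain(c(lastId(st2) - 1L, lastId(st2)))
  expect_error(selectElementType(mixed, st2), "mixes")
})

test_that("concept disambiguation minimizes rank-sum with lexicographic ties", {
  mk <- function() documentStore("aa bb")
  addC <- function(store, code) {
    addAnnotation(store, "refsem.OntologyConcept",
                  features = list(code = code, codingScheme = "UMLS"))
  }
  ## unanimous: both mentions list the same concept first
  store <- mk()
  store <- addC(store, "C1"); c1 <- lastId(store)
  store <- addAnnotation(store, "textsem.EventMention", 0, 2,
                         list(typeID = 3L,
                              ontologyConceptArr = clinRef(c1)))
  store <- addC(store, "C1"); c1b <- lastId(store)
  store <- addAnnotation(store, "textsem.EventMention", 3, 5,
                         list(typeID = 3L,
                              ontologyConceptArr = clinRef(c1b)))
  chains <- buildCorefChains(store)
  chosen <- disambiguateConcept(corefChain(instance_ids(
    getByType(store, "textsem.EventMention"))), store)
  expect_identical(instanceById(store, chosen)@features$code, "C1")
  ## reversed rankings tie on rank-sum; smaller code wins
  store <- mk()
  store <- addC(store, "C0000001"); a1 <- lastId(store)
  store <- addC(store, "C0000002"); a2 <- lastId(store)
  store <- addAnnotation(store, "textsem.EventMention", 0, 2,
                         list(typeID = 3L,
                              ontologyConceptArr = clinRef(c(a1, a2))))
  store <- addC(store, "C0000002"); b2 <- lastId(store)
  store <- addC(store, "C0000001"); b1 <- lastId(store)
  store <- addAnnotation(store, "textsem.EventMention", 3, 5,
                         list(typeID = 3L,
                              ontologyConceptArr = clinRef(c(b2, b1))))
  chosen <- disambiguateConcept(corefChain(instance_ids(
    getByType(store, "textsem.EventMention"))), store)
  expect_identical(instanceById(store, chosen)@features$code, "C0000001")
  ## a lone UMLS hypothesis passes through with its identifiers
  store <- mk()
  store <- addAnnotation(store, "refsem.UMLSConcept",
                         features = list(code = "C0030193",
                                         codingScheme = "UMLS",
                                         cui = "C0030193", tui = "T184"))
  pc <- lastId(store)
  store <- addAnnotation(store, "textsem.EventMention", 0, 2,
                         list(typeID = 3L,
                              ontologyConceptArr = clinRef(pc)))
  chosen <- disambiguateConcept(corefChain(lastId(store)), store)
  concept <- instanceById(store, chosen)
  expect_identical(concept@features$cui, "C0030193")
  expect_identical(concept@features$tui, "T184")
  ## all-empty arrays leave the concept unset
  store <- mk()
  store <- addAnnotation(store, "textsem.EventMention", 0, 2,
                         list(typeID = 3L))
  expect_identical(disambiguateConcept(corefChain(lastId(store)), store),
                   NA_integer_)
})

test_that("context-flag merging passes unanimity through and applies the policy", {
  mk_pol <- function(p1, p2) {
    store <- documentStore("aa bb")
    store <- addAnnotation(store, "textsem.EventMention", 0, 2,
                           list(typeID = 3L, polarity = p1))
    store <- addAnnotation(store, "textsem.EventMention", 3, 5,
                           list(typeID = 3L, polarity = p2))
    list(store = store,
         chain = corefChain(instance_ids(
           getByType(store, "textsem.EventMention"))))
  }
  u <- mk_pol(1L, 1L)
  flags <- mergeContextFlags(u$chain, u$store)
  expect_identical(flags$polarity, 1L)
  expect_identical(flags$subject, "patient")
  ## conservation: any unanimous flag is the common value
  expect_identical(mergeContextFlags(mk_pol(-1L, -1L)$chain,
                                     mk_pol(-1L, -1L)$store)$polarity, -1L)
  c <- mk_pol(1L, -1L)
  expect_identical(mergeContextFlags(c$chain, c$store)$polarity, -1L)
  expect_error(
    mergeContextFlags(c$chain, c$store, bridgeConfig("error")),
    "'polarity'")
})

test_that("relative dates ground against the document date with month clamping", {
  expect_identical(normalizeRelativeDate("2 days ago", "2006-09-03"),
                   list(day = 1L, month = 9L, year = 2006L))
  expect_identical(normalizeRelativeDate("today", "2010-06-15"),
                   list(day = 15L, month = 6L, year = 2010L))
  expect_identical(normalizeRelativeDate("yesterday", "2010-01-01"),
                   list(day = 31L, month = 12L, year = 2009L))
  expect_identical(normalizeRelativeDate("14 days ago", "2006-09-03"),
                   list(day = 20L, month = 8L, year = 2006L))
  ## month-length clamping, including leap years
  expect_identical(normalizeRelativeDate("1 month ago", "2006-03-31"),
                   list(day = 28L, month = 2L, year = 2006L))
  expect_identical(normalizeRelativeDate("1 month ago", "2008-03-31"),
                   list(day = 29L, month = 2L, year = 2008L))
  expect_identical(normalizeRelativeDate("1 year ago", "2016-02-29"),
                   list(day = 28L, month = 2L, year = 2015L))
  ## outside the grammar: unnormalized, not an error
  expect_null(normalizeRelativeDate("next Tuesday", "2006-09-03"))
  expect_null(normalizeRelativeDate("2 fortnights ago", "2006-09-03"))
  expect_error(normalizeRelativeDate("today", "not-a-date"), "valid date")
})

test_that("relative-date normalization equals the lubridate oracle", {
  skip_if_not_installed("lubridate")
  set.seed(7)
  for (k in 1:300) {
    n <- sample(0:60, 1)
    unit <- sample(c("day", "week", "month", "year"), 1)
    D <- as.Date("1990-01-01") + sample(0:15000, 1)
    phrase <- sprintf("%d %ss ago", n, unit)
    expect_identical(normalizeRelativeDate(phrase, D),
                     lubridate_oracle(n, unit, D),
                     info = sprintf("%s from %s", phrase, D))
  }
})

test_that("day-unit normalization is translation equivariant", {
  set.seed(11)
  for (k in 1:50) {
    n <- sample(0:40, 1)
    D <- as.Date("2000-01-01") + sample(0:8000, 1)
    shift <- sample(1:300, 1)
    a <- normalizeRelativeDate(sprintf("%d days ago", n), D + shift)
    b <- normalizeRelativeDate(sprintf("%d days ago", n), D)
    expect_identical(
      as.Date(sprintf("%04d-%02d-%02d", a$year, a$month, a$day)),
      as.Date(sprintf("%04d-%02d-%02d", b$year, b$month, b$day)) + shift)
  }
})

test_that("modifiers attach only to declared attribute slots", {
  store <- documentStore("severe cough")
  store <- addAnnotation(store, "refsem.Severity",
                         features = list(value = "severe"))
  sev <- lastId(store)
  store <- addAnnotation(store, "textsem.Modifier", 0, 6,
                         list(normalized = clinRef(sev)))
  mod <- lastId(store)
  store <- addAnnotation(store, "refsem.SignSymptom")
  el <- lastId(store)
  store <- attachModifier(store, mod, el)
  got <- instanceById(store, el)@features$severity
  expect_identical(unclass(got), sev)
  ## the default "unmarked" severity attaches just as well
  store <- addAnnotation(store, "refsem.Severity")
  unm <- lastId(store)
  store <- addAnnotation(store, "textsem.Modifier", 7, 12,
                         list(normalized = clinRef(unm)))
  store <- attachModifier(store, lastId(store), el)
  expect_identical(unclass(instanceById(store, el)@features$severity), unm)
  ## a medication strength has no slot on a procedure
  store <- addAnnotation(store, "refsem.MedicationStrength",
                         features = list(number = "10", unit = "mg"))
  ms <- lastId(store)
  store <- addAnnotation(store, "textsem.Modifier", 7, 12,
                         list(normalized = clinRef(ms)))
  badmod <- lastId(store)
  store <- addAnnotation(store, "refsem.Procedure")
  proc <- lastId(store)
  expect_error(attachModifier(store, badmod, proc), "not declared")
})

test_that("text relations lift to element relations preserving polarity and uncertainty", {
  mk <- function(category, polarity = 1L, uncertainty = 0L) {
    store <- documentStore("cancer spread lymph nodes")
    store <- addAnnotation(store, "textsem.EventMention", 0, 6,
                           list(typeID = 2L))
    m1 <- lastId(store)
    store <- addAnnotation(store, "textsem.EntityMention", 14, 25,
                           list(typeID = 6L))
    m2 <- lastId(store)
    store <- addAnnotation(store, "refsem.DiseaseDisorder")
    e1 <- lastId(store)
    store <- addAnnotation(store, "refsem.AnatomicalSite")
    e2 <- lastId(store)
    store <- addAnnotation(store, "relation.RelationArgument",
                           features = list(argument = clinRef(m1)))
    a1 <- lastId(store)
    store <- addAnnotation(store, "relation.RelationArgument",
                           features = list(argument = clinRef(m2)))
    a2 <- lastId(store)
    store <- addAnnotation(store, "relation.BinaryTextRelation",
                           features = list(arg1 = clinRef(a1),
                                           arg2 = clinRef(a2),
                                           category = category,
                                           polarity = polarity,
                                           uncertainty = uncertainty))
    list(store = store, rel = lastId(store),
         map = stats::setNames(c(e1, e2), c(m1, m2)))
  }
  x <- mk("locationOf", polarity = -1L)
  store <- liftRelation(x$store, x$rel, x$map)
  lifted <- instanceById(store, lastId(store))
  expect_identical(lifted@typeName, "relation.LocationOf")
  expect_identical(lifted@features$polarity, -1L)
  expect_identical(lifted@features$uncertainty, 0L)
  x <- mk("treats", uncertainty = 1L)
  store <- liftRelation(x$store, x$rel, x$map)
  lifted <- instanceById(store, lastId(store))
  expect_identical(lifted@typeName, "relation.ElementRelation")
  expect_identical(lifted@features$category, "treats")
  expect_identical(lifted@features$uncertainty, 1L)
  ## unmapped arguments are an error
  x <- mk("affects")
  expect_error(liftRelation(x$store, x$rel, x$map[1]), "maps to no element")
})

test_that("the worked example resolves to the deep referential layer", {
  store <- resolveDocument(workedExampleStore())
  expect_no_violations(store)
  elements <- getByType(store, "refsem.SignSymptom", FALSE)
  expect_length(elements, 3)
  cough <- elements[[1]]
  expect_length(cough@features$mention, 2)
  sev <- instanceById(store, unclass(cough@features$severity)[1])
  expect_identical(sev@features$value, "severe")
  tm <- instanceById(store, unclass(cough@features$startTime)[1])
  expect_identical(tm@features$normalizedForm, "2006-09-01")
  concept <- instanceById(store,
                          unclass(cough@features$ontologyConcept)[1])
  expect_identical(concept@features$code, "C0010200")
  ## mention back-pointers are bidirectional
  for (m in unclass(cough@features$mention))
    expect_identical(unclass(instanceById(store, m)@features$event),
                     cough@id)
  ## the negated manifestation is lifted, the degree/temporal ones consumed
  mrel <- getByType(store, "relation.ManifestationOf", FALSE)
  expect_length(mrel, 1)
  expect_identical(mrel[[1]]@features$polarity, -1L)
  expect_length(getByType(store, "relation.ElementRelation", TRUE), 1)
})

test_that("resolution is idempotent and vacuous on empty stores", {
  store <- resolveDocument(workedExampleStore())
  again <- resolveDocument(store)
  expect_identical(serializeStore(again), serializeStore(store))
  empty <- documentStore("no annotations here")
  expect_identical(serializeStore(resolveDocument(empty)),
                   serializeStore(empty))
})

test_that("resolution partitions mentions across elements one chain each", {
  for (seed in c(3, 17, 23)) {
    store <- generateStore(fixtureSpec(seed = seed, corefRate = 0.6,
                                       relativeDateRate = 0.3))
    chains <- buildCorefChains(store)
    resolved <- resolveDocument(store)
    expect_no_violations(resolved)
    elements <- getByType(resolved, "refsem.SignSymptom", FALSE)
    expect_length(elements, length(chains))
    seen <- unlist(lapply(elements, function(el)
      unclass(el@features$mention)))
    mentions <- instance_ids(getByType(resolved, "textsem.EventMention"))
    expect_setequal(seen, mentions)
    expect_false(anyDuplicated(seen) > 0)
  }
})
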