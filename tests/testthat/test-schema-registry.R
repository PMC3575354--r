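test_that("types register under their supertypes and closed namespaces", {
  reg <- schemaRegistry()
  reg <- registerType(reg, typeDescriptor("refsem.Element", "TOP"))
  reg <- registerType(reg, typeDescriptor("refsem.Event", "refsem.Element"))
  reg <- registerType(reg, typeDescriptor("refsem.SignSymptom",
                                          "refsem.Event"))
  expect_identical(lookupType(reg, "refsem.SignSymptom")@supertype,
                   "refsem.Event")
  ## the namespace set is closed
  expect_error(registerType(reg, typeDescriptor("local.Foo", "TOP")),
               "namespace")
  ## unknown supertype
  expect_error(registerType(reg, typeDescriptor("refsem.Lab",
                                                "refsem.Missing",
                                                spanned = FALSE)),
               "unknown supertype")
  ## duplicates are refused, also on the shipped inventory
  expect_error(registerType(reg, typeDescriptor("refsem.Event",
                                                "refsem.Element")),
               "duplicate")
  expect_error(
    registerType(defaultRegistry(),
                 typeDescriptor("textspan.Sentence", "SPAN_ROOT")),
    "duplicate type name 'textspan.Sentence'")
})

test_that("subsumption is the supertype-chain partial order", {
  reg <- defaultRegistry()
  expect_true(subsumes(reg, "textsem.IdentifiedAnnotation",
                       "textsem.EventMention"))
  ## Entity and Event are siblings under Element
  expect_false(subsumes(reg, "refsem.Entity", "refsem.Event"))
  expect_false(subsumes(reg, "refsem.Event", "refsem.Entity"))
  ## reflexive on every registered type
  for (tn in sample(names(reg@types), 10))
    expect_true(subsumes(reg, tn, tn))
  expect_error(subsumes(reg, "refsem.Nope", "refsem.Event"),
               "unknown type")
})

test_that("subsumption agrees with a brute-force chain walk on random registries", {
  for (seed in 1:5) {
    rr <- random_registry(seed, n = 25)
    reg <- rr$registry
    for (k in 1:80) {
      pair <- sample(rr$types, 2, replace = TRUE)
      expect_identical(subsumes(reg, pair[1], pair[2]),
                       oracle_subsumes(rr$supertypes, pair[1], pair[2]),
                       info = sprintf("seed %d: %s vs %s", seed, pair[1],
                                      pair[2]))
    }
    ## transitivity + antisymmetry spot check via the oracle structure
    for (tn in rr$types) {
      anc <- rr$supertypes[[tn]]
      if (!anc %in% c("SPAN_ROOT", "TOP")) {
        expect_true(subsumes(reg, anc, tn))
        expect_false(subsumes(reg, tn, anc) && anc != tn)
      }
    }
  }
})

test_that("instance validation reports value-set, span, and range violations", {
  reg <- defaultRegistry()
  ok <- annotationInstance("refsem.Severity",
                           features = list(value = "severe"))
  expect_identical(validateInstance(reg, ok), character(0))
  bad <- annotationInstance("refsem.Course",
                            features = list(value = "oscillating"))
  v <- validateInstance(reg, bad)
  expect_length(v, 1)
  expect_match(v, "oscillating")
  ## referential types never carry offsets
  spanned_refsem <- annotationInstance("refsem.SignSymptom", 0, 5)
  v <- validateInstance(reg, spanned_refsem)
  expect_length(v, 1)
  expect_match(v, "unspanned")
  ## undeclared features and range mismatches are reported, not raised
  odd <- annotationInstance("textsem.EventMention", 0, 5,
                            features = list(bogus = 1L, polarity = "yes"))
  v <- validateInstance(reg, odd)
  expect_length(v, 2)
  ## concept identifier patterns
  badcui <- annotationInstance("refsem.UMLSConcept",
                               features = list(cui = "X123", tui = "T184"))
  expect_match(validateInstance(reg, badcui), "cui")
  ## calendar-impossible dates
  badday <- annotationInstance("refsem.Date",
                               features = list(day = 31L, month = 2L,
                                               year = 2001L))
  expect_match(validateInstance(reg, badday), "calendar")
})

test_that("schema statistics are additive and namespace-complete", {
  reg <- defaultRegistry()
  st <- schemaStats(reg)
  expect_setequal(st$namespace, clinNamespaces())
  ns <- vapply(reg@types, function(td) td@namespace, character(1))
  expect_identical(sum(st$types), length(reg@types))
  expect_identical(sum(st$features),
                   sum(vapply(reg@types, function(td)
                     length(td@features), integer(1))))
  expect_true(all(ns %in% clinNamespaces()))
})

test_that("schema files round-trip through dump and load", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  reg <- defaultRegistry()
  dumpSchema(reg, tmp)
  ## the shipped file is already in canonical form
  expect_identical(readLines(tmp), readLines(schemaPath()))
  reg2 <- loadSchema(tmp)
  expect_identical(reg2@typeOrder, reg@typeOrder)
  tmp2 <- withr::local_tempfile(fileext = ".jsonl")
  dumpSchema(reg2, tmp2)
  expect_identical(readLines(tmp2), readLines(tmp))
})

test_that("cyclic or unresolvable schema files are rejected", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"name":"util.A","namespace":"util","supertype":"util.B","spanned":false,"features":[]}',
    '{"name":"util.B","namespace":"util","supertype":"util.A","spanned":false,"features":[]}'
  ), tmp)
  expect_error(loadSchema(tmp), "unknown supertype")
  writeLines('{"name":"util.A","namespace":"util"', tmp)
  expect_error(loadSchema(tmp), "line 1")
  writeLines(
    '{"name":"util.A","namespace":"util","supertype":"TOP","spanned":false,"features":[{"name":"x","range":"ref:util.Missing"}]}',
    tmp)
  expect_error(loadSchema(tmp), "unregistered type")
})
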