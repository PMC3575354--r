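test_that("the shipped cough assertion model parses with its printed entries", {
  m <- parseCetypeXml(cemModelPath("CoughAssert"))
  expect_identical(m@kind, "statement")
  expect_identical(m@name, "CoughAssert")
  expect_identical(m@keyCode, "Assertion_KEY_ECID")
  expect_identical(m@dataDomain, "CoughType_VALUESET_ECID")
  expect_identical(m@dataType, "cwe")
  expect_identical(m@quals$name, c("periodicity", "course", "severity"))
  expect_identical(m@quals$card, c("0-M", "0-1", "0-1"))
  expect_identical(m@mods$name, c("subject", "negationInd", "uncertainty"))
  expect_identical(m@atts$name,
                   c("observed", "reportedReceived", "verified"))
})

test_that("malformed cetype documents are rejected", {
  expect_error(parseCetypeXml(
    '<cetype kind="statement" name="X" xmlns=""><key code="K" /><qual card="0-Z" name="q" type="T" /></cetype>'),
    "cardinality")
  expect_error(parseCetypeXml(
    '<cetype kind="statement" name="X" xmlns=""><key code="K" /><slot name="q" /></cetype>'),
    "unknown element")
  expect_error(parseCetypeXml(
    '<cetype kind="statement" name="X" xmlns=""><data domain="D" type="cwe" /></cetype>'),
    "lacks a <key>")
  expect_error(parseCetypeXml("<other/>"), "expected a <cetype>")
})

test_that("write then parse is the identity on models, shipped and random", {
  model_equal <- function(a, b) {
    expect_identical(a@kind, b@kind)
    expect_identical(a@name, b@name)
    expect_identical(a@keyCode, b@keyCode)
    expect_identical(a@dataDomain, b@dataDomain)
    expect_identical(a@dataType, b@dataType)
    expect_identical(a@quals, b@quals)
    expect_identical(a@mods, b@mods)
    expect_identical(a@atts, b@atts)
  }
  for (nm in c("CoughAssert", "SignSymptomAssert", "MedicationAssert",
               "LabAssert")) {
    m <- parseCetypeXml(cemModelPath(nm))
    out <- writeCetypeXml(m)
    model_equal(parseCetypeXml(out), m)
    ## the shipped files are in canonical writer form (bit-stable)
    expect_identical(out, paste0(paste(readLines(cemModelPath(nm)),
                                       collapse = "\n"), "\n"))
  }
  ## empty model: no qual/mod/att children at all
  empty <- parseCetypeXml(
    '<cetype kind="statement" name="Empty" xmlns=""><key code="K" /></cetype>')
  expect_identical(nrow(empty@quals) + nrow(empty@mods) + nrow(empty@atts),
                   0L)
  model_equal(parseCetypeXml(writeCetypeXml(empty)), empty)
  ## random models
  set.seed(5)
  rand_slots <- function(k) {
    if (k == 0) return(data.frame(name = character(), type = character(),
                                  card = character(),
                                  stringsAsFactors = FALSE))
    data.frame(
      name = paste0("n", sample.int(1000, k)),
      type = paste0("Ty", sample.int(1000, k)),
      card = sample(c("0-1", "0-M", "1-1", "2-5"), k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  for (i in 1:25) {
    m <- new("CetypeModel", kind = sample(c("statement", "component"), 1),
             name = paste0("M", i), keyCode = paste0("K", i, "_ECID"),
             dataDomain = paste0("D", i), dataType = sample(c("cwe", "pq"), 1),
             quals = rand_slots(sample(0:4, 1)),
             mods = rand_slots(sample(0:3, 1)),
             atts = rand_slots(sample(0:3, 1)))
    model_equal(parseCetypeXml(writeCetypeXml(m)), m)
  }
})

test_that("duplicate entry names make a model unwritable", {
  df <- data.frame(name = c("severity", "severity"),
                   type = c("Severity", "Severity"),
                   card = c("0-1", "0-1"), stringsAsFactors = FALSE)
  expect_error(
    writeCetypeXml(new("CetypeModel", kind = "statement", name = "Dup",
                       keyCode = "K", dataDomain = "D", dataType = "cwe",
                       quals = df, mods = .empty_df <- df[0, ],
                       atts = df[0, ])),
    "duplicate")
})

test_that("resolved elements export to CEM instances with the modifier semantics", {
  resolved <- resolveDocument(workedExampleStore())
  cough <- getByType(resolved, "refsem.SignSymptom", FALSE)[[1]]
  model <- parseCetypeXml(cemModelPath("CoughAssert"))
  inst <- elementToCem(resolved, cough@id, model)
  expect_identical(inst@dataValue, "C0010200")
  expect_identical(inst@quals$severity, "severe")
  expect_null(inst@mods$negationInd)
  expect_identical(inst@mods$subject, "patient")
  ## the negated expectoration element sets negationInd
  neg <- getByType(resolved, "refsem.SignSymptom", FALSE)[[3]]
  inst2 <- elementToCem(resolved, neg@id)  # shipped SignSymptomAssert model
  expect_identical(inst2@mods$negationInd, "true")
  ## instance XML renders in model order
  xml <- cemInstanceXml(inst, model)
  expect_match(xml, '<qual name="severity" value="severe" />')
  expect_match(xml, '<data value="C0010200" />')
})

test_that("cardinality and model/type mismatches are refused", {
  model <- parseCetypeXml(cemModelPath("CoughAssert"))
  two_sev <- cemInstance("CoughAssert", model@keyCode, "C0010200",
                         quals = list(severity = c("severe", "slight")))
  v <- checkCemCardinality(two_sev, model)
  expect_match(v, "severity.*0-1")
  expect_error(cemInstanceXml(two_sev, model), "cardinality")
  ## 0-M admits any multiplicity
  many <- cemInstance("CoughAssert", model@keyCode, "C0010200",
                      quals = list(periodicity = c("daily", "nocturnal")))
  expect_identical(checkCemCardinality(many, model), character(0))
  ## undeclared entries are reported
  odd <- cemInstance("CoughAssert", model@keyCode, "C0010200",
                     quals = list(flavor = "odd"))
  expect_match(checkCemCardinality(odd, model), "not declared")
  ## a medication model cannot describe a sign/symptom element
  resolved <- resolveDocument(workedExampleStore())
  cough <- getByType(resolved, "refsem.SignSymptom", FALSE)[[1]]
  expect_error(
    elementToCem(resolved, cough@id,
                 parseCetypeXml(cemModelPath("MedicationAssert"))),
    "describes refsem.Medication")
  ## and only core CEM elements export at all
  st <- documentStore("x")
  st <- addAnnotation(st, "refsem.Entity")
  expect_error(elementToCem(st, lastId(st)), "not a core CEM")
})
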