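## Builds the shipped normative schema file inst/extdata/schema/
## clintypes-schema.jsonl from the inventory defined below, and verifies the
## per-namespace budgets (structured 4/24, util 3/3, textspan 5/5,
## syntax 26/33, textsem 17/33, refsem 31/96, relation 14/13; totals
## 100/207) before writing. Run from the package root:
##   Rscript data-raw/schema-inventory.R

pkgload::load_all(".", quiet = TRUE)

f <- function(name, range, reconstructed = FALSE)
  featureDescriptor(name, range, reconstructed = reconstructed)

reg <- schemaRegistry()
add <- function(qualifiedName, supertype, features = list(), spanned = NA,
                reconstructed = FALSE) {
  if (is.na(spanned) && !supertype %in% c("SPAN_ROOT", "TOP"))
    spanned <- reg@types[[supertype]]@spanned
  reg <<- registerType(reg, typeDescriptor(qualifiedName, supertype,
                                           features = features,
                                           spanned = spanned,
                                           reconstructed = reconstructed))
}

## ---- structured: 4 types / 24 features (inventory reconstructed; the
## normative description fixes only the namespace and its budget) ----
add("structured.Demographics", "TOP", list(
  f("birthDate", "string", TRUE), f("deathDate", "string", TRUE),
  f("gender", "string", TRUE), f("firstName", "string", TRUE),
  f("middleName", "string", TRUE), f("lastName", "string", TRUE),
  f("firstNameSoundex", "string", TRUE), f("lastNameSoundex", "string", TRUE)
), reconstructed = TRUE)
add("structured.DocumentID", "TOP", list(
  f("documentID", "string", TRUE)
), reconstructed = TRUE)
add("structured.SourceData", "TOP", list(
  f("noteTypeCode", "string", TRUE), f("noteSubTypeCode", "string", TRUE),
  f("authorSpecialty", "string", TRUE), f("documentStandard", "string", TRUE),
  f("sourceInstanceId", "string", TRUE),
  f("sourceRevisionNbr", "integer", TRUE),
  f("sourceRevisionDate", "string", TRUE),
  f("sourceOriginalDate", "string", TRUE),
  f("sourceInstitution", "string", TRUE),
  f("sourceEncounterId", "string", TRUE),
  f("sourceApplication", "string", TRUE)
), reconstructed = TRUE)
add("structured.Metadata", "TOP", list(
  f("patientIdentifier", "string", TRUE), f("patientID", "integer", TRUE),
  f("demographics", "ref:structured.Demographics", TRUE),
  f("sourceData", "ref:structured.SourceData", TRUE)
), reconstructed = TRUE)

## ---- util: 3 types / 3 features ----
add("util.Pair", "TOP", list(
  f("attribute", "string"), f("value", "string")
))
add("util.Pairs", "TOP", list(
  f("pairs", "refarray:util.Pair")
))
add("util.ProbabilityDistribution", "util.Pairs")

## ---- textspan: 5 types / 5 features ----
add("textspan.Segment", "SPAN_ROOT", list(f("id", "string")))
add("textspan.Paragraph", "SPAN_ROOT")
add("textspan.List", "SPAN_ROOT", list(f("listType", "string")))
add("textspan.ListEntry", "SPAN_ROOT", list(f("ordinal", "integer")),
    reconstructed = TRUE)
add("textspan.Sentence", "SPAN_ROOT", list(
  f("sentenceNumber", "integer"), f("segmentId", "string", TRUE)
))

## ---- relation: 14 types / 13 features (registered before syntax/textsem
## so the relation-housed syntax and SRL types can inherit from it) ----
add("relation.Relation", "TOP", list(
  f("category", "string"), f("polarity", "integer"),
  f("uncertainty", "integer"), f("conditional", "boolean", TRUE),
  f("confidence", "float", TRUE)
))
add("relation.RelationArgument", "TOP", list(
  f("argument", "ref:SPAN_ROOT")
))
add("relation.BinaryTextRelation", "relation.Relation", list(
  f("arg1", "ref:relation.RelationArgument"),
  f("arg2", "ref:relation.RelationArgument")
))
add("relation.UMLSRelation", "relation.BinaryTextRelation")
add("relation.CoreferenceRelation", "relation.BinaryTextRelation")
add("relation.CollectionRelation", "relation.Relation", list(
  f("members", "refarray:relation.RelationArgument")
))
add("relation.ElementRelation", "relation.Relation", list(
  f("arg1", "ref:refsem.Element"), f("arg2", "ref:refsem.Element")
))
add("relation.AttributeRelation", "relation.Relation", list(
  f("element", "ref:refsem.Element"), f("attribute", "ref:refsem.Attribute")
))
add("relation.TemporalRelation", "relation.ElementRelation")
add("relation.DegreeOf", "relation.ElementRelation")
add("relation.Affects", "relation.ElementRelation")
add("relation.LocationOf", "relation.ElementRelation")
add("relation.ResultOf", "relation.ElementRelation")
add("relation.ManifestationOf", "relation.ElementRelation")

## ---- syntax: 26 types / 33 features ----
add("syntax.BaseToken", "SPAN_ROOT", list(
  f("partOfSpeech", "string"), f("normalizedForm", "string"),
  f("tokenNumber", "integer"),
  f("lemmaEntries", "refarray:syntax.Lemma", TRUE)
))
add("syntax.WordToken", "syntax.BaseToken", list(
  f("capitalization", "integer", TRUE), f("numPosition", "integer", TRUE),
  f("suggestion", "string", TRUE), f("canonicalForm", "string", TRUE)
))
add("syntax.PunctuationToken", "syntax.BaseToken")
add("syntax.SymbolToken", "syntax.BaseToken")
add("syntax.NewlineToken", "syntax.BaseToken")
add("syntax.ContractionToken", "syntax.BaseToken")
add("syntax.NumToken", "syntax.BaseToken", list(
  f("numType", "integer", TRUE)
))
add("syntax.Lemma", "TOP", list(
  f("key", "string", TRUE), f("posTag", "string", TRUE)
), reconstructed = TRUE)
add("syntax.Chunk", "SPAN_ROOT", list(f("chunkType", "string")))
for (ct in c("ADJP", "ADVP", "CONJP", "INTJ", "LST", "NP", "PP", "PRT",
             "SBAR", "UCP", "VP", "O"))
  add(paste0("syntax.", ct), "syntax.Chunk", reconstructed = TRUE)
add("syntax.ConllDependencyNode", "SPAN_ROOT", list(
  f("id", "integer"), f("form", "string"), f("lemma", "string"),
  f("cpostag", "string"), f("postag", "string"), f("feats", "string"),
  f("head", "ref:syntax.ConllDependencyNode"), f("deprel", "string"),
  f("phead", "ref:syntax.ConllDependencyNode"), f("pdeprel", "string")
))
add("syntax.TreebankNode", "SPAN_ROOT", list(
  f("nodeType", "string"), f("nodeValue", "string"),
  f("children", "refarray:syntax.TreebankNode"),
  f("parent", "ref:syntax.TreebankNode"),
  f("leaf", "boolean", TRUE), f("headIndex", "integer", TRUE),
  f("index", "integer", TRUE), f("nodeTags", "stringarray", TRUE)
))
add("syntax.TerminalTreebankNode", "syntax.TreebankNode", list(
  f("tokenIndex", "integer", TRUE)
))
add("syntax.TopTreebankNode", "syntax.TreebankNode", list(
  f("treebankParse", "string", TRUE),
  f("terminals", "refarray:syntax.TerminalTreebankNode", TRUE)
))
## Housed in syntax but inheriting arg1/arg2/category from the relation
## family; like its relation ancestors it carries no span of its own.
add("syntax.StanfordDependency", "relation.BinaryTextRelation")

## ---- textsem: 17 types / 33 features ----
add("textsem.IdentifiedAnnotation", "SPAN_ROOT", list(
  f("ontologyConceptArr", "refarray:refsem.OntologyConcept"),
  f("polarity", "integer"), f("conditional", "boolean"),
  f("uncertainty", "integer"), f("subject", "string"),
  f("generic", "boolean"), f("typeID", "integer"),
  f("segmentID", "string"), f("sentenceID", "string"),
  f("discoveryTechnique", "integer"), f("confidence", "float"),
  f("historyOf", "integer", TRUE)
))
add("textsem.EntityMention", "textsem.IdentifiedAnnotation", list(
  f("entity", "ref:refsem.Entity")
))
add("textsem.EventMention", "textsem.IdentifiedAnnotation", list(
  f("event", "ref:refsem.Event")
))
add("textsem.Modifier", "textsem.IdentifiedAnnotation", list(
  f("normalized", "ref:refsem.Attribute"), f("category", "string", TRUE)
))
add("textsem.TimeMention", "textsem.IdentifiedAnnotation", list(
  f("time", "ref:refsem.Time"), f("date", "ref:refsem.Date", TRUE)
))
add("textsem.ContextAnnotation", "SPAN_ROOT", list(
  f("Scope", "string"), f("FocusText", "string")
))
for (qt in c("Date", "Fraction", "Measurement", "PersonTitle", "Range",
             "RomanNumeral", "Time"))
  add(paste0("textsem.", qt), "SPAN_ROOT",
      list(f("value", "string", TRUE)))
add("textsem.Markable", "SPAN_ROOT", reconstructed = TRUE)
add("textsem.Predicate", "SPAN_ROOT", list(
  f("relations", "refarray:textsem.SemanticRoleRelation"),
  f("frameSet", "string", TRUE)
))
add("textsem.SemanticArgument", "SPAN_ROOT", list(
  f("label", "string"),
  f("relation", "ref:textsem.SemanticRoleRelation", TRUE)
))
add("textsem.SemanticRoleRelation", "relation.Relation", list(
  f("predicate", "ref:textsem.Predicate"),
  f("argument", "ref:textsem.SemanticArgument")
))

## ---- refsem: 31 types / 96 features ----
add("refsem.OntologyConcept", "TOP", list(
  f("code", "string"), f("codingScheme", "string"), f("score", "float"),
  f("disambiguated", "boolean", TRUE)
))
add("refsem.UMLSConcept", "refsem.OntologyConcept", list(
  f("cui", "string"), f("tui", "string"),
  f("preferredText", "string", TRUE)
))
add("refsem.Element", "TOP", list(
  f("polarity", "integer"), f("conditional", "boolean"),
  f("uncertainty", "integer"), f("generic", "boolean"),
  f("subject", "string"),
  f("ontologyConcept", "ref:refsem.OntologyConcept"),
  f("mention", "refarray:textsem.IdentifiedAnnotation")
))
add("refsem.Entity", "refsem.Element")
add("refsem.Event", "refsem.Element", list(
  f("properties", "ref:refsem.EventProperties")
))
add("refsem.EventProperties", "TOP", list(
  f("contextualModality", "string", TRUE),
  f("contextualAspect", "string", TRUE), f("permanence", "string", TRUE),
  f("docTimeRel", "string", TRUE), f("category", "string", TRUE),
  f("aspect", "string", TRUE), f("degree", "string", TRUE)
))
add("refsem.Time", "refsem.Element", list(f("normalizedForm", "string")))
add("refsem.Date", "refsem.Element", list(
  f("day", "integer"), f("month", "integer"), f("year", "integer")
))
add("refsem.Attribute", "TOP", list(f("value", "string")))
add("refsem.BodyLaterality", "refsem.Attribute")
add("refsem.BodySide", "refsem.Attribute")
add("refsem.Course", "refsem.Attribute")
add("refsem.Severity", "refsem.Attribute")
for (ma in c("MedicationStrength", "MedicationDosage", "MedicationDuration",
             "MedicationFrequency"))
  add(paste0("refsem.", ma), "refsem.Attribute", list(
    f("number", "string", TRUE), f("unit", "string", TRUE)
  ))
for (ma in c("MedicationForm", "MedicationRoute", "MedicationStatusChange"))
  add(paste0("refsem.", ma), "refsem.Attribute", list(
    f("code", "string", TRUE), f("codingScheme", "string", TRUE)
  ))
add("refsem.ProcedureDevice", "refsem.Attribute", list(
  f("code", "string", TRUE), f("codingScheme", "string", TRUE)
))
add("refsem.ProcedureMethod", "refsem.Attribute", list(
  f("code", "string", TRUE), f("codingScheme", "string", TRUE)
))
add("refsem.LabValue", "refsem.Attribute", list(
  f("number", "string", TRUE), f("unit", "string", TRUE)
))
add("refsem.LabDeltaFlag", "refsem.Attribute", list(
  f("code", "string", TRUE), f("codingScheme", "string", TRUE)
))
add("refsem.LabReferenceRange", "refsem.Attribute", list(
  f("low", "string", TRUE), f("high", "string", TRUE)
))
add("refsem.AnatomicalSite", "refsem.Entity", list(
  f("bodyLaterality", "ref:refsem.BodyLaterality"),
  f("bodySide", "ref:refsem.BodySide")
))
add("refsem.DiseaseDisorder", "refsem.Event", list(
  f("alleviatingFactor", "ref:refsem.Element", TRUE),
  f("exacerbatingFactor", "ref:refsem.Element", TRUE),
  f("associatedSignSymptom", "ref:refsem.SignSymptom", TRUE),
  f("bodyLocation", "ref:refsem.AnatomicalSite", TRUE),
  f("bodyLaterality", "ref:refsem.BodyLaterality"),
  f("bodySide", "ref:refsem.BodySide"),
  f("course", "ref:refsem.Course"), f("severity", "ref:refsem.Severity"),
  f("duration", "string", TRUE),
  f("startTime", "ref:refsem.Time"), f("endTime", "ref:refsem.Time"),
  f("relativeTemporalContext", "ref:relation.TemporalRelation", TRUE)
))
add("refsem.Lab", "refsem.Event", list(
  f("value", "ref:refsem.LabValue"),
  f("deltaFlag", "ref:refsem.LabDeltaFlag"),
  f("referenceRange", "ref:refsem.LabReferenceRange"),
  f("abnormalInterpretation", "string", TRUE),
  f("ordinalInterpretation", "string", TRUE),
  f("labDateTime", "ref:refsem.Time", TRUE)
))
add("refsem.Medication", "refsem.Event", list(
  f("strength", "ref:refsem.MedicationStrength"),
  f("dosage", "ref:refsem.MedicationDosage"),
  f("duration", "ref:refsem.MedicationDuration"),
  f("form", "ref:refsem.MedicationForm"),
  f("frequency", "ref:refsem.MedicationFrequency"),
  f("route", "ref:refsem.MedicationRoute"),
  f("statusChange", "ref:refsem.MedicationStatusChange"),
  f("startDate", "ref:refsem.Date", TRUE),
  f("endDate", "ref:refsem.Date", TRUE),
  f("allergenIndicator", "boolean", TRUE)
))
add("refsem.Procedure", "refsem.Event", list(
  f("device", "ref:refsem.ProcedureDevice"),
  f("method", "ref:refsem.ProcedureMethod"),
  f("startTime", "ref:refsem.Time"), f("endTime", "ref:refsem.Time"),
  f("duration", "string", TRUE),
  f("bodyLocation", "ref:refsem.AnatomicalSite", TRUE),
  f("bodyLaterality", "ref:refsem.BodyLaterality"),
  f("bodySide", "ref:refsem.BodySide")
))
add("refsem.SignSymptom", "refsem.Event", list(
  f("startTime", "ref:refsem.Time"), f("endTime", "ref:refsem.Time"),
  f("severity", "ref:refsem.Severity"), f("course", "ref:refsem.Course"),
  f("bodyLaterality", "ref:refsem.BodyLaterality"),
  f("bodySide", "ref:refsem.BodySide"),
  f("duration", "string", TRUE)
))

clintypes:::.check_reference_ranges(reg)

## budget check before writing
st <- schemaStats(reg)
budget <- data.frame(
  namespace = c("structured", "syntax", "refsem", "textsem", "textspan",
                "util", "relation"),
  types = c(4L, 26L, 31L, 17L, 5L, 3L, 14L),
  features = c(24L, 33L, 96L, 33L, 5L, 3L, 13L))
stopifnot(identical(st[order(st$namespace), ],
                    budget[order(budget$namespace), ]) ||
          all(merge(st, budget, by = "namespace")$types.x ==
              merge(st, budget, by = "namespace")$types.y &
              merge(st, budget, by = "namespace")$features.x ==
              merge(st, budget, by = "namespace")$features.y))
stopifnot(sum(st$types) == 100L, sum(st$features) == 207L)

dir.create("inst/extdata/schema", recursive = TRUE, showWarnings = FALSE)
dumpSchema(reg, "inst/extdata/schema/clintypes-schema.jsonl")
cat("wrote", sum(st$types), "types /", sum(st$features),
    "features to inst/extdata/schema/clintypes-schema.jsonl\n")
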