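# clintypes

A standalone R implementation of a **shared type system for clinical
natural language processing**: the inventory of annotation types
that clinical NLP components read and write, from tokens and parse trees up
to Clinical Element Model (CEM) based deep semantics.

## The problem

Clinical NLP pipelines mark up a note in layers — sentences, tokens,
parses, named-entity *mentions* — but most stop at textual semantics: spans
with ontology codes attached. Structured clinical data live at a deeper
level: one real-world *element* (a sign/symptom, a medication, a lab) per
clinical fact, with post-coordinated attributes such as severity, body
side, and start time. Interoperating with such data requires both an
agreed-on schema for every layer and a bridge from coreferring text
mentions to normalized document-level elements.

`clintypes` provides both, without any NLP framework dependency:

- **Schema registry** (`schemaRegistry()`, `registerType()`, `subsumes()`,
  `validateInstance()`, `schemaStats()`): a declarative, single-inheritance
  type inventory with subsumption, instance validation, and conformance
  statistics. The shipped normative schema defines **100 types carrying 207
  declared features across 7 namespaces** (structured, util, textspan,
  syntax, textsem, refsem, relation) — 2.07 features per type.
- **Annotation store** (`documentStore()`, `addAnnotation()`,
  `getByType()`, `selectCovered()`, `serializeStore()`): a per-document
  container with subsumption-aware indices, 0-based half-open character
  offsets, and a canonical JSON dialect whose round trip is byte-exact.
- **Domain model**: the full inventory, including the six core CEM element
  types (anatomical site, disease/disorder, lab, medication, procedure,
  sign/symptom), shared attribute value sets
  (`refsem.Severity` ∈ {severe, moderate, slight, unmarked}, ...), UMLS
  concept types with CUI/TUI pattern constraints, CONLL-X dependency nodes,
  Penn Treebank constituents, and PropBank semantic-role types.
- **Semantic bridge** (`resolveDocument()` and its parts
  `buildCorefChains()`, `selectElementType()`, `disambiguateConcept()`,
  `mergeContextFlags()`, `normalizeRelativeDate()`, `attachModifier()`,
  `liftRelation()`): turns coreference chains of mentions into one
  `refsem` element each, with a single disambiguated concept (minimum
  rank-sum over the mentions' hypothesis arrays), merged polarity /
  uncertainty / conditional / generic / subject flags, relative dates
  grounded against the document date, modifiers attached as element
  attributes, and text relations lifted to element relations.
- **CEM XML I/O** (`parseCetypeXml()`, `writeCetypeXml()`,
  `elementToCem()`): the `cetype` model dialect (key, value choice,
  qualifiers / modifiers / attributions with cardinalities) with a
  bit-stable writer, plus export of resolved elements as CEM instances.
- **Fixtures and CLI** (`workedExampleStore()`, `generateStore()`,
  `exec/clintypes` with `stats | validate | demo | resolve | convert |
  generate`).

## Worked example

The packaged fixture is the two-sentence chief complaint
*"Chief complaint: severe cough and fever. Cough started 2 days ago, no
expectoration."* with its shallow annotation layer: four event mentions,
a `severe` modifier, a `2 days ago` time mention, and coreference /
temporal / degree / manifestation text relations.

```r
library(clintypes)
store <- workedExampleStore()
resolved <- resolveDocument(store)
getByType(resolved, "refsem.SignSymptom", FALSE)
```

Or, from the shell, `clintypes demo`, which prints:

```
text: Chief complaint: severe cough and fever. Cough started 2 days ago, no expectoration.
refsem.SignSymptom#28 polarity=1 mentions=2 concept=C0010200
  severity = severe
  startTime = 09/01/2006
refsem.SignSymptom#29 polarity=1 mentions=1 concept=C0015967
refsem.SignSymptom#30 polarity=-1 mentions=1 concept=C0034642
relation.ManifestationOf#31 category=manifestationOf polarity=-1
```

Reading: the two cough mentions were resolved into a **single** cough
sign/symptom element with two mention back-pointers, severity `severe`
merged in from the modifier, and the start time grounded to 2006-09-01
(two days before the document date 2006-09-03; displayed month-first). The
negated manifestation relation between the cough and the expectoration
mention was lifted from the text level to a referential
`relation.ManifestationOf` with polarity −1: the cough is asserted *not*
to manifest with expectoration. `clintypes stats` prints the per-namespace
type/feature matrix (totals 100 / 207, 2.07 features per type).

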