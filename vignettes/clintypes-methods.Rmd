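---
title: "The clintypes annotation model and resolution bridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The clintypes annotation model and resolution bridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clintypes)
```

## The model

`clintypes` implements a layered annotation type system for clinical text.
The central modelling commitment is the separation of **textual semantics**
from **referential semantics**. A *mention* (`textsem.*`) is a span of text
that refers to something: it carries character offsets, an array of ranked
ontology-concept hypotheses, and context flags (polarity, uncertainty,
conditional, generic, subject). An *element* (`refsem.*`) is the unspanned,
document-level object one or more coreferring mentions denote: it carries a
single disambiguated concept, merged context flags, mention back-pointers,
and a clinical attribute template. A chain of mentions is not itself a
clinical fact — two sentences mentioning a cough describe one cough — so
the element layer, not the mention layer, is the unit that interoperates
with structured clinical data.

The element templates follow the Clinical Element Model pattern: a coded
key, a value choice, and attribute detail. Six core clinical element types
are modelled in full — anatomical site, disease/disorder, lab, medication,
procedure, sign/symptom — of which anatomical site is the one non-temporal
kind (an Entity); the rest are Events. Internally the CEM distinction
between qualifiers (do not change the meaning of the value), modifiers
(change it, e.g. `negationInd`), and attributions (context of an action) is
flattened into plain features; the shipped per-CEM `cetype` model files
restore the trichotomy on export.

### The inventory and its two roots

Types live in seven closed namespaces — `structured`, `util`, `textspan`,
`syntax`, `textsem`, `refsem`, `relation` — in a single-inheritance forest
with two roots: `SPAN_ROOT` for spanned annotations and `TOP` for unspanned
objects. An instance carries `begin`/`end` offsets exactly when its type
descends from `SPAN_ROOT`. Almost all `textspan`/`syntax`/`textsem` types
are spanned and all `refsem`/`relation`/`structured`/`util` types are
unspanned; the deliberate exceptions are the three relation-family types
housed in the linguistic namespaces (`syntax.StanfordDependency`,
`textsem.SemanticRoleRelation` — both binary relations whose *arguments*
wrap spans — and the lexicon-entry type `syntax.Lemma`). Spanned-ness is
therefore a derived property of the inheritance tree, and registration
refuses a descriptor that contradicts its supertype.

The shipped normative schema (`inst/extdata/schema/clintypes-schema.jsonl`,
line-oriented JSON chosen for diffability and bit-exact round trips)
contains 100 types and 207 declared features:

```{r}
schemaStats(defaultRegistry())
```

Feature counting convention: a feature counts once, at the type that
declares it, never again on subtypes — the only convention under which the
per-namespace budgets are additive. `syntax.StanfordDependency` inherits
`arg1`/`arg2`/`category` from the relation family but is housed in
`syntax`, so its (zero) own declarations land in the syntax budget.

Not every slot of the inventory is named in its normative description; the
description fixes the namespace budgets and names the load-bearing types
and features. Slots completed from the reference implementation's
conventions (e.g. the `structured` namespace contents, `syntax.Lemma`, the
twelve chunk subtypes, `textsem.Markable`, `WordToken`'s morphology
features) are flagged `"reconstructed": true` in the schema file rather
than silently invented, and `refsem.EventProperties`' concrete fields are
likewise flagged reconstructions.

### Validation

`validateInstance()` returns violations instead of raising: type
registered, span present iff spanned, features declared on the type or an
ancestor, values matching the declared ranges. Value sets are deliberately
enforced only where they are documented as closed — the four shared
attributes (`Severity`, `Course`, `BodySide`, `BodyLaterality`) — because
hard-coded value sets on the open attribute kinds hamper downstream tools;
the sets live in a constants file (`clinConstants()`), not in code. UMLS
identifiers are pattern-checked (`^C\d{7}$`, `^T\d{3}$`) but never checked
against a real UMLS release: concepts are created by reference to whatever
resource an application uses. Store-level validation additionally resolves
every id-reference and checks its target's type against the feature's
declared range, and checks `util.ProbabilityDistribution` values parse into
[0, 1].

## The resolution bridge

`resolveDocument()` performs the shallow-to-deep transformation in five
deterministic steps (time normalization, chaining, element creation,
attribute/temporal attachment, relation lifting). Design choices where the
behaviour was genuinely open:

- **Conflict policy.** Aggregating coreferring mentions can meet
  conflicting flags. The default is *last-mention-wins* (greatest `begin`;
  ties by id), on the view that clinical narrative tends to refine earlier
  statements; `bridgeConfig("error")` turns conflicts into hard errors
  naming the feature. Unanimity always passes through unchanged.
- **Concept disambiguation.** The element concept is the concept common to
  every nonempty hypothesis array with the lowest rank-sum; ties break
  lexicographically by code (deterministic and order-independent); with no
  common concept the first mention's top hypothesis wins; with no
  hypotheses at all the concept stays unset rather than guessed.
- **Element typing.** The mentions' integer `typeID` semantic-group code
  selects the core CEM type. The codes themselves are a documented
  constant table (0 unknown, 1 medication, 2 disease/disorder,
  3 sign/symptom, 4 lab, 5 procedure, 6 anatomical site); unmapped codes
  fall back to plain `refsem.Event`/`refsem.Entity`, and entity/event
  mixtures in one chain are an error, not a guess.
- **Relative-time grammar.** Only `"<N> (day|week|month|year)s? ago"`,
  `"yesterday"` and `"today"` are grounded; anything else is left
  unnormalized (the mention simply keeps no `time` link) rather than
  heuristically parsed. Month and year subtraction clamps the day of month
  to the target month's length, so one month before March 31 is
  February 28 (29 in leap years). Dates are stored as day/month/year
  integers plus an ISO `refsem.Time` timestamp; the US month-first
  rendering ("09/01/2006") is purely a display concern of the CLI.
- **Temporal attachment.** A binary text relation whose category is in the
  documented vocabulary (`startTime`, `TIMEX-of`) between a time mention
  and an event mention sets the element's `startTime` slot (or `startDate`
  for date-valued templates such as medications); it is consumed, not
  lifted. Degree relations against modifiers are likewise consumed by
  attribute attachment. Every remaining binary text relation whose two
  mentions resolved lifts to an element relation, with category-directed
  subtyping (degreeOf/affects/locationOf/resultOf/manifestationOf) and
  polarity/uncertainty copied exactly.
- **Idempotence.** A store already holding any `refsem.Element` descendant
  is returned unchanged, making `resolveDocument()` safe to re-run.

The bridge *consumes* coreference relations; it never computes them from
raw text. Coreference resolution, NER, parsing and temporal relation
extraction are upstream NLP tasks outside this package's scope — the
package defines the representations they write into.

## The synthetic document generator

`generateStore()` exists to exercise the representation and the bridge,
not to imitate clinical prose. It emulates: several sentences of
sign/symptom mentions drawn from a small concept vocabulary, per-mention
concept hypotheses, negation wording coupled to polarity (rate 0.15 by
default, a modest figure typical of problem-list narrative), coreference
between repeat mentions of the same concept (rate 0.3), and occasional
relative dates wired to a sentence's first mention (rate 0.2), under a
fixed document date. Defaults were chosen once as a plausible short note
(five sentences, two mentions each) and are not tuned. Generation is a
pure function of the spec and seed, and leaves the caller's RNG stream
untouched.

What it does **not** emulate — and hence what passing tests do not show
about real data: real lexical variation and misspellings, section
structure, entity mentions other than sign/symptoms, hypothesis arrays
longer than one, cross-sentence syntax, or incorrect upstream annotations.
The generator's documents are schema-perfect by construction; robustness
to malformed input is tested separately through corrupted JSON fixtures.

## Numerical and representational choices

- Offsets are 0-based, half-open, over Unicode code points. The worked
  example's offsets ("cough" [24,29), "Cough" [41,46), "2 days ago"
  [55,65), "expectoration" [70,83)) are fixed by character-counting the
  printed sentence.
- Polarity is encoded {−1, 1} and uncertainty {0, 1}, the reference
  implementation's convention; defaults are affirmed/certain/
  unconditional/non-generic/"patient", and value-set attributes default to
  `"unmarked"` where the set includes it.
- Serialization is canonical — metadata keys and feature names sorted,
  annotations in id order, references as `{"$ref": id}` — so store
  equality is byte equality of serializations, and double serialization is
  the identity. Ids are never reused and deletion is unsupported: stores
  are build-once.
- The cetype writer emits a fixed attribute order (`kind, name, xmlns`;
  `card, name, type`) and self-closing entries so that write∘parse is the
  identity and output is bit-stable; the shipped model files are in
  exactly this canonical form. The cough model contains exactly the
  printed entries; elided portions of the published snippet are omitted,
  not invented.
- The document date for the worked example is 2006-09-03 — the only date
  under which "2 days ago" grounds to the published 09/01/2006 — and it is
  recorded in the fixture's metadata, not hard-coded in logic.

## Test design and problem sizes

Property tests check the implementation against independent oracles:
subsumption against a raw supertype-chain walk on random registries
(25 types, hundreds of query pairs), store queries against brute-force
filters, coreference chaining against a boolean-matrix transitive closure
(graphs up to 50 mentions) and igraph components, and date grounding
against lubridate's rollback arithmetic (1,000 random phrase/date pairs).
Serialization identity runs over 200 generated stores of three sentences
each, and the element-per-chain partition property over dozens of seeds —
sizes chosen to exercise the combinatorics while keeping the whole suite
around forty seconds on one CPU.

## Known limitations

- The schema is single-inheritance by design; types needing two parents
  must pick one and reference the other.
- `refsem.Element.mention` ordering is whatever the bridge produced
  (document order per chain); no canonical global mention order is imposed
  across elements.
- The CEM export populates qualifiers only for same-named string-valued
  attribute slots and leaves attributions empty — observed/reported/
  verified context is not recoverable from the element layer.
- The instance-level CEM XML dialect (`<ceinst>`) is defined by this
  package; the published model dialect defines no instance serialization.
- Full HL7 v3 "ANY" value semantics are out of scope: data values are
  coded strings and numbers-with-units only.
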