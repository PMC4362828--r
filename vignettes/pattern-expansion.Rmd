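---
title: "Expanding ontology design patterns from spreadsheets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expanding ontology design patterns from spreadsheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoforge)
```

## The procedure

ontoforge turns an ontology design pattern plus a populated spreadsheet
into OWL axioms. A run takes three inputs:

1. **Axiom settings** — the reusable pattern: annotation templates,
   superclass and equivalent-class expression templates in Manchester OWL
   syntax, a label-to-URI map for every quoted term, the URI start portion,
   and either an ID-minting policy or a key column.
2. **A data table** — one term per row, read from TSV, CSV or XLSX (first
   worksheet). `{$columnA}` in a template refers to the first column of the
   *data* rows; the header row, when present, is names only.
3. **Optionally a target ontology** (RDF/XML or Turtle), consulted for two
   things only: entity URIs, so minted IDs cannot duplicate existing ones,
   and its `rdfs:label` index as a fallback for label resolution.

For each row the engine substitutes the row's cells into every template,
parses each substituted expression, and collects the result into one
generated class. All frames are first rendered as an intermediate
Manchester-syntax document — the human-readable form kept for debugging —
and then serialized as a standalone RDF/XML (or Turtle) ontology meant to
be imported into the target.

The two operation modes differ only in where the subject URI comes from:
`new_classes` mints one identifier per non-empty row, in row order;
`edit_existing` reads the subject from the key column (an absolute URI is
used verbatim, a bare local ID is resolved against the URI start portion)
and emits no class declarations at all.

## The settings dialect

The settings file is line-oriented UTF-8 with bracketed section headers,
`#` comments and one declaration per line; `serialize_settings()` emits the
canonical section order and `parse_settings(serialize_settings(s))` is the
identity on valid settings. The dialect is this package's own: it is
designed to be hand-editable and diff-friendly, and no byte compatibility
with any other tool's configuration format is claimed. Term-URI
declarations are written `'label' <URI>`, matching exactly how labels
appear inside patterns.

Annotation values are plain string literals by default; a per-pattern
`@lang` or `^^<datatype>` suffix is accepted because curation pipelines
occasionally need typed or language-tagged values, but the default stays
plain since pattern values are overwhelmingly bare strings.

## The expression grammar

Class expressions use the Manchester-syntax subset that covers common
OBO-style patterns:

```
expr        := and_expr ("or" and_expr)*          # or binds loosest
and_expr    := not_expr ("and" not_expr)*
not_expr    := "not" not_expr | restriction
restriction := primary [("some" | "only" | "value") primary]
primary     := atom | "(" expr ")"
atom        := 'quoted label' | <URI> | bare CURIE-like token
```

Keywords are lower-case reserved words; quoted labels escape an embedded
quote by doubling it. Cardinality restrictions, datatype ranges, property
chains and non-class frames are deliberately out of scope — they do not
appear in the quick-term-template patterns this tool exists for, and a
smaller contract is easier to verify. The renderer emits minimal
parentheses subject to one structural rule: a boolean operand of the same
connective is parenthesized (`('a' and 'b') and 'c'`), so that
parse(render(e)) reproduces the tree exactly rather than a flattened
equivalent.

Label resolution is strict and total: settings declarations are consulted
first, then the target ontology's label index, and an expression with any
unknown label fails with *all* unknown labels listed, not just the first.
When the target ontology maps one label to several URIs the
lexicographically smallest wins, with a warning — a deterministic tie-break
that is wrong often enough that the warning matters.

## ID minting

OBO-style local IDs are `prefix` + a zero-padded number of fixed width.
The allocator starts at the configured start number and always hands out
the smallest eligible number at or above its cursor, skipping anything
scanned from the target ontology. Two boundary decisions are worth making
explicit:

* **Gap-filling above `start`:** if the target holds `10000` and `10003`,
  allocation yields `10001, 10002, 10004, ...`. Numbers below `start` are
  never assigned, even if free — the start ID is treated as a floor the
  curator chose, not a hint.
* **Scan scope:** classes, object properties and annotation properties are
  all scanned, since any entity URI can collide with a minted one.

Numeric parts are held as doubles and the policy allows up to 18 digits;
values in the exactly-representable range (≤ 15 digits) cover every OBO
Foundry scheme in use, which are 7–9 digits wide.

## Empty cells and multi-valued cells

A pattern whose substitution touches an empty cell is dropped for that row
and recorded in the run report. The alternative — emitting the axiom with a
blank literal or a dangling term — corrupts ontologies silently, which is
worse than a visibly missing axiom. Rows that are entirely empty are
skipped; in edit mode a row with an empty key cell is skipped with a
warning.

Cells may hold several values separated by the settings' delimiter
(default `|`, escapable as `\|`): each value yields its own axiom. When one
pattern references two multi-valued cells the Cartesian product is emitted,
with a warning above 25 combinations — predictable semantics for a case
curators do occasionally produce, and the warning guards against the
accidental quadratic blow-up. The delimiter feature is an extension beyond
the minimal template convention and is flagged as such here.

## Output serialization

The output is a standalone ontology (default IRI: URI start portion +
`ontoforge-output.owl`) rather than an in-place edit of the target:
importing via `owl:imports` keeps the generated axioms reviewable and
revertible as a unit. RDF/XML is the default serialization because it is
what OWL editors universally accept; Turtle is available behind a flag.

Properties referenced by the axioms are declared with their role — a term
used in an expression restriction is an object property, one used in an
annotation pattern is an annotation property — because role ambiguity
genuinely breaks OWL round-tripping. Referenced external classes and
individuals, by contrast, are *not* declared: they are listed in a leading
comment and left to the importing ontology. Declaring them minimally would
blur the line between classes this run generated and classes it merely
mentioned, and the generated-class count of a document would no longer
mean anything; a missing class declaration is also harmless to every
mainstream reasoner, whereas a missing property declaration is not.

The intermediate Manchester document writes term references by their quoted
display label when one is known, else as `<URI>` — it is a debugging
artifact whose job is to be readable next to the settings file, and it uses
the same surface syntax the patterns are written in.

## What the fixtures emulate

The bundled fixtures generate every input the tests use; nothing is
downloaded.

* `make_clo_fixture()` reconstructs a cell-line repository pattern around
  the published fragments of that use case: the catalogue ID `RCB2320` in
  row 0 column A, the `'label' "{$columnA} cell"` annotation, the
  `'is in cell line repository' some 'RIKEN Cell Bank'` superclass, and a
  tissue/animal comment. Everything not printed as text — the other
  catalogue rows, all term URIs — is synthetic, and the URIs use a
  deliberately out-of-range numbering (`CLO_999xxxx`) so they cannot be
  mistaken for real terms.
* `make_biobank_fixture()` models the edit-existing use case: attaching
  definition-editor and definition-source annotations (columns C and D) to
  existing term URIs in the key column.
* `make_random_bundle()` draws operation mode, patterns, cell contents,
  multi-valued cells and blanked cells from a seeded RNG, and computes its
  expected output counts by direct enumeration over patterns × rows ×
  the empty-cell and multi-value rules — string operations that share no
  code with the engine, so the comparison is a genuine cross-check.

What passing these tests shows is that the mechanics — substitution,
parsing, minting, counting, serialization — are correct and deterministic.
What they cannot show is fidelity to any real catalogue: real spreadsheets
bring encoding accidents, inconsistent label spellings against the target
ontology, and URIs that resolve but are wrong, none of which a synthetic
bundle reproduces. The collision-avoidance tests likewise exercise target
ontologies of a few dozen entities, not the tens of thousands in a
production ontology, though nothing in the scan is size-sensitive.

## Test problem sizes and numerical choices

The property suites run at sizes chosen to exercise the combinatorics while
keeping the full check fast on one CPU: 500 randomized settings round
trips, 1,000 random expression trees to depth 5, exhaustive parser/oracle
agreement over all ~11,000 token sequences of length ≤ 4, 100 randomized
allocator configurations plus 10 scanned-target cases, and 50 randomized
bundles compared count-for-count against their enumerated expectations.
All randomness is seeded; `scripts/acceptance.R` takes `--seed` and derives
every internal seed from it.

There is no floating-point estimation anywhere in the package; the only
"numerical" choices are the integer-exactness bound on ID widths noted
above and the strict string equality used for label lookup (no trimming,
no case folding — a label either matches its declaration or it does not).

## Known limitations

* No reasoning or classification; the output is syntactic.
* No instance-level (individual) axiom generation — class frames only.
* The RDF readers are restricted: they extract entities and labels, not
  arbitrary RDF. Exotic RDF/XML abbreviations or Turtle constructs beyond
  the forms OWL serializers emit may be invisible to the snapshot (the
  affected ID would then not be avoided; supplying the target in the
  standard serialization of its release pipeline avoids this).
* One operation per run: tasks that need both new classes and edits are
  chained as separate invocations, which keeps each output attributable to
  one settings file.
* Spreadsheet formulas are not evaluated; XLSX cells contribute their
  stored values.
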