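# ontoforge

Batch generation of OWL ontology classes from design patterns and
spreadsheets.

## The problem

Biomedical ontologies grow in bursts of structurally identical terms: a
thousand cell lines from one repository, hundreds of licensed vaccines, a
batch of assay terms requested by a consortium. Each new class follows the
same ontology design pattern — the same annotation properties, the same
superclass and equivalent-class axioms — and differs from its siblings only
in a handful of strings. Writing those classes by hand in an ontology
editor is slow and error-prone, and it puts an OWL-savvy developer between
the domain experts (who know the content) and the ontology (which needs
it).

ontoforge separates the two roles. An ontology developer writes the pattern
once, as an **axiom settings file**: class expressions in Manchester OWL
syntax and annotation templates, with spreadsheet-column variables —
`{$columnA}` is the first column, `{$columnB}` the second, and so on. A
domain expert fills a spreadsheet, one term per row. ontoforge then either

* **mints new classes** — one per row, with unique zero-padded OBO-style
  identifiers (`prefix` + fixed-width number, e.g. `CLO_0010000`) that are
  guaranteed not to collide with any entity of an optionally supplied
  target ontology; or
* **edits existing classes** — attaching new axioms (typically missing
  annotations such as definition source and term editor) to the term URIs
  listed in a key column, minting nothing.

The axioms of each row are assembled into an intermediate Manchester-syntax
document (kept for debugging) and serialized as a standalone RDF/XML or
Turtle ontology, ready to be pulled into the target ontology with
`owl:imports` or a merge.

The supported class-expression subset is the one OBO-style patterns use:
named terms (quoted labels or `<URI>`s), `some`, `only`, `value`, `and`,
`or`, `not` and parentheses. Every quoted label must be declared in the
settings file (`'label' <URI>`), because a program cannot know a string is
an ontology term unless its URI is supplied.

## A worked example

The bundled cell-line fixture reconstructs a repository catalogue pattern:
each data row is one cell line, the label is the catalogue ID followed by
"cell", a comment records the source tissue and animal, and a superclass
axiom places every new class in the RIKEN Cell Bank repository.

```r
library(ontoforge)

bundle <- make_clo_fixture()
cat(bundle$settings_text)
#> [Operation]
#> new_classes
#>
#> [Term ID]
#> prefix=CLO_
#> digits=7
#> start=10000
#>
#> [Start portion of term URI]
#> http://purl.obolibrary.org/obo/
#>
#> [Term URIs]
#> 'label' <http://www.w3.org/2000/01/rdf-schema#label>
#> 'comment' <http://www.w3.org/2000/01/rdf-schema#comment>
#> 'is in cell line repository' <http://purl.obolibrary.org/obo/CLO_9990001>
#> 'RIKEN Cell Bank' <http://purl.obolibrary.org/obo/CLO_9990002>
#>
#> [Annotations]
#> 'label' "{$columnA} cell"
#> 'comment' "Derived from tissue: {$columnG} in animal: {$columnF}."
#>
#> [Superclasses]
#> 'is in cell line repository' some 'RIKEN Cell Bank'

res <- run_new_classes(bundle$settings, bundle$table)
print(res$report)
#> ontoforge run report
#>   rows read:         3
#>   rows processed:    3
#>   classes generated: 3
#>   axioms:            5 annotation, 3 superclass, 0 equivalent
#>   skipped patterns:  1 (empty referenced cells)
```

Three classes are minted (`CLO_0010000` through `CLO_0010002`, consecutive
from the configured start ID). The first row's column A holds `RCB2320`, so
its generated label is `RCB2320 cell`. Five annotations, not six: the third
row's animal cell is empty, so its comment pattern is skipped rather than
emitted with a hole — that is the one "skipped pattern" in the report. The
intermediate Manchester document shows the assembled frames:

```r
cat(res$manchester)
#> ...
#> Class: <http://purl.obolibrary.org/obo/CLO_0010000>
#>     Annotations:
#>         'label' "RCB2320 cell",
#>         'comment' "Derived from tissue: liver in animal: Mus musculus."
#>     SubClassOf:
#>         'is in cell line repository' some 'RIKEN Cell Bank'
#> ...
```

and `res$output$serialization` holds the final RDF/XML. Supplying a target
ontology shifts allocation past IDs already in use:

```r
pol <- bundle$settings$id_policy
tmp <- tempfile(fileext = ".owl")
writeLines(make_target_ontology(10000, pol), tmp, sep = "")
snap <- load_ontology(tmp)
res2 <- run_new_classes(bundle$settings, bundle$table, snapshot = snap)
res2$classes[[1]]$uri
#> [1] "http://purl.obolibrary.org/obo/CLO_0010001"
```

The same run works from a shell via the bundled CLI
(`inst/scripts/ontoforge` once installed):

```sh
ontoforge run --settings clo-settings.txt --input clo-input.tsv \
    --output clo-out.owl --emit-manchester clo-out.omn
```

For the edit-existing mode, see `make_biobank_fixture()`: five rows with
two annotation patterns on columns C and D yield exactly ten annotation
assertions attached to the key-column URIs, and zero class declarations.

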