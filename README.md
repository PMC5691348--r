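# pgdbwatch

Targeted update notifications for curated pathway/genome databases (PGDBs).

Curated model-organism databases in the BioCyc/Pathway Tools tradition are
re-released periodically, each release carrying thousands of curation edits.
A researcher who cares about a handful of genes, pathways, GO terms or
pathway classes has no practical way to learn which of those edits matter to
them. `pgdbwatch` closes that loop: it compares two releases object by
object, expands every subscription into its **interest closure** of
functionally related objects, applies a **new-citation significance
filter**, and renders one concise, linked change digest per user per
database.

## The method

Two ideas carry the system:

**Interest closures.** A subscription to gene *g* implicitly covers the
fixed point of: *g* → its product → complexes containing the product
(transitively, cycle-safe) → their enzymatic activities → the activities'
reactions → pathways containing those reactions (included but not expanded
further), plus every regulation object targeting any member and every
transcription unit listing *g*. A pathway subscription symmetrically covers
its reactions (sub-pathways recursively), substrates, activities, enzymes
decomposed to monomers, their genes, and regulation. GO-term and
pathway-class subscriptions resolve to member sets under the true-path
rule (annotations propagate through the is-a DAG), in one of two modes:
fire on *new members*, or apply the gene/pathway criteria to *all current
members*.

**New-citation significance.** Curators do not make significant changes
without citing a publication. A subscription therefore fires iff some
closure member carries at least one citation key in the new release that
was absent from that object — and from every object merged into it — in
the old release:

```
new_citations(x) = cit_new(x) \ ( cit_old(x) ∪ ⋃_{m : merged(m → x)} cit_old(m) )
fire(sub)        ⇔ ∃ x ∈ closure(anchor(sub), new) : new_citations(x) ≠ ∅
```

Typo fixes, rewordings, object merges, deletions and annotation removals
are all visible as diffs but silent by construction. Once a subscription
fires, *all* differences of its closure members are collected into the
digest, because the citation rarely says which field change it explains.

## Worked example

```r
library(pgdbwatch)

old <- read_snapshot(system.file("extdata", "fixture-a.dat",
                                 package = "pgdbwatch"), "ECOLI", "27.0")
names(old$objects)
#> [1] "TRPA"         "TRPA-MONOMER" "PUB-1"

citations_of(old$objects$TRPA)
#> [1] "PMID:101"
```

On a fuller trpA neighbourhood (gene → monomer → TrpAB complex → activity
→ reaction → pathway, with a regulation object on the complex; built in
code in `tests/testthat/helper-fixtures.R`):

```r
gene_closure(fixture, "TRPA")$members
#> [1] "ENZRXN-1"     "PWY-TRP"      "REG-1"        "RXN-1"        "TRPA"
#> [6] "TRPA-MONOMER" "TRPAB"
```

When the TrpAB complex gains one citation (`PMID:999`) between releases, a
`GENE TRPA` subscription fires even though the gene object itself never
changed, and the digest reads:

```
# ECOLI update notifications: release 1.0 to 2.0
For: bob@x.org

## gene: [trpA](https://example.org/ECOLI/object/TRPA)
Triggered by new citations on: TRPAB
- [TRPAB](https://example.org/ECOLI/object/TRPAB): citations
New publications: PMID:999

Manage or unsubscribe: https://example.org/notifications
```

i.e. the anchor link, the object whose new citation fired the filter, each
changed related object with its change categories, the new publications,
and the management link — nothing else.

From the shell, the same pipeline:

```sh
pgdbwatch gen-fixture --seed 5 --genes 10 --out-old old.dat --out-new new.dat --truth truth.json
pgdbwatch subscribe --registry reg.tsv --user u@x.org --database SYNCYC --kind GENE --target G0001
pgdbwatch notify --old old.dat --new new.dat --database SYNCYC \
    --registry reg.tsv --outdir reports/
```

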