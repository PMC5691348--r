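---
title: "Deciding what changed and who cares: the pgdbwatch notification model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding what changed and who cares: the pgdbwatch notification model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgdbwatch)
options(pgdbwatch.loglevel = "error")
```

## The problem

A curated pathway/genome database (PGDB) integrates an organism's genes,
gene products, protein complexes, enzymatic activities, reactions,
metabolic pathways and regulation as one object graph, re-released
periodically after continuous curation. Between two releases thousands of
objects change, for reasons ranging from typo fixes and schema maintenance
to newly curated publications. Only the last category is worth a
notification, and whether an edit belongs to it cannot be read off the
diff itself: a reworded mini-review and a newly curated paragraph look the
same as text replacements.

`pgdbwatch` implements a notification engine around two structural
observations about curated databases. First, interests are structural: a
user who registers a gene cares about its product, the complexes the
product joins, their activities, reactions, pathways and regulation, not
just the gene record. Second, significance is citational: curators do not
make significant changes without attaching a publication reference, so the
appearance of a *new* citation anywhere in a subscription's neighbourhood
is a reliable significance signal, and its absence a reliable silence
signal.

## The data model

A release (`snapshot()`) maps frame identifiers to objects; each object
has classes (its `TYPES` slot) and an ordered slot → values mapping where
every value may carry per-value annotations. This mirrors the
attribute-value flatfile dialect the reader and writer speak (records
opened by `UNIQUE-ID`, closed by `//`, `^LABEL` annotation lines, `/`
continuations), so real `.dat`-style exports are near-compatible. Values
are compared exactly — case- and whitespace-sensitive — which is what
makes a typo fix *detectable* as a diff while remaining *non-triggering*.

Citation identity is the publication, not its evidence annotation: tokens
are uppercased, stripped of surrounding brackets, and truncated at the
first `:` qualifier (except `PMID:<digits>`, where the digits are part of
the key). `citations_of()` unions object-level and value-level citations;
a citation moved between attributes of one object is therefore never
"new". Normalization is idempotent, which the test suite checks on
adversarial tokens.

Merge provenance is carried as a `MERGED-FROM` slot on the surviving
object rather than as out-of-band metadata. That choice makes provenance
round-trip through the flatfile with no special cases, and the
snapshot-level merge map is derived from it at construction time.

## Closures

Both closures are worklist fixed points over a relation set shipped as
YAML (`inst/extdata/relations.yaml`), so a schema that renames slots can
be accommodated without code changes. Two deliberate asymmetries:

* Pathways reached *from a gene* are members but are not expanded; one
  gene subscription must not transitively cover most of the database.
  Symmetrically, compounds reached from a pathway are terminal.
* Regulation membership is by regulated entity only. The regulator and
  its own neighbourhood stay outside: the subscription covers regulation
  *of* the user's objects, not everything the regulator touches.

Membership is a set and each object enters the worklist once, so
component-of cycles (which the synthetic generator deliberately produces)
terminate. Term subscriptions use the true-path rule: an annotation to a
term counts for every ancestor, so membership queries walk descendants in
the is-a DAG. We propagate for both term modes; the alternative
(direct-annotation-only membership) silently hides exactly the
annotations users most plausibly care about, those to more specific child
terms. A cycle in `PARENTS` raises an ontology error rather than being
tolerated, since it indicates a corrupted hierarchy.

## Diffing and the significance filter

Slots are compared as multisets of (value, annotations) pairs:
serialization order is not curation, but any content change is a diff. An
object's new-citation set subtracts, besides its own previous citations,
the previous citations of every object merged into it — so consolidating
two redundant enzymes, citations unioned, is silent even though the
surviving record gained citation values. Deletions cannot produce new
citations by construction; removed objects are kept in the diff for
report completeness only.

A gene or pathway subscription fires iff some member of its closure *on
the new release* has a non-empty new-citation set. Computing the closure
on the new snapshot is a choice: current structure defines current
interests, and objects that left the closure between releases behave like
deletions, which are non-triggering anyway. Once fired, the digest
carries *all* member diffs, because the citation tells us something
significant happened but usually not which field changes it explains.

Two decided edge cases: a brand-new object with no citations never
triggers (significant imports are expected to arrive cited), and
`NEW-MEMBERS` term firings need no citation at all — the membership
change itself is the subscribed event.

## Reports

Markdown is canonical; HTML is a line-wise derivation with identical link
targets and visible text, because the contract surface is textual
comparison, not mail-client fidelity. Determinism is absolute: all
collections are sorted, release labels come from snapshot metadata, no
timestamps enter report bodies, and permuting registry rows cannot change
a byte. Members shared between items of one report are listed once and
cross-referenced, and a member that no longer exists in the new release
is rendered as plain text (with a "merged into X" note where applicable)
so no hyperlink ever dangles. A conciseness regression guard bounds a
report with *k* items and *m* distinct changed members at
`10 + 4k + 3m` non-blank lines.

## The synthetic generator and what passing tests mean

`generate_base()` emulates the object neighbourhood the method operates
on: connected gene–product–complex–activity–reaction–pathway chains
(complexes nested to a configurable depth, with occasional component-of
cycles), regulation and transcription units, a small GO DAG with gene
annotations, a pathway-class tree, and publication records backing the
citation tokens. Edit scripts cover the full curation taxonomy: citation
additions (slot- or annotation-level, with and without evidence
qualifiers), typos, summary rewordings, merges with citation union,
deletions, GO-annotation additions and removals, and new objects with and
without citations.

Ground truth comes from an independent oracle (`oracle_firings()`):
closures by repeat-until-no-growth scans of the whole object table, term
membership by exhaustive DAG walking, triggering by raw set algebra. It
shares no code with the production closure/diff/notify path, so exact
agreement between the two routes over seeded fixtures is meaningful.

What the fixtures do **not** emulate: realistic curation rates, real
BioCyc content and its scale-free structure, OCELOT expression values,
multi-organism registries under one run, or free-text summaries whose
rewording correlates with citation changes. Passing tests therefore show
the engine implements its stated semantics exactly; they do not show the
citation heuristic's precision/recall on real curation streams, which
depends on curator discipline, not on this code.

## Sizes, seeds and runtime choices

Property and acceptance runs use release pairs of ≤ 200 objects (10–22
genes), 100 seeds for trigger-oracle equivalence, 50 for closure
equivalence and round-trips, and 20 per excluded edit class — enough to
exercise every edit kind and relation rule many times over while keeping
the full suite fast. The scale check uses a ~10,600-object pair with
~500 subscriptions; `run_notifications()` memoizes closures and term
memberships per anchor within a run (they are pure functions of the new
snapshot), and snapshot indexes (class and reverse-reference maps) make
closure expansion proportional to edges touched rather than database
size. Every stochastic test derives its randomness from an explicit seed
recorded in the test, so failures reproduce exactly.

## Known limitations

* The citation trigger inherits curator discipline: an uncited
  significant change is invisible, and a re-used old citation on new
  content is silent. This is a property of the method, embraced for its
  precision.
* Merge silence relies on recorded provenance (`MERGED-FROM`); a merge
  performed without provenance looks like a deletion plus a modified
  object and may fire if citations moved.
* Value comparison is exact; a reworded summary appears as remove+add
  rather than as a word-level diff. Triggering never depends on diff
  granularity, so this costs report polish, not correctness.
* GO annotations are modelled as a plain `GO-TERMS` slot without
  qualifiers or evidence-code semantics beyond citation normalization.
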