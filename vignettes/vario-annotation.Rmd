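---
title: "Annotating variant effects with the Variation Ontology"
author: "variotools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating variant effects with the Variation Ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(variotools)
```

## The annotation model

The Variation Ontology (VariO, http://variationontology.org) is a
controlled vocabulary for describing what a sequence variant *changes*
relative to a reference state — effects, consequences and mechanisms — as
opposed to describing the wild type itself. Its terms start from the three
biological molecules (DNA, RNA, protein) and branch into four major
sublevels each: *variation type*, *function*, *structure* and *property*,
with up to eight levels of terms in total. A fourth branch holds
*attributes*: modifier terms (quantity change, conservation, pathogenicity
association, interaction) that refine structure and property annotations so
that the ontology does not need separate "increased X" / "decreased X"
terms.

`variotools` implements the machinery a database curator needs to produce
such annotations:

1. **Parse** an HGVS description (`parseHGVS`) into a structured
   `VariantDescription`. The supported subset is the
   classification-relevant one: substitutions, deletions, insertions,
   duplications and deletion–insertions at the `g./c./n./r./p.` levels.
   Intronic offsets, frameshifts and extension variants are rejected
   explicitly rather than mis-parsed, because their classification is not
   representable in the concept table the package ships.
2. **Classify** (`classifyVariant`) the variant into canonical concept
   names per molecular level: the chain-variation concepts per kind, the
   transition/transversion split for substitutions (transition iff both
   bases are purines or both pyrimidines, with U treated as T chemically
   but rendered as given), the coding consequence (missense / nonsense /
   synonymous) and the origin concept (genetic vs non-genetic).
3. **Expand** every assigned concept to its full root-to-leaf path
   (`expandFullPath`), the form in which VariO annotations are reported:
   a full path carries more information and avoids ambiguity when term
   names repeat across branches.
4. **Assemble, validate and render** (`buildAnnotation`,
   `attachAttribute`, `validateAnnotationSet`, `renderAnnotations`) the
   complete per-variant annotation set, stamped once with the ontology
   version, with attribute modifiers, ECO evidence terms and literature
   references.

Classification works on names, not hard-coded ids: every concept the
classifier emits is resolved against the loaded ontology with
`resolveName`. This is what makes the bundled mini-ontology and a full
VariO release interchangeable.

## The bundled mini-ontology

`buildMiniOntology()` constructs (and `inst/extdata/mini_vario.obo`
ships) a self-contained VariO excerpt: the four branch roots — variation
affecting DNA (VariO:0128), RNA (VariO:0297), protein (VariO:0002) and
variation attribute (VariO:0232) — and every concept the classification
and annotation machinery can emit, 76 terms in all. Its deepest chain,
through the protein-structure branch down to *effect on alpha helix*, is 8
terms long, matching the ontology's stated depth.

Two modelling points deserve attention:

* **Placeholders.** Concepts whose canonical ids are not bundled (purine
  transition, transversion, the deletion/insertion/duplication subtypes,
  nonsense/synonymous variation, the conservation attribute subtree, …)
  carry reserved `VariO:9xxx` ids and are flagged (`isPlaceholderTerm`).
  Invented ids are never presented as canonical: annotations built from a
  full ontology release bind the real ids automatically through
  `resolveName`, and origin annotations are emitted only when their
  concept has a canonical id in the loaded ontology (which is why a
  genetic-origin RNA block does not appear in the worked example's
  output).
* **Missense parentage.** The RNA branch prints *missense variation*
  (VariO:0308) directly after the substitution chain, but a consequence is
  not a child of *pyrimidine transition*; the prose says the transition
  *causes* the missense variation. The fixture attaches VariO:0308 under
  *RNA variation classification* (VariO:0328) and records in the term's
  OBO `comment:` tag that the placement is inferred. To keep the printed
  block layout, an `Annotation` may carry `extraTermIds`: consequence
  terms rendered inside the variation-type block after the path.

## Multi-parent terms and path ambiguity

The transition subtree is shared between the DNA and RNA substitution
branches (VariO:0313/0314 have two parent lineages). Path expansion is
therefore parameterized by the level root, and within one root any
residual multiplicity is resolved deterministically: the lexicographically
smallest id sequence is returned and the path is flagged
(`isAmbiguousPath`). Whether the official release models these as shared
nodes or duplicated ids cannot be decided from the bundled excerpt; shared
nodes are assumed.

## Usage rules enforced by the validator

`validateAnnotationSet` reports violations as data (a coded data frame),
so that faulty sets can be inspected rather than merely rejected:

* full paths must be intact parent–child chains starting at the level's
  root (`BROKEN_PATH`);
* attributes modify structure and property terms only — never variation
  type or function (`WRONG_BRANCH_ATTRIBUTE`). "Structure or property" is
  decided by ancestry under the per-level `variation affecting … structure
  / property` terms, by name rather than id so the rule survives loading a
  fuller release; this mechanism is the package's reading of a rule the
  ontology states only verbally;
* interaction attributes span several sublevels and must carry their full
  path from the attribute root (`MISSING_ATTRIBUTE_PATH`), while the
  single-sublevel attributes — quantity change, conservation,
  pathogenicity association — are used without one
  (`SUPERFLUOUS_ATTRIBUTE_PATH`);
* the ontology version is stated once per set (`MISSING_VERSION`), every
  annotated level names its reference state
  (`MISSING_REFERENCE_STATE`), and a variant that changes all three
  molecular levels must carry a variation-type annotation at each
  (`BELOW_MINIMUM`).

Identifiers are zero-padded to four digits on input and output; the one
unpadded attribute id that circulates in print is normalized rather than
reproduced.

## Tunable parameters

* `tolerance` (default **0.05**, dimensionless): half-width of the
  "not changed" band used by `quantityAttributeFromRatio`. A measured
  property at ratio *r* to wild type maps to *missing* when *r* = 0, *not
  changed* when |*r* − 1| ≤ τ, *decreased*/*increased* outside the band.
  The default is an arbitrary but documented choice; measurement-specific
  error models are the curator's business, so the knob is exposed both in
  the API and the CLI.
* the ECO keyword table behind `ecoLookup` is extensible via
  `options(variotools.eco = )`; unknown method keywords raise an error
  rather than guessing an evidence class.

## Rendering conventions

Text output reproduces the one-term-per-line `id name` block layout used
in VariO practice. Single-sublevel attributes are appended to the modified
term's line after `"; "`; interaction attributes follow as separate
full-path blocks. Evidence terms are rendered as flat `ECO:NNNNNNN name`
lines on their own, after the block they support: ECO terms carry no path,
and appending them to a term's line would break the block layout, so the
separate-line convention was chosen (JSON and TSV carry the link
explicitly in `linked_term_id`). JSON rendering is canonical:
`render → parse → render` is byte-identical, which the test suite asserts.

## The synthetic corpus and what passing tests show

`generateSyntheticVariants` emits random valid descriptions from the
supported HGVS grammar — covering every kind × level combination and, in
substitution-only mode with *n* = 12, every ordered base pair exactly
once — together with expected classifications computed by an independent
table-driven oracle (plain lookup tables, no code shared with the
classifier). The corpus emulates the *syntactic* diversity of variant
descriptions, not real mutational spectra: positions are uniform, there
is no transition bias, no reference-sequence consistency, and no linkage
between nucleotide and protein descriptions. Passing the corpus tests
therefore demonstrates grammar coverage and classification correctness,
not calibration against real databases.

Problem sizes used by the default test run: exhaustive enumerations where
the space is small (12 ordered base pairs; 64 × 3 × 3 codon
substitutions; all fixture terms × reachable roots), random DAGs up to 50
nodes against brute-force oracles, and synthetic corpora of a few hundred
cases per property.

## Known limitations

* The HGVS subset is deliberately narrow; anything outside it errors.
  There is no Mutalyzer-style validation against the reference sequence,
  and no genome-to-transcript projection — reference accessions are
  carried as opaque strings.
* Stop-loss and start-loss consequences are outside the concept table and
  rejected, as is classification of a purely synonymous protein
  description (`p.X=` carries no protein-level change).
* When a stated protein change and a codon context disagree, the package
  refuses to choose: contradictions are for the curator to resolve, not
  the software.
* The bundled ontology is an excerpt; analyses needing the complete term
  set should load the official OBO release via `loadOntology(path)` /
  `--ontology FILE`. No test depends on that file.
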