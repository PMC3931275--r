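# variotools

Variation Ontology (VariO) annotation of sequence variants in R.

Variant databases collect enormous numbers of observations, but free-text
effect descriptions are nearly useless for computational analysis. The
Variation Ontology (http://variationontology.org) fixes this with a
controlled vocabulary for the **effects, consequences and mechanisms** of
variations at the three molecular levels — DNA, RNA and protein — each
with *variation type*, *function*, *structure* and *property* sublevels,
plus *attribute* modifiers (quantity change, conservation, pathogenicity
association, interaction) and ECO evidence terms. `variotools` is for
curators of locus-specific and central variant databases who need to
produce such annotations systematically.

The package implements the full annotation method:

* **HGVS parsing** — `parseHGVS` handles the classification-relevant
  subset (`g./c./n./r./p.` substitutions, del, ins, dup, delins) and
  re-serializes canonically with `hgvsFormat`.
* **Classification** — `classifyVariant` maps a parsed variant to
  canonical VariO concepts per level: chain-variation concepts per kind;
  the transition/transversion split (a substitution is a transition iff
  both bases are purines {A,G} or both pyrimidines {C,T/U}); the coding
  consequence (missense / nonsense / synonymous, via the standard genetic
  code); and the genetic / non-genetic origin concept.
* **Full-path expansion** — every assigned term is reported as the
  complete chain from its branch root (`expandFullPath`), the form VariO
  annotations must take; shared subtrees (e.g. *transition* under both DNA
  and RNA substitution) are disambiguated by the level root.
* **Annotation assembly** — `buildAnnotation`, `attachAttribute`,
  `ecoLookup`, `quantityAttributeFromRatio`, `pathogenicityAttribute`
  build per-variant `AnnotationSet` objects; `validateAnnotationSet`
  checks the ontology's usage rules and reports coded violations;
  `renderAnnotations` writes text (block layout), JSON (lossless round
  trip) or TSV.
* **Self-contained fixtures** — `buildMiniOntology` (also shipped as
  `inst/extdata/mini_vario.obo`, OBO 1.2) and the fully worked AIRE
  example (`goldenAireAnnotationSet`).
* **CLI** — `inst/scripts/vario` exposes `classify`, `annotate`,
  `validate`, `expand-path` and `fixture` subcommands.

## Worked example

The AIRE variant g.4789T>C (IDbase reference D0003) causes an L→P
substitution and APECED disease:

```r
library(variotools)
g <- loadOntology()           # bundled mini-ontology, 76 terms, 4 roots
cat(cmdClassify("g.4789T>C", "genetic", proteinChange = c("L", "P"), g))
```

```
variant: g.4789T>C
ontology version: variotools-mini/1.0

VariO:0128 variation affecting DNA
VariO:0129 DNA variation type
VariO:0322 DNA variation classification
VariO:0135 DNA chain variation
VariO:0136 DNA substitution
VariO:0313 transition
VariO:0314 pyrimidine transition

VariO:0128 variation affecting DNA
VariO:0129 DNA variation type
VariO:0127 DNA variation origin
VariO:0130 DNA variation of genetic origin

VariO:0297 variation affecting RNA
VariO:0306 RNA variation type
VariO:0328 RNA variation classification
VariO:0312 RNA substitution
VariO:0313 transition
VariO:0314 pyrimidine transition
VariO:0308 missense variation

VariO:0002 variation affecting protein
VariO:0012 protein variation type
VariO:0325 protein variation classification
VariO:0021 amino acid substitution

VariO:0002 variation affecting protein
VariO:0323 protein variation origin
VariO:0013 protein variation of genetic origin
```

Reading: at the DNA level the variant is a **pyrimidine transition**
(T→C, both pyrimidines) of genetic origin, reported as the full path from
the branch root; the same transition at the RNA level causes a **missense
variation**; at the protein level it is an **amino acid substitution**.
The complete annotation — function, structure (alpha-helix and fold
paths), property annotations with attribute modifiers such as
`VariO:0053 effect on protein activity; VariO:0292 missing`, and the
three ECO evidence terms — is produced from the bundled request document:

```r
res <- cmdAnnotate(system.file("extdata", "aire_request.json",
                               package = "variotools"), g)
cat(res$document)             # validates with zero violations
```

See `vignettes/vario-annotation.Rmd` for the annotation model, the
validator's rule set and the package's design choices.

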