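#' @import methods
NULL

## Identifier grammar shared by validity methods and the OBO parser.
.CURIE_RE <- "^(VariO:[0-9]{4}|ECO:[0-9]{7})$"

.MOLECULAR_LEVELS <- c("DNA", "RNA", "protein")
.VARIANT_LEVELS <- c("g", "c", "n", "r", "p")
.VARIANT_KINDS <- c("substitution", "deletion", "insertion", "duplication",
                    "delins")

## Branch roots named by the ontology; used wherever a level must be tied
## to its root term.
.LEVEL_ROOTS <- c(DNA = "VariO:0128", RNA = "VariO:0297",
                  protein = "VariO:0002", attribute = "VariO:0232")

#' OntologyGraph: a multi-rooted is_a DAG of ontology terms
#'
#' Holds the term set of an ontology read from an OBO 1.2 document (or built
#' in code). Each term record is a list with elements \code{id}, \code{name},
#' \code{def}, \code{parents} (character vector of term ids), \code{extra}
#' (verbatim unhandled OBO tag lines, preserved on round trip) and
#' \code{placeholder} (\code{TRUE} for fixture terms carrying reserved
#' \code{VariO:9xxx} ids that stand in for concepts whose canonical ids are
#' not bundled).
#'
#' @slot terms named list of term records, keyed by term id.
#' @slot version free-text ontology version (OBO \code{data-version}).
#' @slot headerExtra verbatim header lines other than format/data version.
#'
#' @name OntologyGraph-class
#' @rdname OntologyGraph-class
#' @exportClass OntologyGraph
setClass("OntologyGraph",
         representation(terms = "list",
                        version = "character",
                        headerExtra = "character"),
         prototype(terms = list(), version = "", headerExtra = character()))

.detectCycle <- function(terms) {
  ## Kahn-style peeling: returns TRUE if a cycle exists.
  remaining <- names(terms)
  parents <- lapply(terms, `[[`, "parents")
  repeat {
    if (length(remaining) == 0L) return(FALSE)
    leaves <- remaining[vapply(parents[remaining], function(p)
      !any(p %in% remaining), logical(1))]
    if (length(leaves) == 0L) return(TRUE)
    remaining <- setdiff(remaining, leaves)
  }
}

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  ids <- names(object@terms)
  for (t in object@terms) {
    if (!grepl(.CURIE_RE, t$id))
      msgs <- c(msgs, sprintf("malformed term id '%s'", t$id))
    if (!nzchar(t$name))
      msgs <- c(msgs, sprintf("term %s has empty name", t$id))
    if (anyDuplicated(t$parents))
      msgs <- c(msgs, sprintf("term %s lists a duplicate parent", t$id))
    if (t$id %in% t$parents)
      msgs <- c(msgs, sprintf("term %s is its own parent", t$id))
    missing <- setdiff(t$parents, ids)
    if (length(missing))
      msgs <- c(msgs, sprintf("term %s references unknown parent(s) %s",
                              t$id, paste(missing, collapse = ", ")))
  }
  if (length(ids) && anyDuplicated(ids))
    msgs <- c(msgs, "duplicate term ids")
  if (!setequal(ids, vapply(object@terms, `[[`, character(1), "id")))
    msgs <- c(msgs, "term list names disagree with term ids")
  if (length(msgs) == 0L && length(object@terms) && .detectCycle(object@terms))
    msgs <- c(msgs, "cycle detected in is_a graph")
  if (length(object@version) != 1L)
    msgs <- c(msgs, "version must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' AnnotationPath: a full root-to-term chain of ontology ids
#'
#' An ordered chain of term ids from a branch root down to the most specific
#' term, as required by the full-path annotation rule. \code{ambiguous} is
#' set when several chains through the requested root existed and the
#' lexicographically smallest id sequence was chosen.
#'
#' @slot termIds ordered character vector, root first.
#' @slot ambiguous logical flag for multi-lineage terms.
#'
#' @name AnnotationPath-class
#' @rdname AnnotationPath-class
#' @exportClass AnnotationPath
setClass("AnnotationPath",
         representation(termIds = "character", ambiguous = "logical"),
         prototype(termIds = character(), ambiguous = FALSE))

setValidity("AnnotationPath", function(object) {
  msgs <- character()
  if (length(object@termIds) < 1L)
    msgs <- c(msgs, "path must contain at least one term")
  if (!all(grepl(.CURIE_RE, object@termIds)))
    msgs <- c(msgs, "path contains a malformed id")
  if (length(object@ambiguous) != 1L || is.na(object@ambiguous))
    msgs <- c(msgs, "ambiguous must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' VariantDescription: a parsed HGVS variant description
#'
#' Structured form of the supported HGVS subset. Nucleotide levels
#' (\code{g}, \code{c}, \code{n}, \code{r}) populate the allele slots;
#' protein level (\code{p}) populates the residue slots (1-letter codes,
#' \code{"*"} is the stop sentinel, \code{"="} marks a synonymous
#' description). Coordinates are 1-based fully closed intervals.
#'
#' @slot referenceId opaque reference-sequence accession, may be "".
#' @slot level one of g, c, n, r, p.
#' @slot kind substitution, deletion, insertion, duplication or delins.
#' @slot start,end 1-based positions, \code{end >= start}.
#' @slot refAllele,altAllele nucleotide text (uppercase; U kept distinct
#'   from T) or "".
#' @slot refResidues,altResidues amino-acid text or "".
#'
#' @name VariantDescription-class
#' @rdname VariantDescription-class
#' @exportClass VariantDescription
setClass("VariantDescription",
         representation(referenceId = "character", level = "character",
                        kind = "character", start = "integer",
                        end = "integer", refAllele = "character",
                        altAllele = "character", refResidues = "character",
                        altResidues = "character"),
         prototype(referenceId = "", level = "g", kind = "substitution",
                   start = 1L, end = 1L, refAllele = "", altAllele = "",
                   refResidues = "", altResidues = ""))

setValidity("VariantDescription", function(object) {
  msgs <- character()
  if (!object@level %in% .VARIANT_LEVELS)
    msgs <- c(msgs, "level must be one of g/c/n/r/p")
  if (!object@kind %in% .VARIANT_KINDS)
    msgs <- c(msgs, "unknown variation kind")
  if (is.na(object@start) || object@start < 1L)
    msgs <- c(msgs, "start must be >= 1")
  if (is.na(object@end) || object@end < object@start)
    msgs <- c(msgs, "end must be >= start")
  nuc <- object@level %in% c("g", "c", "n", "r")
  if (nuc && (nzchar(object@refResidues) || nzchar(object@altResidues)))
    msgs <- c(msgs, "nucleotide-level description must not carry residues")
  if (!nuc && (nzchar(object@refAllele) || nzchar(object@altAllele)))
    msgs <- c(msgs, "protein-level description must not carry alleles")
  if (object@kind == "substitution") {
    if (object@start != object@end)
      msgs <- c(msgs, "substitution must have start == end")
    if (nuc) {
      if (nchar(object@refAllele) != 1L || nchar(object@altAllele) != 1L)
        msgs <- c(msgs, "substitution requires single-base alleles")
      else if (object@refAllele == object@altAllele)
        msgs <- c(msgs, "substitution reference and alternate alleles are equal")
    } else {
      if (nchar(object@refResidues) != 1L || nchar(object@altResidues) != 1L)
        msgs <- c(msgs, "substitution requires single residues")
      else if (object@refResidues == object@altResidues)
        msgs <- c(msgs, "substitution reference and alternate residues are equal")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ClassificationResult: VariO concepts assigned per molecular level
#'
#' @slot perLevel named list (names among DNA/RNA/protein); each element an
#'   ordered character vector of concept names, general first, most specific
#'   last.
#' @slot originConcepts named character vector of origin concept names per
#'   classified level.
#'
#' @name ClassificationResult-class
#' @rdname ClassificationResult-class
#' @exportClass ClassificationResult
setClass("ClassificationResult",
         representation(perLevel = "list", originConcepts = "character"),
         prototype(perLevel = list(), originConcepts = character()))

setValidity("ClassificationResult", function(object) {
  msgs <- character()
  if (!all(names(object@perLevel) %in% .MOLECULAR_LEVELS))
    msgs <- c(msgs, "perLevel names must be DNA/RNA/protein")
  if (any(vapply(object@perLevel, length, integer(1)) == 0L))
    msgs <- c(msgs, "a classified level must carry at least one concept")
  if (!all(names(object@originConcepts) %in% .MOLECULAR_LEVELS))
    msgs <- c(msgs, "originConcepts names must be DNA/RNA/protein")
  if (length(msgs)) msgs else TRUE
})

#' Annotation: one full-path annotation with modifiers and evidence
#'
#' \code{attributes} is a list of attribute-use records (lists with
#' \code{attributeId}, \code{modifiedTermId} and \code{fullPath}, the latter
#' \code{NULL} except for interaction attributes, which the ontology requires
#' in full). \code{evidence} is a list of evidence-use records (lists with
#' \code{ecoId}, \code{ecoName}, \code{linkedTermId}); ECO terms are stored
#' flat, without a path. \code{extraTermIds} holds terms printed after the
#' path inside the same annotation block (used for coding consequences, which
#' the worked AIRE example prints inside the RNA variation-type block).
#'
#' Only structural invariants are enforced here; graph-dependent rules
#' (parent-child chains, attribute branch membership) are checked by
#' \code{\link{validateAnnotationSet}} so that rule violations can be
#' reported as data.
#'
#' @slot level DNA, RNA or protein.
#' @slot path an \code{AnnotationPath}.
#' @slot extraTermIds character vector of additional term ids.
#' @slot attributes list of attribute-use records.
#' @slot evidence list of evidence-use records.
#' @slot references character vector of opaque citation/database texts.
#'
#' @name Annotation-class
#' @rdname Annotation-class
#' @exportClass Annotation
setClass("Annotation",
         representation(level = "character", path = "AnnotationPath",
                        extraTermIds = "character", attributes = "list",
                        evidence = "list", references = "character"),
         prototype(level = "DNA", extraTermIds = character(),
                   attributes = list(), evidence = list(),
                   references = character()))

setValidity("Annotation", function(object) {
  msgs <- character()
  if (!object@level %in% .MOLECULAR_LEVELS)
    msgs <- c(msgs, "level must be DNA, RNA or protein")
  for (a in object@attributes) {
    if (!all(c("attributeId", "modifiedTermId") %in% names(a)))
      msgs <- c(msgs, "attribute use must carry attributeId and modifiedTermId")
    else if (!grepl(.CURIE_RE, a$attributeId) ||
             !grepl(.CURIE_RE, a$modifiedTermId))
      msgs <- c(msgs, "attribute use carries a malformed id")
  }
  for (e in object@evidence) {
    if (!all(c("ecoId", "ecoName") %in% names(e)))
      msgs <- c(msgs, "evidence use must carry ecoId and ecoName")
    else if (!grepl("^ECO:[0-9]{7}$", e$ecoId))
      msgs <- c(msgs, sprintf("malformed ECO id '%s'", e$ecoId))
  }
  if (length(msgs)) msgs else TRUE
})

#' AnnotationSet: all annotations for one variant
#'
#' The complete annotation of one variant across molecular levels, stamped
#' once with the ontology version. \code{referenceStates} maps levels to the
#' reference accessions the annotations are made against; \code{levelsAffected}
#' states which molecular levels the variant changes (drives the
#' minimum-annotation rule).
#'
#' @slot variant a \code{VariantDescription}.
#' @slot referenceStates named character vector (names among DNA/RNA/protein).
#' @slot annotations list of \code{Annotation} objects.
#' @slot ontologyVersion single version string, stated once per set.
#' @slot levelsAffected character vector of levels the variant changes.
#'
#' @name AnnotationSet-class
#' @rdname AnnotationSet-class
#' @exportClass AnnotationSet
setClass("AnnotationSet",
         representation(variant = "VariantDescription",
                        referenceStates = "character",
                        annotations = "list",
                        ontologyVersion = "character",
                        levelsAffected = "character"),
         prototype(referenceStates = character(), annotations = list(),
                   ontologyVersion = "", levelsAffected = character()))

setValidity("AnnotationSet", function(object) {
  msgs <- character()
  if (!all(vapply(object@annotations, is, logical(1), "Annotation")))
    msgs <- c(msgs, "annotations must all be Annotation objects")
  if (!all(names(object@referenceStates) %in% .MOLECULAR_LEVELS))
    msgs <- c(msgs, "referenceStates names must be DNA/RNA/protein")
  if (!all(object@levelsAffected %in% .MOLECULAR_LEVELS))
    msgs <- c(msgs, "levelsAffected must be among DNA/RNA/protein")
  if (length(object@ontologyVersion) != 1L)
    msgs <- c(msgs, "ontologyVersion must be a single string")
  if (length(msgs)) msgs else TRUE
})
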