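#' @include classify.R
NULL

.QUANTITY_IDS <- c(decreased = "VariO:0290", increased = "VariO:0291",
                   missing = "VariO:0292", not_changed = "VariO:0140")

.PATHOGENICITY_IDS <- c(disease_causing = "VariO:0294",
                        not_disease_causing = "VariO:9018")

## Method-keyword -> ECO term table; extensible via options(variotools.eco=).
.ECO_TABLE <- data.frame(
  keyword = c("reporter gene assay", "gel filtration", "protein separation",
              "immunofluorescence"),
  ecoId = c("ECO:0000049", "ECO:0000156", "ECO:0000156", "ECO:0000007"),
  ecoName = c("reporter gene assay evidence", "protein separation evidence",
              "protein separation evidence", "immunofluorescence evidence"),
  stringsAsFactors = FALSE)

.annotateError <- function(...) {
  stop(structure(class = c("annotateError", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.resolveConcept <- function(graph, concept) {
  if (grepl(.CURIE_RE, concept)) {
    .checkTerm(graph, concept)
    concept
  } else resolveName(graph, concept)
}

#' Build a full-path annotation for one concept
#'
#' Expands the concept to its complete chain from the level's branch root
#' (variation affecting DNA / RNA / protein), the form in which every VariO
#' annotation is reported.
#'
#' @param graph an \code{OntologyGraph}.
#' @param concept a term id or a canonical concept name.
#' @param level DNA, RNA or protein.
#' @param extraConcepts optional concepts appended after the path inside the
#'   same block (coding consequences in the worked example); each must be
#'   reachable from the level root.
#' @param references optional citation/database texts.
#' @return an \code{\linkS4class{Annotation}} with no attributes or
#'   evidence yet.
#' @examples
#' g <- buildMiniOntology()
#' buildAnnotation(g, "effect on alpha helix", "protein")
#' @export
buildAnnotation <- function(graph, concept, level,
                            extraConcepts = character(),
                            references = character()) {
  if (!level %in% .MOLECULAR_LEVELS)
    .annotateError("unknown molecular level: '", level, "'")
  id <- .resolveConcept(graph, concept)
  root <- .LEVEL_ROOTS[[level]]
  path <- tryCatch(expandFullPath(graph, id, root), error = function(e)
    .annotateError("concept ", id, " ('", termName(graph, id),
                   "') is not reachable from the ", level, " root ", root))
  extraIds <- vapply(extraConcepts, function(ec) {
    eid <- .resolveConcept(graph, ec)
    tryCatch(expandFullPath(graph, eid, root), error = function(e)
      .annotateError("extra concept ", eid, " is not reachable from the ",
                     level, " root"))
    eid
  }, character(1), USE.NAMES = FALSE)
  new("Annotation", level = level, path = path, extraTermIds = extraIds,
      references = as.character(references))
}

#' Attach an attribute modifier to an annotation
#'
#' Attributes modify structure and property annotations; they are never
#' used to specify variation-type or function terms. Interaction attributes
#' are stored with their full path from the attribute root; single-sublevel
#' attributes (quantity change, conservation, pathogenicity association)
#' are stored without one.
#'
#' @param graph an \code{OntologyGraph}.
#' @param annotation an \code{Annotation}.
#' @param attributeId id of an attribute-branch term.
#' @param modifiedTermId id of the term the attribute modifies; must lie on
#'   the annotation's path and in a structure or property sub-branch.
#' @return the annotation with the attribute use appended.
#' @export
attachAttribute <- function(graph, annotation, attributeId, modifiedTermId) {
  stopifnot(is(annotation, "Annotation"))
  if (!isAttributeTerm(graph, attributeId))
    .annotateError("term ", attributeId, " is not in the attribute branch")
  if (!modifiedTermId %in% pathTermIds(annotation@path))
    .annotateError("modified term ", modifiedTermId,
                   " is not on the annotation's path")
  cat_ <- .termCategory(graph, modifiedTermId)
  if (!cat_ %in% c("structure", "property"))
    .annotateError("attributes are not used on ", cat_,
                   " terms (", modifiedTermId, ")")
  use <- list(attributeId = attributeId, modifiedTermId = modifiedTermId,
              fullPath = NULL)
  if (attributeRequiresFullPath(graph, attributeId))
    use$fullPath <- pathTermIds(
      expandFullPath(graph, attributeId, .LEVEL_ROOTS[["attribute"]]))
  annotation@attributes <- c(annotation@attributes, list(use))
  validObject(annotation)
  annotation
}

#' Quantity-change attribute id
#'
#' @param change one of decreased, increased, missing, not_changed.
#' @return the attribute term id.
#' @examples
#' quantityAttribute("missing")
#' @export
quantityAttribute <- function(change = c("decreased", "increased", "missing",
                                         "not_changed")) {
  change <- match.arg(change)
  unname(.QUANTITY_IDS[[change]])
}

#' Quantity-change attribute from a measured ratio
#'
#' Maps a measured property value relative to wild type to the quantity
#' attribute: exactly 0 is missing; within \code{tolerance} of 1 is not
#' changed; below/above that band is decreased/increased.
#'
#' @param ratio measured value / wild-type value, >= 0.
#' @param tolerance half-width of the not-changed band around 1 (default
#'   0.05).
#' @return the attribute term id.
#' @examples
#' quantityAttributeFromRatio(0)    # missing
#' quantityAttributeFromRatio(2.0)  # increased
#' @export
quantityAttributeFromRatio <- function(ratio, tolerance = 0.05) {
  if (length(ratio) != 1L || is.na(ratio) || ratio < 0)
    .annotateError("ratio must be a single non-negative number")
  change <- if (ratio == 0) "missing"
    else if (abs(ratio - 1) <= tolerance) "not_changed"
    else if (ratio < 1 - tolerance) "decreased"
    else "increased"
  quantityAttribute(change)
}

#' Pathogenicity-association attribute id
#'
#' @param status disease_causing, not_disease_causing or unknown.
#' @return the attribute term id, or \code{NA_character_} for unknown (an
#'   unknown status asserts nothing, so no attribute is attached).
#' @export
pathogenicityAttribute <- function(status = c("disease_causing",
                                              "not_disease_causing",
                                              "unknown")) {
  status <- match.arg(status)
  if (status == "unknown") return(NA_character_)
  unname(.PATHOGENICITY_IDS[[status]])
}

#' Look up an ECO evidence term for a method keyword
#'
#' ECO terms describe the (usually experimental) method behind an
#' annotation and are used flat, without a path. The bundled table is
#' seeded with reporter gene assay, protein separation (gel filtration) and
#' immunofluorescence evidence and can be extended via
#' \code{options(variotools.eco = <data.frame>)} with columns
#' \code{keyword}, \code{ecoId}, \code{ecoName}. Unknown keywords are an
#' error rather than a guess.
#'
#' @param methodKeyword free-text method keyword (case-insensitive).
#' @param linkedTermId optional id of the VariO term the evidence supports.
#' @return evidence-use record: list with \code{ecoId}, \code{ecoName},
#'   \code{linkedTermId}.
#' @examples
#' ecoLookup("reporter gene assay")$ecoId
#' @export
ecoLookup <- function(methodKeyword, linkedTermId = NA_character_) {
  tbl <- rbind(.ECO_TABLE, getOption("variotools.eco", NULL))
  i <- match(tolower(trimws(methodKeyword)), tolower(tbl$keyword))
  if (is.na(i))
    .annotateError("unknown evidence method keyword: '", methodKeyword, "'")
  list(ecoId = tbl$ecoId[i], ecoName = tbl$ecoName[i],
       linkedTermId = linkedTermId)
}

#' Assemble an annotation set
#'
#' @param variant a \code{VariantDescription}.
#' @param annotations list of \code{Annotation} objects.
#' @param referenceStates named character vector of reference accessions
#'   per level.
#' @param ontologyVersion the ontology version string, stated once per set.
#' @param levelsAffected levels the variant changes; defaults to the levels
#'   present among the annotations.
#' @return an \code{\linkS4class{AnnotationSet}}.
#' @export
AnnotationSet <- function(variant, annotations = list(),
                          referenceStates = character(),
                          ontologyVersion = "",
                          levelsAffected = NULL) {
  if (is.null(levelsAffected))
    levelsAffected <- intersect(.MOLECULAR_LEVELS, unique(
      vapply(annotations, function(a) a@level, character(1))))
  new("AnnotationSet", variant = variant, annotations = annotations,
      referenceStates = referenceStates,
      ontologyVersion = ontologyVersion,
      levelsAffected = as.character(levelsAffected))
}

#' Annotations of an annotation set
#'
#' @rdname annotations
#' @aliases annotations,AnnotationSet-method
#' @param x an \code{AnnotationSet}.
#' @return list of \code{Annotation} objects.
#' @export
setMethod("annotations", "AnnotationSet", function(x) x@annotations)

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %s | %d annotation(s) at level(s) %s\n",
              hgvsFormat(object@variant, withReference = TRUE),
              length(object@annotations),
              paste(unique(vapply(object@annotations, function(a) a@level,
                                  character(1))), collapse = "/")))
  if (nzchar(object@ontologyVersion))
    cat("  ontology version:", object@ontologyVersion, "\n")
})

## ---------------------------------------------------------------------------
## Validation: rule violations reported as data, never as exceptions
## ---------------------------------------------------------------------------

.violation <- function(code, message, annotation = NA_integer_) {
  data.frame(code = code, message = message, annotation = annotation,
             stringsAsFactors = FALSE)
}

#' Validate an annotation set against the ontology's usage rules
#'
#' Checks the assembled set and returns coded violations (an empty frame
#' means the set is valid):
#' \describe{
#'   \item{BROKEN_PATH}{a consecutive path pair is not parent-child, the
#'     path does not start at the level's root, or a path/extra term is
#'     unknown.}
#'   \item{WRONG_BRANCH_ATTRIBUTE}{an attribute modifies a variation-type,
#'     function or other non-structure/property term, or the attribute id
#'     is not in the attribute branch, or the modified term is off the
#'     path.}
#'   \item{MISSING_ATTRIBUTE_PATH}{an interaction attribute stored without
#'     its full path.}
#'   \item{SUPERFLUOUS_ATTRIBUTE_PATH}{a single-sublevel attribute stored
#'     with a path.}
#'   \item{MISSING_VERSION}{empty ontology version stamp.}
#'   \item{MISSING_REFERENCE_STATE}{a level is annotated without a
#'     reference accession.}
#'   \item{BELOW_MINIMUM}{the variant changes all three molecular levels
#'     but some level lacks a variation-type annotation.}
#' }
#'
#' @param graph an \code{OntologyGraph}.
#' @param set an \code{AnnotationSet}.
#' @return data.frame with columns code, message, annotation (index into
#'   \code{annotations(set)} or NA for set-level violations).
#' @export
validateAnnotationSet <- function(graph, set) {
  stopifnot(is(graph, "OntologyGraph"), is(set, "AnnotationSet"))
  v <- .violation(character(), character(), integer())[0, ]

  if (!nzchar(trimws(set@ontologyVersion)))
    v <- rbind(v, .violation("MISSING_VERSION",
                             "ontology version must be stated once per set"))

  annLevels <- vapply(set@annotations, function(a) a@level, character(1))
  for (lv in unique(annLevels)) {
    if (!lv %in% names(set@referenceStates) ||
        !nzchar(set@referenceStates[[lv]]))
      v <- rbind(v, .violation("MISSING_REFERENCE_STATE",
        sprintf("level %s is annotated without a reference accession", lv)))
  }

  checkChain <- function(ids, i, what) {
    bad <- NULL
    unknown <- setdiff(ids, termIds(graph))
    if (length(unknown))
      return(.violation("BROKEN_PATH",
        sprintf("%s contains unknown term(s) %s", what,
                paste(unknown, collapse = ", ")), i))
    if (length(ids) > 1L)
      for (k in seq_len(length(ids) - 1L))
        if (!ids[k] %in% termParents(graph, ids[k + 1L]))
          bad <- rbind(bad, .violation("BROKEN_PATH",
            sprintf("%s: %s is not a parent of %s", what, ids[k],
                    ids[k + 1L]), i))
    bad
  }

  for (i in seq_along(set@annotations)) {
    a <- set@annotations[[i]]
    ids <- pathTermIds(a@path)
    expectedRoot <- .LEVEL_ROOTS[[a@level]]
    if (!identical(ids[1], expectedRoot))
      v <- rbind(v, .violation("BROKEN_PATH",
        sprintf("path must start at the %s root %s", a@level,
                expectedRoot), i))
    v <- rbind(v, checkChain(ids, i, "annotation path"))
    for (x in a@extraTermIds)
      if (!x %in% termIds(graph))
        v <- rbind(v, .violation("BROKEN_PATH",
          sprintf("unknown extra term %s", x), i))

    for (u in a@attributes) {
      known <- u$attributeId %in% termIds(graph)
      if (!known || !isAttributeTerm(graph, u$attributeId)) {
        v <- rbind(v, .violation("WRONG_BRANCH_ATTRIBUTE",
          sprintf("%s is not an attribute-branch term", u$attributeId), i))
        next
      }
      if (!u$modifiedTermId %in% ids) {
        v <- rbind(v, .violation("WRONG_BRANCH_ATTRIBUTE",
          sprintf("modified term %s is not on the annotation path",
                  u$modifiedTermId), i))
      } else {
        cat_ <- .termCategory(graph, u$modifiedTermId)
        if (!cat_ %in% c("structure", "property"))
          v <- rbind(v, .violation("WRONG_BRANCH_ATTRIBUTE",
            sprintf("attribute %s modifies a %s term (%s)", u$attributeId,
                    cat_, u$modifiedTermId), i))
      }
      needsPath <- attributeRequiresFullPath(graph, u$attributeId)
      hasPath <- !is.null(u$fullPath) && length(u$fullPath) > 0L
      if (needsPath && !hasPath)
        v <- rbind(v, .violation("MISSING_ATTRIBUTE_PATH",
          sprintf("interaction attribute %s requires its full path",
                  u$attributeId), i))
      if (!needsPath && hasPath)
        v <- rbind(v, .violation("SUPERFLUOUS_ATTRIBUTE_PATH",
          sprintf("single-sublevel attribute %s is used without a path",
                  u$attributeId), i))
      if (needsPath && hasPath)
        v <- rbind(v, checkChain(u$fullPath, i, "attribute path"))
    }
  }

  if (all(.MOLECULAR_LEVELS %in% set@levelsAffected)) {
    hasType <- function(lv) {
      any(vapply(set@annotations, function(a) {
        if (a@level != lv) return(FALSE)
        last <- utils::tail(pathTermIds(a@path), 1L)
        last %in% termIds(graph) &&
          .termCategory(graph, last) == "variation type"
      }, logical(1)))
    }
    for (lv in .MOLECULAR_LEVELS)
      if (!hasType(lv))
        v <- rbind(v, .violation("BELOW_MINIMUM",
          sprintf(paste0("variant changes all three levels but %s lacks a ",
                         "variation-type annotation"), lv)))
  }
  rownames(v) <- NULL
  v
}
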