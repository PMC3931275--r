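#' @include annotate.R
NULL

.termLine <- function(graph, id) sprintf("%s %s", id, termName(graph, id))

.renderText <- function(graph, set) {
  out <- character()
  out <- c(out, paste0("variant: ", hgvsFormat(set@variant)))
  if (nzchar(set@variant@referenceId))
    out <- c(out, paste0("reference: ", set@variant@referenceId))
  out <- c(out, paste0("ontology version: ", set@ontologyVersion))
  for (lv in names(set@referenceStates))
    out <- c(out, sprintf("reference state %s: %s", lv,
                          set@referenceStates[[lv]]))

  for (a in set@annotations) {
    out <- c(out, "")
    ids <- pathTermIds(a@path)
    for (id in ids) {
      line <- .termLine(graph, id)
      for (u in a@attributes) {
        if (identical(u$modifiedTermId, id) &&
            (is.null(u$fullPath) || length(u$fullPath) == 0L))
          line <- paste0(line, "; ", .termLine(graph, u$attributeId))
      }
      out <- c(out, line)
    }
    for (x in a@extraTermIds)
      out <- c(out, .termLine(graph, x))
    for (u in a@attributes) {
      if (!is.null(u$fullPath) && length(u$fullPath)) {
        out <- c(out, "")
        out <- c(out, vapply(u$fullPath, .termLine, character(1),
                             graph = graph, USE.NAMES = FALSE))
      }
    }
    for (e in a@evidence) {
      out <- c(out, "", sprintf("%s %s", e$ecoId, e$ecoName))
    }
    if (length(a@references))
      out <- c(out, paste0("references: ",
                           paste(a@references, collapse = "; ")))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

## Canonical list form of an AnnotationSet: the one JSON shape the package
## reads and writes. Kept strictly in step with .setFromList so that
## render -> parse -> render is byte-identical.
.setToList <- function(set) {
  list(
    ontology_version = set@ontologyVersion,
    variant = list(hgvs = hgvsFormat(set@variant),
                   reference_id = set@variant@referenceId),
    levels_affected = as.list(set@levelsAffected),
    reference_states = lapply(
      stats::setNames(names(set@referenceStates), names(set@referenceStates)),
      function(lv) set@referenceStates[[lv]]),
    annotations = lapply(set@annotations, function(a) {
      list(
        level = a@level,
        path = as.list(pathTermIds(a@path)),
        ambiguous_path = isAmbiguousPath(a@path),
        extra_terms = as.list(a@extraTermIds),
        attributes = lapply(a@attributes, function(u) {
          list(attribute_id = u$attributeId,
               modified_term_id = u$modifiedTermId,
               full_path = if (is.null(u$fullPath)) NULL
                           else as.list(u$fullPath))
        }),
        evidence = lapply(a@evidence, function(e) {
          list(eco_id = e$ecoId, eco_name = e$ecoName,
               linked_term_id = if (is.na(e$linkedTermId)) NULL
                                else e$linkedTermId)
        }),
        references = as.list(a@references))
    }))
}

.setFromList <- function(x) {
  variant <- parseHGVS(x$variant$hgvs,
                       referenceId = x$variant$reference_id %||% "")
  anns <- lapply(x$annotations, function(a) {
    new("Annotation",
        level = a$level,
        path = new("AnnotationPath",
                   termIds = as.character(unlist(a$path)),
                   ambiguous = isTRUE(a$ambiguous_path)),
        extraTermIds = as.character(unlist(a$extra_terms)),
        attributes = lapply(a$attributes, function(u) {
          list(attributeId = u$attribute_id,
               modifiedTermId = u$modified_term_id,
               fullPath = if (is.null(u$full_path)) NULL
                          else as.character(unlist(u$full_path)))
        }),
        evidence = lapply(a$evidence, function(e) {
          list(ecoId = e$eco_id, ecoName = e$eco_name,
               linkedTermId = e$linked_term_id %||% NA_character_)
        }),
        references = as.character(unlist(a$references)))
  })
  refStates <- unlist(x$reference_states) %||% character()
  AnnotationSet(variant, anns,
                referenceStates = if (is.null(refStates)) character()
                                  else refStates,
                ontologyVersion = x$ontology_version %||% "",
                levelsAffected = as.character(unlist(x$levels_affected)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.renderJSON <- function(set) {
  paste0(jsonlite::toJSON(.setToList(set), auto_unbox = TRUE, null = "null",
                          pretty = 2), "\n")
}

.renderTSV <- function(graph, set) {
  encodeAttr <- function(u) {
    p <- if (is.null(u$fullPath)) "" else paste(u$fullPath, collapse = ">")
    sprintf("%s@%s%s", u$attributeId, u$modifiedTermId,
            if (nzchar(p)) paste0(":", p) else "")
  }
  encodeEv <- function(e) {
    sprintf("%s@%s", e$ecoId,
            if (is.na(e$linkedTermId)) "" else e$linkedTermId)
  }
  header <- paste(c("variant", "level", "path", "extra_terms", "attributes",
                    "evidence", "references", "version"), collapse = "\t")
  rows <- vapply(set@annotations, function(a) {
    paste(c(hgvsFormat(set@variant),
            a@level,
            paste(pathTermIds(a@path), collapse = ">"),
            paste(a@extraTermIds, collapse = ","),
            paste(vapply(a@attributes, encodeAttr, character(1)),
                  collapse = ","),
            paste(vapply(a@evidence, encodeEv, character(1)),
                  collapse = ","),
            paste(a@references, collapse = ";"),
            set@ontologyVersion), collapse = "\t")
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Render an annotation set
#'
#' \code{text} reproduces the one-term-per-line annotation blocks of VariO
#' practice (\code{id name} lines from branch root to most specific term),
#' with single-sublevel attributes appended to the modified term's line
#' after \code{"; "}, interaction attributes as separate full-path blocks,
#' and evidence terms as flat \code{ECO:NNNNNNN name} lines after the block
#' they support. \code{json} and \code{tsv} carry the same content in
#' machine-readable form; JSON output re-parses losslessly with
#' \code{\link{parseAnnotationsJSON}}.
#'
#' @param set an \code{AnnotationSet}.
#' @param format "text", "json" or "tsv".
#' @param graph the \code{OntologyGraph} supplying term names (required for
#'   text and tsv).
#' @return the rendered document as a single string.
#' @export
renderAnnotations <- function(set, format = c("text", "json", "tsv"),
                              graph = NULL) {
  stopifnot(is(set, "AnnotationSet"))
  format <- match.arg(format)
  if (format %in% c("text", "tsv") && !is(graph, "OntologyGraph"))
    .annotateError("rendering as ", format, " requires the ontology graph")
  switch(format,
         text = .renderText(graph, set),
         json = .renderJSON(set),
         tsv = .renderTSV(graph, set))
}

#' Parse a JSON-rendered annotation set
#'
#' Inverse of \code{renderAnnotations(set, "json")}.
#'
#' @param x JSON text or a path to a JSON file.
#' @return an \code{\linkS4class{AnnotationSet}}.
#' @export
parseAnnotationsJSON <- function(x) {
  if (length(x) == 1L && !grepl("[{\n]", x) && file.exists(x))
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  .setFromList(jsonlite::fromJSON(x, simplifyVector = FALSE))
}
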