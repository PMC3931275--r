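#' @include AllGenerics.R
NULL

.newTerm <- function(id, name, def = "", parents = character(),
                     extra = character()) {
  list(id = id, name = name, def = def,
       parents = unique(as.character(parents)),
       extra = as.character(extra),
       placeholder = grepl("^VariO:9", id))
}

#' Construct an ontology graph from term records
#'
#' Low-level constructor used by \code{\link{parseOBO}} and
#' \code{\link{buildMiniOntology}}. Validity (id grammar, dangling parents,
#' acyclicity) is enforced on construction.
#'
#' @param terms list of term records as built by the OBO reader.
#' @param version free-text ontology version string.
#' @param headerExtra verbatim extra header lines to preserve.
#' @return an \code{\linkS4class{OntologyGraph}}.
#' @keywords internal
.OntologyGraph <- function(terms = list(), version = "",
                           headerExtra = character()) {
  names(terms) <- vapply(terms, `[[`, character(1), "id")
  new("OntologyGraph", terms = terms, version = version,
      headerExtra = headerExtra)
}

.checkTerm <- function(graph, id) {
  if (length(id) != 1L || !id %in% names(graph@terms))
    stop("unknown term id: ", paste(id, collapse = ", "), call. = FALSE)
  invisible(id)
}

#' Term ids of an ontology graph
#'
#' @param x an \code{OntologyGraph}.
#' @return character vector of term ids.
#' @aliases termIds,OntologyGraph-method
#' @rdname termIds
#' @export
setMethod("termIds", "OntologyGraph", function(x) names(x@terms))

#' Name of one term
#'
#' @param x an \code{OntologyGraph}.
#' @param id a term id.
#' @return the term's name.
#' @aliases termName,OntologyGraph-method
#' @rdname termName
#' @export
setMethod("termName", "OntologyGraph", function(x, id) {
  .checkTerm(x, id)
  x@terms[[id]]$name
})

#' Direct parents of one term
#'
#' @param x an \code{OntologyGraph}.
#' @param id a term id.
#' @return character vector of parent ids (is_a).
#' @aliases termParents,OntologyGraph-method
#' @rdname termParents
#' @export
setMethod("termParents", "OntologyGraph", function(x, id) {
  .checkTerm(x, id)
  x@terms[[id]]$parents
})

#' Ontology version string
#'
#' @param x an \code{OntologyGraph}.
#' @return the \code{data-version} string ("" if absent).
#' @aliases ontologyVersion,OntologyGraph-method
#' @rdname ontologyVersion
#' @export
setMethod("ontologyVersion", "OntologyGraph", function(x) x@version)

#' Roots (parentless terms) of an ontology graph
#'
#' @param x an \code{OntologyGraph}.
#' @return character vector of root ids.
#' @aliases ontologyRoots,OntologyGraph-method
#' @rdname ontologyRoots
#' @export
setMethod("ontologyRoots", "OntologyGraph", function(x) {
  ids <- names(x@terms)
  ids[vapply(x@terms, function(t) length(t$parents) == 0L, logical(1))]
})

#' Is a term a flagged placeholder?
#'
#' Placeholder terms carry reserved \code{VariO:9xxx} ids standing in for
#' concepts whose canonical ids are not bundled; their canonical ids bind
#' automatically through \code{\link{resolveName}} once a full ontology
#' release is loaded.
#'
#' @param graph an \code{OntologyGraph}.
#' @param id a term id.
#' @return logical.
#' @export
isPlaceholderTerm <- function(graph, id) {
  .checkTerm(graph, id)
  graph@terms[[id]]$placeholder
}

setMethod("show", "OntologyGraph", function(object) {
  cat(sprintf("OntologyGraph with %d terms, %d roots",
              length(object@terms), length(ontologyRoots(object))))
  if (nzchar(object@version))
    cat(sprintf(" (data-version: %s)", object@version))
  cat("\n")
  r <- ontologyRoots(object)
  if (length(r))
    cat("  roots:",
        paste(sprintf("%s [%s]", r,
                      vapply(r, function(i) object@terms[[i]]$name,
                             character(1))),
              collapse = ", "), "\n")
})

#' @rdname pathTermIds
#' @aliases pathTermIds,AnnotationPath-method
#' @param x an \code{AnnotationPath}.
#' @export
setMethod("pathTermIds", "AnnotationPath", function(x) x@termIds)

#' Term ids / ambiguity flag of an annotation path
#'
#' @aliases isAmbiguousPath,AnnotationPath-method
#' @rdname pathTermIds
#' @export
setMethod("isAmbiguousPath", "AnnotationPath", function(x) x@ambiguous)

setMethod("show", "AnnotationPath", function(object) {
  cat("AnnotationPath:", paste(object@termIds, collapse = " > "))
  if (object@ambiguous) cat("  [ambiguous lineage]")
  cat("\n")
})

## ---------------------------------------------------------------------------
## OBO 1.2 reading and writing (is_a only; other tags preserved opaquely)
## ---------------------------------------------------------------------------

#' Parse an OBO 1.2 document into an ontology graph
#'
#' Honors \code{format-version}, \code{data-version}, \code{[Term]} stanzas
#' and their \code{id}, \code{name}, \code{def} and \code{is_a} tags;
#' trailing \code{! comment} tails on \code{is_a} lines are stripped. All
#' other tag lines are preserved verbatim and re-emitted by
#' \code{\link{writeOBO}}. Non-\code{[Term]} stanzas are ignored.
#'
#' @param x path to an OBO file, or a character vector of OBO lines (a
#'   single string may contain embedded newlines).
#' @return an \code{\linkS4class{OntologyGraph}}.
#' @examples
#' g <- parseOBO(c("format-version: 1.2", "", "[Term]",
#'                 "id: VariO:0136", "name: DNA substitution",
#'                 "is_a: VariO:0135 ! DNA chain variation", "", "[Term]",
#'                 "id: VariO:0135", "name: DNA chain variation"))
#' termParents(g, "VariO:0136")
#' @export
parseOBO <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    lines <- readLines(x, warn = FALSE)
  else
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("\r$", "", lines)

  stanzaStarts <- grep("^\\[.*\\]\\s*$", lines)
  headerEnd <- if (length(stanzaStarts)) stanzaStarts[1] - 1L else length(lines)
  header <- lines[seq_len(headerEnd)]

  version <- ""
  headerExtra <- character()
  for (h in header) {
    if (grepl("^data-version:", h))
      version <- trimws(sub("^data-version:", "", h))
    else if (!grepl("^format-version:", h) && nzchar(trimws(h)))
      headerExtra <- c(headerExtra, h)
  }

  terms <- list()
  i <- 1L
  while (i <= length(stanzaStarts)) {
    from <- stanzaStarts[i] + 1L
    to <- if (i < length(stanzaStarts)) stanzaStarts[i + 1L] - 1L else length(lines)
    stanzaType <- trimws(lines[stanzaStarts[i]])
    i <- i + 1L
    if (stanzaType != "[Term]") next
    body <- lines[seq(from, length.out = max(0L, to - from + 1L))]
    body <- body[nzchar(trimws(body))]

    id <- NULL; nm <- NULL; def <- ""; parents <- character(); extra <- character()
    for (ln in body) {
      tag <- sub(":.*$", "", ln)
      val <- trimws(sub("^[^:]+:", "", ln))
      if (tag == "id") id <- val
      else if (tag == "name") nm <- val
      else if (tag == "def") {
        ## strip surrounding quotes and trailing dbxref bracket
        d <- sub("\\s*\\[[^]]*\\]\\s*$", "", val)
        def <- gsub("^\"|\"$", "", d)
      } else if (tag == "is_a") {
        parents <- c(parents, trimws(sub("!.*$", "", val)))
      } else extra <- c(extra, ln)
    }
    if (is.null(id) || is.null(nm) || !nzchar(id) || !nzchar(nm))
      stop("malformed [Term] stanza: missing id or name", call. = FALSE)
    if (id %in% names(terms))
      stop("duplicate term id: ", id, call. = FALSE)
    terms[[id]] <- .newTerm(id, nm, def, parents, extra)
  }
  ## validity catches dangling is_a references and cycles
  .OntologyGraph(terms, version, headerExtra)
}

#' Serialize an ontology graph as an OBO 1.2 document
#'
#' Terms are emitted in ascending id order; \code{parseOBO(writeOBO(g))}
#' reproduces \code{g} term for term (ids, names, definitions, parent sets).
#'
#' @param graph an \code{OntologyGraph}.
#' @param file optional path; when given the document is also written there.
#' @return the document as a single string, invisibly when \code{file} is
#'   given.
#' @export
writeOBO <- function(graph, file = NULL) {
  stopifnot(is(graph, "OntologyGraph"))
  out <- c("format-version: 1.2")
  if (nzchar(graph@version))
    out <- c(out, paste0("data-version: ", graph@version))
  out <- c(out, graph@headerExtra)
  for (id in sort(names(graph@terms))) {
    t <- graph@terms[[id]]
    out <- c(out, "", "[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (nzchar(t$def))
      out <- c(out, sprintf("def: \"%s\" []", t$def))
    for (p in sort(t$parents))
      out <- c(out, sprintf("is_a: %s ! %s", p, graph@terms[[p]]$name))
    out <- c(out, t$extra)
  }
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(doc, file, sep = "")
    return(invisible(doc))
  }
  doc
}

## ---------------------------------------------------------------------------
## Structural queries
## ---------------------------------------------------------------------------

#' All ancestors of a term
#'
#' Transitive closure over is_a parents, excluding the term itself.
#'
#' @param graph an \code{OntologyGraph}.
#' @param id a term id.
#' @return character vector of ancestor ids (unordered).
#' @export
termAncestors <- function(graph, id) {
  .checkTerm(graph, id)
  seen <- character()
  frontier <- graph@terms[[id]]$parents
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(frontier, function(p) graph@terms[[p]]$parents),
                    use.names = FALSE)),
      seen)
  }
  seen
}

## All root->id chains that start at `root`, as a list of character vectors.
.allChains <- function(graph, id, root) {
  if (id == root) return(list(id))
  out <- list()
  for (p in graph@terms[[id]]$parents) {
    for (ch in .allChains(graph, p, root))
      out[[length(out) + 1L]] <- c(ch, id)
  }
  out
}

#' Expand a term to its full root-to-term path
#'
#' Implements the full-path annotation rule: every assigned term is reported
#' as the complete chain from its branch root down, so that the annotation
#' is unambiguous without the ontology at hand. Terms with several lineages
#' under the same root (the ontology shares e.g. the transition subtree
#' between the DNA and RNA substitution branches) are resolved to the
#' lexicographically smallest id sequence and flagged ambiguous.
#'
#' @param graph an \code{OntologyGraph}.
#' @param id id of the most specific term to report.
#' @param levelRoot id of the branch root the path must pass through; must
#'   be a root of the graph.
#' @return an \code{\linkS4class{AnnotationPath}}.
#' @examples
#' g <- buildMiniOntology()
#' pathTermIds(expandFullPath(g, "VariO:0314", "VariO:0128"))
#' @export
expandFullPath <- function(graph, id, levelRoot) {
  .checkTerm(graph, id)
  .checkTerm(graph, levelRoot)
  if (length(graph@terms[[levelRoot]]$parents))
    stop("levelRoot ", levelRoot, " is not a root of the graph", call. = FALSE)
  chains <- .allChains(graph, id, levelRoot)
  if (length(chains) == 0L)
    stop("term ", id, " is not reachable from root ", levelRoot,
         call. = FALSE)
  if (length(chains) > 1L) {
    keys <- vapply(chains, function(ch) paste(ch, collapse = "\r"),
                   character(1))
    chains <- chains[order(keys)]
  }
  new("AnnotationPath", termIds = chains[[1L]],
      ambiguous = length(chains) > 1L)
}

#' Does a term belong to the attribute branch?
#'
#' Attributes (quantity change, conservation, pathogenicity association,
#' interaction) are modifier terms living under the attribute root
#' VariO:0232; they modify structure and property annotations rather than
#' standing alone.
#'
#' @param graph an \code{OntologyGraph}.
#' @param id a term id.
#' @return \code{TRUE} iff \code{id} is the attribute root or one of its
#'   descendants.
#' @export
isAttributeTerm <- function(graph, id) {
  .checkTerm(graph, id)
  root <- .LEVEL_ROOTS[["attribute"]]
  id == root || root %in% termAncestors(graph, id)
}

#' Must an attribute be reported with its full path?
#'
#' Interaction attributes span several sublevels and are therefore reported
#' as full chains from the attribute root; conservation, pathogenicity
#' association and quantity-change attributes have a single sublevel and are
#' used without a path.
#'
#' @param graph an \code{OntologyGraph}.
#' @param id an attribute-branch term id.
#' @return logical.
#' @export
attributeRequiresFullPath <- function(graph, id) {
  if (!isAttributeTerm(graph, id))
    stop("term ", id, " is not in the attribute branch", call. = FALSE)
  interaction <- .resolveNameOrNA(graph, "interaction")
  if (is.na(interaction)) return(FALSE)
  id == interaction || interaction %in% termAncestors(graph, id)
}

#' Longest root-to-leaf chain, in terms
#'
#' @param graph an acyclic \code{OntologyGraph}.
#' @return integer: the number of terms on the deepest chain (0 for an
#'   empty graph).
#' @export
maxDepth <- function(graph) {
  stopifnot(is(graph, "OntologyGraph"))
  if (length(graph@terms) == 0L) return(0L)
  depth <- new.env(parent = emptyenv())
  depthOf <- function(id) {
    if (!is.null(depth[[id]])) return(depth[[id]])
    ps <- graph@terms[[id]]$parents
    d <- if (length(ps) == 0L) 1L
         else 1L + max(vapply(ps, depthOf, integer(1)))
    depth[[id]] <- d
    d
  }
  max(vapply(names(graph@terms), depthOf, integer(1)))
}

.resolveNameOrNA <- function(graph, name) {
  nms <- vapply(graph@terms, `[[`, character(1), "name")
  hit <- names(graph@terms)[tolower(nms) == tolower(name)]
  if (length(hit) == 1L) hit else NA_character_
}

#' Resolve a term name to its id
#'
#' Case-insensitive exact-match lookup. Classification emits canonical
#' concept names; resolving them against whatever ontology file is loaded
#' lets canonical ids replace bundled placeholders automatically.
#'
#' @param graph an \code{OntologyGraph}.
#' @param name a term name.
#' @return the term id.
#' @export
resolveName <- function(graph, name) {
  nms <- vapply(graph@terms, `[[`, character(1), "name")
  hit <- names(graph@terms)[tolower(nms) == tolower(name)]
  if (length(hit) == 0L)
    stop("name not found in ontology: '", name, "'", call. = FALSE)
  if (length(hit) > 1L)
    stop("ambiguous name '", name, "' (matches ",
         paste(hit, collapse = ", "), ")", call. = FALSE)
  hit
}

## Coarse category of a term, by the named sub-branch roots of its level.
## Names rather than hard-coded ids so the rule survives loading a fuller
## ontology release. Returns one of "variation type", "function",
## "structure", "property", "origin", "attribute", "root", "other".
.termCategory <- function(graph, id) {
  .checkTerm(graph, id)
  if (isAttributeTerm(graph, id)) return("attribute")
  lineage <- c(id, termAncestors(graph, id))
  nms <- tolower(vapply(lineage, function(i) graph@terms[[i]]$name,
                        character(1)))
  if (any(grepl("variation origin$", nms))) return("origin")
  if (any(grepl("variation type$", nms))) return("variation type")
  if (any(grepl("^variation affecting .*function$", nms))) return("function")
  if (any(grepl("^variation affecting .*structure$", nms))) return("structure")
  if (any(grepl("^variation affecting .*property$", nms))) return("property")
  if (id %in% unname(.LEVEL_ROOTS)) return("root")
  "other"
}
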