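#' @include AllClasses.R
NULL

#' @rdname termIds
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname termName
#' @export
setGeneric("termName", function(x, id) standardGeneric("termName"))

#' @rdname termParents
#' @export
setGeneric("termParents", function(x, id) standardGeneric("termParents"))

#' @rdname ontologyVersion
#' @export
setGeneric("ontologyVersion", function(x) standardGeneric("ontologyVersion"))

#' @rdname ontologyRoots
#' @export
setGeneric("ontologyRoots", function(x) standardGeneric("ontologyRoots"))

#' @rdname pathTermIds
#' @export
setGeneric("pathTermIds", function(x) standardGeneric("pathTermIds"))

#' @rdname pathTermIds
#' @export
setGeneric("isAmbiguousPath", function(x) standardGeneric("isAmbiguousPath"))

#' @rdname annotations
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
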