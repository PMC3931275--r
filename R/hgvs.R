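#' @include ontology.R
NULL

.AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
          Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
          Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
          Tyr = "Y", Val = "V", Ter = "*")

.hgvsError <- function(...) {
  stop(structure(class = c("hgvsParseError", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Normalize an RNA allele character
#'
#' HGVS r. descriptions are written in lowercase with \code{u}. The base is
#' uppercased; \code{U} is preserved as \code{U} and \code{T} is accepted
#' but kept distinct, so classification can treat U and T as the same
#' chemical class while rendering keeps the letter that was given.
#'
#' @param base a single nucleotide character.
#' @return the uppercase base.
#' @export
normalizeRnaAllele <- function(base) {
  if (length(base) != 1L || !grepl("^[acguACGUTt]$", base))
    .hgvsError("invalid RNA nucleotide: '", base, "'")
  toupper(base)
}

#' Convert an amino-acid code to its 1-letter form
#'
#' Maps the 20 standard residues from 1- or 3-letter codes (3-letter codes
#' case-insensitively); \code{Ter} and \code{*} map to the stop sentinel
#' \code{"*"}.
#'
#' @param code a residue code.
#' @return single 1-letter residue, or \code{"*"} for stop.
#' @export
residueFromCode <- function(code) {
  if (length(code) != 1L || !nzchar(code))
    .hgvsError("empty residue code")
  if (code == "*") return("*")
  if (nchar(code) == 1L) {
    up <- toupper(code)
    if (up %in% .AA3) return(up)
    .hgvsError("unknown residue code: '", code, "'")
  }
  key <- paste0(toupper(substr(code, 1, 1)), tolower(substr(code, 2, 3)))
  if (nchar(code) == 3L && key %in% names(.AA3)) return(unname(.AA3[key]))
  .hgvsError("unknown residue code: '", code, "'")
}

.residueSeqFromText <- function(text) {
  ## A run of 3-letter codes (LeuPro) or of 1-letter codes (LP).
  if (grepl("^([A-Z][a-z]{2})+$", text)) {
    starts <- seq(1L, nchar(text), by = 3L)
    paste(vapply(starts, function(i)
      residueFromCode(substr(text, i, i + 2L)), character(1)), collapse = "")
  } else if (grepl("^[A-Za-z*]+$", text)) {
    paste(vapply(strsplit(text, "")[[1]], residueFromCode, character(1)),
          collapse = "")
  } else .hgvsError("invalid residue text: '", text, "'")
}

.newVariant <- function(referenceId = "", level, kind, start, end = start,
                        refAllele = "", altAllele = "", refResidues = "",
                        altResidues = "") {
  new("VariantDescription", referenceId = referenceId, level = level,
      kind = kind, start = as.integer(start), end = as.integer(end),
      refAllele = refAllele, altAllele = altAllele,
      refResidues = refResidues, altResidues = altResidues)
}

#' Parse an HGVS variant description
#'
#' Recognizes the classification-relevant HGVS subset, optionally prefixed
#' with a reference accession (\code{ACC:}):
#' \itemize{
#'   \item nucleotide substitutions \code{g./c./n.<pos><ref>><alt>} and
#'     \code{r.<pos><ref>><alt>} (lowercase, \code{u}); whitespace around
#'     the description is tolerated (the worked example prints
#'     \code{g.4789 T > C}) and never re-emitted;
#'   \item \code{<start>_<end>del[seq]}, \code{<pos>_<pos+1>ins<seq>},
#'     \code{<start>_<end>dup}, \code{<start>_<end>delins<seq>} at the
#'     nucleotide levels (single-position \code{del}/\code{dup}/\code{delins}
#'     also accepted);
#'   \item protein substitutions \code{p.<Ref3><pos><Alt3>} or 1-letter,
#'     with \code{Ter}/\code{*} (nonsense) and \code{=} (synonymous)
#'     alternates, and protein \code{del}/\code{dup}/\code{delins} ranges.
#' }
#' Intronic offsets, frameshifts and extensions are outside the supported
#' subset and rejected with an explicit error.
#'
#' @param text the HGVS description.
#' @param referenceId optional accession; overrides any \code{ACC:} prefix
#'   found in \code{text}.
#' @return a \code{\linkS4class{VariantDescription}}.
#' @examples
#' parseHGVS("g.4789 T > C")
#' parseHGVS("p.Leu28Pro")
#' @export
parseHGVS <- function(text, referenceId = NULL) {
  if (length(text) != 1L || !nzchar(text))
    .hgvsError("empty HGVS description")
  s <- gsub("[[:space:]]+", "", text)

  acc <- ""
  m <- regmatches(s, regexec("^([^:]+):([gcnrp]\\..*)$", s))[[1]]
  if (length(m)) { acc <- m[2]; s <- m[3] }
  if (!is.null(referenceId)) acc <- referenceId

  if (!grepl("^[gcnrp]\\.", s))
    .hgvsError("unsupported HGVS syntax: '", text, "'")
  level <- substr(s, 1, 1)
  body <- substr(s, 3, nchar(s))

  if (grepl("fs", body) || grepl("ext", body) || grepl("[0-9][+-][0-9]", body))
    .hgvsError("unsupported HGVS subset: '", text, "'")

  if (level == "p") return(.parseProtein(acc, body, text))

  upperBody <- if (level == "r") body else body  # keep case for r. checks
  nucRe <- if (level == "r") "[acgut]" else "[ACGT]"

  ## substitution: <pos><ref>><alt>
  m <- regmatches(body, regexec(
    sprintf("^([0-9]+)(%s)>(%s)$", nucRe, nucRe), body))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2])
    if (pos < 1L) .hgvsError("position must be >= 1")
    ref <- if (level == "r") normalizeRnaAllele(m[3]) else m[3]
    alt <- if (level == "r") normalizeRnaAllele(m[4]) else m[4]
    if (ref == alt)
      .hgvsError("substitution with identical reference and alternate ('",
                 text, "')")
    return(.newVariant(acc, level, "substitution", pos,
                       refAllele = ref, altAllele = alt))
  }

  seqRe <- if (level == "r") "[acgut]*" else "[ACGT]*"
  normSeq <- function(x) {
    if (!nzchar(x)) return("")
    if (level == "r")
      paste(vapply(strsplit(x, "")[[1]], normalizeRnaAllele, character(1)),
            collapse = "")
    else x
  }

  ## delins before del (longest keyword first)
  m <- regmatches(body, regexec(
    sprintf("^([0-9]+)(?:_([0-9]+))?delins(%s)$", sub("\\*$", "+", seqRe)),
    body))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    if (end < start) .hgvsError("end before start in '", text, "'")
    return(.newVariant(acc, level, "delins", start, end,
                       altAllele = normSeq(m[4])))
  }
  m <- regmatches(body, regexec(
    sprintf("^([0-9]+)(?:_([0-9]+))?del(%s)$", seqRe), body))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    if (end < start) .hgvsError("end before start in '", text, "'")
    return(.newVariant(acc, level, "deletion", start, end,
                       refAllele = normSeq(m[4])))
  }
  m <- regmatches(body, regexec(
    sprintf("^([0-9]+)_([0-9]+)ins(%s)$", sub("\\*$", "+", seqRe)),
    body))[[1]]
  if (length(m)) {
    start <- as.integer(m[2]); end <- as.integer(m[3])
    if (end != start + 1L)
      .hgvsError("insertion must use flanking positions pos_pos+1 ('",
                 text, "')")
    return(.newVariant(acc, level, "insertion", start, end,
                       altAllele = normSeq(m[4])))
  }
  m <- regmatches(body, regexec("^([0-9]+)(?:_([0-9]+))?dup$", body))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    if (end < start) .hgvsError("end before start in '", text, "'")
    return(.newVariant(acc, level, "duplication", start, end))
  }

  .hgvsError("unsupported HGVS syntax: '", text, "'")
}

.P_RES <- "(Ter|[A-Z][a-z]{2}|[A-Z*])"

.parseProtein <- function(acc, body, text) {
  ## substitution incl. nonsense (Ter/*) and synonymous (=)
  m <- regmatches(body, regexec(
    paste0("^", .P_RES, "([0-9]+)(=|Ter|[A-Z][a-z]{2}|[A-Z*])$"), body))[[1]]
  if (length(m)) {
    pos <- as.integer(m[3])
    if (pos < 1L) .hgvsError("position must be >= 1")
    ref <- residueFromCode(m[2])
    if (ref == "*") .hgvsError("reference residue may not be a stop")
    alt <- if (m[4] == "=") "=" else residueFromCode(m[4])
    if (identical(ref, alt))
      .hgvsError("substitution with identical residues ('", text, "')")
    return(.newVariant(acc, "p", "substitution", pos,
                       refResidues = ref, altResidues = alt))
  }

  rangeRe <- paste0("^", .P_RES, "([0-9]+)_", .P_RES, "([0-9]+)")
  m <- regmatches(body, regexec(
    paste0(rangeRe, "delins(([A-Z][a-z]{2})+|[A-Z]+)$"), body))[[1]]
  if (length(m)) {
    start <- as.integer(m[3]); end <- as.integer(m[5])
    if (end < start) .hgvsError("end before start in '", text, "'")
    ref <- paste0(residueFromCode(m[2]), residueFromCode(m[4]))
    return(.newVariant(acc, "p", "delins", start, end,
                       refResidues = ref,
                       altResidues = .residueSeqFromText(m[6])))
  }
  m <- regmatches(body, regexec(paste0(rangeRe, "(del|dup)$"), body))[[1]]
  if (length(m)) {
    start <- as.integer(m[3]); end <- as.integer(m[5])
    if (end < start) .hgvsError("end before start in '", text, "'")
    kind <- if (m[6] == "del") "deletion" else "duplication"
    return(.newVariant(acc, "p", kind, start, end,
                       refResidues = paste0(residueFromCode(m[2]),
                                            residueFromCode(m[4]))))
  }
  m <- regmatches(body, regexec(paste0("^", .P_RES, "([0-9]+)del$"),
                                body))[[1]]
  if (length(m)) {
    return(.newVariant(acc, "p", "deletion", as.integer(m[3]),
                       refResidues = residueFromCode(m[2])))
  }
  .hgvsError("unsupported HGVS syntax: '", text, "'")
}

#' Serialize a variant description as compact canonical HGVS
#'
#' The inverse of \code{\link{parseHGVS}} on its supported subset: no
#' whitespace, RNA alleles in lowercase with \code{u}, protein residues in
#' 3-letter codes. \code{parseHGVS(hgvsFormat(v))} reproduces \code{v}.
#'
#' @param variant a \code{VariantDescription}.
#' @param withReference prepend \code{referenceId:} when present.
#' @return a single HGVS string.
#' @export
hgvsFormat <- function(variant, withReference = FALSE) {
  stopifnot(is(variant, "VariantDescription"))
  v <- variant
  lv <- v@level
  rna <- function(x) if (lv == "r") tolower(x) else x
  aa3 <- function(res1) {
    vapply(strsplit(res1, "")[[1]], function(r) {
      if (r == "*") "Ter" else names(.AA3)[match(r, .AA3)]
    }, character(1))
  }
  body <- if (lv != "p") {
    switch(v@kind,
      substitution = sprintf("%d%s>%s", v@start, rna(v@refAllele),
                             rna(v@altAllele)),
      deletion = if (v@start == v@end && !nzchar(v@refAllele))
          sprintf("%ddel", v@start)
        else sprintf("%d_%ddel%s", v@start, v@end, rna(v@refAllele)),
      insertion = sprintf("%d_%dins%s", v@start, v@end, rna(v@altAllele)),
      duplication = if (v@start == v@end) sprintf("%ddup", v@start)
        else sprintf("%d_%ddup", v@start, v@end),
      delins = sprintf("%d_%ddelins%s", v@start, v@end, rna(v@altAllele)))
  } else {
    refs <- aa3(v@refResidues)
    switch(v@kind,
      substitution = sprintf("%s%d%s", refs[1], v@start,
                             if (v@altResidues == "=") "="
                             else aa3(v@altResidues)[1]),
      deletion = if (v@start == v@end)
          sprintf("%s%ddel", refs[1], v@start)
        else sprintf("%s%d_%s%ddel", refs[1], v@start, refs[2], v@end),
      duplication = sprintf("%s%d_%s%ddup", refs[1], v@start, refs[2], v@end),
      delins = sprintf("%s%d_%s%ddelins%s", refs[1], v@start, refs[2],
                       v@end, paste(aa3(v@altResidues), collapse = "")))
  }
  out <- paste0(lv, ".", body)
  if (withReference && nzchar(v@referenceId))
    out <- paste0(v@referenceId, ":", out)
  out
}

setMethod("show", "VariantDescription", function(object) {
  cat(sprintf("VariantDescription: %s (%s-level %s)\n",
              hgvsFormat(object, withReference = TRUE),
              object@level, object@kind))
})
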