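#' @include hgvs.R
NULL

.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T", "U")

.classifyError <- function(...) {
  stop(structure(class = c("classifyError", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

## Most specific chain-variation concept per (kind, level). delins maps to
## the indel concept of the level.
.CHAIN_CONCEPTS <- list(
  DNA = c(substitution = "DNA substitution", deletion = "DNA deletion",
          insertion = "DNA insertion", duplication = "DNA duplication",
          delins = "DNA indel"),
  RNA = c(substitution = "RNA substitution", deletion = "RNA deletion",
          insertion = "RNA insertion", duplication = "RNA duplication",
          delins = "RNA indel"),
  protein = c(substitution = "amino acid substitution",
              deletion = "amino acid deletion",
              insertion = "amino acid insertion",
              duplication = "amino acid duplication",
              delins = "amino acid indel"))

#' Classify a single-nucleotide substitution
#'
#' Orders the substitution into its chemical classes: every substitution is
#' a transition when both bases are purines (A, G) or both pyrimidines
#' (C, T/U) and a transversion otherwise; transitions are further split into
#' purine and pyrimidine transitions. U is treated as T for chemical
#' classing.
#'
#' @param ref,alt single nucleotide characters, \code{ref != alt} (U and T
#'   count as the same base).
#' @return ordered character vector of concept names, general first:
#'   \code{c("substitution", "transition"|"transversion", ...)}.
#' @examples
#' classifyNucleotideSubstitution("T", "C")
#' @export
classifyNucleotideSubstitution <- function(ref, alt) {
  chem <- function(b) {
    b <- toupper(b)
    if (!b %in% c(.PURINES, .PYRIMIDINES))
      .classifyError("invalid nucleotide: '", b, "'")
    if (b %in% .PURINES) "purine" else "pyrimidine"
  }
  canon <- function(b) sub("U", "T", toupper(b))
  cr <- chem(ref); ca <- chem(alt)
  if (canon(ref) == canon(alt))
    .classifyError("substitution with identical bases ('", ref, "')")
  if (cr == ca)
    c("substitution", "transition", paste(cr, "transition"))
  else
    c("substitution", "transversion")
}

#' Chain-variation concepts for a variation kind at one level
#'
#' Returns the level-appropriate chain-variation concept sequence for a
#' variation kind, most specific last; delins maps to the level's indel
#' concept. At the DNA level the chain passes through the explicit "DNA
#' chain variation" concept of the ontology.
#'
#' @param kind one of substitution, deletion, insertion, duplication,
#'   delins.
#' @param level DNA, RNA or protein.
#' @return ordered character vector of concept names.
#' @examples
#' classifyChainVariation("substitution", "DNA")
#' classifyChainVariation("delins", "protein")
#' @export
classifyChainVariation <- function(kind, level) {
  if (!level %in% names(.CHAIN_CONCEPTS))
    .classifyError("unknown molecular level: '", level, "'")
  tbl <- .CHAIN_CONCEPTS[[level]]
  if (!kind %in% names(tbl))
    .classifyError("unsupported variation kind '", kind, "' at level ",
                   level)
  specific <- unname(tbl[[kind]])
  if (level == "DNA") c("DNA chain variation", specific) else specific
}

#' Coding consequence of a residue replacement
#'
#' @param refResidue,altResidue 1-letter residues; \code{"*"} is the stop
#'   sentinel.
#' @return concept name: \code{"synonymous variation"} when the residue is
#'   unchanged, \code{"nonsense variation"} when a stop is introduced,
#'   \code{"missense variation"} otherwise. Replacements of a stop (stop
#'   loss) are outside the concept table and rejected.
#' @examples
#' codingConsequence("L", "P")
#' @export
codingConsequence <- function(refResidue, altResidue) {
  ok <- function(r) length(r) == 1L && (r == "*" || r %in% .AA3)
  if (!ok(refResidue) || !ok(altResidue))
    .classifyError("invalid residue code")
  if (refResidue == altResidue) return("synonymous variation")
  if (refResidue == "*")
    .classifyError("unsupported consequence: replacement of a stop codon")
  if (altResidue == "*") return("nonsense variation")
  "missense variation"
}

#' Translate a codon under the standard genetic code
#'
#' @param codon 3 bases; U and T are equivalent.
#' @return 1-letter residue or \code{"*"} for a stop codon.
#' @examples
#' translateCodon("CUG")
#' @export
translateCodon <- function(codon) {
  if (length(codon) != 1L || nchar(codon) != 3L)
    .classifyError("codon must be exactly 3 bases")
  key <- gsub("U", "T", toupper(codon))
  if (!grepl("^[ACGT]{3}$", key))
    .classifyError("invalid base in codon '", codon, "'")
  unname(Biostrings::GENETIC_CODE[key])
}

#' Coding consequence of a single-base codon substitution
#'
#' Translates the original and substituted codon and delegates to
#' \code{\link{codingConsequence}}.
#'
#' @param codon the reference codon (3 bases, U or T).
#' @param offset 0-based position of the substituted base within the codon
#'   (0..2).
#' @param altBase the alternate base.
#' @return a consequence concept name.
#' @examples
#' consequenceFromCodon("CUG", 1, "C")  # CUG -> CCG, L -> P: missense
#' @export
consequenceFromCodon <- function(codon, offset, altBase) {
  if (length(offset) != 1L || is.na(offset) || !offset %in% 0:2)
    .classifyError("offset must be 0, 1 or 2")
  ref <- translateCodon(codon)
  alt <- toupper(altBase)
  if (!alt %in% c("A", "C", "G", "T", "U"))
    .classifyError("invalid alternate base '", altBase, "'")
  bases <- strsplit(toupper(codon), "")[[1]]
  if (gsub("U", "T", bases[offset + 1L]) == gsub("U", "T", alt))
    .classifyError("alternate base equals the reference base at offset ",
                   offset)
  bases[offset + 1L] <- alt
  codingConsequence(ref, translateCodon(paste(bases, collapse = "")))
}

#' Origin concept for a molecular level
#'
#' Variants derived from changes in DNA carry genetic-origin concepts;
#' changes not originating from DNA (e.g. RNA editing, post-translational
#' or engineered changes) are annotated as variation of non-genetic origin
#' at the DNA level and as variation emerging at the RNA or protein level.
#'
#' @param level DNA, RNA or protein.
#' @param origin \code{"genetic"} or \code{"non_genetic"}.
#' @return a concept name.
#' @examples
#' originConcept("DNA", "genetic")
#' originConcept("protein", "non_genetic")
#' @export
originConcept <- function(level, origin = c("genetic", "non_genetic")) {
  origin <- match.arg(origin)
  if (!level %in% .MOLECULAR_LEVELS)
    .classifyError("unknown molecular level: '", level, "'")
  if (origin == "genetic")
    paste(level, "variation of genetic origin")
  else switch(level,
    DNA = "DNA variation of non-genetic origin",
    RNA = "variation emerging at RNA level",
    protein = "variation emerging at protein level")
}

#' Classify a parsed variant into VariO concepts per molecular level
#'
#' Populates the molecular levels on which the description carries
#' information: DNA for \code{g.}/\code{c.}/\code{n.} input, RNA for
#' \code{r.} input and derived from coding-level input when a protein
#' change or codon context is supplied, protein for \code{p.} input or a
#' supplied protein change. Each populated level receives the ordered
#' variation-type concepts (general to most specific) plus the level's
#' origin concept; levels without information stay absent, consistent with
#' annotating only where changes appear. Coding consequences (missense,
#' nonsense, synonymous) are attached at the RNA level.
#'
#' @param desc a \code{VariantDescription}.
#' @param origin \code{"genetic"} or \code{"non_genetic"}.
#' @param proteinChange optional \code{c(ref, alt)} 1-letter residues (or
#'   \code{"*"}) stating the protein-level change of a nucleotide variant.
#' @param codonContext optional list \code{list(codon=, offset=)} giving the
#'   reference codon and 0-based offset of the substituted base; used to
#'   derive the consequence when no protein change is stated. When both are
#'   supplied they must agree; contradictions are an error, not a
#'   preference.
#' @return a \code{\linkS4class{ClassificationResult}}.
#' @examples
#' classifyVariant(parseHGVS("g.4789T>C"), "genetic",
#'                 proteinChange = c("L", "P"))
#' @export
classifyVariant <- function(desc, origin = c("genetic", "non_genetic"),
                            proteinChange = NULL, codonContext = NULL) {
  stopifnot(is(desc, "VariantDescription"))
  origin <- match.arg(origin)
  validObject(desc)

  perLevel <- list()
  lv <- desc@level

  subConcepts <- NULL
  if (desc@kind == "substitution" && lv != "p")
    subConcepts <- classifyNucleotideSubstitution(desc@refAllele,
                                                  desc@altAllele)[-1L]

  consequence <- NULL
  if (!is.null(codonContext)) {
    if (desc@kind != "substitution" || lv == "p")
      .classifyError("codon context applies to nucleotide substitutions only")
    consequence <- consequenceFromCodon(codonContext$codon,
                                        codonContext$offset,
                                        desc@altAllele)
  }
  if (!is.null(proteinChange)) {
    if (length(proteinChange) != 2L)
      .classifyError("proteinChange must be c(ref, alt)")
    pc <- codingConsequence(proteinChange[1], proteinChange[2])
    if (!is.null(consequence) && !identical(pc, consequence))
      .classifyError("stated protein change (", pc,
                     ") contradicts the codon context (", consequence, ")")
    consequence <- pc
  }

  if (lv %in% c("g", "c", "n")) {
    perLevel$DNA <- c(classifyChainVariation(desc@kind, "DNA"), subConcepts)
    if (!is.null(consequence)) {
      perLevel$RNA <- c(classifyChainVariation(desc@kind, "RNA"),
                        subConcepts, consequence)
      perLevel$protein <- classifyChainVariation("substitution", "protein")
    }
  } else if (lv == "r") {
    perLevel$RNA <- c(classifyChainVariation(desc@kind, "RNA"), subConcepts,
                      consequence)
  } else {  # protein-level description
    if (identical(desc@altResidues, "="))
      .classifyError("synonymous protein description carries no ",
                     "protein-level change to classify")
    perLevel$protein <- classifyChainVariation(desc@kind, "protein")
  }

  originConcepts <- vapply(names(perLevel), originConcept,
                           character(1), origin = origin)
  new("ClassificationResult", perLevel = perLevel,
      originConcepts = originConcepts)
}

setMethod("show", "ClassificationResult", function(object) {
  cat("ClassificationResult\n")
  for (lv in names(object@perLevel)) {
    cat(sprintf("  %s: %s\n", lv,
                paste(object@perLevel[[lv]], collapse = " > ")))
    if (lv %in% names(object@originConcepts))
      cat(sprintf("  %s origin: %s\n", lv, object@originConcepts[[lv]]))
  }
})
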