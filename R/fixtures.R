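#' @include render.R
NULL

## Term table of the bundled mini ontology. Non-placeholder rows carry ids
## and names exactly as printed in VariO annotation practice; parent links
## follow the printed block orderings (consecutive lines = parent -> child).
## Placeholder rows (reserved VariO:9xxx range) stand in for concepts whose
## canonical ids are not bundled; resolveName binds their canonical ids
## automatically when a full VariO release is loaded.
.MINI_TERMS <- list(
  ## DNA branch
  list("VariO:0128", "variation affecting DNA", character()),
  list("VariO:0129", "DNA variation type", "VariO:0128"),
  list("VariO:0322", "DNA variation classification", "VariO:0129"),
  list("VariO:0127", "DNA variation origin", "VariO:0129"),
  list("VariO:0135", "DNA chain variation", "VariO:0322"),
  list("VariO:0136", "DNA substitution", "VariO:0135"),
  list("VariO:0313", "transition", c("VariO:0136", "VariO:0312")),
  list("VariO:0314", "pyrimidine transition", "VariO:0313"),
  list("VariO:0130", "DNA variation of genetic origin", "VariO:0127"),
  list("VariO:0146", "DNA variation of non-genetic origin", "VariO:0127"),
  ## RNA branch
  list("VariO:0297", "variation affecting RNA", character()),
  list("VariO:0306", "RNA variation type", "VariO:0297"),
  list("VariO:0328", "RNA variation classification", "VariO:0306"),
  list("VariO:0312", "RNA substitution", "VariO:0328"),
  ## lineage inferred from prose ("causes a missense variation"); parent
  ## placement within the RNA branch is not printed
  list("VariO:0308", "missense variation", "VariO:0328",
       "comment: lineage inferred; parent placement not printed"),
  list("VariO:0333", "variation emerging at RNA level", "VariO:9016"),
  ## protein branch
  list("VariO:0002", "variation affecting protein", character()),
  list("VariO:0012", "protein variation type", "VariO:0002"),
  list("VariO:0325", "protein variation classification", "VariO:0012"),
  list("VariO:0021", "amino acid substitution", "VariO:0325"),
  list("VariO:0022", "amino acid indel", "VariO:0325"),
  list("VariO:0323", "protein variation origin", "VariO:0002"),
  list("VariO:0013", "protein variation of genetic origin", "VariO:0323"),
  list("VariO:0024", "variation emerging at protein level", "VariO:0323"),
  list("VariO:0003", "variation affecting protein function", "VariO:0002"),
  list("VariO:0011", "effect on protein information transfer", "VariO:0003"),
  list("VariO:0060", "variation affecting protein structure", "VariO:0002"),
  list("VariO:0064", "effect on protein 3D structure", "VariO:0060"),
  list("VariO:0070", "effect on protein tertiary structure", "VariO:0064"),
  list("VariO:0079", "effect on protein secondary structural element",
       "VariO:0070"),
  list("VariO:0080", "effect on protein helix", "VariO:0079"),
  list("VariO:0082", "effect on right handed protein helix", "VariO:0080"),
  list("VariO:0085", "effect on alpha helix", "VariO:0082"),
  list("VariO:0073", "effect on protein fold", "VariO:0070"),
  list("VariO:0074", "protein conformational change", "VariO:0073"),
  list("VariO:0032", "variation affecting protein property", "VariO:0002"),
  list("VariO:0047", "association of protein variation to pathogenicity",
       "VariO:0032"),
  list("VariO:0053", "effect on protein activity", "VariO:0032"),
  list("VariO:0058", "effect on protein interaction", "VariO:0032"),
  list("VariO:0033", "effect on protein subcellular localization",
       "VariO:0032"),
  ## attribute branch
  list("VariO:0232", "variation attribute", character()),
  list("VariO:0236", "interaction", "VariO:0232"),
  list("VariO:0262", "interactor", "VariO:0236"),
  list("VariO:0273", "biopolymer", "VariO:0262"),
  list("VariO:0277", "protein", "VariO:0273"),
  list("VariO:0267", "complex", "VariO:0262"),
  list("VariO:0269", "protein complex", "VariO:0267"),
  list("VariO:0290", "decreased", "VariO:9019"),
  list("VariO:0291", "increased", "VariO:9019"),
  list("VariO:0292", "missing", "VariO:9019"),
  list("VariO:0140", "not changed", "VariO:9019"),
  list("VariO:0294", "disease causing", "VariO:9020"),
  ## placeholders (reserved ids; canonical ids not bundled)
  list("VariO:9001", "purine transition", "VariO:0313"),
  list("VariO:9002", "transversion", c("VariO:0136", "VariO:0312")),
  list("VariO:9003", "synonymous variation", "VariO:0328"),
  list("VariO:9004", "nonsense variation", "VariO:0328"),
  list("VariO:9005", "DNA deletion", "VariO:0135"),
  list("VariO:9006", "DNA insertion", "VariO:0135"),
  list("VariO:9007", "DNA duplication", "VariO:0135"),
  list("VariO:9008", "DNA indel", "VariO:0135"),
  list("VariO:9009", "RNA deletion", "VariO:0328"),
  list("VariO:9010", "RNA insertion", "VariO:0328"),
  list("VariO:9011", "RNA duplication", "VariO:0328"),
  list("VariO:9012", "RNA indel", "VariO:0328"),
  list("VariO:9013", "amino acid deletion", "VariO:0325"),
  list("VariO:9014", "amino acid insertion", "VariO:0325"),
  list("VariO:9015", "amino acid duplication", "VariO:0325"),
  list("VariO:9016", "RNA variation origin", "VariO:0306"),
  list("VariO:9017", "RNA variation of genetic origin", "VariO:9016"),
  list("VariO:9018", "not disease causing", "VariO:9020"),
  list("VariO:9019", "quantity change", "VariO:0232"),
  list("VariO:9020", "pathogenicity association", "VariO:0232"),
  list("VariO:9021", "conservation", "VariO:0232"),
  list("VariO:9022", "conserved", "VariO:9021"),
  list("VariO:9023", "covariant", "VariO:9021"),
  list("VariO:9024", "nonconserved", "VariO:9021"))

.MINI_VERSION <- "variotools-mini/1.0"

#' Build the bundled mini ontology
#'
#' Constructs the self-contained VariO excerpt the package is tested
#' against: the four branch roots (variation affecting DNA / RNA / protein
#' and variation attribute), every concept the classification and
#' annotation machinery emits, and flagged placeholder terms (reserved
#' VariO:9xxx ids) for concepts whose canonical ids are not bundled. The
#' same graph is shipped as \code{inst/extdata/mini_vario.obo}.
#'
#' @return an \code{\linkS4class{OntologyGraph}} with 4 roots and a
#'   maximum root-to-leaf depth of 8 terms.
#' @examples
#' g <- buildMiniOntology()
#' maxDepth(g)
#' @export
buildMiniOntology <- function() {
  terms <- lapply(.MINI_TERMS, function(row) {
    .newTerm(row[[1]], row[[2]], parents = row[[3]],
             extra = if (length(row) > 3L) row[[4]] else character())
  })
  .OntologyGraph(terms, version = .MINI_VERSION)
}

#' Load an ontology, bundled or from file
#'
#' @param path path to an OBO file, or \code{"bundled"} for the packaged
#'   mini ontology.
#' @return an \code{OntologyGraph}.
#' @export
loadOntology <- function(path = "bundled") {
  if (identical(path, "bundled")) {
    f <- system.file("extdata", "mini_vario.obo", package = "variotools")
    if (nzchar(f)) return(parseOBO(f))
    return(buildMiniOntology())
  }
  parseOBO(path)
}

## ---------------------------------------------------------------------------
## Golden AIRE annotation set
## ---------------------------------------------------------------------------

#' The golden AIRE annotation set
#'
#' The fully worked annotation of the AIRE gene variant g.4789T>C (IDbase
#' reference D0003), the pyrimidine transition of genetic origin that
#' causes a missense variation (L to P in the HSR domain) and the APECED
#' disease: variation-type and origin annotations at all three molecular
#' levels, the affected function (information transfer), the structural
#' consequences (alpha-helix and fold/conformational-change paths), the
#' property annotations (pathogenicity, activity, interaction, subcellular
#' localization) with their attribute modifiers, and the three ECO evidence
#' terms. The protein residue position is not part of the source record;
#' the protein change is carried as the residue pair (L, P) only.
#'
#' @param graph the ontology graph to resolve concepts against; defaults to
#'   the bundled mini ontology.
#' @return an \code{\linkS4class{AnnotationSet}} that validates with zero
#'   violations.
#' @export
goldenAireAnnotationSet <- function(graph = buildMiniOntology()) {
  variant <- parseHGVS("g.4789T>C", referenceId = "D0003")
  cls <- classifyVariant(variant, "genetic", proteinChange = c("L", "P"))

  ann <- list()
  mostSpecific <- function(lv) utils::tail(cls@perLevel[[lv]], 1L)

  ## variation type + origin, per level, in the printed order
  ann$dnaType <- buildAnnotation(graph, mostSpecific("DNA"), "DNA")
  ann$dnaOrigin <- buildAnnotation(graph, cls@originConcepts[["DNA"]], "DNA")
  rnaConcepts <- cls@perLevel[["RNA"]]
  consequences <- intersect(rnaConcepts, c("missense variation",
                                           "nonsense variation",
                                           "synonymous variation"))
  rnaType <- utils::tail(setdiff(rnaConcepts, consequences), 1L)
  ann$rnaType <- buildAnnotation(graph, rnaType, "RNA",
                                 extraConcepts = consequences)
  ann$protType <- buildAnnotation(graph, mostSpecific("protein"), "protein")
  ann$protOrigin <- buildAnnotation(graph, cls@originConcepts[["protein"]],
                                    "protein")

  ## function, structure, property annotations (curator-established effects)
  ann$fun <- buildAnnotation(graph, "effect on protein information transfer",
                             "protein")
  ann$helix <- buildAnnotation(graph, "effect on alpha helix", "protein")
  ann$fold <- buildAnnotation(graph, "protein conformational change",
                              "protein")

  patho <- buildAnnotation(graph,
                           "association of protein variation to pathogenicity",
                           "protein")
  ann$patho <- attachAttribute(graph, patho,
                               pathogenicityAttribute("disease_causing"),
                               resolveName(graph, "association of protein variation to pathogenicity"))

  act <- buildAnnotation(graph, "effect on protein activity", "protein")
  act <- attachAttribute(graph, act, quantityAttributeFromRatio(0),
                         resolveName(graph, "effect on protein activity"))
  act@evidence <- list(ecoLookup("reporter gene assay",
                                 resolveName(graph, "effect on protein activity")))
  ann$act <- act

  inter <- buildAnnotation(graph, "effect on protein interaction", "protein")
  interId <- resolveName(graph, "effect on protein interaction")
  inter <- attachAttribute(graph, inter, quantityAttribute("missing"),
                           interId)
  inter <- attachAttribute(graph, inter, resolveName(graph, "protein"),
                           interId)
  inter <- attachAttribute(graph, inter,
                           resolveName(graph, "protein complex"), interId)
  inter@evidence <- list(ecoLookup("gel filtration", interId))
  ann$inter <- inter

  loc <- buildAnnotation(graph,
                         "effect on protein subcellular localization",
                         "protein")
  loc@evidence <- list(ecoLookup(
    "immunofluorescence",
    resolveName(graph, "effect on protein subcellular localization")))
  ann$loc <- loc

  AnnotationSet(
    variant, unname(ann),
    referenceStates = c(DNA = "IDbase:D0003", RNA = "IDbase:C0003",
                        protein = "UniProt:O43918"),
    ontologyVersion = ontologyVersion(graph),
    levelsAffected = c("DNA", "RNA", "protein"))
}

#' The bundled AIRE annotation request
#'
#' The annotation-request document from which \code{\link{annotateRequest}}
#' rebuilds the golden AIRE set; shipped as
#' \code{inst/extdata/aire_request.json}.
#'
#' @return a nested list (the parsed request document).
#' @export
aireRequest <- function() {
  list(
    variant = "g.4789T>C",
    reference_id = "D0003",
    origin = "genetic",
    protein_change = list("L", "P"),
    reference_states = list(DNA = "IDbase:D0003", RNA = "IDbase:C0003",
                            protein = "UniProt:O43918"),
    ontology_version = .MINI_VERSION,
    effects = list(
      list(concept = "effect on protein information transfer",
           level = "protein"),
      list(concept = "effect on alpha helix", level = "protein"),
      list(concept = "protein conformational change", level = "protein"),
      list(concept = "association of protein variation to pathogenicity",
           level = "protein", pathogenicity = "disease_causing"),
      list(concept = "effect on protein activity", level = "protein",
           quantity = "missing", evidence = "reporter gene assay"),
      list(concept = "effect on protein interaction", level = "protein",
           quantity = "missing",
           interaction_attributes = list("protein", "protein complex"),
           evidence = "gel filtration"),
      list(concept = "effect on protein subcellular localization",
           level = "protein", evidence = "immunofluorescence")))
}

## ---------------------------------------------------------------------------
## Synthetic variant corpora with an independent classification oracle
## ---------------------------------------------------------------------------

## Table-driven oracle, deliberately separate from the classify module:
## direct lookups, no shared code paths.
.oracleClassify <- function(hgvs, origin) {
  s <- gsub("\\s", "", hgvs)
  level <- substr(s, 1, 1)
  body <- substr(s, 3, nchar(s))
  lv <- c(g = "DNA", c = "DNA", n = "DNA", r = "RNA", p = "protein")[[level]]

  transitions <- c("AG", "GA", "CT", "TC", "CU", "UC")
  purine <- c("AG", "GA")

  kindWord <- function(b) {
    if (grepl("delins", b)) "delins"
    else if (grepl("del", b)) "deletion"
    else if (grepl("ins", b)) "insertion"
    else if (grepl("dup", b)) "duplication"
    else "substitution"
  }
  kind <- kindWord(body)

  specificTbl <- list(
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

  concepts <- character()
  if (lv == "DNA") concepts <- "DNA chain variation"
  concepts <- c(concepts, unname(specificTbl[[lv]][[kind]]))

  if (kind == "substitution" && level != "p") {
    m <- regmatches(body, regexec("^[0-9]+([a-zA-Z])>([a-zA-Z])$",
                                  body))[[1]]
    pair <- toupper(paste0(m[2], m[3]))
    pairT <- gsub("U", "T", pair)
    if (pairT %in% gsub("U", "T", transitions)) {
      cls <- if (pairT %in% purine) "purine transition"
             else "pyrimidine transition"
      concepts <- c(concepts, "transition", cls)
    } else {
      concepts <- c(concepts, "transversion")
    }
  }

  originTbl <- list(
    genetic = c(DNA = "DNA variation of genetic origin",
                RNA = "RNA variation of genetic origin",
                protein = "protein variation of genetic origin"),
    non_genetic = c(DNA = "DNA variation of non-genetic origin",
                    RNA = "variation emerging at RNA level",
                    protein = "variation emerging at protein level"))

  list(level = lv, concepts = concepts,
       origin = unname(originTbl[[origin]][[lv]]))
}

#' Generate a synthetic HGVS corpus with oracle classifications
#'
#' Emits random valid descriptions from the supported HGVS grammar,
#' covering all kind-by-level combinations, together with the expected
#' classification computed by an independent table-driven oracle (lookup
#' tables separate from the classify module). Deterministic for a fixed
#' seed.
#'
#' @param n number of cases (>= 1).
#' @param seed integer seed.
#' @param substitutionOnly when \code{TRUE}, emit nucleotide substitutions
#'   only; with \code{n = 12} every ordered base pair appears exactly once.
#' @param origin origin flag attached to every case.
#' @return data.frame with columns \code{hgvs}, \code{level},
#'   \code{concepts} (list column, ordered concept names), \code{origin}
#'   (expected origin concept name).
#' @export
generateSyntheticVariants <- function(n, seed = 1L,
                                      substitutionOnly = FALSE,
                                      origin = "genetic") {
  stopifnot(n >= 1L)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]

  mkSub <- function(i, pos) {
    lev <- sample(c("g", "c", "n", "r"), 1L)
    ref <- pairs$ref[i]; alt <- pairs$alt[i]
    if (lev == "r") {
      ref <- chartr("T", "U", ref); alt <- chartr("T", "U", alt)
      sprintf("r.%d%s>%s", pos, tolower(ref), tolower(alt))
    } else sprintf("%s.%d%s>%s", lev, pos, ref, alt)
  }
  mkOther <- function(kind, level) {
    pos <- sample(10:500, 1L)
    seq_ <- paste(sample(bases, sample(1:4, 1L), replace = TRUE),
                  collapse = "")
    if (level == "p") {
      aa <- c("Leu", "Pro", "Ala", "Gly", "Ser", "Arg")
      a1 <- sample(aa, 1L); a2 <- sample(aa, 1L)
      switch(kind,
        deletion = sprintf("p.%s%d_%s%ddel", a1, pos, a2, pos + 2L),
        duplication = sprintf("p.%s%d_%s%ddup", a1, pos, a2, pos + 2L),
        delins = sprintf("p.%s%d_%s%ddelins%s", a1, pos, a2, pos + 2L,
                         sample(aa, 1L)),
        substitution = {
          repeat { a1 <- sample(aa, 1L); a2 <- sample(aa, 1L)
                   if (a1 != a2) break }
          sprintf("p.%s%d%s", a1, pos, a2)
        },
        insertion = sprintf("p.%s%d_%s%ddelins%s", a1, pos, a2, pos + 2L,
                            sample(aa, 1L)))  # protein ins folded into delins
    } else {
      lowerIfR <- function(x) if (level == "r")
        tolower(chartr("T", "U", x)) else x
      switch(kind,
        deletion = sprintf("%s.%d_%ddel%s", level, pos, pos + 2L,
                           lowerIfR(seq_)),
        insertion = sprintf("%s.%d_%dins%s", level, pos, pos + 1L,
                            lowerIfR(seq_)),
        duplication = sprintf("%s.%d_%ddup", level, pos, pos + 3L),
        delins = sprintf("%s.%d_%ddelins%s", level, pos, pos + 2L,
                         lowerIfR(seq_)))
    }
  }

  hgvs <- character(n)
  if (substitutionOnly) {
    for (k in seq_len(n)) {
      i <- if (n == nrow(pairs)) k else sample(nrow(pairs), 1L)
      hgvs[k] <- mkSub(i, sample(10:5000, 1L))
    }
  } else {
    ## first cover the kind x level grid, then sample freely
    grid <- expand.grid(kind = .VARIANT_KINDS,
                        level = c("g", "r", "p"),
                        stringsAsFactors = FALSE)
    k <- 1L
    for (gi in seq_len(nrow(grid))) {
      if (k > n) break
      kind <- grid$kind[gi]; lev <- grid$level[gi]
      hgvs[k] <- if (kind == "substitution" && lev != "p")
        mkSub(sample(nrow(pairs), 1L), sample(10:5000, 1L))
      else if (kind == "insertion" && lev == "p") {
        mkOther("delins", "p")  # no distinct protein insertion syntax here
      } else mkOther(kind, lev)
      k <- k + 1L
    }
    while (k <= n) {
      if (stats::runif(1) < 0.5)
        hgvs[k] <- mkSub(sample(nrow(pairs), 1L), sample(10:5000, 1L))
      else {
        gi <- sample(nrow(grid), 1L)
        kind <- grid$kind[gi]; lev <- grid$level[gi]
        hgvs[k] <- if (kind == "substitution" && lev != "p")
          mkSub(sample(nrow(pairs), 1L), sample(10:5000, 1L))
        else mkOther(if (kind == "insertion" && lev == "p") "delins"
                     else kind, lev)
      }
      k <- k + 1L
    }
  }

  oracle <- lapply(hgvs, .oracleClassify, origin = origin)
  data.frame(
    hgvs = hgvs,
    level = vapply(oracle, `[[`, character(1), "level"),
    concepts = I(lapply(oracle, `[[`, "concepts")),
    origin = vapply(oracle, `[[`, character(1), "origin"),
    stringsAsFactors = FALSE)
}

#' Regenerate the bundled fixture files
#'
#' Writes \code{mini_vario.obo} (OBO 1.2) and \code{aire_golden.json} (the
#' golden AIRE set in the package's JSON form) plus
#' \code{aire_request.json} into a directory.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- buildMiniOntology()
  obo <- file.path(dir, "mini_vario.obo")
  writeOBO(g, obo)
  golden <- file.path(dir, "aire_golden.json")
  writeLines(renderAnnotations(goldenAireAnnotationSet(g), "json"), golden,
             sep = "")
  req <- file.path(dir, "aire_request.json")
  writeLines(paste0(jsonlite::toJSON(aireRequest(), auto_unbox = TRUE,
                                     pretty = 2), "\n"), req, sep = "")
  invisible(c(obo, golden, req))
}
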