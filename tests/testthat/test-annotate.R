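test_that("buildAnnotation expands concepts through the level root", {
  a <- buildAnnotation(miniGraph, "effect on alpha helix", "protein")
  expect_identical(pathTermIds(a@path),
                   c("VariO:0002", "VariO:0060", "VariO:0064", "VariO:0070",
                     "VariO:0079", "VariO:0080", "VariO:0082", "VariO:0085"))
  root <- buildAnnotation(miniGraph, "variation affecting protein",
                          "protein")
  expect_identical(pathTermIds(root@path), "VariO:0002")
  expect_error(buildAnnotation(miniGraph, "pyrimidine transition",
                               "protein"), "not reachable")
})

test_that("attachAttribute enforces the modifier rules", {
  act <- buildAnnotation(miniGraph, "effect on protein activity", "protein")
  act2 <- attachAttribute(miniGraph, act, "VariO:0292", "VariO:0053")
  expect_length(act2@attributes, 1L)
  expect_null(act2@attributes[[1]]$fullPath)

  inter <- buildAnnotation(miniGraph, "effect on protein interaction",
                           "protein")
  inter2 <- attachAttribute(miniGraph, inter, "VariO:0277", "VariO:0058")
  expect_identical(inter2@attributes[[1]]$fullPath,
                   c("VariO:0232", "VariO:0236", "VariO:0262", "VariO:0273",
                     "VariO:0277"))

  dnaType <- buildAnnotation(miniGraph, "DNA substitution", "DNA")
  expect_error(attachAttribute(miniGraph, dnaType, "VariO:0292",
                               "VariO:0136"),
               "not used on variation type")
  fun <- buildAnnotation(miniGraph, "effect on protein information transfer",
                         "protein")
  expect_error(attachAttribute(miniGraph, fun, "VariO:0292", "VariO:0011"),
               "not used on function")
  expect_error(attachAttribute(miniGraph, act, "VariO:0136", "VariO:0053"),
               "not in the attribute branch")
  expect_error(attachAttribute(miniGraph, act, "VariO:0292", "VariO:0058"),
               "not on the annotation")
})

test_that("attribute placement law holds over randomized attachment attempts", {
  set.seed(101)
  allIds <- termIds(miniGraph)
  structProp <- c("effect on alpha helix", "protein conformational change",
                  "effect on protein activity",
                  "effect on protein interaction",
                  "effect on protein subcellular localization")
  for (k in 1:150) {
    concept <- sample(structProp, 1)
    a <- buildAnnotation(miniGraph, concept, "protein")
    attrId <- sample(allIds, 1)
    modId <- sample(pathTermIds(a@path), 1)
    res <- tryCatch(attachAttribute(miniGraph, a, attrId, modId),
                    error = function(e) e)
    if (is(res, "Annotation")) {
      u <- res@attributes[[1]]
      expect_true(isAttributeTerm(miniGraph, u$attributeId))
      expect_true(variotools:::.termCategory(miniGraph, u$modifiedTermId)
                  %in% c("structure", "property"))
      expect_identical(!is.null(u$fullPath),
                       attributeRequiresFullPath(miniGraph, u$attributeId))
    }
  }
})

test_that("quantity attributes map the four-way change and measured ratios", {
  expect_identical(quantityAttribute("missing"), "VariO:0292")
  expect_identical(quantityAttribute("decreased"), "VariO:0290")
  expect_identical(quantityAttribute("increased"), "VariO:0291")
  expect_identical(quantityAttribute("not_changed"), "VariO:0140")
  expect_identical(quantityAttributeFromRatio(0), "VariO:0292")
  expect_identical(quantityAttributeFromRatio(1), "VariO:0140")
  expect_identical(quantityAttributeFromRatio(1.04), "VariO:0140")
  expect_identical(quantityAttributeFromRatio(2), "VariO:0291")
  expect_identical(quantityAttributeFromRatio(0.5), "VariO:0290")
  expect_identical(quantityAttributeFromRatio(0.5, tolerance = 0.6),
                   "VariO:0140")
  expect_error(quantityAttributeFromRatio(-1), "non-negative")
})

test_that("pathogenicity attribute asserts only known statuses", {
  expect_identical(pathogenicityAttribute("disease_causing"), "VariO:0294")
  expect_true(is.na(pathogenicityAttribute("unknown")))
  nd <- pathogenicityAttribute("not_disease_causing")
  expect_true(isPlaceholderTerm(miniGraph, nd))
})

test_that("evidence keywords map to ECO terms and unknowns error", {
  expect_identical(ecoLookup("reporter gene assay")$ecoId, "ECO:0000049")
  expect_identical(ecoLookup("gel filtration")$ecoId, "ECO:0000156")
  expect_identical(ecoLookup("gel filtration")$ecoName,
                   "protein separation evidence")
  expect_identical(ecoLookup("immunofluorescence")$ecoId, "ECO:0000007")
  expect_identical(ecoLookup("Immunofluorescence ")$ecoId, "ECO:0000007")
  expect_error(ecoLookup("crystal ball"), "unknown evidence method")
})

test_that("the golden set validates cleanly", {
  set <- goldenAireAnnotationSet(miniGraph)
  expect_identical(nrow(validateAnnotationSet(miniGraph, set)), 0L)
})

test_that("single-fault mutations each yield exactly the expected violation", {
  golden <- goldenAireAnnotationSet(miniGraph)

  blankVersion <- golden
  blankVersion@ontologyVersion <- ""
  v <- validateAnnotationSet(miniGraph, blankVersion)
  expect_identical(v$code, "MISSING_VERSION")

  stripPath <- golden
  idx <- which(vapply(stripPath@annotations, function(a)
    any(vapply(a@attributes, function(u) !is.null(u$fullPath), logical(1))),
    logical(1)))[1]
  a <- stripPath@annotations[[idx]]
  a@attributes <- lapply(a@attributes, function(u) {
    if (!is.null(u$fullPath) &&
        identical(u$attributeId, "VariO:0277")) u$fullPath <- NULL
    u
  })
  stripPath@annotations[[idx]] <- a
  v <- validateAnnotationSet(miniGraph, stripPath)
  expect_identical(v$code, "MISSING_ATTRIBUTE_PATH")

  wrongBranch <- golden
  dnaIdx <- which(vapply(wrongBranch@annotations, function(a)
    a@level == "DNA", logical(1)))[1]
  a <- wrongBranch@annotations[[dnaIdx]]
  a@attributes <- list(list(attributeId = "VariO:0292",
                            modifiedTermId = "VariO:0136",
                            fullPath = NULL))
  wrongBranch@annotations[[dnaIdx]] <- a
  v <- validateAnnotationSet(miniGraph, wrongBranch)
  expect_identical(v$code, "WRONG_BRANCH_ATTRIBUTE")

  extraPath <- golden
  actIdx <- which(vapply(extraPath@annotations, function(a)
    "VariO:0053" %in% pathTermIds(a@path), logical(1)))[1]
  a <- extraPath@annotations[[actIdx]]
  a@attributes <- lapply(a@attributes, function(u) {
    if (identical(u$attributeId, "VariO:0292"))
      u$fullPath <- c("VariO:0232", "VariO:9019", "VariO:0292")
    u
  })
  extraPath@annotations[[actIdx]] <- a
  v <- validateAnnotationSet(miniGraph, extraPath)
  expect_identical(v$code, "SUPERFLUOUS_ATTRIBUTE_PATH")
})

test_that("broken chains, missing references and minimum annotation are caught", {
  golden <- goldenAireAnnotationSet(miniGraph)

  broken <- golden
  a <- broken@annotations[[1]]
  a@path <- new("AnnotationPath",
                termIds = c("VariO:0128", "VariO:0136"))  # skips 3 levels
  broken@annotations[[1]] <- a
  v <- validateAnnotationSet(miniGraph, broken)
  expect_identical(v$code, "BROKEN_PATH")

  noRef <- golden
  noRef@referenceStates <- noRef@referenceStates[c("DNA", "RNA")]
  v <- validateAnnotationSet(miniGraph, noRef)
  expect_identical(v$code, "MISSING_REFERENCE_STATE")

  below <- golden
  below@annotations <- Filter(function(a) a@level != "RNA",
                              below@annotations)
  v <- validateAnnotationSet(miniGraph, below)
  expect_identical(v$code, "BELOW_MINIMUM")
  expect_match(v$message, "RNA")

  empty <- AnnotationSet(golden@variant, list(),
                         referenceStates = golden@referenceStates,
                         ontologyVersion = golden@ontologyVersion,
                         levelsAffected = c("DNA", "RNA", "protein"))
  v <- validateAnnotationSet(miniGraph, empty)
  expect_setequal(v$code, "BELOW_MINIMUM")
  expect_identical(nrow(v), 3L)
})
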