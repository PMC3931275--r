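test_that("the 12 ordered substitutions split 4 transitions / 8 transversions", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  expect_identical(nrow(pairs), 12L)

  ## brute-force oracle: same chemical class iff both in {A,G} or both in
  ## {C,T}
  oracleTransition <- function(r, a) {
    pur <- c("A", "G")
    (r %in% pur) == (a %in% pur)
  }
  got <- t(mapply(function(r, a) {
    cls <- classifyNucleotideSubstitution(r, a)
    c(isTransition = "transition" %in% cls,
      subclass = if (length(cls) == 3L) cls[3] else cls[2])
  }, pairs$ref, pairs$alt))

  expect_identical(unname(got[, "isTransition"] == "TRUE"),
                   mapply(oracleTransition, pairs$ref, pairs$alt,
                          USE.NAMES = FALSE))
  expect_identical(sum(got[, "isTransition"] == "TRUE"), 4L)
  expect_identical(sum(got[, "subclass"] == "purine transition"), 2L)
  expect_identical(sum(got[, "subclass"] == "pyrimidine transition"), 2L)
  expect_identical(sum(got[, "subclass"] == "transversion"), 8L)
})

test_that("substitution classing treats U as T and orders general to specific", {
  expect_identical(classifyNucleotideSubstitution("T", "C"),
                   c("substitution", "transition", "pyrimidine transition"))
  expect_identical(classifyNucleotideSubstitution("U", "C"),
                   c("substitution", "transition", "pyrimidine transition"))
  expect_identical(classifyNucleotideSubstitution("A", "G"),
                   c("substitution", "transition", "purine transition"))
  expect_identical(classifyNucleotideSubstitution("A", "C"),
                   c("substitution", "transversion"))
  expect_error(classifyNucleotideSubstitution("T", "U"), "identical")
  expect_error(classifyNucleotideSubstitution("A", "X"), "invalid")
})

test_that("chain-variation concepts are level-matched across kinds", {
  expect_identical(classifyChainVariation("substitution", "DNA"),
                   c("DNA chain variation", "DNA substitution"))
  expect_identical(classifyChainVariation("delins", "protein"),
                   "amino acid indel")
  expect_identical(classifyChainVariation("duplication", "DNA"),
                   c("DNA chain variation", "DNA duplication"))
  expect_true(isPlaceholderTerm(miniGraph,
                                resolveName(miniGraph, "DNA duplication")))
  ## DNA and RNA most specific names differ only in the level prefix
  for (kind in c("substitution", "deletion", "insertion", "duplication",
                 "delins")) {
    d <- tail(classifyChainVariation(kind, "DNA"), 1)
    r <- tail(classifyChainVariation(kind, "RNA"), 1)
    expect_identical(sub("^DNA", "", d), sub("^RNA", "", r), info = kind)
  }
  expect_error(classifyChainVariation("inversion", "DNA"), "unsupported")
  expect_error(classifyChainVariation("substitution", "genome"), "unknown")
})

test_that("coding consequences are exhaustive and mutually exclusive", {
  expect_identical(codingConsequence("L", "P"), "missense variation")
  expect_identical(codingConsequence("L", "L"), "synonymous variation")
  expect_identical(codingConsequence("L", "*"), "nonsense variation")
  expect_identical(codingConsequence("*", "*"), "synonymous variation")
  expect_error(codingConsequence("*", "L"), "stop")
  expect_error(codingConsequence("L", "B"), "invalid residue")
  residues <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")
  for (r in residues) for (a in residues) {
    if (r == "*" && a != "*") next
    got <- codingConsequence(r, a)
    want <- if (r == a) "synonymous variation"
      else if (a == "*") "nonsense variation" else "missense variation"
    expect_identical(got, want, info = paste(r, a))
  }
})

test_that("codon translation matches an independent code table", {
  expect_identical(translateCodon("CUG"), "L")
  expect_identical(translateCodon("CCG"), "P")
  expect_identical(translateCodon("UAA"), "*")
  expect_error(translateCodon("CU"), "3 bases")
  expect_error(translateCodon("CUX"), "invalid base")
  for (codon in names(standardCodeOracle))
    expect_identical(translateCodon(codon),
                     unname(standardCodeOracle[codon]), info = codon)
})

test_that("exhaustive codon substitution agrees with a re-translation oracle", {
  bases <- c("A", "C", "G", "T")
  codons <- names(standardCodeOracle)
  for (codon in codons) {
    for (offset in 0:2) {
      orig <- substr(codon, offset + 1L, offset + 1L)
      for (alt in setdiff(bases, orig)) {
        mutated <- codon
        substr(mutated, offset + 1L, offset + 1L) <- alt
        refAA <- unname(standardCodeOracle[codon])
        altAA <- unname(standardCodeOracle[mutated])
        if (refAA == "*" && altAA != "*") {
          expect_error(consequenceFromCodon(codon, offset, alt), "stop")
        } else {
          want <- if (refAA == altAA) "synonymous variation"
            else if (altAA == "*") "nonsense variation"
            else "missense variation"
          expect_identical(consequenceFromCodon(codon, offset, alt), want,
                           info = paste(codon, offset, alt))
        }
      }
    }
  }
  expect_identical(consequenceFromCodon("CUG", 1, "C"), "missense variation")
  expect_identical(consequenceFromCodon("CUG", 2, "A"),
                   "synonymous variation")
  expect_error(consequenceFromCodon("CUG", 2, "G"), "equals the reference")
})

test_that("origin concepts follow the genetic / non-genetic distinction", {
  expect_identical(originConcept("DNA", "genetic"),
                   "DNA variation of genetic origin")
  expect_identical(originConcept("protein", "non_genetic"),
                   "variation emerging at protein level")
  expect_identical(originConcept("RNA", "non_genetic"),
                   "variation emerging at RNA level")
  expect_identical(originConcept("DNA", "non_genetic"),
                   "DNA variation of non-genetic origin")
})

test_that("classifyVariant populates exactly the levels with information", {
  full <- classifyVariant(parseHGVS("g.4789T>C"), "genetic",
                          proteinChange = c("L", "P"))
  expect_setequal(names(full@perLevel), c("DNA", "RNA", "protein"))
  expect_identical(tail(full@perLevel$DNA, 1), "pyrimidine transition")
  expect_identical(tail(full@perLevel$RNA, 1), "missense variation")
  expect_true("pyrimidine transition" %in% full@perLevel$RNA)
  expect_identical(full@perLevel$protein, "amino acid substitution")
  expect_identical(unname(full@originConcepts["DNA"]),
                   "DNA variation of genetic origin")
  expect_length(full@originConcepts, 3L)

  protOnly <- classifyVariant(parseHGVS("p.Leu28Pro"), "non_genetic")
  expect_identical(names(protOnly@perLevel), "protein")
  expect_identical(unname(protOnly@originConcepts["protein"]),
                   "variation emerging at protein level")

  dnaOnly <- classifyVariant(parseHGVS("g.10_12del"), "genetic")
  expect_identical(names(dnaOnly@perLevel), "DNA")
  expect_identical(dnaOnly@perLevel$DNA,
                   c("DNA chain variation", "DNA deletion"))
})

test_that("codon context substitutes for and must agree with a stated change", {
  v <- parseHGVS("g.4789T>C")
  byCodon <- classifyVariant(v, "genetic",
                             codonContext = list(codon = "CTG", offset = 1))
  expect_identical(tail(byCodon@perLevel$RNA, 1), "missense variation")
  expect_no_error(classifyVariant(v, "genetic",
                                  proteinChange = c("L", "P"),
                                  codonContext = list(codon = "CTG",
                                                      offset = 1)))
  expect_error(
    classifyVariant(v, "genetic", proteinChange = c("L", "L"),
                    codonContext = list(codon = "CTG", offset = 1)),
    "contradicts")
})

test_that("classifyVariant agrees with the table-driven oracle on a corpus", {
  for (orig in c("genetic", "non_genetic")) {
    corpus <- generateSyntheticVariants(500, seed = 7,
                                        origin = orig)
    for (k in seq_len(nrow(corpus))) {
      cls <- classifyVariant(parseHGVS(corpus$hgvs[k]), orig)
      lv <- corpus$level[k]
      expect_identical(cls@perLevel[[lv]],
                       c(corpus$concepts[[k]]),
                       info = corpus$hgvs[k])
      expect_identical(unname(cls@originConcepts[lv]), corpus$origin[k],
                       info = corpus$hgvs[k])
    }
  }
})

test_that("classification never emits a name that fails resolution", {
  corpus <- generateSyntheticVariants(200, seed = 9)
  for (k in seq_len(nrow(corpus))) {
    cls <- classifyVariant(parseHGVS(corpus$hgvs[k]), "genetic")
    for (nm in c(unlist(cls@perLevel), unname(cls@originConcepts)))
      expect_no_error(resolveName(miniGraph, nm))
  }
  ## the worked example's concepts, incl. consequence, all resolve too
  full <- classifyVariant(parseHGVS("g.4789T>C"), "genetic",
                          proteinChange = c("L", "P"))
  for (nm in c(unlist(full@perLevel), unname(full@originConcepts)))
    expect_no_error(resolveName(miniGraph, nm))
})
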