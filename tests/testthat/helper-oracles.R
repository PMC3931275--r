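## Independent oracles used by the property tests. Deliberately written
## against plain adjacency lists, sharing no code with the package.

## parents: named list id -> character vector of parent ids
dfsAncestorsOracle <- function(parents, id) {
  out <- character()
  visit <- function(i) {
    for (p in parents[[i]]) {
      if (!p %in% out) {
        out <<- c(out, p)
        visit(p)
      }
    }
  }
  visit(id)
  sort(out)
}

## exhaustive enumeration of all root-to-leaf chains; returns max length
longestChainOracle <- function(parents) {
  ids <- names(parents)
  children <- lapply(ids, function(i)
    ids[vapply(parents, function(p) i %in% p, logical(1))])
  names(children) <- ids
  roots <- ids[vapply(parents, length, integer(1)) == 0L]
  best <- 0L
  walk <- function(i, depth) {
    best <<- max(best, depth)
    for (ch in children[[i]]) walk(ch, depth + 1L)
  }
  for (r in roots) walk(r, 1L)
  best
}

## random DAG as an OBO document + its adjacency list; node k may only have
## parents among nodes 1..k-1, so the graph is acyclic by construction
randomDagObo <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("VariO:%04d", seq_len(n))
  parents <- vector("list", n)
  names(parents) <- ids
  for (k in seq_len(n)) {
    parents[[k]] <- if (k == 1L) character()
      else sample(ids[seq_len(k - 1L)],
                  size = sample(0:min(3L, k - 1L), 1L))
  }
  lines <- c("format-version: 1.2")
  for (k in seq_len(n)) {
    lines <- c(lines, "", "[Term]", paste0("id: ", ids[k]),
               paste0("name: node ", k))
    for (p in parents[[k]]) lines <- c(lines, paste0("is_a: ", p))
  }
  list(obo = paste(lines, collapse = "\n"), parents = parents, ids = ids)
}

## hand-written standard genetic code, independent of the package's table
standardCodeOracle <- local({
  byAA <- list(
    F = c("TTT", "TTC"), L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
    I = c("ATT", "ATC", "ATA"), M = "ATG",
    V = c("GTT", "GTC", "GTA", "GTG"),
    S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
    P = c("CCT", "CCC", "CCA", "CCG"), T = c("ACT", "ACC", "ACA", "ACG"),
    A = c("GCT", "GCC", "GCA", "GCG"), Y = c("TAT", "TAC"),
    H = c("CAT", "CAC"), Q = c("CAA", "CAG"), N = c("AAT", "AAC"),
    K = c("AAA", "AAG"), D = c("GAT", "GAC"), E = c("GAA", "GAG"),
    C = c("TGT", "TGC"), W = "TGG", R = c("CGT", "CGC", "CGA", "CGG",
                                          "AGA", "AGG"),
    G = c("GGT", "GGC", "GGA", "GGG"), "*" = c("TAA", "TAG", "TGA"))
  tab <- character()
  for (aa in names(byAA)) tab[byAA[[aa]]] <- aa
  tab
})

miniGraph <- variotools::buildMiniOntology()

## adjacency list of the mini ontology, extracted once for the oracles
miniParents <- local({
  ids <- variotools::termIds(miniGraph)
  p <- lapply(ids, function(i) variotools::termParents(miniGraph, i))
  names(p) <- ids
  p
})
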