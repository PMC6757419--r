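# Small hand-built DAG sets reused across the semantic-similarity
# tests. Edges point child -> parent.

# dA: singleton {A}. dB: chain B -> A.
chainDagSet <- function() {
  DiseaseDAGSet(list(
    dA = list(term = "A", terms = "A",
              edges = matrix(character(), 0L, 2L)),
    dB = list(term = "B", terms = c("B", "A"),
              edges = matrix(c("B", "A"), 1L, 2L))))
}

# Diamond: S -> {X, Y} -> R.
diamondDagSet <- function() {
  DiseaseDAGSet(list(
    dS = list(term = "S", terms = c("S", "X", "Y", "R"),
              edges = matrix(c("S", "X",
                               "S", "Y",
                               "X", "R",
                               "Y", "R"), 4L, 2L, byrow = TRUE))))
}

# Random tree DAG over at most `maxTerms` nodes, rooted at its term.
randomDagSet <- function(nDiseases, maxTerms = 8L) {
  graphs <- lapply(seq_len(nDiseases), function(i) {
    n <- sample(1:maxTerms, 1L)
    terms <- c(sprintf("D%d", i),
               if (n > 1L) sprintf("t%d_%d", i, seq_len(n - 1L)))
    edges <- if (n > 1L) {
      # node j+1 hangs under a uniformly chosen earlier node -> tree
      # with all edges pointing away from the disease term... parents
      # must be closer to the root, so point child -> parent upward:
      # here term[1] is the disease, ancestors are added above it.
      parent <- vapply(seq(2L, n), function(j) sample(j - 1L, 1L), integer(1))
      # ancestor tree: edge from the lower (child) node to its parent
      # means "term[parent] is an ancestor"; orient so the disease
      # reaches everything: child = earlier node, parent = new node.
      matrix(c(terms[parent], terms[seq(2L, n)]), ncol = 2L)
    } else matrix(character(), 0L, 2L)
    list(term = terms[1L], terms = terms, edges = edges)
  })
  names(graphs) <- sprintf("D%d", seq_len(nDiseases))
  DiseaseDAGSet(graphs)
}
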