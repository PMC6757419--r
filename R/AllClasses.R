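#' @import methods
#' @importFrom stats rbinom runif sd setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

.SIM_KINDS <- c("functional", "semantic1", "semantic2", "semantic",
                "gip_mirna", "gip_disease",
                "integrated_mirna", "integrated_disease")

## kinds whose diagonal is 1 by construction (self-similarity)
.UNIT_DIAG_KINDS <- c("semantic1", "semantic2", "semantic",
                      "gip_mirna", "gip_disease")

.checkIds <- function(ids, what) {
  if (is.null(ids) || length(ids) == 0L)
    return(sprintf("%s identifiers are missing", what))
  if (anyDuplicated(ids))
    return(sprintf("duplicated %s identifiers: %s", what,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (anyNA(ids) || any(!nzchar(ids)))
    return(sprintf("empty or NA %s identifiers", what))
  NULL
}

#' AssociationMatrix: binary miRNA-disease association matrix
#'
#' Stores the adjacency matrix \eqn{A} of the miRNA-disease bipartite
#' network: rows are miRNAs, columns are diseases, and \eqn{A[j,i] = 1}
#' iff miRNA \eqn{m_j} is known to be associated with disease \eqn{d_i}.
#' Row and column names carry the ordered, duplicate-free identifier
#' lists.
#'
#' @slot assoc numeric matrix with entries in \{0, 1\} and complete
#'   dimnames.
#'
#' @seealso [AssociationMatrix()] for construction,
#'   [readAssociationTable()] to load one from an edge list.
#' @export
setClass("AssociationMatrix", slots = c(assoc = "matrix"))

setValidity("AssociationMatrix", function(object) {
  a <- object@assoc
  if (!is.numeric(a)) return("association matrix must be numeric")
  if (nrow(a) < 1L || ncol(a) < 1L)
    return("association matrix needs at least one miRNA and one disease")
  msg <- c(.checkIds(rownames(a), "miRNA"), .checkIds(colnames(a), "disease"))
  if (!is.null(msg)) return(msg)
  if (anyNA(a) || !all(a %in% c(0, 1)))
    return("association matrix entries must all be 0 or 1")
  TRUE
})

#' Construct an AssociationMatrix
#'
#' @param values binary matrix, rows = miRNAs, columns = diseases.
#' @param mirnaIds,diseaseIds ordered unique identifiers; default to the
#'   dimnames of `values`.
#' @return An [AssociationMatrix-class] object.
#' @examples
#' a <- AssociationMatrix(rbind(c(1, 0), c(1, 1)),
#'                        mirnaIds = c("m1", "m2"),
#'                        diseaseIds = c("d1", "d2"))
#' mirnaIds(a)
#' @export
AssociationMatrix <- function(values,
                              mirnaIds = rownames(values),
                              diseaseIds = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(mirnaIds), as.character(diseaseIds))
  new("AssociationMatrix", assoc = values)
}

#' SimilarityMatrix: labeled symmetric similarity matrix
#'
#' A square symmetric matrix of pairwise similarities in \[0, 1\] over a
#' single identifier set (miRNAs or diseases), tagged with the kind of
#' similarity it holds. Semantic and Gaussian-kernel kinds have unit
#' diagonal by construction.
#'
#' @slot values numeric symmetric matrix with identical row/column names.
#' @slot kind one of `"functional"`, `"semantic1"`, `"semantic2"`,
#'   `"semantic"`, `"gip_mirna"`, `"gip_disease"`, `"integrated_mirna"`,
#'   `"integrated_disease"`.
#' @export
setClass("SimilarityMatrix", slots = c(values = "matrix", kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v))
    return("similarity values must form a square numeric matrix")
  msg <- .checkIds(rownames(v), "similarity")
  if (!is.null(msg)) return(msg)
  if (!identical(rownames(v), colnames(v)))
    return("row and column identifiers must be identical and in the same order")
  if (length(object@kind) != 1L || !object@kind %in% .SIM_KINDS)
    return(sprintf("kind must be one of: %s", paste(.SIM_KINDS, collapse = ", ")))
  if (anyNA(v)) return("similarity values must not contain NA")
  if (max(abs(v - t(v))) > 1e-12)
    return("similarity matrix must be symmetric within 1e-12")
  if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
    return("similarity values must lie in [0, 1]")
  if (object@kind %in% .UNIT_DIAG_KINDS && any(abs(diag(v) - 1) > 1e-9))
    return(sprintf("kind '%s' requires a unit diagonal", object@kind))
  TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values square symmetric numeric matrix with entries in \[0, 1\].
#' @param ids ordered unique identifiers; default dimnames of `values`.
#' @param kind similarity kind tag (see [SimilarityMatrix-class]).
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values, ids = rownames(values),
                             kind = "functional") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(ids), as.character(ids))
  ## snap numerically-tiny violations introduced by arithmetic
  values[values < 0 & values > -1e-12] <- 0
  values[values > 1 & values < 1 + 1e-12] <- 1
  new("SimilarityMatrix", values = values, kind = kind)
}

#' DiseaseDAGSet: per-disease ancestor DAGs
#'
#' One directed acyclic graph per disease, in the MeSH style: nodes are
#' ontology terms, edges point child -> parent, and every node of a
#' disease's graph is an ancestor of (or equal to) the disease's own
#' term.
#'
#' @slot graphs named list (one element per disease), each a list with
#'   `term` (the disease's own term), `terms` (all terms, i.e.
#'   \eqn{T(S)}), and `edges` (character matrix with columns `child`,
#'   `parent`; zero rows for a singleton DAG).
#' @export
setClass("DiseaseDAGSet", slots = c(graphs = "list"))

.validateDag <- function(g, id) {
  need <- c("term", "terms", "edges")
  if (!is.list(g) || !all(need %in% names(g)))
    return(sprintf("DAG for '%s' must have elements term, terms, edges", id))
  if (!g$term %in% g$terms)
    return(sprintf("disease '%s': its own term '%s' is absent from its graph",
                   id, g$term))
  e <- g$edges
  if (!is.matrix(e) || ncol(e) != 2L)
    return(sprintf("disease '%s': edges must be a 2-column matrix", id))
  if (nrow(e)) {
    if (!all(c(e) %in% g$terms))
      return(sprintf("disease '%s': edge endpoints outside the term set", id))
    ig <- igraph::graph_from_edgelist(e, directed = TRUE)
    if (!igraph::is_dag(ig))
      return(sprintf("cycle detected in the DAG of disease '%s'", id))
    reach <- igraph::subcomponent(ig, g$term, mode = "out")$name
    if (!setequal(union(reach, g$term), g$terms))
      return(sprintf(
        "disease '%s': not all terms are reachable from '%s' by parent edges",
        id, g$term))
  } else if (length(g$terms) != 1L) {
    return(sprintf("disease '%s': multiple terms but no edges", id))
  }
  NULL
}

setValidity("DiseaseDAGSet", function(object) {
  g <- object@graphs
  msg <- .checkIds(names(g), "disease")
  if (!is.null(msg)) return(msg)
  for (id in names(g)) {
    m <- .validateDag(g[[id]], id)
    if (!is.null(m)) return(m)
  }
  TRUE
})

#' Construct a DiseaseDAGSet
#'
#' @param graphs named list of per-disease graphs; each element is a list
#'   with `term` (character scalar), `terms` (character vector) and
#'   `edges` (2-column character matrix, child then parent).
#' @return A [DiseaseDAGSet-class] object.
#' @seealso [readDiseaseDAGs()] for the on-disk edge-list format.
#' @export
DiseaseDAGSet <- function(graphs) {
  graphs <- lapply(graphs, function(g) {
    e <- g$edges
    if (is.null(e)) e <- matrix(character(), 0L, 2L)
    if (!is.matrix(e)) e <- matrix(as.character(e), ncol = 2L)
    colnames(e) <- c("child", "parent")
    list(term = as.character(g$term),
         terms = as.character(g$terms),
         edges = e)
  })
  new("DiseaseDAGSet", graphs = graphs)
}

#' TransferWeights: similarity-weighted bipartite edge weights
#'
#' The pair of weight matrices placed on the bipartite edges before
#' propagation: `wr[j, i]` weights the edge from miRNA \eqn{m_j} to
#' disease \eqn{d_i} (miRNA-similarity-weighted fraction of miRNAs
#' associated with \eqn{d_i}); `wd[j, i]` weights the reverse edge using
#' disease similarity. Both are weighted averages of binary entries, so
#' lie in \[0, 1\].
#'
#' @slot wr,wd numeric nm x nd matrices with shared dimnames.
#' @export
setClass("TransferWeights", slots = c(wr = "matrix", wd = "matrix"))

setValidity("TransferWeights", function(object) {
  wr <- object@wr; wd <- object@wd
  if (!identical(dim(wr), dim(wd)) || !identical(dimnames(wr), dimnames(wd)))
    return("wr and wd must share dimensions and dimnames")
  msg <- c(.checkIds(rownames(wr), "miRNA"), .checkIds(colnames(wr), "disease"))
  if (!is.null(msg)) return(msg)
  for (w in list(wr, wd))
    if (anyNA(w) || min(w) < -1e-12 || max(w) > 1 + 1e-12)
      return("transfer weights must lie in [0, 1]")
  TRUE
})

.SCORE_STAGES <- c("initial", "disease_based", "mirna_based", "final")

#' ScoreMatrix: recommendation scores over miRNA-disease pairs
#'
#' Real-valued nm x nd matrix produced at the successive stages of the
#' projection: the popularity-damped initial information, the
#' disease-based and miRNA-based propagation outputs, and their average
#' (the final prediction).
#'
#' @slot values numeric matrix, rows = miRNAs, columns = diseases;
#'   finite and nonnegative.
#' @slot stage one of `"initial"`, `"disease_based"`, `"mirna_based"`,
#'   `"final"`.
#' @export
setClass("ScoreMatrix", slots = c(values = "matrix", stage = "character"))

setValidity("ScoreMatrix", function(object) {
  v <- object@values
  msg <- c(.checkIds(rownames(v), "miRNA"), .checkIds(colnames(v), "disease"))
  if (!is.null(msg)) return(msg)
  if (length(object@stage) != 1L || !object@stage %in% .SCORE_STAGES)
    return(sprintf("stage must be one of: %s",
                   paste(.SCORE_STAGES, collapse = ", ")))
  if (anyNA(v) || any(!is.finite(v))) return("scores must be finite")
  if (min(v) < -1e-12) return("scores must be nonnegative")
  TRUE
})

#' Construct a ScoreMatrix
#' @param values numeric matrix with dimnames (miRNAs x diseases).
#' @param stage pipeline stage tag.
#' @return A [ScoreMatrix-class] object.
#' @export
ScoreMatrix <- function(values, stage = "final") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ScoreMatrix", values = values, stage = stage)
}

#' CVResult: cross-validation outcome
#'
#' Per-held-out-pair score records plus the AUC summary for a
#' leave-one-out or repeated k-fold run.
#'
#' @slot records data.frame with one row per held-out known association:
#'   `mirna`, `disease`, `score`, `quantile` (fraction of the fold's
#'   negative scores it beats, ties counted half), `rank` (1-based rank
#'   among the fold's candidate pairs), `fold`, `repetition`.
#' @slot auc pooled AUC (LOOCV, or a single repetition).
#' @slot aucs per-repetition AUCs (k-fold).
#' @slot aucMean,aucSd mean and standard deviation over repetitions.
#' @slot baselineAuc AUC of the degree-product baseline on the same
#'   folds (NA unless requested).
#' @slot failed data.frame describing folds that could not be scored
#'   (isolated nodes), with `mirna`, `disease`, `repetition`, `message`.
#' @slot seed integer seed driving all randomness of the run.
#' @slot protocol `"loocv"` or `"kfold"`.
#' @export
setClass("CVResult",
         slots = c(records = "data.frame", auc = "numeric",
                   aucs = "numeric", aucMean = "numeric", aucSd = "numeric",
                   baselineAuc = "numeric", failed = "data.frame",
                   seed = "integer", protocol = "character"))

setValidity("CVResult", function(object) {
  if (!object@protocol %in% c("loocv", "kfold"))
    return("protocol must be 'loocv' or 'kfold'")
  ok <- function(x) length(x) == 0L || all(is.na(x)) ||
    (min(x, na.rm = TRUE) >= 0 && max(x, na.rm = TRUE) <= 1)
  if (!ok(object@auc) || !ok(object@aucs) || !ok(object@aucMean))
    return("AUC values must lie in [0, 1]")
  TRUE
})
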