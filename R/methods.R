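## Accessor and show methods for the core classes.

#' @rdname accessors
setMethod("mirnaIds", "AssociationMatrix", function(x) rownames(x@assoc))

#' @rdname accessors
setMethod("diseaseIds", "AssociationMatrix", function(x) colnames(x@assoc))

#' @rdname accessors
setMethod("nMirna", "AssociationMatrix", function(x) nrow(x@assoc))

#' @rdname accessors
setMethod("nDisease", "AssociationMatrix", function(x) ncol(x@assoc))

#' @rdname accessors
setMethod("diseaseIds", "DiseaseDAGSet", function(x) names(x@graphs))

#' @rdname accessors
setMethod("mirnaIds", "ScoreMatrix", function(x) rownames(x@values))

#' @rdname accessors
setMethod("diseaseIds", "ScoreMatrix", function(x) colnames(x@values))

#' @rdname accessors
setMethod("simIds", "SimilarityMatrix", function(x) rownames(x@values))

#' @rdname accessors
setMethod("simKind", "SimilarityMatrix", function(x) x@kind)

#' @rdname accessors
setMethod("scoreStage", "ScoreMatrix", function(x) x@stage)

#' @rdname accessors
setMethod("transferWr", "TransferWeights", function(x) x@wr)

#' @rdname accessors
setMethod("transferWd", "TransferWeights", function(x) x@wd)

#' Extract the underlying matrix
#'
#' @param x an [AssociationMatrix-class], [SimilarityMatrix-class] or
#'   [ScoreMatrix-class].
#' @param ... ignored.
#' @return The numeric matrix with its dimnames.
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) x@assoc)

#' @rdname as.matrix-AssociationMatrix-method
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)

#' @rdname as.matrix-AssociationMatrix-method
#' @export
setMethod("as.matrix", "ScoreMatrix", function(x, ...) x@values)

#' Extract one disease's DAG
#'
#' @param x a [DiseaseDAGSet-class].
#' @param disease disease identifier.
#' @return A list with `term`, `terms` and `edges` (child -> parent).
#' @export
diseaseDAG <- function(x, disease) {
  stopifnot(is(x, "DiseaseDAGSet"))
  if (!disease %in% names(x@graphs))
    stop("no DAG for disease '", disease, "'")
  x@graphs[[disease]]
}

setMethod("show", "AssociationMatrix", function(object) {
  a <- object@assoc
  cat(sprintf("AssociationMatrix: %d miRNAs x %d diseases, %d known associations\n",
              nrow(a), ncol(a), as.integer(sum(a))))
  cat("  miRNAs:  ", paste(head(rownames(a), 4L), collapse = ", "),
      if (nrow(a) > 4L) ", ..." else "", "\n", sep = "")
  cat("  diseases:", paste(head(colnames(a), 4L), collapse = ", "),
      if (ncol(a) > 4L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  cat(sprintf("SimilarityMatrix (kind '%s'): %d x %d, off-diagonal range [%.3g, %.3g]\n",
              object@kind, nrow(v), ncol(v),
              if (nrow(v) > 1L) min(v[row(v) != col(v)]) else NA_real_,
              if (nrow(v) > 1L) max(v[row(v) != col(v)]) else NA_real_))
})

setMethod("show", "DiseaseDAGSet", function(object) {
  sizes <- vapply(object@graphs, function(g) length(g$terms), integer(1))
  cat(sprintf("DiseaseDAGSet: %d diseases, DAG sizes %d-%d terms\n",
              length(object@graphs), min(sizes), max(sizes)))
})

setMethod("show", "TransferWeights", function(object) {
  cat(sprintf("TransferWeights: %d miRNAs x %d diseases (wr, wd)\n",
              nrow(object@wr), ncol(object@wr)))
})

setMethod("show", "ScoreMatrix", function(object) {
  v <- object@values
  cat(sprintf("ScoreMatrix (stage '%s'): %d miRNAs x %d diseases, scores in [%.3g, %.3g]\n",
              object@stage, nrow(v), ncol(v), min(v), max(v)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s, seed %d): %d scored folds",
              object@protocol, object@seed, nrow(object@records)))
  if (nrow(object@failed)) cat(sprintf(", %d failed", nrow(object@failed)))
  cat("\n")
  if (object@protocol == "kfold" && length(object@aucs) > 1L)
    cat(sprintf("  AUC %.4f +/- %.4f over %d repetitions\n",
                object@aucMean, object@aucSd, length(object@aucs)))
  else
    cat(sprintf("  AUC %.4f\n", object@auc))
  if (!is.na(object@baselineAuc))
    cat(sprintf("  degree-product baseline AUC %.4f\n", object@baselineAuc))
})

#' Drop isolated miRNAs and diseases
#'
#' The projection cannot score a miRNA or disease with no known
#' association (its weighted degree is zero), so such nodes must be
#' removed before prediction.
#'
#' @param assoc an [AssociationMatrix-class].
#' @return An [AssociationMatrix-class] without all-zero rows/columns.
#' @export
dropIsolated <- function(assoc) {
  a <- as.matrix(assoc)
  keepR <- rowSums(a) > 0
  keepC <- colSums(a) > 0
  if (!any(keepR) || !any(keepC))
    stop("all nodes are isolated: the association matrix is empty")
  if (all(keepR) && all(keepC)) return(assoc)
  AssociationMatrix(a[keepR, keepC, drop = FALSE])
}
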