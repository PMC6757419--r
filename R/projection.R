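## The projection core: similarity-derived transfer weights,
## popularity-damped initial information, two-step weighted bipartite
## propagation in each direction, and fusion of the two score matrices.

#' Transfer weights from integrated similarities
#'
#' Each bipartite edge gets a weight equal to the similarity-weighted
#' fraction of the partner side's associations:
#' \deqn{wr(m_j, d_i) = \frac{\sum_k MS(m_j, m_k) A(m_k, d_i)}
#'                           {\sum_k MS(m_j, m_k)}}
#' and symmetrically for `wd` with disease similarity over the columns
#' of \eqn{A}. The sums include the self term, so with unit diagonals
#' the denominators are always positive. Weighted averages of binary
#' entries stay in \[0, 1\].
#'
#' @param assoc an [AssociationMatrix-class].
#' @param ms integrated miRNA [SimilarityMatrix-class] (nm x nm),
#'   label-aligned with the rows of `assoc`.
#' @param ds integrated disease [SimilarityMatrix-class] (nd x nd),
#'   label-aligned with the columns.
#' @return A [TransferWeights-class].
#' @export
transferWeights <- function(assoc, ms, ds) {
  a <- as.matrix(assoc)
  msv <- as.matrix(ms); dsv <- as.matrix(ds)
  if (!identical(rownames(a), rownames(msv)) ||
      !identical(rownames(msv), colnames(msv)))
    stop("miRNA similarity labels must match the association rows")
  if (!identical(colnames(a), rownames(dsv)) ||
      !identical(rownames(dsv), colnames(dsv)))
    stop("disease similarity labels must match the association columns")
  msRow <- rowSums(msv)
  if (any(msRow == 0))
    stop("miRNA similarity rows summing to zero: ",
         paste(rownames(msv)[msRow == 0], collapse = ", "))
  dsRow <- rowSums(dsv)
  if (any(dsRow == 0))
    stop("disease similarity rows summing to zero: ",
         paste(rownames(dsv)[dsRow == 0], collapse = ", "))
  wr <- (msv %*% a) / msRow
  ## wd[j, i] = sum_k DS(i, k) A(j, k) / sum_k DS(i, k)
  wd <- sweep(a %*% dsv, 2L, dsRow, `/`)
  dimnames(wr) <- dimnames(a); dimnames(wd) <- dimnames(a)
  new("TransferWeights", wr = wr, wd = wd)
}

#' Popularity-damped initial information
#'
#' Places resource on the known association edges, damped by the
#' popularity of the node on the chosen axis:
#' \eqn{S_{ini}(m_j, d_i) = A_{ji} \, k^\beta} with \eqn{k} the disease
#' degree (axis `"disease"`, used by the disease-based network) or the
#' miRNA degree (axis `"mirna"`). With \eqn{\beta < 0} associations of
#' highly connected nodes start with less resource; \eqn{\beta = 0} is
#' the undamped limit where the initial information equals \eqn{A}.
#' Entries with \eqn{A = 0} are zero regardless of degree.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param beta damping exponent in (-1, 0].
#' @param axis which degree damps the resource.
#' @return A [ScoreMatrix-class] with stage `"initial"`.
#' @export
initialInformation <- function(assoc, beta = -0.1,
                               axis = c("disease", "mirna")) {
  axis <- match.arg(axis)
  if (!(beta > -1 && beta <= 0)) stop("beta must lie in (-1, 0]")
  a <- as.matrix(assoc)
  if (axis == "disease") {
    k <- colSums(a)
    damp <- ifelse(k > 0, k^beta, 0)
    v <- sweep(a, 2L, damp, `*`)
  } else {
    k <- rowSums(a)
    damp <- ifelse(k > 0, k^beta, 0)
    v <- a * damp
  }
  ScoreMatrix(v, stage = "initial")
}

## Core of the two-step propagation for one orientation. W and sini are
## n_src x n_dst: sources hold the resource, it flows to destinations
## and back. Returns list(P = n_src x n_src propagation matrix,
## scores = P %*% sini).
.propagateCore <- function(W, sini, srcWhat, dstWhat) {
  dSrc <- rowSums(W)
  dDst <- colSums(W)
  if (any(dSrc <= 0))
    stop("cannot propagate: isolated ", srcWhat, " node(s) with zero ",
         "weighted degree: ", paste(rownames(W)[dSrc <= 0], collapse = ", "))
  if (any(dDst <= 0))
    stop("cannot propagate: isolated ", dstWhat, " node(s) with zero ",
         "weighted degree: ", paste(colnames(W)[dDst <= 0], collapse = ", "))
  ## P[j, k] = (1 / dSrc[k]) * sum_i W[j, i] W[k, i] / dDst[i]
  P <- sweep(W %*% (t(W) / dDst), 2L, dSrc, `/`)
  list(P = P, scores = P %*% sini)
}

#' Two-step weighted bipartite propagation
#'
#' Runs the two-step resource-allocation diffusion. In the
#' disease-based direction the resource sits on the miRNA side and
#' flows miRNA -> disease -> miRNA along the `wr` weights; the result
#' is \eqn{S_M = P \, S_{ini}} with the nm x nm propagation matrix
#' \deqn{P(m_j, m_k) = \frac{1}{d(m_k)} \sum_i
#'       \frac{wr(m_j, d_i)\, wr(m_k, d_i)}{d(d_i)}}
#' whose columns sum to 1, so total resource is conserved. The
#' miRNA-based direction is the exact mirror: `wd` weights,
#' disease-side resource, an nd x nd propagation matrix, producing
#' \eqn{S_D}. Both directions share this one code path (the mirror is a
#' transposition), guaranteeing symmetric treatment.
#'
#' @param weights a [TransferWeights-class].
#' @param sini the matching initial [ScoreMatrix-class] (disease-damped
#'   for `"disease_based"`, miRNA-damped for `"mirna_based"`).
#' @param direction `"disease_based"` or `"mirna_based"`.
#' @return A [ScoreMatrix-class] with the corresponding stage.
#' @export
propagate <- function(weights, sini,
                      direction = c("disease_based", "mirna_based")) {
  direction <- match.arg(direction)
  s <- as.matrix(sini)
  if (direction == "disease_based") {
    W <- transferWr(weights)
    if (!identical(dimnames(W), dimnames(s)))
      stop("weights and initial information must share labels")
    out <- .propagateCore(W, s, "miRNA", "disease")$scores
  } else {
    W <- t(transferWd(weights))
    if (!identical(dimnames(t(W)), dimnames(s)))
      stop("weights and initial information must share labels")
    out <- t(.propagateCore(W, t(s), "disease", "miRNA")$scores)
  }
  ScoreMatrix(pmax(out, 0), stage = direction)
}

#' Propagation matrix of one direction
#'
#' The node-to-node matrix P whose entry (j, k) is the fraction of node
#' k's resource that reaches node j after the two diffusion steps;
#' every column sums to 1. Exposed mainly for diagnostics and testing.
#'
#' @inheritParams propagate
#' @return nm x nm matrix for `"disease_based"`, nd x nd for
#'   `"mirna_based"`.
#' @export
propagationMatrix <- function(weights,
                              direction = c("disease_based", "mirna_based")) {
  direction <- match.arg(direction)
  if (direction == "disease_based") {
    W <- transferWr(weights)
    .propagateCore(W, matrix(0, nrow(W), ncol(W), dimnames = dimnames(W)),
                   "miRNA", "disease")$P
  } else {
    W <- t(transferWd(weights))
    .propagateCore(W, matrix(0, nrow(W), ncol(W), dimnames = dimnames(W)),
                   "disease", "miRNA")$P
  }
}

#' Fuse the two directional score matrices
#'
#' \eqn{S_{fin} = (S_M + S_D) / 2} elementwise.
#'
#' @param sm disease-based [ScoreMatrix-class].
#' @param sd mirna-based [ScoreMatrix-class] with identical labels.
#' @return A [ScoreMatrix-class] with stage `"final"`.
#' @export
finalScores <- function(sm, sd) {
  m <- as.matrix(sm); d <- as.matrix(sd)
  if (!identical(dimnames(m), dimnames(d)))
    stop("the two score matrices must share labels and order")
  ScoreMatrix((m + d) / 2, stage = "final")
}

#' Predict miRNA-disease association scores
#'
#' The full projection: transfer weights from the integrated
#' similarities, popularity-damped initial information on each axis,
#' two-step propagation in both directions, and the average of the two
#' resulting score matrices. Deterministic for fixed inputs.
#'
#' @param assoc an [AssociationMatrix-class] (no isolated nodes; see
#'   [dropIsolated()]).
#' @param ms,ds integrated miRNA / disease similarities, label-aligned
#'   with `assoc`.
#' @param beta popularity damping exponent in (-1, 0]; default -0.1.
#' @param direction `"both"` (default; the averaged final score),
#'   `"disease_based"` or `"mirna_based"` for a single direction.
#' @param weights optionally, precomputed [TransferWeights-class] to
#'   use instead of recomputing from `assoc` (cross-validation uses
#'   this to freeze stages).
#' @param siniDisease,siniMirna optionally, precomputed initial
#'   [ScoreMatrix-class] objects for the two axes.
#' @return A [ScoreMatrix-class].
#' @examples
#' ex <- generateWorkedExample()
#' s <- predictScores(ex$assoc, ex$ms, ex$ds, beta = -0.1)
#' as.matrix(s)
#' @export
predictScores <- function(assoc, ms, ds, beta = -0.1,
                          direction = c("both", "disease_based",
                                        "mirna_based"),
                          weights = NULL,
                          siniDisease = NULL, siniMirna = NULL) {
  direction <- match.arg(direction)
  if (is.null(weights)) weights <- transferWeights(assoc, ms, ds)
  if (direction %in% c("both", "disease_based")) {
    if (is.null(siniDisease))
      siniDisease <- initialInformation(assoc, beta, "disease")
    sm <- propagate(weights, siniDisease, "disease_based")
    if (direction == "disease_based") return(sm)
  }
  if (is.null(siniMirna))
    siniMirna <- initialInformation(assoc, beta, "mirna")
  sd <- propagate(weights, siniMirna, "mirna_based")
  if (direction == "mirna_based") return(sd)
  finalScores(sm, sd)
}
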