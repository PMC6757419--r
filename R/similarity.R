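## Disease semantic similarity from MeSH-style DAGs (two models plus
## their average), Gaussian interaction-profile kernels on both axes of
## the association matrix, and the integrated similarities that fall
## back on the kernel where primary similarity is unavailable.

#' Per-ancestor semantic contributions (model 1)
#'
#' In model 1 the disease's own term contributes 1 and each ancestor
#' term t contributes the best decayed contribution of its children
#' within the disease's DAG:
#' \deqn{D1_S(t) = \max\{\Delta \cdot D1_S(t') : t' \in children(t)\}}
#' so contributions decay geometrically with distance from the disease.
#'
#' @param dagSet a [DiseaseDAGSet-class].
#' @param disease disease identifier present in `dagSet`.
#' @param delta semantic contribution decay factor in (0, 1]; the
#'   conventional value 0.5 is the default.
#' @return Named numeric vector over the disease's term set \eqn{T(S)}.
#' @export
semanticContributionM1 <- function(dagSet, disease, delta = 0.5) {
  if (!(delta > 0 && delta <= 1)) stop("delta must be in (0, 1]")
  g <- diseaseDAG(dagSet, disease)
  contrib <- setNames(rep(NA_real_, length(g$terms)), g$terms)
  contrib[g$term] <- 1
  ## children of t within the DAG: nodes with an edge child -> t
  childrenOf <- split(g$edges[, 1L], g$edges[, 2L])
  evalTerm <- function(t) {
    if (!is.na(contrib[[t]])) return(contrib[[t]])
    kids <- childrenOf[[t]]
    v <- max(vapply(kids, evalTerm, numeric(1))) * delta
    contrib[[t]] <<- v
    v
  }
  for (t in g$terms) evalTerm(t)
  contrib
}

#' Per-ancestor semantic contributions (model 2)
#'
#' Model 2 scores a term by its information content across the whole DAG
#' collection: \eqn{D2_S(t) = -\log(n_t / n)} with \eqn{n_t} the number
#' of disease DAGs containing t and \eqn{n} the number of diseases. The
#' value is identical for a given term in every DAG; a term ubiquitous
#' across all DAGs contributes 0. Natural logarithm is used; the
#' similarity built from these values is invariant to the base since a
#' base change rescales numerator and denominator identically.
#'
#' @inheritParams semanticContributionM1
#' @return Named numeric vector over the disease's term set.
#' @export
semanticContributionM2 <- function(dagSet, disease) {
  g <- diseaseDAG(dagSet, disease)
  freq <- .termFrequencies(dagSet)
  -log(freq[g$terms] / length(dagSet@graphs))
}

.termFrequencies <- function(dagSet) {
  tab <- table(unlist(lapply(dagSet@graphs, `[[`, "terms"), use.names = FALSE))
  setNames(as.numeric(tab), names(tab))
}

#' Semantic value of a disease
#'
#' The sum of the contributions of all terms in the disease's DAG,
#' \eqn{DV(S) = \sum_{t \in T(S)} D_S(t)}.
#'
#' @param contrib named contribution vector from
#'   [semanticContributionM1()] or [semanticContributionM2()].
#' @return A single number.
#' @export
semanticValue <- function(contrib) sum(contrib)

#' Disease semantic similarity matrix
#'
#' Pairwise similarity of diseases from their shared DAG ancestry:
#' \deqn{SS(A,B) = \frac{\sum_{t \in T(A) \cap T(B)} (D_A(t) + D_B(t))}
#'                     {DV(A) + DV(B)}}
#' with contributions from model 1 (depth decay), model 2 (information
#' content), or their elementwise average (`"combined"`, the default
#' used downstream). Self-similarity is 1; diseases with disjoint term
#' sets score 0. Under model 2 a pair whose semantic values are both
#' zero (all terms ubiquitous) is given similarity 0 with a warning.
#'
#' @param dagSet a [DiseaseDAGSet-class] covering all diseases.
#' @param delta decay factor for model 1.
#' @param model `"1"`, `"2"` or `"combined"`.
#' @return A [SimilarityMatrix-class] of kind `semantic1`, `semantic2`
#'   or `semantic`.
#' @export
semanticSimilarity <- function(dagSet, delta = 0.5,
                               model = c("combined", "1", "2")) {
  model <- match.arg(as.character(model), c("combined", "1", "2"))
  if (model == "combined") {
    s1 <- as.matrix(semanticSimilarity(dagSet, delta, "1"))
    s2 <- as.matrix(semanticSimilarity(dagSet, delta, "2"))
    return(SimilarityMatrix((s1 + s2) / 2, kind = "semantic"))
  }
  ids <- diseaseIds(dagSet)
  contribs <- if (model == "1")
    lapply(setNames(ids, ids), semanticContributionM1,
           dagSet = dagSet, delta = delta)
  else
    lapply(setNames(ids, ids), semanticContributionM2, dagSet = dagSet)
  dv <- vapply(contribs, semanticValue, numeric(1))
  n <- length(ids)
  ss <- diag(1, n)
  dimnames(ss) <- list(ids, ids)
  warned <- FALSE
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    shared <- intersect(names(contribs[[i]]), names(contribs[[j]]))
    denom <- dv[i] + dv[j]
    val <- if (denom == 0) {
      warned <- TRUE
      0
    } else if (length(shared)) {
      sum(contribs[[i]][shared] + contribs[[j]][shared]) / denom
    } else 0
    ss[i, j] <- ss[j, i] <- val
  }
  if (warned)
    warning("some disease pairs have zero semantic value under model 2; ",
            "their similarity is set to 0")
  SimilarityMatrix(ss, kind = if (model == "1") "semantic1" else "semantic2")
}

#' Gaussian interaction-profile kernel similarity
#'
#' Treats each disease (column of \eqn{A}) or miRNA (row) as a binary
#' interaction profile and scores pairs with a radial basis function,
#' \eqn{K(i,j) = \exp(-\beta \, \|IP_i - IP_j\|^2)}. The bandwidth is
#' the user bandwidth rescaled by the mean squared profile norm; the
#' default convention divides by it,
#' \eqn{\beta = \beta' / \overline{\|IP\|^2}}, which makes the kernel
#' invariant to the overall density of the network
#' (`bandwidthForm = "multiply"` instead multiplies, preserving the
#' alternative convention in which denser networks get sharper kernels).
#'
#' @param assoc an [AssociationMatrix-class]; must contain at least one
#'   association.
#' @param axis `"disease"` (profiles are columns) or `"mirna"` (rows).
#' @param bandwidthPrime original kernel bandwidth \eqn{\beta' > 0},
#'   default 1.
#' @param bandwidthForm `"divide"` (default) or `"multiply"`.
#' @return A [SimilarityMatrix-class] of kind `gip_disease` or
#'   `gip_mirna`, unit diagonal.
#' @export
gipKernel <- function(assoc, axis = c("disease", "mirna"),
                      bandwidthPrime = 1,
                      bandwidthForm = c("divide", "multiply")) {
  axis <- match.arg(axis)
  bandwidthForm <- match.arg(bandwidthForm)
  if (bandwidthPrime <= 0) stop("bandwidthPrime must be positive")
  a <- as.matrix(assoc)
  prof <- if (axis == "disease") t(a) else a   # profiles as rows
  sq <- rowSums(prof^2)
  meanSq <- mean(sq)
  if (meanSq == 0)
    stop("empty interaction profiles: the association matrix is all zero")
  beta <- if (bandwidthForm == "divide") bandwidthPrime / meanSq
          else bandwidthPrime * meanSq
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(prof)
  d2[d2 < 0] <- 0   # numeric noise
  k <- exp(-beta * d2)
  diag(k) <- 1
  k <- (k + t(k)) / 2
  SimilarityMatrix(k, kind = paste0("gip_", axis))
}

#' Integrate primary and kernel similarity
#'
#' Elementwise selection: pairs for which primary similarity is
#' available keep it; the rest fall back on the Gaussian
#' interaction-profile kernel. Used both for miRNAs (functional
#' similarity vs miRNA kernel) and for diseases (combined semantic
#' similarity vs disease kernel).
#'
#' @param primary a [SimilarityMatrix-class] with the primary scores.
#' @param gip a [SimilarityMatrix-class] with the kernel scores; must
#'   carry the same identifiers in the same order as `primary`.
#' @param hasPrimary either a logical matrix (per-pair mask, TRUE =
#'   take the primary value) or a character vector of identifiers that
#'   have primary information (the mask is then TRUE for pairs where
#'   both ids are covered). Defaults to all pairs.
#' @return A [SimilarityMatrix-class] of kind `integrated_mirna` or
#'   `integrated_disease` according to the kernel axis.
#' @export
integrateSimilarity <- function(primary, gip, hasPrimary = NULL) {
  p <- as.matrix(primary); k <- as.matrix(gip)
  if (!identical(dimnames(p), dimnames(k)))
    stop("primary and kernel similarity matrices must share labels and order")
  mask <- if (is.null(hasPrimary)) {
    matrix(TRUE, nrow(p), ncol(p))
  } else if (is.matrix(hasPrimary)) {
    if (!identical(dim(hasPrimary), dim(p)))
      stop("mask dimensions do not match the similarity matrices")
    hasPrimary
  } else {
    cov <- rownames(p) %in% as.character(hasPrimary)
    outer(cov, cov, `&`)
  }
  out <- ifelse(mask, p, k)
  dimnames(out) <- dimnames(p)
  kind <- if (simKind(gip) == "gip_mirna") "integrated_mirna"
          else "integrated_disease"
  SimilarityMatrix(out, kind = kind)
}

#' Integrated miRNA similarity from functional scores
#'
#' Aligns an (optionally partial) functional-similarity matrix to the
#' miRNAs of the association matrix, computes the miRNA interaction
#' kernel, and integrates the two: a pair takes its functional score
#' when both miRNAs appear in the functional matrix, the kernel value
#' otherwise.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param fs a [SimilarityMatrix-class] of functional scores whose
#'   identifiers are a subset (or superset) of the association miRNAs.
#' @inheritParams gipKernel
#' @return A [SimilarityMatrix-class] of kind `integrated_mirna`.
#' @export
integratedMirnaSimilarity <- function(assoc, fs, bandwidthPrime = 1,
                                      bandwidthForm = "divide") {
  ids <- mirnaIds(assoc)
  km <- gipKernel(assoc, "mirna", bandwidthPrime, bandwidthForm)
  covered <- intersect(ids, simIds(fs))
  p <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  p[covered, covered] <- as.matrix(fs)[covered, covered]
  integrateSimilarity(SimilarityMatrix(p, kind = "functional"), km,
                      hasPrimary = covered)
}

#' Integrated disease similarity from DAG semantics
#'
#' Combined (model-1/model-2 average) semantic similarity for diseases
#' that have DAGs, disease interaction kernel for the rest.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param dagSet a [DiseaseDAGSet-class]; diseases without a DAG fall
#'   back on the kernel for every pair involving them.
#' @param delta model-1 decay factor.
#' @inheritParams gipKernel
#' @return A [SimilarityMatrix-class] of kind `integrated_disease`.
#' @export
integratedDiseaseSimilarity <- function(assoc, dagSet, delta = 0.5,
                                        bandwidthPrime = 1,
                                        bandwidthForm = "divide") {
  ids <- diseaseIds(assoc)
  kd <- gipKernel(assoc, "disease", bandwidthPrime, bandwidthForm)
  covered <- intersect(ids, diseaseIds(dagSet))
  p <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(covered)) {
    ss <- as.matrix(semanticSimilarity(dagSet, delta, "combined"))
    p[covered, covered] <- ss[covered, covered]
  }
  integrateSimilarity(SimilarityMatrix(p, kind = "functional"), kd,
                      hasPrimary = covered)
}
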