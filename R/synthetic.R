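## Synthetic inputs with planted community structure. The generator
## emulates the three real inputs (association edge list, functional
## similarity matrix, disease DAG set) at configurable size so the full
## pipeline and its cross-validation harness run with no download.

## One user seed drives a named sub-stream per artifact so changing the
## DAG construction cannot perturb the association draw.
.subSeeds <- function(seed) {
  set.seed(as.integer(seed))
  setNames(sample.int(.Machine$integer.max - 1L, 3L), c("A", "FS", "DAG"))
}

#' Generate a synthetic miRNA-disease dataset
#'
#' miRNAs and diseases are assigned round-robin to `nBlocks` latent
#' communities; associations are Bernoulli with probability `pWithin`
#' inside a block and `pBetween` across, resampled (up to `maxRetries`
#' times) until no miRNA or disease is isolated. The functional
#' similarity blends block co-membership with uniform noise,
#' \eqn{FS(i,j) = clamp(s \cdot same + (1-s) \cdot U(0,1))} with
#' \eqn{s} = `fsSignal`, symmetrized, unit diagonal. Disease DAGs hang
#' each disease off a per-block ancestor chain that meets a global root,
#' so same-block diseases share more ancestors. Everything is
#' reproducible from `seed`.
#'
#' The defaults are the reference study conditions used throughout the
#' package's tests: two communities of moderate size with a strong
#' within-block association signal and informative but noisy
#' similarities.
#'
#' @param nm,nd numbers of miRNAs and diseases.
#' @param nBlocks number of planted communities.
#' @param pWithin,pBetween association probabilities within / across
#'   blocks (`pWithin >= pBetween`).
#' @param fsSignal in \[0, 1\]: how strongly functional similarity
#'   reflects block co-membership (1 = noise-free block indicator).
#' @param dagDepth maximum DAG depth (edges from a disease's own term
#'   to the global root).
#' @param seed integer seed.
#' @param maxRetries resampling attempts before giving up on an
#'   isolation-free association matrix.
#' @return A list with `assoc` ([AssociationMatrix-class]),
#'   `fs` ([SimilarityMatrix-class], kind `functional`),
#'   `dags` ([DiseaseDAGSet-class]), and `blocks` (list of the two
#'   block-assignment vectors, for diagnostics).
#' @examples
#' d <- generateDataset(nm = 20, nd = 12, seed = 7)
#' d$assoc
#' @export
generateDataset <- function(nm = 60L, nd = 40L, nBlocks = 2L,
                            pWithin = 0.6, pBetween = 0.02,
                            fsSignal = 0.8, dagDepth = 4L, seed = 1L,
                            maxRetries = 100L) {
  stopifnot(nm >= 1L, nd >= 1L, nBlocks >= 1L, dagDepth >= 1L,
            pWithin >= 0, pWithin <= 1, pBetween >= 0, pBetween <= 1,
            fsSignal >= 0, fsSignal <= 1)
  if (pWithin < pBetween) stop("pWithin must be at least pBetween")
  seeds <- .subSeeds(seed)
  mids <- sprintf("miR-%03d", seq_len(nm))
  dids <- sprintf("disease-%03d", seq_len(nd))
  blockM <- rep_len(seq_len(nBlocks), nm)
  blockD <- rep_len(seq_len(nBlocks), nd)

  set.seed(seeds[["A"]])
  p <- ifelse(outer(blockM, blockD, `==`), pWithin, pBetween)
  a <- NULL
  for (try in seq_len(maxRetries)) {
    cand <- matrix(rbinom(nm * nd, 1L, p), nm, nd)
    if (all(rowSums(cand) > 0) && all(colSums(cand) > 0)) { a <- cand; break }
  }
  if (is.null(a))
    stop("could not draw an association matrix without isolated nodes in ",
         maxRetries, " attempts; raise pWithin/pBetween or the retry budget")
  dimnames(a) <- list(mids, dids)
  assoc <- AssociationMatrix(a)

  set.seed(seeds[["FS"]])
  same <- outer(blockM, blockM, `==`) * 1
  noise <- matrix(runif(nm * nm), nm, nm)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  fs <- pmin(pmax(fsSignal * same + (1 - fsSignal) * noise, 0), 1)
  diag(fs) <- 1
  dimnames(fs) <- list(mids, mids)
  fs <- SimilarityMatrix(fs, kind = "functional")

  set.seed(seeds[["DAG"]])
  dags <- .syntheticDags(dids, blockD, dagDepth)

  list(assoc = assoc, fs = fs, dags = dags,
       blocks = list(mirna = setNames(blockM, mids),
                     disease = setNames(blockD, dids)))
}

## Per-block ancestor chains meeting at a global root; each disease
## attaches its own term at a random depth of its block's chain.
.syntheticDags <- function(dids, blockD, dagDepth) {
  root <- "TERM-ROOT"
  chains <- lapply(sort(unique(blockD)), function(b) {
    depth <- max(dagDepth - 1L, 0L)
    if (depth == 0L) return(character())
    sprintf("TERM-B%d-L%d", b, seq_len(depth))
  })
  graphs <- lapply(seq_along(dids), function(i) {
    id <- dids[i]
    chain <- chains[[blockD[i]]]
    if (!length(chain)) {
      ## depth 1: the disease's term sits directly under the root
      edges <- matrix(c(id, root), 1L, 2L)
      return(list(term = id, terms = c(id, root), edges = edges))
    }
    attach <- sample.int(length(chain), 1L)       # deeper = more sharing
    anc <- chain[seq_len(attach)]                  # L1..Lattach
    ## chain runs Lk -> Lk-1 -> ... -> L1 -> root; disease -> Lattach
    edges <- rbind(
      cbind(id, anc[attach]),
      if (attach > 1L) cbind(anc[seq(attach, 2L)], anc[seq(attach - 1L, 1L)]),
      cbind(anc[1L], root))
    list(term = id, terms = c(id, rev(anc), root), edges = edges)
  })
  names(graphs) <- dids
  DiseaseDAGSet(graphs)
}

#' The fixed worked example
#'
#' The tiny instance used throughout the documentation and tests:
#' 3 miRNAs, 2 diseases,
#' \eqn{A = [[1,0],[1,1],[0,1]]}, a fixed integrated miRNA similarity
#' and a fixed integrated disease similarity. Every intermediate of the
#' projection on this instance (transfer weights, damped initial
#' information at \eqn{\beta = -0.1}, propagation matrices, both
#' directional scores and their average) is small enough to evaluate by
#' hand.
#'
#' @return A list with `assoc`, `ms`, `ds` and the reference `beta`.
#' @examples
#' ex <- generateWorkedExample()
#' transferWr(transferWeights(ex$assoc, ex$ms, ex$ds))
#' @export
generateWorkedExample <- function() {
  mids <- c("m1", "m2", "m3"); dids <- c("d1", "d2")
  a <- matrix(c(1, 1, 0,
                0, 1, 1), 3L, 2L, dimnames = list(mids, dids))
  ms <- matrix(c(1, 0.5, 0.1,
                 0.5, 1, 0.2,
                 0.1, 0.2, 1), 3L, 3L, dimnames = list(mids, mids))
  ds <- matrix(c(1, 0.3,
                 0.3, 1), 2L, 2L, dimnames = list(dids, dids))
  list(assoc = AssociationMatrix(a),
       ms = SimilarityMatrix(ms, kind = "integrated_mirna"),
       ds = SimilarityMatrix(ds, kind = "integrated_disease"),
       beta = -0.1)
}

#' Write a synthetic dataset to disk
#'
#' Emits the three artifacts in the package's file dialects
#' (association edge list, labeled similarity matrix, DAG edge list).
#'
#' @param dataset a list as returned by [generateDataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             fs = file.path(dir, "functional_similarity.tsv"),
             dags = file.path(dir, "disease_dags.tsv"))
  writeAssociationTable(dataset$assoc, paths[["associations"]])
  writeSimilarityMatrix(dataset$fs, paths[["fs"]])
  writeDiseaseDAGs(dataset$dags, paths[["dags"]])
  invisible(paths)
}
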