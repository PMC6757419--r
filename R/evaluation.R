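## Cross-validated evaluation: ROC/AUC, leave-one-out and repeated
## k-fold protocols over the full pipeline, the damping-parameter
## sweep, and per-disease candidate extraction.

#' ROC curve and AUC from scores and labels
#'
#' AUC by the rank-sum (Mann-Whitney) formulation with ties counted
#' half; the curve is built by sweeping a threshold over the distinct
#' scores.
#'
#' @param score numeric scores (higher = more likely positive).
#' @param label 0/1 (or logical) labels; both classes must be present.
#' @return A list with `auc` (number) and `roc` (data.frame with
#'   `threshold`, `fpr`, `tpr`, starting at (0,0) and ending at (1,1)).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))$auc
#' @export
rocAuc <- function(score, label) {
  label <- as.numeric(label)
  if (length(score) != length(label) || anyNA(score) || anyNA(label))
    stop("score and label must be equal-length and NA-free")
  if (!all(label %in% c(0, 1))) stop("labels must be 0 or 1")
  npos <- sum(label == 1); nneg <- sum(label == 0)
  if (npos == 0 || nneg == 0)
    stop("need at least one positive and one negative label")
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[label == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(score), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(score >= t & label == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(score >= t & label == 0), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / nneg), tpr = c(0, tp / npos))
  list(auc = auc, roc = roc)
}

#' Cross-validation stage-recomputation flags
#'
#' In each fold the held-out associations are zeroed in \eqn{A};
#' everything downstream of \eqn{A} is then recomputed from the masked
#' matrix by default, which is the leak-free choice. Setting a flag to
#' `FALSE` freezes that stage at its full-matrix value, which lets the
#' contribution of each stage's information leakage be probed: frozen
#' `gip`/`integrated` reuse the full-matrix similarities, frozen
#' `weights`/`initial` reuse the full-matrix transfer weights or
#' initial information (with both of those frozen the score matrix no
#' longer depends on the fold mask at all).
#'
#' @param gip recompute the interaction-profile kernels per fold.
#' @param integrated recompute the integrated similarities per fold.
#' @param weights recompute the transfer weights per fold.
#' @param initial recompute the initial information per fold.
#' @return A named logical list.
#' @export
cvRecomputeFlags <- function(gip = TRUE, integrated = TRUE,
                             weights = TRUE, initial = TRUE) {
  list(gip = isTRUE(gip), integrated = isTRUE(integrated),
       weights = isTRUE(weights), initial = isTRUE(initial))
}

## Static (fold-independent) pieces of the similarity integration.
.cvStatic <- function(assoc, fs, dagSet, delta, bandwidthPrime,
                      bandwidthForm) {
  a <- as.matrix(assoc)
  mids <- rownames(a); dids <- colnames(a)
  coveredM <- if (is.null(fs)) character() else intersect(mids, simIds(fs))
  pM <- matrix(0, length(mids), length(mids), dimnames = list(mids, mids))
  if (length(coveredM))
    pM[coveredM, coveredM] <- as.matrix(fs)[coveredM, coveredM]
  coveredD <- if (is.null(dagSet)) character()
              else intersect(dids, diseaseIds(dagSet))
  pD <- matrix(0, length(dids), length(dids), dimnames = list(dids, dids))
  if (length(coveredD)) {
    ss <- as.matrix(semanticSimilarity(dagSet, delta, "combined"))
    pD[coveredD, coveredD] <- ss[coveredD, coveredD]
  }
  list(pM = pM, coveredM = coveredM, pD = pD, coveredD = coveredD,
       bp = bandwidthPrime, bf = bandwidthForm)
}

.cvSimilarities <- function(assocMasked, static) {
  km <- gipKernel(assocMasked, "mirna", static$bp, static$bf)
  kd <- gipKernel(assocMasked, "disease", static$bp, static$bf)
  ms <- integrateSimilarity(SimilarityMatrix(static$pM, kind = "functional"),
                            km, hasPrimary = static$coveredM)
  ds <- integrateSimilarity(SimilarityMatrix(static$pD, kind = "functional"),
                            kd, hasPrimary = static$coveredD)
  list(km = km, kd = kd, ms = ms, ds = ds)
}

## Shared engine: `folds` is a list of integer matrices (cols j = miRNA
## row index, i = disease column index) of held-out positives;
## `repetition` an integer vector parallel to folds.
.cvEngine <- function(assoc, fs, dagSet, beta, delta, bandwidthPrime,
                      bandwidthForm, recompute, folds, repetition,
                      includeBaseline = FALSE) {
  aFull <- as.matrix(assoc)
  negIdx <- which(aFull == 0)
  if (!length(negIdx))
    stop("no unobserved pairs: nothing to rank the held-out pairs against")
  static <- .cvStatic(assoc, fs, dagSet, delta, bandwidthPrime,
                      bandwidthForm)
  simFull <- .cvSimilarities(assoc, static)
  weightsFull <- transferWeights(assoc, simFull$ms, simFull$ds)
  siniDFull <- initialInformation(assoc, beta, "disease")
  siniMFull <- initialInformation(assoc, beta, "mirna")

  nneg <- length(negIdx)
  recs <- vector("list", length(folds))
  fails <- vector("list", length(folds))
  baseU <- if (includeBaseline) vector("list", length(folds)) else NULL
  for (f in seq_along(folds)) {
    held <- folds[[f]]
    aMask <- aFull
    aMask[held] <- 0
    res <- tryCatch({
      assocMasked <- AssociationMatrix(aMask)
      if (recompute$gip || recompute$integrated) {
        sims <- .cvSimilarities(assocMasked, static)
        if (!recompute$gip) {
          ## kernels frozen but integration redone on the frozen kernels
          sims$ms <- integrateSimilarity(
            SimilarityMatrix(static$pM, kind = "functional"),
            simFull$km, hasPrimary = static$coveredM)
          sims$ds <- integrateSimilarity(
            SimilarityMatrix(static$pD, kind = "functional"),
            simFull$kd, hasPrimary = static$coveredD)
        }
        if (!recompute$integrated) sims <- simFull
        ms <- sims$ms; ds <- sims$ds
      } else {
        ms <- simFull$ms; ds <- simFull$ds
      }
      w <- if (recompute$weights) transferWeights(assocMasked, ms, ds)
           else weightsFull
      sD <- if (recompute$initial) NULL else siniDFull
      sM <- if (recompute$initial) NULL else siniMFull
      sc <- as.matrix(predictScores(assocMasked, ms, ds, beta,
                                    weights = w, siniDisease = sD,
                                    siniMirna = sM))
      neg <- sc[negIdx]
      s <- sc[held]
      u <- vapply(s, function(x)
        (sum(neg < x) + 0.5 * sum(neg == x)) / nneg, numeric(1))
      rk <- vapply(s, function(x)
        1 + sum(neg > x) + 0.5 * sum(neg == x), numeric(1))
      list(rec = data.frame(
        mirna = rownames(aFull)[held[, 1L]],
        disease = colnames(aFull)[held[, 2L]],
        score = s, quantile = u, rank = rk,
        fold = f, repetition = repetition[f],
        stringsAsFactors = FALSE))
    }, error = function(e) {
      list(fail = data.frame(
        mirna = rownames(aFull)[held[, 1L]],
        disease = colnames(aFull)[held[, 2L]],
        repetition = repetition[f],
        message = conditionMessage(e), stringsAsFactors = FALSE))
    })
    if (!is.null(res$rec)) {
      recs[[f]] <- res$rec
      if (includeBaseline) {
        b <- outer(rowSums(aMask), colSums(aMask))
        bneg <- b[negIdx]
        baseU[[f]] <- vapply(b[held], function(x)
          (sum(bneg < x) + 0.5 * sum(bneg == x)) / nneg, numeric(1))
      }
    } else {
      fails[[f]] <- res$fail
    }
  }
  emptyFail <- data.frame(mirna = character(), disease = character(),
                          repetition = integer(), message = character(),
                          stringsAsFactors = FALSE)
  list(records = do.call(rbind, c(recs, list(NULL))),
       failed = if (is.null(ff <- do.call(rbind, fails))) emptyFail else ff,
       baselineU = if (includeBaseline) unlist(baseU) else NULL)
}

#' Leave-one-out cross-validation of the projection
#'
#' Each known association is zeroed in turn, the pipeline is re-run on
#' the masked matrix (stages recomputed per `recompute`), and the
#' held-out pair's score is compared with the scores of all pairs never
#' observed in the full matrix (the negative set, fixed across folds).
#' The reported AUC is the mean over held-out pairs of the fraction of
#' the fold's negative scores they beat (ties counted half) — the
#' pooled Mann-Whitney statistic with fold-matched negatives, free of
#' any leakage from the held-out association. Folds whose masking
#' isolates a node cannot be scored; they are recorded in `failed` and
#' the AUC covers the completed folds, with a warning.
#'
#' @param assoc an [AssociationMatrix-class] with at least 2
#'   associations.
#' @param fs functional miRNA [SimilarityMatrix-class], or `NULL` to
#'   use the interaction kernel for every miRNA pair.
#' @param dagSet a [DiseaseDAGSet-class], or `NULL` to use the kernel
#'   for every disease pair.
#' @param beta popularity damping exponent in (-1, 0].
#' @param delta semantic decay factor.
#' @param bandwidthPrime,bandwidthForm kernel bandwidth settings (see
#'   [gipKernel()]); one bandwidth is used for both axes.
#' @param recompute flags from [cvRecomputeFlags()].
#' @param includeBaseline also evaluate the degree-product score
#'   \eqn{k_m k_d} (computed from each fold's masked matrix) on
#'   identical folds, reporting its AUC in `baselineAuc`.
#' @return A [CVResult-class] with protocol `"loocv"`.
#' @export
loocv <- function(assoc, fs = NULL, dagSet = NULL, beta = -0.1,
                  delta = 0.5, bandwidthPrime = 1,
                  bandwidthForm = "divide",
                  recompute = cvRecomputeFlags(),
                  includeBaseline = FALSE) {
  aFull <- as.matrix(assoc)
  pos <- which(aFull == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop("need at least 2 known associations for LOOCV")
  folds <- lapply(seq_len(nrow(pos)), function(i) pos[i, , drop = FALSE])
  eng <- .cvEngine(assoc, fs, dagSet, beta, delta, bandwidthPrime,
                   bandwidthForm, recompute, folds,
                   repetition = rep(1L, length(folds)),
                   includeBaseline = includeBaseline)
  if (nrow(eng$failed))
    warning(nrow(eng$failed), " LOOCV fold(s) failed (isolated nodes); ",
            "AUC computed over the completed folds")
  if (is.null(eng$records) || !nrow(eng$records))
    stop("no LOOCV fold completed")
  auc <- mean(eng$records$quantile)
  new("CVResult", records = eng$records, auc = auc, aucs = auc,
      aucMean = auc, aucSd = NA_real_,
      baselineAuc = if (includeBaseline) mean(eng$baselineU) else NA_real_,
      failed = eng$failed, seed = 0L, protocol = "loocv")
}

## Documented per-repetition seed derivation: repetition r of a run
## with seed s shuffles with seed (s + 1000003 * r) mod 2^31 - 1.
.repSeed <- function(seed, r) {
  as.integer((as.numeric(seed) + 1000003 * r) %% (2^31 - 1))
}

#' Repeated k-fold cross-validation
#'
#' Per repetition, the known associations are shuffled (with a seed
#' derived from `seed` and the repetition index), split into `k`
#' near-equal groups (sizes differing by at most one, remainder spread
#' over the first groups), and each group is zeroed and scored in turn
#' exactly as in [loocv()]. Each repetition yields one pooled AUC;
#' `aucMean`/`aucSd` summarize the repetitions. With `k` equal to the
#' number of associations and one repetition the protocol reduces to
#' LOOCV.
#'
#' @inheritParams loocv
#' @param k number of groups (at least 2).
#' @param repeats number of repetitions.
#' @param seed integer seed driving the shuffles.
#' @return A [CVResult-class] with protocol `"kfold"`.
#' @export
kfoldCV <- function(assoc, fs = NULL, dagSet = NULL, k = 5L,
                    repeats = 100L, seed = 1L, beta = -0.1, delta = 0.5,
                    bandwidthPrime = 1, bandwidthForm = "divide",
                    recompute = cvRecomputeFlags(),
                    includeBaseline = FALSE) {
  aFull <- as.matrix(assoc)
  pos <- which(aFull == 1, arr.ind = TRUE)
  npos <- nrow(pos)
  if (k < 2L) stop("k must be at least 2")
  if (npos < k) stop("fewer known associations than folds")
  folds <- list(); repetition <- integer()
  sizes <- rep(npos %/% k, k) + c(rep(1L, npos %% k),
                                  rep(0L, k - npos %% k))
  for (r in seq_len(repeats)) {
    set.seed(.repSeed(seed, r))
    perm <- sample.int(npos)
    grp <- rep(seq_len(k), times = sizes)
    for (g in seq_len(k))
      folds[[length(folds) + 1L]] <- pos[perm[grp == g], , drop = FALSE]
    repetition <- c(repetition, rep(r, k))
  }
  eng <- .cvEngine(assoc, fs, dagSet, beta, delta, bandwidthPrime,
                   bandwidthForm, recompute, folds, repetition,
                   includeBaseline = includeBaseline)
  if (nrow(eng$failed))
    warning(nrow(eng$failed), " held-out group(s) failed (isolated nodes); ",
            "AUCs computed over the completed folds")
  if (is.null(eng$records) || !nrow(eng$records))
    stop("no cross-validation fold completed")
  aucs <- vapply(split(eng$records$quantile, eng$records$repetition),
                 mean, numeric(1))
  new("CVResult", records = eng$records, auc = mean(aucs), aucs = aucs,
      aucMean = mean(aucs),
      aucSd = if (length(aucs) > 1L) sd(aucs) else NA_real_,
      baselineAuc = if (includeBaseline) mean(eng$baselineU) else NA_real_,
      failed = eng$failed, seed = as.integer(seed), protocol = "kfold")
}

#' ROC points of a cross-validation result
#'
#' Exact ROC curve implied by the per-positive negative-score quantiles:
#' thresholding at the (1 - x) quantile of a fold's negative scores
#' yields false-positive rate x and true-positive rate equal to the
#' fraction of held-out pairs whose quantile is at least 1 - x.
#'
#' @param result a [CVResult-class].
#' @return data.frame with `fpr`, `tpr`, nondecreasing from (0,0) to
#'   (1,1).
#' @export
cvRoc <- function(result) {
  u <- sort(result@records$quantile, decreasing = TRUE)
  n <- length(u)
  df <- data.frame(fpr = c(0, 1 - u, 1), tpr = c(0, seq_len(n) / n, 1))
  ## collapse ties so the curve is a function of fpr
  df <- df[!duplicated(df$fpr, fromLast = TRUE), ]
  rownames(df) <- NULL
  df
}

#' Sweep the popularity-damping exponent
#'
#' Runs the chosen cross-validation protocol at each requested beta and
#' tabulates the AUC.
#'
#' @inheritParams kfoldCV
#' @param betas numeric vector of damping exponents, all in (-1, 0].
#' @param protocol `"loocv"` or `"kfold"`.
#' @param ... further arguments passed to [loocv()] or [kfoldCV()].
#' @return A list with `table` (data.frame `beta`, `auc`) and
#'   `bestBeta` (the argmax).
#' @export
betaSweep <- function(assoc, fs = NULL, dagSet = NULL,
                      betas = seq(-0.9, 0, by = 0.1),
                      protocol = c("loocv", "kfold"), ...) {
  protocol <- match.arg(protocol)
  if (!all(betas > -1 & betas <= 0)) stop("all betas must lie in (-1, 0]")
  auc <- vapply(betas, function(b) {
    r <- if (protocol == "loocv")
      loocv(assoc, fs, dagSet, beta = b, ...)
    else
      kfoldCV(assoc, fs, dagSet, beta = b, ...)
    r@aucMean
  }, numeric(1))
  tab <- data.frame(beta = betas, auc = auc)
  list(table = tab, bestBeta = betas[which.max(auc)])
}

#' Top-k candidate miRNAs for one disease
#'
#' The highest-scoring miRNAs not yet associated with the disease,
#' descending score, lexicographic identifier tie-break; shorter than k
#' when fewer candidates exist.
#'
#' @param scores a [ScoreMatrix-class].
#' @param assoc the matching [AssociationMatrix-class].
#' @param disease disease identifier.
#' @param k number of candidates requested.
#' @return data.frame with `rank`, `mirna`, `score`.
#' @export
topCandidates <- function(scores, assoc, disease, k = 50L) {
  if (k < 1L) stop("k must be at least 1")
  if (!disease %in% diseaseIds(assoc))
    stop("unknown disease '", disease, "'")
  rp <- rankedPredictions(scores, assoc)
  out <- rp[rp$disease == disease, c("rank", "mirna", "score")]
  out <- head(out, k)
  rownames(out) <- NULL
  out
}
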