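test_that("rocAuc reproduces hand values and degenerate limits", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # 3 of the 4 positive-negative pairs correctly ordered
  expect_equal(rocAuc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(rocAuc(c(1, 2), c(1, 1)), "positive and.*negative")
})

test_that("rocAuc equals brute-force pair counting, and curves are valid", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    score <- sample(round(runif(n), 2))   # coarse grid forces ties
    label <- rbinom(n, 1, 0.4)
    if (sum(label) == 0 || sum(label) == n) next
    r <- rocAuc(score, label)
    expect_equal(r$auc, oracleAucPairs(score, label), tolerance = 1e-12)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
    expect_equal(r$roc$fpr[1], 0)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  }
})

test_that("LOOCV scores every known association against fixed negatives", {
  d <- generateDataset(nm = 16, nd = 10, pWithin = 0.5, pBetween = 0.1,
                       seed = 51)
  res <- suppressWarnings(loocv(d$assoc, d$fs, d$dags))
  npos <- sum(as.matrix(d$assoc))
  expect_equal(nrow(res@records) + nrow(res@failed), npos)
  expect_true(all(res@records$quantile >= 0 & res@records$quantile <= 1))
  expect_equal(res@auc, mean(res@records$quantile))
  # every record is a known pair of the full matrix
  a <- as.matrix(d$assoc)
  expect_true(all(a[cbind(res@records$mirna, res@records$disease)] == 1))
})

test_that("frozen-similarity folds equal prediction with stale similarities", {
  d <- generateDataset(nm = 12, nd = 8, pWithin = 0.6, pBetween = 0.1,
                       seed = 52)
  flags <- cvRecomputeFlags(gip = FALSE, integrated = FALSE)
  res <- suppressWarnings(loocv(d$assoc, d$fs, d$dags, recompute = flags))
  # recompute one fold by hand: stale MS/DS from the full matrix
  ms <- integratedMirnaSimilarity(d$assoc, d$fs)
  ds <- integratedDiseaseSimilarity(d$assoc, d$dags)
  rec <- res@records[1, ]
  a <- as.matrix(d$assoc)
  a[rec$mirna, rec$disease] <- 0
  sc <- as.matrix(predictScores(AssociationMatrix(a), ms, ds, beta = -0.1))
  expect_equal(rec$score, unname(sc[rec$mirna, rec$disease]),
               tolerance = 1e-12)
})

test_that("k-fold partitions are balanced and exhaustive per repetition", {
  d <- generateDataset(nm = 14, nd = 9, pWithin = 0.8, pBetween = 0.3,
                       seed = 53)
  npos <- sum(as.matrix(d$assoc))
  res <- kfoldCV(d$assoc, d$fs, d$dags, k = 5, repeats = 3, seed = 7)
  expect_equal(nrow(res@failed), 0L)
  perRep <- table(res@records$repetition)
  expect_true(all(perRep == npos))   # every pair held out exactly once
  for (r in 1:3) {
    rr <- res@records[res@records$repetition == r, ]
    sizes <- table(rr$fold)
    expect_lte(diff(range(sizes)), 1)          # near-equal groups
    expect_false(any(duplicated(rr[c("mirna", "disease")])))
  }
})

test_that("k-fold with k = n and one repetition reduces to LOOCV", {
  d <- generateDataset(nm = 10, nd = 7, pWithin = 0.7, pBetween = 0.2,
                       seed = 54)
  npos <- sum(as.matrix(d$assoc))
  kf <- suppressWarnings(kfoldCV(d$assoc, d$fs, d$dags, k = npos,
                                 repeats = 1, seed = 1))
  lo <- suppressWarnings(loocv(d$assoc, d$fs, d$dags))
  key <- function(r) {
    o <- order(r@records$mirna, r@records$disease)
    r@records[o, c("mirna", "disease", "score", "quantile")]
  }
  expect_equal(key(kf), key(lo), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(kf@aucMean, lo@auc, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical cross-validation results", {
  d <- generateDataset(nm = 12, nd = 8, pWithin = 0.6, pBetween = 0.1,
                       seed = 55)
  r1 <- suppressWarnings(kfoldCV(d$assoc, d$fs, d$dags, k = 4, repeats = 2,
                                 seed = 31))
  r2 <- suppressWarnings(kfoldCV(d$assoc, d$fs, d$dags, k = 4, repeats = 2,
                                 seed = 31))
  expect_identical(r1@records, r2@records)
  expect_identical(r1@aucMean, r2@aucMean)
  r3 <- suppressWarnings(kfoldCV(d$assoc, d$fs, d$dags, k = 4, repeats = 2,
                                 seed = 32))
  expect_false(identical(r1@records$fold, r3@records$fold))
})

test_that("beta sweep tabulates one AUC per requested beta", {
  d <- generateDataset(nm = 10, nd = 7, pWithin = 0.7, pBetween = 0.2,
                       seed = 56)
  betas <- c(-0.5, -0.1)
  sw <- suppressWarnings(betaSweep(d$assoc, d$fs, d$dags, betas = betas,
                                   protocol = "loocv"))
  expect_equal(sw$table$beta, betas)
  expect_equal(nrow(sw$table), length(betas))
  expect_true(sw$bestBeta %in% betas)
  direct <- suppressWarnings(loocv(d$assoc, d$fs, d$dags, beta = -0.5))
  expect_equal(sw$table$auc[1], direct@auc, tolerance = 1e-12)
  expect_error(betaSweep(d$assoc, betas = c(-1, 0)), "betas")
})

test_that("cross-validation ROC points form a valid curve with matching AUC", {
  d <- generateDataset(nm = 12, nd = 8, pWithin = 0.6, pBetween = 0.1,
                       seed = 57)
  res <- suppressWarnings(loocv(d$assoc, d$fs, d$dags))
  roc <- cvRoc(res)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("top-k candidate lists agree with the ranked-prediction writer", {
  a <- AssociationMatrix(matrix(c(1, 0), 2, 1,
                                dimnames = list(c("m1", "m2"), "d1")))
  s <- ScoreMatrix(matrix(c(0.9, 0.4), 2, 1,
                          dimnames = dimnames(as.matrix(a))))
  top <- topCandidates(s, a, "d1", k = 10)
  expect_identical(top$mirna, "m2")          # k beyond candidates: full list
  expect_error(topCandidates(s, a, "dX", 5), "unknown disease")

  set.seed(58)
  av <- randomAssoc(8, 5)
  sv <- ScoreMatrix(matrix(runif(40), 8, 5, dimnames = dimnames(av)))
  assoc <- AssociationMatrix(av)
  top3 <- topCandidates(sv, assoc, "d03", k = 3)
  rp <- rankedPredictions(sv, assoc)
  want <- head(rp[rp$disease == "d03", c("rank", "mirna", "score")], 3)
  expect_equal(top3, want, ignore_attr = TRUE)
})
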