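test_that("worked-example intermediates match the loop-form oracle", {
  ex <- generateWorkedExample()
  A <- as.matrix(ex$assoc); MS <- as.matrix(ex$ms); DS <- as.matrix(ex$ds)
  want <- oracleTransferWeights(A, MS, DS)
  w <- transferWeights(ex$assoc, ex$ms, ex$ds)
  expect_equal(transferWr(w), want$wr, tolerance = 1e-12)
  expect_equal(transferWd(w), want$wd, tolerance = 1e-12)

  # hand value: wr(m1,d1) = (1*1 + 0.5*1 + 0.1*0) / 1.6 = 0.9375
  expect_equal(unname(transferWr(w)["m1", "d1"]), 0.9375)

  # disease degrees are (2, 2): every known-pair initial entry is 2^-0.1
  sini <- as.matrix(initialInformation(ex$assoc, ex$beta, "disease"))
  expect_equal(sort(unique(sini[A == 1])), 2^-0.1)
  expect_equal(sini, oracleInitial(A, ex$beta, "disease"))

  P <- propagationMatrix(w, "disease_based")
  expect_equal(unname(colSums(P)), c(1, 1, 1), tolerance = 1e-12)

  sM <- propagate(w, initialInformation(ex$assoc, ex$beta, "disease"),
                  "disease_based")
  expect_equal(as.matrix(sM),
               oraclePropagateLoop(want$wr, oracleInitial(A, ex$beta,
                                                          "disease")),
               tolerance = 1e-10)
  sD <- propagate(w, initialInformation(ex$assoc, ex$beta, "mirna"),
                  "mirna_based")
  expect_equal(as.matrix(sD),
               t(oraclePropagateLoop(t(want$wd),
                                     t(oracleInitial(A, ex$beta, "mirna")))),
               tolerance = 1e-10)
  sFin <- predictScores(ex$assoc, ex$ms, ex$ds, beta = ex$beta)
  expect_equal(as.matrix(sFin), oraclePredict(A, MS, DS, ex$beta),
               tolerance = 1e-10)
  expect_equal(as.matrix(sFin), (as.matrix(sM) + as.matrix(sD)) / 2)
})

test_that("degenerate similarity matrices simplify the transfer weights", {
  set.seed(31)
  a <- randomAssoc(6, 4, p = 0.5)
  ids <- dimnames(a)
  eye <- SimilarityMatrix(diag(6), ids = ids[[1]], kind = "integrated_mirna")
  dsEye <- SimilarityMatrix(diag(4), ids = ids[[2]],
                            kind = "integrated_disease")
  w <- transferWeights(AssociationMatrix(a), eye, dsEye)
  expect_equal(transferWr(w), a)            # only the self term survives
  expect_equal(transferWd(w), a)

  ones <- SimilarityMatrix(matrix(1, 6, 6, dimnames = list(ids[[1]],
                                                           ids[[1]])),
                           kind = "integrated_mirna")
  dOnes <- SimilarityMatrix(matrix(1, 4, 4, dimnames = list(ids[[2]],
                                                            ids[[2]])),
                            kind = "integrated_disease")
  wAll <- transferWeights(AssociationMatrix(a), ones, dOnes)
  # wr(m_j, d_i) = k_i / nm for every j
  want <- matrix(colSums(a) / 6, 6, 4, byrow = TRUE, dimnames = ids)
  expect_equal(transferWr(wAll), want)

  # 2x1 hand value: wr(m2, d1) = (0.5*1 + 1*0) / 1.5 = 1/3
  a2 <- matrix(c(1, 0), 2, 1, dimnames = list(c("m1", "m2"), "d1"))
  ms2 <- SimilarityMatrix(matrix(c(1, 0.5, 0.5, 1), 2, 2,
                                 dimnames = list(c("m1", "m2"),
                                                 c("m1", "m2"))),
                          kind = "integrated_mirna")
  ds2 <- SimilarityMatrix(matrix(1, 1, 1, dimnames = list("d1", "d1")),
                          kind = "integrated_disease")
  w2 <- transferWeights(AssociationMatrix(a2), ms2, ds2)
  expect_equal(unname(transferWr(w2)["m2", "d1"]), 1 / 3)
})

test_that("initial information damps by degree and vanishes off known pairs", {
  set.seed(32)
  a <- AssociationMatrix(randomAssoc(8, 5, p = 0.4))
  s0 <- as.matrix(initialInformation(a, beta = 0))
  expect_equal(s0, as.matrix(a))            # undamped limit

  av <- matrix(0, 5, 2, dimnames = list(paste0("m", 1:5), c("d1", "d2")))
  av[1:4, 1] <- 1; av[1, 2] <- 1
  si <- as.matrix(initialInformation(AssociationMatrix(av), beta = -0.1))
  expect_equal(unname(si[1, 1]), 4^-0.1)    # disease degree 4
  expect_equal(unname(si[1, 2]), 1)         # degree 1
  expect_true(all(si[av == 0] == 0))

  # damping is monotone: larger degree, smaller nonzero entry
  expect_lt(si[1, 1], si[1, 2])
  expect_error(initialInformation(a, beta = -1), "beta")
  expect_error(initialInformation(a, beta = 0.2), "beta")
})

test_that("propagation conserves mass and is column-stochastic", {
  set.seed(33)
  for (rep in 1:20) {
    nm <- sample(3:12, 1); nd <- sample(3:10, 1)
    a <- randomAssoc(nm, nd)
    ms <- SimilarityMatrix(randomSim(rownames(a)), kind = "integrated_mirna")
    ds <- SimilarityMatrix(randomSim(colnames(a)),
                           kind = "integrated_disease")
    w <- transferWeights(AssociationMatrix(a), ms, ds)
    for (dir in c("disease_based", "mirna_based")) {
      P <- propagationMatrix(w, dir)
      expect_equal(unname(colSums(P)), rep(1, ncol(P)), tolerance = 1e-10)
    }
    sini <- initialInformation(AssociationMatrix(a), -0.1, "disease")
    sM <- propagate(w, sini, "disease_based")
    expect_equal(sum(as.matrix(sM)), sum(as.matrix(sini)),
                 tolerance = 1e-10)
    expect_true(all(as.matrix(sM) >= 0) && all(is.finite(as.matrix(sM))))
  }
})

test_that("matrix-form propagation equals the nested-loop evaluation", {
  set.seed(34)
  for (rep in 1:20) {
    a <- randomAssoc(20, 15)
    ms <- SimilarityMatrix(randomSim(rownames(a)), kind = "integrated_mirna")
    ds <- SimilarityMatrix(randomSim(colnames(a)),
                           kind = "integrated_disease")
    got <- as.matrix(predictScores(AssociationMatrix(a), ms, ds,
                                   beta = -0.1))
    want <- oraclePredict(a, as.matrix(ms), as.matrix(ds), -0.1)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("identity similarities with beta = 0 reproduce unweighted NBI", {
  # with MS = DS = I the transfer weights collapse to A itself, and the
  # undamped two-step diffusion is the classic resource-allocation
  # projection
  set.seed(35)
  for (rep in 1:5) {
    a <- randomAssoc(10, 8)
    eye <- SimilarityMatrix(diag(10), ids = rownames(a),
                            kind = "integrated_mirna")
    dEye <- SimilarityMatrix(diag(8), ids = colnames(a),
                             kind = "integrated_disease")
    got <- as.matrix(predictScores(AssociationMatrix(a), eye, dEye,
                                   beta = 0, direction = "disease_based"))
    expect_equal(got, oracleNBI(a), tolerance = 1e-10)
  }
})

test_that("all-ones similarities yield the degree-proportional closed form", {
  # with MS all-ones, wr(m_j, d_i) = k_i/nm independently of j, so the
  # propagation matrix is constant and every score is proportional to
  # the target disease's degree
  set.seed(36)
  a <- randomAssoc(9, 6)
  ones <- SimilarityMatrix(matrix(1, 9, 9,
                                  dimnames = list(rownames(a), rownames(a))),
                           kind = "integrated_mirna")
  dEye <- SimilarityMatrix(diag(6), ids = colnames(a),
                           kind = "integrated_disease")
  got <- as.matrix(predictScores(AssociationMatrix(a), ones, dEye,
                                 beta = 0, direction = "disease_based"))
  kd <- colSums(a)
  expect_equal(got, matrix(kd / nrow(a), nrow(a), ncol(a), byrow = TRUE,
                           dimnames = dimnames(a)),
               tolerance = 1e-10)
})

test_that("block-diagonal inputs keep scores inside the blocks", {
  mids <- paste0("m", 1:6); dids <- paste0("d", 1:4)
  a <- matrix(0, 6, 4, dimnames = list(mids, dids))
  a[1:3, 1:2] <- 1; a[4:6, 3:4] <- 1
  blockSim <- function(ids, groups) {
    m <- outer(groups, groups, function(x, y) ifelse(x == y, 1, 0))
    dimnames(m) <- list(ids, ids)
    m
  }
  ms <- SimilarityMatrix(blockSim(mids, rep(1:2, each = 3)),
                         kind = "integrated_mirna")
  ds <- SimilarityMatrix(blockSim(dids, rep(1:2, each = 2)),
                         kind = "integrated_disease")
  s <- as.matrix(predictScores(AssociationMatrix(a), ms, ds, beta = -0.1))
  expect_true(all(s[1:3, 3:4] == 0))
  expect_true(all(s[4:6, 1:2] == 0))
  expect_true(all(s[1:3, 1:2] > 0))
})

test_that("prediction is label-equivariant and deterministic", {
  set.seed(37)
  a <- randomAssoc(8, 6)
  ms <- randomSim(rownames(a)); ds <- randomSim(colnames(a))
  mk <- function(a, ms, ds)
    as.matrix(predictScores(
      AssociationMatrix(a),
      SimilarityMatrix(ms, kind = "integrated_mirna"),
      SimilarityMatrix(ds, kind = "integrated_disease"), beta = -0.1))
  s1 <- mk(a, ms, ds)
  expect_identical(s1, mk(a, ms, ds))       # bit-identical rerun
  perm <- sample(nrow(a))
  s2 <- mk(a[perm, ], ms[perm, perm], ds)
  expect_equal(s2, s1[perm, ], tolerance = 1e-12)
})

test_that("isolated nodes abort propagation with their identifiers", {
  a <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("m1", "m2"),
                                                   c("d1", "d2")))
  eye <- SimilarityMatrix(diag(2), ids = c("m1", "m2"),
                          kind = "integrated_mirna")
  dEye <- SimilarityMatrix(diag(2), ids = c("d1", "d2"),
                           kind = "integrated_disease")
  expect_error(predictScores(AssociationMatrix(a), eye, dEye),
               "isolated.*(m2|d2)")
})

test_that("final score fusion is the elementwise mean", {
  dn <- list(c("m1", "m2"), "d1")
  sm <- ScoreMatrix(matrix(c(0.4, 0), 2, 1, dimnames = dn),
                    stage = "disease_based")
  sd <- ScoreMatrix(matrix(c(0.6, 0.8), 2, 1, dimnames = dn),
                    stage = "mirna_based")
  expect_equal(unname(as.matrix(finalScores(sm, sd))),
               rbind(0.5, 0.4))
  expect_equal(as.matrix(finalScores(sm, sm)), as.matrix(sm))
})
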