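# Independent straight-from-the-equations implementations used as
# oracles. Everything here is deliberately naive (nested loops, direct
# recursion) and shares no code with the package internals.

# wr(m_j, d_i) = sum_k MS(j,k) A(k,i) / sum_k MS(j,k); wd analogous.
oracleTransferWeights <- function(A, MS, DS) {
  nm <- nrow(A); nd <- ncol(A)
  wr <- matrix(0, nm, nd, dimnames = dimnames(A))
  wd <- matrix(0, nm, nd, dimnames = dimnames(A))
  for (j in seq_len(nm)) for (i in seq_len(nd)) {
    num <- 0; den <- 0
    for (k in seq_len(nm)) {
      num <- num + MS[j, k] * A[k, i]
      den <- den + MS[j, k]
    }
    wr[j, i] <- num / den
    num <- 0; den <- 0
    for (k in seq_len(nd)) {
      num <- num + DS[i, k] * A[j, k]
      den <- den + DS[i, k]
    }
    wd[j, i] <- num / den
  }
  list(wr = wr, wd = wd)
}

# S_ini(m_j, d_i) = A[j,i] * k^beta, k the degree on the damping axis.
oracleInitial <- function(A, beta, axis = c("disease", "mirna")) {
  axis <- match.arg(axis)
  out <- A * 0
  for (j in seq_len(nrow(A))) for (i in seq_len(ncol(A))) {
    if (A[j, i] == 1) {
      k <- if (axis == "disease") sum(A[, i]) else sum(A[j, ])
      out[j, i] <- k^beta
    }
  }
  out
}

# Two-step propagation, loop form: for each target column l, resource
# starts on the source side (rows of W), flows source -> dest -> source.
#   step1(i | l) = sum_k W[k,i] S[k,l] / d(src_k)
#   out(j,  l)   = sum_i W[j,i] step1(i | l) / d(dst_i)
oraclePropagateLoop <- function(W, S) {
  nSrc <- nrow(W); nDst <- ncol(W)
  dSrc <- sapply(seq_len(nSrc), function(k) sum(W[k, ]))
  dDst <- sapply(seq_len(nDst), function(i) sum(W[, i]))
  out <- S * 0
  for (l in seq_len(ncol(S))) {
    step1 <- numeric(nDst)
    for (i in seq_len(nDst)) {
      for (k in seq_len(nSrc))
        step1[i] <- step1[i] + W[k, i] * S[k, l] / dSrc[k]
    }
    for (j in seq_len(nSrc)) {
      for (i in seq_len(nDst))
        out[j, l] <- out[j, l] + W[j, i] * step1[i] / dDst[i]
    }
  }
  out
}

# Full pipeline on explicit similarity matrices, loop form throughout.
oraclePredict <- function(A, MS, DS, beta) {
  w <- oracleTransferWeights(A, MS, DS)
  sM <- oraclePropagateLoop(w$wr, oracleInitial(A, beta, "disease"))
  sD <- t(oraclePropagateLoop(t(w$wd), t(oracleInitial(A, beta, "mirna"))))
  (sM + sD) / 2
}

# Classic unweighted two-step resource allocation (network-based
# inference): binary transfer, degree normalization, no damping.
oracleNBI <- function(A) {
  nm <- nrow(A); nd <- ncol(A)
  km <- rowSums(A); kd <- colSums(A)
  out <- A * 0
  for (l in seq_len(nd)) {
    step1 <- numeric(nd)
    for (i in seq_len(nd))
      for (k in seq_len(nm))
        if (A[k, i] == 1 && A[k, l] == 1)
          step1[i] <- step1[i] + 1 / km[k]
    for (j in seq_len(nm))
      for (i in seq_len(nd))
        if (A[j, i] == 1)
          out[j, l] <- out[j, l] + step1[i] / kd[i]
  }
  out
}

# AUC by brute-force enumeration of positive-negative pairs, ties 1/2.
oracleAucPairs <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Model-1 contribution by direct memoization-free recursion.
oracleContributionM1 <- function(edges, term, allTerms, delta) {
  val <- function(t) {
    if (t == term) return(1)
    kids <- edges[edges[, 2L] == t, 1L]
    kids <- kids[kids %in% allTerms]
    max(sapply(kids, function(k) delta * val(k)))
  }
  sapply(setNames(allTerms, allTerms), val)
}

# Random isolation-free binary association matrix.
randomAssoc <- function(nm, nd, p = 0.3) {
  repeat {
    a <- matrix(rbinom(nm * nd, 1, p), nm, nd,
                dimnames = list(sprintf("m%02d", seq_len(nm)),
                                sprintf("d%02d", seq_len(nd))))
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) return(a)
  }
}

# Random symmetric similarity matrix in [0, 1] with unit diagonal.
randomSim <- function(ids) {
  n <- length(ids)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}
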