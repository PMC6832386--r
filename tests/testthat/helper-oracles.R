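# Shared fixtures and independent brute-force oracles.  Oracles are written
# as literal loop translations of the definitions so they stay independent
# of the vectorized implementation paths they check.

# ---- random graph fixtures -------------------------------------------------

randomSignedGraph <- function(n, pEdge = 0.4, seed = 1) {
  set.seed(seed)
  edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < pEdge) {
      w <- runif(1, 0.1, 1) * sample(c(-1, 1), 1)
      edges <- rbind(edges, data.frame(from = i, to = j, weight = w))
    }
  }
  DrugGraph(sprintf("n%02d", seq_len(n)), edges, signed = TRUE)
}

randomUnsignedGraph <- function(n, pEdge = 0.5, seed = 1) {
  set.seed(seed)
  edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < pEdge)
      edges <- rbind(edges, data.frame(from = i, to = j,
                                       weight = runif(1, 0.1, 1)))
  }
  DrugGraph(sprintf("n%02d", seq_len(n)), edges, signed = FALSE)
}

# signed barbell: two positive cliques joined by all-negative cross edges
signedBarbell <- function(k = 10, wPos = 0.8, wNeg = -0.5) {
  n <- 2 * k
  edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- (i <= k) == (j <= k)
    edges <- rbind(edges, data.frame(from = i, to = j,
                                     weight = if (same) wPos else wNeg))
  }
  DrugGraph(sprintf("n%02d", seq_len(n)), edges, signed = TRUE)
}

# ---- oracles ---------------------------------------------------------------

# common-neighbor similarity: literal four-sum definition
oracleLs <- function(W, s, h) {
  tot <- 0
  for (r in seq_len(nrow(W))) {
    if (W[s, r] > 0 && W[h, r] > 0) tot <- tot + W[s, r]
    if (W[s, r] < 0 && W[h, r] < 0) tot <- tot + abs(W[s, r])
    if (W[s, r] < 0 && W[h, r] > 0) tot <- tot - abs(W[s, r])
    if (W[s, r] > 0 && W[h, r] < 0) tot <- tot - W[s, r]
  }
  tot
}

# signed-walk kernel: exhaustive enumeration over friends and all (k, h)
oracleSignedKernel <- function(W, s, p, q) {
  n <- nrow(W)
  score <- numeric(n)
  friends <- which(W[s, ] > 0)
  enemies <- which(W[s, ] < 0)
  dF <- sum(abs(W[s, friends]))
  if (dF == 0) dF <- 1
  for (h in friends) score[h] <- score[h] + p * abs(W[s, h]) / dF
  for (k in enemies) for (h in seq_len(n)) {
    if (W[k, h] < 0 && W[s, h] == 0 && h != s && oracleLs(W, s, h) > 0) {
      dE <- sum(abs(W[k, W[k, ] < 0]))
      score[h] <- score[h] + q * abs(W[s, k]) * abs(W[k, h]) / (dF * dE)
    }
  }
  if (sum(score) > 0) score / sum(score) else score
}

# unsigned second-order kernel: literal per-neighbor evaluation
oracleUnsignedKernel <- function(W, t, s, alpha, beta) {
  n <- nrow(W)
  score <- numeric(n)
  for (h in seq_len(n)) {
    if (W[s, h] <= 0) next
    if (is.null(t)) score[h] <- W[s, h]
    else score[h] <- (if (W[t, h] != 0 || h == t) alpha else beta) * W[s, h]
  }
  if (sum(score) > 0) score / sum(score) else score
}

# triad census by O(n^3) triple enumeration
oracleTriadCensus <- function(W) {
  n <- nrow(W)
  counts <- c(T1 = 0L, T2 = 0L, T3 = 0L, T4 = 0L)
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ws <- c(W[i, j], W[i, k], W[j, k])
    if (any(ws == 0)) next
    neg <- sum(ws < 0)
    cls <- c("T1", "T3", "T2", "T4")[neg + 1L]
    counts[cls] <- counts[cls] + 1L
  }
  c(counts, total = sum(counts))
}

# AUROC by exhaustive positive-negative pair counting (ties get 1/2)
oracleAuc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Top-K hits by explicit per-drug re-ranking
oracleTopk <- function(T, K) {
  hits <- 0L
  for (d in unique(T$drug_id)) {
    sub <- T[T$drug_id == d, ]
    sub <- sub[order(-sub$score, sub$side_effect_id), ]
    if (any(sub$label[seq_len(min(K, nrow(sub)))] == 1)) hits <- hits + 1L
  }
  hits
}

# Rand index of two partitions
randIndex <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

smallBundle <- function(seed = 1, ...) {
  generateBundle(syntheticSpec(nDrugs = 30, nTargets = 18, nSideEffects = 12,
                               nGroups = 3, seed = seed, ...))
}
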