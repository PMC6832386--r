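test_that("friend and enemy sets partition the signed neighborhood", {
  g <- DrugGraph(c("s", "a", "b", "c"),
                 data.frame(from = c("s", "s"), to = c("a", "b"),
                            weight = c(0.8, -0.6)), signed = TRUE)
  fe <- friendEnemySets(g, "s")
  expect_identical(fe$friends, "a")
  expect_identical(fe$enemies, "b")
  iso <- friendEnemySets(g, "c")
  expect_length(iso$friends, 0)
  expect_length(iso$enemies, 0)
  expect_error(friendEnemySets(g, "zz"), "unknown node")

  # random graph: matches a per-edge sign scan
  gr <- randomSignedGraph(10, seed = 3)
  et <- edgeTable(gr)
  for (v in nodeIds(gr)) {
    fe <- friendEnemySets(gr, v)
    pos <- c(et$to[et$from == v & et$weight > 0],
             et$from[et$to == v & et$weight > 0])
    neg <- c(et$to[et$from == v & et$weight < 0],
             et$from[et$to == v & et$weight < 0])
    expect_setequal(fe$friends, pos)
    expect_setequal(fe$enemies, neg)
  }
})

test_that("common-neighbor similarity matches its term-by-term definition", {
  # single shared friend contributes its edge weight
  g1 <- DrugGraph(c("s", "h", "r"),
                  data.frame(from = c("s", "h"), to = c("r", "r"),
                             weight = c(0.9, 0.4)), signed = TRUE)
  expect_equal(commonNeighborSimilarity(g1, "s", "h"), 0.9)

  # one common enemy (+0.7) cancels one enemy-of-s/friend-of-h (-0.7)
  g2 <- DrugGraph(c("s", "h", "n", "m"),
                  data.frame(from = c("s", "h", "s", "h"),
                             to = c("n", "n", "m", "m"),
                             weight = c(-0.7, -0.3, -0.7, 0.5)),
                  signed = TRUE)
  expect_equal(commonNeighborSimilarity(g2, "s", "h"), 0.0)

  # random graphs vs the four-loop oracle
  for (seed in 1:8) {
    g <- randomSignedGraph(10, seed = seed)
    W <- weightMatrix(g)
    ids <- nodeIds(g)
    for (s in c(1, 4, 7)) for (h in c(2, 5, 10)) {
      if (s == h) next
      expect_equal(commonNeighborSimilarity(g, ids[s], ids[h]),
                   oracleLs(W, s, h))
    }
  }
  expect_error(commonNeighborSimilarity(randomSignedGraph(5), "n01", "n01"),
               "distinct")
})

test_that("signed transition reproduces hand-computed distributions", {
  # only positive neighbors: friend branch alone, weight-proportional
  g <- DrugGraph(c("s", "a", "b"),
                 data.frame(from = c("s", "s"), to = c("a", "b"),
                            weight = c(0.6, 0.2)), signed = TRUE)
  d <- signedTransition(g, "s", walkParams(p = 1, q = 1))
  expect_equal(d[["a"]], 0.75)
  expect_equal(d[["b"]], 0.25)

  # enemy's enemy as the single candidate
  g2 <- DrugGraph(c("s", "k", "h", "r"),
                  data.frame(from = c("s", "k", "s", "h"),
                             to = c("k", "h", "r", "r"),
                             weight = c(-0.5, -0.8, -0.4, -0.9)),
                  signed = TRUE)
  # ls(s,h): common enemy r with |w(s,r)| = 0.4 > 0 qualifies h
  d2 <- signedTransition(g2, "s")
  expect_equal(names(d2), "h")
  expect_equal(unname(d2), 1)

  # isolated node: empty distribution
  g3 <- DrugGraph(c("s", "x"), signed = TRUE)
  expect_length(signedTransition(g3, "s"), 0)
})

test_that("signed and unsigned kernels match brute-force oracles on random graphs", {
  nGraphs <- 30  # light version; the acceptance suite sweeps 200 graphs
  for (seed in seq_len(nGraphs)) {
    set.seed(seed + 5000)
    n <- sample(6:12, 1)
    p <- runif(1, 0.2, 3); q <- runif(1, 0.2, 3)
    g <- randomSignedGraph(n, pEdge = runif(1, 0.25, 0.7), seed = seed)
    W <- weightMatrix(g)
    ids <- nodeIds(g)
    for (s in seq_len(n)) {
      d <- signedTransition(g, ids[s], walkParams(p = p, q = q))
      full <- numeric(n); full[match(names(d), ids)] <- d
      expect_equal(full, oracleSignedKernel(W, s, p, q), tolerance = 1e-12)
    }

    a <- runif(1, 0.2, 3); bta <- runif(1, 0.2, 3)
    gu <- randomUnsignedGraph(n, pEdge = runif(1, 0.3, 0.8),
                              seed = seed + 999)
    Wu <- weightMatrix(gu)
    idsu <- nodeIds(gu)
    for (s in sample(n, 3)) {
      d0 <- unsignedTransition(gu, NULL, idsu[s], walkParams(alpha = a, beta = bta))
      full0 <- numeric(n); full0[match(names(d0), idsu)] <- d0
      expect_equal(full0, oracleUnsignedKernel(Wu, NULL, s, a, bta),
                   tolerance = 1e-12)
      for (t in which(Wu[s, ] > 0)) {
        d1 <- unsignedTransition(gu, idsu[t], idsu[s],
                                 walkParams(alpha = a, beta = bta))
        full1 <- numeric(n); full1[match(names(d1), idsu)] <- d1
        expect_equal(full1, oracleUnsignedKernel(Wu, t, s, a, bta),
                     tolerance = 1e-12)
        # compiled sampler sees the identical kernel
        expect_equal(full1,
                     as.numeric(rwshin:::cpp_unsigned_kernel_row(
                       Wu, t - 1L, s - 1L, a, bta)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("unsigned transition honors the BFS/DFS bias cases", {
  # alpha = beta: distribution proportional to edge weights regardless of t
  g <- randomUnsignedGraph(8, seed = 11)
  W <- weightMatrix(g)
  ids <- nodeIds(g)
  s <- which.max(rowSums(W > 0))
  nb <- which(W[s, ] > 0)
  d <- unsignedTransition(g, ids[nb[1]], ids[s], walkParams(alpha = 2, beta = 2))
  expect_equal(unname(d[ids[nb]]), unname(W[s, nb] / sum(W[s, nb])))

  # triangle t-s-h plus pendant gnode on s, unit weights, alpha 2 beta 1
  tg <- DrugGraph(c("t", "s", "h", "gn"),
                  data.frame(from = c("t", "t", "s", "s"),
                             to = c("s", "h", "h", "gn"),
                             weight = 1), signed = FALSE)
  d2 <- unsignedTransition(tg, "t", "s", walkParams(alpha = 2, beta = 1))
  # candidates from s: t (backtrack, alpha), h (adjacent to t, alpha),
  # gn (beta) -> unnormalized 2, 2, 1
  expect_equal(d2[["h"]], 0.4)
  expect_equal(d2[["gn"]], 0.2)
  expect_equal(d2[["t"]], 0.4)
})

test_that("transition distributions are proper and candidates valid", {
  for (seed in 1:20) {
    g <- randomSignedGraph(10, pEdge = 0.5, seed = seed + 300)
    W <- weightMatrix(g)
    ids <- nodeIds(g)
    for (s in seq_len(10)) {
      d <- signedTransition(g, ids[s])
      if (!length(d)) next
      expect_equal(sum(d), 1, tolerance = 1e-9)
      expect_true(all(d > 0))
      for (h in match(names(d), ids)) {
        ok <- W[s, h] > 0 ||
          (W[s, h] == 0 && oracleLs(W, s, h) > 0 &&
             any(W[s, ] < 0 & W[, h] < 0))
        expect_true(ok)
      }
    }
  }
})

test_that("signed walks never traverse a negative edge directly", {
  for (seed in 1:5) {
    g <- randomSignedGraph(12, pEdge = 0.5, seed = seed + 40)
    W <- weightMatrix(g)
    ids <- nodeIds(g)
    cp <- generateSignedWalks(g, walkParams(walksPerNode = 4,
                                            walkLength = 30), seed = seed)
    for (w in walks(cp)) {
      if (length(w) < 2) next
      ij <- cbind(match(w[-length(w)], ids), match(w[-1], ids))
      expect_true(all(W[ij] >= 0))  # positive edge or enemy's-enemy hop
    }
  }
})

test_that("walk generation honors its count, determinism and dead-end contracts", {
  g <- randomSignedGraph(8, seed = 2)
  p <- walkParams(walksPerNode = 3, walkLength = 12)
  c1 <- generateSignedWalks(g, p, seed = 9)
  c2 <- generateSignedWalks(g, p, seed = 9)
  expect_identical(walks(c1), walks(c2))
  expect_length(walks(c1), 3 * 8)

  # isolated node: r walks of length 1
  gi <- DrugGraph(c("a", "b"), signed = TRUE)
  ci <- generateSignedWalks(gi, walkParams(walksPerNode = 2, walkLength = 5))
  expect_length(walks(ci), 4)
  expect_true(all(lengths(walks(ci)) == 1))

  # two-node positive edge: forced alternation to full length
  g2 <- DrugGraph(c("a", "b"),
                  data.frame(from = "a", to = "b", weight = 0.7),
                  signed = TRUE)
  c2n <- generateSignedWalks(g2, walkParams(walksPerNode = 1, walkLength = 5))
  for (w in walks(c2n)) {
    expect_length(w, 5)
    expect_true(all(w[-1] != w[-5]))
  }

  # unsigned: r = 2 on 3 nodes -> exactly 6 walks; deterministic
  gu <- randomUnsignedGraph(3, pEdge = 1, seed = 1)
  cu1 <- generateUnsignedWalks(gu, walkParams(walksPerNode = 2, walkLength = 6),
                               seed = 4)
  cu2 <- generateUnsignedWalks(gu, walkParams(walksPerNode = 2, walkLength = 6),
                               seed = 4)
  expect_length(walks(cu1), 6)
  expect_identical(walks(cu1), walks(cu2))
})

test_that("DFS-heavy bias drives walks outward on a path graph", {
  g <- DrugGraph(c("a", "b", "c"),
                 data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1),
                 signed = FALSE)
  # beta >> alpha: from a the walk goes a-b, then at b prefers c (not
  # adjacent to a) over backtracking
  cp <- generateUnsignedWalks(g, walkParams(alpha = 0.05, beta = 1,
                                            walksPerNode = 1, walkLength = 3),
                              seed = 1, starts = rep("a", 2000))
  third <- vapply(walks(cp), `[`, character(1), 3)
  reachC <- mean(third == "c")
  # exact kernel: P(c | b, prev a) = 1/(1 + 0.05)
  expect_gt(reachC, 0.9)
  expect_lt(abs(reachC - 1 / 1.05), 0.02)
})

test_that("pooled corpus covers the subnetworks and supports the ablation", {
  b <- smallBundle(4)
  hin <- assembleHIN(buildUnsignedSubnetwork(b$chemical),
                     buildUnsignedSubnetwork(b$labels),
                     buildUnsignedSubnetwork(b$target),
                     buildSignedSubnetwork(b$assoc))
  p <- walkParams(walksPerNode = 2, walkLength = 10)
  cp <- buildCorpus(hin, p, seed = 3)
  expect_setequal(unique(walkSource(cp)),
                  c("chemical", "side_effect", "target", "signed_target"))
  expect_lte(length(walks(cp)), 4 * 30 * 2)
  expect_identical(walks(cp), walks(buildCorpus(hin, p, seed = 3)))

  # unsigned-only ablation drops exactly the signed walks
  cpU <- buildCorpus(hin, p, seed = 3, unsignedOnly = TRUE)
  expect_false("signed_target" %in% walkSource(cpU))
  expect_identical(walks(cpU),
                   walks(cp)[walkSource(cp) != "signed_target"])

  # an edgeless signed subnetwork gives the same corpus as the flag
  hin0 <- assembleHIN(subnetwork(hin, "chemical"),
                      subnetwork(hin, "side_effect"),
                      subnetwork(hin, "target"))
  expect_identical(walks(buildCorpus(hin0, p, seed = 3)), walks(cpU))
})

test_that("corpus files round-trip with provenance tags", {
  g <- randomSignedGraph(6, seed = 8)
  cp <- generateSignedWalks(g, walkParams(walksPerNode = 2, walkLength = 8),
                            seed = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  writeCorpus(cp, path)
  cp2 <- readCorpus(path)
  expect_identical(walks(cp2), walks(cp))
  expect_identical(walkSource(cp2), walkSource(cp))
})
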