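#' @include network.R
NULL

#' Random-walk parameter set
#'
#' Bundles the tunable parameters of the two biased walk procedures.
#' `p` and `q` steer the signed walk between friend hops and
#' enemy's-enemy hops; `alpha` and `beta` steer the unsigned walk between
#' breadth-first (stay near the previous node) and depth-first (move away)
#' sampling.  All four are nonnegative relative propensities; equal values
#' give an unbiased weight-proportional walk.
#'
#' @param p friend-hop bias (>= 0) of the signed walk.
#' @param q enemy's-enemy bias (>= 0) of the signed walk.
#' @param alpha BFS bias (>= 0) of the unsigned walk.
#' @param beta DFS bias (>= 0) of the unsigned walk.
#' @param walksPerNode number of walks started from every node (r >= 1).
#' @param walkLength maximum walk length in nodes (l >= 2).
#' @return A validated list of class `WalkParams`.
#' @export
walkParams <- function(p = 1, q = 1, alpha = 1, beta = 1,
                       walksPerNode = 10, walkLength = 80) {
  stopifnot(p >= 0, q >= 0, p + q > 0,
            alpha >= 0, beta >= 0, alpha + beta > 0,
            walksPerNode >= 1, walkLength >= 2)
  structure(list(p = p, q = q, alpha = alpha, beta = beta,
                 walksPerNode = as.integer(walksPerNode),
                 walkLength = as.integer(walkLength)),
            class = "WalkParams")
}

.asWalkParams <- function(params) {
  if (!inherits(params, "WalkParams")) params <- do.call(walkParams, params)
  params
}

.nodeIndex <- function(g, v) {
  i <- match(v, g@nodeIds)
  if (anyNA(i)) stop("unknown node(s): ", paste(v[is.na(i)], collapse = ", "))
  i
}

#' Friend and enemy sets of a node in a signed graph
#'
#' Friends are neighbors joined by a positive edge, enemies by a negative
#' edge; the two sets are disjoint by construction.
#'
#' @param g a signed [DrugGraph-class].
#' @param v a node id.
#' @return List with character components `friends` and `enemies`.
#' @export
friendEnemySets <- function(g, v) {
  stopifnot(is(g, "DrugGraph"), isSigned(g))
  i <- .nodeIndex(g, v)
  W <- weightMatrix(g)
  list(friends = g@nodeIds[W[i, ] > 0],
       enemies = g@nodeIds[W[i, ] < 0])
}

## ls(s,h) on the dense weight matrix; s, h are node indices.
## Common friends and common enemies argue for a positive (latent) relation
## between s and h and enter with positive sign; mixed friend/enemy overlap
## argues against and enters negatively.  All terms are weighted by the
## magnitude of s's edge to the shared neighbor.
.lsScore <- function(W, s, h) {
  ws <- W[s, ]; wh <- W[h, ]
  Fs <- ws > 0; Es <- ws < 0
  Fh <- wh > 0; Eh <- wh < 0
  sum(ws[Fs & Fh]) + sum(abs(ws[Es & Eh])) -
    sum(abs(ws[Es & Fh])) - sum(ws[Fs & Eh])
}

#' Common-neighbor relation similarity in a signed graph
#'
#' Scores the latent relation between two non-adjacent nodes from their
#' shared neighborhoods: shared friends and shared enemies contribute
#' positively (weighted by the first node's edge magnitudes), while
#' neighbors that are an enemy of one but a friend of the other contribute
#' negatively.  The signed walk only hops to an enemy's enemy `h` when this
#' score is strictly positive.
#'
#' @param g a signed [DrugGraph-class].
#' @param s,h distinct node ids.
#' @return Numeric scalar.
#' @export
commonNeighborSimilarity <- function(g, s, h) {
  stopifnot(is(g, "DrugGraph"), isSigned(g))
  idx <- .nodeIndex(g, c(s, h))
  if (idx[1L] == idx[2L]) stop("s and h must be distinct")
  .lsScore(weightMatrix(g), idx[1L], idx[2L])
}

## Unnormalized then renormalized transition scores out of node s (index)
## on a signed graph with dense weight matrix W.  Returns a numeric vector
## of length n (zero where not a candidate).
.signedTransitionRow <- function(W, s, p, q) {
  n <- ncol(W)
  ws <- W[s, ]
  Fi <- which(ws > 0)
  Ei <- which(ws < 0)
  normF <- sum(ws[Fi])
  if (normF == 0) normF <- 1  # no friends: common factor, cancels on renorm
  score <- numeric(n)
  score[Fi] <- p * ws[Fi] / normF
  if (length(Ei) && q > 0) {
    enemyScore <- numeric(n)
    for (k in Ei) {
      wk <- W[k, ]
      Ek <- which(wk < 0)
      normEk <- sum(abs(wk[Ek]))
      cand <- Ek[ws[Ek] == 0 & Ek != s]
      if (length(cand))
        enemyScore[cand] <- enemyScore[cand] +
          q * abs(ws[k]) * abs(wk[cand]) / (normF * normEk)
    }
    for (h in which(enemyScore > 0))
      if (.lsScore(W, s, h) <= 0) enemyScore[h] <- 0
    score <- score + enemyScore
  }
  tot <- sum(score)
  if (tot > 0) score / tot else score
}

#' Signed-walk transition distribution from a node
#'
#' Candidates are (i) the friends of `s`, with probability proportional to
#' `p` times the positive edge weight normalized by the total friend
#' weight, and (ii) enemy's-enemy nodes `h` -- reached through some enemy
#' `k` of `s` via a negative edge (k, h), not adjacent to `s`, distinct
#' from `s`, and with positive common-neighbor similarity -- with
#' probability proportional to `q` times the product of edge magnitudes
#' normalized by the friend-weight of `s` and the enemy-weight of `k`,
#' summed over qualifying intermediaries.  Scores are renormalized to a
#' probability distribution; a node with no candidates yields an empty
#' distribution (walk dead end).
#'
#' @param g a signed [DrugGraph-class].
#' @param s node id.
#' @param params a [walkParams()] list (only `p` and `q` are used).
#' @return Named numeric vector of probabilities over candidate node ids
#'   (empty if there is no candidate).
#' @export
signedTransition <- function(g, s, params = walkParams()) {
  stopifnot(is(g, "DrugGraph"), isSigned(g))
  params <- .asWalkParams(params)
  i <- .nodeIndex(g, s)
  row <- .signedTransitionRow(weightMatrix(g), i, params$p, params$q)
  keep <- row > 0
  stats::setNames(row[keep], g@nodeIds[keep])
}

#' Unsigned-walk transition distribution from a node
#'
#' Second-order kernel: given the previous node `t` and current node `s`,
#' each neighbor `h` of `s` is scored `alpha * w(s, h)` when `h` is
#' adjacent to `t` or equals `t` (breadth-first moves, including the
#' immediate backtrack) and `beta * w(s, h)` otherwise (depth-first moves),
#' then renormalized.  On the first step (`t = NULL`) scores are
#' proportional to the edge weights alone.
#'
#' @param g an unsigned [DrugGraph-class].
#' @param t previous node id, or `NULL` on the first step.
#' @param s current node id.
#' @param params a [walkParams()] list (only `alpha` and `beta` are used).
#' @return Named numeric vector of probabilities over the neighbors of `s`.
#' @export
unsignedTransition <- function(g, t, s, params = walkParams()) {
  stopifnot(is(g, "DrugGraph"), !isSigned(g))
  params <- .asWalkParams(params)
  si <- .nodeIndex(g, s)
  W <- weightMatrix(g)
  nb <- which(W[si, ] > 0)
  if (!length(nb)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(t)) {
    score <- W[si, nb]
  } else {
    ti <- .nodeIndex(g, t)
    bfs <- (W[ti, nb] != 0) | (nb == ti)
    score <- ifelse(bfs, params$alpha, params$beta) * W[si, nb]
  }
  tot <- sum(score)
  if (tot == 0) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(score / tot, g@nodeIds[nb])
}

## Internal subnetwork ids used to derive independent random streams.
.subnetId <- c(chemical = 1L, side_effect = 2L, target = 3L,
               signed_target = 4L, unknown = 0L)

.sourceTagId <- function(tag) {
  id <- .subnetId[tag]
  if (is.na(id)) id <- 0L
  unname(id)
}

.walksToCorpus <- function(paths, nodeIds, tag) {
  WalkCorpus(lapply(paths, function(p) nodeIds[p]), tag)
}

#' Generate biased random walks on the signed subnetwork
#'
#' Starts `walksPerNode` walks from every node (or from explicit `starts`)
#' and extends each by sampling [signedTransition()] until `walkLength`
#' nodes are collected or a dead end (empty candidate set) terminates the
#' walk early.  Each walk draws from its own random stream derived from
#' (`seed`, subnetwork, start node, walk index), so the corpus is
#' reproducible and independent of generation order.
#'
#' @param g a signed [DrugGraph-class].
#' @param params a [walkParams()] list.
#' @param seed integer master seed.
#' @param starts optional character vector of start nodes (overrides the
#'   every-node-times-r default; one walk per entry).
#' @param tag provenance tag recorded in the corpus.
#' @return A [WalkCorpus-class].
#' @export
generateSignedWalks <- function(g, params = walkParams(), seed = 1L,
                                starts = NULL, tag = "signed_target") {
  stopifnot(is(g, "DrugGraph"), isSigned(g))
  params <- .asWalkParams(params)
  W <- weightMatrix(g)
  n <- ncol(W)
  K <- matrix(0, n, n)
  for (s in seq_len(n))
    K[s, ] <- .signedTransitionRow(W, s, params$p, params$q)
  st <- .walkStarts(g, params, seed, starts, .sourceTagId(tag))
  paths <- cpp_walk_first_order(K, st$idx - 1L, params$walkLength,
                                as.integer(seed), st$subnet, st$widx)
  .walksToCorpus(paths, g@nodeIds, tag)
}

#' Generate biased random walks on an unsigned subnetwork
#'
#' Same contract as [generateSignedWalks()] but uses the second-order
#' BFS/DFS-biased kernel of [unsignedTransition()], tracking the previous
#' node along each walk.
#'
#' @inheritParams generateSignedWalks
#' @param g an unsigned [DrugGraph-class].
#' @export
generateUnsignedWalks <- function(g, params = walkParams(), seed = 1L,
                                  starts = NULL, tag = "unknown") {
  stopifnot(is(g, "DrugGraph"), !isSigned(g))
  params <- .asWalkParams(params)
  W <- weightMatrix(g)
  st <- .walkStarts(g, params, seed, starts, .sourceTagId(tag))
  paths <- cpp_walk_second_order(W, st$idx - 1L, params$walkLength,
                                 params$alpha, params$beta,
                                 as.integer(seed), st$subnet, st$widx)
  .walksToCorpus(paths, g@nodeIds, tag)
}

## Start-node bookkeeping: r walks per node in a seed-derived randomized
## order, or explicit starts (walk index counts repeats per start node so
## streams stay distinct).
.walkStarts <- function(g, params, seed, starts, subnetId) {
  if (is.null(starts)) {
    idx <- rep(seq_along(g@nodeIds), params$walksPerNode)
    widx <- rep(seq_len(params$walksPerNode), each = length(g@nodeIds))
    perm <- .derivedPermutation(length(idx), seed, subnetId)
    idx <- idx[perm]; widx <- widx[perm]
  } else {
    idx <- .nodeIndex(g, starts)
    widx <- stats::ave(seq_along(idx), idx, FUN = seq_along)
  }
  list(idx = idx, widx = as.integer(widx), subnet = as.integer(subnetId))
}

.derivedPermutation <- function(n, seed, subnetId) {
  .withSeed((as.integer(seed) * 131L + as.integer(subnetId)) %%
              .Machine$integer.max,
            sample.int(n))
}

#' Pool walks from all subnetworks of a HIN into one corpus
#'
#' Runs the unsigned walk on the chemical, side-effect and target
#' subnetworks and the signed walk on the signed subnetwork, then
#' concatenates the walks with per-subnetwork provenance tags.  With
#' `unsignedOnly = TRUE` (or an edgeless signed subnetwork) the signed
#' walks are omitted, which is exactly the unsigned-ablation variant of
#' the method.
#'
#' @param hin a [DrugHIN-class].
#' @param params a [walkParams()] list.
#' @param seed integer master seed.
#' @param unsignedOnly logical; drop the signed subnetwork walks.
#' @return A [WalkCorpus-class].
#' @export
buildCorpus <- function(hin, params = walkParams(), seed = 1L,
                        unsignedOnly = FALSE) {
  stopifnot(is(hin, "DrugHIN"))
  params <- .asWalkParams(params)
  pieces <- list()
  for (nm in c("chemical", "side_effect", "target"))
    pieces[[nm]] <- generateUnsignedWalks(subnetwork(hin, nm), params,
                                          seed = seed, tag = nm)
  if (!unsignedOnly && nrow(subnetwork(hin, "signed_target")@edges))
    pieces$signed_target <- generateSignedWalks(
      subnetwork(hin, "signed_target"), params, seed = seed,
      tag = "signed_target")
  WalkCorpus(do.call(c, c(lapply(pieces, walks), list())),
             unlist(lapply(pieces, walkSource), use.names = FALSE))
}

#' Write a walk corpus to a text file
#'
#' One walk per line, space-separated drug ids; a `#subnetwork=<tag>`
#' comment line precedes each block of walks and applies until the next
#' tag.  Round-trips through [readCorpus()].
#'
#' @param corpus a [WalkCorpus-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path) {
  w <- walks(corpus); src <- walkSource(corpus)
  con <- file(path, "w")
  on.exit(close(con))
  last <- NA_character_
  for (i in seq_along(w)) {
    if (is.na(last) || src[i] != last) {
      writeLines(paste0("#subnetwork=", src[i]), con)
      last <- src[i]
    }
    writeLines(paste(w[[i]], collapse = " "), con)
  }
  invisible(path)
}

#' Read a walk corpus from a text file
#'
#' @param path file written by [writeCorpus()].
#' @return A [WalkCorpus-class].
#' @export
readCorpus <- function(path) {
  lines <- readLines(path)
  tag <- "unknown"
  wl <- list(); src <- character()
  for (ln in lines) {
    if (startsWith(ln, "#subnetwork=")) {
      tag <- sub("^#subnetwork=", "", ln)
    } else if (nzchar(trimws(ln))) {
      wl[[length(wl) + 1L]] <- strsplit(trimws(ln), " ", fixed = TRUE)[[1L]]
      src <- c(src, tag)
    }
  }
  WalkCorpus(wl, src)
}
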