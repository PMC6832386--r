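#' @include AllClasses.R
NULL

#' Jaccard weight of two binary profile vectors
#'
#' Size of the intersection of set bits over the size of their union.  Two
#' all-zero vectors have weight 0 by convention (no evidence of
#' similarity).
#'
#' @param pi,pj equal-length 0/1 vectors.
#' @return Numeric scalar in \[0, 1\].
#' @examples
#' jaccardWeight(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 2/4
#' @export
jaccardWeight <- function(pi, pj) {
  if (length(pi) != length(pj))
    stop("profile vectors must have equal length")
  stopifnot(all(pi %in% 0:1), all(pj %in% 0:1))
  u <- sum(pi | pj)
  if (u == 0) return(0)
  sum(pi & pj) / u
}

#' Signed action-mode agreement weight of two drugs
#'
#' For signed target vectors `ai`, `aj` over \{-1, 0, +1\}, the weight is
#' the sum of the entrywise products over the sum of their absolute values:
#' +1 when the two drugs act with the same mode on every shared target, -1
#' when they act with opposite modes on every shared target, and 0 when
#' they share no targets (or agreements and disagreements balance).
#'
#' @param ai,aj equal-length vectors over \{-1, 0, +1\}.
#' @return Numeric scalar in \[-1, 1\].
#' @examples
#' signedWeight(c(1, 1), c(1, 1))    # +1
#' signedWeight(c(1), c(-1))         # -1
#' signedWeight(c(0, 0), c(1, -1))   #  0: no shared target
#' @export
signedWeight <- function(ai, aj) {
  if (length(ai) != length(aj))
    stop("signed vectors must have equal length")
  stopifnot(all(ai %in% -1:1), all(aj %in% -1:1))
  prod <- ai * aj
  den <- sum(abs(prod))
  if (den == 0) return(0)
  sum(prod) / den
}

#' Build an unsigned drug subnetwork from a binary profile set
#'
#' Nodes are all drugs of the profile set; an edge joins drugs `i` and `j`
#' when the Jaccard similarity of their profile vectors exceeds
#' `threshold`, and carries that similarity as its weight.  The default
#' threshold 0 keeps every pair with any shared feature; raising it
#' sparsifies dense similarity graphs.
#'
#' @param profiles a [BinaryProfileSet-class].
#' @param threshold numeric in \[0, 1); edges with Jaccard weight
#'   `<= threshold` are dropped.
#' @return An unsigned [DrugGraph-class].
#' @export
buildUnsignedSubnetwork <- function(profiles, threshold = 0) {
  stopifnot(is(profiles, "BinaryProfileSet"),
            threshold >= 0, threshold < 1)
  M <- featureMatrix(profiles)
  storage.mode(M) <- "double"
  inter <- tcrossprod(M)
  rs <- rowSums(M)
  un <- outer(rs, rs, "+") - inter
  J <- ifelse(un > 0, inter / un, 0)
  idx <- which(upper.tri(J) & J > threshold, arr.ind = TRUE)
  DrugGraph(rownames(M),
            data.frame(from = idx[, 1L], to = idx[, 2L],
                       weight = J[idx]),
            signed = FALSE)
}

#' Build the signed drug subnetwork from the association matrix
#'
#' For every drug pair with a nonzero action-mode agreement weight (see
#' [signedWeight()]) an edge carrying that weight is added; pairs with no
#' shared targets or perfectly balanced agreement are omitted.
#'
#' @param A a [SignedAssociationMatrix-class].
#' @return A signed [DrugGraph-class].
#' @export
buildSignedSubnetwork <- function(A) {
  stopifnot(is(A, "SignedAssociationMatrix"))
  a <- assocMatrix(A)
  storage.mode(a) <- "double"
  num <- tcrossprod(a)
  den <- tcrossprod(abs(a))
  W <- ifelse(den > 0, num / den, 0)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  DrugGraph(rownames(a),
            data.frame(from = idx[, 1L], to = idx[, 2L],
                       weight = W[idx]),
            signed = TRUE)
}

#' Dense symmetric weight matrix of a drug graph
#'
#' @param g a [DrugGraph-class].
#' @return Numeric n x n matrix with zero diagonal and dimnames; absent
#'   edges are 0.
#' @export
weightMatrix <- function(g) {
  stopifnot(is(g, "DrugGraph"))
  n <- length(g@nodeIds)
  W <- matrix(0, n, n, dimnames = list(g@nodeIds, g@nodeIds))
  e <- g@edges
  if (nrow(e)) {
    W[cbind(e$from, e$to)] <- e$weight
    W[cbind(e$to, e$from)] <- e$weight
  }
  W
}

#' Triad census of a signed graph
#'
#' Counts every closed triangle once and classifies it by the multiset of
#' its edge signs: T1 (+ + +), T2 (- - +), T3 (+ + -), T4 (- - -).  Under
#' structural balance theory T1 and T2 are balanced ("a friend's friend is
#' a friend", "an enemy's enemy is a friend"); their dominance justifies
#' the enemy's-enemy hop of the signed random walk.
#'
#' @param g a signed [DrugGraph-class].
#' @return Named integer vector with components `T1`, `T2`, `T3`, `T4` and
#'   `total`.
#' @export
triadCensus <- function(g) {
  stopifnot(is(g, "DrugGraph"), isSigned(g))
  W <- weightMatrix(g)
  P <- (W > 0) + 0
  N <- (W < 0) + 0
  t1 <- sum(diag(P %*% P %*% P)) / 6
  t4 <- sum(diag(N %*% N %*% N)) / 6
  t3 <- sum((P %*% P) * N) / 2   # exactly one negative edge
  t2 <- sum((N %*% N) * P) / 2   # exactly two negative edges
  out <- as.integer(round(c(t1, t2, t3, t4)))
  c(T1 = out[1L], T2 = out[2L], T3 = out[3L], T4 = out[4L],
    total = sum(out))
}

#' Triad class shares
#'
#' Converts a triad census into the percentage share of each triangle
#' class, the quantity used to judge whether balanced triads (T1, T2)
#' dominate a signed network.
#'
#' @param census named counts as returned by [triadCensus()] (components
#'   `T1` ... `T4` and `total`).
#' @return Named numeric vector of percentages summing to 100 (all-`NaN`
#'   when the census is empty).
#' @export
triadShares <- function(census) {
  stopifnot(all(c("T1", "T2", "T3", "T4", "total") %in% names(census)))
  100 * census[c("T1", "T2", "T3", "T4")] / as.numeric(census[["total"]])
}

#' Assemble the signed drug heterogeneous information network
#'
#' Validates that the four subnetworks share an identical node universe and
#' bundles them.  An edgeless signed subnetwork is allowed and degenerates
#' the method to its unsigned ablation.
#'
#' @param chemical,sideEffect,target unsigned [DrugGraph-class] objects.
#' @param signedTarget signed [DrugGraph-class]; default an edgeless signed
#'   graph over the same universe.
#' @return A validated [DrugHIN-class].
#' @export
assembleHIN <- function(chemical, sideEffect, target,
                        signedTarget = DrugGraph(nodeIds(chemical),
                                                 signed = TRUE)) {
  new("DrugHIN", subnetworks = list(chemical = chemical,
                                    side_effect = sideEffect,
                                    target = target,
                                    signed_target = signedTarget))
}

#' Write a drug graph as an edge-list TSV
#'
#' Columns `from`, `to`, `weight`; rows sorted lexicographically by
#' (`from`, `to`) with `from` < `to`, so output is deterministic.
#'
#' @param g a [DrugGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  e <- edgeTable(g)
  swap <- e$from > e$to
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  e <- e[order(e$from, e$to), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#nodes=", paste(nodeIds(g), collapse = ",")), con)
  writeLines(paste0("#signed=", tolower(isSigned(g))), con)
  utils::write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug graph from an edge-list TSV
#'
#' @param path file written by [writeEdgeList()].
#' @return A [DrugGraph-class].
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  nodes <- sub("^#nodes=", "", grep("^#nodes=", hdr, value = TRUE))
  signed <- identical(sub("^#signed=", "",
                          grep("^#signed=", hdr, value = TRUE)), "true")
  if (!length(nodes)) stop("missing #nodes= header line")
  nodes <- strsplit(nodes, ",", fixed = TRUE)[[1L]]
  body <- lines[!grepl("^#", lines)]
  if (length(body) <= 1L)
    return(DrugGraph(nodes, signed = signed))
  e <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                         colClasses = c("character", "character", "numeric"))
  DrugGraph(nodes, e, signed = signed)
}
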