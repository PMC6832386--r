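#' @include embedding.R
NULL

#' Fit one per-side-effect classifier
#'
#' L2-regularized logistic regression of a binary side-effect label on the
#' drug embeddings: minimizes the summed logistic log-loss plus
#' `lambda * ||w||^2` (the intercept is not penalized) by damped
#' Newton-Raphson to a gradient-norm tolerance of 1e-6.
#'
#' @param Z numeric matrix of training-drug embeddings (drugs x d).
#' @param y binary 0/1 label vector, one per row of `Z`; must contain both
#'   classes.
#' @param lambda ridge penalty (> 0).
#' @return List of class `seClassifier` with components `w` (length-d
#'   weight vector), `b` (intercept), `lambda`, `gradNorm` and
#'   `converged`.
#' @export
fitSideEffectClassifier <- function(Z, y, lambda = 1) {
  Z <- as.matrix(Z)
  y <- as.numeric(y)
  stopifnot(nrow(Z) == length(y), all(y %in% c(0, 1)), lambda > 0)
  if (length(unique(y)) < 2L)
    stop("degenerate labels: training set must contain both classes")
  d <- ncol(Z)
  theta <- numeric(d + 1L)             # (w, b)
  obj <- function(th) {
    eta <- drop(Z %*% th[1:d]) + th[d + 1L]
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda * sum(th[1:d]^2)
  }
  gradient <- function(th) {
    eta <- drop(Z %*% th[1:d]) + th[d + 1L]
    r <- 1 / (1 + exp(-eta)) - y
    c(drop(crossprod(Z, r)) + 2 * lambda * th[1:d], sum(r))
  }
  for (it in seq_len(200L)) {
    eta <- drop(Z %*% theta[1:d]) + theta[d + 1L]
    mu <- 1 / (1 + exp(-eta))
    g <- gradient(theta)
    if (sqrt(sum(g^2)) < 1e-6) break
    s <- pmax(mu * (1 - mu), 1e-10)
    X1 <- cbind(Z, 1)
    H <- crossprod(X1 * s, X1)
    diag(H)[1:d] <- diag(H)[1:d] + 2 * lambda
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    f0 <- obj(theta)
    t <- 1
    repeat {                           # backtracking line search
      cand <- theta - t * step
      if (obj(cand) <= f0 || t < 1e-8) break
      t <- t / 2
    }
    theta <- cand
  }
  g <- gradient(theta)
  structure(list(w = theta[1:d], b = theta[d + 1L], lambda = lambda,
                 gradNorm = sqrt(sum(g^2)),
                 converged = sqrt(sum(g^2)) < 1e-6),
            class = "seClassifier")
}

#' Predict side-effect probabilities from a fitted classifier
#'
#' @param fit an `seClassifier` from [fitSideEffectClassifier()].
#' @param Z embedding matrix of the drugs to score.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predictScores <- function(fit, Z) {
  stopifnot(inherits(fit, "seClassifier"))
  eta <- drop(as.matrix(Z) %*% fit$w) + fit$b
  1 / (1 + exp(-eta))
}

## Seeded fold assignment: uniform shuffle then contiguous split, sizes
## equal up to a remainder of 1.
.assignFolds <- function(ids, nFolds, seed) {
  n <- length(ids)
  if (n < nFolds) stop("fewer drugs than folds")
  perm <- .withSeed(seed, sample.int(n))
  fold <- integer(n)
  sizes <- rep(n %/% nFolds, nFolds) + (seq_len(nFolds) <= n %% nFolds)
  fold[perm] <- rep(seq_len(nFolds), sizes)
  stats::setNames(fold, ids)
}

#' Drug-wise cross-validated side-effect prediction
#'
#' Splits the drugs into `nFolds` near-equal folds and, for each fold:
#' rebuilds the side-effect subnetwork from the training drugs' profiles
#' only (test drugs' side-effect rows are zeroed before network
#' construction, so label information never leaks into test-drug
#' features), rebuilds the walk corpus and embeddings on the full drug
#' universe, fits one classifier per side-effect term on the training
#' drugs, and scores the held-out drugs.  Side-effect terms with fewer
#' than two training positives (or no negatives) are skipped and scored
#' at the uninformative 0.5.
#'
#' @param chemical,target [BinaryProfileSet-class] objects over the drug
#'   universe.
#' @param signedAssoc a [SignedAssociationMatrix-class], or `NULL` for the
#'   unsigned ablation.
#' @param labels a [BinaryProfileSet-class] of kind `"side_effect"`:
#'   simultaneously the side-effect profile (training-drug features) and
#'   the prediction target.
#' @param nFolds number of folds (default 5).
#' @param params a [walkParams()] list.
#' @param dim,window,epochs,negative,lr Skip-gram hyperparameters, see
#'   [trainSkipgram()].
#' @param lambda ridge penalty of the per-term classifiers.
#' @param threshold Jaccard sparsification threshold for the unsigned
#'   subnetworks.
#' @param seed integer master seed (folds, walks and training).
#' @param unsignedOnly logical; drop the signed subnetwork (ablation).
#' @return A `data.frame` score table with one row per (held-out drug,
#'   side-effect term): columns `drug_id`, `side_effect_id`, `score`,
#'   `label`, `fold`.
#' @export
crossValidate <- function(chemical, target, signedAssoc, labels,
                          nFolds = 5, params = walkParams(), dim = 32,
                          window = 5, epochs = 5, negative = 5, lr = 0.025,
                          lambda = 1, threshold = 0, seed = 1L,
                          unsignedOnly = FALSE) {
  stopifnot(is(chemical, "BinaryProfileSet"), is(target, "BinaryProfileSet"),
            is(labels, "BinaryProfileSet"))
  ids <- drugIds(labels)
  if (!identical(drugIds(chemical), ids) || !identical(drugIds(target), ids))
    stop("profile sets must share one drug universe in identical order")
  if (!is.null(signedAssoc) && !identical(drugIds(signedAssoc), ids))
    stop("signed association matrix must share the drug universe")
  Y <- featureMatrix(labels)
  fold <- .assignFolds(ids, nFolds, seed)
  gChem <- buildUnsignedSubnetwork(chemical, threshold)
  gTarg <- buildUnsignedSubnetwork(target, threshold)
  gSign <- if (is.null(signedAssoc) || unsignedOnly)
    DrugGraph(ids, signed = TRUE) else buildSignedSubnetwork(signedAssoc)
  out <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    test <- ids[fold == f]
    train <- ids[fold != f]
    seFeat <- Y
    seFeat[test, ] <- 0L                   # test drugs contribute no edges
    gSe <- buildUnsignedSubnetwork(BinaryProfileSet(seFeat, "side_effect"),
                                   threshold)
    hin <- assembleHIN(gChem, gSe, gTarg, gSign)
    corpus <- buildCorpus(hin, params, seed = seed + f,
                          unsignedOnly = unsignedOnly)
    emb <- trainSkipgram(corpus, dim = dim, window = window,
                         epochs = epochs, negative = negative, lr = lr,
                         seed = seed + f)
    V <- embeddingMatrix(emb)[ids, , drop = FALSE]
    Ztr <- V[train, , drop = FALSE]
    Zte <- V[test, , drop = FALSE]
    scores <- matrix(0.5, length(test), ncol(Y),
                     dimnames = list(test, colnames(Y)))
    for (s in colnames(Y)) {
      ytr <- Y[train, s]
      if (sum(ytr) < 2L || sum(1 - ytr) < 1L) next   # degenerate term
      fit <- fitSideEffectClassifier(Ztr, ytr, lambda = lambda)
      scores[, s] <- predictScores(fit, Zte)
    }
    out[[f]] <- data.frame(
      drug_id = rep(test, times = ncol(Y)),
      side_effect_id = rep(colnames(Y), each = length(test)),
      score = as.vector(scores),
      label = as.vector(Y[test, , drop = FALSE]),
      fold = f)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.checkScoreTable <- function(T) {
  need <- c("drug_id", "side_effect_id", "score", "label")
  if (!all(need %in% names(T)))
    stop("score table must have columns ", paste(need, collapse = ", "))
  invisible(T)
}

## Tie-averaged rank (Mann-Whitney) AUROC.
.rankAuc <- function(score, label) {
  np <- sum(label == 1); nn <- sum(label == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Merged ROC curve and AUROC of a score table
#'
#' Pools every (drug, side-effect) score-label pair across folds and
#' terms, computes the ROC curve (true-positive rate against
#' false-positive rate over all score thresholds) and the area under it
#' via the tie-averaged rank statistic.
#'
#' @param T score table as returned by [crossValidate()].
#' @return List of class `RocMetrics`: `auroc`, and parallel vectors
#'   `thresholds`, `tpr`, `fpr` describing the curve from (0, 0) to
#'   (1, 1).
#' @export
mergedRocAuc <- function(T) {
  .checkScoreTable(T)
  lab <- as.numeric(T$label)
  if (length(unique(lab)) < 2L)
    stop("score table contains only one class")
  sc <- as.numeric(T$score)
  o <- order(sc, decreasing = TRUE)
  sc <- sc[o]; lab <- lab[o]
  keep <- c(sc[-length(sc)] != sc[-1L], TRUE)     # one point per threshold
  tp <- cumsum(lab)[keep]; fp <- cumsum(1 - lab)[keep]
  np <- sum(lab); nn <- length(lab) - np
  structure(list(auroc = .rankAuc(T$score, as.numeric(T$label)),
                 thresholds = c(Inf, sc[keep]),
                 tpr = c(0, tp / np), fpr = c(0, fp / nn)),
            class = "RocMetrics")
}

#' Per-side-effect AUROC
#'
#' Computes the tie-averaged rank AUROC separately for each side-effect
#' term.  Terms whose pooled test scores contain a single class are
#' reported as `NA` with `defined = FALSE` rather than 0.
#'
#' @param T score table as returned by [crossValidate()].
#' @return `data.frame` with columns `side_effect_id`, `auroc`,
#'   `defined`.
#' @export
perSideEffectAuroc <- function(T) {
  .checkScoreTable(T)
  terms <- unique(T$side_effect_id)
  auc <- vapply(terms, function(s) {
    i <- T$side_effect_id == s
    .rankAuc(as.numeric(T$score[i]), as.numeric(T$label[i]))
  }, numeric(1))
  data.frame(side_effect_id = terms, auroc = unname(auc),
             defined = !is.na(auc))
}

#' Top-K hit count over drugs
#'
#' For each drug, ranks all side-effect terms by its held-out scores
#' (ties broken by ascending side-effect id, so the count is
#' deterministic) and counts the drugs whose K highest-ranked terms
#' contain at least one known side-effect.  Drugs with no known
#' side-effect can never be counted.
#'
#' @param T score table as returned by [crossValidate()].
#' @param K number of top predictions to inspect (>= 1).
#' @return Integer hit count.
#' @export
topkHits <- function(T, K) {
  .checkScoreTable(T)
  stopifnot(K >= 1)
  hits <- 0L
  for (d in unique(T$drug_id)) {
    sub <- T[T$drug_id == d, ]
    o <- order(-sub$score, sub$side_effect_id)
    top <- sub$label[o][seq_len(min(K, nrow(sub)))]
    if (any(top == 1)) hits <- hits + 1L
  }
  hits
}

#' Write a score table TSV
#'
#' @param T score table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(T, path) {
  utils::write.table(T, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table TSV
#'
#' @param path file written by [writeScoreTable()].
#' @return `data.frame` score table.
#' @export
readScoreTable <- function(path) {
  utils::read.delim(path, sep = "\t",
                    colClasses = c(drug_id = "character",
                                   side_effect_id = "character"))
}

#' Summarize a score table into a metrics report
#'
#' @param T score table.
#' @param topK integer vector of K values for the Top-K hit counts.
#' @return List with `mergedAuroc`, `perSideEffect` (data.frame) and
#'   `topK` (named integer vector).
#' @export
metricsReport <- function(T, topK = c(1, 3, 5)) {
  per <- perSideEffectAuroc(T)
  hits <- vapply(topK, function(k) topkHits(T, k), integer(1))
  list(mergedAuroc = mergedRocAuc(T)$auroc,
       perSideEffect = per,
       topK = stats::setNames(hits, paste0("top", topK)))
}
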