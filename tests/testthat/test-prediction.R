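test_that("ridge logistic classifier fits separable data and obeys its limits", {
  set.seed(1)
  Z <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  y <- rep(c(0, 1), each = 20)
  fit <- fitSideEffectClassifier(Z, y, lambda = 1e-4)
  expect_true(fit$converged)
  expect_identical(as.numeric(predictScores(fit, Z) > 0.5), y)

  # lambda -> infinity: weights shrink to 0, scores to the prevalence
  yb <- c(rep(0, 30), rep(1, 10))
  big <- fitSideEffectClassifier(Z, yb, lambda = 1e7)
  expect_lt(sqrt(sum(big$w^2)), 1e-3)
  expect_equal(mean(predictScores(big, Z)), 0.25, tolerance = 1e-3)

  expect_error(fitSideEffectClassifier(Z, rep(1, 40)), "degenerate")
})

test_that("classifier optimum has vanishing finite-difference gradient", {
  set.seed(2)
  Z <- matrix(rnorm(120), 30, 4)
  y <- rbinom(30, 1, plogis(Z[, 1] - Z[, 3]))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  lambda <- 0.5
  fit <- fitSideEffectClassifier(Z, y, lambda = lambda)
  obj <- function(th) {
    eta <- drop(Z %*% th[1:4]) + th[5]
    sum(log(1 + exp(eta)) - y * eta) + lambda * sum(th[1:4]^2)
  }
  th <- c(fit$w, fit$b)
  h <- 1e-6
  gnum <- vapply(1:5, function(i) {
    e <- numeric(5); e[i] <- h
    (obj(th + e) - obj(th - e)) / (2 * h)
  }, numeric(1))
  expect_lt(sqrt(sum(gnum^2)), 1e-4)
})

test_that("classifier agrees with an independent ridge-logistic solver", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  Z <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, plogis(Z[, 1]))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  lambda <- 2
  fit <- fitSideEffectClassifier(Z, y, lambda = lambda)
  # glmnet minimizes (1/n) sum loss + lg/2 ||w||^2  =>  lg = 2*lambda/n
  gl <- glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                       lambda = 2 * lambda / 50, standardize = FALSE,
                       thresh = 1e-12)
  expect_equal(fit$w, as.numeric(gl$beta), tolerance = 1e-3)
  expect_equal(fit$b, as.numeric(gl$a0), tolerance = 1e-3)
})

test_that("merged AUROC matches hand and oracle pair counting", {
  T1 <- data.frame(drug_id = "d", side_effect_id = letters[1:6],
                   score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
                   label = c(1, 0, 1, 1, 0, 0))
  expect_equal(mergedRocAuc(T1)$auroc, 7 / 9)

  # scores equal to labels -> 1; constant scores -> 0.5
  T2 <- data.frame(drug_id = "d", side_effect_id = letters[1:4],
                   score = c(1, 0, 1, 0), label = c(1, 0, 1, 0))
  expect_equal(mergedRocAuc(T2)$auroc, 1)
  T3 <- transform(T2, score = 0.5)
  expect_equal(mergedRocAuc(T3)$auroc, 0.5)

  expect_error(mergedRocAuc(transform(T2, label = 1)), "one class")

  # random tables: rank statistic == pair counting to 1e-9, and the curve
  # is a proper nondecreasing ROC whose trapezoid area matches
  for (seed in 1:10) {
    set.seed(seed)
    n <- 60
    tab <- data.frame(drug_id = "d", side_effect_id = as.character(1:n),
                      score = round(runif(n), 2), label = rbinom(n, 1, 0.4))
    if (length(unique(tab$label)) < 2) next
    roc <- mergedRocAuc(tab)
    expect_equal(roc$auroc, oracleAuc(tab$score, tab$label),
                 tolerance = 1e-9)
    expect_true(all(diff(roc$tpr) >= 0))
    expect_true(all(diff(roc$fpr) >= 0))
    expect_equal(max(roc$tpr), 1)
    expect_equal(max(roc$fpr), 1)
    trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
    expect_equal(trap, roc$auroc, tolerance = 1e-9)
  }
})

test_that("per-side-effect AUROC restricts the merged computation", {
  set.seed(5)
  tab <- data.frame(drug_id = rep(paste0("d", 1:20), 3),
                    side_effect_id = rep(c("s1", "s2", "s3"), each = 20),
                    score = runif(60), label = rbinom(60, 1, 0.5))
  tab$label[tab$side_effect_id == "s3"] <- 1   # single-class term
  per <- perSideEffectAuroc(tab)
  for (s in c("s1", "s2")) {
    sub <- tab[tab$side_effect_id == s, ]
    expect_equal(per$auroc[per$side_effect_id == s],
                 oracleAuc(sub$score, sub$label), tolerance = 1e-9)
  }
  expect_false(per$defined[per$side_effect_id == "s3"])
  expect_true(is.na(per$auroc[per$side_effect_id == "s3"]))

  # a single-term table equals the merged result
  one <- tab[tab$side_effect_id == "s1", ]
  expect_equal(perSideEffectAuroc(one)$auroc, mergedRocAuc(one)$auroc)
})

test_that("top-K hit counting matches brute-force re-ranking", {
  # drug whose top score is its known side-effect counts at K = 1
  t1 <- data.frame(drug_id = "d1", side_effect_id = c("a", "b"),
                   score = c(0.9, 0.1), label = c(1, 0))
  expect_identical(topkHits(t1, 1), 1L)
  # drug with no known side-effect is never counted
  t2 <- data.frame(drug_id = "d1", side_effect_id = c("a", "b"),
                   score = c(0.9, 0.1), label = c(0, 0))
  expect_identical(topkHits(t2, 2), 0L)

  set.seed(6)
  tab <- data.frame(drug_id = rep(paste0("d", 1:20), each = 50),
                    side_effect_id = rep(sprintf("s%02d", 1:50), 20),
                    score = round(runif(1000), 2),
                    label = rbinom(1000, 1, 0.1))
  for (K in c(1, 3, 5, 10))
    expect_identical(topkHits(tab, K), oracleTopk(tab, K))
  # monotone nondecreasing in K
  hits <- vapply(1:10, function(k) topkHits(tab, k), integer(1))
  expect_true(all(diff(hits) >= 0))
})

test_that("cross-validation partitions drugs and is reproducible", {
  b <- smallBundle(9)
  args <- list(b$chemical, b$target, b$assoc, b$labels, nFolds = 5,
               params = walkParams(walksPerNode = 2, walkLength = 10),
               dim = 8, epochs = 2, seed = 13)
  tab <- do.call(crossValidate, args)
  # every drug scored exactly once per side-effect
  cnt <- table(tab$drug_id, tab$side_effect_id)
  expect_true(all(cnt == 1))
  expect_identical(sort(unique(tab$fold)), 1:5)
  # fold sizes equal up to 1
  foldSizes <- table(unique(tab[c("drug_id", "fold")])$fold)
  expect_lte(diff(range(foldSizes)), 1)
  # identical rerun
  expect_identical(do.call(crossValidate, args), tab)
  expect_error(crossValidate(b$chemical, b$target, b$assoc, b$labels,
                             nFolds = 40, seed = 1), "fewer drugs")
})

test_that("test drugs' side-effect profiles cannot leak into their features", {
  # corrupting a held-out drug's side-effect profile must not change any
  # feature-bearing artifact of its fold: the side-effect subnetwork is
  # rebuilt from training drugs only, so the walk corpus is unchanged
  b <- smallBundle(10)
  Y <- featureMatrix(b$labels)
  fold <- rwshin:::.assignFolds(rownames(Y), 5, 13)
  test <- names(fold)[fold == 1]
  Y2 <- Y
  Y2[test, ] <- 1L - Y2[test, ]       # flip every held-out label
  mk <- function(Ym) {
    se <- Ym
    se[test, ] <- 0L
    g <- buildUnsignedSubnetwork(BinaryProfileSet(se, "side_effect"))
    edgeTable(g)
  }
  expect_identical(mk(Y), mk(Y2))
})

test_that("score tables round-trip and summarize into a metrics report", {
  set.seed(8)
  tab <- data.frame(drug_id = rep(paste0("d", 1:6), each = 4),
                    side_effect_id = rep(paste0("s", 1:4), 6),
                    score = runif(24), label = rbinom(24, 1, 0.4),
                    fold = rep(1:3, each = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeScoreTable(tab, path)
  expect_equal(readScoreTable(path), tab)
  rep <- metricsReport(tab, topK = c(1, 3))
  expect_named(rep$topK, c("top1", "top3"))
  expect_equal(rep$mergedAuroc, mergedRocAuc(tab)$auroc)
})
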