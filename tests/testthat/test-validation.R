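test_that("ROC handles perfect, tied and hand-computed cases", {
  expect_equal(rocCurve(c(1, 2, 10, 20), c(0, 0, 1, 1))$auc, 1)
  expect_equal(rocCurve(rep(3, 8), rep(0:1, 4))$auc, 0.5)
  r <- rocCurve(c(1, 2, 3, 2, 3, 4), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 7 / 9)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
})

test_that("trapezoidal AUC equals the normalized U statistic on random tied instances", {
  set.seed(19)
  for (i in 1:150) {
    inst <- randomInstance()
    expect_equal(rocCurve(inst$values, inst$labels)$auc,
                 uStatAUC(inst$values, inst$labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:20) {
    inst <- randomInstance(20)
    ref <- suppressMessages(pROC::auc(inst$labels, inst$values,
                                      direction = "<"))
    expect_equal(rocCurve(inst$values, inst$labels)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U: exact enumeration, tie handling and tiers", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_true(r$exact)
  expect_equal(r$tier, "ns")
  same <- mannWhitneyU(c(5, 5, 5, 5, 5, 5, 5), c(5, 5, 5, 5, 5, 5, 5))
  expect_equal(same$p, 1)
  expect_equal(same$tier, "ns")
  # strong separation at usable n reaches the *** tier
  big <- mannWhitneyU(rnorm(40), rnorm(40) + 5)
  expect_equal(big$tier, "***")
  expect_lt(big$p, 0.001)
  expect_true(mannWhitneyU(1:3, 2:4)$U <= 9)
})

test_that("Mann-Whitney agrees with wilcox.test and the enumeration oracle", {
  set.seed(29)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    r <- mannWhitneyU(x, y)
    expect_equal(r$p, exactMWp(x, y), tolerance = 1e-12)
    expect_equal(r$p, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(r$U, unname(stats::wilcox.test(x, y)$statistic))
  }
  # approximate path: agrees with wilcox.test up to the Edgeworth term
  x <- rnorm(30); y <- rnorm(25) + 0.5
  expect_equal(mannWhitneyU(x, y)$p,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 0.01)
  # with ties the paths coincide exactly
  xt <- sample(1:6, 30, replace = TRUE); yt <- sample(2:7, 25, replace = TRUE)
  expect_equal(mannWhitneyU(xt, yt)$p,
               stats::wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("the trained classifier is consistent and affine-invariant", {
  set.seed(31)
  X <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(0:1, 20)
  X[y == 1, 1] <- X[y == 1, 1] + 10          # linearly separable
  clf <- trainClassifier(X, y)
  expect_equal(clf$trainError, 0)
  sc <- scoreCells(clf, X)
  pred <- as.integer(if (clf$polarity > 0) sc > clf$threshold
                     else sc <= clf$threshold)
  expect_equal(pred, y)
  # rescaling a feature column never changes the rank order of scores
  X2 <- X; X2[, 2] <- X2[, 2] * 100 + 7
  clf2 <- trainClassifier(X2, y)
  expect_equal(order(scoreCells(clf2, X2)), order(sc))
})

test_that("nested CV partitions patients, records selections and reports honestly", {
  coh <- generateCohort(smallCfg(33))
  pps <- lapply(coh$blocks, function(b) preprocessBlock(b)$block)
  ft <- buildFeatureTable(pps, coh$masks)
  rep <- nestedCV(ft, cvConfig(seed = 2))
  pats <- unique(patientIds(ft))
  held <- unlist(rep@folds)
  expect_setequal(held, pats)                 # every patient held out once
  expect_false(anyDuplicated(held) > 0)
  expect_equal(length(rep@foldAUC), 5L)
  expect_equal(nrow(rep@scores), ncol(ft))    # each cell scored exactly once
  for (ch in rep@chosen) {
    expect_true(ch$n %in% cvConfig()$nGrid)
    expect_equal(length(ch$features), ch$n)
  }
  expect_true(rep@pooledAUC > 0.5)
  expect_equal(rep@roc$auc, rep@pooledAUC)
  # pooled AUC consistent with pooled scores
  expect_equal(rep@pooledAUC, uStatAUC(rep@scores$score, rep@scores$label))
  # grouping by cell also partitions cells
  repc <- nestedCV(ft, cvConfig(grouping = "cell", seed = 2))
  expect_setequal(unlist(repc@folds), colnames(ft))
})

test_that("report files are complete and exactly reflect the projection", {
  coh <- generateCohort(smallCfg(35, cellsPerGroup = c(18L, 18L),
                                 nPatientsPerGroup = 3L))
  pps <- lapply(coh$blocks, function(b) preprocessBlock(b)$block)
  ft <- buildFeatureTable(pps, coh$masks)
  rep <- nestedCV(ft, cvConfig(outerFolds = 3L, nGrid = c(3L, 5L), seed = 4))
  proj <- fitCanonicalProjection(ft, features = selectFeatures(
    rankFeatures(ft), ft, n = 5))
  d <- withr::local_tempdir()
  paths <- makeReport(rep, proj, ft, d)
  for (p in paths) expect_true(file.exists(p))
  js <- jsonlite::fromJSON(file.path(d, "report.json"))
  expect_equal(js$pooled_auc, rep@pooledAUC)
  expect_equal(length(js$fold_auc), length(rep@foldAUC))
  expect_named(js$mann_whitney, c("U", "exact", "p", "tier"),
               ignore.order = TRUE)
  expect_equal(js$mann_whitney$tier, rep@groupTest$tier)
  # histogram/scatter coordinates are exactly the 1-D projection output
  prj <- read.csv(file.path(d, "projection.csv"))
  expect_equal(prj$cv1, unname(drop(projectCells(ft, proj, dims = 1L))),
               tolerance = 1e-12)
  roc <- read.csv(file.path(d, "roc.csv"))
  expect_equal(roc$tpr, rep@roc$tpr)
})

test_that("permutation scaffolding stays near chance on a small cohort", {
  coh <- generateCohort(smallCfg(37, cellsPerGroup = c(18L, 18L),
                                 nPatientsPerGroup = 6L))
  pps <- lapply(coh$blocks, function(b) preprocessBlock(b)$block)
  ft <- buildFeatureTable(pps, coh$masks)
  aucs <- permutationNull(ft, cvConfig(nGrid = c(3L, 5L), seed = 5),
                          nPermutations = 12L)
  expect_equal(length(aucs), 12L)
  expect_true(mean(aucs) > 0.3 && mean(aucs) < 0.7)
})
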