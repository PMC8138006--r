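test_that("minimum attainable error matches hand-derived cases", {
  expect_equal(minAttainableError(c(0, 1, 2, 3), c(0, 0, 1, 1))$min_error, 0)
  expect_equal(minAttainableError(rep(1, 6), c(0, 0, 0, 1, 1, 1))$min_error, 0.5)
  # A = {1,2,3}, B = {2,3,4}: exhaustive enumeration over midpoints gives 1/3
  r <- minAttainableError(c(1, 2, 3, 2, 3, 4), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$min_error, 1 / 3)
  # unbalanced majority rule is attainable: error <= min(prior)
  r2 <- minAttainableError(rep(1, 10), c(rep(0, 8), 1, 1))
  expect_equal(r2$min_error, 0.2)
})

test_that("minimum attainable error equals the brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:150) {
    inst <- randomInstance()
    expect_equal(minAttainableError(inst$values, inst$labels)$min_error,
                 bruteMinError(inst$values, inst$labels))
  }
})

test_that("minimum attainable error is invariant under monotone transforms", {
  set.seed(7)
  maps <- list(function(x) exp(x), function(x) x^3,
               function(x) atan(x) * 10, function(x) rank(x, ties.method = "min"))
  for (i in 1:40) {
    inst <- randomInstance()
    e0 <- minAttainableError(inst$values, inst$labels)$min_error
    f <- maps[[sample(length(maps), 1)]]
    expect_equal(minAttainableError(f(inst$values), inst$labels)$min_error, e0)
  }
})

test_that("feature ranking orders by error with a stable name tie-break", {
  y <- c(0, 0, 0, 1, 1, 1)
  m <- rbind(noise = c(5, 1, 3, 2, 4, 6),
             oracle = y,
             dupA = c(1, 2, 3, 4, 5, 6),
             dupB = c(1, 2, 3, 4, 5, 6))
  sc <- rankFeatures(m, y)
  expect_equal(sc$feature[1], "oracle")
  expect_equal(sc$min_error[1], 0)
  # identical columns rank adjacently in canonical (row) order
  iA <- which(sc$feature == "dupA"); iB <- which(sc$feature == "dupB")
  expect_equal(iB, iA + 1L)
  expect_error(rankFeatures(m, rep(0, 6)), "class")
})

test_that("selection enforces the n < N overfitting guard and the redundancy cap", {
  set.seed(5)
  y <- rep(0:1, c(41, 84))
  m <- matrix(rnorm(10 * 125), 10, 125,
              dimnames = list(paste0("f", 1:10), NULL))
  m[1, ] <- y + rnorm(125, 0, 0.3)
  m[2, ] <- m[1, ] * 2 + 1e-8 * rnorm(125)     # near-duplicate of f1
  sc <- rankFeatures(m, y)
  expect_silent(selectFeatures(sc, m, n = 6, N = 41))
  expect_error(selectFeatures(sc, m, n = 41, N = 41), "overfitting")
  kept <- selectFeatures(sc, m, n = 6, N = 41, redundancyRho = 0.95)
  expect_true(xor("f1" %in% kept, "f2" %in% kept))
  keptAll <- selectFeatures(sc, m, n = 6, N = 41, redundancyRho = 1)
  expect_true(all(c("f1", "f2") %in% keptAll))
})

test_that("the Fisher direction recovers the separating axis under exact symmetry", {
  # classes whose within-class scatter is exactly isotropic: points at the
  # class mean plus/minus each coordinate axis
  p <- 4
  base <- rbind(diag(p), -diag(p))
  X <- rbind(base, sweep(base, 2, c(3, 0, 0, 0), `+`))
  y <- rep(0:1, each = 2 * p)
  proj <- fitCanonicalProjection(X, y)
  expect_lt(max(abs(abs(proj@w1) - c(1, 0, 0, 0))), 1e-6)
  expect_gt(sum(proj@w1 * c(1, 0, 0, 0)), 0)   # group 1 projects higher
  expect_equal(sqrt(sum(proj@w1^2)), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(proj@w2^2)), 1, tolerance = 1e-9)
  expect_lt(abs(sum(proj@w1 * proj@w2)), 1e-9)
})

test_that("equal class means trigger the degenerate variance-axis fallback", {
  set.seed(9)
  X <- matrix(rnorm(40 * 3), 40, 3)
  X[, 2] <- X[, 2] * 3
  y <- rep(0:1, 20)
  X[y == 1, ] <- X[y == 0, ]                   # identical class point sets
  expect_warning(proj <- fitCanonicalProjection(X, y), "equal class means")
  expect_equal(proj@criterion, 0)
})

test_that("no random direction beats the Fisher direction", {
  set.seed(11)
  X <- matrix(rnorm(60 * 6), 60, 6) %*% matrix(rnorm(36), 6, 6)
  y <- rep(0:1, 30)
  X[y == 1, ] <- X[y == 1, ] + rep(rnorm(6), each = 30)
  proj <- fitCanonicalProjection(X, y)
  Z <- scale(X, proj@center, proj@scale)
  crit <- function(w) {
    s <- Z %*% w
    (mean(s[y == 1]) - mean(s[y == 0]))^2 /
      (((sum(y == 0) - 1) * var(s[y == 0]) + (sum(y == 1) - 1) * var(s[y == 1])) /
         (length(y) - 2))
  }
  cw1 <- crit(proj@w1)
  for (i in 1:1000) {
    w <- rnorm(6); w <- w / sqrt(sum(w^2))
    expect_lte(crit(w), cw1 * (1 + 1e-8))
  }
})

test_that("the Fisher direction agrees with an established LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(17)
  X <- matrix(rnorm(80 * 5), 80, 5)
  y <- rep(0:1, each = 40)
  X[y == 1, ] <- X[y == 1, ] + rep(c(1, 0.5, 0, -0.5, 0.2), each = 40)
  proj <- fitCanonicalProjection(X, y)
  ld <- MASS::lda(X, grouping = y)$scaling[, 1]
  wOrig <- proj@w1 / proj@scale        # back to original feature units
  cosine <- abs(sum(wOrig * ld)) / sqrt(sum(wOrig^2) * sum(ld^2))
  expect_gt(cosine, 1 - 1e-4)
})

test_that("the Fisher direction is invariant to affine feature rescaling", {
  set.seed(13)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- rep(0:1, 25)
  X[y == 1, 1] <- X[y == 1, 1] + 1.5
  p1 <- fitCanonicalProjection(X, y)
  A <- sweep(sweep(X, 2, c(10, 0.2, 3, 50), `*`), 2, c(1, -5, 0, 2), `+`)
  p2 <- fitCanonicalProjection(A, y)
  s1 <- projectCells(X, p1, dims = 1L)
  s2 <- projectCells(A, p2, dims = 1L)
  expect_equal(drop(s1), drop(s2), tolerance = 1e-8)
})

test_that("projection geometry: linearity, axis identity and training optimality", {
  coh <- generateCohort(smallCfg(21, cellsPerGroup = c(15L, 15L),
                                 nPatientsPerGroup = 3L))
  pps <- lapply(coh$blocks, function(b) preprocessBlock(b)$block)
  ft <- buildFeatureTable(pps, coh$masks)
  y <- groupLabels(ft)
  sc <- rankFeatures(ft)
  feats <- selectFeatures(sc, ft, n = 6)
  proj <- fitCanonicalProjection(ft, features = feats)
  x2 <- projectCells(ft, proj, dims = 2L)
  x1 <- projectCells(ft, proj, dims = 1L)
  expect_equal(unname(x2[, 1]), unname(drop(x1)))
  # zero-feature cell maps to the projected negative standardized mean
  z <- projectCells(matrix(0, 1, length(feats),
                           dimnames = list(NULL, feats)), proj, dims = 1L)
  expect_equal(drop(z),
               sum(-proj@center[feats] / proj@scale[feats] * proj@w1d),
               ignore_attr = TRUE)
  # 1-D projection cannot be worse than its best input feature on training data
  eProj <- minAttainableError(drop(x1), y)$min_error
  eBest <- min(sc$min_error[sc$feature %in% feats])
  expect_lte(eProj, eBest)
  expect_error(projectCells(featureMatrix(ft)[1:3, ] |> t(), proj), "missing feature")
})
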