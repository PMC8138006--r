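featureFixture <- function(seed = 2L, ...) {
  cfg <- smallCfg(seed, cellsPerGroup = c(9L, 9L), nPatientsPerGroup = 2L, ...)
  generateCohort(cfg)
}

test_that("cell pixel extraction is exact and exhaustive", {
  coh <- featureFixture()
  b <- coh$blocks[[1]]; m <- coh$masks[[1]]
  total <- 0
  for (id in cellIds(m)) {
    px <- extractCellPixels(b, m, id)
    expect_equal(ncol(px), 34L)
    expect_equal(nrow(px), sum(labelImage(m) == id))
    total <- total + nrow(px)
  }
  expect_equal(total, sum(labelImage(m) > 0))
  # disjointness: each pixel belongs to exactly one cell
  li <- labelImage(m)
  expect_equal(sum(table(li[li > 0])), sum(li > 0))
  expect_error(extractCellPixels(b, m, 99L), "99")
})

test_that("feature formulas match hand-computed oracles and degenerate rules", {
  pxConst <- matrix(7, 10, 2)
  expect_equal(computeFeature(pxConst, "mean", 1L), 7)
  expect_equal(computeFeature(pxConst, "sd", 1L), 0)
  expect_equal(computeFeature(pxConst, "skewness", 1L), 0)
  expect_equal(computeFeature(pxConst, "kurtosis", 1L), 0)
  expect_equal(computeFeature(pxConst, "top_decile_mean", 1L), 7)

  px <- cbind(1:100, rep(5, 100))
  expect_equal(computeFeature(px, "top_decile_mean", 1L), mean(91:100))
  expect_equal(computeFeature(px, "mean", 1L), 50.5)
  pxr <- cbind(rep(10, 4), rep(5, 4))
  expect_equal(computeFeature(pxr, "ratio", 1L, 2L), 2)
  pxz <- cbind(rep(10, 4), rep(0, 4))
  expect_warning(z <- computeFeature(pxz, "ratio", 1L, 2L), "denominator")
  expect_equal(z, 0)

  # moments against explicit formulas (adjusted Fisher-Pearson / excess)
  set.seed(1)
  v <- rlnorm(40)
  n <- length(v); m2 <- mean((v - mean(v))^2)
  g1 <- mean((v - mean(v))^3) / m2^1.5
  skewOracle <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- mean((v - mean(v))^4) / m2^2 - 3
  kurtOracle <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  expect_equal(computeFeature(cbind(v), "skewness", 1L), skewOracle,
               tolerance = 1e-12)
  expect_equal(computeFeature(cbind(v), "kurtosis", 1L), kurtOracle,
               tolerance = 1e-12)
  expect_equal(computeFeature(cbind(v), "sd", 1L), sd(v))
})

test_that("top-decile mean dominates the mean with equality only for constant cells", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(3:60, 1)
    v <- if (i %% 5 == 0) rep(runif(1), n) else rlnorm(n)
    px <- cbind(v)
    td <- computeFeature(px, "top_decile_mean", 1L)
    mn <- computeFeature(px, "mean", 1L)
    if (length(unique(v)) == 1L) expect_equal(td, mn)
    else expect_gt(td, mn)
  }
})

test_that("features are scale-equivariant in the documented way", {
  set.seed(4)
  px <- matrix(rlnorm(60), 30, 2)
  cf <- function(p, k, a = 1L, b = 2L) computeFeature(p, k, a, b)
  for (c in c(0.5, 3)) {
    expect_equal(cf(px * c, "mean"), c * cf(px, "mean"))
    expect_equal(cf(px * c, "top_decile_mean"), c * cf(px, "top_decile_mean"))
    expect_equal(cf(px * c, "sd"), c * cf(px, "sd"))
    expect_equal(cf(px * c, "ratio"), cf(px, "ratio"))
    expect_equal(cf(px * c, "skewness"), cf(px, "skewness"))
    expect_equal(cf(px * c, "kurtosis"), cf(px, "kurtosis"))
  }
})

test_that("the policy controls the admissible feature set", {
  cons <- featureDescriptors(featurePolicy("conservative"), 34)
  expect_setequal(unique(cons$kind), c("mean", "top_decile_mean", "ratio"))
  expect_equal(sum(cons$kind == "ratio"), 6)   # ordered pairs of {2,15,32}
  ext <- featureDescriptors(featurePolicy("extended"), 34)
  expect_setequal(unique(ext$kind),
                  c("mean", "top_decile_mean", "ratio", "sd", "skewness",
                    "kurtosis"))
  expect_equal(nrow(ext), nrow(cons) + 3 * 34)
  noTop <- featureDescriptors(featurePolicy("conservative", topDecile = FALSE), 34)
  expect_false(any(noTop$kind == "top_decile_mean"))
  # names are uniquely determined by (kind, channels)
  expect_false(anyDuplicated(ext$name) > 0)
})

test_that("feature tables have one row per cell and are input-order invariant", {
  coh <- featureFixture()
  pps <- lapply(coh$blocks, function(b) preprocessBlock(b)$block)
  ft <- buildFeatureTable(pps, coh$masks, featurePolicy("conservative"))
  expect_equal(ncol(ft), nrow(coh$truth))
  expect_false(any(c("sd", "skewness", "kurtosis") %in%
                     rowData(ft)$kind))
  shuf <- rev(seq_along(pps))
  ft2 <- buildFeatureTable(pps[shuf], coh$masks[shuf],
                           featurePolicy("conservative"))
  expect_identical(featureMatrix(ft2), featureMatrix(ft))
  ext <- buildFeatureTable(pps[1], coh$masks[1], featurePolicy("extended"))
  expect_true(all(c("sd_ch01", "skew_ch01", "kurt_ch01") %in% rownames(ext)))
})

test_that("the designed redox-ratio group difference has the right sign across seeds", {
  em <- makeEndmembers(defaultChannelSet(), seed = 99)
  signs <- vapply(1:20, function(s) {
    cfg <- smallCfg(s, cellsPerGroup = c(12L, 12L), nPatientsPerGroup = 3L)
    coh <- generateCohort(cfg, spectra = em)
    ratio <- unlist(lapply(seq_along(coh$blocks), function(i) {
      vapply(cellIds(coh$masks[[i]]), function(id) {
        px <- extractCellPixels(coh$blocks[[i]], coh$masks[[i]], id)
        mean(px[, 2]) / mean(px[, 32])
      }, numeric(1))
    }))
    y <- unlist(lapply(seq_along(coh$blocks), function(i)
      rep(coh$blocks[[i]]@groupLabel, length(cellIds(coh$masks[[i]])))))
    sign(mean(ratio[y == 0]) - mean(ratio[y == 1]))
  }, numeric(1))
  expect_true(all(signs == 1))
})
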