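test_that("endmember spectra honor the fluorophore-channel anchors deterministically", {
  cs <- defaultChannelSet()
  for (s in 1:20) {
    em <- makeEndmembers(cs, seed = s)
    R <- endmemberResponse(em)
    expect_identical(which.max(R[, "NAD(P)H"]), 2L)
    expect_setequal(order(R[, "flavins"], decreasing = TRUE)[1:2], c(15L, 32L))
    expect_true(all(R >= 0))
    expect_true(all(colSums(R) > 0))
  }
  expect_identical(endmemberResponse(makeEndmembers(cs, seed = 7)),
                   endmemberResponse(makeEndmembers(cs, seed = 7)))
})

test_that("generated blocks have the full channel geometry and binomial bad-pixel counts", {
  cfg <- cohortConfig(imageShape = c(256L, 256L), seed = 2)
  em <- makeEndmembers(defaultChannelSet(), seed = 2)
  g <- withr::with_seed(21, generateDataBlock(cfg, em, "P1", 0L, "F1"))
  expect_equal(dim(channelImages(g$block))[3], 34L)
  expect_equal(dim(brightfield(g$block)), c(256L, 256L))
  # hot pixels: rate 0.001 on 256x256 -> 65.5 expected per channel; the
  # total over 34 channels is binomial with mean 2227.5
  nHot <- sum(g$truth$badPixels == 1L)
  expected <- 34 * 256 * 256 * cfg$hotPixelRate
  expect_lt(abs(nHot - expected), 3 * sqrt(expected))
  # hot pixels sit at saturation, dead pixels at zero
  expect_true(all(channelImages(g$block)[g$truth$badPixels == 1L] == 65535))
  expect_true(all(channelImages(g$block)[g$truth$badPixels == 2L] == 0))
})

test_that("cell placement failure on a crowded field is fatal", {
  cfg <- smallCfg(1, cellsPerField = 40L)
  em <- makeEndmembers(defaultChannelSet(), seed = 1)
  expect_error(withr::with_seed(1,
    generateDataBlock(cfg, em, "P", 0L, "F", nCells = 40L)),
    "overlap")
})

test_that("with zero effect the group ratio distributions are exchangeable", {
  em <- makeEndmembers(defaultChannelSet(), seed = 5)
  pvals <- vapply(1:5, function(s) {
    cfg <- smallCfg(s, effect = 0, cellsPerGroup = c(45L, 45L))
    coh <- generateCohort(cfg, spectra = em)
    ratio <- vapply(seq_along(coh$blocks), function(i) {
      px <- extractCellPixels(coh$blocks[[i]], coh$masks[[i]],
                              cellIds(coh$masks[[i]])[1])
      mean(px[, 2]) / mean(px[, 32])
    }, numeric(1))
    y <- vapply(coh$blocks, function(b) b@groupLabel, integer(1))
    suppressWarnings(stats::wilcox.test(ratio[y == 0], ratio[y == 1])$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.05), 4)
})

test_that("cohorts hit the study-scale group totals and the designed effect", {
  cfg <- smallCfg(4)
  coh <- generateCohort(cfg)
  expect_equal(unname(table(coh$truth$group_label)), c(41L, 84L),
               ignore_attr = TRUE)
  expect_equal(length(coh$blocks), ceiling(41 / 3) + ceiling(84 / 3))
  # Monte-Carlo check of the designed log-ratio shift, judged against the
  # patient-level sampling error
  cfg2 <- smallCfg(9, nPatientsPerGroup = 20L, cellsPerGroup = c(200L, 200L))
  coh2 <- generateCohort(cfg2)
  pm <- aggregate(log_ratio ~ patient_id + group_label, coh2$truth, mean)
  d <- diff(rev(tapply(pm$log_ratio, pm$group_label, mean)))
  se <- sqrt(sum(tapply(pm$log_ratio, pm$group_label, var) / 20))
  expect_lt(abs(d - cfg2$effect), 3 * se)
})

test_that("a fixed seed reproduces a byte-identical cohort directory", {
  cfg <- smallCfg(5, cellsPerGroup = c(6L, 6L), nPatientsPerGroup = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateCohort(cfg, outDir = d1)
  generateCohort(cfg, outDir = d2)
  f <- list.files(d1, recursive = TRUE)
  expect_identical(f, list.files(d2, recursive = TRUE))
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
})

test_that("clean signal is linear in exposure and in abundance", {
  cs <- defaultChannelSet()
  em <- makeEndmembers(cs, seed = 3)
  cfg <- smallCfg(2, noise = FALSE)
  g1 <- withr::with_seed(11, generateDataBlock(cfg, em, "P", 0L, "F"))
  # doubled exposures, same draws -> clean signal doubles exactly
  tb <- channelTable(cs); tb$exposure <- pmin(tb$exposure * 2, 5)
  fac <- tb$exposure / channelTable(cs)$exposure
  g2 <- withr::with_seed(11, generateDataBlock(cfg, em, "P", 0L, "F",
                                               channels = ChannelSet(tb)))
  for (c in c(1, 17, 34))
    expect_equal(g2$truth$clean[, , c], g1$truth$clean[, , c] * fac[c],
                 tolerance = 1e-12)
  # doubled abundances -> clean signal doubles at every pixel
  cfg3 <- cfg
  cfg3$baseLogAbundance <- cfg$baseLogAbundance + log(2)
  cfg3$nuisanceLogAbundance <- cfg$nuisanceLogAbundance + log(2)
  g3 <- withr::with_seed(11, generateDataBlock(cfg3, em, "P", 0L, "F"))
  expect_equal(g3$truth$clean, g1$truth$clean * 2, tolerance = 1e-12)
})

test_that("empirical separability of the true log-ratio matches the designed Bayes AUC", {
  for (target in c(0.75, 0.9)) {
    cfg <- smallCfg(31, nPatientsPerGroup = 25L,
                    cellsPerGroup = c(300L, 300L))
    cfg$effect <- effectForAUC(target, cfg)
    coh <- generateCohort(cfg)
    auc <- rocCurve(-coh$truth$log_ratio, coh$truth$group_label)$auc
    expect_lt(abs(auc - target), 0.03)
    expect_equal(designedAUC(cfg), target, tolerance = 1e-12)
  }
})
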