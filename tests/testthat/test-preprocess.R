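test_that("reference subtraction follows the water-as-background rule", {
  w <- matrix(20, 6, 6)
  b <- handBlock(matrix(20, 6, 6), dark = 10, water = w)
  expect_true(all(channelImages(subtractReferences(b)) == 0))  # raw == water
  b2 <- handBlock(matrix(120, 6, 6), dark = 10, water = w)
  expect_true(all(channelImages(subtractReferences(b2)) == 100))
  b3 <- handBlock(matrix(15, 6, 6), dark = 10, water = w)
  expect_true(all(channelImages(subtractReferences(b3)) == 0))  # clipped
  expect_true(all(channelImages(subtractReferences(b3, clipNegative = FALSE)) == -5))
})

test_that("flat-fielding matches the mean-normalized calibration formula", {
  # uniform calibration: exact identity
  b <- handBlock(matrix(runif(36, 10, 60), 6, 6), dark = 0,
                 calibration = matrix(42, 6, 6))
  expect_equal(channelImages(flatfieldCorrect(b)), channelImages(b))
  # calib {1,3} (mean 2), corrected {10,30} -> {20,20}
  cal <- matrix(c(1, 3), 2, 2)
  img <- matrix(c(10, 30), 2, 2)
  b2 <- handBlock(img, dark = 0, calibration = cal, nch = 1)
  expect_equal(as.vector(channelImages(flatfieldCorrect(b2))[, , 1]),
               rep(20, 4))
  # non-positive calibration is rejected with the channel named (the block
  # invariant makes the state unconstructible; flatfieldCorrect re-checks)
  expect_error(handBlock(matrix(5, 4, 4), dark = 3,
                         calibration = matrix(c(3, 8), 4, 4), nch = 2),
               "channel 1")
})

test_that("flat-fielding inverts the generator's illumination exactly on noise-free data", {
  cfg <- smallCfg(3, noise = FALSE)
  em <- makeEndmembers(defaultChannelSet(), seed = 3)
  g <- withr::with_seed(5, generateDataBlock(cfg, em, "P", 0L, "F"))
  # the calibration inversion itself is under test, so the (edge-sensitive)
  # pixel repair is bypassed: noise-free blocks have no bad pixels
  b <- equalizeExposure(flatfieldCorrect(subtractReferences(g$block)))
  expo <- exposures(g$block)
  illum <- g$truth$illumination
  for (c in c(1, 2, 20, 34)) {
    got <- channelImages(b)[, , c]
    want <- g$truth$clean[, , c] / illum * mean(illum) / expo[c]
    expect_lt(max(abs(got - want)) / max(want), 1e-10)
  }
})

test_that("exposure equalization yields counts per second and is idempotent", {
  b <- handBlock(matrix(50, 5, 5), exposure = 5)
  e <- equalizeExposure(b)
  expect_true(all(channelImages(e) == 10))
  expect_equal(exposures(e), rep(1, nChannels(e)))
  expect_equal(channelImages(equalizeExposure(e)), channelImages(e))
  tb <- channelTable(b); tb$exposure <- 0.5
  b2 <- b; b2@channels <- ChannelSet(tb)
  expect_true(all(channelImages(equalizeExposure(b2)) == 100))
})

test_that("equalized images agree across exposures up to shot noise", {
  cs <- defaultChannelSet()
  em <- makeEndmembers(cs, seed = 6)
  cfg <- smallCfg(6, hotPixelRate = 0, deadPixelRate = 0)
  mkExp <- function(e1) {
    tb <- channelTable(cs); tb$exposure[1] <- e1; ChannelSet(tb)
  }
  g1 <- withr::with_seed(8, generateDataBlock(cfg, em, "P", 0L, "F",
                                              channels = mkExp(1)))
  g2 <- withr::with_seed(8, generateDataBlock(cfg, em, "P", 0L, "F",
                                              channels = mkExp(2)))
  e1 <- channelImages(preprocessBlock(g1$block)$block)[, , 1]
  e2 <- channelImages(preprocessBlock(g2$block)$block)[, , 1]
  px <- labelImage(g1$mask) > 0
  m1 <- mean(e1[px]); m2 <- mean(e2[px])
  se <- sqrt(var(e1[px]) / sum(px) + var(e2[px]) / sum(px))
  expect_lt(abs(m1 - m2), 3 * se)
})

test_that("bad-pixel repair flags exactly the right pixels on clean images", {
  img <- matrix(100, 10, 10)
  b <- handBlock(img, dark = 0, calibration = matrix(50, 10, 10))
  r <- repairBadPixels(b)
  expect_equal(sum(r$badPixelMap), 0)
  expect_identical(channelImages(r$block), channelImages(b))
  img2 <- img; img2[5, 5] <- 65535
  b2 <- handBlock(img2, dark = 0, calibration = matrix(50, 10, 10))
  r2 <- repairBadPixels(b2)
  expect_equal(which(r2$badPixelMap[, , 1] != 0), 45L)
  expect_equal(channelImages(r2$block)[5, 5, 1], 100)
  # a channel drowning in flags is declared unusable
  img3 <- matrix(c(0, 65535), 10, 10)
  b3 <- handBlock(img3, dark = 0, calibration = matrix(50, 10, 10))
  expect_error(repairBadPixels(b3), "unusable")
})

test_that("the composed preprocessing chain is idempotent and order-fixed", {
  cfg <- smallCfg(12)
  em <- makeEndmembers(defaultChannelSet(), seed = 12)
  g <- withr::with_seed(13, generateDataBlock(cfg, em, "P", 0L, "F"))
  p1 <- preprocessBlock(g$block)
  expect_identical(p1$block@processing,
                   c("repair", "subtract", "flatfield", "equalize"))
  p2 <- preprocessBlock(p1$block)
  expect_equal(channelImages(p2$block), channelImages(p1$block),
               tolerance = 1e-12)
  expect_equal(sum(p2$badPixelMap), 0)
})

test_that("preprocessing commutes with channel permutation", {
  cfg <- smallCfg(14)
  em <- makeEndmembers(defaultChannelSet(), seed = 14)
  g <- withr::with_seed(15, generateDataBlock(cfg, em, "P", 0L, "F"))
  b <- g$block
  perm <- rev(seq_len(nChannels(b)))
  permute <- function(blk) {
    tb <- channelTable(blk)[perm, ]; tb$index <- seq_len(nrow(tb))
    DataBlock(ChannelSet(tb), blk@images[, , perm], brightfield(blk),
              dark = blk@dark[, , perm], water = blk@water[, , perm],
              calibration = blk@calibration[, , perm],
              fieldId = blk@fieldId, patientId = blk@patientId,
              groupLabel = blk@groupLabel,
              saturationLevel = blk@saturationLevel,
              processing = blk@processing)
  }
  a <- permute(preprocessBlock(b)$block)
  bb <- preprocessBlock(permute(b))$block
  expect_equal(channelImages(a), channelImages(bb), tolerance = 1e-12)
})
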