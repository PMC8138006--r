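# Shared fixtures and independent oracles, all built in code at test time.

# small-image cohort configuration used throughout the suite (desk-scale
# rendering of the study conditions; group sizes and effect stay at their
# defaults unless a test overrides them)
smallCfg <- function(seed = 1L, ...) {
  cohortConfig(imageShape = c(48L, 48L), cellRadiusRange = c(4, 6),
               seed = seed, ...)
}

# a tiny hand-built block: `nch` channels of the given images, references
# chosen so every invariant holds (calibration strictly positive)
handBlock <- function(images, dark = 0, water = NULL, calibration = NULL,
                      exposure = 1, nch = NULL, saturation = 65535) {
  if (is.matrix(images)) images <- list(images)
  if (is.null(nch)) nch <- length(images)
  sp <- dim(images[[1]])
  arr <- array(0, c(sp, nch))
  for (c in seq_len(nch)) arr[, , c] <- images[[min(c, length(images))]]
  mk <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) x <- list(x)
    a <- array(0, c(sp, nch))
    for (c in seq_len(nch)) a[, , c] <- if (is.matrix(x[[min(c, length(x))]]))
      x[[min(c, length(x))]] else matrix(x[[min(c, length(x))]], sp[1], sp[2])
    a
  }
  darkA <- mk(if (is.numeric(dark) && !is.matrix(dark)) list(matrix(dark, sp[1], sp[2])) else dark)
  waterA <- if (is.null(water)) darkA else mk(water)
  calA <- if (is.null(calibration)) darkA + 100 else mk(calibration)
  tb <- channelTable(defaultChannelSet(max(nch, 34)))[seq_len(nch), , drop = FALSE]
  tb$index <- seq_len(nch)
  tb$exposure <- rep(exposure, length.out = nch)
  DataBlock(ChannelSet(tb), arr, matrix(1000, sp[1], sp[2]),
            dark = darkA, water = waterA, calibration = calA,
            fieldId = "F1", patientId = "P1", groupLabel = 0L,
            saturationLevel = saturation)
}

# ---- independent oracles ----------------------------------------------

# brute-force minimum attainable error: every midpoint/end threshold, both
# polarities, counted by explicit loops
bruteMinError <- function(values, labels) {
  u <- sort(unique(values))
  th <- c(min(u) - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
          max(u) + 1)
  best <- 1
  for (t in th) {
    errP <- 0; errM <- 0
    for (i in seq_along(values)) {
      predP <- as.integer(values[i] > t)
      if (predP != labels[i]) errP <- errP + 1
      if ((1L - predP) != labels[i]) errM <- errM + 1
    }
    best <- min(best, errP / length(values), errM / length(values))
  }
  best
}

# AUC as the normalized Mann-Whitney U statistic (midranks)
uStatAUC <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# exact two-sided Mann-Whitney p by direct enumeration over value
# assignments (independent of the package's rank-based route)
exactMWp <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  uOf <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  uObs <- uOf(x, y)
  us <- apply(idx, 2, function(ii) uOf(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

# generate one random ranking instance with ties and duplicates
randomInstance <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:30, 1)
  vals <- sample(c(round(rnorm(n), sample(0:2, 1)), rnorm(n)), n)
  repeat {
    labs <- rbinom(n, 1, runif(1, 0.25, 0.75))
    if (any(labs == 0) && any(labs == 1)) break
  }
  list(values = vals, labels = labs)
}
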