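#' @include features.R
NULL

#' Minimum attainable classification error of one feature
#'
#' The smallest misclassification fraction achievable on the given cells by
#' thresholding the feature, over every threshold and both polarities.
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' values plus minus/plus infinity (so the majority rule is always
#' attainable and \code{min_error <= min(class prior)}). Error is the pooled
#' misclassification fraction over all cells, i.e. classes weighted by their
#' empirical cell counts. Ties in error are broken toward the threshold with
#' the larger margin (the midpoint of the widest achieving gap; the infinite
#' end gaps win any tie), then toward the smaller threshold, then polarity
#' \code{+1}.
#'
#' @param values per-cell feature values.
#' @param labels binary 0/1 labels (group membership), same length.
#' @return list with \code{min_error}, \code{threshold}, \code{polarity}
#'   (\code{+1}: predict group 1 when value > threshold; \code{-1}: the
#'   reverse) and \code{margin}.
#' @examples
#' minAttainableError(c(0, 1, 2, 3), c(0, 0, 1, 1))$min_error  # 0
#' @export
minAttainableError <- function(values, labels) {
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels), all(labels %in% 0:1))
  if (!any(labels == 0L) || !any(labels == 1L))
    stopf("both classes must be non-empty")
  n <- length(values)
  ord <- order(values)
  x <- values[ord]; y <- labels[ord]
  u <- unique(x)
  # counts of label-1 and label-0 at or below each unique value
  lastIdx <- cumsum(tabulate(match(x, u), nbins = length(u)))
  c1 <- cumsum(y)[lastIdx]          # y = 1 with value <= u[k]
  c0 <- lastIdx - c1
  n1 <- sum(y); n0 <- n - n1
  # thresholds: -Inf, midpoints, +Inf; "<= t" counts: 0, c1/c0[k], n1/n0
  th <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  below1 <- c(0, c1[-length(c1)], n1)
  below0 <- c(0, c0[-length(c0)], n0)
  # integer misclassification counts so the error fractions are exact
  cntPlus <- below1 + (n0 - below0)         # predict 1 when value > t
  cntMinus <- n - cntPlus                   # reversed polarity
  err <- pmin(cntPlus, cntMinus) / n
  pol <- ifelse(cntPlus <= cntMinus, 1L, -1L)
  gaps <- c(Inf, if (length(u) > 1) diff(u), Inf)
  best <- min(err)
  cand <- which(err == best)
  cand <- cand[order(-gaps[cand], th[cand], -pol[cand])][1]
  list(min_error = best, threshold = th[cand], polarity = pol[cand],
       margin = gaps[cand])
}

#' Rank features by minimum attainable classification error
#'
#' Scores every feature of the table by [minAttainableError()] and ranks
#' ascending; ties are broken by the table's canonical feature order (the
#' deterministic order of [featureDescriptors()]), so rankings are stable.
#'
#' @param x a [FeatureTable-class], or a features x cells numeric matrix.
#' @param labels binary labels (taken from the table when omitted).
#' @return \code{data.frame}, one row per feature in rank order:
#'   \code{feature}, \code{min_error}, \code{threshold}, \code{polarity},
#'   \code{rank}.
#' @export
rankFeatures <- function(x, labels = NULL) {
  if (is(x, "FeatureTable")) {
    labels <- groupLabels(x)
    x <- featureMatrix(x)
  }
  stopifnot(is.matrix(x), !is.null(labels))
  if (sum(labels == 0L) < 2L || sum(labels == 1L) < 2L)
    stopf("need at least 2 cells per class to rank features")
  sc <- lapply(seq_len(nrow(x)), function(i) minAttainableError(x[i, ], labels))
  out <- data.frame(feature = rownames(x),
                    min_error = vapply(sc, `[[`, numeric(1), "min_error"),
                    threshold = vapply(sc, `[[`, numeric(1), "threshold"),
                    polarity = vapply(sc, `[[`, integer(1), "polarity"))
  ord <- order(out$min_error, seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the best n features under the overfitting guard
#'
#' Walks the ranking from the best feature down, skipping any feature whose
#' absolute Pearson correlation with an already-kept feature exceeds
#' \code{redundancyRho} (top-ranked features are often near-duplicates, e.g.
#' the mean and top-decile mean of one channel). The number of kept
#' features \code{n} must stay below \code{N}, the smaller group's cell
#' count, to limit overfitting.
#'
#' @param scores ranking from [rankFeatures()].
#' @param x the [FeatureTable-class] (or matrix) the ranking came from.
#' @param n number of features to keep.
#' @param N smaller group's cell count; computed from the table when
#'   omitted.
#' @param redundancyRho absolute correlation cap (default 0.95; set to 1 to
#'   disable).
#' @return character vector of feature names in rank order (fewer than
#'   \code{n} with a warning if the ranking is exhausted).
#' @export
selectFeatures <- function(scores, x, n, N = NULL, redundancyRho = 0.95) {
  if (is(x, "FeatureTable")) {
    if (is.null(N)) N <- min(table(factor(groupLabels(x), levels = 0:1)))
    x <- featureMatrix(x)
  }
  if (is.null(N)) stopf("N (smaller group size) is required for matrices")
  if (n >= N)
    stopf("n = %d features with N = %d cells in the smaller group: n must stay below N to reduce the possibility of overfitting", n, N)
  kept <- character()
  for (f in scores$feature) {
    if (length(kept) == n) break
    if (length(kept)) {
      rho <- abs(cor(x[f, ], t(x[kept, , drop = FALSE])))
      rho[is.na(rho)] <- 0
      if (max(rho) > redundancyRho) next
    }
    kept <- c(kept, f)
  }
  if (length(kept) < n)
    warnf("ranking exhausted: %d of %d requested features kept", length(kept), n)
  kept
}

# Fisher direction for standardized data: solve(Sw_gamma, dm), with shrinkage
# gamma toward the diagonal chosen as the smallest grid value giving a
# well-conditioned system.
fisherDirection <- function(Z, y, gammaGrid = c(0, 0.01, 0.05, 0.1, 0.3, 0.5)) {
  m0 <- colMeans(Z[y == 0L, , drop = FALSE])
  m1 <- colMeans(Z[y == 1L, , drop = FALSE])
  dm <- m1 - m0
  S0 <- cov(Z[y == 0L, , drop = FALSE])
  S1 <- cov(Z[y == 1L, , drop = FALSE])
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  Sw <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  dS <- diag(pmax(diag(Sw), 1e-6), nrow(Sw))
  for (g in gammaGrid) {
    Sg <- (1 - g) * Sw + g * dS
    rc <- tryCatch(rcond(Sg), error = function(e) 0)
    if (rc > 1e-8) {
      w <- solve(Sg, dm)
      return(list(w = w, dm = dm, Sg = Sg, gamma = g))
    }
  }
  stopf("within-class scatter singular even after shrinkage")
}

#' Fit the canonical discriminant projection
#'
#' Computes the Fisher direction \code{w1} maximizing between-group scatter
#' over within-group scatter on standardized features (pooled within-class
#' covariance, shrunk toward its diagonal by the smallest grid weight giving
#' a well-conditioned system), and a second direction \code{w2}: the Fisher
#' direction restricted to the orthogonal complement of \code{w1}. This
#' greedy orthogonal construction yields the 2-D discriminative scatter for
#' a two-class problem, where classical canonical analysis provides only one
#' canonical variable. \code{w1d = w1} is the optimal 1-D projection. All
#' directions are unit length with signs fixed so the group-1 mean projects
#' higher than the group-0 mean. If the class means coincide, the fit warns
#' and returns the leading within-class variance axis.
#'
#' @param x a [FeatureTable-class] or cells x features matrix.
#' @param labels binary 0/1 labels (from the table when omitted).
#' @param features feature names to use (default: all rows of the table).
#' @return a [CanonicalProjection-class].
#' @export
fitCanonicalProjection <- function(x, labels = NULL, features = NULL) {
  if (is(x, "FeatureTable")) {
    labels <- groupLabels(x)
    m <- featureMatrix(x)
    if (is.null(features)) features <- rownames(m)
    X <- t(m[features, , drop = FALSE])
  } else {
    X <- as.matrix(x)
    if (is.null(features)) {
      features <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
      colnames(X) <- features
    } else if (!is.null(colnames(X))) {
      miss <- setdiff(features, colnames(X))
      if (length(miss)) stopf("missing feature column(s): %s",
                              paste(miss, collapse = ", "))
      X <- X[, features, drop = FALSE]
    } else {
      stopifnot(ncol(X) == length(features))
      colnames(X) <- features
    }
  }
  y <- as.integer(labels)
  if (sum(y == 0L) < 2L || sum(y == 1L) < 2L)
    stopf("need at least 2 cells per class")
  p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Z <- scale(X, ctr, scl)
  fd <- fisherDirection(Z, y)
  degenerate <- sqrt(sum(fd$dm^2)) < 1e-12
  if (degenerate) {
    warnf("equal class means: Fisher criterion is 0; returning the leading within-class variance axis")
    w1 <- eigen(fd$Sg, symmetric = TRUE)$vectors[, 1]
  } else w1 <- fd$w
  w1 <- w1 / sqrt(sum(w1^2))
  if (!degenerate && sum(w1 * fd$dm) < 0) w1 <- -w1
  crit <- if (degenerate) 0 else (sum(w1 * fd$dm))^2 / drop(t(w1) %*% fd$Sg %*% w1)
  w2 <- numeric(0)
  if (p >= 2L) {
    B <- qr.Q(qr(cbind(w1, diag(p))))[, 2:p, drop = FALSE]
    Zb <- Z %*% B
    fd2 <- fisherDirection(Zb, y)
    v <- if (sqrt(sum(fd2$dm^2)) < 1e-12)
      eigen(fd2$Sg, symmetric = TRUE)$vectors[, 1]
    else fd2$w
    w2 <- drop(B %*% v)
    w2 <- w2 / sqrt(sum(w2^2))
    if (sqrt(sum(fd2$dm^2)) >= 1e-12 && sum(v * fd2$dm) < 0) w2 <- -w2
  }
  new("CanonicalProjection", features = features, w1 = w1, w2 = w2, w1d = w1,
      center = setNames(ctr, features), scale = setNames(scl, features),
      gamma = fd$gamma, criterion = crit)
}

#' Project cells into the discriminative space
#'
#' Standardizes the selected features by the training means/sds stored in
#' the projection and applies the weight vectors: 1-D coordinates feed the
#' maximally separated histograms, 2-D coordinates the canonical scatter
#' plots. The first 2-D axis equals the 1-D projection.
#'
#' @param x a [FeatureTable-class] or cells x features matrix containing the
#'   projection's features.
#' @param projection a [CanonicalProjection-class].
#' @param dims 1 or 2.
#' @return numeric matrix, cells x dims.
#' @export
projectCells <- function(x, projection, dims = 2L) {
  stopifnot(is(projection, "CanonicalProjection"), dims %in% c(1L, 2L))
  feats <- projection@features
  if (is(x, "FeatureTable")) {
    m <- featureMatrix(x)
    miss <- setdiff(feats, rownames(m))
    if (length(miss)) stopf("missing feature column(s): %s",
                            paste(miss, collapse = ", "))
    X <- t(m[feats, , drop = FALSE])
  } else {
    X <- as.matrix(x)
    if (is.null(colnames(X))) {
      if (ncol(X) != length(feats))
        stopf("missing feature column(s): unnamed matrix with %d columns for %d features",
              ncol(X), length(feats))
      colnames(X) <- feats
    }
    miss <- setdiff(feats, colnames(X))
    if (length(miss)) stopf("missing feature column(s): %s",
                            paste(miss, collapse = ", "))
    X <- X[, feats, drop = FALSE]
  }
  Z <- scale(X, projection@center[feats], projection@scale[feats])
  if (dims == 1L) {
    out <- Z %*% cbind(projection@w1d)
    colnames(out) <- "cv1"
  } else {
    if (!length(projection@w2))
      stopf("projection has no second direction (single feature); use dims = 1")
    out <- Z %*% cbind(projection@w1, projection@w2)
    colnames(out) <- c("cv1", "cv2")
  }
  out
}
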