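#' @include validation.R
NULL

#' Write the four-panel report and machine-readable summary
#'
#' Emits the standard result set for one cohort analysis: (a) 2-D canonical
#' scatter with per-cell symbols, (b) pooled held-out ROC curve with its AUC,
#' (c) per-group histograms of the optimal 1-D projection, (d) boxplots of
#' the 1-D projection with Mann-Whitney significance stars -- plus
#' \code{report.json} (pooled and per-fold AUCs, chosen features, U, p,
#' tier, seed, grouping), \code{roc.csv}, \code{folds.csv} and
#' \code{projection.csv} (the exact 1-D/2-D coordinates the panels show).
#'
#' @param report a [ValidationReport-class] from [nestedCV()].
#' @param projection a [CanonicalProjection-class] for the scatter/histogram
#'   panels (typically fit on the full table for visualisation).
#' @param ft the [FeatureTable-class].
#' @param outDir output directory.
#' @return invisibly, the named list of written paths.
#' @export
makeReport <- function(report, projection, ft, outDir) {
  stopifnot(is(report, "ValidationReport"), is(projection, "CanonicalProjection"))
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stopf("cannot create report directory %s", outDir)
  y <- groupLabels(ft)
  xy <- projectCells(ft, projection, dims = if (length(projection@w2)) 2L else 1L)
  x1 <- drop(projectCells(ft, projection, dims = 1L))
  gt <- report@groupTest

  paths <- list()
  paths$summary <- file.path(outDir, "report.json")
  writeCanonicalJSON(list(
    pooled_auc = report@pooledAUC,
    fold_auc = report@foldAUC,
    chosen = lapply(report@chosen, function(ch)
      list(n = ch$n, features = as.list(ch$features))),
    mann_whitney = list(U = gt$U, p = gt$p, tier = gt$tier,
                        exact = gt$exact),
    grouping = report@config$grouping,
    seed = report@config$seed,
    n_cells = ncol(ft),
    n_group = as.list(table(factor(y, levels = 0:1)))), paths$summary)

  paths$roc <- file.path(outDir, "roc.csv")
  write.csv(data.frame(threshold = report@roc$thresholds,
                       fpr = report@roc$fpr, tpr = report@roc$tpr),
            paths$roc, row.names = FALSE)

  paths$folds <- file.path(outDir, "folds.csv")
  write.csv(report@scores, paths$folds, row.names = FALSE)

  paths$projection <- file.path(outDir, "projection.csv")
  projDf <- data.frame(cell = colnames(ft), group = y, cv1 = x1)
  if (ncol(xy) == 2L) projDf$cv2 <- xy[, 2]
  write.csv(projDf, paths$projection, row.names = FALSE)

  paths$figure <- file.path(outDir, "figures.pdf")
  grDevices::pdf(paths$figure, width = 9, height = 8)
  on.exit(grDevices::dev.off(), add = TRUE)
  par(mfrow = c(2, 2), mar = c(4, 4, 2.5, 1))
  colg <- c("#1f78b4", "#e31a1c")[y + 1L]
  pchg <- c(1, 17)[y + 1L]
  if (ncol(xy) == 2L) {
    plot(xy[, 1], xy[, 2], col = colg, pch = pchg,
         xlab = "canonical variable 1", ylab = "canonical variable 2",
         main = "(a) canonical scatter")
  } else {
    plot(x1, jitter(rep(0, length(x1))), col = colg, pch = pchg,
         xlab = "canonical variable 1", ylab = "",
         main = "(a) canonical projection")
  }
  legend("topleft", legend = c("group 1", "group 2"), col = c("#1f78b4", "#e31a1c"),
         pch = c(1, 17), bty = "n")
  plot(report@roc$fpr, report@roc$tpr, type = "l", lwd = 2,
       xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("(b) pooled held-out ROC (AUC = %.2f)", report@pooledAUC))
  abline(0, 1, lty = 3)
  brks <- pretty(range(x1), 20)
  h0 <- hist(x1[y == 0L], breaks = brks, plot = FALSE)
  h1 <- hist(x1[y == 1L], breaks = brks, plot = FALSE)
  ylim <- c(0, max(h0$counts, h1$counts))
  plot(h0, col = grDevices::adjustcolor("#1f78b4", 0.5), ylim = ylim,
       xlab = "1-D projection", main = "(c) cell distribution", border = NA)
  plot(h1, col = grDevices::adjustcolor("#e31a1c", 0.5), add = TRUE, border = NA)
  boxplot(split(x1, factor(y, 0:1, c("group 1", "group 2"))),
          col = c("#1f78b4", "#e31a1c"),
          ylab = "1-D projection", main = "(d) group comparison")
  if (gt$tier != "ns") {
    ytop <- max(x1) + 0.08 * diff(range(x1))
    segments(1, ytop, 2, ytop)
    text(1.5, ytop + 0.04 * diff(range(x1)), gt$tier, cex = 1.3)
  } else {
    mtext("ns", side = 3, line = -1.5)
  }
  invisible(paths)
}
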