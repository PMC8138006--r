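#' @include report.R
NULL

#' Pipeline configuration
#'
#' Bundles the per-stage configurations into one reproducible run
#' description and checks cross-stage consistency up front (the selection
#' size must respect the overfitting guard against the cohort's group
#' sizes, and every candidate feature count of the cross-validation grid
#' must stay below the smaller group). A single master seed drives cohort
#' generation and fold shuffling.
#'
#' @param cohort a [cohortConfig()].
#' @param correction a [correctionSettings()].
#' @param policy a [featurePolicy()].
#' @param selectionN feature count for the full-data visualisation model.
#' @param cv a [cvConfig()].
#' @param seed master seed; overrides the stage seeds.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(cohort = cohortConfig(),
                           correction = correctionSettings(),
                           policy = featurePolicy("conservative"),
                           selectionN = 6L, cv = cvConfig(), seed = 1L) {
  cohort$seed <- childSeed(seed, 1L)
  cv$seed <- childSeed(seed, 2L)
  N <- min(cohort$cellsPerGroup)
  if (selectionN >= N)
    stopf("selectionN = %d must be below the smaller group's cell count (%d)",
          selectionN, N)
  if (all(cv$nGrid >= N))
    stopf("no cv nGrid entry below the smaller group's cell count (%d)", N)
  structure(list(cohort = cohort, correction = correction, policy = policy,
                 selectionN = as.integer(selectionN), cv = cv,
                 seed = as.integer(seed),
                 version = as.character(packageVersion("specell"))),
            class = "pipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' One YAML document with per-stage sections mirroring [pipelineConfig()]
#' field-for-field; unknown keys are rejected.
#'
#' @param path YAML file.
#' @param config a [pipelineConfig()].
#' @return \code{readPipelineConfig}: a validated \code{pipelineConfig};
#'   \code{writePipelineConfig}: the path, invisibly.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("cohort", "correction", "policy", "selectionN", "cv", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown pipeline config key(s): %s",
                         paste(bad, collapse = ", "))
  build <- function(ctor, args) if (is.null(args)) ctor() else do.call(ctor, args)
  cohort <- build(cohortConfig, raw$cohort)
  if (!is.null(raw$cohort$baseLogAbundance))
    cohort$baseLogAbundance <- unlist(raw$cohort$baseLogAbundance)
  pipelineConfig(cohort = cohort,
                 correction = build(correctionSettings, raw$correction),
                 policy = build(featurePolicy, raw$policy),
                 selectionN = raw$selectionN %||% 6L,
                 cv = build(cvConfig, raw$cv),
                 seed = raw$seed %||% 1L)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "pipelineConfig"))
  out <- list(cohort = unclass(config$cohort),
              correction = unclass(config$correction),
              policy = unclass(config$policy),
              selectionN = config$selectionN,
              cv = unclass(config$cv), seed = config$seed)
  out$cohort$baseLogAbundance <- as.list(out$cohort$baseLogAbundance)
  yaml::write_yaml(out, path)
  invisible(path)
}

pipelineStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> features -> discriminate -> validate
#' on one synthetic cohort, writing each stage's outputs under
#' \code{outDir} together with a manifest (\code{manifest.json}) listing
#' the master seed, the package version and an MD5 checksum of every
#' deterministic output file. Two runs with the same configuration produce
#' identical manifests; figure files (PDF carries a creation date) are
#' listed without checksums.
#'
#' @param config a [pipelineConfig()] or path to its YAML form.
#' @param outDir run directory (created; must be empty or absent).
#' @param keepImages keep the cohort and preprocessed image directories
#'   after feature extraction (default TRUE; set FALSE to reclaim the bulk
#'   of the disk space — the manifest then covers the retained tables,
#'   model, report and configuration files).
#' @return invisibly, a list with \code{dir}, \code{featureTable},
#'   \code{model}, \code{report}, \code{manifest}.
#' @export
runPipeline <- function(config, outDir, keepImages = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  if (dir.exists(outDir) && length(list.files(outDir)))
    stopf("output directory %s is not empty", outDir)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stopf("cannot create run directory %s", outDir)

  message("stage simulate: generating cohort (",
          paste(config$cohort$cellsPerGroup, collapse = " + "), " cells)")
  cohortDir <- file.path(outDir, "cohort")
  sim <- pipelineStage("simulate",
    generateCohort(config$cohort, outDir = cohortDir))

  message("stage preprocess: ", length(sim$blockDirs), " blocks")
  preDir <- file.path(outDir, "preprocessed")
  preDirs <- pipelineStage("preprocess", {
    out <- character()
    for (key in names(sim$blockDirs)) {
      b <- readDataBlock(sim$blockDirs[[key]])
      pp <- preprocessBlock(b, config$correction)
      d <- file.path(preDir, key)
      writeDataBlock(pp$block, d)
      writeStack(pp$badPixelMap, file.path(d, "badpixels.tif"), 65535)
      file.copy(file.path(sim$blockDirs[[key]], "mask.tif"),
                file.path(d, "mask.tif"))
      out[key] <- d
    }
    out
  })

  message("stage features")
  ft <- pipelineStage("features", buildFeatureTable(unname(preDirs),
                                                    policy = config$policy))
  featPath <- file.path(outDir, "features.csv")
  writeFeatureTable(ft, featPath)

  message("stage discriminate")
  model <- pipelineStage("discriminate", {
    sc <- rankFeatures(ft)
    feats <- selectFeatures(sc, ft, config$selectionN,
                            redundancyRho = config$cv$redundancyRho)
    proj <- fitCanonicalProjection(ft, features = feats)
    writeCanonicalJSON(list(
      features = as.list(proj@features),
      w1 = proj@w1, w2 = proj@w2, w1d = proj@w1d,
      center = as.list(proj@center), scale = as.list(proj@scale),
      gamma = proj@gamma, criterion = proj@criterion,
      ranking = list(feature = sc$feature, min_error = sc$min_error)),
      file.path(outDir, "model.json"))
    proj
  })

  message("stage validate: nested CV (", config$cv$grouping, "-grouped)")
  report <- pipelineStage("validate", nestedCV(ft, config$cv))
  reportPaths <- makeReport(report, model, ft, file.path(outDir, "report"))

  writePipelineConfig(config, file.path(outDir, "config.yaml"))
  if (!keepImages) {
    unlink(cohortDir, recursive = TRUE)
    unlink(preDir, recursive = TRUE)
  }
  manifest <- buildManifest(outDir, config)
  writeCanonicalJSON(manifest, file.path(outDir, "manifest.json"))
  invisible(list(dir = outDir, featureTable = ft, model = model,
                 report = report, manifest = manifest))
}

# checksum every deterministic file under the run directory; figures are
# listed without checksums (the PDF device embeds a creation date)
UNCHECKED_PATTERNS <- "\\.pdf$"

buildManifest <- function(outDir, config) {
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.json"))
  sums <- lapply(files, function(f) {
    if (grepl(UNCHECKED_PATTERNS, f)) list(path = f, md5 = NULL)
    else list(path = f, md5 = unname(md5sum(file.path(outDir, f))))
  })
  list(version = as.character(packageVersion("specell")),
       seed = config$seed,
       n_files = length(files),
       files = sums)
}

#' Verify a pipeline run directory against its manifest
#'
#' Recomputes the MD5 checksum of every manifest entry; a missing or
#' tampered file is reported.
#'
#' @param dir a run directory written by [runPipeline()].
#' @return \code{TRUE} invisibly on success; otherwise stops with the
#'   offending files named.
#' @export
verifyRun <- function(dir) {
  manPath <- file.path(dir, "manifest.json")
  if (!file.exists(manPath)) stopf("no manifest.json in %s", dir)
  man <- readJSON(manPath)
  bad <- character()
  for (f in man$files) {
    p <- file.path(dir, f$path)
    if (!file.exists(p)) {
      bad <- c(bad, paste0(f$path, " (missing)"))
    } else if (!is.null(f$md5) && unname(md5sum(p)) != f$md5) {
      bad <- c(bad, paste0(f$path, " (checksum mismatch)"))
    }
  }
  if (length(bad))
    stopf("run verification failed:\n  %s", paste(bad, collapse = "\n  "))
  invisible(TRUE)
}
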