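# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# Derive a child seed from a master seed and a stream index, staying inside
# the 32-bit integer range. Deterministic and collision-poor for the small
# stream counts used here.
childSeed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + as.double(stream) * 30269) %% 2147483563
  as.integer(s) + 1L
}

# Canonical JSON: keys sorted recursively, scalars unboxed, full precision.
# Two writes of one object are byte-identical, which makes sidecars and
# manifests diff-able and checksum-stable.
sortNamesRec <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, sortNamesRec)
  } else if (is.list(x)) {
    lapply(x, sortNamesRec)
  } else x
}

writeCanonicalJSON <- function(x, path) {
  txt <- jsonlite::toJSON(sortNamesRec(x), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, null = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

readJSON <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

# zero-padded channel tag: 2 -> "ch02"
chTag <- function(i) sprintf("ch%02d", as.integer(i))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}
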