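#' @include AllClasses.R
NULL

#' Construct a channel set
#'
#' @param table \code{data.frame} with one row per channel; see
#'   \linkS4class{ChannelSet} for required columns and invariants.
#' @return a validated [ChannelSet-class].
#' @export
ChannelSet <- function(table) {
  table <- as.data.frame(table)
  table$index <- as.integer(table$index)
  table$n_averages <- as.integer(table$n_averages)
  new("ChannelSet", table = table)
}

#' Default 34-channel acquisition grid
#'
#' The instrument's exact per-channel wavelength table is configuration that
#' travels with each dataset, so this constructor generates a stand-in grid
#' covering the documented acquisition ranges: 34 channels with excitation
#' centers stepping over 340--510 nm (half-width 5 nm), Stokes-shifted
#' emission bands inside 420--650 nm, exposures cycling through 1/2/5 s and
#' 3-frame averaging. Real channel tables are dropped in via
#' [readChannelSet()].
#'
#' @param nChannels number of channels (default 34).
#' @return a [ChannelSet-class].
#' @examples
#' cs <- defaultChannelSet()
#' nChannels(cs)
#' @export
defaultChannelSet <- function(nChannels = 34L) {
  stopifnot(isWholeNumber(nChannels), nChannels >= 1)
  n <- as.integer(nChannels)
  ex <- round(seq(340, 510, length.out = n), 1)
  emLow <- pmax(ex + 35, 420)
  emHigh <- pmin(emLow + 80, 650)
  emLow <- pmin(emLow, emHigh - 30)          # keep a sensible bandwidth
  ChannelSet(data.frame(
    index = seq_len(n),
    excitation_center = ex,
    excitation_halfwidth = 5,
    emission_low = emLow,
    emission_high = emHigh,
    exposure = rep(c(1, 2, 5), length.out = n),
    n_averages = 3L))
}

#' Read / write a channel set as CSV
#'
#' Plain CSV with one row per channel and the columns of
#' \linkS4class{ChannelSet}; the written file can be edited to carry a real
#' instrument wavelength table.
#'
#' @param path CSV file path.
#' @param x a [ChannelSet-class].
#' @return \code{readChannelSet}: a validated [ChannelSet-class];
#'   \code{writeChannelSet}: the path, invisibly.
#' @export
readChannelSet <- function(path) {
  if (!file.exists(path)) stopf("channel table not found: %s", path)
  ChannelSet(read.csv(path, check.names = FALSE))
}

#' @rdname readChannelSet
#' @export
writeChannelSet <- function(x, path) {
  stopifnot(is(x, "ChannelSet"))
  write.csv(x@table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
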