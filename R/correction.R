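#' Molecular-clock time corrections
#'
#' The mutation-count-to-years conversion may require a nonlinearity
#' correction (time-dependent rate, purifying selection).  A correction is
#' a strictly increasing map from raw clock years to corrected years with
#' `correction(0) = 0`; the identity is the default, and any published
#' calibration curve can be loaded verbatim as a two-column table that is
#' interpolated piecewise-linearly.  The same object rescales rho-based age
#' estimates and skyline time grids, so both use a single calibration
#' source.
#'
#' @param fun function mapping years to years.
#' @param name label for reports.
#' @return object of class `clock_correction` (callable).
#' @export
clock_correction <- function(fun, name = "custom") {
  stopifnot(is.function(fun))
  if (abs(fun(0)) > 1e-9) stop("correction(0) must be 0")
  probe <- seq(0, 1e5, length.out = 41L)
  if (any(diff(fun(probe)) <= 0)) {
    stop("correction must be strictly increasing")
  }
  structure(fun, class = c("clock_correction", "function"), name = name)
}

#' @rdname clock_correction
#' @export
identity_correction <- function() clock_correction(identity, name = "identity")

#' Load a correction from a two-column table
#'
#' @param x data frame (raw years, corrected years) or a path to a
#'   two-column TSV (`raw`, `corrected`; header optional).  Rows must be
#'   strictly increasing in both columns; a (0, 0) anchor is prepended when
#'   absent.  Beyond the last row the curve is extended linearly with the
#'   final segment's slope.
#' @param name label for reports.
#' @return a `clock_correction`.
#' @export
correction_from_table <- function(x, name = "table") {
  if (is.character(x)) {
    x <- utils::read.delim(x, header = grepl("[a-zA-Z]", readLines(x, n = 1L)),
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), ncol(x) >= 2L)
  raw <- as.numeric(x[[1L]]); corr <- as.numeric(x[[2L]])
  if (anyNA(raw) || anyNA(corr)) stop("non-numeric entries in correction table")
  o <- order(raw); raw <- raw[o]; corr <- corr[o]
  if (any(diff(raw) <= 0) || any(diff(corr) <= 0)) {
    stop("correction table must be strictly increasing in both columns")
  }
  if (raw[1L] > 0) { raw <- c(0, raw); corr <- c(0, corr) }
  if (raw[1L] == 0 && corr[1L] != 0) stop("correction(0) must be 0")
  k <- length(raw)
  slope_end <- (corr[k] - corr[k - 1L]) / (raw[k] - raw[k - 1L])
  fun <- function(t) {
    out <- stats::approx(raw, corr, xout = pmin(t, raw[k]), rule = 2L)$y
    over <- t > raw[k]
    out[over] <- corr[k] + (t[over] - raw[k]) * slope_end
    out
  }
  clock_correction(fun, name = name)
}

#' Write a correction table
#' @param correction a `clock_correction`.
#' @param path TSV path.
#' @param raw grid of raw years to tabulate.
#' @return invisibly, the path.
#' @export
write_correction_table <- function(correction, path,
                                   raw = seq(0, 50000, by = 500)) {
  utils::write.table(
    data.frame(raw = raw, corrected = correction(raw)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
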