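#' Construct a skyline track
#'
#' A Bayesian skyline export: effective population size (N_e) medians,
#' means and 95% HPD bounds on an ascending time grid (years before
#' present).
#'
#' @param time_grid strictly increasing numeric vector.
#' @param mean,median,hpd_low,hpd_high N_e values per grid point.
#' @return data frame of class `skyline_track`.
#' @export
skyline_track <- function(time_grid, mean, median, hpd_low, hpd_high) {
  n <- length(time_grid)
  stopifnot(length(mean) == n, length(median) == n,
            length(hpd_low) == n, length(hpd_high) == n)
  if (any(diff(time_grid) <= 0)) stop("time grid must be strictly increasing")
  bad <- which(hpd_low > median | median > hpd_high)
  if (length(bad)) {
    stop("HPD bounds do not bracket the median at row(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(c(mean, median, hpd_low, hpd_high) <= 0)) {
    stop("N_e values must be positive")
  }
  out <- data.frame(time = time_grid, mean = mean, median = median,
                    hpd_low = hpd_low, hpd_high = hpd_high)
  class(out) <- c("skyline_track", "data.frame")
  out
}

#' Read a skyline export
#'
#' Consumes the tab-separated skyline table exported by posterior-analysis
#' software (header with time, mean, median, upper and lower columns; the
#' usual Tracer column names are recognised case-insensitively).
#'
#' @param path TSV path.
#' @return a `skyline_track`.
#' @export
read_skyline <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (!length(hit)) stop("skyline export missing column: ",
                           paste(cands, collapse = "/"))
    hit[1L]
  }
  cols <- c(time = pick(c("time")), mean = pick(c("mean")),
            median = pick(c("median")),
            hpd_low = pick(c("lower", "hpd.lower", "hpd_low")),
            hpd_high = pick(c("upper", "hpd.upper", "hpd_high")))
  num <- lapply(cols, function(j) suppressWarnings(as.numeric(tab[[j]])))
  bad_rows <- sort(unique(unlist(lapply(num, function(x) which(is.na(x))))))
  if (length(bad_rows)) {
    stop("non-numeric skyline fields at data row(s): ",
         paste(bad_rows, collapse = ", "))
  }
  skyline_track(num$time, num$mean, num$median, num$hpd_low, num$hpd_high)
}

#' Write a skyline track
#' @param track a `skyline_track`.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
write_skyline <- function(track, path) {
  out <- data.frame(time = track$time, mean = track$mean,
                    median = track$median, lower = track$hpd_low,
                    upper = track$hpd_high)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rescale a skyline time axis
#'
#' Applies a molecular-clock correction to the time grid pointwise.  N_e
#' values are untouched; because the correction is strictly increasing the
#' grid stays strictly increasing.  Used to post-process skyline plots
#' produced under a linear clock when the true mutation-rate-to-time map is
#' nonlinear.
#'
#' @param track a `skyline_track`.
#' @param correction a `clock_correction` (the same object used for rho
#'   dating).
#' @return the corrected `skyline_track`.
#' @export
correct_timescale <- function(track, correction) {
  stopifnot(inherits(track, "skyline_track"))
  if (!inherits(correction, "clock_correction")) {
    correction <- clock_correction(correction)
  }
  skyline_track(correction(track$time), track$mean, track$median,
                track$hpd_low, track$hpd_high)
}

#' Plot a skyline track
#'
#' Median N_e as a solid line with dashed 95% HPD bounds on a log scale.
#'
#' @param x a `skyline_track`.
#' @param ... passed to [plot()].
#' @return invisibly, the track.
#' @export
plot.skyline_track <- function(x, ...) {
  graphics::plot(x$time, x$median, type = "l", log = "y",
                 xlab = "years before present", ylab = expression(N[e]),
                 ylim = range(c(x$hpd_low, x$hpd_high)), ...)
  graphics::lines(x$time, x$hpd_low, lty = 2)
  graphics::lines(x$time, x$hpd_high, lty = 2)
  invisible(x)
}
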