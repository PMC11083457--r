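#' TCSPC time axis
#'
#' Describes the arrival-time binning of a TCSPC decay histogram: the width
#' of each bin, the number of bins, the laser repetition period bounding the
#' observable window, and the index of the first bin at or after the
#' excitation pulse.
#'
#' @param bin_width Time per bin in ns. Must be positive.
#' @param n_bins Number of arrival-time bins (at least 8).
#' @param period Laser repetition period in ns. Defaults to 12.5 ns
#'   (an 80 MHz pulsed laser).
#' @param rise_bin 0-based index of the first bin at/after the excitation
#'   pulse. Bins before `rise_bin` see only background and are used for
#'   background estimation.
#' @param allow_wrap If `TRUE`, permit `n_bins * bin_width > period`
#'   (a wrapped/incomplete-decay acquisition). Otherwise this is an error.
#'
#' @return An object of class `"time_axis"`.
#' @examples
#' ax <- time_axis(bin_width = 12.5 / 256, n_bins = 256, rise_bin = 16)
#' bin_times(ax)[1:4]
#' @export
time_axis <- function(bin_width, n_bins, period = 12.5, rise_bin = 0L,
                      allow_wrap = FALSE) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0,
            is.numeric(n_bins), length(n_bins) == 1L, n_bins >= 8,
            is.numeric(period), length(period) == 1L, period > 0,
            is.numeric(rise_bin), length(rise_bin) == 1L)
  n_bins <- as.integer(n_bins)
  rise_bin <- as.integer(rise_bin)
  if (rise_bin < 0L || rise_bin >= n_bins)
    stop("rise_bin must satisfy 0 <= rise_bin < n_bins")
  if (n_bins * bin_width > period * (1 + 1e-9) && !allow_wrap)
    stop("n_bins * bin_width exceeds the repetition period; ",
         "set allow_wrap = TRUE for a wrapped acquisition")
  structure(list(bin_width = bin_width, n_bins = n_bins, period = period,
                 rise_bin = rise_bin),
            class = "time_axis")
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf(
    "TCSPC time axis: %d bins x %.4f ns (window %.2f ns), period %.2f ns, rise bin %d\n",
    x$n_bins, x$bin_width, x$n_bins * x$bin_width, x$period, x$rise_bin))
  invisible(x)
}

#' Left edges of the time bins
#'
#' @param axis A [time_axis()].
#' @return Numeric vector of bin start times (ns), length `n_bins`.
#' @export
bin_times <- function(axis) {
  stopifnot(inherits(axis, "time_axis"))
  (seq_len(axis$n_bins) - 1) * axis$bin_width
}

# time of the excitation pulse (start of the rise bin), ns
rise_time <- function(axis) axis$rise_bin * axis$bin_width
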