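#' Single-pixel TCSPC decay histogram
#'
#' Bundles a vector of photon counts per arrival-time bin with its
#' [time_axis()]. This is the per-pixel unit on which background estimation,
#' amplitude estimation, integration and exponential fitting operate.
#'
#' @param counts Non-negative integer photon counts, one per bin.
#' @param axis A [time_axis()] whose `n_bins` matches `length(counts)`.
#' @return An object of class `"decay_curve"`.
#' @examples
#' ax <- time_axis(12.5 / 64, 64, rise_bin = 8)
#' dc <- decay_curve(rpois(64, 5), ax)
#' total_counts(dc)
#' @export
decay_curve <- function(counts, axis) {
  stopifnot(inherits(axis, "time_axis"), is.numeric(counts))
  if (length(counts) != axis$n_bins)
    stop("length(counts) must equal axis$n_bins")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-6 & counts > 0))
    warning("counts are not integers; proceeding with given values")
  structure(list(counts = as.numeric(counts), axis = axis),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("TCSPC decay: %d bins, %.0f photons, peak %d at bin %d\n",
              x$axis$n_bins, sum(x$counts), max(x$counts),
              which.max(x$counts) - 1L))
  invisible(x)
}

#' @export
plot.decay_curve <- function(x, log = "y", ...) {
  y <- x$counts
  if (grepl("y", log)) y <- pmax(y, 0.5)
  graphics::plot(bin_times(x$axis), y, type = "s", log = log,
                 xlab = "time (ns)", ylab = "counts / bin", ...)
  graphics::abline(v = rise_time(x$axis), lty = 3)
  invisible(x)
}

#' @rdname decay_curve
#' @export
total_counts <- function(counts) {
  if (inherits(counts, "decay_curve")) sum(counts$counts) else sum(counts)
}

#' Estimate the background level from pre-pulse bins
#'
#' The bins before the excitation pulse contain only dark counts and ambient
#' light; their mean estimates the per-bin background that must be removed
#' before amplitudes, areas or lifetimes are computed.
#'
#' @param decay A [decay_curve()].
#' @param pre_bins Number of leading bins to average. Defaults to
#'   `max(4, rise_bin %/% 2)`. Must satisfy `1 <= pre_bins <= rise_bin`.
#' @return Background level in counts/bin (a single number).
#' @examples
#' ax <- time_axis(0.05, 64, rise_bin = 8)
#' dc <- decay_curve(c(rep(5, 8), round(1000 * exp(-(0:55) * 0.05 / 3)) + 5), ax)
#' estimate_background(dc, pre_bins = 8)
#' @export
estimate_background <- function(decay, pre_bins = NULL) {
  stopifnot(inherits(decay, "decay_curve"))
  rb <- decay$axis$rise_bin
  if (rb == 0L)
    stop("no pre-pulse window: rise_bin is 0; pass an explicit background ",
         "(possibly 0) instead")
  if (is.null(pre_bins)) pre_bins <- max(4L, rb %/% 2L)
  pre_bins <- as.integer(pre_bins)
  if (pre_bins < 1L || pre_bins > rb)
    stop("pre_bins must satisfy 1 <= pre_bins <= rise_bin")
  mean(decay$counts[seq_len(pre_bins)])
}

#' Estimate the decay amplitude at the excitation pulse
#'
#' The amplitude p0 is the background-subtracted height of the decay at its
#' onset, the denominator of the time-integrated FRET estimator. Two methods
#' are provided: `"peak"` takes the maximum bin minus background (simple but
#' biased upward by the max-of-Poisson statistic), and `"headfit"` (the
#' default) fits a least-squares line to the log of the background-subtracted
#' counts over the first `head_bins` bins starting at the argmax bin and
#' evaluates it at the argmax bin time, which averages out counting noise.
#'
#' @param decay A [decay_curve()].
#' @param background Background level in counts/bin (see
#'   [estimate_background()]).
#' @param method `"headfit"` or `"peak"`.
#' @param head_bins Number of bins in the head-fit window (default 10).
#' @return A list of class `"amplitude_estimate"` with elements `p0`
#'   (counts/bin, background-subtracted) and `method_tag`.
#' @export
estimate_amplitude <- function(decay, background = 0,
                               method = c("headfit", "peak"),
                               head_bins = 10L) {
  stopifnot(inherits(decay, "decay_curve"), background >= 0)
  method <- match.arg(method)
  cts <- decay$counts
  if (max(cts) <= background)
    stop("empty decay: maximum count does not exceed background")
  if (method == "peak") {
    p0 <- max(cts) - background
  } else {
    k0 <- which.max(cts)
    idx <- k0:min(k0 + head_bins - 1L, length(cts))
    y <- cts[idx] - background
    keep <- y > 0
    if (sum(keep) < 3L)
      stop("headfit underdetermined: fewer than 3 usable bins in the head window")
    tt <- bin_times(decay$axis)[idx][keep]
    fit <- stats::lm.fit(cbind(1, tt), log(y[keep]))
    p0 <- unname(exp(sum(fit$coefficients * c(1, bin_times(decay$axis)[k0]))))
  }
  if (!is.finite(p0) || p0 <= 0) stop("empty decay: non-positive amplitude")
  structure(list(p0 = p0, method_tag = method), class = "amplitude_estimate")
}

#' Integrate a background-subtracted decay curve
#'
#' Computes the area under the decay from the rise bin to the end of the
#' window, `sum(max(counts - background, 0)) * bin_width` (counts are clamped
#' at zero so counting noise in empty tail bins cannot produce negative
#' area). With `tail_mode = "monoexp"` a single exponential is fitted to the
#' last quarter of the window (log-linear least squares on the positive
#' background-subtracted counts) and its analytic geometric-series
#' extrapolation beyond the window is added; `tail_fraction` reports the
#' estimated fraction of the total area lying beyond the window.
#'
#' If the tail fit is underdetermined (fewer than 3 positive bins) or yields
#' a non-physical lifetime, the tail is omitted and `tail_fraction` is 0.
#'
#' @param decay A [decay_curve()].
#' @param background Background level in counts/bin.
#' @param tail_mode `"none"` or `"monoexp"`.
#' @return A list of class `"decay_area"` with elements `area` (counts·ns)
#'   and `tail_fraction`.
#' @export
integrate_decay <- function(decay, background = 0,
                            tail_mode = c("none", "monoexp")) {
  stopifnot(inherits(decay, "decay_curve"), background >= 0)
  tail_mode <- match.arg(tail_mode)
  ax <- decay$axis
  idx <- (ax$rise_bin + 1L):ax$n_bins
  net <- pmax(decay$counts[idx] - background, 0)
  area <- sum(net) * ax$bin_width
  if (area <= 0) stop("empty decay: zero area after background subtraction")
  tail_area <- 0
  if (tail_mode == "monoexp") {
    nq <- max(4L, length(idx) %/% 4L)
    tail_idx <- idx[(length(idx) - nq + 1L):length(idx)]
    y <- decay$counts[tail_idx] - background
    keep <- y > 0
    if (sum(keep) >= 3L) {
      tt <- bin_times(ax)[tail_idx][keep]
      cf <- unname(stats::lm.fit(cbind(1, tt), log(y[keep]))$coefficients)
      tau_tail <- -1 / cf[2]
      if (is.finite(tau_tail) && tau_tail > 0 && tau_tail <= 20) {
        # predicted counts in the first bin past the window, then the
        # geometric sum of the discrete bin series continued to infinity
        t_next <- ax$n_bins * ax$bin_width
        c_next <- exp(cf[1] + cf[2] * t_next)
        r <- exp(-ax$bin_width / tau_tail)
        tail_area <- c_next / (1 - r) * ax$bin_width
      }
    }
  }
  structure(list(area = area + tail_area,
                 tail_fraction = tail_area / (area + tail_area)),
            class = "decay_area")
}
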