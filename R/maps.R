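#' Time-resolved fluorescence image stack
#'
#' A 3-D array of photon counts indexed (row, column, time-bin) plus its
#' [time_axis()]. A 4-D array with a trailing scan-series axis (repeated
#' 1-s frame scans) is accepted and summed over scans by default, matching
#' how TCSPC acquisitions accumulate counts across frames; pass
#' `keep_scans = TRUE` to retain the axis (e.g. for photobleaching studies).
#'
#' @param counts 3-D (row, col, bin) or 4-D (row, col, bin, scan)
#'   non-negative array.
#' @param axis A [time_axis()] matching the third dimension.
#' @param keep_scans Keep the scan axis of a 4-D array instead of summing.
#' @return An object of class `"flim_stack"`.
#' @export
flim_stack <- function(counts, axis, keep_scans = FALSE) {
  stopifnot(inherits(axis, "time_axis"), is.array(counts))
  nd <- length(dim(counts))
  if (!nd %in% c(3L, 4L)) stop("counts must be a 3-D or 4-D array")
  if (nd == 4L && !keep_scans) {
    counts <- rowSums(counts, dims = 3L)
    nd <- 3L
  }
  if (dim(counts)[3] != axis$n_bins)
    stop("time-bin dimension (", dim(counts)[3],
         ") does not equal axis$n_bins (", axis$n_bins, ")")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, axis = axis), class = "flim_stack")
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("FLIM stack: %d x %d pixels x %d time bins%s, %.3g photons\n",
              d[1], d[2], d[3],
              if (length(d) == 4L) sprintf(" x %d scans", d[4]) else "",
              sum(x$counts)))
  print(x$axis)
  invisible(x)
}

#' @export
dim.flim_stack <- function(x) dim(x$counts)

# extract one pixel as a decay_curve (1-based row/col)
pixel_decay <- function(stack, row, col) {
  decay_curve(stack$counts[row, col, ], stack$axis)
}

# per-pixel background from the pre-pulse bins, as a matrix
stack_background <- function(stack, pre_bins = NULL) {
  rb <- stack$axis$rise_bin
  if (rb == 0L) return(matrix(0, dim(stack)[1], dim(stack)[2]))
  if (is.null(pre_bins)) pre_bins <- max(4L, rb %/% 2L)
  pre_bins <- min(as.integer(pre_bins), rb)
  rowSums(stack$counts[, , seq_len(pre_bins), drop = FALSE], dims = 2L) /
    pre_bins
}

new_fret_map <- function(E, valid, method_tag, extra = list()) {
  structure(c(list(E = E, valid = valid, method_tag = method_tag), extra),
            class = "fret_map")
}

#' @export
print.fret_map <- function(x, ...) {
  v <- x$E[x$valid]
  cat(sprintf("FRET map (%s): %d x %d pixels, %d valid (%.1f%%)\n",
              x$method_tag, nrow(x$E), ncol(x$E), sum(x$valid),
              100 * mean(x$valid)))
  if (length(v))
    cat(sprintf("  E median %.3f, IQR [%.3f, %.3f]\n",
                stats::median(v), stats::quantile(v, 0.25),
                stats::quantile(v, 0.75)))
  invisible(x)
}

#' @export
summary.fret_map <- function(object, ...) {
  print(object)
  if (any(object$valid)) print(summary(object$E[object$valid]))
  invisible(object)
}

#' @export
plot.fret_map <- function(x, zlim = c(-0.1, 1), ...) {
  z <- x$E
  z[!x$valid] <- NA
  graphics::image(t(z[nrow(z):1, , drop = FALSE]), zlim = zlim, asp = 1,
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, ...)
  invisible(x)
}

#' Per-pixel FRET efficiency map from a FLIM stack
#'
#' Applies one of three per-pixel estimators to every pixel of a stack:
#' `"1exp"` (single-exponential tail fit, then `E = 1 - tau/tau_D`),
#' `"2exp"` (two-exponential fit, then the amplitude-weighted mean
#' lifetime), or `"tifret"` (area under the decay over its amplitude —
#' no component count needed). Pixels with fewer than `min_photons`
#' background-subtracted photons, failed fits, or efficiencies outside
#' `[-0.5, 1]` are marked invalid; a small negative-`E` allowance keeps
#' counting noise at the null from biasing the accepted distribution.
#' Failures never abort the map.
#'
#' @param stack A [flim_stack()].
#' @param donor Donor-only lifetime `tau_D` in ns, or a `"donor_reference"`
#'   from [donor_lifetime_from_maps()].
#' @param method `"tifret"`, `"1exp"` or `"2exp"`.
#' @param min_photons Minimum background-subtracted photons per pixel
#'   (default 100).
#' @param amplitude_method Amplitude estimator for tiFRET
#'   (see [estimate_amplitude()]).
#' @param tail_mode Tail handling for tiFRET integration (default `"none"`:
#'   at typical per-pixel counts the tail bins are noise-dominated and the
#'   analytic extrapolation adds variance; see [integrate_decay()]).
#' @param correction Discretisation handling for tiFRET
#'   (see [fret_from_integral()]).
#' @param background Scalar background (counts/bin) applied to all pixels;
#'   if `NULL`, estimated per pixel from the pre-pulse bins.
#' @param pre_bins Pre-pulse window width for background estimation.
#' @return A `"fret_map"`: list with matrices `E` and `valid`, the
#'   `method_tag`, and `tau_D` used.
#' @export
compute_fret_map <- function(stack, donor, method = c("tifret", "1exp", "2exp"),
                             min_photons = 100,
                             amplitude_method = c("headfit", "peak"),
                             tail_mode = c("none", "monoexp"),
                             correction = c("none", "geometric"),
                             background = NULL, pre_bins = NULL) {
  method <- match.arg(method)
  amplitude_method <- match.arg(amplitude_method)
  tail_mode <- match.arg(tail_mode)
  correction <- match.arg(correction)
  stopifnot(inherits(stack, "flim_stack"))
  tau_D <- if (inherits(donor, "donor_reference")) donor$tau_D else donor
  stopifnot(is.numeric(tau_D), tau_D > 0)
  ax <- stack$axis
  d <- dim(stack)
  bg <- if (is.null(background)) stack_background(stack, pre_bins) else
    matrix(background, d[1], d[2])
  post <- (ax$rise_bin + 1L):ax$n_bins
  net <- rowSums(stack$counts[, , post, drop = FALSE], dims = 2L) -
    length(post) * bg

  E <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (!is.finite(net[i, j]) || net[i, j] < min_photons) next
      e <- tryCatch({
        dc <- decay_curve(stack$counts[i, j, ], ax)
        switch(method,
          tifret = {
            a <- integrate_decay(dc, bg[i, j], tail_mode = tail_mode)
            p0 <- estimate_amplitude(dc, bg[i, j],
                                     method = amplitude_method)
            fret_from_integral(a, p0, tau_D, bin_width = ax$bin_width,
                               correction = correction)
          },
          `1exp` = {
            fit <- fit_exponentials(dc, p = 1L, background = bg[i, j],
                                    min_counts = min_photons)
            fret_from_mixture(fit, tau_D)
          },
          `2exp` = {
            fit <- fit_exponentials(dc, p = 2L, background = bg[i, j],
                                    min_counts = min_photons)
            fret_from_mixture(fit, tau_D)
          })
      }, error = function(err) NA_real_)
      if (is.finite(e) && e >= -0.5 && e <= 1) {
        E[i, j] <- e
        valid[i, j] <- TRUE
      }
    }
  }
  new_fret_map(E, valid, method, list(tau_D = tau_D))
}

#' Per-pixel donor lifetime map
#'
#' Fits a single exponential to every pixel with enough photons and returns
#' the fitted lifetime per pixel; used on donor-only samples to build the
#' donor reference lifetime.
#'
#' @inheritParams compute_fret_map
#' @return A list of class `"lifetime_map"` with matrices `tau` and `valid`.
#' @export
compute_lifetime_map <- function(stack, min_photons = 100,
                                 background = NULL, pre_bins = NULL) {
  stopifnot(inherits(stack, "flim_stack"))
  ax <- stack$axis
  d <- dim(stack)
  bg <- if (is.null(background)) stack_background(stack, pre_bins) else
    matrix(background, d[1], d[2])
  post <- (ax$rise_bin + 1L):ax$n_bins
  net <- rowSums(stack$counts[, , post, drop = FALSE], dims = 2L) -
    length(post) * bg
  tau <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (!is.finite(net[i, j]) || net[i, j] < min_photons) next
      t_ij <- tryCatch(
        fit_exponentials(decay_curve(stack$counts[i, j, ], ax), p = 1L,
                         background = bg[i, j],
                         min_counts = min_photons)$lifetimes,
        error = function(err) NA_real_)
      if (is.finite(t_ij)) {
        tau[i, j] <- t_ij
        valid[i, j] <- TRUE
      }
    }
  }
  structure(list(tau = tau, valid = valid), class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  v <- x$tau[x$valid]
  cat(sprintf("Lifetime map: %d x %d pixels, %d valid\n",
              nrow(x$tau), ncol(x$tau), sum(x$valid)))
  if (length(v)) cat(sprintf("  tau median %.3f ns\n", stats::median(v)))
  invisible(x)
}
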