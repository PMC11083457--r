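#' FRET spectrogram of a map over one or more ROIs
#'
#' The full post-processing chain applied to a per-pixel map: each ROI is
#' segmented into `side x side` squares ([segment_roi()]), a histogram of
#' the valid pixel values in each segment yields a peak value
#' ([histogram_peak()]), the peaks are assembled into a meta-histogram
#' ([build_meta_histogram()]), and a single Gaussian is fitted to it
#' ([fit_gaussian()]); its mean is the sample's most probable value.
#' Segments with fewer than `min_valid_frac` valid pixels are skipped.
#'
#' @param map A `"fret_map"` (matrices `E`, `valid`) or `"lifetime_map"`
#'   (`tau`, `valid`).
#' @param masks A logical matrix, or a list of logical matrices (one ROI
#'   each, optionally named), or a list of lists with `$mask`/`$label`.
#' @param side Segment side in pixels (default 10, i.e. 100-pixel segments).
#' @param seg_bin_width Segment-level histogram bin width (default 0.01 for
#'   efficiencies; use ~0.05 ns for lifetimes).
#' @param meta_bin_width Meta-histogram bin width (default 0.02).
#' @param min_valid_frac Minimum fraction of valid pixels for a segment to
#'   contribute (default 0.5).
#' @param n_components Gaussian components for the meta-histogram fit.
#' @return An object of class `"fret_spectrogram"`: per-segment `peaks`
#'   (data.frame with `roi_label`, `segment_index`, `peak`), the
#'   `meta_histogram`, the Gaussian `fit`, and `mean`/`sd` shortcuts.
#' @export
fret_spectrogram <- function(map, masks, side = 10L, seg_bin_width = 0.01,
                             meta_bin_width = 0.02, min_valid_frac = 0.5,
                             n_components = 1L) {
  values <- if (!is.null(map$E)) map$E else map$tau
  if (is.null(values)) stop("map must carry an E or tau matrix")
  valid <- map$valid
  masks <- as_mask_list(masks)
  peaks <- data.frame(roi_label = character(), segment_index = integer(),
                      peak = numeric())
  for (m in masks) {
    segs <- suppressWarnings(segment_roi(m$mask, side = side, label = m$label))
    if (segs$n_segments == 0L) next
    for (k in seq_len(segs$n_segments)) {
      v <- segment_values(segs, values, valid, k)
      if (length(v) < min_valid_frac * side^2) next
      peaks <- rbind(peaks, data.frame(
        roi_label = m$label, segment_index = k,
        peak = histogram_peak(v, seg_bin_width)))
    }
  }
  if (!nrow(peaks)) stop("no segment produced a peak (ROIs too small or too ",
                         "few valid pixels)")
  meta <- build_meta_histogram(peaks$peak, bin_width = meta_bin_width)
  fit <- fit_gaussian_or_moments(meta, n_components = n_components)
  structure(list(peaks = peaks, meta_histogram = meta, fit = fit,
                 mean = fit$mean[which.max(fit$amplitude)],
                 sd = fit$sd[which.max(fit$amplitude)],
                 n_segments = nrow(peaks)),
            class = "fret_spectrogram")
}

#' @export
print.fret_spectrogram <- function(x, ...) {
  cat(sprintf("FRET spectrogram: %d segments from %d ROI(s)\n",
              x$n_segments, length(unique(x$peaks$roi_label))))
  print(x$fit)
  invisible(x)
}

#' @export
plot.fret_spectrogram <- function(x, ...) {
  plot(x$meta_histogram, fit = x$fit, ...)
}

# normalize the accepted mask inputs to list(list(mask=, label=), ...)
as_mask_list <- function(masks) {
  if (is.matrix(masks)) masks <- list(masks)
  if (!is.list(masks) || !length(masks)) stop("masks must be a non-empty ",
                                              "matrix or list of matrices")
  nm <- names(masks)
  lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    if (is.list(m) && !is.null(m$mask))
      return(list(mask = m$mask,
                  label = if (!is.null(m$label)) m$label else paste0("roi", i)))
    list(mask = m,
         label = if (!is.null(nm) && nzchar(nm[i])) nm[i] else paste0("roi", i))
  })
}

#' Donor reference lifetime from donor-only lifetime maps
#'
#' Runs the spectrogram chain (segmentation, per-segment lifetime histogram
#' peaks, meta-histogram, single-Gaussian fit) over one or more donor-only
#' lifetime maps and returns the fitted mean as the donor reference lifetime
#' `tau_D` with its Gaussian sd. When the per-segment peaks are quantised
#' into too few meta-histogram bins for a Gaussian fit (e.g. a noiseless
#' uniform map), the count-weighted mean is returned with
#' `sd = bin_width / 2` and `degenerate = TRUE`.
#'
#' @param maps A `"lifetime_map"` or list of them (see
#'   [compute_lifetime_map()]).
#' @param masks ROI masks matching `maps` — one mask (or list of masks) per
#'   map; a bare matrix/list is recycled across maps.
#' @param side,seg_bin_width,meta_bin_width,min_valid_frac As in
#'   [fret_spectrogram()]; bin widths default to 0.05 ns for lifetimes.
#' @return An object of class `"donor_reference"`: `tau_D`, `sd`,
#'   `degenerate`, and the underlying `spectrogram`.
#' @export
donor_lifetime_from_maps <- function(maps, masks, side = 10L,
                                     seg_bin_width = 0.05,
                                     meta_bin_width = 0.05,
                                     min_valid_frac = 0.5) {
  if (inherits(maps, "lifetime_map")) maps <- list(maps)
  if (!length(maps)) stop("no lifetime maps supplied")
  if (inherits(masks, "lifetime_map")) stop("masks must be ROI masks")
  per_map_masks <- if (is.list(masks) && length(masks) == length(maps) &&
                       !is.matrix(masks[[1]])) masks else
    rep(list(masks), length(maps))
  all_peaks <- NULL
  for (i in seq_along(maps)) {
    sp <- tryCatch(
      fret_spectrogram(maps[[i]], per_map_masks[[i]], side = side,
                       seg_bin_width = seg_bin_width,
                       meta_bin_width = meta_bin_width,
                       min_valid_frac = min_valid_frac),
      error = function(e) NULL)
    if (!is.null(sp)) {
      sp$peaks$roi_label <- paste0("map", i, ":", sp$peaks$roi_label)
      all_peaks <- rbind(all_peaks, sp$peaks)
    }
  }
  if (is.null(all_peaks) || !nrow(all_peaks))
    stop("no segments found in any donor map")
  meta <- build_meta_histogram(all_peaks$peak, bin_width = meta_bin_width)
  fit <- fit_gaussian_or_moments(meta)
  structure(list(tau_D = fit$mean[which.max(fit$amplitude)],
                 sd = fit$sd[which.max(fit$amplitude)],
                 degenerate = isTRUE(fit$degenerate),
                 spectrogram = structure(
                   list(peaks = all_peaks, meta_histogram = meta, fit = fit,
                        mean = fit$mean[1], sd = fit$sd[1],
                        n_segments = nrow(all_peaks)),
                   class = "fret_spectrogram")),
            class = "donor_reference")
}

#' @export
print.donor_reference <- function(x, ...) {
  cat(sprintf("Donor reference lifetime: tau_D = %.4f ns (sd %.4f)%s\n",
              x$tau_D, x$sd,
              if (x$degenerate) " [degenerate meta-histogram]" else ""))
  invisible(x)
}

#' Inverse-variance weighted combination of experiments
#'
#' Combines per-experiment Gaussian results `(E_k, sigma_k)` into the
#' weighted mean `E = sum(E_k / sigma_k^2) / sum(1 / sigma_k^2)` and its
#' standard error `SEM = (sum(1 / sigma_k^2))^(-1/2)`.
#'
#' @param E Numeric vector of per-experiment means, or a list of
#'   `"fret_spectrogram"`/list objects with `mean` and `sd`.
#' @param sigma Numeric vector of per-experiment standard deviations
#'   (ignored when `E` is a list of objects).
#' @return An object of class `"combined_efficiency"`: `E`, `sem`, `k`.
#' @examples
#' combine_experiments(c(0.3, 0.6), c(0.1, 0.2))  # E = 0.36, sem ~ 0.0894
#' @export
combine_experiments <- function(E, sigma = NULL) {
  if (is.list(E)) {
    sigma <- vapply(E, function(r) r$sd[1], numeric(1))
    E <- vapply(E, function(r) r$mean[1], numeric(1))
  }
  stopifnot(length(E) == length(sigma), length(E) >= 1L)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all sigma_k must be positive and finite")
  w <- 1 / sigma^2
  structure(list(E = sum(w * E) / sum(w), sem = sum(w)^(-0.5),
                 k = length(E)),
            class = "combined_efficiency")
}

#' @export
print.combined_efficiency <- function(x, ...) {
  cat(sprintf("Combined efficiency over %d experiment(s): E = %.4f +/- %.4f (SEM)\n",
              x$k, x$E, x$sem))
  invisible(x)
}
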