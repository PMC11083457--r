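#' Moving-square segmentation of an ROI mask
#'
#' Partitions a region of interest into disjoint square segments of
#' `side x side` pixels (default 10x10 = 100 pixels) by a deterministic
#' greedy sweep: anchors are scanned row-major over the ROI bounding box and
#' a square is placed whenever all of its pixels are inside the ROI and not
#' yet assigned; otherwise the anchor advances by one pixel. Pixels never
#' covered by a square are dropped.
#'
#' @param mask Logical matrix (`TRUE` = inside the ROI), or an object with a
#'   `$mask` element.
#' @param side Square side length in pixels (default 10).
#' @param label Optional ROI label carried through to outputs.
#' @return An object of class `"segment_set"`: list with `seg_map` (integer
#'   matrix, `NA` outside any segment), `n_segments`, `side`, `label`, and
#'   `anchors` (top-left corners, 1-based).
#' @examples
#' m <- matrix(TRUE, 20, 20)
#' segment_roi(m, side = 10)$n_segments  # 4
#' @export
segment_roi <- function(mask, side = 10L, label = "roi") {
  if (is.list(mask) && !is.null(mask$mask)) {
    if (!is.null(mask$label)) label <- mask$label
    mask <- mask$mask
  }
  stopifnot(is.matrix(mask), is.logical(mask), side >= 2)
  side <- as.integer(side)
  seg_map <- matrix(NA_integer_, nrow(mask), ncol(mask))
  anchors <- NULL
  n <- 0L
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) && length(cols)) {
    free <- mask  # in-ROI and unassigned
    for (i in seq(min(rows), max(rows) - side + 1L)) {
      j <- min(cols)
      jmax <- max(cols) - side + 1L
      while (j <= jmax) {
        if (all(free[i:(i + side - 1L), j:(j + side - 1L)])) {
          n <- n + 1L
          seg_map[i:(i + side - 1L), j:(j + side - 1L)] <- n
          free[i:(i + side - 1L), j:(j + side - 1L)] <- FALSE
          anchors <- rbind(anchors, c(i, j))
          j <- j + side
        } else {
          j <- j + 1L
        }
      }
    }
  }
  if (n == 0L)
    warning("no ", side, "x", side, " square fits inside the ROI")
  structure(list(seg_map = seg_map, n_segments = n, side = side,
                 label = label, anchors = anchors),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("Segment set '%s': %d segments of %d x %d pixels\n",
              x$label, x$n_segments, x$side, x$side))
  invisible(x)
}

# values of `mat` falling in segment k (optionally only where `valid`)
segment_values <- function(segments, mat, valid = NULL, k) {
  sel <- !is.na(segments$seg_map) & segments$seg_map == k
  if (!is.null(valid)) sel <- sel & valid
  mat[sel]
}

#' Peak (modal bin centre) of a histogram of values
#'
#' Bins the values into fixed-width bins whose centres lie on integer
#' multiples of `bin_width` and returns the centre of the maximal-count bin.
#' Ties are broken toward the bin containing the median of the values, then
#' toward the lower bin, so the result is deterministic.
#'
#' @param values Numeric vector (FRET efficiencies or lifetimes).
#' @param bin_width Histogram bin width (same units as `values`).
#' @return The peak bin centre (a single number).
#' @export
histogram_peak <- function(values, bin_width) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no valid values to histogram")
  stopifnot(bin_width > 0)
  h <- aligned_hist(values, bin_width)
  top <- which(h$counts == max(h$counts))
  if (length(top) > 1L) {
    med_bin <- bin_index(stats::median(values), h$kmin, bin_width,
                         length(h$counts))
    top <- if (med_bin %in% top) med_bin else min(top)
  }
  h$centers[top]
}

# Histogram on fixed-width bins whose *centers* lie on integer multiples of
# bin_width (bin k covers [(k - 1/2) bw, (k + 1/2) bw)). Center alignment
# makes the grid independent of the data and lets values sitting exactly on
# a grid point (e.g. a constant map) reproduce that value as their peak.
aligned_hist <- function(values, bin_width) {
  k <- floor(values / bin_width + 0.5)  # half-up: bin k covers [(k-.5)bw, (k+.5)bw)
  kmin <- min(k); kmax <- max(k)
  nb <- kmax - kmin + 1L
  counts <- tabulate(k - kmin + 1L, nbins = nb)
  list(kmin = kmin, bin_width = bin_width, counts = counts,
       centers = (kmin:kmax) * bin_width,
       edges = (seq(kmin, kmax + 1L) - 0.5) * bin_width)
}

bin_index <- function(x, kmin, bin_width, nb) {
  pmin(pmax(floor(x / bin_width + 0.5) - kmin, 0) + 1L, nb)
}

#' Meta-histogram of per-segment peak values
#'
#' Second-level histogram: the distribution of the per-segment histogram
#' peaks across all segments of all ROIs in a sample. Its single-Gaussian
#' fit gives the sample's most probable FRET efficiency (or donor lifetime).
#'
#' Bins are fixed-width with centres on integer multiples of `bin_width`,
#' spanning the range of the peaks.
#'
#' @param peaks Numeric vector of per-segment peak values.
#' @param bin_width Meta-histogram bin width (default 0.02 for efficiencies).
#' @return An object of class `"meta_histogram"` with `bin_edges`, `centers`
#'   and `counts` (`sum(counts) == length(peaks)`).
#' @export
build_meta_histogram <- function(peaks, bin_width = 0.02) {
  peaks <- peaks[is.finite(peaks)]
  if (!length(peaks)) stop("no peaks to assemble into a meta-histogram")
  if (length(peaks) < 10L)
    warning("only ", length(peaks),
            " segment peaks; meta-histogram will be poorly determined")
  h <- aligned_hist(peaks, bin_width)
  structure(list(bin_edges = h$edges, centers = h$centers, counts = h$counts,
                 bin_width = bin_width, n = length(peaks)),
            class = "meta_histogram")
}

#' @export
print.meta_histogram <- function(x, ...) {
  cat(sprintf("Meta-histogram: %d peaks in %d bins of width %g over [%g, %g]\n",
              x$n, length(x$counts), x$bin_width,
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' @export
plot.meta_histogram <- function(x, fit = NULL, ...) {
  graphics::plot(x$centers, x$counts, type = "h", lwd = 3,
                 xlab = "peak value", ylab = "segments", ...)
  if (!is.null(fit)) {
    xx <- seq(min(x$bin_edges), max(x$bin_edges), length.out = 200)
    graphics::lines(xx, predict(fit, xx), col = 2)
  }
  invisible(x)
}
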