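# Shared fixtures: all test inputs are generated in code.

# standard acquisition axis: 256 bins over a 12.5 ns period, pulse at bin 16
ax_std <- function(n_bins = 256L, rise_bin = 16L) {
  time_axis(12.5 / n_bins, n_bins, period = 12.5, rise_bin = rise_bin)
}

# noiseless point-sampled mono-exponential counts:
# c_k = A * exp(-(t_k - t_rise)/tau) for t_k >= t_rise, plus background.
# Built directly from exp() so closed-form oracles stay independent of the
# package's own curve generator.
mono_counts <- function(A, tau, axis, background = 0) {
  tt <- bin_times(axis)
  tr <- axis$rise_bin * axis$bin_width
  ifelse(tt >= tr, A * exp(-(tt - tr) / tau), 0) + background
}

mix_counts <- function(a, tau, axis, background = 0) {
  out <- rep(background, axis$n_bins)
  for (i in seq_along(a)) out <- out + mono_counts(a[i], tau[i], axis)
  out
}

noiseless_decay <- function(counts, axis) {
  suppressWarnings(decay_curve(counts, axis))
}

# noiseless stack in which every pixel carries the same counts vector
uniform_stack <- function(counts, axis, rows = 4L, cols = 4L) {
  arr <- array(rep(counts, each = rows * cols), dim = c(rows, cols, axis$n_bins))
  flim_stack(arr, axis)
}

# discrete geometric-series area of a point-sampled mono-exponential over
# N bins starting at the rise bin (the independent closed form)
geom_area <- function(A, tau, axis) {
  N <- axis$n_bins - axis$rise_bin
  dt <- axis$bin_width
  A * dt * (1 - exp(-N * dt / tau)) / (1 - exp(-dt / tau))
}

geom_area_inf <- function(A, tau, axis) {
  dt <- axis$bin_width
  A * dt / (1 - exp(-dt / tau))
}

# random blob-like ROI: union of a few rectangles and an ellipse
random_mask <- function(nr = 40L, nc = 40L) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(sample(1:3, 1))) {
    r0 <- sample(nr - 12L, 1); c0 <- sample(nc - 12L, 1)
    m[r0:(r0 + sample(8:12, 1)), c0:(c0 + sample(8:12, 1))] <- TRUE
  }
  ce <- c(sample(10:(nr - 10), 1), sample(10:(nc - 10), 1))
  rd <- sample(5:12, 2)
  ell <- outer(((seq_len(nr) - ce[1]) / rd[1])^2,
               ((seq_len(nc) - ce[2]) / rd[2])^2, "+") <= 1
  m | ell
}
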