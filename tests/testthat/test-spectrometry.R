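test_that("moving-square segmentation tiles rectangles exactly", {
  s4 <- segment_roi(matrix(TRUE, 20, 20), side = 10)
  expect_identical(s4$n_segments, 4L)
  expect_identical(sum(!is.na(s4$seg_map)), 400L)
  expect_identical(as.integer(table(s4$seg_map)), rep(100L, 4))

  s1 <- segment_roi(matrix(TRUE, 10, 10), side = 10)
  expect_identical(s1$n_segments, 1L)
})

test_that("segmentation of an L-shape finds both arms", {
  m <- matrix(FALSE, 20, 20)
  m[1:10, 1:10] <- TRUE
  m[11:20, 11:20] <- TRUE
  segs <- segment_roi(m, side = 10)
  expect_identical(segs$n_segments, 2L)
  # independent oracle: brute-force enumeration of feasible 10x10 anchors
  feasible <- which(outer(1:11, 1:11, Vectorize(function(i, j)
    all(m[i:(i + 9), j:(j + 9)]))), arr.ind = TRUE)
  expect_identical(nrow(feasible), 2L)
  expect_setequal(paste(segs$anchors[, 1], segs$anchors[, 2]),
                  paste(feasible[, 1], feasible[, 2]))
})

test_that("segmentation invariants hold on random masks", {
  set.seed(99)
  for (rep in 1:20) {
    m <- random_mask()
    segs <- suppressWarnings(segment_roi(m, side = 10))
    if (segs$n_segments == 0L) next
    sizes <- table(segs$seg_map)
    expect_true(all(sizes == 100L))
    expect_true(all(m[!is.na(segs$seg_map)]))
  }
})

test_that("histogram peaks follow the modal bin with median-side tie-breaks", {
  expect_equal(histogram_peak(rep(0.40, 25), 0.05), 0.40)
  # 0.5 sits on a bin edge of the centre-aligned grid and bins upward, so
  # the modal values land in the bin centred 0.6 (covering [0.5, 0.7))
  v <- c(rep(0.1, 3), rep(0.5, 5), rep(0.9, 2))
  expect_equal(histogram_peak(v, 0.2), 0.6, tolerance = 1e-12)
  # tied modal bins centred 0.3 and 0.5 (bin width 0.1): the median falls
  # between them, so the lower bin wins
  tie_low <- c(0.27, 0.29, 0.31, 0.33, 0.46, 0.48, 0.50, 0.52)
  expect_equal(histogram_peak(tie_low, 0.1), 0.3)
  # same tie, but an extra high value drags the median into the 0.5 bin
  tie_med <- c(0.27, 0.29, 0.31, 0.46, 0.48, 0.50, 0.68)
  expect_equal(histogram_peak(tie_med, 0.1), 0.5)
  expect_error(histogram_peak(numeric(0), 0.1), "no valid values")
})

test_that("meta-histograms count every contributing segment", {
  mh <- build_meta_histogram(rep(0.35, 200), bin_width = 0.05)
  expect_identical(sum(mh$counts), 200L)
  expect_identical(sum(mh$counts > 0), 1L)
  expect_equal(mh$centers[which.max(mh$counts)], 0.35)

  expect_warning(one <- build_meta_histogram(0.5, 0.02), "poorly determined")
  expect_identical(sum(one$counts), 1L)
  expect_error(build_meta_histogram(numeric(0)), "no peaks")
})

test_that("binned peak distributions preserve the generating mean", {
  peaks <- withr::with_seed(11, rnorm(500, 0.4, 0.05))
  mh <- build_meta_histogram(peaks, bin_width = 0.02)
  binned_mean <- sum(mh$centers * mh$counts) / sum(mh$counts)
  expect_lt(abs(binned_mean - 0.4), 3 * 0.05 / sqrt(500))
})

test_that("gaussian fits recover exact and sampled meta-histograms", {
  centers <- seq(0.3, 0.8, by = 0.02)
  exact <- list(centers = centers, bin_width = 0.02,
                counts = 120 * exp(-(centers - 0.56)^2 / (2 * 0.06^2)))
  fit <- fit_gaussian(exact)
  expect_equal(fit$mean, 0.56, tolerance = 1e-6)
  expect_equal(fit$sd, 0.06, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  draws <- withr::with_seed(5, rnorm(2000, 0.39, 0.05))
  fit2 <- fit_gaussian(build_meta_histogram(draws, 0.02))
  expect_lt(abs(fit2$mean - 0.39), 0.005)
  expect_lt(abs(fit2$sd - 0.05), 0.01)

  flat <- list(centers = centers, bin_width = 0.02,
               counts = rep(50, length(centers)))
  r2 <- tryCatch(fit_gaussian(flat)$r_squared, error = function(e) 0)
  expect_true(is.na(r2) || abs(r2) < 0.2)  # no structure to explain
  expect_error(fit_gaussian(list(centers = 0.4, counts = 10L,
                                 bin_width = 0.02)),
               "gaussian fit failed")
})

test_that("experiment combination implements the inverse-variance forms", {
  eq <- combine_experiments(c(0.3, 0.4, 0.5), rep(0.05, 3))
  expect_equal(eq$E, 0.4)
  expect_equal(eq$sem, 0.05 / sqrt(3))

  one <- combine_experiments(0.42, 0.07)
  expect_equal(one$E, 0.42)
  expect_equal(one$sem, 0.07)

  two <- combine_experiments(c(0.3, 0.6), c(0.1, 0.2))
  expect_equal(two$E, 0.36)
  expect_equal(two$sem, 125^-0.5)

  expect_error(combine_experiments(c(0.3, 0.4), c(0.1, 0)), "positive")
})

test_that("experiment combination is permutation- and scale-consistent", {
  E <- c(0.31, 0.44, 0.52, 0.38); s <- c(0.05, 0.08, 0.03, 0.06)
  a <- combine_experiments(E, s)
  b <- combine_experiments(rev(E), rev(s))
  expect_equal(a$E, b$E)
  expect_equal(a$sem, b$sem)
  c3 <- combine_experiments(E, 3 * s)
  expect_equal(c3$E, a$E)
  expect_equal(c3$sem, 3 * a$sem)
  expect_true(a$E >= min(E) && a$E <= max(E))
})

test_that("donor lifetime extraction handles degenerate uniform maps", {
  lmap <- structure(list(tau = matrix(2.8, 20, 20),
                         valid = matrix(TRUE, 20, 20)),
                    class = "lifetime_map")
  donor <- suppressWarnings(donor_lifetime_from_maps(lmap, matrix(TRUE, 20, 20)))
  expect_equal(donor$tau_D, 2.8)
  expect_equal(donor$sd, 0.05 / 2)
  expect_true(donor$degenerate)
  expect_error(donor_lifetime_from_maps(list(), matrix(TRUE, 2, 2)),
               "no lifetime maps")
})

test_that("the spectrogram chain recovers a simulated efficiency", {
  spec <- sim_spec(
    regions = list(list(shape = "rect", corners = c(2, 41, 2, 41),
                        config = oligomer_config("ADN", rel_rates = 1.0))),
    image_shape = c(42, 42), photons_per_pixel = 1e4, seed = 55)
  sim <- simulate_flim_stack(spec)
  map <- compute_fret_map(sim$stack, 3.0, method = "tifret")
  sp <- fret_spectrogram(map, sim$truth$masks[[1]])
  expect_gte(sp$n_segments, 16)
  expect_lt(abs(sp$mean - 0.5), 0.02)
  expect_identical(sum(sp$meta_histogram$counts), sp$n_segments)
})
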