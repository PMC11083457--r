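test_that("background is the mean of the pre-pulse window", {
  ax <- ax_std(64L, rise_bin = 8L)
  dc <- noiseless_decay(c(rep(5, 8), mono_counts(1000, 3, ax)[-(1:8)]), ax)
  expect_equal(estimate_background(dc, pre_bins = 3), 5)
  expect_equal(estimate_background(dc), 5)  # default window

  dz <- noiseless_decay(c(rep(0, 8), mono_counts(1000, 3, ax)[-(1:8)]), ax)
  expect_equal(estimate_background(dz, pre_bins = 8), 0)

  ax0 <- ax_std(64L, rise_bin = 0L)
  d0 <- noiseless_decay(mono_counts(1000, 3, ax0), ax0)
  expect_error(estimate_background(d0), "no pre-pulse")
})

test_that("background estimate converges to the Poisson rate", {
  ax <- time_axis(12.5 / 256, 256, rise_bin = 128L)
  bg <- withr::with_seed(42, {
    cts <- c(rpois(128, 4), round(mono_counts(500, 1.5, ax)[-(1:128)]) + 4)
    estimate_background(decay_curve(cts, ax), pre_bins = 64)
  })
  expect_lt(abs(bg - 4), 3 * sqrt(4 / 64))
})

test_that("amplitude estimation: peak and headfit agree on noiseless data", {
  ax <- ax_std()
  dc <- noiseless_decay(mono_counts(1000, 2.5, ax, background = 10), ax)
  pk <- estimate_amplitude(dc, 10, method = "peak")
  expect_equal(pk$p0, 1000)
  expect_identical(pk$method_tag, "peak")
  hf <- estimate_amplitude(dc, 10, method = "headfit", head_bins = 20)
  expect_equal(hf$p0, 1000, tolerance = 1e-9)
  expect_identical(hf$method_tag, "headfit")
})

test_that("amplitude estimation errors on empty or degenerate decays", {
  ax <- ax_std(64L, rise_bin = 8L)
  flat <- noiseless_decay(rep(5, 64), ax)
  expect_error(estimate_amplitude(flat, 5), "empty decay")
  spike <- noiseless_decay(c(rep(0, 30), 100, rep(0, 33)), ax)
  expect_error(estimate_amplitude(spike, 0, method = "headfit"),
               "underdetermined")
})

test_that("peak amplitude is biased above headfit on Poisson data", {
  ax <- ax_std()
  ests <- vapply(1:100, function(s) {
    dc <- simulate_decay(1, 3.0, ax, 1e5, seed = s)
    c(estimate_amplitude(dc, 0, "peak")$p0,
      estimate_amplitude(dc, 0, "headfit")$p0)
  }, numeric(2))
  expect_gt(mean(ests[1, ]), mean(ests[2, ]))
})

test_that("decay integration matches the geometric-series closed forms", {
  ax <- ax_std(rise_bin = 0L)
  for (tau in c(1.0, 2.0, 3.0)) {
    dc <- noiseless_decay(mono_counts(800, tau, ax), ax)
    a0 <- integrate_decay(dc, 0, tail_mode = "none")
    expect_equal(a0$area, geom_area(800, tau, ax), tolerance = 1e-10)
    expect_identical(a0$tail_fraction, 0)
    a1 <- integrate_decay(dc, 0, tail_mode = "monoexp")
    expect_equal(a1$area, geom_area_inf(800, tau, ax), tolerance = 1e-3)
    expect_gt(a1$tail_fraction, 0)
  }
})

test_that("integration rejects empty decays", {
  ax <- ax_std(64L, rise_bin = 8L)
  expect_error(integrate_decay(noiseless_decay(rep(7, 64), ax), 7),
               "empty decay")
})

test_that("single-exponential fits recover noiseless lifetimes exactly", {
  ax <- ax_std()
  dc <- noiseless_decay(mono_counts(1000, 3.0, ax), ax)
  fit <- fit_exponentials(dc, p = 1, background = 0)
  expect_lt(abs(fit$lifetimes - 3.0), 1e-3)
  expect_equal(fit$amplitudes, 1000, tolerance = 1e-2)
  # headfit amplitude and the fit amplitude agree within 1%
  hf <- estimate_amplitude(dc, 0, "headfit")
  expect_lt(abs(fit$amplitudes / hf$p0 - 1), 0.01)
})

test_that("fits are invariant to an exactly-known constant background", {
  ax <- ax_std()
  base <- mono_counts(1000, 2.2, ax)
  f0 <- fit_exponentials(noiseless_decay(base, ax), 1, background = 0)
  f9 <- fit_exponentials(noiseless_decay(base + 9, ax), 1, background = 9)
  expect_equal(f0$lifetimes, f9$lifetimes, tolerance = 1e-4)
  expect_equal(f0$amplitudes, f9$amplitudes, tolerance = 1e-3)
})

test_that("two-exponential fits separate well-spaced lifetimes", {
  ax <- ax_std()
  dc <- noiseless_decay(mix_counts(c(5000, 5000), c(1.0, 3.0), ax), ax)
  fit <- fit_exponentials(dc, p = 2, background = 0)
  expect_identical(fit$p, 2L)
  expect_false(fit$collapsed)
  expect_lt(abs(fit$lifetimes[1] - 1.0), 0.1)
  expect_lt(abs(fit$lifetimes[2] - 3.0), 0.3)
  expect_true(all(diff(fit$lifetimes) > 0))
})

test_that("degenerate two-component data collapse to one lifetime", {
  ax <- ax_std()
  dc <- noiseless_decay(mono_counts(2000, 2.5, ax), ax)
  fit <- fit_exponentials(dc, p = 2, background = 0)
  skip_if(!fit$collapsed && fit$p == 2L,
          "optimizer kept two nearly-equal components")
  expect_identical(fit$p, 1L)
  expect_true(fit$collapsed)
  expect_lt(abs(fit$lifetimes - 2.5), 0.01)
})

test_that("flat curves and starved pixels refuse to fit", {
  ax <- ax_std(64L, rise_bin = 8L)
  expect_error(fit_exponentials(noiseless_decay(rep(3, 64), ax), 1,
                                background = 3),
               "fit failed")
  dim_dc <- simulate_decay(1, 3, ax_std(), 50, seed = 1)
  expect_error(fit_exponentials(dim_dc, 1, background = 0), "fit failed")
})

test_that("fitted lifetimes are unbiased on Poisson mono-exponentials", {
  ax <- ax_std()
  taus <- vapply(1:200, function(s) {
    dc <- simulate_decay(1, 3.0, ax, 1e4, background_rate = 0.5, seed = s)
    fit_exponentials(dc, 1)$lifetimes
  }, numeric(1))
  expect_lt(abs(mean(taus) / 3.0 - 1), 0.02)
})

test_that("mean_lifetime is the amplitude-weighted average", {
  expect_equal(mean_lifetime(list(amplitudes = 1, lifetimes = 3.0)), 3.0)
  expect_equal(mean_lifetime(list(amplitudes = c(1, 1), lifetimes = c(1, 3))), 2.0)
  expect_equal(mean_lifetime(list(amplitudes = c(3, 1), lifetimes = c(2, 4))), 2.5)
})

test_that("decay_fit methods expose coefficients and predictions", {
  ax <- ax_std()
  dc <- noiseless_decay(mono_counts(1000, 3.0, ax, background = 5), ax)
  fit <- fit_exponentials(dc, 1, background = 5)
  cf <- coef(fit)
  expect_named(cf, c("a1", "tau1"))
  pred <- predict(fit)
  expect_length(pred, ax$n_bins)
  expect_lt(max(abs(pred - dc$counts) / pmax(dc$counts, 1)), 0.01)
})
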