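test_that("lifetime-ratio efficiency follows 1 - tau_DA/tau_D", {
  expect_equal(fret_from_lifetime(3.0, 3.0), 0.0)
  expect_equal(fret_from_lifetime(1.5, 3.0), 0.5)
  expect_equal(fret_from_lifetime(1.95, 3.0), 0.35)
  expect_error(fret_from_lifetime(-1, 3.0))
  expect_error(fret_from_lifetime(1, 0))
})

test_that("mixture efficiency uses the amplitude-weighted mean lifetime", {
  expect_equal(fret_from_mixture(list(amplitudes = 1, lifetimes = 2.4), 3.0),
               0.2)
  expect_equal(fret_from_mixture(list(amplitudes = c(1, 1),
                                      lifetimes = c(1, 3)), 4.0), 0.5)
  expect_equal(fret_from_mixture(list(amplitudes = c(3, 1),
                                      lifetimes = c(2, 4)), 5.0), 0.5)
})

test_that("integral efficiency matches the lifetime route on exact curves", {
  expect_equal(fret_from_integral(2.0, 1.0, tau_D = 4.0), 0.5)

  # fine time base so the bin-sum discretisation is negligible
  ax <- time_axis(12.5 / 4096, 4096, rise_bin = 0L)
  for (tau in c(3.0, 1.95)) {
    dc <- noiseless_decay(mono_counts(1e4, tau, ax), ax)
    a <- integrate_decay(dc, 0, tail_mode = "monoexp")
    p0 <- estimate_amplitude(dc, 0, "headfit")
    E <- fret_from_integral(a, p0, tau_D = 3.0)
    expect_lt(abs(E - (1 - tau / 3.0)), 1e-3)
  }

  # the geometric correction is exact even on a coarse axis
  axc <- ax_std(rise_bin = 0L)
  dc <- noiseless_decay(mono_counts(1000, 2.0, axc), axc)
  E <- fret_from_integral(integrate_decay(dc, 0, "monoexp"),
                          estimate_amplitude(dc, 0, "headfit"),
                          tau_D = 3.0, bin_width = axc$bin_width,
                          correction = "geometric")
  expect_equal(E, 1 / 3, tolerance = 1e-6)
})

test_that("efficiency is monotone in the lifetime and in the area ratio", {
  tau_grid <- seq(0.3, 2.9, by = 0.2)
  E1 <- fret_from_lifetime(tau_grid, 3.0)
  expect_true(all(diff(E1) < 0))
  ratios <- seq(0.5, 3, by = 0.25)
  E3 <- vapply(ratios, function(r) fret_from_integral(r, 1, 4), numeric(1))
  expect_true(all(diff(E3) < 0))
})

test_that("the integral equals the amplitude-weighted mixture on exact curves", {
  # area / p(0) of sum(a_i exp(-t/tau_i)) is sum(a tau)/sum(a), so on exact
  # curves the integral route reproduces the mixture formula; the measured
  # estimate sits at or just below it (head-window curvature and bin
  # summation both nudge tau_eff upward, never downward)
  ax <- time_axis(12.5 / 4096, 4096, rise_bin = 0L)
  a <- c(3000, 1000); tau <- c(1.0, 3.0); tau_D <- 3.5
  dc <- noiseless_decay(mix_counts(a, tau, ax), ax)
  E3 <- fret_from_integral(integrate_decay(dc, 0, "monoexp"),
                           estimate_amplitude(dc, 0, "headfit"), tau_D)
  E2 <- fret_from_mixture(list(amplitudes = a, lifetimes = tau), tau_D)
  expect_lte(E3, E2 + 1e-9)
  expect_equal(E3, E2, tolerance = 5e-3)
  # exact-amplitude route: no headfit involved
  E3x <- fret_from_integral(integrate_decay(dc, 0, "monoexp")$area, sum(a),
                            tau_D)
  expect_equal(E3x, E2, tolerance = 1e-3)
})

test_that("all three estimators agree pixelwise on noiseless mono-exponential stacks", {
  ax <- time_axis(12.5 / 512, 512, rise_bin = 32L)
  stack <- uniform_stack(round(mono_counts(2e4, 2.1, ax)), ax)
  maps <- lapply(c("1exp", "2exp", "tifret"), function(m)
    compute_fret_map(stack, 3.0, method = m, tail_mode = "monoexp",
                     correction = "geometric", background = 0))
  expect_true(all(vapply(maps, function(m) all(m$valid), logical(1))))
  E_true <- 1 - 2.1 / 3.0
  for (m in maps) expect_lt(max(abs(m$E - E_true)), 1e-3)
})

test_that("FRET maps recover simulated ground truth", {
  spec <- sim_spec(
    regions = list(list(shape = "rect", corners = c(3, 30, 3, 30),
                        config = oligomer_config("NDA", rel_rates = 1.0))),
    image_shape = c(32, 32), photons_per_pixel = 1e4, seed = 101)
  sim <- simulate_flim_stack(spec)
  map <- compute_fret_map(sim$stack, 3.0, method = "tifret")
  inside <- sim$truth$masks[[1]] & map$valid
  expect_gt(sum(inside), 700)
  expect_lt(abs(median(map$E[inside]) - 0.5), 0.02)
})

test_that("donor-only stacks map to zero efficiency under the 1exp route", {
  spec <- sim_spec(regions = list(list(shape = "rect",
                                       corners = c(3, 26, 3, 26), tau = 3.0)),
                   image_shape = c(28, 28), photons_per_pixel = 1e4, seed = 7)
  sim <- simulate_flim_stack(spec)
  map <- compute_fret_map(sim$stack, 3.0, method = "1exp")
  inside <- sim$truth$masks[[1]] & map$valid
  expect_lt(abs(median(map$E[inside])), 0.02)
})

test_that("dark stacks yield maps with no valid pixel", {
  ax <- ax_std(64L)
  dark <- flim_stack(array(0L, dim = c(6, 6, 64)), ax)
  map <- compute_fret_map(dark, 3.0, method = "tifret")
  expect_false(any(map$valid))
})

test_that("lifetime maps recover per-region lifetimes", {
  spec <- sim_spec(
    regions = list(list(shape = "rect", corners = c(2, 13, 2, 23), tau = 2.0),
                   list(shape = "rect", corners = c(16, 27, 2, 23), tau = 3.0)),
    image_shape = c(28, 24), photons_per_pixel = 1e4, background_rate = 0,
    seed = 31)
  sim <- simulate_flim_stack(spec)
  lmap <- compute_lifetime_map(sim$stack)
  m1 <- median(lmap$tau[sim$truth$masks[[1]] & lmap$valid])
  m2 <- median(lmap$tau[sim$truth$masks[[2]] & lmap$valid])
  expect_lt(abs(m1 - 2.0), 0.03)
  expect_lt(abs(m2 - 3.0), 0.03)
  # starved pixels (outside both regions) are invalid
  outside <- !(sim$truth$masks[[1]] | sim$truth$masks[[2]])
  expect_false(any(lmap$valid[outside]))
})
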