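# Expected (noise-free) per-bin signal of a multi-exponential decay on a
# TCSPC axis. Each bin receives the exact integral of
# sum_i a_i exp(-(t - t_rise)/tau_i) over the bin (not a midpoint sample),
# so closed-form oracles hold to machine precision. With wrap = TRUE the
# decay folds back modulo the repetition period (incomplete-decay
# acquisition): every bin also collects the geometric sum of the tails of
# all earlier pulses, and pre-rise bins see the previous pulse's tail.
expected_curve <- function(amplitudes, lifetimes, axis, irf_sigma = 0,
                           wrap = FALSE) {
  stopifnot(length(amplitudes) == length(lifetimes),
            all(amplitudes >= 0), all(lifetimes > 0))
  edges <- (0:axis$n_bins) * axis$bin_width
  tr <- rise_time(axis)
  y <- numeric(axis$n_bins)
  for (i in seq_along(amplitudes)) {
    tau <- lifetimes[i]
    base <- exp(-pmax(edges[-length(edges)] - tr, 0) / tau) -
      exp(-pmax(edges[-1] - tr, 0) / tau)
    contrib <- amplitudes[i] * tau * base
    if (wrap) {
      g <- 1 / (1 - exp(-axis$period / tau))
      # bins at/after the pulse: own-pulse term plus all earlier tails;
      # bins before the pulse: earlier tails only
      pre <- edges[-length(edges)] < tr - 1e-12
      shifted <- exp(-(edges[-length(edges)][pre] + axis$period - tr) / tau) -
        exp(-(edges[-1][pre] + axis$period - tr) / tau)
      contrib[pre] <- amplitudes[i] * tau * shifted
      contrib <- contrib * g
    }
    y <- y + contrib
  }
  if (irf_sigma > 0) {
    half <- max(1L, ceiling(5 * irf_sigma / axis$bin_width))
    kt <- (-half:half) * axis$bin_width
    kern <- exp(-kt^2 / (2 * irf_sigma^2))
    kern <- kern / sum(kern)
    n <- length(y)
    if (wrap) {
      idx <- outer(seq_len(n), -half:half, function(a, b) ((a - 1 + b) %% n) + 1)
      y <- as.numeric(matrix(y[idx], n) %*% kern)
    } else {
      padded <- c(numeric(half), y, numeric(half))
      y <- vapply(seq_len(n),
                  function(k) sum(padded[k:(k + 2L * half)] * rev(kern)),
                  numeric(1))
    }
  }
  y
}

#' Simulate one TCSPC decay histogram
#'
#' Draws Poisson photon counts per arrival-time bin around the exact
#' expected multi-exponential signal (per-bin integrals of
#' `sum a_i exp(-(t - t_rise)/tau_i)`), optionally blurred by a Gaussian
#' instrument response and wrapped modulo the repetition period. The signal
#' is scaled so the expected background-subtracted total equals
#' `total_photons`; a flat `background_rate` (counts/bin) is added
#' everywhere. Fully reproducible given `seed`.
#'
#' @param amplitudes,lifetimes Mixture components (relative amplitudes,
#'   lifetimes in ns).
#' @param axis A [time_axis()].
#' @param total_photons Expected background-subtracted photon total.
#' @param background_rate Background in counts/bin.
#' @param irf_sigma Gaussian IRF sigma in ns (0 disables).
#' @param wrap Fold the decay modulo the repetition period.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A [decay_curve()].
#' @examples
#' ax <- time_axis(12.5 / 256, 256, rise_bin = 16)
#' dc <- simulate_decay(1, 3.0, ax, total_photons = 1e4, seed = 1)
#' @export
simulate_decay <- function(amplitudes, lifetimes, axis, total_photons,
                           background_rate = 0, irf_sigma = 0, wrap = FALSE,
                           seed = NULL) {
  stopifnot(total_photons >= 0, background_rate >= 0)
  shape <- expected_curve(amplitudes, lifetimes, axis, irf_sigma, wrap)
  lambda <- if (sum(shape) > 0 && total_photons > 0)
    shape * (total_photons / sum(shape)) + background_rate
  else rep(background_rate, axis$n_bins)
  counts <- with_seed(seed, stats::rpois(axis$n_bins, lambda))
  decay_curve(counts, axis)
}

#' Specification of a synthetic FLIM acquisition
#'
#' Collects everything needed to generate a synthetic TCSPC image stack with
#' known ground truth. Defaults emulate a typical two-photon FLIM
#' acquisition: 256 x 256 pixels, 256 time bins spanning a 12.5 ns
#' repetition period (80 MHz laser), a 3.0 ns donor lifetime, 60 summed
#' 1-s frame scans, and log-normal pixel-to-pixel expression heterogeneity
#' (sd 0.3 in log10) around a mean photon budget of 1e4 photons/pixel.
#'
#' @param regions List of region definitions. Each is a list with a
#'   geometry — `shape = "rect"` with `corners = c(rmin, rmax, cmin, cmax)`,
#'   `shape = "ellipse"` with `center = c(r, c)` and `radii = c(rr, rc)`,
#'   or an explicit logical `mask` — plus the emitting species: either
#'   `config` (an [oligomer_config()], whose decay mixture and apparent
#'   efficiency follow from the kinetic theory), explicit `amplitudes` and
#'   `lifetimes`, or a single `tau` (donor-only), and an optional `label`.
#' @param image_shape `c(rows, cols)`.
#' @param axis A [time_axis()].
#' @param tau_D Donor-only lifetime in ns.
#' @param photons_per_pixel Mean of the log-normal per-pixel photon budget.
#' @param expression_sd_log10 sd of the log10 photon budget across pixels.
#' @param background_rate Background counts/bin added to every pixel.
#' @param irf_sigma Gaussian IRF sigma in ns (0 = off; the analysis chain
#'   does no deconvolution, so the default is off).
#' @param n_scans Number of frame scans summed into the stack.
#' @param acceptor_bleach_per_scan Fraction of intact oligomers whose
#'   acceptor photobleaches per scan (see [simulate_with_bleaching()]).
#' @param wrap Wrap decays modulo the repetition period.
#' @param seed Integer seed for the whole simulation.
#' @return An object of class `"sim_spec"`.
#' @export
sim_spec <- function(regions, image_shape = c(256L, 256L),
                     axis = time_axis(12.5 / 256, 256L, period = 12.5,
                                      rise_bin = 16L),
                     tau_D = 3.0, photons_per_pixel = 1e4,
                     expression_sd_log10 = 0.3, background_rate = 0.5,
                     irf_sigma = 0, n_scans = 60L,
                     acceptor_bleach_per_scan = 0, wrap = FALSE, seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1),
            inherits(axis, "time_axis"), tau_D > 0, photons_per_pixel > 0,
            expression_sd_log10 >= 0, background_rate >= 0, n_scans >= 1,
            acceptor_bleach_per_scan >= 0, acceptor_bleach_per_scan < 1)
  if (!is.list(regions) || !length(regions)) stop("at least one region required")
  if (!is.null(regions$shape) || !is.null(regions$mask))
    regions <- list(regions)  # single region passed bare
  structure(list(regions = regions, image_shape = as.integer(image_shape),
                 axis = axis, tau_D = tau_D,
                 photons_per_pixel = photons_per_pixel,
                 expression_sd_log10 = expression_sd_log10,
                 background_rate = background_rate, irf_sigma = irf_sigma,
                 n_scans = as.integer(n_scans),
                 acceptor_bleach_per_scan = acceptor_bleach_per_scan,
                 wrap = wrap, seed = seed),
            class = "sim_spec")
}

# logical mask of one region definition
region_mask <- function(region, image_shape) {
  if (!is.null(region$mask)) {
    m <- region$mask
    stopifnot(is.matrix(m), all(dim(m) == image_shape))
    return(m)
  }
  shape <- if (!is.null(region$shape)) region$shape else "rect"
  m <- matrix(FALSE, image_shape[1], image_shape[2])
  if (shape == "rect") {
    cr <- as.integer(region$corners)
    stopifnot(length(cr) == 4L, cr[1] >= 1, cr[2] <= image_shape[1],
              cr[3] >= 1, cr[4] <= image_shape[2])
    m[cr[1]:cr[2], cr[3]:cr[4]] <- TRUE
  } else if (shape == "ellipse") {
    ce <- region$center; rd <- region$radii
    rr <- outer(((seq_len(image_shape[1]) - ce[1]) / rd[1])^2,
                ((seq_len(image_shape[2]) - ce[2]) / rd[2])^2, "+")
    m <- rr <= 1
  } else stop("unknown region shape: ", shape)
  m
}

# decay mixture and apparent efficiency of one region definition
region_mixture <- function(region, tau_D) {
  if (!is.null(region$config)) {
    mix <- decay_mixture(region$config, tau_D)
    E <- config_apparent_efficiency(region$config)
  } else if (!is.null(region$amplitudes)) {
    stopifnot(length(region$amplitudes) == length(region$lifetimes))
    mix <- list(amplitudes = region$amplitudes / sum(region$amplitudes),
                lifetimes = region$lifetimes)
    E <- 1 - mean_lifetime(mix) / tau_D
  } else if (!is.null(region$tau)) {
    mix <- list(amplitudes = 1, lifetimes = region$tau)
    E <- 1 - region$tau / tau_D
  } else stop("region needs a config, amplitudes/lifetimes, or tau")
  list(mix = mix, E = E)
}

#' Simulate a FLIM image stack with known ground truth
#'
#' Builds per-pixel decay histograms for each region of a [sim_spec()]:
#' the region's decay mixture (from its oligomer configuration via the
#' kinetic theory, or given explicitly) sets the expected curve shape,
#' each pixel draws a log-normal photon budget (expression heterogeneity),
#' and counts are Poisson. Out-of-region pixels receive background only.
#' Deterministic for a given spec and seed.
#'
#' @param spec A [sim_spec()].
#' @return A list with `stack` (a [flim_stack()]) and `truth`: `E_true`
#'   (matrix, `NA` outside regions), per-region `labels`, `mixtures`, and
#'   `masks`.
#' @export
simulate_flim_stack <- function(spec) {
  simulate_stack_impl(spec, bleach = FALSE)
}

#' Simulate an acquisition with acceptor photobleaching across scans
#'
#' Same acquisition model as [simulate_flim_stack()], but the stack is the
#' sum of `n_scans` frame scans during which acceptors photobleach: after
#' scan s, a fraction `(1 - beta)^s` of oligomers still carry an intact
#' acceptor (`beta = acceptor_bleach_per_scan`), and oligomers with a
#' bleached acceptor decay with the unquenched donor lifetime. Each scan
#' therefore contributes a mixture of FRET and FRET-lost decays; the summed
#' stack has FRET weight `mean((1 - beta)^s)`. With `beta = 0` the result
#' is bit-identical to [simulate_flim_stack()] at the same seed. The truth
#' records both the pre-bleach `E_true` and the effective
#' (amplitude-weighted) efficiency of the summed mixture, `E_effective`.
#'
#' @param spec A [sim_spec()] with `acceptor_bleach_per_scan` set.
#' @return As [simulate_flim_stack()], with `truth$E_effective` added.
#' @export
simulate_with_bleaching <- function(spec) {
  simulate_stack_impl(spec, bleach = TRUE)
}

simulate_stack_impl <- function(spec, bleach) {
  stopifnot(inherits(spec, "sim_spec"))
  d <- spec$image_shape
  nb <- spec$axis$n_bins
  masks <- lapply(spec$regions, region_mask, image_shape = d)
  cover <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(cover > 1L)) stop("regions overlap")
  info <- lapply(spec$regions, region_mixture, tau_D = spec$tau_D)

  beta <- if (bleach) spec$acceptor_bleach_per_scan else 0
  w_fret <- mean((1 - beta)^seq_len(spec$n_scans))

  E_true <- matrix(NA_real_, d[1], d[2])
  E_eff <- matrix(NA_real_, d[1], d[2])
  lambda <- matrix(spec$background_rate, d[1] * d[2], nb)
  corr <- exp(-(spec$expression_sd_log10 * log(10))^2 / 2)  # lognormal mean

  draw <- function() {
    for (r in seq_along(spec$regions)) {
      mix <- info[[r]]$mix
      eff_mix <- if (w_fret < 1) {
        list(amplitudes = c(w_fret * mix$amplitudes, 1 - w_fret),
             lifetimes = c(mix$lifetimes, spec$tau_D))
      } else mix
      shape <- expected_curve(eff_mix$amplitudes, eff_mix$lifetimes,
                              spec$axis, spec$irf_sigma, spec$wrap)
      shape <- shape / sum(shape)
      idx <- which(masks[[r]])
      budget <- spec$photons_per_pixel * corr *
        10^stats::rnorm(length(idx), 0, spec$expression_sd_log10)
      lambda[idx, ] <<- lambda[idx, ] + budget %o% shape
      E_true[masks[[r]]] <<- info[[r]]$E
      E_eff[masks[[r]]] <<- 1 - mean_lifetime(eff_mix) / spec$tau_D
    }
    array(stats::rpois(length(lambda), lambda), dim = c(d[1], d[2], nb))
  }
  counts <- with_seed(spec$seed, draw())

  truth <- list(E_true = E_true,
                labels = vapply(seq_along(spec$regions), function(r) {
                  lb <- spec$regions[[r]]$label
                  if (is.null(lb)) paste0("region", r) else lb
                }, character(1)),
                mixtures = lapply(info, `[[`, "mix"),
                masks = masks, tau_D = spec$tau_D)
  if (bleach) truth$E_effective <- E_eff
  list(stack = flim_stack(counts, spec$axis), truth = truth)
}
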