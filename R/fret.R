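#' FRET efficiency from a single donor lifetime
#'
#' Classical FLIM-FRET: `E = 1 - tau_DA / tau_D`, where `tau_DA` is the
#' donor lifetime in the presence of acceptors and `tau_D` the lifetime of
#' the donor alone.
#'
#' @param tau_DA Donor lifetime in the presence of acceptors (ns).
#' @param tau_D Donor-only lifetime (ns).
#' @return FRET efficiency (dimensionless). Vectorised over `tau_DA`.
#' @examples
#' fret_from_lifetime(1.95, 3.0)  # 0.35
#' @export
fret_from_lifetime <- function(tau_DA, tau_D) {
  stopifnot(all(tau_DA > 0), tau_D > 0)
  1 - tau_DA / tau_D
}

#' FRET efficiency from a multi-exponential fit
#'
#' Replaces the single lifetime with the amplitude-weighted mean of the
#' fitted components:
#' `E = 1 - (sum(a_i * tau_i) / sum(a_i)) / tau_D`.
#' With one component this reduces exactly to [fret_from_lifetime()].
#'
#' @param fit A `"decay_fit"` (or list with `amplitudes`, `lifetimes`).
#' @param tau_D Donor-only lifetime (ns).
#' @return FRET efficiency (dimensionless).
#' @export
fret_from_mixture <- function(fit, tau_D) {
  stopifnot(tau_D > 0)
  1 - mean_lifetime(fit) / tau_D
}

#' Time-integrated FRET efficiency
#'
#' Computes `E = 1 - tau_eff / tau_D` with `tau_eff = area / p0`: the area
#' under the background-subtracted decay (counts·ns, from
#' [integrate_decay()]) divided by its amplitude (counts/bin, from
#' [estimate_amplitude()]). No exponential-component count has to be chosen,
#' which is the point of the time-integrated method.
#'
#' Because the area is a discrete bin sum, `tau_eff` for a mono-exponential
#' equals `bin_width / (1 - exp(-bin_width/tau))`, i.e. it overestimates
#' `tau` by about `bin_width/2`. The default reproduces the literal integral
#' formula; `correction = "geometric"` inverts the geometric series,
#' `tau = -bin_width / log(1 - p0 * bin_width / area)`, which is exact for
#' mono-exponential decays (requires `bin_width`).
#'
#' @param area A `"decay_area"` (or its numeric `area` in counts·ns).
#' @param p0 An `"amplitude_estimate"` (or its numeric `p0` in counts/bin).
#' @param tau_D Donor-only lifetime (ns).
#' @param bin_width Bin width in ns; required for `correction = "geometric"`.
#' @param correction `"none"` (literal) or `"geometric"`.
#' @return FRET efficiency (dimensionless).
#' @examples
#' fret_from_integral(2.0, 1.0, tau_D = 4.0)  # 0.5
#' @export
fret_from_integral <- function(area, p0, tau_D, bin_width = NULL,
                               correction = c("none", "geometric")) {
  correction <- match.arg(correction)
  if (inherits(area, "decay_area")) area <- area$area
  if (inherits(p0, "amplitude_estimate")) p0 <- p0$p0
  stopifnot(area > 0, p0 > 0, tau_D > 0)
  tau_eff <- if (correction == "geometric") {
    if (is.null(bin_width)) stop("geometric correction requires bin_width")
    arg <- 1 - p0 * bin_width / area
    if (arg <= 0) return(NA_real_)
    -bin_width / log(arg)
  } else {
    area / p0
  }
  1 - tau_eff / tau_D
}
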