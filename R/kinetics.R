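#' Relative FRET rate from an efficiency
#'
#' Inverts `E = x / (1 + x)`: for a donor transferring to a single acceptor
#' with relative rate `x = Gamma_FRET / Gamma_D` (transfer rate over the
#' donor's intrinsic de-excitation rate), the efficiency is `x / (1 + x)`,
#' so `x = E / (1 - E)`.
#'
#' @param E FRET efficiency in `[0, 1)`. Vectorised.
#' @return Relative rate `x` (dimensionless, >= 0).
#' @export
rate_from_efficiency <- function(E) {
  stopifnot(all(E >= 0), all(E < 1))
  E / (1 - E)
}

#' Efficiency of one donor transferring to several acceptors
#'
#' Rate additivity: a donor that can transfer to acceptors with relative
#' rates `x_a` de-excites through FRET with total relative rate `sum(x)`,
#' giving `E = sum(x) / (1 + sum(x))`. An empty rate list (no acceptors)
#' gives `E = 0`.
#'
#' @param rates Numeric vector of relative rates `x_a >= 0` (may be empty).
#' @return The donor's FRET efficiency.
#' @export
donor_efficiency <- function(rates) {
  stopifnot(all(rates >= 0))
  s <- sum(rates)
  s / (1 + s)
}

#' Predict the two-acceptor efficiency from two single-acceptor efficiencies
#'
#' For a donor flanked by two acceptors (the ADA arrangement), rate
#' additivity composes the two single-acceptor efficiencies `E1`, `E2`
#' (measured on constructs where one acceptor is replaced by a
#' non-fluorescent placeholder) into
#' \deqn{E_{ADA} = \frac{E_1 + E_2 - 2 E_1 E_2}{1 - E_1 E_2},}
#' symmetric in its arguments and never below `max(E1, E2)`.
#'
#' @param E1,E2 Single-acceptor efficiencies in `[0, 1)`.
#' @return Predicted two-acceptor efficiency.
#' @examples
#' predict_two_acceptor_E(0.33, 0.32)  # ~0.49
#' @export
predict_two_acceptor_E <- function(E1, E2) {
  donor_efficiency(c(rate_from_efficiency(E1), rate_from_efficiency(E2)))
}

#' Donor/acceptor configuration of an oligomer
#'
#' Describes one way of placing donors (D), acceptors (A) and non-fluorescent
#' placeholders (N) on the sites of an oligomer, together with the pairwise
#' relative FRET rates `x[d, a] = Gamma_FRET(d -> a) / Gamma_D` for every
#' donor site d and acceptor site a. Rates between pairs that are not
#' (donor, acceptor) are ignored and may be left 0 or NA.
#'
#' @param roles Character vector over sites with entries `"D"`, `"A"`, `"N"`,
#'   or a single string such as `"ADA"`.
#' @param rel_rates Square numeric matrix (`n_sites x n_sites`) of relative
#'   rates, or a single number applied to every donor-acceptor pair.
#' @return An object of class `"oligomer_config"`.
#' @examples
#' cfg <- oligomer_config("ADA", rel_rates = 0.5)
#' config_apparent_efficiency(cfg)
#' @export
oligomer_config <- function(roles, rel_rates) {
  if (is.character(roles) && length(roles) == 1L && nchar(roles) > 1L)
    roles <- strsplit(roles, "")[[1]]
  roles <- toupper(roles)
  if (!all(roles %in% c("D", "A", "N")))
    stop("roles must be D (donor), A (acceptor) or N (placeholder)")
  n <- length(roles)
  if (is.matrix(rel_rates)) {
    if (!all(dim(rel_rates) == n))
      stop("rel_rates must be an n_sites x n_sites matrix")
  } else {
    stopifnot(length(rel_rates) == 1L)
    rel_rates <- matrix(rel_rates, n, n)
  }
  da <- outer(roles == "D", roles == "A")
  rel_rates[!da] <- 0
  if (any(is.na(rel_rates[da])) || any(rel_rates[da] < 0))
    stop("rel_rates for donor-acceptor pairs must be non-negative")
  structure(list(roles = roles, rel_rates = rel_rates), class = "oligomer_config")
}

#' @export
print.oligomer_config <- function(x, ...) {
  cat("Oligomer configuration:", paste(x$roles, collapse = ""), "\n")
  nd <- sum(x$roles == "D")
  if (nd > 0)
    cat(sprintf("  %d donor(s), E_app = %.4f, %d distinct lifetime(s)\n",
                nd, config_apparent_efficiency(x),
                length(unique(signif(donor_rate_sums(x), 9)))))
  invisible(x)
}

donor_rate_sums <- function(config) {
  d <- which(config$roles == "D")
  if (!length(d)) stop("configuration has no donors")
  rowSums(config$rel_rates[d, , drop = FALSE])
}

#' Apparent FRET efficiency of a configuration
#'
#' The average FRET efficiency per donor: for each donor, rate additivity
#' gives its efficiency from the sum of its relative rates to all acceptors,
#' and `E_app` is the mean over donors.
#'
#' @param config An [oligomer_config()] with at least one donor.
#' @return `E_app` (dimensionless).
#' @export
config_apparent_efficiency <- function(config) {
  s <- donor_rate_sums(config)
  mean(s / (1 + s))
}

#' Donor lifetimes of a configuration
#'
#' Each donor's excited-state lifetime is shortened by its total transfer
#' rate: `tau_d = tau_D / (1 + sum_a x_da)`. The number of distinct values
#' (within a relative tolerance) is the configuration's lifetime count.
#'
#' @param config An [oligomer_config()].
#' @param tau_D Donor-only lifetime (ns).
#' @param tol Relative tolerance for treating two lifetimes as equal
#'   (default 1e-9).
#' @return List with `lifetimes` (one per donor) and `n_distinct`.
#' @export
config_lifetimes <- function(config, tau_D, tol = 1e-9) {
  stopifnot(tau_D > 0)
  tau <- tau_D / (1 + donor_rate_sums(config))
  groups <- distinct_groups(tau, tol)
  list(lifetimes = tau, n_distinct = length(unique(groups)))
}

# group indices of values equal within relative tol
distinct_groups <- function(x, tol) {
  ord <- order(x)
  g <- integer(length(x))
  gi <- 1L
  g[ord[1]] <- 1L
  for (i in seq_along(ord)[-1]) {
    if (abs(x[ord[i]] - x[ord[i - 1L]]) >
        tol * max(abs(x[ord[i]]), abs(x[ord[i - 1L]]), 1e-300))
      gi <- gi + 1L
    g[ord[i]] <- gi
  }
  g
}

#' Exponential decay mixture of a configuration
#'
#' The donor fluorescence decay of an oligomer configuration is a sum of
#' exponentials, one per distinct donor lifetime, with amplitude
#' proportional to the number of donors sharing that lifetime (normalised
#' to unit total amplitude).
#'
#' @inheritParams config_lifetimes
#' @return List with `amplitudes` and `lifetimes` (sorted by lifetime,
#'   ascending).
#' @examples
#' cfg <- oligomer_config(c("D", "D"), rel_rates = matrix(0, 2, 2))
#' decay_mixture(cfg, tau_D = 3)  # single component at 3 ns
#' @export
decay_mixture <- function(config, tau_D, tol = 1e-9) {
  stopifnot(tau_D > 0)
  tau <- tau_D / (1 + donor_rate_sums(config))
  g <- distinct_groups(tau, tol)
  reps <- vapply(split(tau, g), mean, numeric(1))
  amps <- vapply(split(tau, g), length, numeric(1))
  ord <- order(reps)
  list(amplitudes = unname(amps[ord] / sum(amps)),
       lifetimes = unname(reps[ord]))
}

#' Enumerate donor/acceptor patterns of a tetramer
#'
#' All assignments of donor or acceptor to the 4 sites of a
#' parallelogram-shaped tetramer with at least one donor and one acceptor:
#' 14 raw patterns, reduced to 8 orbits under the parallelogram's 180-degree
#' rotation (which swaps opposite sites, i.e. maps sites 1,2,3,4 to
#' 3,4,1,2). Each orbit is represented by its lexicographically smallest
#' role string; ordering is deterministic.
#'
#' @param symmetry `"none"` (all 14 patterns) or `"c2"` (rotation orbits).
#' @return Character vector of 4-letter role strings over `{A, D}`.
#' @export
enumerate_tetramer_configs <- function(symmetry = c("none", "c2")) {
  symmetry <- match.arg(symmetry)
  grid <- expand.grid(rep(list(c("A", "D")), 4), stringsAsFactors = FALSE)
  pats <- apply(grid, 1, paste0, collapse = "")
  keep <- vapply(pats, function(p) {
    s <- strsplit(p, "")[[1]]
    any(s == "D") && any(s == "A")
  }, logical(1))
  pats <- sort(pats[keep])
  if (symmetry == "none") return(pats)
  rot <- function(p) {
    s <- strsplit(p, "")[[1]]
    paste0(s[c(3, 4, 1, 2)], collapse = "")
  }
  canon <- vapply(pats, function(p) min(p, rot(p)), character(1))
  sort(unique(canon))
}

#' Relative FRET rate from a donor-acceptor distance
#'
#' Forster's distance law: `x = (R0 / r)^6`, where `R0` is the Forster
#' radius (the distance at which `E = 0.5`).
#'
#' @param r Donor-acceptor distance (same units as `R0`).
#' @param R0 Forster radius.
#' @return Relative rate `x`. Vectorised.
#' @export
rate_from_distance <- function(r, R0) {
  stopifnot(all(r > 0), R0 > 0)
  (R0 / r)^6
}
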