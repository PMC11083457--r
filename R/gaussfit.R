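#' Fit a Gaussian (or sum of Gaussians) to a meta-histogram
#'
#' Unweighted least squares of `sum_j A_j * exp(-(x - mu_j)^2 / (2 sigma_j^2))`
#' on the bin centres. One component is the default — each obligate construct
#' is expected to show a single most-probable efficiency — but the component
#' count is an ordinary argument. Initialisation: `mu` at the count-weighted
#' mean, `sigma` at the count-weighted sd, `A` at the maximum count (for
#' several components the range is split evenly).
#'
#' Needs at least `3 * n_components + 1` occupied bins; histograms narrower
#' than that (e.g. values quantised into one or two bins) cannot constrain
#' the fit and raise an error — see [donor_lifetime_from_maps()] for the
#' degenerate-case fallback.
#'
#' @param meta A `"meta_histogram"` (from [build_meta_histogram()]), or any
#'   list with `centers` and `counts`.
#' @param n_components Number of Gaussian components (default 1).
#' @return An object of class `"gaussian_fit"`: `mean`, `sd`, `amplitude`
#'   (each length `n_components`), and `r_squared`.
#' @export
fit_gaussian <- function(meta, n_components = 1L) {
  x <- meta$centers
  y <- meta$counts
  k <- as.integer(n_components)
  stopifnot(length(x) == length(y), k >= 1L)
  occ <- sum(y > 0)
  if (occ < 3L * k + 1L)
    stop("gaussian fit failed: only ", occ,
         " occupied bins for a ", 3L * k, "-parameter fit")
  w <- y / sum(y)
  mu0 <- sum(w * x)
  sd0 <- sqrt(max(sum(w * (x - mu0)^2), 1e-12))
  bw <- if (!is.null(meta$bin_width)) meta$bin_width else min(diff(sort(x)))
  sd0 <- max(sd0, bw / 2)
  if (k == 1L) {
    start <- c(max(y), mu0, sd0)
  } else {
    qs <- stats::quantile(rep(x, y), probs = (seq_len(k) - 0.5) / k)
    start <- c(rep(max(y), k), as.numeric(qs), rep(sd0 / k, k))
  }
  model <- function(par) {
    A <- par[seq_len(k)]; mu <- par[k + seq_len(k)]; s <- par[2L * k + seq_len(k)]
    colSums(A * exp(-outer(mu, x, "-")^2 / (2 * s^2)))
  }
  res <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = function(p) model(p) - y,
                       lower = c(rep(0, k), rep(min(x) - diff(range(x)), k),
                                 rep(bw / 10, k)),
                       upper = c(rep(Inf, k), rep(max(x) + diff(range(x)), k),
                                 rep(10 * diff(range(x)) + bw, k)),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(res) || !res$info %in% 1:4 || !all(is.finite(res$par)))
    stop("gaussian fit failed: no convergence")
  A <- res$par[seq_len(k)]
  mu <- res$par[k + seq_len(k)]
  s <- res$par[2L * k + seq_len(k)]
  ord <- order(mu)
  yhat <- model(res$par)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum((y - yhat)^2) / sstot else NA_real_
  structure(list(mean = mu[ord], sd = s[ord], amplitude = A[ord],
                 r_squared = r2, n_components = k, degenerate = FALSE),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  for (j in seq_len(x$n_components))
    cat(sprintf("Gaussian %d: mean %.4f, sd %.4f, amplitude %.2f\n",
                j, x$mean[j], x$sd[j], x$amplitude[j]))
  cat(sprintf("R^2 = %.4f%s\n", x$r_squared,
              if (isTRUE(x$degenerate)) " (degenerate: returned histogram moments)" else ""))
  invisible(x)
}

#' @export
coef.gaussian_fit <- function(object, ...) {
  c(mean = object$mean, sd = object$sd, amplitude = object$amplitude)
}

#' @export
predict.gaussian_fit <- function(object, x, ...) {
  colSums(object$amplitude *
            exp(-outer(object$mean, x, "-")^2 / (2 * object$sd^2)))
}

# Gaussian fit with a moment fallback for quantised histograms: when too few
# bins are occupied for a 3-parameter fit, report the count-weighted mean and
# sd (floored at half a bin) and flag the result.
fit_gaussian_or_moments <- function(meta, n_components = 1L) {
  out <- tryCatch(fit_gaussian(meta, n_components), error = function(e) NULL)
  if (!is.null(out)) return(out)
  w <- meta$counts / sum(meta$counts)
  mu <- sum(w * meta$centers)
  s <- sqrt(sum(w * (meta$centers - mu)^2))
  s <- max(s, meta$bin_width / 2)
  structure(list(mean = mu, sd = s, amplitude = max(meta$counts),
                 r_squared = NA_real_, n_components = 1L, degenerate = TRUE),
            class = "gaussian_fit")
}
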