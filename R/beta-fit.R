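#' Kullback-Leibler divergence between discrete distributions
#'
#' \eqn{D_{\mathrm{KL}}(p \| q) = \sum_i p_i \ln(p_i/q_i)} in nats, with
#' \eqn{0 \ln(0/q) = 0}. The direction is fixed throughout the package:
#' `p` is the experimental distribution, `q` the model.
#'
#' @param p,q Probability vectors of equal length; `q` must be positive
#'   wherever `p` is.
#' @return Divergence in nats (nonnegative).
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5)) # log(2)
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) {
    rlang::abort("`p` and `q` must have the same length.")
  }
  if (any(p < 0) || any(q < 0)) {
    rlang::abort("Probabilities must be nonnegative.")
  }
  sup <- p > 0
  if (any(q[sup] == 0)) {
    rlang::abort("Infinite divergence: `p` puts mass where `q` is zero.")
  }
  sum(p[sup] * log(p[sup] / q[sup]))
}

#' Fit the LEUP sensitivity beta to observed cone proportions
#'
#' Finds the \eqn{\beta} whose Gaussian LEUP weights
#' \eqn{Q_i(\beta) = \sigma_i^{-\beta} / \sum_j \sigma_j^{-\beta}}
#' (built from the per-type NND standard deviations) best match the
#' observed cone proportions \eqn{P_i}, by minimising
#' \eqn{D_{\mathrm{KL}}(P \| Q(\beta))}. The objective is scanned on a
#' regular grid over `bounds` and then refined by bounded scalar
#' minimisation ([stats::optimize()]) around the grid argmin.
#'
#' @param stats A [cone_mosaic_stats] tibble (or coercible data frame) with
#'   `proportion` and `nnd_sd` columns.
#' @param bounds Length-2 numeric search interval for beta.
#' @param grid_step Grid spacing for the coarse scan.
#' @param tol Refinement tolerance passed to [stats::optimize()].
#'
#' @return An object of class `leup_beta_fit`: a list with `beta_hat`,
#'   `dkl_min` (nats), `dkl_curve` (tibble of `beta`, `dkl` over the grid),
#'   `bounds`, and the input `stats`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' fit <- fit_beta(cone_mosaic_fixture("kram2010_chicken"))
#' glance(fit)
#' @export
fit_beta <- function(stats, bounds = c(0, 10), grid_step = 1e-3, tol = 1e-8) {
  stats <- as_cone_mosaic_stats(stats)
  if (length(bounds) != 2L || !all(is.finite(bounds)) || bounds[1] >= bounds[2]) {
    rlang::abort("`bounds` must be two finite numbers with low < high.")
  }
  p <- stats$proportion
  sigma <- stats$nnd_sd
  log_sig <- log(sigma)

  sup <- p > 0
  dkl_of <- function(beta) {
    # vectorised over beta; Q computed in log space (stable at large |beta|)
    e <- -outer(beta, log_sig)                     # |beta| x n_states
    e <- e - apply(e, 1L, max)
    w <- exp(e)
    log_q <- e - log(rowSums(w))
    as.vector(log_q[, sup, drop = FALSE] %*% (-p[sup])) +
      sum(p[sup] * log(p[sup]))
  }

  grid <- seq(bounds[1], bounds[2], by = grid_step)
  dkl_grid <- dkl_of(grid)
  if (any(!is.finite(dkl_grid))) {
    rlang::abort("Non-finite divergence encountered on the search grid.")
  }
  i <- which.min(dkl_grid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo < hi) {
    opt <- stats::optimize(dkl_of, interval = c(lo, hi), tol = tol)
    beta_hat <- opt$minimum
    dkl_min <- opt$objective
  } else {
    beta_hat <- grid[i]
    dkl_min <- dkl_grid[i]
  }
  # the refined optimum can never be worse than the best grid point
  if (dkl_grid[i] < dkl_min) {
    beta_hat <- grid[i]
    dkl_min <- dkl_grid[i]
  }
  structure(
    list(
      beta_hat = beta_hat,
      dkl_min = dkl_min,
      dkl_curve = tibble::tibble(beta = grid, dkl = dkl_grid),
      bounds = bounds,
      stats = stats,
      dkl_fun = dkl_of
    ),
    class = "leup_beta_fit"
  )
}

#' @export
print.leup_beta_fit <- function(x, ...) {
  cat(sprintf(
    "LEUP beta fit: beta_hat = %.4f, DKL_min = %.4g nats (search [%g, %g])\n",
    x$beta_hat, x$dkl_min, x$bounds[1], x$bounds[2]
  ))
  invisible(x)
}

#' @describeIn fit_beta One row per cone type comparing observed and fitted
#'   proportions.
#' @param x A `leup_beta_fit` object.
#' @param ... Unused.
#' @method tidy leup_beta_fit
#' @export
tidy.leup_beta_fit <- function(x, ...) {
  tibble::tibble(
    label = x$stats$label,
    observed = x$stats$proportion,
    fitted = gaussian_leup_weights(x$stats$nnd_sd, x$beta_hat),
    nnd_sd = x$stats$nnd_sd
  )
}

#' @describeIn fit_beta One-row model summary (`beta_hat`, `dkl_min`,
#'   `n_states`).
#' @method glance leup_beta_fit
#' @export
glance.leup_beta_fit <- function(x, ...) {
  tibble::tibble(
    beta_hat = x$beta_hat,
    dkl_min = x$dkl_min,
    n_states = nrow(x$stats)
  )
}

#' @describeIn fit_beta Plot the divergence profile with the optimum marked.
#' @param object A `leup_beta_fit` object.
#' @method autoplot leup_beta_fit
#' @export
autoplot.leup_beta_fit <- function(object, ...) {
  ggplot2::ggplot(object$dkl_curve, ggplot2::aes(.data$beta, .data$dkl)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$beta_hat, linetype = 2) +
    ggplot2::labs(
      x = expression(beta),
      y = expression(D[KL] * " (nats)"),
      title = sprintf(
        "KL divergence profile (min %.4g at beta = %.3f)",
        object$dkl_min, object$beta_hat
      )
    )
}

#' Interval of plausible beta values below a divergence threshold
#'
#' Locates the connected interval around the fitted \eqn{\hat\beta} on
#' which \eqn{D_{\mathrm{KL}}(\beta)} stays at or below `dkl_threshold`.
#' Endpoints are found by root bracketing ([stats::uniroot()]) to 1e-6 in
#' beta. If the divergence never rises above the threshold on a side of the
#' search bounds, that bound itself is returned.
#'
#' @param fit A `leup_beta_fit` from [fit_beta()].
#' @param dkl_threshold Divergence threshold in nats; must exceed the
#'   fitted minimum.
#' @return A tibble with columns `lower`, `upper`, `dkl_threshold`.
#' @export
beta_plausible_interval <- function(fit, dkl_threshold) {
  stopifnot(inherits(fit, "leup_beta_fit"))
  if (dkl_threshold < fit$dkl_min) {
    rlang::abort("`dkl_threshold` is below the fitted minimum divergence.")
  }
  if (dkl_threshold == fit$dkl_min) {
    return(tibble::tibble(
      lower = fit$beta_hat, upper = fit$beta_hat,
      dkl_threshold = dkl_threshold
    ))
  }
  g <- function(b) fit$dkl_fun(b) - dkl_threshold
  lower <- fit$bounds[1]
  if (g(lower) > 0) {
    lower <- stats::uniroot(
      g, c(fit$bounds[1], fit$beta_hat), tol = 1e-6
    )$root
  }
  upper <- fit$bounds[2]
  if (g(upper) > 0) {
    upper <- stats::uniroot(
      g, c(fit$beta_hat, fit$bounds[2]), tol = 1e-6
    )$root
  }
  tibble::tibble(lower = lower, upper = upper, dkl_threshold = dkl_threshold)
}
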