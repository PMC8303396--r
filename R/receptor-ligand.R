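#' Receptor-ligand binding parameters
#'
#' An abstract sensing circuit: receptors at concentration `x` bind either
#' two ligand species (`y1`, `y2`, rates `k1`, `k2`) or a single ligand
#' (`y`, rate `k_plus`), forming a complex that decays at rate `d`. The
#' complex concentration is the cell's readout of its microenvironment;
#' the possible dependence of ligand levels on the receptor state is
#' deliberately omitted.
#'
#' @param k1,k2 Two-ligand binding rate constants (per concentration per
#'   time).
#' @param k_plus Single-ligand binding rate constant.
#' @param d Complex decay rate (> 0, per time).
#' @param x Receptor concentration (>= 0).
#' @param y1,y2 Two-ligand concentrations (>= 0).
#' @param y Single-ligand concentration (>= 0).
#' @return An object of class `binding_params`. Supply either (`k1`, `k2`,
#'   `y1`, `y2`) or (`k_plus`, `y`).
#' @export
binding_params <- function(k1 = NULL, k2 = NULL, k_plus = NULL, d, x,
                           y1 = NULL, y2 = NULL, y = NULL) {
  if (!is.finite(d) || d <= 0) {
    rlang::abort("`d` must be positive.")
  }
  two <- !is.null(k1) && !is.null(k2) && !is.null(y1) && !is.null(y2)
  one <- !is.null(k_plus) && !is.null(y)
  if (!xor(two, one)) {
    rlang::abort(
      "Supply either the two-ligand set (k1, k2, y1, y2) or the single-ligand set (k_plus, y)."
    )
  }
  conc <- c(x, y1, y2, y)
  if (any(conc < 0)) {
    rlang::abort("Concentrations must be nonnegative.")
  }
  structure(
    list(
      k1 = k1, k2 = k2, k_plus = k_plus, d = d, x = x,
      y1 = y1, y2 = y2, y = y,
      n_ligands = if (two) 2L else 1L
    ),
    class = "binding_params"
  )
}

#' Closed-form steady state of the binding complex
#'
#' For fast decay the complex relaxes to
#' \eqn{c_{eq} = (k_1/d) x y_1 + (k_2/d) x y_2} (two ligands) or
#' \eqn{c_{eq} = (k_+/d) x y} (single ligand).
#'
#' @param params A [binding_params()].
#' @return Steady-state complex concentration.
#' @examples
#' complex_steady_state(binding_params(k1 = 2, k2 = 3, d = 4, x = 1,
#'                                     y1 = 1, y2 = 2)) # 2
#' @export
complex_steady_state <- function(params) {
  stopifnot(inherits(params, "binding_params"))
  if (params$n_ligands == 2L) {
    (params$k1 / params$d) * params$x * params$y1 +
      (params$k2 / params$d) * params$x * params$y2
  } else {
    (params$k_plus / params$d) * params$x * params$y
  }
}

#' Relax the binding ODE to its steady state
#'
#' Integrates \eqn{dc/dt = (\text{binding flux}) - d \, c} from `c0` to
#' `t_end` with [deSolve::ode()] (lsoda). The exact solution is
#' \eqn{c(t) = c_{eq} (1 - e^{-dt}) + c_0 e^{-dt}}, so with the default
#' horizon \eqn{t_{end} = 20/d} the numeric endpoint agrees with the
#' closed form to well below 1e-6 relative.
#'
#' @param params A [binding_params()].
#' @param c0 Initial complex concentration.
#' @param t_end Integration horizon; defaults to `20 / d`.
#' @return Complex concentration at `t_end`.
#' @export
relax_to_steady_state <- function(params, c0 = 0, t_end = 20 / params$d) {
  stopifnot(inherits(params, "binding_params"))
  influx <- if (params$n_ligands == 2L) {
    params$k1 * params$x * params$y1 + params$k2 * params$x * params$y2
  } else {
    params$k_plus * params$x * params$y
  }
  rhs <- function(t, state, p) {
    list(influx - params$d * state)
  }
  sol <- deSolve::ode(
    y = c(c = c0), times = c(0, t_end), func = rhs, parms = NULL,
    rtol = 1e-10, atol = 1e-12
  )
  if (attr(sol, "istate")[1] < 0) {
    rlang::abort("ODE integration failed.")
  }
  unname(sol[nrow(sol), "c"])
}

#' Entropy-weighted fusion of noisy ligand readouts
#'
#' Combines ligand signals with the Gaussian LEUP weights:
#' \eqn{\hat y = \sum_i w_i(\beta) y_i} with
#' \eqn{w_i \propto \sigma_i^{-\beta}}. At \eqn{\beta = 2} the weights are
#' the inverse-variance weights, and the variance of the fused estimate,
#' \eqn{\sum_i w_i^2 \sigma_i^2} for independent channels, is minimal —
#' the sensing-theoretic ground for \eqn{\beta = 2} being optimal.
#'
#' @param sigmas Channel noise standard deviations (> 0).
#' @param beta Fusion exponent.
#' @param ligands Channel readouts, same length as `sigmas`.
#' @return The fused estimate (scalar).
#' @seealso [fused_variance()]
#' @examples
#' fused_estimate(c(1, 2), beta = 2, ligands = c(10, 0)) # 8
#' @export
fused_estimate <- function(sigmas, beta, ligands) {
  if (length(sigmas) != length(ligands)) {
    rlang::abort("`sigmas` and `ligands` must have the same length.")
  }
  w <- gaussian_leup_weights(sigmas, beta)
  sum(w * ligands)
}

#' Variance of the fused estimate for independent channels
#'
#' @inheritParams fused_estimate
#' @return \eqn{\sum_i w_i(\beta)^2 \sigma_i^2}; vectorised over `beta`.
#' @export
fused_variance <- function(sigmas, beta) {
  vapply(beta, function(b) {
    w <- gaussian_leup_weights(sigmas, b)
    sum(w^2 * sigmas^2)
  }, numeric(1))
}

#' Berg-Purcell consistency check for beta = 2
#'
#' With a single ligand whose molecular count is Poisson, the readout
#' noise variance equals the ligand level (\eqn{\sigma_Y^2 = y}). When the
#' steady-state readout \eqn{P(x) = (k_+/d) x} is inversely proportional
#' to the ligand level (\eqn{P \propto 1/y}), expressing \eqn{P} against
#' the noise gives \eqn{P \propto \sigma_Y^{-2}} — the Gaussian LEUP
#' weight with \eqn{\beta = 2}. This function constructs \eqn{y(x)} to
#' satisfy that proportionality on a receptor grid, regresses
#' \eqn{\ln P} on \eqn{\ln \sigma_Y}, and returns the slope, which is
#' exactly \eqn{-2} up to the optional multiplicative jitter.
#'
#' @param x_grid Receptor concentrations (> 0, at least 2 distinct values).
#' @param k_plus Binding rate constant (> 0).
#' @param d Decay rate (> 0).
#' @param jitter_cv Coefficient of variation of multiplicative log-normal
#'   jitter applied to `y` (default 0, exact relation).
#' @param seed RNG seed used when `jitter_cv > 0`.
#' @return The fitted log-log slope.
#' @export
berg_purcell_check <- function(x_grid, k_plus, d, jitter_cv = 0, seed = 1L) {
  if (length(unique(x_grid)) < 2L || any(x_grid <= 0)) {
    rlang::abort("`x_grid` must contain at least two distinct positive values.")
  }
  if (k_plus <= 0 || d <= 0) {
    rlang::abort("`k_plus` and `d` must be positive.")
  }
  y <- d / (k_plus * x_grid)            # enforces P(x) proportional to 1/y
  if (jitter_cv > 0) {
    y <- withr::with_seed(seed, {
      y * exp(stats::rnorm(length(y), sd = sqrt(log(1 + jitter_cv^2))))
    })
  }
  p <- (k_plus / d) * x_grid            # steady-state readout, unnormalised
  sigma_y <- sqrt(y)                    # Poisson ligand noise
  unname(stats::coef(stats::lm(log(p) ~ log(sigma_y)))[2])
}
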