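#' Parameters of the total-entropy-production landscape
#'
#' Total entropy production across differentiation, as a function of the
#' cell sensing radius \eqn{R}, takes the closed form
#' \deqn{f(R) = C_0 + C_1(\beta_d - \beta_s)
#'   + \tfrac{1}{2}\ln\frac{V^{\beta_d}}{U^{\beta_s}}
#'   + \Gamma \ln R + \tilde{\Delta\mu} R^D,}
#' with \eqn{C_1 = \tfrac{1}{2}\ln(2\pi e)} and
#' \eqn{\Gamma = (A\beta_d - D\beta_s)/2}. It assumes Gaussian
#' microenvironmental statistics whose variances scale with the sensing
#' radius: hyperuniformly for the differentiated mosaic
#' (\eqn{\sigma_d^2 = V R^A}, \eqn{A < D}) and Poisson-like for
#' progenitors (\eqn{\sigma_s^2 = U R^D}). \eqn{C_0} lumps the
#' radius-independent heat, information-gain and partition-function terms
#' into one opaque constant.
#'
#' @param C0 Lumped constant (nats).
#' @param beta_s,beta_d LEUP sensitivities of the progenitor (source) and
#'   differentiated states.
#' @param U,V Progenitor and differentiated neighbour densities (> 0).
#' @param A Hyperuniformity exponent of the differentiated mosaic.
#' @param D Spatial dimension, 2 (planar retina, default) or 3.
#' @param delta_mu Net division-intensity times density difference
#'   \eqn{\tilde{\Delta\mu}}; multiplies \eqn{R^D}.
#' @return An object of class `entropy_production_params`, carrying the
#'   derived `gamma` \eqn{= (A\beta_d - D\beta_s)/2}.
#' @examples
#' entropy_production_params(
#'   C0 = -1, beta_s = 3, beta_d = 3, A = 1, delta_mu = 0.3
#' )
#' @export
entropy_production_params <- function(C0, beta_s, beta_d, U = 1, V = 1,
                                      A, D = 2, delta_mu) {
  if (!(D %in% c(2L, 3L))) {
    rlang::abort("`D` must be 2 or 3.")
  }
  if (U <= 0 || V <= 0) {
    rlang::abort("`U` and `V` must be positive.")
  }
  vals <- c(C0, beta_s, beta_d, U, V, A, delta_mu)
  if (any(!is.finite(vals))) {
    rlang::abort("All parameters must be finite.")
  }
  structure(
    list(
      C0 = C0, beta_s = beta_s, beta_d = beta_d, U = U, V = V,
      A = A, D = as.integer(D), delta_mu = delta_mu,
      gamma = (A * beta_d - D * beta_s) / 2
    ),
    class = "entropy_production_params"
  )
}

C1_CONST <- 0.5 * log(2 * pi * exp(1))

#' Evaluate total entropy production at a sensing radius
#'
#' @param params An [entropy_production_params()].
#' @param R Sensing radius (> 0, same length units as the input NND
#'   standard deviations); vectorised.
#' @return \eqn{f(R)} in nats (dimensionless under the kB = 1 convention).
#' @examples
#' p <- entropy_production_params(-1, 3, 3, A = 1, delta_mu = 0.3)
#' entropy_production_f(p, 1) # -0.7
#' @export
entropy_production_f <- function(params, R) {
  stopifnot(inherits(params, "entropy_production_params"))
  if (any(!is.finite(R)) || any(R <= 0)) {
    rlang::abort("`R` must be positive.")
  }
  params$C0 + delta_s_leup(params, R) + params$delta_mu * R^params$D
}

#' LEUP entropy change as a function of sensing radius
#'
#' The microenvironmental-entropy part of the landscape:
#' \deqn{\langle \Delta S_{\mathrm{LEUP}} \rangle =
#'   (\beta_d - \beta_s)\tfrac{1}{2}\ln(2\pi e)
#'   + \tfrac{1}{2}\ln\frac{V^{\beta_d}}{U^{\beta_s}} + \Gamma \ln R.}
#' The identity \eqn{f(R) = C_0 + \langle \Delta S_{\mathrm{LEUP}} \rangle
#' + \tilde{\Delta\mu} R^D} holds exactly.
#'
#' @inheritParams entropy_production_f
#' @return Entropy change in nats; vectorised over `R`.
#' @export
delta_s_leup <- function(params, R) {
  stopifnot(inherits(params, "entropy_production_params"))
  if (any(!is.finite(R)) || any(R <= 0)) {
    rlang::abort("`R` must be positive.")
  }
  C1_CONST * (params$beta_d - params$beta_s) +
    0.5 * (params$beta_d * log(params$V) - params$beta_s * log(params$U)) +
    params$gamma * log(R)
}

#' Critical sensing radius of the entropy-production landscape
#'
#' The landscape has an interior extremum at
#' \eqn{R_c = (-\Gamma / (\tilde{\Delta\mu} D))^{1/D}} whenever
#' \eqn{\Gamma / \tilde{\Delta\mu} < 0}; the second derivative at
#' \eqn{R_c} is \eqn{-\Gamma D / R_c^2}, so \eqn{R_c} is a minimum when
#' \eqn{\Gamma < 0} and a maximum when \eqn{\Gamma > 0}. Otherwise the
#' landscape is monotone in \eqn{R} (including the degenerate
#' \eqn{\tilde{\Delta\mu} = 0} case, where \eqn{f} is
#' \eqn{\Gamma \ln R} plus a constant).
#'
#' @param params An [entropy_production_params()].
#' @return A one-row tibble with `r_c` (NA when no interior extremum),
#'   `kind` (`"minimum"`, `"maximum"` or `"none"`) and `f_at_rc`.
#' @examples
#' p <- entropy_production_params(-1, 3, 3, A = 1, delta_mu = 0.3)
#' critical_radius(p) # r_c = sqrt(2.5), a minimum
#' @export
critical_radius <- function(params) {
  stopifnot(inherits(params, "entropy_production_params"))
  g <- params$gamma
  dm <- params$delta_mu
  if (dm == 0 || g == 0 || g / dm >= 0) {
    return(tibble::tibble(
      r_c = NA_real_, kind = "none", f_at_rc = NA_real_
    ))
  }
  r_c <- (-g / (dm * params$D))^(1 / params$D)
  tibble::tibble(
    r_c = r_c,
    kind = if (g < 0) "minimum" else "maximum",
    f_at_rc = entropy_production_f(params, r_c)
  )
}

#' Scan the sign of total entropy production over a parameter grid
#'
#' Evaluates \eqn{f} on the inclusive rectangular grid formed by crossing
#' the supplied ranges of `beta_s`, `beta_d`, `delta_mu` and `R` (each
#' defaulting to the single value in `params`), and classifies each point
#' into a ternary region: positive entropy production with \eqn{\Gamma <
#' 0} (robust, no fine-tuning of the sensing radius needed), positive with
#' \eqn{\Gamma \ge 0} (positive only on a bounded radius range), or
#' nonpositive (differentiation not thermodynamically favoured). With
#' `at_critical = TRUE` the radius is the critical radius of each grid
#' point (rows without an interior extremum get `f = NA`).
#'
#' @param params Baseline [entropy_production_params()].
#' @param beta_s,beta_d,delta_mu,R Numeric vectors of grid values; default
#'   to the baseline values.
#' @param at_critical Evaluate at each point's critical radius instead of
#'   at `R`.
#' @return A tibble with the grid coordinates and columns `gamma`, `r_c`
#'   (when `at_critical`), `f`, `positive` and `region`.
#' @export
feasible_region_scan <- function(params, beta_s = NULL, beta_d = NULL,
                                 delta_mu = NULL, R = NULL,
                                 at_critical = FALSE) {
  stopifnot(inherits(params, "entropy_production_params"))
  beta_s <- beta_s %||% params$beta_s
  beta_d <- beta_d %||% params$beta_d
  delta_mu <- delta_mu %||% params$delta_mu
  if (is.null(R) && !at_critical) R <- 1
  if (!at_critical && (any(!is.finite(R)) || any(R <= 0))) {
    rlang::abort("`R` must be positive.")
  }
  grid <- tidyr::expand_grid(
    beta_s = beta_s, beta_d = beta_d, delta_mu = delta_mu,
    R = if (at_critical) NA_real_ else R
  )
  if (nrow(grid) == 0L) {
    rlang::abort("The scan grid is empty.")
  }
  rows <- purrr::pmap(grid, function(beta_s, beta_d, delta_mu, R) {
    p <- entropy_production_params(
      C0 = params$C0, beta_s = beta_s, beta_d = beta_d,
      U = params$U, V = params$V, A = params$A, D = params$D,
      delta_mu = delta_mu
    )
    if (at_critical) {
      cr <- critical_radius(p)
      tibble::tibble(gamma = p$gamma, r_c = cr$r_c, f = cr$f_at_rc)
    } else {
      tibble::tibble(
        gamma = p$gamma, r_c = NA_real_,
        f = entropy_production_f(p, R)
      )
    }
  })
  out <- dplyr::bind_cols(
    grid[setdiff(names(grid), "R")],
    if (at_critical) NULL else grid["R"],
    dplyr::bind_rows(rows)
  )
  dplyr::mutate(
    out,
    positive = .data$f > 0,
    region = dplyr::case_when(
      is.na(.data$f) ~ NA_character_,
      .data$f > 0 & .data$gamma < 0 ~ "positive_gamma_neg",
      .data$f > 0 ~ "positive_gamma_nonneg",
      TRUE ~ "nonpositive"
    )
  )
}

#' Plot an entropy-production landscape over the sensing radius
#'
#' @param params An [entropy_production_params()].
#' @param r_range Length-2 radius range.
#' @param n Number of evaluation points.
#' @return A ggplot object; the critical radius, when it exists, is marked.
#' @export
plot_entropy_production <- function(params, r_range = c(0.2, 4), n = 400) {
  rr <- seq(r_range[1], r_range[2], length.out = n)
  df <- tibble::tibble(R = rr, f = entropy_production_f(params, rr))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$R, .data$f)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "sensing radius R", y = "total entropy production f")
  cr <- critical_radius(params)
  if (!is.na(cr$r_c)) {
    p <- p + ggplot2::geom_vline(xintercept = cr$r_c, linetype = 2)
  }
  p
}

#' Read entropy-production parameters from JSON
#'
#' Expected keys mirror [entropy_production_params()] arguments
#' (`C0`, `beta_s`, `beta_d`, `U`, `V`, `A`, `D`, `delta_mu`).
#'
#' @param path Path to a JSON file holding one parameter set or a named
#'   list of them.
#' @return An `entropy_production_params` object, or a named list of them.
#' @export
read_entropy_production_params <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Parameter file not found: '%s'.", path))
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(x) {
    entropy_production_params(
      C0 = x$C0, beta_s = x$beta_s, beta_d = x$beta_d,
      U = x$U %||% 1, V = x$V %||% 1, A = x$A, D = x$D %||% 2,
      delta_mu = x$delta_mu
    )
  }
  if (!is.null(j$C0)) build(j) else lapply(j, build)
}
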