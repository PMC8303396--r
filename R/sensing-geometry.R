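#' Solve the NND-variance model for the sensing radius
#'
#' The variance of a cone type's nearest-neighbour distance is modelled as
#' a function of its sensing radius,
#' \eqn{\sigma^2(R) = M_1 R^2 + M_2 R \ln R + M_3 R}, with empirically
#' fitted coefficients \eqn{M_1, M_2, M_3} supplied by the user (they come
#' from an external fit to mosaic data and are deliberately not shipped as
#' package data). Given an observed \eqn{\sigma}, the radius is obtained by
#' bracketed root finding on \eqn{\sigma^2(R) - \sigma^2}. If the model is
#' non-monotone and crosses the target more than once inside the bracket,
#' the smallest root is returned with a warning.
#'
#' @param coeffs Numeric length-3 vector `c(M1, M2, M3)`; units such that
#'   \eqn{\sigma^2(R)} is in squared micrometres when `R` is in
#'   micrometres.
#' @param sigma Observed NND standard deviation (> 0, micrometres).
#' @param bracket Length-2 search interval for `R` (micrometres).
#' @return The sensing radius (micrometres), to 1e-10 relative tolerance.
#' @examples
#' solve_sensing_radius(c(1, 0, 0), sigma = 2) # R = 2
#' @export
solve_sensing_radius <- function(coeffs, sigma, bracket = c(1e-6, 100)) {
  if (length(coeffs) != 3L || any(!is.finite(coeffs))) {
    rlang::abort("`coeffs` must be three finite numbers (M1, M2, M3).")
  }
  if (!is.finite(sigma) || sigma <= 0) {
    rlang::abort("`sigma` must be positive.")
  }
  if (bracket[1] <= 0 || bracket[1] >= bracket[2]) {
    rlang::abort("`bracket` must satisfy 0 < low < high.")
  }
  target <- sigma^2
  g <- function(R) coeffs[1] * R^2 + coeffs[2] * R * log(R) +
    coeffs[3] * R - target
  # scan for sign changes so multiple crossings are detected
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 512L))
  vals <- g(grid)
  flips <- which(vals[-1] * vals[-length(vals)] <= 0 &
                   !(vals[-1] == 0 & vals[-length(vals)] == 0))
  if (length(flips) == 0L) {
    rlang::abort(
      "No sign change of sigma^2(R) - sigma^2 inside the bracket."
    )
  }
  if (length(flips) > 1L) {
    rlang::warn(
      "Multiple roots inside the bracket; returning the smallest."
    )
  }
  i <- flips[1]
  stats::uniroot(
    g, c(grid[i], grid[i + 1]), tol = 1e-10 * max(1, bracket[2])
  )$root
}

#' Hyperuniformity exponent from a variance-radius pair
#'
#' Approximating the variance model by a single power law
#' \eqn{\sigma^2 = V R^A} with \eqn{V = 1} gives
#' \eqn{A = \ln \sigma^2 / \ln \bar R = 2 \ln \sigma / \ln \bar R}. For a
#' hyperuniform mosaic the exponent must stay below the spatial dimension
#' (A < 2 on a planar retina): count fluctuations grow more slowly than
#' window area.
#'
#' @param sigma NND standard deviation (> 0).
#' @param radius Average sensing radius \eqn{\bar R} (> 0, not equal to 1:
#'   the exponent is undefined at \eqn{\ln \bar R = 0}).
#' @return The exponent A (dimensionless).
#' @examples
#' hyperuniformity_exponent(2.292, 3.553) # ~ 1.308
#' @export
hyperuniformity_exponent <- function(sigma, radius) {
  if (!is.finite(sigma) || sigma <= 0) {
    rlang::abort("`sigma` must be positive.")
  }
  if (!is.finite(radius) || radius <= 0) {
    rlang::abort("`radius` must be positive.")
  }
  if (radius == 1) {
    rlang::abort("`radius` = 1: the exponent is undefined (ln R = 0).")
  }
  2 * log(sigma) / log(radius)
}

#' Per-type sensing radii and hyperuniformity exponents
#'
#' For every cone type, solves the NND-variance model for the sensing
#' radius and converts the (sigma, radius) pair into a hyperuniformity
#' exponent. Types whose exponent reaches the spatial dimension `D` are
#' flagged: they violate the hyperuniformity assumption \eqn{A < D} under
#' which the entropy-production landscape was derived.
#'
#' @param stats A [cone_mosaic_stats] tibble (or coercible data frame).
#' @param coeffs_by_label Named list mapping every label in `stats` to a
#'   length-3 coefficient vector `c(M1, M2, M3)`; see
#'   [read_variance_coeffs()] for the JSON format.
#' @param bracket Root-finding bracket passed to [solve_sensing_radius()].
#' @param D Spatial dimension used for the hyperuniformity flag.
#' @return A tibble with columns `label`, `sensing_radius`, `exponent_A`,
#'   `hyperuniform` (`A < D`).
#' @export
radii_table <- function(stats, coeffs_by_label, bracket = c(1e-6, 100),
                        D = 2) {
  stats <- as_cone_mosaic_stats(stats)
  missing <- setdiff(stats$label, names(coeffs_by_label))
  if (length(missing) > 0L) {
    rlang::abort(paste0(
      "No variance-model coefficients for label(s): ",
      paste(missing, collapse = ", "), "."
    ))
  }
  out <- purrr::map2(stats$label, stats$nnd_sd, function(lab, s) {
    r <- solve_sensing_radius(coeffs_by_label[[lab]], s, bracket)
    tibble::tibble(
      label = lab,
      sensing_radius = r,
      exponent_A = hyperuniformity_exponent(s, r)
    )
  })
  out <- dplyr::bind_rows(out)
  dplyr::mutate(out, hyperuniform = .data$exponent_A < D)
}

#' Read NND-variance model coefficients from JSON
#'
#' The file maps each cone-type label to its `[M1, M2, M3]` coefficient
#' triple.
#'
#' @param path Path to a JSON file.
#' @return A named list of length-3 numeric vectors.
#' @export
read_variance_coeffs <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Coefficient file not found: '%s'.", path))
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j <- j[!startsWith(names(j), "_")]     # allow "_comment"-style keys
  out <- lapply(j, as.numeric)
  bad <- names(out)[vapply(out, function(x) length(x) != 3L || anyNA(x),
                           logical(1))]
  if (length(bad) > 0L) {
    rlang::abort(paste0(
      "Coefficient entries must be numeric [M1, M2, M3]; offending label(s): ",
      paste(bad, collapse = ", "), "."
    ))
  }
  out
}

#' Write a sensing-radius table to CSV
#'
#' Columns: `label,sensing_radius,exponent_A`.
#'
#' @param table Output of [radii_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_radii_table <- function(table, path) {
  utils::write.csv(
    as.data.frame(table[c("label", "sensing_radius", "exponent_A")]),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
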