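#' The LEUP steady-state phenotype distribution
#'
#' Under the Least microEnvironmental Uncertainty Principle (LEUP), the
#' probability that a cell adopts internal state \eqn{x_i} is
#' \deqn{P(x_i) = \frac{e^{-\beta S_i - \mu N_i}}{Z(\beta, \mu)},}
#' where \eqn{S_i = S(y|x_i)} is the entropy of the microenvironment sensed
#' from state \eqn{i} (nats), \eqn{N_i} the neighbour count, \eqn{\beta} the
#' sensitivity to microenvironmental uncertainty, \eqn{\mu} the
#' asymmetric-division intensity, and \eqn{Z} the partition function over
#' the finite discrete state set. The exponent is shifted by its maximum
#' before exponentiation (log-sum-exp), so the computation is stable for
#' \eqn{|\beta|} well beyond the range any fit explores.
#'
#' @param microenv_entropy Numeric vector of microenvironmental entropies
#'   \eqn{S(y|x_i)}, in nats; must be finite.
#' @param beta LEUP sensitivity \eqn{\beta} (dimensionless, finite).
#' @param mu Asymmetric-division intensity \eqn{\mu} (per cell,
#'   default 0, matching the single-parameter application).
#' @param neighbor_count Numeric vector of neighbour counts \eqn{N(y|x_i)}
#'   (cells, nonnegative); recycled if scalar.
#' @param labels Optional state labels.
#'
#' @return An object of class `leup_distribution`: a list with elements
#'   `probs` (normalised probabilities, named if `labels` given),
#'   `log_partition` (\eqn{\ln Z}, nats), and the inputs `beta`, `mu`,
#'   `microenv_entropy`, `neighbor_count`.
#' @seealso [gaussian_leup_weights()] for the Gaussian-microenvironment
#'   special case, [internal_energy()] and [internal_entropy()].
#' @examples
#' leup_distribution(c(0, log(2)), beta = 1)$probs # (2/3, 1/3)
#' @export
leup_distribution <- function(microenv_entropy, beta, mu = 0,
                              neighbor_count = 0, labels = NULL) {
  if (length(microenv_entropy) == 0L) {
    rlang::abort("The state set is empty: `microenv_entropy` has length 0.")
  }
  if (!all(is.finite(microenv_entropy))) {
    rlang::abort("`microenv_entropy` must be finite.")
  }
  if (!is.finite(beta) || !is.finite(mu)) {
    rlang::abort("`beta` and `mu` must be finite.")
  }
  n <- length(microenv_entropy)
  neighbor_count <- rep_len(as.numeric(neighbor_count), n)
  if (!all(is.finite(neighbor_count)) || any(neighbor_count < 0)) {
    rlang::abort("`neighbor_count` must be finite and nonnegative.")
  }
  expo <- -beta * microenv_entropy - mu * neighbor_count
  m <- max(expo)
  w <- exp(expo - m)
  z <- sum(w)
  probs <- w / z
  if (!is.null(labels)) names(probs) <- labels
  structure(
    list(
      probs = probs,
      log_partition = m + log(z),
      beta = beta,
      mu = mu,
      microenv_entropy = microenv_entropy,
      neighbor_count = neighbor_count
    ),
    class = "leup_distribution"
  )
}

#' @export
print.leup_distribution <- function(x, ...) {
  cat(sprintf(
    "LEUP distribution over %d states (beta = %g, mu = %g, ln Z = %.6g)\n",
    length(x$probs), x$beta, x$mu, x$log_partition
  ))
  print(round(x$probs, 4))
  invisible(x)
}

#' @describeIn leup_distribution Tidy the distribution into a tibble with
#'   one row per state (`state`, `microenv_entropy`, `neighbor_count`,
#'   `prob`).
#' @param x A `leup_distribution` object.
#' @param ... Unused.
#' @method tidy leup_distribution
#' @export
tidy.leup_distribution <- function(x, ...) {
  tibble::tibble(
    state = if (is.null(names(x$probs))) {
      as.character(seq_along(x$probs))
    } else {
      names(x$probs)
    },
    microenv_entropy = x$microenv_entropy,
    neighbor_count = x$neighbor_count,
    prob = unname(x$probs)
  )
}

#' Gaussian-microenvironment LEUP weights
#'
#' When the sensed microenvironmental variable is Gaussian with standard
#' deviation \eqn{\sigma_i} in state \eqn{i}, its differential entropy is
#' \eqn{\frac{1}{2}\ln(2\pi e \sigma_i^2)} and the LEUP distribution (with
#' \eqn{\mu = 0}) collapses to the power-law weights
#' \deqn{P(x_i) = \frac{\sigma_i^{-\beta}}{\sum_j \sigma_j^{-\beta}}.}
#' For cone mosaics, \eqn{\sigma_i} is the per-type standard deviation of
#' the nearest-neighbour distance, so types with more regular (lower
#' variance) spatial arrangements are predicted to be more frequent when
#' \eqn{\beta > 0}.
#'
#' @param nnd_sd Numeric vector of strictly positive standard deviations
#'   (micrometres for mosaic data; any common unit cancels).
#' @param beta LEUP sensitivity (dimensionless).
#' @return A probability vector of the same length as `nnd_sd`.
#' @examples
#' gaussian_leup_weights(c(1, 2), beta = 2) # (0.8, 0.2)
#' @export
gaussian_leup_weights <- function(nnd_sd, beta) {
  if (any(!is.finite(nnd_sd)) || any(nnd_sd <= 0)) {
    rlang::abort("`nnd_sd` must be finite and strictly positive.")
  }
  # equivalent to leup_distribution with S_i = 0.5*log(2*pi*e*sd^2), mu = 0;
  # computed in log space for stability at large |beta|
  leup_distribution(log(nnd_sd), beta = beta, mu = 0)$probs
}

#' Minimum-variance (optimal sensing) weights
#'
#' The inverse-variance weights
#' \eqn{P_i = \sigma_i^{-2} / \sum_j \sigma_j^{-2}} that minimise the
#' variance of a fused estimate from independent noisy channels. They
#' coincide exactly with [gaussian_leup_weights()] at \eqn{\beta = 2},
#' which is what identifies \eqn{\beta = 2} as optimal sensing.
#'
#' @inheritParams gaussian_leup_weights
#' @return A probability vector.
#' @export
min_variance_weights <- function(nnd_sd) {
  gaussian_leup_weights(nnd_sd, beta = 2)
}

#' Shannon entropy of a discrete distribution
#'
#' Internal (phenotypic) entropy \eqn{S = -\sum_i P_i \ln P_i} in nats,
#' with the convention \eqn{0 \ln 0 = 0}.
#'
#' @param probs Probability vector (nonnegative, summing to 1 within 1e-6).
#' @return Entropy in nats.
#' @examples
#' internal_entropy(rep(0.2, 5)) # log(5)
#' @export
internal_entropy <- function(probs) {
  if (any(!is.finite(probs)) || any(probs < 0)) {
    rlang::abort("`probs` must be finite and nonnegative.")
  }
  if (abs(sum(probs) - 1) > 1e-6) {
    rlang::abort("`probs` must sum to 1.")
  }
  p <- probs[probs > 0]
  -sum(p * log(p))
}

#' Phenotypic internal energy of a LEUP distribution
#'
#' The internal energy
#' \eqn{U = \langle S \rangle + (\mu/\beta)\langle N \rangle},
#' the ensemble average of microenvironmental entropy plus the
#' division-weighted neighbour count. It satisfies the identity
#' \eqn{S_{\mathrm{int}} = \beta \langle S \rangle + \mu \langle N \rangle
#' + \ln Z}, which ties the internal entropy of the phenotype distribution
#' to its energetics; `internal_energy()` is defined for \eqn{\beta \ne 0}
#' (for \eqn{\mu = 0} it reduces to \eqn{\langle S \rangle}).
#'
#' @param dist A [leup_distribution()] object.
#' @return Internal energy (nats).
#' @export
internal_energy <- function(dist) {
  stopifnot(inherits(dist, "leup_distribution"))
  mean_s <- sum(dist$probs * dist$microenv_entropy)
  if (dist$mu == 0) {
    return(mean_s)
  }
  if (dist$beta == 0) {
    rlang::abort("Internal energy is undefined for beta = 0 with mu != 0.")
  }
  mean_n <- sum(dist$probs * dist$neighbor_count)
  mean_s + (dist$mu / dist$beta) * mean_n
}
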