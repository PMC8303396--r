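#' Metabolic scenario for the differentiation heat budget
#'
#' Progenitor cells run anaerobic glycolysis (about 109.4 kJ per mole of
#' glucose released); differentiated cells respire aerobically (about
#' 2820 kJ/mol). The heat released along the progenitor-to-differentiated
#' transition is the sum of the two, at body temperature.
#'
#' @param heat_anaerobic Heat released by glycolysis (kJ/mol, >= 0).
#' @param heat_aerobic Heat released by respiration (kJ/mol, >= 0).
#' @param temperature Temperature in kelvin (> 0); default 310 K.
#' @return An object of class `metabolic_scenario`.
#' @examples
#' metabolic_scenario(109.4, 2820)
#' @export
metabolic_scenario <- function(heat_anaerobic = 109.4, heat_aerobic = 2820,
                               temperature = 310) {
  if (!is.finite(temperature) || temperature <= 0) {
    rlang::abort("`temperature` must be positive.")
  }
  if (heat_anaerobic < 0 || heat_aerobic < 0) {
    rlang::abort("Heats must be nonnegative.")
  }
  structure(
    list(
      heat_anaerobic = heat_anaerobic,
      heat_aerobic = heat_aerobic,
      temperature = temperature
    ),
    class = "metabolic_scenario"
  )
}

#' Total heat released over the differentiation transition
#'
#' @param scenario A [metabolic_scenario()].
#' @return Heat in kJ/mol.
#' @examples
#' total_heat(metabolic_scenario(109.4, 2820)) # 2929.4
#' @export
total_heat <- function(scenario) {
  stopifnot(inherits(scenario, "metabolic_scenario"))
  scenario$heat_anaerobic + scenario$heat_aerobic
}

#' Dimensionless heat term of the robustness budget
#'
#' The fluctuation-theorem budget uses the heat divided by temperature with
#' the Boltzmann constant set to 1 and the remaining dimension dropped:
#' kJ/mol divided by K, reported as a pure number. This bookkeeping is the
#' convention used in the source analysis of the avian retina (it yields
#' 2929.4/310 = 9.450); a physically unit-consistent alternative that
#' divides by \eqn{R T} (gas constant R = 8.314462618e-3 kJ/mol/K) is
#' available with `physical_units = TRUE` and gives a much larger number —
#' it is NOT the convention behind the published 9.450.
#'
#' @inheritParams total_heat
#' @param physical_units If `TRUE`, return \eqn{\Delta Q / (R T)} instead of
#'   the dimension-dropping \eqn{\Delta Q / T}.
#' @return Dimensionless heat term.
#' @examples
#' beta_prime_heat(metabolic_scenario(109.4, 2820, 310)) # ~9.450
#' @export
beta_prime_heat <- function(scenario, physical_units = FALSE) {
  stopifnot(inherits(scenario, "metabolic_scenario"))
  q <- total_heat(scenario)
  if (physical_units) {
    q / (8.314462618e-3 * scenario$temperature)
  } else {
    q / scenario$temperature
  }
}

#' Internal-entropy change from pluripotent to differentiated
#'
#' The pluripotent prior over the `n_states` fates is uniform (a
#' progenitor has no commitment), so the change in internal entropy across
#' differentiation is
#' \eqn{\langle \Delta S \rangle = S(P_d) - \ln n}, where \eqn{S(P_d)} is
#' the Shannon entropy of the differentiated fate distribution. For the
#' avian cone proportions this is negative: differentiation sharpens the
#' fate distribution.
#'
#' @param p_differentiated Probability vector over differentiated fates.
#' @param n_states Number of fates in the uniform pluripotent prior;
#'   defaults to `length(p_differentiated)`.
#' @return Entropy change in nats.
#' @examples
#' entropy_change_s_to_d(c(0.204, 0.160, 0.133, 0.094, 0.409)) # ~ -0.136
#' @export
entropy_change_s_to_d <- function(p_differentiated,
                                  n_states = length(p_differentiated)) {
  internal_entropy(p_differentiated) - log(n_states)
}

#' Assemble a fluctuation-theorem robustness budget
#'
#' Collects the three averaged terms of the differentiation robustness
#' inequality: the dimensionless heat \eqn{\langle \beta' \Delta Q \rangle},
#' the internal-entropy change \eqn{\langle \Delta S \rangle}, and the
#' information gain \eqn{\langle \Delta i \rangle} (default 0, the
#' simplifying choice used in the avian application). The log of the
#' maximal forward-to-backward probability ratio is their signed sum.
#'
#' @param beta_prime_dQ Dimensionless heat term (see [beta_prime_heat()]).
#' @param delta_S Internal-entropy change, nats.
#' @param delta_i Average information gain, nats (default 0).
#' @return An object of class `thermo_budget` with fields `beta_prime_dQ`,
#'   `delta_S`, `delta_i`, `log_ratio_max`.
#' @export
thermo_budget <- function(beta_prime_dQ, delta_S, delta_i = 0) {
  stopifnot(is.finite(beta_prime_dQ), is.finite(delta_S), is.finite(delta_i))
  structure(
    list(
      beta_prime_dQ = beta_prime_dQ,
      delta_S = delta_S,
      delta_i = delta_i,
      log_ratio_max = beta_prime_dQ + delta_S - delta_i
    ),
    class = "thermo_budget"
  )
}

#' @export
print.thermo_budget <- function(x, ...) {
  chk <- robustness_check(x)
  cat(sprintf(
    paste0(
      "Differentiation robustness budget\n",
      "  <beta' dQ> = %.4f   <dS> = %.4f   <di> = %.4f\n",
      "  margin = %.4f  (%s)\n"
    ),
    x$beta_prime_dQ, x$delta_S, x$delta_i, chk$margin,
    if (chk$robust) "robust: entropy production positive" else "NOT robust"
  ))
  invisible(x)
}

#' Robustness of differentiation against dedifferentiation
#'
#' Differentiation is thermodynamically robust when the dissipated heat
#' plus the internal-entropy change strictly exceeds the information gain:
#' \eqn{\langle \beta' \Delta Q \rangle + \langle \Delta S \rangle >
#' \langle \Delta i \rangle}. Equality sits on the boundary (total entropy
#' production zero) and is reported as not robust.
#'
#' @param budget A [thermo_budget()].
#' @return A one-row tibble with `robust` (logical) and `margin` (the
#'   left-hand side minus the right, nats).
#' @examples
#' robustness_check(thermo_budget(9.450, -0.136)) # margin ~ 9.314
#' @export
robustness_check <- function(budget) {
  stopifnot(inherits(budget, "thermo_budget"))
  margin <- budget$beta_prime_dQ + budget$delta_S - budget$delta_i
  tibble::tibble(robust = margin > 0, margin = margin)
}

#' Maximal forward-to-backward transition probability ratio
#'
#' The Crooks-type bound on how much more probable forward differentiation
#' is than the reverse transition:
#' \eqn{p_f^{\max}/p_b = \exp(\langle \beta' \Delta Q \rangle +
#' \langle \Delta S \rangle - \langle \Delta i \rangle)}. Both the ratio
#' and its logarithm are returned, the latter usable when the ratio itself
#' overflows.
#'
#' @param budget A [thermo_budget()].
#' @return A one-row tibble with `ratio` and `log_ratio`.
#' @export
max_forward_backward_ratio <- function(budget) {
  stopifnot(inherits(budget, "thermo_budget"))
  lr <- budget$log_ratio_max
  tibble::tibble(ratio = exp(lr), log_ratio = lr)
}

#' Read a metabolic scenario from JSON
#'
#' Expected keys: `heat_anaerobic_kj_mol`, `heat_aerobic_kj_mol`,
#' `temperature_K`, and optionally `delta_i`.
#'
#' @param path Path to a JSON file.
#' @return A list with elements `scenario` (a [metabolic_scenario()]) and
#'   `delta_i`.
#' @export
read_metabolic_scenario <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Scenario file not found: '%s'.", path))
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    scenario = metabolic_scenario(
      heat_anaerobic = j$heat_anaerobic_kj_mol,
      heat_aerobic = j$heat_aerobic_kj_mol,
      temperature = j$temperature_K
    ),
    delta_i = if (!is.null(j$delta_i)) j$delta_i else 0
  )
}
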