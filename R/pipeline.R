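#' Build a pipeline configuration
#'
#' Bundles everything one analysis run needs: the cone-statistics source,
#' the metabolic scenario, named entropy-production parameter sets, the
#' sensing radii (direct values, or variance-model coefficients to solve
#' them from), and thresholds. Defaults reproduce the full avian-retina
#' analysis from the packaged fixture.
#'
#' @param stats Fixture name (see [cone_mosaic_fixture()]), a CSV path, or
#'   a [cone_mosaic_stats] tibble.
#' @param scenario A [metabolic_scenario()].
#' @param delta_i Information-gain term of the robustness budget (nats).
#' @param entropy_scenarios Named list of [entropy_production_params()].
#' @param radii Tibble with `label`, `sensing_radius` giving per-type
#'   sensing radii, or `NULL`; defaults to the packaged avian radii when
#'   `stats` is the avian fixture.
#' @param coeffs_by_label Optional named list of variance-model
#'   coefficients; when given, radii are solved from them instead.
#' @param dkl_threshold Divergence threshold for the plausible-beta
#'   interval (nats).
#' @param bounds Beta search bounds.
#' @param seed Integer seed recorded in the report (the default pipeline
#'   stages are deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stats = "kram2010_chicken",
                            scenario = metabolic_scenario(),
                            delta_i = 0,
                            entropy_scenarios = default_entropy_scenarios(),
                            radii = NULL,
                            coeffs_by_label = NULL,
                            dkl_threshold = 0.01,
                            bounds = c(0, 10),
                            seed = 1L) {
  if (is.character(stats)) {
    if (file.exists(stats)) {
      stats_tbl <- read_cone_stats(stats)
    } else if (stats %in% c("kram2010_chicken")) {
      if (is.null(radii) && is.null(coeffs_by_label)) {
        radii <- cone_mosaic_fixture("kram2010_chicken_radii")
      }
      stats_tbl <- cone_mosaic_fixture(stats)
    } else {
      rlang::abort(sprintf(
        "`stats` is neither an existing CSV path nor a known fixture: '%s'.",
        stats
      ))
    }
  } else {
    stats_tbl <- as_cone_mosaic_stats(stats)
  }
  if (is.null(names(entropy_scenarios)) ||
      anyDuplicated(names(entropy_scenarios))) {
    rlang::abort("`entropy_scenarios` must be a uniquely named list.")
  }
  structure(
    list(
      stats = stats_tbl,
      scenario = scenario,
      delta_i = delta_i,
      entropy_scenarios = entropy_scenarios,
      radii = radii,
      coeffs_by_label = coeffs_by_label,
      dkl_threshold = dkl_threshold,
      bounds = bounds,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Reference entropy-production scenarios
#'
#' The three parameter sets used throughout the package's examples: a
#' landscape with an interior minimum (`min_landscape`: equal
#' sensitivities, positive division term), one with an interior maximum
#' (`max_landscape`: unequal sensitivities, negative division term), and
#' the avian double-cone setup (`avian_double`: hyperuniformity exponent
#' 0.440 measured for the double cone).
#'
#' @return A named list of [entropy_production_params()].
#' @export
default_entropy_scenarios <- function() {
  list(
    min_landscape = entropy_production_params(
      C0 = -1, beta_s = 3, beta_d = 3, U = 1, V = 1, A = 1, D = 2,
      delta_mu = 0.3
    ),
    max_landscape = entropy_production_params(
      C0 = -1, beta_s = 1, beta_d = 3, U = 1, V = 1, A = 1, D = 2,
      delta_mu = -0.3
    ),
    avian_double = entropy_production_params(
      C0 = -1, beta_s = 1, beta_d = 2, U = 1, V = 1, A = 0.440, D = 2,
      delta_mu = 0.3
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `stats` (fixture name or CSV path), `scenario`
#' (`heat_anaerobic_kj_mol`, `heat_aerobic_kj_mol`, `temperature_K`,
#' optional `delta_i`), `entropy_scenarios` (named maps of
#' [entropy_production_params()] arguments), optional `dkl_threshold`,
#' `bounds`, `seed`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Config file not found: '%s'.", path))
  }
  y <- yaml::read_yaml(path)
  scen <- if (!is.null(y$scenario)) {
    metabolic_scenario(
      heat_anaerobic = y$scenario$heat_anaerobic_kj_mol,
      heat_aerobic = y$scenario$heat_aerobic_kj_mol,
      temperature = y$scenario$temperature_K
    )
  } else {
    metabolic_scenario()
  }
  eps <- if (!is.null(y$entropy_scenarios)) {
    lapply(y$entropy_scenarios, function(x) {
      entropy_production_params(
        C0 = x$C0, beta_s = x$beta_s, beta_d = x$beta_d,
        U = x$U %||% 1, V = x$V %||% 1, A = x$A, D = x$D %||% 2,
        delta_mu = x$delta_mu
      )
    })
  } else {
    default_entropy_scenarios()
  }
  pipeline_config(
    stats = y$stats %||% "kram2010_chicken",
    scenario = scen,
    delta_i = y$scenario$delta_i %||% 0,
    entropy_scenarios = eps,
    dkl_threshold = y$dkl_threshold %||% 0.01,
    bounds = unlist(y$bounds %||% c(0, 10)),
    seed = y$seed %||% 1L
  )
}

#' Run the full mosaic analysis pipeline
#'
#' Executes, in order: the beta fit to the cone proportions, the
#' differentiation entropy bookkeeping, the metabolic robustness budget,
#' the critical-radius analysis of every named entropy-production
#' scenario, and (when radii or variance coefficients are available) the
#' per-type hyperuniformity exponents. Any stage failure aborts with a
#' stage-tagged error.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @param out Optional path; when given, the report is written there as
#'   JSON with canonical key order and floats at 6 significant digits.
#' @return A list of class `leup_report` with elements `beta_fit`,
#'   `entropy`, `thermo`, `entropy_production`, `sensing`, `meta`.
#' @export
run_pipeline <- function(config = pipeline_config(), out = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  fit <- stage("fit_beta", fit_beta(config$stats, bounds = config$bounds))
  interval <- stage(
    "beta_interval",
    beta_plausible_interval(fit, config$dkl_threshold)
  )

  p <- config$stats$proportion
  s_d <- internal_entropy(p)
  d_s <- entropy_change_s_to_d(p)

  bq <- stage("thermo", {
    thermo_budget(
      beta_prime_dQ = beta_prime_heat(config$scenario),
      delta_S = d_s,
      delta_i = config$delta_i
    )
  })
  chk <- robustness_check(bq)

  ep <- stage("entropy_production", {
    purrr::imap(config$entropy_scenarios, function(prm, nm) {
      cr <- critical_radius(prm)
      list(
        gamma = prm$gamma, r_c = cr$r_c, kind = cr$kind,
        f_at_rc = cr$f_at_rc
      )
    })
  })

  sensing <- NULL
  if (!is.null(config$coeffs_by_label)) {
    sensing <- stage("sensing_geometry",
                     radii_table(config$stats, config$coeffs_by_label))
  } else if (!is.null(config$radii)) {
    sensing <- stage("sensing_geometry", {
      rr <- dplyr::inner_join(
        config$stats[, c("label", "nnd_sd")], config$radii, by = "label"
      )
      tibble::tibble(
        label = rr$label,
        sensing_radius = rr$sensing_radius,
        exponent_A = purrr::map2_dbl(rr$nnd_sd, rr$sensing_radius,
                                     hyperuniformity_exponent),
        hyperuniform = purrr::map2_dbl(rr$nnd_sd, rr$sensing_radius,
                                       hyperuniformity_exponent) < 2
      )
    })
  }

  report <- structure(
    list(
      beta_fit = list(
        beta_hat = fit$beta_hat,
        dkl_min = fit$dkl_min,
        interval = as.list(interval)
      ),
      entropy = list(s_differentiated = s_d, delta_s = d_s),
      thermo = list(
        total_heat_kj_mol = total_heat(config$scenario),
        beta_prime_dQ = bq$beta_prime_dQ,
        delta_i = bq$delta_i,
        robust = chk$robust,
        margin = chk$margin,
        log_ratio_max = bq$log_ratio_max
      ),
      entropy_production = ep,
      sensing = sensing,
      meta = list(
        seed = config$seed,
        package_version = as.character(utils::packageVersion("leupmosaic")),
        n_types = nrow(config$stats),
        labels = config$stats$label
      )
    ),
    class = "leup_report"
  )
  if (!is.null(out)) write_report(report, out)
  report
}

#' @export
print.leup_report <- function(x, ...) {
  cat("LEUP mosaic analysis report\n")
  cat(sprintf("  beta_hat = %.4f  (DKL_min = %.4g nats)\n",
              x$beta_fit$beta_hat, x$beta_fit$dkl_min))
  cat(sprintf("  S(differentiated) = %.4f nats, delta S = %.4f nats\n",
              x$entropy$s_differentiated, x$entropy$delta_s))
  cat(sprintf("  heat = %.1f kJ/mol, robustness margin = %.4f (%s)\n",
              x$thermo$total_heat_kj_mol, x$thermo$margin,
              if (x$thermo$robust) "robust" else "not robust"))
  for (nm in names(x$entropy_production)) {
    e <- x$entropy_production[[nm]]
    cat(sprintf("  scenario %-14s r_c = %s (%s)\n", nm,
                if (is.na(e$r_c)) "none" else sprintf("%.4f", e$r_c),
                e$kind))
  }
  invisible(x)
}

# recursively round report numerics to 6 significant digits for stable JSON
round_sig <- function(x) {
  if (is.list(x)) {
    lapply(x, round_sig)
  } else if (is.double(x)) {
    signif(x, 6)
  } else {
    x
  }
}

#' Write a pipeline report to JSON
#'
#' Keys keep their construction order (canonical), floats are written at 6
#' significant digits, so identical configs yield byte-identical reports.
#'
#' @param report A `leup_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "leup_report"))
  payload <- round_sig(unclass(report))
  if (!is.null(payload$sensing)) {
    payload$sensing <- round_sig(
      lapply(as.list(payload$sensing), function(col) {
        if (is.double(col)) signif(col, 6) else col
      })
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
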