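#' Build a cone-mosaic statistics table
#'
#' A cone-mosaic statistics table holds, per cone type, the occurrence
#' proportion in the retina and the standard deviation (and optionally the
#' mean) of the nearest-neighbour distance (NND) between same-type cones.
#' These two columns are all the LEUP machinery needs: the proportions are
#' the data being explained and the NND standard deviations parameterise the
#' Gaussian microenvironmental entropy of each type.
#'
#' Proportions that sum to within `[0.99, 1.01]` of 1 (e.g. values printed
#' at three decimals) are renormalised to sum exactly to 1; sums outside
#' that band are treated as data errors.
#'
#' @param label Character vector of cone-type names.
#' @param proportion Numeric vector of occurrence proportions (dimensionless,
#'   nonnegative, summing to 1 after renormalisation).
#' @param nnd_sd Numeric vector of NND standard deviations (micrometres,
#'   strictly positive).
#' @param nnd_mean Optional numeric vector of NND means (micrometres).
#'
#' @return A tibble of class `cone_mosaic_stats` with columns `label`,
#'   `proportion`, `nnd_mean`, `nnd_sd`.
#' @examples
#' cone_mosaic_stats(
#'   label      = c("a", "b"),
#'   proportion = c(0.6, 0.4),
#'   nnd_sd     = c(1.2, 0.9)
#' )
#' @export
cone_mosaic_stats <- function(label, proportion, nnd_sd, nnd_mean = NA_real_) {
  if (length(label) == 0L) {
    rlang::abort("`label` must contain at least one cone type.")
  }
  n <- length(label)
  if (length(proportion) != n || length(nnd_sd) != n) {
    rlang::abort("`label`, `proportion` and `nnd_sd` must have equal length.")
  }
  nnd_mean <- rep_len(as.numeric(nnd_mean), n)
  proportion <- as.numeric(proportion)
  nnd_sd <- as.numeric(nnd_sd)
  if (anyNA(proportion) || any(proportion < 0)) {
    rlang::abort("`proportion` must be nonnegative and non-missing.")
  }
  s <- sum(proportion)
  if (s < 0.99 || s > 1.01) {
    rlang::abort(sprintf(
      "`proportion` sums to %.4f; expected a value in [0.99, 1.01].", s
    ))
  }
  proportion <- proportion / s
  if (anyNA(nnd_sd) || any(nnd_sd <= 0)) {
    rlang::abort("`nnd_sd` must be strictly positive.")
  }
  out <- tibble::tibble(
    label = as.character(label),
    proportion = proportion,
    nnd_mean = nnd_mean,
    nnd_sd = nnd_sd
  )
  class(out) <- c("cone_mosaic_stats", class(out))
  out
}

#' Coerce a data frame to a cone-mosaic statistics table
#'
#' @param x A data frame with columns `label`, `proportion`, `nnd_sd` and
#'   optionally `nnd_mean`.
#' @return A validated [cone_mosaic_stats] tibble.
#' @export
as_cone_mosaic_stats <- function(x) {
  if (inherits(x, "cone_mosaic_stats")) {
    return(x)
  }
  required <- c("label", "proportion", "nnd_sd")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    rlang::abort(paste0(
      "Missing required column(s): ", paste(missing, collapse = ", "), "."
    ))
  }
  cone_mosaic_stats(
    label = x$label,
    proportion = x$proportion,
    nnd_sd = x$nnd_sd,
    nnd_mean = if ("nnd_mean" %in% names(x)) x$nnd_mean else NA_real_
  )
}

#' Read cone-mosaic statistics from CSV
#'
#' The file must have a header `label,proportion,nnd_mean,nnd_sd` (the
#' `nnd_mean` column may be omitted), UTF-8 encoding and `.` as decimal
#' separator.
#'
#' @param path Path to a CSV file.
#' @return A [cone_mosaic_stats] tibble.
#' @export
read_cone_stats <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Cone statistics file not found: '%s'.", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_cone_mosaic_stats(df)
}

#' Write cone-mosaic statistics to CSV
#'
#' @param stats A [cone_mosaic_stats] tibble (or coercible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cone_stats <- function(stats, path) {
  stats <- as_cone_mosaic_stats(stats)
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged cone-mosaic fixtures
#'
#' `cone_mosaic_fixture("kram2010_chicken")` returns the published summary
#' statistics of the chicken retina cone mosaic: occurrence proportions and
#' NND standard deviations for the five avian cone types (green, red, blue,
#' violet, double). `cone_mosaic_fixture("kram2010_chicken_radii")` returns
#' the corresponding per-type average sensing radii (micrometres) derived
#' from the published NND-variance model, as a tibble with columns `label`
#' and `sensing_radius`.
#'
#' @param name Fixture name, one of `"kram2010_chicken"` or
#'   `"kram2010_chicken_radii"`.
#' @return A tibble; for `"kram2010_chicken"`, a [cone_mosaic_stats].
#' @examples
#' cone_mosaic_fixture("kram2010_chicken")
#' @export
cone_mosaic_fixture <- function(name = "kram2010_chicken") {
  name <- match.arg(name, c("kram2010_chicken", "kram2010_chicken_radii"))
  path <- system.file("extdata", paste0(name, ".csv"), package = "leupmosaic")
  if (!nzchar(path)) {
    rlang::abort(sprintf("Fixture '%s' not found in installed package.", name))
  }
  if (name == "kram2010_chicken") {
    read_cone_stats(path)
  } else {
    tibble::as_tibble(
      utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    )
  }
}
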