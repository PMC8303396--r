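#' Construct a typed 2-D point pattern
#'
#' @param x,y Point coordinates (micrometres), inside the window.
#' @param type Character vector of type labels, parallel to `x`.
#' @param window Length-2 numeric `c(width, height)` of the rectangular
#'   observation window, with origin at (0, 0).
#' @param seed Integer seed recorded for provenance (the generator that
#'   produced the pattern, if any).
#' @return A tibble of class `point_pattern` with columns `x`, `y`, `type`
#'   and attributes `window` and `seed`.
#' @export
point_pattern <- function(x, y, type, window, seed = NA_integer_) {
  if (length(x) != length(y) || length(x) != length(type)) {
    rlang::abort("`x`, `y` and `type` must be parallel vectors.")
  }
  if (length(window) != 2L || any(window <= 0)) {
    rlang::abort("`window` must be positive c(width, height).")
  }
  if (length(x) > 0L &&
      (any(x < 0) || any(x > window[1]) || any(y < 0) || any(y > window[2]))) {
    rlang::abort("All points must lie inside the window.")
  }
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        type = as.character(type))
  attr(out, "window") <- as.numeric(window)
  attr(out, "seed") <- seed
  class(out) <- c("point_pattern", class(out))
  out
}

#' Configuration for the synthetic mosaic generator
#'
#' Describes a synthetic cone mosaic: type proportions (given directly, or
#' derived as the Gaussian LEUP weights of `sigma` at `beta_true`), overall
#' point intensity, the spatial mode, and per-type dispersion controls.
#' The three modes cover the statistical regimes the analysis assumes:
#' `"jittered_lattice"` produces hyperuniform-like per-type mosaics
#' (sub-area count-fluctuation growth), `"poisson"` the fully random
#' progenitor benchmark, and `"hard_core"` sequential-inhibition patterns
#' with a per-type exclusion radius.
#'
#' @param proportions Named or unnamed probability vector of type
#'   proportions; omit to derive from (`sigma`, `beta_true`).
#' @param sigma Per-type NND standard deviations used with `beta_true`
#'   when `proportions` is missing.
#' @param beta_true LEUP sensitivity used to derive proportions.
#' @param intensity Total intensity, points per square micrometre.
#' @param jitter_sd Gaussian jitter SD (micrometres), scalar or per type
#'   (`jittered_lattice` mode).
#' @param mode One of `"jittered_lattice"`, `"poisson"`, `"hard_core"`.
#' @param window Window `c(width, height)` in micrometres.
#' @param exclusion_radius Per-type hard-core radius (micrometres); scalar
#'   or per type; defaults to half the per-type mean lattice spacing.
#' @param labels Type labels; defaults to names of `proportions`/`sigma`
#'   or `type1, type2, ...`.
#' @param seed Integer RNG seed; every generator draw is a deterministic
#'   function of the config including this seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(proportions = NULL, sigma = NULL,
                             beta_true = NULL, intensity,
                             jitter_sd = 0.1,
                             mode = c("jittered_lattice", "poisson",
                                      "hard_core"),
                             window = c(20, 20), exclusion_radius = NULL,
                             labels = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(proportions)) {
    if (is.null(sigma) || is.null(beta_true)) {
      rlang::abort(
        "Give `proportions`, or both `sigma` and `beta_true` to derive them."
      )
    }
    proportions <- gaussian_leup_weights(sigma, beta_true)
    if (!is.null(names(sigma))) names(proportions) <- names(sigma)
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-6) {
    rlang::abort("`proportions` must be a probability vector.")
  }
  if (!is.finite(intensity) || intensity <= 0) {
    rlang::abort("`intensity` must be positive.")
  }
  k <- length(proportions)
  labels <- labels %||% names(proportions) %||% paste0("type", seq_len(k))
  structure(
    list(
      proportions = unname(proportions),
      labels = labels,
      intensity = intensity,
      jitter_sd = rep_len(jitter_sd, k),
      mode = mode,
      window = window,
      exclusion_radius = exclusion_radius,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# triangular lattice of intensity lambda covering (and wrapped into) window
triangular_lattice <- function(lambda, window) {
  a <- sqrt(2 / (sqrt(3) * lambda))   # spacing giving 2/(sqrt(3) a^2) = lambda
  dy <- a * sqrt(3) / 2
  ys <- seq(dy / 2, window[2], by = dy)
  pts <- purrr::map(seq_along(ys), function(r) {
    off <- if (r %% 2 == 0) a / 2 else 0
    xs <- seq(a / 2 + off, window[1], by = a)
    cbind(xs, ys[r])
  })
  list(xy = do.call(rbind, pts), spacing = a)
}

#' Generate a synthetic cone mosaic
#'
#' Draws a typed point pattern according to a [generator_config()]. In
#' `jittered_lattice` mode each type gets its own triangular lattice with
#' spacing set by that type's intensity share, perturbed by independent
#' Gaussian jitter and wrapped toroidally into the window; `poisson` mode
#' is a homogeneous Poisson process with multinomial type labels;
#' `hard_core` mode fills each type by simple sequential inhibition with a
#' per-type exclusion radius (bounded proposal attempts, then error). The
#' same config (including seed) always reproduces the same pattern.
#'
#' @param config A [generator_config()].
#' @return A [point_pattern()].
#' @export
generate_mosaic <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  w <- config$window
  area <- w[1] * w[2]
  withr::with_seed(config$seed, {
    if (config$mode == "poisson") {
      n <- stats::rpois(1, config$intensity * area)
      ty <- sample(config$labels, n, replace = TRUE,
                   prob = config$proportions)
      return(point_pattern(stats::runif(n, 0, w[1]),
                           stats::runif(n, 0, w[2]),
                           ty, window = w, seed = config$seed))
    }
    xs <- list()
    for (i in seq_along(config$labels)) {
      lam_i <- config$intensity * config$proportions[i]
      if (config$mode == "jittered_lattice") {
        lat <- triangular_lattice(lam_i, w)
        xy <- lat$xy
        if (config$jitter_sd[i] > 0) {
          xy <- xy + matrix(
            stats::rnorm(length(xy), sd = config$jitter_sd[i]), ncol = 2
          )
        }
        xy[, 1] <- xy[, 1] %% w[1]    # toroidal wrap keeps density exact
        xy[, 2] <- xy[, 2] %% w[2]
      } else {                         # hard_core
        n_target <- max(0L, round(lam_i * area))
        r_i <- if (is.null(config$exclusion_radius)) {
          0.5 / (2 * sqrt(lam_i))      # half the Poisson mean NND
        } else {
          rep_len(config$exclusion_radius, length(config$labels))[i]
        }
        acc <- matrix(numeric(0), ncol = 2)
        attempts <- 0L
        max_attempts <- 200L * max(1L, n_target)
        while (nrow(acc) < n_target && attempts < max_attempts) {
          attempts <- attempts + 1L
          cand <- c(stats::runif(1, 0, w[1]), stats::runif(1, 0, w[2]))
          if (nrow(acc) == 0L ||
              min((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2) >
                r_i^2) {
            acc <- rbind(acc, cand)
          }
        }
        if (nrow(acc) < n_target) {
          rlang::abort(sprintf(
            "Hard-core packing infeasible for type '%s' (placed %d of %d).",
            config$labels[i], nrow(acc), n_target
          ))
        }
        xy <- acc
      }
      xs[[i]] <- tibble::tibble(
        x = xy[, 1], y = xy[, 2], type = config$labels[i]
      )
    }
    df <- dplyr::bind_rows(xs)
    point_pattern(df$x, df$y, df$type, window = w, seed = config$seed)
  })
}

# nearest-neighbour distance of each point to any other point in (x, y);
# chunked cross-distance keeps memory bounded and the arithmetic vectorised
nn_distances <- function(x, y, toroidal = FALSE, window = NULL) {
  n <- length(x)
  if (n < 2L) {
    rlang::abort("Need at least 2 points for nearest-neighbour distances.")
  }
  out <- numeric(n)
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    dx <- abs(outer(x[idx], x, "-"))
    dy <- abs(outer(y[idx], y, "-"))
    if (toroidal) {
      dx <- pmin(dx, window[1] - dx)
      dy <- pmin(dy, window[2] - dy)
    }
    d2 <- dx^2 + dy^2
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Per-type nearest-neighbour-distance statistics of a mosaic
#'
#' For each type, measures the Euclidean distance from every point to its
#' nearest same-type neighbour and summarises the mean and standard
#' deviation, together with the type's share of all points. By default a
#' border-buffer correction is applied: reference points closer to any
#' window edge than the type's mean NND are excluded from the distance
#' summaries (their neighbours still count), which removes the upward bias
#' of censored edge distances in bounded retina patches. `toroidal = TRUE`
#' instead wraps distances around the window, useful for exact lattice
#' checks.
#'
#' @param pattern A [point_pattern()].
#' @param toroidal Use wrapped (periodic) distances and skip the buffer.
#' @return A [cone_mosaic_stats] tibble (labels in order of first
#'   appearance).
#' @export
nnd_statistics <- function(pattern, toroidal = FALSE) {
  stopifnot(inherits(pattern, "point_pattern"))
  w <- attr(pattern, "window")
  types <- unique(pattern$type)
  n_total <- nrow(pattern)
  res <- purrr::map(types, function(ty) {
    sub <- pattern[pattern$type == ty, ]
    if (nrow(sub) < 2L) {
      rlang::abort(sprintf("Type '%s' has fewer than 2 points.", ty))
    }
    d <- nn_distances(sub$x, sub$y, toroidal = toroidal, window = w)
    keep <- rep(TRUE, nrow(sub))
    if (!toroidal) {
      buf <- mean(d)
      keep <- sub$x >= buf & sub$x <= w[1] - buf &
        sub$y >= buf & sub$y <= w[2] - buf
      if (!any(keep)) keep <- rep(TRUE, nrow(sub))  # window too small to buffer
    }
    tibble::tibble(
      label = ty,
      proportion = nrow(sub) / n_total,
      nnd_mean = mean(d[keep]),
      nnd_sd = stats::sd(d[keep])
    )
  })
  df <- dplyr::bind_rows(res)
  # degenerate patterns (perfect lattices) have zero NND spread, which the
  # strict LEUP-input constructor rejects; return them as a plain tibble
  if (all(is.finite(df$nnd_sd)) && all(df$nnd_sd > 0)) {
    cone_mosaic_stats(df$label, df$proportion, df$nnd_sd, df$nnd_mean)
  } else {
    df
  }
}

#' Count-variance scaling exponent of a point pattern
#'
#' Estimates how the variance of the number of points falling in a disk of
#' radius R grows with R, by sampling `n_windows` disk centres uniformly
#' (kept at least R from every border, so disks never leave the window)
#' for each radius and regressing log variance on log radius. A Poisson
#' pattern gives slope D = 2 (variance proportional to area); hyperuniform
#' patterns such as jittered lattices give slopes below 2.
#'
#' @param pattern A [point_pattern()].
#' @param radii At least 3 positive radii, each below half the smaller
#'   window side.
#' @param n_windows Number of sampling disks per radius (>= 100).
#' @param seed RNG seed for disk placement.
#' @return The fitted slope (exponent estimate).
#' @export
count_variance_exponent <- function(pattern, radii, n_windows = 200L,
                                    seed = 1L) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (length(radii) < 3L) {
    rlang::abort("Supply at least 3 radii for the log-log regression.")
  }
  w <- attr(pattern, "window")
  if (any(radii <= 0) || any(2 * radii >= min(w))) {
    rlang::abort("Each radius must be positive and below half the window side.")
  }
  if (n_windows < 100L) {
    rlang::abort("`n_windows` must be at least 100.")
  }
  vars <- withr::with_seed(seed, {
    vapply(radii, function(R) {
      cx <- stats::runif(n_windows, R, w[1] - R)
      cy <- stats::runif(n_windows, R, w[2] - R)
      dx <- outer(pattern$x, cx, "-")
      dy <- outer(pattern$y, cy, "-")
      counts <- colSums(dx^2 + dy^2 <= R^2)
      stats::var(counts)
    }, numeric(1))
  })
  if (any(vars <= 0)) {
    rlang::abort("Degenerate count variance (zero) at some radius.")
  }
  unname(stats::coef(stats::lm(log(vars) ~ log(radii)))[2])
}

#' Beta-recovery experiment on multinomial samples
#'
#' Validation harness for the KL fit: draws `n_reps` multinomial samples
#' of `n_cells` cone fates from the Gaussian LEUP weights at `beta_true`,
#' refits beta on each sampled proportion vector (with the true `sigma`),
#' and summarises the sampling distribution of the estimates.
#'
#' @param sigma Per-type NND standard deviations (> 0).
#' @param beta_true Generating LEUP sensitivity.
#' @param n_cells Cells per sample (>= 100).
#' @param n_reps Number of replicates.
#' @param seed RNG seed.
#' @param bounds,grid_step Passed to [fit_beta()].
#' @return A list of class `leup_recovery` with `estimates` (tibble of
#'   `rep`, `beta_hat`), `beta_true`, `mean`, `sd`, `bias`.
#' @export
recovery_experiment <- function(sigma, beta_true, n_cells, n_reps,
                                seed = 1L, bounds = c(0, 10),
                                grid_step = 0.01) {
  if (n_cells < 100) {
    rlang::abort("`n_cells` must be at least 100.")
  }
  q <- gaussian_leup_weights(sigma, beta_true)
  counts <- withr::with_seed(seed, stats::rmultinom(n_reps, n_cells, q))
  beta_hat <- vapply(seq_len(n_reps), function(r) {
    p <- counts[, r] / n_cells
    st <- cone_mosaic_stats(
      label = paste0("type", seq_along(sigma)),
      proportion = p, nnd_sd = sigma
    )
    fit_beta(st, bounds = bounds, grid_step = grid_step)$beta_hat
  }, numeric(1))
  structure(
    list(
      estimates = tibble::tibble(rep = seq_len(n_reps), beta_hat = beta_hat),
      beta_true = beta_true,
      mean = mean(beta_hat),
      sd = stats::sd(beta_hat),
      bias = mean(beta_hat) - beta_true
    ),
    class = "leup_recovery"
  )
}

#' @export
print.leup_recovery <- function(x, ...) {
  cat(sprintf(
    "Beta recovery: true %.4f, mean %.4f (sd %.4f, bias %+.4f, %d reps)\n",
    x$beta_true, x$mean, x$sd, x$bias, nrow(x$estimates)
  ))
  invisible(x)
}

#' @describeIn point_pattern Scatter plot of the typed pattern.
#' @param object A `point_pattern`.
#' @param ... Unused.
#' @method autoplot point_pattern
#' @export
autoplot.point_pattern <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       colour = .data$type)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' Write a point pattern to CSV with a sidecar window file
#'
#' The CSV has header `x,y,type`; the window and seed go to
#' `<path>.json`.
#'
#' @param pattern A [point_pattern()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_point_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  df <- as.data.frame(pattern)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(window = attr(pattern, "window"), seed = attr(pattern, "seed")),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a point pattern written by [write_point_pattern()]
#'
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return A [point_pattern()].
#' @export
read_point_pattern <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Pattern file not found: '%s'.", path))
  }
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    rlang::abort(sprintf("Sidecar window file not found: '%s'.", side))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  point_pattern(df$x, df$y, df$type, window = meta$window,
                seed = meta$seed %||% NA_integer_)
}
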