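fig5_params <- function() {
  entropy_production_params(C0 = -1, beta_s = 3, beta_d = 3, U = 1, V = 1,
                            A = 1, D = 2, delta_mu = 0.3)
}
fig6_params <- function() {
  entropy_production_params(C0 = -1, beta_s = 1, beta_d = 3, U = 1, V = 1,
                            A = 1, D = 2, delta_mu = -0.3)
}

random_landscape <- function() {
  entropy_production_params(
    C0 = runif(1, -3, 3),
    beta_s = runif(1, 0.2, 4), beta_d = runif(1, 0.2, 4),
    U = runif(1, 0.3, 3), V = runif(1, 0.3, 3),
    A = runif(1, 0.1, 1.9), D = sample(2:3, 1),
    delta_mu = runif(1, -1, 1)
  )
}

test_that("landscape evaluation matches the published extrema", {
  p5 <- fig5_params()
  expect_equal(entropy_production_f(p5, 1), -0.7, tolerance = 1e-12)
  cr5 <- critical_radius(p5)
  expect_equal(cr5$r_c, sqrt(2.5), tolerance = 1e-12)
  expect_equal(cr5$kind, "minimum")
  expect_lt(abs(cr5$f_at_rc - (-0.937)), 1e-3)

  p6 <- fig6_params()
  cr6 <- critical_radius(p6)
  expect_equal(cr6$r_c, sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(cr6$kind, "maximum")
  expect_lt(abs(cr6$f_at_rc - 1.542), 1e-3)

  expect_error(entropy_production_f(p5, -1), "positive")
  expect_error(entropy_production_params(-1, 1, 1, A = 1, D = 4,
                                         delta_mu = 1), "must be 2 or 3")
})

test_that("no interior extremum when the sign condition fails", {
  # Gamma > 0 together with delta_mu > 0 leaves f monotone
  p <- entropy_production_params(-1, beta_s = 0.5, beta_d = 3, A = 1.5,
                                 delta_mu = 0.3)
  expect_gt(p$gamma, 0)
  expect_equal(critical_radius(p)$kind, "none")

  # degenerate delta_mu = 0: f is Gamma * ln R + const
  p0 <- entropy_production_params(-1, beta_s = 3, beta_d = 3, A = 1,
                                  delta_mu = 0)
  expect_equal(critical_radius(p0)$kind, "none")
  rr <- c(0.5, 1, 2, 4)
  expect_equal(diff(entropy_production_f(p0, rr)),
               p0$gamma * diff(log(rr)), tolerance = 1e-12)
})

test_that("LEUP entropy term and decomposition identity", {
  # identical sensitivities, densities and exponents cancel all terms
  p_eq <- entropy_production_params(0, beta_s = 2, beta_d = 2, U = 1.4,
                                    V = 1.4, A = 2, D = 2, delta_mu = 0.1)
  expect_equal(delta_s_leup(p_eq, c(0.3, 1, 7)), rep(0, 3),
               tolerance = 1e-12)

  expect_equal(delta_s_leup(fig5_params(), exp(1)), -1.5,
               tolerance = 1e-12)

  set.seed(31)
  for (i in 1:100) {
    p <- random_landscape()
    r <- runif(1, 0.1, 8)
    expect_equal(entropy_production_f(p, r),
                 p$C0 + delta_s_leup(p, r) + p$delta_mu * r^p$D,
                 tolerance = 1e-12)
  }
})

test_that("closed-form critical radius matches numeric optimisation", {
  set.seed(47)
  done <- 0
  while (done < 200) {
    p <- random_landscape()
    if (p$delta_mu == 0 || p$gamma == 0 || p$gamma / p$delta_mu >= 0) next
    done <- done + 1
    cr <- critical_radius(p)
    obj <- if (cr$kind == "minimum") {
      function(r) entropy_production_f(p, r)
    } else {
      function(r) -entropy_production_f(p, r)
    }
    num <- stats::optimize(obj, interval = c(1e-6, 1e3), tol = 1e-10)
    expect_equal(cr$r_c, num$minimum, tolerance = 1e-6)

    # analytic curvature sign agrees with a central finite difference
    h <- 1e-4 * cr$r_c
    fd2 <- (entropy_production_f(p, cr$r_c + h) - 2 * cr$f_at_rc +
              entropy_production_f(p, cr$r_c - h)) / h^2
    expect_equal(sign(fd2), sign(-p$gamma * p$D / cr$r_c^2))
  }
})

test_that("tail behaviour: unbounded growth vs bounded-above landscapes", {
  # divergence is logarithmic as R -> 0+ and power-law as R -> infinity
  p5 <- fig5_params()       # Gamma < 0, delta_mu > 0
  f5 <- entropy_production_f(p5, c(1e-200, sqrt(2.5), 1e3))
  expect_gt(f5[1], 1e2)
  expect_gt(f5[3], 1e3)

  p6 <- fig6_params()       # Gamma > 0, delta_mu < 0
  f6 <- entropy_production_f(p6, c(1e-200, 1e3))
  expect_true(all(f6 < -1e2))
  cr6 <- critical_radius(p6)
  rr <- exp(seq(log(1e-3), log(100), length.out = 200))
  expect_true(all(entropy_production_f(p6, rr) <= cr6$f_at_rc + 1e-12))
})

test_that("feasibility scans classify the parameter space", {
  # along R, the published minimum landscape is positive exactly outside
  # one interval around the critical radius
  sc <- feasible_region_scan(fig5_params(), R = seq(0.5, 4, by = 0.005))
  runs <- rle(sc$positive)
  expect_equal(runs$values, c(TRUE, FALSE, TRUE))
  neg <- range(sc$R[!sc$positive])
  expect_lt(neg[1], sqrt(2.5))
  expect_gt(neg[2], sqrt(2.5))
  # the two sign-change radii agree with direct root finding
  p5 <- fig5_params()
  r_lo <- stats::uniroot(function(r) entropy_production_f(p5, r),
                         c(0.5, sqrt(2.5)), tol = 1e-10)$root
  r_hi <- stats::uniroot(function(r) entropy_production_f(p5, r),
                         c(sqrt(2.5), 4), tol = 1e-10)$root
  expect_equal(neg[1], r_lo, tolerance = 0.01)
  expect_equal(neg[2], r_hi, tolerance = 0.01)

  # avian double-cone setup: robust region (f > 0 at r_c with Gamma < 0)
  # requires the differentiated state to be the more sensitive one
  pd <- entropy_production_params(C0 = -1, beta_s = 1, beta_d = 2,
                                  U = 1, V = 1, A = 0.440, D = 2,
                                  delta_mu = 0.3)
  grid <- feasible_region_scan(pd, beta_s = seq(0.1, 5, by = 0.1),
                               beta_d = seq(0.1, 5, by = 0.1),
                               at_critical = TRUE)
  rob <- grid[!is.na(grid$region) & grid$region == "positive_gamma_neg", ]
  expect_gt(nrow(rob), 0)
  expect_true(all(rob$beta_d > rob$beta_s))

  one <- feasible_region_scan(fig6_params(), R = sqrt(5 / 6))
  expect_true(one$positive)
  expect_error(feasible_region_scan(fig5_params(), R = numeric(0)),
               "positive|empty")
})

test_that("landscape plot and JSON loader work", {
  expect_s3_class(plot_entropy_production(fig5_params()), "ggplot")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(fig5 = list(C0 = -1, beta_s = 3, beta_d = 3, A = 1,
                     delta_mu = 0.3)),
    path, auto_unbox = TRUE
  )
  got <- read_entropy_production_params(path)
  expect_equal(got$fig5$gamma, -1.5)
})
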