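test_that("LEUP distribution matches hand-computed cases", {
  # beta = 0, mu = 0: exponent vanishes, uniform over any 5 states
  d0 <- leup_distribution(runif(5, -2, 2), beta = 0)
  expect_equal(unname(d0$probs), rep(0.2, 5), tolerance = 1e-14)

  # weights (1, 1/2) for entropies (0, ln 2) at beta = 1
  d1 <- leup_distribution(c(0, log(2)), beta = 1)
  expect_equal(unname(d1$probs), c(2 / 3, 1 / 3), tolerance = 1e-14)

  # two states, equal entropies, neighbour counts (1, 3), beta = mu = 1:
  # odds e^2 : 1
  d2 <- leup_distribution(c(0.5, 0.5), beta = 1, mu = 1,
                          neighbor_count = c(1, 3))
  expect_equal(unname(d2$probs),
               c(exp(2) / (exp(2) + 1), 1 / (exp(2) + 1)),
               tolerance = 1e-12)

  expect_error(leup_distribution(numeric(0), beta = 1), "empty")
  expect_error(leup_distribution(c(0, Inf), beta = 1), "finite")
})

test_that("distribution agrees with brute-force weights and is stable", {
  set.seed(101)
  for (i in 1:50) {
    m <- random_model()
    d <- leup_distribution(m$entropy, beta = m$beta, mu = m$mu,
                           neighbor_count = m$n_count)
    expect_equal(unname(d$probs),
                 brute_leup_probs(m$entropy, m$beta, m$mu, m$n_count),
                 tolerance = 1e-12)
    expect_equal(sum(d$probs), 1, tolerance = 1e-12)
  }
  # log-sum-exp keeps extreme beta finite where naive exp overflows
  dx <- leup_distribution(c(-400, 400), beta = 5)
  expect_true(all(is.finite(dx$probs)))
  expect_equal(unname(dx$probs), c(1, 0), tolerance = 1e-12)
})

test_that("Gaussian weights: symmetry, closed forms, fixture prediction", {
  expect_equal(gaussian_leup_weights(rep(2.7, 5), beta = runif(1, -5, 5)),
               rep(0.2, 5), tolerance = 1e-14)
  expect_equal(gaussian_leup_weights(c(1, 2), 2), c(0.8, 0.2),
               tolerance = 1e-14)

  w2 <- avian_sigma^(-2) / sum(avian_sigma^(-2))
  expect_equal(gaussian_leup_weights(avian_sigma, 2), w2, tolerance = 1e-12)
  expect_equal(round(w2, 3), c(0.238, 0.155, 0.124, 0.071, 0.413))

  # near the fitted sensitivity the weights track the observed proportions
  q <- gaussian_leup_weights(avian_sigma, 1.754)
  expect_lt(max(abs(q - avian_p)), 0.04)

  expect_error(gaussian_leup_weights(c(1, 0), 2), "positive")

  # equivalence with the Gaussian differential entropy route
  sd <- c(1.3, 0.7, 2.2)
  s_gauss <- 0.5 * log(2 * pi * exp(1) * sd^2)
  expect_equal(gaussian_leup_weights(sd, 1.6),
               unname(leup_distribution(s_gauss, beta = 1.6)$probs),
               tolerance = 1e-12)
})

test_that("weights shift monotonically toward the least-variable state", {
  sd <- c(0.6, 1.1, 1.9)
  betas <- seq(0, 30, by = 0.5)
  p_min <- vapply(betas, function(b) gaussian_leup_weights(sd, b)[1],
                  numeric(1))
  expect_true(all(diff(p_min) > 0))
  expect_equal(gaussian_leup_weights(sd, 500)[1], 1, tolerance = 1e-12)
  # permuting states permutes probabilities identically
  perm <- c(3, 1, 2)
  expect_equal(gaussian_leup_weights(sd[perm], 1.7),
               gaussian_leup_weights(sd, 1.7)[perm], tolerance = 1e-14)
})

test_that("internal entropy covers uniform, degenerate and avian cases", {
  expect_equal(internal_entropy(rep(0.2, 5)), log(5), tolerance = 1e-12)
  expect_equal(internal_entropy(c(1, 0, 0, 0, 0)), 0)
  expect_lt(abs(internal_entropy(avian_p) - 1.473), 1e-3)
  expect_error(internal_entropy(c(-0.1, 1.1)), "nonnegative")
})

test_that("internal energy and the entropy identity hold", {
  # mu = 0: energy reduces to mean microenvironmental entropy
  d <- leup_distribution(c(0.2, 0.9, 1.4), beta = 1.3)
  expect_equal(internal_energy(d), sum(d$probs * c(0.2, 0.9, 1.4)),
               tolerance = 1e-14)

  d2 <- leup_distribution(c(0.5, 0.5), beta = 1, mu = 1,
                          neighbor_count = c(1, 3))
  p1 <- exp(2) / (exp(2) + 1)
  expect_equal(internal_energy(d2), 0.5 + p1 * 1 + (1 - p1) * 3,
               tolerance = 1e-10)

  expect_error(
    internal_energy(leup_distribution(c(0, 1), beta = 0, mu = 2,
                                      neighbor_count = c(1, 2))),
    "undefined"
  )

  # S_int = beta <S> + mu <N> + ln Z for random models
  set.seed(77)
  for (i in 1:100) {
    m <- random_model()
    d <- leup_distribution(m$entropy, beta = m$beta, mu = m$mu,
                           neighbor_count = m$n_count)
    lhs <- internal_entropy(d$probs)
    rhs <- m$beta * sum(d$probs * m$entropy) +
      m$mu * sum(d$probs * m$n_count) + d$log_partition
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("minimum-variance weights equal the beta = 2 Gaussian weights", {
  expect_equal(min_variance_weights(c(1, 1)), c(0.5, 0.5))
  expect_equal(min_variance_weights(c(1, 2)), c(0.8, 0.2))
  expect_identical(min_variance_weights(avian_sigma),
                   gaussian_leup_weights(avian_sigma, 2))
})

test_that("tidy methods expose distributions as tibbles", {
  d <- leup_distribution(c(0, log(2)), beta = 1, labels = c("a", "b"))
  td <- tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$state, c("a", "b"))
  expect_equal(sum(td$prob), 1, tolerance = 1e-12)
})
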