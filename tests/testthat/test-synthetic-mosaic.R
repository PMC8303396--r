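test_that("generators are seed-deterministic and stay in the window", {
  cfg <- generator_config(proportions = c(a = 0.6, b = 0.4), intensity = 1,
                          window = c(15, 12), seed = 99)
  p1 <- generate_mosaic(cfg)
  p2 <- generate_mosaic(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_true(all(p1$x >= 0 & p1$x <= 15 & p1$y >= 0 & p1$y <= 12))

  # written CSVs are byte-identical across runs
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_point_pattern(p1, f1)
  write_point_pattern(generate_mosaic(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_point_pattern(f1)
  expect_equal(attr(back, "window"), c(15, 12))
  expect_equal(nrow(back), nrow(p1))

  # different seeds give different patterns
  p3 <- generate_mosaic(generator_config(proportions = c(a = 0.6, b = 0.4),
                                         intensity = 1, window = c(15, 12),
                                         seed = 100))
  expect_false(identical(p1$x, p3$x))
})

test_that("Poisson mode has Poisson point-count concentration", {
  lambda <- 1
  wdim <- c(20, 20)
  area <- prod(wdim)
  counts <- vapply(1:100, function(s) {
    nrow(generate_mosaic(generator_config(
      proportions = c(a = 1), intensity = lambda, mode = "poisson",
      window = wdim, seed = s
    )))
  }, numeric(1))
  inside <- abs(counts - lambda * area) <= 4 * sqrt(lambda * area)
  expect_gte(mean(inside), 0.95)
})

test_that("unjittered lattices have exact spacing and zero NND spread", {
  cfg <- generator_config(proportions = c(a = 0.5, b = 0.5), intensity = 1,
                          jitter_sd = 0, window = c(20, 20), seed = 7)
  st <- nnd_statistics(generate_mosaic(cfg), toroidal = TRUE)
  spacing <- sqrt(2 / (sqrt(3) * 0.5))   # per-type triangular spacing
  expect_equal(st$nnd_mean, rep(spacing, 2), tolerance = 1e-9)
  expect_equal(st$nnd_sd, rep(0, 2), tolerance = 1e-9)

  # hand-built square lattice: NND mean = spacing, SD = 0
  a <- 2
  g <- expand.grid(x = seq(1, 19, by = a), y = seq(1, 19, by = a))
  sq <- point_pattern(g$x, g$y, rep("s", nrow(g)), window = c(20, 20))
  st_sq <- nnd_statistics(sq, toroidal = TRUE)
  expect_equal(st_sq$nnd_mean, a)
  expect_equal(st_sq$nnd_sd, 0)
})

test_that("NND statistics handle small and degenerate inputs", {
  two <- point_pattern(c(1, 4), c(2, 2), c("a", "a"), window = c(10, 10))
  st <- nnd_statistics(two, toroidal = TRUE)
  expect_equal(st$nnd_mean, 3)
  expect_equal(st$nnd_sd, 0)

  one <- point_pattern(c(1, 2, 3), c(1, 2, 3), c("a", "a", "b"),
                       window = c(10, 10))
  expect_error(nnd_statistics(one), "'b'")
  expect_error(point_pattern(c(1, 30), c(1, 1), c("a", "a"),
                             window = c(10, 10)), "inside the window")
})

test_that("Poisson NND mean matches the closed form 1/(2 sqrt(lambda))", {
  lambda <- 1
  means <- vapply(1:100, function(s) {
    pat <- generate_mosaic(generator_config(
      proportions = c(a = 1), intensity = lambda, mode = "poisson",
      window = c(40, 50), seed = s
    ))
    nnd_statistics(pat)$nnd_mean
  }, numeric(1))
  expect_equal(mean(means), 1 / (2 * sqrt(lambda)), tolerance = 0.05)
})

test_that("count-variance exponent separates Poisson from hyperuniform", {
  pois <- generate_mosaic(generator_config(
    proportions = c(a = 1), intensity = 1.05, mode = "poisson",
    window = c(72, 72), seed = 5
  ))
  expect_gte(nrow(pois), 5000)
  a_pois <- count_variance_exponent(pois, radii = 1:6, n_windows = 300,
                                    seed = 11)
  expect_equal(a_pois, 2, tolerance = 0.2)

  spacing <- sqrt(2 / sqrt(3))
  lat <- generate_mosaic(generator_config(
    proportions = c(a = 1), intensity = 1, jitter_sd = 0.1 * spacing,
    window = c(72, 72), seed = 5
  ))
  a_lat <- count_variance_exponent(lat, radii = 1:6, n_windows = 300,
                                   seed = 11)
  expect_lt(a_lat, 1.9)

  expect_error(count_variance_exponent(pois, radii = 2), "at least 3")
  expect_error(count_variance_exponent(pois, radii = c(10, 20, 40)),
               "half the window")
})

test_that("hard-core mode respects the exclusion radius", {
  cfg <- generator_config(proportions = c(a = 0.6, b = 0.4),
                          intensity = 0.5, mode = "hard_core",
                          window = c(20, 20), exclusion_radius = 0.6,
                          seed = 2)
  pat <- generate_mosaic(cfg)
  st <- nnd_statistics(pat, toroidal = TRUE)
  # same-type nearest neighbours can never be closer than the hard core
  expect_true(all(st$nnd_mean >= 0.6))
  expect_error(
    generate_mosaic(generator_config(
      proportions = c(a = 1), intensity = 2, mode = "hard_core",
      window = c(5, 5), exclusion_radius = 3, seed = 1
    )),
    "infeasible"
  )
})

test_that("type proportions converge at the multinomial rate", {
  for (wside in c(25, 70)) {
    pat <- generate_mosaic(generator_config(
      proportions = c(a = 0.3, b = 0.7), intensity = 1,
      mode = "poisson", window = c(wside, wside), seed = 17
    ))
    n <- nrow(pat)
    p_hat <- mean(pat$type == "a")
    expect_lt(abs(p_hat - 0.3), 4 * sqrt(0.3 * 0.7 / n))
  }
})

test_that("beta recovery harness: noiseless limit and degenerate beta", {
  r0 <- recovery_experiment(avian_sigma, beta_true = 0, n_cells = 1e5,
                            n_reps = 5, seed = 8)
  expect_lt(abs(r0$mean), 0.05)

  # noiseless limit: fitting the exact weights returns beta exactly
  q <- gaussian_leup_weights(avian_sigma, 1.754)
  st <- cone_mosaic_stats(avian_labels, q, avian_sigma)
  expect_equal(fit_beta(st)$beta_hat, 1.754, tolerance = 1e-3)
})

test_that("full pipeline on a generated mosaic recovers the sensitivity", {
  b0 <- 1.754
  sig <- stats::setNames(avian_sigma, avian_labels)
  cfg <- generator_config(sigma = sig, beta_true = b0, intensity = 1,
                          jitter_sd = 0.15 * sig, window = c(100, 100),
                          seed = 42)
  pat <- generate_mosaic(cfg)
  expect_gte(nrow(pat), 1e4 * 0.9)
  st <- nnd_statistics(pat)
  fit <- fit_beta(st)
  expect_equal(fit$beta_hat, b0, tolerance = 0.2)
  expect_s3_class(autoplot(pat), "ggplot")
})
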