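# published avian cone-mosaic summary statistics, rebuilt in code so tests
# do not depend on the installed extdata fixture
avian_labels <- c("green", "red", "blue", "violet", "double")
avian_p <- c(0.204, 0.160, 0.133, 0.094, 0.409)
avian_sigma <- c(1.248, 1.548, 1.729, 2.292, 0.948)
avian_radii <- c(1.426, 2.006, 2.288, 3.553, 0.786)
avian_exponents <- c(1.247, 1.256, 1.322, 1.308, 0.440)

avian_stats <- function() {
  cone_mosaic_stats(avian_labels, avian_p, avian_sigma)
}

# brute-force LEUP weights in plain arithmetic, independent of the
# log-sum-exp implementation path
brute_leup_probs <- function(entropy, beta, mu = 0, n_count = 0) {
  w <- exp(-beta * entropy - mu * rep_len(n_count, length(entropy)))
  w / sum(w)
}

random_model <- function(n = 5) {
  list(
    entropy = stats::runif(n, -2, 2),
    n_count = stats::runif(n, 0, 4),
    beta = stats::runif(1, -3, 3),
    mu = stats::runif(1, 0, 2)
  )
}
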