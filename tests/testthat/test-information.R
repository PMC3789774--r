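test_that("binarize produces spike-count letters at the requested resolution", {
  expect_identical(binarize(numeric(0), duration = 10), integer(10))
  lt <- binarize(c(0.5, 1.5, 7.2), duration = 10)
  expect_identical(lt, c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L))
  # conservation: total letters = spike count (also with multi-spike bins)
  set.seed(1)
  st <- sort(runif(200, 0, 1000))
  expect_equal(sum(binarize(st, 1000)), 200)
  expect_equal(sum(binarize(st, 1000, dt_bin = 5)), 200)
})

test_that("total entropy: degenerate, fair-coin and Bernoulli oracles", {
  # identical constant responses carry zero entropy
  expect_equal(as.numeric(total_entropy(matrix(1L, 10, 100), K = 4)), 0)

  # i.i.d. fair coin: 2 bits per 2-letter word = 1000 bits/s at 1 ms letters
  m <- synthetic_fixtures("bernoulli_letters",
                          list(p = 0.5, trials = 60, bins = 1000), seed = 2)
  h2 <- total_entropy(m, K = 2)
  expect_equal(attr(h2, "H_word"), 2, tolerance = 0.001)
  expect_equal(as.numeric(h2), 1000, tolerance = 0.001)
  expect_equal(attr(h2, "occupied"), 4)

  # sparse Bernoulli: rate equals the analytic entropy rate at every K
  p <- 0.02
  m <- synthetic_fixtures("bernoulli_letters",
                          list(p = p, trials = 60, bins = 1000), seed = 3)
  for (K in c(2, 4, 8, 16))
    expect_equal(as.numeric(total_entropy(m, K, correct = TRUE)),
                 bernoulli_rate(p), tolerance = 0.02)
})

test_that("estimator consistency: extrapolated Bernoulli rate within 2%", {
  p <- 0.02
  m <- synthetic_fixtures("bernoulli_letters",
                          list(p = p, trials = 60, bins = 1000), seed = 7)
  trains <- apply(m, 1, function(row) which(row > 0) - 0.5, simplify = FALSE)
  est <- estimate_entropy_rate(trains, duration = 1000, type = "total")
  expect_equal(est$rate, bernoulli_rate(p), tolerance = 0.02)
  # per-K corrected rates are flat in K over the well-sampled range
  flat <- est$corrected_rate[est$K <= 16]
  expect_lt(diff(range(flat)) / bernoulli_rate(p), 0.02)
})

test_that("noise entropy: reproducible, stimulus-independent and two-pattern cases", {
  # identical trains across trials: perfectly reproducible, zero noise
  m <- matrix(rep(c(1L, 0L, 0L, 1L, 0L), 12), nrow = 6, byrow = TRUE)
  expect_equal(as.numeric(noise_entropy(m, K = 2)), 0)

  # stimulus-independent responses: noise entropy equals total entropy
  p <- 0.05
  m <- synthetic_fixtures("bernoulli_letters",
                          list(p = p, trials = 60, bins = 1000), seed = 5)
  # K restricted to word spaces the 60 trials can populate; at larger K the
  # per-start-time distributions are undersampled beyond the first-order
  # correction and the noise estimate is biased low
  for (K in c(2, 4)) {
    tot <- as.numeric(total_entropy(m, K, correct = TRUE))
    noi <- as.numeric(noise_entropy(m, K, correct = TRUE))
    expect_equal(noi, tot, tolerance = 0.05)
    expect_equal(noi, bernoulli_rate(p), tolerance = 0.05)
  }

  # two equiprobable deterministic patterns: H(t) = 1 bit per word
  fx <- synthetic_fixtures("two_pattern_trials", list(K = 8, trials = 60))
  ne <- noise_entropy(fx$unfrozen, K = 8)
  expect_equal(attr(ne, "H_word"), 1)
  expect_equal(as.numeric(noise_entropy(fx$frozen, K = 8)), 0)
})

test_that("noise entropy is exchangeable over trial labels", {
  m <- synthetic_fixtures("bernoulli_letters",
                          list(p = 0.05, trials = 30, bins = 200), seed = 6)
  set.seed(9)
  perm <- sample(nrow(m))
  expect_equal(as.numeric(noise_entropy(m, 4)),
               as.numeric(noise_entropy(m[perm, ], 4)))
})

test_that("bias correction has the first-order form and 1/N decay", {
  expect_equal(bias_correct(1.3, occupied = 1, samples = 50), 1.3)
  expect_equal(bias_correct(0, occupied = 2, samples = 100),
               1 / (200 * log(2)))
  expect_equal(bias_correct(0, occupied = 2, samples = 100), 0.00721,
               tolerance = 1e-3)
  ns <- 10^(2:5)
  corr <- vapply(ns, function(n) bias_correct(0, 5, n), numeric(1))
  expect_equal(corr[-length(ns)] / corr[-1], rep(10, 3))
  expect_error(bias_correct(1, 2, 0), "samples")
})

test_that("word-length extrapolation recovers the intercept and resists outliers", {
  K <- c(2, 4, 6, 8, 12, 16, 24, 32)
  rates <- 120 + 55 / K
  ex <- extrapolate_entropy(K, rates)
  expect_equal(ex$rate, 120)
  expect_equal(ex$slope, 55, tolerance = 1e-8)

  # an outlier at the smallest K is excluded by the most-linear rule
  rates2 <- rates
  rates2[1] <- rates2[1] + 40
  ex2 <- extrapolate_entropy(K, rates2)
  expect_false(2 %in% ex2$K_used)
  expect_equal(ex2$rate, 120)

  # negative intercepts are floored at zero
  expect_equal(extrapolate_entropy(K, -5 + 55 / K)$rate, 0)
  expect_error(extrapolate_entropy(c(2, 4, 6), c(1, 2, 3)), ">= 4")
})

test_that("mutual information subtracts entropies and floors at zero", {
  expect_equal(mutual_information(150, 150), 0)
  expect_equal(mutual_information(150, 90), 60)
  expect_warning(mi <- mutual_information(100, 104), "floored")
  expect_equal(mi, 0)
})

test_that("the full pipeline recovers the information of a two-pattern code", {
  K <- 8
  fx <- synthetic_fixtures("two_pattern_trials", list(K = K, trials = 60))
  to_train <- function(m) apply(m, 1, function(r) which(r > 0) - 0.5,
                                simplify = FALSE)
  info <- estimate_information(to_train(fx$unfrozen), to_train(fx$frozen),
                               duration = K, K_schedule = c(1, 2, 4, 8))
  # noiseless responses to 2 equiprobable stimuli: MI = stimulus entropy rate
  noi_at_K <- as.numeric(noise_entropy(letter_matrix(to_train(fx$frozen), K),
                                       K = K))
  expect_equal(noi_at_K, 0)
  tot_at_K <- as.numeric(total_entropy(letter_matrix(to_train(fx$unfrozen), K),
                                       K = K))
  expect_equal(tot_at_K, 1000 * fx$mi_bits_per_word / K)
})
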