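test_that("strong fields pin every sampled pattern to the bias sign", {
  prof <- morphogen_profile("custom", values = c(50, 50, -50, -50))
  params <- single_gene(4)
  for (m in c("exact_chain", "metropolis")) {
    ss <- sample_patterns(params, prof, 50, m, seed = 2, burn_in = 200)
    expect_true(all(ss$patterns[1, 1:2, ] == 1))
    expect_true(all(ss$patterns[1, 3:4, ] == -1))
  }
})

test_that("both samplers reproduce the exact site marginals", {
  set.seed(99)
  params <- random_nn_model(1, 8, eta_range = c(0.5, 2))
  prof <- lin_profile(8)
  exact <- site_marginals(params, prof)$marginals[1, ]
  n <- 20000
  for (m in c("exact_chain", "metropolis")) {
    ss <- sample_patterns(params, prof, n, m, seed = 3, burn_in = 1000)
    freq <- apply(ss$patterns[1, , , drop = TRUE] == 1, 1, mean)
    se <- sqrt(exact * (1 - exact) / n)
    # metropolis draws are autocorrelated; allow an inflated error band
    infl <- if (m == "metropolis") 8 else 3
    expect_true(all(abs(freq - exact) < infl * se + 1e-3),
                label = paste(m, "frequencies within the error band"))
  }
})

test_that("sampling is reproducible and validates its inputs", {
  params <- single_gene(6)
  prof <- lin_profile(6)
  a <- sample_patterns(params, prof, 20, "exact_chain", seed = 5)
  b <- sample_patterns(params, prof, 20, "exact_chain", seed = 5)
  expect_identical(a$patterns, b$patterns)

  lr <- model_params(N = 6, K = 1, n_slope = 1, E_thresh = 0,
                     spatial = long_range(-0.1, 3), eta = 1)
  expect_error(sample_patterns(lr, prof, 10, "exact_chain"), "nearest-neighbour")
  ss <- sample_patterns(lr, prof, 200, "metropolis", seed = 1, burn_in = 100)
  expect_equal(dim(ss$patterns), c(1, 6, 200))
})

test_that("mean patterns agree with the marginal identity", {
  set.seed(7)
  params <- random_nn_model(2, 7, eta_range = c(0.5, 2))
  prof <- lin_profile(7)
  ss <- sample_patterns(params, prof, 20000, "exact_chain", seed = 9)
  mp <- mean_pattern(ss)
  exact <- mean_pattern(site_marginals(params, prof))
  expect_lt(max(abs(mp - exact)), 4 / sqrt(20000) + 0.01)

  # zero-field symmetric model: means shrink to zero
  flat <- morphogen_profile("custom", values = rep(0, 8))
  s0 <- sample_patterns(single_gene(8, n = 0, J = 0.3), flat, 20000,
                        "exact_chain", seed = 12)
  expect_lt(max(abs(mean_pattern(s0))), 3 / sqrt(20000) * 2 + 0.01)

  expect_error(mean_pattern(constant_sample_set(counter_pattern(1, 4), 0)),
               "Empty")
})

test_that("identical samples average to the pattern itself", {
  pat <- counter_pattern(2, 8)
  expect_equal(mean_pattern(constant_sample_set(pat, 120)), pat,
               ignore_attr = TRUE)
})

test_that("plug-in information is exact on deterministic Counter samples", {
  est <- estimate_pi_from_samples(constant_sample_set(counter_pattern(2, 8), 400))
  expect_equal(est$total_bits, 2)
  expect_error(estimate_pi_from_samples(constant_sample_set(counter_pattern(2, 8), 50)),
               "100")
})

test_that("sampled information estimates track the transfer-matrix value", {
  set.seed(31)
  for (i in 1:3) {
    params <- random_nn_model(sample(1:2, 1), 8, eta_range = c(0.5, 2))
    prof <- lin_profile(8)
    exact <- positional_information(site_marginals(params, prof))$total_bits
    est <- estimate_pi_from_samples(
      sample_patterns(params, prof, 20000, "exact_chain", seed = i))
    expect_lt(abs(est$total_bits - exact), 3 * est$se + 0.003)
  }
})

test_that("plug-in bias decreases with the number of samples", {
  # a two-gene noisy model keeps the plug-in bias (~ states/2n ln 2) well
  # above the seed-averaging noise floor
  params <- model_params(N = 8, K = 2, n_slope = c(1, 1.5),
                         E_thresh = c(0, 0.3), J_local = 0.4,
                         spatial = nearest_neighbor(0.3), eta = 2)
  prof <- lin_profile(8)
  exact <- positional_information(site_marginals(params, prof))$total_bits
  bias_at <- function(n) {
    mean(vapply(1:20, function(s) {
      estimate_pi_from_samples(
        sample_patterns(params, prof, n, "exact_chain", seed = 400 + s)
      )$total_bits - exact
    }, numeric(1)))
  }
  biases <- vapply(c(100, 1000, 10000), bias_at, numeric(1))
  expect_true(all(diff(abs(biases)) < 0))
  # plug-in estimates are biased upward for mutual information
  expect_gt(biases[1], 0)
})

test_that("Miller-Madow correction moves the estimate toward less bias", {
  params <- single_gene(8, n = 1, J = 0.4, eta = 1.5)
  prof <- lin_profile(8)
  ss <- sample_patterns(params, prof, 300, "exact_chain", seed = 77)
  plain <- estimate_pi_from_samples(ss)$total_bits
  mm <- estimate_pi_from_samples(ss, correction = "miller_madow")$total_bits
  expect_lt(mm, plain)
})

test_that("the Metropolis kernel leaves the Boltzmann distribution stationary", {
  # two-site chain: compare joint pattern frequencies against Eq-1 weights
  params <- single_gene(2, n = 1, J = 0.6, eta = 1)
  prof <- morphogen_profile("custom", values = c(0.5, -0.3))
  n <- 1e6
  ss <- sample_patterns(params, prof, n, "metropolis", seed = 8,
                        burn_in = 1000, thinning = 1)
  code <- (ss$patterns[1, 1, ] == 1) * 2 + (ss$patterns[1, 2, ] == 1) + 1
  freq <- tabulate(code, 4) / n
  pats <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  w <- apply(pats, 1, function(s) exp(-pattern_energy(s, params, prof)))
  expect_lt(max(abs(freq - w / sum(w))), 1e-2)
})

test_that("sample sets round-trip through the delimited format", {
  params <- single_gene(5)
  ss <- sample_patterns(params, lin_profile(5), 30, "exact_chain", seed = 6)
  path <- withr::local_tempfile(fileext = ".txt")
  write_samples(ss, path)
  back <- read_samples(path)
  expect_identical(back$patterns, ss$patterns)
  expect_identical(back$method, ss$method)
})
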