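test_that("transfer-matrix marginals solve the uncoupled chain in closed form", {
  prof <- lin_profile(20)
  flat <- morphogen_profile("custom", values = rep(0, 12))
  sym <- site_marginals(single_gene(12, n = 0), flat)
  expect_equal(sym$marginals[1, ], rep(0.5, 12))

  params <- single_gene(20, n = 1.3, E = 0.2, J = 0, eta = 1.7)
  got <- site_marginals(params, prof)$marginals[1, ]
  h <- 1.3 * (profile_values(prof) - 0.2)
  expect_equal(got, exp(h / 1.7) / (2 * cosh(h / 1.7)), tolerance = 1e-12)
})

test_that("transfer matrix agrees with exhaustive enumeration", {
  set.seed(11)
  for (i in 1:12) {
    K <- sample(1:2, 1)
    N <- sample(3:(16 %/% K), 1)
    params <- random_nn_model(K, N)
    prof <- morphogen_profile(sample(c("linear", "exponential"), 1),
                              N = N, chi = 0.3)
    tm <- site_marginals(params, prof)
    bf <- brute_force_distribution(params, prof)
    expect_lt(max(abs(tm$marginals - bf$marginals)), 1e-10)
    expect_equal(tm$log_partition, bf$log_partition, tolerance = 1e-10)
  }
})

test_that("brute force matches a four-pattern hand enumeration", {
  # K = 1, N = 2, h = (1, -1), J = 0, eta = 1: H = -(s1 - s2),
  # weights e^{-H}: (+,+) -> 1, (+,-) -> e^2, (-,+) -> e^-2, (-,-) -> 1
  params <- single_gene(2, n = 1, J = 0)
  prof <- morphogen_profile("custom", values = c(1, -1))
  bf <- brute_force_distribution(params, prof)
  Z <- 2 + exp(2) + exp(-2)
  expect_equal(bf$log_partition, log(Z), tolerance = 1e-12)
  expect_equal(bf$marginals[1, 1], (1 + exp(2)) / Z, tolerance = 1e-12)
  expect_equal(bf$marginals[1, 2], (1 + exp(-2)) / Z, tolerance = 1e-12)
  expect_equal(colSums(bf$marginals), c(1, 1), tolerance = 1e-12)
  expect_error(brute_force_distribution(single_gene(25), lin_profile(25)),
               "K \\* N")
})

test_that("positional information decomposes and hits the reference values", {
  expect_equal(positional_information(
    as_distribution(c(rep(1, 25), rep(-1, 25))))$total_bits, 1)
  expect_equal(positional_information(
    as_distribution(counter_pattern(2, 8)))$total_bits, 2)
  expect_equal(positional_information(
    as_distribution(matrix(1, 1, 30)))$total_bits, 0)

  set.seed(3)
  for (i in 1:8) {
    params <- random_nn_model(sample(1:2, 1), 10)
    pr <- positional_information(site_marginals(params, lin_profile(10)))
    expect_equal(pr$total_bits, pr$state_entropy_bits - pr$noise_entropy_bits,
                 tolerance = 1e-10)
    expect_gte(pr$total_bits, -1e-10)
    expect_lte(pr$total_bits, min(params$K, log2(10)) + 1e-10)
  }
})

test_that("information is invariant under lattice reflection", {
  set.seed(5)
  for (i in 1:5) {
    N <- 12
    params <- random_nn_model(2, N)
    prof <- lin_profile(N)
    refl <- morphogen_profile("custom", values = rev(profile_values(prof)))
    expect_equal(
      positional_information(site_marginals(params, prof))$total_bits,
      positional_information(site_marginals(params, refl))$total_bits,
      tolerance = 1e-10
    )
  }
})

test_that("intrinsic noise drives information between its limits", {
  prof <- lin_profile(30)
  etas <- c(0.01, 0.5, 2, 8, 32)
  pis <- vapply(etas, function(e) {
    positional_information(site_marginals(single_gene(30, eta = e), prof))$total_bits
  }, numeric(1))
  expect_true(all(diff(pis) < 0))
  expect_equal(pis[1], 1, tolerance = 0.01)
  expect_lt(pis[length(pis)], 0.01)
})

test_that("extrinsic averaging degrades gracefully to the exact marginals", {
  prof <- set_noise(lin_profile(15), 1e-8)
  params <- single_gene(15, eta = 1)
  ea <- extrinsic_average(params, prof, n_draws = 20, seed = 2)
  expect_lt(max(abs(ea$marginals -
                    site_marginals(params, set_noise(prof, 0))$marginals)), 1e-3)
  expect_error(extrinsic_average(params, set_noise(prof, 0), 10), "positive")
  expect_error(extrinsic_average(params, prof, 1), "at least 2")
  # reproducibility
  a <- extrinsic_average(params, set_noise(prof, 0.2), 15, seed = 7)
  b <- extrinsic_average(params, set_noise(prof, 0.2), 15, seed = 7)
  expect_identical(a$marginals, b$marginals)
})

test_that("extrinsic noise reduces the information of the boundary readout", {
  params <- single_gene(20, n = 5, J = 1, eta = 0.5)
  pi0 <- positional_information(site_marginals(params, lin_profile(20)))$total_bits
  for (s in 1:5) {
    ea <- extrinsic_average(params, set_noise(lin_profile(20), 0.3), 60, seed = s)
    expect_lt(positional_information(ea)$total_bits, pi0)
  }
})

test_that("Monte Carlo error of averaged information shrinks at the standard rate", {
  params <- single_gene(12, n = 2, J = 0.5, eta = 1)
  prof <- set_noise(lin_profile(12), 0.3)
  draws <- c(25, 50, 100)
  vars <- vapply(draws, function(nd) {
    pis <- vapply(1:20, function(r) {
      positional_information(
        extrinsic_average(params, prof, nd, seed = 1000 + 17 * r + nd)
      )$total_bits
    }, numeric(1))
    var(pis)
  }, numeric(1))
  slope <- coef(lm(log(vars) ~ log(draws)))[2]
  expect_lt(slope, -0.5)
  expect_gt(slope, -1.8)
})

test_that("signal-channel information has the right limits and matches MC", {
  flat <- set_noise(morphogen_profile("custom", values = rep(0.4, 30)), 0.2)
  expect_equal(morphogen_information(flat), 0)

  sharp <- set_noise(lin_profile(16), 1e-6)
  expect_equal(morphogen_information(sharp), log2(16), tolerance = 0.01)

  prof <- set_noise(lin_profile(50), 0.1)
  iq <- morphogen_information(prof)
  # Monte Carlo oracle: I = -E[log2 Pm(m)] - 0.5 log2(2 pi e nu) with m drawn
  # from the mixture; the mixture density is evaluated in closed form
  set.seed(8)
  nmc <- 40000
  m <- profile_values(prof)
  x <- sample.int(50, nmc, replace = TRUE)
  obs <- rnorm(nmc, m[x], sqrt(0.1))
  dens <- rowMeans(vapply(m, function(mu) dnorm(obs, mu, sqrt(0.1)),
                          numeric(nmc)))
  terms <- -log2(dens) - 0.5 * log2(2 * pi * exp(1) * 0.1)
  imc <- mean(terms)
  se <- sd(terms) / sqrt(nmc)
  expect_lt(abs(iq - imc), 3 * se)
  expect_error(morphogen_information(set_noise(prof, 0)), "positive")
})

test_that("uncoupled readouts never beat the signal channel", {
  set.seed(21)
  for (i in 1:5) {
    params <- model_params(N = 12, K = 1, n_slope = runif(1, 0, 4),
                           E_thresh = runif(1, -0.5, 0.5),
                           spatial = nearest_neighbor(0), eta = runif(1, 0.3, 2))
    prof <- set_noise(lin_profile(12), 0.3)
    g <- dpi_gap(params, prof, n_draws = 150, seed = i)
    expect_lte(g$gap, 3 * g$se)
  }
  # destroying the channel sends both informations to zero
  prof_big <- set_noise(lin_profile(12), 100)
  g <- dpi_gap(single_gene(12), prof_big, n_draws = 100, seed = 1)
  expect_lt(abs(g$pi_signal), 0.05)
  expect_lt(abs(g$pi_pattern), 0.05)
})

test_that("marginal columns are proper distributions", {
  set.seed(13)
  params <- random_nn_model(2, 9)
  d <- site_marginals(params, lin_profile(9))
  expect_true(all(d$marginals >= 0))
  expect_lt(max(abs(colSums(d$marginals) - 1)), 1e-10)
})
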