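test_that("reference patterns carry their closed-form information", {
  cp <- counter_pattern(2, 8)
  expect_equal(cp[1, ], rep(c(1L, -1L), each = 4))
  expect_equal(cp[2, ], rep(c(1L, 1L, -1L, -1L, 1L, 1L, -1L, -1L)))
  expect_equal(positional_information(as_distribution(cp))$total_bits, 2)

  expect_equal(length(unique(spin_state_index(counter_pattern(3, 8), 3))), 8)
  expect_equal(counter_pattern(1, 2)[1, ], c(1L, -1L))

  ff <- french_flag_pattern(3, 2, 60)
  expect_equal(positional_information(as_distribution(ff))$total_bits, log2(3))
  expect_equal(french_flag_pattern(2, 1, 50)[1, ],
               c(rep(1L, 25), rep(-1L, 25)))
  ff4 <- french_flag_pattern(4, 3, 8)
  expect_equal(positional_information(as_distribution(ff4))$total_bits, 2)

  # noiseless information equals the entropy of the state-usage vector
  for (pat in list(cp, ff, ff4)) {
    pr <- positional_information(as_distribution(pat))
    usage <- pr$state_usage[pr$state_usage > 0]
    expect_equal(pr$total_bits, -sum(usage * log2(usage)), tolerance = 1e-12)
  }
  expect_error(counter_pattern(2, 10), "divisible")
  expect_error(french_flag_pattern(3, 1, 9), "between")
})

test_that("pattern classification recognizes the canonical archetypes", {
  expect_identical(classify_pattern(counter_pattern(2, 8)),
                   tibble::tibble(label = "counter", n_states = 4L))
  expect_identical(classify_pattern(matrix(1, 1, 20))$label, "uniform")
  alt <- matrix(rep(c(1, -1), 10), 1)
  expect_identical(classify_pattern(alt),
                   tibble::tibble(label = "alternating", n_states = 2L))
  expect_identical(classify_pattern(french_flag_pattern(3, 2, 60))$label,
                   "french_flag")
  both <- rbind(c(rep(1, 5), rep(-1, 5)), c(rep(1, 5), rep(-1, 5)))
  expect_identical(classify_pattern(both)$label, "boundary")
  expect_error(classify_pattern(matrix(2, 1, 4)), "\\[-1, 1\\]")
})

test_that("overlap is the normalized pattern inner product", {
  a <- counter_pattern(2, 8)
  expect_equal(pattern_overlap(a, a), 1)
  expect_equal(pattern_overlap(a, -a), -1)
  half <- a; half[, 1:4] <- -half[, 1:4]
  expect_equal(pattern_overlap(a, half), 0)
  # symmetry and joint-flip invariance
  set.seed(2)
  b <- matrix(runif(16, -1, 1), 2, 8)
  expect_equal(pattern_overlap(a, b), pattern_overlap(b, a))
  expect_equal(pattern_overlap(-a, -b), pattern_overlap(a, b))
  expect_error(pattern_overlap(a, a[, 1:4]), "match")
})

test_that("overlap at zero perturbation is one in the deterministic regime", {
  # S(0) = mean(<sigma>^2) reaches 1 only when expression is deterministic;
  # the Counter network's gene-2 switches are knife-edge at half-maximal
  # signal, so the nearest lattice sites only harden at very low noise
  params <- counter_network(N = 24, eta = 0.02)
  ov <- overlap_profile(params, lin_profile(24), c(-0.2, 0, 0.2))
  expect_equal(ov$overlap[ov$epsilon == 0], 1, tolerance = 1e-3)
  expect_true(all(ov$overlap >= -1 - 1e-9 & ov$overlap <= 1 + 1e-9))
})

test_that("finite-difference susceptibility matches the closed-form derivative", {
  # J = 0 single gene: S(eps) = mean(tanh(h0/eta) tanh(h_eps/eta)) with
  # dS/deps at 0 = (n/eta) mean(tanh(h0/eta) (1 - tanh(h0/eta)^2));
  # an asymmetric (exponential) profile keeps the derivative away from zero
  prof <- morphogen_profile("exponential", N = 30, chi = 0.15)
  n <- 2; E <- 0.2; eta <- 1.5
  params <- single_gene(30, n = n, E = E, J = 0, eta = eta)
  got <- susceptibility(params, prof, delta_eps = 0.05)
  t0 <- tanh(n * (profile_values(prof) - E) / eta)
  analytic <- (n / eta) * mean(t0 * (1 - t0^2))
  expect_lt(abs(got$chi_m - analytic), 1e-3)
  expect_identical(got$se, 0)
  expect_error(susceptibility(params, prof, delta_eps = 0), "positive")
})

test_that("patterns far from threshold are insensitive to small offsets", {
  prof <- morphogen_profile("custom", values = rep(c(50, -50), each = 5))
  params <- single_gene(10, n = 1, J = 0, eta = 1)
  expect_equal(susceptibility(params, prof, delta_eps = 0.05)$chi_m, 0)
})

test_that("the error bound evaluates the printed closed form", {
  expect_equal(positional_error_bound(log2(50), 50), 0)
  expect_equal(positional_error_bound(0, 50), (50^2 - 1) / 12)
  expect_equal(positional_error_bound(1, 50), 52)
  expect_error(positional_error_bound(-0.1, 10), "log2")
  expect_error(positional_error_bound(5, 10), "log2")
})

test_that("optimal estimator mse matches a direct hand computation", {
  # deterministic half/half pattern on N = 4: posterior uniform over two
  # sites per state; best estimate is their midpoint, mse = 0.25
  d <- as_distribution(c(1, 1, -1, -1))
  expect_equal(optimal_estimator_mse(d), 0.25)
  # uninformative distribution: mse equals the prior variance
  flat <- morphogen_profile("custom", values = rep(0, 5))
  d0 <- site_marginals(single_gene(5, n = 0), flat)
  expect_equal(optimal_estimator_mse(d0), var(1:5) * 4 / 5)
})

test_that("boundary extraction interpolates zero crossings", {
  mp <- matrix(c(0.8, 0.4, -0.4, -0.8), 1)
  b <- boundary_positions(mp)
  expect_equal(b$position, 2.5)
  expect_equal(b$fraction, 2.5 / 4)
  expect_equal(nrow(boundary_positions(matrix(1, 1, 6))), 0)
  # main_boundary ignores shallow wiggles away from the principal wall
  wig <- matrix(c(0.9, 0.8, -0.05, 0.05, 0.9, 0.8, -0.8, -0.9, -0.8, -0.9), 1)
  expect_equal(main_boundary(wig)$position, 6.5, tolerance = 0.5)
})

test_that("scaling at the base size reproduces the unperturbed pattern", {
  params <- counter_network(N = 24, eta = 0.3)
  prof <- lin_profile(24)
  sc <- scaling_experiment(params, prof, sizes = 24)
  expect_equal(sc$mean_patterns[["24"]],
               mean_pattern(site_marginals(params, prof)), tolerance = 1e-12)
  expect_error(scaling_experiment(params, prof, sizes = c(1, 24)), "at least 2")
})

test_that("without long-range coupling boundaries sit at absolute positions", {
  params <- counter_network(N = 60, eta = 0.3)
  sc <- scaling_experiment(params, lin_profile(60), sizes = c(50, 60, 70))
  pos <- vapply(sc$mean_patterns, function(mp) main_boundary(mp)$position[1],
                numeric(1))
  expect_lt(max(pos) - min(pos), 1)
})
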