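#' Overlap between two mean expression patterns
#'
#' The normalized inner product
#' `S = (1 / (N K)) sum_{a, x} <sigma_a(x)>_ref <sigma_a(x)>_pert`,
#' averaged over genes as well as sites so that it reduces to the
#' single-gene form at `K = 1`. For deterministic patterns, 1 means the
#' perturbed pattern is identical to the reference, 0 that on average half
#' the expression states are inverted, and -1 that it is the exact inverse.
#'
#' @param mean_ref,mean_perturbed `K x N` matrices of mean expression
#'   values (vectors for `K = 1`).
#' @return The overlap, a scalar in `[-1, 1]`.
#' @export
pattern_overlap <- function(mean_ref, mean_perturbed) {
  if (is.vector(mean_ref)) mean_ref <- matrix(mean_ref, nrow = 1)
  if (is.vector(mean_perturbed)) mean_perturbed <- matrix(mean_perturbed, nrow = 1)
  if (!all(dim(mean_ref) == dim(mean_perturbed))) {
    stop("Mean patterns must have matching dimensions.", call. = FALSE)
  }
  mean(mean_ref * mean_perturbed)
}

# mean pattern under a dosage offset eps, exact when possible else sampled
mean_pattern_at <- function(params, profile, eps, method, n_samples, burn_in,
                            seed, init = "field", n_chains = 1,
                            anneal_factor = 1) {
  prof <- set_offset(profile, attr(profile, "epsilon") + eps)
  if (method == "exact") {
    mean_pattern(site_marginals(params, prof))
  } else {
    chains <- lapply(seq_len(n_chains), function(k) {
      mean_pattern(sample_patterns(params, prof, n_samples, "metropolis",
                                   seed = seed + (k - 1L), burn_in = burn_in,
                                   init = init, anneal_factor = anneal_factor))
    })
    Reduce(`+`, chains) / n_chains
  }
}

#' Overlap profile under morphogen dosage perturbations
#'
#' Computes the overlap `S(eps)` between the mean pattern at dosage offset
#' `eps` and the unperturbed (`eps = 0`) reference, over a grid of offsets.
#' Uses exact marginals for nearest-neighbour models; long-range models are
#' sampled by Metropolis with a common seed across offsets (paired
#' perturbations).
#'
#' @inheritParams site_marginals
#' @param epsilon_grid Numeric vector of offsets.
#' @param method `"auto"`, `"exact"` or `"metropolis"`.
#' @param n_samples,burn_in Metropolis schedule when sampling.
#' @param seed Seed used for every sampled evaluation (common random
#'   numbers).
#' @param init Metropolis initialization (see [sample_patterns()]);
#'   defaults to `"field"` because robustness analyses target strongly
#'   ordered regimes where random starts equilibrate slowly.
#' @param n_chains Number of independent Metropolis chains averaged per
#'   mean-pattern evaluation (consecutive seeds); reduces the freezing of
#'   single chains in metastable wall configurations.
#' @param anneal_factor Burn-in annealing factor passed to
#'   [sample_patterns()]; values above 1 help glassy long-range models
#'   relax to the dominant basin before recording.
#' @return A tibble with columns `epsilon` and `overlap`.
#' @export
overlap_profile <- function(params, profile, epsilon_grid,
                            method = c("auto", "exact", "metropolis"),
                            n_samples = 2000, burn_in = 1000, seed = 1L,
                            init = "field", n_chains = 1, anneal_factor = 1) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (all_nearest_neighbor(params)) "exact" else "metropolis"
  }
  ref <- mean_pattern_at(params, profile, 0, method, n_samples, burn_in, seed,
                         init, n_chains, anneal_factor)
  tibble::tibble(
    epsilon = epsilon_grid,
    overlap = vapply(epsilon_grid, function(eps) {
      pattern_overlap(ref, mean_pattern_at(params, profile, eps, method,
                                           n_samples, burn_in, seed, init,
                                           n_chains, anneal_factor))
    }, numeric(1))
  )
}

#' Susceptibility of the pattern to small dosage perturbations
#'
#' Central finite difference of the overlap with respect to the dosage
#' offset, `chi_m = (S(+delta) - S(-delta)) / (2 delta)`, with the
#' unperturbed pattern as reference. A susceptibility near zero marks the
#' canalized regime in which the pattern is pinned by its internal
#' interactions rather than by the morphogen level.
#'
#' @inheritParams overlap_profile
#' @param delta_eps Positive finite-difference step.
#' @return A one-row tibble with columns `chi_m`, `delta_eps`, `se`
#'   (jackknife-free sampling error estimate: 0 for the exact route, the
#'   difference between two half-sample estimates otherwise).
#' @export
susceptibility <- function(params, profile, delta_eps = 0.05,
                           method = c("auto", "exact", "metropolis"),
                           n_samples = 2000, burn_in = 1000, seed = 1L,
                           init = "field", n_chains = 1, anneal_factor = 1) {
  if (delta_eps <= 0) stop("`delta_eps` must be positive.", call. = FALSE)
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (all_nearest_neighbor(params)) "exact" else "metropolis"
  }
  chi_of <- function(ns, sd_seed) {
    ref <- mean_pattern_at(params, profile, 0, method, ns, burn_in, sd_seed,
                           init, n_chains, anneal_factor)
    s_plus <- pattern_overlap(ref, mean_pattern_at(params, profile, delta_eps,
                                                   method, ns, burn_in, sd_seed,
                                                   init, n_chains,
                                                   anneal_factor))
    s_minus <- pattern_overlap(ref, mean_pattern_at(params, profile, -delta_eps,
                                                    method, ns, burn_in, sd_seed,
                                                    init, n_chains,
                                                    anneal_factor))
    (s_plus - s_minus) / (2 * delta_eps)
  }
  chi <- chi_of(n_samples, seed)
  se <- if (method == "exact") {
    0
  } else {
    half <- c(chi_of(ceiling(n_samples / 2), seed + 101L),
              chi_of(ceiling(n_samples / 2), seed + 202L))
    abs(diff(half)) / 2
  }
  tibble::tibble(chi_m = chi, delta_eps = delta_eps, se = se)
}

#' System-size scaling experiment
#'
#' Starting from a base profile (default size `N = 60`), the tissue is cut
#' short (profile truncated) or extended at a constant posterior signal
#' value, the mean pattern is computed at each size, and per-gene boundary
#' positions are extracted as zero crossings of the mean. Without long-range
#' couplings boundaries stay at fixed absolute positions; with sufficiently
#' strong negative long-range couplings the balance penalty pulls the
#' central boundary to a fixed fractional position (approximate scaling).
#'
#' @param params A [model_params()] defined on the base profile's size.
#' @param base_profile A [morphogen_profile()].
#' @param sizes Integer vector of system sizes to evaluate.
#' @param method,n_samples,burn_in,seed,init,n_chains,anneal_factor As in
#'   [overlap_profile()].
#' @return A list with `boundaries` (tibble: `size`, `gene`, `crossing`,
#'   `position`, `fraction`) and `mean_patterns` (named list of `K x N_s`
#'   matrices).
#' @export
scaling_experiment <- function(params, base_profile, sizes = c(50, 60, 70),
                               method = c("auto", "exact", "metropolis"),
                               n_samples = 2000, burn_in = 1000, seed = 1L,
                               init = "field", n_chains = 1,
                               anneal_factor = 1) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (all_nearest_neighbor(params)) "exact" else "metropolis"
  }
  if (any(sizes < 2)) stop("Sizes must be at least 2.", call. = FALSE)
  base_m <- profile_values(base_profile)
  N0 <- length(base_m)
  means <- list()
  rows <- list()
  for (Ns in sizes) {
    m <- if (Ns <= N0) base_m[seq_len(Ns)] else c(base_m, rep(base_m[N0], Ns - N0))
    prof <- morphogen_profile("custom", values = m,
                              nu = attr(base_profile, "nu"),
                              epsilon = attr(base_profile, "epsilon"))
    p <- set_lattice_size(params, Ns)
    mp <- mean_pattern_at(p, prof, 0, method, n_samples, burn_in, seed, init,
                          n_chains, anneal_factor)
    means[[as.character(Ns)]] <- mp
    b <- boundary_positions(mp)
    if (nrow(b) > 0) b$size <- Ns
    rows[[as.character(Ns)]] <- b
  }
  list(boundaries = dplyr::bind_rows(rows), mean_patterns = means)
}

#' Lower bound on the positional estimation error
#'
#' For a pattern carrying `pi_bits` of positional information on `N` sites
#' with a uniform position prior, the mean squared error of any positional
#' estimator is bounded below by `(1/12) (N^2 2^(-2 pi) - 1)`. At
#' `pi = 0` this is the variance `(N^2 - 1)/12` of the uniform prior; at
#' `pi = log2 N` it vanishes.
#'
#' @param pi_bits Positional information in bits, in `[0, log2 N]`.
#' @param N Lattice size.
#' @return The error bound (site units squared).
#' @export
positional_error_bound <- function(pi_bits, N) {
  if (any(pi_bits < 0) || any(pi_bits > log2(N) + 1e-9)) {
    stop("`pi_bits` must lie in [0, log2(N)].", call. = FALSE)
  }
  (N^2 * 2^(-2 * pi_bits) - 1) / 12
}

#' Mean squared error of the optimal positional estimator
#'
#' Brute-force evaluation of the best achievable estimator of position from
#' the local expression state: the posterior `P(x | sigma)` is formed by
#' Bayesian inversion of the per-site marginals under a uniform prior, the
#' optimal estimator is the posterior mean, and the MSE is averaged over
#' states and positions. Together with [positional_error_bound()] this
#' verifies the information bound on small models.
#'
#' @param dist A `"pattern_distribution"`.
#' @return The mean squared error (site units squared).
#' @export
optimal_estimator_mse <- function(dist) {
  marg <- dist$marginals
  N <- ncol(marg)
  x <- seq_len(N)
  p_state <- rowMeans(marg)                    # P(sigma)
  post <- sweep(marg, 1, N * p_state, "/")     # P(x | sigma), rows over states
  post[p_state == 0, ] <- 0
  xhat <- as.numeric(post %*% x)               # E[x | sigma]
  mse <- 0
  for (s in which(p_state > 0)) {
    mse <- mse + sum((1 / N) * marg[s, ] * (x - xhat[s])^2)
  }
  mse
}
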