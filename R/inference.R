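#' Spin assignments of the 2^K joint local states
#'
#' Local expression states are indexed `1..2^K`; writing `state - 1` in
#' binary with `K` bits (gene 1 = most significant bit), a bit value of 0
#' means the gene is ON (+1) and 1 means OFF (-1). State 1 is therefore
#' all-ON and state `2^K` all-OFF, matching the block order of
#' [counter_pattern()].
#'
#' @param K Number of genes.
#' @return A `2^K x K` matrix of ±1 spins; row `s` gives the spins of state `s`.
#' @export
state_spins <- function(K) {
  S <- 2^K
  out <- matrix(0L, S, K)
  for (a in seq_len(K)) {
    bit <- bitwAnd(bitwShiftR(seq_len(S) - 1L, K - a), 1L)
    out[, a] <- ifelse(bit == 0L, 1L, -1L)
  }
  out
}

# state index (1-based) of a K-vector / K x n matrix of spins
spin_state_index <- function(spins, K) {
  if (is.vector(spins)) spins <- matrix(spins, nrow = K)
  bits <- (1 - spins) / 2 # +1 -> 0, -1 -> 1
  as.integer(colSums(bits * 2^((K - 1):0)) + 1)
}

new_pattern_distribution <- function(marginals, log_partition, params, profile,
                                     se = NULL, n_draws = NULL, draw_pi = NULL) {
  structure(
    list(marginals = marginals, log_partition = log_partition,
         params = params, profile = profile,
         se = se, n_draws = n_draws, draw_pi = draw_pi),
    class = "pattern_distribution"
  )
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("<pattern_distribution> %d local states x %d sites, log Z = %s\n",
              nrow(x$marginals), ncol(x$marginals),
              if (is.finite(x$log_partition)) signif(x$log_partition, 6) else "NA"))
  invisible(x)
}

# per-state on-site log weight (2^K x N) and bond log-weight matrix (2^K x 2^K)
transfer_weights <- function(params, profile) {
  K <- params$K
  S <- state_spins(K)
  h <- gene_biases(params, profile)              # K x N
  loc <- rowSums((S %*% params$J_local) * S)     # sum over ordered gene pairs
  logW <- (S %*% h + loc) / params$eta           # 2^K x N
  Jnn <- vapply(params$spatial, function(sp) sp$J, numeric(1))
  logT <- (S %*% (Jnn * t(S))) / params$eta      # 2^K x 2^K
  list(logW = logW, logT = logT)
}

#' Exact per-site state marginals by transfer matrices
#'
#' Computes the exact marginal distribution `P(sigma | x)` over the `2^K`
#' joint local expression states at every site, together with the log
#' partition function, by forward/backward products of `2^K x 2^K` transfer
#' matrices with Boltzmann weights `exp(-H / eta)`. Applicable to
#' nearest-neighbour spatial couplings only; long-range models must be
#' sampled (see [sample_patterns()]). Extrinsic signal noise is handled by
#' [extrinsic_average()].
#'
#' @param params A [model_params()] with nearest-neighbour spatial specs.
#' @param profile A [morphogen_profile()] of matching length.
#' @return A `"pattern_distribution"`: list with `marginals` (`2^K x N`,
#'   columns summing to 1), `log_partition`, and the generating
#'   `params` / `profile`.
#' @export
site_marginals <- function(params, profile) {
  if (!all_nearest_neighbor(params)) {
    stop(paste("Exact transfer-matrix marginals require nearest-neighbour",
               "spatial couplings; use sample_patterns() for long-range models."),
         call. = FALSE)
  }
  if (nrow(profile) != params$N) {
    stop("Profile length does not match the model.", call. = FALSE)
  }
  N <- params$N
  w <- transfer_weights(params, profile)
  cT <- max(w$logT)
  Tm <- exp(w$logT - cT)

  nstate <- nrow(w$logW)
  fwd <- matrix(0, nstate, N)
  logZ <- (N - 1) * cT
  c1 <- max(w$logW[, 1])
  f <- exp(w$logW[, 1] - c1)
  logZ <- logZ + c1
  z <- sum(f); f <- f / z; logZ <- logZ + log(z)
  fwd[, 1] <- f
  for (x in 2:N) {
    cx <- max(w$logW[, x])
    f <- drop(f %*% Tm) * exp(w$logW[, x] - cx)
    z <- sum(f)
    logZ <- logZ + cx + log(z)
    f <- f / z
    fwd[, x] <- f
  }
  bwd <- matrix(0, nstate, N)
  b <- rep(1, nstate)
  bwd[, N] <- b
  for (x in (N - 1):1) {
    cx <- max(w$logW[, x + 1])
    b <- drop(Tm %*% (exp(w$logW[, x + 1] - cx) * b))
    b <- b / sum(b)
    bwd[, x] <- b
  }
  marg <- fwd * bwd
  marg <- sweep(marg, 2, colSums(marg), "/")
  new_pattern_distribution(marg, logZ, params, profile)
}

#' Exhaustive-enumeration pattern distribution
#'
#' Enumerates all `2^(K N)` patterns, weights each by `exp(-H / eta)`,
#' normalizes, and marginalizes per site. Supports arbitrary (including
#' long-range) spatial kernels; intended as a small-system oracle and
#' therefore refuses `K * N > 20`.
#'
#' @inheritParams site_marginals
#' @return A `"pattern_distribution"` (see [site_marginals()]).
#' @export
brute_force_distribution <- function(params, profile) {
  K <- params$K; N <- params$N
  if (K * N > 20) {
    stop("Exhaustive enumeration is limited to K * N <= 20.", call. = FALSE)
  }
  if (nrow(profile) != N) {
    stop("Profile length does not match the model.", call. = FALSE)
  }
  nspin <- K * N
  M <- 2^nspin
  idx <- seq_len(M) - 1L
  # spins[m, j]: spin j (gene a = (j-1) %/% N + 1, site x = (j-1) %% N + 1)
  spins <- matrix(0, M, nspin)
  for (j in seq_len(nspin)) {
    spins[, j] <- ifelse(bitwAnd(bitwShiftR(idx, nspin - j), 1L) == 0L, 1, -1)
  }
  h <- gene_biases(params, profile)
  logw <- numeric(M)
  for (a in seq_len(K)) {
    cols <- ((a - 1) * N + 1):(a * N)
    Xa <- spins[, cols, drop = FALSE]
    J <- interaction_matrix(params$spatial[[a]], N)
    Ju <- J; Ju[lower.tri(Ju, diag = TRUE)] <- 0
    logw <- logw + Xa %*% h[a, ] + rowSums((Xa %*% Ju) * Xa)
  }
  if (K > 1) {
    for (a in seq_len(K - 1)) {
      for (g in (a + 1):K) {
        Xa <- spins[, ((a - 1) * N + 1):(a * N), drop = FALSE]
        Xg <- spins[, ((g - 1) * N + 1):(g * N), drop = FALSE]
        logw <- logw + 2 * params$J_local[a, g] * rowSums(Xa * Xg)
      }
    }
  }
  logw <- logw / params$eta
  cmax <- max(logw)
  wgt <- exp(logw - cmax)
  Z <- sum(wgt)
  logZ <- cmax + log(Z)
  p <- wgt / Z
  marg <- matrix(0, 2^K, N)
  for (x in seq_len(N)) {
    sp <- t(spins[, (seq_len(K) - 1) * N + x, drop = FALSE]) # K x M
    st <- spin_state_index(sp, K)
    marg[, x] <- vapply(seq_len(2^K), function(s) sum(p[st == s]), numeric(1))
  }
  new_pattern_distribution(marg, logZ, params, profile)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Positional information of a pattern distribution
#'
#' The mutual information between lattice position and the local expression
#' state, `I(sigma; x) = S[P_sigma] - <S[P(sigma|x)]>_x` in bits, with a
#' uniform prior over positions: `P_sigma` is the across-lattice average of
#' the per-site state distributions ("state usage"), its entropy rewards
#' diverse use of expression states, and the average conditional ("noise")
#' entropy penalizes variability uncorrelated with position.
#'
#' @param dist A `"pattern_distribution"` (from [site_marginals()],
#'   [brute_force_distribution()], [extrinsic_average()], or
#'   [as_distribution()]).
#' @return A `"pi_result"`: list with `total_bits`, `state_entropy_bits`,
#'   `noise_entropy_bits`, `state_usage`, and when available an `se` field
#'   (Monte Carlo standard error). Use [glance()] for a one-row tibble.
#' @export
positional_information <- function(dist) {
  stopifnot(inherits(dist, "pattern_distribution"))
  marg <- dist$marginals
  usage <- rowMeans(marg)
  s_state <- entropy_bits(usage)
  s_noise <- mean(apply(marg, 2, entropy_bits))
  se <- NULL
  if (!is.null(dist$draw_pi) && length(dist$draw_pi$loo) > 1) {
    # delete-one jackknife over extrinsic draws
    loo <- dist$draw_pi$loo
    n <- length(loo)
    se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  }
  structure(
    list(total_bits = s_state - s_noise,
         state_entropy_bits = s_state,
         noise_entropy_bits = s_noise,
         state_usage = usage,
         se = se),
    class = "pi_result"
  )
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("<pi_result> I(sigma; x) = %.4f bits (state %.4f - noise %.4f)%s\n",
              x$total_bits, x$state_entropy_bits, x$noise_entropy_bits,
              if (!is.null(x$se)) sprintf(" +/- %.4f", x$se) else ""))
  invisible(x)
}

pi_bits <- function(dist) positional_information(dist)$total_bits

#' Marginalize extrinsic signal noise by Monte Carlo
#'
#' Averages the exact per-site marginals over `n_draws` realizations of the
#' extrinsic Gaussian signal fluctuations (variance `nu` carried by the
#' profile), each realization computed exactly by [site_marginals()].
#' Returns the mixture marginals plus a per-state/site Monte Carlo standard
#' error; downstream [positional_information()] reports a delete-one
#' jackknife standard error over the draws.
#'
#' @inheritParams site_marginals
#' @param n_draws Number of extrinsic realizations (at least 2).
#' @param mode `"iid"` (independent per-site fluctuations) or `"shared"`
#'   (one coherent shift per realization).
#' @param seed Optional integer seed for reproducibility.
#' @return A `"pattern_distribution"` with mixture `marginals`, `se`
#'   (matching matrix of standard errors), and `n_draws`; `log_partition`
#'   is `NA` (it is realization-specific).
#' @export
extrinsic_average <- function(params, profile, n_draws, mode = c("iid", "shared"),
                              seed = NULL) {
  mode <- match.arg(mode)
  nu <- attr(profile, "nu")
  if (nu <= 0) {
    stop("`nu` must be positive; with nu = 0 use site_marginals() directly.",
         call. = FALSE)
  }
  if (n_draws < 2) stop("`n_draws` must be at least 2.", call. = FALSE)
  compute <- function() {
    draws <- lapply(seq_len(n_draws), function(i) {
      site_marginals(params, sample_extrinsic(profile, mode))$marginals
    })
    arr <- simplify2array(draws) # 2^K x N x n_draws
    mix <- apply(arr, c(1, 2), mean)
    se <- apply(arr, c(1, 2), stats::sd) / sqrt(n_draws)
    # leave-one-out PI values for jackknife downstream
    total <- mix * n_draws
    loo <- vapply(seq_len(n_draws), function(i) {
      m <- (total - arr[, , i]) / (n_draws - 1)
      usage <- rowMeans(m)
      entropy_bits(usage) - mean(apply(m, 2, entropy_bits))
    }, numeric(1))
    new_pattern_distribution(mix, NA_real_, params, profile,
                             se = se, n_draws = n_draws,
                             draw_pi = list(loo = loo))
  }
  if (is.null(seed)) compute() else withr::with_seed(seed, compute())
}

#' Positional information carried by the morphogen signal itself
#'
#' For a profile with extrinsic Gaussian noise of variance `nu`, the signal
#' observed at a uniformly random position is distributed as the equal-weight
#' mixture of `N` Gaussians centred at `m(x)`. The mutual information
#' between signal and position is the differential-entropy difference
#' `I(m; x) = h[P_m] - (1/2) log2(2 pi e nu)`, with the mixture entropy
#' evaluated by trapezoidal quadrature on a grid spanning six standard
#' deviations beyond the signal range; the result is clipped to
#' `[0, log2 N]`.
#'
#' @param profile A [morphogen_profile()] with positive `nu`.
#' @param n_grid Number of quadrature points.
#' @return Mutual information in bits.
#' @export
morphogen_information <- function(profile, n_grid = 4096) {
  nu <- attr(profile, "nu")
  if (is.null(nu) || nu <= 0) {
    stop("`nu` must be positive to define the signal channel.", call. = FALSE)
  }
  m <- profile_values(profile) + attr(profile, "epsilon")
  N <- length(m)
  sd <- sqrt(nu)
  grid <- seq(min(m) - 6 * sd, max(m) + 6 * sd, length.out = n_grid)
  dens <- rowMeans(vapply(m, function(mu) stats::dnorm(grid, mu, sd),
                          numeric(n_grid)))
  integrand <- ifelse(dens > 0, -dens * log2(dens), 0)
  dx <- diff(grid)
  h_mix <- sum(dx * (integrand[-1] + integrand[-n_grid]) / 2)
  h_noise <- 0.5 * log2(2 * pi * exp(1) * nu)
  min(max(h_mix - h_noise, 0), log2(N))
}

#' Information gap between expression pattern and morphogen signal
#'
#' Compares the positional information of the gene expression pattern (with
#' extrinsic noise marginalized by [extrinsic_average()]) to the positional
#' information carried by the noisy morphogen signal itself
#' ([morphogen_information()]). When all spatial couplings are zero,
#' position, signal, and expression form a Markov chain and the data
#' processing inequality forces the gap to be nonpositive (up to Monte Carlo
#' error); spatially coupled networks can average extrinsic noise across
#' sites and achieve a positive gap.
#'
#' @inheritParams extrinsic_average
#' @return A one-row tibble with columns `pi_pattern`, `pi_signal`, `gap`
#'   (= `pi_pattern - pi_signal`) and `se` (Monte Carlo standard error of
#'   `pi_pattern`).
#' @export
dpi_gap <- function(params, profile, n_draws = 200, mode = c("iid", "shared"),
                    seed = NULL) {
  mode <- match.arg(mode)
  dist <- extrinsic_average(params, profile, n_draws, mode, seed)
  pi_sigma <- positional_information(dist)
  pi_m <- morphogen_information(profile)
  tibble::tibble(
    pi_pattern = pi_sigma$total_bits,
    pi_signal = pi_m,
    gap = pi_sigma$total_bits - pi_m,
    se = pi_sigma$se %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
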