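#' Draw whole-pattern samples from the model
#'
#' Two samplers are provided. `"exact_chain"` draws independent patterns by
#' forward-filtering/backward-sampling along the transfer-matrix chain and
#' therefore requires nearest-neighbour spatial couplings. `"metropolis"`
#' runs a single-spin-flip Metropolis chain (random scan, acceptance
#' `min(1, exp(-dH/eta))`) and supports arbitrary — including long-range —
#' spatial kernels; samples are recorded after `burn_in` sweeps at intervals
#' of `thinning` sweeps.
#'
#' @inheritParams site_marginals
#' @param n_samples Number of patterns to draw.
#' @param method `"exact_chain"` or `"metropolis"`.
#' @param seed Optional integer seed (draws are reproducible per seed).
#' @param burn_in,thinning Metropolis schedule, in sweeps (one sweep is
#'   `K * N` proposed flips).
#' @param init Metropolis initialization: `"random"` (independent fair
#'   spins) or `"field"` (spins aligned with the sign of the local bias,
#'   which shortens equilibration in strongly ordered regimes; ties are
#'   set ON).
#' @param anneal_factor If greater than 1, the burn-in anneals the
#'   temperature geometrically from `anneal_factor * eta` down to `eta`
#'   before recording, which lets glassy configurations (strong long-range
#'   couplings at low noise) relax into the dominant free-energy basin.
#' @return A `"sample_set"`: list with `patterns` (`K x N x n_samples`
#'   integer array of ±1), `method`, `seed`, `burn_in`, `thinning`, and the
#'   generating `params` / `profile`.
#' @export
sample_patterns <- function(params, profile, n_samples,
                            method = c("exact_chain", "metropolis"),
                            seed = NULL, burn_in = 1000, thinning = 1,
                            init = c("random", "field"), anneal_factor = 1) {
  method <- match.arg(method)
  init <- match.arg(init)
  if (nrow(profile) != params$N) {
    stop("Profile length does not match the model.", call. = FALSE)
  }
  draw <- function() {
    if (method == "exact_chain") {
      if (!all_nearest_neighbor(params)) {
        stop(paste("exact_chain sampling requires nearest-neighbour couplings;",
                   "use method = 'metropolis' for long-range models."),
             call. = FALSE)
      }
      sample_exact_chain(params, profile, n_samples)
    } else {
      sample_metropolis(params, profile, n_samples, burn_in, thinning, init,
                        anneal_factor)
    }
  }
  patterns <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(patterns = patterns, method = method, seed = seed,
         burn_in = if (method == "metropolis") burn_in else NA_integer_,
         thinning = if (method == "metropolis") thinning else NA_integer_,
         params = params, profile = profile),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  d <- dim(x$patterns)
  cat(sprintf("<sample_set> %d patterns (%d genes x %d sites), method = %s\n",
              d[3], d[1], d[2], x$method))
  invisible(x)
}

# i.i.d. draws by forward filtering / backward sampling on the state chain
sample_exact_chain <- function(params, profile, n_samples) {
  N <- params$N; K <- params$K
  w <- transfer_weights(params, profile)
  Tm <- exp(w$logT - max(w$logT))
  nstate <- nrow(w$logW)
  fwd <- matrix(0, nstate, N)
  f <- exp(w$logW[, 1] - max(w$logW[, 1]))
  fwd[, 1] <- f / sum(f)
  for (x in 2:N) {
    f <- drop(fwd[, x - 1] %*% Tm) * exp(w$logW[, x] - max(w$logW[, x]))
    fwd[, x] <- f / sum(f)
  }
  states <- matrix(0L, n_samples, N)
  states[, N] <- sample.int(nstate, n_samples, replace = TRUE, prob = fwd[, N])
  for (x in (N - 1):1) {
    for (t in unique(states[, x + 1])) {
      rows <- which(states[, x + 1] == t)
      p <- fwd[, x] * Tm[, t]
      states[rows, x] <- sample.int(nstate, length(rows), replace = TRUE,
                                    prob = p / sum(p))
    }
  }
  spins <- state_spins(K)
  arr <- array(0L, dim = c(K, N, n_samples))
  for (x in seq_len(N)) {
    arr[, x, ] <- t(spins[states[, x], , drop = FALSE])
  }
  arr
}

sample_metropolis <- function(params, profile, n_samples, burn_in, thinning,
                              init = "random", anneal_factor = 1) {
  K <- params$K; N <- params$N
  kernels <- lapply(params$spatial, interaction_matrix, N = N)
  h <- gene_biases(params, profile)
  s0 <- if (init == "field") {
    matrix(ifelse(h >= 0, 1L, -1L), K, N)
  } else {
    matrix(ifelse(stats::runif(K * N) < 0.5, 1L, -1L), K, N)
  }
  metropolis_chain(s0, h, kernels, params$J_local, params$eta,
                   as.integer(n_samples), as.integer(burn_in),
                   as.integer(thinning), anneal_factor)
}

#' Mean expression pattern
#'
#' Per-gene, per-site average expression `<sigma_a(x)>` in `[-1, 1]`,
#' either across the draws of a [sample_patterns()] sample set or exactly
#' from the per-site state marginals of a `"pattern_distribution"`.
#'
#' @param x A `"sample_set"` or `"pattern_distribution"`.
#' @param ... Unused.
#' @return A `K x N` numeric matrix.
#' @export
mean_pattern <- function(x, ...) UseMethod("mean_pattern")

#' @rdname mean_pattern
#' @export
mean_pattern.sample_set <- function(x, ...) {
  if (length(x$patterns) == 0 || dim(x$patterns)[3] == 0) {
    stop("Empty sample set.", call. = FALSE)
  }
  apply(x$patterns, c(1, 2), mean)
}

#' @rdname mean_pattern
#' @export
mean_pattern.pattern_distribution <- function(x, ...) {
  K <- as.integer(round(log2(nrow(x$marginals))))
  t(state_spins(K)) %*% x$marginals
}

#' Estimate positional information from pattern samples
#'
#' Plug-in estimator: empirical per-site state frequencies replace the exact
#' marginals in the mutual-information definition. An optional Miller–Madow
#' correction adds `(n_used - 1) / (2 n ln 2)` to each entropy term. A
#' standard error is obtained by a delete-one-block jackknife over
#' `n_blocks` contiguous blocks of draws.
#'
#' @param samples A `"sample_set"` with at least 100 draws.
#' @param correction `"none"` (default) or `"miller_madow"`.
#' @param n_blocks Number of jackknife blocks.
#' @return A `"pi_result"` with an `se` field.
#' @export
estimate_pi_from_samples <- function(samples, correction = c("none", "miller_madow"),
                                     n_blocks = 20) {
  correction <- match.arg(correction)
  arr <- samples$patterns
  n <- dim(arr)[3]
  if (n < 100) {
    stop("At least 100 samples are required to estimate information.",
         call. = FALSE)
  }
  K <- dim(arr)[1]; N <- dim(arr)[2]
  # counts[state, site]
  counts <- matrix(0, 2^K, N)
  for (x in seq_len(N)) {
    idx <- spin_state_index(arr[, x, , drop = TRUE], K)
    counts[, x] <- tabulate(idx, nbins = 2^K)
  }
  pi_of <- function(cnt, ndraw) {
    marg <- sweep(cnt, 2, colSums(cnt), "/")
    usage <- rowMeans(marg)
    s_state <- entropy_bits(usage)
    s_noise <- mean(apply(marg, 2, entropy_bits))
    if (correction == "miller_madow") {
      mm <- function(p, nn) (sum(p > 0) - 1) / (2 * nn * log(2))
      s_state <- s_state + mm(usage, ndraw * N)
      s_noise <- s_noise + mean(apply(marg, 2, mm, nn = ndraw))
    }
    list(total = s_state - s_noise, state = s_state, noise = s_noise,
         usage = usage)
  }
  full <- pi_of(counts, n)
  blocks <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  loo <- vapply(blocks, function(b) {
    cnt_b <- matrix(0, 2^K, N)
    for (x in seq_len(N)) {
      idx <- spin_state_index(arr[, x, b, drop = TRUE], K)
      cnt_b[, x] <- tabulate(idx, nbins = 2^K)
    }
    pi_of(counts - cnt_b, n - length(b))$total
  }, numeric(1))
  B <- length(loo)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  structure(
    list(total_bits = full$total, state_entropy_bits = full$state,
         noise_entropy_bits = full$noise, state_usage = full$usage, se = se),
    class = "pi_result"
  )
}

#' Serialize a sample set to a delimited file
#'
#' One pattern per row with genes concatenated (`K * N` columns of ±1), plus
#' a YAML metadata sidecar (`<path>.meta.yml`) recording method, seed and
#' schedule.
#'
#' @param samples A `"sample_set"`.
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_samples <- function(samples, path) {
  arr <- samples$patterns
  K <- dim(arr)[1]; N <- dim(arr)[2]; n <- dim(arr)[3]
  flat <- t(vapply(seq_len(n), function(i) as.integer(t(arr[, , i])),
                   integer(K * N)))
  utils::write.table(flat, path, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(
    list(K = K, N = N, n_samples = n, method = samples$method,
         seed = samples$seed, burn_in = samples$burn_in,
         thinning = samples$thinning),
    paste0(path, ".meta.yml")
  )
  invisible(samples)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  flat <- as.matrix(utils::read.table(path))
  arr <- array(0L, dim = c(meta$K, meta$N, meta$n_samples))
  for (i in seq_len(meta$n_samples)) {
    arr[, , i] <- matrix(as.integer(flat[i, ]), meta$K, meta$N, byrow = TRUE)
  }
  structure(
    list(patterns = arr, method = meta$method, seed = meta$seed,
         burn_in = meta$burn_in %||% NA_integer_,
         thinning = meta$thinning %||% NA_integer_,
         params = NULL, profile = NULL),
    class = "sample_set"
  )
}
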