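# shared shorthand for test models

lin_profile <- function(N, ...) morphogen_profile("linear", N = N, ...)

single_gene <- function(N, n = 1, E = 0, J = 0, eta = 1) {
  model_params(N = N, K = 1, n_slope = n, E_thresh = E,
               spatial = nearest_neighbor(J), eta = eta)
}

# random nearest-neighbour model + linear profile, oracle-safe sizes
random_nn_model <- function(K, N, eta_range = c(0.2, 4), local = TRUE) {
  Jl <- matrix(0, K, K)
  if (K > 1 && local) {
    v <- stats::runif(K * (K - 1) / 2, -1, 1)
    Jl[upper.tri(Jl)] <- v
    Jl <- Jl + t(Jl)
  }
  model_params(
    N = N, K = K,
    n_slope = stats::runif(K, 0, 4),
    E_thresh = stats::runif(K, -1, 1),
    J_local = Jl,
    spatial = lapply(seq_len(K), function(a) {
      nearest_neighbor(stats::runif(1, -1.5, 1.5))
    }),
    eta = stats::runif(1, eta_range[1], eta_range[2])
  )
}

# sample_set wrapper around a fixed deterministic pattern
constant_sample_set <- function(pattern, n = 200) {
  arr <- array(rep(as.integer(pattern), n),
               dim = c(nrow(pattern), ncol(pattern), n))
  structure(
    list(patterns = arr, method = "exact_chain", seed = NA_integer_,
         burn_in = NA_integer_, thinning = NA_integer_,
         params = NULL, profile = NULL),
    class = "sample_set"
  )
}
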