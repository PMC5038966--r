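#' Spatial coupling specifications
#'
#' A gene's spatial coupling along the lattice is specified either as a
#' nearest-neighbour interaction of strength `J`, or as an exponentially
#' decaying long-range kernel `J(i, j) = amplitude * exp(-(|i - j| - 1) / range)`
#' acting between every pair of sites. The long-range kernel reduces to the
#' nearest-neighbour case as `range -> 0` and to a uniform all-to-all
#' coupling as `range -> Inf`; with a negative amplitude the uniform limit
#' penalizes any imbalance between ON and OFF states (it equals
#' `-amplitude * (sum sigma)^2 / 2` up to a pattern-independent constant),
#' which is the mechanism behind pattern scaling and canalization.
#'
#' Several components may be combined with `spatial_sum()`, e.g. positive
#' nearest-neighbour smoothing plus weak long-range repression; their kernels
#' add.
#'
#' @param J,amplitude Coupling strength (may be negative).
#' @param range Positive interaction range `r` (lattice spacings).
#' @param ... Spatial specs to combine.
#' @return An object of class `"spatial_spec"`.
#' @export
nearest_neighbor <- function(J) {
  structure(list(type = "nearest_neighbor", J = J), class = "spatial_spec")
}

#' @rdname nearest_neighbor
#' @export
long_range <- function(amplitude, range) {
  if (range <= 0) stop("`range` must be positive.", call. = FALSE)
  structure(list(type = "long_range", amplitude = amplitude, range = range),
            class = "spatial_spec")
}

#' @rdname nearest_neighbor
#' @export
spatial_sum <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "spatial_spec")))
  structure(list(type = "sum", parts = parts), class = "spatial_spec")
}

is_nearest_neighbor <- function(spec) spec$type == "nearest_neighbor"

#' Build the site-by-site interaction matrix of a spatial spec
#'
#' @param spatial A spatial spec ([nearest_neighbor()], [long_range()], or
#'   [spatial_sum()]).
#' @param N Number of lattice sites (at least 2).
#' @return A symmetric `N x N` matrix with zero diagonal; entry `(i, j)` is
#'   the coupling between sites `i` and `j`.
#' @examples
#' interaction_matrix(long_range(-0.1, 5), 10)[1, 7]  # -0.1 * exp(-1)
#' @export
interaction_matrix <- function(spatial, N) {
  if (N < 2) stop("`N` must be at least 2.", call. = FALSE)
  d <- abs(outer(seq_len(N), seq_len(N), "-"))
  J <- switch(spatial$type,
    nearest_neighbor = ifelse(d == 1, spatial$J, 0),
    long_range = ifelse(d >= 1, spatial$amplitude * exp(-(d - 1) / spatial$range), 0),
    sum = Reduce(`+`, lapply(spatial$parts, interaction_matrix, N = N)),
    stop("Unknown spatial spec.", call. = FALSE)
  )
  diag(J) <- 0
  J
}

#' Full parameterization of the patterning model
#'
#' Collects everything that, together with a morphogen profile, defines the
#' Boltzmann distribution over expression patterns: per-gene readout slopes
#' `n` and thresholds `E` (the bias is `h_a(x) = n_a (m(x) - E_a)`), a
#' symmetric zero-diagonal matrix `J_local` of local gene-gene couplings, a
#' spatial coupling spec per gene, and the intrinsic noise `eta`
#' (temperature-like; `eta -> 0` gives deterministic readout, `eta -> Inf`
#' a fully random one).
#'
#' @param N Lattice size.
#' @param K Number of patterning genes.
#' @param n_slope Numeric vector of length `K` (recycled from length 1).
#' @param E_thresh Numeric vector of length `K` (recycled from length 1).
#' @param J_local `K x K` symmetric matrix with zero diagonal (scalar allowed
#'   for `K = 2`, meaning the single off-diagonal coupling); default none.
#' @param spatial A single spatial spec applied to every gene, or a list of
#'   `K` specs.
#' @param eta Positive intrinsic noise.
#' @return An object of class `"model_params"`.
#' @examples
#' model_params(N = 50, K = 1, n_slope = 1, E_thresh = 0,
#'              spatial = nearest_neighbor(0.5), eta = 1)
#' @export
model_params <- function(N, K, n_slope, E_thresh,
                         J_local = NULL, spatial = nearest_neighbor(0), eta = 1) {
  N <- as.integer(N); K <- as.integer(K)
  if (N < 2) stop("`N` must be at least 2.", call. = FALSE)
  if (K < 1) stop("`K` must be at least 1.", call. = FALSE)
  if (eta <= 0) stop("`eta` must be positive.", call. = FALSE)
  n_slope <- rep_len(as.numeric(n_slope), K)
  E_thresh <- rep_len(as.numeric(E_thresh), K)
  if (is.null(J_local)) J_local <- matrix(0, K, K)
  if (length(J_local) == 1 && K == 2) {
    J_local <- matrix(c(0, J_local, J_local, 0), 2, 2)
  }
  J_local <- as.matrix(J_local)
  if (!all(dim(J_local) == c(K, K))) {
    stop("`J_local` must be a K x K matrix.", call. = FALSE)
  }
  if (any(abs(J_local - t(J_local)) > 1e-12) || any(diag(J_local) != 0)) {
    stop("`J_local` must be symmetric with zero diagonal.", call. = FALSE)
  }
  if (inherits(spatial, "spatial_spec")) spatial <- rep(list(spatial), K)
  if (length(spatial) != K ||
      !all(vapply(spatial, inherits, logical(1), "spatial_spec"))) {
    stop("`spatial` must be one spatial spec or a list of K specs.", call. = FALSE)
  }
  # every kernel entry must be finite
  for (sp in spatial) {
    if (!all(is.finite(interaction_matrix(sp, N)))) {
      stop("Spatial kernel has non-finite entries.", call. = FALSE)
    }
  }
  structure(
    list(N = N, K = K, n_slope = n_slope, E_thresh = E_thresh,
         J_local = J_local, spatial = spatial, eta = eta),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  kinds <- vapply(x$spatial, function(s) s$type, character(1))
  cat(sprintf("<model_params> K = %d genes on N = %d sites, eta = %g\n",
              x$K, x$N, x$eta))
  cat(sprintf("  n = (%s), E = (%s), spatial: %s\n",
              paste(signif(x$n_slope, 3), collapse = ", "),
              paste(signif(x$E_thresh, 3), collapse = ", "),
              paste(kinds, collapse = ", ")))
  invisible(x)
}

all_nearest_neighbor <- function(params) {
  all(vapply(params$spatial, is_nearest_neighbor, logical(1)))
}

#' Change the lattice size of a model
#'
#' Returns a copy of `params` defined on `N` sites; used by
#' [scaling_experiment()] when the tissue is cut short or extended.
#'
#' @param params A [model_params()].
#' @param N New lattice size.
#' @return A `model_params` on `N` sites.
#' @export
set_lattice_size <- function(params, N) {
  model_params(N = N, K = params$K, n_slope = params$n_slope,
               E_thresh = params$E_thresh, J_local = params$J_local,
               spatial = params$spatial, eta = params$eta)
}

#' Number of interaction parameters of a K-gene model
#'
#' Readout slope and threshold plus spatial coupling per gene (`3K`) together
#' with the local couplings counted as `K(K + 1)/2`, i.e. `3K + K(K + 1)/2`
#' (9 parameters for two genes, 15 for three).
#'
#' @param K Number of genes (at least 1).
#' @return Integer parameter count.
#' @export
parameter_count <- function(K) {
  if (K < 1) stop("`K` must be at least 1.", call. = FALSE)
  as.integer(3 * K + K * (K + 1) / 2)
}

# K x N matrix of per-gene biases h_a(x) = n_a (m(x) + eps - E_a)
gene_biases <- function(params, profile) {
  t(vapply(seq_len(params$K), function(a) {
    bias_from_signal(profile, params$n_slope[a], params$E_thresh[a])
  }, numeric(nrow(profile))))
}

as_pattern <- function(states, K = NULL) {
  if (is.vector(states)) states <- matrix(states, nrow = if (is.null(K)) 1 else K)
  if (!all(states %in% c(-1, 1))) {
    stop("Pattern entries must be -1 or +1.", call. = FALSE)
  }
  states
}

#' Energy of an expression pattern
#'
#' Evaluates the Ising energy
#' \deqn{H = -\sum_a \sum_x h_a(x)\sigma_a(x)
#'          - \sum_a \sum_{i<j} J_a(i,j)\sigma_a(i)\sigma_a(j)
#'          - \sum_{a<g} 2 J_{ag} \sum_x \sigma_a(x)\sigma_g(x),}
#' where each unordered site pair and each unordered gene pair is counted
#' once (the factor 2 on the local term reproduces the sum over ordered gene
#' pairs of the K-gene energy). Nearest-neighbour spatial specs reproduce
#' the open-chain bond sum `-J sum_{x<N} sigma(x) sigma(x+1)` exactly.
#'
#' @param pattern `K x N` matrix of ±1 states (a vector is taken as `K = 1`).
#' @param params A [model_params()].
#' @param profile A [morphogen_profile()] of matching length.
#' @return The scalar energy `H`.
#' @export
pattern_energy <- function(pattern, params, profile) {
  s <- as_pattern(pattern, params$K)
  if (nrow(s) != params$K || ncol(s) != params$N || nrow(profile) != params$N) {
    stop("Pattern / profile dimensions do not match the model.", call. = FALSE)
  }
  h <- gene_biases(params, profile)
  e_field <- -sum(h * s)
  e_spatial <- 0
  for (a in seq_len(params$K)) {
    J <- interaction_matrix(params$spatial[[a]], params$N)
    # each unordered pair once: quadratic form / 2
    e_spatial <- e_spatial - 0.5 * drop(s[a, ] %*% J %*% s[a, ])
  }
  e_local <- 0
  if (params$K > 1) {
    for (a in seq_len(params$K - 1)) {
      for (g in seq((a + 1), params$K)) {
        e_local <- e_local - 2 * params$J_local[a, g] * sum(s[a, ] * s[g, ])
      }
    }
  }
  e_field + e_spatial + e_local
}
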