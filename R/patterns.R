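#' Reference Counter pattern
#'
#' The Counter is the noiseless pattern maximizing positional information
#' for `K` binary genes: each of the `2^K` joint expression states occupies
#' an equal contiguous block of the lattice. Site `x` carries the K-bit
#' binary encoding of `floor((x - 1) * 2^K / N)` with gene 1 as the most
#' significant bit, so gene 1 forms a single central ON/OFF boundary and
#' successive genes halve the blocks.
#'
#' @param K Number of genes.
#' @param N Lattice size, divisible by `2^K`.
#' @return A `K x N` matrix of ±1 states.
#' @examples
#' counter_pattern(2, 8)
#' @export
counter_pattern <- function(K, N) {
  S <- 2^K
  if (N %% S != 0) {
    stop("`N` must be divisible by 2^K for a Counter pattern.", call. = FALSE)
  }
  code <- floor((seq_len(N) - 1) * S / N) # 0 .. 2^K - 1
  t(state_spins(K)[code + 1, , drop = FALSE])
}

#' Reference French Flag pattern
#'
#' The cascaded-threshold pattern in which `n_states` nested expression
#' states occupy equal contiguous blocks: gene `a` is ON on the anterior
#' `(n_states - a) / n_states` fraction of the lattice, so the blocks read
#' (all ON), (gene 1 OFF), (genes 1-2 OFF), ... For two genes and three
#' states this is the classic Tricolore with noiseless information
#' `log2(3) ~ 1.59` bits.
#'
#' @param n_states Number of states (at most `K + 1`).
#' @param K Number of genes.
#' @param N Lattice size, divisible by `n_states`.
#' @return A `K x N` matrix of ±1 states.
#' @export
french_flag_pattern <- function(n_states, K, N) {
  if (n_states > K + 1 || n_states < 1) {
    stop("`n_states` must be between 1 and K + 1.", call. = FALSE)
  }
  if (N %% n_states != 0) {
    stop("`N` must be divisible by `n_states`.", call. = FALSE)
  }
  block <- N / n_states
  out <- matrix(-1L, K, N)
  for (a in seq_len(K)) {
    on <- (n_states - a) * block
    if (on > 0) out[a, seq_len(on)] <- 1L
  }
  out
}

#' Point-mass distribution of a deterministic pattern
#'
#' Wraps a noiseless `K x N` pattern as a `"pattern_distribution"` whose
#' per-site state distributions are point masses, so that
#' [positional_information()] reduces to the entropy of the pattern's
#' state-usage vector.
#'
#' @param pattern A `K x N` matrix of ±1 states (vector for `K = 1`).
#' @return A `"pattern_distribution"`.
#' @export
as_distribution <- function(pattern) {
  s <- as_pattern(pattern)
  K <- nrow(s); N <- ncol(s)
  idx <- spin_state_index(s, K)
  marg <- matrix(0, 2^K, N)
  marg[cbind(idx, seq_len(N))] <- 1
  new_pattern_distribution(marg, NA_real_, NULL, NULL)
}

#' Classify a mean expression pattern
#'
#' Binarizes a mean pattern at zero, counts the distinct joint local states
#' used by at least a `threshold` fraction of sites, and assigns a
#' structural label:
#'
#' * `alternating` — neighbouring sites switch state for more than 90% of
#'   adjacent pairs (averaged over genes);
#' * `uniform` — a single state covers the lattice;
#' * `counter` — all `2^K` states used in near-equal fractions;
#' * `french_flag` — every gene forms a single boundary and the ON domains
#'   are nested prefixes of the lattice (a cascade);
#' * `boundary` — every gene forms a single boundary at a shared position;
#' * `other` — anything else.
#'
#' @param mean A `K x N` matrix of mean expression values in \[-1, 1\]
#'   (vector for `K = 1`).
#' @param threshold Minimum usage fraction for a state to count.
#' @return A one-row tibble with columns `label` and `n_states`.
#' @export
classify_pattern <- function(mean, threshold = 0.05) {
  if (is.vector(mean)) mean <- matrix(mean, nrow = 1)
  if (any(mean < -1 - 1e-9) || any(mean > 1 + 1e-9)) {
    stop("Mean pattern entries must lie in [-1, 1].", call. = FALSE)
  }
  K <- nrow(mean); N <- ncol(mean)
  sgn <- ifelse(mean >= 0, 1L, -1L)
  idx <- spin_state_index(sgn, K)
  usage <- tabulate(idx, nbins = 2^K) / N
  used <- which(usage >= threshold)
  n_states <- length(used)

  flips <- rowMeans(sgn[, -1, drop = FALSE] != sgn[, -N, drop = FALSE])
  changes <- apply(sgn, 1, function(r) sum(r[-1] != r[-N]))

  label <- if (mean(flips) > 0.9) {
    "alternating"
  } else if (n_states == 1) {
    "uniform"
  } else if (n_states == 2^K && max(usage[used]) <= 2 * min(usage[used])) {
    "counter"
  } else if (all(changes == 1) && all(sgn[, 1] == 1)) {
    bnd <- apply(sgn, 1, function(r) sum(r == 1))
    if (length(unique(bnd)) == K && K > 1) "french_flag"
    else if (length(unique(bnd)) == 1) "boundary"
    else "other"
  } else if (all(changes == 1)) {
    bnd <- apply(sgn, 1, function(r) match(TRUE, r[-1] != r[-N]))
    if (length(unique(bnd)) == 1) "boundary" else "other"
  } else {
    "other"
  }
  tibble::tibble(label = label, n_states = n_states)
}

#' Boundary positions of a mean pattern
#'
#' Locates the zero crossings of each gene's mean expression by linear
#' interpolation between adjacent sites (ties broken toward the anterior),
#' returning absolute and fractional positions.
#'
#' @param mean A `K x N` matrix of mean expression values (vector for
#'   `K = 1`).
#' @return A tibble with columns `gene`, `crossing`, `position` (absolute,
#'   in site units) and `fraction` (`position / N`).
#' @export
boundary_positions <- function(mean) {
  if (is.vector(mean)) mean <- matrix(mean, nrow = 1)
  K <- nrow(mean); N <- ncol(mean)
  purrr::map_dfr(seq_len(K), function(a) {
    v <- mean[a, ]
    cross <- which(v[-N] * v[-1] < 0 | (v[-N] != 0 & v[-1] == 0))
    if (length(cross) == 0) {
      return(tibble::tibble(gene = integer(), crossing = integer(),
                            position = numeric(), fraction = numeric()))
    }
    pos <- vapply(cross, function(i) {
      i + v[i] / (v[i] - v[i + 1])
    }, numeric(1))
    tibble::tibble(gene = a, crossing = seq_along(cross),
                   position = pos, fraction = pos / N)
  })
}

#' Hand-built two-gene Counter network
#'
#' A parameterization whose low-noise Boltzmann pattern on a linear,
#' unit-amplitude morphogen signal is the four-state two-gene Counter: the
#' first gene reads the signal with a central threshold and positive
#' nearest-neighbour smoothing; the second gene combines a steeper readout
#' with strong mutual repression (`J_local = -1`), which switches it to the
#' inverse of the first gene where the signal is weak, carving the lattice
#' into four near-equal blocks. Optionally each gene is additionally given
#' a negative long-range coupling (the balance penalty behind scaling and
#' canalization).
#'
#' @param N Lattice size.
#' @param eta Intrinsic noise.
#' @param n_slope Readout slopes of the two genes. Gene 1 must out-pull the
#'   repression (`n1 > 4 |J12|`) to hold the all-ON anterior block; gene 2's
#'   slope of exactly `4 |J12|` puts its switches at half-maximal signal,
#'   carving quarters.
#' @param j_spatial Nearest-neighbour coupling per gene (wall tension; larger
#'   values suppress nucleation of spurious domains when a strong balance
#'   term is added).
#' @param long_range_amplitude,long_range_range If non-`NULL`, add a
#'   long-range component with this (typically negative) amplitude and
#'   range to each gene's spatial coupling.
#' @return A [model_params()].
#' @export
counter_network <- function(N = 60, eta = 0.2, n_slope = c(6, 4),
                            j_spatial = c(1, 0.5),
                            long_range_amplitude = NULL,
                            long_range_range = NULL) {
  base <- list(nearest_neighbor(j_spatial[1]), nearest_neighbor(j_spatial[2]))
  spatial <- if (is.null(long_range_amplitude)) {
    base
  } else {
    lapply(base, function(sp) {
      spatial_sum(sp, long_range(long_range_amplitude, long_range_range))
    })
  }
  model_params(
    N = N, K = 2, n_slope = n_slope, E_thresh = c(0, 0),
    J_local = matrix(c(0, -1, -1, 0), 2, 2),
    spatial = spatial, eta = eta
  )
}

#' Principal ON/OFF boundary of each gene
#'
#' Identifies the position of each gene's main expression transition by
#' matching the mean profile against an ideal anterior-ON step (maximizing
#' the cumulative mean), then refines to sub-site precision with the
#' interpolated zero crossing nearest that position. Robust to small
#' noise-induced wiggles of a sampled mean pattern, unlike the raw crossing
#' list of [boundary_positions()]. Genes whose mean never changes sign get
#' `NA`.
#'
#' @param mean A `K x N` matrix of mean expression values (vector for
#'   `K = 1`).
#' @return A tibble with columns `gene`, `position`, `fraction`.
#' @export
main_boundary <- function(mean) {
  if (is.vector(mean)) mean <- matrix(mean, nrow = 1)
  K <- nrow(mean); N <- ncol(mean)
  cross <- boundary_positions(mean)
  purrr::map_dfr(seq_len(K), function(a) {
    v <- mean[a, ]
    # anterior-ON step match: boundary b maximizes sum_{x<=b} v - sum_{x>b} v
    score <- cumsum(v) - (sum(v) - cumsum(v))
    b0 <- which.max(score)
    cand <- cross$position[cross$gene == a]
    pos <- if (length(cand) == 0) NA_real_ else cand[which.min(abs(cand - b0 - 0.5))]
    tibble::tibble(gene = a, position = pos, fraction = pos / N)
  })
}
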