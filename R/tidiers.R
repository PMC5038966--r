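#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for positional-information results
#'
#' `glance()` returns the headline numbers of a `"pi_result"` as a one-row
#' tibble; `tidy()` returns the state-usage distribution with the spin
#' assignment of each joint expression state.
#'
#' @param x A `"pi_result"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.pi_result <- function(x, ...) {
  tibble::tibble(
    total_bits = x$total_bits,
    state_entropy_bits = x$state_entropy_bits,
    noise_entropy_bits = x$noise_entropy_bits,
    se = x$se %||% NA_real_
  )
}

#' @rdname glance.pi_result
#' @export
tidy.pi_result <- function(x, ...) {
  K <- as.integer(round(log2(length(x$state_usage))))
  spins <- state_spins(K)
  tibble::tibble(
    state = seq_along(x$state_usage),
    label = apply(spins, 1, function(r) paste(ifelse(r > 0, "+", "-"),
                                              collapse = "")),
    probability = x$state_usage
  )
}

#' Tidiers for pattern distributions
#'
#' `tidy()` returns the per-site state marginals in long form (`site`,
#' `state`, `probability`); `glance()` summarizes the distribution
#' (dimensions, log partition function, positional information).
#'
#' @param x A `"pattern_distribution"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pattern_distribution <- function(x, ...) {
  marg <- x$marginals
  tidyr::expand_grid(site = seq_len(ncol(marg)), state = seq_len(nrow(marg))) |>
    dplyr::mutate(probability = marg[cbind(.data$state, .data$site)])
}

#' @rdname tidy.pattern_distribution
#' @export
glance.pattern_distribution <- function(x, ...) {
  pr <- positional_information(x)
  tibble::tibble(
    n_states = nrow(x$marginals),
    n_sites = ncol(x$marginals),
    log_partition = x$log_partition,
    total_bits = pr$total_bits
  )
}

#' Tidiers for model parameterizations
#'
#' `tidy()` lists each distinct model parameter (`term`, `gene`, `value`);
#' `glance()` gives the model dimensions and the printed interaction
#' parameter count.
#'
#' @param x A [model_params()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.model_params <- function(x, ...) {
  K <- x$K
  rows <- list(
    tibble::tibble(term = "n_slope", gene = seq_len(K), value = x$n_slope),
    tibble::tibble(term = "E_thresh", gene = seq_len(K), value = x$E_thresh),
    tibble::tibble(
      term = vapply(x$spatial, function(s) {
        if (is_nearest_neighbor(s)) "J_spatial" else "J_long_range"
      }, character(1)),
      gene = seq_len(K),
      value = vapply(x$spatial, function(s) {
        if (is_nearest_neighbor(s)) s$J else s$amplitude
      }, numeric(1))
    )
  )
  if (K > 1) {
    pairs <- which(upper.tri(x$J_local), arr.ind = TRUE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      term = sprintf("J_local_%d_%d", pairs[, 1], pairs[, 2]),
      gene = NA_integer_,
      value = x$J_local[pairs]
    )
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.model_params
#' @export
glance.model_params <- function(x, ...) {
  tibble::tibble(N = x$N, K = x$K, eta = x$eta,
                 n_parameters = parameter_count(x$K))
}

#' Tidiers for optimization results
#'
#' `tidy()` returns the accepted-move trace (`restart`, `iteration`, `pi`,
#' `best_pi`); `glance()` the best information found and run metadata.
#'
#' @param x A `"pi_optimization"` from [maximize_pi()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pi_optimization <- function(x, ...) x$trace

#' @rdname tidy.pi_optimization
#' @export
glance.pi_optimization <- function(x, ...) {
  tibble::tibble(best_pi_bits = x$best_pi_bits, n_restarts = x$n_restarts,
                 seed = x$seed, n_accepted = nrow(x$trace))
}
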