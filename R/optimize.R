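# Flatten the distinct free parameters of a model into a named vector with
# box constraints. Parameter names: n1..nK, E1..EK, Js1..JsK (nearest-neighbour
# strength or long-range amplitude), Jl_a_g for a < g.
param_map <- function(template, free, constraints) {
  K <- template$K
  boxes <- list(n = c(0, 10), E = c(-2, 2), Js = c(-5, 5), Jl = c(-5, 5))
  boxes[names(constraints)] <- constraints
  entries <- list()
  add <- function(name, value, box) {
    entries[[name]] <<- list(value = value, box = box)
  }
  for (a in seq_len(K)) add(paste0("n", a), template$n_slope[a], boxes$n)
  for (a in seq_len(K)) add(paste0("E", a), template$E_thresh[a], boxes$E)
  for (a in seq_len(K)) {
    sp <- template$spatial[[a]]
    v <- if (is_nearest_neighbor(sp)) sp$J else sp$amplitude
    add(paste0("Js", a), v, boxes$Js)
  }
  if (K > 1) {
    for (a in seq_len(K - 1)) {
      for (g in (a + 1):K) {
        add(paste0("Jl", a, "_", g), template$J_local[a, g], boxes$Jl)
      }
    }
  }
  if (is.null(free)) free <- names(entries)
  unknown <- setdiff(free, names(entries))
  if (length(unknown) > 0) {
    stop("Unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(free) == 0) {
    stop("At least one parameter must be free.", call. = FALSE)
  }
  list(entries = entries, free = free)
}

rebuild_params <- function(template, values) {
  K <- template$K
  spatial <- lapply(seq_len(K), function(a) {
    sp <- template$spatial[[a]]
    v <- values[[paste0("Js", a)]]
    if (is_nearest_neighbor(sp)) nearest_neighbor(v) else long_range(v, sp$range)
  })
  Jl <- matrix(0, K, K)
  if (K > 1) {
    for (a in seq_len(K - 1)) {
      for (g in (a + 1):K) {
        Jl[a, g] <- Jl[g, a] <- values[[paste0("Jl", a, "_", g)]]
      }
    }
  }
  model_params(
    N = template$N, K = K,
    n_slope = vapply(seq_len(K), function(a) values[[paste0("n", a)]], numeric(1)),
    E_thresh = vapply(seq_len(K), function(a) values[[paste0("E", a)]], numeric(1)),
    J_local = Jl, spatial = spatial, eta = template$eta
  )
}

#' Maximize positional information over model parameters
#'
#' Simulated annealing on the distinct model parameters (readout slopes and
#' thresholds, one spatial coupling per gene, and the local couplings for
#' each unordered gene pair) at fixed intrinsic noise `eta`. Each iteration
#' perturbs one randomly chosen free parameter by a Gaussian step of
#' standard deviation `step_frac` times its box width, clips the proposal to
#' the box, and accepts with the Metropolis rule at a geometrically cooled
#' temperature (`T0`, `cooling` per iteration, temperature in bits).
#' Multiple restarts are run from independent random initial points inside
#' the boxes and the overall best is returned.
#'
#' The objective is the exact transfer-matrix information when every
#' spatial coupling is nearest-neighbour and the profile carries no
#' extrinsic noise; with extrinsic noise the objective is the Monte Carlo
#' average over `n_draws` signal realizations evaluated with common random
#' numbers (one fixed seed per run) so the optimizer sees a deterministic
#' surface; long-range models are evaluated by Metropolis sampling, again
#' with common random numbers.
#'
#' @param template A [model_params()] supplying `N`, `K`, `eta`, the spatial
#'   kernel types, and initial values for frozen parameters.
#' @param profile A [morphogen_profile()].
#' @param free Character vector of free parameter names (`"n1"`, `"E2"`,
#'   `"Js1"`, `"Jl1_2"`, ...); `NULL` frees all.
#' @param constraints Named list overriding the default parameter boxes
#'   `n` in \[0, 10\], `E` in \[-2, 2\], `Js` and `Jl` in \[-5, 5\]; e.g.
#'   `list(Js = c(0, 5))` restricts spatial couplings to be positive.
#' @param seed Integer seed; the whole optimization is deterministic per
#'   seed.
#' @param budget Iterations per restart.
#' @param n_restarts Number of independent restarts.
#' @param T0,cooling,step_frac Annealing schedule and proposal scale.
#' @param n_draws Extrinsic-noise draws per objective evaluation (only used
#'   when the profile has `nu > 0`).
#' @param n_samples Metropolis draws per objective evaluation (long-range
#'   models only).
#' @return A `"pi_optimization"`: list with `best_params`, `best_pi_bits`,
#'   `trace` (tibble of accepted iterations: `restart`, `iteration`, `pi`,
#'   `best_pi`), `seed`, `constraints`, `n_restarts`.
#' @export
maximize_pi <- function(template, profile, free = NULL, constraints = list(),
                        seed = 1L, budget = 2000, n_restarts = 5,
                        T0 = 0.1, cooling = 0.995, step_frac = 0.3,
                        n_draws = 50, n_samples = 2000) {
  pm <- param_map(template, free, constraints)
  nu <- attr(profile, "nu")
  exact <- all_nearest_neighbor(template)

  objective <- function(values, eval_seed) {
    params <- rebuild_params(template, values)
    if (exact && nu == 0) {
      pi_bits(site_marginals(params, profile))
    } else if (exact) {
      pi_bits(extrinsic_average(params, profile, n_draws, seed = eval_seed))
    } else {
      ss <- sample_patterns(params, profile, n_samples, "metropolis",
                            seed = eval_seed, burn_in = 500)
      estimate_pi_from_samples(ss)$total_bits
    }
  }

  run <- function() {
    eval_seed <- sample.int(.Machine$integer.max, 1)
    best_values <- NULL
    best_pi <- -Inf
    trace <- vector("list", n_restarts)
    for (r in seq_len(n_restarts)) {
      values <- lapply(pm$entries, function(e) e$value)
      # random start inside the boxes for the free coordinates
      for (nm in pm$free) {
        b <- pm$entries[[nm]]$box
        values[[nm]] <- stats::runif(1, b[1], b[2])
      }
      cur_pi <- objective(values, eval_seed)
      temp <- T0
      rows <- list(tibble::tibble(restart = r, iteration = 0L, pi = cur_pi,
                                  best_pi = max(best_pi, cur_pi)))
      if (cur_pi > best_pi) { best_pi <- cur_pi; best_values <- values }
      for (it in seq_len(budget)) {
        nm <- pm$free[[sample.int(length(pm$free), 1)]]
        b <- pm$entries[[nm]]$box
        cand <- values
        cand[[nm]] <- min(max(
          values[[nm]] + stats::rnorm(1, 0, step_frac * (b[2] - b[1])),
          b[1]), b[2])
        cand_pi <- objective(cand, eval_seed)
        if (cand_pi >= cur_pi ||
            stats::runif(1) < exp((cand_pi - cur_pi) / temp)) {
          values <- cand
          cur_pi <- cand_pi
          if (cur_pi > best_pi) { best_pi <- cur_pi; best_values <- values }
          rows[[length(rows) + 1]] <- tibble::tibble(
            restart = r, iteration = it, pi = cur_pi, best_pi = best_pi
          )
        }
        temp <- temp * cooling
      }
      trace[[r]] <- dplyr::bind_rows(rows)
    }
    list(values = best_values, pi = best_pi, trace = dplyr::bind_rows(trace))
  }

  res <- withr::with_seed(seed, run())
  best_params <- rebuild_params(template, res$values)
  structure(
    list(best_params = best_params, best_pi_bits = res$pi, trace = res$trace,
         seed = seed, constraints = constraints, n_restarts = n_restarts,
         profile = profile),
    class = "pi_optimization"
  )
}

#' @export
print.pi_optimization <- function(x, ...) {
  cat(sprintf("<pi_optimization> best PI = %.4f bits (%d restarts, seed %d)\n",
              x$best_pi_bits, x$n_restarts, x$seed))
  invisible(x)
}
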