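#' Read and validate a run configuration
#'
#' A run configuration is a YAML file with four sections: `model` (the
#' [model_params()] fields; `spatial` is either a single spec or one per
#' gene, each written as `{type: nearest_neighbor, J: ...}` or
#' `{type: long_range, amplitude: ..., range: ...}`), `profile` (the
#' [morphogen_profile()] fields), `task` (`name` one of `compute_pi`,
#' `sample`, `optimize`, `robustness`, `scaling`, plus task-specific
#' options), and top-level `seed` and `out_dir`. Schema violations raise an
#' error naming the offending field.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated config list with `params` and `profile` objects
#'   attached.
#' @export
read_run_config <- function(path) {
  # scalar handlers keep bare Y/N keys (e.g. the lattice size field "N")
  # from being parsed as YAML booleans
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = identity,
                                               "bool#no" = identity))
  for (section in c("model", "profile", "task")) {
    if (is.null(cfg[[section]])) {
      stop(sprintf("Config is missing the `%s` section.", section), call. = FALSE)
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  resolve_config(cfg)
}

parse_spatial <- function(sp) {
  if (is.null(sp$type)) stop("spatial spec needs a `type` field.", call. = FALSE)
  switch(sp$type,
    nearest_neighbor = nearest_neighbor(sp$J %||% 0),
    long_range = long_range(sp$amplitude, sp$range),
    sum = do.call(spatial_sum, lapply(sp$parts, parse_spatial)),
    stop(sprintf("Unknown spatial type `%s`.", sp$type), call. = FALSE)
  )
}

spatial_to_list <- function(sp) {
  switch(sp$type,
    nearest_neighbor = list(type = "nearest_neighbor", J = sp$J),
    long_range = list(type = "long_range", amplitude = sp$amplitude,
                      range = sp$range),
    sum = list(type = "sum", parts = lapply(sp$parts, spatial_to_list))
  )
}

resolve_config <- function(cfg) {
  mo <- cfg$model
  if (is.null(mo$eta)) stop("Config field `model.eta` is required.", call. = FALSE)
  if (mo$eta <= 0) stop("Config field `model.eta` must be positive.", call. = FALSE)
  K <- as.integer(mo$K %||% 1L)
  spatial <- mo$spatial %||% list(type = "nearest_neighbor", J = 0)
  spatial <- if (!is.null(spatial$type)) {
    parse_spatial(spatial)
  } else {
    lapply(spatial, parse_spatial)
  }
  Jl <- mo$J_local
  if (!is.null(Jl)) Jl <- matrix(unlist(Jl), K, K, byrow = TRUE)
  pr <- cfg$profile
  profile <- morphogen_profile(
    family = pr$family %||% "linear",
    N = pr$N %||% mo$N,
    amplitude = pr$amplitude %||% 1,
    chi = pr$chi %||% 0,
    values = pr$values,
    nu = pr$nu %||% 0,
    epsilon = pr$epsilon %||% 0
  )
  params <- model_params(
    N = mo$N, K = K,
    n_slope = unlist(mo$n_slope %||% 1),
    E_thresh = unlist(mo$E_thresh %||% 0),
    J_local = Jl, spatial = spatial, eta = mo$eta
  )
  cfg$params <- params
  cfg$profile_obj <- profile
  cfg
}

# fully resolved config (defaults included) for the manifest
config_manifest <- function(cfg) {
  p <- cfg$params
  list(
    model = list(
      N = p$N, K = p$K, n_slope = p$n_slope, E_thresh = p$E_thresh,
      J_local = apply(p$J_local, 1, as.list),
      spatial = lapply(p$spatial, spatial_to_list), eta = p$eta
    ),
    profile = list(
      family = attr(cfg$profile_obj, "family"),
      N = nrow(cfg$profile_obj),
      amplitude = attr(cfg$profile_obj, "amplitude"),
      chi = attr(cfg$profile_obj, "chi"),
      nu = attr(cfg$profile_obj, "nu"),
      epsilon = attr(cfg$profile_obj, "epsilon")
    ),
    task = cfg$task,
    seed = cfg$seed
  )
}

#' Execute a configured run
#'
#' Dispatches the config's task to the corresponding analysis, then writes
#' into `out_dir`: a `manifest.yml` echoing the fully resolved
#' configuration, a machine-readable `result.json` summary, and
#' task-specific delimited data tables (profile, marginals, mean pattern,
#' samples, traces). Identical configs and seeds produce identical result
#' records.
#'
#' @param config A config list from [read_run_config()] (or a path to one).
#' @param out_dir Output directory (created if needed); overrides the
#'   config's `out_dir` if given.
#' @return Invisibly, the result record written to `result.json`.
#' @export
run_patterning <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop(
    "An output directory is required (config `out_dir` or argument).",
    call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- config$params
  profile <- config$profile_obj
  task <- config$task
  seed <- config$seed

  yaml::write_yaml(config_manifest(config), file.path(out_dir, "manifest.yml"))
  write_profile(profile, file.path(out_dir, "profile.tsv"))

  result <- switch(task$name,
    compute_pi = {
      dist <- if (attr(profile, "nu") > 0) {
        extrinsic_average(params, profile, task$n_draws %||% 200,
                          task$mode %||% "iid", seed = seed)
      } else {
        site_marginals(params, profile)
      }
      write_marginals(dist, file.path(out_dir, "marginals.tsv"))
      pr <- positional_information(dist)
      as.list(glance.pi_result(pr))
    },
    sample = {
      ss <- sample_patterns(params, profile, task$n_samples %||% 1000,
                            task$method %||% "exact_chain", seed = seed,
                            burn_in = task$burn_in %||% 1000,
                            thinning = task$thinning %||% 1)
      write_samples(ss, file.path(out_dir, "samples.txt"))
      pr <- estimate_pi_from_samples(ss)
      as.list(glance.pi_result(pr))
    },
    optimize = {
      opt <- maximize_pi(params, profile, free = unlist(task$free),
                         constraints = task$constraints %||% list(),
                         seed = seed, budget = task$budget %||% 2000,
                         n_restarts = task$n_restarts %||% 5)
      readr::write_tsv(opt$trace, file.path(out_dir, "trace.tsv"))
      readr::write_tsv(tidy.model_params(opt$best_params),
                       file.path(out_dir, "best_params.tsv"))
      list(best_pi_bits = opt$best_pi_bits, n_restarts = opt$n_restarts)
    },
    robustness = {
      grid <- unlist(task$epsilon_grid %||% seq(-0.5, 0.5, by = 0.125))
      ov <- overlap_profile(params, profile, grid,
                            n_samples = task$n_samples %||% 2000, seed = seed)
      readr::write_tsv(ov, file.path(out_dir, "overlap.tsv"))
      chi <- susceptibility(params, profile,
                            delta_eps = task$delta_eps %||% 0.05,
                            n_samples = task$n_samples %||% 2000, seed = seed)
      list(chi_m = chi$chi_m, overlap_at_zero = ov$overlap[grid == 0])
    },
    scaling = {
      sc <- scaling_experiment(params, profile,
                               sizes = unlist(task$sizes %||% c(50, 60, 70)),
                               n_samples = task$n_samples %||% 2000, seed = seed)
      readr::write_tsv(sc$boundaries, file.path(out_dir, "boundaries.tsv"))
      list(n_sizes = length(sc$mean_patterns))
    },
    stop(sprintf("Unknown task `%s`.", task$name), call. = FALSE)
  )
  record <- c(list(task = task$name, seed = seed), result)
  record <- record[!vapply(record, function(v) length(v) == 1 && is.na(v),
                           logical(1))]
  jsonlite::write_json(record, file.path(out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' Write / read per-site state marginals as a delimited table
#'
#' Long-form tab-separated table with columns `site`, `state`,
#' `probability`; round-trips through [read_marginals()] without loss.
#'
#' @param dist A `"pattern_distribution"`.
#' @param path File path.
#' @return `read_marginals()` a `"pattern_distribution"` (without source
#'   model); `write_marginals()` the input, invisibly.
#' @export
write_marginals <- function(dist, path) {
  readr::write_tsv(tidy.pattern_distribution(dist), path)
  invisible(dist)
}

#' @rdname write_marginals
#' @export
read_marginals <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    site = readr::col_integer(), state = readr::col_integer(),
    probability = readr::col_double()
  ))
  marg <- matrix(0, max(df$state), max(df$site))
  marg[cbind(df$state, df$site)] <- df$probability
  new_pattern_distribution(marg, NA_real_, NULL, NULL)
}

#' Generate random valid model/profile fixtures
#'
#' Draws `n_models` random parameterizations spanning one to three genes,
#' lattice sizes 4 to 60, all three profile families, both spatial kernel
#' types, intrinsic noise in \[0.1, 5\] and extrinsic variance in
#' \{0, 0.1, 0.3\}. Fixtures with nearest-neighbour kernels and
#' `K * N <= 20` are flagged `oracle_safe` (amenable to exhaustive
#' enumeration); at least one such fixture is always included.
#'
#' @param seed Integer seed (generation is deterministic per seed).
#' @param n_models Number of fixtures (at least 1).
#' @return A tibble with list-columns `params` and `profile` and columns
#'   `id`, `K`, `N`, `family`, `spatial_type`, `eta`, `nu`, `oracle_safe`.
#' @export
generate_fixtures <- function(seed, n_models) {
  stopifnot(n_models >= 1)
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_models), function(i) {
      # guarantee the first fixture is oracle-safe
      oracle <- i == 1 || stats::runif(1) < 0.4
      K <- if (oracle) sample(1:2, 1) else sample(1:3, 1)
      N <- if (oracle) sample(4:(20 %/% K), 1) else sample(4:60, 1)
      family <- sample(c("linear", "exponential", "anchored"), 1)
      spatial_type <- if (oracle) "nearest_neighbor" else {
        sample(c("nearest_neighbor", "long_range"), 1)
      }
      spatial <- lapply(seq_len(K), function(a) {
        if (spatial_type == "nearest_neighbor") {
          nearest_neighbor(stats::runif(1, -1.5, 1.5))
        } else {
          long_range(stats::runif(1, -1, 1), stats::runif(1, 0.5, 10))
        }
      })
      Jl <- matrix(0, K, K)
      if (K > 1) {
        v <- stats::runif(K * (K - 1) / 2, -1, 1)
        Jl[upper.tri(Jl)] <- v
        Jl <- Jl + t(Jl)
      }
      eta <- stats::runif(1, 0.1, 5)
      nu <- sample(c(0, 0.1, 0.3), 1)
      params <- model_params(
        N = N, K = K, n_slope = stats::runif(K, 0, 5),
        E_thresh = stats::runif(K, -1, 1), J_local = Jl,
        spatial = spatial, eta = eta
      )
      profile <- morphogen_profile(
        family, N = N, amplitude = 1,
        chi = if (family == "exponential") stats::runif(1, 0.01, 1) else 0,
        nu = nu
      )
      tibble::tibble(
        id = i, K = K, N = N, family = family, spatial_type = spatial_type,
        eta = eta, nu = nu,
        oracle_safe = spatial_type == "nearest_neighbor" && K * N <= 20,
        params = list(params), profile = list(profile)
      )
    })
    dplyr::bind_rows(rows)
  })
}
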