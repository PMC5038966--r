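#' Construct a morphogen signal profile
#'
#' A morphogen profile assigns to every lattice site `x = 1..N` a scalar
#' signal value `m(x)`, interpreted as the logarithm of the local morphogen
#' concentration, `m(x) = log(c(x))`. Three built-in families are provided:
#'
#' * `"linear"`: `m` decreases linearly from `+amplitude` at `x = 1` to
#'   `-amplitude` at `x = N`. Under the log map this corresponds to the
#'   exponential concentration gradients commonly observed in embryos.
#' * `"exponential"`: a two-point-anchored exponential
#'   `m(x) = a exp(-chi (x - 1)) + b` with `a`, `b` chosen so that
#'   `m(1) = +amplitude` and `m(N) = -amplitude`. The shape parameter `chi`
#'   interpolates between the linear profile (`chi -> 0`) and a signal
#'   concentrated at the anterior boundary (large `chi`).
#' * `"anchored"`: `amplitude` at the first site and exactly zero elsewhere,
#'   modelling a purely boundary-localized patterning cue.
#'
#' The profile also carries two perturbation channels used throughout the
#' package: `nu`, the variance of additive Gaussian extrinsic fluctuations of
#' the signal (see [sample_extrinsic()]), and `epsilon`, a deterministic
#' additive dosage offset applied before the signal is read out (see
#' [bias_from_signal()]).
#'
#' @param family One of `"linear"`, `"exponential"`, `"anchored"`, `"custom"`.
#' @param N Number of lattice sites (at least 2). Ignored when `values` is
#'   supplied.
#' @param amplitude Positive signal amplitude; the linear and exponential
#'   families span `[-amplitude, +amplitude]`.
#' @param chi Nonnegative decay parameter of the exponential family.
#' @param values Numeric vector of signal values for `family = "custom"`.
#' @param nu Nonnegative variance of extrinsic Gaussian signal fluctuations.
#' @param epsilon Additive offset applied to the signal at readout.
#'
#' @return A tibble of class `"morphogen_profile"` with columns `site` and
#'   `m`, carrying `family`, `amplitude`, `chi`, `nu` and `epsilon` as
#'   attributes.
#'
#' @examples
#' morphogen_profile("linear", N = 3)          # m = (1, 0, -1)
#' morphogen_profile("exponential", N = 50, chi = 0.2)
#' @export
morphogen_profile <- function(family = c("linear", "exponential", "anchored", "custom"),
                              N = NULL, amplitude = 1, chi = 0,
                              values = NULL, nu = 0, epsilon = 0) {
  family <- match.arg(family)
  if (family == "custom") {
    if (is.null(values)) {
      stop("`values` must be supplied for a custom profile.", call. = FALSE)
    }
    values <- as.numeric(values)
    N <- length(values)
  }
  if (is.null(N) || N < 2) {
    stop("`N` must be at least 2.", call. = FALSE)
  }
  N <- as.integer(N)
  if (family != "custom" && amplitude <= 0) {
    stop("`amplitude` must be positive.", call. = FALSE)
  }
  if (chi < 0) stop("`chi` must be nonnegative.", call. = FALSE)
  if (nu < 0) stop("`nu` (extrinsic variance) must be nonnegative.", call. = FALSE)

  x <- seq_len(N)
  m <- switch(family,
    linear = amplitude * (1 - 2 * (x - 1) / (N - 1)),
    exponential = {
      if (chi == 0) {
        amplitude * (1 - 2 * (x - 1) / (N - 1))
      } else {
        # a solves a * (exp(-chi (N-1)) - 1) = -2A; expm1 keeps chi -> 0 stable
        a <- -2 * amplitude / expm1(-chi * (N - 1))
        amplitude + a * expm1(-chi * (x - 1))
      }
    },
    anchored = c(amplitude, rep(0, N - 1)),
    custom = values
  )
  if (!all(is.finite(m))) stop("Profile values must all be finite.", call. = FALSE)

  new_morphogen_profile(
    tibble::tibble(site = x, m = m),
    family = family, amplitude = amplitude, chi = chi,
    nu = nu, epsilon = epsilon
  )
}

new_morphogen_profile <- function(df, family, amplitude, chi, nu, epsilon) {
  structure(
    df,
    family = family, amplitude = amplitude, chi = chi,
    nu = nu, epsilon = epsilon,
    class = c("morphogen_profile", class(tibble::tibble()))
  )
}

#' @export
print.morphogen_profile <- function(x, ...) {
  cat(sprintf(
    "<morphogen_profile> family = %s, N = %d, nu = %g, epsilon = %g\n",
    attr(x, "family"), nrow(x), attr(x, "nu"), attr(x, "epsilon")
  ))
  NextMethod()
}

#' Profile accessors and perturbation helpers
#'
#' `profile_values()` extracts the signal vector `m(x)`; `set_offset()` and
#' `set_noise()` return a copy of the profile with the dosage offset
#' `epsilon` or the extrinsic variance `nu` replaced.
#'
#' @param profile A [morphogen_profile()].
#' @param epsilon,nu New offset / extrinsic variance.
#' @return `profile_values()` a numeric vector; the setters a profile.
#' @export
profile_values <- function(profile) {
  stopifnot(inherits(profile, "morphogen_profile"))
  profile$m
}

#' @rdname profile_values
#' @export
set_offset <- function(profile, epsilon) {
  attr(profile, "epsilon") <- epsilon
  profile
}

#' @rdname profile_values
#' @export
set_noise <- function(profile, nu) {
  if (nu < 0) stop("`nu` must be nonnegative.", call. = FALSE)
  attr(profile, "nu") <- nu
  profile
}

#' Hill-type activation probability
#'
#' Probability that a gene regulated cooperatively by `n_hill` binding sites
#' with common affinity `K_half` is ON at morphogen concentration `c`:
#' `c^n / (c^n + K^n)`. With the signal defined as `m = log(c)`, this
#' thermodynamic readout coincides with the single-spin Boltzmann marginal of
#' an uncoupled gene whose bias is `h = n (m - E)` (with `n_hill = 2 n / eta`
#' and `K_half = exp(E)`).
#'
#' @param c Positive morphogen concentration (vectorized).
#' @param n_hill Positive Hill coefficient.
#' @param K_half Positive half-saturation constant.
#' @return Activation probability in (0, 1), monotone increasing in `c`.
#' @export
hill_activation <- function(c, n_hill, K_half) {
  if (any(c <= 0) || K_half <= 0 || n_hill <= 0) {
    stop("`c`, `n_hill` and `K_half` must be positive.", call. = FALSE)
  }
  # logistic form of the Hill function is stable for large n * log(c/K)
  stats::plogis(n_hill * (log(c) - log(K_half)))
}

#' Map a morphogen signal to per-site gene biases
#'
#' The bias experienced by a gene with readout slope `n_slope` and threshold
#' `E_thresh` is the affine map `h(x) = n (m(x) + epsilon - E)`, where
#' `epsilon` is the profile's dosage offset. Positive bias favours the ON
#' state.
#'
#' @param profile A [morphogen_profile()].
#' @param n_slope Readout slope `n`.
#' @param E_thresh Readout threshold `E` (signal units).
#' @return Numeric vector of per-site biases, length `N`.
#' @export
bias_from_signal <- function(profile, n_slope, E_thresh) {
  m <- profile_values(profile) + attr(profile, "epsilon")
  n_slope * (m - E_thresh)
}

#' Draw an extrinsic-noise realization of a profile
#'
#' Adds zero-mean Gaussian fluctuations of variance `nu` (the profile's
#' extrinsic variance) to the signal. In `"iid"` mode each site receives an
#' independent draw; in `"shared"` mode a single draw shifts all sites
#' coherently, modelling correlated (dosage-like) fluctuations. With
#' `nu = 0` the profile is returned unchanged.
#'
#' @param profile A [morphogen_profile()].
#' @param mode `"iid"` or `"shared"`.
#' @param seed Optional integer seed; identical seeds reproduce identical
#'   draws without disturbing the caller's RNG state.
#' @return A `morphogen_profile` whose `m` column carries the realized
#'   fluctuations (family becomes `"custom"`, `nu` is kept for reference).
#' @export
sample_extrinsic <- function(profile, mode = c("iid", "shared"), seed = NULL) {
  mode <- match.arg(mode)
  nu <- attr(profile, "nu")
  if (nu < 0) stop("`nu` must be nonnegative.", call. = FALSE)
  if (nu == 0) return(profile)
  draw <- function() {
    sd <- sqrt(nu)
    delta <- if (mode == "iid") stats::rnorm(nrow(profile), 0, sd) else stats::rnorm(1, 0, sd)
    out <- profile
    out$m <- profile$m + delta
    attr(out, "family") <- "custom"
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Read or write a profile as a two-column table
#'
#' Profiles serialize to a tab-delimited text table with columns `site` and
#' `m`; shape metadata (family, `nu`, `epsilon`) lives in the run
#' configuration, so a re-read profile has family `"custom"`.
#'
#' @param profile A [morphogen_profile()].
#' @param path File path.
#' @param nu,epsilon Extrinsic variance and offset to attach on read.
#' @return `read_profile()` a `morphogen_profile`; `write_profile()` the
#'   input, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile)[, c("site", "m")], path)
  invisible(profile)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, nu = 0, epsilon = 0) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    site = readr::col_integer(), m = readr::col_double()
  ))
  morphogen_profile("custom", values = df$m, nu = nu, epsilon = epsilon)
}
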