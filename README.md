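# patterninfo

How much can a cell know about where it is? In developmental patterning, a
row of `N` nuclei reads a noisy morphogen gradient through `K` ON/OFF
patterning genes, and the quality of the resulting spatial code is measured
by **positional information**: the mutual information, in bits, between a
cell's position `x` and its local joint expression state
`σ(x) ∈ {−1, +1}^K`,

```
I(σ; x) = S[P_σ] − ⟨ S[P(σ|x)] ⟩_x ,
```

with a uniform prior over positions. `patterninfo` implements the minimal
statistical-physics model in which this question is exactly computable: an
Ising spin chain in an inhomogeneous field, with Boltzmann pattern
probabilities `Q(σ) ∝ exp(−H(σ)/η)` and energy

```
H = − Σ_a Σ_x n_a (m(x) − E_a) σ_a(x)          (morphogen readout)
    − Σ_a Σ_{i<j} J_a(i,j) σ_a(i) σ_a(j)       (spatial couplings)
    − Σ_{a<g} 2 J_ag Σ_x σ_a(x) σ_g(x)         (local gene–gene couplings)
```

Here `m(x)` is the log morphogen concentration, `η` a temperature-like
intrinsic noise, and spatial couplings are either nearest-neighbour bonds
or an exponentially decaying long-range kernel
`J(i,j) = J̃ exp(−(|i−j|−1)/r)`. The package is for researchers in
quantitative developmental biology and biophysics who want to explore
optimal patterning strategies (boundary, French Flag, Counter, alternating
codes), the limits set by the data processing inequality, and the
canalization/scaling effects of long-range couplings — with exact answers
where they exist and validated samplers where they do not.

## What's inside

* **Profiles** — `morphogen_profile()` (linear, anchored-exponential with
  shape `χ`, boundary-anchored, custom), dosage offsets `ε`, extrinsic
  Gaussian noise `ν`, `hill_activation()`.
* **Model** — `model_params()`, `nearest_neighbor()` / `long_range()` /
  `spatial_sum()`, `pattern_energy()`, `parameter_count()`.
* **Exact inference** — `site_marginals()` (transfer matrices),
  `brute_force_distribution()` (enumeration oracle),
  `positional_information()`, `extrinsic_average()`,
  `morphogen_information()`, `dpi_gap()`.
* **Sampling** — `sample_patterns()` (i.i.d. exact-chain draws or
  Metropolis for long-range kernels, in compiled code), `mean_pattern()`,
  `estimate_pi_from_samples()`.
* **Optimization** — `maximize_pi()` (simulated annealing with box
  constraints, e.g. positive spatial couplings).
* **Patterns & robustness** — `counter_pattern()`, `french_flag_pattern()`,
  `counter_network()`, `classify_pattern()`, `pattern_overlap()`,
  `susceptibility()`, `scaling_experiment()`, `positional_error_bound()`.
* **Reproducible runs** — YAML run configs (`read_run_config()`,
  `run_patterning()`), fixture generation, tidyverse-style `tidy()` /
  `glance()` methods and `autoplot()` figures, plus a thin CLI at
  `inst/cli/patterninfo.R`.

## Worked example

A hand-built two-gene network with strong mutual repression generates the
four-state "Counter" pattern on a linear gradient and carries nearly the
maximal 2 bits at low intrinsic noise:

```r
library(patterninfo)

prof <- morphogen_profile("linear", N = 60)
net  <- counter_network(N = 60, eta = 0.2)
dist <- site_marginals(net, prof)        # exact transfer-matrix marginals

glance(positional_information(dist))
#> # A tibble: 1 × 4
#>   total_bits state_entropy_bits noise_entropy_bits    se
#>        <dbl>              <dbl>              <dbl> <dbl>
#> 1       1.88               2.00              0.122    NA

tidy(positional_information(dist))       # all four states near 25% usage
#> # A tibble: 4 × 3
#>   state label probability
#>   <int> <chr>       <dbl>
#> 1     1 ++          0.254
#> 2     2 +-          0.246
#> 3     3 -+          0.246
#> 4     4 --          0.254

classify_pattern(mean_pattern(dist))
#> # A tibble: 1 × 2
#>   label   n_states
#>   <chr>      <int>
#> 1 counter        4
```

The state-usage entropy is a full 2 bits; 0.12 bits are lost to intrinsic
noise at the block boundaries. With extrinsic signal noise the same
spatially coupled network extracts *more* positional information than the
noisy signal itself carries — spatial averaging beats the data processing
inequality, which only binds uncoupled readouts:

```r
noisy <- set_noise(prof, 0.3)
dpi_gap(net, noisy, n_draws = 200, seed = 1)
#> # A tibble: 1 × 4
#>   pi_pattern pi_signal   gap     se
#>        <dbl>     <dbl> <dbl>  <dbl>
#> 1      0.719     0.547 0.173 0.0119
```

`autoplot(dist)` draws the greyscale mean pattern; `maximize_pi()` finds
such networks automatically from a blank template.

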