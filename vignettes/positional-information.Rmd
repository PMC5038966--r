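---
title: "Positional information in a spin-chain model of morphogen patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional information in a spin-chain model of morphogen patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patterninfo)
```

## The model

`patterninfo` studies how much a row of `N` cells can learn about their
position from a smooth morphogen gradient when the readout consists of `K`
binary ("ON/OFF") patterning genes. The joint expression pattern
$\vec\sigma = \{\sigma_a(x)\}$, $\sigma_a(x) = \pm 1$, is modelled as an
equilibrium spin chain: patterns occur with Boltzmann probability

$$Q(\vec\sigma) = \frac{1}{Z}\, e^{-H(\vec\sigma)/\eta},$$

where the intrinsic noise $\eta$ plays the role of temperature and the
energy collects three kinds of terms:

$$H = -\sum_a \sum_x h_a(x)\,\sigma_a(x)
      \;-\; \sum_a \sum_{i<j} J_a(i,j)\,\sigma_a(i)\sigma_a(j)
      \;-\; \sum_{a<g} 2 J_{ag} \sum_x \sigma_a(x)\sigma_g(x).$$

* **Morphogen readout.** The bias $h_a(x) = n_a\,(m(x) - E_a)$ is an affine
  readout of the signal $m(x)$, interpreted as log morphogen concentration.
  With $\eta = 1$ and no couplings the ON probability of a single gene is
  exactly a Hill function of the concentration with coefficient $2 n_a$ and
  half-point $e^{E_a}$ (`hill_activation()`).
* **Spatial couplings.** Either nearest-neighbour bonds of strength $J$
  (open chain, no wraparound) or an exponentially decaying long-range kernel
  $J(i,j) = \tilde J\, e^{-(|i-j|-1)/r}$; components add via
  `spatial_sum()`. The $r \to \infty$ limit with $\tilde J < 0$ is, up to a
  constant, a penalty $\propto -\tilde J (\sum_x \sigma(x))^2$ on any
  imbalance between ON and OFF states.
* **Local gene–gene couplings.** One symmetric coupling per unordered gene
  pair; the factor 2 reproduces the sum over ordered pairs of the K-gene
  energy, so `pattern_energy()` agrees term by term with the
  nearest-neighbour chain Hamiltonian.

Positional information (PI) is the mutual information between lattice
position (uniform prior) and the local joint expression state,

$$I(\sigma; x) = S[P_\sigma] - \langle S[P(\sigma \mid x)] \rangle_x
  \quad \text{bits},$$

computed from the per-site marginals $P(\sigma\mid x)$ of the pattern
distribution. It is bounded by $\min(K, \log_2 N)$ bits; the noiseless
maximizer is the *Counter* pattern, in which each of the $2^K$ joint states
occupies an equal fraction of the lattice.

## Exact computation, sampling, and noise channels

For nearest-neighbour couplings, `site_marginals()` computes the marginals
and $\log Z$ exactly with forward/backward products of $2^K \times 2^K$
transfer matrices over the joint local state. On-site terms (bias and local
couplings) are attached to each site's own factor, bond terms to the bond
between consecutive sites; every step is rescaled by its maximum so fields
as large as $|h|/\eta \sim 100$ stay in range. This assignment is pinned by
`brute_force_distribution()`, an exhaustive-enumeration oracle (limited to
$K N \le 20$) that the test suite compares against at $10^{-10}$ on dozens
of random models.

Long-range kernels defeat the transfer matrix, so `sample_patterns()`
provides two samplers: `exact_chain` (forward-filtering/backward-sampling,
i.i.d. draws, nearest-neighbour only) and `metropolis` (single-spin-flip,
random scan, acceptance $\min(1, e^{-\Delta H/\eta})$, any kernel). The
Metropolis schedule defaults to a 1000-sweep burn-in with thinning 1 —
these lattices are small and mix quickly in generic regimes. Two optional
aids matter in strongly ordered regimes: `init = "field"` starts the chain
from the bias-aligned configuration, and `anneal_factor > 1` cools the
temperature geometrically during burn-in, both of which help the chain
reach the dominant free-energy basin when a strong balance coupling makes
single-spin dynamics glassy. `estimate_pi_from_samples()` is the plug-in
information estimate from empirical frequencies with a block-jackknife
standard error; a Miller–Madow correction is available but off by default,
since at these state-space sizes the plug-in bias is already small and
visible only as an upward trend that shrinks with sample size.

Two noise channels enter separately:

* **Intrinsic noise** $\eta$ scales the whole energy; $\eta \to 0$ gives a
  deterministic readout, $\eta \to \infty$ coin-flip expression.
* **Extrinsic noise** adds Gaussian fluctuations of variance $\nu$ to the
  signal, independently per site (`"iid"`) or as one coherent shift
  (`"shared"`). `extrinsic_average()` marginalizes it by Monte Carlo:
  each realization is solved exactly, the marginals are averaged, and a
  delete-one jackknife over realizations provides the standard error of
  downstream information values. A closed-form treatment is not attempted;
  the Monte Carlo route is the ground truth here and its $1/n$ variance
  scaling is verified in the tests.

The signal itself carries positional information
$I(m; x) = h[P_m] - \tfrac12 \log_2 (2\pi e \nu)$, where $P_m$ is the
equal-weight mixture of $N$ Gaussians centred on the profile values.
`morphogen_information()` evaluates the mixture entropy by trapezoidal
quadrature on 4096 points spanning six standard deviations beyond the
signal range, clips to $[0, \log_2 N]$, and is cross-checked against a
Monte Carlo estimate of the same integral. When all spatial couplings are
zero, position → signal → expression is a Markov chain and the data
processing inequality forces $I(\sigma;x) \le I(m;x)$; `dpi_gap()` measures
the difference, and with spatial couplings the gap can turn positive
because neighbouring sites share independent noise realizations that the
chain can average away.

## Morphogen profiles

`morphogen_profile()` builds the signal families: linear (the log of the
exponential concentration gradients commonly observed), a two-point-anchored
exponential $m_\chi(x) = a e^{-\chi(x-1)} + b$ with $m(1) = +A$ and
$m(N) = -A$ — chosen so that $\chi \to 0$ recovers the linear profile
exactly, which also fixes the normalization question (endpoint anchoring,
not total-amplitude normalization) — and an anchored profile that is zero
everywhere except the first site. The default amplitude is 1 so that biases
are of order unity and the interesting noise regime sits at $\eta$ of order
one; sites are indexed $x = 1..N$. The `expm1` form of the exponential
family keeps the $\chi \to 10^{-6}$ limit accurate to $10^{-5}$.

## Maximizing information

`maximize_pi()` performs simulated annealing over the distinct model
parameters: per-gene slope and threshold, one spatial coupling per gene,
and one local coupling per unordered gene pair. (The conventional count of
interaction parameters, $3K + K(K+1)/2$ — 9 for two genes, 15 for three —
is reported by `parameter_count()`; the optimizer works on the distinct
set.) Design choices, pinned by recovery of analytically known optima
rather than by any external prescription:

* parameter boxes $n \in [0, 10]$, $E \in [-2, 2]$, couplings $\in [-5, 5]$,
  which bracket all regimes of interest at unit signal amplitude;
* single-coordinate Gaussian proposals with standard deviation 0.3 of the
  box width, clipped to the box;
* initial temperature 0.1 bits, geometric cooling by 0.995 per iteration,
  five restarts from random interior points by default.

The objective is the exact transfer-matrix information when the model is
nearest-neighbour and noiseless in the signal; with extrinsic noise it is
the Monte Carlo average over a fixed set of signal realizations (common
random numbers, so the optimizer sees a deterministic surface), and for
long-range kernels it is the sampled estimate, again with a fixed
per-evaluation seed.

Two cautions learned from the optimization landscape. First, at low noise
an unconstrained search almost always spends one gene on a strictly
alternating pattern (strongly negative spatial coupling), which contributes
one bit by distinguishing odd from even sites; restricting spatial
couplings to be positive (`constraints = list(Js = c(0, 5))`) removes this
trivially available strategy and recovers boundary-type optima. Second,
because slopes and couplings can grow within their boxes to compensate
noise, the staged loss of expression states happens at larger $\eta$ than
the unit-parameter intuition suggests; the test suite stages a two-gene
system through 4 → 3 → 2 states over $\eta \in \{0.25, 2, 10\}$ on a
40-site lattice (sizes chosen to keep the full suite inside a few minutes
of CPU time).

## Reference patterns and a hand-built Counter network

`counter_pattern()` and `french_flag_pattern()` generate the noiseless
archetypes; the Counter uses binary-counting blocks with gene 1 as the most
significant bit (any state permutation has identical information — this
ordering gives the top gene a single central boundary).
`classify_pattern()` binarizes a mean pattern at zero and labels it
(counter, french_flag, boundary, alternating, uniform, other) with a 5%
usage threshold for counting states.

`counter_network()` is a hand-built two-gene parameterization whose
low-noise pattern is the four-state Counter: gene 1 reads the gradient with
a central threshold, gene 2 with a steeper slope, and strong mutual
repression ($J_{12} = -1$) switches gene 2 to the inverse of gene 1 where
the signal is weak. Two algebraic constraints matter: gene 2's slope of
exactly $4|J_{12}|$ places its switches at half-maximal signal (carving
quarters), and gene 1's slope must exceed $4|J_{12}|$ — and comfortably
exceed gene 2's slope — or the anterior all-ON block loses out to the
anti-aligned configuration favoured by the repression.

## Robustness: canalization and scaling

Dosage perturbations add an offset $\epsilon$ to the signal before readout
(multiplicative in concentration). `overlap_profile()` tracks the overlap
$S(\epsilon)$ — the gene- and site-averaged product of mean patterns with
and without the offset — and `susceptibility()` takes its central
difference $\chi_m = [S(+\delta) - S(-\delta)]/(2\delta)$ with
$\delta = 0.05$ by default, a step pinned by an exact closed-form check on
the uncoupled single-gene model. Two facts shape how these are used:

* $S(0) = \frac{1}{NK}\sum \langle\sigma\rangle^2$ equals 1 only when
  expression is deterministic, so "unperturbed overlap is unity" is a
  statement about the low-noise regime.
* For mirror-symmetric configurations $S(\epsilon)$ is nearly even, making
  the central difference vanish regardless of robustness. A first-order
  susceptibility needs an asymmetric response; the package's demonstration
  places a readout threshold in the flat tail of a steep exponential
  gradient, where a positive offset floods the whole lattice ON while a
  negative one only shifts the boundary. There, $|\chi_m|$ drops from
  above 1 to a fraction of that as the negative long-range amplitude grows
  — the canalized regime.

`scaling_experiment()` cuts the base profile short or extends it at the
posterior value, recomputes mean patterns at each size, and extracts
boundaries as interpolated zero crossings (`boundary_positions()`; ties
toward the anterior). `main_boundary()` additionally matches each gene
against an ideal anterior-ON step before picking the crossing, which makes
the extraction robust to the small wiggles of sampled means. Without
long-range couplings the central boundary stays at a fixed absolute
position; adding a negative long-range component to each gene pulls it
toward a fixed fractional position instead. The regime demonstrated in the
tests uses the Counter network with wall tension raised to
`j_spatial = c(3, 1.5)` and a balance component of amplitude $-0.4$ with
range 200 at $\eta = 0.4$: the stronger nearest-neighbour bonds raise the
nucleation cost of spurious domains above the balance energy gained by
fragmenting, which is the failure mode of weak-tension networks under a
strong balance term; mean patterns average 4 independent chains of 3000
recorded sweeps after a 15000-sweep burn-in.

## Positional-error bound

`positional_error_bound()` evaluates
$(1/12)\,(N^2\, 2^{-2 I} - 1)$, the standard information-theoretic lower
bound on the mean squared error of any positional estimator: the variance
of the uniform prior at $I = 0$, zero at $I = \log_2 N$.
`optimal_estimator_mse()` computes the best achievable MSE by brute force
(posterior mean under Bayesian inversion of the site marginals). A known
limitation, documented rather than hidden: the bound's variance–entropy
step is exact for uniform-like posteriors but not in general — a
bell-shaped posterior carries more entropy per unit variance than a uniform
one (the rigorous constant would be $1/2\pi e$ rather than $1/12$), so on
a minority of small models the optimal estimator beats the printed bound
by up to a few percent of the prior variance. The package reports the
closed form as printed; treat it as a tight approximation, not a strict
bound, for concentrated posteriors.

## What the synthetic models do and do not show

All inputs here are synthetic: profiles are smooth deterministic curves
plus Gaussian noise, expression is binary and at equilibrium, interactions
are symmetric, and the lattice is one-dimensional. Passing tests therefore
demonstrate internal consistency (exact methods vs. enumeration, samplers
vs. exact marginals, optimizers vs. known optima) and the qualitative
phenomenology — combinatorial codes, noise-staged strategy transitions,
information creation by spatial coupling, canalization and scaling — not
quantitative agreement with any real patterning system, where intermediate
expression levels, non-equilibrium dynamics, and asymmetric regulation all
matter.
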