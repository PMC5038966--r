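#include <Rcpp.h>
using namespace Rcpp;

// Single-spin-flip Metropolis sampler for the K-gene Ising patterning chain.
// Proposals flip one (gene, site) spin chosen uniformly at random; a sweep is
// K * N proposals. Acceptance is min(1, exp(-dH / eta)) with
//   dH = 2 s_a(x) * [ h_a(x) + sum_j J_a(x, j) s_a(j)
//                     + 2 sum_{g != a} Jlocal(a, g) s_g(x) ],
// matching the energy convention in which each unordered site pair and gene
// pair contributes once. Uses R's RNG, so draws are reproducible via
// set.seed() on the R side.
// During burn-in the temperature can optionally be annealed from
// anneal_factor * eta down to eta (geometric schedule); this helps the
// chain find the global free-energy basin in glassy regimes (strong
// long-range couplings at low noise) before recording starts.
// [[Rcpp::export]]
IntegerVector metropolis_chain(IntegerMatrix init, NumericMatrix h, List kernels,
                               NumericMatrix Jlocal, double eta,
                               int n_samples, int burn_in, int thinning,
                               double anneal_factor = 1.0) {
  int K = init.nrow(), N = init.ncol();
  std::vector<NumericMatrix> Js;
  for (int a = 0; a < K; a++) Js.push_back(as<NumericMatrix>(kernels[a]));
  IntegerMatrix s = clone(init);
  IntegerVector out(K * N * n_samples);
  out.attr("dim") = Dimension(K, N, n_samples);
  int total_sweeps = burn_in + n_samples * thinning;
  int rec = 0;
  for (int sweep = 0; sweep < total_sweeps; sweep++) {
    double eta_t = eta;
    if (anneal_factor > 1.0 && burn_in > 0 && sweep < burn_in) {
      double frac = 1.0 - (double)sweep / (double)burn_in;
      eta_t = eta * std::pow(anneal_factor, frac);
    }
    for (int step = 0; step < K * N; step++) {
      int a = (int)(unif_rand() * K); if (a == K) a--;
      int x = (int)(unif_rand() * N); if (x == N) x--;
      double field = h(a, x);
      double sp = 0.0;
      for (int j = 0; j < N; j++) sp += Js[a](x, j) * s(a, j);
      double loc = 0.0;
      for (int g = 0; g < K; g++)
        if (g != a) loc += 2.0 * Jlocal(a, g) * s(g, x);
      double dH = 2.0 * s(a, x) * (field + sp + loc);
      if (dH <= 0.0 || unif_rand() < std::exp(-dH / eta_t)) s(a, x) = -s(a, x);
    }
    if (sweep >= burn_in && ((sweep - burn_in) % thinning == 0) && rec < n_samples) {
      for (int x = 0; x < N; x++)
        for (int a = 0; a < K; a++)
          out[rec * K * N + x * K + a] = s(a, x);
      rec++;
    }
  }
  return out;
}
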