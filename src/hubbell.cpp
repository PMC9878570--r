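#include <Rcpp.h>
using namespace Rcpp;

// Weighted index draw proportional to w (sum passed in to avoid recompute).
static inline int draw_weighted(const std::vector<double>& w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int last = (int) w.size() - 1;
  for (int i = 0; i <= last; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return last;
}

// One Hubbell local community: start from `init` (counts per taxon summing
// to J) and run `steps` zero-sum death-replacement events. At each event one
// individual dies; with probability m the replacement immigrates from the
// metacommunity (relative abundances `meta`), otherwise it is a local birth
// proportional to local abundance. Uses R's RNG.
// [[Rcpp::export(name = ".hubbell_steps")]]
IntegerVector hubbell_steps(IntegerVector init, NumericVector meta,
                            double m, int steps) {
  int S = init.size();
  std::vector<double> local(S);
  double J = 0.0;
  for (int i = 0; i < S; ++i) { local[i] = init[i]; J += init[i]; }
  std::vector<double> metav(meta.begin(), meta.end());
  double meta_tot = 0.0;
  for (int i = 0; i < S; ++i) meta_tot += metav[i];

  // the Rcpp attributes wrapper manages GetRNGstate/PutRNGstate
  for (int t = 0; t < steps; ++t) {
    int dead = draw_weighted(local, J);
    local[dead] -= 1.0;
    int born;
    if (unif_rand() < m) {
      born = draw_weighted(metav, meta_tot);
    } else {
      born = draw_weighted(local, J - 1.0);
    }
    local[born] += 1.0;
  }
  IntegerVector out(S);
  for (int i = 0; i < S; ++i) out[i] = (int) local[i];
  return out;
}
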