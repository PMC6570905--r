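#include <Rcpp.h>
using namespace Rcpp;

// Reaction network of the inducer-coupled self-repressor.
//
// Gene states: 0 = A11 (both operators free), 1 = A10, 2 = A01,
// 3 = A00 (fully repressed). A TetR dimer binds one operator with
// propensity h*n*(n-1)/2 and is displaced by a free-monomer competitor
// with propensity f*n (net +2 free monomers on unbinding). Synthesis
// g_ij depends on the gene state; the inducer sequesters free TetR
// into a non-DNA-binding complex Ta.
//
// Channels (fixed order, used by both SSA and the R-side propensity
// reference):
//  0  A11 -> A10   h*n*(n-1)/2        n -= 2
//  1  A11 -> A01   h*n*(n-1)/2        n -= 2
//  2  A10 -> A00   h*n*(n-1)/2        n -= 2
//  3  A01 -> A00   h*n*(n-1)/2        n -= 2
//  4  A10 -> A11   f*n (or f*n_ref)   n += 2
//  5  A01 -> A11   f*n (or f*n_ref)   n += 2
//  6  A00 -> A10   f*n (or f*n_ref)   n += 2
//  7  A00 -> A01   f*n (or f*n_ref)   n += 2
//  8  0 -> TetR    g_ij               n += 1
//  9  TetR -> 0    k1*n               n -= 1
// 10  TetR+I -> Ta b*n*ni             n -= 1, ni -= 1, nta += 1
// 11  Ta -> TetR+I a*nta              n += 1, ni += 1, nta -= 1
// 12  Ta -> 0      k2*nta             nta -= 1
// 13  0 -> I       c*E                ni += 1
// 14  I -> 0       c*ni               ni -= 1

static const int N_CHANNELS = 15;

struct Params {
  double h, f, g[4], k1, b, a, k2, c, E, n_ref;
  bool const_unbind;
};

static Params unpack(const NumericVector& p) {
  Params q;
  q.h = p["h"]; q.f = p["f"];
  q.g[0] = p["g11"]; q.g[1] = p["g10"]; q.g[2] = p["g01"]; q.g[3] = p["g00"];
  q.k1 = p["k1"]; q.b = p["b"]; q.a = p["a"]; q.k2 = p["k2"];
  q.c = p["c"]; q.E = p["E_aTc"];
  q.n_ref = p["n_ref"];
  q.const_unbind = p["const_unbind"] != 0.0;
  return q;
}

static inline void compute_propensities(int gene, double n, double nta,
                                        double ni, const Params& q,
                                        double* a) {
  const double bind = 0.5 * q.h * n * (n - 1.0);
  double unb;
  if (q.const_unbind) {
    unb = q.f * q.n_ref;
  } else {
    unb = q.f * n;
  }
  a[0] = (gene == 0 && n >= 2) ? bind : 0.0;
  a[1] = (gene == 0 && n >= 2) ? bind : 0.0;
  a[2] = (gene == 1 && n >= 2) ? bind : 0.0;
  a[3] = (gene == 2 && n >= 2) ? bind : 0.0;
  // concentration-dependent unbinding needs a competitor monomer (n >= 1);
  // the constant variant has no molecular competitor requirement
  bool can_unbind = q.const_unbind || n >= 1;
  a[4] = (gene == 1 && can_unbind) ? unb : 0.0;
  a[5] = (gene == 2 && can_unbind) ? unb : 0.0;
  a[6] = (gene == 3 && can_unbind) ? unb : 0.0;
  a[7] = (gene == 3 && can_unbind) ? unb : 0.0;
  a[8] = q.g[gene];
  a[9] = q.k1 * n;
  a[10] = q.b * n * ni;
  a[11] = q.a * nta;
  a[12] = q.k2 * nta;
  a[13] = q.c * q.E;
  a[14] = q.c * ni;
}

static inline void apply_reaction(int ch, int& gene, double& n, double& nta,
                                  double& ni) {
  switch (ch) {
    case 0: gene = 1; n -= 2; break;
    case 1: gene = 2; n -= 2; break;
    case 2: gene = 3; n -= 2; break;
    case 3: gene = 3; n -= 2; break;
    case 4: gene = 0; n += 2; break;
    case 5: gene = 0; n += 2; break;
    case 6: gene = 1; n += 2; break;
    case 7: gene = 2; n += 2; break;
    case 8: n += 1; break;
    case 9: n -= 1; break;
    case 10: n -= 1; ni -= 1; nta += 1; break;
    case 11: n += 1; ni += 1; nta -= 1; break;
    case 12: nta -= 1; break;
    case 13: ni += 1; break;
    case 14: ni -= 1; break;
  }
}

// one Gillespie direct-method step; returns channel or -1 if absorbing
static inline int ssa_step(int& gene, double& n, double& nta, double& ni,
                           double& t, const Params& q, double* a) {
  compute_propensities(gene, n, nta, ni, q, a);
  double a0 = 0.0;
  for (int i = 0; i < N_CHANNELS; ++i) a0 += a[i];
  if (a0 <= 0.0) return -1;
  t += -std::log(unif_rand()) / a0;
  double r = unif_rand() * a0, cum = 0.0;
  int ch = N_CHANNELS - 1;
  for (int i = 0; i < N_CHANNELS; ++i) {
    cum += a[i];
    if (r <= cum) { ch = i; break; }
  }
  apply_reaction(ch, gene, n, nta, ni);
  return ch;
}

// [[Rcpp::export]]
NumericVector cpp_propensities(int gene, double n_tetr, double n_ta,
                               double n_i, NumericVector params) {
  Params q = unpack(params);
  NumericVector out(N_CHANNELS);
  compute_propensities(gene, n_tetr, n_ta, n_i, q, &out[0]);
  return out;
}

// Full event recording (small runs); uses R's RNG.
// [[Rcpp::export]]
List cpp_ssa_events(int gene, double n_tetr, double n_ta, double n_i,
                    NumericVector params, double t_end, double max_events) {
  Params q = unpack(params);
  double a[N_CHANNELS];
  std::vector<double> ts, ns, ntas, nis;
  std::vector<int> genes;
  double t = 0.0, n = n_tetr, nta = n_ta, ni = n_i;
  ts.push_back(t); genes.push_back(gene);
  ns.push_back(n); ntas.push_back(nta); nis.push_back(ni);
  std::string status = "completed";
  while (t < t_end) {
    if ((double)ts.size() - 1.0 >= max_events) { status = "max_events"; break; }
    double t_prev = t;
    int g = gene;
    double nn = n, nnta = nta, nni = ni;
    int ch = ssa_step(g, nn, nnta, nni, t, q, a);
    if (ch < 0) { status = "absorbing"; break; }
    if (t > t_end) { t = t_prev; break; }  // last jump overshoots the horizon
    gene = g; n = nn; nta = nnta; ni = nni;
    ts.push_back(t); genes.push_back(gene);
    ns.push_back(n); ntas.push_back(nta); nis.push_back(ni);
  }
  return List::create(_["t"] = ts, _["gene"] = genes, _["n_tetr"] = ns,
                      _["n_ta"] = ntas, _["n_i"] = nis, _["status"] = status);
}

// Time-weighted stationary histogram over a count coordinate
// (0 = free TetR, 1 = total TetR-Venus incl. complex + DNA-bound).
// [[Rcpp::export]]
List cpp_ssa_histogram(int gene, double n_tetr, double n_ta, double n_i,
                       NumericVector params, double t_end, double burn_in,
                       int coord, int max_n) {
  Params q = unpack(params);
  double a[N_CHANNELS];
  NumericVector w(max_n + 1);
  static const int bound[4] = {0, 2, 2, 4};
  double t = 0.0, n = n_tetr, nta = n_ta, ni = n_i;
  double n_events = 0.0;
  std::string status = "completed";
  while (t < t_end) {
    double t_prev = t;
    int g = gene;
    double nn = n, nnta = nta, nni = ni;
    int ch = ssa_step(g, nn, nnta, nni, t, q, a);
    double t_next = (ch < 0) ? t_end : std::min(t, t_end);
    double lo = std::max(t_prev, burn_in), hi = t_next;
    if (hi > lo) {
      double v = (coord == 0) ? n : n + nta + bound[gene];
      int k = (int)std::lround(v);
      if (k > max_n) k = max_n;
      w[k] += hi - lo;
    }
    if (ch < 0) { status = "absorbing"; break; }
    gene = g; n = nn; nta = nnta; ni = nni;
    n_events += 1.0;
  }
  double tot = Rcpp::sum(w);
  if (tot > 0) w = w / tot;
  return List::create(_["p"] = w, _["n_events"] = n_events,
                      _["status"] = status,
                      _["final"] = NumericVector::create(
                          (double)gene, n, nta, ni, std::min(t, t_end)));
}

// State sampled at fixed frame times (for fluorescence conversion).
// [[Rcpp::export]]
List cpp_ssa_frames(int gene, double n_tetr, double n_ta, double n_i,
                    NumericVector params, NumericVector frame_times) {
  Params q = unpack(params);
  double a[N_CHANNELS];
  int nf = frame_times.size();
  IntegerVector fg(nf);
  NumericVector fn(nf), fnta(nf), fni(nf);
  double t = 0.0, n = n_tetr, nta = n_ta, ni = n_i;
  int i = 0;
  std::string status = "completed";
  while (i < nf) {
    // record all frames that fall before the next jump
    double t_prev = t;
    int g = gene;
    double nn = n, nnta = nta, nni = ni;
    int ch = ssa_step(g, nn, nnta, nni, t, q, a);
    double t_next = (ch < 0) ? R_PosInf : t;
    while (i < nf && frame_times[i] >= t_prev && frame_times[i] < t_next) {
      fg[i] = gene; fn[i] = n; fnta[i] = nta; fni[i] = ni;
      ++i;
    }
    if (ch < 0) { status = "absorbing";
      while (i < nf) { fg[i] = gene; fn[i] = n; fnta[i] = nta; fni[i] = ni; ++i; }
      break;
    }
    gene = g; n = nn; nta = nnta; ni = nni;
  }
  return List::create(_["gene"] = fg, _["n_tetr"] = fn, _["n_ta"] = fnta,
                      _["n_i"] = fni, _["status"] = status);
}
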