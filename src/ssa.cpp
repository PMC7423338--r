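#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of a compiled
// regulatory network for one cell.
//
// Compiled-network layout (see compile_network() on the R side; all
// indices arrive 1-based and are shifted here):
//   deg[s]            first-order degradation rate of species s
//                     (free monomers only; bound oligomers are protected)
//   per activator-config c on promoter cfg_prom[c]:
//     bind:    propensity cfg_bind[c] * choose(x_act, n) while the promoter
//              slot is free; sequesters n monomers of the activator
//     unbind:  cfg_unbind[c] while bound in config c; restores n monomers
//     produce: cfg_prod_rate[c] while bound in config c; +1 product monomer
//   basal production per promoter slot while free.
//
// Draws come from R's global RNG (unif_rand/exp_rand), so a cell is fully
// reproducible from the R-side seed set before the call.

struct Net {
  int S, P, C;
  std::vector<double> deg;
  std::vector<int> cfg_prom, cfg_act, cfg_n, cfg_product;
  std::vector<double> cfg_bind, cfg_unbind, cfg_prod;
  std::vector<double> prom_basal;
  std::vector<int> prom_basal_product;
};

static Net unpack(const List& net) {
  Net m;
  NumericVector deg = net["deg"];
  IntegerVector cp = net["cfg_prom"], ca = net["cfg_act"], cn = net["cfg_n"],
                cq = net["cfg_product"], bp = net["prom_basal_product"];
  NumericVector cb = net["cfg_bind"], cu = net["cfg_unbind"],
                cr = net["cfg_prod_rate"], pb = net["prom_basal"];
  m.S = deg.size();
  m.P = pb.size();
  m.C = cp.size();
  m.deg.assign(deg.begin(), deg.end());
  m.prom_basal.assign(pb.begin(), pb.end());
  m.cfg_bind.assign(cb.begin(), cb.end());
  m.cfg_unbind.assign(cu.begin(), cu.end());
  m.cfg_prod.assign(cr.begin(), cr.end());
  m.cfg_prom.resize(m.C); m.cfg_act.resize(m.C);
  m.cfg_n.resize(m.C); m.cfg_product.resize(m.C);
  for (int c = 0; c < m.C; ++c) {
    m.cfg_prom[c] = cp[c] - 1;
    m.cfg_act[c] = ca[c] - 1;
    m.cfg_n[c] = cn[c];
    m.cfg_product[c] = cq[c] - 1;
  }
  m.prom_basal_product.resize(m.P);
  for (int p = 0; p < m.P; ++p) {
    m.prom_basal_product[p] = (bp[p] == NA_INTEGER) ? -1 : bp[p] - 1;
  }
  return m;
}

// channel indexing: [0, 3C): config channels (bind/unbind/produce per
// config); [3C, 3C+S): degradation; [3C+S, 3C+S+P): basal production.
static double propensity(const Net& m, int ch,
                         const std::vector<int>& x,
                         const std::vector<int>& occ) {
  if (ch < 3 * m.C) {
    int c = ch / 3, kind = ch % 3;
    int p = m.cfg_prom[c];
    if (kind == 0) {  // bind
      if (occ[p] != 0) return 0.0;
      return m.cfg_bind[c] * ::Rf_choose((double)x[m.cfg_act[c]],
                                         (double)m.cfg_n[c]);
    }
    if (occ[p] != c + 1) return 0.0;
    return (kind == 1) ? m.cfg_unbind[c] : m.cfg_prod[c];
  }
  ch -= 3 * m.C;
  if (ch < m.S) return m.deg[ch] * x[ch];
  ch -= m.S;
  return (occ[ch] == 0) ? m.prom_basal[ch] : 0.0;
}

static void apply_event(const Net& m, int ch,
                        std::vector<int>& x, std::vector<int>& occ) {
  if (ch < 3 * m.C) {
    int c = ch / 3, kind = ch % 3;
    int p = m.cfg_prom[c];
    if (kind == 0) { occ[p] = c + 1; x[m.cfg_act[c]] -= m.cfg_n[c]; }
    else if (kind == 1) { occ[p] = 0; x[m.cfg_act[c]] += m.cfg_n[c]; }
    else { x[m.cfg_product[c]] += 1; }
    return;
  }
  ch -= 3 * m.C;
  if (ch < m.S) { x[ch] -= 1; return; }
  ch -= m.S;
  x[m.prom_basal_product[ch]] += 1;
}

// [[Rcpp::export]]
List cpp_ssa(List net, IntegerVector init, double t_end,
             IntegerVector w_species, NumericVector w_t0,
             NumericVector w_t1, bool record, double max_events) {
  Net m = unpack(net);
  if ((int)init.size() != m.S) stop("initial counts length mismatch");
  std::vector<int> x(init.begin(), init.end());
  std::vector<int> occ(m.P, 0);
  int nch = 3 * m.C + m.S + m.P;
  std::vector<double> a(nch);
  int W = w_species.size();
  std::vector<double> integ(W, 0.0);

  std::vector<double> rec_t;
  std::vector<int> rec_ch, rec_x, rec_occ;
  if (record) {
    rec_t.push_back(0.0); rec_ch.push_back(NA_INTEGER);
    for (int s = 0; s < m.S; ++s) rec_x.push_back(x[s]);
    for (int p = 0; p < m.P; ++p) rec_occ.push_back(occ[p]);
  }

  double t = 0.0;
  double n_events = 0.0;
  bool absorbed = false;
  while (true) {
    double a0 = 0.0;
    for (int ch = 0; ch < nch; ++ch) { a[ch] = propensity(m, ch, x, occ); a0 += a[ch]; }
    double t_next;
    if (a0 <= 0.0) { absorbed = true; t_next = t_end; }
    else {
      t_next = t + exp_rand() / a0;
      if (t_next > t_end) t_next = t_end;
    }
    // accumulate window integrals over [t, t_next) with pre-event counts
    for (int w = 0; w < W; ++w) {
      double lo = t > w_t0[w] ? t : w_t0[w];
      double hi = t_next < w_t1[w] ? t_next : w_t1[w];
      if (hi > lo) integ[w] += x[w_species[w] - 1] * (hi - lo);
    }
    if (absorbed || t_next >= t_end) { t = t_end; break; }
    t = t_next;
    // channel selection proportional to propensity
    double u = unif_rand() * a0;
    int ch = 0;
    double acc = a[0];
    while (acc < u && ch < nch - 1) { acc += a[++ch]; }
    apply_event(m, ch, x, occ);
    n_events += 1.0;
    if (record) {
      rec_t.push_back(t); rec_ch.push_back(ch);
      for (int s = 0; s < m.S; ++s) rec_x.push_back(x[s]);
      for (int p = 0; p < m.P; ++p) rec_occ.push_back(occ[p]);
    }
    if (n_events >= max_events) stop("event budget exceeded (max_events)");
  }

  List out = List::create(
    _["end_counts"] = IntegerVector(x.begin(), x.end()),
    _["end_occupancy"] = IntegerVector(occ.begin(), occ.end()),
    _["integrals"] = NumericVector(integ.begin(), integ.end()),
    _["n_events"] = n_events,
    _["absorbed"] = absorbed);
  if (record) {
    int ne = rec_t.size();
    IntegerMatrix cm(ne, m.S), om(ne, m.P);
    for (int i = 0; i < ne; ++i) {
      for (int s = 0; s < m.S; ++s) cm(i, s) = rec_x[i * m.S + s];
      for (int p = 0; p < m.P; ++p) om(i, p) = rec_occ[i * m.P + p];
    }
    out["times"] = NumericVector(rec_t.begin(), rec_t.end());
    out["channels"] = IntegerVector(rec_ch.begin(), rec_ch.end());
    out["counts"] = cm;
    out["occupancy"] = om;
  }
  return out;
}
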