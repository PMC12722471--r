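// Exact Gillespie simulation of the coupled RyR2 tetramer lattice.
//
// State: one +/-1 spin per subunit (4 per channel). A closed subunit opens
// at rate kfo*Ca*exp(e), an open one closes at rate kb*exp(-e), with
// e = delta*(ring neighbour sum) + sum sigma_b * partner state, and
// Ca = co + g * n_open (n_open = channels with >= open_min open subunits).
//
// Propensities are maintained incrementally: a flip touches only the
// flipped subunit, its two ring neighbours and its bond partners. All
// opening propensities share the factor kfo*Ca, so a change of n_open
// only rescales that factor. Sums are rebuilt from scratch periodically
// to bound floating-point drift.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <utility>
using namespace Rcpp;

namespace {

class ClusterSSA {
public:
  int nch, nsub;
  double delta, kfo, kb, g, co;
  int open_min;
  std::vector<signed char> s;                       // +1 open, -1 closed
  std::vector<std::vector<std::pair<int, double> > > prt; // bond partners
  std::vector<double> e, ew;                        // exponent, exp(e)
  std::vector<int> osub;                            // open subunits / channel
  std::vector<double> chG, chC;                     // per-channel sums
  double SG, SC, ca;
  int n_open;

  ClusterSSA(int n_channels,
             const IntegerVector& ba, const IntegerVector& bi,
             const IntegerVector& bb, const IntegerVector& bj,
             const NumericVector& bs,
             double delta_, double kfo_, double kb_, double g_, double co_,
             int open_min_)
    : nch(n_channels), nsub(4 * n_channels),
      delta(delta_), kfo(kfo_), kb(kb_), g(g_), co(co_),
      open_min(open_min_),
      s(nsub, -1), prt(nsub), e(nsub), ew(nsub),
      osub(n_channels, 0), chG(n_channels, 0.0), chC(n_channels, 0.0) {
    for (int r = 0; r < ba.size(); ++r) {
      int u = 4 * ba[r] + bi[r];   // already 0-based from R wrapper
      int v = 4 * bb[r] + bj[r];
      prt[u].push_back(std::make_pair(v, bs[r]));
      prt[v].push_back(std::make_pair(u, bs[r]));
    }
    rebuild();
  }

  void reset() {
    std::fill(s.begin(), s.end(), (signed char)-1);
    rebuild();
  }

  void rebuild() {
    SG = SC = 0.0;
    n_open = 0;
    for (int c = 0; c < nch; ++c) { chG[c] = 0.0; chC[c] = 0.0; osub[c] = 0; }
    for (int u = 0; u < nsub; ++u) {
      int c = u >> 2, i = u & 3;
      double ex = delta * (s[(c << 2) | ((i + 3) & 3)] +
                           s[(c << 2) | ((i + 1) & 3)]);
      for (size_t k = 0; k < prt[u].size(); ++k)
        ex += prt[u][k].second * s[prt[u][k].first];
      e[u] = ex;
      ew[u] = std::exp(e[u]);
      if (s[u] > 0) { osub[c]++; chC[c] += kb / ew[u]; }
      else          { chG[c] += ew[u]; }
    }
    for (int c = 0; c < nch; ++c) {
      SG += chG[c]; SC += chC[c];
      if (osub[c] >= open_min) n_open++;
    }
    ca = co + g * n_open;
  }

  double total_rate() const { return kfo * ca * SG + SC; }

  // update subunit v after its exponent changed by de
  void bump(int v, double de) {
    int cv = v >> 2;
    if (s[v] < 0) { chG[cv] -= ew[v]; SG -= ew[v]; }
    else          { double w = kb / ew[v]; chC[cv] -= w; SC -= w; }
    e[v] += de;
    ew[v] = std::exp(e[v]);
    if (s[v] < 0) { chG[cv] += ew[v]; SG += ew[v]; }
    else          { double w = kb / ew[v]; chC[cv] += w; SC += w; }
  }

  void flip(int u) {
    int c = u >> 2, i = u & 3;
    signed char snew = (signed char)(-s[u]);
    // the flipped subunit switches propensity group; its own exponent
    // (a function of its neighbours only) is unchanged
    if (snew > 0) {             // was closed, opens
      chG[c] -= ew[u]; SG -= ew[u];
      double w = kb / ew[u]; chC[c] += w; SC += w;
    } else {                    // was open, closes
      double w = kb / ew[u]; chC[c] -= w; SC -= w;
      chG[c] += ew[u]; SG += ew[u];
    }
    s[u] = snew;
    bool was_cond = osub[c] >= open_min;
    osub[c] += (snew > 0) ? 1 : -1;
    bool is_cond = osub[c] >= open_min;
    if (is_cond != was_cond) {
      n_open += is_cond ? 1 : -1;
      ca = co + g * n_open;
    }
    double dr = 2.0 * delta * (double)snew;     // ring neighbour shift
    double dp = 2.0 * (double)snew;             // bond partner shift / sigma
    bump((c << 2) | ((i + 3) & 3), dr);
    bump((c << 2) | ((i + 1) & 3), dr);
    for (size_t k = 0; k < prt[u].size(); ++k)
      bump(prt[u][k].first, dp * prt[u][k].second);
  }

  // pick the flipping subunit; x uniform in (0, total_rate())
  int select(double x) const {
    double kfca = kfo * ca;
    if (x < kfca * SG) {                 // an opening event
      double t = x / kfca;
      int c = 0;
      double acc = 0.0;
      for (; c < nch - 1; ++c) {
        if (acc + chG[c] >= t) break;
        acc += chG[c];
      }
      double rem = t - acc;
      int base = c << 2, pick = -1;
      for (int k = 0; k < 4; ++k) {
        int v = base + k;
        if (s[v] < 0) {
          if (rem <= ew[v]) { pick = v; break; }
          rem -= ew[v];
        }
      }
      if (pick < 0) {                    // numerical slop: last closed
        for (int k = 3; k >= 0; --k)
          if (s[base + k] < 0) { pick = base + k; break; }
      }
      if (pick < 0) {                    // channel had no closed subunit
        for (int v = 0; v < nsub; ++v)
          if (s[v] < 0) { pick = v; break; }
      }
      return pick;
    } else {                             // a closing event
      double t = x - kfca * SG;
      int c = 0;
      double acc = 0.0;
      for (; c < nch - 1; ++c) {
        if (acc + chC[c] >= t) break;
        acc += chC[c];
      }
      double rem = t - acc;
      int base = c << 2, pick = -1;
      for (int k = 0; k < 4; ++k) {
        int v = base + k;
        if (s[v] > 0) {
          double w = kb / ew[v];
          if (rem <= w) { pick = v; break; }
          rem -= w;
        }
      }
      if (pick < 0) {
        for (int k = 3; k >= 0; --k)
          if (s[base + k] > 0) { pick = base + k; break; }
      }
      if (pick < 0) {
        for (int v = 0; v < nsub; ++v)
          if (s[v] > 0) { pick = v; break; }
      }
      return pick;
    }
  }
};

} // namespace

// Run one first-passage simulation from the all-closed state.
// Bond indices are 0-based (channels and subunits). Returns the crossing
// time T (NA if censored), the elapsed time, event count, and optionally
// the trajectory of n_open changes and the time-weighted occupancy of
// full subunit configurations (track_states, <= 16 subunits only).
// [[Rcpp::export]]
List ssa_run_cpp(int n_channels,
                 IntegerVector bond_a, IntegerVector bond_i,
                 IntegerVector bond_b, IntegerVector bond_j,
                 NumericVector bond_sigma,
                 double delta, double kfo, double kb, double g, double co,
                 int nc, int open_min, double t_max,
                 bool record_trajectory, bool track_states,
                 double max_events, bool audit) {
  if (t_max <= 0) stop("t_max must be positive");
  ClusterSSA eng(n_channels, bond_a, bond_i, bond_b, bond_j, bond_sigma,
                 delta, kfo, kb, g, co, open_min);
  const long long refresh_every = audit ? (1LL << 12) : (1LL << 20);

  std::vector<double> traj_t;
  std::vector<int> traj_no;
  if (record_trajectory) { traj_t.push_back(0.0); traj_no.push_back(eng.n_open); }

  std::vector<double> occ;
  unsigned int code = 0;
  if (track_states) {
    if (eng.nsub > 16) stop("track_states requires at most 16 subunits");
    occ.assign(1u << eng.nsub, 0.0);
  }

  double t = 0.0;
  long long ev = 0;
  bool censored = false;
  bool crossed = eng.n_open >= nc;      // nc <= 0: start state absorbing

  while (!crossed) {
    double R = eng.total_rate();
    if (!(R > 0)) stop("total propensity is not positive");
    double dt = exp_rand() / R;
    if (t + dt > t_max) {
      if (track_states) occ[code] += t_max - t;
      t = t_max;
      censored = true;
      break;
    }
    if (track_states) occ[code] += dt;
    t += dt;
    int u = eng.select(unif_rand() * R);
    int prev_no = eng.n_open;
    eng.flip(u);
    if (track_states) code ^= (1u << u);
    ++ev;
    if (record_trajectory && eng.n_open != prev_no) {
      traj_t.push_back(t);
      traj_no.push_back(eng.n_open);
    }
    if (eng.n_open >= nc) { crossed = true; break; }
    if ((ev % refresh_every) == 0) {
      if (audit) {
        double sg = eng.SG, sc = eng.SC;
        eng.rebuild();
        double tol = 1e-9;
        if (std::fabs(sg - eng.SG) > tol * std::max(1.0, eng.SG) ||
            std::fabs(sc - eng.SC) > tol * std::max(1.0, eng.SC))
          stop("audit failure: incremental propensities drifted (SG %g vs %g, SC %g vs %g)",
               sg, eng.SG, sc, eng.SC);
      } else {
        eng.rebuild();
      }
    }
    if (max_events > 0 && (double)ev >= max_events) break;
  }

  List out = List::create(
    _["T"] = crossed ? t : NA_REAL,
    _["time"] = t,
    _["censored"] = censored,
    _["n_events"] = (double)ev,
    _["n_open"] = eng.n_open);
  if (record_trajectory) {
    out["traj_t"] = NumericVector(traj_t.begin(), traj_t.end());
    out["traj_no"] = IntegerVector(traj_no.begin(), traj_no.end());
  }
  if (track_states)
    out["state_time"] = NumericVector(occ.begin(), occ.end());
  return out;
}

// Draw the first SSA event from the all-closed state n_reps times:
// returns the elapsed time and the flipped subunit (0-based) per draw.
// [[Rcpp::export]]
List ssa_first_event_cpp(int n_reps, int n_channels,
                         IntegerVector bond_a, IntegerVector bond_i,
                         IntegerVector bond_b, IntegerVector bond_j,
                         NumericVector bond_sigma,
                         double delta, double kfo, double kb, double g,
                         double co, int open_min) {
  ClusterSSA eng(n_channels, bond_a, bond_i, bond_b, bond_j, bond_sigma,
                 delta, kfo, kb, g, co, open_min);
  NumericVector dt(n_reps);
  IntegerVector sub(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    double R = eng.total_rate();
    dt[r] = exp_rand() / R;
    sub[r] = eng.select(unif_rand() * R);
  }
  return List::create(_["dt"] = dt, _["subunit"] = sub);
}
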