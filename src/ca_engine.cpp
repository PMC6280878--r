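// Compiled snail-trail cellular automaton engine.
//
// Draws from R's RNG stream in exactly the same order as the pure-R
// reference engine in R/ca_engine.R (see the documented contract there):
// per motility selection -- selection draw, P_m draw, direction draw, and at
// most one anastomosis draw; per branching selection -- selection draw and
// one branching draw. Boundary-aborted moves and self-loop aborts consume no
// anastomosis draw. Dead agents are swap-removed; daughters are appended
// (i, j+1) first. Any change here must be mirrored in the R engine.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct CA {
  int R, n, mode;
  double Pm, Pp, an, ae;
  const double *pxp, *pxm, *c;
  std::vector<int> tc;      // site -> agent slot + 1 (0 = none)
  std::vector<int> ec;      // EC count per site (0/1 in Model 2)
  std::vector<int> ecown;   // depositing agent id (self-loop check, Model 2)
  std::vector<int> ai, aj, aid;
  int next_id;

  inline int site(int i, int j) const { return i * n + j; }

  void deposit(int s, int id) {
    if (mode == 2) ec[s] = 1; else ec[s] += 1;
    ecown[s] = id;
  }

  void remove_agent(int idx) {
    int last = (int)aid.size() - 1;
    if (idx != last) {
      aid[idx] = aid[last];
      ai[idx] = ai[last];
      aj[idx] = aj[last];
      tc[site(ai[idx], aj[idx])] = idx + 1;
    }
    aid.pop_back(); ai.pop_back(); aj.pop_back();
  }

  void attempt_move(int idx) {
    if (unif_rand() >= Pm) return;                       // no_attempt
    int i = ai[idx], j = aj[idx];
    double u = unif_rand();
    int ti = i, tj = j;
    double p1 = pxp[i], p2 = p1 + pxm[i], p3 = p2 + 0.25;
    if (u < p1) ti = i + 1;
    else if (u < p2) ti = i - 1;
    else if (u < p3) tj = j + 1;
    else tj = j - 1;
    if (ti < 0 || ti > R || tj < 0 || tj > R) return;    // boundary abort
    int s = site(ti, tj), s0 = site(i, j);
    int mover_id = aid[idx];
    if (tc[s] > 0) {
      if (unif_rand() < an) {                            // tip-to-tip
        int ridx = tc[s] - 1;
        int resident_id = aid[ridx];
        tc[s0] = 0; tc[s] = 0;
        deposit(s0, mover_id);
        deposit(s, resident_id);
        int hi = idx > ridx ? idx : ridx;
        int lo = idx > ridx ? ridx : idx;
        remove_agent(hi);
        remove_agent(lo);
      }
      return;                                            // else excluded_tc
    }
    if (mode == 2 && ec[s] > 0) {
      if (ecown[s] == mover_id) return;                  // self-loop abort
      if (unif_rand() < ae) {                            // tip-to-sprout
        tc[s0] = 0;
        deposit(s0, mover_id);
        remove_agent(idx);
      }
      return;                                            // else excluded_ec
    }
    tc[s0] = 0;                                          // snail-trail move
    deposit(s0, mover_id);
    ai[idx] = ti; aj[idx] = tj;
    tc[s] = idx + 1;
  }

  void attempt_branch(int idx) {
    int i = ai[idx], j = aj[idx];
    if (unif_rand() >= Pp * c[i]) return;                // no_attempt
    if (j - 1 < 0 || j + 1 > R) return;                  // blocked at edge
    int su = site(i, j + 1), sd = site(i, j - 1);
    bool vu = tc[su] == 0 && (mode == 1 || ec[su] == 0);
    bool vd = tc[sd] == 0 && (mode == 1 || ec[sd] == 0);
    if (!vu || !vd) return;                              // blocked
    tc[site(i, j)] = 0;
    remove_agent(idx);
    for (int d = 0; d < 2; ++d) {
      int tj = d == 0 ? j + 1 : j - 1;
      aid.push_back(next_id++);
      ai.push_back(i);
      aj.push_back(tj);
      tc[site(i, tj)] = (int)aid.size();
    }
  }

  void step() {
    int n1 = (int)aid.size();
    for (int t = 0; t < n1; ++t) {
      int na = (int)aid.size();
      if (na == 0) break;
      int idx = (int)(unif_rand() * na);
      if (idx >= na) idx = na - 1;
      attempt_move(idx);
    }
    int n2 = (int)aid.size();
    for (int t = 0; t < n2; ++t) {
      int na = (int)aid.size();
      if (na == 0) break;
      int idx = (int)(unif_rand() * na);
      if (idx >= na) idx = na - 1;
      attempt_branch(idx);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List ca_run_cpp(int R, double Pm, NumericVector pxp, NumericVector pxm,
                double Pp, NumericVector cgrid, double an, double ae,
                int mode, IntegerVector record_K, bool full,
                IntegerMatrix tc_init) {
  CA ca;
  ca.R = R; ca.n = R + 1; ca.mode = mode;
  ca.Pm = Pm; ca.Pp = Pp; ca.an = an; ca.ae = ae;
  ca.pxp = REAL(pxp); ca.pxm = REAL(pxm); ca.c = REAL(cgrid);
  int nsite = ca.n * ca.n;
  ca.tc.assign(nsite, 0);
  ca.ec.assign(nsite, 0);
  ca.ecown.assign(nsite, 0);
  int m0 = tc_init.nrow();
  for (int a = 0; a < m0; ++a) {
    ca.ai.push_back(tc_init(a, 0));
    ca.aj.push_back(tc_init(a, 1));
    ca.aid.push_back(a + 1);
    ca.tc[ca.site(tc_init(a, 0), tc_init(a, 1))] = a + 1;
  }
  ca.next_id = m0 + 1;

  int nr = record_K.size();
  NumericMatrix tc_cols(ca.n, nr), ec_cols(ca.n, nr);
  List tc_grids(full ? nr : 0), ec_grids(full ? nr : 0);

  int slot = 0;  // RNG state handled by the Rcpp attributes wrapper
  int Kmax = nr > 0 ? record_K[nr - 1] : 0;
  for (int K = 0; K <= Kmax; ++K) {
    if (K > 0) ca.step();
    if (slot < nr && K == record_K[slot]) {
      for (int i = 0; i <= R; ++i) {
        double ts = 0, es = 0;
        for (int j = 0; j <= R; ++j) {
          ts += ca.tc[ca.site(i, j)] > 0 ? 1.0 : 0.0;
          es += ca.ec[ca.site(i, j)];
        }
        tc_cols(i, slot) = ts;
        ec_cols(i, slot) = es;
      }
      if (full) {
        IntegerMatrix tg(ca.n, ca.n), eg(ca.n, ca.n);
        for (int i = 0; i <= R; ++i)
          for (int j = 0; j <= R; ++j) {
            tg(i, j) = ca.tc[ca.site(i, j)] > 0 ? 1 : 0;
            eg(i, j) = ca.ec[ca.site(i, j)];
          }
        tc_grids[slot] = tg;
        ec_grids[slot] = eg;
      }
      ++slot;
    }
  }
  List res = List::create(_["K"] = record_K,
                          _["tc_cols"] = tc_cols, _["ec_cols"] = ec_cols,
                          _["tc_grids"] = R_NilValue,
                          _["ec_grids"] = R_NilValue);
  if (full) {
    res["tc_grids"] = tc_grids;
    res["ec_grids"] = ec_grids;
  }
  return res;
}
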