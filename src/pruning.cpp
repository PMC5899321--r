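// Felsenstein pruning engine with per-site mixture components (CAT-style
// profiles), discrete-gamma rate categories, per-node rescaling, and
// dirty-path partial updates so local branch/age moves cost O(depth).
// Single-component propagation is routed through BLAS dgemm.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cmath>
#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

static const int NS = 20; // amino-acid states

struct EigenSys {
  // P(t) = A * diag(exp(vals * r * t)) * B ; pi used at the root
  std::vector<double> A, B, vals, pi; // A,B row-major 20x20
};

struct Engine {
  int ntip, nnode, root;            // nnode = total nodes (tips first)
  std::vector<std::vector<int>> children; // per node (0-based ids)
  std::vector<int> parent;                // 0-based, -1 at root
  std::vector<double> elen;               // edge length above node
  int nsites, ncat;
  std::vector<double> sitew;              // site (pattern) weights
  std::vector<double> rates, weights;     // gamma categories
  std::vector<EigenSys> comps;
  std::vector<int> sitecomp;              // 0-based component per site
  std::vector<int> tipstate;              // ntip * nsites, -1 = missing
  // partials, internal nodes only; layout (k * S + s) * NS + a.
  // Double-buffered: updates write the inactive buffer and flip, so a
  // rejected move is undone by flipping back (no copying).
  std::vector<std::vector<double>> partial[2];
  std::vector<std::vector<double>> logscale[2];
  std::vector<char> act;                  // active buffer per internal node
  std::vector<char> dirty;
  std::vector<int> postorder;             // internal nodes, children first
  std::vector<double> scratch;            // dgemm target, NS * nsites
  // undo log since the last commit/revert (rejected-move restoration)
  std::vector<std::pair<int, double>> ulen;  // node, old length
  std::vector<int> unodes;                   // nodes whose buffer flipped
  std::vector<char> ulogged;                 // per node flag
  std::vector<double>& part(int v) { return partial[(int)act[v]][v - ntip]; }
  std::vector<double>& lsc(int v) { return logscale[(int)act[v]][v - ntip]; }
};

static void build_postorder(Engine &e) {
  e.postorder.clear();
  std::vector<int> stack{e.root}, out;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    out.push_back(v);
    for (int c : e.children[v]) if (c >= e.ntip) stack.push_back(c);
  }
  for (auto it = out.rbegin(); it != out.rend(); ++it) e.postorder.push_back(*it);
}

// transition matrix for one comp/cat/branch, row-major
static void pmatrix(const EigenSys &cs, double t, double r, double *P) {
  if (t * r == 0.0) { // exact identity at zero length
    for (int a = 0; a < NS; ++a)
      for (int b = 0; b < NS; ++b) P[a * NS + b] = (a == b) ? 1.0 : 0.0;
    return;
  }
  double ev[NS];
  for (int i = 0; i < NS; ++i) ev[i] = std::exp(cs.vals[i] * r * t);
  for (int a = 0; a < NS; ++a) {
    for (int b = 0; b < NS; ++b) {
      double s = 0.0;
      for (int k = 0; k < NS; ++k) s += cs.A[a * NS + k] * ev[k] * cs.B[k * NS + b];
      P[a * NS + b] = s > 0.0 ? s : 0.0;
    }
  }
}

// recompute the partial of internal node v from its children. A node not
// yet touched since the last commit writes its inactive buffer (the
// caller flips and logs it, keeping the old values for cheap rejection);
// a node already flipped in this commit window rewrites its active
// buffer, preserving the pre-commit backup on the other side.
static void update_node(Engine &e, int v) {
  int S = e.nsites, K = e.ncat, C = (int)e.comps.size();
  int tgt = e.ulogged[v] ? (int)e.act[v] : 1 - (int)e.act[v];
  std::vector<double> &part = e.partial[tgt][v - e.ntip];
  std::vector<double> &lsc = e.logscale[tgt][v - e.ntip];
  part.assign((size_t)S * K * NS, 1.0);
  lsc.assign(S, 0.0);
  std::vector<double> P((size_t)C * K * NS * NS);
  for (int c : e.children[v]) {
    for (int ci = 0; ci < C; ++ci)
      for (int k = 0; k < K; ++k)
        pmatrix(e.comps[ci], e.elen[c], e.rates[k], &P[((size_t)ci * K + k) * NS * NS]);
    if (c < e.ntip) {
      for (int s = 0; s < S; ++s) {
        int st = e.tipstate[(size_t)c * S + s];
        if (st < 0) continue; // all-ones tip vector
        const double *Pc = &P[(size_t)e.sitecomp[s] * K * NS * NS];
        for (int k = 0; k < K; ++k) {
          double *pv = &part[((size_t)k * S + s) * NS];
          const double *Pk = Pc + (size_t)k * NS * NS;
          for (int a = 0; a < NS; ++a) pv[a] *= Pk[a * NS + st];
        }
      }
    } else {
      const std::vector<double> &cp = e.part(c);
      const std::vector<double> &cls = e.lsc(c);
      if (C == 1) {
        // y(a,s) = sum_b P(a,b) x(b,s): row-major P is P^T column-major,
        // so op(A) = 'T' recovers P inside dgemm
        const double one = 1.0, zero = 0.0;
        const int ns = NS;
        for (int k = 0; k < K; ++k) {
          const double *Pk = &P[(size_t)k * NS * NS];
          const double *X = &cp[(size_t)k * S * NS];
          double *Y = e.scratch.data();
          F77_CALL(dgemm)("T", "N", &ns, &S, &ns, &one, Pk, &ns, X, &ns,
                          &zero, Y, &ns FCONE FCONE);
          double *pv = &part[(size_t)k * S * NS];
          for (size_t i = 0; i < (size_t)S * NS; ++i) pv[i] *= Y[i];
        }
      } else {
        std::vector<double> y(NS);
        for (int s = 0; s < S; ++s) {
          const double *Pc = &P[(size_t)e.sitecomp[s] * K * NS * NS];
          for (int k = 0; k < K; ++k) {
            const double *x = &cp[((size_t)k * S + s) * NS];
            const double *Pk = Pc + (size_t)k * NS * NS;
            double *pv = &part[((size_t)k * S + s) * NS];
            for (int a = 0; a < NS; ++a) {
              const double *row = Pk + (size_t)a * NS;
              double acc = 0.0;
              for (int b = 0; b < NS; ++b) acc += row[b] * x[b];
              pv[a] *= acc;
            }
          }
        }
      }
      for (int s = 0; s < S; ++s) lsc[s] += cls[s];
    }
  }
  // per-site rescale (triggered only when magnitudes drift far)
  for (int s = 0; s < S; ++s) {
    double mx = 0.0;
    for (int k = 0; k < K; ++k) {
      const double *pv = &part[((size_t)k * S + s) * NS];
      for (int a = 0; a < NS; ++a) if (pv[a] > mx) mx = pv[a];
    }
    if (mx > 0.0 && (mx < 1e-80 || mx > 1e80)) {
      for (int k = 0; k < K; ++k) {
        double *pv = &part[((size_t)k * S + s) * NS];
        for (int a = 0; a < NS; ++a) pv[a] /= mx;
      }
      lsc[s] += std::log(mx);
    }
  }
}

static void refresh(Engine &e) {
  // mark ancestors of dirty nodes (children precede parents in postorder)
  for (int v : e.postorder) {
    if (!e.dirty[v]) {
      for (int c : e.children[v])
        if (c >= e.ntip && e.dirty[c]) { e.dirty[v] = 1; break; }
    }
  }
  for (int v : e.postorder) if (e.dirty[v]) {
    update_node(e, v);
    if (!e.ulogged[v]) {             // first touch since commit/revert
      e.ulogged[v] = 1;
      e.unodes.push_back(v);
      e.act[v] = 1 - e.act[v];       // flip: pre-commit buffer intact
    }
  }
  for (int v : e.postorder) e.dirty[v] = 0;
}

static std::vector<double> site_logliks(Engine &e) {
  refresh(e);
  int S = e.nsites, K = e.ncat;
  const std::vector<double> &rp = e.part(e.root);
  const std::vector<double> &rls = e.lsc(e.root);
  std::vector<double> out(S);
  for (int s = 0; s < S; ++s) {
    const std::vector<double> &pi = e.comps[e.sitecomp[s]].pi;
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      const double *pv = &rp[((size_t)k * S + s) * NS];
      double sk = 0.0;
      for (int a = 0; a < NS; ++a) sk += pi[a] * pv[a];
      tot += e.weights[k] * sk;
    }
    out[s] = (tot > 0.0) ? std::log(tot) + rls[s] : R_NegInf;
  }
  return out;
}

static EigenSys as_eigensys(List x) {
  EigenSys cs;
  NumericMatrix A = x["A"], B = x["B"];
  NumericVector v = x["values"], pi = x["pi"];
  cs.A.resize(NS * NS); cs.B.resize(NS * NS);
  cs.vals.assign(v.begin(), v.end());
  cs.pi.assign(pi.begin(), pi.end());
  for (int i = 0; i < NS; ++i)
    for (int j = 0; j < NS; ++j) {
      cs.A[i * NS + j] = A(i, j);
      cs.B[i * NS + j] = B(i, j);
    }
  return cs;
}

// [[Rcpp::export]]
SEXP engine_create(int ntip, IntegerMatrix edge, NumericVector edge_len_by_node,
                   IntegerMatrix tipstate, IntegerVector sitecomp,
                   NumericVector rates, NumericVector weights, List eigs,
                   NumericVector site_weights) {
  Engine *e = new Engine();
  e->ntip = ntip;
  e->nnode = edge_len_by_node.size();
  e->root = ntip; // ape convention: root id = ntip + 1 (1-based)
  e->children.assign(e->nnode, {});
  e->parent.assign(e->nnode, -1);
  e->elen.assign(edge_len_by_node.begin(), edge_len_by_node.end());
  for (int i = 0; i < edge.nrow(); ++i) {
    int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
    e->children[p].push_back(c);
    e->parent[c] = p;
  }
  e->nsites = tipstate.ncol();
  e->sitew.assign(site_weights.begin(), site_weights.end());
  e->ncat = rates.size();
  e->rates.assign(rates.begin(), rates.end());
  e->weights.assign(weights.begin(), weights.end());
  for (int i = 0; i < eigs.size(); ++i) e->comps.push_back(as_eigensys(eigs[i]));
  e->sitecomp.assign(sitecomp.begin(), sitecomp.end());
  for (auto &x : e->sitecomp) --x;
  e->tipstate.resize((size_t)ntip * e->nsites);
  for (int t = 0; t < ntip; ++t)
    for (int s = 0; s < e->nsites; ++s)
      e->tipstate[(size_t)t * e->nsites + s] = tipstate(t, s);
  int nint = e->nnode - ntip;
  e->partial[0].assign(nint, {});
  e->partial[1].assign(nint, {});
  e->logscale[0].assign(nint, {});
  e->logscale[1].assign(nint, {});
  e->act.assign(e->nnode, 0);
  e->dirty.assign(e->nnode, 1);
  e->scratch.assign((size_t)NS * e->nsites, 0.0);
  e->ulogged.assign(e->nnode, 0);
  build_postorder(*e);
  XPtr<Engine> ptr(e, true);
  return ptr;
}

// [[Rcpp::export]]
void engine_set_lengths(SEXP ptr, IntegerVector nodes, NumericVector lengths) {
  XPtr<Engine> e(ptr);
  for (int i = 0; i < nodes.size(); ++i) {
    int v = nodes[i] - 1;
    e->ulen.push_back({v, e->elen[v]});
    e->elen[v] = lengths[i];
    int p = e->parent[v];
    if (p >= 0) e->dirty[p] = 1; // parent's partial uses this edge
  }
}

// [[Rcpp::export]]
void engine_commit(SEXP ptr) {
  XPtr<Engine> e(ptr);
  e->ulen.clear();
  for (int v : e->unodes) e->ulogged[v] = 0;
  e->unodes.clear();
}

// [[Rcpp::export]]
void engine_revert(SEXP ptr) {
  XPtr<Engine> e(ptr);
  for (auto it = e->ulen.rbegin(); it != e->ulen.rend(); ++it)
    e->elen[it->first] = it->second;
  for (int v : e->unodes) {
    e->act[v] = 1 - e->act[v];  // flip back to the pre-proposal buffer
    e->ulogged[v] = 0;
  }
  std::fill(e->dirty.begin(), e->dirty.end(), 0);
  e->ulen.clear(); e->unodes.clear();
}

// [[Rcpp::export]]
void engine_set_model(SEXP ptr, NumericVector rates, NumericVector weights,
                      List eigs, IntegerVector sitecomp) {
  XPtr<Engine> e(ptr);
  e->ncat = rates.size();
  e->rates.assign(rates.begin(), rates.end());
  e->weights.assign(weights.begin(), weights.end());
  e->comps.clear();
  for (int i = 0; i < eigs.size(); ++i) e->comps.push_back(as_eigensys(eigs[i]));
  e->sitecomp.assign(sitecomp.begin(), sitecomp.end());
  for (auto &x : e->sitecomp) --x;
  std::fill(e->dirty.begin(), e->dirty.end(), 1);
  // model replacement invalidates the undo log
  e->ulen.clear();
  for (int v : e->unodes) e->ulogged[v] = 0;
  e->unodes.clear();
}

// [[Rcpp::export]]
double engine_loglik(SEXP ptr) {
  XPtr<Engine> e(ptr);
  std::vector<double> sl = site_logliks(*e);
  double tot = 0.0;
  for (size_t i = 0; i < sl.size(); ++i) tot += e->sitew[i] * sl[i];
  return tot;
}

// [[Rcpp::export]]
NumericVector engine_site_loglik(SEXP ptr) {
  XPtr<Engine> e(ptr);
  std::vector<double> sl = site_logliks(*e);
  return NumericVector(sl.begin(), sl.end());
}

// [[Rcpp::export]]
NumericVector engine_lengths(SEXP ptr) {
  XPtr<Engine> e(ptr);
  return NumericVector(e->elen.begin(), e->elen.end());
}
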