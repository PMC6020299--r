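#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning over compressed site patterns with per-node scaling.
//
// tipstates: ntip x npat integer matrix, values 0..(k-1), or -1 for
//   gap/ambiguity (treated as missing: partial likelihood 1 for all states).
// edge:      nedge x 2 matrix of 1-based node ids (parent, child) sorted in
//   postorder (all edges into a parent appear after the subtrees below it,
//   as produced by ape::reorder.phylo(tree, "postorder")).
// P:         numeric vector of transition probabilities with dimensions
//   (k, k, nedge, ncat) flattened column-major; P[a,b] = Pr(b | a, t_edge).
// pi:        stationary frequencies (length k).
// catw:      mixture weights over the ncat rate categories.
// weights:   pattern weights (length npat).
//
// Returns the total log-likelihood.

// [[Rcpp::export]]
double prune_loglik_cpp(IntegerMatrix tipstates, NumericVector weights,
                        IntegerMatrix edge, NumericVector P, NumericVector pi,
                        NumericVector catw, int nnode_total, int root) {
  const int ntip = tipstates.nrow();
  const int npat = tipstates.ncol();
  const int nedge = edge.nrow();
  const int k = pi.size();
  const int ncat = catw.size();

  // number of children per internal node, to trigger scaling on completion
  std::vector<int> nchild(nnode_total + 1, 0), seen(nnode_total + 1, 0);
  for (int e = 0; e < nedge; ++e) nchild[edge(e, 0)]++;

  // per-pattern log-likelihood per category
  std::vector<double> sitell((size_t)npat * ncat);
  std::vector<double> partial((size_t)(nnode_total + 1) * k * npat);
  std::vector<double> logscale(npat);
  std::vector<double> tmp(k);

  const size_t kk = (size_t)k * k;
  for (int c = 0; c < ncat; ++c) {
    std::fill(partial.begin(), partial.end(), 0.0);
    std::fill(logscale.begin(), logscale.end(), 0.0);
    std::fill(seen.begin(), seen.end(), 0);
    // tips
    for (int t = 0; t < ntip; ++t) {
      double* pt = &partial[(size_t)(t + 1) * k * npat];
      for (int p = 0; p < npat; ++p) {
        int st = tipstates(t, p);
        if (st < 0) {
          for (int a = 0; a < k; ++a) pt[(size_t)p * k + a] = 1.0;
        } else {
          pt[(size_t)p * k + st] = 1.0;
        }
      }
    }
    // internal nodes start as all-ones products
    for (int v = ntip + 1; v <= nnode_total; ++v) {
      double* pv = &partial[(size_t)v * k * npat];
      std::fill(pv, pv + (size_t)k * npat, 1.0);
    }
    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0), ch = edge(e, 1);
      const double* Pe = &P[((size_t)c * nedge + e) * kk];
      double* pp = &partial[(size_t)par * k * npat];
      const double* pc = &partial[(size_t)ch * k * npat];
      for (int p = 0; p < npat; ++p) {
        const double* x = &pc[(size_t)p * k];
        for (int a = 0; a < k; ++a) {
          double acc = 0.0;
          for (int b = 0; b < k; ++b) acc += Pe[a + (size_t)b * k] * x[b];
          tmp[a] = acc;
        }
        double* y = &pp[(size_t)p * k];
        for (int a = 0; a < k; ++a) y[a] *= tmp[a];
      }
      if (++seen[par] == nchild[par]) {
        // node complete: rescale each pattern column
        for (int p = 0; p < npat; ++p) {
          double* y = &pp[(size_t)p * k];
          double mx = y[0];
          for (int a = 1; a < k; ++a)
            if (y[a] > mx) mx = y[a];
          if (mx > 0 && mx < 1e-80) {
            for (int a = 0; a < k; ++a) y[a] /= mx;
            logscale[p] += std::log(mx);
          }
        }
      }
    }
    const double* pr = &partial[(size_t)root * k * npat];
    for (int p = 0; p < npat; ++p) {
      double acc = 0.0;
      for (int a = 0; a < k; ++a) acc += pi[a] * pr[(size_t)p * k + a];
      sitell[(size_t)p * ncat + c] =
          (acc > 0 ? std::log(acc) : -1e300) + logscale[p];
    }
  }
  // combine categories in log space
  double tot = 0.0;
  for (int p = 0; p < npat; ++p) {
    const double* sl = &sitell[(size_t)p * ncat];
    double mx = sl[0] + std::log(catw[0]);
    for (int c = 1; c < ncat; ++c) {
      double v = sl[c] + std::log(catw[c]);
      if (v > mx) mx = v;
    }
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c) acc += std::exp(sl[c] + std::log(catw[c]) - mx);
    tot += weights[p] * (mx + std::log(acc));
  }
  return tot;
}
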