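#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). Sequences arrive as 0-based integer
// codes indexing rows/columns of the substitution matrix. A gap of length L
// costs gap_open + L * gap_extend (BLAST convention).

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
double align_score_cpp(IntegerVector q, IntegerVector s, NumericMatrix sub,
                       double gap_open, double gap_extend, bool local) {
  const int m = q.size(), n = s.size();
  const double go = gap_open + gap_extend, ge = gap_extend;
  const int nr = sub.nrow();
  const double* subp = sub.begin();
  const int* qp = q.begin();
  const int* sp = s.begin();
  std::vector<double> Hprev(n + 1), H(n + 1), Eprev(n + 1), E(n + 1);
  std::vector<double> Fprev(n + 1), F(n + 1);
  Hprev[0] = 0.0;
  Eprev[0] = NEG_INF;
  Fprev[0] = NEG_INF;
  for (int j = 1; j <= n; ++j) {
    Eprev[j] = local ? NEG_INF : -(go + (j - 1) * ge);
    Hprev[j] = local ? 0.0 : Eprev[j];
    Fprev[j] = NEG_INF;
  }
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    double* h = H.data();
    double* e = E.data();
    double* f = F.data();
    const double* hp = Hprev.data();
    const double* fp = Fprev.data();
    e[0] = NEG_INF;
    f[0] = local ? NEG_INF : -(go + (i - 1) * ge);
    h[0] = local ? 0.0 : f[0];
    const double* subrow = subp + (size_t)qp[i - 1];
    for (int j = 1; j <= n; ++j) {
      double ee = h[j - 1] - go;
      {
        double e2 = e[j - 1] - ge;
        if (e2 > ee) ee = e2;
      }
      double ff = hp[j] - go;
      {
        double f2 = fp[j] - ge;
        if (f2 > ff) ff = f2;
      }
      double hh = hp[j - 1] + subrow[(size_t)sp[j - 1] * nr];
      if (ee > hh) hh = ee;
      if (ff > hh) hh = ff;
      if (local && hh < 0) hh = 0;
      e[j] = ee;
      f[j] = ff;
      h[j] = hh;
      if (local && hh > best) best = hh;
    }
    std::swap(H, Hprev);
    std::swap(E, Eprev);
    std::swap(F, Fprev);
  }
  return local ? best : Hprev[n];
}

// [[Rcpp::export]]
NumericVector align_scores_batch_cpp(IntegerVector q, List subjects,
                                     NumericMatrix sub, double gap_open,
                                     double gap_extend, bool local) {
  int ns = subjects.size();
  NumericVector out(ns);
  for (int k = 0; k < ns; ++k) {
    IntegerVector s = subjects[k];
    out[k] = align_score_cpp(q, s, sub, gap_open, gap_extend, local);
  }
  return out;
}

// Full alignment with traceback. Returns the optimal score and the 1-based
// positions of residue-residue (match) columns in query and subject.
// [[Rcpp::export]]
List align_affine_cpp(IntegerVector q, IntegerVector s, NumericMatrix sub,
                      double gap_open, double gap_extend, bool local) {
  int m = q.size(), n = s.size();
  double go = gap_open + gap_extend, ge = gap_extend;
  size_t W = (size_t)(n + 1);
  std::vector<double> H((m + 1) * W), E((m + 1) * W), F((m + 1) * W);
  // tH: 0 stop, 1 diag, 2 from E (gap in query), 3 from F (gap in subject)
  // tE/tF: 0 opened from H, 1 extended
  std::vector<unsigned char> tH((m + 1) * W, 0), tE((m + 1) * W, 0),
      tF((m + 1) * W, 0);
  auto id = [W](int i, int j) { return (size_t)i * W + (size_t)j; };
  H[id(0, 0)] = 0.0;
  E[id(0, 0)] = NEG_INF;
  F[id(0, 0)] = NEG_INF;
  for (int j = 1; j <= n; ++j) {
    E[id(0, j)] = local ? NEG_INF : -(go + (j - 1) * ge);
    tE[id(0, j)] = (unsigned char)(j == 1 ? 0 : 1);
    F[id(0, j)] = NEG_INF;
    H[id(0, j)] = local ? 0.0 : E[id(0, j)];
    tH[id(0, j)] = (unsigned char)(local ? 0 : 2);
  }
  double best = 0.0;
  int bi = 0, bj = 0;
  const int nr = sub.nrow();
  const double* subp = sub.begin();
  for (int i = 1; i <= m; ++i) {
    E[id(i, 0)] = NEG_INF;
    F[id(i, 0)] = local ? NEG_INF : -(go + (i - 1) * ge);
    tF[id(i, 0)] = (unsigned char)(i == 1 ? 0 : 1);
    H[id(i, 0)] = local ? 0.0 : F[id(i, 0)];
    tH[id(i, 0)] = (unsigned char)(local ? 0 : 3);
    const double* subrow = subp + (size_t)q[i - 1];
    for (int j = 1; j <= n; ++j) {
      double eo = H[id(i, j - 1)] - go, ee = E[id(i, j - 1)] - ge;
      double e = eo >= ee ? eo : ee;
      tE[id(i, j)] = (unsigned char)(eo >= ee ? 0 : 1);
      double fo = H[id(i - 1, j)] - go, fe = F[id(i - 1, j)] - ge;
      double f = fo >= fe ? fo : fe;
      tF[id(i, j)] = (unsigned char)(fo >= fe ? 0 : 1);
      double h = H[id(i - 1, j - 1)] + subrow[(size_t)s[j - 1] * nr];
      unsigned char th = 1;
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      if (local && h < 0) { h = 0; th = 0; }
      E[id(i, j)] = e;
      F[id(i, j)] = f;
      H[id(i, j)] = h;
      tH[id(i, j)] = th;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  double score;
  int i, j;
  if (local) {
    score = best;
    i = bi;
    j = bj;
  } else {
    score = H[id(m, n)];
    i = m;
    j = n;
  }
  std::vector<int> qpos, spos;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char t = tH[id(i, j)];
      if (t == 0) break; // local origin
      if (t == 1) {
        qpos.push_back(i);
        spos.push_back(j);
        --i;
        --j;
      } else if (t == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      unsigned char t = tE[id(i, j)];
      --j;
      state = (t == 0) ? 0 : 1;
    } else {
      unsigned char t = tF[id(i, j)];
      --i;
      state = (t == 0) ? 0 : 2;
    }
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(spos.begin(), spos.end());
  return List::create(_["score"] = score, _["q_idx"] = wrap(qpos),
                      _["s_idx"] = wrap(spos));
}
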