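#include <Rcpp.h>
using namespace Rcpp;

// Pair-distance histogram without materialising the O(N^2) distance vector.
// Bin b (1-based) covers [ (b-1)*bin_width, b*bin_width ).
// [[Rcpp::export]]
List cpp_pair_histogram(NumericMatrix coords, double bin_width) {
  const int n = coords.nrow();
  double dmax = 0.0;
  // first pass: max distance to size the histogram
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i,0) - coords(j,0);
      double dy = coords(i,1) - coords(j,1);
      double dz = coords(i,2) - coords(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > dmax) dmax = d2;
    }
  }
  dmax = std::sqrt(dmax);
  int nbins = (int)std::floor(dmax / bin_width) + 1;
  std::vector<double> counts(nbins, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i,0) - coords(j,0);
      double dy = coords(i,1) - coords(j,1);
      double dz = coords(i,2) - coords(j,2);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      int b = (int)std::floor(d / bin_width);
      if (b >= nbins) b = nbins - 1;
      counts[b] += 1.0;
    }
  }
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["max_distance"] = dmax,
                      _["n_bins"] = nbins);
}

// Exact Debye sum over all bead pairs: I(S) = sum_ij sinc(2*pi*S*r_ij),
// sinc(0) = 1, so I(0) = N^2.
// [[Rcpp::export]]
NumericVector cpp_debye_exact(NumericMatrix coords, NumericVector s) {
  const int n = coords.nrow();
  const int ns = s.size();
  NumericVector intens(ns);
  const double twopi = 2.0 * M_PI;
  // precompute pair distances once (n <= ~2000 in exact mode)
  const R_xlen_t npair = (R_xlen_t)n * (n - 1) / 2;
  std::vector<double> dist(npair);
  R_xlen_t k = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j, ++k) {
      double dx = coords(i,0) - coords(j,0);
      double dy = coords(i,1) - coords(j,1);
      double dz = coords(i,2) - coords(j,2);
      dist[k] = std::sqrt(dx*dx + dy*dy + dz*dz);
    }
  }
  for (int m = 0; m < ns; ++m) {
    double q = twopi * s[m];
    double acc = 0.0;
    if (q == 0.0) {
      acc = (double)npair;
    } else {
      for (R_xlen_t p = 0; p < npair; ++p) {
        double x = q * dist[p];
        acc += (x == 0.0) ? 1.0 : std::sin(x) / x;
      }
    }
    intens[m] = (double)n + 2.0 * acc;
  }
  return intens;
}

// Affine-gap Smith-Waterman with EMBOSS-style penalties: a gap of length L
// costs gap_open + (L - 1) * gap_extend. Traceback from the maximum cell;
// ties prefer the diagonal, then a gap in sequence b, then a gap in a; among
// equal maxima the smallest end coordinates win (first encountered in
// row-major order scanning i then j ascending keeps the smallest (i, j)).
// a, b are 0-based integer codes into the square substitution matrix.
// [[Rcpp::export]]
List cpp_smith_waterman(IntegerVector a, IntegerVector b, NumericMatrix subst,
                        double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  // H: best local score ending at (i,j); E: gap in a (consumes b); F: gap in b
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<double> Fcur(m + 1, NEG);
  // traceback matrices: 0 stop, 1 diag, 2 up(gap in b), 3 left(gap in a)
  // plus state matrices for E/F extension decisions
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = open from H
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  std::vector<double> Fprev(m + 1, NEG);
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t idx = (size_t)i * (m + 1) + j;
      // E: gap in a -> move left (j-1 -> j)
      double e_open = Hcur[j - 1] - gap_open;
      double e_ext  = Ecur[j - 1] - gap_extend;
      if (e_open >= e_ext) { Ecur[j] = e_open; tbE[idx] = 1; }
      else                 { Ecur[j] = e_ext;  tbE[idx] = 0; }
      // F: gap in b -> move up (i-1 -> i)
      double f_open = Hprev[j] - gap_open;
      double f_ext  = Fprev[j] - gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; tbF[idx] = 1; }
      else                 { Fcur[j] = f_ext;  tbF[idx] = 0; }
      double diag = Hprev[j - 1] + subst(a[i - 1], b[j - 1]);
      double h = 0.0; unsigned char t = 0;
      if (diag > h)    { h = diag;    t = 1; }
      if (Fcur[j] > h) { h = Fcur[j]; t = 2; }
      if (Ecur[j] > h) { h = Ecur[j]; t = 3; }
      Hcur[j] = h; tbH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
  }
  // traceback needs full H; recompute scores is avoided by storing moves only,
  // which suffices: tbH/tbE/tbF fully determine the path.
  std::vector<int> ai, bjv; // aligned index pairs; -1 marks a gap
  int i = bi, j = bj;
  int state = 0; // 0 = in H, 2 = in F (gap in b), 3 = in E (gap in a)
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = tbH[idx];
      if (t == 0) break;
      if (t == 1) { ai.push_back(i - 1); bjv.push_back(j - 1); --i; --j; }
      else if (t == 2) { state = 2; }
      else { state = 3; }
    } else if (state == 2) { // gap in b: consume a[i-1]
      ai.push_back(i - 1); bjv.push_back(-1);
      unsigned char open = tbF[idx];
      --i;
      if (open) state = 0;
    } else { // gap in a: consume b[j-1]
      ai.push_back(-1); bjv.push_back(j - 1);
      unsigned char open = tbE[idx];
      --j;
      if (open) state = 0;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());
  return List::create(_["score"] = best,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bjv.begin(), bjv.end()),
                      _["end_a"] = bi, _["end_b"] = bj);
}
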