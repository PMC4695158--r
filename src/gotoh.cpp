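#include <Rcpp.h>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Gotoh global alignment with affine gaps and optionally free end gaps
// (Needle semantics). Gap of length L costs open + ext * (L - 1): the
// first gapped residue pays the opening penalty, each further one the
// extension penalty.
//
// Three-state DP: M (a_i ~ b_j), X (gap in b, consumes a), Y (gap in a,
// consumes b). With free end gaps, leading gaps cost nothing (boundary
// rows/cols are 0) and the optimum is the best cell on the last row or
// column, completed by an unpenalized trailing gap.

static const double NEG = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b, NumericMatrix sub,
                 CharacterVector residues, double gap_open, double gap_ext,
                 bool free_end_gaps) {
  const int n = a.size(), m = b.size();
  // residue -> matrix index
  std::vector<int> lut(256, -1);
  for (int k = 0; k < residues.size(); ++k) {
    std::string r = as<std::string>(residues[k]);
    lut[static_cast<unsigned char>(r[0])] = k;
  }
  std::vector<int> ai(n), bj(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = lut[static_cast<unsigned char>(a[i])];
    if (ai[i] < 0) stop("invalid residue '%s' at position %d of first sequence",
                        std::string(1, a[i]), i + 1);
  }
  for (int j = 0; j < m; ++j) {
    bj[j] = lut[static_cast<unsigned char>(b[j])];
    if (bj[j] < 0) stop("invalid residue '%s' at position %d of second sequence",
                        std::string(1, b[j]), j + 1);
  }

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i)
    X[idx(i, 0)] = free_end_gaps ? 0.0 : -gap_open - gap_ext * (i - 1);
  for (int j = 1; j <= m; ++j)
    Y[idx(0, j)] = free_end_gaps ? 0.0 : -gap_open - gap_ext * (j - 1);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(ai[i - 1], bj[j - 1]);
      double dM = M[idx(i - 1, j - 1)], dX = X[idx(i - 1, j - 1)],
             dY = Y[idx(i - 1, j - 1)];
      M[idx(i, j)] = std::max(dM, std::max(dX, dY)) + s;
      // X: gap in b; opening from M/Y, extending X
      double xo = std::max(M[idx(i - 1, j)], Y[idx(i - 1, j)]) - gap_open;
      double xe = X[idx(i - 1, j)] - gap_ext;
      X[idx(i, j)] = std::max(xo, xe);
      // Y: gap in a
      double yo = std::max(M[idx(i, j - 1)], X[idx(i, j - 1)]) - gap_open;
      double ye = Y[idx(i, j - 1)] - gap_ext;
      Y[idx(i, j)] = std::max(yo, ye);
    }
  }

  // locate the optimum
  int ei = n, ej = m;
  double best;
  auto cellmax = [&](int i, int j) {
    return std::max(M[idx(i, j)], std::max(X[idx(i, j)], Y[idx(i, j)]));
  };
  if (free_end_gaps) {
    best = cellmax(n, m);
    for (int i = 0; i <= n; ++i)
      if (cellmax(i, m) > best) { best = cellmax(i, m); ei = i; ej = m; }
    for (int j = 0; j <= m; ++j)
      if (cellmax(n, j) > best) { best = cellmax(n, j); ei = n; ej = j; }
  } else {
    best = cellmax(n, m);
  }

  // traceback from (ei, ej); state 0 = M, 1 = X, 2 = Y
  std::string ra, rb;
  // trailing free end gaps
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }

  int i = ei, j = ej;
  int state;
  {
    double c = cellmax(i, j);
    state = (c == M[idx(i, j)]) ? 0 : (c == X[idx(i, j)] ? 1 : 2);
  }
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) { // boundary: remaining is a free/leading gap
        state = (i > 0) ? 1 : 2;
        continue;
      }
      double s = sub(ai[i - 1], bj[j - 1]);
      double target = M[idx(i, j)] - s;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      if (std::abs(M[idx(i, j)] - target) < tol) state = 0;
      else if (std::abs(X[idx(i, j)] - target) < tol) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (i == 0) { state = 2; continue; }
      ra.push_back(a[i - 1]); rb.push_back('-');
      double cur = X[idx(i, j)];
      --i;
      if (i == 0 && free_end_gaps) {
        // leading free gap region; stay in X until i == 0
        state = 1;
      } else if (std::abs(X[idx(i, j)] - gap_ext - cur) < tol) {
        state = 1;
      } else if (std::abs(M[idx(i, j)] - gap_open - cur) < tol) {
        state = 0;
      } else if (std::abs(Y[idx(i, j)] - gap_open - cur) < tol) {
        state = 2;
      } else {
        state = 1; // boundary (free leading gap column)
      }
    } else {
      if (j == 0) { state = 1; continue; }
      ra.push_back('-'); rb.push_back(b[j - 1]);
      double cur = Y[idx(i, j)];
      --j;
      if (j == 0 && free_end_gaps) {
        state = 2;
      } else if (std::abs(Y[idx(i, j)] - gap_ext - cur) < tol) {
        state = 2;
      } else if (std::abs(M[idx(i, j)] - gap_open - cur) < tol) {
        state = 0;
      } else if (std::abs(X[idx(i, j)] - gap_open - cur) < tol) {
        state = 1;
      } else {
        state = 2;
      }
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = best);
}
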