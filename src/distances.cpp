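#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Edit operations on nucleotide strings under an affine gap cost model:
// matches cost `match`, substitutions cost `sub`; the first position of
// each maximal run of contiguous insertions or deletions is charged
// `gopen` (the per-gap surcharge) and every further position `gext`.
// Setting gopen == gext == sub recovers the classical unit-cost
// Levenshtein distance. 'N' compares as a mismatch against every base,
// including 'N'.

static const double INF = std::numeric_limits<double>::infinity();

static inline double pair_cost(char a, char b, double match, double sub) {
  return (a == b && a != 'N') ? match : sub;
}

// Block-gap (affine) Levenshtein distance via a three-state DP.
// [[Rcpp::export]]
double cpp_ld(std::string x, std::string y,
              double match, double sub, double gopen, double gext) {
  const int m = (int)x.size(), n = (int)y.size();
  if (m == 0 && n == 0) return 0.0;
  if (m == 0 || n == 0) return gopen + (std::max(m, n) - 1) * gext;

  // rolling rows over i; states: M (aligned pair), D (deletion), I (insertion)
  std::vector<double> Mp(n + 1), Dp(n + 1), Ip(n + 1);
  std::vector<double> Mc(n + 1), Dc(n + 1), Ic(n + 1);
  Mp[0] = 0.0; Dp[0] = INF; Ip[0] = INF;
  for (int j = 1; j <= n; ++j) {
    Mp[j] = INF; Dp[j] = INF;
    Ip[j] = gopen + (j - 1) * gext;
  }
  for (int i = 1; i <= m; ++i) {
    Mc[0] = INF; Ic[0] = INF;
    Dc[0] = gopen + (i - 1) * gext;
    for (int j = 1; j <= n; ++j) {
      double c = pair_cost(x[i - 1], y[j - 1], match, sub);
      Mc[j] = std::min(std::min(Mp[j - 1], Dp[j - 1]), Ip[j - 1]) + c;
      Dc[j] = std::min(std::min(Mp[j] + gopen, Ip[j] + gopen), Dp[j] + gext);
      Ic[j] = std::min(std::min(Mc[j - 1] + gopen, Dc[j - 1] + gopen),
                       Ic[j - 1] + gext);
    }
    std::swap(Mp, Mc); std::swap(Dp, Dc); std::swap(Ip, Ic);
  }
  return std::min(std::min(Mp[n], Dp[n]), Ip[n]);
}

// Normalized edit distance by the path-length-indexed DP: state
// (i, j, k, s) where k is the number of elementary operations so far and
// s the gap state; k <= m + n. Minimizes (W + offset) / L over all paths.
// [[Rcpp::export]]
double cpp_ned_dp(std::string x, std::string y,
                  double match, double sub, double gopen, double gext,
                  double offset) {
  const int m = (int)x.size(), n = (int)y.size();
  if (m == 0 && n == 0) {
    if (offset > 0) stop("NED with a positive offset is undefined for two empty strings");
    return 0.0;
  }
  const int S = 3;                       // 0 = aligned pair, 1 = delete, 2 = insert
  const int cells = (m + 1) * (n + 1) * S;
  std::vector<double> prev(cells, INF), cur(cells, INF);
  auto at = [&](std::vector<double> &a, int i, int j, int s) -> double & {
    return a[(i * (n + 1) + j) * S + s];
  };
  at(prev, 0, 0, 0) = 0.0;               // length-0 path, no open gap
  double best = INF;
  for (int k = 1; k <= m + n; ++k) {
    std::fill(cur.begin(), cur.end(), INF);
    // reachable cells after k ops satisfy max(i, j) <= k <= i + j
    for (int i = 0; i <= std::min(m, k); ++i) {
      for (int j = std::max(0, k - i); j <= std::min(n, k); ++j) {
        double *c = &at(cur, i, j, 0);
        if (i > 0 && j > 0) {
          double pc = pair_cost(x[i - 1], y[j - 1], match, sub);
          double p = std::min(std::min(at(prev, i - 1, j - 1, 0),
                                       at(prev, i - 1, j - 1, 1)),
                              at(prev, i - 1, j - 1, 2));
          if (p < INF) c[0] = p + pc;
        }
        if (i > 0) {
          double open = std::min(at(prev, i - 1, j, 0), at(prev, i - 1, j, 2)) + gopen;
          double ext  = at(prev, i - 1, j, 1) + gext;
          c[1] = std::min(open, ext);
        }
        if (j > 0) {
          double open = std::min(at(prev, i, j - 1, 0), at(prev, i, j - 1, 1)) + gopen;
          double ext  = at(prev, i, j - 1, 2) + gext;
          c[2] = std::min(open, ext);
        }
      }
    }
    for (int s = 0; s < S; ++s) {
      double w = at(cur, m, n, s);
      if (w < INF) best = std::min(best, (w + offset) / k);
    }
    std::swap(prev, cur);
  }
  return best;
}

// One evaluation of the parametric subproblem: minimize W(P) - lambda * L(P)
// over all edit paths, returning the minimum together with the W and L of a
// minimizing path.
static void param_dp(const std::string &x, const std::string &y,
                     double match, double sub, double gopen, double gext,
                     double lambda,
                     double &valOut, double &wOut, double &lOut) {
  const int m = (int)x.size(), n = (int)y.size();
  struct Cell { double v, w, l; };
  const Cell BAD = {INF, 0.0, 0.0};
  std::vector<Cell> Mp(n + 1, BAD), Dp(n + 1, BAD), Ip(n + 1, BAD);
  std::vector<Cell> Mc(n + 1, BAD), Dc(n + 1, BAD), Ic(n + 1, BAD);
  Mp[0] = {0.0, 0.0, 0.0};
  for (int j = 1; j <= n; ++j) {
    double w = gopen + (j - 1) * gext;
    Ip[j] = {w - j * lambda, w, (double)j};
  }
  for (int i = 1; i <= m; ++i) {
    Mc[0] = BAD; Ic[0] = BAD;
    double w0 = gopen + (i - 1) * gext;
    Dc[0] = {w0 - i * lambda, w0, (double)i};
    for (int j = 1; j <= n; ++j) {
      double pc = pair_cost(x[i - 1], y[j - 1], match, sub);
      // aligned pair
      Cell best = BAD;
      const Cell *diag[3] = {&Mp[j - 1], &Dp[j - 1], &Ip[j - 1]};
      for (int s = 0; s < 3; ++s)
        if (diag[s]->v + pc - lambda < best.v)
          best = {diag[s]->v + pc - lambda, diag[s]->w + pc, diag[s]->l + 1};
      Mc[j] = best;
      // deletion (consumes x[i-1]); opening charged unless extending
      best = BAD;
      const Cell *up[3] = {&Mp[j], &Dp[j], &Ip[j]};
      double wdel[3] = {gopen, gext, gopen};
      for (int s = 0; s < 3; ++s)
        if (up[s]->v + wdel[s] - lambda < best.v)
          best = {up[s]->v + wdel[s] - lambda, up[s]->w + wdel[s], up[s]->l + 1};
      Dc[j] = best;
      // insertion (consumes y[j-1]); note same-row dependence
      best = BAD;
      const Cell *left[3] = {&Mc[j - 1], &Dc[j - 1], &Ic[j - 1]};
      double wins[3] = {gopen, gopen, gext};
      for (int s = 0; s < 3; ++s)
        if (left[s]->v + wins[s] - lambda < best.v)
          best = {left[s]->v + wins[s] - lambda, left[s]->w + wins[s], left[s]->l + 1};
      Ic[j] = best;
    }
    std::swap(Mp, Mc); std::swap(Dp, Dc); std::swap(Ip, Ic);
  }
  Cell fin = Mp[n];
  if (Dp[n].v < fin.v) fin = Dp[n];
  if (Ip[n].v < fin.v) fin = Ip[n];
  valOut = fin.v; wOut = fin.w; lOut = fin.l;
}

// Normalized edit distance by Dinkelbach fractional programming: iterate
// lambda <- (W + offset) / L of the path minimizing W - lambda * L until no
// path beats the current ratio. Exact (the returned value is the ratio of an
// optimal path); O(mn) per iteration, few iterations in practice.
// [[Rcpp::export]]
double cpp_ned(std::string x, std::string y,
               double match, double sub, double gopen, double gext,
               double offset) {
  const int m = (int)x.size(), n = (int)y.size();
  if (m == 0 && n == 0) {
    if (offset > 0) stop("NED with a positive offset is undefined for two empty strings");
    return 0.0;
  }
  if (m == 0 || n == 0) {
    int len = std::max(m, n);
    return (gopen + (len - 1) * gext + offset) / len;
  }
  if (offset == 0.0 && match == 0.0 && x == y &&
      x.find('N') == std::string::npos)
    return 0.0;
  double val, w, l;
  param_dp(x, y, match, sub, gopen, gext, 0.0, val, w, l);  // LD path seeds lambda
  double lambda = (w + offset) / l;
  for (int it = 0; it < 200; ++it) {
    param_dp(x, y, match, sub, gopen, gext, lambda, val, w, l);
    double cand = (w + offset) / l;
    if (val + offset >= -1e-12 * std::max(1.0, lambda * (m + n)) || cand >= lambda)
      break;
    lambda = cand;
  }
  return lambda;
}

// Full pairwise distance matrix over CDR3 strings. `metric` is one of
// "ld", "pned", "ned"; `offsets` (germline mismatch penalties S_V + S_J) is
// added to the NED numerator, giving NED_VJ when nonzero.
// [[Rcpp::export]]
NumericMatrix cpp_distance_matrix(std::vector<std::string> seqs,
                                  NumericMatrix offsets,
                                  std::string metric,
                                  double match, double sub,
                                  double gopen, double gext) {
  const int n = (int)seqs.size();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double v;
      if (metric == "ld") {
        v = cpp_ld(seqs[i], seqs[j], match, sub, gopen, gext);
      } else if (metric == "pned") {
        double denom = std::max(seqs[i].size(), seqs[j].size());
        v = denom == 0 ? 0.0
          : cpp_ld(seqs[i], seqs[j], match, sub, gopen, gext) / denom;
      } else {
        v = cpp_ned(seqs[i], seqs[j], match, sub, gopen, gext, offsets(i, j));
      }
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}
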