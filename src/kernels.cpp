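#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// String similarity kernels used on concatenated phonetic match keys.
// Keys are short ASCII strings (~12-18 chars), so the O(|a|*|b|) dynamic
// programmes below are run exhaustively over within-block pairs.

static double jaro_impl(const std::string &a, const std::string &b) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  int window = std::max(la, lb) / 2 - 1;
  if (window < 0) window = 0;
  std::vector<char> am(la, 0), bm(lb, 0);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    const int lo = std::max(0, i - window);
    const int hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!bm[j] && a[i] == b[j]) {
        am[i] = 1; bm[j] = 1; ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;
  // half-transpositions: matched characters out of sequence
  int half = 0, j = 0;
  for (int i = 0; i < la; ++i) {
    if (am[i]) {
      while (!bm[j]) ++j;
      if (a[i] != b[j]) ++half;
      ++j;
    }
  }
  const double t = half / 2.0;
  return ((double)m / la + (double)m / lb + (m - t) / m) / 3.0;
}

static double jw_impl(const std::string &a, const std::string &b, double p,
                      int max_prefix) {
  const double dj = jaro_impl(a, b);
  int l = 0;
  const int lim = std::min((int)std::min(a.size(), b.size()), max_prefix);
  while (l < lim && a[l] == b[l]) ++l;
  return dj + l * p * (1.0 - dj);
}

static double wlev_impl(const std::string &a, const std::string &b, double wd,
                        double wi, double ws) {
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<double> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j * wi;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i * wd;
    for (int j = 1; j <= lb; ++j) {
      const double sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0.0 : ws);
      cur[j] = std::min(sub, std::min(prev[j] + wd, cur[j - 1] + wi));
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Full (unrestricted-gap) Damerau-Levenshtein via the Lowrance-Wagner
// dynamic programme: a transposition may pair characters separated by
// later-deleted/inserted material, but each character takes part in at
// most one transposition.
static double wdl_impl(const std::string &a, const std::string &b, double wd,
                       double wi, double ws, double wt) {
  const int la = (int)a.size(), lb = (int)b.size();
  const double INF = (la + lb + 2) * (wd + wi + ws + wt + 1.0);
  std::vector<std::vector<double> > H(la + 2, std::vector<double>(lb + 2, 0.0));
  H[0][0] = INF;
  for (int i = 0; i <= la; ++i) { H[i + 1][0] = INF; H[i + 1][1] = i * wd; }
  for (int j = 0; j <= lb; ++j) { H[0][j + 1] = INF; H[1][j + 1] = j * wi; }
  int da[256];
  for (int k = 0; k < 256; ++k) da[k] = 0;
  for (int i = 1; i <= la; ++i) {
    int db = 0;
    for (int j = 1; j <= lb; ++j) {
      const int i1 = da[(unsigned char)b[j - 1]];
      const int j1 = db;
      double cost = ws;
      if (a[i - 1] == b[j - 1]) { cost = 0.0; db = j; }
      const double trans =
          H[i1][j1] + (i - i1 - 1) * wd + wt + (j - j1 - 1) * wi;
      H[i + 1][j + 1] = std::min(std::min(H[i][j] + cost, trans),
                                 std::min(H[i + 1][j] + wi, H[i][j + 1] + wd));
    }
    da[(unsigned char)a[i - 1]] = i;
  }
  return H[la + 1][lb + 1];
}

static double edit_sim(double cost, int la, int lb) {
  const int mx = std::max(la, lb);
  if (mx == 0) return 1.0;
  const double s = 1.0 - cost / mx;
  return s < 0.0 ? 0.0 : s;
}

// method codes: 1 jaro, 2 jaro-winkler, 3 levenshtein, 4 damerau-levenshtein
static double pair_sim(const std::string &a, const std::string &b, int method,
                       double p, int max_prefix, double wd, double wi,
                       double ws, double wt) {
  switch (method) {
  case 1: return jaro_impl(a, b);
  case 2: return jw_impl(a, b, p, max_prefix);
  case 3: return edit_sim(wlev_impl(a, b, wd, wi, ws), (int)a.size(), (int)b.size());
  default: return edit_sim(wdl_impl(a, b, wd, wi, ws, wt), (int)a.size(), (int)b.size());
  }
}

// [[Rcpp::export(name = ".jaro_cpp")]]
NumericVector jaro_cpp(CharacterVector s1, CharacterVector s2) {
  const int n = s1.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = jaro_impl(as<std::string>(s1[k]), as<std::string>(s2[k]));
  return out;
}

// [[Rcpp::export(name = ".jaro_winkler_cpp")]]
NumericVector jaro_winkler_cpp(CharacterVector s1, CharacterVector s2,
                               double p, int max_prefix) {
  const int n = s1.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = jw_impl(as<std::string>(s1[k]), as<std::string>(s2[k]), p, max_prefix);
  return out;
}

// [[Rcpp::export(name = ".wlev_cpp")]]
NumericVector wlev_cpp(CharacterVector s1, CharacterVector s2, double wd,
                       double wi, double ws) {
  const int n = s1.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = wlev_impl(as<std::string>(s1[k]), as<std::string>(s2[k]), wd, wi, ws);
  return out;
}

// [[Rcpp::export(name = ".wdl_cpp")]]
NumericVector wdl_cpp(CharacterVector s1, CharacterVector s2, double wd,
                      double wi, double ws, double wt) {
  const int n = s1.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = wdl_impl(as<std::string>(s1[k]), as<std::string>(s2[k]), wd, wi, ws, wt);
  return out;
}

// Banded weighted-Levenshtein with early abort: exact when the true cost
// is at most `maxcost`, otherwise returns a value above maxcost. Any path
// with cost <= maxcost stays within |i - j| <= maxcost / min(wd, wi).
static double wlev_banded(const char *a, int la, const char *b, int lb,
                          double wd, double wi, double ws, double maxcost) {
  const double INF = maxcost * 4 + 100.0;
  const int band = (int)(maxcost / std::min(wd, wi)) + 1;
  static thread_local std::vector<double> prev, cur;
  if ((int)prev.size() < lb + 1) { prev.resize(lb + 1); cur.resize(lb + 1); }
  for (int j = 0; j <= lb; ++j) prev[j] = j <= band ? j * wi : INF;
  for (int i = 1; i <= la; ++i) {
    const int jlo = std::max(1, i - band), jhi = std::min(lb, i + band);
    double rowmin = INF;
    cur[jlo - 1] = (jlo == 1) ? i * wd : INF;
    if (i <= band && jlo == 1) rowmin = cur[0];
    for (int j = jlo; j <= jhi; ++j) {
      const double sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0.0 : ws);
      const double up = (j <= i + band - 1) ? prev[j] + wd : INF;
      const double lf = cur[j - 1] + wi;
      cur[j] = std::min(sub, std::min(up, lf));
      if (cur[j] < rowmin) rowmin = cur[j];
    }
    if (jhi < lb) cur[jhi + 1] = INF;
    if (rowmin > maxcost) return INF;
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Banded Lowrance-Wagner Damerau-Levenshtein with early abort; the full
// H matrix is kept as a reusable workspace because the transposition rule
// looks back across rows.
static double wdl_banded(const char *a, int la, const char *b, int lb,
                         double wd, double wi, double ws, double wt,
                         double maxcost) {
  const double INF = maxcost * 4 + 100.0;
  const int band = (int)(maxcost / std::min(wd, wi)) + 1;
  static thread_local std::vector<double> H;
  static thread_local int Hdim = 0;
  const int dim = std::max(la, lb) + 2;
  if (Hdim < dim) {
    H.assign((size_t)dim * dim, INF);
    Hdim = dim;
  } else {
    std::fill(H.begin(), H.end(), INF);
  }
  const int stride = Hdim;
  H[0] = INF;
  for (int i = 0; i <= la && i <= band; ++i) H[(size_t)(i + 1) * stride + 1] = i * wd;
  for (int j = 0; j <= lb && j <= band; ++j) H[(size_t)stride + j + 1] = j * wi;
  int da[256];
  for (int k = 0; k < 256; ++k) da[k] = 0;
  double result = INF;
  bool aborted = false;
  // a transposition edge can bridge rows whose banded cells all exceed
  // maxcost, so only abort after enough consecutive over-budget rows to
  // rule out any bridge (gap deletions are priced into the edge)
  const int streak_limit =
      (wt > maxcost) ? 1 : 2 + (int)((maxcost - wt) / wd);
  int bad_streak = 0;
  for (int i = 1; i <= la && !aborted; ++i) {
    int db = 0;
    const int jlo = std::max(1, i - band), jhi = std::min(lb, i + band);
    double rowmin = (i <= band) ? i * wd : INF;
    for (int j = jlo; j <= jhi; ++j) {
      const int i1 = da[(unsigned char)b[j - 1]];
      const int j1 = db;
      double cost = ws;
      if (a[i - 1] == b[j - 1]) { cost = 0.0; db = j; }
      const double trans = H[(size_t)i1 * stride + j1] +
                           (i - i1 - 1) * wd + wt + (j - j1 - 1) * wi;
      double v = std::min(std::min(H[(size_t)i * stride + j] + cost, trans),
                          std::min(H[(size_t)(i + 1) * stride + j] + wi,
                                   H[(size_t)i * stride + j + 1] + wd));
      H[(size_t)(i + 1) * stride + j + 1] = v;
      if (v < rowmin) rowmin = v;
    }
    da[(unsigned char)a[i - 1]] = i;
    if (rowmin > maxcost) {
      if (++bad_streak >= streak_limit) { aborted = true; result = INF; }
    } else {
      bad_streak = 0;
    }
  }
  if (!aborted) result = H[(size_t)(la + 1) * stride + lb + 1];
  return result;
}

// Exhaustive within-block pair scoring. Returns only pairs whose similarity
// reaches min_sim (the acceptance threshold minus the audit margin), as
// 1-based local indices into `keys`. A character-multiset prefilter and
// banded dynamic programmes keep the O(n^2) enumeration tractable.
// [[Rcpp::export(name = ".score_block_cpp")]]
List score_block_cpp(CharacterVector keys, int method, double p,
                     int max_prefix, double wd, double wi, double ws,
                     double wt, double min_sim) {
  const int n = keys.size();
  std::vector<std::string> k(n);
  int lmax = 0;
  for (int i = 0; i < n; ++i) {
    k[i] = as<std::string>(keys[i]);
    lmax = std::max(lmax, (int)k[i].size());
  }
  // alphanumeric bucket index for the multiset prefilter
  int bucket[256];
  for (int c = 0; c < 256; ++c) bucket[c] = 63;
  {
    int b = 0;
    for (char c = 'a'; c <= 'z'; ++c) bucket[(unsigned char)c] = b++;
    for (char c = 'A'; c <= 'Z'; ++c) bucket[(unsigned char)c] = b++;
    for (char c = '0'; c <= '9'; ++c) bucket[(unsigned char)c] = b++;
  }
  std::vector<unsigned char> cnt((size_t)n * 64, 0);
  for (int i = 0; i < n; ++i) {
    unsigned char *ci = &cnt[(size_t)i * 64];
    for (size_t q = 0; q < k[i].size(); ++q) ++ci[bucket[(unsigned char)k[i][q]]];
  }
  std::vector<int> ia, ib;
  std::vector<double> sims;
  const double w_indel = std::min(wd, wi);
  const double w_fix = std::min(std::min(wd, wi), ws);
  for (int i = 0; i < n - 1; ++i) {
    const char *si = k[i].c_str();
    const int li = (int)k[i].size();
    const unsigned char *ci = &cnt[(size_t)i * 64];
    for (int j = i + 1; j < n; ++j) {
      const char *sj = k[j].c_str();
      const int lj = (int)k[j].size();
      const int mx = std::max(li, lj), mn = std::min(li, lj);
      if (mx == 0) continue;
      // multiset intersection size bounds the matching potential
      const unsigned char *cj = &cnt[(size_t)j * 64];
      int common = 0;
      for (int q = 0; q < 64; ++q)
        common += ci[q] < cj[q] ? ci[q] : cj[q];
      double s;
      if (method >= 3) {
        const double maxcost = (1.0 - min_sim) * mx;
        // every unit of one-sided multiset excess costs >= w_fix
        const int excess = mx - common;
        if (excess * w_fix > maxcost + 1e-12) continue;
        double cost;
        if (li == lj && std::memcmp(si, sj, li) == 0) cost = 0.0;
        else if (method == 3)
          cost = wlev_banded(si, li, sj, lj, wd, wi, ws, maxcost);
        else
          cost = wdl_banded(si, li, sj, lj, wd, wi, ws, wt, maxcost);
        if (cost > maxcost + 1e-12) continue;
        s = 1.0 - cost / mx;
        if (s < 0) s = 0;
      } else {
        // m <= common, so Jaro is bounded by (common/l1 + common/l2 + 1)/3
        double bound = ((double)common / li + (double)common / lj + 1.0) / 3.0;
        if (method == 2) {
          int l = 0;
          const int lim = std::min(mn, max_prefix);
          while (l < lim && si[l] == sj[l]) ++l;
          bound += l * p * (1.0 - bound);
        }
        if (bound < min_sim) continue;
        s = pair_sim(k[i], k[j], method, p, max_prefix, wd, wi, ws, wt);
      }
      if (s >= min_sim) {
        ia.push_back(i + 1);
        ib.push_back(j + 1);
        sims.push_back(s);
      }
    }
  }
  return List::create(_["i"] = wrap(ia), _["j"] = wrap(ib),
                      _["similarity"] = wrap(sims));
}
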