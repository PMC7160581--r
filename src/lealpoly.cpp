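// Compensated double-double arithmetic and the confluent Vandermonde solver.
//
// Multipoint Hermite-type interpolation in the monomial basis leads to
// confluent Vandermonde systems whose condition number grows roughly
// geometrically with the degree; the degree-26 three-point systems arising
// for the Thomas-Fermi study case are numerically singular in 53-bit
// floating point even after variable scaling.  All linear solves and
// coefficient manipulations therefore run in double-double arithmetic
// (an unevaluated sum of two doubles, ~32 significant decimal digits),
// using the classical error-free transforms of Dekker and Knuth.

#include <Rcpp.h>
#include <cmath>
#include <cstdio>
#include <string>
#include <vector>

using namespace Rcpp;

struct dd {
  double hi, lo;
};

static inline dd two_sum(double a, double b) {
  double s = a + b;
  double bb = s - a;
  double e = (a - (s - bb)) + (b - bb);
  return {s, e};
}

static inline dd quick_two_sum(double a, double b) {
  double s = a + b;
  double e = b - (s - a);
  return {s, e};
}

static inline dd two_prod(double a, double b) {
  double p = a * b;
  double e = std::fma(a, b, -p);
  return {p, e};
}

static inline dd dd_from(double x) { return {x, 0.0}; }

static inline dd dd_add(dd a, dd b) {
  dd s = two_sum(a.hi, b.hi);
  double e = s.lo + a.lo + b.lo;
  return quick_two_sum(s.hi, e);
}

static inline dd dd_neg(dd a) { return {-a.hi, -a.lo}; }

static inline dd dd_sub(dd a, dd b) { return dd_add(a, dd_neg(b)); }

static inline dd dd_mul(dd a, dd b) {
  dd p = two_prod(a.hi, b.hi);
  p.lo += a.hi * b.lo + a.lo * b.hi;
  return quick_two_sum(p.hi, p.lo);
}

static inline dd dd_div(dd a, dd b) {
  double q1 = a.hi / b.hi;
  dd r = dd_sub(a, dd_mul(dd_from(q1), b));
  double q2 = r.hi / b.hi;
  r = dd_sub(r, dd_mul(dd_from(q2), b));
  double q3 = r.hi / b.hi;
  dd q = quick_two_sum(q1, q2);
  return dd_add(q, dd_from(q3));
}

static inline double dd_mag(dd a) { return std::fabs(a.hi); }

static inline dd dd_ipow(dd a, int n) {
  dd r = dd_from(1.0);
  for (int i = 0; i < n; ++i) r = dd_mul(r, a);
  return r;
}

// Build and solve the interpolation conditions in the scaled variable
// t = x / scale, then map the coefficients back to the original variable.
// locs/orders: one entry per expansion point; values: concatenated
// (value, 1st, ..., q-th derivative) blocks in point order.
// [[Rcpp::export]]
List dd_solve_confluent(NumericVector locs, IntegerVector orders,
                        NumericVector values, double scale) {
  int M = locs.size();
  int n = 0;
  for (int p = 0; p < M; ++p) n += orders[p] + 1;

  std::vector<dd> A((size_t)n * n, dd_from(0.0)), b(n);
  int row = 0;
  for (int p = 0; p < M; ++p) {
    dd t = dd_div(dd_from(locs[p]), dd_from(scale));
    for (int k = 0; k <= orders[p]; ++k) {
      for (int i = k; i < n; ++i) {
        dd e = dd_from(1.0);                       // falling factorial i!/(i-k)!
        for (int j = 0; j < k; ++j) e = dd_mul(e, dd_from((double)(i - j)));
        A[(size_t)row * n + i] = dd_mul(e, dd_ipow(t, i - k));
      }
      // d^k/dt^k = scale^k d^k/dx^k
      b[row] = dd_mul(dd_from(values[row]), dd_ipow(dd_from(scale), k));
      ++row;
    }
  }

  std::vector<dd> Asave(A), bsave(b);

  // Gaussian elimination with partial pivoting
  for (int c = 0; c < n; ++c) {
    int best = c;
    double bm = dd_mag(A[(size_t)c * n + c]);
    for (int r2 = c + 1; r2 < n; ++r2) {
      double m = dd_mag(A[(size_t)r2 * n + c]);
      if (m > bm) { bm = m; best = r2; }
    }
    if (bm == 0.0)
      return List::create(_["singular"] = true);
    if (best != c) {
      for (int j = 0; j < n; ++j)
        std::swap(A[(size_t)c * n + j], A[(size_t)best * n + j]);
      std::swap(b[c], b[best]);
    }
    for (int r2 = c + 1; r2 < n; ++r2) {
      dd f = dd_div(A[(size_t)r2 * n + c], A[(size_t)c * n + c]);
      A[(size_t)r2 * n + c] = dd_from(0.0);
      for (int j = c + 1; j < n; ++j)
        A[(size_t)r2 * n + j] =
            dd_sub(A[(size_t)r2 * n + j], dd_mul(f, A[(size_t)c * n + j]));
      b[r2] = dd_sub(b[r2], dd_mul(f, b[c]));
    }
  }

  std::vector<dd> y(n);
  for (int i = n - 1; i >= 0; --i) {
    dd s = b[i];
    for (int j = i + 1; j < n; ++j)
      s = dd_sub(s, dd_mul(A[(size_t)i * n + j], y[j]));
    y[i] = dd_div(s, A[(size_t)i * n + i]);
  }

  // max relative residual of the scaled system, computed from saved copies
  double maxres = 0.0;
  for (int i = 0; i < n; ++i) {
    dd s = dd_from(0.0);
    for (int j = 0; j < n; ++j)
      s = dd_add(s, dd_mul(Asave[(size_t)i * n + j], y[j]));
    s = dd_sub(s, bsave[i]);
    double denom = std::max(1.0, std::fabs(bsave[i].hi));
    maxres = std::max(maxres, std::fabs(s.hi) / denom);
  }

  NumericVector chi(n), clo(n);
  dd sp = dd_from(1.0);
  for (int i = 0; i < n; ++i) {
    dd c = dd_div(y[i], sp);     // coef in x: c_i = y_i / scale^i
    chi[i] = c.hi;
    clo[i] = c.lo;
    sp = dd_mul(sp, dd_from(scale));
  }
  return List::create(_["hi"] = chi, _["lo"] = clo, _["residual"] = maxres,
                      _["singular"] = false);
}

// Horner evaluation with double-double coefficients and carry.
// [[Rcpp::export]]
NumericVector dd_horner(NumericVector chi, NumericVector clo, NumericVector x) {
  int n = chi.size(), m = x.size();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    dd r = dd_from(0.0), xx = dd_from(x[t]);
    for (int i = n - 1; i >= 0; --i)
      r = dd_add(dd_mul(r, xx), {chi[i], clo[i]});
    out[t] = r.hi + r.lo;
  }
  return out;
}

// Coefficients of the k-th derivative.
// [[Rcpp::export]]
List dd_poly_deriv(NumericVector chi, NumericVector clo, int k) {
  int n = chi.size();
  int m = std::max(n - k, 1);
  NumericVector dhi(m), dlo(m);
  if (n - k <= 0) {
    dhi[0] = 0.0; dlo[0] = 0.0;
    return List::create(_["hi"] = dhi, _["lo"] = dlo);
  }
  for (int i = k; i < n; ++i) {
    dd c = {chi[i], clo[i]};
    for (int j = 0; j < k; ++j) c = dd_mul(c, dd_from((double)(i - j)));
    dhi[i - k] = c.hi;
    dlo[i - k] = c.lo;
  }
  return List::create(_["hi"] = dhi, _["lo"] = dlo);
}

// Value of the k-th derivative at x (for interpolation-residual checks).
// [[Rcpp::export]]
double dd_eval_deriv(NumericVector chi, NumericVector clo, double x, int k) {
  List d = dd_poly_deriv(chi, clo, k);
  NumericVector dhi = d["hi"], dlo = d["lo"];
  dd r = dd_from(0.0), xx = dd_from(x);
  for (int i = dhi.size() - 1; i >= 0; --i)
    r = dd_add(dd_mul(r, xx), {dhi[i], dlo[i]});
  return r.hi + r.lo;
}

// Exact mean-square integral (1/(b-a)) * int_a^b (P(x)-Q(x))^2 dx via
// coefficient convolution and closed-form antidifferentiation.
// [[Rcpp::export]]
double dd_mean_square_diff(NumericVector phi_, NumericVector plo_,
                           NumericVector qhi_, NumericVector qlo_,
                           double a, double b) {
  int n = std::max(phi_.size(), qhi_.size());
  std::vector<dd> d(n, dd_from(0.0));
  for (int i = 0; i < n; ++i) {
    dd pi = (i < phi_.size()) ? dd{phi_[i], plo_[i]} : dd_from(0.0);
    dd qi = (i < qhi_.size()) ? dd{qhi_[i], qlo_[i]} : dd_from(0.0);
    d[i] = dd_sub(pi, qi);
  }
  std::vector<dd> sq(2 * n - 1, dd_from(0.0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      sq[i + j] = dd_add(sq[i + j], dd_mul(d[i], d[j]));
  dd at = dd_from(0.0), bt = dd_from(0.0);
  dd pa = dd_from(a), pb = dd_from(b);
  for (int i = 0; i < (int)sq.size(); ++i) {
    dd c = dd_div(sq[i], dd_from((double)(i + 1)));
    at = dd_add(at, dd_mul(c, pa));
    bt = dd_add(bt, dd_mul(c, pb));
    pa = dd_mul(pa, dd_from(a));
    pb = dd_mul(pb, dd_from(b));
  }
  dd r = dd_div(dd_sub(bt, at), dd_from(b - a));
  return r.hi + r.lo;
}

// Decimal string of hi+lo with the requested number of significant digits
// (used for precision-preserving JSON serialization).
// [[Rcpp::export]]
CharacterVector dd_format(NumericVector hi, NumericVector lo, int digits) {
  int n = hi.size();
  CharacterVector out(n);
  for (int t = 0; t < n; ++t) {
    dd v = {hi[t], lo[t]};
    if (v.hi == 0.0 && v.lo == 0.0) { out[t] = "0"; continue; }
    if (!std::isfinite(v.hi)) { out[t] = "NaN"; continue; }
    bool neg = v.hi < 0.0;
    if (neg) v = dd_neg(v);
    int e = (int)std::floor(std::log10(v.hi));
    dd s = dd_from(1.0);
    if (e >= 0) for (int i = 0; i < e; ++i) s = dd_mul(s, dd_from(10.0));
    else        for (int i = 0; i < -e; ++i) s = dd_div(s, dd_from(10.0));
    // adjust so that s <= v < 10 s
    while (dd_sub(v, dd_mul(s, dd_from(10.0))).hi >= 0.0) {
      s = dd_mul(s, dd_from(10.0));
      ++e;
    }
    while (dd_sub(v, s).hi < 0.0) {
      s = dd_div(s, dd_from(10.0));
      --e;
    }
    std::string mant;
    for (int i = 0; i < digits; ++i) {
      int dig = (int)(v.hi / s.hi);
      if (dig < 0) dig = 0;
      if (dig > 9) dig = 9;
      dd r = dd_sub(v, dd_mul(dd_from((double)dig), s));
      while (r.hi < 0.0 && dig > 0) { --dig; r = dd_sub(v, dd_mul(dd_from((double)dig), s)); }
      while (dig < 9 && dd_sub(r, s).hi >= 0.0) {
        ++dig;
        r = dd_sub(v, dd_mul(dd_from((double)dig), s));
      }
      mant.push_back((char)('0' + dig));
      v = r;
      s = dd_div(s, dd_from(10.0));
    }
    char buf[64];
    std::snprintf(buf, sizeof(buf), "e%d", e - digits + 1);
    std::string res = (neg ? "-" : "") + mant + std::string(buf);
    out[t] = res;
  }
  return out;
}

// Parse decimal strings (plain or scientific) into double-double pairs.
// [[Rcpp::export]]
List dd_parse(CharacterVector s) {
  int n = s.size();
  NumericVector hi(n), lo(n);
  for (int t = 0; t < n; ++t) {
    std::string str = as<std::string>(s[t]);
    size_t i = 0;
    bool neg = false;
    if (i < str.size() && (str[i] == '+' || str[i] == '-')) {
      neg = (str[i] == '-');
      ++i;
    }
    dd v = dd_from(0.0);
    int exp10 = 0;
    bool seen_dot = false;
    for (; i < str.size(); ++i) {
      char c = str[i];
      if (c == '.') { seen_dot = true; continue; }
      if (c == 'e' || c == 'E') {
        int ev = 0, esign = 1;
        size_t j = i + 1;
        if (j < str.size() && (str[j] == '+' || str[j] == '-')) {
          if (str[j] == '-') esign = -1;
          ++j;
        }
        for (; j < str.size() && str[j] >= '0' && str[j] <= '9'; ++j)
          ev = ev * 10 + (str[j] - '0');
        exp10 += esign * ev;
        break;
      }
      if (c < '0' || c > '9') break;
      v = dd_add(dd_mul(v, dd_from(10.0)), dd_from((double)(c - '0')));
      if (seen_dot) exp10 -= 1;
    }
    if (exp10 > 0) for (int j = 0; j < exp10; ++j) v = dd_mul(v, dd_from(10.0));
    if (exp10 < 0) for (int j = 0; j < -exp10; ++j) v = dd_div(v, dd_from(10.0));
    if (neg) v = dd_neg(v);
    hi[t] = v.hi;
    lo[t] = v.lo;
  }
  return List::create(_["hi"] = hi, _["lo"] = lo);
}
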