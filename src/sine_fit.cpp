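#include <Rcpp.h>
#include <cmath>

// Box-constrained least-squares fit of y = a + b*sin(c*x + d) at x = 1..K.
//
// The model is linear in (a, b) once (c, d) are fixed, so the inner
// problem min_{a,b in [-1,1]^2} SSR(a, b | c, d) is a 2-D convex box QP
// solved exactly by KKT enumeration (interior solution plus the four
// clamped edges).  The outer search over (c, d) runs a damped
// Gauss-Newton descent from each of n_starts phase offsets; d is
// periodic so steps wrap instead of clamping, c is projected onto its
// (narrow) box.  Start phases follow the base-2 van der Corput sequence
// so start sets are nested: raising n_starts can only lower the SSR.

namespace {

struct InnerFit {
  double a, b, ssr;
};

// exact min over (a,b) in [-1,1]^2 given the regressor s_k = sin(c*k+d)
InnerFit solve_ab(const double* y, const double* s, int K) {
  double sy = 0.0, ss = 0.0, syy = 0.0, sss = 0.0, sys = 0.0;
  for (int k = 0; k < K; ++k) {
    sy += y[k];
    ss += s[k];
    syy += y[k] * y[k];
    sss += s[k] * s[k];
    sys += y[k] * s[k];
  }
  const double n = static_cast<double>(K);
  // SSR(a,b) expanded; exact for the quadratic
  auto ssr_of = [&](double a, double b) {
    return syy - 2.0 * a * sy - 2.0 * b * sys + 2.0 * a * b * ss +
           a * a * n + b * b * sss;
  };
  auto clamp1 = [](double v) { return v > 1.0 ? 1.0 : (v < -1.0 ? -1.0 : v); };

  const double det = n * sss - ss * ss;
  InnerFit best;
  best.a = clamp1(sy / n);
  best.b = 0.0;
  best.ssr = ssr_of(best.a, 0.0);

  if (det > 1e-12) {
    double b0 = (n * sys - ss * sy) / det;
    double a0 = (sy - b0 * ss) / n;
    if (std::fabs(a0) <= 1.0 && std::fabs(b0) <= 1.0) {
      double v = ssr_of(a0, b0);
      if (v < best.ssr) { best.a = a0; best.b = b0; best.ssr = v; }
    } else {
      // minimum lies on the box boundary: four clamped edges
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double bf = static_cast<double>(sgn);            // b fixed at +-1
        double ae = clamp1((sy - bf * ss) / n);
        double v = ssr_of(ae, bf);
        if (v < best.ssr) { best.a = ae; best.b = bf; best.ssr = v; }
        double af = static_cast<double>(sgn);            // a fixed at +-1
        double be = sss > 0.0 ? clamp1((sys - af * ss) / sss) : 0.0;
        v = ssr_of(af, be);
        if (v < best.ssr) { best.a = af; best.b = be; best.ssr = v; }
      }
    }
  }
  if (best.ssr < 0.0) best.ssr = 0.0;  // guard against tiny cancellation
  return best;
}

double wrap_pi(double d) {
  // wrap into [-pi, pi); the objective is 2*pi-periodic in d
  return d - 2.0 * M_PI * std::floor((d + M_PI) / (2.0 * M_PI));
}

double eval_cd(const double* y, int K, double c, double d, double* s,
               InnerFit* fit) {
  for (int k = 0; k < K; ++k) s[k] = std::sin(c * (k + 1) + d);
  *fit = solve_ab(y, s, K);
  return fit->ssr;
}

// base-2 van der Corput sequence (radical inverse), i >= 1
double vdc2(int i) {
  double v = 0.0, base = 0.5;
  while (i > 0) {
    v += base * (i & 1);
    i >>= 1;
    base *= 0.5;
  }
  return v;
}

struct FitResult {
  double a, b, c, d, ssr;
  int converged;
};

// golden-section minimisation of the concentrated objective along one
// coordinate; deterministic, tolerance in the parameter
template <typename F>
double golden_min(F g, double lo, double hi, double tol_x) {
  const double gr = 0.6180339887498949;
  double x1 = hi - gr * (hi - lo);
  double x2 = lo + gr * (hi - lo);
  double f1 = g(x1), f2 = g(x2);
  while (hi - lo > tol_x) {
    if (f1 <= f2) {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo); f1 = g(x1);
    } else {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo); f2 = g(x2);
    }
  }
  return f1 <= f2 ? x1 : x2;
}

struct StartRes {
  double c, d, ssr;
  bool conv;
};

// projected gradient norm of the concentrated objective at (c, d)
double proj_grad(const double* y, int K, double c, double d, double c_lo,
                 double c_hi, double* s) {
  InnerFit in;
  eval_cd(y, K, c, d, s, &in);
  double r1 = 0.0, r2 = 0.0;
  for (int k = 0; k < K; ++k) {
    double x = static_cast<double>(k + 1);
    double res = y[k] - in.a - in.b * s[k];
    double cs = std::cos(c * x + d);
    r1 += -in.b * x * cs * res;
    r2 += -in.b * cs * res;
  }
  const double eps = 1e-6 * (c_hi - c_lo);
  if ((c <= c_lo + eps && r1 > 0.0) || (c >= c_hi - eps && r1 < 0.0))
    r1 = 0.0;
  return std::sqrt(r1 * r1 + r2 * r2);
}

FitResult fit_one(const double* y, int K, double c_lo, double c_hi,
                  int n_starts, int max_iter, double tol) {
  std::vector<double> s(K);
  const double c_mid = 0.5 * (c_lo + c_hi);

  FitResult best;
  best.ssr = R_PosInf;
  best.converged = 0;
  std::vector<StartRes> runs;
  runs.reserve(n_starts);

  for (int st = 1; st <= n_starts; ++st) {
    // the concentrated objective is pi-periodic in d (b -> -b absorbs a
    // half-turn), so phase starts cover [-pi/2, pi/2); frequency starts
    // cycle over the bound midpoint and the two bounds
    double d = -0.5 * M_PI + M_PI * vdc2(st);
    double c = (st % 3 == 1) ? c_mid : ((st % 3 == 2) ? c_lo : c_hi);
    InnerFit in;
    double ssr = eval_cd(y, K, c, d, s.data(), &in);
    double lambda = 1e-3;
    bool conv = false;
    int small_steps = 0;

    for (int it = 0; it < max_iter; ++it) {
      // residuals and Jacobian wrt (c, d) at the concentrated (a, b)
      double g11 = 0.0, g12 = 0.0, g22 = 0.0, r1 = 0.0, r2 = 0.0;
      for (int k = 0; k < K; ++k) {
        double x = static_cast<double>(k + 1);
        double res = y[k] - in.a - in.b * s[k];
        double cs = std::cos(c * x + d);
        double jc = -in.b * x * cs;
        double jd = -in.b * cs;
        g11 += jc * jc;
        g12 += jc * jd;
        g22 += jd * jd;
        r1 += jc * res;
        r2 += jd * res;
      }
      // projected gradient: at an active c bound only the feasible
      // direction counts; d is periodic, never bound
      double pg1 = r1;
      if ((c <= c_lo && r1 > 0.0) || (c >= c_hi && r1 < 0.0)) pg1 = 0.0;
      double grad_norm = std::sqrt(pg1 * pg1 + r2 * r2);
      if (grad_norm < 1e-12) { conv = true; break; }

      bool accepted = false;
      double drop = 0.0;
      // joint damped Gauss-Newton step, c projected onto its box
      for (int tries = 0; tries < 20 && !accepted; ++tries) {
        double a11 = g11 + lambda, a22 = g22 + lambda;
        double det = a11 * a22 - g12 * g12;
        if (det <= 0.0) { lambda *= 4.0; continue; }
        double dc = -(a22 * r1 - g12 * r2) / det;
        double dd = -(a11 * r2 - g12 * r1) / det;
        double c_new = c + dc;
        if (c_new < c_lo) c_new = c_lo;
        if (c_new > c_hi) c_new = c_hi;
        double d_new = wrap_pi(d + dd);
        InnerFit in_new;
        double ssr_new = eval_cd(y, K, c_new, d_new, s.data(), &in_new);
        if (ssr_new < ssr) {
          drop = ssr - ssr_new;
          c = c_new; d = d_new; in = in_new; ssr = ssr_new;
          lambda = std::max(lambda * 0.1, 1e-12);
          accepted = true;
        } else {
          lambda *= 4.0;
          if (lambda > 1e10) break;
        }
      }
      // fallback when the projected joint step stalls (typically with c
      // pinned at a bound): backtracking Newton steps along d, then c
      if (!accepted && g22 > 0.0) {
        double step = -r2 / g22;
        for (int h = 0; h < 25 && !accepted; ++h, step *= 0.5) {
          InnerFit in_new;
          double d_new = wrap_pi(d + step);
          double ssr_new = eval_cd(y, K, c, d_new, s.data(), &in_new);
          if (ssr_new < ssr) {
            drop = ssr - ssr_new;
            d = d_new; in = in_new; ssr = ssr_new;
            accepted = true;
          }
        }
      }
      if (!accepted && g11 > 0.0) {
        double step = -r1 / g11;
        for (int h = 0; h < 25 && !accepted; ++h, step *= 0.5) {
          double c_new = c + step;
          if (c_new < c_lo) c_new = c_lo;
          if (c_new > c_hi) c_new = c_hi;
          if (c_new == c) break;
          InnerFit in_new;
          double ssr_new = eval_cd(y, K, c_new, d, s.data(), &in_new);
          if (ssr_new < ssr) {
            drop = ssr - ssr_new;
            c = c_new; in = in_new; ssr = ssr_new;
            accepted = true;
          }
        }
      }
      if (!accepted) { conv = true; break; }  // no descent direction left
      // three consecutive negligible improvements count as converged; the
      // golden-section polish below supplies the final refinement
      if (drop < tol) {
        if (++small_steps >= 3) { conv = true; break; }
      } else {
        small_steps = 0;
      }
    }
    runs.push_back({c, d, ssr, conv});
  }

  // polish the leading runs: Gauss-Newton can stall a hair short of the
  // valley floor when c is pinned at a bound, so refine the runs within
  // 0.01 SSR of the raw best by coordinate-wise golden section. Runs that
  // landed in an already-polished basin (same c and same d modulo pi, the
  // b-sign symmetry) are skipped.
  double best_raw = R_PosInf;
  for (const StartRes& r : runs) best_raw = std::min(best_raw, r.ssr);
  InnerFit in;
  std::vector<StartRes> polished;
  for (StartRes& r : runs) {
    bool duplicate = false;
    for (const StartRes& p : polished) {
      double dd = std::fabs(r.d - p.d);
      dd -= M_PI * std::floor(dd / M_PI);   // into [0, pi)
      dd = std::min(dd, M_PI - dd);
      if (dd < 1e-3 && std::fabs(r.c - p.c) < 1e-4) {
        duplicate = true;
        if (p.conv) r.conv = true;
        break;
      }
    }
    if (!duplicate && r.ssr <= best_raw + 0.01) {
      double c = r.c, d = r.d;
      for (int round = 0; round < 3; ++round) {
        d = golden_min(
            [&](double dd) { return eval_cd(y, K, c, dd, s.data(), &in); },
            d - 0.35, d + 0.35, 1e-9);
        c = golden_min(
            [&](double cc) { return eval_cd(y, K, cc, d, s.data(), &in); },
            c_lo, c_hi, 1e-10);
        // golden section cannot return an endpoint; snap when a bound wins
        double g_c = eval_cd(y, K, c, d, s.data(), &in);
        if (eval_cd(y, K, c_lo, d, s.data(), &in) <= g_c) c = c_lo;
        else if (eval_cd(y, K, c_hi, d, s.data(), &in) <= g_c) c = c_hi;
      }
      double ssr = eval_cd(y, K, c, wrap_pi(d), s.data(), &in);
      if (ssr < r.ssr) { r.c = c; r.d = wrap_pi(d); r.ssr = ssr; }
      if (!r.conv) {
        // a run that hit the iteration cap counts as converged once the
        // polished point is stationary
        r.conv = proj_grad(y, K, r.c, r.d, c_lo, c_hi, s.data()) < 1e-6;
      }
      polished.push_back(r);
    }
    if (r.conv) best.converged += 1;
    if (r.ssr < best.ssr) {
      eval_cd(y, K, r.c, r.d, s.data(), &in);
      best.a = in.a; best.b = in.b; best.c = r.c; best.d = r.d;
      best.ssr = in.ssr;
    }
  }

  // canonical sign: b >= 0 via the identity b -> -b, d -> d + pi
  if (best.b < 0.0) {
    best.b = -best.b;
    best.d = wrap_pi(best.d + M_PI);
  }
  return best;
}

}  // namespace

//' @name sine_fit_batch_cpp
//' @title Batch constrained sinusoid fits (internal)
//' @description Fits y = a + b*sin(c*x + d), x = 1..K, to each row of
//'   \code{Y} with a, b in \[-1, 1\], c in \[c_lo, c_hi\], d free in phase,
//'   minimising the residual sum of squares by multi-start damped
//'   Gauss-Newton over (c, d) with the exact box-constrained inner solve
//'   for (a, b).
//' @param Y numeric matrix, one profile per row
//' @param c_lo,c_hi angular-frequency bounds (radians per position)
//' @param n_starts number of deterministic phase starts
//' @param max_iter iteration cap per start
//' @param tol stop when the SSR improvement of an accepted step falls below this
//' @return matrix with columns a, b, c, d, ssr, sfi, n_converged
//' @keywords internal
// [[Rcpp::export]]
Rcpp::NumericMatrix sine_fit_batch_cpp(Rcpp::NumericMatrix Y, double c_lo,
                                       double c_hi, int n_starts,
                                       int max_iter, double tol) {
  const int n = Y.nrow(), K = Y.ncol();
  if (K < 2) Rcpp::stop("profiles must have at least 2 points");
  if (n_starts < 1) Rcpp::stop("n_starts must be >= 1");
  if (!(c_lo > 0.0) || !(c_hi >= c_lo))
    Rcpp::stop("invalid frequency bounds");

  Rcpp::NumericMatrix out(n, 7);
  std::vector<double> y(K);
  for (int i = 0; i < n; ++i) {
    double mean = 0.0;
    for (int k = 0; k < K; ++k) { y[k] = Y(i, k); mean += y[k]; }
    mean /= K;
    double tss = 0.0;
    for (int k = 0; k < K; ++k) tss += (y[k] - mean) * (y[k] - mean);

    FitResult f = fit_one(y.data(), K, c_lo, c_hi, n_starts, max_iter, tol);
    out(i, 0) = f.a;
    out(i, 1) = f.b;
    out(i, 2) = f.c;
    out(i, 3) = f.d;
    out(i, 4) = f.ssr;
    out(i, 5) = tss > 0.0 ? f.ssr / tss : NA_REAL;
    out(i, 6) = f.converged;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  Rcpp::colnames(out) = Rcpp::CharacterVector::create(
      "a", "b", "c", "d", "ssr", "sfi", "n_converged");
  return out;
}
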