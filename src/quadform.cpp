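// Tail probabilities of (noncentral) weighted sums of 1-df chi-squares and
// the SKAT-O minimum-p null, used by the gene-based tests.
//
// P(sum_j lambda_j * chisq_1(delta_j^2) > q) is computed by numerical
// inversion of the characteristic function (Imhof's formula).  The
// oscillatory inversion integrand is marched in sub-half-period panels with
// Gauss-Legendre quadrature; with five or more eigenvalues the envelope
// decays fast and marching stops on a per-lobe tail bound, while few-
// eigenvalue (slowly decaying) integrands switch to exact zero-crossing
// segmentation with iterated-averaging acceleration of the alternating
// series.  Deep tails use a Lugannani-Rice saddlepoint (screened by a cheap
// Liu-type moment estimate), and the Liu approximation is the last-resort
// fallback as well as the starting point for quantile inversion.
//
// SKAT-O has two routes: the default conditions exactly on the burden
// component (the SKAT part is then an exact noncentral quadratic form and
// the p-value a one-dimensional adaptive integral), and a moment-matched
// route in the canonical variance-adjusted style for large replication
// loops.

#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct GLRule {
  std::vector<double> x, w;  // nodes/weights on [-1, 1]
};

GLRule gl_rule(int n) {
  GLRule g;
  g.x.assign(n, 0.0);
  g.w.assign(n, 0.0);
  for (int i = 0; i < (n + 1) / 2; ++i) {
    double x = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p2 = p1;
        p1 = p0;
        p0 = ((2.0 * j + 1.0) * x * p1 - j * p2) / (j + 1.0);
      }
      pp = n * (x * p0 - p1) / (x * x - 1.0);
      double dx = p0 / pp;
      x -= dx;
      if (std::fabs(dx) < 1e-15) break;
    }
    g.x[i] = -x;
    g.x[n - 1 - i] = x;
    double w = 2.0 / ((1.0 - x * x) * pp * pp);
    g.w[i] = w;
    g.w[n - 1 - i] = w;
  }
  return g;
}

const GLRule GL12 = gl_rule(12);
const GLRule GL20 = gl_rule(20);
const GLRule GL64 = gl_rule(64);

struct QF {
  arma::vec lam;   // positive eigenvalues
  arma::vec d2;    // noncentralities delta_j^2 (0 for central)
  double q;

  double theta(double u) const {
    double s = 0.0;
    for (arma::uword j = 0; j < lam.n_elem; ++j) {
      double lu = lam[j] * u;
      s += std::atan(lu) + d2[j] * lu / (1.0 + lu * lu);
    }
    return 0.5 * s - 0.5 * q * u;
  }
  double dtheta(double u) const {
    double s = 0.0;
    for (arma::uword j = 0; j < lam.n_elem; ++j) {
      double l2u2 = lam[j] * u * lam[j] * u;
      double den = 1.0 + l2u2;
      s += lam[j] / den + d2[j] * lam[j] * (1.0 - l2u2) / (den * den);
    }
    return 0.5 * s - 0.5 * q;
  }
  double logrho(double u) const {
    double s = 0.0;
    for (arma::uword j = 0; j < lam.n_elem; ++j) {
      double lu = lam[j] * u;
      double lu2 = lu * lu;
      s += 0.25 * std::log1p(lu2) + 0.5 * d2[j] * lu2 / (1.0 + lu2);
    }
    return s;
  }
  double g(double u) const {
    if (u <= 0.0) {
      double s = 0.0;
      for (arma::uword j = 0; j < lam.n_elem; ++j)
        s += lam[j] * (1.0 + d2[j]);
      return 0.5 * (s - q);
    }
    return std::sin(theta(u)) * std::exp(-logrho(u)) / u;
  }
  double panel(const GLRule& gl, double a, double b) const {
    double mid = 0.5 * (a + b), half = 0.5 * (b - a), s = 0.0;
    for (size_t i = 0; i < gl.x.size(); ++i)
      s += gl.w[i] * g(mid + half * gl.x[i]);
    return s * half;
  }
  // bound on the remaining integral beyond u from the envelope decay
  double env_tail_bound(double u) const {
    int m = 0;
    for (arma::uword j = 0; j < lam.n_elem; ++j)
      if (lam[j] * u >= 1.0) ++m;
    if (m < 2) return R_PosInf;
    return std::exp(0.25 * m * std::log(2.0) - logrho(u)) * 2.0 / m;
  }
};

// iterated averaging of the tail partial sums of an alternating series
double accelerate(const std::vector<double>& psums, double* err) {
  size_t n = psums.size();
  std::vector<double> s(psums);
  double last = s[n - 1];
  *err = std::fabs(last);
  while (s.size() > 1) {
    for (size_t i = 0; i + 1 < s.size(); ++i) s[i] = 0.5 * (s[i] + s[i + 1]);
    s.pop_back();
    double cur = s[s.size() - 1];
    *err = std::fabs(cur - last);
    last = cur;
    if (*err < 1e-17) break;
  }
  return last;
}

// fast marching for well-decaying integrands (>= 5 eigenvalues): no zero
// bookkeeping; stops when one full oscillation lobe is below tolerance
double imhof_march(const QF& f, double accI, int* status) {
  *status = 0;
  double sumlam = 0.0, lammax = 0.0;
  for (arma::uword j = 0; j < f.lam.n_elem; ++j) {
    sumlam += f.lam[j] * (1.0 + f.d2[j]);
    lammax = std::max(lammax, f.lam[j]);
  }
  const double qh = std::max(0.5 * f.q, 1e-3 * (sumlam + f.q));
  double total = 0.0, u = 0.0;
  const int max_panels = 20000;
  for (int k = 0; k < max_panels; ++k) {
    double dth = f.dtheta(u);
    double h = 0.5 * M_PI / std::max(std::fabs(dth), qh);
    h = std::min(h, 0.6 * u + 0.5 / (lammax + qh));
    total += f.panel(GL12, u, u + h);
    u += h;
    if ((k & 1) == 0) {
      if (f.env_tail_bound(u) < accI) return total;
      double dth2 = f.dtheta(u);
      if (dth2 < -0.2 * qh) {
        // past the phase peak: tail bounded by the next oscillation lobe
        double lobe = 2.0 / (u * std::exp(f.logrho(u)) *
                             std::max(std::fabs(dth2), qh));
        if (lobe < 0.5 * accI) return total;
      }
    }
  }
  *status = 1;
  return total;
}

// careful path for slowly decaying integrands (few eigenvalues): exact
// zero-crossing segments, alternating-series stopping and acceleration
double imhof_careful(const QF& f, double accI, int* status) {
  *status = 0;
  double sumlam = 0.0, lammax = 0.0;
  for (arma::uword j = 0; j < f.lam.n_elem; ++j) {
    sumlam += f.lam[j] * (1.0 + f.d2[j]);
    lammax = std::max(lammax, f.lam[j]);
  }
  const double qh = std::max(0.5 * f.q, 1e-3 * (sumlam + f.q));
  double total = 0.0, u = 0.0, term = 0.0;
  int kfloor = 0;
  std::vector<double> tail_psums;
  double tail_base = 0.0;
  int nterms = 0, sign_prev = 0, nalt = 0;
  bool tracking = false;

  const int max_steps = 400000;
  for (int step = 0; step < max_steps; ++step) {
    double dth = f.dtheta(u);
    double h = 0.25 * M_PI / std::max(std::fabs(dth), qh);
    h = std::min(h, 0.5 * u + 0.5 / (lammax + qh));
    double unew = u + h;
    double thnew = f.theta(unew);
    int knew = (int)std::floor(thnew / M_PI);
    if (knew != kfloor) {
      double level = (knew > kfloor ? (kfloor + 1) : kfloor) * M_PI;
      double lo = u, hi = unew;
      for (int it = 0; it < 40; ++it) {
        double mid = 0.5 * (lo + hi);
        double tm = f.theta(mid);
        bool below = (knew > kfloor) ? (tm < level) : (tm > level);
        if (below) lo = mid; else hi = mid;
        if (hi - lo < 1e-12 * (1.0 + hi)) break;
      }
      double uz = 0.5 * (lo + hi);
      double piece = f.panel(GL20, u, uz);
      term += piece;
      total += piece;
      ++nterms;
      int sgn = (term > 0) - (term < 0);
      if (sign_prev != 0 && sgn == -sign_prev) ++nalt; else nalt = 0;
      sign_prev = sgn;
      if (!tracking && nalt >= 3) {
        tracking = true;
        tail_base = total;
        tail_psums.clear();
        tail_psums.push_back(0.0);
      } else if (tracking) {
        tail_psums.push_back(total - tail_base);
        if (tail_psums.size() > 160)
          tail_psums.erase(tail_psums.begin(),
                           tail_psums.begin() + (tail_psums.size() - 160));
      }
      if (nalt >= 2 && std::fabs(term) < 0.25 * accI) return total;
      if (tracking && tail_psums.size() >= 12 && nterms % 4 == 0) {
        double err;
        double lim = accelerate(tail_psums, &err);
        if (err < 0.25 * accI) return tail_base + lim;
      }
      term = 0.0;
      u = uz;
      kfloor += (knew > kfloor) ? 1 : -1;
      continue;
    }
    double piece = f.panel(GL20, u, unew);
    term += piece;
    total += piece;
    u = unew;
    kfloor = knew;
    if (u > 1.0 / (lammax + 1e-300) && f.env_tail_bound(u) < accI)
      return total;
  }
  if (tracking && tail_psums.size() >= 6) {
    double err;
    double lim = accelerate(tail_psums, &err);
    if (err < 10.0 * accI) return tail_base + lim;
  }
  *status = 1;
  return total;
}

// Lugannani-Rice saddlepoint survival probability
double saddlepoint_sf(const arma::vec& lam, const arma::vec& d2, double q,
                      int* status) {
  *status = 0;
  double lammax = lam.max();
  double zhi = 0.5 / lammax;
  double mean = 0.0;
  for (arma::uword j = 0; j < lam.n_elem; ++j) mean += lam[j] * (1.0 + d2[j]);
  if (std::fabs(q - mean) < 1e-10 * (1.0 + mean)) return 0.5;
  auto Kp = [&](double z) {
    double s = 0.0;
    for (arma::uword j = 0; j < lam.n_elem; ++j) {
      double den = 1.0 - 2.0 * z * lam[j];
      s += lam[j] / den + d2[j] * lam[j] / (den * den);
    }
    return s;
  };
  double lo, hi;
  if (q > mean) {
    lo = 0.0;
    hi = zhi * (1.0 - 1e-12);
    for (int it = 0; it < 200 && Kp(hi) < q; ++it)
      hi = zhi - (zhi - hi) * 0.1;
  } else {
    hi = 0.0;
    lo = -1.0 / lammax;
    for (int it = 0; it < 400 && Kp(lo) > q; ++it) lo *= 2.0;
    if (Kp(lo) > q) { *status = 1; return NA_REAL; }
  }
  double zr = 0.5 * (lo + hi);
  for (int it = 0; it < 200; ++it) {
    zr = 0.5 * (lo + hi);
    if (Kp(zr) < q) lo = zr; else hi = zr;
    if (hi - lo < 1e-15 * (1.0 + std::fabs(zr))) break;
  }
  double K = 0.0, K2 = 0.0;
  for (arma::uword j = 0; j < lam.n_elem; ++j) {
    double den = 1.0 - 2.0 * zr * lam[j];
    K += -0.5 * std::log(den) + d2[j] * lam[j] * zr / den;
    K2 += 2.0 * lam[j] * lam[j] / (den * den) +
          4.0 * d2[j] * lam[j] * lam[j] / (den * den * den);
  }
  double arg = 2.0 * (zr * q - K);
  if (arg < 0) arg = 0;
  double w = (zr >= 0 ? 1.0 : -1.0) * std::sqrt(arg);
  double v = zr * std::sqrt(K2);
  if (std::fabs(w) < 1e-8) return 0.5;
  double z = w + std::log(v / w) / w;
  return R::pnorm(z, 0.0, 1.0, 0, 0);
}

// Liu-type moment matching (kurtosis-matched variant)
struct LiuPar {
  double muQ, sigmaQ, muX, sigmaX, df, ncp;
};

LiuPar liu_params(const arma::vec& lam, const arma::vec& d2) {
  double c1 = 0, c2 = 0, c3 = 0, c4 = 0;
  for (arma::uword j = 0; j < lam.n_elem; ++j) {
    double l = lam[j], l2 = l * l;
    double dd = (d2.n_elem > j) ? d2[j] : 0.0;
    c1 += l * (1.0 + dd);
    c2 += l2 * (1.0 + 2.0 * dd);
    c3 += l2 * l * (1.0 + 3.0 * dd);
    c4 += l2 * l2 * (1.0 + 4.0 * dd);
  }
  double s1 = c3 / std::pow(c2, 1.5), s2 = c4 / (c2 * c2);
  double a, df, ncp;
  if (s1 * s1 > s2) {
    a = 1.0 / (s1 - std::sqrt(s1 * s1 - s2));
    ncp = s1 * a * a * a - a * a;
    df = a * a - 2.0 * ncp;
  } else {
    df = 1.0 / s2;
    a = std::sqrt(df);
    ncp = 0.0;
  }
  LiuPar p;
  p.muQ = c1;
  p.sigmaQ = std::sqrt(2.0 * c2);
  p.muX = df + ncp;
  p.sigmaX = std::sqrt(2.0 * df + 4.0 * ncp);
  p.df = df;
  p.ncp = ncp;
  return p;
}

double liu_sf_par(const LiuPar& p, double q) {
  double x = (q - p.muQ) / p.sigmaQ * p.sigmaX + p.muX;
  return R::pnchisq(x, p.df, p.ncp, 0, 0);
}

double liu_sf(const arma::vec& lam, const arma::vec& d2, double q) {
  return liu_sf_par(liu_params(lam, d2), q);
}

double liu_quantile_upper(const arma::vec& lam, double pu) {
  LiuPar p = liu_params(lam, arma::vec());
  double x = R::qnchisq(pu, p.df, p.ncp, 0, 0);
  return (x - p.muX) / p.sigmaX * p.sigmaQ + p.muQ;
}

// survival function with special cases and fallbacks; method:
// 0 closed form, 1 imhof, 2 saddlepoint, 3 liu
double qf_sf(const arma::vec& lam_in, const arma::vec& d2_in, double q,
             double acc, int* method) {
  *method = 0;
  arma::uvec keep = arma::find(lam_in > 0.0);
  arma::vec lam = lam_in.elem(keep);
  arma::vec d2 = (d2_in.n_elem == lam_in.n_elem)
                     ? arma::vec(d2_in.elem(keep))
                     : arma::vec(keep.n_elem, arma::fill::zeros);
  if (lam.n_elem == 0) Rcpp::stop("no positive eigenvalues");
  if (q <= 0.0) return 1.0;
  double ncp = arma::accu(d2);
  if (lam.n_elem == 1)
    return R::pnchisq(q / lam[0], 1.0, d2[0], 0, 0);
  if (lam.max() - lam.min() < 1e-12 * lam.max())
    return R::pnchisq(q / lam[0], (double)lam.n_elem, ncp, 0, 0);
  // compress negligible eigenvalues: drop the smallest ones and absorb
  // their mean into q; the residual error is second order (half the
  // dropped variance times the density slope) and kept far below acc
  if (lam.n_elem > 8) {
    arma::uvec ord = arma::sort_index(lam);
    double var_budget =
        std::max(acc, 1e-12) * 2.0 * arma::accu(lam % lam) / 75.0;
    double lmax = lam.max();
    double drop_mean = 0.0, drop_var = 0.0;
    arma::uword ndrop = 0;
    for (arma::uword k = 0; k < ord.n_elem - 2; ++k) {
      arma::uword j = ord[k];
      double dv = drop_var + 2.0 * lam[j] * lam[j] * (1.0 + 2.0 * d2[j]);
      if (lam[j] > 0.01 * lmax || dv > var_budget) break;
      drop_var = dv;
      drop_mean += lam[j] * (1.0 + d2[j]);
      ++ndrop;
    }
    if (ndrop > 0) {
      arma::uvec keep2 = ord.subvec(ndrop, ord.n_elem - 1);
      lam = lam.elem(keep2);
      d2 = d2.elem(keep2);
      q = std::max(q - drop_mean, 0.0);
      if (q <= 0.0) return 1.0;
      ncp = arma::accu(d2);
      if (lam.n_elem == 1) return R::pnchisq(q / lam[0], 1.0, d2[0], 0, 0);
      if (lam.max() - lam.min() < 1e-12 * lam.max())
        return R::pnchisq(q / lam[0], (double)lam.n_elem, ncp, 0, 0);
    }
  }
  // deep-tail screen: inversion would suffer cancellation there anyway
  double pl = liu_sf(lam, d2, q);
  if (pl < 0.02 * std::max(acc, 1e-12)) {
    int st2 = 0;
    double ps = saddlepoint_sf(lam, d2, q, &st2);
    if (st2 == 0 && R_finite(ps)) {
      *method = 2;
      return std::max(ps, 1e-300);
    }
  }
  QF f;
  f.lam = lam;
  f.d2 = d2;
  f.q = q;
  int st = 0;
  double I = (lam.n_elem >= 5) ? imhof_march(f, M_PI * acc, &st)
                               : imhof_careful(f, M_PI * acc, &st);
  double p = 0.5 + I / M_PI;
  *method = 1;
  if (st == 0 && p > 1e-10 && p < 1.0 - 1e-12) return std::min(p, 1.0);
  if (st == 0 && p >= 1.0 - 1e-12) return 1.0;
  int st2 = 0;
  double ps = saddlepoint_sf(lam, d2, q, &st2);
  if (st2 == 0 && R_finite(ps)) {
    *method = 2;
    return std::max(ps, 1e-300);
  }
  *method = 3;
  return std::max(liu_sf(lam, d2, q), 1e-300);
}

// upper-tail quantile: secant iteration on log p (nearly linear in q),
// safeguarded by a bracket; absolute accuracy of each evaluation is tied
// to the target tail probability
double qf_quantile_upper(const arma::vec& lam, double pu, double acc) {
  arma::vec d2;
  int meth;
  double accq = std::max(1e-12, std::min(acc, 2e-4 * pu));
  const double lpu = std::log(pu);
  double x0 = liu_quantile_upper(lam, pu);
  if (!R_finite(x0) || x0 <= 0) x0 = arma::accu(lam);
  double p0 = qf_sf(lam, d2, x0, accq, &meth);
  // bracket [xlo, xhi] with p(xlo) >= pu >= p(xhi)
  double xlo, xhi, plo, phi_;
  if (p0 >= pu) {
    xlo = x0; plo = p0;
    xhi = x0; phi_ = p0;
    for (int it = 0; it < 200 && phi_ > pu; ++it) {
      xhi *= 1.6;
      phi_ = qf_sf(lam, d2, xhi, accq, &meth);
    }
  } else {
    xhi = x0; phi_ = p0;
    xlo = x0; plo = p0;
    for (int it = 0; it < 200 && plo < pu; ++it) {
      xlo *= 0.6;
      if (xlo < 1e-300) { xlo = 0.0; plo = 1.0; break; }
      plo = qf_sf(lam, d2, xlo, accq, &meth);
    }
  }
  double xa = xlo, fa = std::log(std::max(plo, 1e-300)) - lpu;
  double xb = xhi, fb = std::log(std::max(phi_, 1e-300)) - lpu;
  for (int it = 0; it < 60; ++it) {
    if (std::fabs(fb) < 3e-4 || xb - xa < 1e-9 * (1.0 + xb)) break;
    double xm;
    if (std::fabs(fb - fa) > 1e-14) {
      xm = xb - fb * (xb - xa) / (fb - fa);
      if (!(xm > xlo && xm < xhi)) xm = 0.5 * (xlo + xhi);
    } else {
      xm = 0.5 * (xlo + xhi);
    }
    double pm = qf_sf(lam, d2, xm, accq, &meth);
    double fm = std::log(std::max(pm, 1e-300)) - lpu;
    if (pm >= pu) { xlo = xm; } else { xhi = xm; }
    xa = xb; fa = fb;
    xb = xm; fb = fm;
  }
  return xb;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".qf_sf_cpp")]]
List qf_sf_cpp(double q, arma::vec lambda, arma::vec delta2, double acc) {
  if (delta2.n_elem == 0) delta2.zeros(lambda.n_elem);
  if (delta2.n_elem != lambda.n_elem)
    stop("lambda and delta2 lengths differ");
  int method = 0;
  double p = qf_sf(lambda, delta2, q, acc, &method);
  p = std::min(1.0, std::max(p, 1e-300));
  return List::create(_["p"] = p, _["method"] = method);
}

//' @noRd
// [[Rcpp::export(name = ".qf_quantile_cpp")]]
double qf_quantile_cpp(double p_upper, arma::vec lambda, double acc) {
  return qf_quantile_upper(lambda, p_upper, acc);
}

// adaptive Simpson used for the SKAT-O conditional integral
namespace {

template <class F>
double simpson_rec(const F& f, double a, double fa, double b, double fb,
                   double m, double fm, double whole, double tol, int depth) {
  double lm = 0.5 * (a + m), rm = 0.5 * (m + b);
  double flm = f(lm), frm = f(rm);
  double left = (m - a) / 6.0 * (fa + 4.0 * flm + fm);
  double right = (b - m) / 6.0 * (fm + 4.0 * frm + fb);
  double diff = left + right - whole;
  if (depth <= 0 || std::fabs(diff) < 15.0 * tol)
    return left + right + diff / 15.0;
  return simpson_rec(f, a, fa, m, fm, lm, flm, left, 0.5 * tol, depth - 1) +
         simpson_rec(f, m, fm, b, fb, rm, frm, right, 0.5 * tol, depth - 1);
}

template <class F>
double adaptive_simpson(const F& f, double a, double b, double tol,
                        int init_panels) {
  double total = 0.0;
  double h = (b - a) / init_panels;
  for (int i = 0; i < init_panels; ++i) {
    double x0 = a + i * h, x1 = x0 + h, xm = 0.5 * (x0 + x1);
    double f0 = f(x0), f1 = f(x1), fm = f(xm);
    double whole = (x1 - x0) / 6.0 * (f0 + 4.0 * fm + f1);
    total += simpson_rec(f, x0, f0, x1, f1, xm, fm, whole,
                         tol / init_panels, 16);
  }
  return total;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".skato_cpp")]]
List skato_cpp(arma::mat Sigma, double Qskat, double Qbt, arma::vec rho,
               double acc, bool fast) {
  const arma::uword M = Sigma.n_rows;
  const arma::uword nr = rho.n_elem;

  // work in the (reduced) eigenbasis of Sigma: all subsequent
  // eigenproblems are r x r with r the numerical rank
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, Sigma);
  double evmax = eval.max();
  if (evmax <= 0) stop("degenerate weighted covariance");
  double thr = (fast ? 1e-7 : 1e-12) * evmax;
  arma::uvec idx = arma::find(eval > thr);
  arma::vec lamS = eval.elem(idx);                  // r eigenvalues
  arma::mat Vr = evec.cols(idx);
  arma::vec ones(M, arma::fill::ones);
  arma::vec u1 = Vr.t() * ones;
  arma::vec stil = arma::sqrt(lamS) % u1;           // Sigma^{1/2} 1 in basis
  double psi = arma::dot(stil, stil);               // 1' Sigma 1
  const arma::uword r = lamS.n_elem;

  // per-rho p-values
  arma::vec prho(nr), Qrho(nr);
  std::vector<arma::vec> lam_rho(nr);
  int meth;
  for (arma::uword i = 0; i < nr; ++i) {
    double rr_ = rho[i];
    Qrho[i] = (1.0 - rr_) * Qskat + rr_ * Qbt;
    arma::mat B = rr_ * (stil * stil.t());
    B.diag() += (1.0 - rr_) * lamS;
    arma::vec lv;
    arma::eig_sym(lv, B);
    arma::uvec keep = arma::find(lv > 1e-10 * lv.max());
    lam_rho[i] = lv.elem(keep);
    prho[i] = qf_sf(lam_rho[i], arma::vec(), Qrho[i], acc, &meth);
  }
  double T = prho.min();
  double pcap = std::min(1.0, (double)nr * T);

  // rank-one or burden-degenerate cases: all rho give the same test
  if (r <= 1 || psi <= 1e-12 * arma::accu(lamS)) {
    return List::create(_["p"] = T, _["pmin"] = T, _["p_rho"] = prho,
                        _["route"] = "rank1");
  }

  // integration limit from the rho = 1 (pure burden) constraint
  double ximax = 8.5;
  bool has_rho1 = false;
  for (arma::uword i = 0; i < nr; ++i)
    if (rho[i] >= 1.0 - 1e-12) {
      has_rho1 = true;
      double q1 = psi * R::qchisq(T, 1.0, 0, 0);
      ximax = std::min(ximax, std::sqrt(q1 / psi));
    }

  // SKAT component conditional on the burden score: eigenstructure of
  // C = Sigma - Sigma 1 1' Sigma / psi, expressed in the reduced basis
  // (Sigma 1 has coordinates lamS % u1)
  arma::vec g1 = lamS % u1;
  arma::mat C = -(g1 * g1.t()) / psi;
  C.diag() += lamS;
  arma::vec dC;
  arma::mat VC;
  arma::eig_sym(dC, VC, C);
  double dmax = dC.max();
  arma::uvec kd = arma::find(dC > 1e-10 * std::max(dmax, 1e-300));
  arma::vec d = dC.elem(kd);
  arma::mat V = VC.cols(kd);
  arma::vec t = V.t() * g1;
  double s2sum = arma::dot(g1, g1);                 // 1' Sigma^2 1
  double const_coef = (s2sum - arma::dot(t, t)) / psi;
  if (const_coef < 0) const_coef = 0;
  arma::vec dcoef = (t % t) / (d * psi);  // delta_j^2 = xi^2 * dcoef_j

  double p;
  std::string route;
  if (!fast) {
    // exact conditional route: per-rho null quantiles by inversion, inner
    // CDF is an exact noncentral quadratic form
    std::vector<double> qr, rr;
    for (arma::uword i = 0; i < nr; ++i) {
      if (rho[i] >= 1.0 - 1e-12) continue;
      qr.push_back(qf_quantile_upper(lam_rho[i], T, acc));
      rr.push_back(rho[i]);
    }
    const double inner_acc = std::max(1e-10, std::min(acc, 2e-3 * T));
    auto integrand = [&](double xi) -> double {
      double xi2 = xi * xi;
      double smin = R_PosInf;
      for (size_t j = 0; j < qr.size(); ++j) {
        double v = (qr[j] - rr[j] * psi * xi2) / (1.0 - rr[j]);
        if (v < smin) smin = v;
      }
      double sadj = smin - const_coef * xi2;
      double sf;
      if (sadj <= 0) {
        sf = 1.0;
      } else {
        int m2;
        sf = qf_sf(d, dcoef * xi2, sadj, inner_acc, &m2);
      }
      return R::dnorm(xi, 0.0, 1.0, 0) * sf;
    };
    double tol = std::max(1e-13, 2e-4 * T);
    p = 2.0 * adaptive_simpson(integrand, 0.0, ximax, tol, 8) +
        2.0 * R::pnorm(ximax, 0.0, 1.0, 0, 0);
    route = "exact";
  } else {
    // moment-matched route (canonical variance-adjusted construction):
    // Liu-type per-rho quantiles, cross-term variance folded into a
    // rescaling of the threshold, Liu-type CDF of the kappa mixture
    std::vector<double> qr, rr, tauv;
    double tau_skat = s2sum / psi;  // 1' Sigma^2 1 / psi
    for (arma::uword i = 0; i < nr; ++i) {
      if (rho[i] >= 1.0 - 1e-12) continue;
      qr.push_back(liu_quantile_upper(lam_rho[i], T));
      rr.push_back(rho[i]);
      tauv.push_back(rho[i] * psi + (1.0 - rho[i]) * tau_skat);
    }
    double muQ = arma::accu(d);
    double varK = 2.0 * arma::accu(d % d);
    double varRemain = 4.0 * arma::accu(d % (t % t)) / psi;
    double sd1 = std::sqrt(varK / (varK + varRemain));
    LiuPar lk = liu_params(d, arma::vec());
    // integrate over the burden chi-square via x = t^2
    double tmaxi = std::min(8.5, ximax);
    double mid = 0.5 * tmaxi, half = 0.5 * tmaxi;
    double acc_int = 0.0;
    for (size_t i = 0; i < GL64.x.size(); ++i) {
      double xi = mid + half * GL64.x[i];
      double x = xi * xi;
      double smin = R_PosInf;
      for (size_t j = 0; j < qr.size(); ++j) {
        double v = (qr[j] - tauv[j] * x) / (1.0 - rr[j]);
        if (v < smin) smin = v;
      }
      double sadj = (smin - muQ) * sd1 + muQ;
      double sf = (sadj <= 0) ? 1.0 : liu_sf_par(lk, sadj);
      acc_int += GL64.w[i] * R::dnorm(xi, 0.0, 1.0, 0) * sf;
    }
    p = 2.0 * half * acc_int + 2.0 * R::pnorm(tmaxi, 0.0, 1.0, 0, 0);
    route = "moment";
  }
  if (p < T) p = T;
  if (p > pcap) p = pcap;
  return List::create(_["p"] = p, _["pmin"] = T, _["p_rho"] = prho,
                      _["route"] = route);
}
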