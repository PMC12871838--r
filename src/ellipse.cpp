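// Orthogonal-distance kernels for 2D ellipse fitting.
//
// The residual of a point against an ellipse is its exact Euclidean
// distance to the nearest boundary point (negative inside), obtained by
// solving the first-quadrant nearest-point problem with a robust
// bisection on the auxiliary function
//   G(s) = (a p / (s + a^2))^2 + (b q / (s + b^2))^2 - 1,
// which is strictly decreasing in s on (-b^2, inf) and has the nearest
// point at its unique root (a >= b > 0, p = |x|, q = |y| in the ellipse
// frame).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double quadrant_distance(double p, double q, double a, double b) {
  const double eps = 1e-14;
  if (q < eps) {
    // point on the major axis: nearest point leaves the axis when
    // p < (a^2 - b^2) / a
    double crit = (a * a - b * b) / a;
    if (p < crit) {
      double x = a * a * p / (a * a - b * b);
      double y = b * std::sqrt(std::max(0.0, 1.0 - (x / a) * (x / a)));
      return std::sqrt((p - x) * (p - x) + y * y);
    }
    return std::fabs(p - a);
  }
  if (p < eps) {
    // a >= b: nearest point to the minor axis is the co-vertex
    return std::fabs(q - b);
  }
  // bracket the root of G(s)
  double lo = -b * b + b * q;            // G(lo) >= 0
  double hi = std::sqrt(a * a * p * p + b * b * q * q) - b * b;
  if (hi < lo) hi = lo;
  // expand until G(hi) <= 0
  for (int i = 0; i < 200; ++i) {
    double ga = a * p / (hi + a * a), gb = b * q / (hi + b * b);
    if (ga * ga + gb * gb - 1.0 <= 0.0) break;
    hi = 2.0 * hi + a * a;
  }
  for (int i = 0; i < 120; ++i) {
    double s = 0.5 * (lo + hi);
    double ga = a * p / (s + a * a), gb = b * q / (s + b * b);
    double g = ga * ga + gb * gb - 1.0;
    if (g > 0.0) lo = s; else hi = s;
    if (hi - lo <= 1e-14 * (std::fabs(hi) + a * a)) break;
  }
  double s = 0.5 * (lo + hi);
  double x = a * a * p / (s + a * a);
  double y = b * b * q / (s + b * b);
  return std::sqrt((p - x) * (p - x) + (q - y) * (q - y));
}

static void signed_distances(const arma::mat& pts, const arma::vec& par,
                             arma::vec& out) {
  const double cx = par[0], cy = par[1], a = par[2], b = par[3],
               th = par[4];
  const double ct = std::cos(th), st = std::sin(th);
  for (arma::uword i = 0; i < pts.n_rows; ++i) {
    double dx = pts(i, 0) - cx, dy = pts(i, 1) - cy;
    double u = ct * dx + st * dy;
    double v = -st * dx + ct * dy;
    double d = quadrant_distance(std::fabs(u), std::fabs(v), a, b);
    double r = (u / a) * (u / a) + (v / b) * (v / b);
    out[i] = (r < 1.0) ? -d : d;
  }
}

// [[Rcpp::export(name = ".cpp_ellipse_distances")]]
NumericVector cpp_ellipse_distances(const arma::mat& pts,
                                    const arma::vec& par) {
  arma::vec out(pts.n_rows);
  signed_distances(pts, par, out);
  return wrap(out);
}

// Levenberg-Marquardt over (cx, cy, a, b, theta) minimizing the sum of
// squared perpendicular distances; forward-difference Jacobian. Steps are
// accepted only when the objective decreases, so the refined objective
// never exceeds the initial one.
// [[Rcpp::export(name = ".cpp_ellipse_odr")]]
List cpp_ellipse_odr(const arma::mat& pts, const arma::vec& init,
                     int max_iter = 200, double tol = 1e-10) {
  const arma::uword n = pts.n_rows;
  arma::vec par = init;
  arma::vec r(n), r_try(n);
  signed_distances(pts, par, r);
  double obj = arma::dot(r, r);
  const double obj0 = obj;
  double lambda = 1e-3;
  bool converged = false;
  int iter = 0;
  arma::mat J(n, 5);
  for (iter = 0; iter < max_iter; ++iter) {
    // numeric Jacobian
    for (int k = 0; k < 5; ++k) {
      double h = 1e-6 * std::max(1.0, std::fabs(par[k]));
      arma::vec p2 = par;
      p2[k] += h;
      if (p2[3] <= 0 || p2[2] < p2[3]) {
        // keep a >= b > 0 during differencing by stepping the other way
        p2 = par;
        p2[k] -= h;
        h = -h;
      }
      signed_distances(pts, p2, r_try);
      J.col(k) = (r_try - r) / h;
    }
    arma::mat JtJ = J.t() * J;
    arma::vec g = J.t() * r;
    bool accepted = false;
    for (int tries = 0; tries < 30; ++tries) {
      arma::mat Am = JtJ;
      Am.diag() += lambda * JtJ.diag() + 1e-12;
      arma::vec step;
      bool ok = arma::solve(step, Am, -g, arma::solve_opts::no_approx);
      if (ok) {
        arma::vec p_new = par + step;
        if (p_new[3] > 0 && p_new[2] >= p_new[3]) {
          signed_distances(pts, p_new, r_try);
          double obj_new = arma::dot(r_try, r_try);
          if (obj_new < obj) {
            double rel = (obj - obj_new) / std::max(obj, 1e-300);
            par = p_new;
            r = r_try;
            obj = obj_new;
            lambda = std::max(lambda / 3.0, 1e-12);
            accepted = true;
            if (rel < tol) converged = true;
            break;
          }
        }
      }
      lambda *= 5.0;
      if (lambda > 1e12) break;
    }
    if (!accepted) {  // no descent step found: local optimum
      converged = true;
      break;
    }
    if (converged) break;
  }
  // canonicalize theta to [0, pi)
  double th = par[4] - M_PI * std::floor(par[4] / M_PI);
  if (th >= M_PI) th -= M_PI;
  if (th < 0) th += M_PI;
  par[4] = th;
  return List::create(_["par"] = wrap(par), _["residuals"] = wrap(r),
                      _["objective"] = obj, _["objective0"] = obj0,
                      _["converged"] = converged, _["iterations"] = iter);
}
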