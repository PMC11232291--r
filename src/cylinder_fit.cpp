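#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Orthonormal basis (u, v) of the plane perpendicular to unit vector w.
static void perp_basis(const vec& w, vec& u, vec& v) {
  vec e = (std::fabs(w(0)) < 0.9) ? vec("1 0 0") : vec("0 1 0");
  u = normalise(cross(w, e));
  v = cross(w, u);
}

// Least-squares cylinder: minimise sum (distance-to-axis - radius)^2 by
// Gauss-Newton over (axis point in the perpendicular plane, two axis tilt
// angles, radius). Returns axis point nearest the centroid, unit axis,
// radius, rms residual, iteration count and convergence flag.
// [[Rcpp::export]]
Rcpp::List cpp_fit_cylinder(const arma::mat& pts, const arma::vec& init_axis,
                            int max_iter, double tol) {
  int n = pts.n_rows;
  rowvec ctr = mean(pts, 0);
  vec a = ctr.t();
  vec w = normalise(init_axis);
  // initial radius: mean distance to the initial axis
  mat y0 = pts.each_row() - ctr;
  vec t0 = y0 * w;
  mat q0 = y0 - t0 * w.t();
  vec d0 = sqrt(sum(square(q0), 1));
  double r = mean(d0);
  if (!(r > 0)) r = 1e-6;

  double scale = std::max(r, as_scalar(max(sqrt(sum(square(y0), 1)))));
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    vec u, v;
    perp_basis(w, u, v);
    mat y = pts.each_row() - a.t();
    vec t = y * w;
    mat q = y - t * w.t();
    vec d = sqrt(sum(square(q), 1));
    if (d.min() < 1e-14) d = clamp(d, 1e-14, datum::inf);
    vec eu = (q * u) / d;
    vec ev = (q * v) / d;
    mat J(n, 5);
    J.col(0) = -eu;
    J.col(1) = -ev;
    J.col(2) = -t % eu;
    J.col(3) = -t % ev;
    J.col(4) = -ones<vec>(n);
    vec f = d - r;
    vec delta;
    bool ok = solve(delta, J, -f, solve_opts::fast + solve_opts::no_approx);
    if (!ok || !delta.is_finite()) {
      ok = solve(delta, J, -f, solve_opts::force_approx);
      if (!ok || !delta.is_finite()) break;
    }
    a += delta(0) * u + delta(1) * v;
    w = normalise(w + delta(2) * u + delta(3) * v);
    r = std::fabs(r + delta(4));
    double step = norm(delta) / scale;
    if (step < tol) { converged = true; ++it; break; }
  }
  // report the axis point nearest the centroid
  vec yc = ctr.t() - a;
  a += dot(yc, w) * w;
  mat y = pts.each_row() - a.t();
  vec t = y * w;
  mat q = y - t * w.t();
  vec f = sqrt(sum(square(q), 1)) - r;
  double rms = std::sqrt(mean(square(f)));
  return Rcpp::List::create(
      Rcpp::_["point"] = a, Rcpp::_["axis"] = w, Rcpp::_["radius"] = r,
      Rcpp::_["rms"] = rms, Rcpp::_["iterations"] = it,
      Rcpp::_["converged"] = converged);
}
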