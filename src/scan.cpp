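#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Cast rays from one viewpoint against a set of finite cylinders (lateral
// surfaces only). With `occlude` the nearest intersection per ray is kept;
// without it every cylinder's front-surface hit is kept. Gaussian range noise
// of sd `sigma` (m) is added along the ray via R's RNG.
// cyl matrices: start (k x 3), axis (k x 3, unit), len (k), rad (k).
// Returns hit coordinates and 1-based cylinder ids.
// [[Rcpp::export]]
Rcpp::List cpp_scan_rays(const arma::vec& origin, const arma::mat& dirs,
                         const arma::mat& cstart, const arma::mat& caxis,
                         const arma::vec& clen, const arma::vec& crad,
                         double sigma, bool occlude) {
  int nray = dirs.n_rows, ncyl = cstart.n_rows;
  // bounding-sphere precheck data
  mat cmid = cstart + caxis.each_col() % (0.5 * clen);
  vec brad = 0.5 * clen + crad;

  std::vector<double> hx, hy, hz;
  std::vector<int> hid;
  hx.reserve(nray / 4); hy.reserve(nray / 4); hz.reserve(nray / 4);
  hid.reserve(nray / 4);

  auto emit = [&](double t, const vec& d, int c) {
    if (sigma > 0) t += R::rnorm(0.0, sigma);
    hx.push_back(origin(0) + t * d(0));
    hy.push_back(origin(1) + t * d(1));
    hz.push_back(origin(2) + t * d(2));
    hid.push_back(c + 1);
  };

  for (int i = 0; i < nray; ++i) {
    vec d = dirs.row(i).t();
    double best_t = datum::inf;
    int best_c = -1;
    for (int c = 0; c < ncyl; ++c) {
      // sphere reject
      vec oc = cmid.row(c).t() - origin;
      double proj = dot(oc, d);
      double perp2 = dot(oc, oc) - proj * proj;
      if (perp2 > brad(c) * brad(c)) continue;
      if (proj + brad(c) < 0) continue;
      if (occlude && proj - brad(c) > best_t) continue;

      vec W = caxis.row(c).t();
      vec delta = origin - cstart.row(c).t();
      double dW = dot(d, W), deW = dot(delta, W);
      vec dperp = d - dW * W;
      vec eperp = delta - deW * W;
      double A = dot(dperp, dperp);
      if (A < 1e-16) continue;  // ray parallel to axis, no lateral hit
      double B = 2.0 * dot(dperp, eperp);
      double C = dot(eperp, eperp) - crad(c) * crad(c);
      double disc = B * B - 4.0 * A * C;
      if (disc < 0) continue;
      double sq = std::sqrt(disc);
      for (int s = 0; s < 2; ++s) {
        double t = (s == 0) ? (-B - sq) / (2 * A) : (-B + sq) / (2 * A);
        if (t <= 1e-9) continue;
        double h = deW + t * dW;  // height along axis
        if (h < 0 || h > clen(c)) continue;
        if (occlude) {
          if (t < best_t) { best_t = t; best_c = c; }
        } else {
          emit(t, d, c);
        }
        break;  // the smaller root that passes wins
      }
    }
    if (occlude && best_c >= 0) emit(best_t, d, best_c);
  }
  int m = (int)hid.size();
  Rcpp::NumericMatrix pts(m, 3);
  Rcpp::IntegerVector id(m);
  for (int i = 0; i < m; ++i) {
    pts(i, 0) = hx[i]; pts(i, 1) = hy[i]; pts(i, 2) = hz[i];
    id[i] = hid[i];
  }
  return Rcpp::List::create(Rcpp::_["points"] = pts, Rcpp::_["cyl_id"] = id);
}
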