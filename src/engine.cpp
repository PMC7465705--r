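// Numerical core shared by the association scan and the permutation null:
//  - 1-D profiled REML for the variance ratio delta = Ve/Vg on the
//    eigenbasis of the genomic relationship matrix,
//  - EMMAX-style generalized-least-squares Wald scan with delta fixed,
//  - natural cubic smoothing spline on the eigenbasis of the roughness
//    penalty, with GCV lambda selection over a log grid,
//  - exact maximum peak height of the fitted piecewise cubic over its
//    concave-down inflection intervals.
// The R-level fit_spline()/call_peaks() implement the same formulas; the
// two paths are cross-checked in the test suite.

#include <RcppArmadillo.h>
using namespace Rcpp;

// REML negative criterion for a given delta (profile over Vg and fixed
// effects). Wt, yt live in the eigenbasis of K; S holds K's eigenvalues.
static double reml_negll(const arma::mat& Wt, const arma::vec& yt,
                         const arma::vec& S, double delta,
                         double* vg_out = nullptr) {
  const arma::uword n = yt.n_elem, c = Wt.n_cols;
  arma::vec D = S + delta;
  arma::vec w = 1.0 / D;
  arma::mat Ww = Wt.each_col() % w;
  arma::mat A = Wt.t() * Ww;
  arma::vec b = Ww.t() * yt;
  arma::vec beta = arma::solve(A, b, arma::solve_opts::likely_sympd);
  double ytDy = arma::dot(yt % w, yt);
  double rDr = ytDy - arma::dot(b, beta);
  if (rDr < 1e-300) rDr = 1e-300;
  double vg = rDr / double(n - c);
  if (vg_out) *vg_out = vg;
  double logdetA, signA;
  arma::log_det(logdetA, signA, A);
  double nll = 0.5 * (double(n - c) * std::log(rDr) + arma::accu(arma::log(D)) +
                      logdetA);
  return nll;
}

// Profiled REML over delta: coarse log10 grid, then golden-section
// refinement between the neighbours of the grid optimum.
// [[Rcpp::export]]
List reml_delta_cpp(const arma::mat& Wt, const arma::vec& yt,
                    const arma::vec& S, const arma::vec& log10_delta_grid,
                    double tol = 1e-6) {
  const arma::uword n = yt.n_elem, c = Wt.n_cols;
  arma::uword best = 0;
  double best_nll = std::numeric_limits<double>::infinity();
  for (arma::uword i = 0; i < log10_delta_grid.n_elem; ++i) {
    double nll = reml_negll(Wt, yt, S, std::pow(10.0, log10_delta_grid(i)));
    if (nll < best_nll) { best_nll = nll; best = i; }
  }
  double lo = log10_delta_grid(best == 0 ? 0 : best - 1);
  double hi = log10_delta_grid(
      best + 1 >= log10_delta_grid.n_elem ? best : best + 1);
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = reml_negll(Wt, yt, S, std::pow(10.0, x1));
  double f2 = reml_negll(Wt, yt, S, std::pow(10.0, x2));
  for (int it = 0; it < 100 && (b - a) > tol; ++it) {
    if (f1 < f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = reml_negll(Wt, yt, S, std::pow(10.0, x1));
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = reml_negll(Wt, yt, S, std::pow(10.0, x2));
    }
  }
  double log_delta = (f1 < f2) ? x1 : x2;
  double delta = std::pow(10.0, log_delta);
  double vg;
  double nll = reml_negll(Wt, yt, S, delta, &vg);
  bool boundary = (best == 0 && log_delta <= log10_delta_grid(0) + tol) ||
                  (best + 1 >= log10_delta_grid.n_elem &&
                   log_delta >= log10_delta_grid(log10_delta_grid.n_elem - 1) - tol);
  double ll = -nll - 0.5 * double(n - c) * (1.0 + std::log(2.0 * M_PI) -
                                            std::log(double(n - c)));
  return List::create(_["delta"] = delta, _["vg"] = vg,
                      _["ve"] = vg * delta, _["loglik"] = ll,
                      _["boundary"] = boundary);
}

// EMMAX-style single-SNP GLS scan. Gt is the rotated (eigenbasis)
// mean-imputed dosage matrix; Wt, yt rotated covariates/phenotype; S the
// GRM eigenvalues. Returns beta, var(beta), Wald per SNP.
// [[Rcpp::export]]
arma::mat wald_scan_cpp(const arma::mat& Gt, const arma::mat& Wt,
                        const arma::vec& yt, const arma::vec& S,
                        double vg, double ve) {
  const arma::uword m = Gt.n_cols;
  arma::vec D = vg * S + ve;
  D.transform([](double v) { return v > 1e-300 ? v : 1e-300; });
  arma::vec w = 1.0 / D;
  arma::mat Ww = Wt.each_col() % w;                  // n x c
  arma::mat A = Wt.t() * Ww;                         // c x c
  arma::mat Ainv = arma::inv_sympd(arma::symmatu(A));
  arma::mat q = Ww.t() * Gt;                         // c x m
  arma::vec xDx = (Gt % Gt).t() * w;                 // m
  arma::vec xDy = Gt.t() * (yt % w);                 // m
  arma::vec t = Ainv * (Ww.t() * yt);                // c
  arma::mat Sq = Ainv * q;                           // c x m
  arma::vec xPx = xDx - arma::sum(q % Sq, 0).t();
  arma::vec xPy = xDy - q.t() * t;
  arma::mat out(m, 3);
  for (arma::uword j = 0; j < m; ++j) {
    if (xPx(j) <= 1e-10) {
      out(j, 0) = 0.0;
      out(j, 1) = arma::datum::nan;
      out(j, 2) = 0.0;
    } else {
      out(j, 0) = xPy(j) / xPx(j);
      out(j, 1) = 1.0 / xPx(j);
      out(j, 2) = xPy(j) * xPy(j) / xPx(j);
    }
  }
  return out;
}

// Smoothing-spline fit on the penalty eigenbasis. V, d: eigenvectors /
// eigenvalues of the roughness matrix K_pen = Q R^{-1} Q' built from the
// scaled knot positions; lambda chosen by GCV over the grid unless
// lambda_fixed >= 0. The GCV degrees-of-freedom charge is inflated by
// gcv_gamma (default 1.4, the usual guard against occasional
// undersmoothing of heavy-tailed inputs); lambda values whose effective
// df exceed n / gcv_gamma are inadmissible. Ties resolve to the larger
// lambda.
// [[Rcpp::export]]
List spline_fit_cpp(const arma::mat& V, const arma::vec& d,
                    const arma::vec& y, const arma::vec& lambda_grid,
                    double lambda_fixed = -1.0, double gcv_gamma = 1.4) {
  const arma::uword n = y.n_elem;
  arma::vec wt = V.t() * y;
  double lam;
  if (lambda_fixed >= 0.0) {
    lam = lambda_fixed;
  } else {
    double best_gcv = std::numeric_limits<double>::infinity();
    lam = lambda_grid(lambda_grid.n_elem - 1);
    for (arma::uword k = 0; k < lambda_grid.n_elem; ++k) {
      double l = lambda_grid(k);
      double rss = 0.0, tr = 0.0;
      for (arma::uword i = 0; i < n; ++i) {
        double a = 1.0 / (1.0 + l * d(i));
        double r = wt(i) * (1.0 - a);
        rss += r * r;
        tr += a;
      }
      double denom = double(n) - gcv_gamma * tr;
      double gcv = (denom <= 1e-12)
          ? std::numeric_limits<double>::infinity()
          : double(n) * rss / (denom * denom);
      if (gcv <= best_gcv) { best_gcv = gcv; lam = l; }
    }
  }
  arma::vec a = 1.0 / (1.0 + lam * d);
  arma::vec coef = a % wt;
  arma::vec g = V * coef;
  double rss = 0.0, tr = 0.0, pen = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    double r = wt(i) * (1.0 - a(i));
    rss += r * r;
    tr += a(i);
    pen += d(i) * coef(i) * coef(i);
  }
  return List::create(_["lambda"] = lam, _["g"] = g, _["rss"] = rss,
                      _["edf"] = tr, _["penalty"] = pen);
}

// Evaluate the natural cubic spline piece on [x_i, x_{i+1}] at x.
static inline double eval_piece(double x, double xi, double xi1, double gi,
                                double gi1, double ci, double ci1) {
  double h = xi1 - xi, t = x - xi, u = xi1 - x;
  return ci * u * u * u / (6.0 * h) + ci1 * t * t * t / (6.0 * h) +
         (gi / h - ci * h / 6.0) * u + (gi1 / h - ci1 * h / 6.0) * t;
}

// Noise floor for the second derivative (mirrors gamma_tolerance() on the
// R side): values below it are treated as exactly zero so degenerate flat
// fits yield no peaks.
static double gamma_tol(const arma::vec& g) {
  double n = double(g.n_elem);
  double rng = g.max() - g.min();
  double mx = std::max(1.0, std::max(std::fabs(g.max()), std::fabs(g.min())));
  return (1e-4 + 4e-9 * n * n) * rng + 1e-6 * mx;
}

// Exact maximum of g over the concave-down intervals delimited by
// consecutive inflection points (zero crossings of the piecewise-linear
// second derivative) and the chromosome ends. Returns -inf if no
// concave-down interval exists.
// [[Rcpp::export]]
double max_peak_height_cpp(const arma::vec& x, const arma::vec& g,
                           const arma::vec& gam) {
  const arma::uword n = x.n_elem;
  if (n < 2) return -std::numeric_limits<double>::infinity();
  // boundary nodes: ends + zero crossings of gam
  std::vector<double> nodes;
  nodes.push_back(x(0));
  for (arma::uword i = 0; i + 1 < n; ++i) {
    double a = gam(i), b = gam(i + 1);
    if ((a < 0.0 && b > 0.0) || (a > 0.0 && b < 0.0)) {
      nodes.push_back(x(i) + (x(i + 1) - x(i)) * (-a) / (b - a));
    } else if (a != 0.0 && b == 0.0 && i + 2 < n) {
      nodes.push_back(x(i + 1));
    }
  }
  nodes.push_back(x(n - 1));
  double best = -std::numeric_limits<double>::infinity();
  for (size_t k = 0; k + 1 < nodes.size(); ++k) {
    double L = nodes[k], U = nodes[k + 1];
    if (U - L <= 0.0) continue;
    // interval sign: most negative/positive gamma strictly inside
    double s = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      if (x(i) > L && x(i) < U && std::fabs(gam(i)) > std::fabs(s)) s = gam(i);
    }
    if (s == 0.0) {
      // no interior knot: interpolate gamma at the midpoint
      double mid = (L + U) / 2.0;
      arma::uword i = 0;
      while (i + 2 < n && x(i + 1) <= mid) ++i;
      double h = x(i + 1) - x(i);
      s = gam(i) * (x(i + 1) - mid) / h + gam(i + 1) * (mid - x(i)) / h;
    }
    if (s >= 0.0) continue;  // not concave-down
    // maximize g over [L, U]
    for (arma::uword i = 0; i + 1 < n; ++i) {
      double a = std::max(L, x(i)), b = std::min(U, x(i + 1));
      if (b <= a) continue;
      double h = x(i + 1) - x(i);
      double va = eval_piece(a, x(i), x(i + 1), g(i), g(i + 1), gam(i), gam(i + 1));
      double vb = eval_piece(b, x(i), x(i + 1), g(i), g(i + 1), gam(i), gam(i + 1));
      if (va > best) best = va;
      if (vb > best) best = vb;
      // stationary points: g'(s) = A s^2 + B s + C, s = x - x_i
      double A = (gam(i + 1) - gam(i)) / (2.0 * h);
      double B = gam(i);
      double C = (g(i + 1) - g(i)) / h - h * (2.0 * gam(i) + gam(i + 1)) / 6.0;
      double roots[2];
      int nr = 0;
      if (std::fabs(A) < 1e-300) {
        if (std::fabs(B) > 1e-300) { roots[nr++] = -C / B; }
      } else {
        double disc = B * B - 4.0 * A * C;
        if (disc >= 0.0) {
          double sq = std::sqrt(disc);
          roots[nr++] = (-B - sq) / (2.0 * A);
          roots[nr++] = (-B + sq) / (2.0 * A);
        }
      }
      for (int r = 0; r < nr; ++r) {
        double xx = x(i) + roots[r];
        if (xx > a && xx < b) {
          double vv = eval_piece(xx, x(i), x(i + 1), g(i), g(i + 1),
                                 gam(i), gam(i + 1));
          if (vv > best) best = vv;
        }
      }
    }
  }
  return best;
}

// Permutation null of genome-wide maximum peak heights. For each column of
// `perms` (1-based permutation indices): permute y, rotate, re-fit delta
// by REML, run the Wald scan, fit per-chromosome GCV splines and record
// the genome-wide maximum peak height (0 when no concave-down peak).
// chrom_structs: list per chromosome with elements V, d, Mg (second-
// derivative extractor R^{-1}Q'), x (scaled knots), idx (1-based SNP
// column range in the scan output).
// [[Rcpp::export]]
arma::vec perm_null_cpp(const arma::mat& Ut, const arma::mat& Wt0,
                        const arma::mat& Gt, const arma::vec& S,
                        const arma::vec& y, const arma::imat& perms,
                        const List& chrom_structs,
                        const arma::vec& lambda_grid,
                        const arma::vec& log10_delta_grid) {
  const arma::uword B = perms.n_cols, n = y.n_elem;
  const int n_chrom = chrom_structs.size();
  // unpack chromosome structures once
  std::vector<arma::mat> Vs(n_chrom), Mgs(n_chrom);
  std::vector<arma::vec> ds(n_chrom), xs(n_chrom);
  std::vector<arma::uword> i0(n_chrom), i1(n_chrom);
  for (int c = 0; c < n_chrom; ++c) {
    List st = chrom_structs[c];
    Vs[c] = as<arma::mat>(st["V"]);
    ds[c] = as<arma::vec>(st["d"]);
    Mgs[c] = as<arma::mat>(st["Mg"]);
    xs[c] = as<arma::vec>(st["x"]);
    arma::ivec idx = as<arma::ivec>(st["idx"]);
    i0[c] = arma::uword(idx(0) - 1);
    i1[c] = arma::uword(idx(1) - 1);
  }
  arma::vec heights(B);
  for (arma::uword b = 0; b < B; ++b) {
    if (b % 32 == 0) Rcpp::checkUserInterrupt();
    arma::vec yp(n);
    for (arma::uword i = 0; i < n; ++i) yp(i) = y(perms(i, b) - 1);
    arma::vec yt = Ut * yp;
    List fit = reml_delta_cpp(Wt0, yt, S, log10_delta_grid);
    double vg = as<double>(fit["vg"]), ve = as<double>(fit["ve"]);
    arma::mat sc = wald_scan_cpp(Gt, Wt0, yt, S, vg, ve);
    arma::vec wald = sc.col(2);
    double hmax = -std::numeric_limits<double>::infinity();
    for (int c = 0; c < n_chrom; ++c) {
      arma::vec wc = wald.subvec(i0[c], i1[c]);
      List sf = spline_fit_cpp(Vs[c], ds[c], wc, lambda_grid);
      arma::vec g = as<arma::vec>(sf["g"]);
      arma::uword nc = g.n_elem;
      arma::vec gam(nc, arma::fill::zeros);
      gam.subvec(1, nc - 2) = Mgs[c] * g;
      double tol = gamma_tol(g);
      gam.transform([tol](double v) { return std::fabs(v) < tol ? 0.0 : v; });
      double h = max_peak_height_cpp(xs[c], g, gam);
      if (h > hmax) hmax = h;
    }
    heights(b) = std::isfinite(hmax) ? hmax : 0.0;
  }
  return heights;
}
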