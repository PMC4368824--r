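// Power (additively weighted Voronoi) diagrams by half-plane clipping, and
// the centroidal solver that adapts site positions and power weights until
// each cell's area is proportional to its target weight.
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef std::vector<double> dvec;

struct Poly { dvec x, y; };

static void clip_halfplane(Poly &p, double ax, double ay, double b) {
  // keep points with ax*x + ay*y <= b (Sutherland-Hodgman)
  const int n = (int)p.x.size();
  if (n == 0) return;
  dvec ox, oy;
  ox.reserve(n + 4); oy.reserve(n + 4);
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1) % n;
    const double di = ax * p.x[i] + ay * p.y[i] - b;
    const double dj = ax * p.x[j] + ay * p.y[j] - b;
    if (di <= 0) { ox.push_back(p.x[i]); oy.push_back(p.y[i]); }
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      const double t = di / (di - dj);
      ox.push_back(p.x[i] + t * (p.x[j] - p.x[i]));
      oy.push_back(p.y[i] + t * (p.y[j] - p.y[i]));
    }
  }
  p.x.swap(ox); p.y.swap(oy);
}

static double poly_area(const Poly &p) {
  const int n = (int)p.x.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1) % n;
    s += p.x[i] * p.y[j] - p.x[j] * p.y[i];
  }
  return 0.5 * s;
}

static void poly_centroid(const Poly &p, double &cx, double &cy) {
  const int n = (int)p.x.size();
  double a = 0.0, sx = 0.0, sy = 0.0;
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1) % n;
    const double cr = p.x[i] * p.y[j] - p.x[j] * p.y[i];
    a += cr;
    sx += (p.x[i] + p.x[j]) * cr;
    sy += (p.y[i] + p.y[j]) * cr;
  }
  a *= 0.5;
  if (std::fabs(a) < 1e-300) { // degenerate: average vertices
    cx = 0; cy = 0;
    for (int i = 0; i < n; ++i) { cx += p.x[i]; cy += p.y[i]; }
    if (n > 0) { cx /= n; cy /= n; }
    return;
  }
  cx = sx / (6.0 * a); cy = sy / (6.0 * a);
}

static std::vector<Poly> diagram(const dvec &px, const dvec &py, const dvec &w,
                                 const Poly &cont) {
  const int n = (int)px.size();
  std::vector<Poly> cells(n);
  for (int i = 0; i < n; ++i) {
    Poly cell = cont;
    for (int j = 0; j < n && !cell.x.empty(); ++j) {
      if (j == i) continue;
      const double ax = 2.0 * (px[j] - px[i]);
      const double ay = 2.0 * (py[j] - py[i]);
      const double b = px[j] * px[j] + py[j] * py[j]
                     - px[i] * px[i] - py[i] * py[i]
                     + w[i] - w[j];
      clip_halfplane(cell, ax, ay, b);
    }
    cells[i] = cell;
  }
  return cells;
}

static List cells_to_list(const std::vector<Poly> &cells) {
  List out(cells.size());
  for (size_t i = 0; i < cells.size(); ++i) {
    const int n = (int)cells[i].x.size();
    NumericMatrix m(n, 2);
    for (int k = 0; k < n; ++k) { m(k, 0) = cells[i].x[k]; m(k, 1) = cells[i].y[k]; }
    out[i] = m;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_power_diagram(NumericVector px, NumericVector py, NumericVector w,
                       NumericMatrix container) {
  Poly cont;
  for (int i = 0; i < container.nrow(); ++i) {
    cont.x.push_back(container(i, 0)); cont.y.push_back(container(i, 1));
  }
  dvec X(px.begin(), px.end()), Y(py.begin(), py.end()), W(w.begin(), w.end());
  std::vector<Poly> cells = diagram(X, Y, W, cont);
  return cells_to_list(cells);
}

// [[Rcpp::export]]
List cpp_solve_areas(NumericVector px0, NumericVector py0, NumericVector w0,
                     NumericVector targets, NumericMatrix container,
                     double max_area_error, int max_iter) {
  const int n = px0.size();
  Poly cont;
  for (int i = 0; i < container.nrow(); ++i) {
    cont.x.push_back(container(i, 0)); cont.y.push_back(container(i, 1));
  }
  const double A = std::fabs(poly_area(cont));
  double tsum = 0.0;
  for (int i = 0; i < n; ++i) tsum += targets[i];
  dvec t(n);
  for (int i = 0; i < n; ++i) t[i] = targets[i] / tsum * A;
  dvec X(px0.begin(), px0.end()), Y(py0.begin(), py0.end()), W(w0.begin(), w0.end());

  // Damped Newton-style area equalisation: the power bisector between sites
  // at distance d shifts by dw/(2d) when one weight grows by dw, so for
  // cells of diameter ~d with perimeter ~4d a weight increment of about
  // (target - area)/2 is a unit step; 0.5 damping keeps the simultaneous
  // updates stable. Weights are clamped below the squared nearest-site
  // distance so no site is swallowed, and recentred (power diagrams are
  // invariant under adding a constant to all weights).
  const double wdamp = 0.5;
  std::vector<Poly> cells;
  dvec areas(n, 0.0);
  double err = R_PosInf;
  int iter = 0;
  bool converged = false;
  for (iter = 0; iter <= max_iter; ++iter) {
    cells = diagram(X, Y, W, cont);
    err = 0.0;
    for (int i = 0; i < n; ++i) {
      areas[i] = std::fabs(poly_area(cells[i]));
      const double e = std::fabs(areas[i] - t[i]) / t[i];
      if (e > err) err = e;
    }
    if (err <= max_area_error) { converged = true; break; }
    if (iter == max_iter) break;
    for (int i = 0; i < n; ++i) {
      if (!cells[i].x.empty() && areas[i] > 0) {
        double cx, cy; poly_centroid(cells[i], cx, cy);
        X[i] = cx; Y[i] = cy;
      }
    }
    double wmean = 0.0;
    for (int i = 0; i < n; ++i) {
      W[i] += wdamp * (t[i] - areas[i]);
      double d2min = R_PosInf;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double dx = X[i] - X[j], dy = Y[i] - Y[j];
        const double d2 = dx * dx + dy * dy;
        if (d2 < d2min) d2min = d2;
      }
      if (n > 1 && W[i] > d2min) W[i] = d2min;
      wmean += W[i];
    }
    wmean /= n;
    for (int i = 0; i < n; ++i) W[i] -= wmean;
  }
  return List::create(
    _["cells"] = cells_to_list(cells),
    _["x"] = wrap(X), _["y"] = wrap(Y), _["w"] = wrap(W),
    _["areas"] = wrap(areas),
    _["iterations"] = iter,
    _["converged"] = converged,
    _["max_rel_error"] = err);
}
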