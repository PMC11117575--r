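#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Interpolation. Two samplers are used:
//  * Keys bicubic convolution (a = -0.5), applied directly to pixel values:
//    used by the synthetic renderer.
//  * Cubic B-spline interpolation on prefiltered coefficients: used by the
//    DIC engine. The recursive prefilter makes the spline pass through the
//    samples exactly, and its phase bias ("S-curve" pull toward integer
//    shifts) is roughly an order of magnitude below cubic convolution on
//    sharp speckle, which matters because incremental tracking accumulates
//    per-increment bias over a hundred-plus frames.
// ---------------------------------------------------------------------------

static inline int clampi(int k, int lo, int hi) {
  return k < lo ? lo : (k > hi ? hi : k);
}

// mirror (whole-sample symmetric) index into [0, n)
static inline int mirr(int k, int n) {
  if (n == 1) return 0;
  const int per = 2 * (n - 1);
  k = std::abs(k) % per;
  return k >= n ? per - k : k;
}

// Keys cubic convolution weights, fractional t in [0,1), nodes -1..2
static inline void keys_weights(double t, double *w) {
  w[0] = ((-0.5 * t + 1.0) * t - 0.5) * t;
  w[1] = (1.5 * t - 2.5) * t * t + 1.0;
  w[2] = ((-1.5 * t + 2.0) * t + 0.5) * t;
  w[3] = (0.5 * t - 0.5) * t * t;
}

static double interp_keys(const NumericMatrix &img, double x, double y) {
  const int nr = img.nrow(), nc = img.ncol();
  int ix = (int)std::floor(x), iy = (int)std::floor(y);
  double wx[4], wy[4];
  keys_weights(x - ix, wx);
  keys_weights(y - iy, wy);
  double val = 0.0;
  for (int j = 0; j < 4; ++j) {
    int cc = clampi(ix - 1 + j, 0, nc - 1);
    double colv = 0.0;
    for (int i = 0; i < 4; ++i)
      colv += wy[i] * img(clampi(iy - 1 + i, 0, nr - 1), cc);
    val += wx[j] * colv;
  }
  return val;
}

// cubic B-spline basis weights and derivatives, t in [0,1), nodes -1..2
static inline void bspl_weights(double t, double *w, double *dw) {
  const double t1 = 1.0 - t;
  w[0] = t1 * t1 * t1 / 6.0;
  w[1] = 2.0 / 3.0 - t * t + 0.5 * t * t * t;
  w[2] = 2.0 / 3.0 - t1 * t1 + 0.5 * t1 * t1 * t1;
  w[3] = t * t * t / 6.0;
  if (dw) {
    dw[0] = -0.5 * t1 * t1;
    dw[1] = -2.0 * t + 1.5 * t * t;
    dw[2] = 0.5 + t - 1.5 * t * t;
    dw[3] = 0.5 * t * t;
  }
}

// in-place recursive prefilter of one line (stride-accessed), mirror ends
static void bspl_filter_line(double *p, int n, int stride) {
  const double z = std::sqrt(3.0) - 2.0;   // pole of the cubic B-spline
  const double gain = 6.0;
  if (n == 1) { p[0] *= 1.0; return; }
  for (int k = 0; k < n; ++k) p[k * stride] *= gain;
  // causal initialization: truncated mirror sum
  int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z)));
  if (horizon > n) horizon = n;
  double sum = p[0], zk = z;
  for (int k = 1; k < horizon; ++k) {
    sum += zk * p[mirr(k, n) * stride];
    zk *= z;
  }
  p[0] = sum;
  for (int k = 1; k < n; ++k)
    p[k * stride] += z * p[(k - 1) * stride];
  // anticausal initialization and sweep
  p[(n - 1) * stride] = (z / (z * z - 1.0)) *
    (p[(n - 1) * stride] + z * p[(n - 2) * stride]);
  for (int k = n - 2; k >= 0; --k)
    p[k * stride] = z * (p[(k + 1) * stride] - p[k * stride]);
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_bspline_coef(NumericMatrix img) {
  NumericMatrix coef = clone(img);
  const int nr = coef.nrow(), nc = coef.ncol();
  double *p = coef.begin();
  for (int j = 0; j < nc; ++j)            // along rows (down each column)
    bspl_filter_line(p + (size_t)j * nr, nr, 1);
  for (int i = 0; i < nr; ++i)            // along columns
    bspl_filter_line(p + i, nc, nr);
  return coef;
}

// B-spline sample at 0-based (x = column, y = row); optional gradient
static double interp_bspl(const NumericMatrix &coef, double x, double y,
                          double *gx, double *gy) {
  const int nr = coef.nrow(), nc = coef.ncol();
  int ix = (int)std::floor(x), iy = (int)std::floor(y);
  double wx[4], wy[4], dwx[4], dwy[4];
  bspl_weights(x - ix, wx, gx ? dwx : (double *)0);
  bspl_weights(y - iy, wy, gy ? dwy : (double *)0);
  double val = 0.0, dvx = 0.0, dvy = 0.0;
  for (int j = 0; j < 4; ++j) {
    int cc = mirr(ix - 1 + j, nc);
    double colv = 0.0, colg = 0.0;
    for (int i = 0; i < 4; ++i) {
      double c = coef(mirr(iy - 1 + i, nr), cc);
      colv += wy[i] * c;
      if (gy) colg += dwy[i] * c;
    }
    val += wx[j] * colv;
    if (gx) dvx += dwx[j] * colv;
    if (gy) dvy += wx[j] * colg;
  }
  if (gx) *gx = dvx;
  if (gy) *gy = dvy;
  return val;
}

// Keys bicubic sampling of an image at arbitrary points (renderer)
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_interp(NumericMatrix img, NumericVector x, NumericVector y) {
  const int n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = interp_keys(img, x[k], y[k]);
  return out;
}

// B-spline sampling from prefiltered coefficients
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_interp_coef(NumericMatrix coef, NumericVector x,
                              NumericVector y) {
  const int n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = interp_bspl(coef, x[k], y[k], 0, 0);
  return out;
}

// ZNCC between a zero-normalized reference vector and raw window values
static double zncc_of(const std::vector<double> &fn,
                      const std::vector<double> &g) {
  const int n = g.size();
  double gb = 0.0;
  for (int k = 0; k < n; ++k) gb += g[k];
  gb /= n;
  double sg = 0.0, cr = 0.0;
  for (int k = 0; k < n; ++k) {
    double d = g[k] - gb;
    sg += d * d;
    cr += fn[k] * d;
  }
  if (sg < 1e-20) return NA_REAL;
  return cr / std::sqrt(sg);
}

// Match one square subset (half-width `half`) centred at subpixel (cx, cy)
// of the reference frame against the current frame: exhaustive integer
// search of radius `radius` around init on raw pixels, then translation-only
// Gauss-Newton minimizing ZNSSD on the B-spline interpolant (paraboloid fit
// of the 3x3 ZNCC surface as fallback).
// flag: 0 ok, 1 optimum on search border, 2 invalid (flat/out of bounds),
//       3 paraboloid fallback used.
// [[Rcpp::export]]
NumericVector cpp_match_subset(NumericMatrix ref_coef, NumericMatrix cur,
                               NumericMatrix cur_coef,
                               double cx, double cy, int half, int radius,
                               double init_du, double init_dv,
                               int max_iter, double tol) {
  const int nr = cur.nrow(), nc = cur.ncol();
  const int m = 2 * half + 1, npix = m * m;
  NumericVector out = NumericVector::create(NA_REAL, NA_REAL, NA_REAL, 2.0);

  if (cx - half < 1 || cx + half > ref_coef.ncol() - 2 ||
      cy - half < 1 || cy + half > ref_coef.nrow() - 2)
    return out;

  std::vector<double> f(npix), fn(npix), g(npix);
  int k = 0;
  double fb = 0.0;
  for (int j = -half; j <= half; ++j)
    for (int i = -half; i <= half; ++i, ++k) {
      f[k] = interp_bspl(ref_coef, cx + i, cy + j, 0, 0);
      fb += f[k];
    }
  fb /= npix;
  double sf = 0.0;
  for (k = 0; k < npix; ++k) {
    fn[k] = f[k] - fb;
    sf += fn[k] * fn[k];
  }
  sf = std::sqrt(sf);
  if (sf < 1e-10) return out; // flat subset
  for (k = 0; k < npix; ++k) fn[k] /= sf;

  // integer search on the raw pixel grid of cur
  const int bx = (int)std::lround(cx), by = (int)std::lround(cy);
  const int idu = (int)std::lround(init_du), idv = (int)std::lround(init_dv);
  const int nsrch = 2 * radius + 1;
  std::vector<double> surf(nsrch * nsrch, NA_REAL);
  double best = -2.0;
  int bu = 0, bv = 0;
  bool any = false;
  for (int dv = -radius; dv <= radius; ++dv) {
    int y0 = by + idv + dv;
    if (y0 - half < 0 || y0 + half > nr - 1) continue;
    for (int du = -radius; du <= radius; ++du) {
      int x0 = bx + idu + du;
      if (x0 - half < 0 || x0 + half > nc - 1) continue;
      k = 0;
      for (int j = -half; j <= half; ++j)
        for (int i = -half; i <= half; ++i, ++k)
          g[k] = cur(y0 + j, x0 + i);
      double c = zncc_of(fn, g);
      if (ISNA(c)) continue;
      surf[(dv + radius) * nsrch + (du + radius)] = c;
      any = true;
      if (c > best) { best = c; bu = du; bv = dv; }
    }
  }
  if (!any) return out;
  int flag = 0;
  if (std::abs(bu) == radius || std::abs(bv) == radius) flag = 1;

  double pu = bx + idu + bu - cx;
  double pv = by + idv + bv - cy;

  // Gauss-Newton refinement of (pu, pv)
  bool converged = false;
  double gx, gy;
  for (int it = 0; it < max_iter; ++it) {
    double x0 = cx + pu, y0 = cy + pv;
    if (x0 - half < 1 || x0 + half > nc - 2 ||
        y0 - half < 1 || y0 + half > nr - 2) { flag = 1; break; }
    double gb = 0.0;
    std::vector<double> gvx(npix), gvy(npix);
    k = 0;
    for (int j = -half; j <= half; ++j)
      for (int i = -half; i <= half; ++i, ++k) {
        g[k] = interp_bspl(cur_coef, x0 + i, y0 + j, &gx, &gy);
        gvx[k] = gx; gvy[k] = gy;
        gb += g[k];
      }
    gb /= npix;
    double sg = 0.0;
    for (k = 0; k < npix; ++k) { double d = g[k] - gb; sg += d * d; }
    sg = std::sqrt(sg);
    if (sg < 1e-10) break;
    // residual e_k = gn_k - fn_k; d e_k/d p ~ grad g_k / sg (mean/scale
    // terms of the normalization neglected, standard for ZNSSD GN)
    double h11 = 0, h12 = 0, h22 = 0, b1 = 0, b2 = 0;
    for (k = 0; k < npix; ++k) {
      double e = (g[k] - gb) / sg - fn[k];
      double jx = gvx[k] / sg, jy = gvy[k] / sg;
      h11 += jx * jx; h12 += jx * jy; h22 += jy * jy;
      b1 += jx * e; b2 += jy * e;
    }
    double det = h11 * h22 - h12 * h12;
    if (det < 1e-16) break;
    double su = -(h22 * b1 - h12 * b2) / det;
    double sv = -(-h12 * b1 + h11 * b2) / det;
    if (std::sqrt(su * su + sv * sv) > 1.5) break; // diverging
    pu += su; pv += sv;
    if (std::sqrt(su * su + sv * sv) < tol) { converged = true; break; }
  }

  if (!converged && flag != 1) {
    // paraboloid fit of the 3x3 integer ZNCC surface around the optimum
    pu = bx + idu + bu - cx;
    pv = by + idv + bv - cy;
    int iu = bu + radius, iv = bv + radius;
    if (iu > 0 && iu < nsrch - 1 && iv > 0 && iv < nsrch - 1) {
      double cm = surf[iv * nsrch + iu];
      double cl = surf[iv * nsrch + iu - 1], cr = surf[iv * nsrch + iu + 1];
      double cd = surf[(iv - 1) * nsrch + iu], cu2 = surf[(iv + 1) * nsrch + iu];
      if (!ISNA(cl) && !ISNA(cr) && (cl - 2 * cm + cr) < 0)
        pu += 0.5 * (cl - cr) / (cl - 2 * cm + cr);
      if (!ISNA(cd) && !ISNA(cu2) && (cd - 2 * cm + cu2) < 0)
        pv += 0.5 * (cd - cu2) / (cd - 2 * cm + cu2);
    }
    flag = 3;
  }

  // quality: ZNCC at the final position
  double x0 = cx + pu, y0 = cy + pv, q = NA_REAL;
  if (x0 - half >= 1 && x0 + half <= nc - 2 &&
      y0 - half >= 1 && y0 + half <= nr - 2) {
    k = 0;
    for (int j = -half; j <= half; ++j)
      for (int i = -half; i <= half; ++i, ++k)
        g[k] = interp_bspl(cur_coef, x0 + i, y0 + j, 0, 0);
    q = zncc_of(fn, g);
  } else {
    flag = 1;
    q = best;
  }

  out[0] = pu; out[1] = pv; out[2] = q; out[3] = flag;
  return out;
}

// Match every grid point between one frame pair. Positions (px, py) are the
// points' current (accumulated) subpixel locations in the reference frame;
// init_* the per-point initial increment guess. Returns n x 4
// (du, dv, quality, flag).
// [[Rcpp::export]]
NumericMatrix cpp_match_frame(NumericMatrix ref_coef, NumericMatrix cur,
                              NumericMatrix cur_coef,
                              NumericVector px, NumericVector py,
                              int half, int radius,
                              NumericVector init_du, NumericVector init_dv,
                              int max_iter, double tol) {
  const int n = px.size();
  NumericMatrix out(n, 4);
  for (int k = 0; k < n; ++k) {
    NumericVector r = cpp_match_subset(ref_coef, cur, cur_coef,
                                       px[k], py[k], half, radius,
                                       init_du[k], init_dv[k], max_iter, tol);
    for (int j = 0; j < 4; ++j) out(k, j) = r[j];
  }
  return out;
}
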