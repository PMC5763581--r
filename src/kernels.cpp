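#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cubic B-spline basis, 1-indexed convention B1..B4 on the local coordinate
// j in [0,1): B1 weights the control point one knot before floor(u), B4 the
// one two knots after.  Sum over the four is exactly 1 for every j.
static inline void bspline_w(double j, double* w) {
  double j2 = j * j, j3 = j2 * j;
  w[0] = (1.0 - 3.0 * j + 3.0 * j2 - j3) / 6.0;
  w[1] = (3.0 * j3 - 6.0 * j2 + 4.0) / 6.0;
  w[2] = (-3.0 * j3 + 3.0 * j2 + 3.0 * j + 1.0) / 6.0;
  w[3] = j3 / 6.0;
}

// Lattice convention: storage index a (0-based) corresponds to lattice
// coordinate a - 2, i.e. control point a sits at pixel (a - 2) * spacing.
// A pixel coordinate y has u = y / spacing, l = floor(u), and is supported
// by storage rows l .. l + 3 with weights B1..B4(u - l).
struct Axis {
  std::vector<int> l;        // base storage index per sample
  std::vector<double> w;     // 4 weights per sample
};

static Axis axis_weights(const std::vector<double>& coords, double spacing, int K,
                         const char* what) {
  Axis ax;
  size_t n = coords.size();
  ax.l.resize(n);
  ax.w.resize(4 * n);
  for (size_t i = 0; i < n; ++i) {
    double u = coords[i] / spacing;
    int l = (int)std::floor(u);
    if (l < 0 || l + 3 > K - 1)
      stop("%s coordinate %f outside control-point support", what, coords[i]);
    ax.l[i] = l;
    bspline_w(u - l, &ax.w[4 * i]);
  }
  return ax;
}

static std::vector<double> as_dvec(NumericVector v) {
  return std::vector<double>(v.begin(), v.end());
}

// [[Rcpp::export]]
List eval_disp_rows_cpp(NumericVector coef, IntegerVector kdim, double spacing,
                        NumericVector rows, int ncol) {
  int K1 = kdim[0], K2 = kdim[1];
  int nr = rows.size();
  std::vector<double> colc(ncol);
  for (int c = 0; c < ncol; ++c) colc[c] = c;
  Axis ar = axis_weights(as_dvec(rows), spacing, K1, "row");
  Axis ac = axis_weights(colc, spacing, K2, "column");
  NumericMatrix fy(nr, ncol), fx(nr, ncol);
  const double* cf = coef.begin();
  int plane = K1 * K2;
  for (int c = 0; c < ncol; ++c) {
    int lc = ac.l[c];
    const double* wc = &ac.w[4 * c];
    for (int r = 0; r < nr; ++r) {
      int lr = ar.l[r];
      const double* wr = &ar.w[4 * r];
      double sy = 0.0, sx = 0.0;
      for (int b = 0; b < 4; ++b) {
        int off = (lc + b) * K1 + lr;
        double wb = wc[b];
        for (int a = 0; a < 4; ++a) {
          double w = wr[a] * wb;
          sy += w * cf[off + a];
          sx += w * cf[plane + off + a];
        }
      }
      fy(r, c) = sy;
      fx(r, c) = sx;
    }
  }
  return List::create(_["fy"] = fy, _["fx"] = fx);
}

// [[Rcpp::export]]
NumericVector proj_cpg_rows_cpp(NumericMatrix gy, NumericMatrix gx,
                                IntegerVector kdim, double spacing,
                                NumericVector rows) {
  int K1 = kdim[0], K2 = kdim[1];
  int nr = gy.nrow(), ncol = gy.ncol();
  if (gx.nrow() != nr || gx.ncol() != ncol) stop("gradient component shape mismatch");
  if (rows.size() != nr) stop("rows length must match gradient rows");
  std::vector<double> colc(ncol);
  for (int c = 0; c < ncol; ++c) colc[c] = c;
  Axis ar = axis_weights(as_dvec(rows), spacing, K1, "row");
  Axis ac = axis_weights(colc, spacing, K2, "column");
  NumericVector out(K1 * K2 * 2);
  out.attr("dim") = IntegerVector::create(K1, K2, 2);
  double* o = out.begin();
  int plane = K1 * K2;
  for (int c = 0; c < ncol; ++c) {
    int lc = ac.l[c];
    const double* wc = &ac.w[4 * c];
    for (int r = 0; r < nr; ++r) {
      int lr = ar.l[r];
      const double* wr = &ar.w[4 * r];
      double vy = gy(r, c), vx = gx(r, c);
      for (int b = 0; b < 4; ++b) {
        int off = (lc + b) * K1 + lr;
        double wb = wc[b];
        for (int a = 0; a < 4; ++a) {
          double w = wr[a] * wb;
          o[off + a] += w * vy;
          o[plane + off + a] += w * vx;
        }
      }
    }
  }
  return out;
}

static inline double img_get(const double* im, int nr, int nc, int r, int c,
                             double pad) {
  if (r < 0 || r >= nr || c < 0 || c >= nc) return pad;
  return im[r + c * nr];
}

// Pull-interpolation of `img` at positions (rows[i] + fy, c + fx), with the
// exact derivative of the bilinear interpolant with respect to the sample
// position (piecewise-constant per cell), needed for analytic cost gradients.
// [[Rcpp::export]]
List warp_rows_cpp(NumericMatrix img, NumericMatrix fy, NumericMatrix fx,
                   NumericVector rows, double pad, bool want_grad) {
  int nr = fy.nrow(), nc = fy.ncol();
  if (fx.nrow() != nr || fx.ncol() != nc) stop("field component shape mismatch");
  if (rows.size() != nr) stop("rows length must match field rows");
  int inr = img.nrow(), inc = img.ncol();
  const double* im = img.begin();
  NumericMatrix out(nr, nc);
  NumericMatrix gy, gx;
  if (want_grad) { gy = NumericMatrix(nr, nc); gx = NumericMatrix(nr, nc); }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double y = rows[r] + fy(r, c);
      double x = c + fx(r, c);
      if (!std::isfinite(y) || !std::isfinite(x)) stop("non-finite displacement field");
      int iy = (int)std::floor(y), ix = (int)std::floor(x);
      double dy = y - iy, dx = x - ix;
      double v00 = img_get(im, inr, inc, iy, ix, pad);
      double v10 = img_get(im, inr, inc, iy + 1, ix, pad);
      double v01 = img_get(im, inr, inc, iy, ix + 1, pad);
      double v11 = img_get(im, inr, inc, iy + 1, ix + 1, pad);
      out(r, c) = (1 - dy) * ((1 - dx) * v00 + dx * v01) +
                  dy * ((1 - dx) * v10 + dx * v11);
      if (want_grad) {
        gy(r, c) = (1 - dx) * (v10 - v00) + dx * (v11 - v01);
        gx(r, c) = (1 - dy) * (v01 - v00) + dy * (v11 - v10);
      }
    }
  }
  if (want_grad) return List::create(_["warped"] = out, _["gy"] = gy, _["gx"] = gx);
  return List::create(_["warped"] = out);
}

// Push-interpolation (the adjoint of warp_rows_cpp's pull with zero padding):
// each source pixel splats its value to the 4 output pixels around its pushed
// position with bilinear weights; `wgt` accumulates the splat of ones.
// [[Rcpp::export]]
List push_rows_cpp(NumericMatrix vals, NumericMatrix fy, NumericMatrix fx,
                   NumericVector rows, int out_nrow, int out_ncol) {
  int nr = vals.nrow(), nc = vals.ncol();
  if (fy.nrow() != nr || fy.ncol() != nc || fx.nrow() != nr || fx.ncol() != nc)
    stop("field component shape mismatch");
  if (rows.size() != nr) stop("rows length must match value rows");
  NumericMatrix acc(out_nrow, out_ncol), wgt(out_nrow, out_ncol);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double y = rows[r] + fy(r, c);
      double x = c + fx(r, c);
      if (!std::isfinite(y) || !std::isfinite(x)) stop("non-finite displacement field");
      int iy = (int)std::floor(y), ix = (int)std::floor(x);
      double dy = y - iy, dx = x - ix;
      double v = vals(r, c);
      for (int b = 0; b < 2; ++b) {
        int cc = ix + b;
        if (cc < 0 || cc >= out_ncol) continue;
        double wb = b ? dx : 1 - dx;
        for (int a = 0; a < 2; ++a) {
          int rr = iy + a;
          if (rr < 0 || rr >= out_nrow) continue;
          double w = wb * (a ? dy : 1 - dy);
          acc(rr, cc) += w * v;
          wgt(rr, cc) += w;
        }
      }
    }
  }
  return List::create(_["acc"] = acc, _["wgt"] = wgt);
}

static std::vector<double> gauss_kernel_vec(double sigma) {
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto& v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector gauss_kernel_cpp(double sigma) {
  std::vector<double> k = gauss_kernel_vec(sigma);
  return NumericVector(k.begin(), k.end());
}

// Fused total-cost/gradient driver for correspondence-model fitting.
//
// Rcoefs: list of N_r control-point coefficient arrays (K1 x K2 x 2);
// Phi: N_frames x N_r basis-value matrix; frames: list of n_rows x ncol
// partial-data matrices; specm: N_frames x 3 integer matrix (mode, row_start,
// n_rows) with mode 0 = full, 1 = slab/slice row extraction, 2 = Gaussian
// thick-slice profile (sigma per frame in `sigmas`).  Image grid nrow x ncol.
// Per frame only the rows inside the acquisition support are evaluated.
// [[Rcpp::export]]
List cost_grad_total_cpp(NumericMatrix I0, List Rcoefs, NumericMatrix Phi,
                         List frames, IntegerMatrix specm, NumericVector sigmas,
                         IntegerVector kdim, double spacing,
                         int nrow, int ncol, double pad, bool want_grad) {
  int Nf = frames.size();
  int Nr = Rcoefs.size();
  if (Phi.nrow() != Nf || Phi.ncol() != Nr) stop("Phi shape mismatch");
  int K1 = kdim[0], K2 = kdim[1];
  int plane = K1 * K2, csz = plane * 2;
  std::vector<const double*> Rp(Nr);
  for (int n = 0; n < Nr; ++n) {
    NumericVector rn = Rcoefs[n];
    if (rn.size() != csz) stop("coefficient set %d has wrong size", n + 1);
    Rp[n] = rn.begin();
  }
  // column weights shared by every frame
  std::vector<double> colc(ncol);
  for (int c = 0; c < ncol; ++c) colc[c] = c;
  Axis ac = axis_weights(colc, spacing, K2, "column");

  std::vector<double> Mcoef(csz);
  List grads(Nr);
  std::vector<double*> Gp(Nr, (double*)nullptr);
  if (want_grad) {
    for (int n = 0; n < Nr; ++n) {
      NumericVector g(csz);
      g.attr("dim") = IntegerVector::create(K1, K2, 2);
      grads[n] = g;
      Gp[n] = ((NumericVector)grads[n]).begin();
    }
  }
  const double* im = I0.begin();
  int inr = I0.nrow(), inc = I0.ncol();
  double cost = 0.0;
  NumericVector frame_cost(Nf);

  for (int t = 0; t < Nf; ++t) {
    int mode = specm(t, 0), row_start = specm(t, 1), n_rows = specm(t, 2);
    NumericMatrix P = frames[t];
    if (mode == 0) { row_start = 0; n_rows = nrow; }
    if (row_start < 0 || row_start + n_rows > nrow)
      stop("frame %d: acquisition rows out of bounds", t + 1);
    if (P.nrow() != n_rows || P.ncol() != ncol)
      stop("frame %d: partial data shape mismatch", t + 1);

    std::vector<double> kern;
    int rad = 0, need0 = row_start, need1 = row_start + n_rows - 1;
    if (mode == 2) {
      kern = gauss_kernel_vec(sigmas[t]);
      rad = ((int)kern.size() - 1) / 2;
      need0 = std::max(0, row_start - rad);
      need1 = std::min(nrow - 1, row_start + n_rows - 1 + rad);
    }
    int nneed = need1 - need0 + 1;

    // combine model coefficients over the touched control-point row band
    int lr0 = (int)std::floor(need0 / spacing);
    int lr1 = (int)std::floor(need1 / spacing) + 3;
    if (lr1 > K1 - 1) stop("frame %d: rows outside control-point support", t + 1);
    for (int b = 0; b < K2; ++b)
      for (int comp = 0; comp < 2; ++comp)
        for (int a = lr0; a <= lr1; ++a) {
          int idx = comp * plane + b * K1 + a;
          double s = 0.0;
          for (int n = 0; n < Nr; ++n) s += Phi(t, n) * Rp[n][idx];
          Mcoef[idx] = s;
        }

    // displacement, warp (+ interpolation gradient) over the needed rows
    std::vector<double> W(nneed * ncol), Gy, Gx;
    if (want_grad) { Gy.resize(nneed * ncol); Gx.resize(nneed * ncol); }
    std::vector<double> rw(4 * nneed);
    std::vector<int> rl(nneed);
    for (int r = 0; r < nneed; ++r) {
      double u = (need0 + r) / spacing;
      int l = (int)std::floor(u);
      rl[r] = l;
      bspline_w(u - l, &rw[4 * r]);
    }
    for (int c = 0; c < ncol; ++c) {
      int lc = ac.l[c];
      const double* wc = &ac.w[4 * c];
      for (int r = 0; r < nneed; ++r) {
        const double* wr = &rw[4 * r];
        double fy = 0.0, fx = 0.0;
        for (int b = 0; b < 4; ++b) {
          int off = (lc + b) * K1 + rl[r];
          double wb = wc[b];
          for (int a = 0; a < 4; ++a) {
            double w = wr[a] * wb;
            fy += w * Mcoef[off + a];
            fx += w * Mcoef[plane + off + a];
          }
        }
        double y = (need0 + r) + fy, x = c + fx;
        if (!std::isfinite(y) || !std::isfinite(x))
          stop("frame %d: non-finite displacement", t + 1);
        int iy = (int)std::floor(y), ix = (int)std::floor(x);
        double dy = y - iy, dx = x - ix;
        double v00 = img_get(im, inr, inc, iy, ix, pad);
        double v10 = img_get(im, inr, inc, iy + 1, ix, pad);
        double v01 = img_get(im, inr, inc, iy, ix + 1, pad);
        double v11 = img_get(im, inr, inc, iy + 1, ix + 1, pad);
        W[r + c * nneed] = (1 - dy) * ((1 - dx) * v00 + dx * v01) +
                           dy * ((1 - dx) * v10 + dx * v11);
        if (want_grad) {
          Gy[r + c * nneed] = (1 - dx) * (v10 - v00) + dx * (v11 - v01);
          Gx[r + c * nneed] = (1 - dy) * (v01 - v00) + dy * (v11 - v10);
        }
      }
    }

    // simulate the acquisition, residual, cost, and back-projected gradient
    std::vector<double> g(want_grad ? nneed * ncol : 0, 0.0);
    double fc = 0.0;
    if (mode != 2) {
      for (int c = 0; c < ncol; ++c)
        for (int r = 0; r < n_rows; ++r) {
          double resid = W[(row_start - need0 + r) + c * nneed] - P(r, c);
          fc += resid * resid;
          if (want_grad) g[(row_start - need0 + r) + c * nneed] = 2.0 * resid;
        }
    } else {
      for (int s = 0; s < n_rows; ++s) {
        int center = row_start + s;
        for (int c = 0; c < ncol; ++c) {
          double pa = 0.0;
          for (int y = std::max(0, center - rad); y <= std::min(nrow - 1, center + rad); ++y)
            pa += kern[y - center + rad] * W[(y - need0) + c * nneed];
          double resid = pa - P(s, c);
          fc += resid * resid;
          if (want_grad) {
            double dres = 2.0 * resid;
            for (int y = std::max(0, center - rad); y <= std::min(nrow - 1, center + rad); ++y)
              g[(y - need0) + c * nneed] += kern[y - center + rad] * dres;
          }
        }
      }
    }
    cost += fc;
    frame_cost[t] = fc;

    if (want_grad) {
      // project (g * interp-gradient) onto the control-point lattice, then
      // scatter into each coefficient-set gradient scaled by its basis value
      std::vector<double> Gc(csz, 0.0);
      for (int c = 0; c < ncol; ++c) {
        int lc = ac.l[c];
        const double* wc = &ac.w[4 * c];
        for (int r = 0; r < nneed; ++r) {
          double gv = g[r + c * nneed];
          if (gv == 0.0) continue;
          double py = gv * Gy[r + c * nneed];
          double px = gv * Gx[r + c * nneed];
          const double* wr = &rw[4 * r];
          for (int b = 0; b < 4; ++b) {
            int off = (lc + b) * K1 + rl[r];
            double wb = wc[b];
            for (int a = 0; a < 4; ++a) {
              double w = wr[a] * wb;
              Gc[off + a] += w * py;
              Gc[plane + off + a] += w * px;
            }
          }
        }
      }
      for (int n = 0; n < Nr; ++n) {
        double ph = Phi(t, n);
        if (ph == 0.0) continue;
        double* gp = Gp[n];
        for (int b = 0; b < K2; ++b)
          for (int comp = 0; comp < 2; ++comp) {
            int base = comp * plane + b * K1;
            for (int a = lr0; a <= lr1; ++a) gp[base + a] += ph * Gc[base + a];
          }
      }
    }
  }
  if (want_grad)
    return List::create(_["cost"] = cost, _["grads"] = grads,
                        _["frame_cost"] = frame_cost);
  return List::create(_["cost"] = cost, _["frame_cost"] = frame_cost);
}

// Streamed displacement-field-error pooling over all frames of a phantom
// study: per frame the true field is map1 * s_t + map2 * sdot_t per pixel,
// the mask is the body support pulled through the true field, and the
// estimated field is either zero (no-motion baseline) or the dense evaluation
// of the fitted model's control-point field.  Accumulates exact first/second
// moments and a fixed-bin histogram for percentile queries.
// [[Rcpp::export]]
List dfe_stream_cpp(NumericMatrix my1, NumericMatrix my2, NumericMatrix mx1,
                    NumericMatrix mx2, NumericVector s, NumericVector sdot,
                    NumericMatrix body, Nullable<List> Rcoefs_,
                    Nullable<NumericMatrix> Phi_, IntegerVector kdim,
                    double spacing, double bin_width, int nbins) {
  int nrow = my1.nrow(), ncol = my1.ncol();
  int Nf = s.size();
  bool have_model = Rcoefs_.isNotNull();
  List Rcoefs;
  NumericMatrix Phi;
  int Nr = 0, K1 = 0, K2 = 0, plane = 0, csz = 0;
  std::vector<const double*> Rp;
  std::vector<double> Mcoef;
  Axis ac;
  std::vector<int> rl(nrow);
  std::vector<double> rw(4 * nrow);
  if (have_model) {
    Rcoefs = Rcoefs_.get();
    Phi = Phi_.get();
    Nr = Rcoefs.size();
    K1 = kdim[0]; K2 = kdim[1]; plane = K1 * K2; csz = plane * 2;
    Rp.resize(Nr);
    for (int n = 0; n < Nr; ++n) Rp[n] = ((NumericVector)Rcoefs[n]).begin();
    Mcoef.resize(csz);
    std::vector<double> colc(ncol);
    for (int c = 0; c < ncol; ++c) colc[c] = c;
    ac = axis_weights(colc, spacing, K2, "column");
    for (int r = 0; r < nrow; ++r) {
      double u = r / spacing;
      int l = (int)std::floor(u);
      rl[r] = l;
      bspline_w(u - l, &rw[4 * r]);
    }
  }
  const double* bm = body.begin();
  double sum = 0.0, sumsq = 0.0, dmax = 0.0;
  double n_in = 0.0;
  NumericVector hist(nbins);
  for (int t = 0; t < Nf; ++t) {
    double st = s[t], sdt = sdot[t];
    if (have_model) {
      for (int i = 0; i < csz; ++i) {
        double v = 0.0;
        for (int n = 0; n < Nr; ++n) v += Phi(t, n) * Rp[n][i];
        Mcoef[i] = v;
      }
    }
    for (int c = 0; c < ncol; ++c) {
      for (int r = 0; r < nrow; ++r) {
        double fty = my1(r, c) * st + my2(r, c) * sdt;
        double ftx = mx1(r, c) * st + mx2(r, c) * sdt;
        // mask: inside the deformed phantom
        double y = r + fty, x = c + ftx;
        int iy = (int)std::floor(y), ix = (int)std::floor(x);
        double dy = y - iy, dx = x - ix;
        double b00 = img_get(bm, nrow, ncol, iy, ix, 0.0);
        double b10 = img_get(bm, nrow, ncol, iy + 1, ix, 0.0);
        double b01 = img_get(bm, nrow, ncol, iy, ix + 1, 0.0);
        double b11 = img_get(bm, nrow, ncol, iy + 1, ix + 1, 0.0);
        double bv = (1 - dy) * ((1 - dx) * b00 + dx * b01) +
                    dy * ((1 - dx) * b10 + dx * b11);
        if (bv < 0.5) continue;
        double ey = 0.0, ex = 0.0;
        if (have_model) {
          int lc = ac.l[c];
          const double* wc = &ac.w[4 * c];
          const double* wr = &rw[4 * r];
          for (int b = 0; b < 4; ++b) {
            int off = (lc + b) * K1 + rl[r];
            double wb = wc[b];
            for (int a = 0; a < 4; ++a) {
              double w = wr[a] * wb;
              ey += w * Mcoef[off + a];
              ex += w * Mcoef[plane + off + a];
            }
          }
        }
        double d = std::sqrt((fty - ey) * (fty - ey) + (ftx - ex) * (ftx - ex));
        sum += d;
        sumsq += d * d;
        n_in += 1.0;
        if (d > dmax) dmax = d;
        int bin = (int)(d / bin_width);
        if (bin >= nbins) bin = nbins - 1;
        hist[bin] += 1.0;
      }
    }
  }
  return List::create(_["n"] = n_in, _["sum"] = sum, _["sumsq"] = sumsq,
                      _["max"] = dmax, _["hist"] = hist,
                      _["bin_width"] = bin_width);
}
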