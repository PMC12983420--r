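#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Images are numeric matrices [row, col] with intensities in [0, 1],
// column-major as in R: element (r, c) at r + c * H.
// Point coordinates are 0-based (x = column, y = row), pixel centres at
// integer coordinates.

static inline double sample_clamp_ptr(const double* img, int H, int W,
                                      double x, double y) {
  if (x < 0.0) x = 0.0;
  if (x > W - 1.0) x = W - 1.0;
  if (y < 0.0) y = 0.0;
  if (y > H - 1.0) y = H - 1.0;
  int x0 = (int)x, y0 = (int)y;
  int x1 = x0 + 1 < W ? x0 + 1 : W - 1;
  int y1 = y0 + 1 < H ? y0 + 1 : H - 1;
  double fx = x - x0, fy = y - y0;
  const double* c0 = img + (size_t)x0 * H;
  const double* c1 = img + (size_t)x1 * H;
  return (1.0 - fx) * ((1.0 - fy) * c0[y0] + fy * c0[y1]) +
         fx * ((1.0 - fy) * c1[y0] + fy * c1[y1]);
}

// [[Rcpp::export]]
NumericVector sample_bilinear_cpp(NumericMatrix img, NumericVector xs,
                                  NumericVector ys) {
  const int H = img.nrow(), W = img.ncol();
  const double* p = REAL(img);
  const R_xlen_t n = xs.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = sample_clamp_ptr(p, H, W, xs[i], ys[i]);
  return out;
}

// 5-tap binomial blur [1 4 6 4 1]/16, separable, reflect at borders.
static void blur5_into(const double* src, int H, int W, double* tmp,
                       double* dst) {
  static const double k[5] = {1.0 / 16, 4.0 / 16, 6.0 / 16, 4.0 / 16,
                              1.0 / 16};
  // vertical pass (contiguous within a column)
  for (int c = 0; c < W; ++c) {
    const double* col = src + (size_t)c * H;
    double* out = tmp + (size_t)c * H;
    for (int r = 0; r < H; ++r) {
      double s = 0.0;
      for (int t = -2; t <= 2; ++t) {
        int rr = r + t;
        if (rr < 0) rr = -rr;
        if (rr > H - 1) rr = 2 * (H - 1) - rr;
        s += k[t + 2] * col[rr];
      }
      out[r] = s;
    }
  }
  // horizontal pass
  for (int c = 0; c < W; ++c) {
    int cc[5];
    for (int t = -2; t <= 2; ++t) {
      int x = c + t;
      if (x < 0) x = -x;
      if (x > W - 1) x = 2 * (W - 1) - x;
      cc[t + 2] = x;
    }
    double* out = dst + (size_t)c * H;
    const double* c0 = tmp + (size_t)cc[0] * H;
    const double* c1 = tmp + (size_t)cc[1] * H;
    const double* c2 = tmp + (size_t)cc[2] * H;
    const double* c3 = tmp + (size_t)cc[3] * H;
    const double* c4 = tmp + (size_t)cc[4] * H;
    for (int r = 0; r < H; ++r)
      out[r] = k[0] * c0[r] + k[1] * c1[r] + k[2] * c2[r] + k[3] * c3[r] +
               k[4] * c4[r];
  }
}

// [[Rcpp::export]]
List build_pyramid_cpp(NumericMatrix img, int levels) {
  List pyr(levels);
  pyr[0] = img;
  NumericMatrix cur = img;
  for (int L = 1; L < levels; ++L) {
    int H = cur.nrow(), W = cur.ncol();
    std::vector<double> tmp((size_t)H * W), sm((size_t)H * W);
    blur5_into(REAL(cur), H, W, tmp.data(), sm.data());
    int H2 = (H + 1) / 2, W2 = (W + 1) / 2;
    NumericMatrix down(H2, W2);
    double* d = REAL(down);
    for (int c = 0; c < W2; ++c) {
      int sc = 2 * c < W ? 2 * c : W - 1;
      const double* scol = sm.data() + (size_t)sc * H;
      for (int r = 0; r < H2; ++r)
        d[r + (size_t)c * H2] = scol[2 * r < H ? 2 * r : H - 1];
    }
    pyr[L] = down;
    cur = down;
  }
  return pyr;
}

// Iterative pyramidal Lucas-Kanade for a sparse point set.
// pts: n x 2 matrix of (x, y) in the frame-A image; returns n x 2 tracked
// positions in frame B plus a status flag (1 = usable).
// [[Rcpp::export]]
List lk_track_cpp(List pyr_a, List pyr_b, NumericMatrix pts, int win_half,
                  int max_iter, double eps) {
  const int levels = pyr_a.size();
  const int n = pts.nrow();
  const int wsz = 2 * win_half + 1;
  const int npx = wsz * wsz;
  NumericMatrix out(n, 2);
  IntegerVector status(n);
  NumericVector ncc(n);

  std::vector<double> Iw(npx), Ix(npx), Iy(npx);
  std::vector<const double*> pa(levels), pb(levels);
  std::vector<int> Ha(levels), Wa(levels), Hb(levels), Wb(levels);
  for (int L = 0; L < levels; ++L) {
    NumericMatrix A = pyr_a[L], B = pyr_b[L];
    pa[L] = REAL(A); Ha[L] = A.nrow(); Wa[L] = A.ncol();
    pb[L] = REAL(B); Hb[L] = B.nrow(); Wb[L] = B.ncol();
  }

  for (int i = 0; i < n; ++i) {
    double gx = 0.0, gy = 0.0;  // guess displacement at current level
    bool ok = true;
    for (int L = levels - 1; L >= 0; --L) {
      const double* A = pa[L];
      const double* B = pb[L];
      const int HA = Ha[L], WA = Wa[L], HB = Hb[L], WB = Wb[L];
      const double scale = (double)(1 << L);
      const double px = pts(i, 0) / scale, py = pts(i, 1) / scale;

      // reference window and gradients; fast path when the (window + 1 px
      // gradient support) block lies fully inside the image
      double a11 = 0.0, a12 = 0.0, a22 = 0.0;
      const double bx = px - win_half, by = py - win_half;
      const int ix0 = (int)std::floor(bx), iy0 = (int)std::floor(by);
      const double fx = bx - ix0, fy = by - iy0;
      if (ix0 >= 1 && iy0 >= 1 && ix0 + wsz + 1 < WA && iy0 + wsz + 1 < HA) {
        const double w00 = (1 - fx) * (1 - fy), w01 = (1 - fx) * fy;
        const double w10 = fx * (1 - fy), w11 = fx * fy;
        for (int dx = 0; dx < wsz; ++dx) {
          const double* cL = A + (size_t)(ix0 + dx) * HA + iy0;
          const double* cR = cL + HA;
          const double* cLL = cL - HA;
          const double* cRR = cR + HA;
          double* iw = Iw.data() + (size_t)dx * wsz;
          double* ixv = Ix.data() + (size_t)dx * wsz;
          double* iyv = Iy.data() + (size_t)dx * wsz;
          for (int dy = 0; dy < wsz; ++dy) {
            const double v = w00 * cL[dy] + w01 * cL[dy + 1] +
                             w10 * cR[dy] + w11 * cR[dy + 1];
            const double vxp = w00 * cR[dy] + w01 * cR[dy + 1] +
                               w10 * cRR[dy] + w11 * cRR[dy + 1];
            const double vxm = w00 * cLL[dy] + w01 * cLL[dy + 1] +
                               w10 * cL[dy] + w11 * cL[dy + 1];
            const double vyp = w00 * cL[dy + 1] + w01 * cL[dy + 2] +
                               w10 * cR[dy + 1] + w11 * cR[dy + 2];
            const double vym = w00 * cL[dy - 1] + w01 * cL[dy] +
                               w10 * cR[dy - 1] + w11 * cR[dy];
            iw[dy] = v;
            const double ix = 0.5 * (vxp - vxm);
            const double iy = 0.5 * (vyp - vym);
            ixv[dy] = ix; iyv[dy] = iy;
            a11 += ix * ix; a12 += ix * iy; a22 += iy * iy;
          }
        }
      } else {
        int k = 0;
        for (int dx = -win_half; dx <= win_half; ++dx)
          for (int dy = -win_half; dy <= win_half; ++dy, ++k) {
            const double sx = px + dx, sy = py + dy;
            Iw[k] = sample_clamp_ptr(A, HA, WA, sx, sy);
            const double ix =
                0.5 * (sample_clamp_ptr(A, HA, WA, sx + 1.0, sy) -
                       sample_clamp_ptr(A, HA, WA, sx - 1.0, sy));
            const double iy =
                0.5 * (sample_clamp_ptr(A, HA, WA, sx, sy + 1.0) -
                       sample_clamp_ptr(A, HA, WA, sx, sy - 1.0));
            Ix[k] = ix; Iy[k] = iy;
            a11 += ix * ix; a12 += ix * iy; a22 += iy * iy;
          }
      }
      const double det = a11 * a22 - a12 * a12;
      if (det < 1e-12) { ok = false; break; }

      double nx = gx, ny = gy;
      for (int it = 0; it < max_iter; ++it) {
        double b1 = 0.0, b2 = 0.0;
        const double cbx = px + nx - win_half, cby = py + ny - win_half;
        const int jx0 = (int)std::floor(cbx), jy0 = (int)std::floor(cby);
        const double gfx = cbx - jx0, gfy = cby - jy0;
        if (jx0 >= 0 && jy0 >= 0 && jx0 + wsz < WB && jy0 + wsz < HB) {
          const double w00 = (1 - gfx) * (1 - gfy), w01 = (1 - gfx) * gfy;
          const double w10 = gfx * (1 - gfy), w11 = gfx * gfy;
          for (int dx = 0; dx < wsz; ++dx) {
            const double* cL = B + (size_t)(jx0 + dx) * HB + jy0;
            const double* cR = cL + HB;
            const double* iw = Iw.data() + (size_t)dx * wsz;
            const double* ixv = Ix.data() + (size_t)dx * wsz;
            const double* iyv = Iy.data() + (size_t)dx * wsz;
            for (int dy = 0; dy < wsz; ++dy) {
              const double diff = w00 * cL[dy] + w01 * cL[dy + 1] +
                                  w10 * cR[dy] + w11 * cR[dy + 1] - iw[dy];
              b1 += diff * ixv[dy];
              b2 += diff * iyv[dy];
            }
          }
        } else {
          int k = 0;
          for (int dx = -win_half; dx <= win_half; ++dx)
            for (int dy = -win_half; dy <= win_half; ++dy, ++k) {
              const double diff = sample_clamp_ptr(B, HB, WB, px + nx + dx,
                                                   py + ny + dy) - Iw[k];
              b1 += diff * Ix[k];
              b2 += diff * Iy[k];
            }
        }
        const double ux = (a22 * b1 - a12 * b2) / det;
        const double uy = (a11 * b2 - a12 * b1) / det;
        nx -= ux;
        ny -= uy;
        if (ux * ux + uy * uy < eps * eps) break;
      }
      if (L > 0) {
        gx = 2.0 * nx;
        gy = 2.0 * ny;
      } else {
        gx = nx;
        gy = ny;
      }
    }
    const double fxp = pts(i, 0) + gx, fyp = pts(i, 1) + gy;
    if (fxp < 0.0 || fyp < 0.0 || fxp > Wb[0] - 1.0 || fyp > Hb[0] - 1.0)
      ok = false;
    out(i, 0) = fxp;
    out(i, 1) = fyp;
    status[i] = ok ? 1 : 0;
    // appearance check: zero-mean normalized cross-correlation between the
    // level-0 reference window (still held in Iw) and the matched window
    double cc = 0.0;
    if (ok) {
      const double* B0 = pb[0];
      double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
      int k = 0;
      for (int dx = -win_half; dx <= win_half; ++dx)
        for (int dy = -win_half; dy <= win_half; ++dy, ++k) {
          const double a = Iw[k];
          const double b = sample_clamp_ptr(B0, Hb[0], Wb[0],
                                            fxp + dx, fyp + dy);
          sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
        }
      const double va = saa - sa * sa / npx;
      const double vb = sbb - sb * sb / npx;
      if (va > 1e-12 && vb > 1e-12)
        cc = (sab - sa * sb / npx) / std::sqrt(va * vb);
    }
    ncc[i] = cc;
  }
  return List::create(_["points"] = out, _["status"] = status,
                      _["ncc"] = ncc);
}

// Add N(0, sd) noise (drawn from R's RNG stream, column-major order, so
// results match matrix(rnorm(H*W, 0, sd), H, W)) and clip to [0, 1].
// [[Rcpp::export]]
NumericMatrix add_noise_clip_cpp(NumericMatrix img, double sd) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double* p = REAL(img);
  double* o = REAL(out);
  RNGScope scope;
  const size_t n = (size_t)H * W;
  for (size_t i = 0; i < n; ++i) {
    double v = p[i] + (sd > 0 ? norm_rand() * sd : 0.0);
    o[i] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
  }
  return out;
}

// Affine-warp sampler: out(r, c) = img(a21*c + a22*r + a23 (row),
// a11*c + a12*r + a13 (col)) with bilinear interpolation, edge-clamped.
// [[Rcpp::export]]
NumericMatrix warp_affine_cpp(NumericMatrix img, int out_h, int out_w,
                              NumericVector coef) {
  NumericMatrix out(out_h, out_w);
  const double a11 = coef[0], a12 = coef[1], a13 = coef[2];
  const double a21 = coef[3], a22 = coef[4], a23 = coef[5];
  const int H = img.nrow(), W = img.ncol();
  const double* p = REAL(img);
  double* o = REAL(out);
  for (int c = 0; c < out_w; ++c) {
    double sx = a11 * c + a13;
    double sy = a21 * c + a23;
    double* ocol = o + (size_t)c * out_h;
    for (int r = 0; r < out_h; ++r) {
      ocol[r] = sample_clamp_ptr(p, H, W, sx + a12 * r, sy + a22 * r);
    }
  }
  return out;
}
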