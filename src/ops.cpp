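// Low-level numerical kernels: convolution layers for the V-Net (direct
// loops for stride-1 kernels, GEMM for the block up/down convolutions),
// trilinear/nearest resampling for spatial
// augmentation, separable Gaussian smoothing, 3D connected components,
// surface voxel extraction and an exact Euclidean distance transform.
// All grids are column-major R arrays laid out (x, y, z[, channel]).

#include <RcppArmadillo.h>
#include <array>
#include <cstring>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef long long ll;

// ---------------------------------------------------------------------------
// stride-1 "same" convolution, arbitrary odd kernel, direct vectorized loops
// (channel counts are small, so im2col/GEMM would be memory-bound here)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector w, IntegerVector wdim,
                           NumericVector b) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int KX = wdim[0], KY = wdim[1], KZ = wdim[2], Cout = wdim[4];
  const ll N = (ll)X * Y * Z;
  const int px = (KX - 1) / 2, py = (KY - 1) / 2, pz = (KZ - 1) / 2;
  const int K = KX * KY * KZ;
  const double* xp = x.begin();
  const double* wp = w.begin();
  NumericVector y((R_xlen_t)(N * Cout));
  double* yp = y.begin();
  std::vector<double> acc(X);
  for (int co = 0; co < Cout; ++co) {
    double* yc = yp + N * co;
    for (int iz = 0; iz < Z; ++iz)
      for (int iy = 0; iy < Y; ++iy) {
        std::fill(acc.begin(), acc.end(), b[co]);
        for (int kz = 0; kz < KZ; ++kz) {
          const int sz = iz + kz - pz;
          if (sz < 0 || sz >= Z) continue;
          for (int ky = 0; ky < KY; ++ky) {
            const int sy = iy + ky - py;
            if (sy < 0 || sy >= Y) continue;
            for (int ci = 0; ci < Cin; ++ci) {
              const double* xrow = xp + N * ci + (ll)X * (sy + (ll)Y * sz);
              const double* wrow =
                wp + (ll)KX * (ky + KY * kz) + (ll)K * (ci + (ll)Cin * co);
              for (int kx = 0; kx < KX; ++kx) {
                const double wv = wrow[kx];
                const int ox = kx - px;
                const int ix0 = std::max(0, -ox), ix1 = std::min(X, X - ox);
                const double* xs = xrow + ox;
                for (int ix = ix0; ix < ix1; ++ix) acc[ix] += wv * xs[ix];
              }
            }
          }
        }
        std::memcpy(yc + (ll)X * (iy + (ll)Y * iz), acc.data(),
                    sizeof(double) * (size_t)X);
      }
  }
  y.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, IntegerVector xdim,
                  NumericVector w, IntegerVector wdim,
                  NumericVector gy) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int KX = wdim[0], KY = wdim[1], KZ = wdim[2], Cout = wdim[4];
  const ll N = (ll)X * Y * Z;
  const int px = (KX - 1) / 2, py = (KY - 1) / 2, pz = (KZ - 1) / 2;
  const int K = KX * KY * KZ;
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gy.begin();

  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + N * co;
    double s = 0;
    for (ll i = 0; i < N; ++i) s += gc[i];
    gb[co] = s;
  }

  // gx[j, ci] = sum_{o, co} gy[j - o, co] * w[o, ci, co]
  NumericVector gx((R_xlen_t)(N * Cin));
  double* gxp = gx.begin();
  std::vector<double> acc(X);
  for (int ci = 0; ci < Cin; ++ci) {
    double* gxc = gxp + N * ci;
    for (int iz = 0; iz < Z; ++iz)
      for (int iy = 0; iy < Y; ++iy) {
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int kz = 0; kz < KZ; ++kz) {
          const int sz = iz - (kz - pz);
          if (sz < 0 || sz >= Z) continue;
          for (int ky = 0; ky < KY; ++ky) {
            const int sy = iy - (ky - py);
            if (sy < 0 || sy >= Y) continue;
            for (int co = 0; co < Cout; ++co) {
              const double* grow = gp + N * co + (ll)X * (sy + (ll)Y * sz);
              const double* wrow =
                wp + (ll)KX * (ky + KY * kz) + (ll)K * (ci + (ll)Cin * co);
              for (int kx = 0; kx < KX; ++kx) {
                const double wv = wrow[kx];
                const int ox = kx - px;
                // gx[ix] += gy[ix - ox] * w
                const int ix0 = std::max(0, ox), ix1 = std::min(X, X + ox);
                const double* gs = grow - ox;
                for (int ix = ix0; ix < ix1; ++ix) acc[ix] += wv * gs[ix];
              }
            }
          }
        }
        std::memcpy(gxc + (ll)X * (iy + (ll)Y * iz), acc.data(),
                    sizeof(double) * (size_t)X);
      }
  }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);

  // gw[o, ci, co] = sum_n x[n + o, ci] * gy[n, co]
  NumericVector gw(w.size());
  double* gwp = gw.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + N * ci;
      const double* gc = gp + N * co;
      double* gwb = gwp + (ll)K * (ci + (ll)Cin * co);
      for (int iz = 0; iz < Z; ++iz)
        for (int iy = 0; iy < Y; ++iy) {
          const double* grow = gc + (ll)X * (iy + (ll)Y * iz);
          for (int kz = 0; kz < KZ; ++kz) {
            const int sz = iz + kz - pz;
            if (sz < 0 || sz >= Z) continue;
            for (int ky = 0; ky < KY; ++ky) {
              const int sy = iy + ky - py;
              if (sy < 0 || sy >= Y) continue;
              const double* xrow = xc + (ll)X * (sy + (ll)Y * sz);
              double* gwrow = gwb + (ll)KX * (ky + KY * kz);
              for (int kx = 0; kx < KX; ++kx) {
                const int ox = kx - px;
                const int ix0 = std::max(0, -ox), ix1 = std::min(X, X - ox);
                const double* xs = xrow + ox;
                double s = 0;
                for (int ix = ix0; ix < ix1; ++ix) s += xs[ix] * grow[ix];
                gwrow[kx] += s;
              }
            }
          }
        }
    }
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// PReLU forward/backward (per-channel slope)

// [[Rcpp::export]]
NumericVector cpp_prelu_fwd(NumericVector x, IntegerVector xdim,
                            NumericVector alpha) {
  const ll N = (ll)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double a = alpha[c];
    const double* xc = xp + N * c;
    double* yc = yp + N * c;
    for (ll i = 0; i < N; ++i) yc[i] = xc[i] > 0 ? xc[i] : a * xc[i];
  }
  y.attr("dim") = xdim;
  return y;
}

// [[Rcpp::export]]
List cpp_prelu_bwd(NumericVector x, IntegerVector xdim, NumericVector alpha,
                   NumericVector gy) {
  const ll N = (ll)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector gx(x.size());
  NumericVector ga(C);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double a = alpha[c];
    const double* xc = xp + N * c;
    const double* gc = gp + N * c;
    double* gxc = gxp + N * c;
    double s = 0;
    for (ll i = 0; i < N; ++i) {
      if (xc[i] > 0) {
        gxc[i] = gc[i];
      } else {
        gxc[i] = a * gc[i];
        s += gc[i] * xc[i];
      }
    }
    ga[c] = s;
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["ga"] = ga);
}

// ---------------------------------------------------------------------------
// non-overlapping block (strided) down-convolution and its transpose
// ---------------------------------------------------------------------------

static void blockcol_gather(const double* x, int X, int Y, int Z, int Cin,
                            int bx, int by, int bz, arma::mat& col) {
  const int Xo = X / bx, Yo = Y / by, Zo = Z / bz;
  const ll No = (ll)Xo * Yo * Zo;
  const int B = bx * by * bz;
  const ll N = (ll)X * Y * Z;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + N * ci;
    for (int dz = 0; dz < bz; ++dz)
      for (int dy = 0; dy < by; ++dy)
        for (int dx = 0; dx < bx; ++dx) {
          const int bo = dx + bx * (dy + by * dz);
          double* cj = col.colptr(bo + (ll)B * ci);
          for (int oz = 0; oz < Zo; ++oz) {
            const int sz = oz * bz + dz;
            for (int oy = 0; oy < Yo; ++oy) {
              const int sy = oy * by + dy;
              const double* src = xc + dx + (ll)X * (sy + (ll)Y * sz);
              double* dst = cj + (ll)Xo * (oy + (ll)Yo * oz);
              for (int ox = 0; ox < Xo; ++ox) dst[ox] = src[(ll)ox * bx];
            }
          }
        }
  }
  (void)No;
}

// [[Rcpp::export]]
NumericVector cpp_down_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector w, NumericVector b,
                           IntegerVector block, int cout) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int bx = block[0], by = block[1], bz = block[2];
  const int Xo = X / bx, Yo = Y / by, Zo = Z / bz;
  const ll No = (ll)Xo * Yo * Zo;
  const int B = bx * by * bz;
  arma::mat col(No, (ll)B * Cin);
  blockcol_gather(x.begin(), X, Y, Z, Cin, bx, by, bz, col);
  const arma::mat W(const_cast<double*>(w.begin()), (ll)B * Cin, cout, false, true);
  NumericVector y((R_xlen_t)(No * cout));
  arma::mat Ym(y.begin(), No, cout, false, true);
  Ym = col * W;
  for (int co = 0; co < cout; ++co) Ym.col(co) += b[co];
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, cout);
  return y;
}

// [[Rcpp::export]]
List cpp_down_bwd(NumericVector x, IntegerVector xdim,
                  NumericVector w, IntegerVector block, int cout,
                  NumericVector gy) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int bx = block[0], by = block[1], bz = block[2];
  const int Xo = X / bx, Yo = Y / by, Zo = Z / bz;
  const ll No = (ll)Xo * Yo * Zo;
  const int B = bx * by * bz;
  arma::mat col(No, (ll)B * Cin);
  blockcol_gather(x.begin(), X, Y, Z, Cin, bx, by, bz, col);
  const arma::mat W(const_cast<double*>(w.begin()), (ll)B * Cin, cout, false, true);
  const arma::mat Gy(const_cast<double*>(gy.begin()), No, cout, false, true);

  NumericVector gw(w.size());
  arma::mat GW(gw.begin(), (ll)B * Cin, cout, false, true);
  GW = col.t() * Gy;
  gw.attr("dim") = w.attr("dim");

  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) gb[co] = arma::accu(Gy.col(co));

  arma::mat Gcol = Gy * W.t();
  NumericVector gx((R_xlen_t)((ll)X * Y * Z * Cin));
  double* gxp = gx.begin();
  const ll N = (ll)X * Y * Z;
  for (int ci = 0; ci < Cin; ++ci) {
    double* gxc = gxp + N * ci;
    for (int dz = 0; dz < bz; ++dz)
      for (int dy = 0; dy < by; ++dy)
        for (int dx = 0; dx < bx; ++dx) {
          const int bo = dx + bx * (dy + by * dz);
          const double* cj = Gcol.colptr(bo + (ll)B * ci);
          for (int oz = 0; oz < Zo; ++oz) {
            const int sz = oz * bz + dz;
            for (int oy = 0; oy < Yo; ++oy) {
              const int sy = oy * by + dy;
              double* dst = gxc + dx + (ll)X * (sy + (ll)Y * sz);
              const double* src = cj + (ll)Xo * (oy + (ll)Yo * oz);
              for (int ox = 0; ox < Xo; ++ox) dst[(ll)ox * bx] = src[ox];
            }
          }
        }
  }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed block convolution (upsampling). Weight matrix W: Cin x (B*Cout),
// column index bo + B*co.

// [[Rcpp::export]]
NumericVector cpp_up_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, NumericVector b,
                         IntegerVector block, int cout) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int bx = block[0], by = block[1], bz = block[2];
  const int X2 = X * bx, Y2 = Y * by, Z2 = Z * bz;
  const ll N = (ll)X * Y * Z;
  const int B = bx * by * bz;
  const arma::mat Xm(const_cast<double*>(x.begin()), N, Cin, false, true);
  const arma::mat W(const_cast<double*>(w.begin()), Cin, (ll)B * cout, false, true);
  arma::mat Ycol = Xm * W;  // N x B*Cout
  NumericVector y((R_xlen_t)((ll)X2 * Y2 * Z2 * cout));
  double* yp = y.begin();
  const ll N2 = (ll)X2 * Y2 * Z2;
  for (int co = 0; co < cout; ++co) {
    double* yc = yp + N2 * co;
    for (int dz = 0; dz < bz; ++dz)
      for (int dy = 0; dy < by; ++dy)
        for (int dx = 0; dx < bx; ++dx) {
          const int bo = dx + bx * (dy + by * dz);
          const double* src0 = Ycol.colptr(bo + (ll)B * co);
          const double bb = b[co];
          for (int iz = 0; iz < Z; ++iz)
            for (int iy = 0; iy < Y; ++iy) {
              const double* src = src0 + (ll)X * (iy + (ll)Y * iz);
              double* dst = yc + dx +
                (ll)X2 * ((iy * by + dy) + (ll)Y2 * (iz * bz + dz));
              for (int ix = 0; ix < X; ++ix) dst[(ll)ix * bx] = src[ix] + bb;
            }
        }
  }
  y.attr("dim") = IntegerVector::create(X2, Y2, Z2, cout);
  return y;
}

// [[Rcpp::export]]
List cpp_up_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector block, int cout,
                NumericVector gy) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int bx = block[0], by = block[1], bz = block[2];
  const int X2 = X * bx, Y2 = Y * by, Z2 = Z * bz;
  const ll N = (ll)X * Y * Z;
  const ll N2 = (ll)X2 * Y2 * Z2;
  const int B = bx * by * bz;
  const arma::mat Xm(const_cast<double*>(x.begin()), N, Cin, false, true);
  const arma::mat W(const_cast<double*>(w.begin()), Cin, (ll)B * cout, false, true);

  arma::mat Gycol(N, (ll)B * cout);
  const double* gyp = gy.begin();
  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) {
    const double* gc = gyp + N2 * co;
    double sb = 0.0;
    for (ll i = 0; i < N2; ++i) sb += gc[i];
    gb[co] = sb;
    for (int dz = 0; dz < bz; ++dz)
      for (int dy = 0; dy < by; ++dy)
        for (int dx = 0; dx < bx; ++dx) {
          const int bo = dx + bx * (dy + by * dz);
          double* dst0 = Gycol.colptr(bo + (ll)B * co);
          for (int iz = 0; iz < Z; ++iz)
            for (int iy = 0; iy < Y; ++iy) {
              double* dst = dst0 + (ll)X * (iy + (ll)Y * iz);
              const double* src = gc + dx +
                (ll)X2 * ((iy * by + dy) + (ll)Y2 * (iz * bz + dz));
              for (int ix = 0; ix < X; ++ix) dst[ix] = src[(ll)ix * bx];
            }
        }
  }
  NumericVector gx((R_xlen_t)(N * Cin));
  arma::mat GX(gx.begin(), N, Cin, false, true);
  GX = Gycol * W.t();
  gx.attr("dim") = xdim;
  NumericVector gw(w.size());
  arma::mat GW(gw.begin(), Cin, (ll)B * cout, false, true);
  GW = Xm.t() * Gycol;
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing (sigma per axis, in voxels)
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double>& a, int X, int Y, int Z,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double ks = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (i / sigma) * (i / sigma));
    ks += k[i + r];
  }
  for (double& v : k) v /= ks;
  const int dims[3] = {X, Y, Z};
  const int n = dims[axis];
  const ll strides[3] = {1, (ll)X, (ll)X * Y};
  const ll st = strides[axis];
  std::vector<double> line(n);
  // iterate over all lines along `axis`
  const int d1 = (axis == 0) ? 1 : 0;
  const int d2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < dims[d2]; ++j2)
    for (int j1 = 0; j1 < dims[d1]; ++j1) {
      const ll base = strides[d1] * j1 + strides[d2] * j2;
      for (int i = 0; i < n; ++i) line[i] = a[base + st * i];
      for (int i = 0; i < n; ++i) {
        double s = 0, wsum = 0;
        const int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
        for (int q = lo; q <= hi; ++q) {
          const double kw = k[q - i + r];
          s += kw * line[q];
          wsum += kw;
        }
        a[base + st * i] = s / wsum;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector x, IntegerVector dim3,
                             NumericVector sigma) {
  const int X = dim3[0], Y = dim3[1], Z = dim3[2];
  std::vector<double> a(x.begin(), x.end());
  blur_axis(a, X, Y, Z, 0, sigma[0]);
  blur_axis(a, X, Y, Z, 1, sigma[1]);
  blur_axis(a, X, Y, Z, 2, sigma[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim3;
  return out;
}

// ---------------------------------------------------------------------------
// resampling at arbitrary (0-based) voxel coordinates
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector x, IntegerVector dim3,
                           NumericMatrix coords, bool nearest, double fill) {
  const int X = dim3[0], Y = dim3[1], Z = dim3[2];
  const ll n = coords.nrow();
  const double* xp = x.begin();
  NumericVector out((R_xlen_t)n);
  for (ll i = 0; i < n; ++i) {
    const double cx = coords(i, 0), cy = coords(i, 1), cz = coords(i, 2);
    if (nearest) {
      const int ix = (int)std::lround(cx), iy = (int)std::lround(cy),
                iz = (int)std::lround(cz);
      out[i] = (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 || iz >= Z)
                 ? fill
                 : xp[ix + (ll)X * (iy + (ll)Y * iz)];
    } else {
      const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
                z0 = (int)std::floor(cz);
      const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
      double acc = 0;
      for (int dz = 0; dz <= 1; ++dz)
        for (int dy = 0; dy <= 1; ++dy)
          for (int dx = 0; dx <= 1; ++dx) {
            const int ix = x0 + dx, iy = y0 + dy, iz = z0 + dz;
            const double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                               (dz ? fz : 1 - fz);
            const double val =
              (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 || iz >= Z)
                ? fill
                : xp[ix + (ll)X * (iy + (ll)Y * iz)];
            acc += wgt * val;
          }
      out[i] = acc;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// connected components (6- or 26-connectivity), surface voxels, EDT
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim3,
                                   int connectivity) {
  const int X = dim3[0], Y = dim3[1], Z = dim3[2];
  const ll N = (ll)X * Y * Z;
  IntegerVector lab((R_xlen_t)N);
  std::vector<int> stack;
  int cur = 0;
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dx, dy, dz});
      }
  for (ll s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back((int)s);
    lab[s] = cur;
    while (!stack.empty()) {
      const ll p = stack.back();
      stack.pop_back();
      const int pz = (int)(p / ((ll)X * Y));
      const int py = (int)((p / X) % Y);
      const int px = (int)(p % X);
      for (const auto& d : nb) {
        const int qx = px + d[0], qy = py + d[1], qz = pz + d[2];
        if (qx < 0 || qx >= X || qy < 0 || qy >= Y || qz < 0 || qz >= Z)
          continue;
        const ll q = qx + (ll)X * (qy + (ll)Y * qz);
        if (mask[q] && !lab[q]) {
          lab[q] = cur;
          stack.push_back((int)q);
        }
      }
    }
  }
  lab.attr("dim") = dim3;
  return lab;
}

// [[Rcpp::export]]
LogicalVector cpp_surface_voxels(LogicalVector mask, IntegerVector dim3) {
  const int X = dim3[0], Y = dim3[1], Z = dim3[2];
  const ll N = (ll)X * Y * Z;
  LogicalVector out((R_xlen_t)N);
  for (ll p = 0; p < N; ++p) {
    if (!mask[p]) continue;
    const int pz = (int)(p / ((ll)X * Y));
    const int py = (int)((p / X) % Y);
    const int px = (int)(p % X);
    bool surf = false;
    const int off[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                           {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
    for (int k = 0; k < 6 && !surf; ++k) {
      const int qx = px + off[k][0], qy = py + off[k][1], qz = pz + off[k][2];
      if (qx < 0 || qx >= X || qy < 0 || qy >= Y || qz < 0 || qz >= Z)
        surf = true;  // grid border counts as background
      else if (!mask[qx + (ll)X * (qy + (ll)Y * qz)])
        surf = true;
    }
    out[p] = surf;
  }
  out.attr("dim") = dim3;
  return out;
}

static const double DT_INF = 1e300;

static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    const double xq = q * s;
    double sx;
    while (true) {
      const double xv = v[k] * s;
      sx = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sx > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = sx;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double diff = xq - v[k] * s;
    d[q] = diff * diff + f[v[k]];
  }
}

static void edt_axis(std::vector<double>& a, int X, int Y, int Z, int axis,
                     double s) {
  const int dims[3] = {X, Y, Z};
  const int n = dims[axis];
  const ll strides[3] = {1, (ll)X, (ll)X * Y};
  const ll st = strides[axis];
  const int d1 = (axis == 0) ? 1 : 0;
  const int d2 = (axis == 2) ? 1 : 2;
  std::vector<double> f(n), d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  for (int j2 = 0; j2 < dims[d2]; ++j2)
    for (int j1 = 0; j1 < dims[d1]; ++j1) {
      const ll base = strides[d1] * j1 + strides[d2] * j2;
      for (int i = 0; i < n; ++i) f[i] = a[base + st * i];
      dt1d(f.data(), d.data(), n, s, v, z);
      for (int i = 0; i < n; ++i) a[base + st * i] = d[i];
    }
}

// Euclidean distance (physical units) from every voxel to the nearest
// `site` voxel; exact squared-distance transform run axis by axis.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector sites, IntegerVector dim3,
                      NumericVector spacing) {
  const int X = dim3[0], Y = dim3[1], Z = dim3[2];
  const ll N = (ll)X * Y * Z;
  std::vector<double> a((size_t)N);
  bool any = false;
  for (ll i = 0; i < N; ++i) {
    a[i] = sites[i] ? 0.0 : DT_INF;
    any = any || sites[i];
  }
  if (!any) stop("distance transform: no site voxels");
  edt_axis(a, X, Y, Z, 0, spacing[0]);
  edt_axis(a, X, Y, Z, 1, spacing[1]);
  edt_axis(a, X, Y, Z, 2, spacing[2]);
  NumericVector out((R_xlen_t)N);
  for (ll i = 0; i < N; ++i) out[i] = std::sqrt(a[i]);
  out.attr("dim") = dim3;
  return out;
}
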