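#include <Rcpp.h>
using namespace Rcpp;

// 3D convolution kernels for channel-last volumes.
//
// Activations are column-major R arrays with dim (nz, ny, nx, c), i.e. the
// z index is fastest.  Weights have dim (k, k, k, cin, cout) with a cubic
// kernel (k is 1 or 3 in practice).  Padding is always "same": for kernel
// size k and dilation d the spatial pad is d*(k-1)/2 per side, so output
// and input share their spatial shape.  All loops are plain and
// deterministic (single-thread contract).

static inline int aidx(int z, int y, int x, int c, int nz, int ny, int nx) {
  return z + nz * (y + ny * (x + (long long)nx * c));
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector b, int dilation) {
  const int nz = xdim[0], ny = xdim[1], nx = xdim[2], cin = xdim[3];
  const int k = wdim[0], cout = wdim[4];
  if (wdim[3] != cin) stop("weight cin does not match input channels");
  const int pad = dilation * (k - 1) / 2;

  NumericVector y(nz * (long long)ny * nx * cout);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();

  for (int co = 0; co < cout; ++co) {
    const double bias = b[co];
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) {
        for (int iz = 0; iz < nz; ++iz) {
          double acc = bias;
          for (int ci = 0; ci < cin; ++ci) {
            for (int kx = 0; kx < k; ++kx) {
              const int sx = ix + dilation * kx - pad;
              if (sx < 0 || sx >= nx) continue;
              for (int ky = 0; ky < k; ++ky) {
                const int sy = iy + dilation * ky - pad;
                if (sy < 0 || sy >= ny) continue;
                for (int kz = 0; kz < k; ++kz) {
                  const int sz = iz + dilation * kz - pad;
                  if (sz < 0 || sz >= nz) continue;
                  const double wv =
                    pw[kz + k * (ky + k * (kx + k * (ci + (long long)cin * co)))];
                  acc += wv * px[aidx(sz, sy, sx, ci, nz, ny, nx)];
                }
              }
            }
          }
          py[aidx(iz, iy, ix, co, nz, ny, nx)] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector gy, int dilation) {
  const int nz = xdim[0], ny = xdim[1], nx = xdim[2], cin = xdim[3];
  const int k = wdim[0], cout = wdim[4];
  const int pad = dilation * (k - 1) / 2;

  NumericVector gx(x.size()), gw(w.size()), gb(cout);
  const double *px = x.begin(), *pw = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();

  for (int co = 0; co < cout; ++co) {
    double accb = 0.0;
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) {
        for (int iz = 0; iz < nz; ++iz) {
          const double g = pgy[aidx(iz, iy, ix, co, nz, ny, nx)];
          if (g == 0.0) continue;
          accb += g;
          for (int ci = 0; ci < cin; ++ci) {
            for (int kx = 0; kx < k; ++kx) {
              const int sx = ix + dilation * kx - pad;
              if (sx < 0 || sx >= nx) continue;
              for (int ky = 0; ky < k; ++ky) {
                const int sy = iy + dilation * ky - pad;
                if (sy < 0 || sy >= ny) continue;
                for (int kz = 0; kz < k; ++kz) {
                  const int sz = iz + dilation * kz - pad;
                  if (sz < 0 || sz >= nz) continue;
                  const long long wi =
                    kz + k * (ky + k * (kx + k * (ci + (long long)cin * co)));
                  const int xi = aidx(sz, sy, sx, ci, nz, ny, nx);
                  pgw[wi] += g * px[xi];
                  pgx[xi] += g * pw[wi];
                }
              }
            }
          }
        }
      }
    }
    gb[co] = accb;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Average-pool by 2 along each spatial axis (shape must be even).
// [[Rcpp::export(name = ".avgpool2_fwd")]]
NumericVector avgpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int nz = xdim[0], ny = xdim[1], nx = xdim[2], c = xdim[3];
  const int oz = nz / 2, oy = ny / 2, ox = nx / 2;
  NumericVector y(oz * (long long)oy * ox * c);
  const double *px = x.begin();
  double *py = y.begin();
  for (int ci = 0; ci < c; ++ci)
    for (int ix = 0; ix < ox; ++ix)
      for (int iy = 0; iy < oy; ++iy)
        for (int iz = 0; iz < oz; ++iz) {
          double acc = 0.0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              for (int dz = 0; dz < 2; ++dz)
                acc += px[aidx(2 * iz + dz, 2 * iy + dy, 2 * ix + dx, ci, nz, ny, nx)];
          py[aidx(iz, iy, ix, ci, oz, oy, ox)] = acc / 8.0;
        }
  return y;
}

// [[Rcpp::export(name = ".avgpool2_bwd")]]
NumericVector avgpool2_bwd(NumericVector gy, IntegerVector xdim) {
  const int nz = xdim[0], ny = xdim[1], nx = xdim[2], c = xdim[3];
  const int oz = nz / 2, oy = ny / 2, ox = nx / 2;
  NumericVector gx(nz * (long long)ny * nx * c);
  const double *pgy = gy.begin();
  double *pgx = gx.begin();
  for (int ci = 0; ci < c; ++ci)
    for (int ix = 0; ix < ox; ++ix)
      for (int iy = 0; iy < oy; ++iy)
        for (int iz = 0; iz < oz; ++iz) {
          const double g = pgy[aidx(iz, iy, ix, ci, oz, oy, ox)] / 8.0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              for (int dz = 0; dz < 2; ++dz)
                pgx[aidx(2 * iz + dz, 2 * iy + dy, 2 * ix + dx, ci, nz, ny, nx)] = g;
        }
  return gx;
}

// Nearest-neighbour upsample by 2 along each spatial axis.
// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x, IntegerVector xdim) {
  const int nz = xdim[0], ny = xdim[1], nx = xdim[2], c = xdim[3];
  const int oz = nz * 2, oy = ny * 2, ox = nx * 2;
  NumericVector y(oz * (long long)oy * ox * c);
  const double *px = x.begin();
  double *py = y.begin();
  for (int ci = 0; ci < c; ++ci)
    for (int ix = 0; ix < ox; ++ix)
      for (int iy = 0; iy < oy; ++iy)
        for (int iz = 0; iz < oz; ++iz)
          py[aidx(iz, iy, ix, ci, oz, oy, ox)] =
            px[aidx(iz / 2, iy / 2, ix / 2, ci, nz, ny, nx)];
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector gy, IntegerVector xdim) {
  const int nz = xdim[0], ny = xdim[1], nx = xdim[2], c = xdim[3];
  const int oz = nz * 2, oy = ny * 2, ox = nx * 2;
  NumericVector gx(nz * (long long)ny * nx * c);
  const double *pgy = gy.begin();
  double *pgx = gx.begin();
  for (int ci = 0; ci < c; ++ci)
    for (int ix = 0; ix < ox; ++ix)
      for (int iy = 0; iy < oy; ++iy)
        for (int iz = 0; iz < oz; ++iz)
          pgx[aidx(iz / 2, iy / 2, ix / 2, ci, nz, ny, nx)] +=
            pgy[aidx(iz, iy, ix, ci, oz, oy, ox)];
  return gx;
}
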