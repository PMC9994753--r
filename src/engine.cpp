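#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

// Volumes are R arrays with dim (Z, Y, X, C); the first index varies fastest,
// so linear index = z + Z*(y + Y*(x + X*c)).  Convolution is im2col + BLAS
// dgemm, fused and chunked below.  Patch-matrix column order is
// (kz, ky, kx, cin) with kz fastest, matching a weight array of dim
// (kz, ky, kx, cin, cout) flattened to a (kz*ky*kx*cin) x cout matrix.

static inline int valid_lo(int pad, int k, int stride) {
  int lo = pad - k;
  return lo <= 0 ? 0 : (lo + stride - 1) / stride;
}
static inline int valid_hi(int extent, int pad, int k, int stride,
                           int out_extent) {
  const int num = extent - 1 + pad - k;
  if (num < 0) return -1;  // no valid output index (padding-only column)
  const int hi = num / stride;
  return hi >= out_extent - 1 ? out_extent - 1 : hi;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn(NumericVector x, IntegerVector in_dim,
                              IntegerVector scale) {
  const int Z = in_dim[0], Y = in_dim[1], X = in_dim[2], C = in_dim[3];
  const int SZ = scale[0], SY = scale[1], SX = scale[2];
  const int OZ = Z * SZ, OY = Y * SY, OX = X * SX;
  NumericVector out((R_xlen_t)OZ * OY * OX * C);
  out.attr("dim") = IntegerVector::create(OZ, OY, OX, C);
  const double *pi = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int ox = 0; ox < OX; ++ox)
      for (int oy = 0; oy < OY; ++oy) {
        const R_xlen_t obase = (R_xlen_t)OZ * (oy + (R_xlen_t)OY * (ox + (R_xlen_t)OX * c));
        const R_xlen_t ibase = (R_xlen_t)Z * ((oy / SY) + (R_xlen_t)Y * ((ox / SX) + (R_xlen_t)X * c));
        for (int oz = 0; oz < OZ; ++oz)
          po[oz + obase] = pi[(oz / SZ) + ibase];
      }
  return out;
}

// Adjoint of nearest-neighbour upsampling: sum over each scale block.
// [[Rcpp::export]]
NumericVector cpp_upsample_nn_backward(NumericVector dy, IntegerVector out_dim,
                                       IntegerVector scale) {
  const int OZ = out_dim[0], OY = out_dim[1], OX = out_dim[2], C = out_dim[3];
  const int SZ = scale[0], SY = scale[1], SX = scale[2];
  const int Z = OZ / SZ, Y = OY / SY, X = OX / SX;
  NumericVector dx((R_xlen_t)Z * Y * X * C);
  dx.attr("dim") = IntegerVector::create(Z, Y, X, C);
  const double *pd = dy.begin();
  double *po = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int ox = 0; ox < OX; ++ox)
      for (int oy = 0; oy < OY; ++oy) {
        const R_xlen_t obase = (R_xlen_t)OZ * (oy + (R_xlen_t)OY * (ox + (R_xlen_t)OX * c));
        const R_xlen_t ibase = (R_xlen_t)Z * ((oy / SY) + (R_xlen_t)Y * ((ox / SX) + (R_xlen_t)X * c));
        for (int oz = 0; oz < OZ; ++oz)
          po[(oz / SZ) + ibase] += pd[oz + obase];
      }
  return dx;
}

// ---- fused convolution driver ------------------------------------------
//
// The naive path (one im2col matrix per layer) allocates patch matrices of
// up to ~0.7 GB for the top decoder blocks, which dominates runtime on one
// CPU.  The fused driver processes the output in ox-chunks with a small
// reusable buffer and calls BLAS dgemm per chunk, so peak memory stays a
// few tens of MB and nothing needs to be cached for backward (the patch
// chunks are rebuilt on the fly).

#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif

struct ConvGeom {
  int Z, Y, X, C, KZ, KY, KX, SZ, SY, SX, PZ, PY, PX, OZ, OY, OX;
};

static void im2col_chunk(const double *px_, const ConvGeom &g,
                         int ox0, int ox1, double *buf) {
  const int rows = g.OZ * g.OY * (ox1 - ox0);
  const int ncol = g.KZ * g.KY * g.KX * g.C;
  std::memset(buf, 0, (size_t)rows * ncol * sizeof(double));
  for (int c = 0; c < g.C; ++c)
    for (int kx = 0; kx < g.KX; ++kx) {
      int ox_lo = valid_lo(g.PX, kx, g.SX);
      int ox_hi = valid_hi(g.X, g.PX, kx, g.SX, g.OX);
      if (ox_lo < ox0) ox_lo = ox0;
      if (ox_hi > ox1 - 1) ox_hi = ox1 - 1;
      for (int ky = 0; ky < g.KY; ++ky) {
        const int oy_lo = valid_lo(g.PY, ky, g.SY);
        const int oy_hi = valid_hi(g.Y, g.PY, ky, g.SY, g.OY);
        for (int kz = 0; kz < g.KZ; ++kz) {
          const int oz_lo = valid_lo(g.PZ, kz, g.SZ);
          const int oz_hi = valid_hi(g.Z, g.PZ, kz, g.SZ, g.OZ);
          const int zlen = oz_hi - oz_lo + 1;
          if (zlen <= 0) continue;
          const int col = kz + g.KZ * (ky + g.KY * (kx + g.KX * c));
          double *pcol = buf + (R_xlen_t)col * rows;
          for (int ox = ox_lo; ox <= ox_hi; ++ox) {
            const int ix = ox * g.SX - g.PX + kx;
            for (int oy = oy_lo; oy <= oy_hi; ++oy) {
              const int iy = oy * g.SY - g.PY + ky;
              double *dst = pcol + oz_lo +
                (R_xlen_t)g.OZ * (oy + (R_xlen_t)g.OY * (ox - ox0));
              const double *src = px_ + (oz_lo * g.SZ - g.PZ + kz) +
                (R_xlen_t)g.Z * (iy + (R_xlen_t)g.Y *
                                 (ix + (R_xlen_t)g.X * c));
              if (g.SZ == 1) {
                std::memcpy(dst, src, zlen * sizeof(double));
              } else {
                for (int t = 0; t < zlen; ++t)
                  dst[t] = src[(R_xlen_t)t * g.SZ];
              }
            }
          }
        }
      }
    }
}

static void col2im_chunk_add(const double *buf, const ConvGeom &g,
                             int ox0, int ox1, double *pdx) {
  const int rows = g.OZ * g.OY * (ox1 - ox0);
  for (int c = 0; c < g.C; ++c)
    for (int kx = 0; kx < g.KX; ++kx) {
      int ox_lo = valid_lo(g.PX, kx, g.SX);
      int ox_hi = valid_hi(g.X, g.PX, kx, g.SX, g.OX);
      if (ox_lo < ox0) ox_lo = ox0;
      if (ox_hi > ox1 - 1) ox_hi = ox1 - 1;
      for (int ky = 0; ky < g.KY; ++ky) {
        const int oy_lo = valid_lo(g.PY, ky, g.SY);
        const int oy_hi = valid_hi(g.Y, g.PY, ky, g.SY, g.OY);
        for (int kz = 0; kz < g.KZ; ++kz) {
          const int oz_lo = valid_lo(g.PZ, kz, g.SZ);
          const int oz_hi = valid_hi(g.Z, g.PZ, kz, g.SZ, g.OZ);
          const int zlen = oz_hi - oz_lo + 1;
          if (zlen <= 0) continue;
          const int col = kz + g.KZ * (ky + g.KY * (kx + g.KX * c));
          const double *pcol = buf + (R_xlen_t)col * rows;
          for (int ox = ox_lo; ox <= ox_hi; ++ox) {
            const int ix = ox * g.SX - g.PX + kx;
            for (int oy = oy_lo; oy <= oy_hi; ++oy) {
              const int iy = oy * g.SY - g.PY + ky;
              const double *src = pcol + oz_lo +
                (R_xlen_t)g.OZ * (oy + (R_xlen_t)g.OY * (ox - ox0));
              double *dst = pdx + (oz_lo * g.SZ - g.PZ + kz) +
                (R_xlen_t)g.Z * (iy + (R_xlen_t)g.Y *
                                 (ix + (R_xlen_t)g.X * c));
              if (g.SZ == 1) {
                for (int t = 0; t < zlen; ++t) dst[t] += src[t];
              } else {
                for (int t = 0; t < zlen; ++t)
                  dst[(R_xlen_t)t * g.SZ] += src[t];
              }
            }
          }
        }
      }
    }
}

static ConvGeom make_geom(IntegerVector in_dim, IntegerVector kernel,
                          IntegerVector stride, IntegerVector pad_beg,
                          IntegerVector out_dim) {
  ConvGeom g;
  g.Z = in_dim[0]; g.Y = in_dim[1]; g.X = in_dim[2]; g.C = in_dim[3];
  g.KZ = kernel[0]; g.KY = kernel[1]; g.KX = kernel[2];
  g.SZ = stride[0]; g.SY = stride[1]; g.SX = stride[2];
  g.PZ = pad_beg[0]; g.PY = pad_beg[1]; g.PX = pad_beg[2];
  g.OZ = out_dim[0]; g.OY = out_dim[1]; g.OX = out_dim[2];
  return g;
}

static int chunk_width(const ConvGeom &g, int ncol) {
  // target ~8 MB of patch buffer per chunk
  const double target = 8.0 * 1024 * 1024 / sizeof(double);
  int w = (int)(target / ((double)g.OZ * g.OY * ncol));
  if (w < 1) w = 1;
  if (w > g.OX) w = g.OX;
  return w;
}

// Fused "same"-padded strided 3D convolution + bias: returns an array of
// dim (OZ, OY, OX, cout).
// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, IntegerVector in_dim,
                                 NumericMatrix W, NumericVector bias,
                                 IntegerVector kernel, IntegerVector stride,
                                 IntegerVector pad_beg,
                                 IntegerVector out_dim) {
  const ConvGeom g = make_geom(in_dim, kernel, stride, pad_beg, out_dim);
  const int ncol = W.nrow();
  const int cout = W.ncol();
  const R_xlen_t nvox = (R_xlen_t)g.OZ * g.OY * g.OX;
  NumericVector out(nvox * cout);
  out.attr("dim") = IntegerVector::create(g.OZ, g.OY, g.OX, cout);
  const int cw = chunk_width(g, ncol);
  std::vector<double> buf((size_t)g.OZ * g.OY * cw * ncol);
  const double one = 1.0, zero = 0.0;
  for (int ox0 = 0; ox0 < g.OX; ox0 += cw) {
    const int ox1 = ox0 + cw > g.OX ? g.OX : ox0 + cw;
    const int rows = g.OZ * g.OY * (ox1 - ox0);
    im2col_chunk(x.begin(), g, ox0, ox1, buf.data());
    const int ldc = (int)nvox;
    F77_CALL(dgemm)("N", "N", &rows, &cout, &ncol, &one, buf.data(), &rows,
                    REAL(W), &ncol, &zero,
                    REAL(out) + (R_xlen_t)g.OZ * g.OY * ox0, &ldc
                    FCONE FCONE);
  }
  // bias
  double *po = REAL(out);
  for (int co = 0; co < cout; ++co) {
    const double b = bias[co];
    double *p = po + (R_xlen_t)co * nvox;
    for (R_xlen_t i = 0; i < nvox; ++i) p[i] += b;
  }
  return out;
}

// Fused backward: given the layer input x and dM (gradient w.r.t. the
// convolution output, as a (OZ*OY*OX) x cout matrix), returns dx, dW, db.
// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, IntegerVector in_dim,
                         NumericMatrix W, NumericMatrix dM,
                         IntegerVector kernel, IntegerVector stride,
                         IntegerVector pad_beg, IntegerVector out_dim) {
  const ConvGeom g = make_geom(in_dim, kernel, stride, pad_beg, out_dim);
  const int ncol = W.nrow();
  const int cout = W.ncol();
  const R_xlen_t nvox = (R_xlen_t)g.OZ * g.OY * g.OX;
  NumericVector dx((R_xlen_t)g.Z * g.Y * g.X * g.C);
  dx.attr("dim") = in_dim;
  NumericMatrix dW(ncol, cout);
  NumericVector db(cout);
  const int cw = chunk_width(g, ncol);
  std::vector<double> buf((size_t)g.OZ * g.OY * cw * ncol);
  std::vector<double> buf2((size_t)g.OZ * g.OY * cw * ncol);
  const double one = 1.0, zero = 0.0;
  const int ldm = (int)nvox;
  for (int ox0 = 0; ox0 < g.OX; ox0 += cw) {
    const int ox1 = ox0 + cw > g.OX ? g.OX : ox0 + cw;
    const int rows = g.OZ * g.OY * (ox1 - ox0);
    const double *dm_chunk = REAL(dM) + (R_xlen_t)g.OZ * g.OY * ox0;
    im2col_chunk(x.begin(), g, ox0, ox1, buf.data());
    // dW += X_chunk^T %*% dM_chunk
    F77_CALL(dgemm)("T", "N", &ncol, &cout, &rows, &one, buf.data(), &rows,
                    dm_chunk, &ldm, &one, REAL(dW), &ncol FCONE FCONE);
    // dXcol_chunk = dM_chunk %*% W^T
    F77_CALL(dgemm)("N", "T", &rows, &ncol, &cout, &one, dm_chunk, &ldm,
                    REAL(W), &ncol, &zero, buf2.data(), &rows FCONE FCONE);
    col2im_chunk_add(buf2.data(), g, ox0, ox1, REAL(dx));
  }
  const double *pdm = REAL(dM);
  for (int co = 0; co < cout; ++co) {
    double s = 0;
    const double *p = pdm + (R_xlen_t)co * nvox;
    for (R_xlen_t i = 0; i < nvox; ++i) s += p[i];
    db[co] = s;
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 26-connected component labelling of a binary 3D volume (Z, Y, X).
// Labels are assigned in order of first encounter in linear scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components26(LogicalVector mask, IntegerVector dim3) {
  const int Z = dim3[0], Y = dim3[1], X = dim3[2];
  const R_xlen_t n = (R_xlen_t)Z * Y * X;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dim3;
  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    labels[i] = ++next_label;
    q.push(i);
    while (!q.empty()) {
      const R_xlen_t cur = q.front(); q.pop();
      const int z = cur % Z;
      const int y = (cur / Z) % Y;
      const int x = cur / ((R_xlen_t)Z * Y);
      for (int dx_ = -1; dx_ <= 1; ++dx_)
        for (int dy_ = -1; dy_ <= 1; ++dy_)
          for (int dz_ = -1; dz_ <= 1; ++dz_) {
            if (dx_ == 0 && dy_ == 0 && dz_ == 0) continue;
            const int nz = z + dz_, ny = y + dy_, nx = x + dx_;
            if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X)
              continue;
            const R_xlen_t ni = nz + (R_xlen_t)Z * (ny + (R_xlen_t)Y * nx);
            if (mask[ni] && labels[ni] == 0) {
              labels[ni] = next_label;
              q.push(ni);
            }
          }
    }
  }
  return labels;
}
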