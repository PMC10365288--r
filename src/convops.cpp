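#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout throughout: column-major R array with dim (Z, Y, X, C),
// i.e. linear index z + Z*(y + Y*(x + X*c)). Convolutions are 3x3x3,
// stride 1, zero padding 1, expressed as im2col + BLAS matmul on the R
// side; pooling is 2x2x2 max with stored argmax for the backward pass.

// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2], C = dims[3];
  const R_xlen_t N = (R_xlen_t)Z * Y * X;
  NumericMatrix out(N, 27 * C);
  for (int c = 0; c < C; ++c) {
    const R_xlen_t coff = (R_xlen_t)c * Z * Y * X;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          const int j = c * 27 + (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
          double *col = &out(0, j);
          R_xlen_t n = 0;
          for (int px = 0; px < X; ++px) {
            const int sx = px + dx;
            for (int py = 0; py < Y; ++py) {
              const int sy = py + dy;
              if (sx < 0 || sx >= X || sy < 0 || sy >= Y) {
                n += Z;
                continue;
              }
              const R_xlen_t base = coff + (R_xlen_t)Z * (sy + (R_xlen_t)Y * sx);
              for (int pz = 0; pz < Z; ++pz, ++n) {
                const int sz = pz + dz;
                if (sz >= 0 && sz < Z) col[n] = x[base + sz];
              }
            }
          }
        }
  }
  return out;
}

// Adjoint of im2col3: scatter column gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix cols, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2], C = dims[3];
  NumericVector out((R_xlen_t)Z * Y * X * C);
  for (int c = 0; c < C; ++c) {
    const R_xlen_t coff = (R_xlen_t)c * Z * Y * X;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          const int j = c * 27 + (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
          const double *col = &cols(0, j);
          R_xlen_t n = 0;
          for (int px = 0; px < X; ++px) {
            const int sx = px + dx;
            for (int py = 0; py < Y; ++py) {
              const int sy = py + dy;
              if (sx < 0 || sx >= X || sy < 0 || sy >= Y) {
                n += Z;
                continue;
              }
              const R_xlen_t base = coff + (R_xlen_t)Z * (sy + (R_xlen_t)Y * sx);
              for (int pz = 0; pz < Z; ++pz, ++n) {
                const int sz = pz + dz;
                if (sz >= 0 && sz < Z) out[base + sz] += col[n];
              }
            }
          }
        }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
List maxpool3d_cpp(NumericVector x, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2], C = dims[3];
  if (Z % 2 || Y % 2 || X % 2) stop("maxpool3d requires even spatial dims");
  const int Zo = Z / 2, Yo = Y / 2, Xo = X / 2;
  const R_xlen_t No = (R_xlen_t)Zo * Yo * Xo * C;
  NumericVector out(No);
  IntegerVector arg(No);
  R_xlen_t n = 0;
  for (int c = 0; c < C; ++c)
    for (int px = 0; px < Xo; ++px)
      for (int py = 0; py < Yo; ++py)
        for (int pz = 0; pz < Zo; ++pz, ++n) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              for (int dz = 0; dz < 2; ++dz) {
                R_xlen_t idx = (2 * pz + dz) +
                  (R_xlen_t)Z * ((2 * py + dy) +
                  (R_xlen_t)Y * ((2 * px + dx) + (R_xlen_t)X * c));
                if (x[idx] > best) { best = x[idx]; besti = idx; }
              }
          out[n] = best;
          arg[n] = (int)besti;
        }
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}
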