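// Complex-valued 2D convolutions ("same" zero padding) plus the two
// backward kernels needed for reverse-mode gradients. Gradients follow the
// real-pair convention g = dL/d(Re w) + i dL/d(Im w) = 2 dL/d(conj w), so the
// backward kernels conjugate the weights / inputs.
#include <Rcpp.h>
#include <complex>

using namespace Rcpp;

static inline std::complex<double>* cx_ptr(ComplexVector& v) {
  return reinterpret_cast<std::complex<double>*>(COMPLEX(v));
}
static inline const std::complex<double>* cx_ptr(const ComplexVector& v) {
  return reinterpret_cast<const std::complex<double>*>(COMPLEX(v));
}

// input: (NY, NZ, Cin) complex, W: (k, k, Cin, Cout), bias: (Cout)
// out[y,z,co] = bias[co] + sum_{ci,dy,dz} W[dy,dz,ci,co] * in[y+dy-o, z+dz-o, ci]
// [[Rcpp::export(name = ".cx_conv2d")]]
ComplexVector cx_conv2d(ComplexVector input, ComplexVector W, ComplexVector bias) {
  IntegerVector di = input.attr("dim"), dw = W.attr("dim");
  const int NY = di[0], NZ = di[1], Cin = di[2];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != Cin) stop("weight dimensions inconsistent with input");
  if (k % 2 == 0) stop("kernel size must be odd");
  const int o = (k - 1) / 2;
  ComplexVector out(NY * NZ * Cout);
  out.attr("dim") = IntegerVector::create(NY, NZ, Cout);
  const std::complex<double>* in = cx_ptr(input);
  const std::complex<double>* w = cx_ptr(W);
  const std::complex<double>* b = cx_ptr(bias);
  std::complex<double>* op = cx_ptr(out);

  for (int co = 0; co < Cout; ++co) {
    std::complex<double>* oc = op + (size_t)co * NY * NZ;
    const std::complex<double> bc = b[co];
    for (int i = 0; i < NY * NZ; ++i) oc[i] = bc;
    for (int ci = 0; ci < Cin; ++ci) {
      const std::complex<double>* ic = in + (size_t)ci * NY * NZ;
      for (int dz = 0; dz < k; ++dz) {
        const int sz = dz - o;
        for (int dy = 0; dy < k; ++dy) {
          const int sy = dy - o;
          const std::complex<double> wv = w[dy + k * (dz + k * (ci + Cin * co))];
          const double wr = wv.real(), wi = wv.imag();
          if (wr == 0.0 && wi == 0.0) continue;
          const int z0 = std::max(0, -sz), z1 = std::min(NZ, NZ - sz);
          const int y0 = std::max(0, -sy), y1 = std::min(NY, NY - sy);
          for (int z = z0; z < z1; ++z) {
            double* orow = reinterpret_cast<double*>(oc + (size_t)z * NY);
            const double* irow =
                reinterpret_cast<const double*>(ic + (size_t)(z + sz) * NY + sy);
            for (int y = y0; y < y1; ++y) {
              const double ar = irow[2 * y], ai = irow[2 * y + 1];
              orow[2 * y] += wr * ar - wi * ai;
              orow[2 * y + 1] += wr * ai + wi * ar;
            }
          }
        }
      }
    }
  }
  return out;
}

// gradient wrt input: g_in[y,z,ci] = sum_{co,dy,dz} conj(W[dy,dz,ci,co]) *
//                                    gout[y-dy+o, z-dz+o, co]
// [[Rcpp::export(name = ".cx_conv2d_bwd_input")]]
ComplexVector cx_conv2d_bwd_input(ComplexVector gout, ComplexVector W) {
  IntegerVector dg = gout.attr("dim"), dw = W.attr("dim");
  const int NY = dg[0], NZ = dg[1], Cout = dg[2];
  const int k = dw[0], Cin = dw[2];
  if (dw[3] != Cout) stop("weight dimensions inconsistent with gradient");
  const int o = (k - 1) / 2;
  ComplexVector gin(NY * NZ * Cin);
  gin.attr("dim") = IntegerVector::create(NY, NZ, Cin);
  const std::complex<double>* gp = cx_ptr(gout);
  const std::complex<double>* w = cx_ptr(W);
  std::complex<double>* ip = cx_ptr(gin);
  std::fill(ip, ip + (size_t)NY * NZ * Cin, std::complex<double>(0.0, 0.0));

  for (int ci = 0; ci < Cin; ++ci) {
    std::complex<double>* ic = ip + (size_t)ci * NY * NZ;
    for (int co = 0; co < Cout; ++co) {
      const std::complex<double>* gc = gp + (size_t)co * NY * NZ;
      for (int dz = 0; dz < k; ++dz) {
        const int sz = o - dz;  // gout index offset
        for (int dy = 0; dy < k; ++dy) {
          const int sy = o - dy;
          const std::complex<double> wv =
              std::conj(w[dy + k * (dz + k * (ci + Cin * co))]);
          const double wr = wv.real(), wi = wv.imag();
          if (wr == 0.0 && wi == 0.0) continue;
          const int z0 = std::max(0, -sz), z1 = std::min(NZ, NZ - sz);
          const int y0 = std::max(0, -sy), y1 = std::min(NY, NY - sy);
          for (int z = z0; z < z1; ++z) {
            double* irow = reinterpret_cast<double*>(ic + (size_t)z * NY);
            const double* grow =
                reinterpret_cast<const double*>(gc + (size_t)(z + sz) * NY + sy);
            for (int y = y0; y < y1; ++y) {
              const double ar = grow[2 * y], ai = grow[2 * y + 1];
              irow[2 * y] += wr * ar - wi * ai;
              irow[2 * y + 1] += wr * ai + wi * ar;
            }
          }
        }
      }
    }
  }
  return gin;
}

// gradient wrt weights and bias:
// gW[dy,dz,ci,co] = sum_{y,z} conj(in[y+dy-o, z+dz-o, ci]) * gout[y,z,co]
// gb[co]          = sum_{y,z} gout[y,z,co]
// [[Rcpp::export(name = ".cx_conv2d_bwd_weights")]]
List cx_conv2d_bwd_weights(ComplexVector input, ComplexVector gout, int k) {
  IntegerVector di = input.attr("dim"), dg = gout.attr("dim");
  const int NY = di[0], NZ = di[1], Cin = di[2], Cout = dg[2];
  const int o = (k - 1) / 2;
  ComplexVector gW((size_t)k * k * Cin * Cout), gb(Cout);
  gW.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  const std::complex<double>* in = cx_ptr(input);
  const std::complex<double>* gp = cx_ptr(gout);
  std::complex<double>* wp = cx_ptr(gW);
  std::complex<double>* bp = cx_ptr(gb);
  std::fill(wp, wp + (size_t)k * k * Cin * Cout, std::complex<double>(0.0, 0.0));

  for (int co = 0; co < Cout; ++co) {
    const std::complex<double>* gc = gp + (size_t)co * NY * NZ;
    std::complex<double> bsum(0.0, 0.0);
    for (int i = 0; i < NY * NZ; ++i) bsum += gc[i];
    bp[co] = bsum;
    for (int ci = 0; ci < Cin; ++ci) {
      const std::complex<double>* ic = in + (size_t)ci * NY * NZ;
      for (int dz = 0; dz < k; ++dz) {
        const int sz = dz - o;
        for (int dy = 0; dy < k; ++dy) {
          const int sy = dy - o;
          const int z0 = std::max(0, -sz), z1 = std::min(NZ, NZ - sz);
          const int y0 = std::max(0, -sy), y1 = std::min(NY, NY - sy);
          double accr = 0.0, acci = 0.0;
          for (int z = z0; z < z1; ++z) {
            const double* grow = reinterpret_cast<const double*>(gc + (size_t)z * NY);
            const double* irow =
                reinterpret_cast<const double*>(ic + (size_t)(z + sz) * NY + sy);
            for (int y = y0; y < y1; ++y) {
              const double gr = grow[2 * y], gi = grow[2 * y + 1];
              const double xr = irow[2 * y], xi = irow[2 * y + 1];
              accr += xr * gr + xi * gi;   // conj(x) * g
              acci += xr * gi - xi * gr;
            }
          }
          wp[dy + k * (dz + k * (ci + Cin * co))] =
              std::complex<double>(accr, acci);
        }
      }
    }
  }
  return List::create(Named("W") = gW, Named("bias") = gb);
}
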