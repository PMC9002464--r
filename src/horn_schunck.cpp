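#include <Rcpp.h>
using namespace Rcpp;

// Horn-Schunck optical flow between two greyscale frames.
// Derivatives use the classic 4-point forward-difference stencils averaged
// over both frames (replicate borders); the flow is found by the
// Jacobi-style fixed-point iteration with the 1/6-1/12 neighbourhood
// average, run until the largest per-pixel update drops below `tol` or
// `nIter` sweeps are spent.
// [[Rcpp::export]]
List hs_flow_cpp(NumericMatrix I1, NumericMatrix I2, double alpha,
                 int nIter, double tol) {
  const int H = I1.nrow(), W = I1.ncol();
  NumericMatrix Ex(H, W), Ey(H, W), Et(H, W), den(H, W);
  NumericMatrix u(H, W), v(H, W), ub(H, W), vb(H, W);

  auto clampR = [H](int i) { return i < H ? i : H - 1; };
  auto clampC = [W](int j) { return j < W ? j : W - 1; };

  for (int j = 0; j < W; ++j) {
    int jp = clampC(j + 1);
    for (int i = 0; i < H; ++i) {
      int ip = clampR(i + 1);
      double ex = 0.25 * (I1(i, jp) - I1(i, j) + I1(ip, jp) - I1(ip, j) +
                          I2(i, jp) - I2(i, j) + I2(ip, jp) - I2(ip, j));
      double ey = 0.25 * (I1(ip, j) - I1(i, j) + I1(ip, jp) - I1(i, jp) +
                          I2(ip, j) - I2(i, j) + I2(ip, jp) - I2(i, jp));
      double et = 0.25 * (I2(i, j) - I1(i, j) + I2(i, jp) - I1(i, jp) +
                          I2(ip, j) - I1(ip, j) + I2(ip, jp) - I1(ip, jp));
      Ex(i, j) = ex;
      Ey(i, j) = ey;
      Et(i, j) = et;
      den(i, j) = alpha * alpha + ex * ex + ey * ey;
    }
  }

  for (int it = 0; it < nIter; ++it) {
    double delta = 0.0;
    for (int j = 0; j < W; ++j) {
      int jl = j > 0 ? j - 1 : 0, jr = clampC(j + 1);
      for (int i = 0; i < H; ++i) {
        int iu = i > 0 ? i - 1 : 0, id = clampR(i + 1);
        ub(i, j) = (u(iu, j) + u(id, j) + u(i, jl) + u(i, jr)) / 6.0 +
                   (u(iu, jl) + u(iu, jr) + u(id, jl) + u(id, jr)) / 12.0;
        vb(i, j) = (v(iu, j) + v(id, j) + v(i, jl) + v(i, jr)) / 6.0 +
                   (v(iu, jl) + v(iu, jr) + v(id, jl) + v(id, jr)) / 12.0;
      }
    }
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double r = (Ex(i, j) * ub(i, j) + Ey(i, j) * vb(i, j) + Et(i, j)) /
                   den(i, j);
        double un = ub(i, j) - Ex(i, j) * r;
        double vn = vb(i, j) - Ey(i, j) * r;
        double d = std::max(std::fabs(un - u(i, j)),
                            std::fabs(vn - v(i, j)));
        if (d > delta) delta = d;
        u(i, j) = un;
        v(i, j) = vn;
      }
    }
    if (delta < tol) break;
  }
  return List::create(_["vx"] = u, _["vy"] = v);
}
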