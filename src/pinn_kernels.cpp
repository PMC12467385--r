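// Fused forward/backward kernels for the per-vessel networks.
//
// The forward pass carries the value block and both input-tangent blocks
// (d/dx_hat, d/dt_hat) side by side through one GEMM per layer, so the
// exact output derivatives needed by the physics residuals come out of
// the same pass. The backward pass propagates the adjoints of outputs
// and output-derivatives, which makes the tanh second derivative
// (d tanh'(a)/da = -2 tanh(a) tanh'(a)) appear in the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

// [[Rcpp::export]]
List mlp_fwd_cpp(const List& Wl, const List& bl, const arma::mat& X,
                 const arma::vec& out_shift, const arma::vec& out_scale,
                 const bool tangents, const bool keep_cache) {
  const int nL = Wl.size();
  const int N = X.n_cols;
  mat ZZ;
  if (tangents) {
    ZZ.zeros(2, 3 * N);
    ZZ.cols(0, N - 1) = X;
    ZZ.submat(0, N, 0, 2 * N - 1).ones();      // x-tangent of input row 1
    ZZ.submat(1, 2 * N, 1, 3 * N - 1).ones();  // t-tangent of input row 2
  } else {
    ZZ = X;
  }
  List cache(nL - 1);
  for (int l = 0; l < nL - 1; ++l) {
    const mat W = as<mat>(Wl[l]);
    const vec b = as<vec>(bl[l]);
    mat AZ = W * ZZ;
    mat S = AZ.cols(0, N - 1);
    S.each_col() += b;
    S = arma::tanh(S);
    const mat Sp = 1.0 - arma::square(S);
    if (keep_cache) {
      if (tangents) {
        cache[l] = List::create(
          _["ZZp"] = ZZ, _["S"] = S, _["Sp"] = Sp,
          _["Ax"] = mat(AZ.cols(N, 2 * N - 1)),
          _["At"] = mat(AZ.cols(2 * N, 3 * N - 1)));
      } else {
        cache[l] = List::create(_["ZZp"] = ZZ, _["S"] = S, _["Sp"] = Sp);
      }
    }
    if (tangents) {
      mat ZZn(S.n_rows, 3 * N);
      ZZn.cols(0, N - 1) = S;
      ZZn.cols(N, 2 * N - 1) = Sp % AZ.cols(N, 2 * N - 1);
      ZZn.cols(2 * N, 3 * N - 1) = Sp % AZ.cols(2 * N, 3 * N - 1);
      ZZ = std::move(ZZn);
    } else {
      ZZ = std::move(S);
    }
  }
  const mat W = as<mat>(Wl[nL - 1]);
  const vec b = as<vec>(bl[nL - 1]);
  mat YY = W * ZZ;
  mat Y = YY.cols(0, N - 1);
  Y.each_col() += b;
  Y.each_col() %= out_scale;
  Y.each_col() += out_shift;
  List out = List::create(_["Y"] = Y);
  if (tangents) {
    mat Yx = YY.cols(N, 2 * N - 1);       Yx.each_col() %= out_scale;
    mat Yt = YY.cols(2 * N, 3 * N - 1);   Yt.each_col() %= out_scale;
    out["Yx"] = Yx;
    out["Yt"] = Yt;
  }
  if (keep_cache) {
    out["cache"] = cache;
    out["last"] = ZZ;
  }
  return out;
}

// [[Rcpp::export]]
List mlp_bwd_cpp(const List& Wl, const List& cache, const arma::mat& last,
                 const arma::mat& Gy, const arma::mat& Gyx,
                 const arma::mat& Gyt, const arma::vec& out_scale,
                 const bool tangents) {
  const int nL = Wl.size();
  const int N = Gy.n_cols;
  List gW(nL), gb(nL);
  mat GYY = tangents ? arma::join_rows(Gy, Gyx, Gyt) : Gy;
  GYY.each_col() %= out_scale;
  {
    const mat W = as<mat>(Wl[nL - 1]);
    gW[nL - 1] = mat(GYY * last.t());
    gb[nL - 1] = vec(arma::sum(GYY.cols(0, N - 1), 1));
    GYY = W.t() * GYY;  // becomes the adjoint of the last hidden output
  }
  for (int l = nL - 2; l >= 0; --l) {
    const List cc = cache[l];
    const mat S = as<mat>(cc["S"]);
    const mat Sp = as<mat>(cc["Sp"]);
    const mat ZZp = as<mat>(cc["ZZp"]);
    const mat W = as<mat>(Wl[l]);
    mat GA;
    vec gbv;
    if (tangents) {
      const mat Ax = as<mat>(cc["Ax"]);
      const mat At = as<mat>(cc["At"]);
      const mat GZ = GYY.cols(0, N - 1);
      const mat GZx = GYY.cols(N, 2 * N - 1);
      const mat GZt = GYY.cols(2 * N, 3 * N - 1);
      const mat Ga = GZ % Sp + (GZx % Ax + GZt % At) % (-2.0 * S % Sp);
      GA = arma::join_rows(Ga, GZx % Sp, GZt % Sp);
      gbv = arma::sum(Ga, 1);
    } else {
      GA = GYY % Sp;
      gbv = arma::sum(GA, 1);
    }
    gW[l] = mat(GA * ZZp.t());
    gb[l] = gbv;
    if (l > 0) GYY = W.t() * GA;
  }
  return List::create(_["W"] = gW, _["b"] = gb);
}

// ---------------------------------------------------------------------------
// Full training loop. All stochastic inputs (initial weights, collocation
// points, targets) are prepared in R; this routine only iterates the
// deterministic objective/gradient/Adam cycle, so seed-reproducibility is
// inherited from the R side.
//
// Per-vessel batch layout (columns of X): [collocation | boundary data |
// initial condition | interface], sizes nC, nD, nI, nB.

namespace {

struct Cache {
  std::vector<mat> ZZp, S, Sp, Ax, At;
  mat last, Y, Yx, Yt;
};

void fwd_net(const std::vector<mat>& W, const std::vector<vec>& b,
             const vec& osh, const vec& osc, const mat& X, Cache& c) {
  const int nL = W.size();
  const int N = X.n_cols;
  mat ZZ(2, 3 * N, arma::fill::zeros);
  ZZ.cols(0, N - 1) = X;
  ZZ.submat(0, N, 0, 2 * N - 1).ones();
  ZZ.submat(1, 2 * N, 1, 3 * N - 1).ones();
  c.ZZp.resize(nL - 1); c.S.resize(nL - 1); c.Sp.resize(nL - 1);
  c.Ax.resize(nL - 1); c.At.resize(nL - 1);
  for (int l = 0; l < nL - 1; ++l) {
    mat AZ = W[l] * ZZ;
    mat S = AZ.cols(0, N - 1);
    S.each_col() += b[l];
    S = arma::tanh(S);
    c.ZZp[l] = std::move(ZZ);
    c.Sp[l] = 1.0 - arma::square(S);
    c.Ax[l] = AZ.cols(N, 2 * N - 1);
    c.At[l] = AZ.cols(2 * N, 3 * N - 1);
    ZZ.set_size(S.n_rows, 3 * N);
    ZZ.cols(0, N - 1) = S;
    ZZ.cols(N, 2 * N - 1) = c.Sp[l] % c.Ax[l];
    ZZ.cols(2 * N, 3 * N - 1) = c.Sp[l] % c.At[l];
    c.S[l] = std::move(S);
  }
  mat YY = W[nL - 1] * ZZ;
  c.last = std::move(ZZ);
  c.Y = YY.cols(0, N - 1);
  c.Y.each_col() += b[nL - 1];
  c.Y.each_col() %= osc;
  c.Y.each_col() += osh;
  c.Yx = YY.cols(N, 2 * N - 1);     c.Yx.each_col() %= osc;
  c.Yt = YY.cols(2 * N, 3 * N - 1); c.Yt.each_col() %= osc;
}

void bwd_net(const std::vector<mat>& W, const Cache& c, const vec& osc,
             const mat& Gy, const mat& Gyx, const mat& Gyt,
             std::vector<mat>& gW, std::vector<vec>& gb) {
  const int nL = W.size();
  const int N = Gy.n_cols;
  gW.resize(nL); gb.resize(nL);
  mat GYY = arma::join_rows(Gy, Gyx, Gyt);
  GYY.each_col() %= osc;
  gW[nL - 1] = GYY * c.last.t();
  gb[nL - 1] = arma::sum(GYY.cols(0, N - 1), 1);
  GYY = W[nL - 1].t() * GYY;
  for (int l = nL - 2; l >= 0; --l) {
    const mat GZ = GYY.cols(0, N - 1);
    const mat GZx = GYY.cols(N, 2 * N - 1);
    const mat GZt = GYY.cols(2 * N, 3 * N - 1);
    const mat Ga = GZ % c.Sp[l] +
      (GZx % c.Ax[l] + GZt % c.At[l]) % (-2.0 * c.S[l] % c.Sp[l]);
    mat GA = arma::join_rows(Ga, GZx % c.Sp[l], GZt % c.Sp[l]);
    gW[l] = GA * c.ZZp[l].t();
    gb[l] = arma::sum(Ga, 1);
    if (l > 0) GYY = W[l].t() * GA;
  }
}

inline arma::rowvec safe_sqrt_rv(const arma::rowvec& A, double eps) {
  arma::rowvec s(A.n_elem);
  const double se = std::sqrt(eps);
  for (arma::uword i = 0; i < A.n_elem; ++i)
    s[i] = A[i] >= eps ? std::sqrt(A[i]) : se + (A[i] - eps) / (2.0 * se);
  return s;
}

inline arma::rowvec safe_sqrt_grad_rv(const arma::rowvec& A, double eps) {
  arma::rowvec g(A.n_elem);
  const double ge = 0.5 / std::sqrt(eps);
  for (arma::uword i = 0; i < A.n_elem; ++i)
    g[i] = A[i] >= eps ? 0.5 / std::sqrt(A[i]) : ge;
  return g;
}

}  // namespace

// [[Rcpp::export]]
List train_loop_cpp(List netsW, List netsb, const List& out_shifts,
                    const List& out_scales, const List& Xs,
                    const IntegerVector& nC, const IntegerVector& nD,
                    const IntegerVector& nI, const IntegerVector& nB,
                    const List& u_targets, const List& A_targets,
                    const List& consts, const NumericVector& weights,
                    const int epochs, const double lr, const int log_every) {
  const double sqrt_eps = 1e-4;
  const double wP = weights[0], wD = weights[1], wI = weights[2];
  std::vector<std::vector<mat> > W(3), mW(3), vW(3);
  std::vector<std::vector<vec> > b(3), mb(3), vb(3);
  std::vector<mat> X(3);
  std::vector<vec> osh(3), osc(3);
  std::vector<arma::rowvec> uT(3), AT(3);
  // consts per vessel: cx, ct, alpha, Ktilde, b0, b1, cp
  std::vector<vec> K(3);
  for (int j = 0; j < 3; ++j) {
    List Wj = netsW[j], bj = netsb[j];
    for (int l = 0; l < Wj.size(); ++l) {
      W[j].push_back(as<mat>(Wj[l]));
      b[j].push_back(as<vec>(bj[l]));
      mW[j].push_back(mat(arma::size(W[j][l]), arma::fill::zeros));
      vW[j].push_back(mat(arma::size(W[j][l]), arma::fill::zeros));
      mb[j].push_back(vec(arma::size(b[j][l]), arma::fill::zeros));
      vb[j].push_back(vec(arma::size(b[j][l]), arma::fill::zeros));
    }
    X[j] = as<mat>(Xs[j]);
    osh[j] = as<vec>(out_shifts[j]);
    osc[j] = as<vec>(out_scales[j]);
    uT[j] = arma::conv_to<arma::rowvec>::from(as<vec>(u_targets[j]));
    AT[j] = arma::conv_to<arma::rowvec>::from(as<vec>(A_targets[j]));
    K[j] = as<vec>(consts[j]);
  }
  const double b1a = 0.9, b2a = 0.999, epsa = 1e-8;
  std::vector<arma::rowvec> hist;
  Cache c[3];
  mat Gy[3], Gyx[3], Gyt[3];
  for (int ep = 1; ep <= epochs; ++ep) {
    if (ep % 256 == 0) Rcpp::checkUserInterrupt();
    double phys[3], dat[3];
    for (int j = 0; j < 3; ++j) {
      fwd_net(W[j], b[j], osh[j], osc[j], X[j], c[j]);
      const int N = X[j].n_cols;
      Gy[j].zeros(3, N); Gyx[j].zeros(3, N); Gyt[j].zeros(3, N);
      const int c0 = 0, c1 = nC[j] - 1;                  // collocation block
      const double cx = K[j][0], ct = K[j][1], al = K[j][2],
                   Kt = K[j][3], rb0 = K[j][4], rb1 = K[j][5],
                   cp = K[j][6];
      const arma::rowvec A = c[j].Y.row(0).cols(c0, c1);
      const arma::rowvec u = c[j].Y.row(1).cols(c0, c1);
      const arma::rowvec p = c[j].Y.row(2).cols(c0, c1);
      const arma::rowvec Axr = c[j].Yx.row(0).cols(c0, c1);
      const arma::rowvec uxr = c[j].Yx.row(1).cols(c0, c1);
      const arma::rowvec pxr = c[j].Yx.row(2).cols(c0, c1);
      const arma::rowvec Atr = c[j].Yt.row(0).cols(c0, c1);
      const arma::rowvec utr = c[j].Yt.row(1).cols(c0, c1);
      const double am1 = al - 1.0;
      arma::rowvec shape(nC[j], arma::fill::zeros);
      if (am1 != 0.0) shape = am1 * (u % uxr + arma::square(u) % Axr / A);
      const arma::rowvec sA = safe_sqrt_rv(A, sqrt_eps);
      const arma::rowvec rA = ct * Atr + cx * (A % uxr + u % Axr);
      const arma::rowvec ru = ct * utr +
        cx * (al * (u % uxr) + shape + pxr) - Kt * u / A;
      const arma::rowvec rp = cp * p - rb0 - rb1 * sA;
      phys[j] = (arma::mean(arma::square(rA)) +
                 arma::mean(arma::square(ru)) +
                 arma::mean(arma::square(rp)));
      const arma::rowvec g1 = wP * 2.0 * rA / nC[j];
      const arma::rowvec g2 = wP * 2.0 * ru / nC[j];
      const arma::rowvec g3 = wP * 2.0 * rp / nC[j];
      arma::rowvec du = cx * al * uxr - Kt / A;
      arma::rowvec dA(nC[j], arma::fill::zeros);
      dA += Kt * u / arma::square(A);
      if (am1 != 0.0) {
        du += cx * am1 * (uxr + 2.0 * (u % Axr) / A);
        dA -= cx * am1 * arma::square(u) % Axr / arma::square(A);
      }
      Gy[j].row(0).cols(c0, c1) += g1 % (cx * uxr) + g2 % dA -
        g3 % (rb1 * safe_sqrt_grad_rv(A, sqrt_eps));
      Gy[j].row(1).cols(c0, c1) += g1 % (cx * Axr) + g2 % du;
      Gy[j].row(2).cols(c0, c1) += cp * g3;
      Gyx[j].row(0).cols(c0, c1) += g1 % (cx * u) +
        (am1 != 0.0 ? arma::rowvec(g2 % (cx * am1 * arma::square(u) / A))
                    : arma::rowvec(nC[j], arma::fill::zeros));
      Gyx[j].row(1).cols(c0, c1) += g1 % (cx * A) +
        g2 % (cx * (al + am1) * u);
      Gyx[j].row(2).cols(c0, c1) += g2 * cx;
      Gyt[j].row(0).cols(c0, c1) += g1 * ct;
      Gyt[j].row(1).cols(c0, c1) += g2 * ct;
      // data terms: velocity + area at the same boundary columns, then IC
      dat[j] = 0.0;
      if (nD[j] > 0) {
        const int d0 = nC[j], d1 = nC[j] + nD[j] - 1;
        const arma::rowvec eu = c[j].Y.row(1).cols(d0, d1) - uT[j];
        const arma::rowvec eA = c[j].Y.row(0).cols(d0, d1) - AT[j];
        dat[j] += arma::mean(arma::square(eu)) +
                  arma::mean(arma::square(eA));
        Gy[j].row(1).cols(d0, d1) += wD * 2.0 * eu / nD[j];
        Gy[j].row(0).cols(d0, d1) += wD * 2.0 * eA / nD[j];
      }
      if (nI[j] > 0) {
        const int i0 = nC[j] + nD[j], i1 = i0 + nI[j] - 1;
        const arma::rowvec eic = c[j].Y.row(1).cols(i0, i1);
        dat[j] += arma::mean(arma::square(eic));
        Gy[j].row(1).cols(i0, i1) += wD * 2.0 * eic / nI[j];
      }
    }
    // interface block: the trailing nB columns of each vessel batch
    double inter = 0.0;
    {
      const int Nb = nB[0];
      arma::rowvec Ai[3], ui[3], pi[3];
      int f0[3];
      for (int j = 0; j < 3; ++j) {
        f0[j] = nC[j] + nD[j] + nI[j];
        Ai[j] = c[j].Y.row(0).cols(f0[j], f0[j] + Nb - 1);
        ui[j] = c[j].Y.row(1).cols(f0[j], f0[j] + Nb - 1);
        pi[j] = c[j].Y.row(2).cols(f0[j], f0[j] + Nb - 1);
      }
      const arma::rowvec rf = Ai[0] % ui[0] - Ai[1] % ui[1] - Ai[2] % ui[2];
      const arma::rowvec r12 = pi[0] + 0.5 * arma::square(ui[0]) -
                               pi[1] - 0.5 * arma::square(ui[1]);
      const arma::rowvec r13 = pi[0] + 0.5 * arma::square(ui[0]) -
                               pi[2] - 0.5 * arma::square(ui[2]);
      inter = arma::mean(arma::square(rf)) +
              arma::mean(arma::square(r12)) +
              arma::mean(arma::square(r13));
      const arma::rowvec gf = wI * 2.0 * rf / Nb;
      const arma::rowvec g12 = wI * 2.0 * r12 / Nb;
      const arma::rowvec g13 = wI * 2.0 * r13 / Nb;
      const double sgn[3] = {1.0, -1.0, -1.0};
      arma::rowvec gp[3];
      gp[0] = g12 + g13; gp[1] = -g12; gp[2] = -g13;
      for (int j = 0; j < 3; ++j) {
        Gy[j].row(0).cols(f0[j], f0[j] + Nb - 1) += sgn[j] * gf % ui[j];
        Gy[j].row(1).cols(f0[j], f0[j] + Nb - 1) += sgn[j] * gf % Ai[j] +
          gp[j] % ui[j];
        Gy[j].row(2).cols(f0[j], f0[j] + Nb - 1) += gp[j];
      }
    }
    const double total = wP * (phys[0] + phys[1] + phys[2]) +
      wD * (dat[0] + dat[1] + dat[2]) + wI * inter;
    if (!std::isfinite(total))
      Rcpp::stop("non-finite loss at epoch %d", ep);
    // backward + Adam
    const double cb1 = 1.0 - std::pow(b1a, ep);
    const double cb2 = 1.0 - std::pow(b2a, ep);
    for (int j = 0; j < 3; ++j) {
      std::vector<mat> gW; std::vector<vec> gb;
      bwd_net(W[j], c[j], osc[j], Gy[j], Gyx[j], Gyt[j], gW, gb);
      for (size_t l = 0; l < W[j].size(); ++l) {
        mW[j][l] = b1a * mW[j][l] + (1.0 - b1a) * gW[l];
        vW[j][l] = b2a * vW[j][l] + (1.0 - b2a) * arma::square(gW[l]);
        W[j][l] -= lr * (mW[j][l] / cb1) /
          (arma::sqrt(vW[j][l] / cb2) + epsa);
        mb[j][l] = b1a * mb[j][l] + (1.0 - b1a) * gb[l];
        vb[j][l] = b2a * vb[j][l] + (1.0 - b2a) * arma::square(gb[l]);
        b[j][l] -= lr * (mb[j][l] / cb1) /
          (arma::sqrt(vb[j][l] / cb2) + epsa);
      }
    }
    if (ep % log_every == 0 || ep == 1 || ep == epochs) {
      arma::rowvec h(9);
      h[0] = ep; h[1] = phys[0]; h[2] = phys[1]; h[3] = phys[2];
      h[4] = dat[0]; h[5] = dat[1]; h[6] = dat[2]; h[7] = inter;
      h[8] = total;
      hist.push_back(h);
    }
  }
  mat H(hist.size(), 9);
  for (size_t i = 0; i < hist.size(); ++i) H.row(i) = hist[i];
  List outW(3), outb(3);
  for (int j = 0; j < 3; ++j) {
    List Wj(W[j].size()), bj(b[j].size());
    for (size_t l = 0; l < W[j].size(); ++l) { Wj[l] = W[j][l]; bj[l] = b[j][l]; }
    outW[j] = Wj; outb[j] = bj;
  }
  return List::create(_["W"] = outW, _["b"] = outb, _["history"] = H);
}
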