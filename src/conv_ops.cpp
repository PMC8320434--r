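// Low-level tensor kernels for the residual-attention U-Net engine.
//
// Activation tensors are dense R arrays with dim (D, H, W, C, N), column-major,
// so the slice axis d is fastest and channel blocks are contiguous per sample.
// Convolution weights have dim (kd, kh, kw, Cin, Cout); odd kernels use "same"
// zero padding. Convolutions are computed as a sum over kernel offsets of
// GEMMs between a shifted copy of the input and the (Cin x Cout) weight slab,
// which keeps the scratch memory at one (P x Cin) buffer instead of a full
// im2col matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Dims5 {
  int D, H, W, C, N;
  long P() const { return (long)D * H * W; }
};

Dims5 dims5(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 5) stop("expected a 5-d tensor (D,H,W,C,N)");
  return Dims5{d[0], d[1], d[2], d[3], d[4]};
}

// Gather x (one sample, shifted by s, zero-padded) into Xs (P x Cin).
void gather_shifted(const double* xs, const Dims5& dm, const int s[3],
                    arma::mat& Xs) {
  Xs.zeros();
  const int D = dm.D, H = dm.H, W = dm.W;
  int dlo = std::max(0, -s[0]), dhi = std::min(D, D - s[0]);
  int hlo = std::max(0, -s[1]), hhi = std::min(H, H - s[1]);
  int wlo = std::max(0, -s[2]), whi = std::min(W, W - s[2]);
  if (dlo >= dhi || hlo >= hhi || wlo >= whi) return;
  const int dlen = dhi - dlo;
  for (int ci = 0; ci < dm.C; ++ci) {
    const double* xc = xs + (long)ci * dm.P();
    double* col = Xs.colptr(ci);
    for (int w = wlo; w < whi; ++w) {
      for (int h = hlo; h < hhi; ++h) {
        const long dst = dlo + (long)D * (h + (long)H * w);
        const long src = (dlo + s[0]) +
            (long)D * ((h + s[1]) + (long)H * (w + s[2]));
        std::memcpy(col + dst, xc + src, sizeof(double) * dlen);
      }
    }
  }
}

// Scatter-add G (P x Cin) shifted by s into dx (one sample).
void scatter_shifted(double* dxs, const Dims5& dm, const int s[3],
                     const arma::mat& G) {
  const int D = dm.D, H = dm.H, W = dm.W;
  int dlo = std::max(0, -s[0]), dhi = std::min(D, D - s[0]);
  int hlo = std::max(0, -s[1]), hhi = std::min(H, H - s[1]);
  int wlo = std::max(0, -s[2]), whi = std::min(W, W - s[2]);
  if (dlo >= dhi || hlo >= hhi || wlo >= whi) return;
  const int dlen = dhi - dlo;
  for (int ci = 0; ci < dm.C; ++ci) {
    double* xc = dxs + (long)ci * dm.P();
    const double* col = G.colptr(ci);
    for (int w = wlo; w < whi; ++w) {
      for (int h = hlo; h < hhi; ++h) {
        const long srcp = dlo + (long)D * (h + (long)H * w);
        const long dstp = (dlo + s[0]) +
            (long)D * ((h + s[1]) + (long)H * (w + s[2]));
        const double* g = col + srcp;
        double* out = xc + dstp;
        for (int d = 0; d < dlen; ++d) out[d] += g[d];
      }
    }
  }
}

arma::mat weight_slab(const NumericVector& w, const IntegerVector& kd,
                      int a, int b, int c, int Cin, int Cout) {
  arma::mat Wk(Cin, Cout);
  const long kprod = (long)kd[0] * kd[1] * kd[2];
  const double* wp = REAL(w);
  const long base = a + (long)kd[0] * (b + (long)kd[1] * c);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wk(ci, co) = wp[base + kprod * (ci + (long)Cin * co)];
  return Wk;
}

void add_weight_slab(NumericVector& dw, const IntegerVector& kd,
                     int a, int b, int c, int Cin, int Cout,
                     const arma::mat& G) {
  const long kprod = (long)kd[0] * kd[1] * kd[2];
  double* wp = REAL(dw);
  const long base = a + (long)kd[0] * (b + (long)kd[1] * c);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      wp[base + kprod * (ci + (long)Cin * co)] += G(ci, co);
}

} // namespace

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector w, NumericVector b) {
  Dims5 dm = dims5(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("weights must be 5-d (kd,kh,kw,Cin,Cout)");
  const int Cin = wd[3], Cout = wd[4];
  if (Cin != dm.C) stop("channel mismatch between input and weights");
  IntegerVector kd = IntegerVector::create(wd[0], wd[1], wd[2]);
  const int r[3] = {(wd[0] - 1) / 2, (wd[1] - 1) / 2, (wd[2] - 1) / 2};
  const long P = dm.P();

  NumericVector out((long)P * Cout * dm.N);
  out.attr("dim") = IntegerVector::create(dm.D, dm.H, dm.W, Cout, dm.N);
  arma::mat Xs(P, Cin);
  const double* bp = REAL(b);

  for (int n = 0; n < dm.N; ++n) {
    const double* xs = REAL(x) + (long)n * P * dm.C;
    arma::mat O(REAL(out) + (long)n * P * Cout, P, Cout, false, true);
    for (int co = 0; co < Cout; ++co) O.col(co).fill(bp[co]);
    for (int c = 0; c < wd[2]; ++c)
      for (int bb = 0; bb < wd[1]; ++bb)
        for (int a = 0; a < wd[0]; ++a) {
          const int s[3] = {a - r[0], bb - r[1], c - r[2]};
          gather_shifted(xs, dm, s, Xs);
          O += Xs * weight_slab(w, kd, a, bb, c, Cin, Cout);
        }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_conv3d_bw(NumericVector x, NumericVector w, NumericVector gout) {
  Dims5 dm = dims5(x);
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[3], Cout = wd[4];
  IntegerVector kd = IntegerVector::create(wd[0], wd[1], wd[2]);
  const int r[3] = {(wd[0] - 1) / 2, (wd[1] - 1) / 2, (wd[2] - 1) / 2};
  const long P = dm.P();

  NumericVector dx((long)P * Cin * dm.N);
  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  arma::mat Xs(P, Cin);

  for (int n = 0; n < dm.N; ++n) {
    const double* xs = REAL(x) + (long)n * P * Cin;
    double* dxs = REAL(dx) + (long)n * P * Cin;
    arma::mat G(REAL(gout) + (long)n * P * Cout, P, Cout, false, true);
    arma::rowvec cs = arma::sum(G, 0);
    for (int co = 0; co < Cout; ++co) db[co] += cs(co);
    for (int c = 0; c < wd[2]; ++c)
      for (int bb = 0; bb < wd[1]; ++bb)
        for (int a = 0; a < wd[0]; ++a) {
          const int s[3] = {a - r[0], bb - r[1], c - r[2]};
          gather_shifted(xs, dm, s, Xs);
          add_weight_slab(dw, kd, a, bb, c, Cin, Cout, Xs.t() * G);
          arma::mat Gin = G * weight_slab(w, kd, a, bb, c, Cin, Cout).t();
          scatter_shifted(dxs, dm, s, Gin);
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution with kernel == stride == f: every input voxel paints
// a disjoint (fd x fh x fw) output block, so each kernel offset is a plain
// 1x1 convolution scattered onto a strided output lattice.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_upconv_fw(NumericVector x, NumericVector w, NumericVector b) {
  Dims5 dm = dims5(x);
  IntegerVector wd = w.attr("dim");
  const int fd = wd[0], fh = wd[1], fw = wd[2], Cin = wd[3], Cout = wd[4];
  if (Cin != dm.C) stop("channel mismatch between input and weights");
  IntegerVector kd = IntegerVector::create(fd, fh, fw);
  const long P = dm.P();
  const int Do = dm.D * fd, Ho = dm.H * fh, Wo = dm.W * fw;
  const long Po = (long)Do * Ho * Wo;

  NumericVector out(Po * Cout * dm.N);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout, dm.N);
  const double* bp = REAL(b);
  std::fill(REAL(out), REAL(out) + out.size(), 0.0);

  for (int n = 0; n < dm.N; ++n) {
    arma::mat X(const_cast<double*>(REAL(x)) + (long)n * P * Cin,
                P, Cin, false, true);
    double* os = REAL(out) + (long)n * Po * Cout;
    for (int c = 0; c < fw; ++c)
      for (int bb = 0; bb < fh; ++bb)
        for (int a = 0; a < fd; ++a) {
          arma::mat O = X * weight_slab(w, kd, a, bb, c, Cin, Cout);
          for (int co = 0; co < Cout; ++co) {
            const double* src = O.colptr(co);
            double* oc = os + (long)co * Po;
            for (int wi = 0; wi < dm.W; ++wi)
              for (int hi = 0; hi < dm.H; ++hi) {
                const long srcp = (long)dm.D * (hi + (long)dm.H * wi);
                const long dstp = a + (long)Do *
                    ((fh * hi + bb) + (long)Ho * (fw * wi + c));
                for (int di = 0; di < dm.D; ++di)
                  oc[dstp + (long)fd * di] += src[srcp + di];
              }
          }
        }
    // add bias once per output voxel
    for (int co = 0; co < Cout; ++co) {
      double* oc = os + (long)co * Po;
      const double bv = bp[co];
      for (long p = 0; p < Po; ++p) oc[p] += bv;
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_upconv_bw(NumericVector x, NumericVector w, NumericVector gout) {
  Dims5 dm = dims5(x);
  IntegerVector wd = w.attr("dim");
  const int fd = wd[0], fh = wd[1], fw = wd[2], Cin = wd[3], Cout = wd[4];
  IntegerVector kd = IntegerVector::create(fd, fh, fw);
  const long P = dm.P();
  const int Do = dm.D * fd, Ho = dm.H * fh, Wo = dm.W * fw;
  const long Po = (long)Do * Ho * Wo;

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  arma::mat G(P, Cout);

  for (int n = 0; n < dm.N; ++n) {
    arma::mat X(const_cast<double*>(REAL(x)) + (long)n * P * Cin,
                P, Cin, false, true);
    arma::mat DX(REAL(dx) + (long)n * P * Cin, P, Cin, false, true);
    const double* gs = REAL(gout) + (long)n * Po * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gs + (long)co * Po;
      double acc = 0.0;
      for (long p = 0; p < Po; ++p) acc += gc[p];
      db[co] += acc;
    }
    for (int c = 0; c < fw; ++c)
      for (int bb = 0; bb < fh; ++bb)
        for (int a = 0; a < fd; ++a) {
          for (int co = 0; co < Cout; ++co) {
            const double* gc = gs + (long)co * Po;
            double* dst = G.colptr(co);
            for (int wi = 0; wi < dm.W; ++wi)
              for (int hi = 0; hi < dm.H; ++hi) {
                const long dstp = (long)dm.D * (hi + (long)dm.H * wi);
                for (int di = 0; di < dm.D; ++di)
                  dst[dstp + di] = gc[a + (long)fd * di +
                      (long)Do * ((fh * hi + bb) + (long)Ho * (fw * wi + c))];
              }
          }
          add_weight_slab(dw, kd, a, bb, c, Cin, Cout, X.t() * G);
          DX += G * weight_slab(w, kd, a, bb, c, Cin, Cout).t();
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Non-overlapping max pooling; factors must divide the extents.
// [[Rcpp::export(rng = false)]]
List cpp_maxpool_fw(NumericVector x, IntegerVector f) {
  Dims5 dm = dims5(x);
  const int fd = f[0], fh = f[1], fw = f[2];
  if (dm.D % fd || dm.H % fh || dm.W % fw)
    stop("pooling factors must divide the spatial extents");
  const int Do = dm.D / fd, Ho = dm.H / fh, Wo = dm.W / fw;
  const long Po = (long)Do * Ho * Wo;

  NumericVector out(Po * dm.C * dm.N);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, dm.C, dm.N);
  IntegerVector idx(out.size()); // 0-based linear index into x

  const double* xp = REAL(x);
  double* op = REAL(out);
  int* ip = INTEGER(idx);
  long q = 0;
  for (int n = 0; n < dm.N; ++n)
    for (int ci = 0; ci < dm.C; ++ci) {
      const long base = ((long)n * dm.C + ci) * dm.P();
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          for (int dd = 0; dd < Do; ++dd) {
            double best = -1e300;
            long bi = -1;
            for (int c = 0; c < fw; ++c)
              for (int b = 0; b < fh; ++b)
                for (int a = 0; a < fd; ++a) {
                  const long p = base + (fd * dd + a) +
                      (long)dm.D * ((fh * ho + b) +
                                    (long)dm.H * (fw * wo + c));
                  if (xp[p] > best) { best = xp[p]; bi = p; }
                }
            op[q] = best;
            ip[q] = (int)bi;
            ++q;
          }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector gout,
                             IntegerVector xdim) {
  long sz = 1;
  for (int i = 0; i < xdim.size(); ++i) sz *= xdim[i];
  NumericVector dx(sz);
  dx.attr("dim") = xdim;
  double* dp = REAL(dx);
  const double* gp = REAL(gout);
  const int* ip = INTEGER(idx);
  for (long q = 0; q < (long)gout.size(); ++q) dp[ip[q]] += gp[q];
  return dx;
}

// Connected-component labelling of a 3D binary mask (6- or 26-connectivity),
// iterative flood fill. Returns an integer array of component labels (0 = bg).
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int D = dim[0], H = dim[1], W = dim[2];
  const long P = (long)D * H * W;
  IntegerVector lab(P);
  lab.attr("dim") = dim;
  const int* mp = INTEGER(mask);
  int* lp = INTEGER(lab);
  std::vector<long> stack;
  int next = 0;

  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dz && !dy && !dx) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m != 1) continue;
        nb.push_back({dz, dy, dx});
      }

  for (long p0 = 0; p0 < P; ++p0) {
    if (!mp[p0] || lp[p0]) continue;
    ++next;
    lp[p0] = next;
    stack.push_back(p0);
    while (!stack.empty()) {
      long p = stack.back();
      stack.pop_back();
      const int d = p % D, h = (p / D) % H, w = p / ((long)D * H);
      for (auto& o : nb) {
        const int dd = d + o[0], hh = h + o[1], ww = w + o[2];
        if (dd < 0 || dd >= D || hh < 0 || hh >= H || ww < 0 || ww >= W)
          continue;
        const long q = dd + (long)D * (hh + (long)H * ww);
        if (mp[q] && !lp[q]) {
          lp[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Binary morphological dilation with a box structuring element of radius r
// (Chebyshev ball), used to restrict lesion predictions to the liver.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_dilate_box(IntegerVector mask, IntegerVector dim, int r) {
  const int D = dim[0], H = dim[1], W = dim[2];
  IntegerVector out((long)D * H * W);
  out.attr("dim") = dim;
  const int* mp = INTEGER(mask);
  int* op = INTEGER(out);
  // separable along each axis: three passes of 1-d max filters
  std::vector<int> tmp(mp, mp + (long)D * H * W), tmp2(tmp.size());
  auto pass = [&](std::vector<int>& src, std::vector<int>& dst,
                  int axis) {
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          int v = 0;
          for (int k = -r; k <= r && !v; ++k) {
            int dd = d, hh = h, ww = w;
            if (axis == 0) dd += k;
            else if (axis == 1) hh += k;
            else ww += k;
            if (dd < 0 || dd >= D || hh < 0 || hh >= H || ww < 0 || ww >= W)
              continue;
            v = src[dd + (long)D * (hh + (long)H * ww)];
          }
          dst[d + (long)D * (h + (long)H * w)] = v ? 1 : 0;
        }
  };
  pass(tmp, tmp2, 0);
  pass(tmp2, tmp, 1);
  pass(tmp, tmp2, 2);
  std::copy(tmp2.begin(), tmp2.end(), op);
  return out;
}

// Batchnorm helpers: channel-wise statistics and normalisation over a
// (D,H,W,C,N) tensor, where each channel's voxels form contiguous blocks.

// [[Rcpp::export(rng = false)]]
List cpp_channel_stats(NumericVector x) {
  Dims5 dm = dims5(x);
  const long P = dm.P();
  NumericVector mu(dm.C), va(dm.C);
  const double* xp = REAL(x);
  for (int ci = 0; ci < dm.C; ++ci) {
    double s = 0, s2 = 0;
    for (int n = 0; n < dm.N; ++n) {
      const double* b = xp + ((long)n * dm.C + ci) * P;
      for (long p = 0; p < P; ++p) { s += b[p]; s2 += b[p] * b[p]; }
    }
    const double m = s / ((double)P * dm.N);
    mu[ci] = m;
    va[ci] = s2 / ((double)P * dm.N) - m * m;
    if (va[ci] < 0) va[ci] = 0;
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}

// [[Rcpp::export(rng = false)]]
List cpp_bn_apply(NumericVector x, NumericVector mu, NumericVector invstd,
                  NumericVector gamma, NumericVector beta) {
  Dims5 dm = dims5(x);
  const long P = dm.P();
  NumericVector out(x.size()), xhat(x.size());
  out.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  double* op = REAL(out);
  double* hp = REAL(xhat);
  for (int n = 0; n < dm.N; ++n)
    for (int ci = 0; ci < dm.C; ++ci) {
      const long off = ((long)n * dm.C + ci) * P;
      const double m = mu[ci], is = invstd[ci], g = gamma[ci], bt = beta[ci];
      for (long p = 0; p < P; ++p) {
        const double h = (xp[off + p] - m) * is;
        hp[off + p] = h;
        op[off + p] = g * h + bt;
      }
    }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// [[Rcpp::export(rng = false)]]
List cpp_bn_bw(NumericVector dy, NumericVector xhat, NumericVector gamma,
               NumericVector invstd) {
  Dims5 dm = dims5(dy);
  const long P = dm.P();
  const double M = (double)P * dm.N;
  NumericVector dx(dy.size()), dgamma(dm.C), dbeta(dm.C);
  dx.attr("dim") = dy.attr("dim");
  const double* gp = REAL(dy);
  const double* hp = REAL(xhat);
  double* dp = REAL(dx);
  for (int ci = 0; ci < dm.C; ++ci) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < dm.N; ++n) {
      const long off = ((long)n * dm.C + ci) * P;
      for (long p = 0; p < P; ++p) {
        s1 += gp[off + p];
        s2 += gp[off + p] * hp[off + p];
      }
    }
    dbeta[ci] = s1;
    dgamma[ci] = s2;
    const double k = gamma[ci] * invstd[ci] / M;
    for (int n = 0; n < dm.N; ++n) {
      const long off = ((long)n * dm.C + ci) * P;
      for (long p = 0; p < P; ++p)
        dp[off + p] = k * (M * gp[off + p] - s1 - hp[off + p] * s2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
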