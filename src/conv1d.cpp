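#include <Rcpp.h>
using namespace Rcpp;

// Grouped 1D convolution over the time axis of a [N x Cin x L] array
// (R column-major layout, trials fastest). Weights are [Cout x Cin/g x K].
// Covers all three convolution types of the network: full temporal
// convolution (groups = 1), depthwise (groups = Cin, one filter per map)
// and pointwise (groups = 1, K = 1). Inner loops run over the trial index,
// which is contiguous in memory.

static void dims3(const NumericVector& a, int* d) {
  IntegerVector dim = a.attr("dim");
  if (dim.size() != 3) stop("expected a 3-d array");
  d[0] = dim[0]; d[1] = dim[1]; d[2] = dim[2];
}

// [[Rcpp::export(name = ".conv1d_fwd")]]
NumericVector conv1d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int pad_l, int pad_r, int groups) {
  int dx[3], dw[3];
  dims3(x, dx); dims3(w, dw);
  const int N = dx[0], Cin = dx[1], L = dx[2];
  const int Cout = dw[0], cin_g = dw[1], K = dw[2];
  if (Cin % groups != 0 || Cout % groups != 0)
    stop("channel counts not divisible by groups");
  if (Cin / groups != cin_g) stop("weight shape inconsistent with groups");
  const int cout_g = Cout / groups;
  const int Lout = L + pad_l + pad_r - K + 1;
  if (Lout < 1) stop("output length < 1 (input too short for kernel)");

  NumericVector out(static_cast<R_xlen_t>(N) * Cout * Lout);
  out.attr("dim") = IntegerVector::create(N, Cout, Lout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();

  for (int co = 0; co < Cout; ++co) {
    const int g = co / cout_g;
    const double bias = (b.size() > 0) ? b[co] : 0.0;
    for (int l = 0; l < Lout; ++l) {
      double* orow = op + (static_cast<R_xlen_t>(co) + static_cast<R_xlen_t>(Cout) * l) * N;
      if (bias != 0.0) for (int n = 0; n < N; ++n) orow[n] = bias;
      for (int cg = 0; cg < cin_g; ++cg) {
        const int ci = g * cin_g + cg;
        for (int t = 0; t < K; ++t) {
          const int xl = l + t - pad_l;
          if (xl < 0 || xl >= L) continue;
          const double wv = wp[co + Cout * (cg + cin_g * t)];
          if (wv == 0.0) continue;
          const double* xrow = xp + (static_cast<R_xlen_t>(ci) + static_cast<R_xlen_t>(Cin) * xl) * N;
          for (int n = 0; n < N; ++n) orow[n] += wv * xrow[n];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
List conv1d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                int pad_l, int pad_r, int groups, bool has_bias) {
  int dx[3], dw[3], dg[3];
  dims3(x, dx); dims3(w, dw); dims3(gout, dg);
  const int N = dx[0], Cin = dx[1], L = dx[2];
  const int Cout = dw[0], cin_g = dw[1], K = dw[2];
  const int Lout = dg[2];
  if (dg[0] != N || dg[1] != Cout) stop("grad shape mismatch");
  if (Lout != L + pad_l + pad_r - K + 1) stop("grad length mismatch");
  const int cout_g = Cout / groups;

  NumericVector gx(static_cast<R_xlen_t>(N) * Cin * L);
  gx.attr("dim") = IntegerVector::create(N, Cin, L);
  NumericVector gw(static_cast<R_xlen_t>(Cout) * cin_g * K);
  gw.attr("dim") = IntegerVector::create(Cout, cin_g, K);
  NumericVector gb(has_bias ? Cout : 0);

  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gout.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();

  for (int co = 0; co < Cout; ++co) {
    const int g = co / cout_g;
    double bsum = 0.0;
    for (int l = 0; l < Lout; ++l) {
      const double* grow = gp + (static_cast<R_xlen_t>(co) + static_cast<R_xlen_t>(Cout) * l) * N;
      if (has_bias) for (int n = 0; n < N; ++n) bsum += grow[n];
      for (int cg = 0; cg < cin_g; ++cg) {
        const int ci = g * cin_g + cg;
        for (int t = 0; t < K; ++t) {
          const int xl = l + t - pad_l;
          if (xl < 0 || xl >= L) continue;
          const double* xrow = xp + (static_cast<R_xlen_t>(ci) + static_cast<R_xlen_t>(Cin) * xl) * N;
          double* gxrow = gxp + (static_cast<R_xlen_t>(ci) + static_cast<R_xlen_t>(Cin) * xl) * N;
          const double wv = wp[co + Cout * (cg + cin_g * t)];
          double acc = 0.0;
          for (int n = 0; n < N; ++n) {
            acc += grow[n] * xrow[n];
            gxrow[n] += wv * grow[n];
          }
          gwp[co + Cout * (cg + cin_g * t)] += acc;
        }
      }
    }
    if (has_bias) gb[co] = bsum;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
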