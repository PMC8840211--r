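#include <Rcpp.h>
using namespace Rcpp;

// Volumes are R arrays with dim (C, T, H, W); first index fastest.
// Weights for the standard conv have dim (Co, Ci, kt, kh, kw);
// depthwise weights have dim (C, kt, kh, kw).
// Output extent along each axis: (n + 2*pad - k) / stride + 1.

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static void get4(const IntegerVector &d, int &C, int &T, int &H, int &W) {
  C = d[0]; T = d[1]; H = d[2]; W = d[3];
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w,
                             IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C, T, H, W;
  get4(xd, C, T, H, W);
  const int Co = wd[0], Ci = wd[1], kt = wd[2], kh = wd[3], kw = wd[4];
  if (Ci != C) stop("input channel mismatch in conv3d");
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_extent(T, kt, st, pt);
  const int Ho = out_extent(H, kh, sh, ph);
  const int Wo = out_extent(W, kw, sw, pw);
  NumericVector y(static_cast<R_xlen_t>(Co) * To * Ho * Wo);
  const double *px = x.begin(), *pwt = w.begin();
  double *py = y.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int to = 0; to < To; ++to) {
        double *yo = py + static_cast<R_xlen_t>(Co) *
                              (to + static_cast<R_xlen_t>(To) * (ho + static_cast<R_xlen_t>(Ho) * wo));
        for (int d = 0; d < kw; ++d) {
          int wi = wo * sw + d - pw;
          if (wi < 0 || wi >= W) continue;
          for (int b = 0; b < kh; ++b) {
            int hi = ho * sh + b - ph;
            if (hi < 0 || hi >= H) continue;
            for (int a = 0; a < kt; ++a) {
              int ti = to * st + a - pt;
              if (ti < 0 || ti >= T) continue;
              const double *xo = px + static_cast<R_xlen_t>(C) *
                                          (ti + static_cast<R_xlen_t>(T) * (hi + static_cast<R_xlen_t>(H) * wi));
              const double *wk = pwt + static_cast<R_xlen_t>(Co) * Ci *
                                           (a + static_cast<R_xlen_t>(kt) * (b + static_cast<R_xlen_t>(kh) * d));
              for (int ci = 0; ci < C; ++ci) {
                double xv = xo[ci];
                if (xv == 0.0) continue;
                const double *wc = wk + static_cast<R_xlen_t>(Co) * ci;
                for (int co = 0; co < Co; ++co) yo[co] += wc[co] * xv;
              }
            }
          }
        }
      }
  y.attr("dim") = IntegerVector::create(Co, To, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_x(NumericVector gy, NumericVector w,
                               IntegerVector stride, IntegerVector pad,
                               IntegerVector xdim) {
  IntegerVector wd = w.attr("dim");
  const int Co = wd[0], Ci = wd[1], kt = wd[2], kh = wd[3], kw = wd[4];
  int C, T, H, W;
  get4(xdim, C, T, H, W);
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_extent(T, kt, st, pt);
  const int Ho = out_extent(H, kh, sh, ph);
  const int Wo = out_extent(W, kw, sw, pw);
  NumericVector gx(static_cast<R_xlen_t>(C) * T * H * W);
  const double *pg = gy.begin(), *pwt = w.begin();
  double *px = gx.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int to = 0; to < To; ++to) {
        const double *go = pg + static_cast<R_xlen_t>(Co) *
                                    (to + static_cast<R_xlen_t>(To) * (ho + static_cast<R_xlen_t>(Ho) * wo));
        for (int d = 0; d < kw; ++d) {
          int wi = wo * sw + d - pw;
          if (wi < 0 || wi >= W) continue;
          for (int b = 0; b < kh; ++b) {
            int hi = ho * sh + b - ph;
            if (hi < 0 || hi >= H) continue;
            for (int a = 0; a < kt; ++a) {
              int ti = to * st + a - pt;
              if (ti < 0 || ti >= T) continue;
              double *xo = px + static_cast<R_xlen_t>(C) *
                                    (ti + static_cast<R_xlen_t>(T) * (hi + static_cast<R_xlen_t>(H) * wi));
              const double *wk = pwt + static_cast<R_xlen_t>(Co) * Ci *
                                           (a + static_cast<R_xlen_t>(kt) * (b + static_cast<R_xlen_t>(kh) * d));
              for (int ci = 0; ci < C; ++ci) {
                const double *wc = wk + static_cast<R_xlen_t>(Co) * ci;
                double s = 0.0;
                for (int co = 0; co < Co; ++co) s += wc[co] * go[co];
                xo[ci] += s;
              }
            }
          }
        }
      }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_w(NumericVector gy, NumericVector x,
                               IntegerVector wdim, IntegerVector stride,
                               IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  int C, T, H, W;
  get4(xd, C, T, H, W);
  const int Co = wdim[0], Ci = wdim[1], kt = wdim[2], kh = wdim[3], kw = wdim[4];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_extent(T, kt, st, pt);
  const int Ho = out_extent(H, kh, sh, ph);
  const int Wo = out_extent(W, kw, sw, pw);
  NumericVector gw(static_cast<R_xlen_t>(Co) * Ci * kt * kh * kw);
  const double *pg = gy.begin(), *px = x.begin();
  double *pw_ = gw.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int to = 0; to < To; ++to) {
        const double *go = pg + static_cast<R_xlen_t>(Co) *
                                    (to + static_cast<R_xlen_t>(To) * (ho + static_cast<R_xlen_t>(Ho) * wo));
        for (int d = 0; d < kw; ++d) {
          int wi = wo * sw + d - pw;
          if (wi < 0 || wi >= W) continue;
          for (int b = 0; b < kh; ++b) {
            int hi = ho * sh + b - ph;
            if (hi < 0 || hi >= H) continue;
            for (int a = 0; a < kt; ++a) {
              int ti = to * st + a - pt;
              if (ti < 0 || ti >= T) continue;
              const double *xo = px + static_cast<R_xlen_t>(C) *
                                          (ti + static_cast<R_xlen_t>(T) * (hi + static_cast<R_xlen_t>(H) * wi));
              double *wk = pw_ + static_cast<R_xlen_t>(Co) * Ci *
                                     (a + static_cast<R_xlen_t>(kt) * (b + static_cast<R_xlen_t>(kh) * d));
              for (int ci = 0; ci < C; ++ci) {
                double xv = xo[ci];
                if (xv == 0.0) continue;
                double *wc = wk + static_cast<R_xlen_t>(Co) * ci;
                for (int co = 0; co < Co; ++co) wc[co] += go[co] * xv;
              }
            }
          }
        }
      }
  gw.attr("dim") = wdim;
  return gw;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv3d_fwd(NumericVector x, NumericVector w,
                               IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C, T, H, W;
  get4(xd, C, T, H, W);
  const int kt = wd[1], kh = wd[2], kw = wd[3];
  if (wd[0] != C) stop("channel mismatch in depthwise conv3d");
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_extent(T, kt, st, pt);
  const int Ho = out_extent(H, kh, sh, ph);
  const int Wo = out_extent(W, kw, sw, pw);
  NumericVector y(static_cast<R_xlen_t>(C) * To * Ho * Wo);
  const double *px = x.begin(), *pwt = w.begin();
  double *py = y.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int to = 0; to < To; ++to) {
        double *yo = py + static_cast<R_xlen_t>(C) *
                              (to + static_cast<R_xlen_t>(To) * (ho + static_cast<R_xlen_t>(Ho) * wo));
        for (int d = 0; d < kw; ++d) {
          int wi = wo * sw + d - pw;
          if (wi < 0 || wi >= W) continue;
          for (int b = 0; b < kh; ++b) {
            int hi = ho * sh + b - ph;
            if (hi < 0 || hi >= H) continue;
            for (int a = 0; a < kt; ++a) {
              int ti = to * st + a - pt;
              if (ti < 0 || ti >= T) continue;
              const double *xo = px + static_cast<R_xlen_t>(C) *
                                          (ti + static_cast<R_xlen_t>(T) * (hi + static_cast<R_xlen_t>(H) * wi));
              const double *wk = pwt + static_cast<R_xlen_t>(C) *
                                           (a + static_cast<R_xlen_t>(kt) * (b + static_cast<R_xlen_t>(kh) * d));
              for (int c = 0; c < C; ++c) yo[c] += wk[c] * xo[c];
            }
          }
        }
      }
  y.attr("dim") = IntegerVector::create(C, To, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv3d_bwd_x(NumericVector gy, NumericVector w,
                                 IntegerVector stride, IntegerVector pad,
                                 IntegerVector xdim) {
  IntegerVector wd = w.attr("dim");
  int C, T, H, W;
  get4(xdim, C, T, H, W);
  const int kt = wd[1], kh = wd[2], kw = wd[3];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_extent(T, kt, st, pt);
  const int Ho = out_extent(H, kh, sh, ph);
  const int Wo = out_extent(W, kw, sw, pw);
  NumericVector gx(static_cast<R_xlen_t>(C) * T * H * W);
  const double *pg = gy.begin(), *pwt = w.begin();
  double *px = gx.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int to = 0; to < To; ++to) {
        const double *go = pg + static_cast<R_xlen_t>(C) *
                                    (to + static_cast<R_xlen_t>(To) * (ho + static_cast<R_xlen_t>(Ho) * wo));
        for (int d = 0; d < kw; ++d) {
          int wi = wo * sw + d - pw;
          if (wi < 0 || wi >= W) continue;
          for (int b = 0; b < kh; ++b) {
            int hi = ho * sh + b - ph;
            if (hi < 0 || hi >= H) continue;
            for (int a = 0; a < kt; ++a) {
              int ti = to * st + a - pt;
              if (ti < 0 || ti >= T) continue;
              double *xo = px + static_cast<R_xlen_t>(C) *
                                    (ti + static_cast<R_xlen_t>(T) * (hi + static_cast<R_xlen_t>(H) * wi));
              const double *wk = pwt + static_cast<R_xlen_t>(C) *
                                           (a + static_cast<R_xlen_t>(kt) * (b + static_cast<R_xlen_t>(kh) * d));
              for (int c = 0; c < C; ++c) xo[c] += wk[c] * go[c];
            }
          }
        }
      }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv3d_bwd_w(NumericVector gy, NumericVector x,
                                 IntegerVector wdim, IntegerVector stride,
                                 IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  int C, T, H, W;
  get4(xd, C, T, H, W);
  const int kt = wdim[1], kh = wdim[2], kw = wdim[3];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_extent(T, kt, st, pt);
  const int Ho = out_extent(H, kh, sh, ph);
  const int Wo = out_extent(W, kw, sw, pw);
  NumericVector gw(static_cast<R_xlen_t>(C) * kt * kh * kw);
  const double *pg = gy.begin(), *px = x.begin();
  double *pw_ = gw.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int to = 0; to < To; ++to) {
        const double *go = pg + static_cast<R_xlen_t>(C) *
                                    (to + static_cast<R_xlen_t>(To) * (ho + static_cast<R_xlen_t>(Ho) * wo));
        for (int d = 0; d < kw; ++d) {
          int wi = wo * sw + d - pw;
          if (wi < 0 || wi >= W) continue;
          for (int b = 0; b < kh; ++b) {
            int hi = ho * sh + b - ph;
            if (hi < 0 || hi >= H) continue;
            for (int a = 0; a < kt; ++a) {
              int ti = to * st + a - pt;
              if (ti < 0 || ti >= T) continue;
              const double *xo = px + static_cast<R_xlen_t>(C) *
                                          (ti + static_cast<R_xlen_t>(T) * (hi + static_cast<R_xlen_t>(H) * wi));
              double *wk = pw_ + static_cast<R_xlen_t>(C) *
                                     (a + static_cast<R_xlen_t>(kt) * (b + static_cast<R_xlen_t>(kh) * d));
              for (int c = 0; c < C; ++c) wk[c] += go[c] * xo[c];
            }
          }
        }
      }
  gw.attr("dim") = wdim;
  return gw;
}
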