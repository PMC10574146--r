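#include <Rcpp.h>
using namespace Rcpp;

// Dense numeric kernels for the toy segmentation nets and the augmentation
// pipeline. Arrays are R column-major: image/feature maps are H x W x C,
// conv weights are k x k x Cin x Cout. All convolutions are stride-1 with
// "same" zero padding (odd k).

// wraps x into [0, m) without libm's fmod (keeps the binary portable
// across glibc versions)
static inline double wrap_mod(double x, double m) {
  return x - m * std::floor(x / m);
}

static inline int idx3(int i, int j, int c, int H, int W) {
  return i + H * (j + W * c);
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int k = wd[0], Cout = wd[3];
  int p = (k - 1) / 2;
  if (wd[1] != k || wd[2] != Cin) stop("weight dims do not match input");
  NumericVector y(H * W * Cout);
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int co = 0; co < Cout; ++co) {
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        py[idx3(i, j, co, H, W)] = pb[co];
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          double wv = pw[di + k * (dj + k * (ci + Cin * co))];
          if (wv == 0.0) continue;
          int i0 = std::max(0, p - di), i1 = std::min(H, H + p - di);
          int j0 = std::max(0, p - dj), j1 = std::min(W, W + p - dj);
          for (int j = j0; j < j1; ++j) {
            const double *xcol = px + idx3(0, j + dj - p, ci, H, W);
            double *ycol = py + idx3(0, j, co, H, W);
            for (int i = i0; i < i1; ++i)
              ycol[i] += wv * xcol[i + di - p];
          }
        }
      }
    }
  }
  return y;
}

// Backward pass: given upstream gradient gy (H x W x Cout), returns
// gradients for input, weights and bias.
// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int k = wd[0], Cout = wd[3];
  int p = (k - 1) / 2;
  NumericVector gx(H * W * Cin), gw(k * k * Cin * Cout), gb(Cout);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int co = 0; co < Cout; ++co) {
    double s = 0.0;
    const double *gcol0 = pg + idx3(0, 0, co, H, W);
    for (int n = 0; n < H * W; ++n) s += gcol0[n];
    pgb[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          double wv = pw[di + k * (dj + k * (ci + Cin * co))];
          double acc = 0.0;
          int i0 = std::max(0, p - di), i1 = std::min(H, H + p - di);
          int j0 = std::max(0, p - dj), j1 = std::min(W, W + p - dj);
          for (int j = j0; j < j1; ++j) {
            const double *xcol = px + idx3(0, j + dj - p, ci, H, W);
            double *gxcol = pgx + idx3(0, j + dj - p, ci, H, W);
            const double *gcol = pg + idx3(0, j, co, H, W);
            for (int i = i0; i < i1; ++i) {
              double g = gcol[i];
              acc += g * xcol[i + di - p];
              gxcol[i + di - p] += g * wv;
            }
          }
          pgw[di + k * (dj + k * (ci + Cin * co))] = acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Inverse-mapped affine warp. m is the 2x3 matrix taking OUTPUT pixel
// coordinates (row, col, 1), zero-based, to source coordinates. interp:
// 0 = nearest (labels), 1 = bilinear (images). fill has one entry per
// channel and is used outside the source frame.
// [[Rcpp::export]]
NumericVector warp_affine_cpp(NumericVector img, NumericMatrix m, int interp,
                              NumericVector fill, IntegerVector out_dim) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  int Ho = out_dim[0], Wo = out_dim[1];
  NumericVector out(Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double *p = img.begin();
  double *q = out.begin();
  double a11 = m(0, 0), a12 = m(0, 1), a13 = m(0, 2);
  double a21 = m(1, 0), a22 = m(1, 1), a23 = m(1, 2);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double si = a11 * i + a12 * j + a13;
      double sj = a21 * i + a22 * j + a23;
      if (interp == 1 && si >= 0 && sj >= 0 && si < H - 1 && sj < W - 1) {
        // interior fast path: all four corners inside, no bounds checks
        int fi = (int)si, fj = (int)sj;
        double ti = si - fi, tj = sj - fj;
        double w00 = (1 - ti) * (1 - tj), w10 = ti * (1 - tj);
        double w01 = (1 - ti) * tj, w11 = ti * tj;
        const double *base = p + fi + H * fj;
        double *qp = q + i + Ho * j;
        for (int c = 0; c < C; ++c) {
          const double *b0 = base + (R_xlen_t)c * H * W;
          qp[(R_xlen_t)c * Ho * Wo] = w00 * b0[0] + w10 * b0[1] +
              w01 * b0[H] + w11 * b0[H + 1];
        }
        continue;
      }
      if (interp == 0) {
        int ri = (int)(si + 0.5), rj = (int)(sj + 0.5);
        if (si < -0.5) ri = -1;
        if (sj < -0.5) rj = -1;
        bool inside = ri >= 0 && ri < H && rj >= 0 && rj < W;
        for (int c = 0; c < C; ++c)
          q[idx3(i, j, c, Ho, Wo)] =
              inside ? p[idx3(ri, rj, c, H, W)] : fill[c];
      } else {
        int fi = (int)std::floor(si), fj = (int)std::floor(sj);
        double ti = si - fi, tj = sj - fj;
        const int ii[2] = {fi, fi + 1};
        const int jj[2] = {fj, fj + 1};
        const double wi[2] = {1.0 - ti, ti};
        const double wj[2] = {1.0 - tj, tj};
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              double wgt = wi[a] * wj[b];
              if (wgt == 0.0) continue;
              bool in = ii[a] >= 0 && ii[a] < H && jj[b] >= 0 && jj[b] < W;
              acc += wgt * (in ? p[idx3(ii[a], jj[b], c, H, W)] : fill[c]);
            }
          q[idx3(i, j, c, Ho, Wo)] = acc;
        }
      }
    }
  }
  return out;
}

// ---- HSV helpers -----------------------------------------------------------

static inline void rgb2hsv_px(double r, double g, double b, double &h,
                              double &s, double &v) {
  double mx = std::max(r, std::max(g, b));
  double mn = std::min(r, std::min(g, b));
  double d = mx - mn;
  v = mx;
  s = mx > 0 ? d / mx : 0.0;
  if (d <= 0) {
    h = 0.0;
    return;
  }
  if (mx == r)
    h = (g - b) / d;
  else if (mx == g)
    h = (b - r) / d + 2.0;
  else
    h = (r - g) / d + 4.0;
  h /= 6.0;
  if (h < 0) h += 1.0;
}

static inline void hsv2rgb_px(double h, double s, double v, double &r,
                              double &g, double &b) {
  double hh = wrap_mod(h, 1.0) * 6.0;
  int i = (int)std::floor(hh);
  double f = hh - i;
  double p = v * (1.0 - s);
  double q = v * (1.0 - s * f);
  double t = v * (1.0 - s * (1.0 - f));
  switch (i) {
  case 0: r = v; g = t; b = p; break;
  case 1: r = q; g = v; b = p; break;
  case 2: r = p; g = v; b = t; break;
  case 3: r = p; g = q; b = v; break;
  case 4: r = t; g = p; b = v; break;
  default: r = v; g = p; b = q; break;
  }
}

// Multiplicative HSV jitter of an RGB image in [0,255]; factors clamp the
// channels into [0,1] after scaling (hue included, matching the
// augmentation convention).
// [[Rcpp::export]]
NumericVector hsv_scale_cpp(NumericVector img, double fh, double fs,
                            double fv) {
  IntegerVector d = img.attr("dim");
  int n = d[0] * d[1];
  NumericVector out(img.size());
  out.attr("dim") = d;
  const double *p = img.begin();
  double *q = out.begin();
  for (int k = 0; k < n; ++k) {
    double h, s, v, r, g, b;
    rgb2hsv_px(p[k] / 255.0, p[k + n] / 255.0, p[k + 2 * n] / 255.0, h, s, v);
    h = std::min(std::max(h * fh, 0.0), 1.0);
    s = std::min(std::max(s * fs, 0.0), 1.0);
    v = std::min(std::max(v * fv, 0.0), 1.0);
    hsv2rgb_px(h, s, v, r, g, b);
    q[k] = r * 255.0;
    q[k + n] = g * 255.0;
    q[k + 2 * n] = b * 255.0;
  }
  return out;
}

// Season shift: hue rotation (degrees), saturation/brightness gains and a
// texture-contrast stretch of V about each flagged class's mean V.
// Unflagged pixels are copied bit-exactly.
// [[Rcpp::export]]
NumericVector season_shift_cpp(NumericVector img, IntegerVector label,
                               LogicalVector flags, double hue_deg,
                               double sat_gain, double v_gain,
                               double tc_gain) {
  IntegerVector d = img.attr("dim");
  int n = d[0] * d[1];
  NumericVector out = clone(img);
  const double *p = img.begin();
  double *q = out.begin();
  int C = flags.size();
  // pass 1: per-class mean V over flagged pixels
  std::vector<double> vsum(C, 0.0);
  std::vector<int> vcnt(C, 0);
  std::vector<double> hbuf(n), sbuf(n), vbuf(n);
  for (int k = 0; k < n; ++k) {
    int c = label[k] - 1;
    if (c < 0 || c >= C || !flags[c]) continue;
    rgb2hsv_px(p[k] / 255.0, p[k + n] / 255.0, p[k + 2 * n] / 255.0,
               hbuf[k], sbuf[k], vbuf[k]);
    vsum[c] += vbuf[k];
    vcnt[c] += 1;
  }
  double hshift = hue_deg / 360.0;
  for (int k = 0; k < n; ++k) {
    int c = label[k] - 1;
    if (c < 0 || c >= C || !flags[c]) continue;
    double h = wrap_mod(hbuf[k] + hshift, 1.0);
    double s = std::min(std::max(sbuf[k] * sat_gain, 0.0), 1.0);
    double v = vbuf[k];
    if (tc_gain != 1.0 && vcnt[c] > 0) {
      double vbar = vsum[c] / vcnt[c];
      v = vbar + tc_gain * (v - vbar);
    }
    v = std::min(std::max(v * v_gain, 0.0), 1.0);
    double r, g, b;
    hsv2rgb_px(h, s, v, r, g, b);
    q[k] = std::min(std::max(r * 255.0, 0.0), 255.0);
    q[k + n] = std::min(std::max(g * 255.0, 0.0), 255.0);
    q[k + 2 * n] = std::min(std::max(b * 255.0, 0.0), 255.0);
  }
  return out;
}

// Adds precomputed noise and clamps to [0,255] in one pass.
// [[Rcpp::export]]
NumericVector add_clamp_cpp(NumericVector img, NumericVector noise) {
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  for (R_xlen_t k = 0; k < img.size(); ++k) {
    double v = img[k] + noise[k];
    out[k] = std::min(std::max(v, 0.0), 255.0);
  }
  return out;
}

// Per-class oriented sinusoid texture, evaluated per pixel for the pixel's
// own class: amp[c] * sin(2*pi*freq[c]*(i*cos(th[c]) + j*sin(th[c])) + ph[c]).
// [[Rcpp::export]]
NumericMatrix scene_texture_cpp(IntegerMatrix label, NumericVector freq,
                                NumericVector amp, NumericVector theta,
                                NumericVector phase) {
  int H = label.nrow(), W = label.ncol();
  NumericMatrix out(H, W);
  const double twopi = 2.0 * M_PI;
  std::vector<double> ct(freq.size()), st(freq.size());
  for (int c = 0; c < freq.size(); ++c) {
    ct[c] = std::cos(theta[c]);
    st[c] = std::sin(theta[c]);
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int c = label(i, j) - 1;
      out(i, j) = amp[c] *
          std::sin(twopi * freq[c] * (i * ct[c] + j * st[c]) + phase[c]);
    }
  return out;
}


// ---- fast seeded Gaussian noise -------------------------------------------

// splitmix64; the stream is seeded from R's RNG so augmentation stays
// reproducible from the config seed.
static inline uint64_t sm64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double unif01(uint64_t &state) {
  return (sm64(state) >> 11) * (1.0 / 9007199254740992.0);
}

// Marsaglia polar method (trig-free); fills buf with two standard normals.
static inline void gauss_pair(uint64_t &state, double *buf) {
  double u, v, s2;
  do {
    u = 2.0 * unif01(state) - 1.0;
    v = 2.0 * unif01(state) - 1.0;
    s2 = u * u + v * v;
  } while (s2 >= 1.0 || s2 == 0.0);
  double f = std::sqrt(-2.0 * std::log(s2) / s2);
  buf[0] = u * f;
  buf[1] = v * f;
}

// Adds N(mean, sd) noise to an image in [0,255] and clamps, in one pass.
// [[Rcpp::export]]
NumericVector gauss_noise_add_cpp(NumericVector img, double mean, double sd,
                                  double useed) {
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  uint64_t state = (uint64_t)(useed * 9007199254740992.0) ^
      0xdeadbeefcafef00dULL;
  R_xlen_t n = img.size();
  double z[2];
  for (R_xlen_t k = 0; k < n; k += 2) {
    gauss_pair(state, z);
    double v = img[k] + mean + sd * z[0];
    out[k] = std::min(std::max(v, 0.0), 255.0);
    if (k + 1 < n) {
      v = img[k + 1] + mean + sd * z[1];
      out[k + 1] = std::min(std::max(v, 0.0), 255.0);
    }
  }
  return out;
}

// Scene image composition: per-class base colour + shared texture +
// N(0, sd) pixel noise from a stream seeded out of R's RNG, clamped to
// [0,255].
// [[Rcpp::export]]
NumericVector compose_image_cpp(IntegerMatrix label, NumericMatrix base,
                                NumericMatrix tex, double sd, double useed) {
  int H = label.nrow(), W = label.ncol();
  R_xlen_t n = (R_xlen_t)H * W;
  NumericVector out(n * 3);
  out.attr("dim") = IntegerVector::create(H, W, 3);
  uint64_t state = (uint64_t)(useed * 9007199254740992.0) ^
      0xabcdef0123456789ULL;
  double z[2];
  int zi = 2;
  for (int ch = 0; ch < 3; ++ch) {
    double *q = out.begin() + ch * n;
    const int *lab = label.begin();
    const double *tx = tex.begin();
    for (R_xlen_t k = 0; k < n; ++k) {
      if (zi == 2) { gauss_pair(state, z); zi = 0; }
      double v = base(lab[k] - 1, ch) + tx[k] + sd * z[zi++];
      q[k] = std::min(std::max(v, 0.0), 255.0);
    }
  }
  return out;
}

// Offset argmax over class fields (ties to the first/lowest class).
// [[Rcpp::export]]
IntegerMatrix argmax_fields_cpp(List fields, NumericVector offs,
                                IntegerVector active) {
  NumericMatrix f0 = fields[0];
  int H = f0.nrow(), W = f0.ncol();
  int A = active.size();
  std::vector<const double *> fp(A);
  for (int a = 0; a < A; ++a) {
    NumericMatrix fa = fields[active[a] - 1];
    fp[a] = fa.begin();
  }
  IntegerMatrix out(H, W);
  R_xlen_t n = (R_xlen_t)H * W;
  for (R_xlen_t k = 0; k < n; ++k) {
    int best = 0;
    double bv = fp[0][k] + offs[active[0] - 1];
    for (int a = 1; a < A; ++a) {
      double v = fp[a][k] + offs[active[a] - 1];
      if (v > bv) { bv = v; best = a; }
    }
    out[k] = active[best];
  }
  return out;
}
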