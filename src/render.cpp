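#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dedicated noise stream: xorshift128+ uniforms (seeded through a
// splitmix64 scramble of the 31-bit seed R supplies) feeding the polar
// Box-Muller transform. Exactly Gaussian, deterministic given the seed,
// and fast enough to draw per-pixel camera noise for thousands of stacks.
// Callers draw the seed with sample.int so everything stays reproducible
// under a single set.seed().
namespace {
struct GaussStream {
  uint64_t s0, s1;
  bool have = false;
  double cache = 0.0;
  explicit GaussStream(uint64_t seed) {
    // splitmix64 to spread a small seed over both state words
    auto sm = [&seed]() {
      uint64_t z = (seed += 0x9e3779b97f4a7c15ULL);
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    s0 = sm(); s1 = sm();
  }
  double unif() {
    uint64_t x = s0, y = s1;
    s0 = y; x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return ((s1 + y) >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have) { have = false; return cache; }
    double v1, v2, rsq;
    do {
      v1 = 2.0 * unif() - 1.0; v2 = 2.0 * unif() - 1.0;
      rsq = v1 * v1 + v2 * v2;
    } while (rsq >= 1.0 || rsq == 0.0);
    double f = std::sqrt(-2.0 * std::log(rsq) / rsq);
    cache = v2 * f; have = true;
    return v1 * f;
  }
};
}  // namespace

// Gaussian deviates from the noise stream (exposed for tests).
// [[Rcpp::export]]
NumericVector cpp_gauss_noise(int n, double sd, int seed) {
  NumericVector out(n);
  GaussStream g(static_cast<uint64_t>(seed));
  for (int i = 0; i < n; ++i) out[i] = sd * g.norm();
  return out;
}

// Adds Gaussian camera noise to an image in place and clamps to the camera
// range, in a single pass (img is freshly allocated by the R caller).
// [[Rcpp::export]]
void cpp_noise_clamp(NumericMatrix img, double sd, int seed,
                     double lo = 0.0, double hi = 65535.0) {
  const R_xlen_t n = img.size();
  GaussStream g(static_cast<uint64_t>(seed));
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = img[i] + (sd > 0 ? sd * g.norm() : 0.0);
    img[i] = v < lo ? lo : (v > hi ? hi : v);
  }
}

// Per-pixel maximum over the given (1-based) slices of an H x W x Z array.
// [[Rcpp::export]]
NumericMatrix cpp_max_project(NumericVector arr, IntegerVector slices) {
  IntegerVector d = arr.attr("dim");
  const R_xlen_t H = d[0], W = d[1], page = H * W;
  NumericMatrix out(H, W);
  for (R_xlen_t s = 0; s < slices.size(); ++s) {
    const double *p = &arr[(R_xlen_t)(slices[s] - 1) * page];
    if (s == 0) std::copy(p, p + page, out.begin());
    else for (R_xlen_t i = 0; i < page; ++i)
      if (p[i] > out[i]) out[i] = p[i];
  }
  return out;
}

// Separable Gaussian blur with reflected edges (kernel truncated at
// 3.5 sigma). Direct convolution; used on the detection path where the
// FFT round trip would dominate the per-well cost.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  const int r = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> k(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i)
    ksum += (k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)));
  for (double &v : k) v /= ksum;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)        // blur along rows (y)
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * img(reflect(y + i, H), c);
      tmp(y, c) = acc;
    }
  for (int y = 0; y < H; ++y)        // blur along columns (x)
    for (int c = 0; c < W; ++c) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp(y, reflect(c + i, W));
      out(y, c) = acc;
    }
  return out;
}

// Adds isotropic Gaussian spots to an image in place (img is freshly
// allocated by the R caller, so in-place mutation never aliases user data).
// x, y are 1-based pixel coordinates; each spot is truncated at trunc*sigma.
// [[Rcpp::export]]
void cpp_add_spots(NumericMatrix img, NumericVector x, NumericVector y,
                   NumericVector sigma, NumericVector amp,
                   double trunc = 5.0) {
  const int H = img.nrow(), W = img.ncol(), n = x.size();
  for (int s = 0; s < n; ++s) {
    const double sx = x[s], sy = y[s], sg = sigma[s], a = amp[s];
    if (sg <= 0 || a == 0) continue;
    const double inv2s2 = 1.0 / (2.0 * sg * sg);
    const int r = (int)std::ceil(trunc * sg);
    const int c0 = std::max(1, (int)std::floor(sx) - r),
              c1 = std::min(W, (int)std::ceil(sx) + r),
              r0 = std::max(1, (int)std::floor(sy) - r),
              r1 = std::min(H, (int)std::ceil(sy) + r);
    for (int c = c0; c <= c1; ++c) {
      const double dx2 = (c - sx) * (c - sx);
      for (int rr = r0; rr <= r1; ++rr) {
        const double d2 = dx2 + (rr - sy) * (rr - sy);
        img(rr - 1, c - 1) += a * std::exp(-d2 * inv2s2);
      }
    }
  }
}
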