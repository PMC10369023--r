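#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// symmetric (half-sample) reflection of an out-of-range index into [0, n)
static inline int reflect_index(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable convolution of one image plane with an odd-length 1-d kernel,
// reflective boundary. Kernel is applied along rows then columns.
// [[Rcpp::export]]
NumericMatrix conv_separable_cpp(NumericMatrix x, NumericVector kernel) {
  const int h = x.nrow(), w = x.ncol(), k = kernel.size();
  if (k % 2 == 0) stop("kernel length must be odd");
  const int r = (k - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  // vertical pass (down the rows of each column)
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t)
        acc += kernel[t + r] * x(reflect_index(i + t, h), j);
      tmp(i, j) = acc;
    }
  // horizontal pass
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t)
        acc += kernel[t + r] * tmp(i, reflect_index(j + t, w));
      out(i, j) = acc;
    }
  return out;
}

// RNL ranked filter. `stack` is an H x W x C array (column-major, R layout)
// whose first C-1 channels are chromatic and last channel is luminance.
// Per iteration each pixel becomes the channelwise mean of the m kernel
// neighbours (centre included) closest to the centre in combined
// chromatic/achromatic delta-S, m = ceil(keep_frac * kernel size).
// `A` is the (C-1) x (C-1) receptor-noise quadratic form on log contrasts.
// [[Rcpp::export]]
NumericVector ranked_filter_cpp(NumericVector stack, IntegerVector dims,
                                NumericMatrix A, double lum_weber,
                                int radius, int n_iter, double keep_frac) {
  const int h = dims[0], w = dims[1], C = dims[2];
  const int nc = C - 1; // chromatic channels
  if (A.nrow() != nc || A.ncol() != nc) stop("noise matrix size mismatch");
  const int side = 2 * radius + 1, K = side * side;
  if (side > h || side > w) stop("ranked-filter kernel larger than image");
  const int m = std::max(1, (int)std::ceil(keep_frac * K));
  const long npix = (long)h * w;

  std::vector<double> cur(stack.begin(), stack.end());
  std::vector<double> nxt(cur.size());
  std::vector<double> lg(cur.size());

  // flatten the noise matrix for tight inner-loop access
  std::vector<double> a(nc * nc);
  for (int c = 0; c < nc; ++c)
    for (int c2 = 0; c2 < nc; ++c2) a[c * nc + c2] = A(c, c2);

  std::vector<long> interior_off(K);
  {
    int q = 0;
    for (int dj = -radius; dj <= radius; ++dj)
      for (int di = -radius; di <= radius; ++di)
        interior_off[q++] = di + (long)dj * h;
  }

  std::vector<double> ds2(K);
  std::vector<int> idx(K);
  std::vector<long> nb(K);
  std::vector<double> df(nc);
  const double inv_lw2 = 1.0 / (lum_weber * lum_weber);

  for (int iter = 0; iter < n_iter; ++iter) {
    for (size_t p = 0; p < cur.size(); ++p) lg[p] = std::log(cur[p]);
    const double *lgp = lg.data();
    const double *curp = cur.data();
    for (int j = 0; j < w; ++j) {
      const bool j_in = (j >= radius && j < w - radius);
      for (int i = 0; i < h; ++i) {
        const long centre = i + (long)j * h;
        if (j_in && i >= radius && i < h - radius) {
          for (int q = 0; q < K; ++q) nb[q] = centre + interior_off[q];
        } else {
          int q = 0;
          for (int dj = -radius; dj <= radius; ++dj) {
            const int jj = reflect_index(j + dj, w);
            for (int di = -radius; di <= radius; ++di)
              nb[q++] = reflect_index(i + di, h) + (long)jj * h;
          }
        }
        for (int q = 0; q < K; ++q) {
          const long n0 = nb[q];
          for (int c = 0; c < nc; ++c)
            df[c] = lgp[centre + c * npix] - lgp[n0 + c * npix];
          double chrom2 = 0.0;
          for (int c = 0; c < nc; ++c) {
            double acc = 0.0;
            const double *arow = &a[c * nc];
            for (int c2 = 0; c2 < nc; ++c2) acc += arow[c2] * df[c2];
            chrom2 += df[c] * acc;
          }
          if (chrom2 < 0.0) chrom2 = 0.0;
          const double dl = lgp[centre + nc * npix] - lgp[n0 + nc * npix];
          ds2[q] = chrom2 + dl * dl * inv_lw2; // monotone in delta-S
          idx[q] = q;
        }
        std::nth_element(idx.begin(), idx.begin() + (m - 1), idx.end(),
                         [&](int x, int y) {
                           if (ds2[x] != ds2[y]) return ds2[x] < ds2[y];
                           return x < y; // deterministic tie-break
                         });
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          const double *chan = curp + (long)c * npix;
          for (int q = 0; q < m; ++q) acc += chan[nb[idx[q]]];
          nxt[centre + (long)c * npix] = acc / m;
        }
      }
    }
    std::swap(cur, nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dims;
  return out;
}
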