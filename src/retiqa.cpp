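// Low-level numerical kernels: FFT convolution, FOV extension,
// circular Hough voting, exact 5x5 median.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
#include <algorithm>

using namespace Rcpp;

// Spectrum of a spatial kernel placed on an nr x nc padded grid with its
// centre wrapped to (0,0), so that pointwise products implement centred
// ("same") convolution after cropping.
// [[Rcpp::export]]
arma::cx_mat kernel_spectrum_cpp(const arma::mat& kernel, int nr, int nc) {
  int kr = kernel.n_rows, kc = kernel.n_cols;
  int cr = (kr - 1) / 2, cc = (kc - 1) / 2;
  arma::mat pad(nr, nc, arma::fill::zeros);
  for (int j = 0; j < kc; ++j) {
    int pj = ((j - cc) % nc + nc) % nc;
    for (int i = 0; i < kr; ++i) {
      int pi = ((i - cr) % nr + nr) % nr;
      pad(pi, pj) += kernel(i, j);
    }
  }
  return arma::fft2(arma::cx_mat(pad, arma::mat(nr, nc, arma::fill::zeros)));
}

// Convolve two real padded images (packed as real + i*imag) with a
// precomputed kernel spectrum in one forward/backward FFT pair.
// Returns list(a=conv(x1), b=conv(x2)); x2 may be empty (then b is empty).
// [[Rcpp::export]]
List conv2_packed_cpp(const arma::mat& x1, const arma::mat& x2,
                      const arma::cx_mat& kspec) {
  bool packed = (x2.n_elem == x1.n_elem) && x1.n_elem > 0 && x2.n_rows == x1.n_rows;
  arma::cx_mat z = packed
    ? arma::cx_mat(x1, x2)
    : arma::cx_mat(x1, arma::mat(x1.n_rows, x1.n_cols, arma::fill::zeros));
  arma::cx_mat w = arma::ifft2(arma::fft2(z) % kspec);
  if (packed)
    return List::create(_["a"] = arma::mat(arma::real(w)),
                        _["b"] = arma::mat(arma::imag(w)));
  return List::create(_["a"] = arma::mat(arma::real(w)), _["b"] = R_NilValue);
}

// Iterative FOV extension. Pixels are filled outward from the mask in
// city-block (4-neighbour dilation) distance order; each new pixel takes
// the mean of its 8-neighbours already inside the previously extended
// mask. Values inside the original mask are untouched. Returns the
// filled channels and the per-iteration count of newly added pixels.
// [[Rcpp::export]]
List fov_extend_cpp(NumericVector img, LogicalMatrix mask) {
  IntegerVector dims = img.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2];
  int n = H * W;
  std::vector<int> dist(n, -1);
  std::queue<int> q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (mask(i, j)) { dist[i + j * H] = 0; q.push(i + j * H); }
  if (q.empty()) stop("mask has no interior pixel");
  // multi-source BFS, 4-neighbourhood == L1 distance to the mask
  int maxd = 0;
  std::vector<int> order; order.reserve(n);
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int i = p % H, j = p / H;
    const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
    for (int k = 0; k < 4; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      int pp = ii + jj * H;
      if (dist[pp] < 0) {
        dist[pp] = dist[p] + 1;
        if (dist[pp] > maxd) maxd = dist[pp];
        order.push_back(pp);
        q.push(pp);
      }
    }
  }
  NumericVector out = clone(img);
  double* o = REAL(out);
  std::vector<int> added(maxd, 0);
  // order is already sorted by distance (BFS property)
  for (size_t t = 0; t < order.size(); ++t) {
    int p = order[t];
    int i = p % H, j = p / H, d = dist[p];
    added[d - 1] += 1;
    double sum[16]; int cnt = 0;
    for (int c = 0; c < C; ++c) sum[c] = 0.0;
    for (int dj2 = -1; dj2 <= 1; ++dj2)
      for (int di2 = -1; di2 <= 1; ++di2) {
        if (di2 == 0 && dj2 == 0) continue;
        int ii = i + di2, jj = j + dj2;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        int pp = ii + jj * H;
        if (dist[pp] <= d - 1) {
          ++cnt;
          for (int c = 0; c < C; ++c) sum[c] += o[pp + c * n];
        }
      }
    // BFS guarantees at least one 4-neighbour at distance d-1
    for (int c = 0; c < C; ++c) o[p + c * n] = sum[c] / cnt;
  }
  out.attr("dim") = dims;
  return List::create(_["pixels"] = out, _["iterations"] = maxd,
                      _["added"] = wrap(added));
}

// Circular Hough accumulator over edge pixels. Votes for centres at each
// candidate radius; returns the best (row, col, radius) and its votes.
// Edge pixel coordinates are 1-based rows/cols.
// [[Rcpp::export]]
List hough_circle_cpp(IntegerVector er, IntegerVector ec,
                      IntegerVector radii, int H, int W) {
  int best = -1, bi = 0, bj = 0, br = 0;
  std::vector<int> acc((size_t)H * W);
  int ne = er.size();
  for (int ri = 0; ri < radii.size(); ++ri) {
    int r = radii[ri];
    std::fill(acc.begin(), acc.end(), 0);
    int nang = std::max(90, (int)std::round(2 * M_PI * r / 4.0));
    for (int a = 0; a < nang; ++a) {
      double th = 2.0 * M_PI * a / nang;
      double dy = r * std::sin(th), dx = r * std::cos(th);
      for (int e = 0; e < ne; ++e) {
        int ci = (int)std::lround(er[e] - 1 - dy);
        int cj = (int)std::lround(ec[e] - 1 - dx);
        if (ci >= 0 && ci < H && cj >= 0 && cj < W)
          ++acc[(size_t)ci + (size_t)cj * H];
      }
    }
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        int v = acc[(size_t)i + (size_t)j * H];
        if (v > best) { best = v; bi = i; bj = j; br = r; }
      }
  }
  return List::create(_["row"] = bi + 1, _["col"] = bj + 1,
                      _["radius"] = br, _["votes"] = best);
}

// Exact 5x5 median filter with reflect (mirror-without-repeat) padding.
// [[Rcpp::export]]
arma::mat median_filter5_cpp(const arma::mat& x) {
  int H = x.n_rows, W = x.n_cols;
  if (H < 5 || W < 5) stop("grid must be at least 5x5");
  arma::mat out(H, W);
  double buf[25];
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int k = 0;
      for (int dj = -2; dj <= 2; ++dj)
        for (int di = -2; di <= 2; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii < 0) ii = -ii; else if (ii >= H) ii = 2 * H - 2 - ii;
          if (jj < 0) jj = -jj; else if (jj >= W) jj = 2 * W - 2 - jj;
          buf[k++] = x(ii, jj);
        }
      std::nth_element(buf, buf + 12, buf + 25);
      out(i, j) = buf[12];
    }
  return out;
}

// Forward FFT of a real matrix.
// [[Rcpp::export]]
arma::cx_mat fft2_real_cpp(const arma::mat& x) {
  return arma::fft2(arma::cx_mat(x, arma::mat(x.n_rows, x.n_cols,
                                              arma::fill::zeros)));
}

// Two inverse transforms packed into one: returns real parts of
// ifft2(F % K1) and ifft2(F % K2) (both convolutions of real signals).
// [[Rcpp::export]]
List ifft2_pack2_cpp(const arma::cx_mat& F, const arma::cx_mat& K1,
                     const arma::cx_mat& K2) {
  bool two = (K2.n_elem == K1.n_elem) && K2.n_rows == K1.n_rows;
  arma::cx_mat z = two
    ? arma::cx_mat(F % (K1 + arma::cx_double(0, 1) * K2))
    : arma::cx_mat(F % K1);
  arma::cx_mat w = arma::ifft2(z);
  if (two)
    return List::create(_["a"] = arma::mat(arma::real(w)),
                        _["b"] = arma::mat(arma::imag(w)));
  return List::create(_["a"] = arma::mat(arma::real(w)), _["b"] = R_NilValue);
}
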