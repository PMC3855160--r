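// Hot paths of the disparity pipeline: per-hypothesis binocular energy,
// per-pixel extremum selection, and iterative robust pooling.
//
// Layout conventions:
//  - R-side images and maps are height x width matrices.
//  - The energy kernels receive "half-transformed" responses Z
//    (width x height, x-frequency along rows, y already spatial) so each
//    fractional shift class costs one column-wise inverse FFT.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// One separable running-mean (box) pass with edge truncation: near borders
// the window shrinks instead of wrapping, so circular-convolution artifacts
// are not spread further by the smoothing step. First along rows of e
// (the x direction, contiguous), then along columns (y), via cumulative
// sums. Iterating this pass three times (see energy_slice) makes the
// effective kernel close to a Gaussian of sigma = width/2 (central limit
// of three boxes: sigma^2 = 3 * width^2 / 12).
static void box_smooth_inplace(mat& e, const int width) {
  if (width <= 1) return;
  const int half = (width - 1) / 2;
  const int nr = e.n_rows, nc = e.n_cols;
  {
    vec cs(nr), buf(nr);
    for (int j = 0; j < nc; ++j) {
      double* col = e.colptr(j);
      double acc = 0;
      for (int i = 0; i < nr; ++i) { acc += col[i]; cs[i] = acc; }
      for (int i = 0; i < nr; ++i) {
        const int lo = std::max(i - half, 0);
        const int hi = std::min(i + half, nr - 1);
        const double s = (lo == 0) ? cs[hi] : cs[hi] - cs[lo - 1];
        buf[i] = s / (hi - lo + 1);
      }
      std::copy(buf.begin(), buf.begin() + nr, col);
    }
  }
  {
    mat cs = cumsum(e, 1);
    for (int j = 0; j < nc; ++j) {
      const int lo = std::max(j - half, 0);
      const int hi = std::min(j + half, nc - 1);
      const double n = hi - lo + 1;
      if (lo == 0) e.col(j) = cs.col(hi) / n;
      else e.col(j) = (cs.col(hi) - cs.col(lo - 1)) / n;
    }
  }
}

// Fractionally shifted spatial responses per shift class (see R wrapper):
// CL[f](x) = c_left(x - frac_f), CR[f](x) = c_right(x + frac_f).
static void shift_classes(const cx_mat& ZL, const cx_mat& ZR,
                          const cx_mat& fracRamps, std::vector<cx_mat>& CL,
                          std::vector<cx_mat>& CR) {
  const uword w = ZL.n_rows, h = ZL.n_cols, nf = fracRamps.n_cols;
  CL.resize(nf); CR.resize(nf);
  cx_mat tmp(w, h);
  for (uword f = 0; f < nf; ++f) {
    const cx_vec r = fracRamps.col(f);
    for (uword j = 0; j < h; ++j) tmp.col(j) = ZL.col(j) % r;
    CL[f] = ifft(tmp);
    const cx_vec rc = conj(r);
    for (uword j = 0; j < h; ++j) tmp.col(j) = ZR.col(j) % rc;
    CR[f] = ifft(tmp);
  }
}

// Binocular energy map (width x height) for one hypothesis, given the
// fractional-class responses and the integer circular shift m:
// energy(x,y) = |cl(x - m, y) + cr(x + m, y)|^2, then box-smoothed.
static void energy_slice(const cx_mat& cl, const cx_mat& cr, const long m,
                         const int boxWidth, mat& e) {
  const uword w = cl.n_rows, h = cl.n_cols;
  const long offL = ((m % (long)w) + w) % w;
  const long offR = (((-m) % (long)w) + w) % w;
  for (uword j = 0; j < h; ++j) {
    const std::complex<double>* pl = cl.colptr(j);
    const std::complex<double>* pr = cr.colptr(j);
    double* pe = e.colptr(j);
    for (uword x = 0; x < w; ++x) {
      const uword xl = (x + w - offL) % w;
      const uword xr = (x + w - offR) % w;
      const double re = pl[xl].real() + pr[xr].real();
      const double im = pl[xl].imag() + pr[xr].imag();
      pe[x] = re * re + im * im;
    }
  }
  // RF-envelope (approximately Gaussian, sigma ~ width/2) integration
  box_smooth_inplace(e, boxWidth);
  box_smooth_inplace(e, boxWidth);
  box_smooth_inplace(e, boxWidth);
}

// Complex-cell energies for every hypothesis of one channel, as an R cube
// (height x width x n). Exact equivalent of one full phase ramp + inverse
// FFT per hypothesis.
// [[Rcpp::export]]
arma::cube cpp_energy_stack(const arma::cx_mat& ZL, const arma::cx_mat& ZR,
                            const arma::cx_mat& fracRamps,
                            const arma::ivec& fracIdx,
                            const arma::ivec& intShift, const int boxWidth) {
  const uword w = ZL.n_rows, h = ZL.n_cols, n = fracIdx.n_elem;
  std::vector<cx_mat> CL, CR;
  shift_classes(ZL, ZR, fracRamps, CL, CR);
  cube E(h, w, n);
  mat e(w, h);
  for (uword k = 0; k < n; ++k) {
    energy_slice(CL[(uword)fracIdx[k] - 1], CR[(uword)fracIdx[k] - 1],
                 intShift[k], boxWidth, e);
    E.slice(k) = e.t();
  }
  return E;
}

// ---- per-pixel extremum bookkeeping -------------------------------------

// Interior local extrema of a profile with plateau handling: a maximal run
// of equal values flanked on both sides by strictly lower (max) or strictly
// higher (min) values is one extremum at the run's centre; for even-length
// runs the centre candidate with the smaller |hypothesis| wins, the lower
// index breaking exact ties. Runs touching either end are not extrema.
// Writes indices into ex_idx, returns the count.
static int profile_extrema(const double* p, const int n, const double* hyp,
                           int* ex_idx) {
  int cnt = 0;
  int t = 0;
  while (t < n) {
    int u = t;
    while (u + 1 < n && p[u + 1] == p[t]) ++u;
    if (t > 0 && u < n - 1) {
      const bool is_max = p[t - 1] < p[t] && p[u + 1] < p[t];
      const bool is_min = p[t - 1] > p[t] && p[u + 1] > p[t];
      if (is_max || is_min) {
        int c;
        const int len = u - t + 1;
        if (len % 2 == 1) {
          c = t + len / 2;
        } else {
          const int m1 = t + len / 2 - 1, m2 = m1 + 1;
          c = (std::fabs(hyp[m2]) < std::fabs(hyp[m1])) ? m2 : m1;
        }
        ex_idx[cnt++] = c;
      }
    }
    t = u + 1;
  }
  return cnt;
}

// First-scale rule at one pixel: biggest |extremum value|; ties to smaller
// |hypothesis|, then lower index. Fallback: global maximum of the profile.
static void select_first_pixel(const double* p, const int n,
                               const double* hyp, int* exbuf, double& disp,
                               double& resp) {
  const int ne = profile_extrema(p, n, hyp, exbuf);
  if (ne > 0) {
    int best = exbuf[0];
    for (int q = 1; q < ne; ++q) {
      const int i = exbuf[q];
      const double va = std::fabs(p[i]), vb = std::fabs(p[best]);
      if (va > vb || (va == vb && std::fabs(hyp[i]) < std::fabs(hyp[best])))
        best = i;
    }
    disp = hyp[best]; resp = p[best];
  } else {
    int bi = 0;
    for (int k = 1; k < n; ++k)
      if (p[k] > p[bi] ||
          (p[k] == p[bi] && std::fabs(hyp[k]) < std::fabs(hyp[bi])))
        bi = k;
    disp = hyp[bi]; resp = p[bi];
  }
}

// Refinement rule at one pixel: extremum nearest the previous disparity;
// equidistant ties to smaller |hypothesis|, then lower index. Fallback:
// keep the previous value (response from the nearest hypothesis).
static void select_refine_pixel(const double* p, const int n,
                                const double* hyp, const double pv,
                                int* exbuf, double& disp, double& resp) {
  const int ne = profile_extrema(p, n, hyp, exbuf);
  if (ne > 0) {
    int best = exbuf[0];
    for (int q = 1; q < ne; ++q) {
      const int i = exbuf[q];
      const double da = std::fabs(hyp[i] - pv),
                   db = std::fabs(hyp[best] - pv);
      if (da < db ||
          (da == db && std::fabs(hyp[i]) < std::fabs(hyp[best])))
        best = i;
    }
    disp = hyp[best]; resp = p[best];
  } else {
    disp = pv;
    int bi = 0;
    for (int k = 1; k < n; ++k)
      if (std::fabs(hyp[k] - pv) < std::fabs(hyp[bi] - pv)) bi = k;
    resp = p[bi];
  }
}

// Selection over an R-side energy cube (height x width x n).
// [[Rcpp::export]]
Rcpp::List cpp_select_first(const arma::cube& E, const arma::vec& hyp) {
  const uword h = E.n_rows, w = E.n_cols, n = E.n_slices;
  mat disp(h, w), resp(h, w);
  std::vector<double> prof(n);
  std::vector<int> exbuf(n);
  for (uword i = 0; i < h; ++i)
    for (uword j = 0; j < w; ++j) {
      for (uword k = 0; k < n; ++k) prof[k] = E(i, j, k);
      select_first_pixel(prof.data(), n, hyp.memptr(), exbuf.data(),
                         disp(i, j), resp(i, j));
    }
  return Rcpp::List::create(Rcpp::Named("disparity") = disp,
                            Rcpp::Named("response") = resp);
}

// [[Rcpp::export]]
Rcpp::List cpp_select_refine(const arma::cube& E, const arma::vec& hyp,
                             const arma::mat& prev) {
  const uword h = E.n_rows, w = E.n_cols, n = E.n_slices;
  mat disp(h, w), resp(h, w);
  std::vector<double> prof(n);
  std::vector<int> exbuf(n);
  for (uword i = 0; i < h; ++i)
    for (uword j = 0; j < w; ++j) {
      for (uword k = 0; k < n; ++k) prof[k] = E(i, j, k);
      select_refine_pixel(prof.data(), n, hyp.memptr(), prev(i, j),
                          exbuf.data(), disp(i, j), resp(i, j));
    }
  return Rcpp::List::create(Rcpp::Named("disparity") = disp,
                            Rcpp::Named("response") = resp);
}

// Fused per-channel pass used by the coarse-to-fine driver: computes the
// energy of every hypothesis and selects per pixel without materialising
// the stack on the R side. Profiles are laid out contiguously
// (hypothesis-major) for the selection scan. `prev` empty => first-scale
// rule, otherwise refinement against prev (height x width).
// [[Rcpp::export]]
Rcpp::List cpp_channel_map(const arma::cx_mat& ZL, const arma::cx_mat& ZR,
                           const arma::cx_mat& fracRamps,
                           const arma::ivec& fracIdx,
                           const arma::ivec& intShift, const int boxWidth,
                           const arma::vec& hyp, const arma::mat& prev) {
  const uword w = ZL.n_rows, h = ZL.n_cols, n = fracIdx.n_elem;
  const bool first = prev.n_elem == 0;
  std::vector<cx_mat> CL, CR;
  shift_classes(ZL, ZR, fracRamps, CL, CR);
  // profiles: n x (w*h), pixel-major over (x, y)
  mat P(n, w * h);
  mat e(w, h);
  for (uword k = 0; k < n; ++k) {
    energy_slice(CL[(uword)fracIdx[k] - 1], CR[(uword)fracIdx[k] - 1],
                 intShift[k], boxWidth, e);
    const double* ep = e.memptr();
    double* pp = P.memptr() + k;
    for (uword q = 0; q < w * h; ++q) pp[q * n] = ep[q];
  }
  mat disp(h, w), resp(h, w);
  std::vector<int> exbuf(n);
  for (uword j = 0; j < h; ++j)        // y
    for (uword x = 0; x < w; ++x) {    // x
      const double* prof = P.colptr(j * w + x);
      if (first)
        select_first_pixel(prof, n, hyp.memptr(), exbuf.data(),
                           disp(j, x), resp(j, x));
      else
        select_refine_pixel(prof, n, hyp.memptr(), prev(j, x),
                            exbuf.data(), disp(j, x), resp(j, x));
    }
  return Rcpp::List::create(Rcpp::Named("disparity") = disp,
                            Rcpp::Named("response") = resp);
}

// Iterative robust average across channel maps, independently per pixel:
// repeatedly drop the value farthest from the current mean (ties: the value
// from the lowest-indexed channel) until `keep` remain; return their mean.
// [[Rcpp::export]]
arma::vec cpp_robust_pool(const arma::mat& vals, const int keep) {
  const uword npix = vals.n_rows, m = vals.n_cols;
  vec out(npix);
  std::vector<char> active(m);
  std::vector<double> x(m);
  // mean of the active values, accumulated exactly as R's mean(): long
  // double sum, then a long double correction pass -- so tie distances
  // match an R-side reference bit for bit
  auto active_mean = [&](const std::vector<double>& x,
                         const std::vector<char>& act, const int count) {
    long double s = 0;
    for (size_t j = 0; j < x.size(); ++j)
      if (act[j]) s += x[j];
    s /= count;
    long double t = 0;
    for (size_t j = 0; j < x.size(); ++j)
      if (act[j]) t += (x[j] - s);
    return (double)(s + t / count);
  };
  for (uword i = 0; i < npix; ++i) {
    std::fill(active.begin(), active.end(), 1);
    for (uword j = 0; j < m; ++j) x[j] = vals(i, j);
    int count = (int)m;
    while (count > keep) {
      const double mean = active_mean(x, active, count);
      int worst = -1;
      double wd = -1;
      for (uword j = 0; j < m; ++j) {
        if (!active[j]) continue;
        const double d = std::fabs(x[j] - mean);
        if (d > wd) { wd = d; worst = (int)j; }
      }
      active[worst] = 0;
      --count;
    }
    out(i) = active_mean(x, active, count);
  }
  return out;
}
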