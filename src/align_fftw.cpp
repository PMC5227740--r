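// FFT-based exhaustive projection matching.  Cross-correlation
// surfaces are computed with FFTW real-to-complex transforms
// (half-spectrum products, plans cached per call); images are
// standardised so the reported peak is a normalised correlation
// coefficient.

#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <vector>
using namespace Rcpp;

NumericMatrix rotate_shift_image_cpp(NumericMatrix img, double angle_deg,
                                     double dx, double dy);

typedef std::complex<double> cd;

// Our images are column-major; FFTW's row-major view transposes them,
// which transposes the correlation surface consistently.  The linear
// index of correlation value C(sx, sy) (sx = shift along image rows)
// in the real output buffer is sy * n + sx, as derived from the
// double transposition.
struct Rfft2 {
  int n, nc;
  std::vector<double> rbuf;
  std::vector<cd> cbuf;
  fftw_plan fwd, bwd;
  explicit Rfft2(int n_)
      : n(n_), nc(n_ / 2 + 1), rbuf((size_t)n_ * n_),
        cbuf((size_t)n_ * (n_ / 2 + 1)) {
    fftw_complex* c = reinterpret_cast<fftw_complex*>(cbuf.data());
    fwd = fftw_plan_dft_r2c_2d(n, n, rbuf.data(), c, FFTW_ESTIMATE);
    bwd = fftw_plan_dft_c2r_2d(n, n, c, rbuf.data(), FFTW_ESTIMATE);
  }
  ~Rfft2() {
    fftw_destroy_plan(fwd);
    fftw_destroy_plan(bwd);
  }
  // standardise a real image and return its half-spectrum transform
  std::vector<cd> forward_standardised(const double* x) {
    size_t N = (size_t)n * n;
    double mean = 0;
    for (size_t i = 0; i < N; i++) mean += x[i];
    mean /= N;
    double ss = 0;
    for (size_t i = 0; i < N; i++) ss += (x[i] - mean) * (x[i] - mean);
    double sd = std::sqrt(ss / N);
    if (sd <= 0) sd = 1;
    for (size_t i = 0; i < N; i++) rbuf[i] = (x[i] - mean) / sd;
    fftw_execute(fwd);
    return cbuf;  // copy
  }
};

// [[Rcpp::export]]
NumericMatrix align_batch_cpp(NumericVector segs, NumericVector refs,
                              NumericVector ref_azimuth,
                              NumericVector ref_tilt, NumericMatrix psis,
                              int shift_limit, IntegerMatrix cand) {
  IntegerVector d = segs.attr("dim");
  int n = d[0], S = d[2];
  IntegerVector dr = refs.attr("dim");
  int R = dr[2];
  int P = psis.ncol();
  size_t N = (size_t)n * n;
  size_t NC = (size_t)n * (n / 2 + 1);
  double norm = (double)N * (double)N;  // ifft scale * correlation scale

  Rfft2 fft(n);
  std::vector<std::vector<cd> > refF(R);
  std::vector<bool> refF_done(R, false);

  int L = shift_limit;
  std::vector<int> idxs;  // linear indices of allowed shifts
  std::vector<int> sxv, syv;
  for (int sy = -L; sy <= L; sy++) {
    int jy = sy >= 0 ? sy : n + sy;
    for (int sx = -L; sx <= L; sx++) {
      int jx = sx >= 0 ? sx : n + sx;
      idxs.push_back(jy * n + jx);
      sxv.push_back(sx);
      syv.push_back(sy);
    }
  }

  NumericMatrix out(S, 5);
  NumericMatrix segmat(n, n);
  for (int s = 0; s < S; s++) {
    std::vector<std::vector<cd> > segF(P);
    std::copy(segs.begin() + (size_t)s * N, segs.begin() + (size_t)(s + 1) * N,
              segmat.begin());
    for (int p = 0; p < P; p++) {
      NumericMatrix rot =
          rotate_shift_image_cpp(segmat, -psis(s, p), 0.0, 0.0);
      segF[p] = fft.forward_standardised(rot.begin());
    }
    double best_cc = -2.0, best_psi = 0.0;
    int best_r = 0, best_sx = 0, best_sy = 0;
    for (int ci = 0; ci < cand.ncol(); ci++) {
      int r = cand(s, ci) - 1;
      if (r < 0 || r >= R) continue;
      if (!refF_done[r]) {
        refF[r] = fft.forward_standardised(refs.begin() + (size_t)r * N);
        refF_done[r] = true;
      }
      const std::vector<cd>& B = refF[r];
      for (int p = 0; p < P; p++) {
        const std::vector<cd>& A = segF[p];
        for (size_t k = 0; k < NC; k++)
          fft.cbuf[k] = A[k] * std::conj(B[k]);
        fftw_execute(fft.bwd);
        for (size_t q = 0; q < idxs.size(); q++) {
          double cc = fft.rbuf[idxs[q]] / norm;
          int sx = sxv[q], sy = syv[q];
          bool better = cc > best_cc + 1e-9;
          if (!better && cc > best_cc - 1e-9) {
            double t_new = std::fabs(ref_tilt[r]);
            double t_old = std::fabs(ref_tilt[best_r]);
            if (t_new < t_old - 1e-12) {
              better = true;
            } else if (std::fabs(t_new - t_old) <= 1e-12) {
              double sh_new = (double)sx * sx + (double)sy * sy;
              double sh_old =
                  (double)best_sx * best_sx + (double)best_sy * best_sy;
              if (sh_new < sh_old - 1e-12) {
                better = true;
              } else if (std::fabs(sh_new - sh_old) <= 1e-12 &&
                         ref_azimuth[r] < ref_azimuth[best_r] - 1e-12) {
                better = true;
              }
            }
          }
          if (better) {
            best_cc = cc;
            best_r = r;
            best_psi = psis(s, p);
            best_sx = sx;
            best_sy = sy;
          }
        }
      }
    }
    out(s, 0) = best_r + 1;
    out(s, 1) = best_psi;
    out(s, 2) = best_sx;
    out(s, 3) = best_sy;
    out(s, 4) = best_cc;
  }
  return out;
}
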