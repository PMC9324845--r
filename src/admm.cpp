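// ADMM inner loop for TV-regularized dipole inversion.
//
// Mirrors the pure-R reference engine in R/solvers.R exactly (same update
// order: TV split -> data split -> chi -> multipliers), with the
// FFT-diagonal chi update done through FFTW. Arrays are R column-major;
// fftw_plan_dft_3d takes dimensions reversed (nz, ny, nx) so the plan
// operates on the R layout directly.

#include <Rcpp.h>
#include <fftw3.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct FFT3 {
  int nx, ny, nz, n;
  fftw_complex *buf;
  fftw_plan fwd, bwd;
  FFT3(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_), n(nx_ * ny_ * nz_) {
    buf = (fftw_complex *) fftw_malloc(sizeof(fftw_complex) * n);
    fwd = fftw_plan_dft_3d(nz, ny, nx, buf, buf, FFTW_FORWARD, FFTW_ESTIMATE);
    bwd = fftw_plan_dft_3d(nz, ny, nx, buf, buf, FFTW_BACKWARD, FFTW_ESTIMATE);
  }
  ~FFT3() {
    fftw_destroy_plan(fwd);
    fftw_destroy_plan(bwd);
    fftw_free(buf);
  }
  void load_real(const std::vector<double> &x) {
    for (int i = 0; i < n; ++i) { buf[i][0] = x[i]; buf[i][1] = 0.0; }
  }
};

inline double soft(double x, double t) {
  double a = std::fabs(x) - t;
  return a > 0 ? (x > 0 ? a : -a) : 0.0;
}

// forward difference along an axis with periodic wrap, column-major layout
void grad_axis(const std::vector<double> &x, std::vector<double> &g,
               int nx, int ny, int nz, int axis) {
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx) {
        int i = xx + nx * (y + ny * z);
        int j;
        if (axis == 0) j = ((xx + 1) % nx) + nx * (y + ny * z);
        else if (axis == 1) j = xx + nx * (((y + 1) % ny) + ny * z);
        else j = xx + nx * (y + ny * ((z + 1) % nz));
        g[i] = x[j] - x[i];
      }
}

// accumulate adjoint (v[i - e_a] - v[i]) of axis `axis` into `out`
void grad_adjoint_axis(const std::vector<double> &v, std::vector<double> &out,
                       int nx, int ny, int nz, int axis) {
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx) {
        int i = xx + nx * (y + ny * z);
        int j;
        if (axis == 0) j = ((xx + nx - 1) % nx) + nx * (y + ny * z);
        else if (axis == 1) j = xx + nx * (((y + ny - 1) % ny) + ny * z);
        else j = xx + nx * (y + ny * ((z + nz - 1) % nz));
        out[i] += v[j] - v[i];
      }
}

std::vector<double> as_vec(const NumericVector &v) {
  return std::vector<double>(v.begin(), v.end());
}

} // namespace

// [[Rcpp::export(name = "admm_run_cpp")]]
List admm_run_cpp(NumericVector phi_, NumericVector weight_, NumericVector dk_,
                  IntegerVector dim, double lambda, double mu1, double mu2,
                  int n_iter, bool l1norm, bool isotropic,
                  NumericVector chi0, List zg0, List sg0,
                  NumericVector zd0, NumericVector sd0,
                  NumericVector truth_, NumericVector mask_) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  FFT3 fft(nx, ny, nz);

  std::vector<double> phi = as_vec(phi_), w = as_vec(weight_), dk = as_vec(dk_);
  std::vector<double> chi = as_vec(chi0), zd = as_vec(zd0), sd = as_vec(sd0);
  std::vector<std::vector<double>> zg(3), sg(3), g(3);
  for (int a = 0; a < 3; ++a) {
    zg[a] = as_vec(as<NumericVector>(zg0[a]));
    sg[a] = as_vec(as<NumericVector>(sg0[a]));
    g[a].assign(n, 0.0);
  }

  const bool have_truth = truth_.size() == n;
  std::vector<double> truth, mask;
  double tnorm = 0.0;
  if (have_truth) {
    truth = as_vec(truth_);
    mask = as_vec(mask_);
    for (int i = 0; i < n; ++i)
      if (mask[i] != 0) tnorm += truth[i] * truth[i];
    tnorm = std::sqrt(tnorm);
  }
  NumericVector nrmse(have_truth ? n_iter : 0);

  // denominator: mu2 D^2 + mu1 sum_a |exp(2 pi i k_a/N_a) - 1|^2
  std::vector<double> den(n);
  {
    std::vector<double> fx(nx), fy(ny), fz(nz);
    for (int i = 0; i < nx; ++i) fx[i] = 2.0 - 2.0 * std::cos(2.0 * M_PI * i / nx);
    for (int i = 0; i < ny; ++i) fy[i] = 2.0 - 2.0 * std::cos(2.0 * M_PI * i / ny);
    for (int i = 0; i < nz; ++i) fz[i] = 2.0 - 2.0 * std::cos(2.0 * M_PI * i / nz);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int xx = 0; xx < nx; ++xx) {
          int i = xx + nx * (y + ny * z);
          den[i] = mu2 * dk[i] * dk[i] + mu1 * (fx[xx] + fy[y] + fz[z]);
        }
    den[0] = 1.0; // guarded: chi-hat zero bin forced to 0
  }

  // spectra of chi carried across the iteration: chat (complex), Dchi, grad
  std::vector<double> chat_re(n), chat_im(n), dchi(n), div(n), tmp(n);
  fft.load_real(chi);
  fftw_execute(fft.fwd);
  for (int i = 0; i < n; ++i) { chat_re[i] = fft.buf[i][0]; chat_im[i] = fft.buf[i][1]; }
  for (int i = 0; i < n; ++i) { fft.buf[i][0] = dk[i] * chat_re[i]; fft.buf[i][1] = dk[i] * chat_im[i]; }
  fftw_execute(fft.bwd);
  for (int i = 0; i < n; ++i) dchi[i] = fft.buf[i][0] / n;
  for (int a = 0; a < 3; ++a) grad_axis(chi, g[a], nx, ny, nz, a);

  const double thresh = lambda / mu1;

  for (int it = 0; it < n_iter; ++it) {
    // TV split update
    if (isotropic) {
      for (int i = 0; i < n; ++i) {
        double v0 = g[0][i] + sg[0][i], v1 = g[1][i] + sg[1][i], v2 = g[2][i] + sg[2][i];
        double mag = std::sqrt(v0 * v0 + v1 * v1 + v2 * v2);
        double sh = mag > 0 ? std::max(1.0 - thresh / mag, 0.0) : 0.0;
        zg[0][i] = sh * v0; zg[1][i] = sh * v1; zg[2][i] = sh * v2;
      }
    } else {
      for (int a = 0; a < 3; ++a)
        for (int i = 0; i < n; ++i)
          zg[a][i] = soft(g[a][i] + sg[a][i], thresh);
    }
    // data split update
    if (l1norm) {
      for (int i = 0; i < n; ++i)
        zd[i] = phi[i] + soft(dchi[i] + sd[i] - phi[i], w[i] / mu2);
    } else {
      for (int i = 0; i < n; ++i) {
        double w2 = w[i] * w[i];
        zd[i] = (w2 * phi[i] + mu2 * (dchi[i] + sd[i])) / (w2 + mu2);
      }
    }
    // chi update: chat = (mu2 D F(zd - sd) + mu1 F(div(zg - sg))) / den
    std::fill(div.begin(), div.end(), 0.0);
    for (int a = 0; a < 3; ++a) {
      for (int i = 0; i < n; ++i) tmp[i] = zg[a][i] - sg[a][i];
      grad_adjoint_axis(tmp, div, nx, ny, nz, a);
    }
    for (int i = 0; i < n; ++i) { fft.buf[i][0] = zd[i] - sd[i]; fft.buf[i][1] = 0.0; }
    fftw_execute(fft.fwd);
    for (int i = 0; i < n; ++i) {
      chat_re[i] = mu2 * dk[i] * fft.buf[i][0];
      chat_im[i] = mu2 * dk[i] * fft.buf[i][1];
    }
    fft.load_real(div);
    fftw_execute(fft.fwd);
    for (int i = 0; i < n; ++i) {
      chat_re[i] = (chat_re[i] + mu1 * fft.buf[i][0]) / den[i];
      chat_im[i] = (chat_im[i] + mu1 * fft.buf[i][1]) / den[i];
    }
    chat_re[0] = 0.0; chat_im[0] = 0.0;
    for (int i = 0; i < n; ++i) { fft.buf[i][0] = chat_re[i]; fft.buf[i][1] = chat_im[i]; }
    fftw_execute(fft.bwd);
    for (int i = 0; i < n; ++i) chi[i] = fft.buf[i][0] / n;
    for (int i = 0; i < n; ++i) { fft.buf[i][0] = dk[i] * chat_re[i]; fft.buf[i][1] = dk[i] * chat_im[i]; }
    fftw_execute(fft.bwd);
    for (int i = 0; i < n; ++i) dchi[i] = fft.buf[i][0] / n;
    // multiplier ascent against the new chi
    for (int a = 0; a < 3; ++a) {
      grad_axis(chi, g[a], nx, ny, nz, a);
      for (int i = 0; i < n; ++i) sg[a][i] += g[a][i] - zg[a][i];
    }
    for (int i = 0; i < n; ++i) sd[i] += dchi[i] - zd[i];

    if (have_truth) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i)
        if (mask[i] != 0) { double d = chi[i] - truth[i]; ss += d * d; }
      nrmse[it] = 100.0 * std::sqrt(ss) / tnorm;
    }
    if (it % 16 == 15) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["chi"] = NumericVector(chi.begin(), chi.end()),
    _["z_grad"] = List::create(NumericVector(zg[0].begin(), zg[0].end()),
                               NumericVector(zg[1].begin(), zg[1].end()),
                               NumericVector(zg[2].begin(), zg[2].end())),
    _["s_grad"] = List::create(NumericVector(sg[0].begin(), sg[0].end()),
                               NumericVector(sg[1].begin(), sg[1].end()),
                               NumericVector(sg[2].begin(), sg[2].end())),
    _["z_data"] = NumericVector(zd.begin(), zd.end()),
    _["s_data"] = NumericVector(sd.begin(), sd.end()),
    _["nrmse"] = nrmse);
}
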