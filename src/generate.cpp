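// Fused synthesis of multi-unit oscillatory epochs.
//
// Each unit/trial is
//   x(t) = amp_uk * (1 + m sin(mod_phase0_k + 2 pi fm t + phi_u))
//            * sin(2 pi f0 (t0_k + t) + theta_u)  +  noise(t)
// with band-limited 1/f^beta Gaussian noise synthesised in the frequency
// domain (random phases, independent per unit and trial).  Phases of the
// carrier and the slow modulation advance on the session clock (t0_k is the
// session time at which trial k starts), so excised epochs stay mutually
// coherent the way cut-outs of a continuous recording would.
//
// All randomness comes from the R RNG (norm_rand), so results are fully
// reproducible via set.seed() and identical between platforms.

#include <Rcpp.h>
#include <fftw3.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_generate_segment(int n_unit, int n_trial, int n_samp,
                                   double fs, NumericVector trial_t0,
                                   NumericVector mod_phase0,
                                   double isf,
                                   double mod_freq, double mod_depth,
                                   NumericVector theta, NumericVector phi,
                                   NumericMatrix amp,
                                   double noise_amp, double noise_exponent,
                                   double noise_fmin, double noise_fmax) {
  if (theta.size() != n_unit || phi.size() != n_unit)
    stop("per-unit parameter vectors must have length n_unit");
  if (trial_t0.size() != n_trial || mod_phase0.size() != n_trial)
    stop("per-trial parameter vectors must have length n_trial");
  if (amp.nrow() != n_unit || amp.ncol() != n_trial)
    stop("'amp' must be n_unit x n_trial");

  NumericVector out(static_cast<R_xlen_t>(n_samp) * n_unit * n_trial);
  out.attr("dim") = IntegerVector::create(n_samp, n_unit, n_trial);

  // noise spectrum support: bins j (frequency j/T) inside [fmin, fmax]
  const double T = n_samp / fs;
  int jmin = (int)std::ceil(noise_fmin * T);
  if (jmin < 1) jmin = 1;
  int jmax = (int)std::floor(noise_fmax * T);
  if (jmax > n_samp / 2 - 1) jmax = n_samp / 2 - 1;
  const int nbin = (jmax >= jmin) ? (jmax - jmin + 1) : 0;

  std::vector<double> coef(nbin > 0 ? nbin : 1);
  double csum = 0.0;
  for (int b = 0; b < nbin; ++b) {
    double f = (jmin + b) / T;
    coef[b] = std::pow(f, -noise_exponent / 2.0);
    csum += coef[b] * coef[b];
  }
  // Re(sum_j c_j z_j e^{i w_j t}) with z standard complex normal has
  // variance sum_j c_j^2 at every t; scale to noise_amp.
  const double nscale =
      (csum > 0.0 && noise_amp > 0.0) ? noise_amp / std::sqrt(csum) : 0.0;

  fftw_complex *buf = fftw_alloc_complex(n_samp);
  fftw_complex *nout = fftw_alloc_complex(n_samp);
  fftw_plan plan = fftw_plan_dft_1d(n_samp, buf, nout, FFTW_BACKWARD,
                                    FFTW_ESTIMATE);

  std::vector<double> sc(n_samp), cc(n_samp), sm(n_samp), cm(n_samp);
  const double wc = 2.0 * M_PI * isf;
  const double wm = 2.0 * M_PI * mod_freq;

  double *o = REAL(out);
  for (int k = 0; k < n_trial; ++k) {
    // carrier on the session clock; the slow modulator additionally
    // carries a per-trial phase offset (quasi-periodic drive)
    for (int t = 0; t < n_samp; ++t) {
      double tt = trial_t0[k] + t / fs;
      double ma = mod_phase0[k] + wm * (t / fs);
      sc[t] = std::sin(wc * tt);
      cc[t] = std::cos(wc * tt);
      sm[t] = std::sin(ma);
      cm[t] = std::cos(ma);
    }
    for (int u = 0; u < n_unit; ++u) {
      double *col = o + (static_cast<R_xlen_t>(k) * n_unit + u) * n_samp;
      const double a = amp(u, k);
      const double md = mod_depth;
      const double cth = std::cos(theta[u]), sth = std::sin(theta[u]);
      const double cph = std::cos(phi[u]), sph = std::sin(phi[u]);

      if (nscale > 0.0 && nbin > 0) {
        std::memset(buf, 0, sizeof(fftw_complex) * n_samp);
        for (int b = 0; b < nbin; ++b) {
          buf[jmin + b][0] = coef[b] * norm_rand();
          buf[jmin + b][1] = coef[b] * norm_rand();
        }
        fftw_execute(plan);
        for (int t = 0; t < n_samp; ++t) {
          double env = 1.0 + md * (sm[t] * cph + cm[t] * sph);
          double car = sc[t] * cth + cc[t] * sth;
          col[t] = a * env * car + nscale * nout[t][0];
        }
      } else {
        for (int t = 0; t < n_samp; ++t) {
          double env = 1.0 + md * (sm[t] * cph + cm[t] * sph);
          double car = sc[t] * cth + cc[t] * sth;
          col[t] = a * env * car;
        }
      }
    }
  }

  fftw_destroy_plan(plan);
  fftw_free(buf);
  fftw_free(nout);
  return out;
}
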