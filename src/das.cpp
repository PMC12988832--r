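#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Delay-and-sum beamforming of one photoacoustic channel-data frame.
//
// data:   n_samples x n_elements real RF matrix (receive channels)
// elem_x: element center lateral positions [mm], length n_elements
// grid_x: pixel lateral positions [mm]
// grid_z: pixel axial positions (depth) [mm]
// fs:     sampling frequency [Hz]
// c:      speed of sound [m/s]
//
// One-way (receive-only) delays: a photoacoustic source emits at t = 0,
// so the sample index for pixel (x, z) and element e is
// fs * sqrt(z^2 + (x - x_e)^2) / c. Samples are linearly interpolated;
// delays falling outside the recorded window contribute zero. Uniform
// (rectangular) apodization over the full aperture.
// [[Rcpp::export]]
NumericMatrix das_core(NumericMatrix data, NumericVector elem_x,
                       NumericVector grid_x, NumericVector grid_z,
                       double fs, double c) {
  const int n_samples = data.nrow();
  const int n_elem = data.ncol();
  const int nz = grid_z.size();
  const int nx = grid_x.size();
  NumericMatrix out(nz, nx);
  const double mm_to_samples = fs / (c * 1000.0);  // c in m/s, positions in mm

  for (int ix = 0; ix < nx; ++ix) {
    const double x = grid_x[ix];
    for (int e = 0; e < n_elem; ++e) {
      const double dx = x - elem_x[e];
      const double dx2 = dx * dx;
      for (int iz = 0; iz < nz; ++iz) {
        const double z = grid_z[iz];
        const double r = std::sqrt(z * z + dx2);      // mm
        const double s = r * mm_to_samples;           // fractional sample index (0-based)
        const int s0 = (int)std::floor(s);
        if (s0 < 0 || s0 >= n_samples - 1) continue;  // outside window -> zero
        const double frac = s - s0;
        out(iz, ix) += (1.0 - frac) * data(s0, e) + frac * data(s0 + 1, e);
      }
    }
  }
  return out;
}

// Forward model for the synthetic generator: sum of 1/r-weighted,
// time-shifted copies of a pulse evaluated analytically per sample.
//
// amp, ax, az: absorber amplitudes and positions [mm]
// elem_x:      element lateral positions [mm]
// f0:          pulse center frequency [Hz]
// sigma_t:     Gaussian envelope sigma [s]
// r_min:       amplitude clamp distance [mm]
// [[Rcpp::export]]
NumericMatrix channel_forward(NumericVector amp, NumericVector ax,
                              NumericVector az, NumericVector elem_x,
                              int n_samples, double fs, double c,
                              double f0, double sigma_t, double r_min) {
  const int n_elem = elem_x.size();
  const int n_abs = amp.size();
  NumericMatrix out(n_samples, n_elem);
  const double two_pi_f0 = 2.0 * M_PI * f0;
  // beyond 5 sigma the Gaussian envelope is negligible
  const double t_half = 5.0 * sigma_t;

  for (int e = 0; e < n_elem; ++e) {
    for (int k = 0; k < n_abs; ++k) {
      const double dx = ax[k] - elem_x[e];
      const double r = std::sqrt(dx * dx + az[k] * az[k]);  // mm
      const double t0 = r / (c * 1000.0);                   // arrival time [s]
      const double a = amp[k] / std::max(r, r_min);
      int i_lo = (int)std::floor((t0 - t_half) * fs);
      int i_hi = (int)std::ceil((t0 + t_half) * fs);
      if (i_lo < 0) i_lo = 0;
      if (i_hi > n_samples - 1) i_hi = n_samples - 1;
      for (int i = i_lo; i <= i_hi; ++i) {
        const double t = i / fs - t0;
        out(i, e) += a * std::exp(-t * t / (2.0 * sigma_t * sigma_t)) *
                     std::sin(two_pi_f0 * t);
      }
    }
  }
  return out;
}
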