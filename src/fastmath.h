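#ifndef DIETBHM_FASTMATH_H
#define DIETBHM_FASTMATH_H

#include <cmath>

// Asymptotic lgamma/digamma for large arguments. Counts beyond the
// per-OTU lookup-table cap (1024) fall back to these instead of per-cell
// libm lgamma/digamma calls; at x > 1000 the Stirling/asymptotic series
// are accurate to ~1e-14 and cost one log each.

namespace dietbhm {

inline double lgamma_big(double x) {
  const double lx = std::log(x);
  const double ix = 1.0 / x;
  const double ix2 = ix * ix;
  return (x - 0.5) * lx - x + 0.91893853320467274178 +
         ix * (8.33333333333333333e-2 +
               ix2 * (-2.77777777777777778e-3 +
                      ix2 * (7.93650793650793651e-4 -
                             ix2 * 5.95238095238095238e-4)));
}

inline double digamma_big(double x) {
  const double ix = 1.0 / x;
  const double ix2 = ix * ix;
  return std::log(x) - 0.5 * ix -
         ix2 * (8.33333333333333333e-2 -
                ix2 * (8.33333333333333333e-3 -
                       ix2 * 3.96825396825396825e-3));
}

} // namespace dietbhm

#endif
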