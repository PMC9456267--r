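#include <Rcpp.h>
using namespace Rcpp;

// First-passage random walk of independent vesicles in a liquid column of
// height `height` (metres): Gaussian displacement of sd sigma[i] per step,
// absorption when z <= 0 at a step end (vesicle attaches and leaves the
// simulation), specular reflection z -> 2*height - z at the drop top.
// Returns the 1-based step index of attachment, NA if still suspended after
// n_steps. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector settle_walk(NumericVector z0, NumericVector sigma,
                          double height, int n_steps) {
  const R_xlen_t n = z0.size();
  if (sigma.size() != n) stop("z0 and sigma must have the same length");
  if (height <= 0.0) stop("height must be positive");
  if (n_steps < 1) stop("n_steps must be at least 1");
  IntegerVector out(n, NA_INTEGER);
  for (R_xlen_t i = 0; i < n; ++i) {
    double z = z0[i];
    const double s = sigma[i];
    if (s < 0.0 || !R_finite(s)) stop("step sd must be finite and >= 0");
    if (z <= 0.0) { out[i] = 1; continue; }
    for (int k = 1; k <= n_steps; ++k) {
      z += norm_rand() * s;
      if (z > height) {
        z = 2.0 * height - z;
        // a single mirror fold must suffice; reachable only if a step
        // exceeds the whole column, i.e. the time step is far too coarse
        if (z < 0.0) stop("single displacement exceeded the drop height; "
                          "decrease dt");
      }
      if (z <= 0.0) { out[i] = k; break; }
    }
  }
  return out;
}
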