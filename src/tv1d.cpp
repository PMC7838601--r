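#include <Rcpp.h>
using namespace Rcpp;

// Exact 1-D total-variation denoising (fused-lasso signal approximator):
//   minimize 0.5 * sum_i (y_i - b_i)^2 + lam * sum_i |b_{i+1} - b_i|
// Direct non-iterative algorithm (Condat 2013, "A direct algorithm for
// 1-D total variation denoising"). O(n) typical, O(n^2) worst case,
// exact up to floating point.
//
// [[Rcpp::export(name = ".tv1dCondat")]]
NumericVector tv1dCondat(NumericVector y, double lam) {
    const int n = y.size();
    NumericVector x(n);
    if (n == 0) return x;
    if (n == 1 || lam <= 0.0) {
        for (int i = 0; i < n; ++i) x[i] = y[i];
        return x;
    }

    int k = 0, k0 = 0;       // current and segment-start indices
    int kminus = 0, kplus = 0;   // last positions of min/max candidate jumps
    double umin = lam, umax = -lam;
    double vmin = y[0] - lam, vmax = y[0] + lam;
    const double twolam = 2.0 * lam;

    for (;;) {
        while (k == n - 1) {
            if (umin < 0.0) {
                // negative jump necessary: flush segment at vmin
                do { x[k0++] = vmin; } while (k0 <= kminus);
                k = kminus = kplus = k0;
                vmin = y[k];
                umin = lam;
                umax = y[k] + lam - vmax;
            } else if (umax > 0.0) {
                // positive jump necessary: flush segment at vmax
                do { x[k0++] = vmax; } while (k0 <= kplus);
                k = kminus = kplus = k0;
                vmax = y[k];
                umax = -lam;
                umin = y[k] - lam - vmin;
            } else {
                // tube can be closed: final segment value
                vmin += umin / (k - k0 + 1);
                do { x[k0++] = vmin; } while (k0 <= k);
                return x;
            }
            if (k0 > n - 1) return x;
        }
        umin += y[k + 1] - vmin;
        if (umin < -lam) {
            // lower bound violated: emit segment ending at kminus
            do { x[k0++] = vmin; } while (k0 <= kminus);
            k = kminus = kplus = k0;
            vmin = y[k];
            vmax = y[k] + twolam;
            umin = lam;
            umax = -lam;
        } else {
            umax += y[k + 1] - vmax;
            if (umax > lam) {
                // upper bound violated: emit segment ending at kplus
                do { x[k0++] = vmax; } while (k0 <= kplus);
                k = kminus = kplus = k0;
                vmin = y[k] - twolam;
                vmax = y[k];
                umin = lam;
                umax = -lam;
            } else {
                // no violation: extend segment
                ++k;
                if (umin >= lam) {
                    vmin += (umin - lam) / (k - k0 + 1);
                    umin = lam;
                    kminus = k;
                }
                if (umax <= -lam) {
                    vmax += (umax + lam) / (k - k0 + 1);
                    umax = -lam;
                    kplus = k;
                }
            }
        }
    }
}
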