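#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Streamline sets are passed as flat arrays laid out
// [streamline][point][xyz], i.e. coords[(s * npts + p) * 3 + c].

static inline double mdf_pair(const double *a, const double *b, int npts) {
    double dsum = 0.0, fsum = 0.0;
    for (int p = 0; p < npts; ++p) {
        const double *ap = a + 3 * p;
        const double *bp = b + 3 * p;
        const double *bf = b + 3 * (npts - 1 - p);
        double dx = ap[0] - bp[0], dy = ap[1] - bp[1], dz = ap[2] - bp[2];
        dsum += std::sqrt(dx * dx + dy * dy + dz * dz);
        double fx = ap[0] - bf[0], fy = ap[1] - bf[1], fz = ap[2] - bf[2];
        fsum += std::sqrt(fx * fx + fy * fy + fz * fz);
    }
    return std::min(dsum, fsum) / npts;
}

// [[Rcpp::export(name = ".mdf_matrix_cpp")]]
NumericMatrix mdf_matrix_cpp(NumericVector coords, int npts, int nsl) {
    NumericMatrix out(nsl, nsl);
    const double *c = coords.begin();
    for (int i = 0; i < nsl; ++i) {
        for (int j = i + 1; j < nsl; ++j) {
            double d = mdf_pair(c + (size_t)i * npts * 3, c + (size_t)j * npts * 3, npts);
            out(i, j) = d;
            out(j, i) = d;
        }
    }
    return out;
}

// Nearest template streamline (by MDF) for every target streamline.
// Ties go to the lowest template index because strict '<' is used.
// [[Rcpp::export(name = ".mdf_nearest_cpp")]]
List mdf_nearest_cpp(NumericVector tar, NumericVector ref, int npts,
                     int ntar, int nref) {
    IntegerVector idx(ntar);
    NumericVector dist(ntar);
    const double *t = tar.begin();
    const double *r = ref.begin();
    for (int i = 0; i < ntar; ++i) {
        double best = R_PosInf;
        int bestj = -1;
        for (int j = 0; j < nref; ++j) {
            double d = mdf_pair(t + (size_t)i * npts * 3, r + (size_t)j * npts * 3, npts);
            if (d < best) { best = d; bestj = j; }
        }
        idx[i] = bestj + 1;  // 1-based
        dist[i] = best;
    }
    return List::create(_["index"] = idx, _["distance"] = dist);
}
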