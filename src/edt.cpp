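#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher 2012)
// over samples at positions x_q = q * step, lower envelope of parabolas.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double step) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; q++) {
        if (f[q] == INF) continue;
        double xq = q * step;
        double s;
        while (true) {
            if (f[v[k]] == INF) {
                // previous vertex unusable: drop it
                if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; s = -INF; break; }
                k--;
                continue;
            }
            double xv = v[k] * step;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
            if (s <= z[k]) { k--; continue; }
            break;
        }
        if (v[k] != q) {
            k++;
            v[k] = q;
            z[k] = s;
            z[k + 1] = INF;
        }
    }
    if (f[v[0]] == INF) {
        // whole line empty
        for (int q = 0; q < n; q++) d[q] = INF;
        return;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        double xq = q * step;
        while (z[k + 1] < xq) k++;
        double dx = xq - v[k] * step;
        d[q] = dx * dx + f[v[k]];
    }
}

//' @noRd
// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims,
                              NumericVector spacing) {
    const double INF = std::numeric_limits<double>::infinity();
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // along x
    for (int kz = 0; kz < nz; kz++)
        for (int jy = 0; jy < ny; jy++) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)jy * nx;
            for (int i = 0; i < nx; i++) f[i] = out[base + i];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; i++) out[base + i] = d[i];
        }
    // along y
    for (int kz = 0; kz < nz; kz++)
        for (int ix = 0; ix < nx; ix++) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + ix;
            for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = d[j];
        }
    // along z
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int jy = 0; jy < ny; jy++)
        for (int ix = 0; ix < nx; ix++) {
            R_xlen_t base = (R_xlen_t)jy * nx + ix;
            for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * nxy];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; k++) out[base + (R_xlen_t)k * nxy] = d[k];
        }
    out.attr("dim") = dims;
    return out;
}
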