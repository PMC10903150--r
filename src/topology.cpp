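#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Euler-Poincare characteristic of the cubical complex formed by the union of
// closed unit voxels (foreground implicitly 26-connected): chi = n0-n1+n2-n3.
// Each k-cell is attributed to the lattice point at its minimal corner, so chi
// is a sum over lattice points of a contribution determined entirely by the
// 2x2x2 voxel block around that point. The 256-entry table below holds those
// contributions; bit (dx + 2*dy + 4*dz) of the index flags voxel
// (i-1+dx, j-1+dy, k-1+dz) relative to lattice point (i,j,k).

static int chi_tab[256];
static bool chi_tab_ready = false;

static void init_chi_tab() {
    if (chi_tab_ready) return;
    for (int b = 0; b < 256; ++b) {
        int v = (b != 0);
        int ex = 0, ey = 0, ez = 0; // edges along +x/+y/+z from the point
        int fxy = 0, fxz = 0, fyz = 0, cc = 0;
        for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                    if (!(b & (1 << (dx + 2 * dy + 4 * dz)))) continue;
                    if (dx == 1) ex = 1;
                    if (dy == 1) ey = 1;
                    if (dz == 1) ez = 1;
                    if (dx == 1 && dy == 1) fxy = 1;
                    if (dx == 1 && dz == 1) fxz = 1;
                    if (dy == 1 && dz == 1) fyz = 1;
                    if (dx == 1 && dy == 1 && dz == 1) cc = 1;
                }
        chi_tab[b] = v - (ex + ey + ez) + (fxy + fxz + fyz) - cc;
    }
    chi_tab_ready = true;
}

static inline int vox_in(const int* a, int nx, long nxy,
                         int x, int y, int z,
                         int x0, int x1, int y0, int y1, int z0, int z1) {
    if (x < x0 || x > x1 || y < y0 || y > y1 || z < z0 || z > z1) return 0;
    return a[x + (long)nx * y + nxy * z] != 0;
}

// chi of (foreground restricted to the box [x0,x1]x[y0,y1]x[z0,z1])
static long chi_region(const int* a, int nx, int ny,
                       int x0, int x1, int y0, int y1, int z0, int z1) {
    init_chi_tab();
    long nxy = (long)nx * ny;
    long s = 0;
    for (int k = z0; k <= z1 + 1; ++k) {
        for (int j = y0; j <= y1 + 1; ++j) {
            int b = 0;
            for (int i = x0; i <= x1 + 1; ++i) {
                if (i == x0) {
                    b = 0;
                    for (int dz = 0; dz < 2; ++dz)
                        for (int dy = 0; dy < 2; ++dy)
                            for (int dx = 0; dx < 2; ++dx)
                                if (vox_in(a, nx, nxy, i - 1 + dx, j - 1 + dy,
                                           k - 1 + dz, x0, x1, y0, y1, z0, z1))
                                    b |= 1 << (dx + 2 * dy + 4 * dz);
                } else {
                    // shift: previous dx=1 planes become the new dx=0 planes
                    b = (b & 0xAA) >> 1;
                    for (int dz = 0; dz < 2; ++dz)
                        for (int dy = 0; dy < 2; ++dy)
                            if (vox_in(a, nx, nxy, i, j - 1 + dy, k - 1 + dz,
                                       x0, x1, y0, y1, z0, z1))
                                b |= 1 << (1 + 2 * dy + 4 * dz);
                }
                s += chi_tab[b];
            }
        }
    }
    return s;
}

// [[Rcpp::export(name = ".euler3d_cpp")]]
int euler3d_cpp(IntegerVector arr, IntegerVector dim) {
    if (dim.size() != 3) stop("dim must have length 3");
    int nx = dim[0], ny = dim[1], nz = dim[2];
    if ((long)nx * ny * nz != (long)arr.size()) stop("dim does not match array length");
    long chi = chi_region(arr.begin(), nx, ny, 0, nx - 1, 0, ny - 1, 0, nz - 1);
    return (int)chi;
}

// 3D summed-area table with a leading zero plane per axis
static std::vector<double> integral3d(const int* a, int nx, int ny, int nz) {
    int px = nx + 1, py = ny + 1, pz = nz + 1;
    std::vector<double> S((size_t)px * py * pz, 0.0);
    long pxy = (long)px * py;
    long nxy = (long)nx * ny;
    for (int k = 1; k <= nz; ++k)
        for (int j = 1; j <= ny; ++j) {
            double row = 0.0;
            for (int i = 1; i <= nx; ++i) {
                row += a[(i - 1) + (long)nx * (j - 1) + nxy * (k - 1)] != 0;
                S[i + (long)px * j + pxy * k] =
                    row + S[i + (long)px * (j - 1) + pxy * k]
                        + S[i + (long)px * j + pxy * (k - 1)]
                        - S[i + (long)px * (j - 1) + pxy * (k - 1)];
            }
        }
    return S;
}

static inline double boxsum(const std::vector<double>& S, int px, long pxy,
                            int x0, int x1, int y0, int y1, int z0, int z1) {
    // inclusive voxel bounds, 0-based
    int xa = x0, xb = x1 + 1, ya = y0, yb = y1 + 1, za = z0, zb = z1 + 1;
    return S[xb + (long)px * yb + pxy * zb] - S[xa + (long)px * yb + pxy * zb]
         - S[xb + (long)px * ya + pxy * zb] - S[xb + (long)px * yb + pxy * za]
         + S[xa + (long)px * ya + pxy * zb] + S[xa + (long)px * yb + pxy * za]
         + S[xb + (long)px * ya + pxy * za] - S[xa + (long)px * ya + pxy * za];
}

// Windowed Minkowski maps on the stride grid. V(c) = voxel (cube-cell) count of
// class within the clipped window over the lung count in the same window;
// chi(c) = chi(class in window) / lung count in window. Windows with no lung
// voxels are flagged invalid.
// [[Rcpp::export(name = ".window_maps_cpp")]]
List window_maps_cpp(IntegerVector class_arr, IntegerVector lung_arr,
                     IntegerVector dim, int window, int stride) {
    if (dim.size() != 3) stop("dim must have length 3");
    if (window < 1 || window % 2 == 0) stop("window must be odd and >= 1");
    if (stride < 1) stop("stride must be >= 1");
    int nx = dim[0], ny = dim[1], nz = dim[2];
    long n = (long)nx * ny * nz;
    if (n != (long)class_arr.size() || n != (long)lung_arr.size())
        stop("dim does not match array length");
    int h = (window - 1) / 2;

    std::vector<int> cx, cy, cz;
    for (int i = 0; i < nx; i += stride) cx.push_back(i);
    for (int j = 0; j < ny; j += stride) cy.push_back(j);
    for (int k = 0; k < nz; k += stride) cz.push_back(k);
    int gx = cx.size(), gy = cy.size(), gz = cz.size();

    std::vector<double> Sc = integral3d(class_arr.begin(), nx, ny, nz);
    std::vector<double> Sl = integral3d(lung_arr.begin(), nx, ny, nz);
    int px = nx + 1;
    long pxy = (long)px * (ny + 1);

    NumericVector V((R_xlen_t)gx * gy * gz);
    NumericVector CHI((R_xlen_t)gx * gy * gz);
    LogicalVector valid((R_xlen_t)gx * gy * gz);
    const int* ca = class_arr.begin();

    for (int kc = 0; kc < gz; ++kc)
        for (int jc = 0; jc < gy; ++jc)
            for (int ic = 0; ic < gx; ++ic) {
                int x0 = std::max(0, cx[ic] - h), x1 = std::min(nx - 1, cx[ic] + h);
                int y0 = std::max(0, cy[jc] - h), y1 = std::min(ny - 1, cy[jc] + h);
                int z0 = std::max(0, cz[kc] - h), z1 = std::min(nz - 1, cz[kc] + h);
                long idx = ic + (long)gx * jc + (long)gx * gy * kc;
                double lungN = boxsum(Sl, px, pxy, x0, x1, y0, y1, z0, z1);
                if (lungN <= 0) {
                    V[idx] = NA_REAL;
                    CHI[idx] = NA_REAL;
                    valid[idx] = false;
                    continue;
                }
                double classN = boxsum(Sc, px, pxy, x0, x1, y0, y1, z0, z1);
                V[idx] = classN / lungN;
                if (classN <= 0) {
                    CHI[idx] = 0.0;
                } else {
                    long chi = chi_region(ca, nx, ny, x0, x1, y0, y1, z0, z1);
                    CHI[idx] = (double)chi / lungN;
                }
                valid[idx] = true;
            }

    return List::create(
        _["V"] = V, _["chi"] = CHI, _["valid"] = valid,
        _["centers_x"] = IntegerVector(cx.begin(), cx.end()),
        _["centers_y"] = IntegerVector(cy.begin(), cy.end()),
        _["centers_z"] = IntegerVector(cz.begin(), cz.end()),
        _["grid_dim"] = IntegerVector::create(gx, gy, gz));
}

// box-filter count of foreground voxels in an edge^3 window centred at every
// voxel (clipped at the array boundary); used for patch eligibility checks
// [[Rcpp::export(name = ".box_count_cpp")]]
NumericVector box_count_cpp(IntegerVector arr, IntegerVector dim, int edge) {
    if (dim.size() != 3) stop("dim must have length 3");
    if (edge < 1 || edge % 2 == 0) stop("edge must be odd and >= 1");
    int nx = dim[0], ny = dim[1], nz = dim[2];
    long n = (long)nx * ny * nz;
    if (n != (long)arr.size()) stop("dim does not match array length");
    int h = (edge - 1) / 2;
    std::vector<double> S = integral3d(arr.begin(), nx, ny, nz);
    int px = nx + 1;
    long pxy = (long)px * (ny + 1);
    NumericVector out(n);
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                int x0 = std::max(0, i - h), x1 = std::min(nx - 1, i + h);
                int y0 = std::max(0, j - h), y1 = std::min(ny - 1, j + h);
                int z0 = std::max(0, k - h), z1 = std::min(nz - 1, k + h);
                out[i + (long)nx * j + (long)nx * ny * k] =
                    boxsum(S, px, pxy, x0, x1, y0, y1, z0, z1);
            }
    return out;
}
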