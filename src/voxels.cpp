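#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Voxel class codes shared with R/voxelize.R: 0 air, 1 tissue, 2 target, 3 fiducial.
// Precedence is enforced by write order (tissue, then targets, then fiducials)
// plus an explicit "never downgrade" rule.

static inline double wcoord(int idx, double origin, double spacing) {
  return origin + idx * spacing;
}

// [[Rcpp::export(name = ".rasterize_envelope")]]
IntegerVector rasterize_envelope(IntegerVector dims, NumericVector origin,
                                 NumericVector spacing, NumericVector centre,
                                 NumericVector semi_axes, double exponent) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector cls((R_xlen_t)nx * ny * nz);
  // superellipsoid |x/a|^p + |y/b|^p + |z/c|^p <= 1 is separable per axis
  std::vector<double> tx(nx), ty(ny), tz(nz);
  for (int i = 0; i < nx; ++i)
    tx[i] = std::pow(std::fabs((wcoord(i, origin[0], spacing[0]) - centre[0]) / semi_axes[0]), exponent);
  for (int j = 0; j < ny; ++j)
    ty[j] = std::pow(std::fabs((wcoord(j, origin[1], spacing[1]) - centre[1]) / semi_axes[1]), exponent);
  for (int k = 0; k < nz; ++k)
    tz[k] = std::pow(std::fabs((wcoord(k, origin[2], spacing[2]) - centre[2]) / semi_axes[2]), exponent);
  int* c = INTEGER(cls);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const double tyz = ty[j] + tz[k];
      for (int i = 0; i < nx; ++i, ++idx)
        if (tx[i] + tyz <= 1.0) c[idx] = 1;
    }
  return cls;
}

static inline void bbox_range(double lo, double hi, double origin, double spacing,
                              int n, int& i0, int& i1) {
  i0 = (int)std::ceil((lo - origin) / spacing - 1e-12);
  i1 = (int)std::floor((hi - origin) / spacing + 1e-12);
  if (i0 < 0) i0 = 0;
  if (i1 > n - 1) i1 = n - 1;
}

// Paint voxels whose centre lies inside a solid, never downgrading class.
// shapes: list of lists, each with $type in {"sphere","ellipsoid","cylinder","slab"}
// and parameters in world mm.
// [[Rcpp::export(name = ".rasterize_solids")]]
void rasterize_solids(IntegerVector cls, IntegerVector dims, NumericVector origin,
                      NumericVector spacing, List shapes, int class_code) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int* c = INTEGER(cls);
  for (int s = 0; s < shapes.size(); ++s) {
    List sh = shapes[s];
    std::string type = as<std::string>(sh["type"]);
    NumericVector ctr = sh["centre"];
    double rad = 0.0;
    NumericVector ax1, ax2, ax3, semi;
    double half_len = 0, edge2 = 0, th2 = 0;
    if (type == "sphere") {
      rad = as<double>(sh["radius"]);
    } else if (type == "ellipsoid") {
      semi = sh["semi_axes"]; ax1 = sh["axis1"]; ax2 = sh["axis2"]; ax3 = sh["axis3"];
      rad = std::max(semi[0], std::max(semi[1], semi[2]));
    } else if (type == "cylinder") {
      ax1 = sh["axis"];            // unit vector along the bar
      half_len = as<double>(sh["half_length"]);
      rad = as<double>(sh["radius"]);
    } else if (type == "slab") {
      ax1 = sh["axis1"]; ax2 = sh["axis2"]; ax3 = sh["normal"];
      edge2 = as<double>(sh["edge"]) / 2.0;
      th2 = as<double>(sh["thickness"]) / 2.0;
    } else {
      stop("unknown shape type: %s", type.c_str());
    }
    // conservative world bounding box
    double reach;
    if (type == "cylinder") reach = half_len + rad;
    else if (type == "slab") reach = std::sqrt(2.0) * edge2 + th2;
    else reach = rad;
    int i0, i1, j0, j1, k0, k1;
    bbox_range(ctr[0] - reach, ctr[0] + reach, origin[0], spacing[0], nx, i0, i1);
    bbox_range(ctr[1] - reach, ctr[1] + reach, origin[1], spacing[1], ny, j0, j1);
    bbox_range(ctr[2] - reach, ctr[2] + reach, origin[2], spacing[2], nz, k0, k1);
    for (int k = k0; k <= k1; ++k) {
      const double dz = wcoord(k, origin[2], spacing[2]) - ctr[2];
      for (int j = j0; j <= j1; ++j) {
        const double dy = wcoord(j, origin[1], spacing[1]) - ctr[1];
        for (int i = i0; i <= i1; ++i) {
          const double dx = wcoord(i, origin[0], spacing[0]) - ctr[0];
          bool inside = false;
          if (type == "sphere") {
            inside = dx * dx + dy * dy + dz * dz <= rad * rad;
          } else if (type == "ellipsoid") {
            const double u = (dx * ax1[0] + dy * ax1[1] + dz * ax1[2]) / semi[0];
            const double v = (dx * ax2[0] + dy * ax2[1] + dz * ax2[2]) / semi[1];
            const double w = (dx * ax3[0] + dy * ax3[1] + dz * ax3[2]) / semi[2];
            inside = u * u + v * v + w * w <= 1.0;
          } else if (type == "cylinder") {
            const double a = dx * ax1[0] + dy * ax1[1] + dz * ax1[2];
            if (std::fabs(a) <= half_len) {
              const double r2 = dx * dx + dy * dy + dz * dz - a * a;
              inside = r2 <= rad * rad;
            }
          } else { // slab
            const double u = dx * ax1[0] + dy * ax1[1] + dz * ax1[2];
            const double v = dx * ax2[0] + dy * ax2[1] + dz * ax2[2];
            const double w = dx * ax3[0] + dy * ax3[1] + dz * ax3[2];
            inside = std::fabs(u) <= edge2 && std::fabs(v) <= edge2 &&
                     std::fabs(w) <= th2;
          }
          if (inside) {
            const R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
            if (c[idx] < class_code) c[idx] = class_code;
          }
        }
      }
    }
  }
}

// 26-connected component labelling of voxels with intensity in [lo, hi].
// Returns labels in first-visit order (raster scan); relabelling by size is
// done on the R side.
// [[Rcpp::export(name = ".label_components_26")]]
IntegerVector label_components_26(NumericVector vol, IntegerVector dims,
                                  double lo, double hi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int* L = INTEGER(lab);
  const double* v = REAL(vol);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (L[start] != 0 || v[start] < lo || v[start] > hi) continue;
    ++next;
    L[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = (int)(cur % nx);
      const int j = (int)((cur / nx) % ny);
      const int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            const R_xlen_t nb = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (L[nb] == 0 && v[nb] >= lo && v[nb] <= hi) {
              L[nb] = next;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
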