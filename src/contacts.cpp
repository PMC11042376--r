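// Cell-list neighbour search for polymer contact detection.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(NumericMatrix xyz, double radius) {
  int n = xyz.nrow();
  double r2 = radius * radius;
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, xyz(i, 0));
    ymin = std::min(ymin, xyz(i, 1));
    zmin = std::min(zmin, xyz(i, 2));
  }
  double h = radius;
  std::vector<int> cx(n), cy(n), cz(n);
  int nx = 1, ny = 1, nz = 1;
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor((xyz(i, 0) - xmin) / h);
    cy[i] = (int)std::floor((xyz(i, 1) - ymin) / h);
    cz[i] = (int)std::floor((xyz(i, 2) - zmin) / h);
    nx = std::max(nx, cx[i] + 1);
    ny = std::max(ny, cy[i] + 1);
    nz = std::max(nz, cz[i] + 1);
  }
  // hash cells into buckets
  std::vector<std::vector<int> > bucket((size_t)nx * ny * nz);
  for (int i = 0; i < n; ++i)
    bucket[((size_t)cz[i] * ny + cy[i]) * nx + cx[i]].push_back(i);

  std::vector<int> pi, pj;
  for (int i = 0; i < n; ++i) {
    for (int dz = -1; dz <= 1; ++dz) {
      int z = cz[i] + dz;
      if (z < 0 || z >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = cy[i] + dy;
        if (y < 0 || y >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int x = cx[i] + dx;
          if (x < 0 || x >= nx) continue;
          const std::vector<int> &b = bucket[((size_t)z * ny + y) * nx + x];
          for (size_t k = 0; k < b.size(); ++k) {
            int j = b[k];
            if (j <= i) continue;
            double ddx = xyz(i, 0) - xyz(j, 0);
            double ddy = xyz(i, 1) - xyz(j, 1);
            double ddz = xyz(i, 2) - xyz(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) {
              pi.push_back(i + 1);
              pj.push_back(j + 1);
            }
          }
        }
      }
    }
  }
  IntegerMatrix out((int)pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k];
    out(k, 1) = pj[k];
  }
  return out;
}
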