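#include <Rcpp.h>
#include <vector>
#include <set>
#include <map>
#include <cmath>

using namespace Rcpp;

// Connected-component labelling of a 3D logical mask stored as an R array
// with dim = c(ny, nx, nz) (column-major: y fastest, then x, then z).
// connectivity is 6 (faces) or 26 (faces + edges + corners).
// Labels are assigned in scan order of the array; relabelling by a
// different ordering key is done on the R side.

// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  // neighbour offsets in (dy, dx, dz)
  std::vector<int> dy, dx, dz;
  for (int az = -1; az <= 1; ++az)
    for (int ax = -1; ax <= 1; ++ax)
      for (int ay = -1; ay <= 1; ++ay) {
        if (ax == 0 && ay == 0 && az == 0) continue;
        int manh = std::abs(ax) + std::abs(ay) + std::abs(az);
        if (connectivity == 6 && manh != 1) continue;
        dy.push_back(ay); dx.push_back(ax); dz.push_back(az);
      }
  const int noff = (int)dy.size();

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur / ((R_xlen_t)ny * nx));
      int rem = (int)(cur - (R_xlen_t)z * ny * nx);
      int x = rem / ny;
      int y = rem % ny;
      for (int k = 0; k < noff; ++k) {
        int yy = y + dy[k], xx = x + dx[k], zz = z + dz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// Minimum physical distance between the surface voxels of label pairs.
// labels: 3D label array (dim = c(ny, nx, nz), column-major); voxel:
// pitch (x, y, z) in um; pairs: 2-column matrix of label ids. A voxel is
// "surface" when one of its 6 neighbours is background or lies outside the
// array. Distances are between voxel centres.

// [[Rcpp::export]]
NumericVector min_border_distances(IntegerVector labels, IntegerVector dims,
                                   NumericVector voxel, IntegerMatrix pairs) {
  if (dims.size() != 3 || voxel.size() != 3) stop("dims/voxel must be length 3");
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (labels.size() != n) stop("labels length does not match dims");

  // labels needed
  std::set<int> wanted;
  for (int p = 0; p < pairs.nrow(); ++p) {
    wanted.insert(pairs(p, 0));
    wanted.insert(pairs(p, 1));
  }
  std::map<int, std::vector<double> > sx, sy, sz;

  const int dy6[6] = { -1, 1, 0, 0, 0, 0 };
  const int dx6[6] = { 0, 0, -1, 1, 0, 0 };
  const int dz6[6] = { 0, 0, 0, 0, -1, 1 };
  for (R_xlen_t i = 0; i < n; ++i) {
    int lab = labels[i];
    if (lab == 0 || wanted.find(lab) == wanted.end()) continue;
    int z = (int)(i / ((R_xlen_t)ny * nx));
    int rem = (int)(i - (R_xlen_t)z * ny * nx);
    int x = rem / ny;
    int y = rem % ny;
    bool surface = false;
    for (int k = 0; k < 6; ++k) {
      int yy = y + dy6[k], xx = x + dx6[k], zz = z + dz6[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) {
        surface = true; break;
      }
      R_xlen_t j = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
      if (labels[j] == 0) { surface = true; break; }
    }
    if (!surface) continue;
    sx[lab].push_back((x + 0.5) * voxel[0]);
    sy[lab].push_back((y + 0.5) * voxel[1]);
    sz[lab].push_back((z + 0.5) * voxel[2]);
  }

  NumericVector out(pairs.nrow());
  for (int p = 0; p < pairs.nrow(); ++p) {
    int a = pairs(p, 0), b = pairs(p, 1);
    const std::vector<double> &ax = sx[a], &ay = sy[a], &az = sz[a];
    const std::vector<double> &bx = sx[b], &by = sy[b], &bz = sz[b];
    if (ax.empty() || bx.empty()) { out[p] = NA_REAL; continue; }
    double best = R_PosInf;
    for (size_t i = 0; i < ax.size(); ++i) {
      for (size_t j = 0; j < bx.size(); ++j) {
        double dx = ax[i] - bx[j], dy = ay[i] - by[j], dz = az[i] - bz[j];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
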