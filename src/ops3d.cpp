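// Compiled kernels for 3-D canal image operations: tube rasterization,
// Euclidean distance transform, connected components, morphological region
// growing with per-slice shape filtering, narrow-band surface refinement,
// fast-marching eikonal solver and sub-voxel path back-tracing.
//
// Grids are R arrays in column-major order with dim = (nx, ny, nz);
// axis 1 = X (right), axis 2 = Y (ventral), axis 3 = Z (cranial).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <cstring>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

static inline size_t vidx(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// ---------------------------------------------------------------------------
// distance to a polyline, evaluated only within max_dist of the curve
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_tube_distance(NumericMatrix pts, IntegerVector dims,
                                NumericVector spacing, NumericVector origin,
                                double max_dist) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  NumericVector out((size_t)nx * ny * nz, INF);
  const int nseg = pts.nrow() - 1;
  for (int s = 0; s < nseg; ++s) {
    const double ax = pts(s, 0), ay = pts(s, 1), az = pts(s, 2);
    const double bx = pts(s + 1, 0), by = pts(s + 1, 1), bz = pts(s + 1, 2);
    const double dx = bx - ax, dy = by - ay, dz = bz - az;
    const double len2 = dx * dx + dy * dy + dz * dz;
    // bounding box in voxel indices, padded by max_dist
    int i0 = (int)std::floor((std::min(ax, bx) - max_dist - ox) / sx);
    int i1 = (int)std::ceil((std::max(ax, bx) + max_dist - ox) / sx);
    int j0 = (int)std::floor((std::min(ay, by) - max_dist - oy) / sy);
    int j1 = (int)std::ceil((std::max(ay, by) + max_dist - oy) / sy);
    int k0 = (int)std::floor((std::min(az, bz) - max_dist - oz) / sz);
    int k1 = (int)std::ceil((std::max(az, bz) + max_dist - oz) / sz);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0); k0 = std::max(k0, 0);
    i1 = std::min(i1, nx - 1); j1 = std::min(j1, ny - 1); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double pz = oz + k * sz;
      for (int j = j0; j <= j1; ++j) {
        const double py = oy + j * sy;
        for (int i = i0; i <= i1; ++i) {
          const double px = ox + i * sx;
          double t = 0.0;
          if (len2 > 0)
            t = ((px - ax) * dx + (py - ay) * dy + (pz - az) * dz) / len2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          const double qx = ax + t * dx - px, qy = ay + t * dy - py,
                       qz = az + t * dz - pz;
          const double d = std::sqrt(qx * qx + qy * qy + qz * qz);
          size_t id = vidx(i, j, k, nx, ny);
          if (d < out[id]) out[id] = d;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// exact Euclidean distance transform (squared-distance lower envelopes,
// separable per axis with anisotropic spacing)
// ---------------------------------------------------------------------------

static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int i = 1; i < n; ++i) {
    double s;
    while (true) {
      double xi = i * h, xv = v[q] * h;
      s = ((f[i] + xi * xi) - (f[v[q]] + xv * xv)) / (2 * xi - 2 * xv);
      if (s <= z[q]) { --q; } else break;
    }
    ++q; v[q] = i; z[q] = s; z[q + 1] = INF;
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    double xi = i * h;
    while (z[q + 1] < xi) ++q;
    double dx = xi - v[q] * h;
    d[i] = dx * dx + f[v[q]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  // large finite stand-in for "no background here yet": keeps the
  // lower-envelope parabola intersections well-defined (Inf - Inf is NaN)
  const double BIG = 1e15;
  for (size_t t = 0; t < n; ++t) out[t] = mask[t] ? BIG : 0.0;
  std::vector<double> f(std::max(nx, std::max(ny, nz))),
                      d(std::max(nx, std::max(ny, nz)));
  // X pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = out[vidx(i, j, k, nx, ny)];
      edt1d(f, d, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[vidx(i, j, k, nx, ny)] = d[i];
    }
  // Y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = out[vidx(i, j, k, nx, ny)];
      edt1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[vidx(i, j, k, nx, ny)] = d[j];
    }
  // Z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = out[vidx(i, j, k, nx, ny)];
      edt1d(f, d, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[vidx(i, j, k, nx, ny)] = d[k];
    }
  for (size_t t = 0; t < n; ++t) out[t] = std::sqrt(out[t]);
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component containing a seed; and largest component
// ---------------------------------------------------------------------------

static void flood26(const int* mask, int* lab, int label, size_t seed,
                    int nx, int ny, int nz, std::vector<size_t>& member) {
  std::vector<size_t> stack;
  stack.push_back(seed);
  lab[seed] = label;
  while (!stack.empty()) {
    size_t c = stack.back(); stack.pop_back();
    member.push_back(c);
    int i = (int)(c % nx), j = (int)((c / nx) % ny), k = (int)(c / ((size_t)nx * ny));
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          size_t q = vidx(ii, jj, kk, nx, ny);
          if (mask[q] && !lab[q]) { lab[q] = label; stack.push_back(q); }
        }
  }
}

// keep = "seed": component containing seed_idx (1-based); keep = "largest"
// [[Rcpp::export]]
LogicalVector cpp_keep_component(LogicalVector mask, IntegerVector dims,
                                 int seed_idx, bool use_seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> m(n), lab(n, 0);
  for (size_t t = 0; t < n; ++t) m[t] = mask[t] ? 1 : 0;
  LogicalVector out(n);
  if (use_seed) {
    size_t s = (size_t)(seed_idx - 1);
    if (!m[s]) return out;
    std::vector<size_t> member;
    flood26(m.data(), lab.data(), 1, s, nx, ny, nz, member);
    for (size_t t : member) out[t] = true;
    return out;
  }
  int label = 0;
  std::vector<size_t> best;
  for (size_t t = 0; t < n; ++t) {
    if (m[t] && !lab[t]) {
      std::vector<size_t> member;
      flood26(m.data(), lab.data(), ++label, t, nx, ny, nz, member);
      if (member.size() > best.size()) best.swap(member);
    }
  }
  for (size_t t : best) out[t] = true;
  return out;
}

// ---------------------------------------------------------------------------
// per-slice 8-connected labeling with area/circularity screening
// ---------------------------------------------------------------------------

// in-plane flood fill (8-connected) over a predicate, from a set of seeds;
// returns member pixel indices and the exposed-edge count
struct SliceComp {
  std::vector<size_t> member; // in-plane indices i + nx*j
  long edges = 0;
};

// flood the candidate region from every seed, but return only the single
// 8-connected component with the largest seed overlap: satellite
// components (noise specks, severed foramen stubs) must not ride along
// with the canal cross-section
template <class Pred>
static SliceComp slice_flood_main(int nx, int ny, Pred inside,
                                  const std::vector<size_t>& seeds) {
  std::vector<unsigned char> visited((size_t)nx * ny, 0);
  SliceComp best;
  long best_overlap = -1;
  for (size_t s0 : seeds) {
    if (!inside(s0) || visited[s0]) continue;
    SliceComp comp;
    std::vector<size_t> stack(1, s0);
    visited[s0] = 1;
    while (!stack.empty()) {
      size_t c = stack.back(); stack.pop_back();
      comp.member.push_back(c);
      int i = (int)(c % nx), j = (int)(c / nx);
      const int d4[4][2] = {{1,0},{-1,0},{0,1},{0,-1}};
      for (int e = 0; e < 4; ++e) {
        int ii = i + d4[e][0], jj = j + d4[e][1];
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny ||
            !inside((size_t)ii + (size_t)nx * jj))
          ++comp.edges;
      }
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
          size_t q = (size_t)ii + (size_t)nx * jj;
          if (inside(q) && !visited[q]) { visited[q] = 1; stack.push_back(q); }
        }
    }
    std::vector<unsigned char> inc((size_t)nx * ny, 0);
    for (size_t m : comp.member) inc[m] = 1;
    long overlap = 0;
    for (size_t s : seeds) if (inc[s]) ++overlap;
    if (overlap > best_overlap) { best_overlap = overlap; best = comp; }
  }
  return best;
}

template <class Pred>
static SliceComp slice_flood(int nx, int ny, Pred inside,
                             const std::vector<size_t>& seeds,
                             std::vector<unsigned char>& visited) {
  SliceComp comp;
  std::vector<size_t> stack;
  for (size_t s : seeds)
    if (inside(s) && !visited[s]) { visited[s] = 1; stack.push_back(s); }
  while (!stack.empty()) {
    size_t c = stack.back(); stack.pop_back();
    comp.member.push_back(c);
    int i = (int)(c % nx), j = (int)(c / nx);
    const int d4[4][2] = {{1,0},{-1,0},{0,1},{0,-1}};
    for (int e = 0; e < 4; ++e) {
      int ii = i + d4[e][0], jj = j + d4[e][1];
      if (ii < 0 || jj < 0 || ii >= nx || jj >= ny ||
          !inside((size_t)ii + (size_t)nx * jj))
        ++comp.edges;
    }
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        size_t q = (size_t)ii + (size_t)nx * jj;
        if (inside(q) && !visited[q]) { visited[q] = 1; stack.push_back(q); }
      }
  }
  return comp;
}

// Morphological region growing by cross-section propagation: the enclosed
// cross-section on the seed slice is flooded first, then the canal is
// propagated one slice at a time in both directions. On each slice the
// candidate region is the in-band set within `drift_mm` (in-plane Euclidean
// distance) of the previous slice's accepted region, flooded from the
// pixels overlapping that region; it is accepted only if its area lies in
// [area_min, area_max] and its circularity (4 pi A / P^2, edge-count
// perimeter) reaches circ_min. Propagation in a direction stops at the
// first failing or empty slice. The drift restriction is what keeps the
// region from escaping through disc-level ring openings.
// [[Rcpp::export]]
List cpp_region_grow(NumericVector vol, IntegerVector dims,
                     NumericVector spacing, int seed_idx,
                     double lo, double hi,
                     double area_min, double area_max, double circ_min,
                     int max_iter, double cap_voxels, double drift_mm,
                     int bridge_max) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1];
  const double pix = sx * sy, edge_len = 0.5 * (sx + sy);
  size_t nslice = (size_t)nx * ny;
  size_t seed = (size_t)(seed_idx - 1);
  if (vol[seed] < lo || vol[seed] > hi)
    return List::create(_["status"] = "seed_invalid");
  int k0 = (int)(seed / nslice);
  size_t seed_in = seed % nslice;
  // structuring element of the drift disk
  std::vector<std::pair<int,int>> disk;
  int ri = (int)std::ceil(drift_mm / sx), rj = (int)std::ceil(drift_mm / sy);
  for (int dj = -rj; dj <= rj; ++dj)
    for (int di = -ri; di <= ri; ++di)
      if (di * sx * di * sx + dj * sy * dj * sy <= drift_mm * drift_mm)
        disk.emplace_back(di, dj);
  LogicalVector mask((size_t)nx * ny * nz);
  std::vector<int> per_slice(nz, 0);
  auto band_at = [&](int k) {
    return [&, k](size_t p) {
      double v = vol[p + (size_t)k * nslice];
      return v >= lo && v <= hi;
    };
  };
  // seed slice: flood the component containing the seed, unscreened (the
  // seed was vetted by the seed finder)
  std::vector<unsigned char> visited(nslice, 0);
  SliceComp cur = slice_flood(nx, ny, band_at(k0),
                              std::vector<size_t>(1, seed_in), visited);
  if (cur.member.empty())
    return List::create(_["status"] = "seed_invalid");
  size_t total = cur.member.size();
  for (size_t p : cur.member) mask[p + (size_t)k0 * nslice] = true;
  per_slice[k0] = (int)cur.member.size();
  int iter = 0;
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<size_t> prev = cur.member;
    int bridged = 0;
    for (int k = k0 + dir; k >= 0 && k < nz; k += dir) {
      if (++iter > max_iter) break;
      // allowed = prev dilated by the drift disk
      std::vector<unsigned char> allowed(nslice, 0);
      for (size_t p : prev) {
        int i = (int)(p % nx), j = (int)(p / nx);
        for (auto& d : disk) {
          int ii = i + d.first, jj = j + d.second;
          if (ii >= 0 && jj >= 0 && ii < nx && jj < ny)
            allowed[(size_t)ii + (size_t)nx * jj] = 1;
        }
      }
      auto inside = [&](size_t p) {
        if (!allowed[p]) return false;
        double v = vol[p + (size_t)k * nslice];
        return v >= lo && v <= hi;
      };
      SliceComp comp = slice_flood_main(nx, ny, inside, prev);
      if (comp.member.empty()) break;
      double area = comp.member.size() * pix;
      double perim = comp.edges * edge_len;
      double circ = (perim > 0) ? 4.0 * M_PI * area / (perim * perim) : 1.0;
      if (area < area_min || area > area_max || circ < circ_min) {
        // shape screen failed (e.g. a disc-level opening let the region
        // mushroom): bridge with the in-band flood restricted to the
        // previous cross-section's exact footprint, for a limited run
        std::vector<unsigned char> foot(nslice, 0);
        for (size_t p : prev) foot[p] = 1;
        auto inside_foot = [&](size_t p) {
          if (!foot[p]) return false;
          double v = vol[p + (size_t)k * nslice];
          return v >= lo && v <= hi;
        };
        comp = slice_flood_main(nx, ny, inside_foot, prev);
        double barea = comp.member.size() * pix;
        if (comp.member.empty() || barea < area_min || barea > area_max)
          break;
        if (++bridged > bridge_max) break;
      } else {
        bridged = 0;
      }
      for (size_t p : comp.member) mask[p + (size_t)k * nslice] = true;
      per_slice[k] = (int)comp.member.size();
      total += comp.member.size();
      if ((double)total > cap_voxels)
        return List::create(_["status"] = "leak", _["iterations"] = iter);
      prev.swap(comp.member);
    }
  }
  return List::create(_["status"] = "ok", _["mask"] = mask,
                      _["iterations"] = iter,
                      _["added_per_iter"] = wrap(per_slice));
}

// label the in-band pixels of one slice (8-connected); returns the label
// image and per-component stats: count, exposed 4-neighbor edges, centroid
// [[Rcpp::export]]
List cpp_slice_label(NumericVector slice, int nx, int ny,
                     double lo, double hi) {
  std::vector<int> lab((size_t)nx * ny, 0);
  std::vector<double> cnt, edg, cx, cy;
  int label = 0;
  for (int j0 = 0; j0 < ny; ++j0)
    for (int i0 = 0; i0 < nx; ++i0) {
      size_t p0 = (size_t)i0 + (size_t)nx * j0;
      double v0 = slice[p0];
      if (v0 < lo || v0 > hi || lab[p0]) continue;
      ++label;
      lab[p0] = label;
      std::vector<size_t> stack(1, p0);
      double n = 0, e = 0, sx = 0, sy = 0;
      while (!stack.empty()) {
        size_t c = stack.back(); stack.pop_back();
        int i = (int)(c % nx), j = (int)(c / nx);
        ++n; sx += i; sy += j;
        const int d4[4][2] = {{1,0},{-1,0},{0,1},{0,-1}};
        for (int t = 0; t < 4; ++t) {
          int ii = i + d4[t][0], jj = j + d4[t][1];
          bool inb = ii >= 0 && jj >= 0 && ii < nx && jj < ny;
          double v = inb ? slice[(size_t)ii + (size_t)nx * jj] : lo - 1;
          if (!inb || v < lo || v > hi) ++e;
        }
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
            size_t q = (size_t)ii + (size_t)nx * jj;
            double v = slice[q];
            if (v >= lo && v <= hi && !lab[q]) {
              lab[q] = label;
              stack.push_back(q);
            }
          }
      }
      cnt.push_back(n); edg.push_back(e);
      cx.push_back(sx / n + 1); cy.push_back(sy / n + 1); // 1-based
    }
  IntegerMatrix labels(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      labels(i, j) = lab[(size_t)i + (size_t)nx * j];
  return List::create(_["labels"] = labels, _["count"] = wrap(cnt),
                      _["edges"] = wrap(edg), _["cx"] = wrap(cx),
                      _["cy"] = wrap(cy));
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing and gradient magnitude
// ---------------------------------------------------------------------------

static void conv_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, const std::vector<double>& ker) {
  int r = ((int)ker.size() - 1) / 2;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(len), res(len);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b)
    for (int a1 = 0; a1 < n1; ++a1) {
      for (int t = 0; t < len; ++t) {
        int i, j, k;
        if (axis == 0) { i = t; j = a1; k = b; }
        else if (axis == 1) { i = a1; j = t; k = b; }
        else { i = a1; j = b; k = t; }
        line[t] = a[vidx(i, j, k, nx, ny)];
      }
      for (int t = 0; t < len; ++t) {
        double s = 0;
        for (int u = -r; u <= r; ++u) {
          int tt = t + u;
          if (tt < 0) tt = 0; else if (tt >= len) tt = len - 1;
          s += line[tt] * ker[u + r];
        }
        res[t] = s;
      }
      for (int t = 0; t < len; ++t) {
        int i, j, k;
        if (axis == 0) { i = t; j = a1; k = b; }
        else if (axis == 1) { i = a1; j = t; k = b; }
        else { i = a1; j = b; k = t; }
        a[vidx(i, j, k, nx, ny)] = res[t];
      }
    }
}

static std::vector<double> gauss_kernel(double sigma_vox) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma_vox));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int u = -r; u <= r; ++u) {
    k[u + r] = std::exp(-0.5 * u * u / (sigma_vox * sigma_vox));
    s += k[u + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_gradmag(NumericVector vol, IntegerVector dims,
                          NumericVector spacing, double sigma_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> sm(n);
  for (size_t t = 0; t < n; ++t) sm[t] = vol[t];
  for (int ax = 0; ax < 3; ++ax) {
    double sv = sigma_mm / spacing[ax];
    if (sv > 1e-6) conv_axis(sm, nx, ny, nz, ax, gauss_kernel(sv));
  }
  NumericVector out(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double gx = (sm[vidx(std::min(i + 1, nx - 1), j, k, nx, ny)] -
                     sm[vidx(std::max(i - 1, 0), j, k, nx, ny)]) /
                    (2 * spacing[0]);
        double gy = (sm[vidx(i, std::min(j + 1, ny - 1), k, nx, ny)] -
                     sm[vidx(i, std::max(j - 1, 0), k, nx, ny)]) /
                    (2 * spacing[1]);
        double gz = (sm[vidx(i, j, std::min(k + 1, nz - 1), nx, ny)] -
                     sm[vidx(i, j, std::max(k - 1, 0), nx, ny)]) /
                    (2 * spacing[2]);
        out[vidx(i, j, k, nx, ny)] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return out;
}

// ---------------------------------------------------------------------------
// narrow-band surface refinement (masked ballooning + edge stop)
// ---------------------------------------------------------------------------

// allowed: voxels the surface may occupy (coarse dilated by band)
// core:    voxels it may never lose (coarse eroded by band)
// [[Rcpp::export]]
LogicalVector cpp_refine(NumericVector vol, LogicalVector coarse,
                         IntegerVector dims, NumericVector edge_g,
                         double edge_stop, double gate_lo, double gate_hi,
                         double tight_lo, double tight_hi,
                         int iterations, int band) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<unsigned char> mask(n), allowed(n), core(n);
  for (size_t t = 0; t < n; ++t) {
    mask[t] = coarse[t] ? 1 : 0;
    allowed[t] = mask[t];
    core[t] = mask[t];
  }
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  // build band: dilate `allowed` and erode `core` `band` times (6-conn)
  for (int b = 0; b < band; ++b) {
    std::vector<unsigned char> na(allowed), nc(core);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t c = vidx(i, j, k, nx, ny);
          bool any_on = false, any_off = false;
          for (int e = 0; e < 6; ++e) {
            int ii = i + d6[e][0], jj = j + d6[e][1], kk = k + d6[e][2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
              any_off = true; continue;
            }
            size_t q = vidx(ii, jj, kk, nx, ny);
            if (allowed[q]) any_on = true;
            if (!core[q]) any_off = true;
          }
          if (!allowed[c] && any_on) na[c] = 1;
          if (core[c] && any_off) nc[c] = 0;
        }
    allowed.swap(na); core.swap(nc);
  }
  for (int it = 0; it < iterations; ++it) {
    std::vector<size_t> to_add, to_del;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t c = vidx(i, j, k, nx, ny);
          int nb = 0;
          bool touches = false;
          for (int e = 0; e < 6; ++e) {
            int ii = i + d6[e][0], jj = j + d6[e][1], kk = k + d6[e][2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            if (mask[vidx(ii, jj, kk, nx, ny)]) { ++nb; touches = true; }
          }
          if (!mask[c]) {
            // balloon outward: inside band, supported by >= 2 neighbors
            // (curvature-like penalty against one-voxel tendrils), and
            // either away from a strong edge with a plausible intensity,
            // or with an intensity squarely matching the region (lets the
            // surface advance onto edge-adjacent canal voxels, where the
            // gradient of the bone interface already spills over)
            bool gate = vol[c] >= gate_lo && vol[c] <= gate_hi;
            bool tight = vol[c] >= tight_lo && vol[c] <= tight_hi;
            // strong intensity evidence may extend thin structure; weak
            // (gate-only) evidence needs 2-neighbor support
            if (touches && allowed[c] &&
                ((tight && nb >= 1) ||
                 (gate && nb >= 2 && edge_g[c] > edge_stop)))
              to_add.push_back(c);
          } else {
            // retreat from voxels whose intensity does not belong, unless
            // they are deep core
            if (!core[c] && nb < 6 && (vol[c] < gate_lo || vol[c] > gate_hi))
              to_del.push_back(c);
          }
        }
    if (to_add.empty() && to_del.empty()) break;
    for (size_t c : to_add) mask[c] = 1;
    for (size_t c : to_del) mask[c] = 0;
  }
  LogicalVector out(n);
  for (size_t t = 0; t < n; ++t) out[t] = mask[t] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// fast marching (first-order, 6-neighbor upwind) and back-tracing
// ---------------------------------------------------------------------------

struct HeapNode {
  double t; size_t idx;
  bool operator>(const HeapNode& o) const { return t > o.t; }
};

// [[Rcpp::export]]
NumericVector cpp_fast_march(NumericVector speed, IntegerVector dims,
                             NumericVector spacing, int start_idx,
                             int stop_idx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector T(n, INF);
  std::vector<unsigned char> frozen(n, 0);
  std::priority_queue<HeapNode, std::vector<HeapNode>, std::greater<HeapNode>> heap;
  size_t start = (size_t)(start_idx - 1);
  size_t stop = stop_idx > 0 ? (size_t)(stop_idx - 1) : (size_t)-1;
  T[start] = 0.0;
  heap.push({0.0, start});
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  const double h[3] = {spacing[0], spacing[1], spacing[2]};
  while (!heap.empty()) {
    HeapNode nd = heap.top(); heap.pop();
    if (frozen[nd.idx]) continue;
    frozen[nd.idx] = 1;
    if (nd.idx == stop) break;
    int i = (int)(nd.idx % nx), j = (int)((nd.idx / nx) % ny),
        k = (int)(nd.idx / ((size_t)nx * ny));
    for (int e = 0; e < 6; ++e) {
      int ii = i + d6[e][0], jj = j + d6[e][1], kk = k + d6[e][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      size_t q = vidx(ii, jj, kk, nx, ny);
      if (frozen[q]) continue;
      double F = speed[q];
      if (F <= 0) continue;
      // upwind quadratic: sum over axes ((T - Ta)/ha)^2 = 1/F^2
      double ta[3], ha[3];
      int m = 0;
      const int axes[3][2][3] = {{{1,0,0},{-1,0,0}},
                                 {{0,1,0},{0,-1,0}},
                                 {{0,0,1},{0,0,-1}}};
      for (int ax = 0; ax < 3; ++ax) {
        double best = INF;
        for (int s = 0; s < 2; ++s) {
          int ai = ii + axes[ax][s][0], aj = jj + axes[ax][s][1],
              ak = kk + axes[ax][s][2];
          if (ai < 0 || aj < 0 || ak < 0 || ai >= nx || aj >= ny || ak >= nz)
            continue;
          size_t aq = vidx(ai, aj, ak, nx, ny);
          if (frozen[aq] && T[aq] < best) best = T[aq];
        }
        if (best < INF) { ta[m] = best; ha[m] = h[ax]; ++m; }
      }
      if (m == 0) continue;
      // solve with decreasing set of contributing axes
      // sort contributors ascending
      for (int a1 = 0; a1 < m; ++a1)
        for (int b1 = a1 + 1; b1 < m; ++b1)
          if (ta[b1] < ta[a1]) { std::swap(ta[a1], ta[b1]); std::swap(ha[a1], ha[b1]); }
      double tnew = INF;
      for (int use = m; use >= 1; --use) {
        double A = 0, B = 0, C = -1.0 / (F * F);
        for (int a1 = 0; a1 < use; ++a1) {
          double w = 1.0 / (ha[a1] * ha[a1]);
          A += w; B -= 2.0 * ta[a1] * w; C += ta[a1] * ta[a1] * w;
        }
        double disc = B * B - 4 * A * C;
        if (disc < 0) continue;
        double cand = (-B + std::sqrt(disc)) / (2 * A);
        // causality: solution must exceed all contributors used
        if (cand >= ta[use - 1]) { tnew = cand; break; }
      }
      if (tnew < T[q]) { T[q] = tnew; heap.push({tnew, q}); }
    }
  }
  return T;
}

static double interpT(const NumericVector& T, int nx, int ny, int nz,
                      double x, double y, double z, double big) {
  // trilinear interpolation in voxel coordinates; Inf replaced by `big`
  if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1; if (y > ny - 1) y = ny - 1; if (z > nz - 1) z = nz - 1;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
      k1 = std::min(k0 + 1, nz - 1);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double s = 0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        double v = T[vidx(di ? i1 : i0, dj ? j1 : j0, dk ? k1 : k0, nx, ny)];
        if (!R_finite(v)) v = big;
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        s += v * w;
      }
  return s;
}

// [[Rcpp::export]]
NumericMatrix cpp_backtrace(NumericVector T, IntegerVector dims,
                            NumericVector spacing, NumericVector start_vox,
                            NumericVector end_vox, double step_frac,
                            int max_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double h[3] = {spacing[0], spacing[1], spacing[2]};
  double hmin = std::min(h[0], std::min(h[1], h[2]));
  double step = step_frac * hmin;
  double big = 0;
  for (R_xlen_t t = 0; t < T.size(); ++t)
    if (R_finite(T[t]) && T[t] > big) big = T[t];
  big *= 10.0; if (big <= 0) big = 1e12;
  std::vector<double> px, py, pz, pt;
  double x = end_vox[0], y = end_vox[1], z = end_vox[2]; // 0-based voxel coords
  double sx = start_vox[0], sy = start_vox[1], sz = start_vox[2];
  double tcur = interpT(T, nx, ny, nz, x, y, z, big);
  px.push_back(x); py.push_back(y); pz.push_back(z); pt.push_back(tcur);
  for (int it = 0; it < max_steps; ++it) {
    double dx = (x - sx) * h[0], dy = (y - sy) * h[1], dz = (z - sz) * h[2];
    if (std::sqrt(dx * dx + dy * dy + dz * dz) <= hmin) break;
    // numeric gradient of T in mm (finite differences of interpolated field)
    double e = 0.5;
    double gx = (interpT(T, nx, ny, nz, x + e, y, z, big) -
                 interpT(T, nx, ny, nz, x - e, y, z, big)) / (2 * e * h[0]);
    double gy = (interpT(T, nx, ny, nz, x, y + e, z, big) -
                 interpT(T, nx, ny, nz, x, y - e, z, big)) / (2 * e * h[1]);
    double gz = (interpT(T, nx, ny, nz, x, y, z + e, big) -
                 interpT(T, nx, ny, nz, x, y, z - e, big)) / (2 * e * h[2]);
    double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
    bool moved = false;
    if (gn > 1e-12) {
      double nxp = x - step * gx / (gn * h[0]);
      double nyp = y - step * gy / (gn * h[1]);
      double nzp = z - step * gz / (gn * h[2]);
      double tn = interpT(T, nx, ny, nz, nxp, nyp, nzp, big);
      if (tn < tcur) {
        x = nxp; y = nyp; z = nzp; tcur = tn; moved = true;
      }
    }
    if (!moved) {
      // discrete fallback: hop to the 26-neighbor voxel with smallest T
      int ci = (int)std::round(x), cj = (int)std::round(y), ck = (int)std::round(z);
      double bestT = tcur; int bi = ci, bj = cj, bk = ck;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            double v = T[vidx(ii, jj, kk, nx, ny)];
            if (R_finite(v) && v < bestT) { bestT = v; bi = ii; bj = jj; bk = kk; }
          }
      if (bestT >= tcur) break; // stuck at a minimum (should be the start)
      x = bi; y = bj; z = bk; tcur = bestT;
    }
    px.push_back(x); py.push_back(y); pz.push_back(z); pt.push_back(tcur);
  }
  px.push_back(sx); py.push_back(sy); pz.push_back(sz); pt.push_back(0.0);
  NumericMatrix out((int)px.size(), 4);
  for (int r = 0; r < (int)px.size(); ++r) {
    out(r, 0) = px[r]; out(r, 1) = py[r]; out(r, 2) = pz[r];
    out(r, 3) = pt[r];
  }
  return out;
}
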