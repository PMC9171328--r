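#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared helpers
// ---------------------------------------------------------------------------

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

struct Grid {
  int nx, ny, nz;
  inline int idx(int x, int y, int z) const { return x + nx * (y + ny * z); }
  inline int n() const { return nx * ny * nz; }
};

static Grid grid_of(SEXP a) {
  IntegerVector d = Rf_getAttrib(a, R_DimSymbol);
  if (d.size() != 3) stop("expected a 3-D array");
  Grid g; g.nx = d[0]; g.ny = d[1]; g.nz = d[2];
  return g;
}

// Mean squared intensity difference between two patches (edge replication at
// borders); the normalized L2 distance used for all patch comparisons.
static inline double patch_ssd(const double* a, int ax, int ay, int az,
                               const double* b, int bx, int by, int bz,
                               const Grid& g, int half) {
  double s = 0.0;
  int n = 0;
  for (int dz = -half; dz <= half; ++dz)
    for (int dy = -half; dy <= half; ++dy)
      for (int dx = -half; dx <= half; ++dx) {
        int x1 = clampi(ax + dx, 0, g.nx - 1);
        int y1 = clampi(ay + dy, 0, g.ny - 1);
        int z1 = clampi(az + dz, 0, g.nz - 1);
        int x2 = clampi(bx + dx, 0, g.nx - 1);
        int y2 = clampi(by + dy, 0, g.ny - 1);
        int z2 = clampi(bz + dz, 0, g.nz - 1);
        double d = a[g.idx(x1, y1, z1)] - b[g.idx(x2, y2, z2)];
        s += d * d;
        ++n;
      }
  return s / n;
}

// xorshift64* PRNG: self-contained so approximate-nearest-neighbor fields are
// bit-reproducible for a given seed regardless of R's RNG state.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  inline uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  inline int unif_int(int n) { return (int)(next() % (uint64_t)n); }
  // uniform integer in [lo, hi] inclusive
  inline int unif_range(int lo, int hi) { return lo + unif_int(hi - lo + 1); }
};

// ---------------------------------------------------------------------------
// Exhaustive non-local label fusion: every window position of every library
// member votes for its central label, weighted by exp(-D / h^2) with
// h^2 = min(D) + eps per target voxel.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_fuse_exhaustive")]]
NumericVector cpp_fuse_exhaustive(NumericVector subj, List imgs, List labs,
                                  LogicalVector mask, int patch, int radius,
                                  double h_eps, IntegerVector label_ids) {
  Grid g = grid_of(subj);
  int half = patch / 2, N = imgs.size(), L = label_ids.size();
  int max_lab = 0;
  for (int l = 0; l < L; ++l) if (label_ids[l] > max_lab) max_lab = label_ids[l];
  std::vector<int> lab_row(max_lab + 1, -1);
  for (int l = 0; l < L; ++l) lab_row[label_ids[l]] = l;

  std::vector<const double*> ip(N);
  std::vector<const int*> lp(N);
  for (int s = 0; s < N; ++s) {
    NumericVector im = imgs[s];
    IntegerVector lb = labs[s];
    ip[s] = REAL(im);
    lp[s] = INTEGER(lb);
  }
  const double* sp = REAL(subj);

  NumericVector out((R_xlen_t)g.n() * L);
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz, L);
  double* op = REAL(out);
  long stride = (long)g.n();

  std::vector<double> dist;
  std::vector<int> vlab;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int i = g.idx(x, y, z);
        if (!mask[i]) continue;
        dist.clear(); vlab.clear();
        double dmin = R_PosInf;
        int x0 = clampi(x - radius, 0, g.nx - 1), x1 = clampi(x + radius, 0, g.nx - 1);
        int y0 = clampi(y - radius, 0, g.ny - 1), y1 = clampi(y + radius, 0, g.ny - 1);
        int z0 = clampi(z - radius, 0, g.nz - 1), z1 = clampi(z + radius, 0, g.nz - 1);
        for (int s = 0; s < N; ++s)
          for (int zz = z0; zz <= z1; ++zz)
            for (int yy = y0; yy <= y1; ++yy)
              for (int xx = x0; xx <= x1; ++xx) {
                double d = patch_ssd(sp, x, y, z, ip[s], xx, yy, zz, g, half);
                if (d < dmin) dmin = d;
                dist.push_back(d);
                vlab.push_back(lp[s][g.idx(xx, yy, zz)]);
              }
        double h2 = dmin + h_eps, wsum = 0.0;
        std::vector<double> acc(L, 0.0);
        for (size_t c = 0; c < dist.size(); ++c) {
          double w = std::exp(-dist[c] / h2);
          wsum += w;
          int lb = vlab[c];
          if (lb >= 0 && lb <= max_lab && lab_row[lb] >= 0) acc[lab_row[lb]] += w;
        }
        for (int l = 0; l < L; ++l) op[i + stride * l] = acc[l] / wsum;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Approximate nearest neighbor field (PatchMatch-style): random init,
// propagation from raster-scan neighbors, random search with geometrically
// decaying radius. Candidates kept sorted by distance, unique by (s, j).
// ---------------------------------------------------------------------------

struct CandSet {
  int k;
  std::vector<int> s, j;
  std::vector<double> d;
  CandSet(int k_) : k(k_), s(k_, -1), j(k_, -1), d(k_, R_PosInf) {}
  // insert keeping ascending order; reject duplicates; return true if inserted
  inline bool insert(int ss, int jj, double dd) {
    if (dd >= d[k - 1]) {
      // may still be a duplicate check short-cut: not better than worst -> skip
      return false;
    }
    for (int c = 0; c < k; ++c)
      if (s[c] == ss && j[c] == jj) return false;
    int pos = k - 1;
    while (pos > 0 && d[pos - 1] > dd) {
      d[pos] = d[pos - 1]; s[pos] = s[pos - 1]; j[pos] = j[pos - 1];
      --pos;
    }
    d[pos] = dd; s[pos] = ss; j[pos] = jj;
    return true;
  }
};

// [[Rcpp::export(name = ".cpp_build_annf")]]
List cpp_build_annf(NumericVector subj, List imgs, LogicalVector mask,
                    int patch, int radius, int k, int iters, double seed) {
  Grid g = grid_of(subj);
  int half = patch / 2, N = imgs.size();
  std::vector<const double*> ip(N);
  for (int s = 0; s < N; ++s) { NumericVector im = imgs[s]; ip[s] = REAL(im); }
  const double* sp = REAL(subj);

  // masked voxels in raster order + reverse lookup for propagation
  std::vector<int> mvox;
  std::vector<int> row_of(g.n(), -1);
  for (int i = 0; i < g.n(); ++i)
    if (mask[i]) { row_of[i] = (int)mvox.size(); mvox.push_back(i); }
  int M = (int)mvox.size();
  if (M == 0) stop("empty mask");

  XorShift rng((uint64_t)seed);
  std::vector<CandSet> cs(M, CandSet(k));

  // per-voxel clamped window; pool = window positions x members
  for (int r = 0; r < M; ++r) {
    int i = mvox[r];
    int x = i % g.nx, y = (i / g.nx) % g.ny, z = i / (g.nx * g.ny);
    int x0 = clampi(x - radius, 0, g.nx - 1), x1 = clampi(x + radius, 0, g.nx - 1);
    int y0 = clampi(y - radius, 0, g.ny - 1), y1 = clampi(y + radius, 0, g.ny - 1);
    int z0 = clampi(z - radius, 0, g.nz - 1), z1 = clampi(z + radius, 0, g.nz - 1);
    long pool = (long)N * (x1 - x0 + 1) * (y1 - y0 + 1) * (z1 - z0 + 1);
    if (pool <= (long)k) {
      // degenerate window: enumerate exhaustively (exact best-k)
      for (int s = 0; s < N; ++s)
        for (int zz = z0; zz <= z1; ++zz)
          for (int yy = y0; yy <= y1; ++yy)
            for (int xx = x0; xx <= x1; ++xx) {
              int jj = g.idx(xx, yy, zz);
              cs[r].insert(s, jj, patch_ssd(sp, x, y, z, ip[s], xx, yy, zz, g, half));
            }
    } else {
      // the library is affinely co-registered, so the aligned position is a
      // strong prior: seed with the identity correspondence of each member
      for (int s = 0; s < N && s < k; ++s)
        cs[r].insert(s, i, patch_ssd(sp, x, y, z, ip[s], x, y, z, g, half));
      int placed = std::min(N, k), attempts = 0;
      while (placed < k && attempts < 50 * k) {
        ++attempts;
        int s = rng.unif_int(N);
        int xx = rng.unif_range(x0, x1), yy = rng.unif_range(y0, y1), zz = rng.unif_range(z0, z1);
        int jj = g.idx(xx, yy, zz);
        if (cs[r].insert(s, jj, patch_ssd(sp, x, y, z, ip[s], xx, yy, zz, g, half)))
          ++placed;
      }
    }
  }

  // iterations: alternate forward/backward raster scans
  for (int it = 0; it < iters; ++it) {
    bool fwd = (it % 2 == 0);
    for (int rr = 0; rr < M; ++rr) {
      int r = fwd ? rr : (M - 1 - rr);
      int i = mvox[r];
      int x = i % g.nx, y = (i / g.nx) % g.ny, z = i / (g.nx * g.ny);
      int x0 = clampi(x - radius, 0, g.nx - 1), x1 = clampi(x + radius, 0, g.nx - 1);
      int y0 = clampi(y - radius, 0, g.ny - 1), y1 = clampi(y + radius, 0, g.ny - 1);
      int z0 = clampi(z - radius, 0, g.nz - 1), z1 = clampi(z + radius, 0, g.nz - 1);

      // propagation from the three already-scanned axis neighbors
      int step = fwd ? -1 : 1;
      int nbx[3] = { x + step, x, x };
      int nby[3] = { y, y + step, y };
      int nbz[3] = { z, z, z + step };
      for (int q = 0; q < 3; ++q) {
        if (nbx[q] < 0 || nbx[q] >= g.nx || nby[q] < 0 || nby[q] >= g.ny ||
            nbz[q] < 0 || nbz[q] >= g.nz) continue;
        int nr = row_of[g.idx(nbx[q], nby[q], nbz[q])];
        if (nr < 0) continue;
        for (int c = 0; c < cs[nr].k; ++c) {
          int s = cs[nr].s[c];
          if (s < 0) continue;
          int pj = cs[nr].j[c];
          int px = pj % g.nx, py = (pj / g.nx) % g.ny, pz = pj / (g.nx * g.ny);
          // shift the neighbor's match by the neighbor->voxel offset
          int xx = clampi(px - (nbx[q] - x), x0, x1);
          int yy = clampi(py - (nby[q] - y), y0, y1);
          int zz = clampi(pz - (nbz[q] - z), z0, z1);
          cs[r].insert(s, g.idx(xx, yy, zz),
                       patch_ssd(sp, x, y, z, ip[s], xx, yy, zz, g, half));
        }
      }

      // random search around the current best, radius halving per probe
      int bj = cs[r].j[0];
      if (bj >= 0) {
        int bx = bj % g.nx, by = (bj / g.nx) % g.ny, bz = bj / (g.nx * g.ny);
        for (int w = radius; w >= 1; w >>= 1) {
          int s = rng.unif_int(N);
          int xx = clampi(bx + rng.unif_range(-w, w), x0, x1);
          int yy = clampi(by + rng.unif_range(-w, w), y0, y1);
          int zz = clampi(bz + rng.unif_range(-w, w), z0, z1);
          cs[r].insert(s, g.idx(xx, yy, zz),
                       patch_ssd(sp, x, y, z, ip[s], xx, yy, zz, g, half));
        }
      }
    }
  }

  IntegerVector vox(M);
  IntegerMatrix ms(M, k), mj(M, k);
  NumericMatrix md(M, k);
  for (int r = 0; r < M; ++r) {
    vox[r] = mvox[r];
    for (int c = 0; c < k; ++c) {
      ms(r, c) = cs[r].s[c];
      mj(r, c) = cs[r].j[c];
      md(r, c) = cs[r].d[c];
    }
  }
  return List::create(_["vox"] = vox, _["subject"] = ms, _["position"] = mj,
                      _["distance"] = md);
}

// ---------------------------------------------------------------------------
// Label fusion over an ANNF field. Central mode: each candidate votes its
// central label at the target voxel (matches the exhaustive rule restricted
// to the candidates). Patchwise mode: each matched patch votes labels for
// every voxel it covers (OPAL-style late aggregation).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_fuse_annf")]]
NumericVector cpp_fuse_annf(IntegerVector dims, List labs, IntegerVector vox,
                            IntegerMatrix ms, IntegerMatrix mj, NumericMatrix md,
                            int patch, double h_eps, IntegerVector label_ids,
                            bool patchwise, LogicalVector mask) {
  Grid g; g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  int half = patch / 2, L = label_ids.size(), M = vox.size(), k = ms.ncol();
  int N = labs.size();
  int max_lab = 0;
  for (int l = 0; l < L; ++l) if (label_ids[l] > max_lab) max_lab = label_ids[l];
  std::vector<int> lab_row(max_lab + 1, -1);
  for (int l = 0; l < L; ++l) lab_row[label_ids[l]] = l;
  std::vector<const int*> lp(N);
  for (int s = 0; s < N; ++s) { IntegerVector lb = labs[s]; lp[s] = INTEGER(lb); }

  NumericVector out((R_xlen_t)g.n() * L);
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz, L);
  double* op = REAL(out);
  long stride = (long)g.n();
  std::vector<double> wsum(g.n(), 0.0);

  for (int r = 0; r < M; ++r) {
    double dmin = R_PosInf;
    for (int c = 0; c < k; ++c)
      if (ms(r, c) >= 0 && md(r, c) < dmin) dmin = md(r, c);
    if (!R_FINITE(dmin)) continue;
    double h2 = dmin + h_eps;
    int i = vox[r];
    int x = i % g.nx, y = (i / g.nx) % g.ny, z = i / (g.nx * g.ny);
    for (int c = 0; c < k; ++c) {
      int s = ms(r, c);
      if (s < 0) continue;
      double w = std::exp(-md(r, c) / h2);
      int j = mj(r, c);
      int jx = j % g.nx, jy = (j / g.nx) % g.ny, jz = j / (g.nx * g.ny);
      if (!patchwise) {
        int lb = lp[s][j];
        if (lb >= 0 && lb <= max_lab && lab_row[lb] >= 0) {
          op[i + stride * lab_row[lb]] += w;
          wsum[i] += w;
        } else {
          wsum[i] += w;  // background votes still normalize
        }
      } else {
        for (int dz = -half; dz <= half; ++dz)
          for (int dy = -half; dy <= half; ++dy)
            for (int dx = -half; dx <= half; ++dx) {
              int tx = x + dx, ty = y + dy, tz = z + dz;
              if (tx < 0 || tx >= g.nx || ty < 0 || ty >= g.ny || tz < 0 || tz >= g.nz)
                continue;
              int t = g.idx(tx, ty, tz);
              if (!mask[t]) continue;
              int sx = clampi(jx + dx, 0, g.nx - 1);
              int sy = clampi(jy + dy, 0, g.ny - 1);
              int sz = clampi(jz + dz, 0, g.nz - 1);
              int lb = lp[s][g.idx(sx, sy, sz)];
              if (lb >= 0 && lb <= max_lab && lab_row[lb] >= 0)
                op[t + stride * lab_row[lb]] += w;
              wsum[t] += w;
            }
      }
    }
  }
  for (int r = 0; r < M; ++r) {
    int i = vox[r];
    if (wsum[i] > 0)
      for (int l = 0; l < L; ++l) op[i + stride * l] /= wsum[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared-distance lower envelope of
// parabolas, applied separably along the three axes).
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb, int n) {
  int first = -1;
  for (int q = 0; q < n; ++q)
    if (R_FINITE(f[q])) { first = q; break; }
  if (first < 0) {
    for (int q = 0; q < n; ++q) d[q] = R_PosInf;
    return;
  }
  int q0 = 0;
  v[0] = first;
  zb[0] = -R_PosInf;
  zb[1] = R_PosInf;
  for (int q = first + 1; q < n; ++q) {
    if (!R_FINITE(f[q])) continue;
    double s = ((f[q] + q * (double)q) - (f[v[q0]] + v[q0] * (double)v[q0])) /
               (2.0 * q - 2.0 * v[q0]);
    while (q0 > 0 && s <= zb[q0]) {
      --q0;
      s = ((f[q] + q * (double)q) - (f[v[q0]] + v[q0] * (double)v[q0])) /
          (2.0 * q - 2.0 * v[q0]);
    }
    ++q0;
    v[q0] = q;
    zb[q0] = s;
    zb[q0 + 1] = R_PosInf;
  }
  int qi = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[qi + 1] < q) ++qi;
    double dq = q - (double)v[qi];
    d[q] = dq * dq + f[v[qi]];
  }
}

// squared Euclidean distance to the nearest TRUE voxel of `feature`
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector feature) {
  Grid g = grid_of(feature);
  int n = g.n();
  NumericVector out(n);
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  std::vector<double> D(n);
  for (int i = 0; i < n; ++i) D[i] = feature[i] ? 0.0 : R_PosInf;
  int nmax = std::max(g.nx, std::max(g.ny, g.nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // x
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y) {
      for (int x = 0; x < g.nx; ++x) f[x] = D[g.idx(x, y, z)];
      dt1d(f, d, v, zb, g.nx);
      for (int x = 0; x < g.nx; ++x) D[g.idx(x, y, z)] = d[x];
    }
  // y
  for (int z = 0; z < g.nz; ++z)
    for (int x = 0; x < g.nx; ++x) {
      for (int y = 0; y < g.ny; ++y) f[y] = D[g.idx(x, y, z)];
      dt1d(f, d, v, zb, g.ny);
      for (int y = 0; y < g.ny; ++y) D[g.idx(x, y, z)] = d[y];
    }
  // z
  for (int y = 0; y < g.ny; ++y)
    for (int x = 0; x < g.nx; ++x) {
      for (int z = 0; z < g.nz; ++z) f[z] = D[g.idx(x, y, z)];
      dt1d(f, d, v, zb, g.nz);
      for (int z = 0; z < g.nz; ++z) D[g.idx(x, y, z)] = d[z];
    }
  for (int i = 0; i < n; ++i) out[i] = D[i];
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur (clamped borders), used to smooth random
// displacement fields in the phantom generator.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_gauss3d")]]
NumericVector cpp_gauss3d(NumericVector arr, double sigma) {
  Grid g = grid_of(arr);
  if (sigma <= 0) return clone(arr);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double ks = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    ks += ker[t + rad];
  }
  for (auto& v : ker) v /= ks;

  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  auto pass = [&](int axis) {
    int n = axis == 0 ? g.nx : axis == 1 ? g.ny : g.nz;
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        for (int x = 0; x < g.nx; ++x) {
          double s = 0.0;
          for (int t = -rad; t <= rad; ++t) {
            int xx = x, yy = y, zz = z;
            if (axis == 0) xx = clampi(x + t, 0, n - 1);
            else if (axis == 1) yy = clampi(y + t, 0, n - 1);
            else zz = clampi(z + t, 0, n - 1);
            s += ker[t + rad] * a[g.idx(xx, yy, zz)];
          }
          b[g.idx(x, y, z)] = s;
        }
    std::swap(a, b);
  };
  pass(0); pass(1); pass(2);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  return out;
}

// ---------------------------------------------------------------------------
// Backward warping by a displacement field: value at voxel v is sampled at
// v + disp(v). Trilinear for intensities, nearest-neighbor for labels.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_warp_trilinear")]]
NumericVector cpp_warp_trilinear(NumericVector arr, NumericVector dx,
                                 NumericVector dy, NumericVector dz) {
  Grid g = grid_of(arr);
  NumericVector out(g.n());
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  const double* a = REAL(arr);
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int i = g.idx(x, y, z);
        double sx = x + dx[i], sy = y + dy[i], sz = z + dz[i];
        sx = std::min(std::max(sx, 0.0), (double)(g.nx - 1));
        sy = std::min(std::max(sy, 0.0), (double)(g.ny - 1));
        sz = std::min(std::max(sz, 0.0), (double)(g.nz - 1));
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
        int x1 = std::min(x0 + 1, g.nx - 1), y1 = std::min(y0 + 1, g.ny - 1),
            z1 = std::min(z0 + 1, g.nz - 1);
        double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double c00 = a[g.idx(x0, y0, z0)] * (1 - fx) + a[g.idx(x1, y0, z0)] * fx;
        double c10 = a[g.idx(x0, y1, z0)] * (1 - fx) + a[g.idx(x1, y1, z0)] * fx;
        double c01 = a[g.idx(x0, y0, z1)] * (1 - fx) + a[g.idx(x1, y0, z1)] * fx;
        double c11 = a[g.idx(x0, y1, z1)] * (1 - fx) + a[g.idx(x1, y1, z1)] * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[i] = c0 * (1 - fz) + c1 * fz;
      }
  return out;
}

// [[Rcpp::export(name = ".cpp_warp_nearest")]]
IntegerVector cpp_warp_nearest(IntegerVector arr, NumericVector dx,
                               NumericVector dy, NumericVector dz) {
  Grid g = grid_of(arr);
  IntegerVector out(g.n());
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  const int* a = INTEGER(arr);
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int i = g.idx(x, y, z);
        int sx = clampi((int)std::lround(x + dx[i]), 0, g.nx - 1);
        int sy = clampi((int)std::lround(y + dy[i]), 0, g.ny - 1);
        int sz = clampi((int)std::lround(z + dz[i]), 0, g.nz - 1);
        out[i] = a[g.idx(sx, sy, sz)];
      }
  return out;
}

// ---------------------------------------------------------------------------
// Non-local means smoothing of a scalar grid (partial-volume regularization).
// Weights follow the fusion convention: per voxel h^2 = strength *
// (min off-center patch distance + eps); the center contributes weight 1.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_nlm")]]
NumericVector cpp_nlm(NumericVector arr, int patch, int radius, double strength,
                      double h_eps) {
  Grid g = grid_of(arr);
  int half = patch / 2;
  NumericVector out(g.n());
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  const double* a = REAL(arr);
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int i = g.idx(x, y, z);
        int x0 = clampi(x - radius, 0, g.nx - 1), x1 = clampi(x + radius, 0, g.nx - 1);
        int y0 = clampi(y - radius, 0, g.ny - 1), y1 = clampi(y + radius, 0, g.ny - 1);
        int z0 = clampi(z - radius, 0, g.nz - 1), z1 = clampi(z + radius, 0, g.nz - 1);
        double dmin = R_PosInf;
        for (int zz = z0; zz <= z1; ++zz)
          for (int yy = y0; yy <= y1; ++yy)
            for (int xx = x0; xx <= x1; ++xx) {
              if (xx == x && yy == y && zz == z) continue;
              double d = patch_ssd(a, x, y, z, a, xx, yy, zz, g, half);
              if (d < dmin) dmin = d;
            }
        double h2 = strength * (R_FINITE(dmin) ? dmin + h_eps : h_eps);
        double num = a[i], den = 1.0;  // center, weight 1
        for (int zz = z0; zz <= z1; ++zz)
          for (int yy = y0; yy <= y1; ++yy)
            for (int xx = x0; xx <= x1; ++xx) {
              if (xx == x && yy == y && zz == z) continue;
              double d = patch_ssd(a, x, y, z, a, xx, yy, zz, g, half);
              double w = std::exp(-d / h2);
              num += w * a[g.idx(xx, yy, zz)];
              den += w;
            }
        out[i] = num / den;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Corrector feature extraction: for each query voxel the 112-vector
// (intensity 3^3 full; intensity 7^3 subsampled at offsets {-3,0,+3};
//  segmentation 3^3; segmentation 7^3 subsampled; distance-map value;
//  world x, y, z). Borders handled by edge replication.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_pec_features")]]
NumericMatrix cpp_pec_features(NumericVector t1, NumericVector seg,
                               NumericVector dmap, IntegerMatrix coords,
                               NumericMatrix affine) {
  Grid g = grid_of(t1);
  int n = coords.nrow();
  NumericMatrix out(n, 112);
  const double* tp = REAL(t1);
  const double* sp = REAL(seg);
  const double* dp = REAL(dmap);
  const int off3[3] = { -1, 0, 1 };
  const int off7[3] = { -3, 0, 3 };
  for (int r = 0; r < n; ++r) {
    int x = coords(r, 0), y = coords(r, 1), z = coords(r, 2);
    int col = 0;
    for (int pass = 0; pass < 4; ++pass) {
      const int* off = (pass % 2 == 0) ? off3 : off7;
      const double* src = (pass < 2) ? tp : sp;
      for (int cz = 0; cz < 3; ++cz)
        for (int cy = 0; cy < 3; ++cy)
          for (int cx = 0; cx < 3; ++cx) {
            int xx = clampi(x + off[cx], 0, g.nx - 1);
            int yy = clampi(y + off[cy], 0, g.ny - 1);
            int zz = clampi(z + off[cz], 0, g.nz - 1);
            out(r, col++) = src[g.idx(xx, yy, zz)];
          }
    }
    out(r, col++) = dp[g.idx(x, y, z)];
    for (int w = 0; w < 3; ++w)
      out(r, col++) = affine(w, 0) * x + affine(w, 1) * y + affine(w, 2) * z +
                      affine(w, 3);
  }
  return out;
}

// 3^3 patch values of an array at given coordinates (same offset order as the
// feature extractor); used for corrector targets and overlapping-vote scatter.
// [[Rcpp::export(name = ".cpp_patch3")]]
NumericMatrix cpp_patch3(NumericVector arr, IntegerMatrix coords) {
  Grid g = grid_of(arr);
  int n = coords.nrow();
  NumericMatrix out(n, 27);
  const double* a = REAL(arr);
  for (int r = 0; r < n; ++r) {
    int x = coords(r, 0), y = coords(r, 1), z = coords(r, 2);
    int col = 0;
    for (int cz = -1; cz <= 1; ++cz)
      for (int cy = -1; cy <= 1; ++cy)
        for (int cx = -1; cx <= 1; ++cx) {
          int xx = clampi(x + cx, 0, g.nx - 1);
          int yy = clampi(y + cy, 0, g.ny - 1);
          int zz = clampi(z + cz, 0, g.nz - 1);
          out(r, col++) = a[g.idx(xx, yy, zz)];
        }
  }
  return out;
}

// Scatter overlapping 3^3 patch predictions back onto the grid, averaging
// contributions per voxel. pred is n x 27 in the cpp_patch3 offset order.
// [[Rcpp::export(name = ".cpp_scatter_patch3")]]
List cpp_scatter_patch3(NumericMatrix pred, IntegerMatrix coords,
                        IntegerVector dims) {
  Grid g; g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  NumericVector acc(g.n()), cnt(g.n());
  acc.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  cnt.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  int n = pred.nrow();
  for (int r = 0; r < n; ++r) {
    int x = coords(r, 0), y = coords(r, 1), z = coords(r, 2);
    int col = 0;
    for (int cz = -1; cz <= 1; ++cz)
      for (int cy = -1; cy <= 1; ++cy)
        for (int cx = -1; cx <= 1; ++cx) {
          int xx = x + cx, yy = y + cy, zz = z + cz;
          int c = col++;
          if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny || zz < 0 || zz >= g.nz)
            continue;
          int i = g.idx(xx, yy, zz);
          acc[i] += pred(r, c);
          cnt[i] += 1.0;
        }
  }
  return List::create(_["sum"] = acc, _["count"] = cnt);
}
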