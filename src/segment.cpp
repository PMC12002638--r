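// Low-level voxel operations for 3D nanocluster segmentation.
//
// Conventions (shared with the R layer):
//  - arrays are dim (nz, ny, nx), z fastest-varying (R column-major);
//  - linear indices are 1-based at the R boundary, 0-based internally;
//  - all inequalities at thresholds are strict;
//  - ties are broken toward the lower linear index, so every routine is
//    deterministic for a given input.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Dim3 {
  int nz, ny, nx;
  Dim3(const IntegerVector& d) : nz(d[0]), ny(d[1]), nx(d[2]) {}
  inline int n() const { return nz * ny * nx; }
  inline void unpack(int lin, int& k, int& j, int& i) const {
    k = lin % nz;
    j = (lin / nz) % ny;
    i = lin / (nz * ny);
  }
  inline int pack(int k, int j, int i) const { return k + nz * (j + ny * i); }
  inline bool inside(int k, int j, int i) const {
    return k >= 0 && k < nz && j >= 0 && j < ny && i >= 0 && i < nx;
  }
};

// 26-neighbourhood offsets (8-neighbourhood when nz == 1).
static const int NB[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},
  {-1,1,-1},{-1,1,0},{-1,1,1},{0,-1,-1},{0,-1,0},{0,-1,1},
  {0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},
  {1,-1,-1},{1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},
  {1,1,-1},{1,1,0},{1,1,1}
};

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  Dim3 d(dim);
  IntegerVector labels(d.n(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int v = 0; v < d.n(); ++v) {
    if (!mask[v] || labels[v] != 0) continue;
    ++next;
    labels[v] = next;
    stack.push_back(v);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int k, j, i;
      d.unpack(cur, k, j, i);
      for (int t = 0; t < 26; ++t) {
        int kk = k + NB[t][0], jj = j + NB[t][1], ii = i + NB[t][2];
        if (!d.inside(kk, jj, ii)) continue;
        int u = d.pack(kk, jj, ii);
        if (mask[u] && labels[u] == 0) {
          labels[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  return labels;
}

// Strict local maxima above `thr` within an ellipsoidal neighbourhood of
// radii (rxy, rxy, rz) voxels: (di^2 + dj^2)/rxy^2 + dk^2/rz^2 <= 1.
// A voxel survives a tie with an equal-valued neighbour only if its linear
// index is lower. Returns 1-based linear indices in ascending order.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector img, IntegerVector dim,
                               double rxy, double rz, double thr) {
  Dim3 d(dim);
  // Precompute the ellipsoidal offset set.
  std::vector<int> offs;
  int mxy = (int)std::floor(rxy), mz = (int)std::floor(rz);
  for (int dk = -mz; dk <= mz; ++dk)
    for (int dj = -mxy; dj <= mxy; ++dj)
      for (int di = -mxy; di <= mxy; ++di) {
        if (dk == 0 && dj == 0 && di == 0) continue;
        double q = (double)(di * di + dj * dj) / (rxy * rxy) +
                   (double)(dk * dk) / (rz * rz);
        if (q <= 1.0) {
          offs.push_back(dk);
          offs.push_back(dj);
          offs.push_back(di);
        }
      }
  std::vector<int> out;
  for (int v = 0; v < d.n(); ++v) {
    double val = img[v];
    if (!(val > thr)) continue;
    int k, j, i;
    d.unpack(v, k, j, i);
    bool is_max = true;
    for (size_t t = 0; t < offs.size(); t += 3) {
      int kk = k + offs[t], jj = j + offs[t + 1], ii = i + offs[t + 2];
      if (!d.inside(kk, jj, ii)) continue;
      int u = d.pack(kk, jj, ii);
      double nv = img[u];
      if (nv > val || (nv == val && u < v)) {
        is_max = false;
        break;
      }
    }
    if (is_max) out.push_back(v + 1);
  }
  return wrap(out);
}

struct QItem {
  double val;
  int idx;
};
struct QLess {
  // max-heap on value; ties pop the lower index first
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.val != b.val) return a.val < b.val;
    return a.idx > b.idx;
  }
};

// Seeded watershed on inverted intensity restricted to per-seed admissible
// sets. A voxel v may join region s iff img[v] > thr[s] and v lies within
// the region's radius box around seed s (|di|,|dj| <= maxr_xy and
// |dk| <= maxr_z voxels). Flooding proceeds in decreasing intensity order
// (Meyer's algorithm); a popped voxel joins the admissible region owning
// its brightest labelled 26-neighbour (tie: lower neighbour index).
// [[Rcpp::export]]
IntegerVector cpp_flood(NumericVector img, IntegerVector dim,
                        IntegerVector seeds, NumericVector thr,
                        double maxr_xy, double maxr_z) {
  Dim3 d(dim);
  int ns = seeds.size();
  IntegerVector labels(d.n(), 0);
  std::vector<int> sk(ns), sj(ns), si(ns);
  double thr_min = R_PosInf;
  for (int s = 0; s < ns; ++s) {
    int v = seeds[s] - 1;
    labels[v] = s + 1;
    d.unpack(v, sk[s], sj[s], si[s]);
    if (thr[s] < thr_min) thr_min = thr[s];
  }
  if (ns == 0) return labels;

  std::priority_queue<QItem, std::vector<QItem>, QLess> pq;
  std::vector<char> inq(d.n(), 0);

  auto push_nbrs = [&](int v) {
    int k, j, i;
    d.unpack(v, k, j, i);
    for (int t = 0; t < 26; ++t) {
      int kk = k + NB[t][0], jj = j + NB[t][1], ii = i + NB[t][2];
      if (!d.inside(kk, jj, ii)) continue;
      int u = d.pack(kk, jj, ii);
      if (labels[u] == 0 && !inq[u] && img[u] > thr_min) {
        inq[u] = 1;
        pq.push(QItem{img[u], u});
      }
    }
  };
  for (int s = 0; s < ns; ++s) push_nbrs(seeds[s] - 1);

  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int v = it.idx;
    inq[v] = 0;
    if (labels[v] != 0) continue;
    int k, j, i;
    d.unpack(v, k, j, i);
    int best_lab = 0, best_idx = -1;
    double best_val = R_NegInf;
    for (int t = 0; t < 26; ++t) {
      int kk = k + NB[t][0], jj = j + NB[t][1], ii = i + NB[t][2];
      if (!d.inside(kk, jj, ii)) continue;
      int u = d.pack(kk, jj, ii);
      int lab = labels[u];
      if (lab == 0) continue;
      int s = lab - 1;
      if (!(img[v] > thr[s])) continue;
      if (std::abs(i - si[s]) > maxr_xy || std::abs(j - sj[s]) > maxr_xy ||
          std::abs(k - sk[s]) > maxr_z)
        continue;
      double nv = img[u];
      if (nv > best_val || (nv == best_val && u < best_idx)) {
        best_val = nv;
        best_idx = u;
        best_lab = lab;
      }
    }
    if (best_lab != 0) {
      labels[v] = best_lab;
      push_nbrs(v);
    }
    // otherwise: left unlabelled; re-pushed if a neighbour is labelled later
  }
  return labels;
}

// Separable lateral (y,x) Gaussian blur, reflective boundaries; sigma in
// pixels. Applied per z-plane, matching the 2D per-slice smoothing of
// the analysis pipeline.
// [[Rcpp::export]]
NumericVector cpp_blur_lateral(NumericVector img, IntegerVector dim,
                               double sigma) {
  Dim3 d(dim);
  int half = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * half + 1);
  double ksum = 0;
  for (int t = -half; t <= half; ++t) {
    kern[t + half] = std::exp(-0.5 * t * t / (sigma * sigma));
    ksum += kern[t + half];
  }
  for (double& k : kern) k /= ksum;
  NumericVector tmp(d.n()), out(d.n());
  // along y
  for (int i = 0; i < d.nx; ++i)
    for (int j = 0; j < d.ny; ++j)
      for (int k = 0; k < d.nz; ++k) {
        double acc = 0;
        for (int t = -half; t <= half; ++t) {
          int jj = j + t;
          if (jj < 0) jj = -jj - 1;
          if (jj >= d.ny) jj = 2 * d.ny - jj - 1;
          acc += kern[t + half] * img[d.pack(k, jj, i)];
        }
        tmp[d.pack(k, j, i)] = acc;
      }
  // along x
  for (int i = 0; i < d.nx; ++i)
    for (int j = 0; j < d.ny; ++j)
      for (int k = 0; k < d.nz; ++k) {
        double acc = 0;
        for (int t = -half; t <= half; ++t) {
          int ii = i + t;
          if (ii < 0) ii = -ii - 1;
          if (ii >= d.nx) ii = 2 * d.nx - ii - 1;
          acc += kern[t + half] * tmp[d.pack(k, j, ii)];
        }
        out[d.pack(k, j, i)] = acc;
      }
  return out;
}
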