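// Low-level grayscale morphology for marker-controlled watershed segmentation.
// All operators use replicate (clamp) border handling and column-major R
// matrices. Connectivity is 4 or 8; the neighbour order below is part of the
// determinism contract shared with the pure-R flooding oracle used in tests:
// up, down, left, right, then the four diagonals.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const int DI[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DJ[8] = {0, 0, -1, 1, -1, 1, -1, 1};

static inline int n_neigh(int connectivity) {
  return connectivity == 8 ? 8 : 4;
}

// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericMatrix cpp_gaussian_blur(NumericMatrix im, double sigma) {
  int nr = im.nrow(), nc = im.ncol();
  if (sigma <= 0) return clone(im);
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * rad + 1);
  double s = 0.0;
  for (int k = -rad; k <= rad; ++k) {
    w[k + rad] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
    s += w[k + rad];
  }
  for (double &x : w) x /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -rad; k <= rad; ++k) {
        int ii = std::min(std::max(i + k, 0), nr - 1);
        acc += w[k + rad] * im(ii, j);
      }
      tmp(i, j) = acc;
    }
  // along columns (horizontal)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -rad; k <= rad; ++k) {
        int jj = std::min(std::max(j + k, 0), nc - 1);
        acc += w[k + rad] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// Morphological gradient (dilation - erosion) with a discrete disk of the
// given radius: offsets with di^2 + dj^2 <= r^2.
// [[Rcpp::export(name = ".cpp_disk_gradient")]]
NumericMatrix cpp_disk_gradient(NumericMatrix im, int radius) {
  int nr = im.nrow(), nc = im.ncol();
  std::vector<int> oi, oj;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      if (di * di + dj * dj <= radius * radius) {
        oi.push_back(di);
        oj.push_back(dj);
      }
  NumericMatrix out(nr, nc);
  int m = (int)oi.size();
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int k = 0; k < m; ++k) {
        int ii = std::min(std::max(i + oi[k], 0), nr - 1);
        int jj = std::min(std::max(j + oj[k], 0), nc - 1);
        double v = im(ii, jj);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      out(i, j) = hi - lo;
    }
  return out;
}

// Grayscale reconstruction by dilation of marker under mask (marker <= mask),
// Vincent's hybrid algorithm (raster, anti-raster, then FIFO propagation).
// [[Rcpp::export(name = ".cpp_reconstruct_dilation")]]
NumericMatrix cpp_reconstruct_dilation(NumericMatrix marker, NumericMatrix mask,
                                       int connectivity) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J = clone(marker);
  int nn = n_neigh(connectivity);

  // predecessors in column-major raster order
  std::vector<int> pi, pj, si, sj;
  for (int k = 0; k < nn; ++k) {
    int di = DI[k], dj = DJ[k];
    if (dj < 0 || (dj == 0 && di < 0)) { pi.push_back(di); pj.push_back(dj); }
    if (dj > 0 || (dj == 0 && di > 0)) { si.push_back(di); sj.push_back(dj); }
  }

  // forward raster
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = J(i, j);
      for (size_t k = 0; k < pi.size(); ++k) {
        int ii = i + pi[k], jj = j + pj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (J(ii, jj) > v) v = J(ii, jj);
      }
      J(i, j) = std::min(v, mask(i, j));
    }
  // backward raster + queue seeding
  std::queue<int> fifo;
  for (int j = nc - 1; j >= 0; --j)
    for (int i = nr - 1; i >= 0; --i) {
      double v = J(i, j);
      for (size_t k = 0; k < si.size(); ++k) {
        int ii = i + si[k], jj = j + sj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (J(ii, jj) > v) v = J(ii, jj);
      }
      J(i, j) = std::min(v, mask(i, j));
      for (size_t k = 0; k < si.size(); ++k) {
        int ii = i + si[k], jj = j + sj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (J(ii, jj) < J(i, j) && J(ii, jj) < mask(ii, jj)) {
          fifo.push(i + j * nr);
          break;
        }
      }
    }
  // propagation
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int i = p % nr, j = p / nr;
    for (int k = 0; k < nn; ++k) {
      int ii = i + DI[k], jj = j + DJ[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (J(ii, jj) < J(i, j) && mask(ii, jj) != J(ii, jj)) {
        J(ii, jj) = std::min(J(i, j), mask(ii, jj));
        fifo.push(ii + jj * nr);
      }
    }
  }
  return J;
}

// Regional minima as a label image: connected plateaus with no strictly lower
// neighbour get labels 1..k in column-major scan order of first encounter.
// [[Rcpp::export(name = ".cpp_regional_minima")]]
IntegerMatrix cpp_regional_minima(NumericMatrix im, int connectivity) {
  int nr = im.nrow(), nc = im.ncol(), n = nr * nc;
  int nn = n_neigh(connectivity);
  std::vector<int> comp(n, -1);
  IntegerMatrix out(nr, nc);
  int next_label = 0;
  std::vector<int> stack, members;
  for (int p = 0; p < n; ++p) {
    if (comp[p] >= 0) continue;
    double v = im[p];
    bool is_min = true;
    stack.clear(); members.clear();
    stack.push_back(p);
    comp[p] = 0; // visited marker (plateau id resolved later)
    while (!stack.empty()) {
      int q = stack.back(); stack.pop_back();
      members.push_back(q);
      int i = q % nr, j = q / nr;
      for (int k = 0; k < nn; ++k) {
        int ii = i + DI[k], jj = j + DJ[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int r = ii + jj * nr;
        double w = im[r];
        if (w < v) is_min = false;
        else if (w == v && comp[r] < 0) {
          comp[r] = 0;
          stack.push_back(r);
        }
      }
    }
    int lab = is_min ? ++next_label : 0;
    for (int q : members) out[q] = lab;
  }
  return out;
}

// Connected-component labelling of a logical/integer mask (non-zero =
// foreground); labels assigned 1..k in column-major scan order.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  int nn = n_neigh(connectivity);
  IntegerMatrix out(nr, nc);
  int next_label = 0;
  std::vector<int> stack;
  for (int p = 0; p < n; ++p) {
    if (mask[p] == 0 || out[p] != 0) continue;
    ++next_label;
    stack.clear();
    stack.push_back(p);
    out[p] = next_label;
    while (!stack.empty()) {
      int q = stack.back(); stack.pop_back();
      int i = q % nr, j = q / nr;
      for (int k = 0; k < nn; ++k) {
        int ii = i + DI[k], jj = j + DJ[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int r = ii + jj * nr;
        if (mask[r] != 0 && out[r] == 0) {
          out[r] = next_label;
          stack.push_back(r);
        }
      }
    }
  }
  return out;
}

// Meyer's marker-controlled watershed with watershed lines.
// Flooding order: priority (gradient value, insertion counter); each pixel is
// queued at most once, at the first moment a finalized labelled neighbour
// exists. On dequeue, the distinct positive labels among finalized neighbours
// decide: one label -> assign; several -> watershed line (0). Marker pixels
// are finalized before flooding; seeding scans pixels in column-major order
// and neighbours in the fixed order above.
struct QEntry {
  double value;
  std::int64_t counter;
  int pixel;
};
struct QCompare {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.counter > b.counter;
  }
};

// [[Rcpp::export(name = ".cpp_watershed_meyer")]]
IntegerMatrix cpp_watershed_meyer(NumericMatrix im, IntegerMatrix markers,
                                  int connectivity) {
  int nr = im.nrow(), nc = im.ncol(), n = nr * nc;
  int nn = n_neigh(connectivity);
  IntegerMatrix label(nr, nc);
  // status: 0 unvisited, 1 queued, 2 finalized
  std::vector<std::uint8_t> status(n, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  std::int64_t counter = 0;

  for (int p = 0; p < n; ++p)
    if (markers[p] > 0) {
      label[p] = markers[p];
      status[p] = 2;
    }
  for (int p = 0; p < n; ++p) {
    if (status[p] != 2) continue;
    int i = p % nr, j = p / nr;
    for (int k = 0; k < nn; ++k) {
      int ii = i + DI[k], jj = j + DJ[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int q = ii + jj * nr;
      if (status[q] == 0) {
        status[q] = 1;
        pq.push({im[q], counter++, q});
      }
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int p = e.pixel;
    if (status[p] == 2) continue;
    int i = p % nr, j = p / nr;
    int lab = 0;
    bool multiple = false;
    for (int k = 0; k < nn; ++k) {
      int ii = i + DI[k], jj = j + DJ[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int q = ii + jj * nr;
      if (status[q] == 2 && label[q] > 0) {
        if (lab == 0) lab = label[q];
        else if (label[q] != lab) multiple = true;
      }
    }
    status[p] = 2;
    label[p] = multiple ? 0 : lab;
    if (!multiple && lab > 0) {
      for (int k = 0; k < nn; ++k) {
        int ii = i + DI[k], jj = j + DJ[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int q = ii + jj * nr;
        if (status[q] == 0) {
          status[q] = 1;
          pq.push({im[q], counter++, q});
        }
      }
    }
  }
  return label;
}
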