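#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling of a logical mask by breadth-first flood
// fill. connectivity is 4 or 8. Labels are 1..k in scan order (column-major,
// as R stores matrices); background stays 0.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Per-component region properties from a label image. Perimeter is the
// exposed-edge count: the number of (pixel, 4-neighbour) pairs where the
// neighbour carries a different label or lies outside the image. Bounding
// boxes are 0-based half-open.
// [[Rcpp::export(name = ".region_props")]]
DataFrame region_props(const IntegerMatrix& lab, int nlab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  std::vector<double> area(nlab, 0.0), perim(nlab, 0.0);
  std::vector<double> sr(nlab, 0.0), sc(nlab, 0.0);
  std::vector<int> r0(nlab, nr), r1(nlab, -1), c0(nlab, nc), c1(nlab, -1);
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int v = lab(r, c);
      if (v == 0) continue;
      int i = v - 1;
      area[i] += 1.0;
      sr[i] += r;
      sc[i] += c;
      if (r < r0[i]) r0[i] = r;
      if (r > r1[i]) r1[i] = r;
      if (c < c0[i]) c0[i] = c;
      if (c > c1[i]) c1[i] = c;
      for (int k = 0; k < 4; ++k) {
        int r2 = r + dr[k], c2 = c + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || lab(r2, c2) != v)
          perim[i] += 1.0;
      }
    }
  }
  NumericVector A(nlab), P(nlab), CR(nlab), CC(nlab);
  IntegerVector R0(nlab), C0(nlab), R1(nlab), C1(nlab), L(nlab);
  for (int i = 0; i < nlab; ++i) {
    L[i] = i + 1;
    A[i] = area[i];
    P[i] = perim[i];
    CR[i] = sr[i] / area[i];
    CC[i] = sc[i] / area[i];
    R0[i] = r0[i];
    C0[i] = c0[i];
    R1[i] = r1[i] + 1;
    C1[i] = c1[i] + 1;
  }
  return DataFrame::create(
    _["label"] = L, _["area"] = A, _["perimeter"] = P,
    _["centroid_r"] = CR, _["centroid_c"] = CC,
    _["r0"] = R0, _["c0"] = C0, _["r1"] = R1, _["c1"] = C1);
}

// Exposed-edge perimeter of the whole foreground of a mask.
// [[Rcpp::export(name = ".mask_perimeter")]]
double mask_perimeter(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  double p = 0.0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (int k = 0; k < 4; ++k) {
        int r2 = r + dr[k], c2 = c + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || !mask(r2, c2))
          p += 1.0;
      }
    }
  return p;
}

static inline int reflect_index(int i, int n) {
  // symmetric reflection with edge duplication: for n=4, -1 -> 0, -2 -> 1,
  // n -> n-1, n+1 -> n-2
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Dense 2-D correlation with reflected (symmetric) borders; kernel given as
// a (2a+1) x (2b+1) matrix.
// [[Rcpp::export(name = ".conv2_reflect")]]
NumericMatrix conv2_reflect(const NumericMatrix& img,
                            const NumericMatrix& kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kernel.nrow(), kc = kernel.ncol();
  if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
  const int a = kr / 2, b = kc / 2;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int dc = -b; dc <= b; ++dc) {
        int cc = reflect_index(c + dc, nc);
        for (int dr = -a; dr <= a; ++dr) {
          int rr = reflect_index(r + dr, nr);
          s += img(rr, cc) * kernel(dr + a, dc + b);
        }
      }
      out(r, c) = s;
    }
  }
  return out;
}

// Fused per-threshold measurement block used by the feature extractor:
// for each tau, binarize (pixel < min + tau*(max-min)), label components,
// filter by minimum clump area, and compute the 26 per-threshold
// measurements (19 clump statistics over filtered components + 7
// whole-foreground measures over the unfiltered mask). Semantics mirror
// binarizeDark / labelClumps / clumpMeasurements / the bin measures
// exactly; the R compositional path remains the reference in tests.
// [[Rcpp::export(name = ".per_tau_block")]]
NumericMatrix per_tau_block(const NumericMatrix& img,
                            const NumericVector& taus, int connectivity,
                            int minArea) {
  const int nr = img.nrow(), nc = img.ncol();
  const int npx = nr * nc;
  const int nt = taus.size();
  NumericMatrix out(nt, 26);
  double lo = img[0], hi = img[0];
  for (int i = 0; i < npx; ++i) {
    if (img[i] < lo) lo = img[i];
    if (img[i] > hi) hi = img[i];
  }
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  std::vector<int> lab(npx), stack;
  std::vector<char> mask(npx);

  for (int t = 0; t < nt; ++t) {
    double thr = lo + taus[t] * (hi - lo);
    int fg = 0;
    int mr0 = nr, mr1 = -1, mc0 = nc, mc1 = -1;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        bool m = (hi > lo) && (img(r, c) < thr);
        mask[r + c * nr] = m;
        if (m) {
          ++fg;
          if (r < mr0) mr0 = r;
          if (r > mr1) mr1 = r;
          if (c < mc0) mc0 = c;
          if (c > mc1) mc1 = c;
        }
      }
    // whole-foreground measures
    double binPer = 0.0;
    if (fg > 0) {
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          if (!mask[r + c * nr]) continue;
          for (int k = 0; k < 4; ++k) {
            int r2 = r + dr8[k], c2 = c + dc8[k];
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc ||
                !mask[r2 + c2 * nr])
              binPer += 1.0;
          }
        }
    }
    // connected components + per-clump stats
    std::fill(lab.begin(), lab.end(), 0);
    std::vector<double> areas, perims, ncs, extents, aspects, eqds;
    int next = 0;
    for (int c0 = 0; c0 < nc; ++c0)
      for (int r0 = 0; r0 < nr; ++r0) {
        int idx0 = r0 + c0 * nr;
        if (!mask[idx0] || lab[idx0] != 0) continue;
        ++next;
        lab[idx0] = next;
        stack.clear();
        stack.push_back(idx0);
        double area = 0.0, per = 0.0;
        int br0 = nr, br1 = -1, bc0 = nc, bc1 = -1;
        while (!stack.empty()) {
          int idx = stack.back();
          stack.pop_back();
          int rr = idx % nr, cc = idx / nr;
          area += 1.0;
          if (rr < br0) br0 = rr;
          if (rr > br1) br1 = rr;
          if (cc < bc0) bc0 = cc;
          if (cc > bc1) bc1 = cc;
          for (int k = 0; k < 4; ++k) {
            int r2 = rr + dr8[k], c2 = cc + dc8[k];
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc ||
                !mask[r2 + c2 * nr])
              per += 1.0;
          }
          for (int k = 0; k < nnb; ++k) {
            int r2 = rr + dr8[k], c2 = cc + dc8[k];
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            int idx2 = r2 + c2 * nr;
            if (mask[idx2] && lab[idx2] == 0) {
              lab[idx2] = next;
              stack.push_back(idx2);
            }
          }
        }
        if (area >= minArea) {
          double bh = br1 - br0 + 1.0, bw = bc1 - bc0 + 1.0;
          double nc_ = 1.0 - 4.0 * M_PI * area / (per * per);
          if (nc_ < 0) nc_ = 0;
          areas.push_back(area);
          perims.push_back(per);
          ncs.push_back(nc_);
          eqds.push_back(2.0 * std::sqrt(area / M_PI));
          extents.push_back(area / (bh * bw));
          aspects.push_back(std::max(bh, bw) / std::min(bh, bw));
        }
      }
    auto meanv = [](const std::vector<double>& v) {
      double s = 0;
      for (double x : v) s += x;
      return s / v.size();
    };
    auto sdv = [&](const std::vector<double>& v) {
      if (v.size() < 2) return 0.0;
      double m = meanv(v), s = 0;
      for (double x : v) s += (x - m) * (x - m);
      return std::sqrt(s / (v.size() - 1));
    };
    auto minv = [](const std::vector<double>& v) {
      double m = v[0];
      for (double x : v) if (x < m) m = x;
      return m;
    };
    auto maxv = [](const std::vector<double>& v) {
      double m = v[0];
      for (double x : v) if (x > m) m = x;
      return m;
    };
    int k = (int)areas.size();
    double tot = 0;
    for (double a : areas) tot += a;
    if (k > 0) {
      out(t, 0) = k;
      out(t, 1) = 1000.0 * k / npx;
      out(t, 2) = tot;
      out(t, 3) = tot / npx;
      out(t, 4) = meanv(areas);
      out(t, 5) = sdv(areas);
      out(t, 6) = minv(areas);
      out(t, 7) = maxv(areas);
      out(t, 8) = meanv(eqds);
      out(t, 9) = maxv(eqds);
      out(t, 10) = meanv(perims);
      out(t, 11) = sdv(perims);
      out(t, 12) = maxv(perims);
      out(t, 13) = meanv(ncs);
      out(t, 14) = sdv(ncs);
      out(t, 15) = minv(ncs);
      out(t, 16) = maxv(ncs);
      out(t, 17) = meanv(extents);
      out(t, 18) = meanv(aspects);
    }
    if (fg > 0) {
      double bh = mr1 - mr0 + 1.0, bw = mc1 - mc0 + 1.0;
      out(t, 19) = fg;
      out(t, 20) = (double)fg / npx;
      out(t, 21) = binPer;
      out(t, 22) = 4.0 * M_PI * fg / (binPer * binPer);
      out(t, 23) = fg / (bh * bw);
      out(t, 24) = bh / nr;
      out(t, 25) = bw / nc;
    }
  }
  return out;
}
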