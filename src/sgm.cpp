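#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Census descriptors as uint64 bit fields (window^2 - 1 <= 48 bits for
// windows up to 7x7). Border pixels use clamped (replicated) neighbours.
static std::vector<uint64_t> census64(const NumericMatrix& im, int win) {
  const int nr = im.nrow(), nc = im.ncol(), h = win / 2;
  std::vector<uint64_t> out((size_t)nr * nc, 0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double ctr = im(r, c);
      uint64_t bits = 0;
      for (int dc = -h; dc <= h; ++dc) {
        for (int dr = -h; dr <= h; ++dr) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          rr = rr < 0 ? 0 : (rr >= nr ? nr - 1 : rr);
          cc = cc < 0 ? 0 : (cc >= nc ? nc - 1 : cc);
          bits = (bits << 1) | (im(rr, cc) < ctr ? 1u : 0u);
        }
      }
      out[(size_t)c * nr + r] = bits;
    }
  }
  return out;
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int n = 0; while (x) { x &= x - 1; ++n; } return n;
#endif
}

// Cost volume, reference image first. refSign = +1: reference is the left
// view and cost(r,c,d) compares ref(r,c) with target(r,c-d); refSign = -1:
// reference is the right view and the target column is c+d. Out-of-bounds
// target columns carry the sentinel cost.
// [[Rcpp::export(name = ".costVolumeCensusCpp")]]
NumericVector costVolumeCensusCpp(NumericMatrix ref, NumericMatrix tgt,
                                  int dMin, int dMax, int win, int refSign,
                                  double sentinel) {
  const int nr = ref.nrow(), nc = ref.ncol(), nd = dMax - dMin + 1;
  std::vector<uint64_t> cr = census64(ref, win), ct = census64(tgt, win);
  NumericVector vol((R_xlen_t)nr * nc * nd);
  for (int di = 0; di < nd; ++di) {
    const int d = dMin + di;
    for (int c = 0; c < nc; ++c) {
      const int c2 = c - refSign * d;
      double* col = &vol[(R_xlen_t)di * nr * nc + (R_xlen_t)c * nr];
      if (c2 < 0 || c2 >= nc) {
        for (int r = 0; r < nr; ++r) col[r] = sentinel;
      } else {
        const uint64_t* a = &cr[(size_t)c * nr];
        const uint64_t* b = &ct[(size_t)c2 * nr];
        for (int r = 0; r < nr; ++r) col[r] = popcount64(a[r] ^ b[r]);
      }
    }
  }
  vol.attr("dim") = IntegerVector::create(nr, nc, nd);
  return vol;
}

// Window-mean absolute-difference cost, scaled to [0, 100] for images in
// [0, 1]; separable box average with replicated borders.
// [[Rcpp::export(name = ".costVolumeSadCpp")]]
NumericVector costVolumeSadCpp(NumericMatrix ref, NumericMatrix tgt,
                               int dMin, int dMax, int win, int refSign,
                               double sentinel) {
  const int nr = ref.nrow(), nc = ref.ncol(), nd = dMax - dMin + 1;
  const int h = win / 2;
  NumericVector vol((R_xlen_t)nr * nc * nd);
  std::vector<double> ad((size_t)nr * nc), tmp((size_t)nr * nc);
  for (int di = 0; di < nd; ++di) {
    const int d = dMin + di;
    for (int c = 0; c < nc; ++c) {
      const int c2 = c - refSign * d;
      double* a = &ad[(size_t)c * nr];
      if (c2 < 0 || c2 >= nc) {
        for (int r = 0; r < nr; ++r) a[r] = NA_REAL;  // filled later
      } else {
        for (int r = 0; r < nr; ++r) a[r] = std::fabs(ref(r, c) - tgt(r, c2));
      }
    }
    // horizontal box average over in-bounds columns (clamped)
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double s = 0; int n = 0;
        for (int dc = -h; dc <= h; ++dc) {
          int cc = c + dc;
          cc = cc < 0 ? 0 : (cc >= nc ? nc - 1 : cc);
          double v = ad[(size_t)cc * nr + r];
          if (!ISNAN(v)) { s += v; ++n; }
        }
        tmp[(size_t)c * nr + r] = (n > 0) ? s / n : NA_REAL;
      }
    }
    // vertical box average (clamped)
    for (int c = 0; c < nc; ++c) {
      const bool oob = ISNAN(ad[(size_t)c * nr]);
      double* col = &vol[(R_xlen_t)di * nr * nc + (R_xlen_t)c * nr];
      for (int r = 0; r < nr; ++r) {
        if (oob) { col[r] = sentinel; continue; }
        double s = 0; int n = 0;
        for (int dr = -h; dr <= h; ++dr) {
          int rr = r + dr;
          rr = rr < 0 ? 0 : (rr >= nr ? nr - 1 : rr);
          double v = tmp[(size_t)c * nr + rr];
          if (!ISNAN(v)) { s += v; ++n; }
        }
        col[r] = 100.0 * s / n;
      }
    }
  }
  vol.attr("dim") = IntegerVector::create(nr, nc, nd);
  return vol;
}

// Semi-global aggregation: sum over path directions of
//   L_p(x,d) = C(x,d) + min(L_p(x-p,d), L_p(x-p,d+-1)+P1, min_k L_p(x-p,k)+P2)
//              - min_k L_p(x-p,k)
// Directions given as an npaths x 2 matrix of (dRow, dCol) steps.
// [[Rcpp::export(name = ".sgmAggregateCpp")]]
NumericVector sgmAggregateCpp(NumericVector vol, IntegerMatrix dirs,
                              double P1, double P2) {
  IntegerVector dim = vol.attr("dim");
  const int nr = dim[0], nc = dim[1], nd = dim[2];
  const R_xlen_t npx = (R_xlen_t)nr * nc;
  NumericVector out((R_xlen_t)npx * nd);
  std::vector<double> L((size_t)npx * nd), prev(nd), cur(nd);
  for (int p = 0; p < dirs.nrow(); ++p) {
    const int drr = dirs(p, 0), dcc = dirs(p, 1);
    // traversal order so that (r-drr, c-dcc) is visited first
    const int r0 = drr >= 0 ? 0 : nr - 1, rstep = drr >= 0 ? 1 : -1;
    const int c0 = dcc >= 0 ? 0 : nc - 1, cstep = dcc >= 0 ? 1 : -1;
    for (int ci = 0, c = c0; ci < nc; ++ci, c += cstep) {
      for (int ri = 0, r = r0; ri < nr; ++ri, r += rstep) {
        const R_xlen_t px = (R_xlen_t)c * nr + r;
        const int rp = r - drr, cp = c - dcc;
        const bool has = rp >= 0 && rp < nr && cp >= 0 && cp < nc;
        if (has) {
          const R_xlen_t pp = (R_xlen_t)cp * nr + rp;
          double mn = R_PosInf;
          for (int d = 0; d < nd; ++d) {
            prev[d] = L[(size_t)d * npx + pp];
            if (prev[d] < mn) mn = prev[d];
          }
          for (int d = 0; d < nd; ++d) {
            double best = prev[d];
            if (d > 0 && prev[d - 1] + P1 < best) best = prev[d - 1] + P1;
            if (d < nd - 1 && prev[d + 1] + P1 < best) best = prev[d + 1] + P1;
            if (mn + P2 < best) best = mn + P2;
            cur[d] = vol[(size_t)d * npx + px] + best - mn;
          }
        } else {
          for (int d = 0; d < nd; ++d) cur[d] = vol[(size_t)d * npx + px];
        }
        for (int d = 0; d < nd; ++d) L[(size_t)d * npx + px] = cur[d];
      }
    }
    for (size_t i = 0; i < L.size(); ++i) out[i] += L[i];
  }
  out.attr("dim") = dim;
  return out;
}
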