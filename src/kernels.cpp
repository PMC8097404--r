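#include <Rcpp.h>
using namespace Rcpp;

// Orthorhombic minimum-image squared distance.
static inline double mi_d2(double dx, double dy, double dz,
                           double lx, double ly, double lz) {
  dx -= lx * std::round(dx / lx);
  dy -= ly * std::round(dy / ly);
  dz -= lz * std::round(dz / lz);
  return dx * dx + dy * dy + dz * dz;
}

static inline double crd(const NumericVector &c, int natoms, int a, int d, int f) {
  return c[a + natoms * (d + 3 * f)];
}

// Per-frame minimum-image distances for a list of atom pairs.
// coords: array (natoms, 3, nframes); box: nframes x 3; i/j: 0-based atoms.
// [[Rcpp::export]]
NumericMatrix cpp_dist_pairs(NumericVector coords, NumericMatrix box,
                             IntegerVector i_idx, IntegerVector j_idx) {
  IntegerVector dim = coords.attr("dim");
  int natoms = dim[0], nframes = dim[2];
  int npairs = i_idx.size();
  NumericMatrix out(nframes, npairs);
  for (int f = 0; f < nframes; ++f) {
    double lx = box(f, 0), ly = box(f, 1), lz = box(f, 2);
    for (int p = 0; p < npairs; ++p) {
      int a = i_idx[p], b = j_idx[p];
      double d2 = mi_d2(crd(coords, natoms, a, 0, f) - crd(coords, natoms, b, 0, f),
                        crd(coords, natoms, a, 1, f) - crd(coords, natoms, b, 1, f),
                        crd(coords, natoms, a, 2, f) - crd(coords, natoms, b, 2, f),
                        lx, ly, lz);
      out(f, p) = std::sqrt(d2);
    }
  }
  return out;
}

// Per-frame minimum distance between two atom sets (0-based indices).
// [[Rcpp::export]]
NumericVector cpp_min_dist_series(NumericVector coords, NumericMatrix box,
                                  IntegerVector setA, IntegerVector setB) {
  IntegerVector dim = coords.attr("dim");
  int natoms = dim[0], nframes = dim[2];
  NumericVector out(nframes);
  for (int f = 0; f < nframes; ++f) {
    double lx = box(f, 0), ly = box(f, 1), lz = box(f, 2);
    double best = R_PosInf;
    for (int i = 0; i < setA.size(); ++i) {
      int a = setA[i];
      double ax = crd(coords, natoms, a, 0, f);
      double ay = crd(coords, natoms, a, 1, f);
      double az = crd(coords, natoms, a, 2, f);
      for (int j = 0; j < setB.size(); ++j) {
        int b = setB[j];
        double d2 = mi_d2(ax - crd(coords, natoms, b, 0, f),
                          ay - crd(coords, natoms, b, 1, f),
                          az - crd(coords, natoms, b, 2, f), lx, ly, lz);
        if (d2 < best) best = d2;
      }
    }
    out[f] = std::sqrt(best);
  }
  return out;
}

// Boolean presence tensor (nframes x nGroupsA x nGroupsB): any atom of group a
// within cutoff of any atom of group b, under minimum image.
// atomsA/groupA: 0-based atom index and 0-based group id per lipid atom;
// atomsB/groupB: likewise for residue atoms.
// [[Rcpp::export]]
LogicalVector cpp_contact_tensor(NumericVector coords, NumericMatrix box,
                                 IntegerVector atomsA, IntegerVector groupA, int nA,
                                 IntegerVector atomsB, IntegerVector groupB, int nB,
                                 double cutoff) {
  IntegerVector dim = coords.attr("dim");
  int natoms = dim[0], nframes = dim[2];
  double c2 = cutoff * cutoff;
  LogicalVector out(static_cast<R_xlen_t>(nframes) * nA * nB, false);
  for (int f = 0; f < nframes; ++f) {
    double lx = box(f, 0), ly = box(f, 1), lz = box(f, 2);
    for (int i = 0; i < atomsA.size(); ++i) {
      int a = atomsA[i], ga = groupA[i];
      double ax = crd(coords, natoms, a, 0, f);
      double ay = crd(coords, natoms, a, 1, f);
      double az = crd(coords, natoms, a, 2, f);
      for (int j = 0; j < atomsB.size(); ++j) {
        int b = atomsB[j], gb = groupB[j];
        R_xlen_t k = f + static_cast<R_xlen_t>(nframes) * (ga + static_cast<R_xlen_t>(nA) * gb);
        if (out[k]) continue;
        double d2 = mi_d2(ax - crd(coords, natoms, b, 0, f),
                          ay - crd(coords, natoms, b, 1, f),
                          az - crd(coords, natoms, b, 2, f), lx, ly, lz);
        if (d2 <= c2) out[k] = true;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nframes, nA, nB);
  return out;
}

// Discrete-time lipid walk with Markov on/off binding at planted anchors.
// head0: nlip x 2 initial lateral positions; boxxy: (Lx, Ly); eligible: may a
// lipid bind at all; anchorXY / pinXY: nanch x 2; pOn/kOff: nlip x nanch
// per-frame probabilities; initBound: 0 = free, else 1-based anchor index.
// On release a lipid is emitted at releaseRadius from the anchor at a uniform
// random angle (an unbinding event ends the site visit; emitting inside the
// capture zone would let high-affinity species re-bind in bursts and decouple
// occupancy from the planted on/off rates).
// Uses R's RNG (reproducible under set.seed). Returns per-frame head x, y and
// bound-anchor index (0 = free).
// [[Rcpp::export]]
List cpp_simulate_walk(int nframes, NumericMatrix head0, NumericVector boxxy,
                       LogicalVector eligible, double sigma,
                       NumericMatrix anchorXY, NumericMatrix pinXY,
                       double captureRadius, double releaseRadius,
                       NumericMatrix pOn, NumericMatrix kOff,
                       IntegerVector initBound) {
  int nlip = head0.nrow(), nanch = anchorXY.nrow();
  double lx = boxxy[0], ly = boxxy[1];
  double cap2 = captureRadius * captureRadius;
  NumericMatrix hx(nframes, nlip), hy(nframes, nlip);
  IntegerMatrix bound(nframes, nlip);
  std::vector<double> x(nlip), y(nlip);
  std::vector<int> bnd(nlip);
  for (int l = 0; l < nlip; ++l) {
    bnd[l] = initBound[l];
    if (bnd[l] > 0) {
      x[l] = pinXY(bnd[l] - 1, 0);
      y[l] = pinXY(bnd[l] - 1, 1);
    } else {
      x[l] = head0(l, 0);
      y[l] = head0(l, 1);
    }
    hx(0, l) = x[l]; hy(0, l) = y[l]; bound(0, l) = bnd[l];
  }
  for (int f = 1; f < nframes; ++f) {
    for (int l = 0; l < nlip; ++l) {
      if (bnd[l] > 0) {
        if (unif_rand() < kOff(l, bnd[l] - 1)) {
          int a = bnd[l] - 1;
          double phi = 2.0 * M_PI * unif_rand();
          x[l] = anchorXY(a, 0) + releaseRadius * std::cos(phi);
          y[l] = anchorXY(a, 1) + releaseRadius * std::sin(phi);
          x[l] -= lx * std::floor(x[l] / lx);
          y[l] -= ly * std::floor(y[l] / ly);
          bnd[l] = 0;
        }
      } else {
        x[l] += norm_rand() * sigma;
        y[l] += norm_rand() * sigma;
        x[l] -= lx * std::floor(x[l] / lx);
        y[l] -= ly * std::floor(y[l] / ly);
        if (eligible[l]) {
          int best = -1; double bestd2 = cap2;
          for (int a = 0; a < nanch; ++a) {
            double dx = x[l] - anchorXY(a, 0), dy = y[l] - anchorXY(a, 1);
            dx -= lx * std::round(dx / lx);
            dy -= ly * std::round(dy / ly);
            double d2 = dx * dx + dy * dy;
            if (d2 <= bestd2) { bestd2 = d2; best = a; }
          }
          if (best >= 0 && unif_rand() < pOn(l, best)) {
            bnd[l] = best + 1;
            x[l] = pinXY(best, 0);
            y[l] = pinXY(best, 1);
          }
        }
      }
      hx(f, l) = x[l]; hy(f, l) = y[l]; bound(f, l) = bnd[l];
    }
  }
  return List::create(_["x"] = hx, _["y"] = hy, _["bound"] = bound);
}
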