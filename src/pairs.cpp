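#include <Rcpp.h>
using namespace Rcpp;

// 12-6 Lennard-Jones sum over ligand x receptor pairs within the cutoff.
// sig2 holds the squared pair sigma (minimum at radius contact when derived
// from van der Waals radii). Coincident atoms give +Inf (singularity).
// [[Rcpp::export]]
double cpp_lj_energy(const NumericMatrix& lx, const NumericMatrix& rx,
                     const NumericMatrix& sig2, double cutoff2,
                     double eps4) {
  const int n = lx.nrow(), m = rx.nrow();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = lx(i, 0), yi = lx(i, 1), zi = lx(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = xi - rx(j, 0), dy = yi - rx(j, 1),
                   dz = zi - rx(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= cutoff2) continue;
      if (d2 < 1e-20) return R_PosInf;
      const double s2 = sig2(i, j) / d2;
      const double s6 = s2 * s2 * s2;
      e += eps4 * (s6 * s6 - s6);
    }
  }
  return e;
}

// number of pairs with squared distance below the pairwise threshold thr2
// [[Rcpp::export]]
int cpp_pair_count(const NumericMatrix& lx, const NumericMatrix& rx,
                   const NumericMatrix& thr2) {
  const int n = lx.nrow(), m = rx.nrow();
  int cnt = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = lx(i, 0), yi = lx(i, 1), zi = lx(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = xi - rx(j, 0), dy = yi - rx(j, 1),
                   dz = zi - rx(j, 2);
      if (dx * dx + dy * dy + dz * dz < thr2(i, j)) ++cnt;
    }
  }
  return cnt;
}

// minimum pair count over a grid of rigid placements: rotated ligand bead
// sets (one block per orientation, n beads each, pre-centred) are swept
// over the translation grid; early exit at zero
// [[Rcpp::export]]
int cpp_min_clash_grid(const NumericMatrix& blocks, int n_beads,
                       const NumericMatrix& trans,
                       const NumericMatrix& rx,
                       const NumericMatrix& thr2) {
  const int n_or = blocks.nrow() / n_beads;
  const int n_tr = trans.nrow();
  const int m = rx.nrow();
  int best = -1;
  for (int o = 0; o < n_or; ++o) {
    for (int t = 0; t < n_tr; ++t) {
      int cnt = 0;
      for (int b = 0; b < n_beads; ++b) {
        const int row = o * n_beads + b;
        const double xi = blocks(row, 0) + trans(t, 0);
        const double yi = blocks(row, 1) + trans(t, 1);
        const double zi = blocks(row, 2) + trans(t, 2);
        for (int j = 0; j < m; ++j) {
          const double dx = xi - rx(j, 0), dy = yi - rx(j, 1),
                       dz = zi - rx(j, 2);
          if (dx * dx + dy * dy + dz * dz < thr2(b, j)) ++cnt;
        }
      }
      if (best < 0 || cnt < best) {
        best = cnt;
        if (best == 0) return 0;
      }
    }
  }
  return best;
}
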