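#include <Rcpp.h>
using namespace Rcpp;

// Periodic 4-neighbor binding energy of one site: sum of pairwise
// interaction magnitudes between the site's class and its von Neumann
// neighbors.  Grid holds 0-based class codes.
static inline double site_binding(const IntegerMatrix &g, const NumericMatrix &ff,
                                  int r, int c, int H, int W) {
  const int k  = g(r, c);
  const int up = (r == 0) ? H - 1 : r - 1;
  const int dn = (r == H - 1) ? 0 : r + 1;
  const int lf = (c == 0) ? W - 1 : c - 1;
  const int rt = (c == W - 1) ? 0 : c + 1;
  return ff(k, g(up, c)) + ff(k, g(dn, c)) + ff(k, g(r, lf)) + ff(k, g(r, rt));
}

// Run the stochastic swap dynamics.
//
// grid        0-based class codes (modified copy returned)
// ff          KxK symmetric interaction matrix (J)
// iterations  number of sweeps; one sweep visits every site once in a
//             fresh random permutation
// theta       swap-rule energy scale (J)
// bfloor      reference binding subtracted in the kinetic rule (J)
// rule        0 = kinetic arrest: p = exp(-(B_cur - bfloor)/theta)
//             1 = Metropolis:     p = min(1, exp((B_swap - B_cur)/theta))
//             B_cur/B_swap sum the two participating sites' 4-neighbor
//             bindings (shared bond counted in both, consistently).
// count_same  whether an accepted same-class exchange marks mobility
// record_rmsd store per-sweep RMSD of the binding-energy field vs start
//
// Uses R's RNG (seed with set.seed() before calling).
// [[Rcpp::export]]
List run_sim_cpp(IntegerMatrix grid_in, NumericMatrix ff, int iterations,
                 double theta, double bfloor, int rule, bool count_same,
                 bool record_rmsd) {
  const int H = grid_in.nrow(), W = grid_in.ncol(), N = H * W;
  IntegerMatrix grid = clone(grid_in);
  IntegerMatrix acc(H, W);            // iterations in which the site moved
  NumericVector rmsd(record_rmsd ? iterations : 0);
  std::vector<double> b0;             // binding field at start
  std::vector<int> perm(N);
  std::vector<char> moved(N);
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  if (record_rmsd) {
    b0.resize(N);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        b0[r + (size_t)c * H] = site_binding(grid, ff, r, c, H, W);
  }
  for (int i = 0; i < N; ++i) perm[i] = i;

  for (int it = 0; it < iterations; ++it) {
    // RMSD of the binding field *before* this sweep relative to the
    // initial configuration; entry 1 is therefore exactly 0.
    if (record_rmsd) {
      double ss = 0.0;
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          double d = site_binding(grid, ff, r, c, H, W) - b0[r + (size_t)c * H];
          ss += d * d;
        }
      rmsd[it] = std::sqrt(ss / N);
    }

    // Fisher-Yates shuffle so every site gets one active proposal.
    for (int i = N - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    std::fill(moved.begin(), moved.end(), 0);

    for (int i = 0; i < N; ++i) {
      const int s = perm[i];
      const int r = s % H, c = s / H;
      int d = (int)(unif_rand() * 4);
      if (d > 3) d = 3;
      int r2 = r + dr[d], c2 = c + dc[d];
      if (r2 < 0) r2 = H - 1; else if (r2 >= H) r2 = 0;
      if (c2 < 0) c2 = W - 1; else if (c2 >= W) c2 = 0;

      const int ka = grid(r, c), kb = grid(r2, c2);
      const double bcur = site_binding(grid, ff, r, c, H, W) +
                          site_binding(grid, ff, r2, c2, H, W);
      double p;
      if (rule == 0) {
        p = std::exp(-(bcur - bfloor) / theta);
      } else {
        grid(r, c) = kb; grid(r2, c2) = ka;
        const double bswap = site_binding(grid, ff, r, c, H, W) +
                             site_binding(grid, ff, r2, c2, H, W);
        grid(r, c) = ka; grid(r2, c2) = kb;
        const double x = (bswap - bcur) / theta;
        p = (x >= 0.0) ? 1.0 : std::exp(x);
      }
      if (unif_rand() < p) {
        grid(r, c) = kb;
        grid(r2, c2) = ka;
        if (ka != kb || count_same) {
          moved[r + (size_t)c * H] = 1;
          moved[r2 + (size_t)c2 * H] = 1;
        }
      }
    }
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        if (moved[r + (size_t)c * H]) acc(r, c) += 1;
  }

  return List::create(_["grid"] = grid, _["accepted"] = acc, _["rmsd"] = rmsd);
}

// Binding-energy field (4-neighbor sums, periodic wrap) for a whole grid.
// [[Rcpp::export]]
NumericMatrix binding_field_cpp(IntegerMatrix grid, NumericMatrix ff) {
  const int H = grid.nrow(), W = grid.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = site_binding(grid, ff, r, c, H, W);
  return out;
}

// Connected components of a logical mask, 4-connectivity with periodic
// wrap.  Returns 0 for background and 1..n component labels.
// [[Rcpp::export]]
IntegerMatrix label_mask_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int s = stack.back(); stack.pop_back();
        int rr = s % H, cc = s / H;
        for (int d = 0; d < 4; ++d) {
          int r2 = rr + dr[d], c2 = cc + dc[d];
          if (r2 < 0) r2 = H - 1; else if (r2 >= H) r2 = 0;
          if (c2 < 0) c2 = W - 1; else if (c2 >= W) c2 = 0;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * H);
          }
        }
      }
    }
  return lab;
}
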