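#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Bases are encoded A=0, C=1, G=2, U=3 on the R side.
// Pair types: 0 = not allowed, 1=AU, 2=UA, 3=CG, 4=GC, 5=GU, 6=UG.

namespace {

struct FoldModel {
  double stack[7][7];      // [outer pair type][inner pair type]
  double hairpin_a, hairpin_b;
  double interior_a, interior_b;
  double ml_a, ml_b, ml_c; // multiloop: a + b*(branches incl. closing) + c*unpaired
  double beta;             // 1/RT
  int min_hairpin;
  int max_loop;            // interior/bulge loops larger than this are disallowed
  int ptab[4][4];          // pair type lookup
};

FoldModel build_model(const List& model) {
  FoldModel fm;
  NumericMatrix st = model["stack"];
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b)
      fm.stack[a][b] = st(a - 1, b - 1);
  NumericVector hp = model["hairpin"], in = model["interior"], ml = model["multiloop"];
  fm.hairpin_a = hp[0]; fm.hairpin_b = hp[1];
  fm.interior_a = in[0]; fm.interior_b = in[1];
  fm.ml_a = ml[0]; fm.ml_b = ml[1]; fm.ml_c = ml[2];
  double temp = as<double>(model["temperature"]);
  fm.beta = 1.0 / (0.0019872 * temp);
  fm.min_hairpin = as<int>(model["min_hairpin"]);
  fm.max_loop = as<int>(model["max_loop"]);
  IntegerMatrix pt = model["pair_table"];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      fm.ptab[a][b] = pt(a, b);
  return fm;
}

inline double bw(double e, double beta) { return std::exp(-beta * e); }

} // namespace

// Equilibrium base-pair probabilities by the inside-outside (McCaskill)
// algorithm over pseudoknot-free structures under a loop-decomposed
// nearest-neighbor model. O(n^3) time, O(n^2) space.
// [[Rcpp::export(name = ".mccaskill_bppm_cpp")]]
NumericMatrix mccaskill_bppm_cpp(IntegerVector seq, List model) {
  const int n = seq.size();
  FoldModel fm = build_model(model);
  NumericMatrix P(n, n);
  if (n < fm.min_hairpin + 2) return P;

  const int N = n + 2;
  std::vector<double> b(N * N, 0.0), m(N * N, 0.0), m1(N * N, 0.0);
  std::vector<double> bhat(N * N, 0.0), H1(N * N, 0.0), H2(N * N, 0.0);
  std::vector<double> f(N, 0.0), g(N + 1, 0.0);
  std::vector<double> emcpow(N, 1.0);
  const double emb = bw(fm.ml_b, fm.beta), emc = bw(fm.ml_c, fm.beta);
  for (int k = 1; k < N; ++k) emcpow[k] = emcpow[k - 1] * emc;
  const double eml_close = bw(fm.ml_a + fm.ml_b, fm.beta);      // closing pair's a + b
  const double eml_branch = bw(fm.ml_a + 2.0 * fm.ml_b, fm.beta); // closing + this branch

  auto IDX = [N](int i, int j) { return i * N + j; };
  auto ptype = [&](int i, int j) { return fm.ptab[seq[i - 1]][seq[j - 1]]; };

  // precomputed Boltzmann factors (exp() is the hot cost otherwise)
  double estack[7][7];
  for (int a = 1; a <= 6; ++a)
    for (int c = 1; c <= 6; ++c)
      estack[a][c] = bw(fm.stack[a][c], fm.beta);
  std::vector<double> eint(fm.max_loop + 1), ehp(n + 1);
  for (int s2 = 0; s2 <= fm.max_loop; ++s2)
    eint[s2] = bw(fm.interior_a + fm.interior_b * s2, fm.beta);
  for (int l = 0; l <= n; ++l)
    ehp[l] = bw(fm.hairpin_a + fm.hairpin_b * l, fm.beta);

  // ---- inside ----
  for (int d = fm.min_hairpin + 1; d <= n - 1; ++d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      int pt = ptype(i, j);
      if (pt > 0) {
        double v = ehp[j - i - 1];
        // single inner branch: stack or interior/bulge (loop size capped)
        int kmax = std::min(j - 1, i + 1 + fm.max_loop);
        for (int k = i + 1; k <= kmax; ++k) {
          int rem = fm.max_loop - (k - i - 1);
          int lmin = std::max(k + fm.min_hairpin + 1, j - 1 - rem);
          for (int l = lmin; l <= j - 1; ++l) {
            double bkl = b[IDX(k, l)];
            if (bkl <= 0.0) continue;
            int pt2 = ptype(k, l);
            double w;
            if (k == i + 1 && l == j - 1)
              w = estack[pt][pt2];
            else
              w = eint[(k - i - 1) + (j - l - 1)];
            v += w * bkl;
          }
        }
        // multiloop: >= 2 inner branches
        double vm = 0.0;
        for (int u = i + 2; u <= j - 2 - fm.min_hairpin; ++u)
          vm += m[IDX(i + 1, u - 1)] * m1[IDX(u, j - 1)];
        v += eml_close * vm;
        b[IDX(i, j)] = v;
      }
      // m1: exactly one branch starting at i, tail unpaired
      m1[IDX(i, j)] = m1[IDX(i, j - 1)] * emc + b[IDX(i, j)] * emb;
      // m: >= 1 branches on [i, j]
      double vm = m[IDX(i, j - 1)] * emc;
      for (int k = i; k <= j - fm.min_hairpin - 1; ++k) {
        double bkj = b[IDX(k, j)];
        if (bkj <= 0.0) continue;
        double left = emcpow[k - i] + (k > i ? m[IDX(i, k - 1)] : 0.0);
        vm += left * bkj * emb;
      }
      m[IDX(i, j)] = vm;
    }
  }

  // ---- exterior ----
  f[0] = 1.0;
  for (int j = 1; j <= n; ++j) {
    double v = f[j - 1];
    for (int i = 1; i <= j - fm.min_hairpin - 1; ++i)
      v += f[i - 1] * b[IDX(i, j)];
    f[j] = v;
  }
  g[n + 1] = 1.0;
  for (int i = n; i >= 1; --i) {
    double v = g[i + 1];
    for (int l = i + fm.min_hairpin + 1; l <= n; ++l)
      v += b[IDX(i, l)] * g[l + 1];
    g[i] = v;
  }
  const double Z = f[n];

  // ---- outside ----
  for (int d = n - 1; d >= fm.min_hairpin + 1; --d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      if (b[IDX(i, j)] <= 0.0) continue;
      double v = f[i - 1] * g[j + 1];
      // parent closes a stack / interior loop around (i, j)
      int pmin = std::max(1, i - 1 - fm.max_loop);
      for (int p = pmin; p <= i - 1; ++p) {
        int rem = fm.max_loop - (i - p - 1);
        int qmax = std::min(n, j + 1 + rem);
        for (int q = j + 1; q <= qmax; ++q) {
          double bh = bhat[IDX(p, q)];
          if (bh <= 0.0) continue;
          int pt = ptype(p, q);
          double w;
          if (p == i - 1 && q == j + 1)
            w = estack[pt][ptype(i, j)];
          else
            w = eint[(i - p - 1) + (q - j - 1)];
          v += bh * w;
        }
      }
      // (i, j) is one branch of a parent multiloop; other branches left/right
      double vm = 0.0;
      for (int p = 1; p <= i - 1; ++p) {
        double h1 = H1[IDX(p, j)], h2 = H2[IDX(p, j)];
        if (h1 == 0.0 && h2 == 0.0) continue;
        double mleft = (p <= i - 2) ? m[IDX(p + 1, i - 1)] : 0.0;
        vm += mleft * (h1 + h2) + emcpow[i - 1 - p] * h2;
      }
      v += eml_branch * vm;
      bhat[IDX(i, j)] = v;
    }
    // fold this span's outside values into the multiloop accumulators:
    // H1[p][jj] collects parents (p, q) with all of (jj, q) unpaired;
    // H2[p][jj] collects parents with >= 1 further branch right of jj.
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      double bh = bhat[IDX(i, j)];
      if (bh <= 0.0) continue;
      for (int jj = i + fm.min_hairpin + 2; jj <= j - 1; ++jj) {
        H1[IDX(i, jj)] += bh * emcpow[j - 1 - jj];
        if (jj + 1 <= j - 1) H2[IDX(i, jj)] += bh * m[IDX(jj + 1, j - 1)];
      }
    }
  }

  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j) {
      double p = b[IDX(i, j)] * bhat[IDX(i, j)] / Z;
      if (p < 0.0) p = 0.0;
      if (p > 1.0 && p < 1.0 + 1e-9) p = 1.0;
      P(i - 1, j - 1) = p;
      P(j - 1, i - 1) = p;
    }
  return P;
}

// Anchored antiparallel complementarity alignment of a miRNA against a target
// subsequence, one register at a time. A register anchors miRNA position 1
// opposite target position t; the alignment extends toward the target 5' end
// with affine gaps, and may end anywhere (trailing miRNA 3' bases unaligned).
// Columns opposite miRNA seed positions are weighted by `scale`.
// [[Rcpp::export(name = ".duplex_scan_cpp")]]
DataFrame duplex_scan_cpp(IntegerVector mir, IntegerVector tgt, List model,
                          List params) {
  FoldModel fm = build_model(model);
  const double duplex_init = as<double>(model["duplex_init"]);
  const double sc_match = as<double>(params["match"]);
  const double sc_gu = as<double>(params["gu"]);
  const double sc_mis = as<double>(params["mismatch"]);
  const double gap_open = as<double>(params["gap_open"]);
  const double gap_ext = as<double>(params["gap_extend"]);
  const double scale = as<double>(params["scale"]);
  const int seed_lo = as<int>(params["seed_lo"]);
  const int seed_hi = as<int>(params["seed_hi"]);
  const double score_min = as<double>(params["score_min"]);
  const double energy_max = as<double>(params["energy_relaxed"]);
  const int L = mir.size(), nt = tgt.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<int> r_reg; std::vector<double> r_score, r_energy;
  std::vector<int> r_start, r_end, r_npairs;

  auto colscore = [&](int x, int p) {
    int pt = fm.ptab[mir[x - 1]][tgt[p - 1]];
    double s = (pt == 0) ? sc_mis : (pt >= 5 ? sc_gu : sc_match);
    if (x >= seed_lo && x <= seed_hi) s *= scale;
    return s;
  };

  for (int t = 1; t <= nt; ++t) {
    const int Ymax = std::min(t - 1, L + 8);
    // DP over miRNA position x (rows) and target offset y (cols)
    std::vector<std::vector<double>> M(L + 1, std::vector<double>(Ymax + 1, NEG));
    std::vector<std::vector<double>> X(L + 1, std::vector<double>(Ymax + 1, NEG));
    std::vector<std::vector<double>> Y(L + 1, std::vector<double>(Ymax + 1, NEG));
    M[1][0] = colscore(1, t);
    for (int x = 1; x <= L; ++x) {
      for (int y = 0; y <= Ymax; ++y) {
        if (!(x == 1 && y == 0)) {
          double best = NEG;
          if (x > 1 && y > 0) {
            best = std::max(M[x - 1][y - 1], std::max(X[x - 1][y - 1], Y[x - 1][y - 1]));
          }
          M[x][y] = (best == NEG) ? NEG : colscore(x, t - y) + best;
        }
        if (x > 1) {
          double a = (M[x - 1][y] == NEG) ? NEG : M[x - 1][y] + gap_open;
          double e = (X[x - 1][y] == NEG) ? NEG : X[x - 1][y] + gap_ext;
          X[x][y] = std::max(a, e);
        }
        if (y > 0) {
          double a = (M[x][y - 1] == NEG) ? NEG : M[x][y - 1] + gap_open;
          double e = (Y[x][y - 1] == NEG) ? NEG : Y[x][y - 1] + gap_ext;
          Y[x][y] = std::max(a, e);
        }
      }
    }
    // best M-cell
    double best = NEG; int bx = -1, by = -1;
    for (int x = 1; x <= L; ++x)
      for (int y = 0; y <= Ymax; ++y)
        if (M[x][y] > best) { best = M[x][y]; bx = x; by = y; }
    if (bx < 0 || best < score_min) continue;
    // traceback collecting aligned columns
    std::vector<std::pair<int, int>> cols; // (mir pos, target pos), 3'->5' on target
    int x = bx, y = by; char state = 'M';
    while (true) {
      if (state == 'M') {
        cols.push_back(std::make_pair(x, t - y));
        if (x == 1 && y == 0) break;
        double prev = M[x][y] - colscore(x, t - y);
        if (std::abs(prev - M[x - 1][y - 1]) < 1e-9) state = 'M';
        else if (std::abs(prev - X[x - 1][y - 1]) < 1e-9) state = 'X';
        else state = 'Y';
        --x; --y;
      } else if (state == 'X') {
        if (M[x - 1][y] != NEG && std::abs(X[x][y] - (M[x - 1][y] + gap_open)) < 1e-9)
          state = 'M';
        --x;
      } else {
        if (M[x][y - 1] != NEG && std::abs(Y[x][y] - (M[x][y - 1] + gap_open)) < 1e-9)
          state = 'M';
        --y;
      }
    }
    // paired columns (WC or GU), ordered from miRNA 5' end
    std::vector<std::pair<int, int>> pairs;
    for (int k = (int)cols.size() - 1; k >= 0; --k) {
      int px = cols[k].first, pp = cols[k].second;
      if (fm.ptab[mir[px - 1]][tgt[pp - 1]] > 0) pairs.push_back(std::make_pair(px, pp));
    }
    // duplex energy: stacks over consecutive paired columns, affine
    // interior/bulge penalties between them, plus initiation. The reported
    // energy is that of the energetically best contiguous block of paired
    // columns (distant weak matches picked up by the score alignment do
    // not dilute the site energy).
    double energy = 0.0;
    size_t blk_lo = 0, blk_hi = 0;
    if (pairs.size() >= 2) {
      size_t np = pairs.size();
      std::vector<double> step(np - 1);
      for (size_t k = 0; k + 1 < np; ++k) {
        int x1 = pairs[k].first, p1 = pairs[k].second;
        int x2 = pairs[k + 1].first, p2 = pairs[k + 1].second;
        int t1 = fm.ptab[mir[x1 - 1]][tgt[p1 - 1]];
        int t2 = fm.ptab[mir[x2 - 1]][tgt[p2 - 1]];
        if (x2 == x1 + 1 && p2 == p1 - 1)
          step[k] = fm.stack[t1][t2];
        else
          step[k] = fm.interior_a +
            fm.interior_b * ((x2 - x1 - 1) + (p1 - p2 - 1));
      }
      // min-subarray over steps (block of >= 2 pairs)
      double best_e = step[0], run = step[0];
      size_t run_lo = 0, b_lo = 0, b_hi = 1;
      for (size_t k = 1; k < np - 1; ++k) {
        if (run > 0) { run = step[k]; run_lo = k; }
        else run += step[k];
        if (run < best_e) { best_e = run; b_lo = run_lo; b_hi = k + 1; }
      }
      energy = duplex_init + best_e;
      blk_lo = b_lo; blk_hi = b_hi;
    }
    if (pairs.size() < 2 || energy > energy_max) continue;
    int smin = std::min(pairs[blk_lo].second, pairs[blk_hi].second);
    int smax = std::max(pairs[blk_lo].second, pairs[blk_hi].second);
    r_reg.push_back(t); r_score.push_back(best); r_energy.push_back(energy);
    r_start.push_back(smin); r_end.push_back(smax);
    r_npairs.push_back((int)pairs.size());
  }
  return DataFrame::create(_["register"] = r_reg, _["score"] = r_score,
                           _["energy"] = r_energy, _["span_start"] = r_start,
                           _["span_end"] = r_end, _["n_pairs"] = r_npairs);
}
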