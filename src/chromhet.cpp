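#include <Rcpp.h>
#include <set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// ---- <Rs> distance kernel -------------------------------------------------

// Mean Euclidean distance between bead pairs (i, i+s) for s = 1..s_max.
// coords: n x 3 matrix of bead centers.
// [[Rcpp::export]]
NumericVector cpp_rs_curve(const NumericMatrix& coords, int s_max) {
  const int n = coords.nrow();
  NumericVector out(s_max);
  for (int s = 1; s <= s_max; ++s) {
    double acc = 0.0;
    const int m = n - s;
    for (int i = 0; i < m; ++i) {
      const double dx = coords(i + s, 0) - coords(i, 0);
      const double dy = coords(i + s, 1) - coords(i, 1);
      const double dz = coords(i + s, 2) - coords(i, 2);
      acc += std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    out[s - 1] = acc / m;
  }
  return out;
}

// ---- MC-TAD lattice paths -------------------------------------------------
//
// A path is a sequence of N^3 bin centers (N^3 - 1 segments) on the N x N x N
// lattice obeying the calibrated permissibility rules:
//   * axis-aligned unit steps,
//   * no lattice edge traversed twice,
//   * at most `max_revisit` bins visited twice (never three times), and,
//   * when `entry_only` is true, a revisited bin must be the path's entry bin
//     (the single permitted self-crossing at a bin center).

namespace {

struct Lattice {
  int N;
  int idx(int x, int y, int z) const { return (x * N + y) * N + z; }
};

const int MOVES[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                         {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};

struct GrowState {
  std::vector<int> path;            // bin indices
  std::vector<char> used_edges;     // flat: bin * 3 + axis (lower endpoint)
  std::vector<int> visits;
  int n_multi;

  void init(int nbins, int start) {
    path.assign(1, start);
    used_edges.assign((size_t)nbins * 3, 0);
    visits.assign(nbins, 0);
    visits[start] = 1;
    n_multi = 0;
  }
};

// flat edge id for the lattice edge between adjacent bins a < b on axis ax
inline size_t flat_edge(int lo, int ax) { return (size_t)lo * 3 + ax; }

// Candidate next bins from the current state; fills move axis alongside.
void candidates(const Lattice& lat, const GrowState& st, int max_revisit,
                bool entry_only, std::vector<int>* out) {
  out->clear();
  const int cur = st.path.back();
  const int z = cur % lat.N, y = (cur / lat.N) % lat.N, x = cur / (lat.N * lat.N);
  for (int m = 0; m < 6; ++m) {
    const int nx = x + MOVES[m][0], ny = y + MOVES[m][1], nz = z + MOVES[m][2];
    if (nx < 0 || nx >= lat.N || ny < 0 || ny >= lat.N || nz < 0 || nz >= lat.N)
      continue;
    const int nxt = lat.idx(nx, ny, nz);
    const int ax = m / 2;
    if (st.used_edges[flat_edge(cur < nxt ? cur : nxt, ax)]) continue;
    const int v = st.visits[nxt];
    if (v >= 2) continue;
    if (v == 1) {
      if (st.n_multi >= max_revisit) continue;
      if (entry_only && nxt != st.path.front()) continue;
    }
    out->push_back(nxt);
  }
}

inline int step_axis(const Lattice& lat, int a, int b) {
  int d = a < b ? b - a : a - b;
  if (d == 1) return 2;
  if (d == lat.N) return 1;
  return 0;
}

void push_step(const Lattice& lat, GrowState* st, int nxt) {
  const int cur = st->path.back();
  st->used_edges[flat_edge(cur < nxt ? cur : nxt,
                           step_axis(lat, cur, nxt))] = 1;
  st->visits[nxt] += 1;
  if (st->visits[nxt] == 2) st->n_multi += 1;
  st->path.push_back(nxt);
}

void pop_step(const Lattice& lat, GrowState* st) {
  const int nxt = st->path.back();
  st->path.pop_back();
  const int cur = st->path.back();
  st->used_edges[flat_edge(cur < nxt ? cur : nxt,
                           step_axis(lat, cur, nxt))] = 0;
  if (st->visits[nxt] == 2) st->n_multi -= 1;
  st->visits[nxt] -= 1;
}

void enum_rec(const Lattice& lat, GrowState* st, int n_steps, int max_revisit,
              bool entry_only, std::vector<std::vector<int> >* out,
              long max_paths) {
  if ((long)out->size() >= max_paths)
    stop("exhaustive enumeration exceeded max_paths; use stochastic mode");
  if ((int)st->path.size() == n_steps + 1) {
    out->push_back(st->path);
    return;
  }
  std::vector<int> cands;
  candidates(lat, *st, max_revisit, entry_only, &cands);
  for (size_t k = 0; k < cands.size(); ++k) {
    push_step(lat, st, cands[k]);
    enum_rec(lat, st, n_steps, max_revisit, entry_only, out, max_paths);
    pop_step(lat, st);
  }
}

IntegerMatrix paths_to_matrix(const std::vector<std::vector<int> >& paths,
                              int N) {
  const int L = paths.empty() ? 0 : (int)paths[0].size();
  IntegerMatrix out(paths.size(), 3 * L);
  for (size_t i = 0; i < paths.size(); ++i) {
    for (int j = 0; j < L; ++j) {
      const int b = paths[i][j];
      out(i, 3 * j) = b / (N * N);
      out(i, 3 * j + 1) = (b / N) % N;
      out(i, 3 * j + 2) = b % N;
    }
  }
  return out;
}

}  // namespace

// Exhaustive enumeration of all permissible single-cube paths.
// [[Rcpp::export]]
IntegerMatrix cpp_enum_paths(int N, int max_revisit, bool entry_only,
                             double max_paths) {
  Lattice lat{N};
  const int nbins = N * N * N;
  std::vector<std::vector<int> > out;
  for (int s = 0; s < nbins; ++s) {
    GrowState st;
    st.init(nbins, s);
    if (nbins == 1) {
      out.push_back(st.path);
      continue;
    }
    enum_rec(lat, &st, nbins - 1, max_revisit, entry_only, &out,
             (long)max_paths);
  }
  return paths_to_matrix(out, N);
}

// One stochastic growth attempt: depth-first growth with random move order
// and limited backtracking (budgeted node expansions), so that one attempt
// almost always yields a complete permissible path even on larger lattices.
// Uses R's RNG so results are reproducible under set.seed().
static bool grow_dfs(const Lattice& lat, GrowState* st, int n_steps,
                     int max_revisit, bool entry_only, long* budget,
                     std::vector<int>* out) {
  if ((int)st->path.size() == n_steps + 1) {
    *out = st->path;
    return true;
  }
  if (--(*budget) <= 0) return false;
  std::vector<int> cands;
  candidates(lat, *st, max_revisit, entry_only, &cands);
  // shuffle candidate order (Fisher-Yates with R's RNG)
  for (int i = (int)cands.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(cands[i], cands[j]);
  }
  for (size_t k = 0; k < cands.size(); ++k) {
    push_step(lat, st, cands[k]);
    if (grow_dfs(lat, st, n_steps, max_revisit, entry_only, budget, out))
      return true;
    pop_step(lat, st);
    if (*budget <= 0) return false;
  }
  return false;
}

static bool grow_once(const Lattice& lat, int max_revisit, bool entry_only,
                      std::vector<int>* path) {
  const int nbins = lat.N * lat.N * lat.N;
  GrowState st;
  int start = (int)(unif_rand() * nbins);
  if (start >= nbins) start = nbins - 1;
  st.init(nbins, start);
  long budget = 200L * nbins;
  return grow_dfs(lat, &st, nbins - 1, max_revisit, entry_only, &budget,
                  path);
}

// Stochastic generation with restarts, de-duplication, and convergence by
// stagnation: stop after `stagnation` consecutive attempts that produce no
// new unique path (or at `max_attempts` / `max_unique`).
// [[Rcpp::export]]
List cpp_sample_paths(int N, double stagnation, double max_attempts,
                      double max_unique, bool adaptive_stagnation,
                      int max_revisit, bool entry_only) {
  Lattice lat{N};
  std::set<std::vector<int> > seen;
  std::vector<std::vector<int> > uniq;
  long attempts = 0, since_new = 0;
  std::vector<int> path;
  while (attempts < (long)max_attempts) {
    double limit = stagnation;
    if (adaptive_stagnation) {
      const double adaptive = 50.0 * (double)uniq.size();
      if (adaptive > limit) limit = adaptive;
    }
    if (since_new >= (long)limit) break;
    if ((long)uniq.size() >= (long)max_unique) break;
    ++attempts;
    if (!grow_once(lat, max_revisit, entry_only, &path)) {
      ++since_new;
      continue;
    }
    if (seen.insert(path).second) {
      uniq.push_back(path);
      since_new = 0;
    } else {
      ++since_new;
    }
  }
  return List::create(Named("paths") = paths_to_matrix(uniq, N),
                      Named("attempts") = (double)attempts,
                      Named("since_new") = (double)since_new);
}

// First-step axis (0, 1, 2) of each path in a path matrix.
// [[Rcpp::export]]
IntegerVector cpp_first_axis(const IntegerMatrix& paths) {
  IntegerVector out(paths.nrow());
  for (int i = 0; i < paths.nrow(); ++i) {
    int ax = -1;
    for (int a = 0; a < 3; ++a)
      if (paths(i, 3 + a) != paths(i, a)) ax = a;
    out[i] = ax;
  }
  return out;
}

// Build two-cube paths by pairing: first-cube path + second-cube path
// translated by N along x, keeping pairs whose starting-face axes differ
// (the face constraint). exhaustive = all allowed ordered pairs; otherwise
// n_pairs pairs are drawn with R's RNG (p1 uniform, p2 uniform among allowed).
// [[Rcpp::export]]
IntegerMatrix cpp_pair_paths(const IntegerMatrix& p1,
                             const IntegerMatrix& p2, int N,
                             bool face_constraint, bool exhaustive,
                             double n_pairs) {
  const int L = p1.ncol();  // 3 * N^3
  IntegerVector ax1 = cpp_first_axis(p1);
  IntegerVector ax2 = cpp_first_axis(p2);
  std::vector<std::pair<int, int> > keep;
  if (exhaustive) {
    for (int i = 0; i < p1.nrow(); ++i)
      for (int j = 0; j < p2.nrow(); ++j)
        if (!face_constraint || ax1[i] != ax2[j]) keep.push_back({i, j});
  } else {
    std::vector<std::vector<int> > by_axis(3);
    for (int j = 0; j < p2.nrow(); ++j) by_axis[ax2[j]].push_back(j);
    std::set<std::pair<int, int> > seen;
    long want = (long)n_pairs, guard = 0;
    while ((long)keep.size() < want && guard < 50 * want) {
      ++guard;
      int i = (int)(unif_rand() * p1.nrow());
      if (i >= p1.nrow()) i = p1.nrow() - 1;
      int j;
      if (face_constraint) {
        int a = ax1[i];
        int pick = (int)(unif_rand() * 2);
        int axis = (pick == 0) ? (a + 1) % 3 : (a + 2) % 3;
        if (by_axis[axis].empty()) continue;
        int k = (int)(unif_rand() * by_axis[axis].size());
        if (k >= (int)by_axis[axis].size()) k = by_axis[axis].size() - 1;
        j = by_axis[axis][k];
      } else {
        j = (int)(unif_rand() * p2.nrow());
        if (j >= p2.nrow()) j = p2.nrow() - 1;
      }
      if (seen.insert({i, j}).second) keep.push_back({i, j});
    }
  }
  IntegerMatrix out(keep.size(), 2 * L);
  for (size_t r = 0; r < keep.size(); ++r) {
    const int i = keep[r].first, j = keep[r].second;
    for (int c = 0; c < L; ++c) out(r, c) = p1(i, c);
    for (int c = 0; c < L; ++c)
      out(r, L + c) = p2(j, c) + ((c % 3 == 0) ? N : 0);
  }
  return out;
}

// End-to-end Euclidean distances of all windows of `contour` consecutive
// segments, in cube-edge units (lattice spacing 1/N).
// [[Rcpp::export]]
NumericVector cpp_window_distances(const IntegerMatrix& paths, int N,
                                   int contour) {
  const int L = paths.ncol() / 3;  // vertices per path
  const int nwin = L - contour;
  if (nwin < 1) stop("contour length exceeds path length");
  NumericVector out((double)paths.nrow() * nwin);
  long k = 0;
  for (int i = 0; i < paths.nrow(); ++i) {
    for (int w = 0; w < nwin; ++w) {
      const double dx = paths(i, 3 * (w + contour)) - paths(i, 3 * w);
      const double dy = paths(i, 3 * (w + contour) + 1) - paths(i, 3 * w + 1);
      const double dz = paths(i, 3 * (w + contour) + 2) - paths(i, 3 * w + 2);
      out[k++] = std::sqrt(dx * dx + dy * dy + dz * dz) / N;
    }
  }
  return out;
}
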