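// Core engine for HP-lattice folding: chain geometry, SAW validation,
// contact energy, guided initialization, mutation operators (corner, pull,
// motif splices), the evolutionary-programming generation step, greedy local
// search, and the exhaustive enumeration oracle.
//
// Conventions shared with the R layer:
//  - lattice id: 0 = square (F,B,U,D), 1 = tri8 (adds FU,BU,BD,FD),
//    2 = tri6 (square moves plus FU, BD);
//  - move codes are 0-based indices into the lattice alphabet, in that order;
//  - a conformation of L residues is L-1 move codes with move[0] == 0 (F),
//    anchoring residues 1 and 2 at (0,0) and (1,0);
//  - all randomness uses R's RNG stream (unif_rand), so set.seed() in R
//    makes every routine reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Lat {
  int k;
  int sx[8], sy[8];
};

Lat get_lat(int id) {
  static const int sq[4][2]  = {{1,0},{-1,0},{0,1},{0,-1}};
  static const int t8[8][2]  = {{1,0},{-1,0},{0,1},{0,-1},{1,1},{-1,1},{-1,-1},{1,-1}};
  static const int t6[6][2]  = {{1,0},{-1,0},{0,1},{0,-1},{1,1},{-1,-1}};
  Lat l;
  const int (*tab)[2];
  if (id == 0)      { l.k = 4; tab = sq; }
  else if (id == 1) { l.k = 8; tab = t8; }
  else              { l.k = 6; tab = t6; }
  for (int i = 0; i < l.k; ++i) { l.sx[i] = tab[i][0]; l.sy[i] = tab[i][1]; }
  return l;
}

int step_code(const Lat& l, int dx, int dy) {
  for (int m = 0; m < l.k; ++m)
    if (l.sx[m] == dx && l.sy[m] == dy) return m;
  return -1;
}

// Stamped occupancy grid: O(1) clear via epoch counter. Coordinates of an
// L-residue chain anchored at the origin satisfy |x|,|y| <= L.
struct Grid {
  int L, D, cur;
  std::vector<int> stamp, val;
  explicit Grid(int L_) : L(L_), D(2 * L_ + 3), cur(0),
                          stamp(D * D, -1), val(D * D, -1) {}
  void clear() { ++cur; }
  int idx(int x, int y) const { return (x + L + 1) * D + (y + L + 1); }
  bool inside(int x, int y) const { return x >= -L - 1 && x <= L + 1 && y >= -L - 1 && y <= L + 1; }
  void set(int x, int y, int v) { int i = idx(x, y); stamp[i] = cur; val[i] = v; }
  // returns residue index or -1 if free
  int get(int x, int y) const {
    if (!inside(x, y)) return -1;
    int i = idx(x, y);
    return stamp[i] == cur ? val[i] : -1;
  }
};

inline int rint(int n) {
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// decode codes -> coords; returns false if a code is out of range
bool decode(const std::vector<int>& mv, const Lat& l,
            std::vector<int>& xs, std::vector<int>& ys) {
  int L = static_cast<int>(mv.size()) + 1;
  xs.resize(L); ys.resize(L);
  xs[0] = 0; ys[0] = 0;
  for (int i = 0; i < L - 1; ++i) {
    int m = mv[i];
    if (m < 0 || m >= l.k) return false;
    xs[i + 1] = xs[i] + l.sx[m];
    ys[i + 1] = ys[i] + l.sy[m];
  }
  return true;
}

bool is_saw(const std::vector<int>& xs, const std::vector<int>& ys, Grid& g) {
  g.clear();
  int L = static_cast<int>(xs.size());
  for (int i = 0; i < L; ++i) {
    if (g.get(xs[i], ys[i]) >= 0) return false;
    g.set(xs[i], ys[i], i);
  }
  return true;
}

// energy = -(# nonconsecutive H-H lattice contacts); assumes SAW
int energy_of(const std::vector<int>& xs, const std::vector<int>& ys,
              const std::vector<char>& isH, const Lat& l, Grid& g) {
  g.clear();
  int L = static_cast<int>(xs.size());
  for (int i = 0; i < L; ++i) g.set(xs[i], ys[i], i);
  int cnt = 0;
  for (int i = 0; i < L; ++i) {
    if (!isH[i]) continue;
    for (int m = 0; m < l.k; ++m) {
      int j = g.get(xs[i] + l.sx[m], ys[i] + l.sy[m]);
      if (j > i + 1 && isH[j]) ++cnt;
    }
  }
  return -cnt;
}

// Rigid re-frame so that pos0=(0,0), pos1=(1,0), using pure rotations that
// are symmetries of the move set (square/tri8: all four 90-degree rotations;
// tri6: identity and 180 only). Returns false if no rotation restores the
// anchor (e.g. a diagonal first bond on tri8).
bool reframe(std::vector<int>& xs, std::vector<int>& ys, int latId) {
  int L = static_cast<int>(xs.size());
  int bx = xs[1] - xs[0], by = ys[1] - ys[0];
  int cand[4][2] = {{bx, by}, {-by, bx}, {-bx, -by}, {by, -bx}};
  int rot = -1;
  for (int r = 0; r < 4; ++r) {
    if (latId == 2 && (r == 1 || r == 3)) continue;
    if (cand[r][0] == 1 && cand[r][1] == 0) { rot = r; break; }
  }
  if (rot < 0) return false;
  int ox = xs[0], oy = ys[0];
  for (int i = 0; i < L; ++i) {
    int x = xs[i] - ox, y = ys[i] - oy, nx, ny;
    switch (rot) {
      case 0: nx = x;  ny = y;  break;
      case 1: nx = -y; ny = x;  break;
      case 2: nx = -x; ny = -y; break;
      default: nx = y; ny = -x; break;
    }
    xs[i] = nx; ys[i] = ny;
  }
  return true;
}

// coords -> codes; false if a bond is not a lattice step
bool encode(const std::vector<int>& xs, const std::vector<int>& ys,
            const Lat& l, std::vector<int>& mv) {
  int L = static_cast<int>(xs.size());
  mv.resize(L - 1);
  for (int i = 0; i < L - 1; ++i) {
    int c = step_code(l, xs[i + 1] - xs[i], ys[i + 1] - ys[i]);
    if (c < 0) return false;
    mv[i] = c;
  }
  return true;
}

// Full proposal validation: legal bonds, SAW, anchored frame; on success
// fills mv/energy.
bool finalize(std::vector<int>& xs, std::vector<int>& ys,
              const std::vector<char>& isH, const Lat& l, int latId,
              Grid& g, std::vector<int>& mv, int& en) {
  if (!reframe(xs, ys, latId)) return false;
  if (!encode(xs, ys, l, mv)) return false;
  if (mv[0] != 0) return false;  // should not happen after reframe
  if (!is_saw(xs, ys, g)) return false;
  en = energy_of(xs, ys, isH, l, g);
  return true;
}

// ---------------- mutation operators ------------------------------------

// corner flip at residue i (parallelogram flip of bonds i-1, i)
bool op_corner(const std::vector<int>& xs0, const std::vector<int>& ys0,
               int i, const std::vector<char>& isH, const Lat& l, int latId,
               Grid& g, std::vector<int>& mv, int& en) {
  int L = static_cast<int>(xs0.size());
  if (i <= 0 || i >= L - 1) return false;
  int ax = xs0[i - 1] + xs0[i + 1] - xs0[i];
  int ay = ys0[i - 1] + ys0[i + 1] - ys0[i];
  if (ax == xs0[i] && ay == ys0[i]) return false;  // collinear triple
  g.clear();
  for (int j = 0; j < L; ++j) if (j != i) g.set(xs0[j], ys0[j], j);
  if (g.get(ax, ay) >= 0) return false;            // target occupied
  std::vector<int> xs(xs0), ys(ys0);
  xs[i] = ax; ys[i] = ay;
  return finalize(xs, ys, isH, l, latId, g, mv, en);
}

// pull move at residue i: relocate i next to residue i+1 and drag
// predecessors along vacated positions until the chain reconnects;
// chain ends relocate to a free neighbor of their single neighbor.
// Direction is symmetric: with `rev` the chain is traversed from the tail,
// so successors are dragged instead (the standard bidirectional pull set).
bool op_pull_dir(const std::vector<int>& xsIn, const std::vector<int>& ysIn,
                 int i, bool rev, const std::vector<char>& isH, const Lat& l,
                 int latId, Grid& g, std::vector<int>& mv, int& en) {
  int L = static_cast<int>(xsIn.size());
  if (i < 0 || i >= L) return false;
  std::vector<int> xs0(xsIn), ys0(ysIn);
  if (rev) {
    std::reverse(xs0.begin(), xs0.end());
    std::reverse(ys0.begin(), ys0.end());
    i = L - 1 - i;
  }
  g.clear();
  for (int j = 0; j < L; ++j) g.set(xs0[j], ys0[j], j);
  std::vector<int> xs(xs0), ys(ys0);
  auto done = [&](void) {
    if (rev) {
      std::reverse(xs.begin(), xs.end());
      std::reverse(ys.begin(), ys.end());
    }
    return finalize(xs, ys, isH, l, latId, g, mv, en);
  };

  if (i == 0 || i == L - 1) {
    int nb = (i == 0) ? 1 : L - 2;
    int cx[8], cy[8], nc = 0;
    for (int m = 0; m < l.k; ++m) {
      int tx = xs0[nb] + l.sx[m], ty = ys0[nb] + l.sy[m];
      if (g.get(tx, ty) < 0) { cx[nc] = tx; cy[nc] = ty; ++nc; }
    }
    if (nc == 0) return false;
    int c = rint(nc);
    xs[i] = cx[c]; ys[i] = cy[c];
    return done();
  }

  // candidate new sites for residue i: free step-neighbors of residue i+1
  int cx[8], cy[8], nc = 0;
  for (int m = 0; m < l.k; ++m) {
    int tx = xs0[i + 1] + l.sx[m], ty = ys0[i + 1] + l.sy[m];
    if (g.get(tx, ty) < 0) { cx[nc] = tx; cy[nc] = ty; ++nc; }
  }
  if (nc == 0) return false;
  int c = rint(nc);
  int Lx = cx[c], Ly = cy[c];

  if (step_code(l, Lx - xs0[i - 1], Ly - ys0[i - 1]) >= 0) {
    // new site already bonds to residue i-1: single relocation
    xs[i] = Lx; ys[i] = Ly;
    return done();
  }

  // companion site C: bonded to both the new site and residue i; must be
  // free or be residue i-1 itself
  int gx[8], gy[8], ng = 0;
  bool prevIsC = false;
  for (int m = 0; m < l.k; ++m) {
    int tx = Lx + l.sx[m], ty = Ly + l.sy[m];
    if (step_code(l, xs0[i] - tx, ys0[i] - ty) < 0) continue;
    if (tx == xs0[i - 1] && ty == ys0[i - 1]) { prevIsC = true; continue; }
    if (g.get(tx, ty) < 0) { gx[ng] = tx; gy[ng] = ty; ++ng; }
  }
  if (prevIsC) {
    xs[i] = Lx; ys[i] = Ly;
    return done();
  }
  if (ng == 0) return false;
  int cc = rint(ng);
  xs[i] = Lx; ys[i] = Ly;
  xs[i - 1] = gx[cc]; ys[i - 1] = gy[cc];
  for (int j = i - 2; j >= 0; --j) {
    if (step_code(l, xs[j + 1] - xs0[j], ys[j + 1] - ys0[j]) >= 0) break;
    xs[j] = xs0[j + 2]; ys[j] = ys0[j + 2];
  }
  return done();
}

// splice a code substring (motif template) into the move vector
bool op_splice(const std::vector<int>& mv0, int start,
               const std::vector<int>& codes, const std::vector<char>& isH,
               const Lat& l, int latId, Grid& g,
               std::vector<int>& mv, int& en) {
  if (start < 1) return false;  // never rewrite the anchored first bond
  if (start + static_cast<int>(codes.size()) > static_cast<int>(mv0.size()))
    return false;
  std::vector<int> m(mv0);
  for (size_t t = 0; t < codes.size(); ++t) m[start + t] = codes[t];
  std::vector<int> xs, ys;
  if (!decode(m, l, xs, ys)) return false;
  return finalize(xs, ys, isH, l, latId, g, mv, en);
}

// ----------------- operator dispatch -------------------------------------

// Operator spec drawn once and applied ("similar mutation") to one or more
// parents. kinds: 0 corner, 1 pull, 2 helix-down, 3 helix-up, 4 sheet.
struct OpSpec {
  int kind;
  int index;        // residue index for corner/pull
  int mstart;       // motif start residue (0-based) for kinds 2-4
  int span;         // motif span in residues
};

// motifs: n x 3 integer matrix (kind 0=down/1=up/2=sheet, start, span)
OpSpec draw_op(int L, const IntegerMatrix& motifs, double motifProb) {
  OpSpec op;
  int nm = motifs.nrow();
  if (nm > 0 && unif_rand() < motifProb) {
    int s = rint(nm);
    op.kind = 2 + motifs(s, 0);
    op.mstart = motifs(s, 1);
    op.span = motifs(s, 2);
    op.index = -1;
    return op;
  }
  if (unif_rand() < 0.5 && L >= 3) {
    op.kind = 0;
    op.index = 1 + rint(L - 2);
  } else {
    op.kind = 1;
    op.index = rint(L);
  }
  op.mstart = -1; op.span = 0;
  return op;
}

// helix template cycles per lattice (period 4), direction per kind
void helix_cycle(int latId, bool down, int cyc[4]) {
  if (latId == 1) {           // tri8: diagonal serpentine
    if (down) { cyc[0] = 7; cyc[1] = 0; cyc[2] = 4; cyc[3] = 0; }   // FD F FU F
    else      { cyc[0] = 4; cyc[1] = 0; cyc[2] = 7; cyc[3] = 0; }   // FU F FD F
  } else {                    // square / tri6: axis serpentine
    if (down) { cyc[0] = 3; cyc[1] = 0; cyc[2] = 2; cyc[3] = 0; }   // D F U F
    else      { cyc[0] = 2; cyc[1] = 0; cyc[2] = 3; cyc[3] = 0; }   // U F D F
  }
}

// build the splice codes of a motif op for a given parent (sheet extends the
// parent's entering direction; helix uses the fixed template cycle)
void motif_codes(const OpSpec& op, const std::vector<int>& parent, int latId,
                 int& start, std::vector<int>& codes) {
  int s = op.mstart;
  int bLast = s + op.span - 2;              // last bond inside the site
  start = s < 1 ? 1 : s;
  codes.clear();
  if (op.kind == 4) {
    int dir = s > 0 ? parent[s - 1] : 0;
    for (int b = start; b <= bLast; ++b) codes.push_back(dir);
  } else {
    int cyc[4];
    helix_cycle(latId, op.kind == 2, cyc);
    for (int b = start; b <= bLast; ++b) codes.push_back(cyc[(b - s) % 4]);
  }
}

bool apply_op(const OpSpec& op, const std::vector<int>& parent,
              const std::vector<char>& isH, const Lat& l, int latId,
              Grid& g, std::vector<int>& mv, int& en) {
  std::vector<int> xs, ys;
  if (op.kind == 0 || op.kind == 1) {
    if (!decode(parent, l, xs, ys)) return false;
    return op.kind == 0
      ? op_corner(xs, ys, op.index, isH, l, latId, g, mv, en)
      : op_pull_dir(xs, ys, op.index, unif_rand() < 0.5, isH, l, latId,
                    g, mv, en);
  }
  int start; std::vector<int> codes;
  motif_codes(op, parent, latId, start, codes);
  if (codes.empty()) return false;
  return op_splice(parent, start, codes, isH, l, latId, g, mv, en);
}

std::vector<char> to_flags(const LogicalVector& isH) {
  std::vector<char> f(isH.size());
  for (int i = 0; i < isH.size(); ++i) f[i] = isH[i] ? 1 : 0;
  return f;
}

std::vector<int> row_of(const IntegerMatrix& m, int r) {
  std::vector<int> v(m.ncol());
  for (int j = 0; j < m.ncol(); ++j) v[j] = m(r, j);
  return v;
}

}  // namespace

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_decode(IntegerVector mv, int latId) {
  Lat l = get_lat(latId);
  std::vector<int> m(mv.begin(), mv.end()), xs, ys;
  if (!decode(m, l, xs, ys)) stop("unknown move code for this lattice");
  int L = static_cast<int>(xs.size());
  Grid g(L);
  bool valid = is_saw(xs, ys, g);
  IntegerMatrix coords(L, 2);
  for (int i = 0; i < L; ++i) { coords(i, 0) = xs[i]; coords(i, 1) = ys[i]; }
  return List::create(_["coords"] = coords, _["valid"] = valid);
}

// [[Rcpp::export]]
List cpp_contacts(IntegerMatrix coords, LogicalVector isH, int latId) {
  Lat l = get_lat(latId);
  int L = coords.nrow();
  Grid g(L + 2);
  g.clear();
  for (int i = 0; i < L; ++i) {
    if (!g.inside(coords(i, 0), coords(i, 1)))
      stop("coordinates out of range; re-anchor the chain at the origin");
    if (g.get(coords(i, 0), coords(i, 1)) >= 0) stop("conformation is not self-avoiding");
    g.set(coords(i, 0), coords(i, 1), i);
  }
  std::vector<int> pi, pj;
  for (int i = 0; i < L; ++i) {
    if (!isH[i]) continue;
    for (int m = 0; m < l.k; ++m) {
      int j = g.get(coords(i, 0) + l.sx[m], coords(i, 1) + l.sy[m]);
      if (j > i + 1 && isH[j]) { pi.push_back(i + 1); pj.push_back(j + 1); }
    }
  }
  int n = static_cast<int>(pi.size());
  IntegerMatrix pairs(n, 2);
  for (int t = 0; t < n; ++t) { pairs(t, 0) = pi[t]; pairs(t, 1) = pj[t]; }
  return List::create(_["pairs"] = pairs, _["energy"] = -n);
}

// [[Rcpp::export]]
IntegerVector cpp_energy_batch(IntegerMatrix pop, LogicalVector isH, int latId) {
  Lat l = get_lat(latId);
  std::vector<char> f = to_flags(isH);
  int L = pop.ncol() + 1;
  Grid g(L);
  IntegerVector out(pop.nrow());
  std::vector<int> xs, ys;
  for (int r = 0; r < pop.nrow(); ++r) {
    std::vector<int> m = row_of(pop, r);
    if (!decode(m, l, xs, ys)) stop("unknown move code");
    if (!is_saw(xs, ys, g)) stop("population contains a non-SAW conformation");
    out[r] = energy_of(xs, ys, f, l, g);
  }
  return out;
}

// Guided (constraint-aware) initializer: always returns a SAW conformation.
// At each extension a random free neighbor is taken; when the current
// residue is hydrophobic, with probability hBias the draw prefers free sites
// already in contact with a placed H residue. Dead ends trigger bounded
// backtracking (step back one residue and re-randomize).
// [[Rcpp::export]]
IntegerVector cpp_guided(LogicalVector isH, int latId, double hBias) {
  Lat l = get_lat(latId);
  std::vector<char> f = to_flags(isH);
  int L = isH.size();
  if (L < 2) stop("need at least two residues");
  Grid g(L);
  std::vector<int> xs(L), ys(L), mv(L - 1);
  long guard = 0;
  for (;;) {
    g.clear();
    xs[0] = 0; ys[0] = 0; xs[1] = 1; ys[1] = 0; mv[0] = 0;
    g.set(0, 0, 0); g.set(1, 0, 1);
    int i = 2;
    while (i < L) {
      if (++guard > 2000L * L) { guard = 0; break; }  // full restart (never hit in practice)
      int fm[8], nf = 0, hm[8], nh = 0;
      for (int m = 0; m < l.k; ++m) {
        int tx = xs[i - 1] + l.sx[m], ty = ys[i - 1] + l.sy[m];
        if (g.get(tx, ty) >= 0) continue;
        fm[nf++] = m;
        if (f[i]) {
          for (int c = 0; c < l.k; ++c) {
            int j = g.get(tx + l.sx[c], ty + l.sy[c]);
            if (j >= 0 && j != i - 1 && f[j]) { hm[nh++] = m; break; }
          }
        }
      }
      if (nf == 0) {                       // dead end: back up one residue
        if (i > 2) { --i; g.set(xs[i], ys[i], -1); }
        continue;
      }
      int m = (nh > 0 && unif_rand() < hBias) ? hm[rint(nh)] : fm[rint(nf)];
      xs[i] = xs[i - 1] + l.sx[m];
      ys[i] = ys[i - 1] + l.sy[m];
      g.set(xs[i], ys[i], i);
      mv[i - 1] = m;
      ++i;
    }
    if (i == L) break;
  }
  return IntegerVector(mv.begin(), mv.end());
}

// Batch of naive random conformations kept only when self-avoiding: returns
// n valid move-code rows plus the number of invalid draws discarded on the
// way (the SAW yield of uniform move strings decays exponentially in L, so
// the rejection loop lives here rather than in R).
// [[Rcpp::export]]
List cpp_random_pop(LogicalVector isH, int latId, int n) {
  Lat l = get_lat(latId);
  int L = isH.size();
  if (L < 2) stop("need at least two residues");
  Grid g(L);
  IntegerMatrix pop(n, L - 1);
  int nInvalid = 0;
  std::vector<int> mv(L - 1), xs, ys;
  for (int r = 0; r < n; ++r) {
    for (;;) {
      mv[0] = 0;
      for (int j = 1; j < L - 1; ++j) mv[j] = rint(l.k);
      decode(mv, l, xs, ys);
      if (is_saw(xs, ys, g)) break;
      ++nInvalid;
    }
    for (int j = 0; j < L - 1; ++j) pop(r, j) = mv[j];
  }
  return List::create(_["pop"] = pop, _["n_invalid"] = nInvalid);
}

// [[Rcpp::export]]
List cpp_try_op(IntegerVector mv, LogicalVector isH, int latId,
                int kind, int index, int mstart, int span) {
  Lat l = get_lat(latId);
  std::vector<char> f = to_flags(isH);
  std::vector<int> parent(mv.begin(), mv.end()), out;
  int L = static_cast<int>(parent.size()) + 1;
  Grid g(L);
  OpSpec op; op.kind = kind; op.index = index; op.mstart = mstart; op.span = span;
  int en = 0;
  bool ok = apply_op(op, parent, f, l, latId, g, out, en);
  return List::create(
    _["accepted"] = ok,
    _["moves"] = ok ? IntegerVector(out.begin(), out.end()) : mv,
    _["energy"] = ok ? en : NA_INTEGER);
}

// Greedy local search: random corner/pull proposals, keeping improvements
// (and, with allow_equal, equal-energy moves, enabling plateau walks; the
// returned energy is still never worse than the input).
// [[Rcpp::export]]
List cpp_local_search(IntegerVector mv, LogicalVector isH, int latId,
                      int budget, IntegerMatrix motifs, double motifProb,
                      bool allow_equal = false) {
  Lat l = get_lat(latId);
  std::vector<char> f = to_flags(isH);
  std::vector<int> cur(mv.begin(), mv.end()), out, xs, ys;
  int L = static_cast<int>(cur.size()) + 1;
  Grid g(L);
  decode(cur, l, xs, ys);
  int en = energy_of(xs, ys, f, l, g);
  is_saw(xs, ys, g);
  for (int t = 0; t < budget; ++t) {
    OpSpec op = draw_op(L, motifs, motifProb);
    int e2;
    if (apply_op(op, cur, f, l, latId, g, out, e2) &&
        (e2 < en || (allow_equal && e2 == en))) {
      cur = out; en = e2;
    }
  }
  return List::create(_["moves"] = IntegerVector(cur.begin(), cur.end()),
                      _["energy"] = en);
}

// One evolutionary-programming generation (variation + survivor selection).
//
// Variation: every individual produces one offspring by a single mutation
// attempt (a rejected attempt leaves a copy of the parent standing in).
// Selection over the combined parent+offspring pool of size 2n, best
// individuals making multiple copies while the rest are discarded:
//  - elites (eliteFrac, at least 1): best of the pool, carried unchanged
//    (parents that stay elite keep aging);
//  - tournament share (tourFrac): an equal-fitness group of up to nTs pool
//    members (seeded by a rank draw) receives the same probe mutation; the
//    member whose offspring scores best survives;
//  - rank share (the rest): nested-uniform rank selection over the sorted
//    pool, with replacement.
// Returns the new population, energies, ages and operator usage counts.
// [[Rcpp::export]]
List cpp_generation(IntegerMatrix pop, IntegerVector energy, IntegerVector age,
                    LogicalVector isH, int latId, IntegerMatrix motifs,
                    double motifProb, double eliteFrac, double tourFrac,
                    int nTs) {
  Lat l = get_lat(latId);
  std::vector<char> f = to_flags(isH);
  int n = pop.nrow(), nm = pop.ncol(), L = nm + 1;
  Grid g(L);

  IntegerVector opCount(5), opAccept(5);

  // ---- variation: one offspring per individual -> pool of size 2n
  int np = 2 * n;
  std::vector< std::vector<int> > poolMv(np);
  std::vector<int> poolEn(np), poolAge(np);
  std::vector<int> out;
  for (int i = 0; i < n; ++i) {
    poolMv[i] = row_of(pop, i);
    poolEn[i] = energy[i];
    poolAge[i] = age[i];
  }
  for (int i = 0; i < n; ++i) {
    OpSpec op = draw_op(L, motifs, motifProb);
    ++opCount[op.kind];
    int en;
    if (apply_op(op, poolMv[i], f, l, latId, g, out, en)) {
      ++opAccept[op.kind];
      poolMv[n + i] = out;
      poolEn[n + i] = en;
    } else {
      poolMv[n + i] = poolMv[i];
      poolEn[n + i] = poolEn[i];
    }
    poolAge[n + i] = 0;
  }

  // ---- sort pool indices by energy ascending (best fitness first)
  std::vector<int> ord(np);
  for (int i = 0; i < np; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return poolEn[a] < poolEn[b]; });

  int nE = std::max(1, static_cast<int>(std::lround(eliteFrac * n)));
  int nT = static_cast<int>(std::lround(tourFrac * n));
  if (nE + nT > n) nT = n - nE;
  int slot = 0;

  IntegerMatrix newPop(n, nm);
  IntegerVector newEn(n), newAge(n);
  auto put = [&](int s, int poolIdx, bool elite) {
    const std::vector<int>& m = poolMv[poolIdx];
    for (int j = 0; j < nm; ++j) newPop(s, j) = m[j];
    newEn[s] = poolEn[poolIdx];
    newAge[s] = elite ? poolAge[poolIdx] + 1 : 0;
  };

  for (int e = 0; e < nE; ++e, ++slot) put(slot, ord[e], true);

  // tournament share: similar mutation probes an equal-fitness group; the
  // best-performing member survives
  std::vector<int> members;
  for (int t = 0; t < nT; ++t, ++slot) {
    int mb = rint(np);
    int seed = ord[rint(mb + 1)];
    int eb = poolEn[seed];
    members.clear();
    members.push_back(seed);
    for (int i = 0; i < np && static_cast<int>(members.size()) < nTs; ++i)
      if (i != seed && poolEn[i] == eb) members.push_back(i);
    OpSpec op = draw_op(L, motifs, motifProb);
    int bestEn = 1, bestIdx = seed;
    for (size_t k = 0; k < members.size(); ++k) {
      int en;
      if (apply_op(op, poolMv[members[k]], f, l, latId, g, out, en)) {
        if (en < bestEn) { bestEn = en; bestIdx = members[k]; }
      }
    }
    put(slot, bestIdx, false);
  }

  // rank share: nested-uniform draws over the sorted pool, without
  // replacement (multiple copies of one individual arise only through
  // elitism and tournaments, preserving diversity in the rank share)
  std::vector<char> used(np, 0);
  for (int e = 0; e < nE; ++e) used[ord[e]] = 1;
  while (slot < n) {
    int pick = -1;
    for (int tries = 0; tries < 8 && pick < 0; ++tries) {
      int m = rint(np);
      int cand = ord[rint(m + 1)];
      if (!used[cand]) pick = cand;
    }
    if (pick < 0) {  // fall back to the best unused pool member
      for (int i = 0; i < np; ++i) if (!used[ord[i]]) { pick = ord[i]; break; }
    }
    used[pick] = 1;
    put(slot, pick, false);
    ++slot;
  }

  return List::create(_["pop"] = newPop, _["energy"] = newEn, _["age"] = newAge,
                      _["op_count"] = opCount, _["op_accept"] = opAccept);
}

namespace {

struct Enum {
  Lat l;
  int L;
  std::vector<char> f;
  Grid* g;
  std::vector<int> xs, ys;
  int best;
  double nbest;
  void dfs(int i, int contacts, bool turned) {
    if (i == L) {
      int en = -contacts;
      if (en < best) { best = en; nbest = 1; }
      else if (en == best) nbest += 1;
      return;
    }
    for (int m = 0; m < l.k; ++m) {
      if (!turned && l.sy[m] < 0) continue;  // reflection canonicalization
      int tx = xs[i - 1] + l.sx[m], ty = ys[i - 1] + l.sy[m];
      if (g->get(tx, ty) >= 0) continue;
      int add = 0;
      if (f[i]) {
        for (int c = 0; c < l.k; ++c) {
          int j = g->get(tx + l.sx[c], ty + l.sy[c]);
          if (j >= 0 && j < i - 1 && f[j]) ++add;
        }
      }
      xs[i] = tx; ys[i] = ty;
      g->set(tx, ty, i);
      dfs(i + 1, contacts + add, turned || l.sy[m] != 0);
      g->set(tx, ty, -1);
    }
  }
};

}  // namespace

// Exhaustive ground-state oracle over the nonisomorphic encoding (first move
// F, first vertical deviation up). Returns the exact minimum energy and the
// number of optimal canonical conformations.
// [[Rcpp::export]]
List cpp_exhaustive(LogicalVector isH, int latId) {
  Enum e;
  e.l = get_lat(latId);
  e.L = isH.size();
  e.f = to_flags(isH);
  if (e.L < 1) stop("empty sequence");
  Grid g(e.L);
  e.g = &g;
  g.clear();
  e.xs.assign(e.L, 0); e.ys.assign(e.L, 0);
  e.best = 1; e.nbest = 0;
  if (e.L == 1) {
    e.best = 0; e.nbest = 1;
  } else {
    e.xs[0] = 0; e.ys[0] = 0; e.xs[1] = 1; e.ys[1] = 0;
    g.set(0, 0, 0); g.set(1, 0, 1);
    e.dfs(2, 0, false);
  }
  return List::create(_["best_energy"] = e.best, _["n_optimal"] = e.nbest);
}
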