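// Cellular Potts lattice engine: effective energy, Metropolis pixel-copy
// dynamics, geometric bookkeeping, reaction-diffusion fields, and the
// structural operations (division, ECM spawning, removal, fragment culling)
// that the R-level behaviour rules drive.
//
// Conventions (shared with the R side):
//  - lattice is a W x H integer grid, 0 = Medium, stored column-major like an
//    R matrix with nrow = W ("x" is the row index);
//  - contact energy / surface / contact counts use the 2nd-order Moore
//    neighbourhood (8 neighbours); copy-attempt adjacency is von Neumann (4);
//  - "surface" of a cell is the number of unlike in-lattice Moore pixel
//    pairs (a, b) with a in the cell, b not in it; off-lattice sites do not
//    form pairs (closed, non-periodic boundary);
//  - coordinates handed to/from R are 1-based; internal storage is 0-based.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

enum CellType { T_MEDIUM = 0, T_FIB = 1, T_MYO = 2, T_MAC = 3,
                T_SNC = 4, T_PRE = 5, T_ECM = 6 };
static const int NTYPES = 7;
static const int NFIELDS = 4; // PDGF, CSF1, MMP, INF

// offsets: first 4 = von Neumann, all 8 = Moore
static const int OX[8] = { 1, -1, 0, 0, 1, 1, -1, -1 };
static const int OY[8] = { 0, 0, 1, -1, 1, -1, 1, -1 };

struct Cell {
  int type = T_MEDIUM;
  bool alive = false;
  double target_volume = 0.0, lambda_vol = 0.0;
  double target_surface = 0.0, lambda_surf = 0.0;
  int volume = 0;
  int surface = 0;
  double sx = 0.0, sy = 0.0;              // coordinate sums (0-based)
  double secr[NFIELDS] = {0, 0, 0, 0};    // per-cell rate, split per pixel
  int chem_field = -1;                    // -1 = no chemotaxis
  double chem_lambda = 0.0, chem_lambda_ecm = 0.0;
  bool on_ecm = false;                    // ECM-contact flag (sweep-updated)
  bool secretes = false;                  // any nonzero secretion rate
};

struct State {
  int W = 0, H = 0;
  std::vector<int> grid;
  std::vector<Cell> cells;                // index = cell id; [0] unused
  std::vector<double> fields[NFIELDS];
  std::vector<double> scratch;
  std::vector<double> J;                  // NTYPES x NTYPES contact energies
  double temperature = 10.0;
  double D[NFIELDS] = {0, 0, 0, 0};
  double decay[NFIELDS] = {0, 0, 0, 0};
  int substeps[NFIELDS] = {1, 1, 1, 1};
  std::mt19937_64 rng;
  long long mcs = 0;
  long long attempts = 0, accepts = 0;
};

typedef XPtr<State> SPtr;

static inline int gidx(const State& S, int x, int y) { return x + y * S.W; }
static inline bool inb(const State& S, int x, int y) {
  return x >= 0 && x < S.W && y >= 0 && y < S.H;
}
static inline int type_of(const State& S, int id) {
  return id ? S.cells[id].type : T_MEDIUM;
}
static inline double jval(const State& S, int t1, int t2) {
  return S.J[t1 * NTYPES + t2];
}
static inline double sq(double v) { return v * v; }
static inline double runif01(State& S) {
  return std::uniform_real_distribution<double>(0.0, 1.0)(S.rng);
}

static void rebuild_caches(State& S) {
  for (size_t i = 1; i < S.cells.size(); ++i) {
    Cell& c = S.cells[i];
    c.volume = 0; c.surface = 0; c.sx = 0.0; c.sy = 0.0;
  }
  for (int y = 0; y < S.H; ++y) {
    for (int x = 0; x < S.W; ++x) {
      int id = S.grid[gidx(S, x, y)];
      if (!id) continue;
      Cell& c = S.cells[id];
      c.volume += 1; c.sx += x; c.sy += y;
      for (int k = 0; k < 8; ++k) {
        int nx = x + OX[k], ny = y + OY[k];
        if (!inb(S, nx, ny)) continue;
        if (S.grid[gidx(S, nx, ny)] != id) c.surface += 1;
      }
    }
  }
  for (size_t i = 1; i < S.cells.size(); ++i) {
    Cell& c = S.cells[i];
    if (c.volume == 0) c.alive = false;
  }
}

// ---- energy ----------------------------------------------------------------

// Energy change for copying the value of pixel (sx,sy) into pixel (tx,ty).
// Includes contact + volume + surface constraints and, optionally, the
// chemotaxis bias of the extending (source) cell.
static double delta_energy(State& S, int sxp, int syp, int txp, int typ,
                           bool with_chemotaxis) {
  int ti = gidx(S, txp, typ);
  int si = gidx(S, sxp, syp);
  int oldv = S.grid[ti];
  int newv = S.grid[si];
  int told = type_of(S, oldv), tnew = type_of(S, newv);

  double dH = 0.0;
  int n_old = 0, n_new = 0, nN = 0;
  for (int k = 0; k < 8; ++k) {
    int nx = txp + OX[k], ny = typ + OY[k];
    if (!inb(S, nx, ny)) continue;
    ++nN;
    int b = S.grid[gidx(S, nx, ny)];
    int tb = type_of(S, b);
    if (b != newv) dH += jval(S, tnew, tb);
    if (b != oldv) dH -= jval(S, told, tb);
    if (b == oldv) ++n_old;
    if (b == newv) ++n_new;
  }
  if (oldv) {
    const Cell& c = S.cells[oldv];
    dH += c.lambda_vol *
          (sq(c.volume - 1 - c.target_volume) - sq(c.volume - c.target_volume));
    int ds = 2 * n_old - nN;
    dH += c.lambda_surf *
          (sq(c.surface + ds - c.target_surface) - sq(c.surface - c.target_surface));
  }
  if (newv) {
    const Cell& c = S.cells[newv];
    dH += c.lambda_vol *
          (sq(c.volume + 1 - c.target_volume) - sq(c.volume - c.target_volume));
    int ds = nN - 2 * n_new;
    dH += c.lambda_surf *
          (sq(c.surface + ds - c.target_surface) - sq(c.surface - c.target_surface));
  }
  if (with_chemotaxis && newv) {
    const Cell& c = S.cells[newv];
    if (c.chem_field >= 0) {
      double lam = c.on_ecm ? c.chem_lambda_ecm : c.chem_lambda;
      if (lam != 0.0)
        dH -= lam * (S.fields[c.chem_field][ti] - S.fields[c.chem_field][si]);
    }
  }
  return dH;
}

// Apply the copy (target pixel takes the source pixel's cell id), updating
// volume / surface / COM caches incrementally.
static void apply_flip(State& S, int txp, int typ, int newv) {
  int ti = gidx(S, txp, typ);
  int oldv = S.grid[ti];
  int n_old = 0, n_new = 0, nN = 0;
  for (int k = 0; k < 8; ++k) {
    int nx = txp + OX[k], ny = typ + OY[k];
    if (!inb(S, nx, ny)) continue;
    ++nN;
    int b = S.grid[gidx(S, nx, ny)];
    if (b == oldv) ++n_old;
    if (b == newv) ++n_new;
  }
  if (oldv) {
    Cell& c = S.cells[oldv];
    c.volume -= 1; c.sx -= txp; c.sy -= typ;
    c.surface += 2 * n_old - nN;
    if (c.volume == 0) { c.alive = false; c.surface = 0; }
  }
  if (newv) {
    Cell& c = S.cells[newv];
    c.volume += 1; c.sx += txp; c.sy += typ;
    c.surface += nN - 2 * n_new;
  }
  S.grid[ti] = newv;
}

static bool attempt_copy(State& S) {
  ++S.attempts;
  uint64_t r = S.rng();
  int ti = (int)((r >> 2) % (uint64_t)(S.W * S.H));
  int txp = ti % S.W, typ = ti / S.W;
  int k = (int)(r & 3u);
  int sxp = txp + OX[k], syp = typ + OY[k];
  if (!inb(S, sxp, syp)) return false;
  if (S.grid[gidx(S, sxp, syp)] == S.grid[ti]) return false;
  double dH = delta_energy(S, sxp, syp, txp, typ, true);
  bool accept = dH <= 0.0 || runif01(S) < std::exp(-dH / S.temperature);
  if (accept) {
    apply_flip(S, txp, typ, S.grid[gidx(S, sxp, syp)]);
    ++S.accepts;
  }
  return accept;
}

// ---- fields ----------------------------------------------------------------

// One forward-Euler substep of 5-point no-flux diffusion plus multiplicative
// decay on a raw buffer. Exactly mass-conserving when decay = 0. The interior
// is updated without bounds checks; edges/corners use the reflecting stencil.
static void diffuse_substep(int W, int H, std::vector<double>& f,
                            std::vector<double>& tmp, double lam, double dec) {
  const double* src = f.data();
  double* dst = tmp.data();
  auto cell = [&](int x, int y) {
    int i = x + y * W;
    double c = src[i], acc = 0.0;
    if (x > 0)      acc += src[i - 1] - c;
    if (x < W - 1)  acc += src[i + 1] - c;
    if (y > 0)      acc += src[i - W] - c;
    if (y < H - 1)  acc += src[i + W] - c;
    double v = (c + lam * acc) * dec;
    dst[i] = v > 0.0 ? v : 0.0;
  };
  for (int x = 0; x < W; ++x) { cell(x, 0); cell(x, H - 1); }
  for (int y = 1; y < H - 1; ++y) {
    cell(0, y); cell(W - 1, y);
    const double* row = src + (size_t)y * W;
    double* out = dst + (size_t)y * W;
    for (int x = 1; x < W - 1; ++x) {
      double c = row[x];
      double v = (c + lam * (row[x - 1] + row[x + 1] + row[x - W] + row[x + W]
                             - 4.0 * c)) * dec;
      out[x] = v > 0.0 ? v : 0.0;
    }
  }
  f.swap(tmp);
}

static void secrete(State& S) {
  int N = S.W * S.H;
  const int* g = S.grid.data();
  for (int i = 0; i < N; ++i) {
    int id = g[i];
    if (!id) continue;
    const Cell& c = S.cells[id];
    if (c.volume <= 0 || !c.secretes) continue;
    double inv = 1.0 / c.volume;
    for (int f = 0; f < NFIELDS; ++f)
      if (c.secr[f] != 0.0) S.fields[f][i] += c.secr[f] * inv;
  }
}

static void step_fields_state(State& S) {
  for (int f = 0; f < NFIELDS; ++f) {
    int m = S.substeps[f];
    double dt = 1.0 / m;
    double lam = S.D[f] * dt;
    double dec = 1.0 - S.decay[f] * dt;
    if (dec < 0.0) dec = 0.0;
    for (int s = 0; s < m; ++s)
      diffuse_substep(S.W, S.H, S.fields[f], S.scratch, lam, dec);
  }
}

// ---- exported API ----------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_state_new(int width, int height, NumericMatrix J, double temperature,
                   NumericVector D, NumericVector decay) {
  State* S = new State();
  S->W = width; S->H = height;
  S->grid.assign((size_t)width * height, 0);
  S->scratch.assign((size_t)width * height, 0.0);
  for (int f = 0; f < NFIELDS; ++f)
    S->fields[f].assign((size_t)width * height, 0.0);
  S->J.assign(NTYPES * NTYPES, 0.0);
  if (J.nrow() != NTYPES || J.ncol() != NTYPES)
    stop("contact-energy matrix must be %d x %d", NTYPES, NTYPES);
  for (int i = 0; i < NTYPES; ++i)
    for (int j = 0; j < NTYPES; ++j)
      S->J[i * NTYPES + j] = J(i, j);
  S->temperature = temperature;
  for (int f = 0; f < NFIELDS; ++f) {
    S->D[f] = D[f]; S->decay[f] = decay[f];
    // keep D*dt <= 0.2: the 1/4 stability limit is non-damping for the
    // highest lattice mode, which a point source excites
    S->substeps[f] = std::max(1, (int)std::ceil(S->D[f] / 0.2 - 1e-12));
  }
  S->cells.resize(1);
  S->rng.seed(1);
  return SPtr(S, true);
}

// [[Rcpp::export]]
void cpp_set_seed(SEXP p, double seed) {
  SPtr S(p); S->rng.seed((uint64_t)seed);
}

// Populate grid + per-cell energy parameters (vectors indexed by cell id
// 1..n) and rebuild all caches.
// [[Rcpp::export]]
void cpp_load(SEXP p, IntegerMatrix grid, IntegerVector type,
              NumericVector target_volume, NumericVector lambda_vol,
              NumericVector target_surface, NumericVector lambda_surf) {
  SPtr S(p);
  if (grid.nrow() != S->W || grid.ncol() != S->H)
    stop("grid dimensions do not match the state");
  int n = type.size();
  S->cells.assign(n + 1, Cell());
  for (int i = 0; i < n; ++i) {
    Cell& c = S->cells[i + 1];
    c.type = type[i];
    c.alive = true;
    c.target_volume = target_volume[i];
    c.lambda_vol = lambda_vol[i];
    c.target_surface = target_surface[i];
    c.lambda_surf = lambda_surf[i];
  }
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x) {
      int id = grid(x, y);
      if (id < 0 || id > n) stop("grid id %d has no cell record", id);
      S->grid[gidx(*S, x, y)] = id;
    }
  rebuild_caches(*S);
  S->mcs = 0;
}

// [[Rcpp::export]]
IntegerMatrix cpp_grid(SEXP p) {
  SPtr S(p);
  IntegerMatrix g(S->W, S->H);
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x) g(x, y) = S->grid[gidx(*S, x, y)];
  return g;
}

// [[Rcpp::export]]
double cpp_mcs(SEXP p) { SPtr S(p); return (double)S->mcs; }

// [[Rcpp::export]]
NumericVector cpp_acceptance(SEXP p) {
  SPtr S(p);
  return NumericVector::create(_["attempts"] = (double)S->attempts,
                               _["accepts"] = (double)S->accepts);
}

// [[Rcpp::export]]
double cpp_delta_energy(SEXP p, int sx, int sy, int tx, int ty,
                        bool chemotaxis = true) {
  SPtr S(p);
  --sx; --sy; --tx; --ty;
  if (!inb(*S, sx, sy) || !inb(*S, tx, ty))
    stop("pixel coordinates out of bounds");
  if (std::abs(sx - tx) + std::abs(sy - ty) != 1)
    stop("source and target must be von Neumann neighbours");
  if (S->grid[gidx(*S, sx, sy)] == S->grid[gidx(*S, tx, ty)])
    stop("source and target pixels belong to the same cell");
  return delta_energy(*S, sx, sy, tx, ty, chemotaxis);
}

// [[Rcpp::export]]
bool cpp_attempt(SEXP p) { SPtr S(p); return attempt_copy(*S); }

// n Monte-Carlo steps; each = W*H copy attempts, then (optionally) one MCS of
// secretion + field integration.
// [[Rcpp::export]]
void cpp_run_mcs(SEXP p, int n, bool do_fields = true) {
  SPtr S(p);
  int A = S->W * S->H;
  for (int s = 0; s < n; ++s) {
    for (int a = 0; a < A; ++a) attempt_copy(*S);
    if (do_fields) { secrete(*S); step_fields_state(*S); }
    ++S->mcs;
  }
}

// Run n MCS (no fields) recording the COM of one cell after every step.
// [[Rcpp::export]]
NumericMatrix cpp_track_com(SEXP p, int id, int n) {
  SPtr S(p);
  if (id <= 0 || id >= (int)S->cells.size() || !S->cells[id].alive)
    stop("unknown cell id");
  NumericMatrix out(n, 2);
  int A = S->W * S->H;
  for (int s = 0; s < n; ++s) {
    for (int a = 0; a < A; ++a) attempt_copy(*S);
    ++S->mcs;
    const Cell& c = S->cells[id];
    if (c.volume == 0) stop("tracked cell vanished at MCS %d", s + 1);
    out(s, 0) = c.sx / c.volume + 1.0;
    out(s, 1) = c.sy / c.volume + 1.0;
  }
  return out;
}

// [[Rcpp::export]]
void cpp_step_fields(SEXP p, bool with_secretion = true) {
  SPtr S(p);
  if (with_secretion) secrete(*S);
  step_fields_state(*S);
}

// Standalone field step on a plain matrix (used by the fields module and as
// the refined-timestep oracle in tests).
// [[Rcpp::export]]
NumericMatrix cpp_diffuse_matrix(NumericMatrix field, double D, double decay,
                                 NumericMatrix secretion, int substeps) {
  int W = field.nrow(), H = field.ncol();
  if (substeps < 1) stop("substeps must be >= 1");
  if (D / substeps > 0.25 + 1e-12)
    stop("explicit-scheme stability requires D/substeps <= 0.25");
  std::vector<double> f((size_t)W * H), tmp((size_t)W * H);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) f[x + y * W] = field(x, y);
  if (secretion.nrow() == W && secretion.ncol() == H)
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) f[x + y * W] += secretion(x, y);
  double dt = 1.0 / substeps;
  double lam = D * dt;
  double dec = 1.0 - decay * dt;
  if (dec < 0.0) dec = 0.0;
  for (int s = 0; s < substeps; ++s) diffuse_substep(W, H, f, tmp, lam, dec);
  NumericMatrix out(W, H);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) out(x, y) = f[x + y * W];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_field(SEXP p, int f) {
  SPtr S(p);
  if (f < 0 || f >= NFIELDS) stop("field index out of range");
  NumericMatrix out(S->W, S->H);
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x) out(x, y) = S->fields[f][gidx(*S, x, y)];
  return out;
}

// [[Rcpp::export]]
void cpp_set_field(SEXP p, int f, NumericMatrix m) {
  SPtr S(p);
  if (f < 0 || f >= NFIELDS) stop("field index out of range");
  if (m.nrow() != S->W || m.ncol() != S->H) stop("field dimensions mismatch");
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x) {
      double v = m(x, y);
      S->fields[f][gidx(*S, x, y)] = v > 0.0 ? v : 0.0;
    }
}

// Subtract `amount` at pixels (xs, ys), clamped at zero (TIMP rule).
// [[Rcpp::export]]
void cpp_field_sub_at(SEXP p, int f, IntegerVector xs, IntegerVector ys,
                      double amount) {
  SPtr S(p);
  if (f < 0 || f >= NFIELDS) stop("field index out of range");
  for (int i = 0; i < xs.size(); ++i) {
    int x = xs[i] - 1, y = ys[i] - 1;
    if (!inb(*S, x, y)) stop("pixel out of bounds");
    double& v = S->fields[f][gidx(*S, x, y)];
    v -= amount;
    if (v < 0.0) v = 0.0;
  }
}

// [[Rcpp::export]]
void cpp_field_add_at(SEXP p, int f, IntegerVector xs, IntegerVector ys,
                      NumericVector amount) {
  SPtr S(p);
  if (f < 0 || f >= NFIELDS) stop("field index out of range");
  for (int i = 0; i < xs.size(); ++i) {
    int x = xs[i] - 1, y = ys[i] - 1;
    if (!inb(*S, x, y)) stop("pixel out of bounds");
    S->fields[f][gidx(*S, x, y)] += amount[i % amount.size()];
  }
}

// [[Rcpp::export]]
double cpp_field_at(SEXP p, int f, int x, int y) {
  SPtr S(p);
  --x; --y;
  if (!inb(*S, x, y)) stop("pixel out of bounds");
  return S->fields[f][gidx(*S, x, y)];
}

// ---- cell queries ----------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_cells_table(SEXP p) {
  SPtr S(p);
  std::vector<int> id, type, volume, surface;
  std::vector<double> comx, comy, tv;
  for (size_t i = 1; i < S->cells.size(); ++i) {
    const Cell& c = S->cells[i];
    if (!c.alive) continue;
    id.push_back((int)i); type.push_back(c.type);
    volume.push_back(c.volume); surface.push_back(c.surface);
    comx.push_back(c.sx / c.volume + 1.0);
    comy.push_back(c.sy / c.volume + 1.0);
    tv.push_back(c.target_volume);
  }
  return DataFrame::create(_["id"] = id, _["type"] = type,
                           _["volume"] = volume, _["surface"] = surface,
                           _["com_x"] = comx, _["com_y"] = comy,
                           _["target_volume"] = tv);
}

// [[Rcpp::export]]
NumericVector cpp_com(SEXP p, int id) {
  SPtr S(p);
  if (id <= 0 || id >= (int)S->cells.size() || !S->cells[id].alive)
    stop("unknown cell id %d", id);
  const Cell& c = S->cells[id];
  return NumericVector::create(c.sx / c.volume + 1.0, c.sy / c.volume + 1.0);
}

// Contact pixel-pair count between one cell and any cell of the given type
// (Moore neighbourhood; type 0 = Medium).
// [[Rcpp::export]]
int cpp_contact_surface(SEXP p, int id, int other_type) {
  SPtr S(p);
  if (id <= 0 || id >= (int)S->cells.size() || !S->cells[id].alive)
    stop("unknown cell id %d", id);
  int count = 0;
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x) {
      if (S->grid[gidx(*S, x, y)] != id) continue;
      for (int k = 0; k < 8; ++k) {
        int nx = x + OX[k], ny = y + OY[k];
        if (!inb(*S, nx, ny)) continue;
        int b = S->grid[gidx(*S, nx, ny)];
        if (b != id && type_of(*S, b) == other_type) ++count;
      }
    }
  return count;
}

// Per-cell census used once per behaviour sweep: geometry, contact pairs with
// Medium and each cell type, and the four field values at the COM pixel
// (round-half-up convention).
// [[Rcpp::export]]
DataFrame cpp_sweep_census(SEXP p) {
  SPtr S(p);
  size_t n = S->cells.size();
  std::vector<std::array<int, NTYPES>> contact(n);
  for (size_t i = 0; i < n; ++i) contact[i].fill(0);
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x) {
      int a = S->grid[gidx(*S, x, y)];
      if (!a) continue;
      for (int k = 0; k < 8; ++k) {
        int nx = x + OX[k], ny = y + OY[k];
        if (!inb(*S, nx, ny)) continue;
        int b = S->grid[gidx(*S, nx, ny)];
        if (b != a) contact[a][type_of(*S, b)] += 1;
      }
    }
  std::vector<int> id, type, volume, surface;
  std::vector<int> cmed, cfib, cmyo, cmac, csnc, cpre, cecm;
  std::vector<double> comx, comy, tv;
  std::vector<double> fv[NFIELDS];
  for (size_t i = 1; i < n; ++i) {
    const Cell& c = S->cells[i];
    if (!c.alive || c.volume == 0) continue;
    id.push_back((int)i); type.push_back(c.type);
    volume.push_back(c.volume); surface.push_back(c.surface);
    tv.push_back(c.target_volume);
    cmed.push_back(contact[i][T_MEDIUM]); cfib.push_back(contact[i][T_FIB]);
    cmyo.push_back(contact[i][T_MYO]);   cmac.push_back(contact[i][T_MAC]);
    csnc.push_back(contact[i][T_SNC]);   cpre.push_back(contact[i][T_PRE]);
    cecm.push_back(contact[i][T_ECM]);
    double cx = c.sx / c.volume, cy = c.sy / c.volume;
    comx.push_back(cx + 1.0); comy.push_back(cy + 1.0);
    int px = (int)std::floor(cx + 0.5), py = (int)std::floor(cy + 0.5);
    px = std::min(std::max(px, 0), S->W - 1);
    py = std::min(std::max(py, 0), S->H - 1);
    for (int f = 0; f < NFIELDS; ++f)
      fv[f].push_back(S->fields[f][gidx(*S, px, py)]);
  }
  return DataFrame::create(
      _["id"] = id, _["type"] = type, _["volume"] = volume,
      _["surface"] = surface, _["target_volume"] = tv,
      _["com_x"] = comx, _["com_y"] = comy,
      _["c_medium"] = cmed, _["c_fib"] = cfib, _["c_myo"] = cmyo,
      _["c_mac"] = cmac, _["c_snc"] = csnc, _["c_pre"] = cpre,
      _["c_ecm"] = cecm,
      _["f_pdgf"] = fv[0], _["f_csf1"] = fv[1], _["f_mmp"] = fv[2],
      _["f_inf"] = fv[3]);
}

// Contact pairs between every cell and any member of `ids` (e.g. the set of
// fibrogenic-phase senescent cells). Returns a vector indexed by cell id.
// [[Rcpp::export]]
IntegerVector cpp_contact_with_ids(SEXP p, IntegerVector ids) {
  SPtr S(p);
  size_t n = S->cells.size();
  std::vector<char> mark(n, 0);
  for (int i = 0; i < ids.size(); ++i) {
    int v = ids[i];
    if (v > 0 && v < (int)n) mark[v] = 1;
  }
  IntegerVector out(n, 0);
  for (int y = 0; y < S->H; ++y)
    for (int x = 0; x < S->W; ++x) {
      int a = S->grid[gidx(*S, x, y)];
      if (!a) continue;
      for (int k = 0; k < 8; ++k) {
        int nx = x + OX[k], ny = y + OY[k];
        if (!inb(*S, nx, ny)) continue;
        int b = S->grid[gidx(*S, nx, ny)];
        if (b != a && b && mark[b]) out[a] += 1;
      }
    }
  return out;
}

// ---- per-cell attribute setters -------------------------------------------

// [[Rcpp::export]]
void cpp_set_type(SEXP p, IntegerVector ids, IntegerVector types) {
  SPtr S(p);
  for (int i = 0; i < ids.size(); ++i) {
    int id = ids[i];
    if (id <= 0 || id >= (int)S->cells.size()) stop("unknown cell id %d", id);
    S->cells[id].type = types[i % types.size()];
  }
}

// [[Rcpp::export]]
void cpp_set_target_volume(SEXP p, IntegerVector ids, NumericVector tv) {
  SPtr S(p);
  for (int i = 0; i < ids.size(); ++i) {
    int id = ids[i];
    if (id <= 0 || id >= (int)S->cells.size()) stop("unknown cell id %d", id);
    S->cells[id].target_volume = tv[i % tv.size()];
  }
}

// [[Rcpp::export]]
void cpp_set_secretion(SEXP p, IntegerVector ids, NumericMatrix rates) {
  SPtr S(p);
  if (rates.ncol() != NFIELDS) stop("secretion matrix must have 4 columns");
  for (int i = 0; i < ids.size(); ++i) {
    int id = ids[i];
    if (id <= 0 || id >= (int)S->cells.size()) stop("unknown cell id %d", id);
    bool any = false;
    for (int f = 0; f < NFIELDS; ++f) {
      S->cells[id].secr[f] = rates(i, f);
      if (rates(i, f) != 0.0) any = true;
    }
    S->cells[id].secretes = any;
  }
}

// [[Rcpp::export]]
void cpp_set_chemotaxis(SEXP p, IntegerVector ids, IntegerVector field,
                        NumericVector lambda, NumericVector lambda_ecm,
                        LogicalVector on_ecm) {
  SPtr S(p);
  for (int i = 0; i < ids.size(); ++i) {
    int id = ids[i];
    if (id <= 0 || id >= (int)S->cells.size()) stop("unknown cell id %d", id);
    Cell& c = S->cells[id];
    c.chem_field = field[i % field.size()];
    c.chem_lambda = lambda[i % lambda.size()];
    c.chem_lambda_ecm = lambda_ecm[i % lambda_ecm.size()];
    c.on_ecm = on_ecm[i % on_ecm.size()];
  }
}

// ---- structural operations -------------------------------------------------

// [[Rcpp::export]]
void cpp_remove_cells(SEXP p, IntegerVector ids) {
  SPtr S(p);
  if (ids.size() == 0) return;
  std::vector<char> mark(S->cells.size(), 0);
  for (int i = 0; i < ids.size(); ++i) {
    int id = ids[i];
    if (id <= 0 || id >= (int)S->cells.size()) stop("unknown cell id %d", id);
    mark[id] = 1;
    S->cells[id].alive = false;
  }
  int N = S->W * S->H;
  for (int i = 0; i < N; ++i)
    if (S->grid[i] && mark[S->grid[i]]) S->grid[i] = 0;
  rebuild_caches(*S);
}

// Mitosis: split each listed cell along a random line through its COM. Both
// halves keep the parent's energy/secretion/chemotaxis parameters; R resets
// target volumes and copies behaviour flags afterwards. Returns the
// parent -> daughter id map (parents whose split failed are omitted).
// [[Rcpp::export]]
DataFrame cpp_divide_cells(SEXP p, IntegerVector ids) {
  SPtr S(p);
  std::unordered_map<int, std::vector<int>> pix;
  for (int i = 0; i < ids.size(); ++i) {
    int id = ids[i];
    if (id <= 0 || id >= (int)S->cells.size() || !S->cells[id].alive)
      stop("unknown cell id %d", id);
    pix[id] = {};
  }
  int N = S->W * S->H;
  for (int i = 0; i < N; ++i) {
    auto it = pix.find(S->grid[i]);
    if (it != pix.end()) it->second.push_back(i);
  }
  std::vector<int> parents, daughters;
  bool changed = false;
  for (int i = 0; i < ids.size(); ++i) {
    int id = ids[i];
    std::vector<int>& px = pix[id];
    if (px.size() < 2) continue;
    const Cell& c = S->cells[id];
    double cx = c.sx / c.volume, cy = c.sy / c.volume;
    bool ok = false;
    std::vector<char> side(px.size(), 0);
    for (int attempt = 0; attempt < 24 && !ok; ++attempt) {
      double th = runif01(*S) * 2.0 * M_PI;
      double nx = std::cos(th), ny = std::sin(th);
      int na = 0, nb = 0;
      for (size_t j = 0; j < px.size(); ++j) {
        int x = px[j] % S->W, y = px[j] / S->W;
        double d = (x - cx) * nx + (y - cy) * ny;
        side[j] = d >= 0 ? 1 : 0;
        if (side[j]) ++na; else ++nb;
      }
      ok = na > 0 && nb > 0;
    }
    if (!ok) continue;
    int nid = (int)S->cells.size();
    Cell d = S->cells[id];          // copy parameters
    d.volume = 0; d.surface = 0; d.sx = 0; d.sy = 0;
    S->cells.push_back(d);
    for (size_t j = 0; j < px.size(); ++j)
      if (side[j]) S->grid[px[j]] = nid;
    parents.push_back(id);
    daughters.push_back(nid);
    changed = true;
  }
  if (changed) rebuild_caches(*S);
  return DataFrame::create(_["parent"] = parents, _["daughter"] = daughters);
}

// Spawn one-pixel ECM cells on Medium pixels von-Neumann-adjacent to each
// producer; counts[i] requested per producer. Returns the number spawned.
// [[Rcpp::export]]
IntegerVector cpp_spawn_ecm(SEXP p, IntegerVector ids, IntegerVector counts,
                            double target_volume, double lambda_vol,
                            double target_surface, double lambda_surf) {
  SPtr S(p);
  std::unordered_map<int, std::vector<int>> cand;
  for (int i = 0; i < ids.size(); ++i) cand[ids[i]] = {};
  std::vector<int> stamp((size_t)S->W * S->H, -1);
  int N = S->W * S->H;
  for (int i = 0; i < N; ++i) {
    int a = S->grid[i];
    if (!a) continue;
    auto it = cand.find(a);
    if (it == cand.end()) continue;
    int x = i % S->W, y = i / S->W;
    for (int k = 0; k < 4; ++k) {
      int nx = x + OX[k], ny = y + OY[k];
      if (!inb(*S, nx, ny)) continue;
      int ni = gidx(*S, nx, ny);
      if (S->grid[ni] == 0 && stamp[ni] != a) {
        stamp[ni] = a;
        it->second.push_back(ni);
      }
    }
  }
  IntegerVector spawned(ids.size(), 0);
  bool changed = false;
  for (int i = 0; i < ids.size(); ++i) {
    std::vector<int>& cs = cand[ids[i]];
    std::shuffle(cs.begin(), cs.end(), S->rng);
    int want = counts[i];
    for (size_t j = 0; j < cs.size() && spawned[i] < want; ++j) {
      if (S->grid[cs[j]] != 0) continue;   // taken by an earlier producer
      int nid = (int)S->cells.size();
      Cell c;
      c.type = T_ECM; c.alive = true;
      c.target_volume = target_volume; c.lambda_vol = lambda_vol;
      c.target_surface = target_surface; c.lambda_surf = lambda_surf;
      S->cells.push_back(c);
      S->grid[cs[j]] = nid;
      ++spawned[i];
      changed = true;
    }
  }
  if (changed) rebuild_caches(*S);
  return spawned;
}

// Lazy connectivity repair: for cells split into several 4-connected
// components, components smaller than 2 pixels (other than the largest) are
// culled to Medium. Returns ids of cells removed entirely (volume hit zero).
// [[Rcpp::export]]
IntegerVector cpp_cull_fragments(SEXP p) {
  SPtr S(p);
  int N = S->W * S->H;
  std::vector<int> label(N, -1);
  // component id -> (cell id, size); grid flood fill
  std::vector<int> comp_cell, comp_size;
  std::vector<int> stack;
  for (int i = 0; i < N; ++i) {
    if (S->grid[i] == 0 || label[i] >= 0) continue;
    int cellid = S->grid[i];
    int cid = (int)comp_cell.size();
    comp_cell.push_back(cellid);
    comp_size.push_back(0);
    stack.clear(); stack.push_back(i); label[i] = cid;
    while (!stack.empty()) {
      int j = stack.back(); stack.pop_back();
      comp_size[cid] += 1;
      int x = j % S->W, y = j / S->W;
      for (int k = 0; k < 4; ++k) {
        int nx = x + OX[k], ny = y + OY[k];
        if (!inb(*S, nx, ny)) continue;
        int nj = gidx(*S, nx, ny);
        if (label[nj] < 0 && S->grid[nj] == cellid) {
          label[nj] = cid; stack.push_back(nj);
        }
      }
    }
  }
  // largest component per cell
  std::unordered_map<int, int> best;     // cell id -> comp id
  std::unordered_map<int, int> ncomp;
  for (size_t cid = 0; cid < comp_cell.size(); ++cid) {
    int cell = comp_cell[cid];
    ncomp[cell] += 1;
    auto it = best.find(cell);
    if (it == best.end() || comp_size[cid] > comp_size[it->second])
      best[cell] = (int)cid;
  }
  std::vector<char> cull(comp_cell.size(), 0);
  bool any = false;
  for (size_t cid = 0; cid < comp_cell.size(); ++cid) {
    int cell = comp_cell[cid];
    if (ncomp[cell] > 1 && (int)cid != best[cell] && comp_size[cid] < 2) {
      cull[cid] = 1; any = true;
    }
  }
  std::vector<int> removed;
  if (any) {
    for (int i = 0; i < N; ++i)
      if (S->grid[i] && label[i] >= 0 && cull[label[i]]) S->grid[i] = 0;
    rebuild_caches(*S);
  }
  for (size_t i = 1; i < S->cells.size(); ++i)
    if (S->cells[i].alive && S->cells[i].volume == 0) {
      S->cells[i].alive = false;
      removed.push_back((int)i);
    }
  return wrap(removed);
}

// [[Rcpp::export]]
void cpp_rebuild_caches(SEXP p) { SPtr S(p); rebuild_caches(*S); }
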