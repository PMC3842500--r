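#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Monte-Carlo streamline propagation through a fibre-orientation-distribution
// field (PICo style). The FOD is represented by its amplitudes on a fixed
// sphere point set, precomputed per masked voxel; because the amplitude is
// linear in the SH coefficients, trilinear interpolation of per-voxel
// amplitudes is identical to interpolating the SH coefficients first.
//
// Conventions: voxel indices are 0-based, voxel centres sit at integer
// continuous coordinates, world coordinates in mm via the affine.

namespace {

// termination codes (keep in sync with R side)
const int TERM_NONE = 0;
const int TERM_CURVATURE = 1;
const int TERM_MAX_LENGTH = 2;
const int TERM_EXITED_MASK = 3;
const int TERM_LOW_FOD = 4;

struct Field {
  const double* ampT;   // nsph x nmask, column per masked voxel
  int nsph, nmask;
  const int* idx;       // nx*ny*nz, 0-based column into ampT, or -1
  int nx, ny, nz;
  const double* dirs;   // nsph x 3, column-major (R matrix layout)
  double minv[12];      // world -> continuous voxel coords (3 x 4, row-major)
  double aff[12];       // continuous voxel coords -> world (3 x 4, row-major)
  bool nearest;         // nearest-neighbour instead of trilinear lookup
};

inline void world2vox(const Field& f, const double* p, double* v) {
  for (int r = 0; r < 3; ++r)
    v[r] = f.minv[4 * r] * p[0] + f.minv[4 * r + 1] * p[1] +
           f.minv[4 * r + 2] * p[2] + f.minv[4 * r + 3];
}

inline void vox2world(const Field& f, const double* v, double* p) {
  for (int r = 0; r < 3; ++r)
    p[r] = f.aff[4 * r] * v[0] + f.aff[4 * r + 1] * v[1] +
           f.aff[4 * r + 2] * v[2] + f.aff[4 * r + 3];
}

inline long voxlin(const Field& f, int i, int j, int k) {
  return (long)i + (long)f.nx * ((long)j + (long)f.ny * (long)k);
}

inline bool in_grid(const Field& f, int i, int j, int k) {
  return i >= 0 && j >= 0 && k >= 0 && i < f.nx && j < f.ny && k < f.nz;
}

// voxel index containing a continuous voxel coordinate
inline bool containing_voxel(const Field& f, const double* v, int* out) {
  for (int r = 0; r < 3; ++r) out[r] = (int)std::lround(v[r]);
  return in_grid(f, out[0], out[1], out[2]);
}

inline bool voxel_in_mask(const Field& f, const int* vx) {
  return in_grid(f, vx[0], vx[1], vx[2]) &&
         f.idx[voxlin(f, vx[0], vx[1], vx[2])] >= 0;
}

// trilinearly interpolate FOD amplitudes at continuous voxel coordinate v;
// returns false when no in-mask neighbour contributes
inline bool interp_amp(const Field& f, const double* v, double* buf) {
  if (f.nearest) {
    int vx[3];
    if (!containing_voxel(f, v, vx)) return false;
    int col = f.idx[voxlin(f, vx[0], vx[1], vx[2])];
    if (col < 0) return false;
    const double* colp = f.ampT + (size_t)col * f.nsph;
    for (int i = 0; i < f.nsph; ++i) buf[i] = colp[i];
    return true;
  }
  int b[3];
  double fr[3];
  for (int r = 0; r < 3; ++r) {
    b[r] = (int)std::floor(v[r]);
    fr[r] = v[r] - b[r];
  }
  for (int i = 0; i < f.nsph; ++i) buf[i] = 0.0;
  bool any = false;
  for (int c = 0; c < 8; ++c) {
    int i = b[0] + (c & 1), j = b[1] + ((c >> 1) & 1), k = b[2] + ((c >> 2) & 1);
    if (!in_grid(f, i, j, k)) continue;
    int col = f.idx[voxlin(f, i, j, k)];
    if (col < 0) continue;
    double w = ((c & 1) ? fr[0] : 1.0 - fr[0]) *
               (((c >> 1) & 1) ? fr[1] : 1.0 - fr[1]) *
               (((c >> 2) & 1) ? fr[2] : 1.0 - fr[2]);
    if (w <= 0.0) continue;
    const double* colp = f.ampT + (size_t)col * f.nsph;
    for (int i2 = 0; i2 < f.nsph; ++i2) buf[i2] += w * colp[i2];
    any = true;
  }
  return any;
}

// draw a direction with probability proportional to the (non-negative) FOD
// amplitude over the suprathreshold support, restricted to the hemisphere
// within 90 degrees of prev (if have_prev). Amplitudes below thresh carry no
// probability mass (the standard cutoff of amplitude-sampled CSD tracking);
// an empty support signals low_fod (-1).
inline int sample_dir(const Field& f, const double* buf, const double* prev,
                      bool have_prev, double thresh) {
  double total = 0.0;
  for (int i = 0; i < f.nsph; ++i) {
    double a = buf[i];
    if (a <= 0.0 || a < thresh) continue;
    if (have_prev) {
      double dot = f.dirs[i] * prev[0] + f.dirs[i + f.nsph] * prev[1] +
                   f.dirs[i + 2 * f.nsph] * prev[2];
      if (dot <= 0.0) continue;
    }
    total += a;
  }
  if (total <= 0.0) return -1;
  double u = unif_rand() * total;
  double acc = 0.0;
  int last = -1;
  for (int i = 0; i < f.nsph; ++i) {
    double a = buf[i];
    if (a <= 0.0 || a < thresh) continue;
    if (have_prev) {
      double dot = f.dirs[i] * prev[0] + f.dirs[i + f.nsph] * prev[1] +
                   f.dirs[i + 2 * f.nsph] * prev[2];
      if (dot <= 0.0) continue;
    }
    acc += a;
    last = i;
    if (acc >= u) return i;
  }
  return last;  // floating-point guard
}

struct Visitor {
  std::vector<int>* stamp;       // per-voxel streamline id stamp
  std::vector<long>* touched;    // linear voxel ids visited this streamline
  int id;
  void visit(const Field& f, const int* vx) {
    if (!in_grid(f, vx[0], vx[1], vx[2])) return;
    long lin = voxlin(f, vx[0], vx[1], vx[2]);
    if ((*stamp)[lin] != id) {
      (*stamp)[lin] = id;
      touched->push_back(lin);
    }
  }
};

// propagate one half-track from p0 (world mm). Appends step points to `rec`
// when rec != NULL, marks visited voxels through `vis` when vis != NULL.
// first_dir: output of the first accepted step direction (when steps > 0).
// Returns termination reason; steps_used set to the number of steps taken.
int propagate_half(const Field& f, const double* p0, const double* prev0,
                   bool have_prev0, int budget, double step, double curv_limit,
                   double thresh, std::vector<double>* rec, Visitor* vis,
                   double* first_dir, int* steps_used, double* amp_buf) {
  double p[3] = {p0[0], p0[1], p0[2]};
  double prev[3] = {0, 0, 0};
  bool have_prev = have_prev0;
  if (have_prev0) { prev[0] = prev0[0]; prev[1] = prev0[1]; prev[2] = prev0[2]; }
  double v[3];
  int cur_vox[3];
  world2vox(f, p, v);
  if (!containing_voxel(f, v, cur_vox) || !voxel_in_mask(f, cur_vox)) {
    *steps_used = 0;
    return TERM_EXITED_MASK;
  }
  double cum_turn = 0.0;
  int steps = 0;
  while (true) {
    if (steps >= budget) { *steps_used = steps; return TERM_MAX_LENGTH; }
    world2vox(f, p, v);
    if (!interp_amp(f, v, amp_buf)) { *steps_used = steps; return TERM_EXITED_MASK; }
    int di = sample_dir(f, amp_buf, prev, have_prev, thresh);
    if (di < 0) { *steps_used = steps; return TERM_LOW_FOD; }
    double d[3] = {f.dirs[di], f.dirs[di + f.nsph], f.dirs[di + 2 * f.nsph]};
    if (have_prev) {
      double dot = d[0] * prev[0] + d[1] * prev[1] + d[2] * prev[2];
      if (dot > 1.0) dot = 1.0;
      if (dot < -1.0) dot = -1.0;
      cum_turn += std::acos(dot) * 180.0 / M_PI;
      if (cum_turn > curv_limit) { *steps_used = steps; return TERM_CURVATURE; }
    }
    // advance
    p[0] += step * d[0];
    p[1] += step * d[1];
    p[2] += step * d[2];
    ++steps;
    if (steps == 1 && first_dir) {
      first_dir[0] = d[0]; first_dir[1] = d[1]; first_dir[2] = d[2];
    }
    prev[0] = d[0]; prev[1] = d[1]; prev[2] = d[2];
    have_prev = true;
    world2vox(f, p, v);
    int vx[3];
    bool inb = containing_voxel(f, v, vx);
    if (!inb || !voxel_in_mask(f, vx)) {
      // the exit point itself is recorded/visited, then tracking stops
      if (rec) { rec->push_back(p[0]); rec->push_back(p[1]); rec->push_back(p[2]); }
      if (vis && inb) vis->visit(f, vx);
      *steps_used = steps;
      return TERM_EXITED_MASK;
    }
    if (rec) { rec->push_back(p[0]); rec->push_back(p[1]); rec->push_back(p[2]); }
    if (vis) vis->visit(f, vx);
    if (vx[0] != cur_vox[0] || vx[1] != cur_vox[1] || vx[2] != cur_vox[2]) {
      cum_turn = 0.0;
      cur_vox[0] = vx[0]; cur_vox[1] = vx[1]; cur_vox[2] = vx[2];
    }
  }
}

Field make_field(const NumericMatrix& ampT, const IntegerVector& idxgrid,
                 const IntegerVector& dim, const NumericMatrix& dirs,
                 const NumericMatrix& minv, const NumericMatrix& affine,
                 bool nearest) {
  Field f;
  f.nearest = nearest;
  f.ampT = ampT.begin();
  f.nsph = ampT.nrow();
  f.nmask = ampT.ncol();
  f.idx = idxgrid.begin();
  f.nx = dim[0]; f.ny = dim[1]; f.nz = dim[2];
  f.dirs = dirs.begin();
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) {
      f.minv[4 * r + c] = minv(r, c);
      f.aff[4 * r + c] = affine(r, c);
    }
  return f;
}

// combined bidirectional propagation used by both the single-streamline and
// the bulk entry points
int propagate_both(const Field& f, const double* p0, int total_budget,
                   double step, double curv_limit, double thresh,
                   std::vector<double>* rec1, std::vector<double>* rec2,
                   Visitor* vis, int* total_steps, double* amp_buf) {
  double d0[3] = {0, 0, 0};
  int steps1 = 0, steps2 = 0;
  int r1 = propagate_half(f, p0, NULL, false, total_budget, step, curv_limit,
                          thresh, rec1, vis, d0, &steps1, amp_buf);
  int budget2 = total_budget - steps1;
  int r2 = TERM_NONE;
  if (budget2 > 0) {
    double nd0[3] = {-d0[0], -d0[1], -d0[2]};
    bool have = steps1 > 0;
    steps2 = 0;
    r2 = propagate_half(f, p0, nd0, have, budget2, step, curv_limit, thresh,
                        rec2, vis, NULL, &steps2, amp_buf);
  }
  *total_steps = steps1 + steps2;
  if (*total_steps >= total_budget) return TERM_MAX_LENGTH;
  return (r2 != TERM_NONE && steps2 >= 0 && budget2 > 0) ? r2 : r1;
}

}  // namespace

// Track n_per_seed streamlines from each seed voxel, with uniform start-point
// jitter inside the voxel; per-streamline binary visitation counting.
// Returns a list of integer count vectors (one per seed voxel, length
// prod(dim)).
// [[Rcpp::export]]
List cpp_track_voxels(NumericMatrix ampT, IntegerVector idxgrid,
                      IntegerVector dim, NumericMatrix dirs,
                      NumericMatrix minv, NumericMatrix affine,
                      IntegerMatrix seed_voxels, int n_per_seed, double step,
                      double max_path, double curv_limit, double thresh,
                      bool nearest) {
  Field f = make_field(ampT, idxgrid, dim, dirs, minv, affine, nearest);
  int total_budget = (int)std::floor(max_path / step + 1e-9);
  long nvox = (long)f.nx * f.ny * f.nz;
  std::vector<double> amp_buf(f.nsph);
  List out(seed_voxels.nrow());

  for (int s = 0; s < seed_voxels.nrow(); ++s) {
    IntegerVector counts(nvox);
    std::vector<int> stamp(nvox, -1);
    std::vector<long> touched;
    int seed_vx[3] = {seed_voxels(s, 0), seed_voxels(s, 1), seed_voxels(s, 2)};
    for (int t = 0; t < n_per_seed; ++t) {
      touched.clear();
      Visitor vis{&stamp, &touched, t};
      // jittered start point within the seed voxel
      double v0[3], p0[3];
      for (int r = 0; r < 3; ++r) v0[r] = seed_vx[r] + (unif_rand() - 0.5);
      vox2world(f, v0, p0);
      vis.visit(f, seed_vx);
      int total_steps = 0;
      propagate_both(f, p0, total_budget, step, curv_limit, thresh, NULL, NULL,
                     &vis, &total_steps, amp_buf.data());
      for (size_t u = 0; u < touched.size(); ++u) counts[touched[u]] += 1;
      if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    out[s] = counts;
  }
  return out;
}

// Propagate a single bidirectional streamline from a world-mm seed point.
// Returns the ordered point list and the termination reason code.
// [[Rcpp::export]]
List cpp_propagate(NumericMatrix ampT, IntegerVector idxgrid, IntegerVector dim,
                   NumericMatrix dirs, NumericMatrix minv, NumericMatrix affine,
                   NumericVector seed_point, double step, double max_path,
                   double curv_limit, double thresh, bool nearest) {
  Field f = make_field(ampT, idxgrid, dim, dirs, minv, affine, nearest);
  int total_budget = (int)std::floor(max_path / step + 1e-9);
  std::vector<double> amp_buf(f.nsph);
  std::vector<double> rec1, rec2;
  double p0[3] = {seed_point[0], seed_point[1], seed_point[2]};
  int total_steps = 0;
  int reason = propagate_both(f, p0, total_budget, step, curv_limit, thresh,
                              &rec1, &rec2, NULL, &total_steps, amp_buf.data());
  // assemble: reversed half2, seed, half1
  int n2 = rec2.size() / 3, n1 = rec1.size() / 3;
  NumericMatrix pts(n1 + n2 + 1, 3);
  for (int i = 0; i < n2; ++i)
    for (int r = 0; r < 3; ++r) pts(i, r) = rec2[3 * (n2 - 1 - i) + r];
  for (int r = 0; r < 3; ++r) pts(n2, r) = p0[r];
  for (int i = 0; i < n1; ++i)
    for (int r = 0; r < 3; ++r) pts(n2 + 1 + i, r) = rec1[3 * i + r];
  return List::create(Named("points") = pts, Named("reason") = reason,
                      Named("n_steps") = total_steps);
}

// Draw n directions from the FOD at a world-mm position (shared sampling core
// with the tracker). Returns the drawn unit vectors; errors are signalled by
// ok = FALSE when every permitted amplitude is below thresh.
// [[Rcpp::export]]
List cpp_sample_directions(NumericMatrix ampT, IntegerVector idxgrid,
                           IntegerVector dim, NumericMatrix dirs,
                           NumericMatrix minv, NumericMatrix affine,
                           NumericVector position, Nullable<NumericVector> prev,
                           int n, double thresh, bool nearest) {
  Field f = make_field(ampT, idxgrid, dim, dirs, minv, affine, nearest);
  std::vector<double> amp_buf(f.nsph);
  double p[3] = {position[0], position[1], position[2]};
  double v[3];
  world2vox(f, p, v);
  bool have_prev = prev.isNotNull();
  double pv[3] = {0, 0, 0};
  if (have_prev) {
    NumericVector pd(prev);
    pv[0] = pd[0]; pv[1] = pd[1]; pv[2] = pd[2];
  }
  if (!interp_amp(f, v, amp_buf.data()))
    return List::create(Named("ok") = false, Named("directions") = R_NilValue);
  NumericMatrix out(n, 3);
  for (int t = 0; t < n; ++t) {
    int di = sample_dir(f, amp_buf.data(), pv, have_prev, thresh);
    if (di < 0)
      return List::create(Named("ok") = false, Named("directions") = R_NilValue);
    out(t, 0) = f.dirs[di];
    out(t, 1) = f.dirs[di + f.nsph];
    out(t, 2) = f.dirs[di + 2 * f.nsph];
  }
  return List::create(Named("ok") = true, Named("directions") = out);
}
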