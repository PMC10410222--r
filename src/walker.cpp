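// Reflecting Brownian random-walk core.
//
// Geometry: an infinite periodic lattice (period 2p per axis) of identical
// solids, each solid given as a small set of disjoint axis-aligned boxes in
// the local frame of a cell centre; cell centres sit at odd multiples of p,
// so the global origin is a lattice vertex. Each Gaussian step is ray-traced
// against the faces of every solid box in the (at most 8) cells overlapping
// the segment's bounding box and specularly reflected at the first
// intersection until the step length is consumed.
//
// Units: micrometres and seconds throughout.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// xoshiro256++ (public-domain algorithm) seeded via splitmix64: the walker
// draws ~1e10 deviates in a full study run, so it needs a lean generator
// with an explicit recorded seed.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Marsaglia polar method with one cached deviate.
struct NormalGen {
  Xoshiro rng;
  bool has_spare = false;
  double spare = 0.0;
  explicit NormalGen(uint64_t seed) : rng(seed) {}
  inline double draw() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * rng.unif() - 1.0;
      v = 2.0 * rng.unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

struct Geometry {
  std::vector<double> lo;   // 3*k, local frame
  std::vector<double> hi;
  int nbox = 0;
  double p = 1.0;           // lattice half-period
  double a = 0.0;           // half-extent of the solid in the local frame
  bool empty = true;
};

// First intersection of segment x -> x + d with any solid box of any cell
// overlapping the segment AABB. Returns axis (0..2) of the face hit, or -1.
// On hit: *thit in (tmin_eps, 1], *face = global face coordinate.
inline int first_hit(const Geometry& g, const double x[3], const double d[3],
                     double* thit, double* face) {
  if (g.empty) return -1;
  const double twop = 2.0 * g.p;
  double mn[3], mx[3];
  long klo[3], khi[3];
  for (int k = 0; k < 3; ++k) {
    const double e = x[k] + d[k];
    mn[k] = x[k] < e ? x[k] : e;
    mx[k] = x[k] < e ? e : x[k];
    klo[k] = (long)std::floor(mn[k] / twop);
    khi[k] = (long)std::floor(mx[k] / twop);
  }
  const double EPS = 1e-13;
  double best_t = 2.0; int best_axis = -1; double best_face = 0.0;
  for (long ix = klo[0]; ix <= khi[0]; ++ix)
    for (long iy = klo[1]; iy <= khi[1]; ++iy)
      for (long iz = klo[2]; iz <= khi[2]; ++iz) {
        const double c[3] = {(2 * ix + 1) * g.p, (2 * iy + 1) * g.p,
                             (2 * iz + 1) * g.p};
        // skip cells whose solid cube cannot touch the segment AABB
        if (mx[0] < c[0] - g.a || mn[0] > c[0] + g.a ||
            mx[1] < c[1] - g.a || mn[1] > c[1] + g.a ||
            mx[2] < c[2] - g.a || mn[2] > c[2] + g.a)
          continue;
        double u[3] = {x[0] - c[0], x[1] - c[1], x[2] - c[2]};
        for (int b = 0; b < g.nbox; ++b) {
          const double* lo = &g.lo[3 * b];
          const double* hi = &g.hi[3 * b];
          double tmin = -1e300, tmax = 1e300;
          int axis = -1; double fc = 0.0;
          bool miss = false;
          for (int k = 0; k < 3; ++k) {
            if (d[k] == 0.0) {
              if (u[k] <= lo[k] || u[k] >= hi[k]) { miss = true; break; }
            } else {
              const double inv = 1.0 / d[k];
              double t1 = (lo[k] - u[k]) * inv;
              double t2 = (hi[k] - u[k]) * inv;
              double fnear = lo[k], ffar = hi[k];
              if (t1 > t2) { std::swap(t1, t2); std::swap(fnear, ffar); }
              if (t1 > tmin) { tmin = t1; axis = k; fc = fnear + c[k]; }
              if (t2 < tmax) tmax = t2;
              if (tmin >= tmax) { miss = true; break; }
            }
          }
          if (miss || axis < 0) continue;
          if (tmin > EPS && tmin <= 1.0 && tmin < best_t) {
            best_t = tmin; best_axis = axis; best_face = fc;
          }
        }
      }
  if (best_axis < 0) return -1;
  *thit = best_t; *face = best_face;
  return best_axis;
}

// Advance one molecule by displacement d with specular reflections.
// Returns number of reflections, or -1 if max_reflections exceeded
// (caller resamples the step).
inline int move_reflect(const Geometry& g, double x[3], double d[3],
                        int max_reflections) {
  int nrefl = 0;
  double t, face;
  int axis;
  while ((axis = first_hit(g, x, d, &t, &face)) >= 0) {
    if (++nrefl > max_reflections) return -1;
    for (int k = 0; k < 3; ++k) x[k] += t * d[k];
    x[axis] = face;  // snap exactly onto the face plane
    for (int k = 0; k < 3; ++k) d[k] *= (1.0 - t);
    d[axis] = -d[axis];
  }
  for (int k = 0; k < 3; ++k) x[k] += d[k];
  return nrefl;
}

Geometry make_geometry(const NumericMatrix& boxes, double p) {
  Geometry g;
  g.p = p;
  g.nbox = boxes.nrow();
  g.empty = (g.nbox == 0);
  g.lo.resize(3 * g.nbox);
  g.hi.resize(3 * g.nbox);
  for (int b = 0; b < g.nbox; ++b)
    for (int k = 0; k < 3; ++k) {
      g.lo[3 * b + k] = boxes(b, k);
      g.hi[3 * b + k] = boxes(b, k + 3);
      g.a = std::max(g.a, std::max(std::fabs(g.lo[3 * b + k]),
                                   std::fabs(g.hi[3 * b + k])));
    }
  return g;
}

}  // namespace

// [[Rcpp::export(name = ".walk_cpp")]]
List walk_cpp(NumericMatrix solid_boxes, double p, double bounds,
              NumericVector origin, int n_molecules, double D, double dt,
              int n_steps, int output_every, int max_reflections,
              double seed) {
  const Geometry g = make_geometry(solid_boxes, p);
  const double sd = std::sqrt(2.0 * D * dt);
  NormalGen gen((uint64_t)seed);

  std::vector<double> pos(3 * n_molecules);
  for (int i = 0; i < n_molecules; ++i)
    for (int k = 0; k < 3; ++k) pos[3 * i + k] = origin[k];

  const int n_out = n_steps / output_every;
  NumericVector out_t(n_out), out_msd(n_out);
  long left_count = 0, first_escape_step = -1, resample_count = 0;
  long long total_reflections = 0;
  std::vector<bool> left(n_molecules, false);

  int out_idx = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n_molecules; ++i) {
      double* x = &pos[3 * i];
      double d[3], x0[3] = {x[0], x[1], x[2]};
      int r;
      int tries = 0;
      do {
        for (int k = 0; k < 3; ++k) d[k] = sd * gen.draw();
        x[0] = x0[0]; x[1] = x0[1]; x[2] = x0[2];
        r = move_reflect(g, x, d, max_reflections);
        if (r < 0) ++resample_count;
      } while (r < 0 && ++tries < 100);
      if (r < 0) { x[0] = x0[0]; x[1] = x0[1]; x[2] = x0[2]; r = 0; }
      total_reflections += r;
      if (!left[i] &&
          (std::fabs(x[0]) > bounds || std::fabs(x[1]) > bounds ||
           std::fabs(x[2]) > bounds)) {
        left[i] = true;
        ++left_count;
        if (first_escape_step < 0) first_escape_step = step;
      }
    }
    if (step % output_every == 0) {
      double acc = 0.0;
      for (int i = 0; i < n_molecules; ++i) {
        const double dx = pos[3 * i] - origin[0];
        const double dy = pos[3 * i + 1] - origin[1];
        const double dz = pos[3 * i + 2] - origin[2];
        acc += dx * dx + dy * dy + dz * dz;
      }
      out_t[out_idx] = step * dt;
      out_msd[out_idx] = acc / n_molecules;
      ++out_idx;
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix final_pos(n_molecules, 3);
  for (int i = 0; i < n_molecules; ++i)
    for (int k = 0; k < 3; ++k) final_pos(i, k) = pos[3 * i + k];

  return List::create(
      _["t"] = out_t, _["msd"] = out_msd, _["positions"] = final_pos,
      _["left_count"] = (double)left_count,
      _["first_escape_step"] = (double)first_escape_step,
      _["resample_count"] = (double)resample_count,
      _["total_reflections"] = (double)total_reflections);
}

// Deterministic single-step reflector, exposed for testing the mirror
// identities and path-length conservation.
// [[Rcpp::export(name = ".reflect_step_cpp")]]
List reflect_step_cpp(NumericMatrix solid_boxes, double p,
                      NumericVector from, NumericVector disp,
                      int max_reflections) {
  const Geometry g = make_geometry(solid_boxes, p);
  double x[3] = {from[0], from[1], from[2]};
  double d[3] = {disp[0], disp[1], disp[2]};

  // track total path length across reflections
  double path = 0.0;
  double t, face;
  int axis, nrefl = 0;
  while ((axis = first_hit(g, x, d, &t, &face)) >= 0 &&
         nrefl < max_reflections) {
    ++nrefl;
    const double seg = t * std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    path += seg;
    for (int k = 0; k < 3; ++k) x[k] += t * d[k];
    x[axis] = face;
    for (int k = 0; k < 3; ++k) d[k] *= (1.0 - t);
    d[axis] = -d[axis];
  }
  path += std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  for (int k = 0; k < 3; ++k) x[k] += d[k];
  return List::create(_["end"] = NumericVector::create(x[0], x[1], x[2]),
                      _["n_reflections"] = nrefl,
                      _["path_length"] = path);
}
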