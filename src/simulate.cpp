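#include <Rcpp.h>
#include <vector>
#include "rng.h"
using namespace Rcpp;

// Conical channel: radius R(z) = R0 + slope*z, wall extrapolated beyond
// [0, L] wherever a particle body overhangs the end planes.
struct Cone {
  double L, R0, slope, inv_norm;
  Cone(double L_, double R0_, double RL_)
      : L(L_), R0(R0_), slope((RL_ - R0_) / L_),
        inv_norm(1.0 / std::sqrt(1.0 + ((RL_ - R0_) / L_) * ((RL_ - R0_) / L_))) {}
};

// Perpendicular (3D) distance from a point to the cone surface, positive when
// the point is radially inside: (R(z) - rho) / sqrt(1 + slope^2).
static inline double clearance(const Cone &ch, double x, double y, double z) {
  double rho = std::sqrt(x * x + y * y);
  return (ch.R0 + ch.slope * z - rho) * ch.inv_norm;
}

// Body containment by endpoint reduction: the capsule (segment Minkowski-sum
// ball of radius r) avoids the wall iff the clearance at BOTH axis-segment
// endpoints is >= r. Valid because clearance along the segment is concave
// (linear wall radius minus convex radial distance), so its minimum sits at
// an endpoint.
static inline bool body_inside(const Cone &ch, double r, double hl, double cx,
                               double cy, double cz, double ux, double uy,
                               double uz) {
  double ex = hl * ux, ey = hl * uy, ez = hl * uz;
  return clearance(ch, cx + ex, cy + ey, cz + ez) >= r &&
         clearance(ch, cx - ex, cy - ey, cz - ez) >= r;
}

static inline void sample_unit_vector(Xoshiro256pp &rng, double &x, double &y,
                                      double &z) {
  double n2;
  do {
    x = rng.rnorm();
    y = rng.rnorm();
    z = rng.rnorm();
    n2 = x * x + y * y + z * z;
  } while (n2 < 1e-24);
  double inv = 1.0 / std::sqrt(n2);
  x *= inv;
  y *= inv;
  z *= inv;
}

// Rodrigues rotation of unit vector u about unit axis a, renormalized.
static inline void rodrigues(double &ux, double &uy, double &uz, double ax,
                             double ay, double az, double angle) {
  double c = std::cos(angle), s = std::sin(angle);
  double dot = ax * ux + ay * uy + az * uz;
  double crx = ay * uz - az * uy;
  double cry = az * ux - ax * uz;
  double crz = ax * uy - ay * ux;
  double k = dot * (1.0 - c);
  double nx = ux * c + crx * s + ax * k;
  double ny = uy * c + cry * s + ay * k;
  double nz = uz * c + crz * s + az * k;
  double inv = 1.0 / std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx * inv;
  uy = ny * inv;
  uz = nz * inv;
}

// [[Rcpp::export]]
LogicalVector cpp_body_inside(double L, double R0, double RL, double l,
                              double r, NumericMatrix states) {
  Cone ch(L, R0, RL);
  double hl = 0.5 * l;
  int n = states.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = body_inside(ch, r, hl, states(i, 0), states(i, 1), states(i, 2),
                         states(i, 3), states(i, 4), states(i, 5));
  }
  return out;
}

// Brute-force containment oracle: area-weighted random points on the capsule
// surface (cylindrical shell + two hemispherical caps); the body counts as
// inside iff every sampled point is radially inside the wall.
// [[Rcpp::export]]
LogicalVector cpp_collision_oracle(double L, double R0, double RL, double l,
                                   double r, NumericMatrix states,
                                   int n_samples, double seed) {
  Cone ch(L, R0, RL);
  double hl = 0.5 * l;
  int n = states.nrow();
  LogicalVector out(n);
  double area_cyl = 2.0 * M_PI * r * l;
  double area_sph = 4.0 * M_PI * r * r;
  double p_cyl = area_cyl / (area_cyl + area_sph);
  for (int i = 0; i < n; ++i) {
    Xoshiro256pp rng((uint64_t)seed, (uint64_t)i + 0x6F1Du);
    double cx = states(i, 0), cy = states(i, 1), cz = states(i, 2);
    double ux = states(i, 3), uy = states(i, 4), uz = states(i, 5);
    // orthonormal basis perpendicular to u
    double bx, by, bz;
    if (std::fabs(ux) < 0.9) {
      bx = 1.0; by = 0.0; bz = 0.0;
    } else {
      bx = 0.0; by = 1.0; bz = 0.0;
    }
    double n1x = by * uz - bz * uy, n1y = bz * ux - bx * uz,
           n1z = bx * uy - by * ux;
    double inv = 1.0 / std::sqrt(n1x * n1x + n1y * n1y + n1z * n1z);
    n1x *= inv; n1y *= inv; n1z *= inv;
    double n2x = uy * n1z - uz * n1y, n2y = uz * n1x - ux * n1z,
           n2z = ux * n1y - uy * n1x;
    bool ok = true;
    for (int k = 0; k < n_samples && ok; ++k) {
      double px, py, pz;
      if (rng.runif() < p_cyl) {
        double s = (rng.runif() * 2.0 - 1.0) * hl;
        double phi = rng.runif() * 2.0 * M_PI;
        double cphi = std::cos(phi), sphi = std::sin(phi);
        px = cx + s * ux + r * (cphi * n1x + sphi * n2x);
        py = cy + s * uy + r * (cphi * n1y + sphi * n2y);
        pz = cz + s * uz + r * (cphi * n1z + sphi * n2z);
      } else {
        double vx, vy, vz;
        sample_unit_vector(rng, vx, vy, vz);
        double side = (vx * ux + vy * uy + vz * uz) >= 0.0 ? 1.0 : -1.0;
        px = cx + side * hl * ux + r * vx;
        py = cy + side * hl * uy + r * vy;
        pz = cz + side * hl * uz + r * vz;
      }
      double rho = std::sqrt(px * px + py * py);
      if (rho > ch.R0 + ch.slope * pz) ok = false;
    }
    out[i] = ok;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_ensemble(double L, double R0, double RL, double l, double r,
                      double sigma_x, int n_rep, double seed, double max_steps,
                      NumericVector sample_times, double occ_stride,
                      int occ_per_traj, double stream_offset) {
  Cone ch(L, R0, RL);
  double hl = 0.5 * l;
  long long tmax = (long long)max_steps;
  long long stride = (long long)occ_stride;

  // inertia components for unit total mass (masses m1 cylinder, m2 hemisphere)
  double m1 = (l > 0.0) ? 3.0 * l / (3.0 * l + 4.0 * r) : 0.0;
  double m2 = (1.0 - m1) / 2.0;
  double Mxx = m1 * (l * l / 12.0 + r * r / 4.0) +
               2.0 * m2 * (0.4 * r * r + l * l / 4.0 + 3.0 * l * r / 8.0);
  double Mzz = (0.5 * m1 + 0.8 * m2) * r * r;

  int n_times = sample_times.size();
  std::vector<long long> st(n_times);
  for (int i = 0; i < n_times; ++i) st[i] = (long long)sample_times[i];

  // state records: row 0 is t=0, then one row per sample time; NA past
  // absorption / censoring
  NumericMatrix X(n_times + 1, n_rep), Y(n_times + 1, n_rep),
      Z(n_times + 1, n_rep), UX(n_times + 1, n_rep), UY(n_times + 1, n_rep),
      UZ(n_times + 1, n_rep);
  std::fill(X.begin(), X.end(), NA_REAL);
  std::fill(Y.begin(), Y.end(), NA_REAL);
  std::fill(Z.begin(), Z.end(), NA_REAL);
  std::fill(UX.begin(), UX.end(), NA_REAL);
  std::fill(UY.begin(), UY.end(), NA_REAL);
  std::fill(UZ.begin(), UZ.end(), NA_REAL);

  NumericVector fpt(n_rep, NA_REAL);
  NumericVector acc_trans(n_rep), acc_rot(n_rep), steps_run(n_rep);
  NumericVector stream_id(n_rep);

  // pooled occupation samples (z, |u_z|), linear stride in time
  NumericMatrix occ((R_xlen_t)n_rep * occ_per_traj, 2);
  R_xlen_t n_occ = 0;

  for (int j = 0; j < n_rep; ++j) {
    uint64_t stream = (uint64_t)(stream_offset + j);
    stream_id[j] = (double)(stream_offset + j);
    Xoshiro256pp rng((uint64_t)seed, stream);

    // insertion at the wide end: center of mass on-axis at z=0, orientation
    // uniform on the sphere, redrawn until the body fits (wall extrapolated)
    double cx = 0.0, cy = 0.0, cz = 0.0;
    double ux, uy, uz;
    bool placed = false;
    for (long long tr = 0; tr < 1000000; ++tr) {
      sample_unit_vector(rng, ux, uy, uz);
      if (body_inside(ch, r, hl, cx, cy, cz, ux, uy, uz)) {
        placed = true;
        break;
      }
    }
    if (!placed)
      stop("no feasible initial orientation found in 1e6 draws "
           "(infeasible particle for this channel)");

    X(0, j) = cx; Y(0, j) = cy; Z(0, j) = cz;
    UX(0, j) = ux; UY(0, j) = uy; UZ(0, j) = uz;

    int k = 0;  // next sample-time index
    long long n_acc_t = 0, n_acc_r = 0;
    long long t = 0;
    bool absorbed = false;
    int my_occ = 0;

    while (t < tmax) {
      ++t;
      // translation attempt: reject on wall collision or entrance ejection
      double nx = cx + sigma_x * rng.rnorm();
      double ny = cy + sigma_x * rng.rnorm();
      double nz = cz + sigma_x * rng.rnorm();
      if (nz >= 0.0 && body_inside(ch, r, hl, nx, ny, nz, ux, uy, uz)) {
        cx = nx; cy = ny; cz = nz;
        ++n_acc_t;
      }
      // rotation attempt: uniform axis, equipartition angle scale, reject on
      // wall collision
      double ax, ay, az;
      sample_unit_vector(rng, ax, ay, az);
      double cospsi = ax * ux + ay * uy + az * uz;
      double moment = Mxx + (Mzz - Mxx) * cospsi * cospsi;
      double sigma_phi = sigma_x / std::sqrt(moment);
      double angle = sigma_phi * rng.rnorm();
      double vx = ux, vy = uy, vz = uz;
      rodrigues(vx, vy, vz, ax, ay, az, angle);
      if (body_inside(ch, r, hl, cx, cy, cz, vx, vy, vz)) {
        ux = vx; uy = vy; uz = vz;
        ++n_acc_r;
      }
      // time advanced by 1 whatever was accepted; absorption checked last
      if (cz >= L) {
        absorbed = true;
        fpt[j] = (double)t;
        break;
      }
      while (k < n_times && st[k] == t) {
        X(k + 1, j) = cx; Y(k + 1, j) = cy; Z(k + 1, j) = cz;
        UX(k + 1, j) = ux; UY(k + 1, j) = uy; UZ(k + 1, j) = uz;
        ++k;
      }
      // skip any sample times already passed (defensive; st is increasing)
      while (k < n_times && st[k] < t) ++k;
      if (stride > 0 && (t % stride == 0) && my_occ < occ_per_traj) {
        occ(n_occ, 0) = cz;
        occ(n_occ, 1) = std::fabs(uz);
        ++n_occ;
        ++my_occ;
      }
      if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    steps_run[j] = (double)t;
    acc_trans[j] = (double)n_acc_t;
    acc_rot[j] = (double)n_acc_r;
    (void)absorbed;
  }

  return List::create(
      _["fpt"] = fpt, _["accepted_translations"] = acc_trans,
      _["accepted_rotations"] = acc_rot, _["steps_run"] = steps_run,
      _["stream_id"] = stream_id, _["x"] = X, _["y"] = Y, _["z"] = Z,
      _["ux"] = UX, _["uy"] = UY, _["uz"] = UZ, _["occ"] = occ,
      _["n_occ"] = (double)n_occ, _["Mxx"] = Mxx, _["Mzz"] = Mzz);
}
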