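// Inner simulation loops for the dimer heat-bath models. All randomness is
// drawn from R's RNG (seed with set.seed() from the calling R code).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double SQRT_PI = 1.7724538509055160273;
static const double SQRT_2PI = 2.5066282746310005024;

// scaled complementary error function exp(x^2) erfc(x), stable for x >= 0
static double erfcx_pos(double x) {
  if (x < 6.0) return std::exp(x * x) * std::erfc(x);
  const double x2 = x * x;
  return (1.0 - 0.5 / x2 + 0.75 / (x2 * x2) - 1.875 / (x2 * x2 * x2)) /
         (x * SQRT_PI);
}

// one draw from p(z; beta) = C3(beta) erfc(z + beta), z >= 0, by
// exponential-proposal acceptance-rejection
static double erfc_tail_draw(double beta) {
  double a1, a2 = 0.0;
  bool ratio_form = beta >= 0.0;   // use erfc(z+b)/erfc(b) in ratio form
  if (beta >= 0.0) {
    a1 = 0.5 * SQRT_PI * erfcx_pos(beta);
  } else {
    a1 = 0.5 * SQRT_PI;
    a2 = std::exp(2.0 * beta / SQRT_PI);
  }
  for (int it = 0; it < 1000000; ++it) {
    double e1 = unif_rand();
    double e2 = unif_rand();
    double z = -a1 * std::log(e1);
    double env;
    if (ratio_form) {
      env = erfcx_pos(z + beta) / erfcx_pos(beta) *
            std::exp(-z * z - 2.0 * beta * z);
    } else {
      env = a2 * std::erfc(z + beta);
    }
    if (e1 * e2 < env) return z;
  }
  stop("erfc-tail sampler failed to accept (internal inconsistency)");
  return 0.0; // unreachable
}

// N(0, sd^2) conditioned on exceeding `lower`
static double tnorm_lower_draw(double sd, double lower) {
  double a = lower / sd;
  if (a <= 0.5) {
    for (;;) {
      double x = norm_rand();
      if (x > a) return x * sd;
    }
  }
  double lam = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a + exp_rand() / lam;
    double d = x - lam;
    if (unif_rand() < std::exp(-0.5 * d * d)) return x * sd;
  }
}

// expected boundary influx through one face; Vn = frame velocity along the
// inward normal of that face
static double face_influx(double lambda, double sigma, double L, double dt,
                          double Vn) {
  double p = lambda * L * L * dt *
             (sigma / SQRT_2PI * std::exp(-Vn * Vn / (2.0 * sigma * sigma)) -
              0.5 * Vn * std::erfc(Vn / (sigma * std::sqrt(2.0))));
  return p > 0.0 ? p : 0.0;
}

struct V3 {
  double v[3];
  double &operator[](int i) { return v[i]; }
  const double &operator[](int i) const { return v[i]; }
};

static inline double dot(const V3 &a, const V3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// ---------------------------------------------------------------------------
// Langevin dimer
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_langevin_run(NumericMatrix X, NumericMatrix V, double M, double D,
                      double gamma, double k, double ell0, double dt,
                      int n_steps, int sample_every, bool bbk) {
  V3 x1, x2, v1, v2;
  for (int c = 0; c < 3; ++c) {
    x1[c] = X(0, c); x2[c] = X(1, c);
    v1[c] = V(0, c); v2[c] = V(1, c);
  }
  int n_samp = sample_every > 0 ? n_steps / sample_every : 0;
  NumericMatrix samples(n_samp, 8);
  int row = 0;
  const double noise_em = gamma * std::sqrt(2.0 * D * dt);
  const double noise_bbk = gamma * std::sqrt(2.0 * D / dt);

  V3 A1 = {{0, 0, 0}}, A2 = {{0, 0, 0}};
  auto spring_acc = [&](V3 &f1) {
    // f1 = Phi'(R)/M * Rhat, force on monomer 1 divided by M
    V3 r;
    for (int c = 0; c < 3; ++c) r[c] = x2[c] - x1[c];
    double R = std::sqrt(dot(r, r));
    double f = 0.0;
    if (k != 0.0) {
      if (R <= 0.0) stop("degenerate separation: R = 0");
      f = k * (R - ell0) / (M * R);
    }
    for (int c = 0; c < 3; ++c) f1[c] = f * r[c];
    return R;
  };

  if (bbk) {
    V3 fs;
    spring_acc(fs);
    for (int c = 0; c < 3; ++c) {
      A1[c] = fs[c] - gamma * v1[c] + noise_bbk * norm_rand();
      A2[c] = -fs[c] - gamma * v2[c] + noise_bbk * norm_rand();
    }
  }

  for (int step = 0; step < n_steps; ++step) {
    double R;
    if (!bbk) {
      // symplectic-Euler ordering: drift, then kick with the updated force
      for (int c = 0; c < 3; ++c) { x1[c] += v1[c] * dt; x2[c] += v2[c] * dt; }
      V3 fs;
      R = spring_acc(fs);
      for (int c = 0; c < 3; ++c) {
        double nv1 = v1[c] + fs[c] * dt - gamma * v1[c] * dt +
                     noise_em * norm_rand();
        double nv2 = v2[c] - fs[c] * dt - gamma * v2[c] * dt +
                     noise_em * norm_rand();
        v1[c] = nv1; v2[c] = nv2;
      }
    } else {
      for (int c = 0; c < 3; ++c) {
        v1[c] += 0.5 * A1[c] * dt;
        v2[c] += 0.5 * A2[c] * dt;
        x1[c] += v1[c] * dt;
        x2[c] += v2[c] * dt;
      }
      V3 fs;
      R = spring_acc(fs);
      for (int c = 0; c < 3; ++c) {
        A1[c] = fs[c] - gamma * v1[c] + noise_bbk * norm_rand();
        A2[c] = -fs[c] - gamma * v2[c] + noise_bbk * norm_rand();
        v1[c] += 0.5 * A1[c] * dt;
        v2[c] += 0.5 * A2[c] * dt;
      }
    }
    if (sample_every > 0 && (step + 1) % sample_every == 0 && row < n_samp) {
      samples(row, 0) = (step + 1) * dt;
      for (int c = 0; c < 3; ++c) {
        samples(row, 1 + c) = 0.5 * (x1[c] + x2[c]);
        samples(row, 4 + c) = 0.5 * (v1[c] + v2[c]);
      }
      samples(row, 7) = R;
      ++row;
    }
  }
  NumericMatrix Xo(2, 3), Vo(2, 3);
  for (int c = 0; c < 3; ++c) {
    Xo(0, c) = x1[c]; Xo(1, c) = x2[c];
    Vo(0, c) = v1[c]; Vo(1, c) = v2[c];
  }
  return List::create(_["X"] = Xo, _["V"] = Vo, _["samples"] = samples);
}

// ---------------------------------------------------------------------------
// Short-range (collision) heat bath in a co-moving frame
// ---------------------------------------------------------------------------

// modes
enum SrMode { ONE_BATH = 0, TWO_BATH = 1, MIXED = 2, BATH_ONLY = 3,
              DRAG = 4 };

struct Bath {
  std::vector<V3> pos, vel;
  V3 centre;      // frame centre
  V3 centre_old;  // frame centre at the start of the step
};

struct CollisionEvent {
  int bath, particle, monomer;
  double s; // contact time within the step
  bool operator<(const CollisionEvent &o) const { return s < o.s; }
};

// [[Rcpp::export]]
List cpp_short_range_run(int mode, NumericMatrix X, NumericMatrix V,
                         List sol_pos, List sol_vel, double r0, double mu,
                         double gamma, double D, double M, double k,
                         double ell0, double L, double dt, int n_steps,
                         int sample_every, int anchor,
                         NumericVector frame_centre,
                         NumericVector drag_velocity, bool record_counts,
                         bool pool_velocities) {
  const double sigma = std::sqrt((mu + 1.0) * D * gamma);
  const double lambda = 3.0 / (8.0 * r0 * r0) *
                        std::sqrt((mu + 1.0) * gamma / (2.0 * M_PI * D));
  const double r0sq = r0 * r0;
  const double cmono = 2.0 / (mu + 1.0);       // monomer normal exchange
  const double csolv = 2.0 * mu / (mu + 1.0);  // solvent normal exchange

  const int n_baths = (mode == TWO_BATH) ? 2 : 1;
  const bool has_monomers = (mode != BATH_ONLY);
  const bool has_dimer = (mode == ONE_BATH || mode == TWO_BATH ||
                          mode == MIXED);

  V3 Xm[2], Vm[2];
  for (int i = 0; i < 2; ++i)
    for (int c = 0; c < 3; ++c) { Xm[i][c] = X(i, c); Vm[i][c] = V(i, c); }

  std::vector<Bath> baths(n_baths);
  for (int b = 0; b < n_baths; ++b) {
    NumericMatrix p = sol_pos[b], v = sol_vel[b];
    int n = p.nrow();
    baths[b].pos.resize(n);
    baths[b].vel.resize(n);
    for (int j = 0; j < n; ++j)
      for (int c = 0; c < 3; ++c) {
        baths[b].pos[j][c] = p(j, c);
        baths[b].vel[j][c] = v(j, c);
      }
  }
  // which monomers a bath collides with
  auto collides = [&](int b, int i) -> bool {
    switch (mode) {
      case ONE_BATH: return true;
      case TWO_BATH: return i == b;
      case MIXED:    return i == 0;
      case DRAG:     return i == 0;
      default:       return false;
    }
  };
  // frame centres
  auto recentre = [&](double step_dt) {
    if (mode == BATH_ONLY) {
      for (int c = 0; c < 3; ++c)
        baths[0].centre[c] += drag_velocity[c] * step_dt;
    } else if (mode == TWO_BATH) {
      for (int b = 0; b < 2; ++b) baths[b].centre = Xm[b];
    } else if (mode == MIXED || mode == DRAG) {
      baths[0].centre = Xm[0];
    } else { // ONE_BATH honours the requested anchor
      if (anchor == 1) baths[0].centre = Xm[0];
      else if (anchor == 2) baths[0].centre = Xm[1];
      else
        for (int c = 0; c < 3; ++c)
          baths[0].centre[c] = 0.5 * (Xm[0][c] + Xm[1][c]);
    }
  };
  for (int b = 0; b < n_baths; ++b)
    for (int c = 0; c < 3; ++c) baths[b].centre[c] = frame_centre[c];
  if (mode != BATH_ONLY) recentre(0.0);

  long n_collisions = 0, n_insertions = 0, n_deletions = 0;
  long n_attempted = 0, n_multi = 0, n_overlap_culled = 0, n_jzero = 0;
  V3 impulse = {{0, 0, 0}};

  int n_samp = sample_every > 0 ? n_steps / sample_every : 0;
  NumericMatrix samples((has_dimer || mode == DRAG) ? n_samp : 0, 8);
  std::vector<int> counts;
  std::vector<double> vpool;
  int row = 0;

  std::vector<CollisionEvent> events;

  for (int step = 0; step < n_steps; ++step) {
    if (step % 8192 == 0) Rcpp::checkUserInterrupt();
    for (int b = 0; b < n_baths; ++b) baths[b].centre_old = baths[b].centre;
    V3 Xpre[2], Vpre[2];
    for (int i = 0; i < 2; ++i) { Xpre[i] = Xm[i]; Vpre[i] = Vm[i]; }

    // [S1] free flight of the monomers
    if (has_monomers)
      for (int i = 0; i < 2; ++i)
        for (int c = 0; c < 3; ++c) Xm[i][c] += Vm[i][c] * dt;

    // [S1]-[S2] free flight of the solvent with overlap detection
    events.clear();
    for (int b = 0; b < n_baths; ++b) {
      int n = (int)baths[b].pos.size();
      for (int j = 0; j < n; ++j) {
        V3 xh;
        for (int c = 0; c < 3; ++c)
          xh[c] = baths[b].pos[j][c] + baths[b].vel[j][c] * dt;
        double best_s = dt * 2.0;
        int best_i = -1;
        if (has_monomers) {
          for (int i = 0; i < 2; ++i) {
            if (!collides(b, i)) continue;
            V3 d0, dv;
            for (int c = 0; c < 3; ++c) {
              d0[c] = baths[b].pos[j][c] - Xpre[i][c];
              dv[c] = baths[b].vel[j][c] - Vpre[i][c];
            }
            double c0 = dot(d0, d0) - r0sq;
            double bq = 2.0 * dot(d0, dv);
            if (c0 < 0.0) {
              // a collision replay can shift a monomer by O(dV * dt) and
              // leave a grazing particle marginally inside at the next
              // step start; resolve it as an immediate contact if it is
              // shallow and approaching, otherwise the state is broken
              if (dot(d0, d0) < 0.81 * r0sq)
                stop("integrity error: solvent particle deep inside a "
                     "monomer at the start of a step (reduce dt)");
              if (bq < 0.0 && 0.0 < best_s) { best_s = 0.0; best_i = i; }
              continue;
            }
            V3 dd;
            for (int c = 0; c < 3; ++c) dd[c] = xh[c] - Xm[i][c];
            if (dot(dd, dd) >= r0sq) continue;
            // contact solve on the pre-step trajectories
            double a = dot(dv, dv);
            double disc = bq * bq - 4.0 * a * c0;
            if (a <= 0.0 || disc <= 0.0) continue;
            double s = (-bq - std::sqrt(disc)) / (2.0 * a);
            if (s <= 0.0 || s >= dt) continue;
            if (s < best_s) { best_s = s; best_i = i; }
          }
        }
        if (best_i >= 0) {
          events.push_back({b, j, best_i, best_s});
        } else {
          baths[b].pos[j] = xh;
        }
      }
    }
    if (events.size() > 1) ++n_multi;
    std::sort(events.begin(), events.end());
    // per-monomer piecewise trajectory bookkeeping
    V3 Xcur[2];
    double s_last[2] = {0.0, 0.0};
    bool hit[2] = {false, false};
    for (int i = 0; i < 2; ++i) Xcur[i] = Xpre[i];
    for (const CollisionEvent &ev : events) {
      int b = ev.bath, j = ev.particle, i = ev.monomer;
      // positions at contact
      V3 xc, Xc;
      for (int c = 0; c < 3; ++c) {
        xc[c] = baths[b].pos[j][c] + baths[b].vel[j][c] * ev.s;
        Xc[c] = Xcur[i][c] + Vm[i][c] * (ev.s - s_last[i]);
      }
      Xcur[i] = Xc;
      s_last[i] = ev.s;
      hit[i] = true;
      V3 nh;
      double nn = 0.0;
      for (int c = 0; c < 3; ++c) { nh[c] = xc[c] - Xc[c]; nn += nh[c] * nh[c]; }
      nn = std::sqrt(nn);
      for (int c = 0; c < 3; ++c) nh[c] /= nn;
      double Vn = dot(Vm[i], nh), vn = dot(baths[b].vel[j], nh);
      double dmon = cmono * (vn - Vn);
      double dsol = csolv * (Vn - vn);
      if (mode == DRAG) {
        for (int c = 0; c < 3; ++c) impulse[c] += M * dmon * nh[c];
      } else {
        for (int c = 0; c < 3; ++c) Vm[i][c] += dmon * nh[c];
      }
      for (int c = 0; c < 3; ++c) {
        baths[b].vel[j][c] += dsol * nh[c];
        baths[b].pos[j][c] = xc[c] + baths[b].vel[j][c] * (dt - ev.s);
      }
      ++n_collisions;
    }
    if (has_monomers && mode != DRAG)
      for (int i = 0; i < 2; ++i)
        if (hit[i])
          for (int c = 0; c < 3; ++c)
            Xm[i][c] = Xcur[i][c] + Vm[i][c] * (dt - s_last[i]);

    // [S3] spring kick (and the Langevin update of monomer 2 in MIXED)
    if (has_dimer) {
      V3 r;
      for (int c = 0; c < 3; ++c) r[c] = Xm[1][c] - Xm[0][c];
      double R = std::sqrt(dot(r, r));
      double f = 0.0;
      if (k != 0.0) {
        if (R <= 0.0) stop("degenerate separation: R = 0");
        f = k * (R - ell0) / (M * R); // Phi'(R)/(M R)
      }
      if (mode == MIXED) {
        double amp = gamma * std::sqrt(2.0 * D * dt);
        for (int c = 0; c < 3; ++c) {
          Vm[0][c] += f * r[c] * dt;
          Vm[1][c] += -f * r[c] * dt - gamma * Vm[1][c] * dt +
                      amp * norm_rand();
        }
      } else {
        for (int c = 0; c < 3; ++c) {
          Vm[0][c] += f * r[c] * dt;
          Vm[1][c] -= f * r[c] * dt;
        }
      }
    }

    // [S4] recentre the frame(s) and cull departed particles
    recentre(dt);
    for (int b = 0; b < n_baths; ++b) {
      int n = (int)baths[b].pos.size();
      for (int j = n - 1; j >= 0; --j) {
        bool out = false;
        for (int c = 0; c < 3; ++c)
          if (std::fabs(baths[b].pos[j][c] - baths[b].centre[c]) > 0.5 * L) {
            out = true;
            break;
          }
        if (out) {
          baths[b].pos[j] = baths[b].pos.back();
          baths[b].vel[j] = baths[b].vel.back();
          baths[b].pos.pop_back();
          baths[b].vel.pop_back();
          ++n_deletions;
        }
      }
    }

    // [S5]-[S6] frame velocity and boundary insertion
    for (int b = 0; b < n_baths; ++b) {
      V3 Vf;
      for (int c = 0; c < 3; ++c)
        Vf[c] = (baths[b].centre[c] - baths[b].centre_old[c]) / dt;
      double pf[6], ptot = 0.0;
      for (int face = 0; face < 6; ++face) {
        int axis = face / 2;
        double sgn = (face % 2 == 0) ? 1.0 : -1.0; // inward normal sign
        pf[face] = face_influx(lambda, sigma, L, dt, sgn * Vf[axis]);
        ptot += pf[face];
      }
      if (ptot > 0.1)
        stop("step-size error: total boundary influx probability %.3g > 0.1;"
             " reduce dt", ptot);
      double r1 = unif_rand();
      if (r1 >= ptot) continue;
      ++n_attempted;
      int face = 0;
      double cum = pf[0];
      while (r1 >= cum && face < 5) cum += pf[++face];
      int axis = face / 2;
      double sgn = (face % 2 == 0) ? 1.0 : -1.0;
      double Vn = sgn * Vf[axis];
      double beta = Vn / (sigma * std::sqrt(2.0));
      double depth = sigma * dt * std::sqrt(2.0) * erfc_tail_draw(beta);
      double vn = tnorm_lower_draw(sigma, depth / dt + Vn);
      V3 pos, vel;
      pos[axis] = baths[b].centre[axis] + sgn * (depth - 0.5 * L);
      vel[axis] = sgn * vn;
      for (int c = 0; c < 3; ++c) {
        if (c == axis) continue;
        pos[c] = baths[b].centre[c] - 0.5 * L + unif_rand() * L;
        vel[c] = sigma * norm_rand();
      }
      // edge/corner overcount thinning on the back-propagated origin
      int jout = 0;
      for (int c = 0; c < 3; ++c) {
        double y = pos[c] - vel[c] * dt - baths[b].centre_old[c];
        if (std::fabs(y) > 0.5 * L) ++jout;
      }
      if (jout == 0) { ++n_jzero; jout = 1; } // rounding guard; see tests
      if (unif_rand() >= 1.0 / jout) continue;
      // never create a particle inside a monomer it can collide with
      bool inside = false;
      if (has_monomers)
        for (int i = 0; i < 2 && !inside; ++i) {
          if (!collides(b, i)) continue;
          V3 dd;
          for (int c = 0; c < 3; ++c) dd[c] = pos[c] - Xm[i][c];
          if (dot(dd, dd) < r0sq) inside = true;
        }
      if (inside) { ++n_overlap_culled; continue; }
      baths[b].pos.push_back(pos);
      baths[b].vel.push_back(vel);
      ++n_insertions;
    }

    // sampling
    if (sample_every > 0 && (step + 1) % sample_every == 0) {
      if ((has_dimer || mode == DRAG) && row < n_samp) {
        V3 r;
        for (int c = 0; c < 3; ++c) r[c] = Xm[1][c] - Xm[0][c];
        samples(row, 0) = (step + 1) * dt;
        for (int c = 0; c < 3; ++c) {
          samples(row, 1 + c) = 0.5 * (Xm[0][c] + Xm[1][c]);
          samples(row, 4 + c) = 0.5 * (Vm[0][c] + Vm[1][c]);
        }
        samples(row, 7) = std::sqrt(dot(r, r));
        ++row;
      }
      if (record_counts) counts.push_back((int)baths[0].pos.size());
      if (pool_velocities)
        for (const V3 &v : baths[0].vel)
          for (int c = 0; c < 3; ++c) vpool.push_back(v[c]);
    }
  }

  NumericMatrix Xo(2, 3), Vo(2, 3);
  for (int i = 0; i < 2; ++i)
    for (int c = 0; c < 3; ++c) { Xo(i, c) = Xm[i][c]; Vo(i, c) = Vm[i][c]; }
  List out_pos(n_baths), out_vel(n_baths);
  for (int b = 0; b < n_baths; ++b) {
    int n = (int)baths[b].pos.size();
    NumericMatrix p(n, 3), v(n, 3);
    for (int j = 0; j < n; ++j)
      for (int c = 0; c < 3; ++c) {
        p(j, c) = baths[b].pos[j][c];
        v(j, c) = baths[b].vel[j][c];
      }
    out_pos[b] = p;
    out_vel[b] = v;
  }
  NumericVector fc(3), fv(3), imp(3);
  for (int c = 0; c < 3; ++c) {
    fc[c] = baths[0].centre[c];
    fv[c] = (baths[0].centre[c] - baths[0].centre_old[c]) / dt;
    imp[c] = impulse[c];
  }
  return List::create(
      _["X"] = Xo, _["V"] = Vo, _["sol_pos"] = out_pos,
      _["sol_vel"] = out_vel, _["samples"] = samples,
      _["frame_centre"] = fc, _["frame_velocity"] = fv,
      _["counts"] = wrap(counts), _["velocity_pool"] = wrap(vpool),
      _["impulse"] = imp,
      _["counters"] = List::create(
          _["collisions"] = (double)n_collisions,
          _["insertions"] = (double)n_insertions,
          _["deletions"] = (double)n_deletions,
          _["attempted_insertions"] = (double)n_attempted,
          _["multi_collision_steps"] = (double)n_multi,
          _["overlap_culled_insertions"] = (double)n_overlap_culled,
          _["origin_inside_guard"] = (double)n_jzero));
}

// ---------------------------------------------------------------------------
// Long-range (harmonic-oscillator) heat bath, velocity Verlet
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_long_range_run(NumericMatrix X, NumericMatrix V,
                        NumericMatrix osc_pos, NumericMatrix osc_vel,
                        NumericVector k1, NumericVector a1, NumericVector k2,
                        NumericVector a2, double m, double M, double k,
                        double ell0, double gamma, double D, double dt,
                        int n_steps, int sample_every, bool monomer2_langevin,
                        bool record_energy) {
  const int N = osc_pos.nrow();
  V3 x1, x2, v1, v2;
  for (int c = 0; c < 3; ++c) {
    x1[c] = X(0, c); x2[c] = X(1, c);
    v1[c] = V(0, c); v2[c] = V(1, c);
  }
  std::vector<double> xp(3 * N), vp(3 * N), ap(3 * N);
  for (int j = 0; j < N; ++j)
    for (int c = 0; c < 3; ++c) {
      xp[3 * j + c] = osc_pos(j, c);
      vp[3 * j + c] = osc_vel(j, c);
    }
  const double *K1 = k1.begin(), *A1v = a1.begin();
  const double *K2 = k2.begin(), *A2v = a2.begin();

  V3 Am1, Am2;
  const double noise_bbk = gamma * std::sqrt(2.0 * D / dt);

  auto accelerations = [&]() {
    V3 r;
    for (int c = 0; c < 3; ++c) r[c] = x2[c] - x1[c];
    double R = std::sqrt(dot(r, r));
    double f = 0.0;
    if (k != 0.0) {
      if (R <= 0.0) stop("degenerate separation: R = 0");
      f = k * (R - ell0) / (M * R);
    }
    V3 b1 = {{0, 0, 0}}, b2 = {{0, 0, 0}};
    for (int j = 0; j < N; ++j) {
      const double kj1 = K1[j], kj2 = K2[j];
      const double al1 = A1v[j], al2 = A2v[j];
      for (int c = 0; c < 3; ++c) {
        double xc = xp[3 * j + c];
        double d1 = xc - al1 * x1[c];
        double d2 = xc - al2 * x2[c];
        if (kj1 != 0.0) b1[c] += kj1 * al1 * d1;
        if (kj2 != 0.0) b2[c] += kj2 * al2 * d2;
        ap[3 * j + c] = (-kj1 * d1 - kj2 * d2) / m;
      }
    }
    for (int c = 0; c < 3; ++c) Am1[c] = f * r[c] + b1[c] / M;
    if (monomer2_langevin) {
      for (int c = 0; c < 3; ++c)
        Am2[c] = -f * r[c] - gamma * v2[c] + noise_bbk * norm_rand();
    } else {
      for (int c = 0; c < 3; ++c) Am2[c] = -f * r[c] + b2[c] / M;
    }
    return R;
  };

  int n_samp = sample_every > 0 ? n_steps / sample_every : 0;
  NumericMatrix samples(n_samp, 8);
  std::vector<double> energies;
  int row = 0;

  auto total_energy = [&]() {
    V3 r;
    for (int c = 0; c < 3; ++c) r[c] = x2[c] - x1[c];
    double R = std::sqrt(dot(r, r));
    double E = 0.5 * M * (dot(v1, v1) + dot(v2, v2)) +
               0.5 * k * (R - ell0) * (R - ell0);
    for (int j = 0; j < N; ++j)
      for (int c = 0; c < 3; ++c) {
        double xc = xp[3 * j + c], vc = vp[3 * j + c];
        double d1 = xc - A1v[j] * x1[c];
        double d2 = xc - A2v[j] * x2[c];
        E += 0.5 * m * vc * vc + 0.5 * K1[j] * d1 * d1 +
             0.5 * K2[j] * d2 * d2;
      }
    return E;
  };

  accelerations();
  if (record_energy) energies.push_back(total_energy());

  for (int step = 0; step < n_steps; ++step) {
    if (step % 1024 == 0) Rcpp::checkUserInterrupt();
    const double hdt = 0.5 * dt;
    for (int c = 0; c < 3; ++c) {
      v1[c] += Am1[c] * hdt;
      v2[c] += Am2[c] * hdt;
      x1[c] += v1[c] * dt;
      x2[c] += v2[c] * dt;
    }
    for (int j = 0; j < N; ++j)
      for (int c = 0; c < 3; ++c) {
        vp[3 * j + c] += ap[3 * j + c] * hdt;
        xp[3 * j + c] += vp[3 * j + c] * dt;
      }
    double R = accelerations();
    for (int c = 0; c < 3; ++c) {
      v1[c] += Am1[c] * hdt;
      v2[c] += Am2[c] * hdt;
    }
    for (int j = 0; j < N; ++j)
      for (int c = 0; c < 3; ++c) vp[3 * j + c] += ap[3 * j + c] * hdt;

    if (sample_every > 0 && (step + 1) % sample_every == 0 && row < n_samp) {
      samples(row, 0) = (step + 1) * dt;
      for (int c = 0; c < 3; ++c) {
        samples(row, 1 + c) = 0.5 * (x1[c] + x2[c]);
        samples(row, 4 + c) = 0.5 * (v1[c] + v2[c]);
      }
      samples(row, 7) = R;
      ++row;
      if (record_energy) energies.push_back(total_energy());
    }
  }

  NumericMatrix Xo(2, 3), Vo(2, 3), Po(N, 3), Wo(N, 3);
  for (int c = 0; c < 3; ++c) {
    Xo(0, c) = x1[c]; Xo(1, c) = x2[c];
    Vo(0, c) = v1[c]; Vo(1, c) = v2[c];
  }
  for (int j = 0; j < N; ++j)
    for (int c = 0; c < 3; ++c) {
      Po(j, c) = xp[3 * j + c];
      Wo(j, c) = vp[3 * j + c];
    }
  return List::create(_["X"] = Xo, _["V"] = Vo, _["osc_pos"] = Po,
                      _["osc_vel"] = Wo, _["samples"] = samples,
                      _["energies"] = wrap(energies));
}
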