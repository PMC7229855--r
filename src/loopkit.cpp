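// Rigid base-pair chain geometry, constrained loop minimization, and
// discrete wormlike-chain sampling.
//
// Conventions (documented in the package vignette):
//  - Each base pair carries a right-handed orthonormal triad; column 1 is the
//    long in-plane axis (backbone attachment axis), column 2 the short
//    in-plane axis, column 3 the helical axis.
//  - Step i rotates triad i into triad i+1 as T[i+1] = T[i] * Rz(twist) *
//    Ry(roll) * Rx(tilt) (intrinsic rotations: twist about the local helical
//    axis first, then roll about the local short axis, then tilt about the
//    local long axis).
//  - Origins advance by `rise` along the *new* triad's helical axis.
//  - Backbone attachment points sit at the two corners of the longer side of
//    the base-pair rectangle: strand a at (+ax, +ay), strand b at (-ax, +ay)
//    in the local (long, short) axes, with ax^2 + ay^2 = helix_radius^2.  The
//    common short-axis offset ay encodes the groove asymmetry of the double
//    helix (the two strands are not diametrically opposite).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 v3(double x, double y, double z) { return {x, y, z}; }
inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }

// 3x3 rotation stored row-major.
struct Mat3 {
  double m[9];
};

inline Mat3 identity3() {
  Mat3 r;
  for (int i = 0; i < 9; ++i) r.m[i] = 0.0;
  r.m[0] = r.m[4] = r.m[8] = 1.0;
  return r;
}

inline Mat3 mul(const Mat3 &a, const Mat3 &b) {
  Mat3 r;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += a.m[3 * i + k] * b.m[3 * k + j];
      r.m[3 * i + j] = s;
    }
  return r;
}

inline Vec3 col(const Mat3 &a, int j) { return {a.m[j], a.m[3 + j], a.m[6 + j]}; }

inline Mat3 rotx(double t) {
  double c = std::cos(t), s = std::sin(t);
  Mat3 r = identity3();
  r.m[4] = c; r.m[5] = -s; r.m[7] = s; r.m[8] = c;
  return r;
}
inline Mat3 roty(double t) {
  double c = std::cos(t), s = std::sin(t);
  Mat3 r = identity3();
  r.m[0] = c; r.m[2] = s; r.m[6] = -s; r.m[8] = c;
  return r;
}
inline Mat3 rotz(double t) {
  double c = std::cos(t), s = std::sin(t);
  Mat3 r = identity3();
  r.m[0] = c; r.m[1] = -s; r.m[3] = s; r.m[4] = c;
  return r;
}

// Chain workspace: triads, origins, and per-junction lab-frame rotation axes
// for the three step angles (used for analytic constraint gradients).
struct Chain {
  int n_bp;
  std::vector<Mat3> T;    // n_bp triads
  std::vector<Vec3> o;    // n_bp origins
  std::vector<Vec3> ax_tilt, ax_roll, ax_twist;  // n_bp - 1 axes each
};

// angles: (n_bp-1) x 3 column-major buffer [tilt, roll, twist]
void build_chain(const double *angles, int n_bp, double rise, Chain &ch,
                 bool want_axes) {
  int ns = n_bp - 1;
  ch.n_bp = n_bp;
  ch.T.resize(n_bp);
  ch.o.resize(n_bp);
  if (want_axes) {
    ch.ax_tilt.resize(ns);
    ch.ax_roll.resize(ns);
    ch.ax_twist.resize(ns);
  }
  ch.T[0] = identity3();
  ch.o[0] = v3(0, 0, 0);
  for (int i = 0; i < ns; ++i) {
    double ti = angles[i];
    double ro = angles[ns + i];
    double tw = angles[2 * ns + i];
    Mat3 Tz = mul(ch.T[i], rotz(tw));
    Mat3 Tzy = mul(Tz, roty(ro));
    Mat3 Tn = mul(Tzy, rotx(ti));
    if (want_axes) {
      ch.ax_twist[i] = col(ch.T[i], 2);
      ch.ax_roll[i] = col(Tz, 1);
      ch.ax_tilt[i] = col(Tzy, 0);
    }
    ch.T[i + 1] = Tn;
    ch.o[i + 1] = ch.o[i] + rise * col(Tn, 2);
  }
}

inline Vec3 backbone_point(const Chain &ch, int bp, int strand, double ax,
                           double ay) {
  // strand: +1 = strand a, -1 = strand b
  return ch.o[bp] + (strand * ax) * col(ch.T[bp], 0) + ay * col(ch.T[bp], 1);
}

}  // namespace

// [[Rcpp::export(name = ".build_chain_cpp")]]
List build_chain_cpp(NumericMatrix angles, double rise, double ax,
                     double ay) {
  int ns = angles.nrow();
  int n_bp = ns + 1;
  Chain ch;
  build_chain(REAL(angles), n_bp, rise, ch, false);
  NumericMatrix origins(n_bp, 3), bba(n_bp, 3), bbb(n_bp, 3);
  NumericVector triads(Dimension(3, 3, n_bp));
  for (int i = 0; i < n_bp; ++i) {
    origins(i, 0) = ch.o[i].x;
    origins(i, 1) = ch.o[i].y;
    origins(i, 2) = ch.o[i].z;
    Vec3 pa = backbone_point(ch, i, +1, ax, ay);
    Vec3 pb = backbone_point(ch, i, -1, ax, ay);
    bba(i, 0) = pa.x; bba(i, 1) = pa.y; bba(i, 2) = pa.z;
    bbb(i, 0) = pb.x; bbb(i, 1) = pb.y; bbb(i, 2) = pb.z;
    // store triad column-major: triads[r, c, i]
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) triads[9 * i + 3 * c + r] = ch.T[i].m[3 * r + c];
  }
  return List::create(_["origins"] = origins, _["triads"] = triads,
                      _["backbone_a"] = bba, _["backbone_b"] = bbb);
}

// Recover step angles from a stack of triads (inverse of the build
// convention); triads as returned by .build_chain_cpp.
// [[Rcpp::export(name = ".extract_angles_cpp")]]
NumericMatrix extract_angles_cpp(NumericVector triads) {
  IntegerVector dim = triads.attr("dim");
  int n_bp = dim[2];
  int ns = n_bp - 1;
  NumericMatrix out(ns, 3);
  for (int i = 0; i < ns; ++i) {
    // M = T_i^T T_{i+1}; triads stored column-major per slice
    double A[9], B[9], M[9];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) {
        A[3 * r + c] = triads[9 * i + 3 * c + r];
        B[3 * r + c] = triads[9 * (i + 1) + 3 * c + r];
      }
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) {
        double s = 0.0;
        for (int k = 0; k < 3; ++k) s += A[3 * k + r] * B[3 * k + c];
        M[3 * r + c] = s;
      }
    // M = Rz(tw) Ry(ro) Rx(ti)
    double ro = -std::asin(std::max(-1.0, std::min(1.0, M[6])));
    double tw = std::atan2(M[3], M[0]);
    double ti = std::atan2(M[7], M[8]);
    out(i, 0) = ti;
    out(i, 1) = ro;
    out(i, 2) = tw;
  }
  return out;
}

namespace {

struct Objective {
  int n_bp, ns;
  const double *x0;     // ground-state angles, (ns x 3) column-major
  const double *alpha;  // stiffnesses, same layout
  double rise, ax, ay;
  double d_target, kc;
  int mode;  // 0 = sticky ends (bb_a[N-1] vs bb_b[0]); 1 = nick (bb_a both ends)
  int ev_n;  // excluded-volume segment length in bp (0 = off)
  double ev_radius, ev_k;

  // Evaluate objective; optionally fill gradient (length 3*ns).
  double eval(const double *x, Chain &ch, double *grad, double *e_elastic,
              double *dist_out) const {
    build_chain(x, n_bp, rise, ch, grad != nullptr);
    double eel = 0.0;
    for (int j = 0; j < 3 * ns; ++j) {
      double d = x[j] - x0[j];
      eel += alpha[j] * d * d;
      if (grad) grad[j] = 2.0 * alpha[j] * d;
    }
    Vec3 P = backbone_point(ch, n_bp - 1, +1, ax, ay);
    Vec3 Q = backbone_point(ch, 0, mode == 0 ? -1 : +1, ax, ay);
    Vec3 dPQ = P - Q;
    double d = norm(dPQ);
    // one-sided capture constraint: only end separations beyond the target
    // are penalized (the sticky ends merely need to come within reach)
    double excess = d - d_target;
    if (excess < 0) excess = 0;
    double f = eel + 0.5 * kc * excess * excess;
    if (grad && d > 1e-12 && excess > 0) {
      Vec3 u = (1.0 / d) * dPQ;
      double pref = kc * excess;
      for (int i = 0; i < ns; ++i) {
        Vec3 rel = P - ch.o[i];
        grad[i] += pref * dot(u, cross(ch.ax_tilt[i], rel));
        grad[ns + i] += pref * dot(u, cross(ch.ax_roll[i], rel));
        grad[2 * ns + i] += pref * dot(u, cross(ch.ax_twist[i], rel));
      }
    }
    if (ev_n > 0) {
      // Half-harmonic repulsion between origins of the first and last ev_n
      // base pairs.  For the gradient, a junction rotation only changes the
      // distance of pairs it straddles (p <= i < q); accumulate the straddle
      // sums with prefix accumulation over p.
      double eev = 0.0;
      int q0 = n_bp - ev_n;
      // per-p accumulators of force terms
      std::vector<Vec3> Ap(ev_n, v3(0, 0, 0)), Bp(ev_n, v3(0, 0, 0));
      for (int p = 0; p < ev_n; ++p) {
        for (int q = q0; q < n_bp; ++q) {
          Vec3 w = ch.o[p] - ch.o[q];
          double dd = norm(w);
          if (dd < ev_radius && dd > 1e-12) {
            double gap = ev_radius - dd;
            eev += 0.5 * ev_k * gap * gap;
            if (grad) {
              double s = -ev_k * gap;  // dE/dd
              Vec3 wh = (1.0 / dd) * w;
              // contribution to junction i (p<=i<q):  s * u . (a x (o_q - o_i))
              // with u = (o_q - o_p)/d = -wh:  s * a . ((o_q - o_i) x (-wh))
              // accumulate  A += s * (o_q x (-wh)),  B += s * (-wh)
              Vec3 nwh = -1.0 * wh;
              Ap[p] = Ap[p] + s * cross(ch.o[q], nwh);
              Bp[p] = Bp[p] + s * nwh;
            }
          }
        }
      }
      f += eev;
      eel += 0.0;  // excluded volume reported separately from elastic energy
      if (grad) {
        Vec3 A = v3(0, 0, 0), B = v3(0, 0, 0);
        int p_next = 0;
        for (int i = 0; i < ns; ++i) {
          while (p_next <= i && p_next < ev_n) {
            A = A + Ap[p_next];
            B = B + Bp[p_next];
            ++p_next;
          }
          // junctions i >= q0 no longer straddle pairs with q <= i
          // (q ranges over the last ev_n bps; require q > i)
          if (i >= q0) {
            // recompute exactly for the few tail junctions
            Vec3 Ai = v3(0, 0, 0), Bi = v3(0, 0, 0);
            for (int p = 0; p < ev_n; ++p)
              for (int q = std::max(q0, i + 1); q < n_bp; ++q) {
                Vec3 w = ch.o[p] - ch.o[q];
                double dd = norm(w);
                if (dd < ev_radius && dd > 1e-12) {
                  double s = -ev_k * (ev_radius - dd);
                  Vec3 nwh = (-1.0 / dd) * w;
                  Ai = Ai + s * cross(ch.o[q], nwh);
                  Bi = Bi + s * nwh;
                }
              }
            Vec3 g3 = Ai - cross(ch.o[i], Bi);
            grad[i] += dot(ch.ax_tilt[i], g3);
            grad[ns + i] += dot(ch.ax_roll[i], g3);
            grad[2 * ns + i] += dot(ch.ax_twist[i], g3);
            continue;
          }
          Vec3 g3 = A - cross(ch.o[i], B);
          grad[i] += dot(ch.ax_tilt[i], g3);
          grad[ns + i] += dot(ch.ax_roll[i], g3);
          grad[2 * ns + i] += dot(ch.ax_twist[i], g3);
        }
      }
    }
    if (e_elastic) *e_elastic = eel;
    if (dist_out) *dist_out = d;
    return f;
  }
};

}  // namespace

// Gradient-descent minimization with backtracking line search and a
// geometrically ramped constraint stiffness.
// [[Rcpp::export(name = ".minimize_loop_cpp")]]
List minimize_loop_cpp(NumericMatrix x_init, NumericMatrix x_ground,
                       NumericMatrix alpha, double rise, double ax, double ay,
                       double d_target, int mode, NumericVector kc_schedule,
                       double grad_tol, int max_iter, double step_init,
                       double step_max, int flow_iters, double flow_ftol,
                       int polish, int ev_n, double ev_radius, double ev_k) {
  int ns = x_init.nrow();
  int n_bp = ns + 1;
  int nv = 3 * ns;
  std::vector<double> x(REAL(x_init), REAL(x_init) + nv);
  std::vector<double> g(nv), xtrial(nv);
  Chain ch;
  Objective ob;
  ob.n_bp = n_bp;
  ob.ns = ns;
  ob.x0 = REAL(x_ground);
  ob.alpha = REAL(alpha);
  ob.rise = rise;
  ob.ax = ax;
  ob.ay = ay;
  ob.d_target = d_target;
  ob.mode = mode;
  ob.ev_n = ev_n;
  ob.ev_radius = ev_radius;
  ob.ev_k = ev_k;

  int total_iter = 0;
  int n_increase = 0;
  double eel = 0.0, dist = 0.0, gnorm = R_PosInf;
  bool converged = false;
  double step = step_init;

  // Limited-memory quasi-Newton descent (L-BFGS two-loop recursion) with
  // Armijo backtracking: every accepted iterate strictly decreases the
  // objective, and the search direction falls back to the raw gradient
  // whenever the curvature pairs do not define a descent direction.
  const int mem = 8;
  std::vector<std::vector<double>> S(mem, std::vector<double>(nv)),
      Y(mem, std::vector<double>(nv));
  std::vector<double> rho(mem), alpha_lb(mem), dir(nv), g_old(nv), x_old(nv);
  (void)step;
  (void)step_max;
  for (int stage = 0; stage < kc_schedule.size(); ++stage) {
    ob.kc = kc_schedule[stage];
    double f = ob.eval(x.data(), ch, g.data(), &eel, &dist);
    if (stage == 0 || !polish) {
      // Flow-tracking phase: plain gradient descent with a small bounded
      // step, approximating the continuous gradient flow from the initial
      // arc, so the minimization relaxes within the basin belonging to the
      // requested bending direction instead of hopping to the global one.
      // With polish enabled it runs until the iterate sits near a basin
      // floor (gradient norm 0.5 kT/rad) and hands over to the quasi-Newton
      // polish; without polish it runs to grad_tol and is the whole
      // minimization.
      // The flow is preconditioned by the inverse elastic stiffness
      // (descent in the metric of the quadratic energy): per-coordinate
      // direction g_j / (2 alpha_j).  This leaves the trajectory a
      // continuous descent flow while equalizing the convergence rate of
      // bend and twist degrees of freedom.
      double flow_tol = polish ? 0.5 : grad_tol;
      double fs = step_init;
      int n_small = 0;
      std::vector<double> pdir(nv);
      for (int it = 0; it < flow_iters; ++it) {
        ++total_iter;
        double g2 = 0.0, dg = 0.0;
        for (int j = 0; j < nv; ++j) {
          g2 += g[j] * g[j];
          pdir[j] = g[j] / (2.0 * ob.alpha[j]);
          dg += g[j] * pdir[j];
        }
        if (std::sqrt(g2) < flow_tol) break;
        if (flow_ftol > 0 && n_small >= 50) break;
        double s = fs;
        double fnew = R_PosInf;
        for (int bt = 0; bt < 40; ++bt) {
          for (int j = 0; j < nv; ++j) xtrial[j] = x[j] - s * pdir[j];
          fnew = ob.eval(xtrial.data(), ch, nullptr, nullptr, nullptr);
          if (fnew <= f - 1e-4 * s * dg) break;
          s *= 0.5;
        }
        if (fnew > f) break;
        if (f - fnew < flow_ftol) ++n_small; else n_small = 0;
        x.swap(xtrial);
        fs = std::min(s * 1.2, step_max);
        f = ob.eval(x.data(), ch, g.data(), &eel, &dist);
      }
    }
    int nmem = 0, head = 0;
    double h0 = 1e-3;
    for (int it = 0; polish && it < max_iter; ++it) {
      ++total_iter;
      double g2 = 0.0;
      for (int j = 0; j < nv; ++j) g2 += g[j] * g[j];
      gnorm = std::sqrt(g2);
      if (gnorm < grad_tol) break;
      // two-loop recursion: dir = -H * g
      for (int j = 0; j < nv; ++j) dir[j] = g[j];
      for (int k = 0; k < nmem; ++k) {
        int idx = (head - 1 - k + 2 * mem) % mem;
        double a = 0.0;
        for (int j = 0; j < nv; ++j) a += S[idx][j] * dir[j];
        a *= rho[idx];
        alpha_lb[idx] = a;
        for (int j = 0; j < nv; ++j) dir[j] -= a * Y[idx][j];
      }
      for (int j = 0; j < nv; ++j) dir[j] *= h0;
      for (int k = nmem - 1; k >= 0; --k) {
        int idx = (head - 1 - k + 2 * mem) % mem;
        double b = 0.0;
        for (int j = 0; j < nv; ++j) b += Y[idx][j] * dir[j];
        b *= rho[idx];
        for (int j = 0; j < nv; ++j) dir[j] += (alpha_lb[idx] - b) * S[idx][j];
      }
      double dg = 0.0;
      for (int j = 0; j < nv; ++j) dg += dir[j] * g[j];
      if (!(dg > 0)) {  // not a descent direction: restart from gradient
        for (int j = 0; j < nv; ++j) dir[j] = 1e-3 * g[j];
        dg = 1e-3 * g2;
        nmem = 0;
      }
      // trust cap: bound the per-angle move so the polish cannot hop out of
      // the basin selected by the flow phase
      double dmax = 0.0;
      for (int j = 0; j < nv; ++j) dmax = std::max(dmax, std::fabs(dir[j]));
      if (dmax > step_max) {
        double sc = step_max / dmax;
        for (int j = 0; j < nv; ++j) dir[j] *= sc;
        dg *= sc;
      }
      double s = 1.0;
      double fnew = R_PosInf;
      for (int bt = 0; bt < 40; ++bt) {
        for (int j = 0; j < nv; ++j) xtrial[j] = x[j] - s * dir[j];
        fnew = ob.eval(xtrial.data(), ch, nullptr, nullptr, nullptr);
        if (fnew <= f - 1e-4 * s * dg) break;
        s *= 0.5;
      }
      if (fnew > f) {  // no descent found: numerically converged
        ++n_increase;
        break;
      }
      x_old = x;
      g_old = g;
      x.swap(xtrial);
      f = ob.eval(x.data(), ch, g.data(), &eel, &dist);
      // curvature pair
      double sy = 0.0, yy = 0.0;
      for (int j = 0; j < nv; ++j) {
        double sj = x[j] - x_old[j];
        double yj = g[j] - g_old[j];
        S[head][j] = sj;
        Y[head][j] = yj;
        sy += sj * yj;
        yy += yj * yj;
      }
      if (sy > 1e-14 && yy > 0) {
        rho[head] = 1.0 / sy;
        h0 = sy / yy;
        head = (head + 1) % mem;
        if (nmem < mem) ++nmem;
      }
    }
  }
  // final metrics at the optimum
  double f = ob.eval(x.data(), ch, g.data(), &eel, &dist);
  (void)f;
  double g2 = 0.0;
  for (int j = 0; j < nv; ++j) g2 += g[j] * g[j];
  gnorm = std::sqrt(g2);
  double viol = dist - d_target;
  if (viol < 0) viol = 0;
  converged = (gnorm < grad_tol) && (viol <= 0.05);

  NumericMatrix xout(ns, 3);
  for (int j = 0; j < nv; ++j) xout[j] = x[j];
  return List::create(
      _["angles"] = xout, _["energy_kT"] = eel, _["distance_nm"] = dist,
      _["constraint_violation_nm"] = viol,
      _["grad_norm"] = gnorm, _["iterations"] = total_iter,
      _["converged"] = converged, _["n_objective_increase"] = n_increase);
}

// Discrete wormlike chain sampler.  Per-joint bend drawn from the exact
// Boltzmann measure p(cos t) ~ exp(k cos t) with k = Lp / segment_length,
// uniform azimuth; uses R's RNG so set.seed() governs reproducibility.
// Returns n x 6: end-to-end vector r (nm), final tangent. The initial tangent
// is always (0, 0, 1).
// [[Rcpp::export(name = ".wlc_sample_cpp")]]
NumericMatrix wlc_sample_cpp(int n_chains, int n_seg, double seg_len,
                             double kappa) {
  NumericMatrix out(n_chains, 6);
  double e2k = std::exp(-2.0 * kappa);
  for (int c = 0; c < n_chains; ++c) {
    Vec3 t = v3(0, 0, 1);
    Vec3 r = v3(0, 0, seg_len);  // first segment along z
    for (int i = 1; i < n_seg; ++i) {
      double u = unif_rand();
      double ct;
      if (kappa > 0) {
        // inverse CDF of p(cos) ~ exp(k cos) on [-1, 1]
        double arg = u + (1.0 - u) * e2k;
        ct = 1.0 + std::log(arg) / kappa;
        if (ct < -1.0) ct = -1.0;
        if (ct > 1.0) ct = 1.0;
      } else {
        ct = 2.0 * u - 1.0;
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * unif_rand();
      // orthonormal frame around t
      Vec3 a = (std::fabs(t.z) < 0.9) ? v3(0, 0, 1) : v3(1, 0, 0);
      Vec3 uax = cross(t, a);
      double un = norm(uax);
      uax = (1.0 / un) * uax;
      Vec3 vax = cross(t, uax);
      t = ct * t + st * (std::cos(phi) * uax + std::sin(phi) * vax);
      double tn = norm(t);
      t = (1.0 / tn) * t;
      r = r + seg_len * t;
    }
    out(c, 0) = r.x; out(c, 1) = r.y; out(c, 2) = r.z;
    out(c, 3) = t.x; out(c, 4) = t.y; out(c, 5) = t.z;
  }
  return out;
}

// Metropolis sampler for the discrete wormlike chain constrained to a short
// end-to-end distance |r| <= r_max (a hard wall).  Moves are tail pivots: a
// random rotation of all tangents from a random joint onward, which changes
// a single joint's bending energy; acceptance is Metropolis in the bending
// energy times the constraint indicator.  The initial state is a uniform
// planar ring (|r| ~ 0), which always satisfies the constraint.  Returns
// n x 6 (end-to-end vector, final tangent) like the direct sampler; the
// first tangent is held at (0, 0, 1).
// [[Rcpp::export(name = ".wlc_sample_constrained_cpp")]]
NumericMatrix wlc_sample_constrained_cpp(int n_samples, int n_seg,
                                         double seg_len, double kappa,
                                         double r_max, int burn, int thin,
                                         double step_sd) {
  std::vector<Vec3> t(n_seg);
  // planar ring initial state
  for (int i = 0; i < n_seg; ++i) {
    double a = 2.0 * M_PI * i / n_seg;
    t[i] = v3(std::sin(a), 0.0, std::cos(a));
  }
  Vec3 r = v3(0, 0, 0);
  for (int i = 0; i < n_seg; ++i) r = r + seg_len * t[i];
  double r2max = r_max * r_max;

  NumericMatrix out(n_samples, 6);
  long total_moves = (long)burn + (long)n_samples * thin;
  int collected = 0;
  std::vector<Vec3> tail;  // workspace
  for (long mv = 0; mv < total_moves; ++mv) {
    // pivot joint j in 1..n_seg-1 (tangent 0 stays fixed as the reference)
    int j = 1 + (int)(unif_rand() * (n_seg - 1));
    if (j > n_seg - 1) j = n_seg - 1;
    // random small rotation
    double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
    double an = std::sqrt(ax * ax + ay * ay + az * az);
    if (an < 1e-12) continue;
    double ang = step_sd * norm_rand();
    double c = std::cos(ang), s1 = std::sin(ang), C = 1 - c;
    double ux = ax / an, uy = ay / an, uz = az / an;
    auto rot = [&](Vec3 v) {
      Vec3 u = v3(ux, uy, uz);
      return c * v + s1 * cross(u, v) + (C * dot(u, v)) * u;
    };
    Vec3 tj_new = rot(t[j]);
    // energy change at joint j only (tail rotates rigidly)
    double dE = -kappa * (dot(tj_new, t[j - 1]) - dot(t[j], t[j - 1]));
    // new end-to-end vector: r - sum(tail) + rot(sum(tail))
    Vec3 tail_sum = v3(0, 0, 0);
    for (int i = j; i < n_seg; ++i) tail_sum = tail_sum + t[i];
    Vec3 r_new = r - seg_len * tail_sum + seg_len * rot(tail_sum);
    if (dot(r_new, r_new) <= r2max &&
        (dE <= 0 || unif_rand() < std::exp(-dE))) {
      for (int i = j; i < n_seg; ++i) t[i] = rot(t[i]);
      r = r_new;
    }
    if (mv >= burn && (mv - burn) % thin == thin - 1) {
      out(collected, 0) = r.x; out(collected, 1) = r.y;
      out(collected, 2) = r.z;
      out(collected, 3) = t[n_seg - 1].x; out(collected, 4) = t[n_seg - 1].y;
      out(collected, 5) = t[n_seg - 1].z;
      if (++collected >= n_samples) break;
    }
  }
  return out;
}
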