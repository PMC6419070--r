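// Generalized bead-rod (GBR) Brownian dynamics core.
//
// Overdamped dynamics of N beads linked by N-1 inextensible rods of length b,
// with discrete wormlike-chain bending (E/kBT = kappa * sum(1 - cos theta)),
// optional axial tension on the end beads, hard rectangular channel walls
// realized as penalty displacements (clamping to the nearest wall plane), and
// rod constraints enforced by a projection built from the tridiagonal
// Lagrange-multiplier system along reference bond directions (Newton
// iteration, Thomas solves), polished by a current-direction sweep.
//
// All randomness comes from R's RNG so runs are reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static void bending_forces_impl(const NumericMatrix& r, double kappa,
                                NumericMatrix& F) {
  const int N = r.nrow();
  for (int j = 1; j < N - 1; ++j) {
    double Ax = r(j,0)-r(j-1,0), Ay = r(j,1)-r(j-1,1), Az = r(j,2)-r(j-1,2);
    double Bx = r(j+1,0)-r(j,0), By = r(j+1,1)-r(j,1), Bz = r(j+1,2)-r(j,2);
    double na = std::sqrt(Ax*Ax + Ay*Ay + Az*Az);
    double nb = std::sqrt(Bx*Bx + By*By + Bz*Bz);
    if (na <= 0.0 || nb <= 0.0)
      stop("degenerate (zero-length) bond at joint %d", j);
    double ax = Ax/na, ay = Ay/na, az = Az/na;
    double bx = Bx/nb, by = By/nb, bz = Bz/nb;
    double c = ax*bx + ay*by + az*bz;
    // d cos/dA = (bhat - c ahat)/|A|, d cos/dB = (ahat - c bhat)/|B|
    double gAx = (bx - c*ax)/na, gAy = (by - c*ay)/na, gAz = (bz - c*az)/na;
    double gBx = (ax - c*bx)/nb, gBy = (ay - c*by)/nb, gBz = (az - c*bz)/nb;
    F(j-1,0) -= kappa*gAx; F(j-1,1) -= kappa*gAy; F(j-1,2) -= kappa*gAz;
    F(j,0)   += kappa*(gAx-gBx); F(j,1) += kappa*(gAy-gBy); F(j,2) += kappa*(gAz-gBz);
    F(j+1,0) += kappa*gBx; F(j+1,1) += kappa*gBy; F(j+1,2) += kappa*gBz;
  }
}

static double max_rod_error(const NumericMatrix& r, double b) {
  const int N = r.nrow();
  double m = 0.0;
  for (int k = 0; k < N - 1; ++k) {
    double ex = r(k+1,0)-r(k,0), ey = r(k+1,1)-r(k,1), ez = r(k+1,2)-r(k,2);
    double e = std::fabs(std::sqrt(ex*ex+ey*ey+ez*ez) - b) / b;
    if (e > m) m = e;
  }
  return m;
}

// Projection onto the rod-length manifold. The linearized projection is a
// Newton iteration on the tridiagonal Lagrange-multiplier system along the
// reference bond directions (Thomas solves); its basin is limited for long
// near-straight chains, so Newton attempts (reverted when they fail to
// improve) are interleaved with blocks of current-direction Gauss-Seidel
// length restoration, which make slow but safe progress. Returns the final
// max relative rod error.
static double newton_pass(NumericMatrix& r,
                          const std::vector<double>& d0x,
                          const std::vector<double>& d0y,
                          const std::vector<double>& d0z,
                          double b, double tol, int itmax) {
  const int M = static_cast<int>(d0x.size());
  const double b2 = b * b;
  std::vector<double> G(M), dl(M), lo(M), di(M), up(M), cp(M);
  std::vector<double> dx(M), dy(M), dz(M);
  double maxerr = 0.0;
  for (int it = 0; it < itmax; ++it) {
    maxerr = 0.0;
    for (int k = 0; k < M; ++k) {
      dx[k] = r(k+1,0) - r(k,0);
      dy[k] = r(k+1,1) - r(k,1);
      dz[k] = r(k+1,2) - r(k,2);
      double g = dx[k]*dx[k] + dy[k]*dy[k] + dz[k]*dz[k] - b2;
      G[k] = g;
      double e = std::fabs(std::sqrt(g + b2) - b) / b;
      if (e > maxerr) maxerr = e;
    }
    if (maxerr < tol) return maxerr;
    // correction r_k += dl_k d0_k, r_{k+1} -= dl_k d0_k  =>  d_k -= 2 dl_k d0_k
    for (int k = 0; k < M; ++k) {
      di[k] = -4.0 * (dx[k]*d0x[k] + dy[k]*d0y[k] + dz[k]*d0z[k]);
      if (k > 0)     lo[k] = 2.0 * (dx[k]*d0x[k-1] + dy[k]*d0y[k-1] + dz[k]*d0z[k-1]);
      if (k < M - 1) up[k] = 2.0 * (dx[k]*d0x[k+1] + dy[k]*d0y[k+1] + dz[k]*d0z[k+1]);
    }
    bool ok = std::fabs(di[0]) > 1e-300;
    if (ok) {
      cp[0] = up[0] / di[0];
      dl[0] = -G[0] / di[0];
      for (int k = 1; k < M && ok; ++k) {
        double m = di[k] - lo[k] * cp[k-1];
        if (std::fabs(m) < 1e-300) { ok = false; break; }
        if (k < M - 1) cp[k] = up[k] / m;
        dl[k] = (-G[k] - lo[k] * dl[k-1]) / m;
      }
    }
    if (!ok) return maxerr;
    for (int k = M - 2; k >= 0; --k) dl[k] -= cp[k] * dl[k+1];
    for (int k = 0; k < M; ++k) {
      r(k,0)   += dl[k]*d0x[k]; r(k,1)   += dl[k]*d0y[k]; r(k,2)   += dl[k]*d0z[k];
      r(k+1,0) -= dl[k]*d0x[k]; r(k+1,1) -= dl[k]*d0y[k]; r(k+1,2) -= dl[k]*d0z[k];
    }
  }
  return max_rod_error(r, b);
}

static double gs_pass(NumericMatrix& r, double b, double tol, int sweeps) {
  const int M = r.nrow() - 1;
  double maxerr = 0.0;
  for (int it = 0; it < sweeps; ++it) {
    maxerr = 0.0;
    for (int k = 0; k < M; ++k) {
      double ex = r(k+1,0)-r(k,0), ey = r(k+1,1)-r(k,1), ez = r(k+1,2)-r(k,2);
      double L = std::sqrt(ex*ex+ey*ey+ez*ez);
      double e = std::fabs(L - b) / b;
      if (e > maxerr) maxerr = e;
      if (L <= 0.0) continue;
      double s = 0.5 * (L - b) / L;
      r(k,0) += s*ex; r(k,1) += s*ey; r(k,2) += s*ez;
      r(k+1,0) -= s*ex; r(k+1,1) -= s*ey; r(k+1,2) -= s*ez;
    }
    if (maxerr < tol) break;
  }
  return max_rod_error(r, b);
}

static double project_rods_impl(NumericMatrix& r, const NumericMatrix& ref,
                                double b, double tol, int newton_max,
                                int gs_max) {
  const int N = r.nrow();
  const int M = N - 1;
  std::vector<double> d0x(M), d0y(M), d0z(M);
  for (int k = 0; k < M; ++k) {
    d0x[k] = ref(k+1,0) - ref(k,0);
    d0y[k] = ref(k+1,1) - ref(k,1);
    d0z[k] = ref(k+1,2) - ref(k,2);
  }
  double err = max_rod_error(r, b);
  NumericMatrix r_save(N, 3);
  for (int outer = 0; outer < 30; ++outer) {
    if (err < tol) return err;
    // Newton attempt; revert if it does not improve
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c) r_save(i,c) = r(i,c);
    double err_n = newton_pass(r, d0x, d0y, d0z, b, tol, newton_max);
    if (err_n >= err) {
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < 3; ++c) r(i,c) = r_save(i,c);
    } else {
      err = err_n;
    }
    if (err < tol) return err;
    err = gs_pass(r, b, tol, gs_max);
  }
  return err;
}

static double clamp_walls_impl(NumericMatrix& r, double half_w, double half_h) {
  const int N = r.nrow();
  double maxviol = 0.0;
  for (int i = 0; i < N; ++i) {
    if (R_finite(half_w)) {
      if (r(i,0) >  half_w) { maxviol = std::max(maxviol, r(i,0)-half_w); r(i,0) = half_w; }
      else if (r(i,0) < -half_w) { maxviol = std::max(maxviol, -half_w-r(i,0)); r(i,0) = -half_w; }
    }
    if (R_finite(half_h)) {
      if (r(i,1) >  half_h) { maxviol = std::max(maxviol, r(i,1)-half_h); r(i,1) = half_h; }
      else if (r(i,1) < -half_h) { maxviol = std::max(maxviol, -half_h-r(i,1)); r(i,1) = -half_h; }
    }
  }
  return maxviol;
}

static double wall_violation_impl(const NumericMatrix& r, double half_w,
                                  double half_h) {
  const int N = r.nrow();
  double v = 0.0;
  for (int i = 0; i < N; ++i) {
    if (R_finite(half_w)) v = std::max(v, std::fabs(r(i,0)) - half_w);
    if (R_finite(half_h)) v = std::max(v, std::fabs(r(i,1)) - half_h);
  }
  return std::max(v, 0.0);
}

// [[Rcpp::export]]
NumericMatrix bending_forces_cpp(NumericMatrix pos, double kappa) {
  NumericMatrix F(pos.nrow(), 3);
  bending_forces_impl(pos, kappa, F);
  return F;
}

// [[Rcpp::export]]
NumericMatrix project_rods_cpp(NumericMatrix pos, NumericMatrix ref, double b,
                               double tol, int newton_max, int gs_max) {
  NumericMatrix r(clone(pos));
  project_rods_impl(r, ref, b, tol, newton_max, gs_max);
  return r;
}

// [[Rcpp::export]]
List gbr_run_cpp(NumericMatrix pos, double b, double kappa, double fz,
                 double mobdt, double sq2Ddt, int steps,
                 double half_w, double half_h,
                 double rod_tol, int newton_max, int gs_max,
                 int wall_maxit, double wall_tol, int max_retries,
                 int thin, int frame_every) {
  const int N = pos.nrow();
  NumericMatrix r(clone(pos));
  const int nrec = (thin > 0) ? steps / thin : 0;
  NumericVector ext(nrec);
  const int nframes = (frame_every > 0) ? steps / frame_every : 0;
  NumericVector frames(static_cast<R_xlen_t>(nframes) * N * 3);
  double max_rod = 0.0, max_wall = 0.0;
  int n_rejected = 0, failed_step = -1;
  NumericMatrix F(N, 3), rnew(N, 3);
  int irec = 0, ifr = 0;
  for (int s = 0; s < steps; ++s) {
    bool accepted = false;
    double rod_err = 0.0;
    for (int att = 0; att <= max_retries; ++att) {
      std::fill(F.begin(), F.end(), 0.0);
      bending_forces_impl(r, kappa, F);
      F(0,2) -= fz; F(N-1,2) += fz;
      // unconstrained proposal; wall penalty of the current positions is
      // zero whenever they are interior (they are, after any accepted step)
      for (int c = 0; c < 3; ++c)
        for (int i = 0; i < N; ++i)
          rnew(i,c) = r(i,c) + mobdt * F(i,c) + sq2Ddt * norm_rand();
      for (int w = 0; w < wall_maxit; ++w) {
        clamp_walls_impl(rnew, half_w, half_h);
        rod_err = project_rods_impl(rnew, r, b, rod_tol, newton_max, gs_max);
        if (wall_violation_impl(rnew, half_w, half_h) <= wall_tol) break;
      }
      if (rod_err <= rod_tol &&
          wall_violation_impl(rnew, half_w, half_h) <= wall_tol) {
        accepted = true;
        break;
      }
      ++n_rejected;
    }
    if (!accepted) { failed_step = s + 1; break; }
    max_rod = std::max(max_rod, rod_err);
    max_wall = std::max(max_wall, wall_violation_impl(rnew, half_w, half_h));
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c) r(i,c) = rnew(i,c);
    if (thin > 0 && (s + 1) % thin == 0 && irec < nrec)
      ext[irec++] = r(N-1,2) - r(0,2);
    if (frame_every > 0 && (s + 1) % frame_every == 0 && ifr < nframes) {
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < 3; ++c)
          frames[static_cast<R_xlen_t>(ifr)*N*3 + c*N + i] = r(i,c);
      ++ifr;
    }
  }
  return List::create(_["extension"] = ext, _["positions"] = r,
                      _["frames"] = frames, _["n_frames"] = ifr,
                      _["max_rod_err"] = max_rod,
                      _["max_wall_violation"] = max_wall,
                      _["n_rejected"] = n_rejected,
                      _["failed_step"] = failed_step);
}
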