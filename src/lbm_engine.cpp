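// D2Q9 BGK lattice Boltzmann engine with immersed-boundary coupling.
//
// Single workhorse loop used by all scenario drivers.  Direction indexing:
//   0 rest; 1 E(1,0); 2 N(0,1); 3 W(-1,0); 4 S(0,-1);
//   5 NE(1,1); 6 NW(-1,1); 7 SW(-1,-1); 8 SE(1,-1)
// Internal storage is node-major: f[(y*nx + x)*9 + i].
// Boundary codes
//   bcx: 0 periodic, 1 uniform-inflow west / zero-gradient outflow east,
//        2 stationary link bounce-back walls
//   bcy: 0 periodic, 2 link bounce-back walls, tangential wall velocities
//        wall_u_bottom / wall_u_top (half-way reflection, wall sits half a
//        cell outside the last fluid row)
// Forcing follows the Shan-Chen velocity shift: the equilibrium is evaluated
// at u_eq = u + tau*F/rho, which injects exactly F of momentum per step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const int EX[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
static const int EY[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
static const int OPP[9] = {0, 3, 4, 1, 2, 7, 8, 5, 6};
static const double W9[9] = {4.0 / 9.0,
                             1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0,
                             1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0};

static inline void feq9(double rho, double ux, double uy, double *out) {
  const double usq = 1.5 * (ux * ux + uy * uy);
  for (int i = 0; i < 9; ++i) {
    const double eu = 3.0 * (EX[i] * ux + EY[i] * uy);
    out[i] = W9[i] * rho * (1.0 + eu + 0.5 * eu * eu - usq);
  }
}

// status codes reported back to R
enum { ST_OK = 0, ST_UNSTABLE = 1, ST_WALL_CONTACT = 2, ST_OUT_OF_DOMAIN = 3 };

// [[Rcpp::export]]
List cpp_lbm_run(NumericVector f0, int nx, int ny, double tau,
                 double gx, double gy,
                 int bcx, double inflow_u,
                 int bcy, double wall_u_bottom, double wall_u_top,
                 NumericMatrix mem_nodes, NumericMatrix mem_ref,
                 double mem_gain, bool mem_mobile,
                 double mem_mass,
                 double fext_x, double fext_y,
                 bool ac_active, double ac_amp, double ac_lambda,
                 double ac_phase,
                 int nsteps, int sample_every,
                 int conv_mode, double conv_tol, int conv_every,
                 int min_steps) {
  const int ncell = nx * ny;
  std::vector<double> f(f0.begin(), f0.end());  // expects internal layout
  std::vector<double> fn(ncell * 9, 0.0);
  std::vector<double> Fxf(ncell, 0.0), Fyf(ncell, 0.0);

  const int nmem = mem_nodes.nrow();
  std::vector<double> Xm(nmem), Ym(nmem), Rx(nmem), Ry(nmem);
  for (int k = 0; k < nmem; ++k) {
    Xm[k] = mem_nodes(k, 0);
    Ym[k] = mem_nodes(k, 1);
    Rx[k] = mem_ref(k, 0);   // offsets from the anchor centroid
    Ry[k] = mem_ref(k, 1);
  }
  // Direct-forcing rigid membrane: the nodes ride rigidly on a body frame
  // (reference offsets about the body position); the immersed-boundary
  // force at each node is a velocity-mismatch forcing
  // F = gain * (U_rigid - u_fluid), and the body obeys Newton's law under
  // the forcing reactions plus the external (acoustic/gravity) force.  An
  // immobile membrane is the infinite-mass limit (U_rigid = 0).
  double body_x = 0.0, body_y = 0.0, body_vx = 0.0, body_vy = 0.0;
  for (int k = 0; k < nmem; ++k) { body_x += Xm[k]; body_y += Ym[k]; }
  if (nmem > 0) { body_x /= nmem; body_y /= nmem; }

  double cum_cx = body_x;  // unwrapped body x (periodic domains wrap Xm)

  // sampling buffers
  const int nsamp_max = nsteps / std::max(1, sample_every) + 2;
  NumericMatrix traj(nsamp_max, 9);
  int nsamp = 0;

  std::vector<double> uxprev, uyprev;
  if (conv_mode == 1) { uxprev.assign(ncell, 0.0); uyprev.assign(ncell, 0.0); }
  double drag_win_sum = 0.0, drag_win_prev = R_NaReal;

  int status = ST_OK;
  bool converged = false;
  int step = 0;

  const double inv_tau = 1.0 / tau;
  double feq[9];

  // pre-compute inflow equilibrium column
  double fin[9];
  feq9(1.0, inflow_u, 0.0, fin);

  double drag_x = 0.0, drag_y = 0.0, f_ac = 0.0;

  for (step = 1; step <= nsteps && status == ST_OK; ++step) {
    // ---- membrane constitutive forces + spreading -----------------------
    drag_x = 0.0; drag_y = 0.0; f_ac = 0.0;
    if (nmem > 0) {
      std::memset(Fxf.data(), 0, ncell * sizeof(double));
      std::memset(Fyf.data(), 0, ncell * sizeof(double));
      if (ac_active) {
        // lateral position measured from the bottom wall (half a cell below
        // the first fluid row): y_wall = y_lattice + 0.5
        const double yp = body_y + 0.5;
        f_ac = -ac_amp * std::sin(4.0 * M_PI * (yp - ac_phase) / ac_lambda);
      }
      for (int k = 0; k < nmem; ++k) {
        // rigid node position in the body frame
        double xk = body_x + Rx[k];
        const double yk = body_y + Ry[k];
        if (bcx == 0) xk -= nx * std::floor(xk / nx);
        else if (xk < 1.0 || xk > nx - 2.0) { status = ST_OUT_OF_DOMAIN; break; }
        if (yk < 0.5 || yk > ny - 1.5) {
          status = mem_mobile ? ST_WALL_CONTACT : ST_OUT_OF_DOMAIN;
          break;
        }
        Xm[k] = xk; Ym[k] = yk;
        // interpolate the pre-collision fluid velocity at the node
        const int xb = (int)std::floor(xk);
        const int yb = (int)std::floor(yk);
        double ukx = 0.0, uky = 0.0;
        for (int dyc = 0; dyc <= 1; ++dyc) {
          const int yc = yb + dyc;
          const double wy = 1.0 - std::fabs(yk - yc);
          for (int dxc = 0; dxc <= 1; ++dxc) {
            int xc = xb + dxc;
            if (bcx == 0) xc = (xc % nx + nx) % nx;
            const double wx = 1.0 - std::fabs(xk - (xb + dxc));
            const double *fp = &f[(yc * nx + xc) * 9];
            double rho = 0.0;
            for (int i = 0; i < 9; ++i) rho += fp[i];
            ukx += wx * wy * (fp[1] - fp[3] + fp[5] - fp[6] - fp[7] + fp[8]) / rho;
            uky += wx * wy * (fp[2] - fp[4] + fp[5] + fp[6] - fp[7] - fp[8]) / rho;
          }
        }
        // velocity-mismatch forcing toward the rigid-body velocity
        const double fbx = mem_gain * (body_vx - ukx);
        const double fby = mem_gain * (body_vy - uky);
        drag_x -= fbx;  // reaction force of the fluid on the body
        drag_y -= fby;
        for (int dyc = 0; dyc <= 1; ++dyc) {
          const int yc = yb + dyc;
          const double wy = 1.0 - std::fabs(yk - yc);
          for (int dxc = 0; dxc <= 1; ++dxc) {
            int xc = xb + dxc;
            if (bcx == 0) xc = (xc % nx + nx) % nx;
            const double wx = 1.0 - std::fabs(xk - (xb + dxc));
            const double wgt = wx * wy;
            Fxf[yc * nx + xc] += wgt * fbx;
            Fyf[yc * nx + xc] += wgt * fby;
          }
        }
      }
      if (status != ST_OK) break;
    }

    // ---- fused moments + BGK collision + push streaming ------------------
    // One pass: read a node's nine populations, collide toward the
    // velocity-shifted equilibrium, and push the post-collision values to
    // their target slots.  Interior nodes take a branch-free fast path;
    // edge nodes handle periodic wrap / link bounce-back / open faces.
    const bool has_spread = (nmem > 0);
    for (int y = 0; y < ny && status == ST_OK; ++y) {
      const bool yedge = (y == 0 || y == ny - 1);
      for (int x = 0; x < nx; ++x) {
        const int c = y * nx + x;
        const double *fp = &f[c * 9];
        const double rho = fp[0] + fp[1] + fp[2] + fp[3] + fp[4] + fp[5] +
                           fp[6] + fp[7] + fp[8];
        if (!(rho > 0.0) || !std::isfinite(rho)) { status = ST_UNSTABLE; break; }
        const double ux = (fp[1] - fp[3] + fp[5] - fp[6] - fp[7] + fp[8]) / rho;
        const double uy = (fp[2] - fp[4] + fp[5] + fp[6] - fp[7] - fp[8]) / rho;
        const double Fx = gx + (has_spread ? Fxf[c] : 0.0);
        const double Fy = gy + (has_spread ? Fyf[c] : 0.0);
        const double uex = ux + tau * Fx / rho;
        const double uey = uy + tau * Fy / rho;
        feq9(rho, uex, uey, feq);
        double fpost[9];
        for (int i = 0; i < 9; ++i)
          fpost[i] = fp[i] - (fp[i] - feq[i]) * inv_tau;
        if (!yedge && x > 0 && x < nx - 1) {
          double *row = &fn[c * 9];
          row[0] = fpost[0];
          row[9 + 1] = fpost[1];                 // E  -> (x+1, y)
          row[nx * 9 + 2] = fpost[2];            // N  -> (x, y+1)
          row[-9 + 3] = fpost[3];                // W  -> (x-1, y)
          row[-nx * 9 + 4] = fpost[4];           // S  -> (x, y-1)
          row[(nx + 1) * 9 + 5] = fpost[5];      // NE -> (x+1, y+1)
          row[(nx - 1) * 9 + 6] = fpost[6];      // NW -> (x-1, y+1)
          row[(-nx - 1) * 9 + 7] = fpost[7];     // SW -> (x-1, y-1)
          row[(-nx + 1) * 9 + 8] = fpost[8];     // SE -> (x+1, y-1)
        } else {
          fn[c * 9 + 0] = fpost[0];
          for (int i = 1; i < 9; ++i) {
            int tx = x + EX[i], ty = y + EY[i];
            bool crossx = false, crossy = false;
            if (bcx == 0) tx = (tx + nx) % nx;
            else if (tx < 0 || tx >= nx) crossx = true;
            if (bcy == 0) ty = (ty + ny) % ny;
            else if (ty < 0 || ty >= ny) crossy = true;
            if (!crossx && !crossy) {
              fn[(ty * nx + tx) * 9 + i] = fpost[i];
            } else if (bcx == 1 && crossx) {
              continue;  // leaves through the open x face; column reset below
            } else {
              // half-way link bounce-back (optionally a moving y wall);
              // the momentum-exchange term uses this node's pre-collision rho
              double corr = 0.0;
              if (crossy) {
                const double uw = (EY[i] > 0) ? wall_u_top : wall_u_bottom;
                corr = 6.0 * W9[i] * rho * (EX[i] * uw);
              }
              fn[c * 9 + OPP[i]] = fpost[i] - corr;
            }
          }
        }
      }
    }
    if (status != ST_OK) break;
    if (bcx == 1) {
      // equilibrium inflow column / zero-gradient outflow column
      for (int y = 0; y < ny; ++y) {
        double *fi = &fn[(y * nx + 0) * 9];
        for (int i = 0; i < 9; ++i) fi[i] = fin[i];
        double *fo = &fn[(y * nx + (nx - 1)) * 9];
        const double *fc = &fn[(y * nx + (nx - 2)) * 9];
        for (int i = 0; i < 9; ++i) fo[i] = fc[i];
      }
    }
    f.swap(fn);

    // ---- rigid-body update (Euler, dt = 1) -------------------------------
    double mvx = 0.0, mvy = 0.0;
    if (nmem > 0 && mem_mobile) {
      // Newton's law for the rigid particle: forcing reactions + external
      body_vx += (drag_x + fext_x) / mem_mass;
      body_vy += (drag_y + fext_y + f_ac) / mem_mass;
      body_x += body_vx;
      body_y += body_vy;
      cum_cx += body_vx;
      if (bcx == 0) body_x -= nx * std::floor(body_x / nx);
      mvx = body_vx; mvy = body_vy;
    }

    // ---- sampling --------------------------------------------------------
    if (sample_every > 0 && (step % sample_every == 0 || step == nsteps ||
                             status != ST_OK)) {
      double mass = 0.0;
      for (size_t q = 0; q < f.size(); ++q) mass += f[q];
      double cy = 0.0;
      if (nmem > 0) {
        if (mem_mobile) cy = body_y;
        else { for (int k = 0; k < nmem; ++k) cy += Ym[k]; cy /= nmem; }
      }
      if (nsamp < nsamp_max) {
        traj(nsamp, 0) = step;
        traj(nsamp, 1) = cum_cx;
        traj(nsamp, 2) = cy;
        traj(nsamp, 3) = mvx;
        traj(nsamp, 4) = mvy;
        traj(nsamp, 5) = f_ac;
        traj(nsamp, 6) = drag_x;
        traj(nsamp, 7) = drag_y;
        traj(nsamp, 8) = mass;
        ++nsamp;
      }
    }

    // ---- convergence checks ---------------------------------------------
    if (conv_mode == 1 && conv_every > 0 && step % conv_every == 0) {
      // recompute moments of the streamed field for the comparison
      double maxdiff = 0.0;
      for (int c = 0; c < ncell; ++c) {
        const double *fp = &f[c * 9];
        double rho = 0.0;
        for (int i = 0; i < 9; ++i) rho += fp[i];
        const double ux = (fp[1] - fp[3] + fp[5] - fp[6] - fp[7] + fp[8]) / rho;
        const double uy = (fp[2] - fp[4] + fp[5] + fp[6] - fp[7] - fp[8]) / rho;
        double d = std::fabs(ux - uxprev[c]);
        if (d > maxdiff) maxdiff = d;
        d = std::fabs(uy - uyprev[c]);
        if (d > maxdiff) maxdiff = d;
        uxprev[c] = ux; uyprev[c] = uy;
      }
      if (step >= min_steps && maxdiff < conv_tol) { converged = true; break; }
    } else if (conv_mode == 2 && conv_every > 0) {
      drag_win_sum += drag_x;
      if (step % conv_every == 0) {
        const double m = drag_win_sum / conv_every;
        if (R_finite(drag_win_prev) && step >= min_steps &&
            std::fabs(m - drag_win_prev) <=
                conv_tol * std::max(std::fabs(m), 1e-300)) {
          converged = true;
          drag_win_prev = m;
          break;
        }
        drag_win_prev = m;
        drag_win_sum = 0.0;
      }
    }
  }
  if (step > nsteps) step = nsteps;

  // ---- pack results ----------------------------------------------------
  NumericVector fout(ncell * 9);
  std::copy(f.begin(), f.end(), fout.begin());
  NumericMatrix rho_out(nx, ny), ux_out(nx, ny), uy_out(nx, ny);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      const double *fp = &f[(y * nx + x) * 9];
      double rho = 0.0;
      for (int i = 0; i < 9; ++i) rho += fp[i];
      rho_out(x, y) = rho;
      ux_out(x, y) = (fp[1] - fp[3] + fp[5] - fp[6] - fp[7] + fp[8]) / rho;
      uy_out(x, y) = (fp[2] - fp[4] + fp[5] + fp[6] - fp[7] - fp[8]) / rho;
    }
  }
  NumericMatrix mem_out(nmem, 2);
  for (int k = 0; k < nmem; ++k) { mem_out(k, 0) = Xm[k]; mem_out(k, 1) = Ym[k]; }
  NumericMatrix traj_out(nsamp, 9);
  for (int r = 0; r < nsamp; ++r)
    for (int c2 = 0; c2 < 9; ++c2) traj_out(r, c2) = traj(r, c2);
  colnames(traj_out) = CharacterVector::create(
      "step", "cx", "cy", "vx", "vy", "f_ac", "drag_x", "drag_y", "mass");

  return List::create(
      _["f"] = fout, _["rho"] = rho_out, _["ux"] = ux_out, _["uy"] = uy_out,
      _["membrane"] = mem_out, _["traj"] = traj_out,
      _["steps"] = step, _["converged"] = converged,
      _["status"] = status,
      _["drag_mean"] = drag_win_prev);
}
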