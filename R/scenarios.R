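#' Reference data for the benchmark scenarios
#'
#' \code{ghiaReference} returns the classical Re = 100 lid-driven-cavity
#' centerline profile (horizontal velocity along the vertical line through
#' the cavity centre, normalized by the lid speed).
#' \code{cylinderDragReference} returns the literature drag-coefficient
#' fixture for a circular cylinder in a laterally bounded uniform stream:
#' for Re <= 1 a matched Oseen/Faxen form
#' \eqn{C_d = 8\pi / (Re \, S_{eff})} with
#' \eqn{S_{eff} = \min(\ln(7.4/Re),\ \ln(H/D) - 0.9157)} (the inertial wake
#' cutoff or the wall cutoff, whichever screens the Stokes logarithm first),
#' and for larger Re the Sucker-Brauer experimental correlation.
#'
#' @return data frames read from the packaged fixtures.
#' @export
ghiaReference <- function() {
  read.csv(system.file("extdata", "ghia_re100_centerline_u.csv",
                       package = "acoustoLBM"), comment.char = "#")
}

#' @rdname ghiaReference
#' @export
cylinderDragReference <- function() {
  read.csv(system.file("extdata", "cylinder_drag_reference.csv",
                       package = "acoustoLBM"), comment.char = "#")
}

.benchmark <- function(profile, error_norm, reference_id, extra = list()) {
  structure(c(list(profile = profile, error_norm = error_norm,
                   reference_id = reference_id), extra),
            class = "lbm_benchmark")
}

#' @export
print.lbm_benchmark <- function(x, ...) {
  cat(sprintf("<lbm_benchmark> vs %s: error norm %.4g\n",
              x$reference_id, x$error_norm))
  invisible(x)
}

#' Plane Poiseuille benchmark
#'
#' Body-force-driven channel flow between bounce-back walls with periodic
#' ends, run to steady state and compared against the analytic parabola
#' \eqn{u_x(y) = u_{max}\,[1 - (2y/H)^2]} (y from the centerline).  A uniform
#' body force g stands in for the pressure gradient, \eqn{g = -dP/dx / \rho},
#' which is equivalent for fully developed flow.
#'
#' @param ny,nx grid size (fluid nodes; walls sit half a cell outside).
#' @param nu lattice kinematic viscosity.
#' @param u_max target centerline speed (lattice units); alternatively give
#'   \code{re} to set it from \code{re = u_max ny / nu}.
#' @param re optional target Reynolds number.
#' @param max_steps step budget; exceeding it without meeting the steady
#'   criterion is a convergence error.
#' @param conv_tol steady-state criterion: max change of any velocity
#'   component over \code{conv_every} steps.
#' @param conv_every,sample_every cadences.
#' @return an \code{lbm_benchmark} with the normalized profile and the
#'   relative L2 error against the analytic solution.
#' @export
runPoiseuille <- function(ny = 40, nx = 40, nu = 1 / 6, u_max = 0.05,
                          re = NULL, max_steps = 60000,
                          conv_tol = 1e-11, conv_every = 200,
                          sample_every = 1000) {
  if (!is.null(re)) u_max <- re * nu / ny
  tau <- tauFromViscosity(nu)
  g <- 8 * nu * u_max / ny^2
  f <- array(rep(equilibriumDistribution(1, c(0, 0)), each = nx * ny),
             c(nx, ny, 9))
  res <- .run_engine(f, tau, gx = g, bcx = 0L, bcy = 2L,
                     nsteps = max_steps, sample_every = sample_every,
                     conv_mode = 1L, conv_tol = conv_tol,
                     conv_every = conv_every, min_steps = 2 * conv_every)
  .engine_status_check(res, "poiseuille")
  if (!res$converged)
    .stop_stability(sprintf(
      "poiseuille benchmark did not reach steady state in %d steps",
      max_steps))
  u <- res$ux[max(1L, nx %/% 2L), ]
  s <- (seq_len(ny) - 0.5) / ny
  ua <- 4 * u_max * s * (1 - s)
  l2 <- sqrt(sum((u - ua)^2) / sum(ua^2))
  .benchmark(data.frame(y = s, u = u / max(u), u_analytic = ua / u_max),
             l2, "analytic_poiseuille",
             list(steps = res$steps, u_max = max(u), u_max_target = u_max,
                  field = list(ux = res$ux, uy = res$uy, rho = res$rho)))
}

#' Lid-driven cavity benchmark at Re = 100
#'
#' Square cavity with three stationary walls and a tangentially moving top
#' wall, run to steady state; the horizontal velocity along the vertical
#' centerline is compared with the Ghia et al. reference profile.  The
#' default scheme uses link bounce-back walls with a momentum-exchange moving
#' lid (exactly mass conserving); \code{scheme = "reconstruction"} runs the
#' Zou-He wet-node reconstruction through the plain-R reference stepper
#' (small grids only).
#'
#' @param n cavity size in nodes.
#' @param re target Reynolds number based on lid speed and cavity size.
#' @param u_lid lid speed (lattice units, must stay well below the sound
#'   speed).
#' @param max_steps,conv_tol,conv_every steady-state control
#'   (\code{conv_tol} is relative to the lid speed).
#' @param scheme \code{"bounceback"} or \code{"reconstruction"}.
#' @return an \code{lbm_benchmark} with the centerline profile and the RMS
#'   deviation from the reference, normalized by lid speed.
#' @export
runCavity <- function(n = 50, re = 100, u_lid = 0.1, max_steps = 200000,
                      conv_tol = 1e-6, conv_every = 500,
                      scheme = c("bounceback", "reconstruction")) {
  scheme <- match.arg(scheme)
  if (u_lid >= 0.1 + 1e-12)
    .stop_invalid("u_lid", "must stay below 0.1 for low-Mach validity")
  nu <- u_lid * n / re
  tau <- tauFromViscosity(nu)
  if (scheme == "bounceback") {
    f <- array(rep(equilibriumDistribution(1, c(0, 0)), each = n * n),
               c(n, n, 9))
    res <- .run_engine(f, tau, bcx = 2L, bcy = 2L, wall_u_top = u_lid,
                       nsteps = max_steps, sample_every = 1000,
                       conv_mode = 1L, conv_tol = conv_tol * u_lid,
                       conv_every = conv_every, min_steps = 2 * conv_every)
    .engine_status_check(res, "cavity")
    if (!res$converged)
      .stop_stability(sprintf("cavity did not reach steady state in %d steps",
                              max_steps))
    ux <- res$ux; steps <- res$steps
  } else {
    state <- latticeState(n, n, tau)
    plan <- boundaryPlan(
      left = boundarySpec("left", "reconstruction"),
      right = boundarySpec("right", "reconstruction"),
      bottom = boundarySpec("bottom", "reconstruction"),
      top = boundarySpec("top", "moving_wall", c(u_lid, 0)))
    uxprev <- matrix(0, n, n); steps <- 0L; converged <- FALSE
    while (steps < max_steps) {
      for (k in seq_len(conv_every)) state <- lbmStep(state, plan)
      steps <- steps + conv_every
      m <- latticeMoments(state$f)
      if (max(abs(m$u[, , 1] - uxprev)) < conv_tol * u_lid &&
          steps >= 2 * conv_every) { converged <- TRUE; break }
      uxprev <- m$u[, , 1]
    }
    if (!converged)
      .stop_stability("cavity (reconstruction scheme) did not converge")
    ux <- latticeMoments(state$f)$u[, , 1]
  }
  # centerline profile: average the two central columns of an even grid,
  # wall-to-wall coordinates with the walls half a cell outside the grid
  mid <- if (n %% 2 == 0) c(n %/% 2, n %/% 2 + 1) else (n + 1) %/% 2
  uprof <- rowMeans(cbind(ux[mid[1], ], ux[mid[length(mid)], ]))
  yprof <- if (scheme == "bounceback") (seq_len(n) - 0.5) / n
           else (seq_len(n) - 1) / (n - 1)
  y_all <- c(0, yprof, 1)
  u_all <- c(0, uprof / u_lid, 1)
  ref <- ghiaReference()
  u_at_ref <- approx(y_all, u_all, xout = ref$y)$y
  rms <- sqrt(mean((u_at_ref - ref$u)^2))
  .benchmark(data.frame(y = ref$y, u = u_at_ref, u_ref = ref$u),
             rms, "ghia1982_re100",
             list(steps = steps, scheme = scheme, u_lid = u_lid,
                  centerline = data.frame(y = y_all, u = u_all)))
}

#' Drag of a fixed circular cylinder at low Reynolds number
#'
#' A rigid membrane cylinder is held fixed (penalty anchoring) in a uniform
#' stream: equilibrium inflow at the west face, zero-gradient outflow at the
#' east face, and side walls co-moving with the stream, which realizes a
#' cylinder translating through a laterally bounded quiescent fluid.  For
#' each Reynolds number the run proceeds to steady drag and
#' \eqn{C_d = F_{drag}/(\tfrac12 \rho D u_r^2)} is reported together with the
#' deviation from the literature fixture at the same confinement ratio.
#'
#' @param re_values Reynolds numbers to sweep (steady regime, <= ~40).
#' @param lx,ly domain size in nodes.
#' @param diameter cylinder diameter in lattice units (blockage
#'   \code{diameter/ly} must not exceed 0.04).
#' @param gain direct-forcing coupling gain; the default scales as
#'   \code{1/tau} (the velocity-shift forcing amplifies spread forces by
#'   tau, so large gains destabilize at large relaxation times).
#' @param conv_tol relative change of window-averaged drag that counts as
#'   steady.
#' @param conv_every drag-averaging window (steps).
#' @param max_steps optional per-Re cap (default scales with the viscous or
#'   advective time).
#' @return an \code{lbm_benchmark} whose profile is the Cd-Re table with
#'   fixture values and relative deviations.
#' @export
runCylinder <- function(re_values = c(0.1, 1, 10), lx = 1000, ly = 500,
                        diameter = 20, gain = NULL,
                        conv_tol = 2e-4, conv_every = 2000,
                        max_steps = NULL) {
  if (diameter / ly > 0.04 + 1e-12)
    .stop_invalid("diameter", "blockage ratio diameter/ly must be <= 0.04")
  ref_all <- cylinderDragReference()
  rows <- lapply(re_values, function(re) {
    nu <- if (re <= 2) 0.5 else 0.06
    U <- re * nu / diameter
    if (U > 0.1) .stop_config(sprintf(
      "Re = %g needs inflow speed %.3g > 0.1; refine the setup", re, U))
    tau <- tauFromViscosity(nu)
    k_pen <- if (is.null(gain)) min(1, 1 / tau) else gain
    steps_cap <- if (!is.null(max_steps)) max_steps
                 else if (re <= 2) ceiling(1.3 * (ly / 2)^2 / nu)
                 else ceiling(4 * lx / U)
    mem <- makeCircleMembrane(c(lx / 4, (ly - 1) / 2), diameter / 2,
                              mobile = FALSE, gain = k_pen)
    f <- array(rep(equilibriumDistribution(1, c(U, 0)), each = lx * ly),
               c(lx, ly, 9))
    res <- .run_engine(f, tau, bcx = 1L, inflow_u = U,
                       bcy = 2L, wall_u_bottom = U, wall_u_top = U,
                       membrane = mem, nsteps = steps_cap,
                       sample_every = 100,
                       conv_mode = 2L, conv_tol = conv_tol,
                       conv_every = conv_every,
                       min_steps = 3 * conv_every)
    .engine_status_check(res, sprintf("cylinder Re=%g", re))
    drag_tail <- tail(res$traj[, "drag_x"], max(5, conv_every %/% 100))
    drag <- mean(drag_tail)
    nonstat <- sd(drag_tail) > 0.01 * abs(drag)
    cd <- if (nonstat) NA_real_
          else dragCoefficient(drag, rho = 1, A = diameter, u_r = U)
    i <- which(abs(ref_all$re - re) < 1e-9)
    cd_ref <- if (length(i) == 1) ref_all$cd_ref[i] else NA_real_
    data.frame(re = re, cd = cd, cd_ref = cd_ref,
               rel_dev = if (is.na(cd_ref)) NA_real_ else cd / cd_ref - 1,
               u_r = U, nu = nu, steps = res$steps,
               converged = res$converged, nonstationary = nonstat)
  })
  tab <- do.call(rbind, rows)
  err <- if (all(is.na(tab$rel_dev))) NA_real_
         else max(abs(tab$rel_dev), na.rm = TRUE)
  .benchmark(tab, err, "lowRe_cylinder_correlation",
             list(confinement = ly / diameter))
}

# --- focusing ---------------------------------------------------------------

#' Default configuration of the SSAW focusing experiments
#'
#' The reference conditions: a 160 um channel resolved by 80 nodes (2 um per
#' lattice spacing), DI water with the tabulated density 1027 kg/m^3 and
#' viscosity 1e-6 m^2/s mapped to a lattice viscosity 0.0167, axial flow at
#' Re = 0.70, SSAW wavelength twice the channel width with the single
#' pressure node on the centerline, and an acoustic energy density of
#' 400 J/m^3 (a one-off calibration so the 10 um polystyrene particle
#' settles well inside the default step budget and clear of the hat-kernel
#' pinning floor; see the methods vignette).
#'
#' @return a named list of defaults consumed by \code{\link{runFocusing}}.
#' @export
focusingDefaults <- function() {
  list(width = 160e-6, ny = 80, nx = 40,
       rho_f = 1027, rho_lbm = 1, nu_phys = 1e-6, nu_lbm = 0.0167,
       re = 0.70, energy_density = 400, wavelength = 320e-6,
       beta_f = 4.5e-10,
       coupling_gain = 1, target_spacing = 0.65,
       sample_every = 100, steady_tol = 0.5e-6, steady_window = 5000,
       max_steps = 200000)
}

#' Simulate SSAW focusing of a single microparticle
#'
#' Couples a body-force-driven axial channel flow (periodic in x, bounce-back
#' walls), an immersed-boundary rigid particle, and the primary acoustic
#' radiation force evaluated at the particle centroid every step.  The run
#' stops once the lateral position satisfies the steady criterion (maximum
#' deviation from the trailing-window median below \code{steady_tol}) or the
#' step budget is exhausted.
#'
#' @param particle a \code{\link{particleSpec}} (default: 10 um polystyrene).
#' @param acoustic an \code{\link{acousticConfig}}; by default built from
#'   \code{\link{focusingDefaults}} with the pressure node on the centerline.
#'   Set \code{phase_offset} (or pass a config with \code{active = FALSE}) to
#'   move or disable the field.
#' @param initial_y initial lateral position of the particle centre (metres
#'   from the bottom wall).
#' @param re axial-flow Reynolds number (maximum channel speed, channel
#'   width, fluid viscosity).
#' @param gravity optional net gravity-minus-buoyancy force on the particle
#'   in newtons (negative = toward the bottom wall); default 0.
#' @param defaults the condition set from \code{\link{focusingDefaults}};
#'   individual entries can be overridden.
#' @param max_steps step budget.
#' @return a \code{trajectory} data frame with columns \code{time_s},
#'   \code{x_um}, \code{y_um}, \code{uy_um_per_s},
#'   \code{acoustic_force_N}, and attributes \code{settled},
#'   \code{settle_time_s}, \code{steady_y_m}, \code{units}, \code{config}.
#' @export
runFocusing <- function(particle = particleSpec(5e-6, 1050, 2.49e-10),
                        acoustic = NULL,
                        initial_y = 70e-6,
                        re = NULL,
                        gravity = 0,
                        defaults = focusingDefaults(),
                        max_steps = NULL) {
  d <- defaults
  if (is.null(re)) re <- d$re
  if (is.null(max_steps)) max_steps <- d$max_steps
  if (is.null(acoustic))
    acoustic <- acousticConfig(wavelength = d$wavelength,
                               energy_density = d$energy_density,
                               phase_offset = d$wavelength / 4,
                               fluid_density = d$rho_f,
                               fluid_compressibility = d$beta_f)
  units <- buildUnitSystem(d$width, d$ny, d$rho_f, d$rho_lbm,
                           d$nu_phys, d$nu_lbm)
  tau <- tauFromViscosity(d$nu_lbm)
  u_phys <- re * d$nu_phys / d$width
  u_lat <- convertUnits(u_phys, "velocity", "to_lattice", units)
  g <- 8 * d$nu_lbm * u_lat / d$ny^2
  if (initial_y <= 0 || initial_y >= d$width)
    .stop_invalid("initial_y", "must lie strictly inside the channel")

  phi <- contrastFactor(particle$compressibility,
                        acoustic$fluid_compressibility,
                        particle$density, acoustic$fluid_density)
  amp_phys <- 2 * pi * particle$volume * acoustic$energy_density /
    acoustic$wavelength * phi
  amp_lat <- convertUnits(amp_phys, "force", "to_lattice", units)
  ac <- list(active = isTRUE(acoustic$active), amp = amp_lat,
             lambda = acoustic$wavelength / units$cf_length,
             phase = acoustic$phase_offset / units$cf_length)
  grav_lat <- convertUnits(gravity, "force", "to_lattice", units)

  r_lat <- particle$radius / units$cf_length
  y0_lat <- initial_y / units$cf_length - 0.5
  mass_lat <- particle$density / units$cf_density * pi * r_lat^2
  mem <- makeCircleMembrane(c(d$nx / 2, y0_lat), r_lat,
                            target_spacing = d$target_spacing,
                            mobile = TRUE, mass = mass_lat)
  # the body-velocity feedback n*gain/mass must stay below the explicit
  # Euler stability bound (2); cap the coupling gain for small rings
  mem$gain <- min(d$coupling_gain, 0.8 * mass_lat / mem$n)
  # start from the developed axial profile
  s <- (seq_len(d$ny) - 0.5) / d$ny
  uprof <- 4 * u_lat * s * (1 - s)
  u0 <- array(0, c(d$nx, d$ny, 2))
  u0[, , 1] <- matrix(uprof, d$nx, d$ny, byrow = TRUE)
  f <- equilibriumDistribution(matrix(1, d$nx, d$ny), u0)

  chunk <- max(2L * d$steady_window, 20000L)
  samples <- NULL
  steps_done <- 0L
  x_off <- 0
  settled <- FALSE
  res <- NULL
  while (steps_done < max_steps) {
    nst <- min(chunk, max_steps - steps_done)
    start_cx <- mean(mem$nodes[, 1])
    res <- tryCatch(
      .run_engine(f, tau, gx = g, bcx = 0L, bcy = 2L,
                  membrane = mem, fext = c(0, grav_lat), acoustic = ac,
                  nsteps = nst, sample_every = d$sample_every),
      error = function(e) e)
    if (inherits(res, "error")) stop(res)
    tr <- res$traj
    tr[, "step"] <- tr[, "step"] + steps_done
    tr[, "cx"] <- tr[, "cx"] + x_off
    samples <- rbind(samples, tr)
    .engine_status_check(res, "focusing",
                         traj = .make_trajectory(samples, units, acoustic,
                                                 d, settled = FALSE))
    steps_done <- steps_done + res$steps
    x_off <- tail(tr[, "cx"], 1) - mean(res$membrane[, 1])
    f <- res$f
    mem$nodes <- res$membrane
    mem$centroid <- colMeans(res$membrane)
    traj <- .make_trajectory(samples, units, acoustic, d, settled = FALSE)
    ss <- detectSteadyState(traj, tolerance = d$steady_tol,
                            window = d$steady_window)
    if (ss$settled) { settled <- TRUE; break }
  }
  traj <- .make_trajectory(samples, units, acoustic, d, settled = settled)
  attr(traj, "membrane") <- mem
  attr(traj, "field") <- list(ux = res$ux, uy = res$uy, rho = res$rho)
  traj
}

# assemble the physical-unit trajectory object from engine samples
.make_trajectory <- function(samples, units, acoustic, d, settled = FALSE) {
  cf_t <- units$cf_time; cf_l <- units$cf_length
  out <- data.frame(
    time_s = samples[, "step"] * cf_t,
    x_um = (samples[, "cx"] + 0.5) * cf_l * 1e6,
    y_um = (samples[, "cy"] + 0.5) * cf_l * 1e6,
    uy_um_per_s = samples[, "vy"] * units$cf_velocity * 1e6,
    acoustic_force_N = samples[, "f_ac"] * units$cf_force)
  class(out) <- c("trajectory", "data.frame")
  attr(out, "steps") <- samples[, "step"]
  attr(out, "mass") <- samples[, "mass"]
  attr(out, "units") <- unitLedger(units)
  attr(out, "config") <- c(d[c("width", "ny", "nx", "re", "nu_lbm")],
                           list(wavelength = acoustic$wavelength,
                                energy_density = acoustic$energy_density,
                                phase_offset = acoustic$phase_offset,
                                active = acoustic$active))
  ss <- detectSteadyState(out, tolerance = d$steady_tol,
                          window = d$steady_window)
  attr(out, "settled") <- ss$settled
  attr(out, "settle_time_s") <- ss$settle_time
  attr(out, "steady_y_m") <- ss$steady_y
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples over %.4g ms\n", nrow(x),
              1e3 * max(x$time_s)))
  if (isTRUE(attr(x, "settled")))
    cat(sprintf("  settled at y = %.3f um (t = %.4g ms)\n",
                1e6 * attr(x, "steady_y_m"),
                1e3 * attr(x, "settle_time_s")))
  else cat("  not settled within the simulated window\n")
  invisible(x)
}

#' Detect the steady (settled) state of a trajectory
#'
#' The particle counts as settled when the maximum deviation of its lateral
#' position from the trailing-window median stays below \code{tolerance};
#' the settle time is the first time from which the criterion holds through
#' the end of the record.
#'
#' @param traj a \code{trajectory} from \code{\link{runFocusing}} (or any
#'   data frame with \code{time_s} and \code{y_um}).
#' @param tolerance steady tolerance in metres.
#' @param window trailing window length in lattice steps (converted using
#'   the trajectory's sampling cadence; at least 2 samples).
#' @return list with \code{settled}, \code{settle_time} (seconds, NA when
#'   unsettled) and \code{steady_y} (metres, trailing-window median).
#' @export
detectSteadyState <- function(traj, tolerance = 0.5e-6, window = 5000) {
  y <- traj$y_um * 1e-6
  t <- traj$time_s
  n <- length(y)
  steps <- attr(traj, "steps")
  if (!is.null(steps) && n > 1) {
    per <- median(diff(steps))
    nwin <- max(2L, as.integer(round(window / per)))
  } else nwin <- max(2L, as.integer(window))
  if (n < nwin) return(list(settled = FALSE, settle_time = NA_real_,
                            steady_y = median(tail(y, max(1, n)))))
  ywin <- tail(y, nwin)
  med <- median(ywin)
  settled <- max(abs(ywin - med)) < tolerance
  settle_time <- NA_real_
  if (settled) {
    dev_ok <- abs(y - med) < tolerance
    k <- n
    while (k > 1 && dev_ok[k - 1]) k <- k - 1
    settle_time <- t[k]
  }
  list(settled = settled, settle_time = settle_time, steady_y = med)
}

#' Parametric sweeps of the focusing experiment
#'
#' Runs \code{\link{runFocusing}} once per value of the swept parameter,
#' sharing every other setting.  Supported parameters: \code{initial_y}
#' (metres), \code{radius} (metres), \code{particle_type} (rows of
#' \code{\link{particleTable}}).
#'
#' @param parameter which parameter to sweep.
#' @param values vector of values (material names for
#'   \code{particle_type}).
#' @param ... passed on to \code{\link{runFocusing}}.
#' @return named list of trajectories (class \code{focusing_sweep});
#'   errors in member runs propagate with their key.
#' @export
sweepFocusing <- function(parameter = c("initial_y", "radius",
                                        "particle_type"),
                          values, ...) {
  parameter <- match.arg(parameter)
  if (length(values) == 0) .stop_invalid("values", "must be nonempty")
  base <- list(...)
  runs <- lapply(seq_along(values), function(i) {
    v <- values[[i]]
    args <- base
    if (parameter == "initial_y") args$initial_y <- v
    if (parameter == "radius") {
      p <- if (!is.null(base$particle)) base$particle
           else particleSpec(5e-6, 1050, 2.49e-10)
      args$particle <- particleSpec(v, p$density, p$compressibility)
    }
    if (parameter == "particle_type") {
      tab <- particleTable()
      row <- tab[tab$particle == v, ]
      if (nrow(row) != 1)
        .stop_invalid("values", sprintf("unknown particle type '%s'", v))
      r <- if (!is.null(base$particle)) base$particle$radius else 5e-6
      args$particle <- particleSpec(r, row$density, row$compressibility)
    }
    tryCatch(do.call(runFocusing, args),
             error = function(e) {
               e$message <- sprintf("sweep member %s = %s: %s", parameter,
                                    format(v), e$message)
               stop(e)
             })
  })
  names(runs) <- vapply(values, format, "")
  structure(runs, class = "focusing_sweep", parameter = parameter)
}
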