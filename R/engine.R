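# Internal bridge to the compiled D2Q9 engine.
#
# R-side arrays are [nx, ny, 9]; the engine stores node-major
# f[(y*nx + x)*9 + i].  That layout equals an array with dims (9, nx, ny),
# direction index fastest, so the conversion is a single aperm.

.to_engine <- function(f) as.vector(aperm(f, c(3, 1, 2)))

.from_engine <- function(v, nx, ny) aperm(array(v, c(9, nx, ny)), c(2, 3, 1))

.engine_status_check <- function(res, what, traj = NULL) {
  if (res$status == 1L)
    .stop_stability(sprintf(
      "%s: numerical instability (non-positive or non-finite density) at step %d",
      what, res$steps), data = traj)
  if (res$status == 2L)
    stop(structure(class = c("acoustoLBM_wall_contact", "error", "condition"),
                   list(message = sprintf(
                     "%s: particle contacted a wall at step %d", what,
                     res$steps), call = NULL, data = traj)))
  if (res$status == 3L)
    stop(structure(class = c("acoustoLBM_out_of_domain", "error", "condition"),
                   list(message = sprintf(
                     "%s: membrane node left the domain interior at step %d",
                     what, res$steps), call = NULL, data = traj)))
  invisible(res)
}

# Run the compiled engine.  `membrane` may be NULL.  `acoustic` is a list
# with amp (lattice force, contrast sign included), lambda, phase (lattice
# lengths), active.  Boundary codes as documented in src/lbm_engine.cpp.
.run_engine <- function(f, tau, gx = 0, gy = 0,
                        bcx = 0L, inflow_u = 0,
                        bcy = 2L, wall_u_bottom = 0, wall_u_top = 0,
                        membrane = NULL, fext = c(0, 0),
                        acoustic = NULL,
                        nsteps, sample_every = 100L,
                        conv_mode = 0L, conv_tol = 0, conv_every = 0L,
                        min_steps = 0L) {
  nx <- dim(f)[1]; ny <- dim(f)[2]
  if (is.null(membrane)) {
    nodes <- matrix(0, 0, 2); ref <- matrix(0, 0, 2)
    gain <- 0; mobile <- FALSE; mmass <- 1
  } else {
    nodes <- membrane$nodes; ref <- membrane$reference
    gain <- membrane$gain %||% 1
    mobile <- membrane$mobile
    mmass <- membrane$mass %||% 1
  }
  if (is.null(acoustic))
    acoustic <- list(active = FALSE, amp = 0, lambda = 1, phase = 0)
  res <- cpp_lbm_run(.to_engine(f), nx, ny, tau, gx, gy,
                     as.integer(bcx), inflow_u,
                     as.integer(bcy), wall_u_bottom, wall_u_top,
                     nodes, ref, gain, mobile, mmass,
                     fext[1], fext[2],
                     isTRUE(acoustic$active), acoustic$amp, acoustic$lambda,
                     acoustic$phase,
                     as.integer(nsteps), as.integer(sample_every),
                     as.integer(conv_mode), conv_tol, as.integer(conv_every),
                     as.integer(min_steps))
  res$f <- .from_engine(res$f, nx, ny)
  res
}
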