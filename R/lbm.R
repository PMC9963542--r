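#' The D2Q9 stencil
#'
#' Nine discrete velocities (rest, four axis, four diagonal), the standard
#' weights 4/9, 1/9 and 1/36, the lattice sound speed \eqn{c_s = 1/\sqrt{3}},
#' and the map pairing each direction with its reverse.  Direction order:
#' rest; E, N, W, S; NE, NW, SW, SE.
#'
#' @return list with \code{e} (9 x 2 integer matrix), \code{w} (length-9
#'   weights), \code{cs2} (= 1/3) and \code{opposite} (length-9 index map).
#' @export
d2q9Stencil <- function() {
  e <- cbind(c(0, 1, 0, -1, 0, 1, -1, -1, 1),
             c(0, 0, 1, 0, -1, 1, 1, -1, -1))
  w <- c(4 / 9, rep(1 / 9, 4), rep(1 / 36, 4))
  structure(list(e = e, w = w, cs2 = 1 / 3,
                 opposite = c(1L, 4L, 5L, 2L, 3L, 8L, 9L, 6L, 7L)),
            class = "d2q9_stencil")
}

#' Equilibrium distribution
#'
#' The second-order low-Mach equilibrium
#' \deqn{f_i^{eq} = \rho w_i \left[1 + \frac{e_i\cdot u}{c_s^2}
#'   + \frac{(e_i\cdot u)^2}{2 c_s^4} - \frac{u^2}{2 c_s^2}\right].}
#'
#' @param rho density: a scalar or an \code{nx x ny} matrix.
#' @param u velocity: a length-2 vector, or an \code{nx x ny x 2} array.
#' @param stencil a \code{\link{d2q9Stencil}}.
#' @return length-9 vector (scalar input) or \code{nx x ny x 9} array.
#' @export
equilibriumDistribution <- function(rho, u, stencil = d2q9Stencil()) {
  e <- stencil$e; w <- stencil$w; cs2 <- stencil$cs2
  if (is.matrix(rho) || (is.array(u) && length(dim(u)) == 3)) {
    if (!is.matrix(rho)) rho <- matrix(rho, dim(u)[1], dim(u)[2])
    nx <- nrow(rho); ny <- ncol(rho)
    ux <- u[, , 1]; uy <- u[, , 2]
    usq <- (ux^2 + uy^2) / (2 * cs2)
    f <- array(0, c(nx, ny, 9))
    for (i in 1:9) {
      eu <- (e[i, 1] * ux + e[i, 2] * uy) / cs2
      f[, , i] <- w[i] * rho * (1 + eu + 0.5 * eu^2 - usq)
    }
    return(f)
  }
  eu <- as.vector(e %*% u) / cs2
  usq <- sum(u^2) / (2 * cs2)
  w * rho * (1 + eu + 0.5 * eu^2 - usq)
}

#' Macroscopic moments of a distribution set
#'
#' \eqn{\rho = \sum_i f_i}, \eqn{\rho u = \sum_i f_i e_i}.
#'
#' @param f length-9 vector or \code{nx x ny x 9} array.
#' @param stencil a \code{\link{d2q9Stencil}}.
#' @return list with \code{rho} and \code{u}; shapes follow the input.
#'   A non-positive density anywhere raises an instability error naming the
#'   node.
#' @export
latticeMoments <- function(f, stencil = d2q9Stencil()) {
  e <- stencil$e
  if (is.array(f) && length(dim(f)) == 3) {
    rho <- apply(f, c(1, 2), sum)
    if (any(!is.finite(rho)) || any(rho <= 0)) {
      bad <- which(!(is.finite(rho) & rho > 0), arr.ind = TRUE)[1, ]
      .stop_stability(sprintf(
        "non-positive or non-finite density at node (%d, %d)", bad[1], bad[2]))
    }
    ux <- matrix(0, dim(f)[1], dim(f)[2]); uy <- ux
    for (i in 1:9) {
      ux <- ux + f[, , i] * e[i, 1]
      uy <- uy + f[, , i] * e[i, 2]
    }
    u <- array(0, c(dim(f)[1], dim(f)[2], 2))
    u[, , 1] <- ux / rho; u[, , 2] <- uy / rho
    return(list(rho = rho, u = u))
  }
  rho <- sum(f)
  if (!is.finite(rho) || rho <= 0)
    .stop_stability("non-positive or non-finite density")
  list(rho = rho, u = as.vector(crossprod(f, e)) / rho)
}

#' Relaxation time from lattice viscosity
#'
#' Inverts \eqn{\nu = c_s^2 (\tau - 1/2) \Delta t} with \eqn{\Delta t = 1}:
#' \eqn{\tau = \nu / c_s^2 + 1/2}.  Positive viscosity requires
#' \eqn{\tau > 1/2}.
#'
#' @param nu_lbm lattice kinematic viscosity (> 0).
#' @return relaxation time tau.
#' @export
tauFromViscosity <- function(nu_lbm) {
  if (!is.numeric(nu_lbm) || length(nu_lbm) != 1L || !is.finite(nu_lbm) ||
      nu_lbm <= 0)
    .stop_invalid("nu_lbm", "must be a single positive number (tau > 0.5)")
  nu_lbm * 3 + 0.5
}

#' Create an Eulerian lattice state
#'
#' Bundles the distribution array, the relaxation time and the body-force
#' field.  Unless \code{f} is supplied the distributions are initialized at
#' equilibrium for density \code{rho0} and velocity \code{u0}.
#'
#' @param nx,ny grid size.
#' @param tau relaxation time (> 0.5).
#' @param rho0,u0 initial density and velocity of the equilibrium fill.
#' @param f optional initial \code{nx x ny x 9} distribution array.
#' @return object of class \code{lattice_state} with fields \code{f},
#'   \code{tau}, \code{force} (an \code{nx x ny x 2} body-force density
#'   field, cleared after every step).
#' @export
latticeState <- function(nx, ny, tau, rho0 = 1, u0 = c(0, 0), f = NULL) {
  if (tau <= 0.5) .stop_invalid("tau", "must exceed 0.5 (positive viscosity)")
  if (is.null(f)) {
    feq <- equilibriumDistribution(rho0, u0)
    f <- array(rep(feq, each = nx * ny), c(nx, ny, 9))
  }
  structure(list(f = f, nx = nx, ny = ny, tau = tau,
                 force = array(0, c(nx, ny, 2))),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  m <- latticeMoments(x$f)
  cat(sprintf("<lattice_state> %d x %d, tau = %.4f\n", x$nx, x$ny, x$tau))
  cat(sprintf("  mass %.6g, max|u| = %.3g\n", sum(m$rho),
              max(abs(m$u))))
  invisible(x)
}

# Collision with Shan-Chen velocity-shift forcing: the equilibrium is formed
# at u_eq = u + tau*F/rho, injecting exactly F of momentum per step.
.collide <- function(state, stencil = d2q9Stencil()) {
  m <- latticeMoments(state$f, stencil)
  u <- m$u
  u[, , 1] <- u[, , 1] + state$tau * state$force[, , 1] / m$rho
  u[, , 2] <- u[, , 2] + state$tau * state$force[, , 2] / m$rho
  feq <- equilibriumDistribution(m$rho, u, stencil)
  state$f <- state$f - (state$f - feq) / state$tau
  state
}

# Pure streaming with periodic wrap on both axes; boundary handlers repair
# wall rows afterwards.
.stream_periodic <- function(f, stencil = d2q9Stencil()) {
  e <- stencil$e
  fn <- f
  for (i in 1:9) {
    fi <- f[, , i]
    if (e[i, 1] == 1) fi <- fi[c(nrow(fi), 1:(nrow(fi) - 1)), , drop = FALSE]
    if (e[i, 1] == -1) fi <- fi[c(2:nrow(fi), 1), , drop = FALSE]
    if (e[i, 2] == 1) fi <- fi[, c(ncol(fi), 1:(ncol(fi) - 1)), drop = FALSE]
    if (e[i, 2] == -1) fi <- fi[, c(2:ncol(fi), 1), drop = FALSE]
    fn[, , i] <- fi
  }
  fn
}

#' Advance a lattice state by one collide-and-stream step (reference path)
#'
#' Plain-R reference implementation of one LBM update: moments, BGK collision
#' toward the velocity-shifted equilibrium, streaming, then the boundary
#' handlers of the plan applied in order.  The compiled engine used by the
#' scenario drivers follows exactly the same sequence; an equivalence test
#' keeps the two in lockstep.  The body-force field is cleared after the step.
#'
#' @param state a \code{\link{latticeState}}.
#' @param plan a \code{\link{boundaryPlan}}.
#' @param stencil a \code{\link{d2q9Stencil}}.
#' @return the advanced \code{lattice_state}.
#' @export
lbmStep <- function(state, plan = boundaryPlan(), stencil = d2q9Stencil()) {
  pre <- latticeMoments(state$f, stencil)   # wall reflections use pre-step rho
  state <- .collide(state, stencil)
  fpost <- state$f
  f <- .stream_periodic(fpost, stencil)
  f <- .apply_plan(f, fpost, pre$rho, plan, stencil)
  state$f <- f
  state$force[] <- 0
  # post-step sanity check
  invisible(latticeMoments(state$f, stencil))
  state
}
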