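#' Particle material properties
#'
#' @param radius particle radius in metres.
#' @param density particle density in kg/m^3.
#' @param compressibility particle compressibility in 1/Pa.
#' @return a \code{particle_spec} list; the particle volume
#'   \eqn{V_p = (4/3)\pi r^3} is derived.
#' @export
particleSpec <- function(radius, density, compressibility) {
  for (nm in c("radius", "density", "compressibility")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      .stop_invalid(nm, "must be a single positive number")
  }
  structure(list(radius = radius, density = density,
                 compressibility = compressibility,
                 volume = 4 / 3 * pi * radius^3),
            class = "particle_spec")
}

#' Reference particle materials
#'
#' Densities and compressibilities of the three materials exercised in the
#' parametric studies: polystyrene, iron oxide and PMMA.
#'
#' @return data.frame with columns \code{particle}, \code{density}
#'   (kg/m^3) and \code{compressibility} (1/Pa).
#' @export
particleTable <- function() {
  data.frame(
    particle = c("PS", "FeO", "PMMA"),
    density = c(1050, 1500, 1200),
    compressibility = c(2.49e-10, 1.5e-11, 1.7e-10),
    stringsAsFactors = FALSE)
}

#' Discretize a circular membrane
#'
#' The particle (or a fixed obstacle) is a closed ring of Lagrangian nodes.
#' Node positions are continuous-valued lattice coordinates; the undeformed
#' shape is stored as offsets from the centroid so a penalty force can hold
#' the ring rigid.
#'
#' @param center length-2 lattice coordinates of the centre.
#' @param radius lattice radius (> 0).
#' @param target_spacing desired node spacing along the ring, in (0.3, 1]
#'   lattice units.
#' @param stiffness penalty spring constant (lattice units).
#' @param mobile logical; \code{FALSE} anchors the ring in place (fixed
#'   obstacle), \code{TRUE} makes it a rigid particle whose anchor frame
#'   moves by Newton's law under the spring reactions and external forces.
#' @param damping dashpot coefficient of the Kelvin-Voigt tether (lattice
#'   force per unit node velocity relative to the body frame); damps the
#'   node rattle without affecting rigid motion.
#' @param mass rigid-body mass in lattice units (defaults to the area of the
#'   disc at unit density); only meaningful for mobile membranes.
#' @param gain direct-forcing coupling gain used by the simulation engine:
#'   the immersed-boundary force at each node is
#'   \code{gain * (u_rigid - u_fluid)}, driving the local fluid velocity to
#'   the rigid-body velocity (no-slip enforcement).  The default
#'   (\code{NULL}) picks \code{min(0.5, 0.8 * mass / n_nodes)}, which keeps
#'   the body-velocity feedback inside the explicit-Euler stability bound.
#'   The displacement-based constitutive surface
#'   (\code{\link{constitutiveForces}}) is available for membrane-level
#'   analysis.
#' @return an object of class \code{membrane} with fields \code{nodes}
#'   (N x 2), \code{reference} (N x 2 offsets), \code{centroid},
#'   \code{node_forces} (N x 2 accumulator), \code{stiffness}, \code{mobile}.
#' @export
makeCircleMembrane <- function(center, radius, target_spacing = 0.65,
                               stiffness = 0.05, mobile = TRUE,
                               gain = NULL, mass = NULL) {
  if (!is.numeric(radius) || radius <= 0)
    .stop_invalid("radius", "must be > 0")
  if (target_spacing <= 0.3 || target_spacing > 1)
    .stop_invalid("target_spacing", "must lie in (0.3, 1]")
  n <- ceiling(2 * pi * radius / target_spacing)
  if (n < 3)
    .stop_config("radius too small to honour the node-spacing bounds")
  th <- 2 * pi * (seq_len(n) - 1) / n
  ref <- cbind(radius * cos(th), radius * sin(th))
  if (is.null(mass)) mass <- pi * radius^2
  if (is.null(gain)) gain <- min(0.5, 0.8 * mass / n)
  structure(list(nodes = sweep(ref, 2, center, "+"),
                 reference = ref,
                 centroid = as.numeric(center),
                 node_forces = matrix(0, n, 2),
                 stiffness = stiffness,
                 mobile = mobile,
                 gain = gain,
                 mass = mass,
                 n = n),
            class = "membrane")
}

#' @export
print.membrane <- function(x, ...) {
  cat(sprintf("<membrane> %d nodes, centroid (%.3f, %.3f), %s\n",
              x$n, x$centroid[1], x$centroid[2],
              if (x$mobile) "mobile" else "anchored"))
  invisible(x)
}

#' Hat-kernel interpolation weight
#'
#' 2D tensor product of the 1D hat \eqn{\delta(x) = 1 - |x|} on
#' \eqn{[-1, 1]} (zero outside): \code{(1 - |dx|) (1 - |dy|)}.
#'
#' @param dx,dy offsets between a Lagrangian node and a lattice site.
#' @return the kernel weight (vectorized).
#' @export
deltaWeight <- function(dx, dy) {
  wx <- pmax(0, 1 - abs(dx))
  wy <- pmax(0, 1 - abs(dy))
  wx * wy
}

# support sites (<= 4) of one continuous position; wrap_x gives periodic x
.support <- function(pos, nx, ny, wrap_x) {
  xb <- floor(pos[1]); yb <- floor(pos[2])
  xs <- c(xb, xb + 1); ys <- c(yb, yb + 1)
  g <- expand.grid(x = xs, y = ys)
  g$w <- deltaWeight(pos[1] - g$x, pos[2] - g$y)
  if (wrap_x) g$x <- ((g$x %% nx) + nx) %% nx
  if (any(g$y < 0 | g$y > ny - 1) || (!wrap_x && any(g$x < 0 | g$x > nx - 1)))
    .stop_stability("membrane node support extends outside the fluid domain")
  g
}

#' Spread membrane node forces onto the lattice force field
#'
#' Each node's force is distributed over its (at most four) surrounding
#' lattice sites with the hat kernel; contributions accumulate additively.
#' The kernel's partition of unity makes the total spread force equal the
#' total membrane force.
#'
#' @param membrane a \code{\link{makeCircleMembrane}} with populated
#'   \code{node_forces}.
#' @param force_field \code{nx x ny x 2} lattice force-density field.
#' @param wrap_x logical; wrap the x coordinate periodically.
#' @return the updated force field.
#' @export
spreadForces <- function(membrane, force_field, wrap_x = FALSE) {
  nx <- dim(force_field)[1]; ny <- dim(force_field)[2]
  for (k in seq_len(membrane$n)) {
    g <- .support(membrane$nodes[k, ], nx, ny, wrap_x)
    for (r in seq_len(nrow(g))) {
      ix <- g$x[r] + 1L; iy <- g$y[r] + 1L
      force_field[ix, iy, 1] <- force_field[ix, iy, 1] +
        g$w[r] * membrane$node_forces[k, 1]
      force_field[ix, iy, 2] <- force_field[ix, iy, 2] +
        g$w[r] * membrane$node_forces[k, 2]
    }
  }
  force_field
}

#' Interpolate the fluid velocity at the membrane nodes
#'
#' Uses the same hat kernel as the force spreading, which reproduces linear
#' velocity fields exactly, so the advected nodes satisfy the zero-slip
#' contract by construction.
#'
#' @param u_field \code{nx x ny x 2} lattice velocity field.
#' @param membrane a \code{membrane}.
#' @param wrap_x logical; wrap the x coordinate periodically.
#' @return N x 2 matrix of node velocities.
#' @export
interpolateVelocity <- function(u_field, membrane, wrap_x = FALSE) {
  nx <- dim(u_field)[1]; ny <- dim(u_field)[2]
  v <- matrix(0, membrane$n, 2)
  for (k in seq_len(membrane$n)) {
    g <- .support(membrane$nodes[k, ], nx, ny, wrap_x)
    for (r in seq_len(nrow(g))) {
      ix <- g$x[r] + 1L; iy <- g$y[r] + 1L
      v[k, 1] <- v[k, 1] + g$w[r] * u_field[ix, iy, 1]
      v[k, 2] <- v[k, 2] + g$w[r] * u_field[ix, iy, 2]
    }
  }
  v
}

#' Constitutive (penalty) forces on the membrane
#'
#' A rigid particle is realized as a penalty-spring tether: each node is
#' pulled back toward its reference position anchored at the centroid (or at
#' the fixed anchor for an immobile obstacle), and any external force on the
#' particle (acoustic radiation, optional gravity minus buoyancy) is shared
#' equally over the nodes.
#'
#' @param membrane a \code{membrane}.
#' @param external_force_per_node length-2 force applied to every node
#'   (lattice units).
#' @return the membrane with \code{node_forces} populated.
#' @export
constitutiveForces <- function(membrane, external_force_per_node = c(0, 0)) {
  anchor <- if (membrane$mobile) colMeans(membrane$nodes) else membrane$centroid
  target <- sweep(membrane$reference, 2, anchor, "+")
  membrane$node_forces <-
    -membrane$stiffness * (membrane$nodes - target) +
    matrix(external_force_per_node, membrane$n, 2, byrow = TRUE)
  membrane
}

#' Advance the membrane by one Euler step
#'
#' Moves every node by its interpolated velocity times \code{dt} and, for a
#' mobile membrane, recomputes the centroid as the node mean.  Node forces
#' are cleared (they are re-derived each step).
#'
#' @param membrane a \code{membrane}.
#' @param node_velocities N x 2 matrix (from
#'   \code{\link{interpolateVelocity}}).
#' @param dt lattice time step (normally 1).
#' @return the advanced membrane.
#' @export
advanceMembrane <- function(membrane, node_velocities, dt = 1) {
  if (dt <= 0) .stop_invalid("dt", "must be > 0")
  membrane$nodes <- membrane$nodes + node_velocities * dt
  if (membrane$mobile) membrane$centroid <- colMeans(membrane$nodes)
  membrane$node_forces[] <- 0
  membrane
}

#' Drag coefficient of an obstacle
#'
#' \eqn{C_d = F_{drag} / (\tfrac12 \rho A u_r^2)} with the drag force per
#' unit length obtained as minus the sum of the x components of the penalty
#' forces on the fixed membrane.
#'
#' @param F_drag drag force per unit length (lattice or physical, consistent
#'   with the other arguments).
#' @param rho fluid density.
#' @param A projected length of the obstacle (the diameter, per unit depth).
#' @param u_r speed of the obstacle relative to the oncoming flow.
#' @return the dimensionless drag coefficient.
#' @export
dragCoefficient <- function(F_drag, rho, A, u_r) {
  if (!is.numeric(u_r) || u_r == 0)
    .stop_invalid("u_r", "division by zero relative speed")
  if (rho <= 0 || A <= 0 || u_r < 0)
    .stop_invalid("rho/A/u_r", "must be > 0")
  F_drag / (0.5 * rho * A * u_r^2)
}
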