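#' Declare a boundary condition for one side of the domain
#'
#' @param side one of \code{"top"}, \code{"bottom"}, \code{"left"},
#'   \code{"right"}.
#' @param kind one of \code{"periodic"}, \code{"bounce_back"} (link
#'   bounce-back, wall half a cell outside the last fluid node; a tangential
#'   \code{wall_velocity} makes it a moving wall), \code{"moving_wall"}
#'   (Zou-He moment reconstruction, lid style) or \code{"reconstruction"}
#'   (Zou-He stationary-wall reconstruction).
#' @param wall_velocity length-2 lattice velocity of the wall (tangential
#'   motion only; low-Mach validity requires \eqn{|u_w| < c_s}).
#' @return a \code{boundary_spec} list.
#' @export
boundarySpec <- function(side = c("top", "bottom", "left", "right"),
                         kind = c("periodic", "bounce_back", "moving_wall",
                                  "reconstruction"),
                         wall_velocity = c(0, 0)) {
  side <- match.arg(side)
  kind <- match.arg(kind)
  if (length(wall_velocity) != 2L || !is.numeric(wall_velocity))
    .stop_invalid("wall_velocity", "must be a numeric length-2 vector")
  if (sqrt(sum(wall_velocity^2)) >= 1 / sqrt(3))
    .stop_invalid("wall_velocity", "must stay below the lattice sound speed")
  normal <- switch(side, top = c(0, 1), bottom = c(0, -1),
                   left = c(-1, 0), right = c(1, 0))
  if (kind %in% c("moving_wall", "reconstruction", "bounce_back") &&
      abs(sum(wall_velocity * normal)) > 0)
    .stop_config(sprintf(
      "side '%s': a nonzero wall-normal velocity component is not supported",
      side))
  structure(list(side = side, kind = kind, wall_velocity = wall_velocity),
            class = "boundary_spec")
}

#' Assemble and validate a boundary plan
#'
#' Periodic sides must come in opposite pairs; the handlers are applied in a
#' fixed order (left/right, then bottom/top, then corner repair for
#' reconstruction walls).
#'
#' @param left,right,bottom,top \code{\link{boundarySpec}} objects (defaults:
#'   periodic left/right, stationary bounce-back bottom/top, i.e. an infinite
#'   straight channel).
#' @return a \code{boundary_plan} list.
#' @export
boundaryPlan <- function(left = boundarySpec("left", "periodic"),
                         right = boundarySpec("right", "periodic"),
                         bottom = boundarySpec("bottom", "bounce_back"),
                         top = boundarySpec("top", "bounce_back")) {
  plan <- list(left = left, right = right, bottom = bottom, top = top)
  for (nm in names(plan)) {
    if (!inherits(plan[[nm]], "boundary_spec") || plan[[nm]]$side != nm)
      .stop_config(sprintf("boundary plan entry '%s' must be a boundary_spec for that side", nm))
  }
  for (pair in list(c("left", "right"), c("bottom", "top"))) {
    kinds <- c(plan[[pair[1]]]$kind, plan[[pair[2]]]$kind)
    if (xor(kinds[1] == "periodic", kinds[2] == "periodic"))
      .stop_config(sprintf(
        "periodic sides must come in opposite pairs (%s is %s but %s is %s)",
        pair[1], kinds[1], pair[2], kinds[2]))
  }
  structure(plan, class = "boundary_plan")
}

#' Periodic wrap of distributions along one axis
#'
#' Shifts every direction by its velocity component along the given axis with
#' wraparound, so populations leaving one edge re-enter at the opposite edge
#' unchanged.  Applying it for both axes performs a full streaming step.
#'
#' @param f \code{nx x ny x 9} distribution array (post-collision).
#' @param axis \code{"x"} or \code{"y"}.
#' @param stencil a \code{\link{d2q9Stencil}}.
#' @return the shifted array.
#' @export
applyPeriodic <- function(f, axis = c("x", "y"), stencil = d2q9Stencil()) {
  axis <- match.arg(axis)
  e <- stencil$e
  a <- if (axis == "x") 1L else 2L
  for (i in 1:9) {
    s <- e[i, a]
    if (s == 0) next
    fi <- f[, , i]
    n <- dim(fi)[a]
    idx <- if (s == 1) c(n, 1:(n - 1)) else c(2:n, 1)
    if (a == 1L) f[, , i] <- fi[idx, , drop = FALSE]
    else f[, , i] <- fi[, idx, drop = FALSE]
  }
  f
}

# direction bookkeeping (1-based): 1 rest, 2 E, 3 N, 4 W, 5 S, 6 NE, 7 NW,
# 8 SW, 9 SE
.incoming <- list(bottom = c(3L, 6L, 7L), top = c(5L, 8L, 9L),
                  left = c(2L, 6L, 9L), right = c(4L, 7L, 8L))

#' Link bounce-back at a straight wall
#'
#' Half-way bounce-back: every population that streamed into the wall is
#' returned to its source node with reversed direction; a tangentially moving
#' wall adds the momentum-exchange term \eqn{-6 w_i \rho (e_i \cdot u_w)}.
#' The wall sits half a cell outside the last fluid node, which makes the
#' scheme exactly mass conserving.
#'
#' @param f streamed \code{nx x ny x 9} array whose wall-incoming populations
#'   are to be repaired.
#' @param wall a \code{\link{boundarySpec}} with kind \code{"bounce_back"}.
#' @param f_post the post-collision (pre-streaming) array the reflected
#'   populations are read from.
#' @param rho pre-collision density matrix (only needed for a moving wall;
#'   defaults to 1).
#' @param stencil a \code{\link{d2q9Stencil}}.
#' @return the repaired array.
#' @export
applyBounceBack <- function(f, wall, f_post, rho = NULL,
                            stencil = d2q9Stencil()) {
  if (wall$kind == "periodic")
    .stop_config("bounce-back applied to a periodic side")
  e <- stencil$e; w <- stencil$w; opp <- stencil$opposite
  side <- wall$side
  uw <- wall$wall_velocity[1]  # tangential (x) component for y walls
  nx <- dim(f)[1]; ny <- dim(f)[2]
  if (is.null(rho)) rho <- matrix(1, nx, ny)
  for (j in .incoming[[side]]) {
    k <- opp[j]
    if (side %in% c("bottom", "top")) {
      row <- if (side == "bottom") 1L else ny
      corr <- 6 * w[j] * rho[, row] * e[j, 1] * uw
      f[, row, j] <- f_post[, row, k] + corr
    } else {
      col <- if (side == "left") 1L else nx
      uwy <- wall$wall_velocity[2]
      corr <- 6 * w[j] * rho[col, ] * e[j, 2] * uwy
      f[col, , j] <- f_post[col, , k] + corr
    }
  }
  f
}

#' Zou-He reconstruction at a tangentially moving lid
#'
#' Reconstructs the wall density from the known populations and sets the
#' three unknown populations so that the wall node's moments are exactly
#' \eqn{(\rho_N, u_w)}.  Only a top lid moving tangentially is supported.
#'
#' @param f streamed \code{nx x ny x 9} array.
#' @param lid a \code{\link{boundarySpec}} with \code{kind = "moving_wall"},
#'   side \code{"top"}.
#' @param stencil a \code{\link{d2q9Stencil}}.
#' @return the array with the top-row unknowns reconstructed.
#' @export
applyMovingLid <- function(f, lid, stencil = d2q9Stencil()) {
  if (lid$kind != "moving_wall" || lid$side != "top")
    .stop_config("moving-lid reconstruction expects a top moving_wall spec")
  u <- lid$wall_velocity[1]
  if (lid$wall_velocity[2] != 0)
    .stop_config("lid normal velocity must be zero")
  ny <- dim(f)[2]
  rhoN <- f[, ny, 1] + f[, ny, 2] + f[, ny, 4] +
    2 * (f[, ny, 3] + f[, ny, 6] + f[, ny, 7])
  f[, ny, 5] <- f[, ny, 3]
  f[, ny, 8] <- f[, ny, 6] + 0.5 * (f[, ny, 2] - f[, ny, 4]) - 0.5 * rhoN * u
  f[, ny, 9] <- f[, ny, 7] - 0.5 * (f[, ny, 2] - f[, ny, 4]) + 0.5 * rhoN * u
  f
}

#' Zou-He reconstruction at a stationary wall
#'
#' The zero-velocity variant of the moment reconstruction: the unknown
#' populations are the bounce of their opposites plus tangential corrections,
#' so the reconstructed wall node carries exactly zero velocity.
#'
#' @param f streamed \code{nx x ny x 9} array.
#' @param wall a \code{\link{boundarySpec}} for the side to repair (kinds
#'   \code{"reconstruction"} or \code{"bounce_back"} are accepted; periodic is
#'   an error).
#' @param stencil a \code{\link{d2q9Stencil}}.
#' @return the repaired array.
#' @export
applyStationaryReconstruction <- function(f, wall, stencil = d2q9Stencil()) {
  if (wall$kind == "periodic")
    .stop_config("wall reconstruction applied to a periodic side")
  nx <- dim(f)[1]; ny <- dim(f)[2]
  switch(wall$side,
    bottom = {
      d <- 0.5 * (f[, 1, 2] - f[, 1, 4])
      f[, 1, 3] <- f[, 1, 5]
      f[, 1, 6] <- f[, 1, 8] - d
      f[, 1, 7] <- f[, 1, 9] + d
    },
    top = {
      d <- 0.5 * (f[, ny, 2] - f[, ny, 4])
      f[, ny, 5] <- f[, ny, 3]
      f[, ny, 8] <- f[, ny, 6] + d
      f[, ny, 9] <- f[, ny, 7] - d
    },
    left = {
      d <- 0.5 * (f[1, , 3] - f[1, , 5])
      f[1, , 2] <- f[1, , 4]
      f[1, , 6] <- f[1, , 8] - d
      f[1, , 9] <- f[1, , 7] + d
    },
    right = {
      d <- 0.5 * (f[nx, , 3] - f[nx, , 5])
      f[nx, , 4] <- f[nx, , 2]
      f[nx, , 7] <- f[nx, , 9] - d
      f[nx, , 8] <- f[nx, , 6] + d
    })
  f
}

# Corner repair for the reconstruction (wet-node) cavity: corners belong to
# the stationary side walls; the fully unknown diagonal pair is split so the
# node matches the density of its inward diagonal neighbour at zero velocity.
.apply_corners_reconstruction <- function(f) {
  nx <- dim(f)[1]; ny <- dim(f)[2]
  fix <- function(f, x, y, xin, yin, pairs, free) {
    for (p in pairs) f[x, y, p[1]] <- f[x, y, p[2]]
    rho_nb <- sum(f[xin, yin, ])
    rest <- sum(f[x, y, -free])
    f[x, y, free] <- 0.5 * (rho_nb - rest)
    f
  }
  # unknown-from-known bounces; `free` is the diagonal pair with both unknown
  f <- fix(f, 1, ny, 2, ny - 1, list(c(2, 4), c(5, 3), c(9, 7)), c(6, 8))
  f <- fix(f, nx, ny, nx - 1, ny - 1, list(c(4, 2), c(5, 3), c(8, 6)), c(7, 9))
  f <- fix(f, 1, 1, 2, 2, list(c(2, 4), c(3, 5), c(6, 8)), c(7, 9))
  f <- fix(f, nx, 1, nx - 1, 2, list(c(4, 2), c(3, 5), c(7, 9)), c(6, 8))
  f
}

# Apply a full boundary plan to a freshly streamed array.  `f_post` is the
# post-collision array, `rho_pre` the pre-collision density (both needed by
# the bounce-back handlers).
.apply_plan <- function(f, f_post, rho_pre, plan, stencil = d2q9Stencil()) {
  recon <- FALSE
  for (nm in c("left", "right")) {
    sp <- plan[[nm]]
    if (sp$kind == "bounce_back")
      f <- applyBounceBack(f, sp, f_post, rho_pre, stencil)
    else if (sp$kind == "reconstruction") {
      f <- applyStationaryReconstruction(f, sp, stencil); recon <- TRUE
    }
  }
  for (nm in c("bottom", "top")) {
    sp <- plan[[nm]]
    if (sp$kind == "bounce_back")
      f <- applyBounceBack(f, sp, f_post, rho_pre, stencil)
    else if (sp$kind == "reconstruction") {
      f <- applyStationaryReconstruction(f, sp, stencil); recon <- TRUE
    } else if (sp$kind == "moving_wall") {
      f <- applyMovingLid(f, sp, stencil); recon <- TRUE
    }
  }
  if (recon) f <- .apply_corners_reconstruction(f)
  f
}
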