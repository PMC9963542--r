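st <- d2q9Stencil()

test_that("periodic wrap re-introduces leaving populations unchanged", {
  f <- array(0, c(5, 4, 9))
  f[5, 2, 2] <- 1  # east-moving population at the right edge
  f2 <- applyPeriodic(f, "x", st)
  expect_equal(f2[1, 2, 2], 1)
  expect_equal(sum(f2), sum(f))
  # full streaming = wrap along both axes; mass conserved
  ff <- smooth_field(6, 5)
  expect_equal(sum(applyPeriodic(applyPeriodic(ff, "x"), "y")), sum(ff))
})

test_that("boundary plans reject mismatched periodic pairs", {
  expect_error(boundaryPlan(left = boundarySpec("left", "periodic"),
                            right = boundarySpec("right", "bounce_back")),
               "opposite pairs", class = "acoustoLBM_config_error")
  expect_error(applyBounceBack(smooth_field(4, 4),
                               boundarySpec("bottom", "periodic"),
                               smooth_field(4, 4)),
               class = "acoustoLBM_config_error")
})

test_that("bounce-back maps each wall unknown to its reversed known", {
  nx <- 6; ny <- 5
  fpost <- smooth_field(nx, ny, seed = 11)
  f <- applyPeriodic(applyPeriodic(fpost, "x"), "y")
  wall <- boundarySpec("bottom", "bounce_back")
  f2 <- applyBounceBack(f, wall, fpost)
  # at the bottom wall the incoming N, NE, NW populations are the reversed
  # post-collision S, SW, SE populations of the same node
  expect_equal(f2[, 1, 3], fpost[, 1, 5])
  expect_equal(f2[, 1, 6], fpost[, 1, 8])
  expect_equal(f2[, 1, 7], fpost[, 1, 9])
})

test_that("a closed channel conserves mass under bounce-back walls", {
  f0 <- smooth_field(10, 8)
  s <- latticeState(10, 8, tau = 0.9, f = f0)
  plan <- boundaryPlan()
  for (k in 1:50) s <- lbmStep(s, plan)
  expect_equal(sum(s$f), sum(f0), tolerance = 1e-13)
})

test_that("channel flow satisfies no-slip at the walls within one cell", {
  bm <- runPoiseuille(ny = 40, nx = 8)
  u <- bm$field$ux[4, ]
  # extrapolating the first two fluid nodes to the wall (half a cell out)
  # must give nearly zero tangential velocity
  u_wall <- u[1] - 0.5 * (u[2] - u[1])
  expect_lt(abs(u_wall) / max(u), 0.01)
})

test_that("moving-lid reconstruction returns exact wall moments", {
  nx <- 7; ny <- 6
  f <- smooth_field(nx, ny, seed = 5)
  lid <- boundarySpec("top", "moving_wall", c(0.08, 0))
  f2 <- applyMovingLid(f, lid, st)
  for (x in 2:(nx - 1)) {
    m <- latticeMoments(f2[x, ny, ], st)
    expect_equal(m$u, c(0.08, 0), tolerance = 1e-12)
  }
  # zero lid velocity reduces to the stationary-wall relations
  lid0 <- boundarySpec("top", "moving_wall", c(0, 0))
  wall0 <- boundarySpec("top", "reconstruction")
  expect_equal(applyMovingLid(f, lid0, st),
               applyStationaryReconstruction(f, wall0, st))
})

test_that("stationary reconstruction zeroes the wall velocity on every side", {
  nx <- 7; ny <- 6
  f <- smooth_field(nx, ny, seed = 9)
  for (side in c("bottom", "left", "right", "top")) {
    f2 <- applyStationaryReconstruction(f, boundarySpec(side, "reconstruction"), st)
    idx <- switch(side,
                  bottom = cbind(2:(nx - 1), 1),
                  top = cbind(2:(nx - 1), ny),
                  left = cbind(1, 2:(ny - 1)),
                  right = cbind(nx, 2:(ny - 1)))
    for (r in seq_len(nrow(idx))) {
      m <- latticeMoments(f2[idx[r, 1], idx[r, 2], ], st)
      expect_equal(m$u, c(0, 0), tolerance = 1e-13)
    }
  }
})

test_that("left and right wall reconstructions mirror each other", {
  nx <- 6; ny <- 5
  f <- smooth_field(nx, ny, seed = 13)
  # mirror x: swap columns and the E/W, NE/NW, SE/SW directions
  mirror <- function(f) {
    g <- f[nx:1, , c(1, 4, 3, 2, 5, 7, 6, 9, 8)]
    g
  }
  fL <- applyStationaryReconstruction(f, boundarySpec("left", "reconstruction"), st)
  fR <- applyStationaryReconstruction(mirror(f),
                                      boundarySpec("right", "reconstruction"), st)
  expect_equal(mirror(fR), fL, tolerance = 1e-14)
})

test_that("the cavity run conserves mass over ten thousand steps", {
  n <- 30
  f0 <- array(rep(equilibriumDistribution(1, c(0, 0)), each = n * n),
              c(n, n, 9))
  res <- engine(f0, tau = 0.65, bcx = 2L, bcy = 2L, wall_u_top = 0.1,
                nsteps = 10000, sample_every = 1000)
  mass <- res$traj[, "mass"]
  expect_lt(abs(mass[length(mass)] / mass[1] - 1), 1e-10)
})

test_that("the lid-driven cavity develops the primary vortex", {
  bm <- runCavity(n = 40, re = 100)
  # backflow (negative u) in the lower half of the centerline and strong
  # forward flow just below the lid: the signature of the primary vortex
  expect_lt(min(bm$centerline$u), -0.1)
  near_lid <- bm$profile$u[bm$profile$y > 0.95 & bm$profile$y < 1]
  expect_true(all(near_lid > 0.5))
})
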