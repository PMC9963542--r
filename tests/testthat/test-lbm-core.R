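st <- d2q9Stencil()

test_that("the stencil satisfies the D2Q9 identities", {
  expect_equal(sum(st$w), 1)
  expect_equal(as.vector(crossprod(st$w, st$e)), c(0, 0))
  expect_equal(t(st$e) %*% diag(st$w) %*% st$e, st$cs2 * diag(2),
               tolerance = 1e-15)
  expect_equal(st$cs2, 1 / 3)
  expect_equal(st$w[1], 4 / 9)
  expect_true(all(st$w[2:5] == 1 / 9) && all(st$w[6:9] == 1 / 36))
  expect_identical(st$opposite[st$opposite], 1:9)
})

test_that("equilibrium reduces to the weights at rest and matches a hand value", {
  expect_equal(equilibriumDistribution(1, c(0, 0), st), st$w)
  # east direction at rho = 1, u = (0.1, 0): (1/9)(1 + 0.3 + 0.045 - 0.015)
  feq <- equilibriumDistribution(1, c(0.1, 0), st)
  expect_equal(feq[2], (1 / 9) * (1 + 0.3 + 0.045 - 0.015))
  expect_equal(feq[2], 0.1477778, tolerance = 1e-6)
})

test_that("moments invert the equilibrium and scale homogeneously", {
  m <- latticeMoments(equilibriumDistribution(1.3, c(0.05, -0.02), st), st)
  expect_equal(m$rho, 1.3)
  expect_equal(m$u, c(0.05, -0.02))
  m0 <- latticeMoments(st$w, st)
  expect_equal(m0$rho, 1)
  expect_equal(m0$u, c(0, 0))
  m2 <- latticeMoments(2 * equilibriumDistribution(1.3, c(0.05, -0.02), st), st)
  expect_equal(m2$rho, 2.6)
  expect_equal(m2$u, c(0.05, -0.02))
})

test_that("relaxation time inverts the viscosity relation", {
  expect_equal(tauFromViscosity(1 / 6), 1)
  expect_equal(tauFromViscosity(0.0167), 0.5501)
  expect_error(tauFromViscosity(0), class = "acoustoLBM_invalid_parameter")
  expect_error(tauFromViscosity(-0.1), class = "acoustoLBM_invalid_parameter")
  expect_gt(tauFromViscosity(1e-9), 0.5)
})

test_that("a uniform equilibrium state is a fixed point of the step", {
  state <- latticeState(8, 6, tau = 0.8, rho0 = 1.2, u0 = c(0, 0))
  plan <- boundaryPlan()  # periodic x, bounce-back walls
  s2 <- lbmStep(state, plan)
  expect_equal(s2$f, state$f, tolerance = 1e-14)
})

test_that("a uniformly translating equilibrium stays in equilibrium (Galilean)", {
  plan <- boundaryPlan(bottom = boundarySpec("bottom", "periodic"),
                       top = boundarySpec("top", "periodic"))
  state <- latticeState(8, 6, tau = 0.9, rho0 = 1, u0 = c(0.05, 0.02))
  s2 <- state
  for (k in 1:5) s2 <- lbmStep(s2, plan)
  expect_equal(s2$f, state$f, tolerance = 1e-13)
})

test_that("mass is conserved and momentum balances the injected body force", {
  f0 <- smooth_field(12, 10)
  state <- latticeState(12, 10, tau = 0.7, f = f0)
  plan <- boundaryPlan()  # closed channel: periodic x, walls y
  g <- c(1e-5, -2e-6)
  nsteps <- 40
  p0 <- total_momentum(f0)
  s <- state
  for (k in seq_len(nsteps)) {
    s$force[, , 1] <- g[1]
    s$force[, , 2] <- g[2]
    s <- lbmStep(s, plan)
  }
  expect_equal(total_mass(s$f), total_mass(f0), tolerance = 1e-12)
  # walls absorb y momentum and, with stationary walls, also tangential
  # momentum; check the x balance over a frictionless direction instead on a
  # fully periodic domain
  plan_p <- boundaryPlan(bottom = boundarySpec("bottom", "periodic"),
                         top = boundarySpec("top", "periodic"))
  s <- latticeState(12, 10, tau = 0.7, f = f0)
  for (k in seq_len(nsteps)) {
    s$force[, , 1] <- g[1]
    s$force[, , 2] <- g[2]
    s <- lbmStep(s, plan_p)
  }
  p1 <- total_momentum(s$f)
  expect_equal(p1 - p0, nsteps * g * 12 * 10, tolerance = 1e-10)
})

test_that("compiled engine and R reference stepper agree step for step", {
  nx <- 12; ny <- 10
  f0 <- smooth_field(nx, ny, seed = 7)
  # periodic box with body force
  plan_p <- boundaryPlan(bottom = boundarySpec("bottom", "periodic"),
                         top = boundarySpec("top", "periodic"))
  s <- latticeState(nx, ny, tau = 0.8, f = f0)
  for (k in 1:10) {
    s$force[, , 1] <- 3e-5
    s <- lbmStep(s, plan_p)
  }
  res <- engine(f0, tau = 0.8, gx = 3e-5, bcx = 0L, bcy = 0L,
                nsteps = 10, sample_every = 0)
  expect_equal(res$f, s$f, tolerance = 1e-12)

  # channel with one moving wall
  plan_w <- boundaryPlan(
    bottom = boundarySpec("bottom", "bounce_back"),
    top = boundarySpec("top", "bounce_back", c(0.04, 0)))
  s <- latticeState(nx, ny, tau = 1.1, f = f0)
  for (k in 1:10) s <- lbmStep(s, plan_w)
  res <- engine(f0, tau = 1.1, bcx = 0L, bcy = 2L,
                wall_u_bottom = 0, wall_u_top = 0.04,
                nsteps = 10, sample_every = 0)
  expect_equal(res$f, s$f, tolerance = 1e-12)
})

test_that("engine and R path agree for the coupled membrane update", {
  nx <- 16; ny <- 14
  f0 <- smooth_field(nx, ny, seed = 3)
  mem <- makeCircleMembrane(c(8, 7), 2.2, mobile = TRUE, gain = 0.6)
  plan <- boundaryPlan()
  s <- latticeState(nx, ny, tau = 0.75, f = f0)
  m <- mem
  body <- list(x = mem$centroid, v = c(0, 0))
  fext <- c(2e-4, -1e-4)
  for (k in 1:5) {
    step <- r_coupled_step(s, m, body, plan, fext_total = fext)
    s <- step$state; m <- step$mem; body <- step$body
  }
  res <- engine(f0, tau = 0.75, bcx = 0L, bcy = 2L, membrane = mem,
                fext = fext, nsteps = 5, sample_every = 0)
  expect_equal(res$f, s$f, tolerance = 1e-12)
  expect_equal(res$membrane, unname(m$nodes), tolerance = 1e-12)
})

test_that("Poiseuille error shrinks under grid refinement at fixed Re", {
  b40 <- runPoiseuille(ny = 40, nx = 8, re = 8)
  b80 <- runPoiseuille(ny = 80, nx = 8, re = 8, max_steps = 250000)
  expect_lt(b80$error_norm, b40$error_norm)
})

test_that("instability is reported with an error, not clamped", {
  f0 <- smooth_field(6, 6)
  f0[3, 3, ] <- -1
  expect_error(latticeMoments(f0), "density",
               class = "acoustoLBM_stability_error")
})
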