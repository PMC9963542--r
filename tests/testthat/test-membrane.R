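test_that("circle membranes honour centre, radius and spacing bounds", {
  mem <- makeCircleMembrane(c(10, 12), 2.5, target_spacing = 0.65)
  expect_equal(mem$centroid, c(10, 12))
  expect_equal(colMeans(mem$nodes), c(10, 12), tolerance = 1e-12)
  r <- sqrt(rowSums(sweep(mem$nodes, 2, c(10, 12))^2))
  expect_equal(r, rep(2.5, mem$n), tolerance = 1e-12)
  expect_equal(mem$n, ceiling(2 * pi * 2.5 / 0.65))
  spacing <- sqrt(sum((mem$nodes[1, ] - mem$nodes[2, ])^2))
  expect_true(spacing > 0.3 && spacing <= 1)
  # a 10 um particle on the tabulated 2 um mapping has lattice radius 2.5
  us <- table1_units()
  expect_equal(5e-6 / us$cf_length, 2.5)
  expect_error(makeCircleMembrane(c(0, 0), 0.1),
               class = "acoustoLBM_config_error")
  expect_error(makeCircleMembrane(c(0, 0), 2, target_spacing = 2),
               class = "acoustoLBM_invalid_parameter")
})

test_that("the hat kernel evaluates and vanishes as specified", {
  expect_equal(deltaWeight(0, 0), 1)
  expect_equal(deltaWeight(1, 0.3), 0)
  expect_equal(deltaWeight(0.2, 1.7), 0)
  expect_equal(deltaWeight(0.5, 0.5), 0.25)
  expect_equal(deltaWeight(-0.25, 0.5), 0.375)
})

test_that("force spreading partitions unity and hits single sites exactly", {
  mem <- makeCircleMembrane(c(8.3, 7.1), 2.1)
  set.seed(4)
  mem$node_forces <- matrix(rnorm(2 * mem$n, sd = 1e-3), mem$n, 2)
  field <- spreadForces(mem, array(0, c(16, 16, 2)))
  expect_equal(colSums(apply(field, 3, identity)),
               colSums(mem$node_forces), tolerance = 1e-14)
  # node exactly on a site
  m1 <- makeCircleMembrane(c(8, 8), 3, target_spacing = 0.9)
  m1$nodes[1, ] <- c(5, 8)  # grid site (lattice coords are 0-based)
  m1$node_forces[1, ] <- c(1, 2)
  fld <- spreadForces(m1, array(0, c(16, 16, 2)))
  expect_equal(fld[6, 9, 1], 1)
  expect_equal(fld[6, 9, 2], 2)
  # node at a cell centre splits the force four ways
  m1$nodes[1, ] <- c(5.5, 8.5)
  fld <- spreadForces(m1, array(0, c(16, 16, 2)))
  expect_equal(fld[6, 9, 1], 0.25)
  expect_equal(fld[7, 10, 1], 0.25)
})

test_that("velocity interpolation reproduces uniform and linear fields", {
  mem <- makeCircleMembrane(c(8.3, 7.6), 2.4)
  u <- array(0, c(16, 16, 2))
  u[, , 1] <- 0.03; u[, , 2] <- -0.01
  v <- interpolateVelocity(u, mem)
  expect_equal(v, matrix(c(0.03, -0.01), mem$n, 2, byrow = TRUE),
               tolerance = 1e-14)
  # linear field u = a + b x + c y is reproduced exactly by the hat kernel
  xs <- matrix(0:15, 16, 16); ys <- t(xs)
  u[, , 1] <- 0.001 + 2e-4 * xs - 1e-4 * ys
  u[, , 2] <- 3e-4 * ys
  v <- interpolateVelocity(u, mem)
  expect_equal(v[, 1],
               0.001 + 2e-4 * mem$nodes[, 1] - 1e-4 * mem$nodes[, 2],
               tolerance = 1e-14)
  expect_equal(v[, 2], 3e-4 * mem$nodes[, 2], tolerance = 1e-14)
  # node on a site returns that site's value
  mem$nodes[1, ] <- c(4, 9)
  v <- interpolateVelocity(u, mem)
  expect_equal(v[1, 1], u[5, 10, 1])
})

test_that("penalty forces are Hookean and vanish for rigid translations", {
  mem <- makeCircleMembrane(c(10, 10), 2, stiffness = 0.07)
  m0 <- constitutiveForces(mem)
  expect_equal(m0$node_forces, matrix(0, mem$n, 2), tolerance = 1e-14)
  # single displaced node feels a restoring force; the anchor follows the
  # centroid, so the restoring force is reduced by the 1/N centroid shift
  d <- c(0.2, -0.1)
  m1 <- mem; m1$nodes[3, ] <- m1$nodes[3, ] + d
  m1 <- constitutiveForces(m1)
  expect_equal(m1$node_forces[3, ], -0.07 * d * (1 - 1 / mem$n),
               tolerance = 1e-12)
  # anchored membranes restore the full displacement
  m2 <- mem; m2$mobile <- FALSE
  m2$nodes[3, ] <- m2$nodes[3, ] + d
  m2 <- constitutiveForces(m2)
  expect_equal(m2$node_forces[3, ], -0.07 * d, tolerance = 1e-12)
  # rigid translation of nodes and centroid leaves no penalty force
  m3 <- mem
  m3$nodes <- sweep(m3$nodes, 2, c(1.4, -0.8), "+")
  m3 <- constitutiveForces(m3, external_force_per_node = c(1e-4, 0))
  expect_equal(m3$node_forces[, 1], rep(1e-4, mem$n), tolerance = 1e-10)
  expect_equal(max(abs(m3$node_forces[, 2])), 0, tolerance = 1e-14)
})

test_that("the Euler update advects nodes and recomputes the centroid", {
  mem <- makeCircleMembrane(c(5, 5), 1.5)
  m0 <- advanceMembrane(mem, matrix(0, mem$n, 2))
  expect_equal(m0$nodes, mem$nodes)
  v <- matrix(c(0.01, 0.005), mem$n, 2, byrow = TRUE)
  m1 <- mem
  for (k in 1:10) m1 <- advanceMembrane(m1, v)
  expect_equal(m1$centroid, c(5.1, 5.05), tolerance = 1e-12)
  expect_error(advanceMembrane(mem, v, dt = 0),
               class = "acoustoLBM_invalid_parameter")
})

test_that("membranes advect with a uniform flow like passive tracers", {
  nx <- 20; ny <- 16
  U <- 0.02
  f0 <- array(rep(equilibriumDistribution(1, c(U, 0)), each = nx * ny),
              c(nx, ny, 9))
  mem <- makeCircleMembrane(c(6, 8), 2, stiffness = 0.03, mobile = TRUE)
  res <- engine(f0, tau = 0.8, bcx = 0L, bcy = 0L, membrane = mem,
                nsteps = 1000, sample_every = 1000)
  expect_equal(res$status, 0L)
  drift <- res$traj[nrow(res$traj), "cx"] - 6
  expect_lt(abs(drift - 1000 * U), 1)  # within one lattice cell of a tracer
})

test_that("action equals reaction between membrane and fluid", {
  mem <- makeCircleMembrane(c(8.2, 7.9), 2.3, stiffness = 0.05)
  set.seed(8)
  mem$nodes <- mem$nodes + matrix(rnorm(2 * mem$n, sd = 0.05), mem$n, 2)
  mem <- constitutiveForces(mem, external_force_per_node = c(2e-4, -1e-4))
  field <- spreadForces(mem, array(0, c(16, 16, 2)))
  expect_equal(sum(field[, , 1]), sum(mem$node_forces[, 1]), tolerance = 1e-14)
  expect_equal(sum(field[, , 2]), sum(mem$node_forces[, 2]), tolerance = 1e-14)
})

test_that("drag coefficient formula and scalings", {
  expect_equal(dragCoefficient(1, 1, 1, 1), 2)
  expect_equal(dragCoefficient(1, 1, 1, 2), 0.5)  # doubling u_r quarters Cd
  expect_error(dragCoefficient(1, 1, 1, 0), "division")
})
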