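# shared fixtures built in code

table1_units <- function() buildUnitSystem(160e-6, 80, 1027, 1, 1e-6, 0.0167)

# a smooth, strictly positive, non-equilibrium distribution field
smooth_field <- function(nx, ny, seed = 1) {
  set.seed(seed)
  st <- d2q9Stencil()
  rho <- 1 + 0.05 * outer(sin(2 * pi * seq_len(nx) / nx),
                          cos(2 * pi * seq_len(ny) / ny))
  u <- array(0, c(nx, ny, 2))
  u[, , 1] <- 0.02 * outer(cos(2 * pi * seq_len(nx) / nx), rep(1, ny))
  u[, , 2] <- 0.01 * outer(rep(1, nx), sin(2 * pi * seq_len(ny) / ny))
  f <- equilibriumDistribution(rho, u, st)
  f * (1 + 0.01 * array(runif(length(f)), dim(f)))  # break equilibrium
}

total_mass <- function(f) sum(f)

total_momentum <- function(f, stencil = d2q9Stencil()) {
  e <- stencil$e
  c(sum(sapply(1:9, function(i) sum(f[, , i]) * e[i, 1])),
    sum(sapply(1:9, function(i) sum(f[, , i]) * e[i, 2])))
}

# run the compiled engine with the package-internal wrapper
engine <- function(...) acoustoLBM:::.run_engine(...)

# One R-reference coupled IB-LBM step (membrane in a periodic-x channel),
# mirroring the engine's direct-forcing rigid-body scheme: nodes ride
# rigidly on the body frame, the node force is gain * (v_body - u_fluid),
# and the body obeys Newton's law under the reactions plus external force.
# `body` is list(x, v).
r_coupled_step <- function(state, mem, body, plan, fext_total = c(0, 0)) {
  mem$nodes <- sweep(mem$reference, 2, body$x, "+")
  u <- latticeMoments(state$f)$u
  uk <- interpolateVelocity(u, mem, wrap_x = TRUE)
  forcing <- mem$gain * sweep(-uk, 2, body$v, "+")
  mem$node_forces <- forcing
  field <- array(0, c(state$nx, state$ny, 2))
  state$force <- spreadForces(mem, field, wrap_x = TRUE)
  state <- lbmStep(state, plan)
  body$v <- body$v + (-colSums(forcing) + fext_total) / mem$mass
  body$x <- body$x + body$v
  list(state = state, mem = mem, body = body)
}

fast_defaults <- function(...) {
  d <- focusingDefaults()
  utils::modifyList(d, list(...))
}
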