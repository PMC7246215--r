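# Shared test helpers: finite-difference oracle for the selection
# gradients, and a generator of random admissible states/parameter sets.

# Central finite difference of a scalar function of one variable.
fd_deriv <- function(f, x, h = 1e-7) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# Finite-difference gradients of the log-fitness functions with respect to
# each trait, independent of the analytic gradient code path.
fd_plant_gradient <- function(state, params, h = 1e-7) {
  g1 <- fd_deriv(function(u1) {
    s <- state; s$u1 <- u1
    log_fitness_plant(s, params)
  }, state$u1, h)
  g2 <- fd_deriv(function(u2) {
    s <- state; s$u2 <- u2
    log_fitness_plant(s, params)
  }, state$u2, h)
  c(u1 = g1, u2 = g2)
}

fd_pollinator_gradient <- function(state, params, h = 1e-7) {
  g1 <- fd_deriv(function(v1) {
    s <- state; s$v1 <- v1
    log_fitness_pollinator(1L, s, params)
  }, state$v1, h)
  g2 <- fd_deriv(function(v2) {
    s <- state; s$v2 <- v2
    log_fitness_pollinator(2L, s, params)
  }, state$v2, h)
  c(v1 = g1, v2 = g2)
}

# Relative error with a small absolute floor so near-zero gradients (sign
# changes of the selection gradient) do not blow up the ratio.
rel_err <- function(got, want, floor = 1e-4) {
  abs(got - want) / pmax(abs(want), floor)
}

# Random admissible parameter set: every rate/cost/benefit jittered around
# its standard value, carrying capacities kept comfortably positive.
random_params <- function() {
  jit <- function(x, lo = 0.5, hi = 2) x * stats::runif(1, lo, hi)
  bv_params(r1 = jit(0.01), r2 = jit(0.01), rP = jit(0.01), rX = jit(0.5),
            c1 = stats::runif(1, 0, 1.5), c2 = stats::runif(1, 0, 1.5),
            f1 = jit(0.5), f2 = jit(0.5), fP1 = jit(0.2), fP2 = jit(0.2),
            k1 = jit(1.5), k2 = jit(1.5), kP = jit(0.5),
            d1 = jit(0.8), d2 = jit(0.8),
            theta1 = jit(0.05), theta2 = jit(0.05),
            thetaP1 = jit(0.5), thetaP2 = jit(0.25),
            a01 = jit(0.5), a02 = jit(0.5))
}

# Random state admissible under `params`: traits drawn so that every
# carrying capacity keeps a positive margin (> 10% of its zero-trait
# value), leaving room for the finite-difference probe.
random_state <- function(params) {
  frac <- stats::runif(3, 0, 0.8)
  u_budget <- frac[1] * params$kP
  w1 <- stats::runif(1)
  u1 <- if (params$fP1 > 0) w1 * u_budget / params$fP1 else stats::runif(1, 0, 1)
  u2 <- if (params$fP2 > 0) (1 - w1) * u_budget / params$fP2 else stats::runif(1, 0, 1)
  v1 <- if (params$f1 > 0) frac[2] * params$k1 / params$f1 else stats::runif(1, 0, 2)
  v2 <- if (params$f2 > 0) frac[3] * params$k2 / params$f2 else stats::runif(1, 0, 2)
  bv_state(P = stats::runif(1, 0, 5), X = stats::runif(1, 0, 10),
           N1 = stats::runif(1, 0, 3), N2 = stats::runif(1, 0, 3),
           u1 = u1, u2 = u2, v1 = v1, v2 = v2, params = params)
}

state_vec <- function(state) {
  unlist(state[c("P", "X", "N1", "N2", "u1", "u2", "v1", "v2")])
}
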