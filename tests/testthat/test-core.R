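p_std <- bv_params()

test_that("visitation rate matches its closed form and boundary cases", {
  expect_equal(visitation_rate(v = 0, u = 0, d = 0.8, a0 = 0.5, P = 0.5), 0)
  expect_equal(visitation_rate(v = exp(1) - 1, u = 0, d = 0.8,
                               a0 = 0.5, P = 0.5), 1.0)
  # ln(1.009)/0.55, evaluated independently
  expect_equal(visitation_rate(v = 0.005, u = 0.005, d = 0.8,
                               a0 = 0.5, P = 0.05),
               0.016290438857221454, tolerance = 1e-12)
  expect_error(visitation_rate(v = -0.1, u = 0, d = 0.8, a0 = 0.5, P = 0),
               ">= 0")
  expect_error(visitation_rate(v = 0, u = 0, d = 0.8, a0 = 0, P = 0), "a0")
})

test_that("visitation is monotone: down in P, up in both traits", {
  set.seed(11)
  for (rep in 1:50) {
    v <- runif(1, 0, 2); u <- runif(1, 0, 2); d <- runif(1, 0.1, 2)
    a0 <- runif(1, 0.1, 2); P <- runif(1, 0, 5); eps <- 1e-3
    a <- visitation_rate(v, u, d, a0, P)
    expect_lte(visitation_rate(v, u, d, a0, P + eps), a)
    expect_gte(visitation_rate(v + eps, u, d, a0, P), a)
    expect_gte(visitation_rate(v, u + eps, d, a0, P), a)
  }
})

test_that("plant log fitness has its logistic fixed point and closed form", {
  # P = kP with zero traits and no pollinators: logistic fixed point
  s <- bv_state(P = 0.5, X = 0, N1 = 0, N2 = 0,
                u1 = 0, u2 = 0, v1 = 0, v2 = 0)
  expect_equal(log_fitness_plant(s, p_std), 0)
  # P = 2 bP: exponent is rP - 2 rP = -rP
  s2 <- bv_state(P = 1.0, X = 0, N1 = 0, N2 = 0,
                 u1 = 0, u2 = 0, v1 = 0, v2 = 0)
  expect_equal(log_fitness_plant(s2, p_std), -0.01)
  # hand-evaluated closed form with one pollinator present
  s3 <- bv_state(P = 0.05, X = 0, N1 = 0.05, N2 = 0,
                 u1 = 0.005, u2 = 0, v1 = 0.005, v2 = 0)
  expect_equal(log_fitness_plant(s3, p_std),
               0.0094052569634145052, tolerance = 1e-12)
  # exp(result) * P equals the one-step plant update
  eco <- step_ecology(s3, p_std)
  expect_equal(eco[["P"]], 0.05 * exp(log_fitness_plant(s3, p_std)))
})

test_that("pollinator log fitness: fixed point, symmetry, closed form", {
  s <- bv_state(P = 0, X = 0, N1 = 1.5, N2 = 0,
                u1 = 0, u2 = 0, v1 = 0, v2 = 0)
  expect_equal(log_fitness_pollinator(1L, s, p_std), 0)
  # fully symmetric parameters and state give identical values
  p_sym <- bv_params(thetaP2 = 0.5)
  s_sym <- bv_state(P = 0.3, X = 0.2, N1 = 0.4, N2 = 0.4,
                    u1 = 0.1, u2 = 0.1, v1 = 0.2, v2 = 0.2)
  expect_identical(log_fitness_pollinator(1L, s_sym, p_sym),
                   log_fitness_pollinator(2L, s_sym, p_sym))
  # hand-evaluated closed form
  s3 <- bv_state(P = 0.05, X = 0.1, N1 = 0.05, N2 = 0.05,
                 u1 = 0.005, u2 = 0.005, v1 = 0.005, v2 = 0.005)
  expect_equal(log_fitness_pollinator(1L, s3, p_std),
               0.0094971450156550556, tolerance = 1e-12)
  expect_error(log_fitness_pollinator(3L, s3, p_std), "1 or 2")
})

test_that("degenerate carrying capacities raise errors", {
  s <- bv_state(P = 0.1, X = 0, N1 = 0.1, N2 = 0.1,
                u1 = 1.3, u2 = 1.3, v1 = 0, v2 = 0)  # bP < 0
  expect_error(log_fitness_plant(s, p_std), "degenerate")
  expect_error(plant_selection_gradient(s, p_std), "degenerate")
  s2 <- bv_state(v1 = 3.5)  # b1 < 0
  expect_error(log_fitness_pollinator(1L, s2, p_std), "degenerate")
})

test_that("one ecological step matches the hand-evaluated maps", {
  # extinction is absorbing
  s0 <- bv_state(P = 0, X = 0, N1 = 0, N2 = 0,
                 u1 = 0.1, u2 = 0.1, v1 = 0.1, v2 = 0.1)
  expect_equal(unname(step_ecology(s0, p_std)), c(0, 0, 0, 0))
  # with no consumers, rewards are pure production: X' = rX * P
  s1 <- bv_state(P = 1, X = 0, N1 = 0, N2 = 0,
                 u1 = 0, u2 = 0, v1 = 0, v2 = 0)
  expect_equal(step_ecology(s1, p_std)[["X"]], 0.5)
  # hand-evaluated full tuple from the standard sweep starting state
  s2 <- bv_state(P = 0.05, X = 0, N1 = 0.05, N2 = 0,
                 u1 = 0.005, u2 = 0, v1 = 0.005, v2 = 0)
  eco <- step_ecology(s2, p_std)
  expect_equal(eco[["P"]], 0.050472481269119622, tolerance = 1e-12)
  expect_equal(eco[["X"]], 0.025, tolerance = 1e-12)
  expect_equal(eco[["N1"]], 0.050485648895725647, tolerance = 1e-12)
  expect_equal(eco[["N2"]], 0)
})

test_that("trait updates freeze with zero genetic variance", {
  p0 <- bv_params(sigma1_sq = 0, sigma2_sq = 0,
                  sigmaP1_sq = 0, sigmaP2_sq = 0)
  s <- bv_state(P = 0.4, X = 0.2, N1 = 0.3, N2 = 0.2,
                u1 = 0.1, u2 = 0.05, v1 = 0.2, v2 = 0.1)
  expect_equal(plant_trait_update(s, p0), c(u1 = 0.1, u2 = 0.05))
  expect_equal(pollinator_trait_update(s, p0), c(v1 = 0.2, v2 = 0.1))
})

test_that("cost-only selection pushes traits down", {
  # no associated pollinator: plant trait 1 can only decline
  s <- bv_state(P = 0.4, X = 0, N1 = 0, N2 = 0.2,
                u1 = 0.1, u2 = 0.05, v1 = 0.2, v2 = 0.1)
  expect_lt(plant_trait_update(s, p_std)[["u1"]], 0.1)
  # no rewards: pollinator trait is pure cost
  expect_lt(pollinator_trait_update(s, p_std)[["v2"]], 0.1)
  # clamping keeps traits nonnegative
  s2 <- bv_state(P = 2, X = 0, N1 = 0, N2 = 0,
                 u1 = 1e-9, u2 = 0, v1 = 1e-9, v2 = 0)
  expect_gte(plant_trait_update(s2, p_std)[["u1"]], 0)
  expect_gte(pollinator_trait_update(s2, p_std)[["v1"]], 0)
})

test_that("trait updates match the finite-difference oracle at a fixed state", {
  s <- bv_state(P = 0.05, X = 0.1, N1 = 0.05, N2 = 0.05,
                u1 = 0.005, u2 = 0.005, v1 = 0.005, v2 = 0.005)
  gu <- fd_plant_gradient(s, p_std)
  gv <- fd_pollinator_gradient(s, p_std)
  u_exp <- c(u1 = s$u1 + p_std$sigmaP1_sq * gu[["u1"]],
             u2 = s$u2 + p_std$sigmaP2_sq * gu[["u2"]])
  v_exp <- c(v1 = s$v1 + p_std$sigma1_sq * gv[["v1"]],
             v2 = s$v2 + p_std$sigma2_sq * gv[["v2"]])
  expect_equal(plant_trait_update(s, p_std), u_exp, tolerance = 1e-8)
  expect_equal(pollinator_trait_update(s, p_std), v_exp, tolerance = 1e-8)
})

test_that("a full step composes ecology and evolution synchronously", {
  s <- bv_state(P = 0.05, X = 0.05, N1 = 0.05, N2 = 0.05,
                u1 = 0.005, u2 = 0.005, v1 = 0.005, v2 = 0.005)
  nxt <- bv_step(s, p_std, bv_flags())
  eco <- step_ecology(s, p_std)   # time-t values only
  u <- plant_trait_update(s, p_std)
  v <- pollinator_trait_update(s, p_std)
  expect_equal(nxt$t, 1L)
  expect_equal(nxt$P, eco[["P"]])
  expect_equal(nxt$X, eco[["X"]])
  expect_equal(nxt$N1, eco[["N1"]])
  expect_equal(nxt$u1, u[["u1"]])
  expect_equal(nxt$v2, v[["v2"]])
  # with flags off the traits are carried over unchanged
  frozen <- bv_step(s, p_std, bv_flags(FALSE, FALSE))
  expect_equal(frozen$u1, s$u1)
  expect_equal(frozen$v1, s$v1)
  expect_equal(frozen$P, eco[["P"]])
  # symmetric pollinators stay symmetric after one step
  p_sym <- bv_params(thetaP2 = 0.5)
  s_sym <- bv_state(P = 0.3, X = 0.2, N1 = 0.4, N2 = 0.4,
                    u1 = 0.1, u2 = 0.1, v1 = 0.2, v2 = 0.2)
  nxt_sym <- bv_step(s_sym, p_sym, bv_flags())
  expect_identical(nxt_sym$N1, nxt_sym$N2)
  expect_identical(nxt_sym$v1, nxt_sym$v2)
  expect_identical(nxt_sym$u1, nxt_sym$u2)
})
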