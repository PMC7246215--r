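p_std <- bv_params()

test_that("logistic limits are recovered with zero traits and no evolution", {
  flags0 <- bv_flags(FALSE, FALSE)
  z <- function(...) bv_state(..., u1 = 0, u2 = 0, v1 = 0, v2 = 0)
  # plant alone converges to kP
  tr <- bv_simulate(z(P = 0.05, X = 0, N1 = 0, N2 = 0), p_std, flags0,
                    max_steps = 1e6, eq_window = 0)
  expect_equal(tr$final$P, 0.5, tolerance = 1e-9)
  # each isolated pollinator converges to its own k
  tr1 <- bv_simulate(z(P = 0, X = 0, N1 = 0.05, N2 = 0), p_std, flags0,
                     max_steps = 1e6, eq_window = 0)
  expect_equal(tr1$final$N1, 1.5, tolerance = 1e-9)
  tr2 <- bv_simulate(z(P = 0, X = 0, N1 = 0, N2 = 0.05), p_std, flags0,
                     max_steps = 1e6, eq_window = 0)
  expect_equal(tr2$final$N2, 1.5, tolerance = 1e-9)
})

test_that("the compiled loop reproduces the R reference step exactly", {
  p <- bv_params(c1 = 1, c2 = 0.75)
  s <- bv_state(P = 0.05, X = 0.02, N1 = 0.05, N2 = 0.05,
                u1 = 0.005, u2 = 0.005, v1 = 0.01, v2 = 0.005)
  s_r <- s
  for (i in 1:500) s_r <- bv_step(s_r, p, bv_flags())
  tr <- bv_simulate(s, p, bv_flags(), max_steps = 500, eq_window = 0)
  a <- state_vec(s_r)
  b <- state_vec(tr$final)
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), 1e-12)
})

test_that("zero abundance is absorbing and everything stays nonnegative", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_params()
    s <- random_state(p)
    # knock one species to exactly zero
    hit <- sample(c("P", "N1", "N2"), 1)
    s[[hit]] <- 0
    tr <- bv_simulate(s, p, bv_flags(), max_steps = 200, eq_window = 0,
                      max_abundance = 1e12)
    expect_identical(tr$final[[hit]], 0)
    expect_true(all(tr$states[-1] >= 0))
  }
})

test_that("symmetric pollinators follow identical trajectories", {
  p_sym <- bv_params(thetaP2 = 0.5)
  s <- bv_state(P = 0.05, X = 0, N1 = 0.05, N2 = 0.05,
                u1 = 0.005, u2 = 0.005, v1 = 0.005, v2 = 0.005)
  tr <- bv_simulate(s, p_sym, bv_flags(), max_steps = 50000)
  expect_lt(max(abs(tr$states$N1 - tr$states$N2) /
                  pmax(abs(tr$states$N1), 1e-12)), 1e-12)
  expect_lt(max(abs(tr$states$v1 - tr$states$v2) /
                  pmax(abs(tr$states$v1), 1e-12)), 1e-12)
})

test_that("simulation runs are deterministic", {
  pr <- bv_protocol(burn_in_steps = 5000, post_steps = 5000)
  inv1 <- bv_invasion(pr, p_std)
  inv2 <- bv_invasion(pr, p_std)
  expect_identical(inv1$burn_in$states, inv2$burn_in$states)
  expect_identical(inv1$post$states, inv2$post$states)
  expect_identical(state_vec(inv1$post$final), state_vec(inv2$post$final))
})

test_that("trajectories record strictly increasing time and exact terminals", {
  tr <- bv_simulate(bv_state(), p_std, max_steps = 250000)  # strided run
  expect_true(all(diff(tr$states$t) > 0))
  last <- tr$states[nrow(tr$states), ]
  expect_equal(last$P, tr$final$P)   # terminal row is the exact final state
  expect_equal(last$t, tr$final$t)
})

test_that("runaway abundance aborts with regime unbounded", {
  # large honey bee carrying capacity destabilises the positive feedback
  ps <- bv_preset("fig2b")
  pv <- bv_params_update(ps$params, k2 = 30)
  inv <- bv_invasion(ps$protocol, pv)
  expect_identical(inv$post$regime, "unbounded")
  expect_true(inv$post$unbounded)
  # all-zero start stays collapsed
  z <- bv_state(P = 0, X = 0, N1 = 0, N2 = 0,
                u1 = 0, u2 = 0, v1 = 0, v2 = 0)
  tr <- bv_simulate(z, p_std, max_steps = 100)
  expect_identical(tr$regime, "collapse")
  expect_equal(unname(state_vec(tr$final)), rep(0, 8))
})

test_that("regime classification applies the extinction threshold", {
  tr <- bv_simulate(bv_state(), p_std, max_steps = 1000)
  fake <- tr
  fake$final$N2 <- 1e-9
  expect_identical(classify_regime(fake), "wild_only")
  fake$final$N1 <- 1e-9
  expect_identical(classify_regime(fake), "plant_only")
  fake$final$N1 <- 0.2; fake$final$N2 <- 0.2
  expect_identical(classify_regime(fake), "coexistence")
  fake$final$P <- 1e-9
  expect_identical(classify_regime(fake), "collapse")
  # threshold override
  fake$final$P <- 0.2; fake$final$N2 <- 1e-4
  expect_identical(classify_regime(fake, extinction_threshold = 1e-3),
                   "wild_only")
})

test_that("invasion phases join continuously except for the introduction", {
  pr <- bv_protocol(burn_in_steps = 20000, post_steps = 2000)
  inv <- bv_invasion(pr, bv_params(c1 = 1, c2 = 0.75))
  eq <- inv$burn_in$final
  intro <- inv$introduction_state
  expect_equal(intro$P, eq$P)
  expect_equal(intro$X, eq$X)
  expect_equal(intro$N1, eq$N1)
  expect_equal(intro$u1, eq$u1)
  expect_equal(intro$v1, eq$v1)
  expect_equal(intro$N2, eq$N1)       # match_wild introduction
  expect_equal(intro$v2, 0.001)
  expect_equal(intro$u2, 0.001)
  # burn-in has no honey bees at any recorded step
  expect_true(all(inv$burn_in$states$N2 == 0))
})

test_that("re-running the burn-in from its own equilibrium barely moves", {
  pr <- bv_protocol()
  inv <- bv_invasion(pr, bv_params(c1 = 1, c2 = 0.75))
  eq <- inv$burn_in$final
  expect_true(inv$burn_in$converged)
  again <- bv_simulate(eq, bv_params(c1 = 1, c2 = 0.75), bv_flags(),
                       max_steps = 1000, eq_window = 0)
  drift <- abs(state_vec(again$final) - state_vec(eq)) /
    pmax(abs(state_vec(eq)), 1e-9)
  expect_lt(max(drift), 1e-10)
})

test_that("introducing the honey bee at zero abundance changes nothing", {
  pr0 <- bv_protocol(burn_in_steps = 5000, post_steps = 3000,
                     intro_abundance_mode = "fixed",
                     intro_abundance_value = 0,
                     intro_trait_v2 = 0, intro_trait_u2 = 0,
                     eq_window = 0)
  inv <- bv_invasion(pr0, p_std)
  cont <- bv_simulate(pr0$initial_state, p_std, bv_flags(),
                      max_steps = 8000, eq_window = 0)
  fin <- inv$post$final
  expect_identical(fin$N2, 0)
  for (nm in c("P", "X", "N1", "u1", "v1")) {
    expect_equal(fin[[nm]], cont$final[[nm]], tolerance = 1e-12)
  }
})
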