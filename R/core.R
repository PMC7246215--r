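#' Per-capita visitation rate
#'
#' The per-capita rate at which a pollinator visits the focal plant,
#' \deqn{a = \log(v + d\,u + 1) / (a_0 + P).}
#' It rises with both partners' investment traits and declines with plant
#' abundance: the more plants there are, the less likely any individual
#' plant is visited, with `a0` setting the half-saturation density.
#'
#' @param v Pollinator investment trait (>= 0).
#' @param u Plant attraction trait (>= 0).
#' @param d Scaling of the plant trait relative to the pollinator trait.
#' @param a0 Half-saturation constant (> 0).
#' @param P Plant abundance (>= 0).
#' @return The per-capita visitation rate (>= 0); zero exactly when
#'   `v + d*u == 0`.
#' @examples
#' visitation_rate(v = exp(1) - 1, u = 0, d = 0.8, a0 = 0.5, P = 0.5)  # 1
#' @export
visitation_rate <- function(v, u, d, a0, P) {
  if (any(c(v, u, d, P) < 0)) stop("v, u, d and P must be >= 0", call. = FALSE)
  if (a0 <= 0) stop("a0 must be > 0", call. = FALSE)
  log(v + d * u + 1) / (a0 + P)
}

stop_degenerate <- function(which, value) {
  stop("degenerate state: carrying capacity ", which, " = ", signif(value, 6),
       " is not positive (trait cost exceeds base capacity)", call. = FALSE)
}

#' Per-capita log fitness of the plant
#'
#' Log of the per-capita growth factor in the plant map:
#' \deqn{r_P - (r_P/b_P)\,P + \theta_{P1} a_1 N_1 + \theta_{P2} a_2 N_2,}
#' with \eqn{b_P = k_P - f_{P1}u_1 - f_{P2}u_2} the trait-depressed carrying
#' capacity and \eqn{a_i} the visitation rates. Without pollinators this is
#' the discrete logistic exponent, zero at \eqn{P = b_P}.
#'
#' @param state A [bv_state()].
#' @param params A [bv_params()].
#' @return A single number; `exp(result) * P` is next step's plant abundance.
#' @export
log_fitness_plant <- function(state, params) {
  caps <- carrying_capacities(state, params)
  if (caps[["bP"]] <= 0) stop_degenerate("bP", caps[["bP"]])
  a1 <- visitation_rate(state$v1, state$u1, params$d1, params$a01, state$P)
  a2 <- visitation_rate(state$v2, state$u2, params$d2, params$a02, state$P)
  params$rP - (params$rP / caps[["bP"]]) * state$P +
    params$thetaP1 * a1 * state$N1 + params$thetaP2 * a2 * state$N2
}

#' Per-capita log fitness of a pollinator
#'
#' Log of the per-capita growth factor of pollinator `i`:
#' \deqn{r_i - (r_i/b_i)(N_i + c_i N_j) + \theta_i a_i X,}
#' where \eqn{j} is the other pollinator, \eqn{b_i = k_i - f_i v_i}, and the
#' reward pool \eqn{X} is what visits convert into reproduction.
#'
#' @param i Species index: 1 = wild pollinator, 2 = managed honey bee.
#' @inheritParams log_fitness_plant
#' @return A single number; `exp(result) * N_i` is next step's abundance.
#' @export
log_fitness_pollinator <- function(i, state, params) {
  if (!i %in% c(1L, 2L)) stop("i must be 1 or 2", call. = FALSE)
  caps <- carrying_capacities(state, params)
  if (i == 1L) {
    b <- caps[["b1"]]
    if (b <= 0) stop_degenerate("b1", b)
    a <- visitation_rate(state$v1, state$u1, params$d1, params$a01, state$P)
    params$r1 - (params$r1 / b) * (state$N1 + params$c1 * state$N2) +
      params$theta1 * a * state$X
  } else {
    b <- caps[["b2"]]
    if (b <= 0) stop_degenerate("b2", b)
    a <- visitation_rate(state$v2, state$u2, params$d2, params$a02, state$P)
    params$r2 - (params$r2 / b) * (state$N2 + params$c2 * state$N1) +
      params$theta2 * a * state$X
  }
}

#' One synchronous ecological step
#'
#' Advances the four abundances one time step, all from time-t values:
#' \itemize{
#'   \item `P' = P * exp(log_fitness_plant)`
#'   \item `X' = rX * P + X * exp(-(a1 N1 + a2 N2))` (new production plus
#'     the rewards not consumed by pollinator visits)
#'   \item `Ni' = Ni * exp(log_fitness_pollinator(i))`
#' }
#' Traits are untouched.
#'
#' @inheritParams log_fitness_plant
#' @return Named numeric vector `c(P, X, N1, N2)`.
#' @export
step_ecology <- function(state, params) {
  a1 <- visitation_rate(state$v1, state$u1, params$d1, params$a01, state$P)
  a2 <- visitation_rate(state$v2, state$u2, params$d2, params$a02, state$P)
  P_new <- if (state$P > 0) state$P * exp(log_fitness_plant(state, params)) else 0
  X_new <- params$rX * state$P +
    state$X * exp(-(a1 * state$N1 + a2 * state$N2))
  N1_new <- if (state$N1 > 0) {
    state$N1 * exp(log_fitness_pollinator(1L, state, params))
  } else 0
  N2_new <- if (state$N2 > 0) {
    state$N2 * exp(log_fitness_pollinator(2L, state, params))
  } else 0
  c(P = P_new, X = X_new, N1 = N1_new, N2 = N2_new)
}

#' Selection gradients of the plant traits
#'
#' Analytic derivative of the plant's per-capita log fitness with respect
#' to each plant trait:
#' \deqn{\partial \log W_P / \partial u_i =
#'   -r_P P f_{Pi} / b_P^2 +
#'   \theta_{Pi} N_i d_i / ((v_i + d_i u_i + 1)(a_{0i} + P)).}
#' The first term is the marginal carrying-capacity cost, the second the
#' marginal attraction benefit, which scales with the abundance of the
#' associated pollinator.
#'
#' @inheritParams log_fitness_plant
#' @return Named numeric vector `c(u1, u2)` of gradients.
#' @export
plant_selection_gradient <- function(state, params) {
  caps <- carrying_capacities(state, params)
  if (caps[["bP"]] <= 0) stop_degenerate("bP", caps[["bP"]])
  bP2 <- caps[["bP"]]^2
  g1 <- -params$rP * state$P * params$fP1 / bP2 +
    params$thetaP1 * state$N1 * params$d1 /
      ((state$v1 + params$d1 * state$u1 + 1) * (params$a01 + state$P))
  g2 <- -params$rP * state$P * params$fP2 / bP2 +
    params$thetaP2 * state$N2 * params$d2 /
      ((state$v2 + params$d2 * state$u2 + 1) * (params$a02 + state$P))
  c(u1 = g1, u2 = g2)
}

#' Selection gradients of the pollinator traits
#'
#' Analytic derivative of each pollinator's per-capita log fitness with
#' respect to its own trait:
#' \deqn{\partial \log W_{Ni} / \partial v_i =
#'   -r_i (N_i + c_i N_j) f_i / b_i^2 +
#'   \theta_i X / ((v_i + d_i u_i + 1)(a_{0i} + P)).}
#'
#' @inheritParams log_fitness_plant
#' @return Named numeric vector `c(v1, v2)` of gradients.
#' @export
pollinator_selection_gradient <- function(state, params) {
  caps <- carrying_capacities(state, params)
  if (caps[["b1"]] <= 0) stop_degenerate("b1", caps[["b1"]])
  if (caps[["b2"]] <= 0) stop_degenerate("b2", caps[["b2"]])
  g1 <- -params$r1 * (state$N1 + params$c1 * state$N2) * params$f1 /
    caps[["b1"]]^2 +
    params$theta1 * state$X /
      ((state$v1 + params$d1 * state$u1 + 1) * (params$a01 + state$P))
  g2 <- -params$r2 * (state$N2 + params$c2 * state$N1) * params$f2 /
    caps[["b2"]]^2 +
    params$theta2 * state$X /
      ((state$v2 + params$d2 * state$u2 + 1) * (params$a02 + state$P))
  c(v1 = g1, v2 = g2)
}

# Keep carrying capacities strictly positive after a trait update.
# Each trait is clamped to [0, (k - eps)/f]; the two plant traits share kP,
# so if the joint cost still exceeds kP - eps both are scaled back
# proportionally.
CAP_EPS <- 1e-6

clamp_pollinator_trait <- function(v, k, f) {
  v <- max(v, 0)
  if (f > 0) v <- min(v, (k - CAP_EPS) / f)
  v
}

clamp_plant_traits <- function(u1, u2, params) {
  u1 <- max(u1, 0)
  u2 <- max(u2, 0)
  if (params$fP1 > 0) u1 <- min(u1, (params$kP - CAP_EPS) / params$fP1)
  if (params$fP2 > 0) u2 <- min(u2, (params$kP - CAP_EPS) / params$fP2)
  cost <- params$fP1 * u1 + params$fP2 * u2
  if (cost > params$kP - CAP_EPS) {
    scale <- (params$kP - CAP_EPS) / cost
    u1 <- u1 * scale
    u2 <- u2 * scale
  }
  c(u1 = u1, u2 = u2)
}

#' Quantitative-genetics update of the plant traits
#'
#' One step of trait evolution: each plant trait moves by its genetic
#' variance times the selection gradient of log fitness,
#' `u_i' = u_i + sigmaPi_sq * d log W_P / d u_i`, then is clamped so traits
#' stay nonnegative and the plant carrying capacity stays positive.
#'
#' @inheritParams log_fitness_plant
#' @return Named numeric vector `c(u1, u2)` of next-step trait values.
#' @export
plant_trait_update <- function(state, params) {
  g <- plant_selection_gradient(state, params)
  clamp_plant_traits(state$u1 + params$sigmaP1_sq * g[["u1"]],
                     state$u2 + params$sigmaP2_sq * g[["u2"]],
                     params)
}

#' Quantitative-genetics update of the pollinator traits
#'
#' One step of trait evolution for both pollinators:
#' `v_i' = v_i + sigmai_sq * d log W_Ni / d v_i`, clamped to keep each
#' pollinator's carrying capacity positive.
#'
#' @inheritParams log_fitness_plant
#' @return Named numeric vector `c(v1, v2)` of next-step trait values.
#' @export
pollinator_trait_update <- function(state, params) {
  g <- pollinator_selection_gradient(state, params)
  c(v1 = clamp_pollinator_trait(state$v1 + params$sigma1_sq * g[["v1"]],
                                params$k1, params$f1),
    v2 = clamp_pollinator_trait(state$v2 + params$sigma2_sq * g[["v2"]],
                                params$k2, params$f2))
}

#' One full synchronous model step
#'
#' Composes the ecological map with the trait updates: all eight time-t+1
#' quantities are computed from the time-t state (abundances in the trait
#' updates are the pre-step abundances). Traits whose evolution switch is
#' off are carried over unchanged.
#'
#' @inheritParams log_fitness_plant
#' @param flags A [bv_flags()] object.
#' @return A [bv_state()] at `t + 1`.
#' @examples
#' s <- bv_state(P = 0.05, X = 0, N1 = 0.05, N2 = 0,
#'               u1 = 0.005, u2 = 0, v1 = 0.005, v2 = 0)
#' bv_step(s, bv_params(), bv_flags())
#' @export
bv_step <- function(state, params, flags = bv_flags()) {
  eco <- step_ecology(state, params)
  if (flags$plant_evolves) {
    u <- plant_trait_update(state, params)
  } else {
    u <- c(u1 = state$u1, u2 = state$u2)
  }
  if (flags$pollinators_evolve) {
    v <- pollinator_trait_update(state, params)
  } else {
    v <- c(v1 = state$v1, v2 = state$v2)
  }
  bv_state(P = eco[["P"]], X = eco[["X"]], N1 = eco[["N1"]], N2 = eco[["N2"]],
           u1 = u[["u1"]], u2 = u[["u2"]], v1 = v[["v1"]], v2 = v[["v2"]],
           t = state$t + 1L)
}
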