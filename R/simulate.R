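#' Run the model forward to equilibrium or a step budget
#'
#' Iterates the full synchronous step (ecology + trait evolution) from an
#' initial state until (i) the system is numerically at equilibrium, (ii)
#' the step budget is exhausted, or (iii) an abundance exceeds the runaway
#' guard, whichever comes first.
#'
#' Equilibrium is declared when the largest relative change of any of the
#' eight state variables across a trailing window of `eq_window` steps falls
#' below `eq_tol` (relative to the current magnitude, floored at 1e-9 so
#' variables decaying to zero can converge). Runs that hit the runaway
#' guard are labelled `"unbounded"`.
#'
#' @param initial A [bv_state()] starting state.
#' @param params A [bv_params()].
#' @param flags A [bv_flags()]; defaults to full eco-evolutionary dynamics.
#' @param max_steps Step budget (default 200000).
#' @param record_stride Record every `record_stride`-th state. `NULL`
#'   (default) records every step for runs of at most 1e5 steps and every
#'   100th step for longer runs; the terminal state is always recorded
#'   exactly.
#' @param eq_window,eq_tol Equilibrium-detection window (steps) and relative
#'   tolerance. `eq_window = 0` disables early stopping.
#' @param max_abundance Runaway guard; any abundance above this aborts the
#'   run with regime `"unbounded"`.
#' @param extinction_threshold Abundance below which a species is treated as
#'   displaced when classifying the terminal state. Classification only;
#'   dynamics are never truncated.
#'
#' @return A `bv_trajectory`: a list with
#'   \item{states}{data.frame of recorded states, columns
#'     `t,P,X,N1,N2,u1,u2,v1,v2`.}
#'   \item{final}{the exact terminal [bv_state()].}
#'   \item{steps}{number of steps actually taken.}
#'   \item{converged}{logical, equilibrium reached before the budget.}
#'   \item{regime}{terminal regime label, see [classify_regime()].}
#' @examples
#' traj <- bv_simulate(bv_state(), bv_params(), max_steps = 1000)
#' traj$final
#' @export
bv_simulate <- function(initial, params, flags = bv_flags(),
                        max_steps = 200000L, record_stride = NULL,
                        eq_window = 1000L, eq_tol = 1e-10,
                        max_abundance = 1e9,
                        extinction_threshold = 1e-6) {
  stopifnot(inherits(initial, "bv_state"), inherits(params, "bv_params"))
  max_steps <- as.integer(max_steps)
  if (is.null(record_stride)) {
    record_stride <- if (max_steps <= 100000L) 1L else 100L
  }
  res <- simulate_loop_cpp(state_as_vector(initial), unclass(params),
                           flags$plant_evolves, flags$pollinators_evolve,
                           max_steps, as.integer(record_stride),
                           as.integer(eq_window), eq_tol,
                           max_abundance, initial$t)
  states <- as.data.frame(res$record)
  final <- state_from_vector(res$final, t = initial$t + as.integer(res$steps))
  regime <- classify_terminal(final, extinction_threshold, res$unbounded)
  structure(list(states = states,
                 final = final,
                 steps = as.integer(res$steps),
                 converged = res$converged,
                 unbounded = res$unbounded,
                 regime = regime,
                 extinction_threshold = extinction_threshold),
            class = "bv_trajectory")
}

#' @export
print.bv_trajectory <- function(x, ...) {
  cat("<bv_trajectory>", x$steps, "steps;",
      if (x$converged) "converged" else "not converged",
      "; regime:", x$regime, "\n")
  cat("terminal state:\n")
  print(x$final)
  invisible(x)
}

#' @export
as.data.frame.bv_trajectory <- function(x, ...) x$states

classify_terminal <- function(final, threshold, unbounded) {
  if (isTRUE(unbounded)) return("unbounded")
  if (final$P < threshold) return("collapse")
  wild <- final$N1 >= threshold
  bee <- final$N2 >= threshold
  if (wild && bee) "coexistence"
  else if (wild) "wild_only"
  else if (bee) "honeybee_only"
  else "plant_only"
}

#' Classify the terminal regime of a trajectory
#'
#' Applies the extinction threshold to the exact terminal state: a species
#' with terminal abundance below the threshold counts as displaced. Labels:
#' `coexistence` (plant and both pollinators persist), `wild_only`,
#' `honeybee_only`, `plant_only`, `collapse` (plant below threshold), and
#' `unbounded` (run aborted at the runaway guard).
#'
#' @param trajectory A `bv_trajectory` from [bv_simulate()].
#' @param extinction_threshold Optional override of the trajectory's own
#'   threshold.
#' @return A single regime string.
#' @export
classify_regime <- function(trajectory, extinction_threshold = NULL) {
  stopifnot(inherits(trajectory, "bv_trajectory"))
  thr <- extinction_threshold %||% trajectory$extinction_threshold
  classify_terminal(trajectory$final, thr, trajectory$unbounded)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation protocol for honey bee introduction experiments
#'
#' Bundles the two-phase protocol settings: a burn-in phase in which only
#' the plant and the wild pollinator are present and coevolve to their
#' two-species eco-evolutionary equilibrium, followed by introduction of
#' the managed honey bee and a post-introduction phase.
#'
#' Defaults follow the package's standard protocol: the resident community
#' starts at abundance 0.05 with wild-mutualism traits double the honey
#' bee's introduction traits; the honey bee enters at the wild pollinator's
#' current abundance with trait values 0.001.
#'
#' @param burn_in_steps Steps of the two-species phase (default 200000).
#' @param post_steps Steps after introduction (default 800000).
#' @param intro_abundance_mode `"match_wild"` (honey bee enters at the wild
#'   pollinator's burn-in abundance) or `"fixed"`.
#' @param intro_abundance_value Introduction abundance when mode is
#'   `"fixed"`.
#' @param intro_trait_v2,intro_trait_u2 Honey bee trait and matching plant
#'   trait at introduction (default 0.001 each).
#' @param initial_state Phase-1 starting [bv_state()]; default abundances
#'   0.05 for plant and wild pollinator, rewards 0, traits
#'   `u1 = v1 = 2 * intro_trait` and `u2 = v2 = 0`.
#' @param flags A [bv_flags()] applied after introduction. The burn-in
#'   always runs with full evolution; `plant_evolves = FALSE` freezes the
#'   plant traits at their burn-in equilibrium values for phase 2.
#' @param max_abundance,eq_window,eq_tol,extinction_threshold Passed to
#'   [bv_simulate()].
#' @return A `bv_protocol` object.
#' @export
bv_protocol <- function(burn_in_steps = 200000L, post_steps = 800000L,
                        intro_abundance_mode = c("match_wild", "fixed"),
                        intro_abundance_value = NULL,
                        intro_trait_v2 = 0.001, intro_trait_u2 = 0.001,
                        initial_state = NULL,
                        flags = bv_flags(),
                        max_abundance = 1e9,
                        eq_window = 1000L, eq_tol = 1e-10,
                        extinction_threshold = 1e-6) {
  intro_abundance_mode <- match.arg(intro_abundance_mode)
  if (intro_abundance_mode == "fixed" && is.null(intro_abundance_value)) {
    stop("intro_abundance_mode = \"fixed\" requires intro_abundance_value",
         call. = FALSE)
  }
  stopifnot(burn_in_steps > 0, post_steps > 0,
            extinction_threshold > 0, eq_tol > 0)
  if (is.null(initial_state)) {
    initial_state <- bv_state(P = 0.05, X = 0, N1 = 0.05, N2 = 0,
                              u1 = 2 * intro_trait_u2, u2 = 0,
                              v1 = 2 * intro_trait_v2, v2 = 0)
  }
  structure(list(burn_in_steps = as.integer(burn_in_steps),
                 post_steps = as.integer(post_steps),
                 intro_abundance_mode = intro_abundance_mode,
                 intro_abundance_value = intro_abundance_value,
                 intro_trait_v2 = intro_trait_v2,
                 intro_trait_u2 = intro_trait_u2,
                 initial_state = initial_state,
                 flags = flags,
                 max_abundance = max_abundance,
                 eq_window = as.integer(eq_window),
                 eq_tol = eq_tol,
                 extinction_threshold = extinction_threshold),
            class = "bv_protocol")
}

#' Burn-in / invasion experiment
#'
#' Runs the two-phase introduction protocol: phase 1 iterates the resident
#' plant--wild pollinator system (honey bee absent, full evolution) for the
#' burn-in budget or until its eco-evolutionary equilibrium; then the
#' managed honey bee is introduced by setting `N2`, `v2` and `u2` per the
#' protocol, and phase 2 runs the three-species system under the protocol's
#' evolution flags.
#'
#' The first state of phase 2 differs from the last state of phase 1 only
#' in `N2`, `v2` and `u2`.
#'
#' @param protocol A [bv_protocol()].
#' @param params A [bv_params()].
#' @return A list with elements `burn_in` and `post`, both `bv_trajectory`
#'   objects, plus `introduction_state`, the phase-2 initial [bv_state()].
#' @examples
#' \donttest{
#' pr <- bv_protocol(burn_in_steps = 20000, post_steps = 50000)
#' inv <- bv_invasion(pr, bv_params(c1 = 1))
#' inv$post$regime
#' }
#' @export
bv_invasion <- function(protocol, params) {
  stopifnot(inherits(protocol, "bv_protocol"), inherits(params, "bv_params"))
  burn <- bv_simulate(protocol$initial_state, params,
                      flags = bv_flags(TRUE, TRUE),
                      max_steps = protocol$burn_in_steps,
                      eq_window = protocol$eq_window,
                      eq_tol = protocol$eq_tol,
                      max_abundance = protocol$max_abundance,
                      extinction_threshold = protocol$extinction_threshold)
  eq <- burn$final
  N2_intro <- switch(protocol$intro_abundance_mode,
                     match_wild = eq$N1,
                     fixed = protocol$intro_abundance_value)
  intro <- bv_state(P = eq$P, X = eq$X, N1 = eq$N1, N2 = N2_intro,
                    u1 = eq$u1, u2 = protocol$intro_trait_u2,
                    v1 = eq$v1, v2 = protocol$intro_trait_v2,
                    t = eq$t, params = params)
  post <- bv_simulate(intro, params,
                      flags = protocol$flags,
                      max_steps = protocol$post_steps,
                      eq_window = protocol$eq_window,
                      eq_tol = protocol$eq_tol,
                      max_abundance = protocol$max_abundance,
                      extinction_threshold = protocol$extinction_threshold)
  list(burn_in = burn, post = post, introduction_state = intro)
}
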