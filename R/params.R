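#' Model parameters for the plant--pollinator--honey bee mutualism model
#'
#' Builds the full 26-scalar parameter set of the discrete-time mutualism
#' model. The defaults are the standard values used throughout the package's
#' simulations; any subset can be overridden by name.
#'
#' The model couples a plant (abundance \eqn{P}), its standing pool of
#' pollination rewards (\eqn{X}, nectar/pollen), a wild pollinator
#' (\eqn{N_1}) and a managed honey bee (\eqn{N_2}). Pollinator \eqn{i} visits
#' the plant at per-capita rate
#' \deqn{a_i = \log(v_i + d_i u_i + 1) / (a_{0i} + P),}
#' increasing with the pollinator's own investment trait \eqn{v_i} and the
#' plant's matching attraction trait \eqn{u_i}, and saturating with plant
#' density. Each trait linearly depresses its bearer's carrying capacity
#' (\eqn{b_P = k_P - f_{P1} u_1 - f_{P2} u_2}, \eqn{b_i = k_i - f_i v_i}),
#' which is the cost that keeps selection from running away.
#'
#' @param r1,r2,rP Intrinsic growth rates (per step) of wild pollinator,
#'   honey bee, and plant.
#' @param rX Reward production rate per plant per step.
#' @param c1 Per-capita competitive effect of the honey bee on the wild
#'   pollinator.
#' @param c2 Per-capita competitive effect of the wild pollinator on the
#'   honey bee.
#' @param f1,f2 Carrying-capacity cost per unit trait for the wild
#'   pollinator and honey bee.
#' @param fP1,fP2 Carrying-capacity cost per unit of each plant trait.
#' @param sigma1_sq,sigma2_sq Genetic variances of the two pollinator
#'   traits (speed of the evolutionary response).
#' @param sigmaP1_sq,sigmaP2_sq Genetic variances of the two plant traits.
#' @param k1,k2,kP Zero-trait carrying capacities.
#' @param d1,d2 Scaling of the plant trait relative to the pollinator trait
#'   inside the visitation rate.
#' @param theta1,theta2 Per-visit reward benefit to each pollinator.
#' @param thetaP1,thetaP2 Per-visit pollination benefit to the plant from
#'   each pollinator.
#' @param a01,a02 Visitation half-saturation constants (plant density at
#'   which per-plant visitation halves).
#' @param sigma_is One of `"variance"` (default) or `"sd"`. The standard
#'   value 0.05 tabulated for the genetic-variance symbols is ambiguous
#'   between the variance itself and its square root; `"variance"` feeds
#'   0.05 straight into the trait updates, `"sd"` squares the four sigma
#'   fields first.
#' @param ... Unused; present so misspelled parameter names are caught.
#'
#' @return An object of class `bv_params`: a named list of the 26 scalars
#'   (with the sigma fields already on the variance scale).
#'
#' @examples
#' p <- bv_params()                # standard values
#' p2 <- bv_params(c1 = 1.0)      # honey bee outcompetes the wild pollinator
#' @export
bv_params <- function(r1 = 0.01, r2 = 0.01, rP = 0.01, rX = 0.5,
                      c1 = 0.75, c2 = 0.75,
                      f1 = 0.5, f2 = 0.5, fP1 = 0.2, fP2 = 0.2,
                      sigma1_sq = 0.05, sigma2_sq = 0.05,
                      sigmaP1_sq = 0.05, sigmaP2_sq = 0.05,
                      k1 = 1.5, k2 = 1.5, kP = 0.5,
                      d1 = 0.8, d2 = 0.8,
                      theta1 = 0.05, theta2 = 0.05,
                      thetaP1 = 0.5, thetaP2 = 0.25,
                      a01 = 0.5, a02 = 0.5,
                      sigma_is = c("variance", "sd"), ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown parameter name(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  }
  sigma_is <- match.arg(sigma_is)
  p <- list(r1 = r1, r2 = r2, rP = rP, rX = rX,
            c1 = c1, c2 = c2,
            f1 = f1, f2 = f2, fP1 = fP1, fP2 = fP2,
            sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
            sigmaP1_sq = sigmaP1_sq, sigmaP2_sq = sigmaP2_sq,
            k1 = k1, k2 = k2, kP = kP,
            d1 = d1, d2 = d2,
            theta1 = theta1, theta2 = theta2,
            thetaP1 = thetaP1, thetaP2 = thetaP2,
            a01 = a01, a02 = a02)
  if (sigma_is == "sd") {
    for (nm in c("sigma1_sq", "sigma2_sq", "sigmaP1_sq", "sigmaP2_sq")) {
      p[[nm]] <- p[[nm]]^2
    }
  }
  validate_bv_params(p)
  structure(p, class = "bv_params")
}

validate_bv_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("parameter '", nm, "' must be >= 0", call. = FALSE)
  }
  for (nm in c("k1", "k2", "kP", "a01", "a02")) {
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be > 0", call. = FALSE)
  }
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params A [bv_params()] object.
#' @param ... Named scalar replacements, e.g. `c1 = 1`.
#' @return A `bv_params` object.
#' @export
bv_params_update <- function(params, ...) {
  stopifnot(inherits(params, "bv_params"))
  repl <- list(...)
  if (length(repl) == 0) return(params)
  bad <- setdiff(names(repl), names(params))
  if (length(bad) > 0) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_bv_params(p)
  structure(p, class = "bv_params")
}

#' @export
print.bv_params <- function(x, ...) {
  cat("<bv_params> mutualism model parameters\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}

#' System state of the mutualism model at one time step
#'
#' @param P,X Plant and reward abundances.
#' @param N1,N2 Wild pollinator and managed honey bee abundances.
#' @param u1,u2 Plant traits attracting the wild pollinator and honey bee.
#' @param v1,v2 Wild pollinator and honey bee investment traits.
#' @param t Integer step index (>= 0).
#' @param params Optional [bv_params()]; when supplied the derived carrying
#'   capacities are checked to be positive.
#'
#' @return An object of class `bv_state`: a named list with fields
#'   `t, P, X, N1, N2, u1, u2, v1, v2`.
#' @examples
#' s <- bv_state(P = 0.05, X = 0, N1 = 0.05, N2 = 0,
#'               u1 = 0.005, u2 = 0, v1 = 0.005, v2 = 0)
#' @export
bv_state <- function(P = 0.05, X = 0, N1 = 0.05, N2 = 0.05,
                     u1 = 0.005, u2 = 0.005, v1 = 0.005, v2 = 0.005,
                     t = 0L, params = NULL) {
  s <- list(t = as.integer(t), P = P, X = X, N1 = N1, N2 = N2,
            u1 = u1, u2 = u2, v1 = v1, v2 = v2)
  for (nm in c("P", "X", "N1", "N2", "u1", "u2", "v1", "v2")) {
    v <- s[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("state field '", nm, "' must be a single finite number >= 0",
           call. = FALSE)
    }
  }
  if (s$t < 0) stop("t must be >= 0", call. = FALSE)
  if (!is.null(params)) {
    caps <- carrying_capacities(s, params)
    if (any(caps <= 0)) {
      stop("derived carrying capacities must stay positive; got bP = ",
           signif(caps[["bP"]], 6), ", b1 = ", signif(caps[["b1"]], 6),
           ", b2 = ", signif(caps[["b2"]], 6), call. = FALSE)
    }
  }
  structure(s, class = "bv_state")
}

#' Trait-dependent carrying capacities
#'
#' Computes `bP = kP - fP1*u1 - fP2*u2`, `b1 = k1 - f1*v1`,
#' `b2 = k2 - f2*v2` for a state.
#'
#' @param state A [bv_state()] (or any list with fields u1, u2, v1, v2).
#' @param params A [bv_params()].
#' @return Named numeric vector `c(bP, b1, b2)`.
#' @export
carrying_capacities <- function(state, params) {
  c(bP = params$kP - params$fP1 * state$u1 - params$fP2 * state$u2,
    b1 = params$k1 - params$f1 * state$v1,
    b2 = params$k2 - params$f2 * state$v2)
}

#' @export
print.bv_state <- function(x, ...) {
  cat("<bv_state> t =", x$t, "\n")
  print(unlist(x[c("P", "X", "N1", "N2", "u1", "u2", "v1", "v2")]))
  invisible(x)
}

#' Evolution switches
#'
#' Independent on/off switches for plant and pollinator trait evolution.
#' With both `TRUE` the full eco-evolutionary model runs; freezing the plant
#' traits (`plant_evolves = FALSE`) reproduces the fixed-plant-trait
#' analyses, in which the pollinators keep evolving by default.
#'
#' @param plant_evolves Logical; update the plant traits u1, u2 each step?
#' @param pollinators_evolve Logical; update the pollinator traits v1, v2?
#' @return An object of class `bv_flags`.
#' @export
bv_flags <- function(plant_evolves = TRUE, pollinators_evolve = TRUE) {
  stopifnot(is.logical(plant_evolves), length(plant_evolves) == 1L,
            is.logical(pollinators_evolve), length(pollinators_evolve) == 1L)
  structure(list(plant_evolves = plant_evolves,
                 pollinators_evolve = pollinators_evolve),
            class = "bv_flags")
}

state_as_vector <- function(state) {
  unlist(state[c("P", "X", "N1", "N2", "u1", "u2", "v1", "v2")])
}

state_from_vector <- function(x, t = 0L) {
  bv_state(P = x[[1]], X = x[[2]], N1 = x[[3]], N2 = x[[4]],
           u1 = x[[5]], u2 = x[[6]], v1 = x[[7]], v2 = x[[8]], t = t)
}
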