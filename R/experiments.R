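#' Named scenario presets
#'
#' Returns the parameter overrides, introduction protocol and default sweep
#' for each of the package's canonical experiment designs:
#'
#' \describe{
#'   \item{`fig2a`, `fig2b`, `fig2c`}{Simultaneous-introduction sweeps under
#'     standard parameters: all three species start at abundance 0.05 with
#'     trait value 0.005, the honey bee entering after 2,000 steps, 200,000
#'     steps in total. Swept parameter: `c1` over `[0.25*c2, 2*c2]`, `k2`
#'     over `[0.5*k1, 2*k1]`, `theta2` over `[0.5*theta1, 4*theta1]`.}
#'   \item{`fig3a`, `fig3b`}{As above but with no direct competition
#'     between the pollinators (`c1 = c2 = 0`); `k2` and `theta2` sweeps.}
#'   \item{`fig4_s1`, `fig4_s2`, `fig4_s3`}{Honey-bee trait-cost (`f2`)
#'     sweeps in three displacement scenarios: (1) stronger per-capita
#'     competition on the wild pollinator (`c1 = 0.95`, `c2 = 0.75`; the
#'     variant `fig4_s1_text` uses `c1 = 1`), (2) higher honey bee carrying
#'     capacity (`k2 = 1.75`), (3) higher honey bee per-visit benefit
#'     (`theta1 = 0.005`, `theta2 = 0.075`).}
#'   \item{`fig5_s1`, `fig5_s2`, `fig5_s3`}{The same three scenarios
#'     sweeping the plant-side trait cost `fP2`.}
#' }
#'
#' @param name Preset name (see above).
#' @param params Base [bv_params()] onto which the scenario overrides are
#'   applied.
#' @return A list with elements `params` (scenario parameter set),
#'   `protocol` (a [bv_protocol()]), `sweep_param` and `sweep_range`.
#' @export
bv_preset <- function(name, params = bv_params()) {
  stopifnot(inherits(params, "bv_params"))
  known <- c("fig2a", "fig2b", "fig2c", "fig3a", "fig3b",
             "fig4_s1", "fig4_s1_text", "fig4_s2", "fig4_s3",
             "fig5_s1", "fig5_s1_text", "fig5_s2", "fig5_s3")
  if (!name %in% known) {
    stop("unknown preset '", name, "'; known presets: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  p <- params
  if (name %in% c("fig3a", "fig3b")) p <- bv_params_update(p, c1 = 0, c2 = 0)
  if (name %in% c("fig4_s1", "fig5_s1")) {
    p <- bv_params_update(p, c1 = 0.95, c2 = 0.75)
  }
  if (name %in% c("fig4_s1_text", "fig5_s1_text")) {
    p <- bv_params_update(p, c1 = 1, c2 = 0.75)
  }
  if (name %in% c("fig4_s2", "fig5_s2")) {
    p <- bv_params_update(p, k1 = 1.5, k2 = 1.75)
  }
  if (name %in% c("fig4_s3", "fig5_s3")) {
    p <- bv_params_update(p, theta1 = 0.005, theta2 = 0.075)
  }
  sweep_param <- switch(name,
                        fig2a = "c1", fig2b = "k2", fig2c = "theta2",
                        fig3a = "k2", fig3b = "theta2",
                        fig4_s1 = , fig4_s1_text = , fig4_s2 = ,
                        fig4_s3 = "f2",
                        fig5_s1 = , fig5_s1_text = , fig5_s2 = ,
                        fig5_s3 = "fP2")
  sweep_range <- switch(sweep_param,
                        c1 = c(0.25 * p$c2, 2 * p$c2),
                        k2 = c(0.5 * p$k1, 2 * p$k1),
                        theta2 = c(0.5 * p$theta1, 4 * p$theta1),
                        f2 = c(0.25 * p$f1, 4 * p$f1),
                        fP2 = c(0.25 * p$fP1, 10 * p$fP1))
  list(params = p,
       protocol = simultaneous_intro_protocol(),
       sweep_param = sweep_param,
       sweep_range = sweep_range,
       name = name)
}

# Standard sweep protocol: plant and wild pollinator start at abundance
# 0.05 with traits 0.005; honey bee enters after 2,000 steps at abundance
# 0.05 and trait 0.005; 200,000 steps in total.
simultaneous_intro_protocol <- function(total_steps = 200000L,
                                        intro_step = 2000L,
                                        abundance = 0.05, trait = 0.005) {
  bv_protocol(burn_in_steps = intro_step,
              post_steps = total_steps - intro_step,
              intro_abundance_mode = "fixed",
              intro_abundance_value = abundance,
              intro_trait_v2 = trait, intro_trait_u2 = trait,
              initial_state = bv_state(P = abundance, X = 0,
                                       N1 = abundance, N2 = 0,
                                       u1 = trait, u2 = 0,
                                       v1 = trait, v2 = 0))
}

#' Parameter sweep over independent full simulations
#'
#' Runs the two-phase introduction protocol once per grid value of a single
#' parameter, each run starting from the same initial protocol (no
#' continuation between neighbouring grid points, so no hysteresis
#' tracking), and summarises each terminal equilibrium.
#'
#' @param param Name of the swept parameter: one of `c1`, `k2`, `theta2`,
#'   `f2`, `fP2` (any [bv_params()] field is accepted).
#' @param values Explicit grid (strictly monotone). If `NULL`, an evenly
#'   spaced grid of `n` points over `range` is used.
#' @param range Length-2 numeric range for the implicit grid; defaults to
#'   the preset's standard range.
#' @param n Number of grid points (default 41).
#' @param preset A [bv_preset()] name or the list it returns; fixes the
#'   non-swept parameters and the protocol.
#' @param params Base parameters passed to [bv_preset()].
#' @param protocol Optional [bv_protocol()] overriding the preset's.
#' @return A data.frame of class `bv_sweep`, one row per grid value:
#'   `param`, `value`, terminal `P,X,N1,N2,u1,u2,v1,v2`, `regime`,
#'   `converged`, `steps`.
#' @examples
#' \donttest{
#' sw <- bv_sweep("c1", n = 5, preset = "fig2a")
#' sw[, c("value", "N1", "N2", "regime")]
#' }
#' @export
bv_sweep <- function(param, values = NULL, range = NULL, n = 41L,
                     preset = "fig2a", params = bv_params(),
                     protocol = NULL) {
  ps <- if (is.character(preset)) bv_preset(preset, params) else preset
  base <- ps$params
  if (!param %in% names(base)) {
    stop("unknown sweep parameter '", param, "'", call. = FALSE)
  }
  if (is.null(values)) {
    if (is.null(range)) {
      if (param != ps$sweep_param) {
        stop("no default range for parameter '", param,
             "' under preset '", ps$name, "'; supply `values` or `range`",
             call. = FALSE)
      }
      range <- ps$sweep_range
    }
    values <- seq(range[1], range[2], length.out = n)
  }
  if (length(values) == 0) stop("empty sweep grid", call. = FALSE)
  if (length(values) > 1 && any(diff(values) <= 0) && any(diff(values) >= 0)) {
    if (!(all(diff(values) > 0) || all(diff(values) < 0))) {
      stop("sweep grid must be strictly monotone", call. = FALSE)
    }
  }
  proto <- protocol %||% ps$protocol
  rows <- lapply(values, function(val) {
    pv <- do.call(bv_params_update,
                  c(list(base), stats::setNames(list(val), param)))
    inv <- bv_invasion(proto, pv)
    fin <- inv$post$final
    data.frame(param = param, value = val,
               P = fin$P, X = fin$X, N1 = fin$N1, N2 = fin$N2,
               u1 = fin$u1, u2 = fin$u2, v1 = fin$v1, v2 = fin$v2,
               regime = inv$post$regime,
               converged = inv$post$converged,
               steps = inv$post$steps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bv_sweep", "data.frame")
  out
}

#' Bisection search for a regime boundary along one parameter
#'
#' Locates the critical value of a parameter at which the terminal regime
#' of the introduction protocol changes (for example the competition
#' strength at which pollinator coexistence gives way to wild-pollinator
#' exclusion). The endpoint regimes must differ; the boundary is refined by
#' bisection on the regime label and reported as the midpoint of the final
#' bracket.
#'
#' @inheritParams bv_sweep
#' @param lo,hi Initial bracket (regimes must differ at the two ends).
#' @param tol Bracket width at which bisection stops (parameter units).
#' @param transition Optional length-2 character vector of expected regimes
#'   at `lo` and `hi`; an error is raised if the endpoints disagree with it.
#' @return A list: `critical` (bracket midpoint), `bracket` (`c(lo, hi)`
#'   final bracket), `regimes` (labels at the bracket ends), `evaluations`
#'   (number of full simulations run).
#' @examples
#' \donttest{
#' thr <- bv_find_threshold("c1", lo = 0.8, hi = 1.2, tol = 0.01,
#'                          preset = "fig2a")
#' thr$critical
#' }
#' @export
bv_find_threshold <- function(param, lo, hi, tol = 1e-3,
                              preset = "fig2a", params = bv_params(),
                              protocol = NULL, transition = NULL) {
  stopifnot(lo < hi, tol > 0)
  ps <- if (is.character(preset)) bv_preset(preset, params) else preset
  proto <- protocol %||% ps$protocol
  regime_at <- function(val) {
    pv <- do.call(bv_params_update,
                  c(list(ps$params), stats::setNames(list(val), param)))
    bv_invasion(proto, pv)$post$regime
  }
  r_lo <- regime_at(lo)
  r_hi <- regime_at(hi)
  n_eval <- 2L
  if (r_lo == r_hi) {
    stop("no regime transition in bracket: regime is '", r_lo,
         "' at both ", lo, " and ", hi, call. = FALSE)
  }
  if (!is.null(transition)) {
    if (!identical(c(r_lo, r_hi), as.character(transition))) {
      stop("bracket regimes (", r_lo, ", ", r_hi,
           ") do not match the requested transition (",
           paste(transition, collapse = ", "), ")", call. = FALSE)
    }
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r_mid <- regime_at(mid)
    n_eval <- n_eval + 1L
    if (r_mid == r_lo) lo <- mid else hi <- mid
  }
  list(critical = (lo + hi) / 2,
       bracket = c(lo, hi),
       regimes = c(lo = r_lo, hi = r_hi),
       evaluations = n_eval)
}

#' Run a full figure-style experiment bundle
#'
#' Batch driver reproducing the package's canonical experiment designs and
#' writing their outputs (trajectory/sweep CSVs plus a JSON manifest) to a
#' directory:
#' \describe{
#'   \item{1}{Two invasion time series under strong competition
#'     (`c1 = 1`, `c2 = 0.75`): plant evolution on vs. plant traits frozen
#'     at the burn-in equilibrium.}
#'   \item{2}{Three sweeps (`c1`, `k2`, `theta2`) under standard
#'     parameters.}
#'   \item{3}{`k2` and `theta2` sweeps without direct competition.}
#'   \item{4}{`f2` sweeps for displacement scenarios 1--3.}
#'   \item{5}{`fP2` sweeps for displacement scenarios 1--3.}
#' }
#'
#' @param id Figure id, 1--5.
#' @param out_dir Output directory (created if missing).
#' @param params Base [bv_params()].
#' @param n Grid points per sweep.
#' @return Invisibly, the manifest (named list of written files).
#' @export
bv_run_figure <- function(id, out_dir, params = bv_params(), n = 41L) {
  if (!id %in% 1:5) stop("unknown figure id ", id, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  if (id == 1) {
    p <- bv_params_update(params, c1 = 1, c2 = 0.75)
    for (mode in c("plant_evolution", "fixed_plant_traits")) {
      proto <- bv_protocol(flags = bv_flags(
        plant_evolves = (mode == "plant_evolution"),
        pollinators_evolve = TRUE))
      inv <- bv_invasion(proto, p)
      f <- file.path(out_dir, paste0("fig1_", mode, ".csv"))
      write_trajectory_csv(inv$post, f)
      files[[paste0("fig1_", mode)]] <- f
    }
  } else if (id == 2) {
    for (pre in c("fig2a", "fig2b", "fig2c")) {
      ps <- bv_preset(pre, params)
      sw <- bv_sweep(ps$sweep_param, preset = ps, n = n)
      f <- file.path(out_dir, paste0(pre, "_sweep.csv"))
      write_sweep_csv(sw, f)
      files[[pre]] <- f
    }
  } else if (id == 3) {
    for (pre in c("fig3a", "fig3b")) {
      ps <- bv_preset(pre, params)
      sw <- bv_sweep(ps$sweep_param, preset = ps, n = n)
      f <- file.path(out_dir, paste0(pre, "_sweep.csv"))
      write_sweep_csv(sw, f)
      files[[pre]] <- f
    }
  } else {
    presets <- if (id == 4) c("fig4_s1", "fig4_s2", "fig4_s3")
               else c("fig5_s1", "fig5_s2", "fig5_s3")
    for (pre in presets) {
      ps <- bv_preset(pre, params)
      sw <- bv_sweep(ps$sweep_param, preset = ps, n = n)
      f <- file.path(out_dir, paste0(pre, "_sweep.csv"))
      write_sweep_csv(sw, f)
      files[[pre]] <- f
    }
  }
  manifest <- write_manifest(files, out_dir,
                             command = paste0("figures --id ", id))
  invisible(manifest)
}
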