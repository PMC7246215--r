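#' Load a run configuration from JSON or YAML
#'
#' Reads a configuration file with an optional `params` block (fields of
#' [bv_params()]), an optional `protocol` block (arguments of
#' [bv_protocol()], with `flags` given as the two logical switches and
#' `initial_state` as a named list), and optional top-level `out_dir`.
#' Omitted keys take the standard defaults; unknown keys in any block are
#' rejected by name.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `params` ([bv_params()]), `protocol`
#'   ([bv_protocol()]), and `out_dir` (possibly `NULL`).
#' @export
bv_load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension '.", ext, "' (use .json or .yaml)",
         call. = FALSE)
  }
  if (is.null(cfg)) cfg <- list()
  known_top <- c("params", "protocol", "out_dir")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  par_block <- as.list(cfg$params %||% list())
  params <- do.call(bv_params, par_block)  # rejects unknown names itself
  proto_block <- as.list(cfg$protocol %||% list())
  known_proto <- setdiff(names(formals(bv_protocol)), "...")
  bad <- setdiff(names(proto_block), known_proto)
  if (length(bad) > 0) {
    stop("unknown protocol key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(proto_block$flags)) {
    proto_block$flags <- do.call(bv_flags, as.list(proto_block$flags))
  }
  if (!is.null(proto_block$initial_state)) {
    proto_block$initial_state <-
      do.call(bv_state, as.list(proto_block$initial_state))
  }
  protocol <- do.call(bv_protocol, proto_block)
  list(params = params, protocol = protocol, out_dir = cfg$out_dir)
}

# Numbers are written with 17 significant digits so that regression
# comparisons of output files are bit-stable.
fmt_num <- function(x) {
  vapply(x, function(xi) {
    if (is.finite(xi) && xi == round(xi) && abs(xi) < 1e15) {
      format(xi, scientific = FALSE)
    } else {
      formatC(xi, digits = 17, format = "g")
    }
  }, character(1))
}

#' Write a trajectory to CSV
#'
#' One row per recorded state, columns `t,P,X,N1,N2,u1,u2,v1,v2`, one
#' header row; numbers carry full double precision.
#'
#' @param trajectory A `bv_trajectory` from [bv_simulate()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "bv_trajectory"))
  df <- trajectory$states
  out <- df
  for (nm in setdiff(names(out), "t")) out[[nm]] <- fmt_num(df[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sweep result to CSV
#'
#' One row per grid value, in grid order, columns
#' `param_value,P,X,N1,N2,u1,u2,v1,v2,regime,converged`.
#'
#' @param sweep A `bv_sweep` from [bv_sweep()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "bv_sweep"))
  out <- data.frame(param_value = fmt_num(sweep$value))
  for (nm in c("P", "X", "N1", "N2", "u1", "u2", "v1", "v2")) {
    out[[nm]] <- fmt_num(sweep[[nm]])
  }
  out$regime <- sweep$regime
  out$converged <- sweep$converged
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a terminal summary JSON for a trajectory
#'
#' Records the regime label, convergence flag, step count and exact
#' terminal state.
#'
#' @inheritParams write_trajectory_csv
#' @export
write_summary_json <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "bv_trajectory"))
  fin <- trajectory$final
  obj <- list(regime = trajectory$regime,
              converged = trajectory$converged,
              steps = trajectory$steps,
              final = fin[c("t", "P", "X", "N1", "N2",
                            "u1", "u2", "v1", "v2")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Manifest: every produced file with the command that made it and a content
# hash, so identical configs can be checked to give identical outputs.
write_manifest <- function(files, out_dir, command) {
  entries <- lapply(names(files), function(nm) {
    f <- files[[nm]]
    list(name = nm, file = basename(f), command = command,
         md5 = unname(tools::md5sum(f)))
  })
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  c(files, manifest = path)
}
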