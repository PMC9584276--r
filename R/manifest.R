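#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the
#' operation name, its full argument record (parameters expanded), the
#' master seed, the package version and a timestamp. The manifest is the
#' JSON companion of every CLI output and can be replayed with
#' [replay_manifest()].
#'
#' @param path Output JSON path.
#' @param operation Name of the exported function that produced the run.
#' @param args Named list of arguments (S3 parameter objects are stored
#'   as plain lists).
#' @param seed Master seed of the run.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, operation, args, seed) {
  flat <- lapply(args, function(a) if (is.object(a)) unclass(a) else a)
  jsonlite::write_json(
    list(operation = operation, args = flat, seed = seed,
         package = "evoepi",
         version = as.character(utils::packageVersion("evoepi")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Replay a manifest
#'
#' Re-executes the recorded operation with the recorded arguments and
#' seed. Supported operations: `run_sir`, `run_sis` (network is
#' regenerated from the recorded generator arguments).
#'
#' @param path Manifest JSON path.
#' @return The operation's return value.
#' @export
replay_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!m$operation %in% c("run_sir", "run_sis")) {
    stop("replay supports run_sir / run_sis manifests")
  }
  a <- m$args
  net <- generate_er_network(a$network_n, a$network_kbar,
                             seed = a$network_seed)
  pars <- do.call(epi_params, a$params[c("alpha0", "beta0", "kbar", "sigma",
                                         "mutation_mode", "eta0", "psi_max",
                                         "psi_min", "t_max", "drift")])
  if (m$operation == "run_sir") {
    sch <- if (!is.null(a$t_R)) apply_mitigation(pars, a$t_R, a$R_R)
    run_sir(net, pars, seed = m$seed, schedule = sch)
  } else {
    run_sis(net, pars, seed = m$seed)
  }
}

#' Summarize a trajectory as a JSON run record
#'
#' @param trajectory An `epi_trajectory`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(trajectory, path) {
  x <- trajectory
  jsonlite::write_json(
    list(r_inf = x$r_inf, r_integral = x$r_integral,
         max_psi_seen = x$max_psi_seen,
         crossed_critical = x$crossed_critical,
         crossing_time = x$crossing_time,
         first_critical_time = x$first_critical_time,
         truncated = x$truncated, t_end = x$t_end,
         seed = x$seed, params = unclass(x$params),
         mitigation = x$mitigation),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
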