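#' Define a simulation scenario
#'
#' A scenario bundles the epidemiological parameters, the network
#' specification, the replicate count and the pandemic classification
#' threshold used by all experiment drivers.
#'
#' @param params An [epi_params()] object.
#' @param N Network size (ignored when `network` is given).
#' @param kbar Network mean degree (ignored when `network` is given).
#' @param network Optional fixed `epi_network` shared by all replicates;
#'   by default each replicate draws a fresh Erdos-Renyi network.
#' @param n_reps Number of stochastic realizations.
#' @param epsilon Final-size threshold: a realization counts as a
#'   breakthrough when its ever-infected fraction exceeds `epsilon`.
#' @param seed Master seed; replicate seeds are derived from it with
#'   [derive_seeds()].
#' @return An object of class `scenario`.
#' @export
scenario <- function(params, N = 5000, kbar = params$kbar, network = NULL,
                     n_reps = 50, epsilon = 0.2, seed = NULL) {
  stopifnot(inherits(params, "epi_params"), n_reps >= 1,
            epsilon > 0, epsilon < 1)
  if (!is.null(network)) stopifnot(inherits(network, "epi_network"))
  structure(
    list(params = params, N = as.integer(N), kbar = kbar, network = network,
         n_reps = as.integer(n_reps), epsilon = epsilon, seed = seed),
    class = "scenario"
  )
}

.scenario_run <- function(sc, rep_seeds, schedule = NULL, record_dt = 0.5) {
  lapply(seq_len(sc$n_reps), function(r) {
    s <- rep_seeds[r]
    net <- if (is.null(sc$network)) {
      generate_er_network(sc$N, sc$kbar, seed = s + 1L)
    } else sc$network
    run_sir(net, sc$params, seed = s, schedule = schedule,
            record_dt = record_dt)
  })
}

#' Estimate the breakthrough probability P of a scenario
#'
#' Runs `n_reps` independent SIR realizations and returns the fraction
#' whose final ever-infected share exceeds the scenario's `epsilon` --
#' the probability that the pathogen gains macroscopic coverage.
#'
#' @param sc A [scenario()].
#' @return Object of class `breakthrough_estimate`: list with `P`, the
#'   binomial standard error `se`, and a per-replicate data frame `reps`
#'   (seed, final size, critical-mutation times, max fitness).
#' @examples
#' sc <- scenario(epi_params(R0 = 0.25, sigma = 0, t_max = 400),
#'                N = 1000, kbar = 10, n_reps = 5, seed = 1)
#' estimate_P(sc)$P   # deeply subcritical: 0
#' @export
estimate_P <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  rep_seeds <- derive_seeds(sc$seed, sc$n_reps)
  runs <- .scenario_run(sc, rep_seeds)
  reps <- data.frame(
    rep = seq_len(sc$n_reps),
    seed = rep_seeds,
    r_inf = vapply(runs, `[[`, numeric(1), "r_inf"),
    crossed = vapply(runs, `[[`, logical(1), "crossed_critical"),
    crossing_time = vapply(runs, `[[`, numeric(1), "crossing_time"),
    first_critical_time = vapply(runs, `[[`, numeric(1),
                                 "first_critical_time"),
    max_psi = vapply(runs, `[[`, numeric(1), "max_psi_seen"),
    truncated = vapply(runs, `[[`, logical(1), "truncated")
  )
  P <- mean(reps$r_inf > sc$epsilon)
  structure(list(P = P, se = sqrt(P * (1 - P) / sc$n_reps),
                 epsilon = sc$epsilon, reps = reps),
            class = "breakthrough_estimate")
}

#' @export
print.breakthrough_estimate <- function(x, ...) {
  cat(sprintf("<breakthrough_estimate> P = %.3f (se %.3f, %d reps, epsilon %.2f)\n",
              x$P, x$se, nrow(x$reps), x$epsilon))
  invisible(x)
}

#' Scan the (sigma, R0) phase diagram
#'
#' Estimates P on a grid: for each (R0, sigma) pair the wild-type
#' infection rate is set by beta0 = alpha0 R0 / kbar and [estimate_P()]
#' is run. Theoretical boundary curves are attached for overlay.
#'
#' @param R0_values,sigma_values Grid axes (sigma is typically
#'   log-spaced).
#' @param template A [scenario()] providing every non-grid parameter.
#' @param prefactors Boundary prefactors for the attached curves.
#' @return Object of class `phase_diagram`: `grid` (long data frame with
#'   R0, sigma, P, se, mean_r_inf, n_reps) and `boundaries`.
#' @export
phase_diagram_scan <- function(R0_values, sigma_values, template,
                               prefactors = calibrated_prefactors()) {
  stopifnot(inherits(template, "scenario"),
            length(R0_values) >= 1, length(sigma_values) >= 1)
  pts <- expand.grid(R0 = R0_values, sigma = sigma_values,
                     KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- derive_seeds(template$seed, nrow(pts))
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    p0 <- template$params
    pars <- tryCatch(
      epi_params(alpha0 = p0$alpha0, R0 = pts$R0[i], kbar = template$kbar,
                 sigma = pts$sigma[i], mutation_mode = p0$mutation_mode,
                 eta0 = p0$eta0, psi_max = p0$psi_max, psi_min = p0$psi_min,
                 t_max = p0$t_max, drift = p0$drift),
      error = function(e) NULL)
    if (is.null(pars)) {
      return(data.frame(R0 = pts$R0[i], sigma = pts$sigma[i], P = NA_real_,
                        se = NA_real_, mean_r_inf = NA_real_,
                        n_reps = template$n_reps,
                        error = "invalid parameters"))
    }
    est <- tryCatch(
      estimate_P(scenario(pars, N = template$N, kbar = template$kbar,
                          network = template$network,
                          n_reps = template$n_reps,
                          epsilon = template$epsilon,
                          seed = cell_seeds[i])),
      error = function(e) NULL)
    if (is.null(est)) {
      return(data.frame(R0 = pts$R0[i], sigma = pts$sigma[i], P = NA_real_,
                        se = NA_real_, mean_r_inf = NA_real_,
                        n_reps = template$n_reps, error = "run failed"))
    }
    data.frame(R0 = pts$R0[i], sigma = pts$sigma[i], P = est$P, se = est$se,
               mean_r_inf = mean(est$reps$r_inf), n_reps = template$n_reps,
               error = NA_character_)
  })
  grid <- do.call(rbind, rows)
  sub <- R0_values[R0_values > 0 & R0_values <= 1]
  boundaries <- if (length(sub)) {
    boundary_curves(sub, alpha0 = template$params$alpha0,
                    I0 = round(template$params$eta0 * template$N),
                    psi_max = template$params$psi_max,
                    prefactors = prefactors)
  } else NULL
  structure(list(grid = grid, boundaries = boundaries,
                 prefactors = prefactors),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d grid points (R0 x sigma = %d x %d)\n",
              nrow(x$grid), length(unique(x$grid$R0)),
              length(unique(x$grid$sigma))))
  invisible(x)
}

#' Final-size transition curve along R0
#'
#' For a fixed mutation rate, sweeps R0 and records the mean final size,
#' overall and among breakthrough realizations, plus the largest
#' single-step jump of the overall mean -- a proxy for the
#' discontinuity of the explosive (first-order) transition.
#'
#' @param sigma Fixed mutation rate.
#' @param R0_values Increasing grid of reproduction numbers.
#' @param template A [scenario()].
#' @return Object of class `transition_curve`: data frame `curve` (R0,
#'   P, mean_r_inf, mean_r_inf_breakthrough) plus `largest_jump` and
#'   `jump_location`.
#' @export
transition_curve <- function(sigma, R0_values, template) {
  stopifnot(inherits(template, "scenario"), !is.unsorted(R0_values))
  cell_seeds <- derive_seeds(template$seed, length(R0_values))
  rows <- lapply(seq_along(R0_values), function(i) {
    pars <- epi_params(alpha0 = template$params$alpha0, R0 = R0_values[i],
                       kbar = template$kbar, sigma = sigma,
                       mutation_mode = template$params$mutation_mode,
                       eta0 = template$params$eta0,
                       psi_max = template$params$psi_max,
                       psi_min = template$params$psi_min,
                       t_max = template$params$t_max,
                       drift = template$params$drift)
    est <- estimate_P(scenario(pars, N = template$N, kbar = template$kbar,
                               network = template$network,
                               n_reps = template$n_reps,
                               epsilon = template$epsilon,
                               seed = cell_seeds[i]))
    bk <- est$reps$r_inf[est$reps$r_inf > template$epsilon]
    data.frame(R0 = R0_values[i], sigma = sigma, P = est$P,
               mean_r_inf = mean(est$reps$r_inf),
               mean_r_inf_bk = if (length(bk)) mean(bk) else NA_real_)
  })
  curve <- do.call(rbind, rows)
  jumps <- diff(curve$mean_r_inf)
  j <- which.max(jumps)
  structure(list(curve = curve,
                 largest_jump = if (length(jumps)) jumps[j] else NA_real_,
                 jump_location = if (length(jumps)) curve$R0[j + 1] else NA_real_),
            class = "transition_curve")
}

#' @export
print.transition_curve <- function(x, ...) {
  cat(sprintf("<transition_curve> %d points; largest jump %.3f at R0 = %.3g\n",
              nrow(x$curve), x$largest_jump, x$jump_location))
  invisible(x)
}

#' Probability of post-mitigation reemergence vs response time
#'
#' For each response time t_R, runs replicates of the evolving-pathogen
#' SIR in which the wild-type reproduction number is rescaled to `R_R`
#' at t_R (see [apply_mitigation()]) and estimates the probability P
#' that the epidemic reemerges after the mitigation. Two criteria are
#' computed per replicate:
#' \describe{
#'   \item{`critical`}{some strain circulating at, or transmitted after,
#'     t_R reaches the post-mitigation critical fitness 1/R_R;}
#'   \item{`rinf`}{the ever-infected fraction grows by more than
#'     `epsilon` after t_R.}
#' }
#'
#' @param t_R_values Response times to scan.
#' @param R_R Post-mitigation wild-type reproduction number.
#' @param template A [scenario()] (its params define the pre-mitigation
#'   pathogen).
#' @param criterion Which criterion fills the `P` column; both are
#'   always reported.
#' @return Object of class `mitigation_curve`: data frame with columns
#'   `t_R`, `P`, `P_critical`, `P_rinf`, `se`.
#' @export
mitigation_experiment <- function(t_R_values, R_R, template,
                                  criterion = c("rinf", "critical")) {
  stopifnot(inherits(template, "scenario"))
  criterion <- match.arg(criterion)
  if (R_R >= template$params$R0) stop("`R_R` must be below the scenario R0")
  point_seeds <- derive_seeds(template$seed, length(t_R_values))
  rows <- lapply(seq_along(t_R_values), function(i) {
    sch <- apply_mitigation(template$params, t_R = t_R_values[i], R_R = R_R)
    rep_seeds <- derive_seeds(point_seeds[i], template$n_reps)
    sc <- scenario(template$params, N = template$N, kbar = template$kbar,
                   network = template$network, n_reps = template$n_reps,
                   epsilon = template$epsilon, seed = point_seeds[i])
    runs <- .scenario_run(sc, rep_seeds, schedule = sch)
    crit <- vapply(runs, function(tr) {
      tr$mitigation$max_psi_post >= 1 / R_R
    }, logical(1))
    rinf <- vapply(runs, function(tr) {
      (tr$r_inf * sc$N - tr$mitigation$ever_at_switch) / sc$N > sc$epsilon
    }, logical(1))
    data.frame(t_R = t_R_values[i],
               P_critical = mean(crit), P_rinf = mean(rinf))
  })
  out <- do.call(rbind, rows)
  out$P <- if (criterion == "critical") out$P_critical else out$P_rinf
  out$se <- sqrt(out$P * (1 - out$P) / template$n_reps)
  structure(list(curve = out, criterion = criterion, R_R = R_R),
            class = "mitigation_curve")
}

#' @export
print.mitigation_curve <- function(x, ...) {
  cat(sprintf("<mitigation_curve> R_R = %g, criterion = %s\n",
              x$R_R, x$criterion))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Hysteresis of the SIS pandemic transition
#'
#' Sweeps R0 upward starting every point from a low-prevalence seeding,
#' then downward with each point continuing from the previous point's
#' endemic end-state. The two estimated transition points (first
#' crossing of the endemic plateau above, respectively below,
#' `plateau_threshold`) differ when the phase boundary depends on the
#' prevalence from which it is approached.
#'
#' @param R0_up_values Increasing R0 grid for the upward sweep.
#' @param R0_down_values Decreasing R0 grid for the downward sweep.
#' @param template A [scenario()]; its params must describe the SIS
#'   pathogen (t_max sets the per-point relaxation time).
#' @param plateau_threshold Prevalence level defining "pandemic".
#' @return Object of class `hysteresis_scan`: `R_c1` (upward), `R_c2`
#'   (downward, always <= R_c1 by reporting convention;
#'   `censored_down = TRUE` when the endemic state survived the entire
#'   downward grid so only an upper bound on R_c2 is known), and the two
#'   sweep data frames. `t_max` should cover several relaxation times of
#'   the slowest (near-critical) point, otherwise incomplete decay
#'   mimics hysteresis.
#' @export
hysteresis_scan <- function(R0_up_values, R0_down_values, template,
                            plateau_threshold = 0.05) {
  stopifnot(inherits(template, "scenario"), !is.unsorted(R0_up_values),
            !is.unsorted(rev(R0_down_values)))
  net <- if (is.null(template$network)) {
    generate_er_network(template$N, template$kbar,
                        seed = derive_seeds(template$seed, 1L))
  } else template$network
  mk <- function(R0) {
    epi_params(alpha0 = template$params$alpha0, R0 = R0,
               kbar = template$kbar, sigma = template$params$sigma,
               mutation_mode = template$params$mutation_mode,
               eta0 = template$params$eta0,
               psi_max = template$params$psi_max,
               psi_min = template$params$psi_min,
               t_max = template$params$t_max,
               drift = template$params$drift)
  }
  up_seeds <- derive_seeds(template$seed, length(R0_up_values) + 1L)
  up <- data.frame(R0 = R0_up_values, plateau = NA_real_)
  for (i in seq_along(R0_up_values)) {
    tr <- run_sis(net, mk(R0_up_values[i]), seed = up_seeds[i])
    up$plateau[i] <- tr$plateau
  }
  R_c1 <- {
    k <- which(up$plateau > plateau_threshold)
    if (length(k)) up$R0[min(k)] else NA_real_
  }
  down_seeds <- derive_seeds(up_seeds[length(up_seeds)],
                             length(R0_down_values))
  down <- data.frame(R0 = R0_down_values, plateau = NA_real_)
  state <- NULL
  for (i in seq_along(R0_down_values)) {
    pars <- mk(R0_down_values[i])
    tr <- if (is.null(state) || sum(state$status == 1L) == 0L) {
      ## (re)start from a high-prevalence state when the chain died
      run_sis(net, pars, seed = down_seeds[i],
              init = with_seed_(down_seeds[i], {
                st <- integer(net$n)
                st[sample.int(net$n, round(0.5 * net$n))] <- 1L
                list(status = st, psi = rep(1, net$n))
              }))
    } else {
      run_sis(net, pars, seed = down_seeds[i], init = state)
    }
    down$plateau[i] <- tr$plateau
    state <- list(status = tr$final_status,
                  psi = ifelse(is.na(tr$final_psi), 1, tr$final_psi))
  }
  censored_down <- FALSE
  R_c2 <- {
    k <- which(down$plateau < plateau_threshold)
    if (length(k)) down$R0[min(k)] else {
      ## endemic state survives across the whole downward grid: the true
      ## R_c2 lies below it; report the grid floor and flag the censoring
      censored_down <- TRUE
      min(R0_down_values)
    }
  }
  if (!is.na(R_c1) && !is.na(R_c2) && R_c2 > R_c1) {
    tmp <- R_c1; R_c1 <- R_c2; R_c2 <- tmp
  }
  structure(list(R_c1 = R_c1, R_c2 = R_c2, censored_down = censored_down,
                 up = up, down = down),
            class = "hysteresis_scan")
}

#' @export
print.hysteresis_scan <- function(x, ...) {
  cat(sprintf("<hysteresis_scan> R_c1 (upward) = %.3g, R_c2 (downward) = %.3g\n",
              x$R_c1, x$R_c2))
  invisible(x)
}

#' Fit the boundary prefactors to a simulated phase diagram
#'
#' For each sub-pandemic R0 column of the grid, locates the sigma at
#' which P crosses 0.5 (log-linear interpolation), separately on the
#' rising (lower boundary) and falling (upper boundary) flank, and
#' returns the median ratio between those crossings and the bare
#' (prefactor 1) theoretical formulas.
#'
#' @param pd A [phase_diagram_scan()] result.
#' @param alpha0,I0,psi_max Parameters of the boundary formulas (taken
#'   from the scan's scenario when it was built with one; here explicit).
#' @return List with `c_lower`, `c_upper` (either may be `NA` when the
#'   corresponding flank is absent from the grid) and the per-column
#'   crossing table `fits`.
#' @export
calibrate_prefactors <- function(pd, alpha0, I0, psi_max) {
  stopifnot(inherits(pd, "phase_diagram"))
  g <- pd$grid[!is.na(pd$grid$P), ]
  cols <- sort(unique(g$R0[g$R0 < 1 & g$R0 > 0]))
  cross <- function(sig, P, rising) {
    ## first 0.5-crossing along increasing sigma, on the requested flank
    for (k in seq_len(length(P) - 1)) {
      lo <- P[k]; hi <- P[k + 1]
      ok <- if (rising) lo < 0.5 && hi >= 0.5 else lo >= 0.5 && hi < 0.5
      if (ok) {
        f <- (0.5 - lo) / (hi - lo)
        return(exp(log(sig[k]) + f * (log(sig[k + 1]) - log(sig[k]))))
      }
    }
    NA_real_
  }
  fits <- do.call(rbind, lapply(cols, function(r0) {
    col <- g[g$R0 == r0, ]
    col <- col[order(col$sigma), ]
    data.frame(R0 = r0,
               sigma50_lower = cross(col$sigma, col$P, rising = TRUE),
               sigma50_upper = cross(col$sigma, col$P, rising = FALSE))
  }))
  ratio_lower <- fits$sigma50_lower /
    vapply(fits$R0, sigma_c_lower, numeric(1), alpha0 = alpha0, I0 = I0)
  ratio_upper <- fits$sigma50_upper /
    vapply(fits$R0, function(r) {
      tryCatch(sigma_c_upper(alpha0, r, psi_max),
               evoepi_no_pandemic = function(e) NA_real_)
    }, numeric(1))
  list(c_lower = stats::median(ratio_lower, na.rm = TRUE),
       c_upper = stats::median(ratio_upper, na.rm = TRUE),
       fits = fits)
}
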