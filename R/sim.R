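# Event-driven (Gillespie) epidemic engine shared by run_sir and run_sis.
#
# State: status 0 = S, 1 = I, 2 = R. Infected nodes live in slot arrays
# (id, psi, alpha, beta, #susceptible-neighbours) with swap-removal, so all
# per-event work is O(#infected + degree). All rates are piecewise constant
# in time, so a mitigation switch at t_R is handled exactly by truncating
# the current waiting time at t_R and redrawing (memorylessness).

.simulate_epidemic <- function(network, params, seed = NULL, schedule = NULL,
                               record_dt = 0.5, sis = FALSE,
                               single_seed = FALSE, init = NULL) {
  stopifnot(inherits(network, "epi_network"), inherits(params, "epi_params"))
  if (!is.null(schedule) && !inherits(schedule, "mitigation_schedule")) {
    stop("`schedule` must come from apply_mitigation()")
  }
  with_seed_(seed, {
    N <- network$n
    adj <- network$adj
    alpha0 <- params$alpha0
    beta0_cur <- params$beta0
    t_max <- params$t_max
    kbar <- if (network$kbar > 0) network$kbar else params$kbar
    R0_init <- kbar * beta0_cur / alpha0
    psi_c <- 1 / R0_init

    rates_for <- function(psi, beta0) {
      if (params$mutation_mode == "alpha") {
        list(alpha = alpha0 / pmax(psi, params$psi_min),
             beta = rep_len(beta0, length(psi)))
      } else {
        list(alpha = rep_len(alpha0, length(psi)), beta = beta0 * psi)
      }
    }

    status <- integer(N)                      # 0 S, 1 I, 2 R
    inf_id <- integer(N)
    pos <- integer(N)
    psi_s <- numeric(N)
    alpha_s <- numeric(N)
    beta_s <- numeric(N)
    nsi_s <- integer(N)

    if (is.null(init)) {
      n_seed <- if (single_seed) 1L else as.integer(round(params$eta0 * N))
      if (n_seed < 1L) stop("eta0 * N must round to at least one seed node")
      seeds <- sample.int(N, n_seed)
      status[seeds] <- 1L
      n_inf <- n_seed
      inf_id[seq_len(n_inf)] <- seeds
      psi_s[seq_len(n_inf)] <- 1
    } else {
      stopifnot(length(init$status) == N)
      status <- as.integer(init$status)
      ids <- which(status == 1L)
      if (!length(ids)) stop("`init` has no infected nodes")
      n_inf <- length(ids)
      inf_id[seq_len(n_inf)] <- ids
      psi_s[seq_len(n_inf)] <- init$psi[ids]
    }
    pos[inf_id[seq_len(n_inf)]] <- seq_len(n_inf)
    rt <- rates_for(psi_s[seq_len(n_inf)], beta0_cur)
    alpha_s[seq_len(n_inf)] <- rt$alpha
    beta_s[seq_len(n_inf)] <- rt$beta
    for (k in seq_len(n_inf)) {
      nsi_s[k] <- sum(status[adj[[inf_id[k]]]] == 0L)
    }

    ever_inf <- sum(status != 0L)
    sum_psi <- sum(psi_s[seq_len(n_inf)])
    max_psi_seen <- max(psi_s[seq_len(n_inf)])
    cross_t <- NA_real_
    if (n_inf > 0 && sum_psi / n_inf >= psi_c) cross_t <- 0
    crit_strain_t <- if (max_psi_seen >= psi_c) 0 else NA_real_

    switched <- is.null(schedule)
    switch_t <- if (switched) Inf else schedule$t_R
    ever_at_switch <- NA_integer_
    max_psi_post <- NA_real_
    infections_post <- NA_integer_
    do_switch <- function() {
      beta0_cur <<- schedule$beta0_new
      if (n_inf > 0) {
        rt <- rates_for(psi_s[seq_len(n_inf)], beta0_cur)
        alpha_s[seq_len(n_inf)] <<- rt$alpha
        beta_s[seq_len(n_inf)] <<- rt$beta
      }
      ever_at_switch <<- ever_inf
      max_psi_post <<- if (n_inf > 0) max(psi_s[seq_len(n_inf)]) else 0
      infections_post <<- 0L
      switched <<- TRUE
      switch_t <<- Inf
    }
    if (!switched && schedule$t_R <= 0) do_switch()

    n_grid <- as.integer(floor(t_max / record_dt)) + 2L
    rec_t <- numeric(n_grid); rec_eta <- numeric(n_grid)
    rec_psi <- numeric(n_grid); rec_s <- numeric(n_grid); rec_r <- numeric(n_grid)
    n_rec <- 0L
    next_rec <- 0
    n_s_cur <- sum(status == 0L)
    n_r_cur <- N - n_s_cur - n_inf
    record_at <- function(tg) {
      n_rec <<- n_rec + 1L
      rec_t[n_rec] <<- tg
      rec_eta[n_rec] <<- n_inf / N
      rec_psi[n_rec] <<- if (n_inf > 0) sum_psi / n_inf else NA_real_
      rec_s[n_rec] <<- n_s_cur / N
      rec_r[n_rec] <<- n_r_cur / N
    }

    tt <- 0
    truncated <- FALSE
    ev_count <- 0L
    dpsi_sum <- 0
    n_trans <- 0L
    repeat {
      if (n_inf == 0L) break
      idx <- seq_len(n_inf)
      av <- alpha_s[idx]
      wv <- beta_s[idx] * nsi_s[idx]
      r_rec <- sum(av)
      r_new <- sum(wv)
      tot <- r_rec + r_new
      tn <- tt + stats::rexp(1L, tot)
      if (tn > switch_t) {
        while (next_rec <= switch_t && next_rec <= t_max) {
          record_at(next_rec); next_rec <- next_rec + record_dt
        }
        tt <- switch_t
        do_switch()
        next
      }
      while (next_rec <= min(tn, t_max)) {
        record_at(next_rec); next_rec <- next_rec + record_dt
      }
      if (tn >= t_max) {
        tt <- t_max
        truncated <- TRUE
        break
      }
      tt <- tn
      if (stats::runif(1L) * tot < r_new) {
        ## transmission along a uniformly chosen S-I edge of the chosen node
        slot <- if (n_inf == 1L) 1L else sample.int(n_inf, 1L, prob = wv)
        i <- inf_id[slot]
        nb <- adj[[i]]
        snb <- nb[status[nb] == 0L]
        j <- if (length(snb) == 1L) snb else snb[sample.int(length(snb), 1L)]
        psi_new <- psi_jump(psi_s[slot], params, n = 1L)
        dpsi_sum <- dpsi_sum + (psi_new - psi_s[slot])
        n_trans <- n_trans + 1L
        status[j] <- 1L
        ever_inf <- ever_inf + 1L
        n_s_cur <- n_s_cur - 1L
        n_inf <- n_inf + 1L
        inf_id[n_inf] <- j
        pos[j] <- n_inf
        psi_s[n_inf] <- psi_new
        rt <- rates_for(psi_new, beta0_cur)
        alpha_s[n_inf] <- rt$alpha
        beta_s[n_inf] <- rt$beta
        nbj <- adj[[j]]
        infnb <- nbj[status[nbj] == 1L]
        pu <- pos[infnb]
        nsi_s[pu] <- nsi_s[pu] - 1L
        nsi_s[n_inf] <- sum(status[nbj] == 0L)
        sum_psi <- sum_psi + psi_new
        if (psi_new > max_psi_seen) max_psi_seen <- psi_new
        if (is.na(crit_strain_t) && psi_new >= psi_c) crit_strain_t <- tt
        if (switched && !is.na(infections_post)) {
          infections_post <- infections_post + 1L
          if (psi_new > max_psi_post) max_psi_post <- psi_new
        }
      } else {
        ## recovery (SIR) or return to susceptibility (SIS)
        slot <- if (n_inf == 1L) 1L else sample.int(n_inf, 1L, prob = av)
        i <- inf_id[slot]
        sum_psi <- sum_psi - psi_s[slot]
        if (sis) {
          status[i] <- 0L
          n_s_cur <- n_s_cur + 1L
          nb <- adj[[i]]
          infnb <- nb[status[nb] == 1L]
          pu <- pos[infnb]
          nsi_s[pu] <- nsi_s[pu] + 1L
        } else {
          status[i] <- 2L
          n_r_cur <- n_r_cur + 1L
        }
        if (slot != n_inf) {
          inf_id[slot] <- inf_id[n_inf]
          psi_s[slot] <- psi_s[n_inf]
          alpha_s[slot] <- alpha_s[n_inf]
          beta_s[slot] <- beta_s[n_inf]
          nsi_s[slot] <- nsi_s[n_inf]
          pos[inf_id[slot]] <- slot
        }
        n_inf <- n_inf - 1L
        pos[i] <- 0L
      }
      if (is.na(cross_t) && n_inf > 0L && sum_psi / n_inf >= psi_c) {
        cross_t <- tt
      }
      ev_count <- ev_count + 1L
      if (ev_count %% 16384L == 0L) {
        sum_psi <- sum(psi_s[seq_len(n_inf)])  # refresh running sum
      }
    }
    record_at(tt)
    if (!switched) {
      ## the epidemic ended before the scheduled mitigation engaged
      ever_at_switch <- ever_inf
      max_psi_post <- 0
      infections_post <- 0L
      switched <- TRUE
    }

    keep <- seq_len(n_rec)
    times <- rec_t[keep]
    eta <- rec_eta[keep]
    ## r_infinity: final ever-infected fraction; the integral form
    ## alpha0 * int eta dt is kept as a secondary diagnostic.
    r_integral <- if (n_rec > 1L) {
      alpha0 * sum(diff(times) * (eta[-1L] + eta[-n_rec]) / 2)
    } else 0
    structure(
      list(
        times = times, eta = eta, psi_bar = rec_psi[keep],
        s_frac = rec_s[keep], r_frac = rec_r[keep],
        r_inf = ever_inf / N, r_integral = r_integral,
        n_transmissions = n_trans,
        mean_delta_psi = if (n_trans > 0) dpsi_sum / n_trans else NA_real_,
        max_psi_seen = max_psi_seen,
        crossed_critical = !is.na(cross_t), crossing_time = cross_t,
        first_critical_time = crit_strain_t,
        psi_c = psi_c, truncated = truncated, t_end = tt,
        n_infected_final = n_inf, sis = sis,
        mitigation = if (is.null(schedule)) NULL else list(
          t_R = schedule$t_R, R_R = schedule$R_R,
          ever_at_switch = ever_at_switch,
          infections_post = infections_post,
          max_psi_post = max_psi_post),
        params = params, seed = seed,
        final_status = status,
        final_psi = {
          p <- rep(NA_real_, N)
          if (n_inf > 0) p[inf_id[seq_len(n_inf)]] <- psi_s[seq_len(n_inf)]
          p
        }
      ),
      class = "epi_trajectory"
    )
  })
}

#' Simulate an evolving-pathogen SIR epidemic on a network
#'
#' Exact event-driven continuous-time simulation of network SIR in which
#' every transmission applies a random fitness jump to the transmitted
#' strain (see [psi_jump()]). Each S-I edge fires at the infecting node's
#' strain-specific infection rate and each infected node recovers at its
#' strain-specific recovery rate (see [strain_rates()]). With sigma = 0 the
#' dynamics are the classic network SIR in law.
#'
#' @param network An `epi_network`.
#' @param params An `epi_params`.
#' @param seed Optional integer seed for full reproducibility.
#' @param schedule Optional [apply_mitigation()] schedule.
#' @param record_dt Spacing of the uniform recording grid.
#' @param single_seed If `TRUE`, start from one infected node instead of
#'   `round(eta0 * N)`.
#' @return An `epi_trajectory`: recorded series `times`, `eta`
#'   (prevalence), `psi_bar` (mean fitness over currently infected, `NA`
#'   when none), `s_frac`, `r_frac`; summary fields `r_inf` (final
#'   ever-infected fraction), `r_integral` (alpha0 * integral of eta dt,
#'   diagnostic), `max_psi_seen`, `crossed_critical`/`crossing_time` (first
#'   time mean fitness exceeded 1/R0), `truncated`, and a `mitigation`
#'   block when a schedule was supplied.
#' @examples
#' net <- generate_er_network(500, 8, seed = 1)
#' p <- epi_params(R0 = 1.5, kbar = 8, sigma = 0, t_max = 300)
#' tr <- run_sir(net, p, seed = 2)
#' tr$r_inf
#' @export
run_sir <- function(network, params, seed = NULL, schedule = NULL,
                    record_dt = 0.5, single_seed = FALSE) {
  .simulate_epidemic(network, params, seed = seed, schedule = schedule,
                     record_dt = record_dt, sis = FALSE,
                     single_seed = single_seed)
}

#' Simulate an evolving-pathogen SIS epidemic on a network
#'
#' Identical to [run_sir()] except that recovered nodes return to the
#' susceptible pool, so a supercritical epidemic settles on an endemic
#' plateau instead of burning out. The long-time prevalence is reported as
#' the time average of eta over the last quarter of the horizon.
#'
#' @inheritParams run_sir
#' @param init Optional initial state `list(status =, psi =)` (full-length
#'   vectors) used to continue from a previous run, e.g. for hysteresis
#'   sweeps; overrides `eta0` seeding.
#' @return An `epi_trajectory` with the additional field `plateau`.
#' @export
run_sis <- function(network, params, seed = NULL, record_dt = 0.5,
                    single_seed = FALSE, init = NULL) {
  tr <- .simulate_epidemic(network, params, seed = seed, schedule = NULL,
                           record_dt = record_dt, sis = TRUE,
                           single_seed = single_seed, init = init)
  sel <- tr$times >= 0.75 * params$t_max
  tr$plateau <- if (any(sel)) mean(tr$eta[sel]) else 0
  tr
}

#' Seed an outbreak state without running the dynamics
#'
#' Places `round(eta0 * N)` uniformly chosen nodes (or a single node) in
#' the infected compartment with wild-type fitness 1; all others start
#' susceptible.
#'
#' @inheritParams run_sir
#' @return List with `status` (0 = S, 1 = I integer vector) and `psi`
#'   (fitness, `NA` for non-infected), usable as `init` for [run_sis()].
#' @export
init_outbreak <- function(network, params, seed = NULL, single_seed = FALSE) {
  stopifnot(inherits(network, "epi_network"), inherits(params, "epi_params"))
  N <- network$n
  n_seed <- if (single_seed) 1L else as.integer(round(params$eta0 * N))
  if (n_seed < 1L) stop("eta0 * N must round to at least one seed node")
  with_seed_(seed, {
    seeds <- sample.int(N, n_seed)
    status <- integer(N)
    status[seeds] <- 1L
    psi <- rep(NA_real_, N)
    psi[seeds] <- 1
    list(status = status, psi = psi)
  })
}

#' @export
print.epi_trajectory <- function(x, ...) {
  kind <- if (isTRUE(x$sis)) "SIS" else "SIR"
  cat(sprintf("<epi_trajectory> %s, t_end=%.1f%s, r_inf=%.3f, max psi seen=%.2f\n",
              kind, x$t_end, if (x$truncated) " (truncated)" else "", x$r_inf,
              x$max_psi_seen))
  if (x$crossed_critical) {
    cat(sprintf("  mean fitness crossed psi_c=%.3g at t=%.2f\n",
                x$psi_c, x$crossing_time))
  }
  if (!is.null(x$plateau)) cat(sprintf("  endemic plateau: %.4f\n", x$plateau))
  invisible(x)
}

#' @export
as.data.frame.epi_trajectory <- function(x, ...) {
  data.frame(time = x$times, eta = x$eta, psi_bar = x$psi_bar,
             s_frac = x$s_frac, r_frac = x$r_frac)
}

#' Write a trajectory's recorded series to CSV
#'
#' @param trajectory An `epi_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
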