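#' Staged disease-cycle parameters
#'
#' Parameters of a COVID-19-like infection cycle. Exposed individuals (E)
#' incubate without shedding, then shed pre-symptomatically (PS) until
#' symptom onset, at which point a fraction `p_asymptomatic` never
#' develops symptoms (AS) and keeps shedding until recovery, while the
#' rest split into mild (IM), severe (IS) and critical (IC) courses that
#' isolate (stop transmitting) unless non-compliant. Severe and critical
#' courses may end in death. All durations are means of exponential
#' stage times, in days.
#'
#' Defaults: a 5-day pre-symptomatic period with shedding starting after
#' ~3 days (2-4 day window), 30\% asymptomatic, ~7 days to recovery for
#' the shedding courses, full isolation compliance of the mildly
#' symptomatic. The symptomatic severity split and death probabilities
#' are adjustable placeholders in the range reported for SARS-CoV-2.
#'
#' @param d_E Mean non-shedding incubation (days).
#' @param d_PS Mean shedding pre-symptomatic stage (days).
#' @param d_AS Mean asymptomatic shedding stage (days).
#' @param d_IM,d_IS,d_IC Mean mild / severe / critical stage durations.
#' @param p_asymptomatic Fraction of infections that never develop
#'   symptoms.
#' @param p_mild,p_severe,p_critical Severity split among symptomatic
#'   courses (must sum to 1).
#' @param p_death_IS,p_death_IC Death probabilities at the end of the
#'   severe / critical stages.
#' @param compliance Fraction of mildly symptomatic individuals who keep
#'   their contacts (0 = all isolate; 0.3 models partial compliance).
#' @return Object of class `disease_cycle`.
#' @export
disease_cycle_params <- function(d_E = 3, d_PS = 2, d_AS = 7,
                                 d_IM = 7, d_IS = 10, d_IC = 14,
                                 p_asymptomatic = 0.30,
                                 p_mild = 0.81, p_severe = 0.14,
                                 p_critical = 0.05,
                                 p_death_IS = 0.15, p_death_IC = 0.5,
                                 compliance = 0) {
  stopifnot(d_E > 0, d_PS > 0, d_AS > 0, d_IM > 0, d_IS > 0, d_IC > 0,
            p_asymptomatic >= 0, p_asymptomatic <= 1,
            p_death_IS >= 0, p_death_IS <= 1,
            p_death_IC >= 0, p_death_IC <= 1,
            compliance >= 0, compliance <= 1)
  if (abs(p_mild + p_severe + p_critical - 1) > 1e-9) {
    stop("severity split p_mild + p_severe + p_critical must sum to 1")
  }
  structure(
    list(d_E = d_E, d_PS = d_PS, d_AS = d_AS, d_IM = d_IM, d_IS = d_IS,
         d_IC = d_IC, p_asymptomatic = p_asymptomatic, p_mild = p_mild,
         p_severe = p_severe, p_critical = p_critical,
         p_death_IS = p_death_IS, p_death_IC = p_death_IC,
         compliance = compliance),
    class = "disease_cycle"
  )
}

#' @export
print.disease_cycle <- function(x, ...) {
  cat(sprintf("<disease_cycle> E %gd -> PS %gd -> {AS %.0f%% (%gd) | IM/IS/IC %g/%g/%g}\n",
              x$d_E, x$d_PS, 100 * x$p_asymptomatic, x$d_AS,
              x$p_mild, x$p_severe, x$p_critical))
  cat(sprintf("  death: IS %g, IC %g; mild compliance gap: %g\n",
              x$p_death_IS, x$p_death_IC, x$compliance))
  invisible(x)
}

#' Read / write a disease cycle as a JSON config file
#'
#' @param path File path.
#' @return `read_disease_cycle` returns a `disease_cycle`;
#'   `write_disease_cycle` returns `path` invisibly.
#' @export
read_disease_cycle <- function(path) {
  do.call(disease_cycle_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_disease_cycle
#' @param cycle A `disease_cycle`.
#' @export
write_disease_cycle <- function(cycle, path) {
  jsonlite::write_json(unclass(cycle), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Variant-evolution parameters of the reinfection model
#'
#' Each strain is summarized by its normalized genetic distance z in
#' [0, 1] from the wild-type. z performs a per-transmission random walk
#' (step sd `sigma_z`, reflected at 0 and capped at 1); the probability
#' that a strain at distance z evades wild-type immunity is the sigmoid
#' [reinfection_fitness()] with midpoint `z_r` and steepness `h`.
#'
#' @param z_r Genetic distance at which immune evasion reaches 50\%.
#' @param h Sigmoid steepness (large h approaches a step at z_r).
#' @param sigma_z Per-transmission step scale of z.
#' @return Object of class `variant_params`.
#' @export
variant_params <- function(z_r = 0.4, h = 8, sigma_z = 0.01) {
  stopifnot(z_r > 0, z_r < 1, h > 0, sigma_z >= 0)
  structure(list(z_r = z_r, h = h, sigma_z = sigma_z),
            class = "variant_params")
}

#' Immune-evasion (reinfection) fitness of a variant
#'
#' phi(z) = z^h / (z_r^h + z^h): the probability that a variant at
#' normalized genetic distance z from the wild-type can reinfect an
#' individual recovered from the wild-type. Near z = 0 there is no
#' reinfection; for z >> z_r the variant fully evades wild-type
#' immunity; at z = z_r the sigmoid crosses 1/2.
#'
#' @param z Normalized genetic distance(s) in [0, 1].
#' @param z_r Midpoint of the sigmoid.
#' @param h Steepness.
#' @return Evasion probability in [0, 1], vectorized over `z`.
#' @examples
#' reinfection_fitness(0.25, 0.25, 8)   # 0.5
#' @export
reinfection_fitness <- function(z, z_r, h) {
  stopifnot(all(z >= 0), all(z <= 1), z_r > 0, h > 0)
  z^h / (z_r^h + z^h)
}

## compartment codes used by the disease-cycle engine
.cc <- c(S = 0L, E = 1L, PS = 2L, AS = 3L, IM = 4L, IS = 5L, IC = 6L,
         R = 7L, D = 8L)

#' Simulate the staged disease cycle with immunity-evasion reinfection
#'
#' Event-driven simulation of the COVID-19-like cycle on a contact
#' network. Shedding nodes (PS, AS, and non-compliant IM) infect
#' susceptible neighbours at per-edge rate `beta0`, and *recovered*
#' neighbours at rate `beta0 * phi(z)` where z is the shedding node's
#' strain distance -- immune evasion is the only selection channel.
#' Every transmission perturbs z by a Normal(0, sigma_z^2) step
#' (reflected at 0, capped at 1). Dead nodes are removed from the
#' dynamics. Only evasion of *wild-type* immunity is modelled: a node
#' recovering from a reinfection becomes terminally immune, so at most
#' two macroscopic waves can arise.
#'
#' @param network An `epi_network`.
#' @param cycle A [disease_cycle_params()].
#' @param variant A [variant_params()].
#' @param beta0 Wild-type per-edge infection rate (see
#'   [beta0_from_R0()]).
#' @param eta0 Initial exposed fraction (wild-type, z = 0).
#' @param t_max Simulation horizon (days).
#' @param seed Optional integer seed.
#' @param record_dt Recording grid spacing.
#' @return Object of class `cycle_trajectory`: series `times`, `eta`
#'   (fraction in any infected stage) and one column per compartment;
#'   counters `reinfections`, `n_asymptomatic`, `n_symptom_onsets`,
#'   `ever_infected`, `deaths`; and `max_z`.
#' @export
run_covid_cycle <- function(network, cycle, variant, beta0,
                            eta0 = 0.02, t_max = 365, seed = NULL,
                            record_dt = 0.5) {
  stopifnot(inherits(network, "epi_network"), inherits(cycle, "disease_cycle"),
            inherits(variant, "variant_params"), beta0 > 0)
  with_seed_(seed, {
    N <- network$n
    adj <- network$adj
    n_seed <- max(1L, as.integer(round(eta0 * N)))

    status <- integer(N)
    act_id <- integer(N); act_stage <- integer(N)
    act_z <- numeric(N); act_phi <- numeric(N)
    act_rate <- numeric(N); act_infw <- numeric(N)
    act_nsi <- integer(N); act_nri <- integer(N)
    act_reinf <- logical(N)
    immune <- logical(N)   # recovered from a reinfection: terminally immune
    pos <- integer(N)
    n_act <- 0L
    cnt <- integer(9L)  # indexed by code + 1

    stage_rate <- c(0, 1 / cycle$d_E, 1 / cycle$d_PS, 1 / cycle$d_AS,
                    1 / cycle$d_IM, 1 / cycle$d_IS, 1 / cycle$d_IC, 0, 0)

    reinfections <- 0L; n_as <- 0L; n_onsets <- 0L
    ever <- 0L; deaths <- 0L; max_z <- 0

    add_active <- function(j, z, reinf = FALSE) {
      n_act <<- n_act + 1L
      act_id[n_act] <<- j
      act_stage[n_act] <<- .cc[["E"]]
      act_z[n_act] <<- z
      act_phi[n_act] <<- reinfection_fitness(z, variant$z_r, variant$h)
      act_rate[n_act] <<- stage_rate[.cc[["E"]] + 1L]
      act_infw[n_act] <<- 0
      nb <- adj[[j]]
      act_nsi[n_act] <<- sum(status[nb] == .cc[["S"]])
      act_nri[n_act] <<- sum(status[nb] == .cc[["R"]] & !immune[nb])
      act_reinf[n_act] <<- reinf
      pos[j] <<- n_act
      status[j] <<- .cc[["E"]]
      cnt[.cc[["E"]] + 1L] <<- cnt[.cc[["E"]] + 1L] + 1L
      if (z > max_z) max_z <<- z
    }
    drop_active <- function(slot) {
      i <- act_id[slot]
      if (slot != n_act) {
        act_id[slot] <<- act_id[n_act]; act_stage[slot] <<- act_stage[n_act]
        act_z[slot] <<- act_z[n_act]; act_phi[slot] <<- act_phi[n_act]
        act_rate[slot] <<- act_rate[n_act]; act_infw[slot] <<- act_infw[n_act]
        act_nsi[slot] <<- act_nsi[n_act]; act_nri[slot] <<- act_nri[n_act]
        act_reinf[slot] <<- act_reinf[n_act]
        pos[act_id[slot]] <<- slot
      }
      n_act <<- n_act - 1L
      pos[i] <<- 0L
    }

    seeds <- sample.int(N, n_seed)
    for (j in seeds) add_active(j, 0)
    for (k in seq_len(n_act)) {
      ## adjacent seeds: recount now that all seeds are exposed
      act_nsi[k] <- sum(status[adj[[act_id[k]]]] == .cc[["S"]])
    }
    cnt[.cc[["S"]] + 1L] <- N - n_seed
    ever <- n_seed

    n_grid <- as.integer(floor(t_max / record_dt)) + 2L
    rec <- matrix(0, n_grid, 11L)
    colnames(rec) <- c("time", "eta", "S", "E", "PS", "AS", "IM", "IS",
                       "IC", "R", "D")
    n_rec <- 0L
    next_rec <- 0
    record_at <- function(tg) {
      n_rec <<- n_rec + 1L
      rec[n_rec, ] <<- c(tg, n_act / N, cnt / N)
    }

    tt <- 0
    truncated <- FALSE
    repeat {
      if (n_act == 0L) break
      idx <- seq_len(n_act)
      sv <- act_rate[idx]
      wsv <- act_infw[idx] * act_nsi[idx]
      wrv <- act_infw[idx] * act_phi[idx] * act_nri[idx]
      r_stage <- sum(sv)
      r_S <- beta0 * sum(wsv)
      r_R <- beta0 * sum(wrv)
      tot <- r_stage + r_S + r_R
      tn <- tt + stats::rexp(1L, tot)
      while (next_rec <= min(tn, t_max)) {
        record_at(next_rec); next_rec <- next_rec + record_dt
      }
      if (tn >= t_max) {
        tt <- t_max; truncated <- TRUE; break
      }
      tt <- tn
      u <- stats::runif(1L) * tot
      if (u < r_S + r_R) {
        ## transmission (to a susceptible or to a recovered neighbour)
        to_R <- u >= r_S
        w <- if (to_R) wrv else wsv
        slot <- if (n_act == 1L) 1L else sample.int(n_act, 1L, prob = w)
        i <- act_id[slot]
        nb <- adj[[i]]
        tgt <- if (to_R) nb[status[nb] == .cc[["R"]] & !immune[nb]]
               else nb[status[nb] == .cc[["S"]]]
        j <- if (length(tgt) == 1L) tgt else tgt[sample.int(length(tgt), 1L)]
        z_new <- act_z[slot] +
          (if (variant$sigma_z > 0) stats::rnorm(1L, 0, variant$sigma_z) else 0)
        z_new <- min(abs(z_new), 1)      # reflect at 0, cap at 1
        old <- status[j]
        cnt[old + 1L] <- cnt[old + 1L] - 1L
        ## neighbours lose one susceptible/recovered contact
        nbj <- adj[[j]]
        actnb <- pos[nbj[pos[nbj] > 0L]]
        if (to_R) {
          act_nri[actnb] <- act_nri[actnb] - 1L
          reinfections <- reinfections + 1L
        } else {
          act_nsi[actnb] <- act_nsi[actnb] - 1L
        }
        add_active(j, z_new, reinf = to_R)
        ever <- ever + 1L
      } else {
        ## stage transition
        slot <- if (n_act == 1L) 1L else sample.int(n_act, 1L, prob = sv)
        i <- act_id[slot]
        st <- act_stage[slot]
        cnt[st + 1L] <- cnt[st + 1L] - 1L
        if (st == .cc[["E"]]) {
          act_stage[slot] <- .cc[["PS"]]
          act_rate[slot] <- stage_rate[.cc[["PS"]] + 1L]
          act_infw[slot] <- 1
          status[i] <- .cc[["PS"]]
          cnt[.cc[["PS"]] + 1L] <- cnt[.cc[["PS"]] + 1L] + 1L
        } else if (st == .cc[["PS"]]) {
          if (stats::runif(1L) < cycle$p_asymptomatic) {
            ns <- .cc[["AS"]]; n_as <- n_as + 1L
            act_infw[slot] <- 1
          } else {
            n_onsets <- n_onsets + 1L
            v <- stats::runif(1L)
            ns <- if (v < cycle$p_mild) .cc[["IM"]]
                  else if (v < cycle$p_mild + cycle$p_severe) .cc[["IS"]]
                  else .cc[["IC"]]
            act_infw[slot] <- if (ns == .cc[["IM"]] &&
                                  stats::runif(1L) < cycle$compliance) 1 else 0
          }
          act_stage[slot] <- ns
          act_rate[slot] <- stage_rate[ns + 1L]
          status[i] <- ns
          cnt[ns + 1L] <- cnt[ns + 1L] + 1L
        } else {
          ## terminal stage exit: recover or die
          dies <- (st == .cc[["IS"]] && stats::runif(1L) < cycle$p_death_IS) ||
                  (st == .cc[["IC"]] && stats::runif(1L) < cycle$p_death_IC)
          fin <- if (dies) .cc[["D"]] else .cc[["R"]]
          status[i] <- fin
          cnt[fin + 1L] <- cnt[fin + 1L] + 1L
          if (dies) deaths <- deaths + 1L
          was_reinf <- act_reinf[slot]
          drop_active(slot)
          if (!dies) {
            if (was_reinf) {
              ## recovering from the evading variant ends susceptibility:
              ## only reinfection relative to the wild-type is modelled
              immune[i] <- TRUE
            } else {
              nb <- adj[[i]]
              actnb <- pos[nb[pos[nb] > 0L]]
              act_nri[actnb] <- act_nri[actnb] + 1L
            }
          }
        }
      }
      if (isTRUE(getOption("evoepi.debug"))) {
        for (k in seq_len(n_act)) {
          nb <- adj[[act_id[k]]]
          tru_s <- sum(status[nb] == .cc[["S"]])
          tru_r <- sum(status[nb] == .cc[["R"]] & !immune[nb])
          if (tru_s != act_nsi[k] || tru_r != act_nri[k]) {
            stop(sprintf("count mismatch node %d: nsi %d/%d nri %d/%d",
                         act_id[k], act_nsi[k], tru_s, act_nri[k], tru_r))
          }
        }
      }
    }
    record_at(tt)

    keep <- seq_len(n_rec)
    structure(
      list(times = rec[keep, "time"], eta = rec[keep, "eta"],
           compartments = rec[keep, 3:11, drop = FALSE],
           reinfections = reinfections, n_asymptomatic = n_as,
           n_symptom_onsets = n_onsets, ever_infected = ever,
           deaths = deaths, max_z = max_z, truncated = truncated,
           t_end = tt, N = N, cycle = cycle, variant = variant,
           beta0 = beta0, seed = seed),
      class = "cycle_trajectory"
    )
  })
}

#' @export
print.cycle_trajectory <- function(x, ...) {
  cat(sprintf("<cycle_trajectory> t_end=%.1f%s ever=%d reinfections=%d deaths=%d max_z=%.3f\n",
              x$t_end, if (x$truncated) " (truncated)" else "",
              x$ever_infected, x$reinfections, x$deaths, x$max_z))
  invisible(x)
}

#' @export
as.data.frame.cycle_trajectory <- function(x, ...) {
  data.frame(time = x$times, eta = x$eta, x$compartments)
}

#' Wild-type infection rate from a target reproduction number
#'
#' Inverts R0 = kbar * beta0 * D for the staged cycle, where D is the
#' mean time an infection spends shedding: the PS stage plus the AS
#' stage for asymptomatic courses plus the IM stage for the
#' non-compliant mildly symptomatic.
#'
#' @param cycle A `disease_cycle`.
#' @param R0 Target wild-type reproduction number.
#' @param kbar Network mean degree.
#' @return beta0 (per-edge, per-day).
#' @export
beta0_from_R0 <- function(cycle, R0, kbar) {
  stopifnot(R0 > 0, kbar > 0)
  D <- cycle$d_PS + cycle$p_asymptomatic * cycle$d_AS +
    (1 - cycle$p_asymptomatic) * cycle$p_mild * cycle$compliance * cycle$d_IM
  R0 / (kbar * D)
}

#' Detect a double-peaked epidemic curve
#'
#' Smooths the prevalence with a centred moving average and searches for
#' at least two local maxima, each at least `prominence_frac` of the
#' global peak, separated by a trough below half the smaller of the two
#' peaks.
#'
#' @param trajectory A `cycle_trajectory` or `epi_trajectory` (anything
#'   with `times` and `eta` on a uniform grid), or a numeric eta vector.
#' @param window Moving-average window (number of grid points, odd).
#' @param prominence_frac Minimal peak height as a fraction of the
#'   global maximum.
#' @return Logical with attributes `peak_times` and `peak_heights`.
#' @export
detect_second_wave <- function(trajectory, window = 9L,
                               prominence_frac = 0.1) {
  eta <- if (is.numeric(trajectory)) trajectory else trajectory$eta
  times <- if (is.numeric(trajectory)) seq_along(eta) else trajectory$times
  eta[is.na(eta)] <- 0
  if (length(eta) < 3L || max(eta) <= 0) {
    return(structure(FALSE, peak_times = numeric(0),
                     peak_heights = numeric(0)))
  }
  w <- max(1L, as.integer(window))
  if (w %% 2L == 0L) w <- w + 1L
  s <- as.numeric(stats::filter(eta, rep(1 / w, w), sides = 2))
  half <- (w - 1L) %/% 2L
  for (k in seq_len(half)) {
    s[k] <- mean(eta[1:(k + half)])
    s[length(s) - k + 1L] <- mean(eta[(length(eta) - k - half + 1L):length(eta)])
  }
  n <- length(s)
  thr <- prominence_frac * max(s)
  cand <- which(s >= thr &
                  s >= c(-Inf, s[-n]) &
                  s > c(s[-1], -Inf))
  if (length(cand) < 2L) {
    return(structure(length(cand) >= 2L,
                     peak_times = times[cand], peak_heights = s[cand]))
  }
  ## greedily accept peaks separated by a deep enough trough
  acc <- cand[1L]
  for (p in cand[-1L]) {
    prev <- acc[length(acc)]
    trough <- min(s[prev:p])
    if (trough < 0.5 * min(s[prev], s[p])) {
      acc <- c(acc, p)
    } else if (s[p] > s[prev]) {
      acc[length(acc)] <- p   # same wave, keep the higher summit
    }
  }
  structure(length(acc) >= 2L,
            peak_times = times[acc], peak_heights = s[acc])
}

#' Reemergence risk map over (R0, sigma_z)
#'
#' For each grid point, runs replicates of [run_covid_cycle()] (with
#' beta0 set from R0 via [beta0_from_R0()]) and estimates the
#' probability of a double-peaked epidemic curve, i.e. a second wave
#' driven by immune evasion.
#'
#' @param R0_values,sigma_values Grid axes (`sigma_values` are per-
#'   transmission z-step scales).
#' @param cycle A `disease_cycle`.
#' @param variant_template A `variant_params` providing `z_r` and `h`.
#' @param N,kbar Network size and mean degree (fresh Erdos-Renyi per
#'   replicate).
#' @param n_reps Replicates per grid point.
#' @param eta0,t_max Passed to [run_covid_cycle()].
#' @param seed Master seed.
#' @return Data frame with columns R0, sigma_z, P, se, mean_reinfections.
#' @export
risk_map <- function(R0_values, sigma_values, cycle, variant_template,
                     N = 1000, kbar = 15, n_reps = 10, eta0 = 0.02,
                     t_max = 365, seed = NULL) {
  stopifnot(length(R0_values) >= 1, length(sigma_values) >= 1)
  pts <- expand.grid(R0 = R0_values, sigma_z = sigma_values,
                     KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- derive_seeds(seed, nrow(pts))
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    vr <- variant_params(z_r = variant_template$z_r, h = variant_template$h,
                         sigma_z = pts$sigma_z[i])
    b0 <- beta0_from_R0(cycle, pts$R0[i], kbar)
    rep_seeds <- derive_seeds(cell_seeds[i], n_reps)
    out <- tryCatch({
      runs <- lapply(rep_seeds, function(s) {
        net <- generate_er_network(N, kbar, seed = s + 1L)
        run_covid_cycle(net, cycle, vr, b0, eta0 = eta0, t_max = t_max,
                        seed = s)
      })
      two <- vapply(runs, function(tr) as.logical(detect_second_wave(tr)),
                    logical(1))
      P <- mean(two)
      data.frame(R0 = pts$R0[i], sigma_z = pts$sigma_z[i], P = P,
                 se = sqrt(P * (1 - P) / n_reps),
                 mean_reinfections = mean(vapply(runs, `[[`, numeric(1),
                                                 "reinfections")),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(R0 = pts$R0[i], sigma_z = pts$sigma_z[i], P = NA_real_,
                 se = NA_real_, mean_reinfections = NA_real_,
                 error = conditionMessage(e))
    })
    out
  })
  do.call(rbind, rows)
}
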