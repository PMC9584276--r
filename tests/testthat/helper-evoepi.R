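# Shared fixtures and independent oracles for the test suite.

# Well-mixed SIR final-size fixed point r = 1 - exp(-R0 (r + eta0)).
final_size_wm <- function(R0, eta0) {
  r <- 0.5
  for (k in 1:500) r <- 1 - exp(-R0 * (r + eta0))
  r
}

# Exact static oracle for sigma = 0 network SIR final size: each node i
# draws a recovery time Exp(alpha); edge i -> j transmits iff an
# Exp(beta) clock beats it. Reachability from the seeds then has the
# same law as the event-driven dynamics.
percolation_final_size <- function(net, alpha, beta, n_seed, seed) {
  set.seed(seed)
  N <- net$n
  Ti <- rexp(N, alpha)
  infected <- logical(N)
  queue <- sample.int(N, n_seed)
  infected[queue] <- TRUE
  while (length(queue)) {
    i <- queue[[1]]
    queue <- queue[-1]
    for (j in net$adj[[i]]) {
      if (!infected[j] && rexp(1, beta) < Ti[i]) {
        infected[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  mean(infected)
}

# Plain network SIR without any fitness machinery, mirroring the engine's
# RNG consumption exactly, so that with sigma = 0 and a shared seed the
# evolving-pathogen simulation must reproduce it run for run.
plain_sir <- function(net, alpha0, beta0, eta0, t_max, seed) {
  set.seed(seed)
  N <- net$n
  adj <- net$adj
  status <- integer(N)
  n_seed <- as.integer(round(eta0 * N))
  seeds <- sample.int(N, n_seed)
  status[seeds] <- 1L
  inf_id <- integer(N); pos <- integer(N); nsi <- integer(N)
  n_inf <- n_seed
  inf_id[seq_len(n_inf)] <- seeds
  pos[seeds] <- seq_len(n_inf)
  for (k in seq_len(n_inf)) nsi[k] <- sum(status[adj[[inf_id[k]]]] == 0L)
  ever <- n_inf
  tt <- 0
  repeat {
    if (n_inf == 0L) break
    idx <- seq_len(n_inf)
    av <- rep(alpha0, n_inf)
    wv <- beta0 * nsi[idx]
    tot <- sum(av) + sum(wv)
    tt <- tt + rexp(1L, tot)
    if (tt >= t_max) break
    if (runif(1L) * tot < sum(wv)) {
      slot <- if (n_inf == 1L) 1L else sample.int(n_inf, 1L, prob = wv)
      i <- inf_id[slot]
      nb <- adj[[i]]
      snb <- nb[status[nb] == 0L]
      j <- if (length(snb) == 1L) snb else snb[sample.int(length(snb), 1L)]
      status[j] <- 1L
      ever <- ever + 1L
      n_inf <- n_inf + 1L
      inf_id[n_inf] <- j
      pos[j] <- n_inf
      nbj <- adj[[j]]
      infnb <- nbj[status[nbj] == 1L]
      pu <- pos[infnb]
      nsi[pu] <- nsi[pu] - 1L
      nsi[n_inf] <- sum(status[nbj] == 0L)
    } else {
      slot <- if (n_inf == 1L) 1L else sample.int(n_inf, 1L, prob = av)
      i <- inf_id[slot]
      status[i] <- 2L
      if (slot != n_inf) {
        inf_id[slot] <- inf_id[n_inf]
        nsi[slot] <- nsi[n_inf]
        pos[inf_id[slot]] <- slot
      }
      n_inf <- n_inf - 1L
      pos[i] <- 0L
    }
  }
  ever / N
}

# Small reusable test network (generated once per test run).
tiny_net <- function(n = 500, kbar = 10, seed = 424) {
  generate_er_network(n, kbar, seed = seed)
}
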