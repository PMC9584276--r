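test_that("strain chain construction matches the mutation model", {
  # p = 0: the mutation matrix is the identity
  ch0 <- build_strain_chain(11, p = 0, sigma_phi = 0.1, sigma_psi = 0.1,
                            seed = 1)
  expect_equal(mutation_matrix(ch0), diag(11))

  # interior rows are (p, 1 - 2p, p) and all rows sum to 1
  ch <- build_strain_chain(9, p = 0.25, sigma_phi = 0, sigma_psi = 0)
  M <- mutation_matrix(ch)
  expect_equal(unname(M[5, 4:6]), c(0.25, 0.5, 0.25))
  expect_equal(rowSums(M), rep(1, 9))

  # zero-variance draws give flat unit fitness; draws are clamped at 0
  expect_equal(ch$phi, rep(1, 9))
  expect_equal(ch$psi, rep(1, 9))
  big <- build_strain_chain(2000, p = 0.1, sigma_phi = 5, sigma_psi = 5,
                            seed = 2)
  expect_true(all(big$phi >= 0) && all(big$psi >= 0))

  # determinism and input validation
  expect_identical(build_strain_chain(15, 0.1, 0.2, 0.2, seed = 7),
                   build_strain_chain(15, 0.1, 0.2, 0.2, seed = 7))
  expect_error(build_strain_chain(1, 0.1, 0, 0), "n_strains")
  expect_error(build_strain_chain(5, 0.6, 0, 0), "1 - 2p")
})

test_that("replicator-mutator dynamics select, diffuse and stay normalized", {
  # neutral, mutation-free: composition unchanged
  ch <- build_strain_chain(5, p = 0, sigma_phi = 0, sigma_psi = 0)
  z <- multistrain(ch, freqs = c(0.1, 0.2, 0.4, 0.2, 0.1))
  expect_equal(replicate_select(ch, z, 10)$freqs, z$freqs)

  # one selection step, analytic: phi = (2, 1), z = (1/2, 1/2) -> (2/3, 1/3)
  ch2 <- build_strain_chain(2, p = 0, sigma_phi = 0, sigma_psi = 0)
  ch2$phi <- c(2, 1)
  z2 <- multistrain(ch2, freqs = c(0.5, 0.5))
  expect_equal(replicate_select(ch2, z2, 1)$freqs, c(2 / 3, 1 / 3))

  # long-run composition approaches the leading eigenvector of the
  # selection-mutation operator (power-iteration oracle)
  ch3 <- build_strain_chain(15, p = 0.05, sigma_phi = 0.3, sigma_psi = 0.1,
                            seed = 11)
  z3 <- replicate_select(ch3, multistrain(ch3), 5000)
  A <- t(mutation_matrix(ch3)) %*% diag(ch3$phi)
  v <- Re(eigen(A)$vectors[, 1])
  v <- abs(v) / sum(abs(v))
  expect_lt(max(abs(z3$freqs - v)), 1e-8)

  # normalization is conserved by every call (property over random cases)
  set.seed(42)
  for (k in 1:10) {
    chk <- build_strain_chain(21, p = runif(1, 0, 0.4),
                              sigma_phi = runif(1, 0, 0.5),
                              sigma_psi = runif(1, 0, 0.5))
    zk <- replicate_select(chk, multistrain(chk), sample(1:200, 1))
    expect_lt(abs(sum(zk$freqs) - 1), 1e-9)
    expect_true(all(zk$freqs >= 0))
  }

  # degenerate chain (all reachable fitness clamped to zero) is an error
  chd <- build_strain_chain(3, p = 0, sigma_phi = 0, sigma_psi = 0)
  chd$phi <- c(0, 0, 0)
  expect_error(replicate_select(chd, multistrain(chd), 1), "degenerate")
})

test_that("flat intra-host landscape reduces to pure diffusion on the chain", {
  ch <- build_strain_chain(41, p = 0.2, sigma_phi = 0, sigma_psi = 0.3,
                           seed = 3)
  z <- replicate_select(ch, multistrain(ch), 300)
  mean_idx <- sum(seq_len(41) * z$freqs)
  expect_lt(abs(mean_idx - 21), 1e-9)  # mean strain index conserved
  expect_gt(sum((seq_len(41) - 21)^2 * z$freqs), 1)  # but it spreads
})

test_that("marginals show phi-selection but neutral psi drift", {
  ch <- build_strain_chain(21, p = 0.1, sigma_phi = 0.3, sigma_psi = 0.3,
                           seed = 5)
  z1 <- multistrain(ch, strain = 4)
  m1 <- fitness_marginals(ch, z1)
  expect_equal(sum(m1$phi$mass), 1)
  expect_equal(sum(m1$psi$mass), 1)
  expect_equal(m1$phi$value[m1$phi$mass > 0.999], ch$phi[4])
  expect_equal(m1$psi$value[m1$psi$mass > 0.999], ch$psi[4])

  # across many chains: mean intra-host fitness rises above the initial
  # strain's phi (selection), mean inter-host fitness stays at the
  # initial psi (neutral drift)
  set.seed(8)
  dphi <- dpsi <- numeric(40)
  for (k in 1:40) {
    chk <- build_strain_chain(31, p = 0.05, sigma_phi = 0.3, sigma_psi = 0.3)
    zk <- replicate_select(chk, multistrain(chk), 400)
    mk <- fitness_marginals(chk, zk)
    c0 <- 16
    dphi[k] <- sum(mk$phi$value * mk$phi$mass) - chk$phi[c0]
    dpsi[k] <- sum(mk$psi$value * mk$psi$mass) - chk$psi[c0]
  }
  expect_gt(mean(dphi) / (sd(dphi) / sqrt(40)), 3)   # clear phi gain
  expect_lt(abs(mean(dpsi)) / (sd(dpsi) / sqrt(40)), 3)  # psi unbiased
})

test_that("transmission sampling follows the composition", {
  ch <- build_strain_chain(6, p = 0.1, sigma_phi = 0.2, sigma_psi = 0.2,
                           seed = 6)
  zpt <- multistrain(ch, strain = 4)
  for (k in 1:5) {
    tr <- sample_transmission(ch, zpt, seed = k)
    expect_equal(unname(tr["phi"]), ch$phi[4])
    expect_equal(unname(tr["psi"]), ch$psi[4])
  }

  # empirical frequencies match Z within 3 binomial standard errors
  z <- multistrain(ch, freqs = c(0.05, 0.1, 0.2, 0.3, 0.25, 0.1))
  set.seed(9)
  draws <- replicate(20000, attr(sample_transmission(ch, z), "strain"))
  emp <- tabulate(draws, 6) / 20000
  se <- sqrt(z$freqs * (1 - z$freqs) / 20000)
  expect_true(all(abs(emp - z$freqs) < 3 * se + 1e-12))

  # two equal strains: close to 50/50
  z5050 <- multistrain(ch, freqs = c(0.5, 0.5, 0, 0, 0, 0))
  set.seed(10)
  d2 <- replicate(4000, attr(sample_transmission(ch, z5050), "strain"))
  expect_lt(abs(mean(d2 == 1) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("effective sigma estimation captures the neutral psi random walk", {
  # no mutation: exactly zero
  expect_equal(as.numeric(
    estimate_effective_sigma(11, 0, 0.2, 0.2, rho = 10, n_passages = 20,
                             seed = 1)), 0)
  expect_true(attr(estimate_effective_sigma(11, 0, 0.2, 0.2, rho = 10,
                                            n_passages = 20, seed = 1),
                   "wide_ci"))

  # monotone in p on a 3-point grid at fixed rho, sigma_psi
  ests <- vapply(c(0.005, 0.05, 0.3), function(p) {
    as.numeric(estimate_effective_sigma(41, p, 0.1, 0.3, rho = 150,
                                        n_passages = 120, seed = 21))
  }, numeric(1))
  expect_true(all(diff(ests) > 0))

  # per-passage changes are centred at zero (no inter-host selection)
  est <- estimate_effective_sigma(41, 0.05, 0.1, 0.3, rho = 150,
                                  n_passages = 150, seed = 22)
  expect_lt(abs(attr(est, "mean_delta")), 3 * attr(est, "se_mean"))

  # the reduction claim: delta-psi passes a moment-based normality check
  dp <- attr(estimate_effective_sigma(41, 0.05, 0.1, 0.3, rho = 120,
                                      n_passages = 200, seed = 23),
             "delta_psi")
  zs <- (dp - mean(dp)) / sd(dp)
  skew <- mean(zs^3)
  exkurt <- mean(zs^4) - 3
  expect_lt(abs(skew), 6 * sqrt(6 / 200))     # |skewness| within 6 se
  expect_lt(abs(exkurt), 6 * sqrt(24 / 200))  # |excess kurtosis| within 6 se

  # determinism
  expect_identical(
    as.numeric(estimate_effective_sigma(21, 0.05, 0.1, 0.2, 50, 30, seed = 4)),
    as.numeric(estimate_effective_sigma(21, 0.05, 0.1, 0.2, 50, 30, seed = 4)))
})

test_that("chain serialization writes one row per strain", {
  ch <- build_strain_chain(7, 0.1, 0.2, 0.2, seed = 2)
  z <- replicate_select(ch, multistrain(ch), 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_strain_chain(ch, f, z)
  df <- read.csv(f)
  expect_equal(nrow(df), 7)
  expect_equal(df$phi, ch$phi)
  expect_equal(sum(df$freq), 1, tolerance = 1e-9)
})
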