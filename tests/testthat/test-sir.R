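test_that("outbreak seeding places the right number of wild-type seeds", {
  net <- tiny_net()
  p <- epi_params(R0 = 1.2, kbar = 10, eta0 = 0.02)
  st <- init_outbreak(net, p, seed = 1)
  expect_equal(sum(st$status == 1L), 10)   # round(0.02 * 500)
  expect_true(all(st$psi[st$status == 1L] == 1))
  expect_identical(init_outbreak(net, p, seed = 1), st)
  expect_equal(sum(init_outbreak(net, p, seed = 2,
                                 single_seed = TRUE)$status), 1)
  pall <- epi_params(R0 = 1.2, kbar = 10, eta0 = 1)
  expect_equal(sum(init_outbreak(net, pall, seed = 3)$status == 1L), 500)
  ptiny <- epi_params(R0 = 1.2, kbar = 10, eta0 = 1e-4)
  expect_error(init_outbreak(net, ptiny, seed = 1), "at least one seed")
})

test_that("with sigma = 0 the engine reproduces a plain network SIR run for run", {
  net <- tiny_net(800, 12, seed = 77)
  p <- epi_params(alpha0 = 0.1, R0 = 1.3, kbar = 12, sigma = 0,
                  eta0 = 0.02, t_max = 500)
  for (s in c(5, 6, 7, 8)) {
    tr <- run_sir(net, p, seed = s)
    expect_equal(tr$r_inf, plain_sir(net, 0.1, p$beta0, 0.02, 500, s))
  }
})

test_that("sigma = 0 final sizes match the exact percolation oracle in law", {
  net <- tiny_net(1500, 12, seed = 13)
  p <- epi_params(alpha0 = 0.1, R0 = 1.5, kbar = 12, sigma = 0,
                  eta0 = 0.02, t_max = 2000)
  sim <- vapply(1:12, function(s) run_sir(net, p, seed = s)$r_inf,
                numeric(1))
  orc <- vapply(1:12, function(s) {
    percolation_final_size(net, 0.1, p$beta0, 30, seed = 1000 + s)
  }, numeric(1))
  se <- sqrt(var(sim) / 12 + var(orc) / 12)
  expect_lt(abs(mean(sim) - mean(orc)), 3 * se + 0.02)
})

test_that("trajectories conserve compartments and respect fitness bounds", {
  net <- tiny_net()
  p <- epi_params(alpha0 = 0.1, R0 = 1.2, kbar = 10, sigma = 1,
                  psi_max = 6, t_max = 400)
  tr <- run_sir(net, p, seed = 3)
  expect_equal(tr$s_frac + tr$eta + tr$r_frac,
               rep(1, length(tr$times)), tolerance = 1e-12)
  expect_true(all(diff(tr$times) > 0))
  expect_lte(tr$max_psi_seen, 6)
  expect_true(all(tr$final_psi >= 0, na.rm = TRUE))
  expect_true(tr$r_inf >= 0 && tr$r_inf <= 1)
  # ended by extinction: prevalence at the last record is zero
  expect_true(tr$truncated || tr$eta[length(tr$eta)] == 0)
})

test_that("same seed gives bit-identical trajectories", {
  net <- tiny_net()
  p <- epi_params(R0 = 1.1, kbar = 10, sigma = 0.5, t_max = 300)
  expect_identical(run_sir(net, p, seed = 42), run_sir(net, p, seed = 42))
})

test_that("subcritical epidemics die out quickly", {
  net <- tiny_net(1000, 10, seed = 21)
  p <- epi_params(alpha0 = 0.1, R0 = 0.25, kbar = 10, sigma = 0,
                  t_max = 1000)
  rinf <- vapply(1:10, function(s) run_sir(net, p, seed = s)$r_inf,
                 numeric(1))
  expect_true(all(rinf < 0.1))
})

test_that("tiny horizons flag truncation instead of failing", {
  net <- tiny_net()
  p <- epi_params(R0 = 1.5, kbar = 10, sigma = 0, t_max = 2)
  tr <- run_sir(net, p, seed = 1)
  expect_true(tr$truncated)
  expect_equal(tr$t_end, 2)
})

test_that("reducing beta0 from the start stochastically lowers the final size", {
  net <- tiny_net(1000, 10, seed = 55)
  hi <- epi_params(alpha0 = 0.1, R0 = 1.5, kbar = 10, sigma = 0, t_max = 600)
  lo <- epi_params(alpha0 = 0.1, R0 = 1.0, kbar = 10, sigma = 0, t_max = 600)
  r_hi <- vapply(1:8, function(s) run_sir(net, hi, seed = s)$r_inf, numeric(1))
  r_lo <- vapply(1:8, function(s) run_sir(net, lo, seed = s)$r_inf, numeric(1))
  se <- sqrt(var(r_hi) / 8 + var(r_lo) / 8)
  expect_gt(mean(r_hi) - mean(r_lo), -2 * se)
  expect_gt(mean(r_hi), mean(r_lo))
})

test_that("mitigation at t = 0 equals running with R_R from the start", {
  net <- tiny_net()
  p <- epi_params(alpha0 = 0.1, R0 = 1.4, kbar = 10, sigma = 0, t_max = 400)
  sch <- apply_mitigation(p, t_R = 0, R_R = 0.7)
  direct <- epi_params(alpha0 = 0.1, R0 = 0.7, kbar = 10, sigma = 0,
                       t_max = 400)
  expect_equal(run_sir(net, p, seed = 9, schedule = sch)$r_inf,
               run_sir(net, direct, seed = 9)$r_inf)
})

test_that("per-transmission fitness steps average to the drift", {
  # selection shows up only through differential spread; the realized
  # jump kernel itself must stay unbiased (mean step = drift = 0)
  net <- tiny_net(1000, 10, seed = 99)
  p <- epi_params(alpha0 = 0.1, R0 = 1.5, kbar = 10, sigma = 0.2,
                  psi_max = Inf, t_max = 600)
  trs <- lapply(1:5, function(s) run_sir(net, p, seed = s))
  steps <- sum(vapply(trs, `[[`, numeric(1), "n_transmissions"))
  mstep <- sum(vapply(trs, function(tr) {
    tr$mean_delta_psi * tr$n_transmissions
  }, numeric(1))) / steps
  expect_gt(steps, 500)
  expect_lt(abs(mstep - 0), 3 * 0.2 / sqrt(steps))
})

test_that("trajectory export writes the recorded series", {
  net <- tiny_net()
  p <- epi_params(R0 = 1.2, kbar = 10, sigma = 0, t_max = 200)
  tr <- run_sir(net, p, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  df <- read.csv(f)
  expect_named(df, c("time", "eta", "psi_bar", "s_frac", "r_frac"))
  expect_equal(nrow(df), length(tr$times))
})
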