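test_that("the exponential rate xi has the right limits and shape", {
  expect_equal(xi(0, 0.1, 0.25, 2), 0)
  expect_equal(xi(10, 0.1, 0.25, 0), -0.75)   # linear decay term only
  # sub-pandemic with mutations: negative early, positive late
  expect_lt(xi(1, 0.1, 0.25, 1), 0)
  expect_gt(xi(200, 0.1, 0.25, 1), 0)
})

test_that("the theoretical prevalence starts at eta0 and decays when sigma = 0", {
  expect_equal(eta_theory(0, 0.02, 0.1, 0.25, 2), 0.02)
  tt <- c(5, 10, 20)
  expect_equal(eta_theory(tt, 0.02, 0.1, 0.25, 0),
               0.02 * exp(-0.1 * 0.75 * tt))
  expect_true(all(eta_theory(seq(0, 100, 5), 0.02, 0.1, 0.5, 0.3) > 0))
})

test_that("early simulated decay matches the theoretical rate", {
  # rep-averaged log-slope of eta(t) for a mutation-free subcritical
  # pathogen vs -alpha0 (1 - R0)
  net <- tiny_net(2000, 15, seed = 31)
  p <- epi_params(alpha0 = 0.1, R0 = 0.25, kbar = 15, sigma = 0,
                  eta0 = 0.05, t_max = 300)
  etas <- sapply(1:20, function(s) {
    tr <- run_sir(net, p, seed = s)
    sel <- tr$times <= 20
    approx(tr$times[sel], tr$eta[sel], xout = seq(0, 20, 0.5),
           rule = 2)$y
  })
  eta_bar <- rowMeans(etas)
  tgrid <- seq(0, 20, 0.5)
  fit <- lm(log(eta_bar) ~ tgrid)
  expect_lt(abs(unname(coef(fit)[2]) - (-0.1 * 0.75)) / (0.1 * 0.75), 0.15)
})

test_that("tau_c is the argmin of xi and behaves at the limits", {
  expect_equal(tau_c(0.1, 0.25, 2), sqrt(20))
  # numerical argmin oracle on a random parameter grid
  set.seed(12)
  for (k in 1:20) {
    a <- runif(1, 0.02, 0.5)
    r <- runif(1, 0.05, 0.95)
    s <- runif(1, 0.05, 5)
    tc <- tau_c(a, r, s)
    num <- optimize(function(t) xi(t, a, r, s), c(0, 10 * tc))$minimum
    expect_lt(abs(tc - num) / tc, 1e-4)
    # first derivative vanishes, second derivative positive
    h <- tc * 1e-4
    d1 <- (xi(tc + h, a, r, s) - xi(tc - h, a, r, s)) / (2 * h)
    d2 <- (xi(tc + h, a, r, s) - 2 * xi(tc, a, r, s) +
             xi(tc - h, a, r, s)) / h^2
    expect_lt(abs(d1), 1e-6 * max(1, abs(xi(tc, a, r, s))))
    expect_gt(d2, 0)
  }
  expect_lt(tau_c(0.1, 0.999, 1), 0.3)   # R0 -> 1: tau_c -> 0
  expect_error(tau_c(0.1, 1.2, 1), "0 < R0 < 1")
  expect_error(tau_c(0.1, 0.5, 0), "sigma")
})

test_that("critical fitness is the inverse reproduction number", {
  expect_equal(psi_critical(0.25), 4)
  expect_equal(psi_critical(1), 1)
  expect_equal(psi_critical(2), 0.5)
  expect_error(psi_critical(0), "positive")
})

test_that("the lower boundary vanishes at R0 = 1 and scales with ln I0", {
  expect_equal(sigma_c_lower(0.1, 1, 100), 0)
  expect_lt(sigma_c_lower(0.1, 0.5, 1e8), sigma_c_lower(0.1, 0.5, 1e2))
  expect_equal(sigma_c_lower(0.1, 0.5, 100^2),
               sigma_c_lower(0.1, 0.5, 100) / 2)
  expect_error(sigma_c_lower(0.1, 0.5, 1), "I0")
  expect_error(sigma_c_lower(0.1, 1.5, 100), "0 < R0 <= 1")
})

test_that("the upper boundary grows with psi_max from a zero base", {
  expect_equal(sigma_c_upper(0.1, 0.5, 2), 0)  # psi_max R0 = 1
  expect_equal(sigma_c_upper(0.1, 0.5, 10, c_upper = 1),
               sqrt(0.1 / 3) * 4^1.5 / 0.5)
  caps <- c(3, 5, 8, 12)
  vals <- vapply(caps, function(m) sigma_c_upper(0.1, 0.5, m), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(sigma_c_upper(0.1, 0.25, 2), class = "evoepi_no_pandemic")
})

test_that("phase labels traverse the ordered sequence along sigma", {
  # pandemic iff R0 >= 1
  expect_equal(classify_phase(0.1, 1.2, 0.02, 100, 6)$label, "pandemic")
  expect_equal(classify_phase(0.1, 1.0, 5, 100, 6)$label, "pandemic")
  # for fixed R0 < 1 the label sequence along sigma is
  # infection-free -> mutation-driven -> volatile, in that order
  for (r0 in c(0.2, 0.35, 0.5, 0.8)) {
    labs <- vapply(10^seq(-3, 4, 0.1), function(s) {
      classify_phase(0.1, r0, s, 100, 60)$label
    }, character(1))
    runs <- rle(labs)$values
    expect_equal(runs, c("infection-free", "mutation-driven", "volatile"))
  }
  # boundary margin is the distance to the nearest boundary
  ph <- classify_phase(0.1, 0.35, 2, 100, 6)
  expect_equal(ph$label, "mutation-driven")
  expect_equal(ph$boundary_margin,
               min(2 - ph$sigma_c_lower, ph$sigma_c_upper - 2))
  # unreachable pandemic fitness: infection-free at any sigma
  expect_equal(classify_phase(0.1, 0.1, 5, 100, 6)$label, "infection-free")
})

test_that("the unit-line criterion separates the known scenarios", {
  expect_false(unit_line_check(0.02, 5000, 0.1, 0.25, 0.1))
  expect_true(unit_line_check(0.02, 5000, 0.1, 0.25, 0.5))
  # N -> infinity: any positive prevalence clears the unit line
  expect_true(unit_line_check(0.02, 1e12, 0.1, 0.25, 0.1))
})

test_that("boundary curves tabulate both boundaries over R0", {
  bc <- boundary_curves(c(0.25, 0.5, 0.9), alpha0 = 0.1, I0 = 100,
                        psi_max = 6)
  expect_equal(nrow(bc), 3)
  expect_true(all(bc$sigma_c_lower > 0))
  expect_true(all(diff(bc$sigma_c_lower) < 0))  # decreasing towards R0 = 1
})
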