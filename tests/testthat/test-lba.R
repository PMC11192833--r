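test_that("drift-rate mapping mirrors evidence between accumulators", {
  d0 <- drift_rates(0, V0 = 2, V = 1, gamma = 50)
  expect_equal(d0$v_old, 3)
  expect_equal(d0$v_new, 1)
  g <- runif(10, 0, 0.05)
  dd <- drift_rates(g, V0 = 2, V = -1, gamma = 80)
  expect_equal(dd$v_old + dd$v_new, rep(4, 10))
  # gamma = 0 baseline: drifts are independent of similarity
  flat <- drift_rates(g, V0 = 2, V = -1, gamma = 0)
  expect_equal(flat$v_old, rep(1, 10))
})

test_that("defective density integrates to the defective CDF", {
  grid <- expand.grid(b = c(1, 1.8), A = c(0.3, 0.8), v = c(0.8, 2.5),
                      eta = c(0.7, 1.3))
  grid <- grid[grid$b > grid$A, ]
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    up <- c(0.4, 1.1, 3)
    for (tt in up) {
      quad <- integrate(function(t) lba_density(t, p$b, p$A, p$v, p$eta),
                        0, tt, rel.tol = 1e-9)$value
      expect_equal(quad, lba_cdf(tt, p$b, p$A, p$v, p$eta),
                   tolerance = 1e-6, info = paste(unlist(p), collapse = "/"))
    }
    # total finishing probability equals the positive-drift mass
    expect_equal(lba_cdf(1e7, p$b, p$A, p$v, p$eta),
                 pnorm(p$v / p$eta), tolerance = 1e-5)
  }
})

test_that("the A -> 0, eta -> 0 limit degenerates to a spike at b/v", {
  b <- 1.5; v <- 2
  hit <- b / v
  expect_lt(lba_cdf(hit * 0.98, b, 0, v, 1e-6), 1e-8)
  expect_gt(lba_cdf(hit * 1.02, b, 0, v, 1e-6), 1 - 1e-8)
})

test_that("Monte-Carlo finishing times match the defective density", {
  settings <- list(c(b = 1.5, A = 0.5, v = 2, eta = 1),
                   c(b = 1.2, A = 0.3, v = 1, eta = 0.8),
                   c(b = 2.0, A = 0.8, v = 3, eta = 1.5))
  for (k in seq_along(settings)) {
    p <- as.list(settings[[k]])
    n <- 1e6
    tt <- simulate_lba_accumulator(n, p$b, p$A, p$v, p$eta, seed = 100 + k)
    # never-finishing draws (negative drift) carry the defective mass
    p_never <- mean(!is.finite(tt))
    expect_lt(abs(p_never - pnorm(-p$v / p$eta)),
              5 * sqrt(0.25 / n) + 1e-4)
    breaks <- c(seq(0, 3, by = 0.25), Inf)
    obs <- table(cut(tt[is.finite(tt)], breaks))
    probs <- diff(vapply(breaks, function(x)
      if (is.finite(x)) lba_cdf(x, p$b, p$A, p$v, p$eta)
      else pnorm(p$v / p$eta), numeric(1)))
    expected <- n * probs
    tol <- 5 * sqrt(pmax(expected * (1 - probs), 1))
    expect_true(all(abs(as.vector(obs) - expected) <= tol),
                info = paste("setting", k))
  }
})

test_that("race likelihood integrates to one under the redraw convention", {
  pars <- list(A = 0.5, B_old = 1, B_new = 0.8, t0 = 0.25)
  for (vv in list(c(2.5, 1.5), c(0.6, -0.2), c(-0.4, 1.1))) {
    total <- sum(vapply(c("old", "new"), function(resp)
      integrate(function(t)
        exp(lba_trial_loglik(t + pars$t0, rep(resp, length(t)),
                             vv[1], vv[2], 1, pars)),
        0, Inf, rel.tol = 1e-9)$value, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-4,
                 info = paste(vv, collapse = "/"))
  }
})

test_that("rt at or below t0 yields -Inf log-likelihood, not an error", {
  pars <- list(A = 0.5, B_old = 1, B_new = 1, t0 = 0.3)
  ll <- lba_trial_loglik(c(0.1, 0.3, 0.5), c("old", "old", "old"),
                         2, 1, 1, pars)
  expect_equal(ll[1:2], c(-Inf, -Inf))
  expect_true(is.finite(ll[3]))
})

test_that("simulator and likelihood are a matched pair", {
  pars <- lba_params(A = 0.5, B_old = 1, B_new = 1, t0 = 0.25)
  v_old <- 1.2; v_new <- 2.8
  n <- 1e5
  sim <- simulate_lba(rep(v_old, n), rep(v_new, n), 1, pars, seed = 77)
  ll_pars <- list(A = 0.5, B_old = 1, B_new = 1, t0 = 0.25)
  p_old_hat <- mean(sim$response == "old")
  p_old <- integrate(function(t)
    exp(lba_trial_loglik(t + 0.25, rep("old", length(t)), v_old, v_new,
                         1, ll_pars)), 0, 60, rel.tol = 1e-8)$value
  expect_lt(abs(p_old_hat - p_old), 4 * sqrt(p_old / n) + 0.002)
  # RT deciles of correct-new responses against likelihood-implied quantiles
  f_new <- function(t) exp(lba_trial_loglik(t + 0.25, rep("new", length(t)),
                                            v_old, v_new, 1, ll_pars))
  p_new_tot <- integrate(f_new, 0, 60, rel.tol = 1e-8)$value
  rt_new <- sim$rt_seconds[sim$response == "new"]
  for (q in c(0.1, 0.5, 0.9)) {
    qq <- quantile(rt_new, q)
    implied <- integrate(f_new, 0, qq - 0.25, rel.tol = 1e-8)$value / p_new_tot
    expect_lt(abs(implied - q), 0.01)
  }
  # determinism
  sim2 <- simulate_lba(rep(v_old, 10), rep(v_new, 10), 1, pars, seed = 77)
  expect_identical(sim2, simulate_lba(rep(v_old, 10), rep(v_new, 10), 1,
                                      pars, seed = 77))
})

test_that("the deterministic limit picks the larger drift at rt = t0 + b/v", {
  pars <- lba_params(A = 1e-12, B_old = 1, B_new = 1, t0 = 0.2,
                     eta_target = 1)
  sim <- simulate_lba(3, 1, 1e-9, pars, seed = 5)
  expect_equal(sim$response, "old")
  expect_equal(sim$rt_seconds, 0.2 + (pars$A + 1) / 3, tolerance = 1e-6)
})

test_that("raising both thresholds trades speed for accuracy", {
  lo <- lba_params(A = 0.5, B_old = 0.6, B_new = 0.6, t0 = 0.25)
  hi <- lba_params(A = 0.5, B_old = 2.2, B_new = 2.2, t0 = 0.25)
  n <- 2e4
  sim_lo <- simulate_lba(rep(2.4, n), rep(1.6, n), 1, lo, seed = 31)
  sim_hi <- simulate_lba(rep(2.4, n), rep(1.6, n), 1, hi, seed = 32)
  expect_gt(mean(sim_hi$rt_seconds), mean(sim_lo$rt_seconds))
  expect_gt(mean(sim_hi$response == "old"), mean(sim_lo$response == "old"))
})

test_that("higher global similarity speeds and strengthens old responses", {
  pars <- lba_params()
  n <- 2e4
  gs <- c(0.002, 0.006, 0.012)
  p_old <- numeric(3); rt_old <- numeric(3)
  for (i in seq_along(gs)) {
    dr <- drift_rates(gs[i], V0 = 2, V = -1, gamma = 100)
    sim <- simulate_lba(rep(dr$v_old, n), rep(dr$v_new, n), 1, pars,
                        seed = 40 + i)
    p_old[i] <- mean(sim$response == "old")
    rt_old[i] <- mean(sim$rt_seconds[sim$response == "old"])
  }
  expect_true(all(diff(p_old) > 0))
  expect_true(all(diff(rt_old) < 0))
})
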