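# Small shared fixture: a 2-participant synthetic study.
small_study <- local({
  design <- study_design(n_participants = 2, list_length = 30, n_test = 60,
                         pool_size = 200)
  simulate_study(design, seed = 101)
})

test_that("WAIC matches direct arithmetic on a hand-built matrix", {
  ll <- rbind(c(-1.0, -2.0), c(-1.5, -1.0), c(-0.5, -1.5))
  got <- waic(ll)
  lppd <- sum(log(colMeans(exp(ll))))
  p_w <- sum(apply(ll, 2, var))
  expect_equal(got$lppd, lppd)
  expect_equal(got$p_waic, p_w)
  expect_equal(got$waic, -2 * (lppd - p_w))
  # identical draws: no penalty, waic = -2 * total log-lik
  same <- rbind(c(-1, -2), c(-1, -2))
  expect_equal(waic(same)$p_waic, 0)
  expect_equal(waic(same)$waic, -2 * (-3))
  expect_error(waic(matrix(-1, 1, 3)), "at least two")
})

test_that("pure-noise draws inflate the WAIC penalty", {
  set.seed(7)
  base <- matrix(rep(c(-1, -1.2, -0.8), 50), nrow = 50, byrow = TRUE)
  noisy <- base + matrix(rnorm(150, 0, 0.5), 50)
  expect_gt(waic(noisy)$p_waic, waic(base + 1e-8)$p_waic)
})

test_that("DE-MCMC recovers a correlated 2-D normal target", {
  rho <- 0.8
  siginv <- solve(matrix(c(1, rho, rho, 1), 2))
  log_target <- function(th) -0.5 * drop(t(th) %*% siginv %*% th)
  init <- matrix(rnorm(10 * 2, 0, 3), 10, 2)
  out <- de_mcmc(log_target, init, n_iter = 1500, seed = 5)
  keep <- 501:1500
  draws <- apply(out$draws[keep, , ], 3, c)
  # posterior mean within Monte-Carlo error of zero
  n_eff <- 200  # conservative effective size given autocorrelation
  expect_lt(abs(mean(draws[, 1])), 3 / sqrt(n_eff))
  expect_lt(abs(mean(draws[, 2])), 3 / sqrt(n_eff))
  expect_lt(abs(cor(draws[, 1], draws[, 2]) - rho), 0.1)
  expect_gt(mean(out$acceptance), 0.1)
})

test_that("the sampler rejects degenerate configurations", {
  lt <- function(th) -0.5 * sum(th^2)
  expect_error(de_mcmc(lt, matrix(0, 3, 2)), "chains")
  expect_error(de_mcmc(lt, matrix(rnorm(5), 5, 1), gamma_de = 0, jitter = 0),
               "degenerate")
  init <- matrix(seq(-1, 1, length.out = 6), 6, 1)
  out <- de_mcmc(lt, init, n_iter = 50, seed = 2)
  expect_identical(out$draws,
                   de_mcmc(lt, init, n_iter = 50, seed = 2)$draws)
})

test_that("log posterior composes likelihood, group density, and hyperprior", {
  spec <- parameter_spec(c("B", "t0"))
  model <- gsm_model(small_study$trials, scheme = "slot", spec = spec,
                     fixed = list(A = 0.5, V0 = 2, eta_target = 1,
                                  alpha = 1, omega = 1, w = 0.75,
                                  d = 1.544, r = 1.094, epsilon = 0,
                                  p = 3, gamma_target = 0, gamma_lure = 100,
                                  V_target = 1, V_lure = -1))
  theta <- rbind(c(1, 0.2), c(1.1, 0.22))
  mu <- c(1, 0.2); sigma <- c(0.3, 0.05)
  lp <- log_posterior(model, theta, mu, sigma)
  expect_true(is.finite(lp))
  manual <- log_hyper_prior(mu, sigma, spec) +
    sum(vapply(1:2, function(s)
      log_group_density(theta[s, ], mu, sigma, spec) +
        subject_loglik(model, s, setNames(theta[s, ], spec$name)),
      numeric(1)))
  expect_equal(lp, manual)
  # out-of-support participant draw: -Inf, not an error
  expect_identical(log_posterior(model, rbind(c(-1, 0.2), c(1, 0.2)),
                                 mu, sigma), -Inf)
  # a trial with rt <= t0 propagates -Inf through the likelihood
  theta_bad <- rbind(c(1, 10), c(1, 10))  # t0 above every rt
  expect_identical(log_posterior(model, theta_bad, c(1, 10), sigma), -Inf)
})

test_that("tightening the group scale shrinks participants towards the mean", {
  # 1-D normal-normal toy with known posterior mode: participant parameter
  # theta with a single observation x ~ N(theta, 1) and group N(mu, sigma).
  x <- 2
  post_mode <- function(sigma) (x / 1 + 0 / sigma^2) / (1 + 1 / sigma^2)
  for (sigma in c(10, 1, 0.3, 0.1)) {
    lt <- function(th) dnorm(x, th, 1, log = TRUE) +
      dnorm(th, 0, sigma, log = TRUE)
    opt <- optimize(lt, c(-5, 5), maximum = TRUE)$maximum
    expect_equal(opt, post_mode(sigma), tolerance = 1e-4)
  }
  # the MAP marches towards the group mean as sigma drops
  modes <- vapply(c(10, 1, 0.3, 0.1), post_mode, numeric(1))
  expect_true(all(diff(abs(modes)) < 0))
})

test_that("a short hierarchical fit runs end to end and reports diagnostics", {
  fit <- fit_gsm(small_study$trials, scheme = "open-bigram",
                 spec = parameter_spec(c("B", "t0", "V_target", "V_lure")),
                 fixed = list(A = 0.5, V0 = 2, eta_target = 1,
                              alpha = 1, omega = 1, w = 0.75,
                              d = 1.544, r = 1.094, epsilon = 0,
                              p = 3, gamma_target = 0, gamma_lure = 100),
                 n_iter = 120, seed = 3)
  expect_s3_class(fit, "gsm_fit")
  expect_equal(dim(fit$mu)[3], 4L)
  expect_length(fit$rhat, 4L)
  summ <- group_posterior_summary(fit)
  expect_true(all(is.finite(summ)))
  expect_true(all(summ[, "hdi_lower"] <= summ[, "hdi_upper"]))
  # pointwise log-likelihood has one column per trial
  ll <- pointwise_loglik(fit, n_draws = 20, seed = 4)
  expect_equal(ncol(ll), nrow(small_study$trials))
  expect_equal(nrow(ll), 20L)
  expect_true(all(ll < 10))
  w <- suppressWarnings(model_waic(fit, n_draws = 20, seed = 4))
  expect_true(is.finite(w$waic))
  expect_gte(w$p_waic, 0)
  # posterior predictive summaries are proportions and positive RTs
  pp <- posterior_predictive(fit, n_draws = 10, seed = 5)
  expect_true(all(pp$mean[pp$summary %in% c("hit_rate", "far")] >= 0))
  expect_true(all(pp$mean[pp$summary %in% c("hit_rate", "far")] <= 1))
  expect_gt(pp$mean[pp$summary == "rt_median_correct"], 0)
  expect_true(all(pp$hdi_lower <= pp$hdi_upper))
  # determinism of the whole chain given the seed
  fit2 <- fit_gsm(small_study$trials, scheme = "open-bigram",
                  spec = parameter_spec(c("B", "t0", "V_target", "V_lure")),
                  fixed = fit$fixed, n_iter = 120, seed = 3)
  expect_identical(fit$mu, fit2$mu)
})

test_that("a point-mass posterior makes the predictive equal plain simulation", {
  fit <- fit_gsm(small_study$trials, scheme = "slot",
                 spec = parameter_spec(c("B", "t0")),
                 fixed = list(A = 0.5, V0 = 2, eta_target = 1,
                              alpha = 1, omega = 1, w = 0.75,
                              d = 1.544, r = 1.094, epsilon = 0,
                              p = 3, gamma_target = 0, gamma_lure = 100,
                              V_target = 1, V_lure = -1),
                 n_iter = 60, seed = 9)
  # collapse the posterior onto a single draw
  fit$theta[] <- 1
  fit$theta[, , , 2] <- 0.2  # t0 column
  pp <- posterior_predictive(fit, n_draws = 5, seed = 6)
  expect_true(all(pp$hdi_upper - pp$hdi_lower < 0.2))
})
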