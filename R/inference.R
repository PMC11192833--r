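#' Parameter specification for the hierarchical model
#'
#' One row per estimated participant-level parameter: its support, the
#' hyperprior on the group mean (`Normal(mu0, s0)`), and the half-normal
#' scale of the group standard deviation.  Participant-level parameters are
#' drawn from `Normal(mu, sigma)` truncated to the support.  The default
#' spec covers the single-condition recognition model: threshold offset `B`,
#' non-decision time `t0`, similarity nonlinearity `p`, similarity scales
#' `gamma_target`/`gamma_lure`, and mean-drift components
#' `V_target`/`V_lure`.  Priors are weakly informative defaults and can be
#' overridden row-wise.
#'
#' @param names Which of the default parameters to estimate.
#' @return A data.frame of class `parameter_spec` with columns `name`,
#'   `support`, `mu0`, `s0`, `sigma_scale`, `lower`, `upper`.
#' @export
parameter_spec <- function(names = c("B", "t0", "p", "gamma_target",
                                     "gamma_lure", "V_target", "V_lure")) {
  all <- data.frame(
    name = c("B", "t0", "p", "gamma_target", "gamma_lure",
             "V_target", "V_lure"),
    support = c("positive", "positive", "positive", "real", "real",
                "real", "real"),
    mu0 = c(1, 0.3, 2, 0, 0, 0, 0),
    s0 = c(1, 0.3, 2, 100, 100, 2, 2),
    sigma_scale = c(0.5, 0.2, 1, 10, 10, 1, 1),
    init_spread = c(0.3, 0.05, 0.5, 10, 10, 0.3, 0.3),
    stringsAsFactors = FALSE)
  miss <- setdiff(names, all$name)
  if (length(miss) > 0L) stop("unknown parameter(s): ",
                              paste(miss, collapse = ", "))
  spec <- all[match(names, all$name), , drop = FALSE]
  spec$lower <- ifelse(spec$support == "positive", 1e-3,
                       ifelse(spec$support == "unit", 0, -Inf))
  spec$upper <- ifelse(spec$support == "unit", 1, Inf)
  rownames(spec) <- spec$name
  class(spec) <- c("parameter_spec", class(spec))
  spec
}

# Log density of participant parameters under the (truncated) group normals.
log_group_density <- function(theta, mu, sigma, spec) {
  if (any(sigma <= 0)) return(-Inf)
  if (any(theta < spec$lower | theta > spec$upper)) return(-Inf)
  z <- stats::pnorm(spec$upper, mu, sigma) - stats::pnorm(spec$lower, mu, sigma)
  if (any(z <= 0)) return(-Inf)
  sum(stats::dnorm(theta, mu, sigma, log = TRUE) - log(z))
}

# Hyperprior over the group-level location and scale vectors.
log_hyper_prior <- function(mu, sigma, spec) {
  if (any(sigma <= 0)) return(-Inf)
  sum(stats::dnorm(mu, spec$mu0, spec$s0, log = TRUE)) +
    sum(stats::dnorm(sigma, 0, spec$sigma_scale, log = TRUE) + log(2))
}

#' Precompute the model context for a trial table
#'
#' Splits a trial table by participant and precomputes, per participant, the
#' probe-by-list-position similarity matrix for the chosen representation
#' (self-matches zeroed).  Pairwise similarities do not depend on the
#' sampled parameters once the representation parameters are fixed, so they
#' are computed once; the nonlinearity `p` is applied per likelihood
#' evaluation.
#'
#' @param trials Trial table with observed `response` and `rt_seconds`.
#' @param scheme Orthographic scheme.
#' @param spec A [parameter_spec()].
#' @param fixed Named list of constants: `A`, `V0`, `eta_target` and the
#'   representation parameters (`alpha`, `omega`, `w`, `d`, `r`, `epsilon`),
#'   plus values for any model parameter absent from `spec` (e.g. `p = 1`
#'   for the linear model).
#' @return A list of class `gsm_model`.
#' @export
gsm_model <- function(trials, scheme = "open-bigram",
                      spec = parameter_spec(),
                      fixed = list(A = 0.5, V0 = 2, eta_target = 1,
                                   alpha = 1, omega = 1, w = 0.75,
                                   d = 1.544, r = 1.094, epsilon = 0)) {
  ids <- unique(trials$participant_id)
  subjects <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    S <- similarity_matrix(tr$probe, study_lists(tr), scheme = scheme,
                           alpha = fixed$alpha, omega = fixed$omega,
                           w = fixed$w, d = fixed$d, r = fixed$r,
                           epsilon = fixed$epsilon)
    is_target <- tr$status == "target"
    sub <- list(id = id, rt = tr$rt_seconds, response = tr$response,
                is_target = is_target, S = S, n = nrow(tr),
                idx_t = which(is_target), idx_l = which(!is_target),
                resp_old = tr$response == "old",
                eta = ifelse(is_target, fixed$eta_target, 1))
    # Discrete schemes produce few distinct similarity values (small-integer
    # ratios M/a), so rowSums(S^p) factors as C %*% u^p with u the unique
    # nonzero values and C their per-trial counts -- far cheaper per
    # likelihood evaluation than powering the full matrix.
    uv <- sort(unique(as.vector(S)))
    uv <- uv[uv > 0]
    if (length(uv) > 0L && length(uv) <= 500L) {
      idx <- match(as.vector(S), uv)
      rows <- rep.int(seq_len(nrow(S)), ncol(S))
      keep <- !is.na(idx)
      C <- unname(as.matrix(table(factor(rows[keep], levels = seq_len(nrow(S))),
                                  factor(idx[keep],
                                         levels = seq_along(uv)))))
      storage.mode(C) <- "double"
      sub$u <- uv
      sub$C <- C
    }
    sub
  })
  structure(list(subjects = subjects, spec = spec, fixed = fixed,
                 scheme = scheme, n_subjects = length(subjects)),
            class = "gsm_model")
}

MODEL_PARAMS <- c("B", "t0", "p", "gamma_target", "gamma_lure",
                  "V_target", "V_lure")

# Resolve the seven model parameters from an estimated vector plus the fixed
# list; returns a numeric vector in MODEL_PARAMS order.
resolve_params <- function(theta, spec_names, fixed) {
  idx <- match(MODEL_PARAMS, spec_names)
  vals <- numeric(7L)
  for (k in seq_len(7L)) {
    vals[k] <- if (!is.na(idx[k])) theta[[idx[k]]]
      else if (!is.null(fixed[[MODEL_PARAMS[k]]])) fixed[[MODEL_PARAMS[k]]]
      else stop("parameter ", MODEL_PARAMS[k],
                " neither estimated nor fixed")
  }
  vals
}

# Likelihood hot path: `vals` ordered as MODEL_PARAMS.
subject_loglik_core <- function(sub, fx, vals, pointwise = FALSE) {
  B <- vals[1L]; t0 <- vals[2L]; p <- vals[3L]
  if (p <= 0 || B <= 0 || t0 < 0) {
    return(if (pointwise) rep(-Inf, sub$n) else -Inf)
  }
  g <- if (!is.null(sub$C)) drop(sub$C %*% sub$u^p) / ncol(sub$S)
    else rowSums(sub$S^p) / ncol(sub$S)
  shift <- numeric(sub$n)
  shift[sub$idx_t] <- vals[6L] + vals[4L] * g[sub$idx_t]
  shift[sub$idx_l] <- vals[7L] + vals[5L] * g[sub$idx_l]
  v_old <- fx$V0 + shift
  v_new <- fx$V0 - shift
  t <- sub$rt - t0
  ll <- rep(-Inf, sub$n)
  ok <- which(t > 0)
  if (length(ok) > 0L) {
    vw <- v_new; vw[sub$resp_old] <- v_old[sub$resp_old]
    vl <- v_old; vl[sub$resp_old] <- v_new[sub$resp_old]
    b <- fx$A + B
    fw <- lba_density_vecb(t[ok], b, fx$A, vw[ok], sub$eta[ok])
    Fl <- lba_cdf_vecb(t[ok], b, fx$A, vl[ok], sub$eta[ok])
    p_none <- stats::pnorm(-v_old[ok] / sub$eta[ok]) *
      stats::pnorm(-v_new[ok] / sub$eta[ok])
    val <- log(fw) + log1p(-Fl) - log1p(-p_none)
    val[!is.finite(val)] <- -Inf
    ll[ok] <- val
  }
  if (pointwise) ll else sum(ll)
}

# Per-trial log-likelihood of one participant at named parameter vector theta.
subject_loglik <- function(model, s, theta, pointwise = FALSE) {
  vals <- resolve_params(theta, names(theta), model$fixed)
  subject_loglik_core(model$subjects[[s]], model$fixed, vals,
                      pointwise = pointwise)
}

# Batched likelihood over several parameter vectors (rows of `vals_mat`,
# MODEL_PARAMS order) for one participant: one vectorized pass over
# chains x trials instead of a per-chain loop.
subject_loglik_batch <- function(sub, fx, vals_mat) {
  m <- nrow(vals_mat)
  n <- sub$n
  out <- rep(-Inf, m)
  ok <- which(vals_mat[, 3L] > 0 & vals_mat[, 1L] > 0 & vals_mat[, 2L] >= 0)
  if (length(ok) == 0L) return(out)
  vm <- vals_mat[ok, , drop = FALSE]
  k <- nrow(vm)
  n_l <- ncol(sub$S)
  if (!is.null(sub$C)) {
    g <- sub$C %*% outer(sub$u, vm[, 3L], "^") / n_l
  } else {
    g <- matrix(0, n, k)
    for (i in seq_len(k)) {
      g[, i] <- .rowSums(sub$S^vm[i, 3L], n, n_l)
    }
    g <- g / n_l
  }
  gam <- outer(sub$is_target, vm[, 4L]) + outer(!sub$is_target, vm[, 5L])
  Vm <- outer(sub$is_target, vm[, 6L]) + outer(!sub$is_target, vm[, 7L])
  shift <- Vm + gam * g
  v_old <- fx$V0 + shift
  v_new <- fx$V0 - shift
  t <- matrix(sub$rt, n, k) - matrix(vm[, 2L], n, k, byrow = TRUE)
  vw <- v_new; vw[sub$resp_old, ] <- v_old[sub$resp_old, ]
  vl <- v_old; vl[sub$resp_old, ] <- v_new[sub$resp_old, ]
  b <- matrix(fx$A + vm[, 1L], n, k, byrow = TRUE)
  eta <- matrix(sub$eta, n, k)
  ll <- matrix(-Inf, n, k)
  pos <- which(t > 0)
  if (length(pos) > 0L) {
    fw <- lba_density_vecb(t[pos], b[pos], fx$A, vw[pos], eta[pos])
    Fl <- lba_cdf_vecb(t[pos], b[pos], fx$A, vl[pos], eta[pos])
    p_none <- stats::pnorm(-v_old[pos] / eta[pos]) *
      stats::pnorm(-v_new[pos] / eta[pos])
    val <- log(fw) + log1p(-Fl) - log1p(-p_none)
    val[!is.finite(val)] <- -Inf
    ll[pos] <- val
  }
  out[ok] <- colSums(ll)
  out
}

#' Joint log posterior of the hierarchical model
#'
#' Sum of (i) every participant's data log-likelihood at their parameters,
#' (ii) the log density of those parameters under the group-level truncated
#' normals, and (iii) the hyperprior over the group means and SDs.
#'
#' @param model A [gsm_model()].
#' @param theta Matrix of participant parameters (participants x
#'   parameters, columns ordered as `model$spec`).
#' @param mu,sigma Group-level mean and SD vectors.
#' @return A single log-posterior value (`-Inf` outside the support).
#' @export
log_posterior <- function(model, theta, mu, sigma) {
  spec <- model$spec
  lp <- log_hyper_prior(mu, sigma, spec)
  if (!is.finite(lp)) return(-Inf)
  for (s in seq_len(model$n_subjects)) {
    th <- stats::setNames(theta[s, ], spec$name)
    pr <- log_group_density(theta[s, ], mu, sigma, spec)
    if (!is.finite(pr)) return(-Inf)
    lp <- lp + pr + subject_loglik(model, s, th)
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

# Conditional log posterior of one group-level (mu, sigma) pair given the
# participant draws of that parameter across subjects.
group_column_logpost <- function(theta_col, mu, sigma, lower, upper,
                                 mu0, s0, sigma_scale) {
  if (sigma <= 0) return(-Inf)
  z <- stats::pnorm(upper, mu, sigma) - stats::pnorm(lower, mu, sigma)
  if (z <= 0) return(-Inf)
  sum(stats::dnorm(theta_col, mu, sigma, log = TRUE)) -
    length(theta_col) * log(z) +
    stats::dnorm(mu, mu0, s0, log = TRUE) +
    stats::dnorm(sigma, 0, sigma_scale, log = TRUE) + log(2)
}

# DE crossover proposal for chain i over the rows of `state` (chains x d).
de_propose <- function(state, i, gamma_de, jitter) {
  others <- resample(setdiff(seq_len(nrow(state)), i), 2L)
  state[i, ] + gamma_de * (state[others[1L], ] - state[others[2L], ]) +
    stats::runif(ncol(state), -jitter, jitter)
}

#' Differential-evolution MCMC on an arbitrary log target
#'
#' Plain (non-hierarchical) DE-MCMC: each chain proposes
#' \eqn{\theta^* = \theta_i + \gamma(\theta_j - \theta_k) + U(-j, j)} using
#' two other randomly chosen chains and accepts by the Metropolis rule.
#' Differences of chain states automatically align proposals with the
#' target's correlation structure, which is what makes the sampler suited
#' to strongly correlated posteriors.  With probability 0.1 a proposal uses
#' \eqn{\gamma = 1} to allow mode jumps.
#'
#' @param log_target Function of a parameter vector returning a log density.
#' @param init Matrix of starting states (chains x dimension); at least
#'   `2 * dimension + 1` chains.
#' @param n_iter Number of iterations.
#' @param gamma_de Scale of the difference vector; default
#'   `2.38 / sqrt(2 d)`.  A value of 0 with `jitter = 0` is rejected as
#'   degenerate (chains could never move).
#' @param jitter Half-width of the uniform perturbation (default `1e-4`).
#' @param seed Integer seed (the sampler is deterministic given it).
#' @return A list with `draws` (array `n_iter` x chains x dimension) and
#'   `acceptance` (per-chain acceptance rate).
#' @export
de_mcmc <- function(log_target, init, n_iter = 500L,
                    gamma_de = 2.38 / sqrt(2 * ncol(init)),
                    jitter = 1e-4, seed = 1L) {
  K <- nrow(init); d <- ncol(init)
  if (K < 2L * d + 1L) {
    stop("need at least 2 * dimension + 1 chains (got ", K, " for d = ", d, ")")
  }
  if (gamma_de == 0 && jitter == 0) {
    stop("degenerate tuning: gamma_de = 0 with jitter = 0 can never move")
  }
  with_seed(seed, {
    state <- init
    lp <- apply(state, 1L, log_target)
    draws <- array(NA_real_, c(n_iter, K, d))
    acc <- numeric(K)
    for (it in seq_len(n_iter)) {
      for (i in seq_len(K)) {
        g <- if (stats::runif(1L) < 0.1) 1 else gamma_de
        prop <- de_propose(state, i, g, jitter)
        lp_new <- log_target(prop)
        if (is.finite(lp_new) &&
            log(stats::runif(1L)) < lp_new - lp[i]) {
          state[i, ] <- prop
          lp[i] <- lp_new
          acc[i] <- acc[i] + 1L
        }
      }
      draws[it, , ] <- state
    }
    list(draws = draws, acceptance = acc / n_iter)
  })
}

#' Fit the hierarchical global-similarity LBA model by DE-MCMC
#'
#' Blocked differential-evolution MCMC for the hierarchical model:
#' participant-level parameter blocks are updated conditional on the
#' group-level means/SDs (each proposal re-evaluating that participant's
#' trial likelihood), then the group-level block is updated conditional on
#' the participant parameters (no likelihood evaluation needed).  Chains are
#' initialized by drawing from the hyperpriors, shrunk towards their
#' centers.
#'
#' @inheritParams gsm_model
#' @param n_chains Number of chains; defaults to `2 d + 1` with `d` the
#'   number of estimated parameters.
#' @param n_iter Total iterations (the first `burn` fraction is discarded in
#'   summaries).
#' @param burn Burn-in fraction (default 0.5).
#' @param gamma_de,jitter DE proposal tuning; defaults `2.38 / sqrt(2 d)`
#'   and `1e-4`.
#' @param seed Integer seed.
#' @return A list of class `gsm_fit`: posterior arrays `theta`
#'   (iteration x chain x participant x parameter), `mu`, `sigma`
#'   (iteration x chain x parameter), the model context, burn-in index,
#'   split-chain R-hat per group mean, and acceptance rates.
#' @export
fit_gsm <- function(trials, scheme = "open-bigram", spec = parameter_spec(),
                    fixed = list(A = 0.5, V0 = 2, eta_target = 1,
                                 alpha = 1, omega = 1, w = 0.75,
                                 d = 1.544, r = 1.094, epsilon = 0),
                    n_chains = NULL, n_iter = 500L, burn = 0.5,
                    gamma_de = NULL, jitter = 1e-4, seed = 1L) {
  model <- gsm_model(trials, scheme = scheme, spec = spec, fixed = fixed)
  spec <- model$spec
  d <- nrow(spec)
  n_subj <- model$n_subjects
  if (is.null(n_chains)) n_chains <- 2L * d + 1L
  if (n_chains < 2L * d + 1L) {
    stop("need at least 2 * dimension + 1 chains (got ", n_chains, ")")
  }
  if (is.null(gamma_de)) gamma_de <- 2.38 / sqrt(2 * d)
  K <- n_chains

  # Parameter resolution table for the likelihood hot path.
  par_idx <- match(MODEL_PARAMS, spec$name)
  est <- !is.na(par_idx)
  fb <- vapply(MODEL_PARAMS, function(nm) {
    v <- fixed[[nm]]
    if (is.null(v)) NA_real_ else v
  }, numeric(1L))
  if (any(!est & is.na(fb))) {
    stop("parameter(s) neither estimated nor fixed: ",
         paste(MODEL_PARAMS[!est & is.na(fb)], collapse = ", "))
  }
  loglik_fast <- function(s, th, pointwise = FALSE) {
    vals <- fb
    vals[est] <- th[par_idx[est]]
    subject_loglik_core(model$subjects[[s]], fixed, vals,
                        pointwise = pointwise)
  }

  # Plain-vector views of the spec columns for the inner loops.
  lo <- spec$lower; up <- spec$upper
  mu0v <- spec$mu0; s0v <- spec$s0; sscale <- spec$sigma_scale
  grp_dens <- function(theta, mu, sigma) {
    if (any(theta < lo) || any(theta > up)) return(-Inf)
    z <- stats::pnorm(up, mu, sigma) - stats::pnorm(lo, mu, sigma)
    if (any(z <= 0)) return(-Inf)
    sum(stats::dnorm(theta, mu, sigma, log = TRUE)) - sum(log(z))
  }

  # Cheap data-driven chain-start centers (standard practice: start near a
  # plausible point so the burn-in is spent exploring, not finding, the
  # posterior mass).  The drift-rate mapping implies
  # P("old") ~ Phi(sqrt(2) (V + gamma g) / eta), so a probit regression of
  # the old/new response on global similarity (evaluated at the p start
  # value) gives moment-style starts for V and gamma within each status.
  p_init <- 2
  centers <- c(B = 1,
               t0 = max(0.05, 0.7 * min(trials$rt_seconds)),
               p = p_init, gamma_target = 0, gamma_lure = 0,
               V_target = 0.5, V_lure = -0.5)
  g_all <- unlist(lapply(model$subjects, function(sub)
    rowSums(sub$S^p_init) / ncol(sub$S)))
  old_all <- unlist(lapply(model$subjects, function(sub) sub$resp_old))
  targ_all <- unlist(lapply(model$subjects, function(sub) sub$is_target))
  for (st in c("target", "lure")) {
    sel <- if (st == "target") targ_all else !targ_all
    co <- tryCatch(
      suppressWarnings(stats::coef(stats::glm(
        old_all[sel] ~ g_all[sel],
        family = stats::binomial("probit")))),
      error = function(e) c(0, 0))
    co[!is.finite(co)] <- 0
    centers[[paste0("V_", st)]] <- min(max(co[[1L]] / sqrt(2), -2.5), 2.5)
    centers[[paste0("gamma_", st)]] <-
      min(max(co[[2L]] / sqrt(2), -500), 500)
  }
  mu_center <- centers[spec$name]

  with_seed(seed, {
    mu_s <- matrix(stats::rnorm(K * d, rep(mu_center, each = K),
                                rep(spec$init_spread, each = K)), K, d)
    sigma_s <- matrix(abs(stats::rnorm(K * d, 0,
                                       rep(spec$sigma_scale, each = K) / 4)),
                      K, d) + 0.05
    theta_s <- array(NA_real_, c(K, n_subj, d))
    for (i in seq_len(K)) {
      for (s in seq_len(n_subj)) {
        theta_s[i, s, ] <- pmin(pmax(
          stats::rnorm(d, mu_s[i, ], sigma_s[i, ]),
          spec$lower + 1e-6), 1e6)
      }
    }

    # Redraw any chain x participant start state with a degenerate (-Inf)
    # likelihood, shrinking towards the data-driven centers.
    ll_data <- matrix(NA_real_, K, n_subj)
    for (i in seq_len(K)) {
      for (s in seq_len(n_subj)) {
        ll_data[i, s] <- loglik_fast(s, theta_s[i, s, ])
        attempt <- 0L
        while (!is.finite(ll_data[i, s]) && attempt < 60L) {
          shrink <- 0.7^min(attempt, 12L)
          theta_s[i, s, ] <- pmin(pmax(
            stats::rnorm(d, mu_center, spec$init_spread * shrink),
            spec$lower + 1e-6), 1e6)
          ll_data[i, s] <- loglik_fast(s, theta_s[i, s, ])
          attempt <- attempt + 1L
        }
        if (!is.finite(ll_data[i, s])) {
          stop("could not find a finite-likelihood start state for ",
               "participant ", s, "; check rt_seconds against t0")
        }
      }
    }

    theta_draws <- array(NA_real_, c(n_iter, K, n_subj, d))
    mu_draws <- array(NA_real_, c(n_iter, K, d))
    sigma_draws <- array(NA_real_, c(n_iter, K, d))
    acc_theta <- 0L; acc_group <- 0L

    gamma_grp <- 2.38 / sqrt(2 * 2)  # group blocks are 2-D (mu, sigma)
    burn_end <- floor(n_iter * burn)
    for (it in seq_len(n_iter)) {
      # Burn-in-only chain rescue: a chain whose participant block is far
      # below the best chain's log-likelihood is stuck (e.g. started in a
      # region the DE differences cannot bridge); re-seed it near a
      # well-performing chain.  Restricted to burn-in, which is discarded,
      # so the stationary distribution of the kept draws is untouched.
      if (it <= burn_end && it %% 20L == 0L) {
        for (s in seq_len(n_subj)) {
          best <- which.max(ll_data[, s])
          stuck <- which(ll_data[, s] < ll_data[best, s] - 30)
          for (i in stuck) {
            prop <- theta_s[best, s, ] +
              stats::rnorm(d, 0, pmax(abs(theta_s[best, s, ]) * 0.02, 1e-3))
            prop <- pmin(pmax(prop, spec$lower + 1e-6), 1e6)
            ll_new <- loglik_fast(s, prop)
            if (is.finite(ll_new)) {
              theta_s[i, s, ] <- prop
              ll_data[i, s] <- ll_new
            }
          }
        }
      }
      # Participant-level blocks: all chains propose against the current
      # generation simultaneously (synchronous DE-MCMC), which lets the
      # trial likelihood be evaluated in one vectorized pass per
      # participant.
      for (s in seq_len(n_subj)) {
        cur <- theta_s[, s, , drop = TRUE]
        if (d == 1L) cur <- matrix(cur, ncol = 1L)
        gmult <- ifelse(stats::runif(K) < 0.1, 1, gamma_de)
        jk <- vapply(seq_len(K), function(i)
          resample(setdiff(seq_len(K), i), 2L), integer(2L))
        prop <- cur + gmult * (cur[jk[1L, ], , drop = FALSE] -
                                 cur[jk[2L, ], , drop = FALSE]) +
          matrix(stats::runif(K * d, -jitter, jitter), K, d)
        in_support <- .colSums(t(prop) < lo | t(prop) > up, d, K) == 0
        pr_new <- rep(-Inf, K)
        pr_old <- numeric(K)
        for (i in seq_len(K)) {
          pr_old[i] <- grp_dens(cur[i, ], mu_s[i, ], sigma_s[i, ])
          if (in_support[i]) {
            pr_new[i] <- grp_dens(prop[i, ], mu_s[i, ], sigma_s[i, ])
          }
        }
        cand <- which(is.finite(pr_new))
        if (length(cand) > 0L) {
          vals_mat <- matrix(fb, length(cand), 7L, byrow = TRUE)
          vals_mat[, est] <- prop[cand, par_idx[est], drop = FALSE]
          ll_new <- subject_loglik_batch(model$subjects[[s]], fixed,
                                         vals_mat)
          u <- log(stats::runif(length(cand)))
          accept <- is.finite(ll_new) &
            u < (ll_new + pr_new[cand]) - (ll_data[cand, s] + pr_old[cand])
          take <- cand[accept]
          if (length(take) > 0L) {
            theta_s[take, s, ] <- prop[take, , drop = FALSE]
            ll_data[take, s] <- ll_new[accept]
            acc_theta <- acc_theta + length(take)
          }
        }
      }
      # Group-level blocks (conditional on theta; data likelihood drops
      # out): one (mu_j, sigma_j) pair per parameter, so each 2-D block
      # mixes on its own scale.
      for (j in seq_len(d)) {
        th_j <- theta_s[, , j, drop = TRUE]  # chains x subjects
        if (n_subj == 1L) th_j <- matrix(th_j, ncol = 1L)
        phi <- cbind(mu_s[, j], sigma_s[, j])
        lp_col <- vapply(seq_len(K), function(i)
          group_column_logpost(th_j[i, ], phi[i, 1L], phi[i, 2L],
                               lo[j], up[j],
                               mu0v[j], s0v[j], sscale[j]),
          numeric(1L))
        for (i in seq_len(K)) {
          g <- if (stats::runif(1L) < 0.1) 1 else gamma_grp
          prop <- de_propose(phi, i, g, jitter)
          if (prop[2L] <= 0) next
          lp_new <- group_column_logpost(th_j[i, ], prop[1L], prop[2L],
                                         lo[j], up[j], mu0v[j], s0v[j],
                                         sscale[j])
          if (is.finite(lp_new) &&
              log(stats::runif(1L)) < lp_new - lp_col[i]) {
            mu_s[i, j] <- prop[1L]
            sigma_s[i, j] <- prop[2L]
            phi[i, ] <- prop
            lp_col[i] <- lp_new
            acc_group <- acc_group + 1L
          }
        }
      }
      theta_draws[it, , , ] <- theta_s
      mu_draws[it, , ] <- mu_s
      sigma_draws[it, , ] <- sigma_s
    }

    keep <- seq.int(floor(n_iter * burn) + 1L, n_iter)
    rhat <- vapply(seq_len(d), function(j)
      split_rhat(mu_draws[keep, , j, drop = TRUE]), numeric(1L))
    names(rhat) <- spec$name
    structure(list(theta = theta_draws, mu = mu_draws, sigma = sigma_draws,
                   keep = keep, model = model, spec = spec, fixed = fixed,
                   scheme = scheme, seed = seed, rhat = rhat,
                   acceptance = c(theta = acc_theta / (n_iter * K * n_subj),
                                  group = acc_group / (n_iter * K * d))),
              class = "gsm_fit")
  })
}

#' @export
print.gsm_fit <- function(x, ...) {
  cat(sprintf("hierarchical global-similarity LBA fit (%s scheme)\n", x$scheme))
  cat(sprintf("  %d participants, %d chains, %d iterations (%d kept)\n",
              x$model$n_subjects, dim(x$mu)[2L], dim(x$mu)[1L],
              length(x$keep)))
  cat(sprintf("  acceptance: theta %.2f, group %.2f; max split R-hat %.3f\n",
              x$acceptance[["theta"]], x$acceptance[["group"]], max(x$rhat)))
  print(round(group_posterior_summary(x), 3))
  invisible(x)
}

# Split-chain R-hat on a draws matrix (iterations x chains).
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2L)
  if (half < 2L) return(NA_real_)
  chains <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(chains); nn <- nrow(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2L, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Posterior draws and summaries of the group-level means
#'
#' @param fit A [fit_gsm()] result.
#' @param param Parameter name (e.g. `"gamma_lure"`).
#' @return `group_mu_draws()`: numeric vector of post-burn-in draws pooled
#'   over chains.  `group_posterior_summary()`: a matrix of posterior means
#'   and 95% HDIs per parameter.
#' @export
group_mu_draws <- function(fit, param) {
  j <- match(param, fit$spec$name)
  if (is.na(j)) stop("unknown parameter: ", param)
  as.vector(fit$mu[fit$keep, , j])
}

#' @rdname group_mu_draws
#' @export
group_posterior_summary <- function(fit) {
  t(vapply(fit$spec$name, function(p) {
    x <- group_mu_draws(fit, p)
    h <- hdi(x)
    c(mean = mean(x), hdi_lower = h[["lower"]], hdi_upper = h[["upper"]])
  }, numeric(3L)))
}

#' Pointwise posterior log-likelihood matrix
#'
#' Evaluates the per-trial log-likelihood at a subsample of posterior draws,
#' giving the draws-by-trials matrix WAIC needs.
#'
#' @param fit A [fit_gsm()] result.
#' @param n_draws Number of posterior draws to use.
#' @param seed Seed for the draw subsample.
#' @return Matrix (draws x trials, trials ordered participant-major).
#' @export
pointwise_loglik <- function(fit, n_draws = 100L, seed = 1L) {
  model <- fit$model
  spec <- fit$spec
  K <- dim(fit$mu)[2L]
  grid <- expand.grid(it = fit$keep, ch = seq_len(K))
  pick <- with_seed(seed,
                    grid[sample.int(nrow(grid), min(n_draws, nrow(grid))), ])
  n_trials <- sum(vapply(model$subjects, `[[`, integer(1L), "n"))
  ll <- matrix(NA_real_, nrow(pick), n_trials)
  for (r in seq_len(nrow(pick))) {
    row <- numeric(0)
    for (s in seq_len(model$n_subjects)) {
      th <- stats::setNames(fit$theta[pick$it[r], pick$ch[r], s, ], spec$name)
      row <- c(row, subject_loglik(model, s, th, pointwise = TRUE))
    }
    ll[r, ] <- row
  }
  ll
}

#' Widely applicable information criterion
#'
#' `lppd = sum_i log mean_s exp(ll_si)` and the penalty
#' `p_waic = sum_i var_s(ll_si)`; `waic = -2 (lppd - p_waic)`.  Lower values
#' are preferred.  The penalty is driven by the per-trial variability of the
#' log-likelihood across posterior draws, so redundant parameters increase
#' it.
#'
#' @param ll Matrix of pointwise log-likelihoods (posterior draws x data
#'   points), e.g. from [pointwise_loglik()]; at least two draws.
#' @return A list with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(ll) {
  if (!is.matrix(ll) || nrow(ll) < 2L) {
    stop("need a matrix with at least two posterior draws")
  }
  S <- nrow(ll)
  lppd <- sum(apply(ll, 2L, function(col) log_sum_exp(col) - log(S)))
  p_waic <- sum(apply(ll, 2L, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' WAIC of a fitted model (with a convergence guard)
#'
#' @param fit A [fit_gsm()] result.
#' @param n_draws,seed Passed to [pointwise_loglik()].
#' @param rhat_limit Warn if any group-mean split R-hat exceeds this.
#' @return As [waic()].
#' @export
model_waic <- function(fit, n_draws = 100L, seed = 1L, rhat_limit = 1.05) {
  if (any(is.finite(fit$rhat) & fit$rhat > rhat_limit)) {
    warning("split R-hat above ", rhat_limit, " for: ",
            paste(names(fit$rhat)[fit$rhat > rhat_limit], collapse = ", "),
            "; WAIC may be unreliable")
  }
  waic(pointwise_loglik(fit, n_draws = n_draws, seed = seed))
}

#' Posterior predictive summaries
#'
#' Simulates replicate datasets over the fitted trial structure from a
#' subsample of posterior draws and summarizes each with the overall hit
#' rate, false-alarm rate, and median correct RT; returns the predictive
#' mean and 95% HDI of each summary.
#'
#' @param fit A [fit_gsm()] result.
#' @param n_draws Number of posterior draws to simulate from.
#' @param seed Seed for the subsample and simulations.
#' @return A data.frame with columns `summary`, `mean`, `hdi_lower`,
#'   `hdi_upper`.
#' @export
posterior_predictive <- function(fit, n_draws = 50L, seed = 1L) {
  model <- fit$model
  spec <- fit$spec
  fx <- fit$fixed
  K <- dim(fit$mu)[2L]
  grid <- expand.grid(it = fit$keep, ch = seq_len(K))
  pick <- with_seed(seed,
                    grid[sample.int(nrow(grid), min(n_draws, nrow(grid))), ])
  stats_mat <- matrix(NA_real_, nrow(pick), 3L,
                      dimnames = list(NULL, c("hit_rate", "far",
                                              "rt_median_correct")))
  for (r in seq_len(nrow(pick))) {
    hits <- 0L; n_t <- 0L; fas <- 0L; n_l <- 0L; rts <- numeric(0)
    for (s in seq_len(model$n_subjects)) {
      sub <- model$subjects[[s]]
      th <- stats::setNames(fit$theta[pick$it[r], pick$ch[r], s, ], spec$name)
      get <- function(nm) if (nm %in% names(th)) th[[nm]] else fx[[nm]]
      g <- global_similarity_from_matrix(sub$S, get("p"))
      V <- ifelse(sub$is_target, get("V_target"), get("V_lure"))
      gam <- ifelse(sub$is_target, get("gamma_target"), get("gamma_lure"))
      dr <- drift_rates(g, fx$V0, V, gam)
      pars <- lba_params(A = fx$A, B_old = get("B"), B_new = get("B"),
                         t0 = get("t0"), eta_target = fx$eta_target,
                         V0 = fx$V0)
      eta <- ifelse(sub$is_target, fx$eta_target, 1)
      sim <- simulate_lba(dr$v_old, dr$v_new, eta, pars,
                          seed = derive_seed(seed, r * 1000L + s))
      old <- sim$response == "old"
      hits <- hits + sum(old & sub$is_target)
      n_t <- n_t + sum(sub$is_target)
      fas <- fas + sum(old & !sub$is_target)
      n_l <- n_l + sum(!sub$is_target)
      correct <- old == sub$is_target
      rts <- c(rts, sim$rt_seconds[correct])
    }
    stats_mat[r, ] <- c(hits / n_t, fas / n_l, stats::median(rts))
  }
  out <- lapply(colnames(stats_mat), function(nm) {
    x <- stats_mat[, nm]
    h <- hdi(x)
    data.frame(summary = nm, mean = mean(x), hdi_lower = h[["lower"]],
               hdi_upper = h[["upper"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
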