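#' Linear ballistic accumulator parameters
#'
#' Convenience constructor (with validity checks) for the decision-model
#' parameters shared by the likelihood and the simulator.
#'
#' @param A Starting-point range (>= 0); the start of each accumulator is
#'   drawn from Uniform(0, A).
#' @param B_old,B_new Threshold offsets (> 0); the response threshold is
#'   `b = A + B` for each accumulator.
#' @param t0 Non-decision time in seconds (>= 0).
#' @param eta_target Drift-rate standard deviation on target trials (> 0).
#'   The lure drift SD is fixed at 1 for identifiability; the SD applies to
#'   both accumulators on a trial, chosen by the probe's status.
#' @param V0 Drift shift keeping mean drifts positive.
#' @param V Named numeric vector of mean-drift components, one per
#'   condition-by-status cell (e.g. `c(target = 1, lure = -1)`).
#' @param gamma Named numeric vector of similarity-scale parameters matching
#'   `V` (e.g. `c(target = 0, lure = 25)`).
#' @return A list of class `lba_params`.
#' @export
lba_params <- function(A = 0.5, B_old = 1, B_new = 1, t0 = 0.25,
                       eta_target = 1, V0 = 2,
                       V = c(target = 1, lure = -1),
                       gamma = c(target = 0, lure = 100)) {
  stopifnot(A >= 0, B_old > 0, B_new > 0, t0 >= 0, eta_target > 0)
  if (!setequal(names(V), names(gamma))) {
    stop("V and gamma must be named over the same condition/status cells")
  }
  structure(list(A = A, B_old = B_old, B_new = B_new, t0 = t0,
                 eta_target = eta_target, eta_lure = 1, V0 = V0,
                 V = V, gamma = gamma),
            class = "lba_params")
}

#' Trial-level drift rates from global similarity
#'
#' Maps the global similarity `g` of a trial into the mean drift rates of
#' the "old" and "new" accumulators,
#' \deqn{v_{old} = V_0 + V + \gamma g, \qquad v_{new} = V_0 - (V + \gamma g),}
#' so that evidence gained by one response is lost by the other
#' (`v_old + v_new = 2 V0` always).
#'
#' @param g Numeric vector of global similarities.
#' @param V0 Drift shift.
#' @param V Mean-drift component for this condition/status cell (vector
#'   recycled against `g`).
#' @param gamma Similarity scale for this cell.
#' @return A data.frame with columns `v_old` and `v_new`.
#' @examples
#' drift_rates(g = c(0, 0.1), V0 = 2, V = -1, gamma = 25)
#' @export
drift_rates <- function(g, V0, V, gamma) {
  shift <- V + gamma * g
  data.frame(v_old = V0 + shift, v_new = V0 - shift)
}

#' Defective density and distribution of one LBA accumulator
#'
#' First-passage density/CDF of a single linear ballistic accumulator with
#' threshold `b`, start point Uniform(0, A) and drift Normal(`v`, `eta`),
#' *not* conditioned on winning the race: as `t` grows the CDF approaches
#' the probability the accumulator ever finishes (`pnorm(v/eta)`), which is
#' below 1 whenever negative drifts have mass.
#'
#' @param t Decision time (seconds after non-decision time), > 0;
#'   vectorized.
#' @param b Threshold (> A).
#' @param A Starting-point range (>= 0).
#' @param v Mean drift rate.
#' @param eta Drift-rate standard deviation (> 0).
#' @return Numeric vector of densities (`lba_density`) or probabilities
#'   (`lba_cdf`).
#' @examples
#' tt <- seq(0.05, 3, by = 0.05)
#' f <- lba_density(tt, b = 1.5, A = 0.5, v = 2, eta = 1)
#' @export
lba_density <- function(t, b, A, v, eta) {
  stopifnot(b > A, A >= 0, eta > 0)
  out <- numeric(length(t))
  pos <- which(t > 0)
  tt <- t[pos]
  if (A < 1e-10) {
    # Degenerate start point: first passage of b / drift.
    out[pos] <- b / (eta * tt^2) * stats::dnorm((b / tt - v) / eta)
  } else {
    z1 <- (b - A - tt * v) / (tt * eta)
    z2 <- (b - tt * v) / (tt * eta)
    out[pos] <- (1 / A) * (-v * stats::pnorm(z1) + eta * stats::dnorm(z1) +
                             v * stats::pnorm(z2) - eta * stats::dnorm(z2))
  }
  pmax(out, 0)
}

#' @rdname lba_density
#' @export
lba_cdf <- function(t, b, A, v, eta) {
  stopifnot(b > A, A >= 0, eta > 0)
  out <- numeric(length(t))
  pos <- which(t > 0)
  tt <- t[pos]
  if (A < 1e-10) {
    out[pos] <- stats::pnorm((v - b / tt) / eta)
  } else {
    z1 <- (b - A - tt * v) / (tt * eta)
    z2 <- (b - tt * v) / (tt * eta)
    out[pos] <- 1 + ((b - A - tt * v) / A) * stats::pnorm(z1) -
      ((b - tt * v) / A) * stats::pnorm(z2) +
      ((tt * eta) / A) * (stats::dnorm(z1) - stats::dnorm(z2))
  }
  pmin(pmax(out, 0), 1)
}

# eta for a trial given probe status (both accumulators share it).
status_eta <- function(status, params) {
  ifelse(status == "target", params$eta_target, params$eta_lure)
}

#' Trial log-likelihood of the two-accumulator LBA race
#'
#' Log density of observing response `response` at time `rt` given the mean
#' drift rates of the two accumulators: the winner's defective density times
#' the loser's survival, renormalized by the probability that at least one
#' drift is positive (matching the simulator's convention of redrawing the
#' drift pair when both are nonpositive).  Trials with `rt <= t0` receive
#' `-Inf` rather than an error so samplers can reject them.
#'
#' @param rt Response times in seconds (vector).
#' @param response Character vector, `"old"` or `"new"`.
#' @param v_old,v_new Mean drift rates per trial.
#' @param eta Drift SD per trial (scalar or vector).
#' @param params An [lba_params()] object supplying `A`, `B_old`, `B_new`,
#'   `t0`.
#' @return Numeric vector of per-trial log-likelihoods.
#' @export
lba_trial_loglik <- function(rt, response, v_old, v_new, eta, params) {
  n <- length(rt)
  eta <- rep_len(eta, n)
  v_old <- rep_len(v_old, n)
  v_new <- rep_len(v_new, n)
  t <- rt - params$t0
  b_old <- params$A + params$B_old
  b_new <- params$A + params$B_new
  old_resp <- response == "old"

  vw <- ifelse(old_resp, v_old, v_new)
  vl <- ifelse(old_resp, v_new, v_old)
  bw <- ifelse(old_resp, b_old, b_new)
  bl <- ifelse(old_resp, b_new, b_old)

  ll <- rep(-Inf, n)
  ok <- which(t > 0)
  if (length(ok) > 0L) {
    fw <- lba_density_vecb(t[ok], bw[ok], params$A, vw[ok], eta[ok])
    Fl <- lba_cdf_vecb(t[ok], bl[ok], params$A, vl[ok], eta[ok])
    p_none <- stats::pnorm(-v_old[ok] / eta[ok]) *
      stats::pnorm(-v_new[ok] / eta[ok])
    val <- log(fw) + log1p(-Fl) - log1p(-p_none)
    val[!is.finite(val)] <- -Inf
    ll[ok] <- val
  }
  ll
}

# Vector-b variants used internally (b and eta vary by trial).
lba_density_vecb <- function(t, b, A, v, eta) {
  if (A < 1e-10) return(b / (eta * t^2) * stats::dnorm((b / t - v) / eta))
  te <- t * eta
  z1 <- (b - A - t * v) / te
  z2 <- (b - t * v) / te
  out <- (1 / A) * (-v * stats::pnorm(z1) + eta * stats::dnorm(z1) +
                      v * stats::pnorm(z2) - eta * stats::dnorm(z2))
  out[out < 0] <- 0
  out
}

lba_cdf_vecb <- function(t, b, A, v, eta) {
  if (A < 1e-10) return(stats::pnorm((v - b / t) / eta))
  te <- t * eta
  z1 <- (b - A - t * v) / te
  z2 <- (b - t * v) / te
  out <- 1 + ((b - A - t * v) / A) * stats::pnorm(z1) -
    ((b - t * v) / A) * stats::pnorm(z2) +
    (te / A) * (stats::dnorm(z1) - stats::dnorm(z2))
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Simulate choices and response times from the LBA race
#'
#' Generative counterpart of [lba_trial_loglik()]: per trial, each
#' accumulator draws a start point Uniform(0, A) and a drift Normal(v, eta);
#' if both drifts are nonpositive the trial's draws are rejected and
#' redrawn (the convention the likelihood renormalizes for).  The response
#' is the accumulator reaching its threshold first and
#' `rt = t0 + decision time`.
#'
#' @param v_old,v_new Mean drift rates per trial (vectors, recycled).
#' @param eta Drift SD per trial.
#' @param params An [lba_params()] object.
#' @param seed Optional integer seed for a reproducible draw.
#' @return A data.frame with columns `response` ("old"/"new") and
#'   `rt_seconds`.
#' @export
simulate_lba <- function(v_old, v_new, eta, params, seed = NULL) {
  n <- max(length(v_old), length(v_new))
  v_old <- rep_len(v_old, n)
  v_new <- rep_len(v_new, n)
  eta <- rep_len(eta, n)
  run <- function() {
    d_old <- stats::rnorm(n, v_old, eta)
    d_new <- stats::rnorm(n, v_new, eta)
    redo <- which(d_old <= 0 & d_new <= 0)
    guard <- 0L
    while (length(redo) > 0L && guard < 1000L) {
      d_old[redo] <- stats::rnorm(length(redo), v_old[redo], eta[redo])
      d_new[redo] <- stats::rnorm(length(redo), v_new[redo], eta[redo])
      redo <- redo[d_old[redo] <= 0 & d_new[redo] <= 0]
      guard <- guard + 1L
    }
    s_old <- stats::runif(n, 0, params$A)
    s_new <- stats::runif(n, 0, params$A)
    t_old <- ifelse(d_old > 0, (params$A + params$B_old - s_old) / d_old, Inf)
    t_new <- ifelse(d_new > 0, (params$A + params$B_new - s_new) / d_new, Inf)
    old_wins <- t_old <= t_new
    data.frame(response = ifelse(old_wins, "old", "new"),
               rt_seconds = params$t0 + pmin(t_old, t_new),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Single-accumulator finishing times (Monte Carlo helper)
#'
#' Draws finishing times of one accumulator in isolation; used to validate
#' the defective density/CDF against simulation.  Trials whose drift draw is
#' nonpositive never finish and are returned as `Inf`.
#'
#' @inheritParams lba_density
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Numeric vector of finishing times (possibly `Inf`).
#' @export
simulate_lba_accumulator <- function(n, b, A, v, eta, seed = NULL) {
  run <- function() {
    drift <- stats::rnorm(n, v, eta)
    start <- stats::runif(n, 0, A)
    ifelse(drift > 0, (b - start) / drift, Inf)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
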