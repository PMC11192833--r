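# English letter frequencies used by the random-string word generator, so
# that chance letter overlap between generated "words" is language-like.
ENGLISH_LETTER_FREQ <- c(
  a = 0.08167, b = 0.01492, c = 0.02782, d = 0.04253, e = 0.12702,
  f = 0.02228, g = 0.02015, h = 0.06094, i = 0.06966, j = 0.00153,
  k = 0.00772, l = 0.04025, m = 0.02406, n = 0.06749, o = 0.07507,
  p = 0.01929, q = 0.00095, r = 0.05987, s = 0.06327, t = 0.09056,
  u = 0.02758, v = 0.00978, w = 0.02360, x = 0.00150, y = 0.01974,
  z = 0.00074)

#' Demo word list shipped with the package
#'
#' A small list of common English words (one per line under `extdata/`),
#' used for realistic demonstrations; the random-string generator is the
#' default fixture for tests.
#'
#' @return Character vector of words.
#' @export
demo_wordlist <- function() {
  path <- system.file("extdata", "wordlist.txt", package = "orthomem",
                      mustWork = TRUE)
  normalize_word(readLines(path, warn = FALSE))
}

#' Generate a word pool
#'
#' Builds a pool of unique normalized words either by sampling
#' letter-frequency-weighted random strings (default; no external resources
#' needed and chance orthographic overlap is realistic) or by sampling the
#' packaged demo word list.
#'
#' @param size Number of words.
#' @param length_range Integer vector `c(min, max)` of word lengths.
#' @param mode `"random-strings"` or `"wordlist"`.
#' @param seed Integer seed; the pool is deterministic given it.
#' @return Character vector of `size` unique words.
#' @export
generate_pool <- function(size, length_range = c(3L, 10L),
                          mode = c("random-strings", "wordlist"),
                          seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(size >= 1, length_range[1L] >= 1,
            length_range[2L] >= length_range[1L])
  with_seed(seed, {
    if (mode == "wordlist") {
      words <- demo_wordlist()
      words <- words[nchar(words) >= length_range[1L] &
                       nchar(words) <= length_range[2L]]
      if (length(words) < size) {
        stop("packaged word list has only ", length(words),
             " words in the requested length range")
      }
      sample(words, size)
    } else {
      n_possible <- sum(26^(seq(length_range[1L], length_range[2L])))
      if (size > 0.5 * n_possible) {
        stop("could not generate ", size,
             " unique words in the requested length range")
      }
      pool <- character(0)
      letters26 <- names(ENGLISH_LETTER_FREQ)
      guard <- 0L
      while (length(pool) < size && guard < 200L) {
        need <- size - length(pool)
        lens <- sample(seq(length_range[1L], length_range[2L]),
                       need, replace = TRUE)
        new <- vapply(lens, function(W)
          paste(sample(letters26, W, replace = TRUE,
                       prob = ENGLISH_LETTER_FREQ), collapse = ""),
          character(1L))
        pool <- unique(c(pool, new))
        guard <- guard + 1L
      }
      if (length(pool) < size) {
        stop("could not generate ", size,
             " unique words in the requested length range")
      }
      pool[seq_len(size)]
    }
  })
}

#' Study design for a synthetic recognition experiment
#'
#' Bundles the structural choices of a recognition memory session: list
#' length, number of test trials, target/lure mix, word lengths, and the
#' rate at which high-similarity (edit-distance-1) lures are planted.
#' Defaults mirror typical unrelated-word recognition studies: 50-word study
#' lists, 3-10 letter words, a 50/50 target/lure test, and roughly 2% of
#' test trials carrying a planted edit-distance-1 lure.
#'
#' @param n_participants Number of simulated participants.
#' @param list_length Study-list length (conventionally 40-150).
#' @param n_test Number of test trials per participant.
#' @param target_ratio Proportion of test trials that are targets.
#' @param word_length `c(min, max)` word lengths (3-11 typical).
#' @param pool_size Word-pool size (at least `2 * list_length`).
#' @param pool_mode Passed to [generate_pool()].
#' @param hs_lure_rate Fraction of test trials whose lure is a planted
#'   single-letter deletion of a studied word.
#' @param condition Label attached to every trial (single condition).
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_participants = 8L, list_length = 50L,
                         n_test = 100L, target_ratio = 0.5,
                         word_length = c(3L, 10L), pool_size = 500L,
                         pool_mode = "random-strings",
                         hs_lure_rate = 0.02, condition = "none") {
  stopifnot(list_length >= 2, n_test >= 2,
            target_ratio > 0, target_ratio < 1,
            pool_size >= 2 * list_length,
            hs_lure_rate >= 0, hs_lure_rate < 1)
  structure(list(n_participants = as.integer(n_participants),
                 list_length = as.integer(list_length),
                 n_test = as.integer(n_test),
                 target_ratio = target_ratio,
                 word_length = as.integer(word_length),
                 pool_size = as.integer(pool_size),
                 pool_mode = pool_mode,
                 hs_lure_rate = hs_lure_rate,
                 condition = condition),
            class = "study_design")
}

# Delete one letter from a word, position class start/middle/end.
delete_letter <- function(word, where = c("start", "middle", "end")) {
  where <- match.arg(where)
  l <- word_letters(word)
  W <- length(l)
  pos <- switch(where,
                start = 1L,
                end = W,
                middle = if (W > 2L) resample(2:(W - 1L)) else 1L)
  paste(l[-pos], collapse = "")
}

#' Generate one study/test session
#'
#' Draws a study list from the pool and builds a test of studied targets and
#' unstudied lures.  A controllable fraction of lure trials is planted as a
#' single-letter deletion of a studied word (a high-similarity lure), with
#' the deleted position cycling over start/middle/end so lure-subtype
#' analyses have all cells.  No lure ever appears in its own study list.
#'
#' @param pool Character vector of candidate words.
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @param participant_id Identifier stored in the trial table.
#' @return A trial-table data.frame with columns `participant_id`,
#'   `condition`, `status`, `probe`, `study_list` (semicolon-joined),
#'   `response`, `rt_seconds` (the last two `NA` until simulated).
#' @export
generate_session <- function(pool, design, seed = 1L,
                             participant_id = "p1") {
  stopifnot(inherits(design, "study_design"))
  if (length(pool) < 2L * design$list_length) {
    stop("pool too small for the requested list length")
  }
  with_seed(seed, {
    study <- sample(pool, design$list_length)
    n_target <- round(design$n_test * design$target_ratio)
    n_lure <- design$n_test - n_target
    targets <- sample(study, n_target, replace = n_target > length(study))
    candidates <- setdiff(pool, study)
    lures <- sample(candidates, n_lure, replace = n_lure > length(candidates))
    # Plant high-similarity (edit-distance-1) lures at the design rate.
    n_hs <- round(design$hs_lure_rate * design$n_test)
    if (n_hs > 0L && n_lure > 0L) {
      subtypes <- rep_len(c("start", "middle", "end"), n_hs)
      slots <- sample(seq_len(n_lure), min(n_hs, n_lure))
      for (i in seq_along(slots)) {
        base <- resample(study[nchar(study) >= 4L])
        cand <- delete_letter(base, subtypes[i])
        if (!(cand %in% study)) lures[slots[i]] <- cand
      }
    }
    probes <- c(targets, lures)
    status <- c(rep("target", n_target), rep("lure", n_lure))
    ord <- sample(seq_along(probes))
    data.frame(participant_id = participant_id,
               condition = design$condition,
               status = status[ord],
               probe = probes[ord],
               study_list = paste(study, collapse = ";"),
               response = NA_character_,
               rt_seconds = NA_real_,
               stringsAsFactors = FALSE)
  })
}

#' Group-level generating parameters for a simulated study
#'
#' Participant parameters are drawn from normal distributions with means
#' `mu` and standard deviations `sigma` (truncated to each parameter's
#' support: `B`, `t0` and `p` are kept positive).  Parameters not listed in
#' `mu` are held at the values in `fixed` for every participant.
#'
#' Defaults encode the generating regime used throughout the package's
#' recovery and signature checks: a nonlinear similarity function (`p = 3`),
#' a strong similarity effect on lures and none on targets
#' (`gamma_lure = 25`, `gamma_target = 0`), and unbiased thresholds.
#'
#' @param mu Named means for `B`, `t0`, `p`, `gamma_target`, `gamma_lure`,
#'   `V_target`, `V_lure`.
#' @param sigma Named SDs for the same parameters.
#' @param fixed Named list of constants: `A`, `V0`, `eta_target`, plus the
#'   representation parameters `alpha`, `omega`, `w`, `d`, `r`, `epsilon`.
#' @return A list of class `group_params`.
#' @export
group_params <- function(mu = c(B = 1, t0 = 0.25, p = 3, gamma_target = 0,
                                gamma_lure = 100, V_target = 1, V_lure = -1),
                         sigma = c(B = 0.15, t0 = 0.04, p = 0.3,
                                   gamma_target = 0.5, gamma_lure = 10,
                                   V_target = 0.2, V_lure = 0.2),
                         fixed = list(A = 0.5, V0 = 2, eta_target = 1,
                                      alpha = 1, omega = 1, w = 0.75,
                                      d = 1.544, r = 1.094, epsilon = 0)) {
  stopifnot(setequal(names(mu), names(sigma)))
  structure(list(mu = mu, sigma = sigma, fixed = fixed),
            class = "group_params")
}

rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

PARAM_LOWER <- c(B = 1e-3, t0 = 0, p = 1e-2, gamma_target = -Inf,
                 gamma_lure = -Inf, V_target = -Inf, V_lure = -Inf)

#' Simulate a full synthetic recognition study
#'
#' The parameter-recovery harness: draws participant parameters from the
#' group distributions, generates a study/test session per participant,
#' computes each trial's global similarity under the chosen representation,
#' maps it to drift rates, and simulates choices and RTs from the LBA race.
#'
#' @param design A [study_design()].
#' @param group A [group_params()] object.
#' @param scheme Orthographic scheme used by the generator.
#' @param seed Master seed; per-participant streams are derived from it.
#' @return A list of class `synthetic_study` with elements `trials` (the
#'   filled trial table over all participants), `truth` (group parameters,
#'   per-participant draws, scheme, seed), and `design`.
#' @export
simulate_study <- function(design, group = group_params(),
                           scheme = "open-bigram", seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(group, "group_params"))
  pool <- generate_pool(design$pool_size, design$word_length,
                        mode = design$pool_mode,
                        seed = derive_seed(seed, 0L))
  fx <- group$fixed
  nm <- names(group$mu)
  part_params <- with_seed(derive_seed(seed, 1L), {
    draws <- sapply(nm, function(k)
      rtnorm(design$n_participants, group$mu[[k]], group$sigma[[k]],
             lower = PARAM_LOWER[[k]]))
    matrix(draws, nrow = design$n_participants,
           dimnames = list(NULL, nm))
  })
  all_trials <- vector("list", design$n_participants)
  for (i in seq_len(design$n_participants)) {
    th <- part_params[i, ]
    trials <- generate_session(pool, design, seed = derive_seed(seed, 100L + i),
                               participant_id = sprintf("p%02d", i))
    sl <- strsplit(trials$study_list, ";", fixed = TRUE)
    S <- similarity_matrix(trials$probe, sl, scheme = scheme,
                           alpha = fx$alpha, omega = fx$omega, w = fx$w,
                           d = fx$d, r = fx$r, epsilon = fx$epsilon)
    g <- global_similarity_from_matrix(S, th[["p"]])
    is_target <- trials$status == "target"
    V <- ifelse(is_target, th[["V_target"]], th[["V_lure"]])
    gam <- ifelse(is_target, th[["gamma_target"]], th[["gamma_lure"]])
    dr <- drift_rates(g, fx$V0, V, gam)
    pars <- lba_params(A = fx$A, B_old = th[["B"]], B_new = th[["B"]],
                       t0 = th[["t0"]], eta_target = fx$eta_target,
                       V0 = fx$V0)
    eta <- ifelse(is_target, fx$eta_target, 1)
    sim <- simulate_lba(dr$v_old, dr$v_new, eta, pars,
                        seed = derive_seed(seed, 200L + i))
    trials$response <- sim$response
    trials$rt_seconds <- sim$rt_seconds
    trials$g <- g
    all_trials[[i]] <- trials
  }
  structure(list(trials = do.call(rbind, all_trials),
                 truth = list(group = group,
                              participants = as.data.frame(part_params),
                              scheme = scheme, seed = seed),
                 design = design),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic recognition study: %d participants x %d trials (scheme %s, seed %d)\n",
              x$design$n_participants, x$design$n_test,
              x$truth$scheme, x$truth$seed))
  invisible(x)
}
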