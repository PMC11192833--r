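#' Power transform of a similarity value
#'
#' Raises a similarity in \[0, 1\] to the exponent `p`.  For `p > 1` low
#' similarities are pushed towards zero while values at 1 are unaffected, so
#' the memory set is effectively reduced to the few items most similar to
#' the probe; `p = 1` leaves similarities untouched.
#'
#' @param s Numeric vector of similarities in \[0, 1\].
#' @param p Nonlinearity exponent (> 0; `p = 0` is rejected because it would
#'   map zero similarity to 1).
#' @return `s^p`.
#' @examples
#' power_transform(c(0.1, 0.5, 1), p = 3)
#' @export
power_transform <- function(s, p) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("similarities must lie in [0, 1]")
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0) {
    stop("invalid parameter: p must be positive")
  }
  s^p
}

#' Global similarity of a probe to a study list
#'
#' The memory-strength statistic of a global matching model: pairwise
#' similarities between the probe and every study-list word are
#' power-transformed and summed, then divided by the list length,
#' \deqn{g_i = \sum_{j \in L,\, j \ne i} s_{ij}^{\,p} / N_L.}
#' List entries equal to the probe word (the self-match on target trials)
#' are excluded from the sum; the divisor remains the full list length
#' \eqn{N_L}.  When an embedding table is supplied the orthographic and
#' semantic channels are mixed per item:
#' \deqn{g_i = \sum_{j \ne i} [\,w_o s_{ij}^{\,p} + (1-w_o) c_{ij}^{\,p^*}\,] / N_L}
#' with \eqn{c_{ij}} the truncated cosine ([truncated_cosine()]).
#'
#' @inheritParams pairwise_similarity
#' @param study_list Character vector of studied words (non-empty).
#' @param p Orthographic nonlinearity exponent (> 0).
#' @param embeddings Optional `embedding_table` enabling the semantic
#'   channel.
#' @param w_o Weight of the orthographic channel in \[0, 1\]; 1 (default)
#'   disables the semantic channel.
#' @param p_star Semantic nonlinearity exponent (> 0).
#' @param missing Embedding-lookup fallback policy (see
#'   [truncated_cosine()]).
#' @return A list of class `global_similarity`: `g` (the statistic),
#'   `n_items` (\eqn{N_L}), and `contributions` (a data.frame with the
#'   per-item raw and transformed similarities; excluded self-matches carry
#'   zero contribution).
#' @examples
#' gs <- global_similarity("ledge", c("ledger", "sultan", "dog"),
#'                         scheme = "slot", p = 3)
#' gs$g
#' @export
global_similarity <- function(probe, study_list,
                              scheme = similarity_schemes(), p = 1,
                              alpha = 1, omega = 1, w = 0.75,
                              d = 1.544, r = 1.094, epsilon = 0,
                              embeddings = NULL, w_o = 1, p_star = 1,
                              missing = c("zero", "error")) {
  if (length(study_list) == 0L) stop("empty study list")
  scheme <- match.arg(scheme)
  missing <- match.arg(missing)
  if (w_o < 0 || w_o > 1) stop("invalid parameter: w_o must lie in [0, 1]")
  probe_n <- normalize_word(probe)
  list_n <- normalize_word(study_list)
  n_l <- length(list_n)
  excluded <- list_n == probe_n

  s <- pairwise_similarity(probe_n, list_n, scheme = scheme, alpha = alpha,
                           omega = omega, w = w, d = d, r = r,
                           epsilon = epsilon)
  s_p <- power_transform(pmin(pmax(s, 0), 1), p)

  if (!is.null(embeddings) && w_o < 1) {
    cvals <- vapply(list_n, function(x)
      truncated_cosine(probe_n, x, embeddings, missing = missing),
      numeric(1L), USE.NAMES = FALSE)
    c_p <- power_transform(cvals, p_star)
    contrib <- w_o * s_p + (1 - w_o) * c_p
  } else {
    cvals <- rep(NA_real_, n_l)
    contrib <- s_p
  }
  contrib[excluded] <- 0
  structure(list(
    g = sum(contrib) / n_l,
    n_items = n_l,
    contributions = data.frame(
      word = list_n, similarity = s, semantic = cvals,
      contribution = contrib, excluded = excluded,
      stringsAsFactors = FALSE)
  ), class = "global_similarity")
}

#' @export
print.global_similarity <- function(x, ...) {
  cat(sprintf("global similarity g = %.5f over %d study items (%d excluded self-match)\n",
              x$g, x$n_items, sum(x$contributions$excluded)))
  invisible(x)
}

# Fast path used by the fitting and simulation code: precompute the raw
# pairwise-similarity matrix once (trials x list positions, self-matches
# already zeroed), then evaluate g for any nonlinearity p via
# g = rowSums(S^p) / N_L.  Zero entries stay zero for every p > 0.
global_similarity_from_matrix <- function(S, p) {
  rowSums(S^p) / ncol(S)
}

# Probes x words similarity matrix with per-scheme fast paths.  The slot and
# bigram codes and the Levenshtein metric dominate the fitting loops, so
# their pairwise values are computed from precomputed per-word profiles; the
# overlap schemes fall back to the per-pair functions.
pairwise_matrix <- function(probes, words,
                            scheme = similarity_schemes(),
                            alpha = 1, omega = 1, w = 0.75,
                            d = 1.544, r = 1.094, epsilon = 0) {
  scheme <- match.arg(scheme)
  if (epsilon > 0 || scheme %in% c("overlap", "both-overlap")) {
    out <- t(vapply(probes, function(p)
      pairwise_similarity(p, words, scheme = scheme, alpha = alpha,
                          omega = omega, w = w, d = d, r = r,
                          epsilon = epsilon),
      numeric(length(words))))
    dim(out) <- c(length(probes), length(words))
    return(out)
  }
  if (scheme == "levenshtein") {
    D <- utils::adist(probes, words)
    a <- outer(nchar(probes), nchar(words), pmax)
    return(pmax((a - D) / a, 0))
  }
  if (scheme %in% c("closed-bigram", "open-bigram")) {
    extractor <- if (scheme == "closed-bigram") closed_bigrams else open_bigrams
    vocab <- unique(c(probes, words))
    bags <- lapply(vocab, function(x) {
      b <- extractor(x)
      tb <- sort(table(b))
      list(counts = as.vector(tb), tokens = names(tb), size = length(b))
    })
    names(bags) <- vocab
    S <- matrix(0, length(probes), length(words))
    bw <- bags[words]
    for (i in seq_along(probes)) {
      bp <- bags[[probes[i]]]
      for (j in seq_along(words)) {
        bs <- bw[[j]]
        m <- match(bp$tokens, bs$tokens)
        hit <- which(!is.na(m))
        if (length(hit) > 0L) {
          tok <- bp$tokens[hit]
          cnt <- pmin(bp$counts[hit], bs$counts[m[hit]])
          wts <- rep(1, length(tok))
          if (alpha != 1) wts[startsWith(tok, "_")] <- alpha
          if (omega != 1) wts[endsWith(tok, "_")] <- omega
          M <- sum(wts * cnt)
          S[i, j] <- M / (max(bp$size, bs$size) + (1 - alpha) + (1 - omega))
        }
      }
    }
    return(S)
  }
  # slot / both-slot
  lp <- lapply(probes, word_letters)
  lw <- lapply(words, word_letters)
  S <- matrix(0, length(probes), length(words))
  for (i in seq_along(probes)) {
    for (j in seq_along(words)) {
      pl <- lp[[i]]; sl <- lw[[j]]
      a <- max(length(pl), length(sl))
      denom <- a + (1 - alpha) + (1 - omega)
      Mf <- slot_match_sum(pl, sl, alpha, omega)
      if (scheme == "slot") {
        S[i, j] <- Mf / denom
      } else {
        n <- min(length(pl), length(sl))
        hits <- rev(pl)[seq_len(n)] == rev(sl)[seq_len(n)]
        wts <- rep(1, n)
        wts[1L] <- omega
        if (length(sl) <= n && length(sl) > 1L) wts[length(sl)] <- alpha
        Mb <- sum(wts[hits])
        S[i, j] <- (w * Mf + (1 - w) * Mb) / denom
      }
    }
  }
  S
}

# Precompute the trial x list-position similarity matrix for a trial table.
# Entries where the list word equals the probe are set to zero (self-match
# exclusion with fixed divisor).  Trials sharing a study list (the common
# case: one list per participant) are computed together over unique probes.
similarity_matrix <- function(probes, study_lists,
                              scheme = similarity_schemes(),
                              alpha = 1, omega = 1, w = 0.75,
                              d = 1.544, r = 1.094, epsilon = 0) {
  scheme <- match.arg(scheme)
  stopifnot(length(probes) == length(study_lists))
  probes <- normalize_word(probes)
  study_lists <- lapply(study_lists, normalize_word)
  n_l <- unique(lengths(study_lists))
  if (length(n_l) != 1L) stop("all study lists must share one length")
  S <- matrix(0, nrow = length(probes), ncol = n_l)
  keys <- vapply(study_lists, paste, character(1L), collapse = ";")
  for (key in unique(keys)) {
    idx <- which(keys == key)
    lst <- study_lists[[idx[1L]]]
    up <- unique(probes[idx])
    block <- pairwise_matrix(up, lst, scheme = scheme, alpha = alpha,
                             omega = omega, w = w, d = d, r = r,
                             epsilon = epsilon)
    block[outer(up, lst, "==")] <- 0
    S[idx, ] <- block[match(probes[idx], up), , drop = FALSE]
  }
  S
}
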