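#' @title Pairwise orthographic similarity
#'
#' @description
#' Seven representational schemes for the similarity between two letter
#' strings, each bounded on \[0, 1\]:
#'
#' * **slot**: letters match only at identical absolute positions counted
#'   from the start of the word.
#' * **both-slot**: a weighted mixture (weight `w` on the forward code) of
#'   the start-anchored slot code and an end-anchored slot code in which
#'   positions are counted backwards from the final letter.
#' * **overlap**: a "noisy" slot code; each studied letter's position is a
#'   Gaussian with position-dependent standard deviation
#'   \eqn{\sigma_l = d(1 - e^{-(l - 0.5)/r})}, and the match for a probe
#'   letter is the Gaussian mass falling in its position bin.
#' * **both-overlap**: the same weighted mixture applied to a forward and
#'   an end-anchored overlap pass.
#' * **closed-bigram**: adjacent ordered letter pairs plus start/end edge
#'   markers, matched once-only across the two bags.
#' * **open-bigram**: ordered letter pairs separated by up to two letters,
#'   plus edge markers, matched once-only.
#' * **levenshtein**: `(a - D)/a` where `D` is the edit distance and `a` the
#'   length of the longer word.
#'
#' For the positional and bigram schemes the similarity is
#' \deqn{s = M / (a + (1 - \alpha) + (1 - \Omega))}
#' where `M` is the summed match, `a` the alignment length (letters or
#' bigrams of the longer word), and `alpha`/`omega` weight matches on the
#' start and end letters (or edge-marker bigrams).  `omega` applies to the
#' final letter of the *studied* word only, so asymmetry is confined to
#' unequal-length pairs.
#'
#' @param probe,studied Single words (normalized internally).
#' @param alpha Weight of a match on the start letter (default 1).
#' @param omega Weight of a match on the studied word's final letter
#'   (default 1).
#' @param w Mixture weight of the forward (start-anchored) code in the
#'   both-edges schemes, in \[0, 1\].
#' @param d,r Asymptote and growth rate of the overlap model's
#'   positional-uncertainty schedule; both must be positive.
#' @return An object of class `pair_similarity`: a list with elements
#'   `value` (the similarity), `matches` (`M`), and `alignment` (`a`).
#'   `as.numeric()` extracts `value`.
#' @examples
#' slot_similarity("baseball", "based")$value       # 0.5
#' slot_similarity("ledge", "ledger")$value         # 5/6
#' closed_bigram_similarity("sustain", "sultan")$value  # 0.5
#' open_bigram_similarity("sustain", "station")$value   # 10/17
#' levenshtein_similarity("ledge", "ledger")$value      # 5/6
#' @name orthographic-similarity
NULL

pair_similarity <- function(value, matches, alignment) {
  structure(list(value = value, matches = matches, alignment = alignment),
            class = "pair_similarity")
}

#' @export
as.numeric.pair_similarity <- function(x, ...) x$value

#' @export
print.pair_similarity <- function(x, ...) {
  cat(sprintf("pair similarity: %.4f  (M = %.4f, alignment = %d)\n",
              x$value, x$matches, x$alignment))
  invisible(x)
}

check_exterior_weights <- function(alpha, omega) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0 ||
      !is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega < 0) {
    stop("invalid parameter: alpha and omega must be single nonnegative numbers")
  }
}

check_mix_weight <- function(w) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    stop("invalid parameter: w must lie in [0, 1]")
  }
}

# Match-count normalization shared by the slot/overlap/bigram schemes.
similarity_from_matches <- function(M, a, alpha, omega) {
  pair_similarity(M / (a + (1 - alpha) + (1 - omega)), M, a)
}

# ---- slot codes -----------------------------------------------------------

# Positional match weights for a forward slot comparison.  Position 1 carries
# alpha; the position equal to the studied word's length carries omega.  For a
# single-letter studied word the start weight takes precedence.
slot_match_sum <- function(pl, sl, alpha, omega) {
  n <- min(length(pl), length(sl))
  if (n == 0L) return(0)
  hits <- pl[seq_len(n)] == sl[seq_len(n)]
  wts <- rep(1, n)
  wts[1L] <- alpha
  if (length(sl) <= n && length(sl) > 1L) wts[length(sl)] <- omega
  sum(wts[hits])
}

#' @rdname orthographic-similarity
#' @export
slot_similarity <- function(probe, studied, alpha = 1, omega = 1) {
  check_exterior_weights(alpha, omega)
  pl <- word_letters(normalize_word(probe))
  sl <- word_letters(normalize_word(studied))
  M <- slot_match_sum(pl, sl, alpha, omega)
  similarity_from_matches(M, max(length(pl), length(sl)), alpha, omega)
}

#' @rdname orthographic-similarity
#' @export
end_slot_similarity <- function(probe, studied, alpha = 1, omega = 1) {
  check_exterior_weights(alpha, omega)
  pl <- word_letters(normalize_word(probe))
  sl <- word_letters(normalize_word(studied))
  # Reverse both words so that backward position b (1 = final letter) becomes
  # forward position b.  The studied word's final letter then sits at
  # position 1 (weight omega) and its first letter at position W(j)
  # (weight alpha): the exterior weights still refer to the start and end of
  # the original string.
  n <- min(length(pl), length(sl))
  M <- 0
  if (n > 0L) {
    rp <- rev(pl)[seq_len(n)]
    rs <- rev(sl)[seq_len(n)]
    hits <- rp == rs
    wts <- rep(1, n)
    wts[1L] <- omega
    if (length(sl) <= n && length(sl) > 1L) wts[length(sl)] <- alpha
    M <- sum(wts[hits])
  }
  similarity_from_matches(M, max(length(pl), length(sl)), alpha, omega)
}

#' @rdname orthographic-similarity
#' @export
both_edges_slot_similarity <- function(probe, studied, alpha = 1, omega = 1,
                                       w = 0.75) {
  check_mix_weight(w)
  s1 <- slot_similarity(probe, studied, alpha, omega)
  s2 <- end_slot_similarity(probe, studied, alpha, omega)
  pair_similarity(w * s1$value + (1 - w) * s2$value,
                  w * s1$matches + (1 - w) * s2$matches,
                  s1$alignment)
}

# ---- overlap model --------------------------------------------------------

#' Positional-uncertainty schedule of the overlap model
#'
#' Standard deviation of the Gaussian position code for the letter in serial
#' position `l`, \eqn{\sigma_l = d (1 - \exp(-(l - 0.5)/r))}: uncertainty
#' grows with position and saturates at the asymptote `d`.
#'
#' @param l Serial position (>= 1); vectorized.
#' @param d Asymptote (> 0).
#' @param r Growth rate (> 0).
#' @return Numeric vector of standard deviations.
#' @examples
#' sigma_schedule(1:6, d = 1.544, r = 1.094)
#' @export
sigma_schedule <- function(l, d, r) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0 ||
      !is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    stop("invalid parameter: d and r must be positive")
  }
  if (any(l < 1)) stop("invalid parameter: serial position l must be >= 1")
  d * (1 - exp(-(l - 0.5) / r))
}

# Forward overlap match sum.  Probe letter at position k gathers the Gaussian
# mass [k - .5, k + .5] from EVERY studied position l holding that letter,
# with sd sigma[l]; the exterior weight multiplies the probe position.
overlap_match_sum <- function(pl, sl, sigma, alpha, omega, omega_pos) {
  Wp <- length(pl)
  M <- 0
  for (k in seq_len(Wp)) {
    ls <- which(sl == pl[k])
    if (length(ls) == 0L) next
    mass <- sum(stats::pnorm(k + 0.5, mean = ls, sd = sigma[ls]) -
                  stats::pnorm(k - 0.5, mean = ls, sd = sigma[ls]))
    G <- if (k == 1L) alpha else if (k == omega_pos) omega else 1
    M <- M + G * mass
  }
  M
}

#' @rdname orthographic-similarity
#' @export
overlap_similarity <- function(probe, studied, alpha = 1, omega = 1,
                               d = 1.544, r = 1.094) {
  check_exterior_weights(alpha, omega)
  pl <- word_letters(normalize_word(probe))
  sl <- word_letters(normalize_word(studied))
  sigma <- sigma_schedule(seq_along(sl), d, r)
  M <- overlap_match_sum(pl, sl, sigma, alpha, omega, length(sl))
  similarity_from_matches(M, max(length(pl), length(sl)), alpha, omega)
}

#' @rdname orthographic-similarity
#' @export
both_edges_overlap_similarity <- function(probe, studied, alpha = 1, omega = 1,
                                          d = 1.544, r = 1.094, w = 0.75) {
  check_mix_weight(w)
  check_exterior_weights(alpha, omega)
  pl <- word_letters(normalize_word(probe))
  sl <- word_letters(normalize_word(studied))
  a <- max(length(pl), length(sl))
  sigma <- sigma_schedule(seq_len(max(length(pl), length(sl))), d, r)
  Mf <- overlap_match_sum(pl, sl, sigma[seq_along(sl)], alpha, omega,
                          length(sl))
  # Backward pass: positions counted from the end of each string; sigma is
  # indexed by the studied letter's backward position (final letter -> sigma_1)
  # and the exterior weights again track the original string's start (alpha,
  # backward position W(j)) and end (omega, backward position 1).
  Mb <- overlap_match_sum(rev(pl), rev(sl), sigma[seq_along(sl)],
                          omega, alpha, length(sl))
  sf <- Mf / (a + (1 - alpha) + (1 - omega))
  sb <- Mb / (a + (1 - alpha) + (1 - omega))
  pair_similarity(w * sf + (1 - w) * sb, w * Mf + (1 - w) * Mb, a)
}

# ---- bigram codes ---------------------------------------------------------

#' Bigram decompositions of a word
#'
#' `closed_bigrams()` returns the adjacent ordered letter pairs of a word
#' plus two edge markers (`_x` for the first letter, `x_` for the last), as a
#' multiset.  `open_bigrams()` additionally includes ordered pairs of letters
#' separated by one or two intervening letters.  A word of length `W` has
#' `W + 1` closed bigrams and
#' `max(W-1, 0) + max(W-2, 0) + max(W-3, 0) + 2` open bigrams.
#'
#' @param word A single word (normalized internally).
#' @return Character vector of bigram tokens; duplicates are retained.
#' @examples
#' closed_bigrams("cat")  # "_c" "ca" "at" "t_"
#' open_bigrams("ab")     # "_a" "ab" "b_"
#' @export
closed_bigrams <- function(word) {
  l <- word_letters(normalize_word(word))
  W <- length(l)
  interior <- if (W >= 2L) paste0(l[-W], l[-1L]) else character(0)
  c(paste0("_", l[1L]), interior, paste0(l[W], "_"))
}

#' @rdname closed_bigrams
#' @export
open_bigrams <- function(word) {
  l <- word_letters(normalize_word(word))
  W <- length(l)
  pairs <- character(0)
  for (gap in 1:3) {
    if (W > gap) {
      idx <- seq_len(W - gap)
      pairs <- c(pairs, paste0(l[idx], l[idx + gap]))
    }
  }
  c(paste0("_", l[1L]), pairs, paste0(l[W], "_"))
}

# Once-only matching over two bigram multisets: each token matches
# min(multiplicity_i, multiplicity_j) times.  Matched edge markers carry the
# exterior weights; start/end markers are identified by their "_" position.
bigram_match_sum <- function(bag_p, bag_s, alpha, omega) {
  tp <- table(bag_p)
  ts <- table(bag_s)
  common <- intersect(names(tp), names(ts))
  if (length(common) == 0L) return(0)
  counts <- pmin(as.vector(tp[common]), as.vector(ts[common]))
  wts <- rep(1, length(common))
  wts[startsWith(common, "_")] <- alpha
  wts[endsWith(common, "_")] <- omega
  sum(wts * counts)
}

bigram_similarity <- function(probe, studied, alpha, omega, extractor) {
  check_exterior_weights(alpha, omega)
  bag_p <- extractor(probe)
  bag_s <- extractor(studied)
  M <- bigram_match_sum(bag_p, bag_s, alpha, omega)
  similarity_from_matches(M, max(length(bag_p), length(bag_s)), alpha, omega)
}

#' @rdname orthographic-similarity
#' @export
closed_bigram_similarity <- function(probe, studied, alpha = 1, omega = 1) {
  bigram_similarity(probe, studied, alpha, omega, closed_bigrams)
}

#' @rdname orthographic-similarity
#' @export
open_bigram_similarity <- function(probe, studied, alpha = 1, omega = 1) {
  bigram_similarity(probe, studied, alpha, omega, open_bigrams)
}

# ---- Levenshtein ----------------------------------------------------------

#' Levenshtein edit distance and similarity
#'
#' `levenshtein_distance()` is the minimum number of single-letter
#' substitutions, insertions, or deletions transforming one word into the
#' other (computed with [utils::adist()]).  `levenshtein_similarity()`
#' converts it to a similarity, `(a - D)/a`, with `a` the length of the
#' longer word, floored at zero.
#'
#' @param a,b Single words (normalized internally).
#' @return `levenshtein_distance()`: a nonnegative integer.
#'   `levenshtein_similarity()`: a `pair_similarity` object.
#' @examples
#' levenshtein_distance("dog", "dogs")       # 1
#' levenshtein_similarity("trail", "trial")$value  # 3/5
#' @export
levenshtein_distance <- function(a, b) {
  as.integer(utils::adist(normalize_word(a), normalize_word(b))[1L, 1L])
}

#' @rdname levenshtein_distance
#' @export
levenshtein_similarity <- function(a, b) {
  wa <- normalize_word(a)
  wb <- normalize_word(b)
  align <- max(nchar(wa), nchar(wb))
  D <- levenshtein_distance(wa, wb)
  pair_similarity(max((align - D) / align, 0), align - D, align)
}

# ---- letter-"e" modification ---------------------------------------------

#' Letter-"e" modified similarity
#'
#' Shallow letter-detection encoding tasks make the presence of the target
#' letter (here `"e"`) an explicit feature of the studied representation.
#' The modified similarity adds a positionless bonus `epsilon` to the match
#' when `"e"` occurs in *both* words, renormalizing so the value stays in
#' \[0, 1\]:
#' \deqn{s^* = (M + E) / (a + (1-\alpha) + (1-\Omega) + \epsilon)}
#' with `E = epsilon` if both words contain "e" and 0 otherwise.
#'
#' @param probe,studied Single words.
#' @param scheme Base similarity scheme (see [string_similarity()]).
#' @param epsilon Nonnegative strength of the letter-"e" feature.
#' @param letter The diagnostic letter (default `"e"`).
#' @inheritParams string_similarity
#' @return A `pair_similarity` object.
#' @export
e_modified_similarity <- function(probe, studied, scheme = "slot",
                                  epsilon = 0, letter = "e",
                                  alpha = 1, omega = 1, w = 0.75,
                                  d = 1.544, r = 1.094) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0) {
    stop("invalid parameter: epsilon must be nonnegative")
  }
  base <- string_similarity(probe, studied, scheme = scheme, alpha = alpha,
                            omega = omega, w = w, d = d, r = r)
  joint_e <- grepl(letter, normalize_word(probe), fixed = TRUE) &&
    grepl(letter, normalize_word(studied), fixed = TRUE)
  E <- if (joint_e) epsilon else 0
  value <- (base$matches + E) /
    (base$alignment + (1 - alpha) + (1 - omega) + epsilon)
  pair_similarity(value, base$matches + E, base$alignment)
}

# ---- dispatcher & pools ---------------------------------------------------

#' Names of the available similarity schemes
#' @return Character vector of scheme identifiers.
#' @export
similarity_schemes <- function() {
  c("slot", "both-slot", "overlap", "both-overlap",
    "closed-bigram", "open-bigram", "levenshtein")
}

#' Pairwise string similarity under a named scheme
#'
#' Dispatcher over the seven schemes of [orthographic-similarity].
#'
#' @param probe,studied Single words.
#' @param scheme One of [similarity_schemes()].
#' @param alpha,omega Exterior-letter weights.
#' @param w Forward-code weight for the both-edges schemes.
#' @param d,r Overlap-model uncertainty parameters.
#' @return A `pair_similarity` object.
#' @examples
#' string_similarity("ledge", "ledger", "open-bigram")$value  # 10/14
#' @export
string_similarity <- function(probe, studied,
                              scheme = similarity_schemes(),
                              alpha = 1, omega = 1, w = 0.75,
                              d = 1.544, r = 1.094) {
  scheme <- match.arg(scheme)
  switch(scheme,
    "slot" = slot_similarity(probe, studied, alpha, omega),
    "both-slot" = both_edges_slot_similarity(probe, studied, alpha, omega, w),
    "overlap" = overlap_similarity(probe, studied, alpha, omega, d, r),
    "both-overlap" = both_edges_overlap_similarity(probe, studied, alpha,
                                                   omega, d, r, w),
    "closed-bigram" = closed_bigram_similarity(probe, studied, alpha, omega),
    "open-bigram" = open_bigram_similarity(probe, studied, alpha, omega),
    "levenshtein" = levenshtein_similarity(probe, studied)
  )
}

#' Similarity of one probe to many words
#'
#' Vectorized convenience wrapper returning bare similarity values; used by
#' the global-similarity aggregator and the neighbor ranking.
#'
#' @inheritParams string_similarity
#' @param words Character vector of comparison words.
#' @param epsilon Optional letter-"e" bonus passed to
#'   [e_modified_similarity()]; 0 leaves the base scheme untouched.
#' @return Numeric vector of similarities, one per element of `words`.
#' @export
pairwise_similarity <- function(probe, words,
                                scheme = similarity_schemes(),
                                alpha = 1, omega = 1, w = 0.75,
                                d = 1.544, r = 1.094, epsilon = 0) {
  scheme <- match.arg(scheme)
  if (epsilon > 0) {
    return(vapply(words, function(x)
      e_modified_similarity(probe, x, scheme = scheme, epsilon = epsilon,
                            alpha = alpha, omega = omega, w = w,
                            d = d, r = r)$value,
      numeric(1L), USE.NAMES = FALSE))
  }
  vapply(words, function(x)
    string_similarity(probe, x, scheme = scheme, alpha = alpha, omega = omega,
                      w = w, d = d, r = r)$value,
    numeric(1L), USE.NAMES = FALSE)
}

#' Nearest orthographic neighbors of a probe within a word pool
#'
#' Ranks the pool by similarity to the probe under the chosen scheme.  The
#' probe itself is excluded from its neighbor list; ties are broken
#' lexicographically for determinism.
#'
#' @inheritParams pairwise_similarity
#' @param pool Character vector of candidate words.
#' @param k Number of neighbors to return (capped at the pool size).
#' @return A data.frame with columns `word` and `similarity`, sorted by
#'   decreasing similarity.
#' @examples
#' pool <- c("ledger", "ladle", "wedge", "dog")
#' nearest_neighbors("ledge", pool, scheme = "slot", k = 2)
#' @export
nearest_neighbors <- function(probe, pool, scheme = similarity_schemes(),
                              k = 5L, alpha = 1, omega = 1, w = 0.75,
                              d = 1.544, r = 1.094, epsilon = 0) {
  if (length(pool) == 0L) stop("invalid input: empty word pool")
  scheme <- match.arg(scheme)
  probe_n <- normalize_word(probe)
  pool_n <- normalize_word(pool)
  keep <- pool_n != probe_n
  pool_n <- pool_n[keep]
  if (length(pool_n) == 0L) stop("invalid input: pool contains only the probe")
  sims <- pairwise_similarity(probe_n, pool_n, scheme = scheme, alpha = alpha,
                              omega = omega, w = w, d = d, r = r,
                              epsilon = epsilon)
  ord <- order(-sims, pool_n)
  top <- utils::head(ord, max(1L, as.integer(k)))
  data.frame(word = pool_n[top], similarity = sims[top],
             row.names = NULL, stringsAsFactors = FALSE)
}
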