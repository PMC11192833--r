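test_that("word normalization lowercases, strips, and rejects empty input", {
  expect_equal(normalize_word("Ledge"), "ledge")
  expect_equal(normalize_word("dog"), "dog")
  expect_equal(normalize_word(" Dog-1! "), "dog")
  expect_equal(normalize_word(normalize_word("Ledge")), "ledge")
  expect_error(normalize_word(""), "invalid word")
  expect_error(normalize_word("123"), "invalid word")
})

test_that("slot code reproduces the worked examples", {
  expect_equal(slot_similarity("baseball", "based")$value, 0.5)
  s <- slot_similarity("raided", "hamburger")
  expect_equal(s$matches, 1)
  expect_equal(s$value, 1 / 9)
  expect_equal(slot_similarity("ledge", "ledger")$value, 5 / 6)
  expect_equal(slot_similarity("dog", "dog")$value, 1)
})

test_that("end-anchored slot code counts matches from the final letter", {
  # kitten/smitten share the five end-aligned letters of "itten"
  # (positions -1..-5 in both words).
  s <- end_slot_similarity("kitten", "smitten")
  expect_equal(s$matches, 5)
  expect_equal(s$value, 5 / 7)
  # hand enumeration: no end-aligned positions agree for ledge/ledger
  expect_equal(end_slot_similarity("ledge", "ledger")$value, 0)
  expect_equal(end_slot_similarity("trial", "trial")$value, 1)
})

test_that("both-edges slot code mixes forward and end-anchored codes", {
  expect_equal(both_edges_slot_similarity("ledge", "ledger", w = 0.75)$value,
               0.75 * 5 / 6 + 0.25 * 0)
  # w = 1 reduces to the forward slot code
  for (pair in list(c("kitten", "smitten"), c("sustain", "sultan"))) {
    expect_equal(
      both_edges_slot_similarity(pair[1], pair[2], w = 1)$value,
      slot_similarity(pair[1], pair[2])$value)
  }
  expect_equal(
    both_edges_slot_similarity("kitten", "smitten", w = 0.75)$value,
    0.75 * slot_similarity("kitten", "smitten")$value +
      0.25 * end_slot_similarity("kitten", "smitten")$value)
  expect_error(both_edges_slot_similarity("a", "b", w = 1.2),
               "invalid parameter")
})

test_that("positional uncertainty schedule is increasing and bounded", {
  expect_equal(sigma_schedule(1, d = 1.544, r = 1.094),
               1.544 * (1 - exp(-0.5 / 1.094)))
  sig <- sigma_schedule(1:12, d = 1.544, r = 1.094)
  expect_true(all(diff(sig) > 0))
  expect_true(all(sig < 1.544))
  expect_equal(sigma_schedule(1:5, d = 1e-12, r = 1), rep(0, 5),
               tolerance = 1e-11)
  expect_error(sigma_schedule(1, d = -1, r = 1), "invalid parameter")
  expect_error(sigma_schedule(1, d = 1, r = 0), "invalid parameter")
})

test_that("overlap model matches the worked nearest-neighbor values", {
  # Gomez et al. uncertainty-schedule parameters; worked values are quoted
  # to 1-2 decimals
  expect_equal(round(overlap_similarity("ledge", "ledger",
                                        d = 1.544, r = 1.094)$value, 1), 0.3)
  expect_equal(round(both_edges_overlap_similarity(
    "ledge", "ledger", d = 1.544, r = 1.094, w = 0.75)$value, 2), 0.28)
})

test_that("overlap model reverts to the slot code as uncertainty vanishes", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_word(sample(3:8, 1))
    b <- random_word(sample(3:8, 1))
    expect_equal(overlap_similarity(a, b, d = 1e-6, r = 1.094)$value,
                 slot_similarity(a, b)$value, tolerance = 1e-6)
  }
  expect_equal(overlap_similarity("abc", "abc", d = 1e-9, r = 1)$value, 1,
               tolerance = 1e-6)
  expect_equal(both_edges_overlap_similarity("abc", "abc", d = 1e-9,
                                             r = 1, w = 0.3)$value, 1,
               tolerance = 1e-6)
})

test_that("probe letters absent from the studied word contribute nothing", {
  # "xyz" shares no letters with "ledge": every m_k is zero
  expect_equal(overlap_similarity("xyz", "ledge")$value, 0)
  # both-edges overlap at w = 1 equals the forward overlap
  expect_equal(
    both_edges_overlap_similarity("trail", "trial", w = 1)$value,
    overlap_similarity("trail", "trial")$value)
})

test_that("bigram bags have the predicted sizes and members", {
  expect_setequal(closed_bigrams("cat"), c("_c", "ca", "at", "t_"))
  expect_length(closed_bigrams("ledger"), 7)
  expect_setequal(closed_bigrams("a"), c("_a", "a_"))
  expect_setequal(open_bigrams("ab"), c("_a", "ab", "b_"))
  expect_length(open_bigrams("sustain"), 17)
  expect_true(all(c("ab", "ao", "au") %in% open_bigrams("about")))
  set.seed(21)
  for (i in 1:15) {
    W <- sample(1:9, 1)
    word <- random_word(W, letters)
    expect_length(closed_bigrams(word), W + 1)
    expect_length(open_bigrams(word),
                  max(W - 1, 0) + max(W - 2, 0) + max(W - 3, 0) + 2)
  }
})

test_that("bigram similarities reproduce the worked examples", {
  expect_equal(closed_bigram_similarity("ledge", "ledger")$value, 5 / 7)
  expect_equal(closed_bigram_similarity("sustain", "sultan")$value, 0.5)
  expect_equal(open_bigram_similarity("sustain", "station")$value, 10 / 17)
  expect_equal(open_bigram_similarity("ledge", "ledger")$value, 10 / 14)
  expect_equal(open_bigram_similarity("trail", "trail")$value, 1)
})

test_that("once-only matching equals the bipartite-matching oracle", {
  # the motivating case: repeated bigrams may not match twice
  expect_equal(closed_bigram_similarity("ababab", "ab")$value, 3 / 7)
  set.seed(31)
  for (i in 1:25) {
    a <- random_word(sample(2:6, 1), letters[1:3])
    b <- random_word(sample(2:6, 1), letters[1:3])
    for (extractor in list(closed_bigrams, open_bigrams)) {
      ba <- extractor(a); bb <- extractor(b)
      got <- bigram_match_sum(ba, bb, 1, 1)
      expect_equal(got, match_bruteforce(ba, bb),
                   info = paste(a, b))
    }
  }
})

test_that("edit distance agrees with a recursive oracle on short words", {
  expect_equal(levenshtein_distance("dog", "dogs"), 1L)
  expect_equal(levenshtein_distance("trail", "trial"), 2L)
  expect_equal(levenshtein_distance("cargo", "large"), 2L)
  expect_equal(levenshtein_distance("noodle", "nude"), 3L)
  set.seed(41)
  for (i in 1:30) {
    a <- random_word(sample(1:6, 1), letters[1:4])
    b <- random_word(sample(1:6, 1), letters[1:4])
    expect_identical(levenshtein_distance(a, b),
                     lev_recursive(a, b), label = paste(a, b))
    expect_identical(levenshtein_distance(a, b), levenshtein_distance(b, a))
  }
})

test_that("Levenshtein similarity is (a - D)/a on the longer length", {
  expect_equal(levenshtein_similarity("ledge", "ledger")$value, 5 / 6)
  expect_equal(levenshtein_similarity("dog", "dogs")$value, 3 / 4)
  expect_equal(levenshtein_similarity("same", "same")$value, 1)
})

test_that("letter-e modification rewards joint presence only", {
  # epsilon = 0 leaves every scheme unchanged
  for (sch in c("slot", "open-bigram", "levenshtein")) {
    expect_equal(
      e_modified_similarity("ledge", "ledger", scheme = sch, epsilon = 0)$value,
      string_similarity("ledge", "ledger", scheme = sch)$value)
  }
  base <- slot_similarity("ledge", "ledger")
  mod <- e_modified_similarity("ledge", "ledger", scheme = "slot",
                               epsilon = 0.5)
  expect_equal(mod$value, (base$matches + 0.5) / (base$alignment + 0.5))
  expect_gt(mod$value, base$value * base$alignment / (base$alignment + 0.5))
  # no shared letters and no "e" in either word: zero either way
  expect_equal(e_modified_similarity("cat", "dog", scheme = "slot",
                                     epsilon = 2)$value, 0)
  # "e" in only one word gets no bonus but the denominator still grows
  one_e <- e_modified_similarity("ledge", "dog", scheme = "slot",
                                 epsilon = 1)
  expect_equal(one_e$value, 0)
  expect_error(e_modified_similarity("a", "b", epsilon = -1),
               "invalid parameter")
})

test_that("similarities are bounded, self-similar, and suitably symmetric", {
  set.seed(51)
  schemes <- similarity_schemes()
  for (i in 1:12) {
    len <- sample(3:8, 1)
    a <- random_word(len)
    b <- random_word(len)
    long <- random_word(len + sample(1:3, 1))
    for (sch in schemes) {
      sab <- string_similarity(a, b, scheme = sch)$value
      expect_gte(sab, 0); expect_lte(sab, 1)
      if (sch %in% c("overlap", "both-overlap")) {
        # positional uncertainty lives in the studied word, so the overlap
        # schemes are exactly self-similar and symmetric only in the
        # sigma -> 0 limit
        expect_equal(string_similarity(a, a, scheme = sch, d = 1e-9)$value,
                     1, tolerance = 1e-6)
        expect_lt(abs(sab - string_similarity(b, a, scheme = sch)$value),
                  0.05)
      } else {
        expect_equal(string_similarity(a, a, scheme = sch)$value, 1)
        # equal lengths with alpha = omega = 1: fully symmetric
        expect_equal(sab, string_similarity(b, a, scheme = sch)$value)
      }
    }
    # unequal lengths with omega != 1: asymmetry is allowed for positional
    # codes but values stay within bounds in both directions
    for (sch in c("slot", "overlap")) {
      s1 <- string_similarity(a, long, scheme = sch, omega = 2)$value
      s2 <- string_similarity(long, a, scheme = sch, omega = 2)$value
      expect_gte(min(s1, s2), 0); expect_lte(max(s1, s2), 1)
    }
  }
})

test_that("nearest neighbors rank by similarity with lexicographic ties", {
  pool <- c("ledger", "ladle", "wedge", "redeem", "midget", "dog", "ledge")
  nn <- nearest_neighbors("ledge", pool, scheme = "slot", k = 3)
  expect_equal(nn$word[1], "ledger")
  expect_false("ledge" %in% nn$word)  # probe excluded
  expect_equal(nn$similarity, sort(nn$similarity, decreasing = TRUE))
  # k larger than pool returns the whole ranked pool
  nn_all <- nearest_neighbors("ledge", pool, scheme = "slot", k = 50)
  expect_equal(nrow(nn_all), length(pool) - 1L)
  # all-zero similarities fall back to lexicographic order
  nn0 <- nearest_neighbors("xyz", c("bb", "aa", "cc"), scheme = "slot", k = 3)
  expect_equal(nn0$word, c("aa", "bb", "cc"))
  expect_error(nearest_neighbors("ledge", character(0)), "invalid input")
})
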