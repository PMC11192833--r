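# Independent oracles used across the suite.

# Recursive brute-force edit distance (exponential; words <= 6 letters only).
lev_recursive <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
  min(lev_recursive(substr(a, 2L, nchar(a)), b) + 1L,
      lev_recursive(a, substr(b, 2L, nchar(b))) + 1L,
      lev_recursive(substr(a, 2L, nchar(a)), substr(b, 2L, nchar(b))) + cost)
}

# Maximum bipartite matching between two token multisets where tokens match
# only if identical: brute force over assignments.
match_bruteforce <- function(bag_a, bag_b) {
  if (length(bag_a) == 0L || length(bag_b) == 0L) return(0L)
  best <- 0L
  recurse <- function(i, used, count) {
    if (i > length(bag_a)) {
      best <<- max(best, count)
      return(invisible())
    }
    # skip token i
    recurse(i + 1L, used, count)
    for (j in seq_along(bag_b)) {
      if (!used[j] && bag_a[i] == bag_b[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
        break  # identical tokens: matching any one copy is equivalent
      }
    }
  }
  recurse(1L, rep(FALSE, length(bag_b)), 0L)
  best
}

# Random lowercase word from a reduced alphabet (repeats likely).
random_word <- function(len, alphabet = letters[1:6]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Plain per-item loop for the global similarity statistic.
global_similarity_loop <- function(probe, study_list, scheme, p, ...) {
  n_l <- length(study_list)
  total <- 0
  for (w in study_list) {
    if (w == probe) next
    total <- total + string_similarity(probe, w, scheme = scheme, ...)$value^p
  }
  total / n_l
}
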