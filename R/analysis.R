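#' Equal-count global-similarity bin summaries
#'
#' Splits trials into equal-count ("equal area") bins of global similarity,
#' separately within targets and lures, and summarizes each bin with its
#' old-response rate (the hit rate for targets, the false-alarm rate for
#' lures) and the .1/.5/.9 RT quantiles for correct and error responses.
#'
#' @param trials Trial table including `response` and `rt_seconds`.
#' @param g Numeric vector of global similarities, one per trial (taken
#'   from a `g` column of `trials` if omitted).
#' @param n_bins Number of bins (>= 2).
#' @return A data.frame with one row per status x bin: columns `status`,
#'   `bin`, `n`, `g_mean`, `p_old`, and RT quantile columns
#'   `rt_correct_q10/q50/q90`, `rt_error_q10/q50/q90`.
#' @export
bin_by_global_similarity <- function(trials, g = trials$g, n_bins = 4L) {
  if (is.null(g)) stop("global similarities g are required")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  stopifnot(length(g) == nrow(trials))
  out <- list()
  for (st in c("target", "lure")) {
    idx <- which(trials$status == st)
    if (length(idx) == 0L) next
    if (length(idx) < n_bins) stop("fewer ", st, " trials than bins")
    gs <- g[idx]
    if (length(unique(gs)) == 1L) {
      warning("all global similarities identical for ", st,
              " trials; assigning bins round-robin")
      bins <- rep_len(seq_len(n_bins), length(idx))
    } else {
      # Equal-count bins via the rank; ties broken by stable original order.
      rk <- rank(gs, ties.method = "first")
      bins <- ceiling(rk / (length(idx) / n_bins))
      bins <- pmin(pmax(bins, 1L), n_bins)
    }
    for (b in seq_len(n_bins)) {
      sel <- idx[bins == b]
      tr <- trials[sel, ]
      correct_resp <- if (st == "target") "old" else "new"
      rt_c <- tr$rt_seconds[tr$response == correct_resp]
      rt_e <- tr$rt_seconds[tr$response != correct_resp]
      q <- function(x) if (length(x) > 0L)
        stats::quantile(x, c(.1, .5, .9), names = FALSE) else rep(NA_real_, 3L)
      qc <- q(rt_c); qe <- q(rt_e)
      out[[length(out) + 1L]] <- data.frame(
        status = st, bin = b, n = length(sel),
        g_mean = mean(g[sel]),
        p_old = mean(tr$response == "old"),
        rt_correct_q10 = qc[1L], rt_correct_q50 = qc[2L],
        rt_correct_q90 = qc[3L],
        rt_error_q10 = qe[1L], rt_error_q50 = qe[2L], rt_error_q90 = qe[3L],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Classify a lure by its minimum Levenshtein distance to the study list
#'
#' Lures are classed by the smallest edit distance to any studied word:
#' 1 = HS (high similarity), 2 = MS, 3 = LS, >= 4 = VLS.  Multiplicity
#' records whether one (`"1x"`) or more (`"2x"`) studied words sit at that
#' minimum distance.  For HS lures related to their closest studied word by
#' a pure single-letter deletion/insertion (lengths differ by 1) or a
#' substitution (equal lengths), the affected letter position is reported as
#' `start`, `middle`, or `end`; otherwise the subtype is `none`.
#'
#' @param probe A lure word (must not itself be on the study list).
#' @param study_list Character vector of studied words.
#' @return A list of class `lure_class`: `class`, `min_distance`,
#'   `multiplicity`, `subtype`, `nearest` (the studied word used for the
#'   subtype).
#' @export
classify_lure <- function(probe, study_list) {
  probe <- normalize_word(probe)
  study_list <- normalize_word(study_list)
  if (probe %in% study_list) stop("probe is present in the study list")
  dists <- as.integer(utils::adist(probe, study_list)[1L, ])
  dmin <- min(dists)
  cls <- if (dmin == 1L) "HS" else if (dmin == 2L) "MS"
    else if (dmin == 3L) "LS" else "VLS"
  at_min <- which(dists == dmin)
  multiplicity <- if (length(at_min) >= 2L) "2x" else "1x"
  subtype <- "none"
  nearest <- study_list[at_min[1L]]
  if (cls == "HS") {
    subtype <- hs_subtype(probe, nearest)
  }
  structure(list(class = cls, min_distance = dmin,
                 multiplicity = multiplicity, subtype = subtype,
                 nearest = nearest),
            class = "lure_class")
}

# Position class of the single differing letter of a distance-1 pair.
# For unequal lengths the differing letter is the one deleted from the
# longer word; for equal lengths it is the substituted position.
hs_subtype <- function(a, b) {
  la <- word_letters(a)
  lb <- word_letters(b)
  if (abs(length(la) - length(lb)) > 1L) return("none")
  long <- if (length(la) >= length(lb)) la else lb
  short <- if (length(la) >= length(lb)) lb else la
  W <- length(long)
  if (length(long) == length(short)) {
    pos <- which(long != short)
    if (length(pos) != 1L) return("none")
    pos <- pos[1L]
  } else {
    # First position where the alignment breaks is the deleted letter.
    i <- 1L
    while (i <= length(short) && long[i] == short[i]) i <- i + 1L
    if (!identical(long[-i], short)) return("none")
    pos <- i
  }
  if (pos == 1L) "start" else if (pos == W) "end" else "middle"
}

#' Per-trial lure classification of a trial table
#'
#' @param trials Trial table.
#' @return The lure rows of `trials` with added columns `lure_class`,
#'   `min_distance`, `multiplicity`, `subtype`.
#' @export
classify_lures <- function(trials) {
  lures <- trials[trials$status == "lure", , drop = FALSE]
  if (nrow(lures) == 0L) return(lures)
  sl <- study_lists(lures)
  cl <- lapply(seq_len(nrow(lures)), function(i)
    classify_lure(lures$probe[i], sl[[i]]))
  lures$lure_class <- vapply(cl, `[[`, character(1L), "class")
  lures$min_distance <- vapply(cl, `[[`, integer(1L), "min_distance")
  lures$multiplicity <- vapply(cl, `[[`, character(1L), "multiplicity")
  lures$subtype <- vapply(cl, `[[`, character(1L), "subtype")
  lures
}

#' False-alarm rate and median RT by lure-similarity class
#'
#' Summarizes lure trials by Levenshtein class (HS/MS/LS/VLS) and, within
#' the HS class, by missing-letter subtype.  Medians are used for RT since
#' high-similarity lures are rare.  Classes with no trials are reported as
#' missing (`NA`), never as zero.
#'
#' @param trials Trial table (lure rows are classified internally if the
#'   `lure_class` column is absent).
#' @return A data.frame with columns `lure_class`, `subtype`, `n`, `far`,
#'   `rt_median`; every class x subtype cell appears.
#' @export
summarize_by_lure_class <- function(trials) {
  lures <- if ("lure_class" %in% names(trials) &&
               all(trials$status == "lure")) trials else classify_lures(trials)
  cells <- rbind(
    expand.grid(lure_class = "HS", subtype = c("start", "middle", "end"),
                stringsAsFactors = FALSE),
    data.frame(lure_class = c("HS", "MS", "LS", "VLS"),
               subtype = c("none", "all", "all", "all"),
               stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cls <- cells$lure_class[i]; sub <- cells$subtype[i]
    sel <- lures$lure_class == cls
    if (sub != "all") sel <- sel & lures$subtype == sub
    n <- sum(sel)
    data.frame(lure_class = cls, subtype = sub, n = n,
               far = if (n > 0L) mean(lures$response[sel] == "old")
                     else NA_real_,
               rt_median = if (n > 0L)
                 stats::median(lures$rt_seconds[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
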