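# Internal utilities: seed scoping and small numeric helpers.

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child stream seed from a master seed; stays below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9973) %%
               (.Machine$integer.max - 1)) + 1L
}

# sample() without the length-1 surprise.
resample <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# log(sum(exp(x))) without overflow.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing a given probability mass of an empirical
#' sample; for symmetric unimodal samples it approximates the central
#' interval.
#'
#' @param x Numeric sample.
#' @param prob Mass to cover (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) stop("need at least two finite values for an HDI")
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(m + 1L):n] - x[1L:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}
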