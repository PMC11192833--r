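#' Read a word-embedding table from plain text
#'
#' Reads embeddings in the common text format `word v1 v2 ... vD`, one word
#' per line, optionally preceded by a `count dim` header line (as written by
#' word2vec/FastText exporters).  Vectors are L2-normalized at load, so
#' cosine similarity later reduces to a dot product.
#'
#' @param path Path to the text file.
#' @param restrict_to Optional character vector; only these words are kept.
#'   Requested words missing from the file are reported in the
#'   `"missing_words"` attribute (with a warning).
#' @return A numeric matrix with one row per word (row names are the words);
#'   class `embedding_table`.
#' @export
read_embedding_table <- function(path, restrict_to = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty embedding file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  # Tolerate a "count dim" header: a first line of 1-2 purely numeric tokens.
  first <- fields[[1L]]
  if (length(first) <= 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("embedding file has a header but no rows")
  }
  words <- vapply(fields, `[[`, character(1L), 1L)
  dims <- lengths(fields) - 1L
  if (length(unique(dims)) != 1L) {
    bad <- which(dims != dims[1L])[1L]
    stop(sprintf("embedding dimension mismatch at line for word '%s': %d values, expected %d",
                 words[bad], dims[bad], dims[1L]))
  }
  vecs <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(dims[1L])))
  if (anyNA(vecs)) stop("non-numeric embedding values in ", path)
  rownames(vecs) <- words
  if (!is.null(restrict_to)) {
    restrict_to <- normalize_word(restrict_to)
    missing <- setdiff(restrict_to, words)
    vecs <- vecs[intersect(restrict_to, words), , drop = FALSE]
    if (length(missing) > 0L) {
      warning(length(missing), " requested word(s) missing from embeddings: ",
              paste(utils::head(missing, 5L), collapse = ", "))
    }
    attr(vecs, "missing_words") <- missing
  }
  norms <- sqrt(rowSums(vecs^2))
  if (any(norms == 0)) {
    stop("zero-norm embedding vector(s): ",
         paste(utils::head(rownames(vecs)[norms == 0], 5L), collapse = ", "))
  }
  vecs <- vecs / norms
  class(vecs) <- c("embedding_table", class(vecs))
  vecs
}

#' Truncated cosine similarity between two embedded words
#'
#' The semantic similarity channel: the cosine of the angle between the two
#' word vectors, truncated at zero (`max(cos, 0)`) so that the subsequent
#' power transform can only shrink values towards zero.
#'
#' @param w1,w2 Words to compare.
#' @param table An `embedding_table` (rows already unit-normalized).
#' @param missing What to do when a word has no vector: `"error"` (default)
#'   or `"zero"` (similarity 0 with a warning; conservative fallback used
#'   during model evaluation).
#' @return A number in \[0, 1\].
#' @export
truncated_cosine <- function(w1, w2, table, missing = c("error", "zero")) {
  missing <- match.arg(missing)
  w1 <- normalize_word(w1)
  w2 <- normalize_word(w2)
  absent <- setdiff(c(w1, w2), rownames(table))
  if (length(absent) > 0L) {
    if (missing == "error") {
      stop("word(s) not in embedding table: ", paste(absent, collapse = ", "))
    }
    warning("word(s) not in embedding table, using similarity 0: ",
            paste(absent, collapse = ", "))
    return(0)
  }
  max(sum(table[w1, ] * table[w2, ]), 0)
}

#' Synthetic cluster-structured word embeddings
#'
#' Builds unit vectors for a word pool with a controllable semantic-cluster
#' structure: words are assigned round-robin to `n_clusters` cluster centers
#' (random orthogonal-in-expectation directions), and each word's vector is
#' a mixture of its center and independent noise calibrated so the expected
#' within-cluster cosine is approximately `within_cluster_cos` while
#' between-cluster cosines are approximately zero.  Deterministic given
#' `seed`.
#'
#' @param pool Character vector of words.
#' @param d Embedding dimension (>= 2).
#' @param n_clusters Number of clusters (default: every word its own).
#' @param within_cluster_cos Target expected within-cluster cosine in
#'   \[0, 1).
#' @param seed Integer seed.
#' @return An `embedding_table` matrix (rows unit-normalized).
#' @export
synthetic_embeddings <- function(pool, d = 50L, n_clusters = length(pool),
                                 within_cluster_cos = 0.5, seed = 1L) {
  if (d < 2L) stop("embedding dimension d must be >= 2")
  if (within_cluster_cos < 0 || within_cluster_cos >= 1) {
    stop("within_cluster_cos must lie in [0, 1)")
  }
  pool <- unique(normalize_word(pool))
  n <- length(pool)
  vecs <- with_seed(seed, {
    centers <- matrix(stats::rnorm(n_clusters * d), n_clusters, d)
    centers <- centers / sqrt(rowSums(centers^2))
    # v = sqrt(rho) * center + sqrt(1 - rho) * noise gives E[cos] ~ rho within
    # a cluster (noise directions are orthogonal in expectation at large d).
    rho <- within_cluster_cos
    cl <- rep_len(seq_len(n_clusters), n)
    noise <- matrix(stats::rnorm(n * d), n, d)
    noise <- noise / sqrt(rowSums(noise^2))
    v <- sqrt(rho) * centers[cl, , drop = FALSE] + sqrt(1 - rho) * noise
    v / sqrt(rowSums(v^2))
  })
  rownames(vecs) <- pool
  class(vecs) <- c("embedding_table", class(vecs))
  vecs
}

#' Write an embedding table in the plain-text interchange format
#'
#' @param table An `embedding_table` or numeric matrix with word row names.
#' @param path Output path.
#' @param header Whether to write the `count dim` header line.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path, header = TRUE) {
  lines <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], format(table[i, ], digits = 10)),
          collapse = " ")
  }, character(1L))
  if (header) lines <- c(paste(nrow(table), ncol(table)), lines)
  writeLines(lines, path)
  invisible(path)
}
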