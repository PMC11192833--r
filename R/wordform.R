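#' Normalize a word to a lowercase alphabetic letter sequence
#'
#' All similarity schemes in this package operate on normalized word forms:
#' lowercase letters `a`-`z` with every non-alphabetic character stripped.
#' Normalization is idempotent.
#'
#' @param text Character vector of raw words.
#' @return Character vector of normalized words.  An element that contains no
#'   alphabetic character after stripping is an error.
#' @examples
#' normalize_word("Ledge")   # "ledge"
#' normalize_word(" dog!")   # "dog"
#' @export
normalize_word <- function(text) {
  if (!is.character(text) || length(text) == 0L) {
    stop("invalid word: input must be a non-empty character vector")
  }
  out <- gsub("[^a-z]", "", tolower(text))
  if (any(is.na(out)) || any(!nzchar(out))) {
    stop("invalid word: no alphabetic characters in ",
         paste(utils::head(text[!nzchar(out) | is.na(out)], 3L), collapse = ", "))
  }
  out
}

# Split a normalized word into its letter vector.
word_letters <- function(word) {
  strsplit(word, "", fixed = TRUE)[[1L]]
}
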