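Package: orthomem
Title: Orthographic and Semantic Global Matching Models of Recognition Memory
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Word-form similarity codes (slot, both-edges slot, overlap,
    both-edges overlap, closed and open bigrams, Levenshtein), semantic
    similarity from word embeddings, and their aggregation into a
    power-transformed global similarity statistic over a study list.
    Global similarity drives trial-level drift rates in a two-accumulator
    linear ballistic accumulator (LBA) race, giving a joint likelihood for
    old/new choices and response times.  Includes hierarchical Bayesian
    estimation by differential-evolution MCMC, WAIC model comparison,
    posterior predictive checks, a synthetic-data generator for recognition
    experiments, and descriptive summaries (global-similarity bins,
    Levenshtein-based lure classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
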