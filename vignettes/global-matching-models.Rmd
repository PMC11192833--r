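---
title: "Global matching models of recognition memory with orthographic and semantic word representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global matching models of recognition memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomem)
```

## The modeling problem

In a recognition memory experiment a participant studies a list of words and
is then shown test probes — *targets* that were on the list and *lures* that
were not — responding "old" or "new" to each.  Global matching theories hold
that the evidence behind this decision is the aggregate similarity between
the probe and *everything* on the study list: a lure that happens to
resemble several studied words attracts false alarms, and it does so faster
than a dissimilar lure attracts them.  Making that account quantitative
requires committing to (i) what "similarity between two words" means, (ii)
how pairwise similarities aggregate over the list, and (iii) how the
aggregate drives the joint distribution of choices and response times.
`orthomem` implements one full chain of such commitments and the machinery
to fit and criticize it.

## Pairwise word-form similarity

Seven orthographic codes are implemented, all normalized so that a pair of
words receives a similarity in [0, 1]:

* **Slot code** (`slot_similarity`): letters match only at the same
  absolute position from the start of the word.  The match sum `M` is
  divided by the *alignment length* `a`, the length of the longer word:
  `s = M / (a + (1 - alpha) + (1 - omega))`.  The weights `alpha` and
  `omega` scale matches on the start letter and on the *studied* word's
  final letter; at `alpha = omega = 1` the correction terms vanish and the
  denominator is simply `a`.
* **Both-edges slot code** (`both_edges_slot_similarity`): a mixture
  `w * s_start + (1 - w) * s_end` of the start-anchored code and an
  end-anchored code in which position −1 is the final letter.  This lets
  words of different lengths align on shared suffixes.
* **Overlap model** (`overlap_similarity`): a "noisy slot code".  Each
  studied letter occupies a Gaussian distribution over positions with
  standard deviation `sigma_l = d * (1 - exp(-(l - 0.5)/r))` — uncertainty
  grows with serial position `l` and saturates at `d`.  A probe letter at
  position `k` collects the Gaussian mass on the interval
  `[k - .5, k + .5]` from **every** studied position holding that letter.
  We adopted the every-position convention (rather than
  nearest-position-only) because it reproduces the worked value the
  literature quotes for the ledge–ledger pair (0.30) under the standard
  Gomez et al. schedule `r = 1.094`, `d = 1.544`; nearest-position
  summation gives ≈ 0.29.
* **Both-edges overlap** (`both_edges_overlap_similarity`): the same
  weighted mixture applied to a forward overlap pass and an end-anchored
  pass.  The backward pass indexes `sigma` by the letter's position counted
  from the end (final letter ↦ `sigma_1`).  That indexing is a genuine
  design choice — mirror symmetry with the forward code — and is only
  softly constrained by the corresponding worked value (0.28), which it
  reproduces.
* **Closed bigrams** (`closed_bigram_similarity`): adjacent ordered letter
  pairs plus two edge-marker bigrams (`_x` start, `x_` end), matched
  *once-only* across the two multisets, divided by the larger bag size.
  Once-only matching is implemented as the exact multiset intersection
  (per-token minimum of multiplicities), which for identical tokens equals
  optimal bipartite matching — the test suite verifies this against a
  brute-force matcher.
* **Open bigrams** (`open_bigram_similarity`): ordered pairs of letters at
  distances 1–3 plus the edge markers; the "relative position" analog of
  the overlap model.
* **Levenshtein** (`levenshtein_similarity`): `(a - D)/a` with `D` the
  edit distance; a useful reference scheme with no psychological
  commitments about letter position.

```{r}
string_similarity("ledge", "ledger", scheme = "slot")$value
string_similarity("ledge", "ledger", scheme = "open-bigram")$value
round(string_similarity("ledge", "ledger", scheme = "overlap")$value, 2)
```

Two boundary behaviors matter for interpretation.  First, the overlap
schemes are *not* exactly self-similar or symmetric at nonzero `d`: the
positional uncertainty lives in the studied word and varies with serial
position, so `s(a, b)` and `s(b, a)` differ slightly even for equal-length
words, and `s(x, x) < 1`.  Both properties collapse onto the slot-code
values as `d -> 0`, which the tests assert at `d = 1e-6`.  Second, a
caution about end-anchored counting illustrated by the *kitten*/*smitten*
comparison: the five end-aligned letters of "itten" all match, so the
end-based similarity is 5/7 ≈ 0.71, although a miscount to 4/7 (≈ .571) is
easy to make — "itten" reads like four letters — and circulates in the
literature.  The implementation follows the positional definitions and the
tests assert the recomputed value.  (The forward direction of the same
pair has one match, the "t" at position 4, not zero.)

The letter-"e" modification (`e_modified_similarity`) supports
depth-of-processing designs in which a shallow encoding task asks whether
an "e" is present: a positionless bonus `epsilon` enters the numerator when
both words contain the letter, with `epsilon` also added to the denominator
so the value stays in [0, 1].  The bonus requires *joint* presence rather
than presence in either word: under an either-word rule a probe containing
"e" would gain similarity to every studied word regardless of their
letters, which defeats the purpose of the modification.

## Global similarity

`global_similarity()` aggregates pairwise similarities over the study list:

`g = sum_{j in L, j != probe} s_j^p / N_L`

with three commitments worth making explicit:

* **Self-exclusion with a fixed divisor.**  List entries equal to the probe
  word are excluded from the sum — self-match similarity is identically 1
  in most schemes and would swamp the inter-item signal — but the divisor
  stays at the full list length `N_L`.  The aggregation rule divides by
  list length, not by the count of summed terms.
* **The nonlinearity `p`.**  Raising similarities to `p > 1` pushes small
  values towards zero while leaving 1 untouched, so only the handful of
  list items genuinely similar to the probe survive; `p` is bounded away
  from zero in fitting (`p > 0`) so that `0^p = 0` and zeroed self-matches
  stay inert.
* **The semantic channel.**  With an embedding table the per-item quantity
  becomes `w_o * s^p + (1 - w_o) * c^p*`, where `c` is the cosine between
  the two word vectors truncated at zero (`truncated_cosine`).  Truncation
  keeps the power transform monotone (a negative cosine raised to an even
  power would *gain* similarity).  Vectors are L2-normalized at load so the
  cosine is a dot product.  Out-of-vocabulary words are a repository-level
  decision: the default fallback scores a missing word as similarity 0
  with a warning (conservative; keeps the trial usable), and a strict mode
  errors instead.

`synthetic_embeddings()` builds cluster-structured unit vectors for tests
and demos: the expected within-cluster cosine is controllable and
between-cluster cosines concentrate near zero as the dimension grows.

## From similarity to choices and response times

The decision stage is a two-accumulator linear ballistic accumulator.
Each response ("old", "new") has an accumulator that starts at a uniform
random point in `[0, A]`, accumulates evidence linearly at a rate drawn
once per trial from `Normal(v, eta)`, and triggers its response on reaching
the threshold `b = A + B`; the response time adds a non-decision offset
`t0` (seconds).  Global similarity enters through the mean drift rates,

`v_old = V0 + V + gamma * g`,  `v_new = V0 - (V + gamma * g)`,

so evidence gained by "old" is exactly lost by "new"
(`v_old + v_new = 2 V0` always), and `gamma` measures how strongly the
memory signal moves the race.  `V` and `gamma` may differ across
experimental conditions and probe status; `eta` is fixed at 1 for lures
and estimated for targets (`eta_target`), applying to both accumulators on
a trial — the drift-variability parameter describes the probe, not the
response.

The likelihood (`lba_trial_loglik`) is the winner's defective first-passage
density times the loser's survival function.  Trials on which both
sampled drifts are nonpositive would never finish; the simulator
(`simulate_lba`) redraws the drift pair in that case, and the likelihood
divides by `1 - P(both drifts <= 0)` so the two stay an exactly matched
pair — the suite verifies that the race density integrates to 1 and that
simulated choice probabilities and RT deciles match likelihood-implied
values at Monte-Carlo precision.  RTs at or below `t0` receive a `-Inf`
log-likelihood rather than an error so samplers can reject proposals
gracefully.

## Hierarchical estimation and model comparison

`fit_gsm()` estimates participant-level parameters under group-level
normal (location parameters) or truncated-normal (positive parameters)
distributions with means `mu` and SDs `sigma`, by blocked
differential-evolution MCMC: a chain proposes
`theta* = theta_i + gamma_DE (theta_j - theta_k) + U(-jitter, jitter)`
using two other chains, which automatically aligns proposals with the
posterior's correlation structure — important here because `gamma` and `p`
trade off strongly (larger `p` shrinks every `s^p`, which a larger `gamma`
can compensate).  Design choices, stated as package defaults rather than
facts about any dataset:

* `gamma_DE = 2.38 / sqrt(2 d)`, `jitter = 1e-4`, burn-in fraction 0.5,
  and at least `2 d + 1` chains; with probability 0.1 a proposal uses
  `gamma_DE = 1` to allow mode jumps.
* Group blocks are updated one `(mu, sigma)` pair at a time (each a 2-D
  DE-MCMC block), conditional on the participant draws; the data
  likelihood cancels from that conditional.
* Priors are weakly informative: normal hyperpriors on the group means,
  half-normal on the group SDs, with scales listed in `parameter_spec()`
  and overridable row-wise.  The similarity-scale parameters get wide
  priors (SD 100) because on the `g` scale produced by list-averaged,
  power-transformed similarities (order 10^-3), scientifically meaningful
  `gamma` values are of order 10–100.
* Chains start from cheap data-driven centers — `t0` below the fastest
  observed RT, and `V`/`gamma` from a probit regression of the old/new
  response on `g` within each probe status (the race model implies
  `P("old")` is approximately `Phi(sqrt(2)(V + gamma g) / eta)`) — with
  any start state that has a degenerate likelihood redrawn.  This spends
  the burn-in exploring the posterior rather than locating it.
* Pairwise similarity matrices are precomputed once per fit (they do not
  depend on sampled parameters when the representation parameters are
  fixed); the nonlinearity is applied per likelihood evaluation.
  Representation parameters such as `alpha` or `d` can in principle be
  estimated too, at the cost of recomputing similarities per proposal;
  the package's fitting surface fixes them and estimates the
  decision-side parameters plus `p` and the `gamma`s.

Model comparison uses WAIC (`waic`, `model_waic`) computed from the
pointwise log-likelihood matrix over posterior draws: `waic = -2 (lppd -
p_waic)`, lower is better, with the penalty given by the per-trial variance
of the log-likelihood across draws.  `model_waic()` warns when any group
mean's split-chain R-hat exceeds 1.05.  `posterior_predictive()` simulates
replicate data from posterior draws and summarizes them with means and 95%
highest-density intervals (`hdi`).

## The synthetic-data generator

Because the package is exercised without any external datasets, the
generator (`study_design`, `generate_pool`, `generate_session`,
`simulate_study`) emulates the structure of unrelated-word recognition
studies: study lists of 40–150 words (default 50), word lengths 3–11
letters (default 3–10), an approximately 50/50 target/lure test, and RTs
in seconds.  Word pools are letter-frequency-weighted random strings by
default, so chance orthographic overlap is language-like without shipping
a lexicon; a ~4,600-word English demo list is included for realistic
examples (`demo_wordlist`).  A small fraction of lure trials (default 2%,
configurable; the empirical range for unselected lists is about 1–3%) is
planted as single-letter deletions of studied words, cycling the deleted
position over start/middle/end so that lure-subtype analyses have all
cells.

The generating group-level parameters (`group_params`) encode the regime
the modeling literature reports for unrelated-word lists: a nonlinear
similarity function (`p = 3`, the classic cubing value), a strong
similarity effect on lures and none on targets (`gamma_lure = 100`,
`gamma_target = 0`), `V_target = 1` and `V_lure = -1` around `V0 = 2`,
thresholds `B = 1` over `A = 0.5`, and `t0 = 0.25` s.  The value
`gamma_lure = 100` deserves a note: with 50-item lists and `p = 3`, global
similarities fall around 10^-3–10^-2, so a scale of ~100 is what makes a
planted high-similarity lure shift the "old" drift by about one unit and
produces a false-alarm-rate rise of roughly .10 from the lowest to the
highest similarity bin — the effect size this paradigm typically shows.
Under these conditions hit rates sit near .90 and false-alarm rates near
.08 with strongly elevated false alarms (≈ .4) to edit-distance-1 lures.

What the generator does *not* emulate: word frequency and
age-of-acquisition structure, semantic relatedness of real lexicons (the
synthetic embedding clusters are a geometric stand-in), phonology,
sequential effects within the test, and participant-level contaminant
processes (fast guesses, lapses).  Passing tests therefore certify the
pipeline's internal consistency — simulator, likelihood, sampler, and
summaries agreeing with each other and with hand-computable cases — not
that any particular representation wins on real data.

## Descriptive summaries

`bin_by_global_similarity()` forms equal-count bins of `g` within each
probe status and reports hit/false-alarm rates with .1/.5/.9 RT quantiles
for correct and error responses; ties are broken by stable trial order,
and the degenerate all-equal case falls back to round-robin assignment
with a warning.  `classify_lure()` classes each lure by its minimum edit
distance to the study list (1 → HS, 2 → MS, 3 → LS, ≥ 4 → VLS), records
whether one or at least two studied words sit at that distance (1x/2x),
and, for HS lures related by a clean single-letter deletion/insertion or
substitution, reports whether the affected letter was the start, an
interior, or the end letter.  For substitution pairs the "missing letter"
notion is ambiguous; the substituted position is used.  Median RTs are
reported per class because HS lures are rare; empty cells are `NA`, never
zero.

## Numerical choices and limitations

* Normal CDFs use R's `pnorm`; worked similarity values are asserted after
  rounding to the one or two decimals at which such values are
  conventionally quoted.
* The LBA density/CDF switch to the degenerate-start closed form when
  `A < 1e-10` to avoid 0/0; densities are floored at 0 and CDFs clipped to
  [0, 1] against floating-point undershoot.
* `hdi()` returns the shortest sample interval; with heavy MCMC
  autocorrelation it can be slightly narrower than a converged interval,
  which is one reason the recovery checks use pooled chains.
* Problem sizes in the test suite — 8 participants × 300 trials for
  recovery, 4 × 200 for WAIC comparisons, 10 seeds each, 250–600
  DE-MCMC iterations — were chosen as the smallest sizes at which the
  checks are statistically meaningful; they are scaled-down analogs, and
  real applications should use longer chains and verify R-hat < 1.05
  before interpreting WAIC.
* Fitting currently exposes a single-condition parameterization
  (`V_target`, `V_lure`, `gamma_target`, `gamma_lure`); multi-condition
  sharing maps are a straightforward extension of `parameter_spec()` but
  are not wired into `fit_gsm()`.
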