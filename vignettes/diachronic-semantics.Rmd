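---
title: "Methods: year-sliced distributional semantics in diasem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: year-sliced distributional semantics in diasem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`diasem` quantifies lexical change from year-stamped co-occurrence counts.
This vignette documents the model, the parameters that matter, the numerical
conventions, what the synthetic test-bed does and does not establish, and the
package's known limitations. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The model

All analyses derive from one object: the co-occurrence tensor, a symmetric
matrix per year whose entry `c(v_i, v_j)` counts how often two vocabulary
words appeared together. Two counting modes exist and are never mixed within
one tensor:

* **5-gram mode** (`accumulate_cooccurrence`): every unordered pair of token
  positions within a 5-gram record contributes the record's `match_count`
  (10 pairs per complete 5-gram), with flat weighting — no distance decay.
  This is the natural mode for the public Google Books 5-gram distribution.
* **window mode** (`accumulate_window_cooccurrence`): for running text, every
  position pair at distance < 5 contributes 1.

The two modes differ on overlapping windows (consecutive 5-grams drawn from
running text overlap in 4 positions, so 5-gram counting multiply-counts
pairs relative to a single pass with a sliding window). Published
descriptions of this family of pipelines use both phrasings; we implement
both and leave the choice to the caller rather than resolving the ambiguity
silently.

Repeated words within one window accumulate on the matrix diagonal, which
keeps marginals well defined, but the diagonal is excluded from PPMI and
from neighbour retrieval: self-co-occurrence says nothing about a word's
neighbours.

### PPMI

Each year's slice is reweighted entrywise as

```
PPMI(v_i, v_j) = max(0, ln P(v_i, v_j) - ln P(v_i) - ln P(v_j))
```

with probabilities taken over ordered co-occurrence events, diagonal
excluded: writing `C` for the full symmetric off-diagonal count matrix and
`N = sum(C)`, we use `P(v_i, v_j) = C[i, j] / N` and `P(v_i) =
rowSums(C)[i] / N`. This convention is chosen so that *empirical
independence is the zero point*: a pair co-occurring at exactly the product
of its marginals has PMI 0, and the PPMI of an i.i.d.-sampled corpus
converges to 0 entrywise (asserted in the suite at 10^5 windows, median
|PPMI| < 0.05). An alternative normalization over unordered pairs
(`N = sum over i < j`) makes marginals sum to 2 and shifts every
independent pair to PMI = ln(1/2), which clips the rows of profile-free
high-frequency words to all zeros; we rejected it for that reason. Under our
convention the degenerate one-pair corpus has PPMI = ln 2, not 0 — the
price of putting the zero where the statistics need it. The log base is
natural; cosine rankings are insensitive to it. No add-k smoothing and no
context-distribution exponent are applied by default (the plain formula is
the documented behaviour).

### Embeddings

The PPMI matrix is factored by (deterministic, LAPACK) truncated SVD and
word *i* receives row *i* of `U_d S_d^p`. Two parameters matter:

* `d` (dimension, default 300): appropriate for 10^4-plus vocabularies. For
  the synthetic test corpus (466 words, ~5 true structural dimensions: 4
  topics plus a function-word axis) the suite uses `d = 10`; pushing `d`
  far past the true rank only adds noise dimensions and degrades stability
  estimates.
* `p` (singular-value exponent, default 0.5): symmetric square-root
  weighting, the established default for PPMI-SVD embeddings. `p = 1`
  makes full-rank embedding cosines reproduce the PPMI row cosines exactly
  (used as the dense-oracle cross-check in the tests); `p = 0.5` generally
  ranks neighbours better in practice. The exponent is recorded in every
  embedding's metadata rather than hidden.

Sign indeterminacy of singular vectors is fixed by forcing each left
singular vector's largest-magnitude component non-negative, so repeated runs
are bit-identical.

### Alignment, stability, drift

Embedding spaces from different years are arbitrary orthogonal
transformations of one another. `procrustes_align` computes the closed-form
orthogonal Procrustes rotation (no translation, no scaling) on anchor rows
— by default all words shared by both spaces with nonzero vectors. A pure
rotation/reflection cannot distort intra-space geometry; the suite asserts
pairwise cosines are unchanged to 10^-10 and orthogonality to 10^-8.

Stability between two years is the cosine of the word's aligned vectors.
Distant years are aligned in a single hop (earlier space directly onto the
later one), not by chaining year-over-year rotations: chaining accumulates
estimation error from every intermediate year and adds nothing when both
endpoint spaces are available. The reported default is clipped to [0, 1] —
once two aligned senses are orthogonal they are simply "unrelated", and the
sign of a near-zero cosine carries no further gradation — but the raw cosine
is always retained alongside.

Drift trajectories re-express a word's aligned historical vectors in a fixed
2-D plane. The plane is a PCA fitted on *modern* vectors only: the top
`k_anchors` (default 10) neighbours of the word in the start year and in
the end year, each taken in its end-year sense, plus the word's own modern
vector. Fitting the plane on modern vectors keeps the anchor layout an
interpretable map of the modern semantic neighbourhood; the historical
waypoints are then projected into that map. Waypoints default to 50-year
steps; the drifting word's missing years are skipped with a warning rather
than interpolated.

### Networks

Synonym networks connect seed words and their top-k neighbours wherever
cosine exceeds a threshold (default .8, user-settable). Context networks
around a target admit words with `PPMI(target, w)` above a threshold
(default 3) *and* a normalized co-occurrence rate of at least `min_rate`
(default 200) per `per` corpus words; edges among admitted words reuse the
same PPMI threshold, keeping the parameter surface small. `per` defaults to
10^10 ("per ten billion words"), but a per-billion convention also
circulates for the same 200-count threshold, so `per` is an explicit
argument everywhere rather than a constant. Communities come from Louvain
modularity optimization (igraph's multilevel implementation) under a fixed
seed and deterministic node order; an edgeless graph is one singleton
community per node with modularity 0 by convention. Note the in-topic PMI
of a balanced T-topic corpus is about ln T, so on small synthetic corpora a
PPMI threshold of 3 (natural for 50,000-word historical vocabularies) admits
nothing; the suite therefore exercises context networks on a 20-topic
configuration where planted blocks sit well above threshold.

Change tables (largest co-occurrence increases/decreases between two years)
use rates normalized by each year's token total, not raw counts, so corpus
growth between years cannot masquerade as contextual change.

### Contextual affect

A word's valence/arousal/concreteness in a year is a mean of published norm
ratings over its context words. The published phrase "the mean of the
ratings of all words that co-occurred" is ambiguous between token and type
weighting; the default is token-weighted (each rated context word weighted
by its co-occurrence count), which is robust to one-off contexts, with the
unweighted variant one flag away. Every score carries `coverage` (the share
of co-occurrence mass that is rated) and `n_context_types`, so low-coverage
years can be masked downstream; the package itself never imposes a coverage
threshold. Contemporary norms are applied to all years — an interpretive
caveat inherent to the method, since historical re-normed ratings do not
exist.

## Corpus accounting choices

* Tokens are lowercased; tokens carrying the Google POS-tag separator `_`
  are dropped by default (tagged ngrams duplicate untagged ones in the
  public corpus); a strip-the-suffix policy is available. Sentinel markers
  (`_START_`-style) are always dropped.
* Vocabulary rank is by aggregate count across all years, ties broken
  lexicographically — deterministic builds.
* Year totals count all surviving tokens (5 x `match_count` per complete
  record), not just vocabulary tokens. Because consecutive 5-grams from
  running text overlap, totals computed this way overstate underlying text
  length by a bounded constant factor; this affects only the absolute scale
  of relative frequencies and normalized rates, never comparisons across
  words or years, and is surfaced here as a documented caveat rather than
  guessed away.
* Malformed corpus lines are skipped and counted, with a hard abort above a
  10% fraction — real ngram shards contain header and edge artifacts, but a
  mostly malformed file is an error, not data.

## The synthetic test-bed

`generate_corpus` emulates a year-stamped 5-gram stream with planted,
manifest-recorded structure. Reference conditions (the package defaults):
4 disjoint topics x 100 words; 60 shared function words drawn with Zipf
weights carrying 8% of tokens; 100,000 5-grams per year, 1850-2000 in
25-year slices; `match_count ~ 1 + Poisson(1)`; one drift word moving
linearly from topic 1 to topic 2 between 1900 and 1950 (2% of grams); one
stable word per topic (1% of grams each, fixed topic); one word whose
emission rate grows linearly (0.2% to 1%); valence blocks at topic means
7/3/5/5 (sd 0.1), plus an arousal and a concreteness block. Rationale for
the non-obvious choices:

* *Disjoint topics* (concentration 1) make planted facts exactly
  recoverable (zero cross-topic co-occurrence), which is what parameter-
  recovery tests need; the `concentration` dial reintroduces leakage, and a
  dedicated test verifies the leaked co-occurrence share matches the
  configured concentration analytically.
* *Zipf function words* mimic the heavy head of natural frequency
  distributions and exercise the PPMI penalization path with realistic
  ubiquitous words.
* The drift window (onset 1900, completion 1950) sits strictly inside the
  year range so pre-drift and post-drift regimes are observable on both
  sides.

What the generator does **not** emulate: natural unigram statistics, syntax,
polysemy without drift, word birth/death, OCR noise, and — importantly —
words with individually distinctive context profiles within a topic. Words
of one topic are exchangeable, so their true pairwise embedding distance is
0 and any ranking among stationary words reflects estimation noise, not
meaning. Consequently, passing tests establish that the pipeline recovers
*planted between-topic structure and its timing*; they do not certify
recall of subtler within-topic semantics in real corpora. Two published-
style claims do not transfer to this test-bed at all and are tested in
comparative form instead: function words cannot top the stability ranking
here (synthetic function words are profile-free, so their PPMI rows are
truly zero), and a stable word's trajectory cannot sit inside the 10th
percentile of its anchor distances (same-topic anchor distances are
themselves pure noise).

Suite problem sizes — 10^5 grams/year for the reference corpus, 10^5
windows for the independence check, 200-word slices for dense-oracle
comparisons, `d = 10` embeddings — were chosen as the smallest sizes at
which the planted effects are estimated with comfortable margins on a single
CPU in seconds to a couple of minutes.

## Numerical conventions and degenerate inputs

* Natural log throughout PPMI; zero-count pairs stay exactly 0.
* SVD and PCA are deterministic; all generator randomness flows through one
  integer seed, and identical (config, seed) reproduce corpora byte for
  byte.
* Cosine of a zero vector is an error, never NaN; words whose PPMI row is
  all zero are treated as absent from the space by alignment and retrieval.
* Ties in synonym ranking break by descending corpus frequency, then
  lexicographically; vocabulary rank ties break lexicographically.
* An all-zero co-occurrence slice, an empty vocabulary, a missing year, or
  fewer Procrustes anchors than dimensions are explicit errors; an empty
  context-network candidate set returns an empty network with its
  parameters echoed (an empty result is an answer, a missing year is not).
* A rank-deficient anchor matrix yields a flagged pseudo-solution with a
  warning rather than silent garbage.

## Limitations

* Dense SVD bounds practical vocabulary size to a few thousand words per
  year on one machine; corpus-scale (50,000-word) runs need an iterative
  truncated solver behind the same interface.
* Single-hop alignment assumes both endpoint spaces are well estimated; for
  very sparse early years a chained or regularized alignment may be
  preferable.
* Affect scores inherit every bias of contemporary norm lexicons applied to
  historical text.
* The frequency-totals overlap caveat above: absolute rates are comparable
  within a corpus build, not across counting conventions.
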