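---
title: "Storytelling across abstracts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storytelling across abstracts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(storyline)
```

## The problem

Literature-based discovery in the Swanson tradition looks for connections
between two bodies of literature that are *complementary but disjoint*
(CBD): no single paper links them, but a chain of intermediaries does. Given
a start and an end abstract with little or no overlap in content, this
package searches for a *story*: an ordered chain of documents in which every
consecutive pair is similar enough to make the step defensible, every link
is backed by a clique of supporting neighbors, and the chain as a whole is
statistically surprising, contextually consistent, and summarizable sentence
by sentence.

## Document model

Documents (title plus abstract) are tokenized, lowercased, Porter-stemmed,
and stripped of stopwords, pure numerals, and DNA-like tokens (six or more
characters over A/C/G/T). Each document `d` becomes a sparse vector with
weights

```
w_td = f_td * ln(N / n_t),  then  w_d <- w_d / ||w_d||_2
```

where `f_td` is the term frequency, `n_t` the number of documents containing
`t`, and `N` the corpus size: a tf-idf variant with cosine normalization, so
abstract length does not dominate. Terms appearing in every document get
zero weight and drop out. The idf log is natural; this is a convention, not
a tuning, since any base rescales all weights of a vector equally and the
distance below is scale-invariant per term ratio only in the aggregate —
base e is simply fixed once.

Similarity is measured by the Soergel distance

```
D(u, v) = sum_t |u_t - v_t| / sum_t max(u_t, v_t)
```

over the union of stored terms: 0 exactly for identical vectors, 1 exactly
for disjoint term sets, symmetric, and obeying the triangle inequality. The
triangle inequality is load-bearing twice: it makes the straight-line
heuristic admissible, and it bounds how much a chain of short steps can
drift.

The Porter stemmer is implemented in the package (the original 1980 rule
set) and verified against canonical word/stem pairs in the test suite.

## Review pruning, seeds, and start-end pairs

Review papers act as "lowest common denominator" hubs: a story can
short-circuit through a review that merely lists both endpoint topics. A
document is pruned when its publication types include a review type, its
title contains the token "review" (token-level on purpose — "reviewed" is
legitimate), or a sentence contains "this review".

Seed documents are labeled by keyword lists; each document receives at most
one label (the first matching label in a deterministic label order — a
document capped out of its first label does not fall through to a later
one), and each label keeps at most `cap` documents (default 700) ranked by
keyword occurrence count, ties by corpus order. Start-end pairs are all
label combinations whose *modeled* term sets are disjoint, so a discovered
chain can never be a trivial overlap.

## Candidate generation: the concept lattice

The search never materializes the pairwise similarity graph (quadratic in
corpus size). Instead, the binarized term-document matrix (term present iff
modeled weight is positive) is mined for *concepts* — closed (document set,
term set) pairs in which neither side can grow without shrinking the other.
The miner enumerates closed sets by the intersection method: every closed
term set with nonempty support is an intersection of document term sets.
Any correct closed-set miner yields the same output; the test suite pins
the contract to brute-force enumeration on random matrices. The default
minimum support keeps concepts shared by about two documents.

Approximate nearest neighbors of a document are read off its concepts in
decreasing term-set-size order: documents co-occurring in a concept with a
long term set share many terms with the query. The per-document concept
ordering breaks ties by the lexicographically smallest term set (the
ordering of concepts per document, rather than of documents per concept,
is the reading under which the neighbor lookup is well defined; the
alternative reading leaves the lookup unspecified).

## Search

With clique size `k` and branching factor `b`, the successor generator
retrieves the top `m` lattice candidates, where `m` is the smallest integer
with `choose(m, k-1) >= b` — so junction-plus-(k-1)-subset combinations
yield at least `b` candidate cliques. Every candidate clique is verified
pairwise against the distance threshold `theta` (the lattice is
approximate), scored by the mean distance from the junction to the other
members, and the best `b` survive as a priority queue.

A* minimizes `f = g + h` where `g` accumulates the junction-to-junction
Soergel distance along the chain and `h(d)` is the straight-line Soergel
distance to the end document. Design choices worth recording:

* **What enters `g`.** The path cost is the cumulative distance over
  consecutive junctions; the clique's average distance is used only to
  order the successor queue. This is the reading under which the
  straight-line heuristic never overestimates the remaining cost, hence
  the search is optimal under the `b`-constrained successor structure.
* **Cliques contain the junction.** A clique is the junction plus `k-1`
  candidates; the same convention is used by the significance test, which
  samples `k-1` pool documents around the junction.
* **Every clique member is a candidate next junction**, not just the
  clique's best member — discarding members could discard the optimal
  path.
* **Simple paths.** A document may appear once per chain; with a
  consistent heuristic (triangle inequality guarantees consistency here)
  this costs nothing, since a shortest path under nonnegative costs never
  revisits.
* **Tie-breaks** on equal `f`: smaller `h`, then doc id. Defaults:
  `theta = 0.90`, `k = 3`, `b = 5`, `max_expansions = 100000` — inside the
  recommended operating region of distance thresholds 0.92–0.86 and clique
  sizes 2–8.

The test suite checks optimality against an exhaustive branch-and-bound
oracle over the same successor structure, on random corpora of up to 30
documents across `theta` in {0.95, 0.90, 0.85} and `k` in {2, 3}.

## Significance

For each link, the junction's clique is scored by Monte Carlo: draw `k-1`
documents uniformly from the junction's candidate pool, count the draws in
which all pairwise edges (including those to the junction) satisfy
`theta`, and report the success fraction, floored at `1/R` so that `R`
iterations (default 50,000) bound the smallest reportable p-value. The
chain-level p-value is the product over links; q-values over a batch of
chains are Benjamini-Hochberg (deterministic and parameter-free; a fixed
lambda Storey variant is available behind `method = "storey"`).

**Pool definition.** The pool defaults to the junction's *exhaustive*
concept-lattice candidate list — every document sharing at least one
modeled term with it. Restricting the pool to the top `m` candidates the
search itself consumes (available as `pool = "top-m"`) makes the null
nearly degenerate at desk scale: with `k = 2, b = 5` the pool has five
members, so p-values are multiples of 1/5 regardless of `R`. A
whole-corpus pool is also available (`pool = "corpus"`). Default filter
thresholds are `p_max = 0.001`, `q_max = 0.05`; they are configuration,
not estimated quantities.

## Context and cohesion filters

Abstracts typically state background and methodology first, findings last.
A naive Bayes classifier over (a) ten equal Distance-From-Title bins
(`DFT = preceding / N_s`, bin edges `[0, 0.1), ..., [0.9, 1.0]` with the
last bin closed) and (b) presence of indicator phrases ("investigated",
"observed", ...) labels each sentence *context* or *result*. Likelihoods
are tallied per bin / per phrase with Laplace smoothing `alpha = 1`
(unsmoothed zero counts would veto a class outright); phrase features are
presence-only; exact posterior ties go to *context*. The shipped
14-phrase lexicon is configuration and user-replaceable.

The **context overlap filter** requires, for every consecutive document
pair, a minimum Jaccard coefficient (`j_min`, default 0.05) between the
stemmed, stopword-free token sets of their concatenated context sentences
(the token-set reading; a whole-sentence reading would make the score
almost always zero). A document with no context sentences scores zero on
its links.

The **sentence cohesion filter** builds a layered graph — one layer of
sentences per junction, edges between consecutive layers when named-entity
sets intersect (default recognizer: case-insensitive longest-match
gazetteer lookup, chosen for offline determinism; any recognizer's output
can be substituted) — and requires start-to-end reachability
(breadth-first). Passing stories are summarized by the sentence path
maximizing the summed per-edge entity Jaccard, ties resolved toward the
earliest sentence positions.

## Dispersion

A story is CBD-shaped when only consecutive documents satisfy the
threshold. For junctions `d_0..d_{n-1}`, the dispersion plot marks the
non-adjacent pairs `(i, j)`, `j >= i+2`, within `theta`, and

```
eta = 1 - sum_filled (j - i - 1) / sum_all (j - i - 1)
```

so a cell far from the diagonal (a shortcut across many links) costs more
than one near it. `eta` is 1 when no cell is filled and 0 when all are;
stories with fewer than three documents score 1. The linear weight
`j - i - 1` is the simplest function satisfying all of these endpoint and
corner-heaviness requirements at once; it is a reconstruction, and the
weight function is a pluggable argument for anyone preferring a different
corner-heavy profile. Dispersion evaluates the junctions only, never the
evidence cliques.

## The synthetic corpus generator

Real corpora at the scale this method targets (tens to hundreds of
thousands of abstracts) cannot ship with a package, so validation runs on
generated corpora with planted structure:

* **Topic clusters** of mutually similar documents over disjoint term
  pools — background mass for the lattice and the significance pools.
* **A planted bridge chain** whose adjacent documents share a controlled
  fraction (`chain_overlap`, default 0.4) of their vocabulary through
  dedicated link pools, while non-adjacent bridge documents share
  essentially nothing: the CBD shape. The generator recomputes the actual
  Soergel distances of its output and reports the midpoint threshold
  `theta_star` separating adjacent from non-adjacent pairs (erroring if
  the separation collapses). `chain_overlap = 0` plants a broken chain
  that must yield no story.
* **Evidence documents** per link (default 2), built mostly from the link
  pool, so cliques of size three and above have support at loose
  thresholds.
* **Sentence structure**: early sentences use context-indicator phrases,
  late ones result phrases; all template filler is either a stopword or an
  indicator word present in *every* document, so filler gets zero idf
  weight and the vector geometry stays analytically controllable.
* **Entities** threaded along the bridge (each link's entity appears in a
  sentence of both its documents) guarantee exactly the planted cohesive
  sentence path; entities are synthetic strings registered in the emitted
  gazetteer, deliberately not real gene names.
* **Reviews**: a fraction of cluster documents is flagged so ingestion
  pruning is exercised; review documents can never appear in stories.
* The planted endpoints carry seed keywords in their titles and draw from
  disjoint halves of the weak shared pool, so they are modeled
  term-disjoint and form a legal start-end pair.

For the classifier's training data, the context/result boundary of each
generated abstract wobbles by one sentence around the requested fraction
(probabilities 0.2/0.6/0.2), and each sentence carries its own class's
indicator phrase with probability 0.9 and the other class's with
probability 0.05 — a band of ambiguous positions exists, but position and
phrases remain strongly informative, which is what the classifier's
assumptions require.

What passing tests on these corpora do **not** show: robustness to real
abstracts' vocabulary burstiness, synonymy ("IL-8" = "CXCL8"), entity
polysemy, real MeSH structure, or PubMed's term frequency distributions.
The generator makes no attempt to mimic those; it validates the machinery,
not the linguistics.

## Problem sizes and numerical choices

The shipped tests run at desk scale by design: metric properties on 1,000
random sparse vector triples; miner-versus-enumeration on 100 random
boolean matrices up to 8x10; search optimality on 50 random corpora of up
to 30 documents; significance calibration at R = 10,000 against engineered
pools with analytic success probabilities (binomial 99% interval);
monotonicity of story counts on a fixed 10-junction synthetic corpus over
`theta` in {0.95, 0.90, 0.85, 0.80, 0.77} and `k` in {2, 3} with all
non-adjacent bridge pairs as fixed start-end pairs; and full-pipeline
recovery of the planted chain (with the `chain_overlap = 0` negative
control). Distance comparisons against thresholds use exact arithmetic
with a 1e-12 slack only where floating-point ties are possible; the
Monte-Carlo p-value floor is `1/R`; all randomness flows through explicit
seeds and generation restores the caller's RNG state.

## Known limitations

* Story counts are counts of *found* chains — one optimal chain per seed
  pair — so "number of stories" compares search outcomes, not an
  enumeration of all satisfying chains.
* The branching-factor truncation means optimality is relative to the
  `b`-constrained successor structure, as designed; raising `b` widens the
  structure.
* The gazetteer recognizer knows nothing about synonymy or nesting beyond
  longest-match; swap in a statistical recognizer's output for real
  corpora.
* Monte-Carlo p-values below `1/R` are reported as `1/R`; raise `R` when
  chains are long and products get small.
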