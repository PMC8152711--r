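---
title: "A semi-automated two-phase workflow for title/abstract screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semi-automated two-phase workflow for title/abstract screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Title/abstract screening is the stage of a systematic or scoping review in
which two reviewers independently read every citation retrieved by the
literature search and judge it against the eligibility criteria. Searches
commonly return 10,000–20,000 citations of which only a few percent are
eligible, so this stage consumes hundreds of person-hours. `screenflow`
implements a semi-automated alternative: a human-in-the-loop active-learning
loop that tries to surface all eligible abstracts while showing reviewers
only a fraction of the corpus. Human reviewers (here simulated by an oracle
built from a reference standard) retain the final say on every included
abstract — the machinery only chooses *what* to show them, never *what to
decide*.

## The model

### Phase 1 — representations and a seeded training set

Each citation's title and abstract are combined into one text, tokenized,
lemmatized and POS-tagged. Three token streams feed three numerical
representations of every document:

1. **Latent semantic vectors.** A document-feature matrix (DFM) of 1-, 2-
   and 3-gram lemma counts is built; only the high-frequency n-grams that
   jointly cover a fraction $\phi$ (default 0.70) of total token mass are
   retained; a truncated SVD maps each document to scores
   $u_i \Sigma$ on the top $d$ (default 300) singular directions.
2. **Topic proportions.** Latent Dirichlet allocation over the noun/verb
   stream (collapsed Gibbs sampler; symmetric priors $\alpha = 1/T$,
   $\beta = 0.01$) represents each document by its posterior topic
   distribution over $T$ (default 300) topics.
3. **Embedding averages.** Each document is the frequency-weighted average
   of the word vectors of its in-vocabulary words,
   $e_i = \sum_w c_{iw} v_w / \sum_w c_{iw}$.

Each representation induces a document distance: cosine distance
($1 - \cos$) for the SVD and topic vectors, and word-mover distance (WMD)
for the embedding representation — the minimum total cost of transporting
one document's normalized word-frequency mass onto the other's, with
cosine distance between word vectors as the ground cost. From 3–5 known
eligible *seed* abstracts, the $k_1 = 8$ nearest neighbours under each of
the three distances are pooled (at most $|seeds| \times k_1 \times 3$
candidates), screened by the reviewer pair, and every newly confirmed
eligible abstract is expanded in turn, until at least $r = 600$ documents
have decisions. Because candidates are semantic neighbours of eligible
documents, this training set is strongly enriched in eligibles relative to
the corpus prevalence.

### Phase 2 — classify, screen, expand, repeat

The screening decisions so far, joined to the SVD features, train a
random-forest classifier (500 trees). Because eligible documents are rare
(≈ 5%), each training fold is rebalanced 1:1 with SMOTE — synthetic
minority rows $x_i + u (x_{nn} - x_i)$, $u \sim U(0,1)$ — applied *inside*
each cross-validation training fold only, so validation folds never contain
synthetic rows. The features-per-split value is chosen from
$\{\sqrt D/2, \sqrt D, 2\sqrt D\}$ by 5-fold stratified CV maximizing mean
validation sensitivity at the 0.5 decision threshold (ties to the smaller
value). The fitted model predicts eligibility over the whole corpus; unscreened
predicted-eligible documents are screened; every confirmed eligible
document — inherited from phase 1, confirmed from a predicted batch, or
confirmed from an earlier neighbour batch — is expanded exactly once by
its $k_2 = 15$ nearest neighbours under the three distances, those are
screened too, and everything is folded into the next training set. The
loop reaches saturation, and stops, when an iteration confirms no new
eligible document anywhere: the predicted batch adds nothing and no
confirmed eligible is left unexpanded.

Two design points deserve emphasis. First, saturation is gated on the
whole iteration, not the predicted batch alone: otherwise eligibles
discovered by neighbour screening could terminate the loop without their
own neighbourhoods ever being explored, silently severing the
nearest-neighbour cascade that drives recall. Second, the phase-1
eligibles join the phase-2 expansion queue, because phase 1 explores
neighbourhoods only at the shallower $k_1 = 8$; $k_2 > k_1$ exists
precisely to deepen the search once a training set is in place, and the
two-phase design's characteristic screening depth (roughly 35–55% of the
corpus) arises from every confirmed eligible contributing one
$k_2$-deep, three-distance neighbourhood. A safety cap (default 25
iterations) guards against oscillation under noisy oracles; hitting it
flags the result `capped` rather than erroring.

### Evaluation

Against a reference standard with $N_S$ eligible documents, with $N_{WF}$
eligible documents identified by the workflow and $N_P$ documents ever
predicted eligible: precision $= 100\,N_{WF}/N_P$, sensitivity
$= 100\,N_{WF}/N_S$, F1 the harmonic mean, specificity and accuracy from
the standard confusion matrix over all $N$ documents with
"predicted eligible" = ever-predicted. Workload reduction is
$100 (N - n_{screened})/N$ and person-hours saved
$2 (N - n_{screened})/200$ — two reviewers at about 200 abstracts per
reviewer-hour. A shortcut specificity formula sometimes quoted for this
design, $100 (N - N_{WF})/(N - N_S)$, exceeds 100% whenever
$N_{WF} < N_S$; the package computes the confusion-matrix value and
reports the shortcut separately (`specificity_shortcut`) for transparency.

## Design choices in the open points

* **Feature selection semantics.** "Common features" is implemented as
  cumulative-mass selection: features ranked by corpus frequency (ties
  lexicographic), keeping the smallest prefix reaching $\phi$ of total
  token mass. This reading makes $\phi$ independent of corpus size and
  vocabulary growth.
* **Distance transform.** "Inversely proportional to the cosine" is
  implemented as $1 - \cos$, which is bounded, symmetric and standard;
  $1/\cos$ is unbounded and sign-unstable.
* **SVD scores.** Documents are represented by $U\Sigma$ rows (not bare
  $U$), preserving inner-product geometry so that cosine distances at full
  rank equal those on the raw counts.
* **Stop-words and n-grams.** N-grams never cross sentence boundaries;
  stop-words are dropped from unigrams, the words stream and the
  noun/verb stream but retained inside bigrams/trigrams (phrases like
  "risk of bias" survive as `risk_of_bias`). Numerals and single-character
  tokens are dropped from all streams.
* **Sensitivity maximization.** The CV objective selects model
  hyper-parameters at a fixed decision threshold; the threshold itself is
  exposed in the configuration but not tuned.
* **Phase-2 expansion seeds.** Only the *newly* confirmed eligibles of the
  current iteration are expanded, not all historical eligibles — repeated
  expansion of old seeds adds nothing once their neighbourhoods are
  screened.
* **Reproducibility.** One master seed derives per-component seeds (LDA,
  SMOTE, random forest, reviewer noise) by fixed offsets; identical
  configuration, seed and corpus give a byte-identical screening log.
  kNN ties break by ascending document id.

## Numerical notes

* The WMD transport problem is solved exactly by a transportation simplex
  (north-west-corner start, MODI pivoting) with a $10^{-12}$ marginal
  perturbation against degenerate pivoting; the induced objective error is
  below $10^{-9}$. Documents contribute at most their 50 most frequent
  in-vocabulary words (configurable; `Inf` disables the cap).
* Nearest-neighbour WMD queries use prefetch-and-prune: the relaxed
  one-sided transport bound — always a lower bound — is computed against
  the whole corpus, and the exact simplex runs only for documents whose
  bound cannot exclude them from the top $k$. Results are identical to
  exhaustive exact search; a clearly labelled relaxed mode
  (`wmd_exact = FALSE`) is available for very large corpora.
* The truncated SVD is computed from the symmetric eigendecomposition of
  the document Gram matrix, so only an $n \times n$ problem is densified;
  signs follow a largest-loading-positive convention.
* LDA burns in for up to 375 Gibbs sweeps, stopping early once the
  per-token predictive log-likelihood moves by less than $10^{-4}$
  between checks 20 sweeps apart (minimum 100 sweeps), then averages
  document-topic counts over 125 further sweeps; rows are renormalized to
  the simplex within $10^{-8}$. The degenerate $T = 1$ model returns
  exact unit distributions.
* Zero-vector documents (no retained features / no in-vocabulary words)
  are flagged and excluded from distance queries instead of producing
  undefined cosines; empty documents get the uniform topic distribution.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` draws topic-word distributions from a sparse Dirichlet
(concentration 0.05 over a 500-word synthetic vocabulary), gives every
document a Dirichlet topic mixture (base concentration 0.5) and a Poisson
length (mean 150 words, floor 20), and *boosts* the eligible-topic weights
by a factor (default 5) for the documents designated eligible — exactly
`floor(prevalence * n)` of them, labels assigned by construction, with 3
eligible documents flagged as seeds. This reproduces the statistical
structure the workflow relies on: rare eligibles, semantically clustered
around identifiable topics, reachable from a handful of seeds. POS tags
are assigned cyclically over the synthetic vocabulary so the noun/verb
stream is a non-trivial subset.

It does **not** emulate real abstracts: no English morphology or syntax,
no near-duplicate records, no section-structured abstracts, no drifting
terminology, and class separation is governed by a single boost knob
rather than the messy partial overlaps of real eligibility criteria.
Passing the end-to-end suite therefore demonstrates that the machinery is
correct and that the loop converges with high recall at low screening cost
*under the generative assumptions* — it does not certify recall levels on
any particular real review, which depend on how separable that review's
eligible literature actually is.

The end-to-end study conditions used by the tests and the acceptance
script are: $N = 2000$ documents, 5% prevalence, boost 5, $d = T = D = 50$
dimensions, with the workflow defaults $k_1 = 8$, $k_2 = 15$, $r = 600$,
$\phi = 0.70$. The representation sizes are scaled with the corpus
(roughly $\sqrt N$-sized latent spaces are conventional at a few thousand
documents); all other parameters are the main-analysis defaults.

## Known limitations

* The rule-based lemmatizer and suffix-heuristic POS tagger are
  deliberately lightweight; the preprocessing contract (aligned tokens /
  lemmas / coarse tags) accepts any stronger tagger, and synthetic corpora
  carry their own exact POS lexicon.
* Concept-level annotation for clinical corpora (UMLS-style) is exposed
  only through the stream interface: any annotator that emits a token
  stream per document can feed `build_dfm()` and `embed_docs()`; none is
  shipped.
* Title-only citations are excluded up front (the workflow is known to
  perform poorly on them) and database-level deduplication is out of
  scope.
* `N_P` counts the union of documents ever predicted eligible across
  iterations; per-iteration prediction sets are recoverable from the
  iteration summary.

## A worked example

```{r example}
library(screenflow)

corpus <- generate_corpus(synth_config(n_docs = 2000, seed = 1))
config <- workflow_config(svd_d = 50, topics_T = 50, embed_D = 50, seed = 1)
result <- screen_corpus(corpus, config)
summary(result)
compute_metrics(result, corpus)
```
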