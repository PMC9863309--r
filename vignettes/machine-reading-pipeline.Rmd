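---
title: "A desk-scale machine-reading pipeline for biomedical literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale machine-reading pipeline for biomedical literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A focused biomedical field — say, proteomics applied to nutrition and diet —
accumulates hundreds to thousands of publications, too many to review by
hand but few enough that heavyweight infrastructure is unnecessary.
`litminer` implements the analysis layer of a machine-reading pipeline for
such corpora: sentence segmentation, dictionary-based entity tagging and
normalization, sentence-level comention networks, tf-idf + K-means thematic
clustering with theme keywords and a 2-D embedding, and per-cluster
overrepresentation statistics. Everything downstream of corpus retrieval is
covered; fetching records from bibliographic services is deliberately out of
scope, so the pipeline starts from a documented corpus JSON dialect.

Because real corpora come with no ground truth, the package ships a
synthetic-corpus generator with *planted* topics and *planted* entity
mentions. Every pipeline stage is validated against that recoverable truth;
the test suite and `scripts/acceptance.R` are built entirely on it.

```{r, eval = FALSE}
library(litminer)
gen  <- generate_corpus(generator_config(n_docs = 140, seed = 5))
corp <- sentencize(gen$corpus)
m    <- tag_entities(corp, synthetic_lexicon())
mat  <- tfidf(tokenize_corpus(corp, ngram_max = 1, min_df = 2,
                              stopwords = character(0)))
cl   <- kmeans_docs(mat, k = 7, seed = 0)
cluster_themes(mat, cl, corp)
```

## Sentence segmentation

Large pipelines use statistical sentencizers; this package instead defines a
deterministic rule so that results are reproducible with no model download.
A sentence ends at `.`, `!` or `?` followed by whitespace and an uppercase
letter or digit, except when the period (i) closes a protected abbreviation
(`e.g.`, `i.e.`, `et al.`, `vs.`, `Fig.`, `ca.`, or a single capital initial
as in "J. Smith") or (ii) sits between digits, as in "4.9 and 6.0 °C".
Offsets are 0-based half-open so a `Sentence` is exactly a slice of its
source field; the spans partition the non-whitespace text, and degenerate
text yields one sentence. When a document carries both an abstract and full
text, the abstract is analyzed — abstracts are the denser, more consistently
available field.

## Dictionary tagging and normalization

Production annotation tools couple statistical taggers with normalization to
controlled vocabularies. The package keeps the *contract* of that stage —
each mention records `text_found`, a normalized `preflabel` under which all
synonyms are collapsed, and a `type` (protein or disease; genes and proteins
are not distinguished) — but implements it as deterministic dictionary
matching:

* candidate matches are synonym occurrences aligned to token boundaries
  (a token is a run of letters, digits and hyphens);
* matching is case-insensitive for synonyms of 4+ characters and exact for
  shorter ones — the 4-character threshold keeps short gene symbols such as
  `INS` from firing on the word "ins";
* overlaps resolve leftmost-longest: earliest start, then longest span,
  then lexicon order, so "milk fat globule membrane" beats "milk".

The tagger has no abbreviation detection, coreference or context
disambiguation; on real text its precision depends entirely on lexicon
curation. On generated corpora whose vocabulary is disjoint from the lexicon
surface forms it is provably exact, which is what the recall/precision
tests assert.

## Comention networks

Two entities are *comentioned* when they appear in the same sentence. A
comention carries no direction or meaning — the relation-extraction layer
that would assign semantics is explicitly out of scope — so records are
canonical unordered pairs (vertices sorted lexicographically), deduplicated
per sentence. Network edge weight is the number of *distinct documents*
supporting the pair, not the number of sentences: a pair comentioned in
three sentences of one paper has support 1. The default reporting threshold
keeps edges with five or more supporting publications, the conventional
cut-off for plotting clarity; node weight is the number of distinct
documents mentioning the entity. Exports are GraphML plus flat TSVs,
including the publication-ID / sentence / date / protein / disease table
used for interactive browsing.

## Thematic clustering

Documents are vectorized with tf-idf. The variant is fixed and stated:
raw term counts, smoothed inverse document frequency

$$\mathrm{idf}(t) = \ln\frac{1+N}{1+\mathrm{df}(t)} + 1,$$

and L2 row normalization — the de-facto standard of the ecosystem this kind
of analysis is usually run in. Tokens are lowercased runs of length >= 2;
n-grams up to 4 are included by default so multi-word themes ("milk fat
globule membrane") can surface as single terms; terms below a minimum
document frequency (default 2) are pruned. The bundled stop-word list is
deliberately minimal (function words only): thematic keyword lists in this
literature retain generic domain words like "study" and "human", so a
aggressive list would distort themes.

Clustering is K-means: k-means++ seeding, Lloyd iterations, 10 restarts
keeping the lowest within-cluster sum of squares (WSS), convergence when the
largest centroid shift drops below `1e-6`, at most 300 iterations, and
empty clusters repaired by reseeding to the point farthest from its
centroid. All randomness flows from one integer seed, so results are
exactly reproducible. K defaults to 7 but is always user-chosen; the WSS
curve's elbow suggestion (the K maximizing the second forward difference of
the curve) is advisory only. Per-cluster *themes* are the top 10 terms by
mean tf-idf over the cluster's documents (ties alphabetical), reported with
cluster size in documents, median SJR, and median/earliest/latest year.
Cluster letters are arbitrary stable labels (A, B, ... in cluster-index
order); nothing downstream depends on them.

The 2-D view is an exact (quadratic-cost) t-SNE: per-point perplexity
calibration by binary search, Student-t low-dimensional kernel, gradient
descent with momentum (0.5 rising to 0.8), adaptive gains, early
exaggeration (factor 12 for 100 iterations), learning rate 200, and
initialization from the first two principal components with a fixed sign
convention, which makes the embedding deterministic given the seed.
Identical documents are collapsed before optimization and share their
representative's coordinates — with few points, optimizing duplicates
independently lets numerical noise drive them apart, and coincident inputs
should remain coincident outputs. The implementation is suited to hundreds
up to a few thousand documents; beyond that a Barnes-Hut implementation
would be the right tool.

## Overrepresentation statistics

Whether a protein (or a disease-ontology category) is concentrated in a
cluster is tested with the upper-tail hypergeometric probability

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

equivalent to a one-sided Fisher exact test; `k = 0` returns exactly 1 and
the computation runs through the log-space-stable distribution function.
For entity tests the background is the full analyzed corpus (`N` documents,
`K` containing the entity, cluster of size `n` with `k` hits); for category
tests the background is the set of lexicon proteins with at least one
category mapping, and unmapped proteins are counted out. Entities observed
in fewer than 2 cluster documents are dropped — below that the test is
uninformative, and published per-cluster tables conventionally bottom out
at 2 — and rows at or above the reporting cut-off (`p < 0.1` by default)
are omitted. Because it is genuinely ambiguous whether such tables should
be multiplicity-corrected, raw p-values and Benjamini–Hochberg FDRs
(step-up rule, computed within each cluster's family) are reported side by
side.

## The synthetic-corpus generator

The generator is the package's source of ground truth, and its defaults are
the study conditions used for validation: 7 topics with pairwise-disjoint
15-keyword vocabularies, keyword weight 0.6, Poisson document lengths with
mean 120 tokens (truncated at 20), one planted entity mention per document
on average with 30% synonym variation, and years uniform on 2000–2022.
Each document samples a topic, draws tokens i.i.d. (keyword vs shared
background vocabulary), chunks them into 8–15-token sentences, capitalizes
sentence-initial tokens, and splices in entity surface forms as whole
tokens — never at sentence start (capitalization would alter the surface)
and never across a sentence boundary, so comention truth stays exact — with
exact character spans recorded. Per-document substreams are derived from
`(seed, document index)`, so generated prefixes are stable when only
`n_docs` changes.

What it emulates: disjoint topical vocabularies (so between-topic document
similarity on keywords is zero in expectation, the property that makes
clustering-recovery tests meaningful), synonym variation, and
entity-placement randomness. What it does not emulate: syntax, discourse,
ambiguous or nested entity names, abbreviations, topical overlap, or
correlated entity–topic structure. Passing recovery tests therefore shows
the pipeline machinery is correct, not that real corpora are this easy; on
real text the binding constraints are lexicon quality and topic
separability.

The built-in lexicon (12 proteins, 8 diseases, real identifiers) is
synthetic in assembly: surfaces are chosen so that no synonym — and no
token-prefix of a multi-word synonym that could be extended by a vocabulary
token — collides with the generator's vocabularies. This is what makes
exact precision/recall a *theorem* about the generator rather than an
empirical accident.

## Numerical and design choices

* Offsets: 0-based half-open everywhere — unambiguous slicing.
* Vocabulary order, theme tie-breaks, and canonical pair order all use C
  collation (`sort(method = "radix")`), independent of the session locale.
* K-means tolerance `1e-6` on centroid shift; WSS is recomputed from the
  final assignment so the reported value matches the reported labels.
* Null enrichment calibration is checked at sizes (clusters of ~80
  documents, entity presence ~0.3) where the hypergeometric distribution's
  discreteness leaves the attainable p-values dense below 0.05; at much
  smaller counts the test is conservative by construction.
* Validation problem sizes: topic recovery uses 700-document corpora across
  5 seeds with unigram tokenization (the planted keywords are unigrams);
  calibration uses 8 corpora of 560 short documents (2240 tests);
  end-to-end determinism uses 140 documents. These sizes make every
  property measurable while keeping the full suite fast on one CPU.
* Degenerate inputs: text without boundaries is one sentence; an empty
  mention table yields empty (not missing) downstream tables; documents
  with no vocabulary terms are an explicit error naming the documents;
  `k = 0` in the hypergeometric test returns exactly 1.

## Limitations

Rule-based sentencization will split or merge unusually punctuated text
that a learned model would handle. Dictionary tagging cannot resolve
ambiguous surface forms. Comentions are co-occurrence, not relations.
tf-idf + K-means assumes roughly balanced, lexically separable themes;
heavily overlapping topics call for mixed-membership models. The exact
t-SNE is quadratic in the number of documents. Query-set overlap, SJR and
journal metadata are passthrough inputs — the package neither fetches nor
verifies them.
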