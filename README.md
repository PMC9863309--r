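# litminer

Machine reading for focused biomedical literature corpora: sentence-level
entity comention networks, tf-idf + K-means thematic clustering, and
per-cluster overrepresentation statistics — with a synthetic-corpus
generator that plants recoverable ground truth under every stage.

`litminer` is aimed at researchers who need to survey a domain corpus
(hundreds to a few thousand abstracts, e.g. the proteomics-of-nutrition
literature) more systematically than manual reviewing allows, but at desk
scale: no services, no model downloads, fully deterministic given a seed.

## What it computes

Starting from a corpus JSON file (one record per publication: ID, title,
abstract, optional full text, year, journal, SJR, query tags):

1. **Sentencization** — deterministic rules: split after `.` `!` `?` +
   whitespace + uppercase/digit, protecting abbreviations (`e.g.`,
   `et al.`, `Fig.`, single initials) and decimals (`4.9`).
2. **Entity tagging and normalization** — dictionary matching against a
   synonym lexicon (TSV), leftmost-longest on token boundaries,
   case-sensitive for short symbols (`INS`) and case-insensitive otherwise;
   every match is normalized to its preferred label (`preflabel`) and type
   (protein or disease).
3. **Comentions** — every unordered pair of distinct entities in one
   sentence is a comention record (no direction, no semantics). The network
   weighs edges by the number of *distinct documents* supporting the pair
   and drops edges below a support threshold (default 5).
4. **Thematic clustering** — tf-idf with raw counts, smoothed idf
   `idf(t) = ln((1+N)/(1+df(t))) + 1` and L2 row normalization; K-means
   (k-means++, Lloyd, restarts, seeded) with a within-cluster
   sum-of-squares (WSS) curve and an advisory elbow; per-cluster themes =
   top-10 terms by mean tf-idf; an exact t-SNE 2-D embedding; and
   cluster-by-year trend tables.
5. **Enrichment** — upper-tail hypergeometric tests
   `p = Σ_{i≥k} C(K,i) C(N−K,n−i) / C(N,n)` for entities per cluster
   (background = whole corpus) and for entity categories (background =
   mapped lexicon), with Benjamini–Hochberg FDRs reported beside raw
   p-values.

The synthetic generator (`generate_corpus()`) plants disjoint topic
vocabularies and entity mentions with exact character spans, so clustering
recovery, tagger exactness and enrichment calibration are all measurable.

## Worked example

```r
library(litminer)

gen  <- generate_corpus(generator_config(n_docs = 140, seed = 5))
corp <- sentencize(gen$corpus)
corp
#> <corpus> 140 documents, 1548 sentences

m <- tag_entities(corp, synthetic_lexicon())
head(entity_document_counts(m), 4)
#> # A tibble: 4 × 3
#>   preflabel                  type    n_documents
#>   <chr>                      <chr>         <int>
#> 1 LALBA                      protein          11
#> 2 inflammatory bowel disease disease          11
#> 3 CRP                        protein          10
#> 4 APOE                       protein           9

mat <- tfidf(tokenize_corpus(corp, ngram_max = 1, min_df = 2,
                             stopwords = character(0)))
cl <- kmeans_docs(mat, k = 7, seed = 0)
cl
#> <doc_clustering> k = 7, n = 140, WSS = 27.3693 (seed 0, 10 restarts)

wss_curve(mat, 2:10, seed = 0, n_restarts = 5)
#> <wss_curve> K in [2, 10], elbow suggestion: 7

cluster_themes(mat, cl, corp)
#> <cluster_themes> 7 clusters
#>   A (n=31): legume, cultivar, plant, fruit, germination, cereal, harvest, allergen, gluten, crop
#>   B (n=25): triglyceride, steatosis, dietary, plasma, cholesterol, rat, diet, hepatic, rodent, mouse
#>   C (n=9): dairy, bovine, membrane, breastfeeding, colostrum, infant, suckling, lactose, formula, globule
#>   ...
```

The clustering recovers the planted topics exactly here
(`mclust::adjustedRandIndex(cl$labels, gen$truth$topics)` returns `1`), the
elbow sits at the planted K = 7, and each theme is made of that topic's
planted keywords. Enrichment rows look like:

```r
cluster_entity_enrichment(m, cl, type_filter = "protein", alpha = 0.1)
#> # A tibble: 3 × 9
#>   cluster preflabel type        k     n  K_bg  N_bg p_value    fdr
#> 1       1 APOE      protein     4    25     9   140  0.0538 0.269
#> 2       2 TF        protein     2     9     3   140  0.0107 0.0214
#> 3       3 LEP       protein     2    13     6   140  0.0967 0.0967
```

i.e. `k` of the cluster's `n` documents mention the protein, against `K_bg`
of `N_bg` corpus-wide — with 140 small documents and a mention rate of 1,
only chance-level concentrations appear, as they should.

`run_pipeline(pipeline_config(...))` executes all stages end to end and
writes every table (mentions, comention records/edges/GraphML, themes,
assignments, WSS curve, embedding, year trends, enrichment) plus a manifest
with per-stage row counts and file hashes; two runs with the same config
and seed are byte-identical. A thin CLI over the same functions lives at
`inst/scripts/litminer` (subcommands `simulate`, `sentencize`, `tag`,
`comention`, `cluster`, `enrich`, `run`).

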