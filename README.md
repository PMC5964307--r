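# newsdx

Infodemiology asks what health-related content circulates in information
media, because media attention both reflects and shapes public concern,
research priorities and policy. `newsdx` is an R toolkit for mining disease
coverage from large news archives: it cleans newswire text, finds disease
mentions with a synonym dictionary, normalizes them to PheWAS disease
concepts through a terminology mapping chain, and summarizes each concept's
media coverage, sentiment and topical content across study periods.

## What the package computes

Given a corpus of dated news articles and three lookup tables (disease
synonyms → CUIs, CUIs → ICD-9-CM codes, ICD-9-CM codes → PheWAS codes):

1. **Cleaning** — an ordered rule chain removes agency tags (`"(Reuters)"`),
   editorial byline sentences (`"Editing by …"`), boilerplate comments,
   hyperlinks (replaced by the word `link`), runs of repeated special
   characters, and `*`/`>` sentence delimiters, then lowercases. Cleaning is
   total and idempotent.
2. **Terminology** — mentions are matched token-anchored,
   longest-match-first, non-overlapping (so "cancer" is not double-counted
   inside "lung cancer"). Each synonym resolves through every
   CUI → ICD → PheWAS path; a synonym reaching exactly one PheWAS code is
   *definitive*, two or more *ambiguous*. By default only definitive
   mentions attribute articles to concepts.
3. **Coverage** — for concept *c* in period *p*,
   `coverage(c, p) = 100 · |articles mentioning c| / |articles mentioning
   any disease|`. Cumulative shares of concept subsets use set unions, so
   multi-concept articles are counted once. Cross-period means/SDs and a
   four-way trend label (increasing / decreasing / steady / fluctuating)
   summarize temporal behaviour.
4. **Sentiment** — each disease-mentioning sentence gets a lexicon-and-rule
   compound score: summed term valences, adjusted for negation (factor
   −0.74 within three tokens) and boosters (±0.293), normalized as
   `s / sqrt(s² + 15)` into [−1, 1]; concept sentiment is the mean over its
   mention sentences, banded against a neutral interval (default ±0.05).
5. **Topics** — latent Dirichlet allocation fitted by a collapsed Gibbs
   sampler (Rcpp); per-token conditionals
   `P(z=t) ∝ (n_dt+α)(n_wt+β)/(n_t+Vβ)`. Multi-word disease names are
   concatenated (`lung cancer → lung_cancer`) before tokenization, stopword
   removal, lemmatization and optional n-gram phrase merging. With the
   working default K = 1 per concept group, term weights are reported in
   permille (1000 · P(w|t)).

A synthetic-corpus generator (`simulate_corpus()`) produces corpora with
full ground truth — planted mentions with character spans, planted topic
and valence structure, injected Reuters-style noise — so every stage is
testable without licensed news archives or UMLS tables.

## Worked example

```r
library(newsdx)

sim <- simulate_corpus(simulation_config(seed = 7), dir = "run7")
run <- run_pipeline(sim$corpus, sim$lexicon, sim$chain, sim$valence_lexicon,
                    out_dir = "out7", topic_iterations = 50, seed = 7)
print(run)
#> pipeline run over 3000 articles
#>     period n_articles n_disease_articles rate_pct n_concepts
#>  1996/1997       1000                  4      0.4          4
#>       2008       1000                  6      0.6          4
#>       2016       1000                  8      0.8          5
#> reports:
#>   out7/coverage.csv
#>   out7/sentiment.csv
#>   out7/topics.csv
#>   out7/run_summary.json
#>   out7/run_summary.txt

head(run$coverage[run$coverage$n_articles > 0, ], 3)
#>   phewas_code          phewas_name    period n_articles coverage_pct
#> 3       052.1 zika virus infection      2016          1         12.5
#> 4       165.1          lung cancer 1996/1997          1         25.0
#> 5       165.1          lung cancer      2008          3         50.0
```

Each period's `rate_pct` is the percentage of articles mentioning any
disease (the synthetic defaults plant 0.44%, 0.57% and 0.81%);
`coverage_pct` is the share of that period's disease-mentioning articles
attributed to each concept, e.g. 3 of the 6 disease-mentioning 2008
articles (50%) mention lung cancer. `sentiment.csv` holds per-concept mean
compound scores with their band, and `topics.csv` the top topic terms in
permille.

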