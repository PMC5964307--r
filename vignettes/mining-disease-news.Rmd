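---
title: "Mining disease coverage, sentiment and topics from news corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining disease coverage, sentiment and topics from news corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(newsdx)
```

`newsdx` turns a corpus of dated news articles into per-concept,
per-period statistics of media attention to diseases: coverage
percentages, mean sentence sentiment, and topic-term rankings. This
vignette is the package's account of the methods: the model behind each
stage, the parameters that matter, the design choices that were genuinely
open, and what the synthetic-data tests do and do not establish.

## The pipeline and its assumptions

The unit of observation is the news article; the unit of aggregation is
the PheWAS disease concept within a study period. The pipeline runs

cleaning → mention detection → concept normalization → coverage →
sentiment → topics

and every stage is a pure function of its inputs and the seed, so a run is
reproducible byte for byte. Three assumptions frame everything downstream:

* A dictionary of disease synonyms is an adequate mention detector.
  No morphological expansion or word-sense disambiguation is attempted,
  and negated mentions ("no evidence of cancer") count as mentions.
* The synonym → CUI → ICD-9-CM → PheWAS chain is how surface forms become
  analyzable concepts. Synonyms whose chain reaches exactly one PheWAS
  code (one-to-one or multiple-to-one) are *definitive*; the rest are
  *ambiguous* or *unmapped*. The default attribution policy counts only
  definitive mentions toward concepts — ambiguity is treated as an error
  bound, not a signal — while `expand_ambiguous` is available for
  sensitivity analysis. `definitive_fraction()` reports how much of a
  lexicon that policy retains.
* Periods (for yearly news archives, one per archive year) are compared on
  normalized coverage percentages, not raw counts, because archive sizes
  differ by orders of magnitude.

## Cleaning

Newswire noise is removed by an ordered rule chain: agency tags, byline
sentences, boilerplate comment sentences, hyperlinks → `link`, runs of at
least `min_repeat_run` (default 3) identical special characters → a
space, `*`/`>` delimiters → periods, then lowercasing. Lowercasing comes
last deliberately: the byline cue "Editing by" is a capitalization
convention of the source, and the same ordering means capitalization is no
longer available to the sentiment stage (see below). Runs of special
characters become a space rather than nothing so that words they separated
are not glued together. Cleaning is total (never errors on content) and
idempotent, which the tests check on a thousand noisy articles.

Sentence segmentation is rule-based — split on `.?!` with an abbreviation
guard ("dr.", "u.s.", single-letter initials, month abbreviations) and no
splitting between digits — because cleaned lowercase newswire is regular
enough that a deterministic, dependency-free splitter is preferable to a
trained model whose behaviour can drift between versions.

## Mention detection

Matching is exact-string against the lexicon, anchored at token boundaries
(characters outside `[a-z0-9_]`), longest-match-first with ties to the
leftmost start, non-overlapping within a sentence. Longest-first is the
substantive choice: it prevents "cancer" from also being counted inside
"lung cancer". Matching runs on cleaned text; multi-word synonyms match
across single spaces only, which the cleaning stage's whitespace
normalization guarantees.

## Coverage statistics

For concept $c$ in period $p$ with denominator $D_p$ = number of articles
mentioning any disease concept in $p$:

$$\mathrm{coverage}(c,p) = 100 \cdot \frac{|A_{c,p}|}{D_p},$$

where $A_{c,p}$ is the set of articles attributed to $c$. Cumulative
shares of concept subsets use $|\bigcup_c A_{c,p}|$ — a union, because
"share of disease-mentioning articles" counts articles, and an article
mentioning two concepts in the subset must not be counted twice.

Cross-period spread uses the sample SD ($n-1$) by default. With as few as
three periods the convention is material, so the population SD is exposed
as an option rather than silently chosen.

Trend labels are a package-defined heuristic (narrative descriptions of
temporal trends do not define a rule): *increasing*/*decreasing* when every
step moves by more than 5% relative change in the same direction, checked
first; otherwise *steady* when the coefficient of variation is at most
0.25; otherwise *fluctuating*. Both criteria are relative, so the label is
invariant to rescaling — reclassifying coverage in percent or per mille
changes nothing.

## Sentiment

Sentence scores follow the lexicon-and-rule compound construction: each
token found in the valence lexicon contributes its valence $v \in [-4,4]$,
adjusted by two rules — negation within the three preceding tokens flips
and damps it ($v \mapsto -0.74\,v$), and each booster or dampener in that
window moves it toward or away from its sign by 0.293 — and the sum $s$ is
normalized to

$$\mathrm{compound} = \frac{s}{\sqrt{s^2 + \alpha}}, \qquad \alpha = 15,$$

which is odd, strictly increasing, bounded in $(-1,1)$, and 0 for
sentences without lexicon terms. Capitalization and punctuation emphasis
rules are deliberately absent: the pipeline lowercases and strips emphasis
before scoring, so those rules could never fire — implementing them would
suggest a sensitivity the pipeline does not have. Only disease-mentioning
sentences are scored; a concept's sentiment is the mean over sentences
mentioning it (a sentence mentioning $k$ concepts contributes to all $k$),
and concepts with no scored sentence are omitted rather than zero-filled,
because absence of evidence is not neutrality. Mean scores are banded
negative / neutral / positive against a neutral band, default
$[-0.05, 0.05]$ — the conventional threshold for this score family; the
band is configuration, not a constant.

## Topic modeling

The topic stage fits LDA with symmetric Dirichlet priors $\alpha$ (on
document–topic mixtures) and $\beta$ (on topic–word distributions).
Inference is collapsed Gibbs sampling: the Dirichlet parameters are
integrated out and each token's topic is resampled from

$$P(z_i = t \mid z_{-i}, w) \propto
  (n_{dt}^{-i} + \alpha)\,
  \frac{n_{w_i t}^{-i} + \beta}{n_t^{-i} + V\beta}.$$

A deterministic variant (`mode = "icm"`, iterated conditional modes)
assigns each token the argmax of the same conditional — the
hill-climbing reading of "update the assignment that maximizes
P(w|t)·P(t|d)" — and is provided alongside the sampler; the sampler is the
default because it explores the posterior rather than a single mode.
Point estimates are $\hat\phi_{wt} = (n_{wt}+\beta)/(n_t+V\beta)$ and
$\hat\theta_{dt} = (n_{dt}+\alpha)/(n_d+K\alpha)$.

Defaults: $K = 1$, $\alpha = 50/K$, $\beta = 0.01$, 500 sweeps, top 50
terms. $K = 1$ reflects the analysis goal — one aggregate topic per
concept group, whose term ranking (in permille, $1000\,P(w\mid t)$) is the
deliverable — rather than a belief that news text has one topic; perplexity-
based selection of $K$ is out of scope. With $K = 1$ the fit has a closed
form, $(\mathrm{count}(w)+\beta)/(N+V\beta)$, which the tests exploit as an
exact oracle. $\alpha$ and $\beta$ are fixed and documented here because
"library defaults" are version-dependent and not reproducible.

Before fitting, multi-word disease names are concatenated
(`lung cancer → lung_cancer`) so compound concepts can surface as topic
terms; text is tokenized with a shipped stopword list and a
lookup-table-plus-suffix-rules lemmatizer (no model download), and an
optional n-gram pass (n = 1–4) merges adjacent pairs whose collocation
score $(\mathrm{count}(ab) - \mathrm{min\_count}) \cdot N /
(\mathrm{count}(a)\,\mathrm{count}(b))$, with $N$ the current vocabulary
size, clears a threshold — left-to-right, deterministically, one pass per
additional gram. Phrase detection defaults off (`ngram_max = 1`) in the
pipeline because permille rankings of merged tokens are only comparable
across periods when the merge vocabulary is stable; it is a per-analysis
choice.

### Correctness of the sampler

Two oracles gate `fit_lda()`. First, the $K=1$ closed form must hold to
1e-12 regardless of seed or iteration count. Second, on a 2-document,
6-token, $K=2$ toy corpus the sampler's long-run behaviour is compared
with exhaustive enumeration of all $2^6$ assignments weighted by the
collapsed joint. Because the posterior is exchangeable in topic labels,
per-token marginals are 1/2 by symmetry and would not detect a broken
sampler; the comparison therefore uses pairwise co-assignment frequencies
$P(z_i = z_j)$, which are invariant under relabelling and fully
informative. Agreement is within 0.02 over 50,000 sweeps (observed ~0.006).
A planted-topic recovery experiment ($K=3$, $V=300$, $D=400$, 120
tokens/document, $\alpha=0.1$, $\beta=0.01$, 800 sweeps) requires
best-permutation mean cosine ≥ 0.9 between planted and fitted topics
(observed ~0.997).

## The synthetic-data generator

`simulate_corpus()` emulates the statistical structure of yearly newswire
archives: three one-year periods labelled 1996/1997, 2008 and 2016; 1,000
articles per period by default, of which 0.44%, 0.57% and 0.81% mention a
disease — the disease-article rates of the corresponding archives, which
makes those rates recoverable end to end. Background text is drawn from a
planted LDA model ($\theta_d \sim \mathrm{Dirichlet}(0.1)$, $K=3$ topics
over 300 pronounceable pseudo-words); designated disease articles receive
synonym insertions at recorded sentence positions and character spans. The
concept table mixes single- and multi-word synonyms (up to three words) and
includes a multiple-to-one chain collapse, an ambiguous synonym and an
unmapped one, so the terminology stage's whole classification is
exercised.

Sentiment planting inserts exactly one word from a two-word valence pool
($v = \pm 3$, single-word compounds $\pm 0.6124$) into each mention
sentence, choosing the positive word with probability
$p = (\tau - c_B)/(c_A - c_B)$ so the expected sentence compound equals
the concept's target $\tau$ exactly; with 500+ sentences per concept the
estimate's standard error is ~0.03, comfortably inside the 0.1 recovery
tolerance.

Noise injection mirrors the cleaning rules (tags, bylines, comments, URLs,
character runs, delimiters) and is constructed to be *exactly* reversible:
every injection site is chosen so that cleaning restores the recorded
noise-free text byte for byte. URL noise illustrates the discipline: since
cleaning replaces URLs with the word `link`, a URL can only be injected
where the clean text already reads `link`, so the generator plants `link`
tokens for the noise stage to corrupt. Byline and comment sentences are
appended at the article end so planted mention positions never shift.

What passing these tests shows — and does not. The generator's text is not
English; its vocabulary is disjoint by construction from synonyms and
valence terms. Exact matcher recovery on synthetic corpora therefore
validates the matching *algorithm* (anchoring, longest-match, spans), not
robustness to real-world morphology, abbreviations or typos, which
exact-string matching will miss by design. Likewise sentiment recovery
validates aggregation and normalization, not lexicon quality.

## Numerical and reporting conventions

Rates are reported to 2 decimals, coverage/mean/SD to 1, matching the
precision conventional for such tables. Ties in topic-term rankings break
lexicographically so output is deterministic. All randomness flows from a
single integer seed; per-group topic fits derive sub-seeds so groups are
independent but reproducible. Degenerate inputs fail fast with named
errors: zero denominators, empty vocabularies, $K$ exceeding the token
count, undefined definitive fractions (no mapped synonym), invalid
configurations.

## Problem sizes used in the test suite

The shipped suites run the end-to-end pipeline on 3 × 1,000 articles, the
cleaning round trip on 1,000 noisy articles, matcher recovery on 500
articles, sentiment recovery on 3,300 single-period articles (≥ 500
sentences per concept), topic recovery at $D=400$, $V=300$, and 100 random
instances each for the $K=1$ closed form and the definitive-fraction
oracle. These sizes were chosen to make sampling error a small fraction of
each tolerance while keeping the default check quick on one CPU.

## Known limitations

* No deduplication of republished or updated articles; each record counts
  once.
* Exact-string dictionary matching misses morphological variants and
  abbreviations; the definitive-only policy discards ambiguous synonyms
  entirely.
* The sentence splitter's abbreviation list is English-specific.
* The trend taxonomy and the neutral band are reporting conventions, not
  inferential statements; no statistical test is attached to either.
* With $K=1$ the topic model cannot separate themes within a concept
  group; it ranks the group's aggregate vocabulary.
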