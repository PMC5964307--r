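Package: newsdx
Title: Disease Coverage, Sentiment and Topics in News Media Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An infodemiology toolkit for mining disease-related content from
    large news corpora. Cleans newswire text with an ordered, configurable rule
    chain; detects disease mentions with a synonym dictionary and normalizes
    them to PheWAS disease concepts through a CUI to ICD-9-CM to PheWAS mapping
    chain; computes per-concept media coverage statistics and temporal trend
    labels; scores sentence sentiment with a lexicon-and-rule compound model;
    and fits latent Dirichlet allocation topic models by collapsed Gibbs
    sampling. Ships a synthetic-corpus generator with full ground truth so
    every pipeline stage can be validated without licensed news archives or
    terminology releases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
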