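lex <- default_valence_lexicon()

test_that("compound scores follow the summation/normalization formula", {
  expect_equal(score_sentence(c("plain", "words", "only"), lex), 0)
  expect_equal(score_sentence(character(0), lex), 0)
  # single term of valence 1.9 ("good"), alpha_norm = 15
  expect_equal(score_sentence(c("a", "good", "day"), lex),
               1.9 / sqrt(1.9^2 + 15), tolerance = 1e-12)
  # negation within three tokens: factor -0.74
  s <- 1.9 * -0.74
  expect_equal(score_sentence(c("not", "a", "good", "day"), lex),
               s / sqrt(s^2 + 15), tolerance = 1e-12)
  # negation more than three tokens back does not fire
  expect_equal(score_sentence(c("not", "x", "y", "z", "good"), lex),
               1.9 / sqrt(1.9^2 + 15), tolerance = 1e-12)
  # odd symmetry: a mirrored valence (-1.9, "epidemic") mirrors the compound
  expect_equal(score_sentence("epidemic", lex),
               -score_sentence("good", lex), tolerance = 1e-12)
  # booster moves the valence toward its sign by the increment
  sv <- 1.9 + 0.293
  expect_equal(score_sentence(c("very", "good"), lex),
               sv / sqrt(sv^2 + 15), tolerance = 1e-12)
  sd_ <- 1.9 - 0.293
  expect_equal(score_sentence(c("slightly", "good"), lex),
               sd_ / sqrt(sd_^2 + 15), tolerance = 1e-12)
})

test_that("normalization is bounded, odd and strictly increasing in the raw sum", {
  set.seed(408)
  f <- function(s) s / sqrt(s^2 + 15)
  s <- sort(runif(200, -30, 30))
  expect_true(all(abs(f(s)) < 1))
  expect_equal(f(-s), -f(s), tolerance = 1e-12)
  expect_true(all(diff(f(s)) > 0))

  # end-to-end: every sentence score lies in [-1, 1]
  words <- c(names(lex$valence), "filler", "words", "not", "very")
  for (rep in 1:50) {
    toks <- sample(words, sample(1:12, 1), replace = TRUE)
    sc <- score_sentence(toks, lex)
    expect_true(sc >= -1 && sc <= 1)
  }
})

test_that("appending a positive token outside negation scope never lowers the score", {
  set.seed(409)
  words <- c(names(lex$valence), "filler", "stuff")
  for (rep in 1:40) {
    toks <- sample(words, sample(1:8, 1), replace = TRUE)
    base <- score_sentence(toks, lex)
    more <- score_sentence(c(toks, "great"), lex)
    expect_gte(more, base)
  }
})

test_that("identical token streams always score identically", {
  toks <- c("not", "a", "good", "outbreak", "very", "severe", "crisis")
  expect_identical(score_sentence(toks, lex), score_sentence(toks, lex))
})

test_that("per-concept sentiment averages mention sentences within periods", {
  tl <- tiny_lexicon()
  # valence lexicon with one known word so scores are hand-computable
  vpath <- write_tsv_tmp(data.frame(term = c("grim", "fine"),
                                    valence = c(-2, 2)))
  vlex <- load_valence_lexicon(vpath)
  sents <- list(
    a1 = c("asthma news is grim.", "flu is fine."),
    a2 = c("asthma and flu together."))
  m <- find_mentions(sents, tl$lexicon, tl$chain)
  scores <- score_mention_sentences(sents, m, vlex)
  expect_equal(nrow(scores), 3L)
  cs <- concept_sentiment(scores, c(a1 = "2016", a2 = "2016"))
  c2 <- 2 / sqrt(4 + 15)
  # asthma: sentences grim (-c2) and neutral (0) -> mean -c2/2
  expect_equal(cs$mean_compound[cs$phewas_code == "P493"], -c2 / 2,
               tolerance = 1e-12)
  expect_equal(cs$n_sentences[cs$phewas_code == "P493"], 2L)
  # flu: fine (+c2) and neutral -> +c2/2; the shared sentence counts for both
  expect_equal(cs$mean_compound[cs$phewas_code == "P487"], c2 / 2,
               tolerance = 1e-12)
  # concepts with no scored sentences are omitted
  expect_false("P162" %in% cs$phewas_code)
})

test_that("banding splits negative, neutral and positive at the band edges", {
  expect_identical(sentiment_band(-0.59), "negative")
  expect_identical(sentiment_band(0), "neutral")
  expect_identical(sentiment_band(0.73), "positive")
  expect_identical(sentiment_band(c(-0.05, 0.05)), c("neutral", "neutral"))
  expect_identical(sentiment_band(0.2, c(-0.3, 0.3)), "neutral")
  expect_error(sentiment_band(0, c(0.1, 0.2)))
})

test_that("planted per-concept valences are recovered within 0.1 at 500 sentences per concept", {
  con <- default_concept_table()
  con$weights[] <- 1 / length(con$weights)
  sim <- simulate_corpus(simulation_config(
    seed = 410, periods = period_table("2016", "2016-01-01", "2016-12-31"),
    n_articles = 3300L, disease_fraction = 1, concepts = con,
    doc_sentences = 3L, sentence_len = 6L, noise = NULL))
  cl <- clean_corpus(sim$corpus)
  sents <- setNames(lapply(cl$corpus$articles$clean_text, split_sentences),
                    cl$corpus$articles$article_id)
  m <- find_mentions(sents, sim$lexicon, sim$chain)
  scores <- score_mention_sentences(sents, m, sim$valence_lexicon)
  period_of <- setNames(cl$corpus$articles$period,
                        cl$corpus$articles$article_id)
  cs <- concept_sentiment(scores, period_of)
  target <- sim$ground_truth$target_valence
  expect_true(all(cs$n_sentences >= 500L))
  for (ph in names(target)) {
    got <- cs$mean_compound[cs$phewas_code == ph]
    expect_length(got, 1L)
    expect_lt(abs(got - target[[ph]]), 0.1)
  }
})
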