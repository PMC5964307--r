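test_that("multi-word disease names are joined for topic modeling", {
  tl <- tiny_lexicon()
  expect_identical(concat_compound_terms("lung cancer trial", tl$lexicon),
                   "lung_cancer trial")
  expect_identical(concat_compound_terms("asthma trial", tl$lexicon),
                   "asthma trial")
  # longest-first: nested "flu" inside "bird flu" joins as one token
  expect_identical(concat_compound_terms("bird flu spreads", tl$lexicon),
                   "bird_flu spreads")
  expect_identical(concat_compound_terms(c("", "no match here"), tl$lexicon),
                   c("", "no match here"))
})

test_that("topic tokenization removes stopwords, lemmatizes, and passes compounds through", {
  expect_identical(tokenize_for_topics("the studies of drugs"),
                   c("study", "drug"))
  expect_identical(tokenize_for_topics("lung_cancer"), "lung_cancer")
  expect_identical(tokenize_for_topics(""), character(0))
  expect_identical(tokenize_for_topics("children were running"),
                   c("child", "run"))
  expect_identical(tokenize_for_topics("viruses and diseases"),
                   c("virus", "disease"))
})

test_that("phrase detection merges pairs exactly when the collocation score clears threshold", {
  # corpus: "zika virus" occurs 12 times; "zika" and "virus" appear only in
  # the pair; 40 distinct filler tokens pad the vocabulary.
  filler <- sprintf("filler%02d", 1:40)
  docs <- c(replicate(12, c("zika", "virus"), simplify = FALSE),
            lapply(filler, function(w) c(w, "end")))
  # counts: c(ab)=12, c(a)=c(b)=12, N = 43 distinct tokens
  # score = (12 - 5) * 43 / 144 = 2.09 < 10 -> no merge
  out <- detect_phrases(docs, ngram_max = 2, min_count = 5, threshold = 10)
  expect_identical(out, docs)
  # lower threshold: merge happens
  out2 <- detect_phrases(docs, ngram_max = 2, min_count = 5, threshold = 2)
  expect_identical(out2[[1]], "zika_virus")
  # direct count arithmetic for the score bound
  expect_true((12 - 5) * 43 / (12 * 12) < 10)
  expect_true((12 - 5) * 43 / (12 * 12) >= 2)

  # repeated passes build up to 4-grams (the vocabulary, and with it the
  # score, shrinks at each pass: 0.129 in pass 1, 0.064 in pass 2)
  quad <- replicate(30, c("a1", "a2", "a3", "a4"), simplify = FALSE)
  out4 <- detect_phrases(quad, ngram_max = 4, min_count = 1,
                         threshold = 0.05)
  expect_identical(out4[[1]], "a1_a2_a3_a4")
  # ngram_max = 1 disables merging
  expect_identical(detect_phrases(quad, ngram_max = 1), quad)
})

test_that("K=1 LDA is the closed-form smoothed unigram distribution", {
  set.seed(411)
  for (rep in 1:20) {
    V <- sample(3:12, 1)
    D <- sample(1:5, 1)
    words <- sprintf("w%02d", 1:V)
    toks <- lapply(seq_len(D), function(d) {
      sample(words, sample(2:30, 1), replace = TRUE)
    })
    td <- tokenized_docs(toks)
    beta <- runif(1, 0.001, 1)
    fit <- fit_lda(td, K = 1, beta = beta, iterations = sample(1:10, 1),
                   seed = rep)
    counts <- table(factor(unlist(toks), levels = td$vocab))
    N <- sum(counts)
    Veff <- length(td$vocab)
    expect_equal(unname(fit$phi[, 1]),
                 unname((as.numeric(counts) + beta) / (N + Veff * beta)),
                 tolerance = 1e-12)
    expect_equal(unname(fit$theta[, 1]), rep(1, D), tolerance = 1e-12)
  }
})

test_that("fitted state is internally consistent and normalized", {
  set.seed(412)
  words <- sprintf("w%02d", 1:15)
  toks <- lapply(1:6, function(d) sample(words, 25, replace = TRUE))
  td <- tokenized_docs(toks)
  for (mode in c("gibbs", "icm")) {
    fit <- fit_lda(td, K = 3, alpha = 0.5, beta = 0.1, iterations = 30,
                   seed = 42, mode = mode)
    # count tables are exact marginals of z
    z <- fit$z
    n_dt <- t(vapply(z, function(zd) tabulate(zd, 3), numeric(3)))
    expect_equal(unname(fit$n_dt), unname(n_dt))
    n_wt <- matrix(0L, length(td$vocab), 3)
    for (d in seq_along(z)) {
      for (i in seq_along(z[[d]])) {
        w <- td$docs[[d]][i]
        n_wt[w, z[[d]][i]] <- n_wt[w, z[[d]][i]] + 1L
      }
    }
    expect_equal(unname(fit$n_wt), unname(n_wt))
    expect_equal(as.numeric(fit$n_t), colSums(n_wt))
    # normalization
    expect_equal(rowSums(fit$theta), rep(1, 6), tolerance = 1e-9)
    expect_equal(colSums(fit$phi), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("fits are bit-reproducible under a fixed seed", {
  set.seed(413)
  words <- sprintf("w%02d", 1:10)
  toks <- lapply(1:4, function(d) sample(words, 20, replace = TRUE))
  td <- tokenized_docs(toks)
  f1 <- fit_lda(td, K = 2, iterations = 50, seed = 99)
  f2 <- fit_lda(td, K = 2, iterations = 50, seed = 99)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$phi, f2$phi)
})

test_that("degenerate topic-model inputs are rejected", {
  expect_error(fit_lda(tokenized_docs(list(character(0))), K = 1),
               "empty vocabulary")
  td <- tokenized_docs(list(c("a", "b")))
  expect_error(fit_lda(td, K = 5), "exceeds")
  expect_error(fit_lda(td, K = 0), ">= 1")
  expect_error(fit_lda(td, K = 1, alpha = -1), "> 0")
})

test_that("topic summaries rank by permille with lexicographic ties", {
  set.seed(414)
  toks <- list(rep(c("apple", "pear"), 5), rep("plum", 4))
  td <- tokenized_docs(toks)
  fit <- fit_lda(td, K = 1, beta = 0.01, iterations = 1)
  ts <- summarize_topic(fit, 1, top_n = 50)
  # apple and pear tie on count 5; lexicographic order breaks the tie
  expect_identical(ts$term, c("apple", "pear", "plum"))
  expect_true(all(diff(ts$permille) <= 0))
  expect_equal(ts$permille, 1000 * unname(fit$phi[ts$term, 1]))
  # top_n larger than V returns all terms; permille is 1000 * P(w|t)
  expect_equal(nrow(summarize_topic(fit, 1, top_n = 999)), 3L)
  expect_error(summarize_topic(fit, 2), "out of range")

  # uniform distribution: every permille equals 1000/V
  uni <- tokenized_docs(list(sprintf("u%02d", 1:50)))
  ufit <- fit_lda(uni, K = 1, iterations = 1)
  expect_equal(summarize_topic(ufit, 1, top_n = 50)$permille, rep(20, 50))
})

test_that("per-concept topic summaries equal the smoothed empirical frequencies at K=1", {
  tl <- tiny_lexicon()
  set.seed(415)
  # two disjoint concept groups with known unigram content
  vocabA <- c("trial", "dose", "vaccine")
  vocabB <- c("market", "price")
  mkdoc <- function(words, n, dis) {
    paste0(paste(sample(words, n, replace = TRUE), collapse = " "),
           " ", dis, ".")
  }
  articles <- data.frame(
    article_id = c("a1", "a2", "b1", "b2"),
    date = as.Date("2016-02-01") + 0:3,
    period = "2016",
    raw_text = "x",
    clean_text = c(mkdoc(vocabA, 7, "asthma"), mkdoc(vocabA, 8, "asthma"),
                   mkdoc(vocabB, 6, "flu"), mkdoc(vocabB, 9, "flu")),
    stringsAsFactors = FALSE)
  corpus <- news_corpus(articles,
                        period_table("2016", "2016-01-01", "2016-12-31"))
  groups <- list("2016" = list(P493 = c("a1", "a2"), P487 = c("b1", "b2")))
  res <- topics_per_concept(corpus, groups, tl$lexicon, K = 1,
                            beta = 0.01, iterations = 5, seed = 1)
  for (ph in c("P493", "P487")) {
    sub <- res[res$phewas_code == ph, ]
    ids <- groups[["2016"]][[ph]]
    toks <- unlist(lapply(articles$clean_text[articles$article_id %in% ids],
                          tokenize_for_topics))
    counts <- table(toks)
    V <- length(counts)
    want <- 1000 * (as.numeric(counts) + 0.01) / (sum(counts) + V * 0.01)
    names(want) <- names(counts)
    expect_equal(setNames(sub$permille, sub$term),
                 want[order(-want, names(want))], tolerance = 1e-9)
  }
  # summaries are independent of the other group's text
  expect_false(any(c("market", "price") %in%
                     res$term[res$phewas_code == "P493"]))
})

test_that("small planted-topic corpora are recovered by the sampler", {
  phi_true <- planted_topic_model(2, 60, seed = 416)
  gen <- simulate_lda_docs(phi_true, 0.2, 80, 40, seed = 417)
  words <- sprintf("w%03d", 1:60)
  td <- tokenized_docs(lapply(gen$docs, function(d) words[d]))
  fit <- fit_lda(td, K = 2, alpha = 0.2, beta = 0.01, iterations = 300,
                 seed = 418)
  phi_hat <- t(fit$phi[match(words, rownames(fit$phi)), ])
  expect_gte(best_perm_cosine(phi_true, phi_hat), 0.9)
})
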