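test_that("lexicon and chain loaders normalize, validate and report line numbers", {
  f <- tiny_lexicon_files()
  lex <- load_lexicon(f$lexicon)
  expect_s3_class(lex, "concept_lexicon")
  expect_equal(nrow(lex), 6L)

  up <- write_tsv_tmp(data.frame(synonym = c("Lung  Cancer", "ASTHMA"),
                                 cui = c("C1", "C3")))
  lex2 <- load_lexicon(up)
  expect_setequal(lex2$synonym, c("lung cancer", "asthma"))

  empty <- write_tsv_tmp(data.frame(synonym = character(), cui = character()))
  expect_warning(load_lexicon(empty), "empty")

  bad <- tempfile()
  writeLines(c("synonym\tcui", "flu\tC1", "asthma-no-tab"), bad)
  expect_error(load_lexicon(bad), "line 3")

  dup_icd <- write_tsv_tmp(data.frame(
    icd = c("162", "162"), phewas = c("P1", "P2"), phewas_name = c("a", "b")))
  expect_error(load_chain(f$cui_icd, dup_icd), "single-valued")
})

test_that("synonym resolution follows every path and classifies ambiguity", {
  tl <- tiny_lexicon()
  one <- resolve_synonym("lung cancer", tl$lexicon, tl$chain)
  expect_identical(one$phewas_set, "P162")
  expect_identical(one$mapping_class, "definitive")

  # multiple-to-one: two ICD codes collapsing onto one PheWAS code
  m2o <- resolve_synonym("bird flu", tl$lexicon, tl$chain)
  expect_identical(m2o$phewas_set, "P487")
  expect_identical(m2o$mapping_class, "definitive")

  amb <- resolve_synonym("cancer", tl$lexicon, tl$chain)
  expect_identical(amb$phewas_set, c("P199", "P239"))
  expect_identical(amb$mapping_class, "ambiguous")

  expect_identical(resolve_synonym("mystery illness", tl$lexicon,
                                   tl$chain)$mapping_class, "unmapped")
  expect_identical(resolve_synonym("never seen", tl$lexicon,
                                   tl$chain)$mapping_class, "unmapped")
})

test_that("definitive fraction matches hand counts and errors when undefined", {
  tl <- tiny_lexicon()
  # mapped synonyms: lung cancer, cancer(amb), asthma, flu, bird flu -> 4/5
  expect_equal(definitive_fraction(tl$lexicon, tl$chain), 0.8)

  all_def <- write_tsv_tmp(data.frame(synonym = c("flu", "asthma"),
                                      cui = c("C4", "C3")))
  f <- tiny_lexicon_files()
  lex <- load_lexicon(all_def)
  expect_equal(definitive_fraction(lex, tl$chain), 1.0)

  none <- load_lexicon(write_tsv_tmp(
    data.frame(synonym = "mystery illness", cui = "C9")))
  expect_error(definitive_fraction(none, tl$chain), "undefined")
})

test_that("definitive fraction equals the path-enumeration oracle on random chains", {
  set.seed(404)
  for (rep in 1:100) {
    tabs <- random_chain_tables()
    truth <- oracle_definitive_fraction(tabs$lexicon, tabs$cui_icd,
                                        tabs$icd_phewas)
    lex <- load_lexicon(write_tsv_tmp(tabs$lexicon))
    chain <- load_chain(write_tsv_tmp(tabs$cui_icd),
                        write_tsv_tmp(tabs$icd_phewas))
    if (is.na(truth)) {
      expect_error(definitive_fraction(lex, chain), "undefined")
    } else {
      expect_equal(definitive_fraction(lex, chain), truth)
    }
  }
})

test_that("mention matching is longest-first, token-anchored and non-overlapping", {
  tl <- tiny_lexicon()
  sents <- list(a1 = "patients with lung cancer and asthma improved.")
  m <- find_mentions(sents, tl$lexicon, tl$chain)
  expect_identical(m$synonym, c("lung cancer", "asthma"))
  # nested "cancer" suppressed by the longest match
  expect_false("cancer" %in% m$synonym)
  # spans reproduce the matched text (half-open offsets)
  for (i in seq_len(nrow(m))) {
    expect_identical(substr(sents$a1, m$start[i], m$end[i] - 1L),
                     m$synonym[i])
  }

  # token anchoring: no match inside a larger word
  m2 <- find_mentions(list(a = "influenza-like cancerous growth."),
                      tl$lexicon, tl$chain)
  expect_equal(nrow(m2), 0L)

  expect_equal(nrow(find_mentions(list(a = "nothing here."),
                                  tl$lexicon, tl$chain)), 0L)
})

test_that("mentions never overlap within a sentence", {
  tl <- tiny_lexicon()
  sents <- list(a = "bird flu and flu and bird flu again flu.",
                b = "cancer lung cancer cancer.")
  m <- find_mentions(sents, tl$lexicon, tl$chain)
  for (key in unique(paste(m$article_id, m$sentence_index))) {
    sub <- m[paste(m$article_id, m$sentence_index) == key, ]
    covered <- integer(0)
    for (i in seq_len(nrow(sub))) {
      span <- sub$start[i]:(sub$end[i] - 1L)
      expect_length(intersect(covered, span), 0L)
      covered <- c(covered, span)
    }
  }
})

test_that("matcher exactly recovers planted mentions on a noise-free corpus", {
  sim <- simulate_corpus(simulation_config(
    seed = 405, periods = period_table("2016", "2016-01-01", "2016-12-31"),
    n_articles = 400L, disease_fraction = 0.05, noise = NULL))
  cl <- clean_corpus(sim$corpus)
  sents <- setNames(lapply(cl$corpus$articles$clean_text, split_sentences),
                    cl$corpus$articles$article_id)
  m <- find_mentions(sents, sim$lexicon, sim$chain)
  gt <- sim$ground_truth$mentions
  expect_gt(nrow(gt), 5L)
  got <- m[order(m$article_id, m$sentence_index, m$start),
           c("article_id", "sentence_index", "start", "end", "synonym")]
  want <- gt[order(gt$article_id, gt$sentence_index, gt$start),
             c("article_id", "sentence_index", "start", "end", "synonym")]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
  # and every recovered mention resolves to the planted concept
  expect_identical(unlist(m[order(m$article_id), "phewas_set"],
                          use.names = FALSE),
                   gt$phewas[order(gt$article_id)])
})

test_that("article attribution honors the ambiguity policy", {
  tl <- tiny_lexicon()
  sents <- list(a1 = "lung cancer confirmed.", a2 = "cancer suspected.")
  m <- find_mentions(sents, tl$lexicon, tl$chain)

  strict <- articles_by_concept(m, "definitive_only")
  expect_identical(strict$concepts, list(P162 = "a1"))
  expect_setequal(strict$all_articles, c("a1", "a2"))

  wide <- articles_by_concept(m, "expand_ambiguous")
  expect_setequal(wide$concepts$P199, "a2")
  expect_setequal(wide$concepts$P239, "a2")
  expect_setequal(wide$concepts$P162, "a1")

  expect_error(articles_by_concept(m, "whatever"))

  # every concept's article set is within the all-mentioning set
  for (ph in names(wide$concepts)) {
    expect_true(all(wide$concepts[[ph]] %in% wide$all_articles))
  }
})
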