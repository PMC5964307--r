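test_that("generation is deterministic and matches its own ground truth", {
  cfg <- simulation_config(
    seed = 420, periods = period_table("2016", "2016-01-01", "2016-12-31"),
    n_articles = 100L, disease_fraction = 0.2, noise = NULL)
  sim1 <- simulate_corpus(cfg)
  sim2 <- simulate_corpus(cfg)
  expect_identical(sim1$corpus$articles, sim2$corpus$articles)
  expect_identical(sim1$ground_truth$mentions, sim2$ground_truth$mentions)

  gt <- sim1$ground_truth
  expect_equal(unname(gt$totals), 100)
  expect_equal(unname(gt$denominators), 20)
  expect_equal(sum(gt$concept_counts$n_articles), 20)
  # with one mention per article, counts are the mention tally
  expect_equal(length(unique(gt$mentions$article_id)), 20L)
})

test_that("run directories are written with all artifacts, byte-stable under the seed", {
  cfg <- simulation_config(
    seed = 421, periods = period_table("2016", "2016-01-01", "2016-12-31"),
    n_articles = 30L, disease_fraction = 0.2)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_corpus(cfg, dir = d1)
  s2 <- simulate_corpus(cfg, dir = d2)
  for (f in c("corpus.jsonl", "lexicon.tsv", "cui_icd.tsv", "icd_phewas.tsv",
              "valence.tsv", "ground_truth.json", "config.json")) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
  # written tables load back through the standard loaders
  lex <- load_lexicon(file.path(d1, "lexicon.tsv"))
  expect_gt(nrow(lex), 10)
  chain <- load_chain(file.path(d1, "cui_icd.tsv"),
                      file.path(d1, "icd_phewas.tsv"))
  expect_s3_class(chain, "mapping_chain")
  expect_s3_class(load_valence_lexicon(file.path(d1, "valence.tsv")),
                  "valence_lexicon")
})

test_that("noise injection is logged and exactly reversed by cleaning", {
  set.seed(422)
  cfg <- cleaning_config()
  base <- paste("the virus spread quickly. officials met to discuss link",
                "options. cases fell later in the year.")
  heavy <- noise_config(tag_rate = 1, byline_rate = 1, comment_rate = 1,
                        link_rate = 1, repeat_rate = 1, delimiter_rate = 1)
  for (rep in 1:25) {
    nz <- make_noise(base, heavy)
    expect_gt(nrow(nz$log), 3)
    expect_identical(clean_text(nz$text, cfg)$text, clean_text(base, cfg)$text)
  }
  # link injection replaces the planted "link" token with a URL...
  nz <- make_noise(base, noise_config(link_rate = 1, tag_rate = 0,
                                      byline_rate = 0, comment_rate = 0,
                                      repeat_rate = 0, delimiter_rate = 0))
  expect_match(nz$text, "http://")
  # ...and cleaning restores "link" at that position
  expect_identical(clean_text(nz$text, cfg)$text, base)

  # zero rates: identity
  off <- noise_config(0, 0, 0, 0, 0, 0)
  expect_identical(make_noise(base, off)$text, base)
})

test_that("clean recovery holds across random articles under every noise pattern", {
  cfg <- cleaning_config()
  sim <- simulate_corpus(simulation_config(
    seed = 423, periods = period_table("2016", "2016-01-01", "2016-12-31"),
    n_articles = 200L, disease_fraction = 0.1,
    noise = noise_config(tag_rate = 0.7, byline_rate = 0.7,
                         comment_rate = 0.5, link_rate = 0.9,
                         repeat_rate = 0.7, delimiter_rate = 0.7),
    link_plant_rate = 0.8))
  # cleaning the noisy raw text restores the recorded noise-free text
  ids <- sim$corpus$articles$article_id
  for (i in seq_along(ids)) {
    expect_identical(
      clean_text(sim$corpus$articles$raw_text[i], cfg)$text,
      unname(sim$ground_truth$clean_text[[ids[i]]]))
  }
  # and with noise off, raw text already is the clean text
  off <- simulate_corpus(simulation_config(
    seed = 425, periods = period_table("2016", "2016-01-01", "2016-12-31"),
    n_articles = 50L, disease_fraction = 0.1, noise = NULL))
  expect_identical(off$corpus$articles$raw_text,
                   unname(off$ground_truth$clean_text))
})

test_that("emitted background tokens follow the planted topic mixture", {
  cfg <- simulation_config(
    seed = 424, periods = period_table("2016", "2016-01-01", "2016-12-31"),
    n_articles = 400L, disease_fraction = 0, noise = NULL,
    link_plant_rate = 0)
  sim <- simulate_corpus(cfg)
  gt <- sim$ground_truth
  toks <- unlist(strsplit(gsub("\\.", "", sim$corpus$articles$raw_text), " "))
  counts <- table(factor(toks, levels = gt$vocab))
  N <- sum(counts)
  # marginal word law under the realized document mixtures; the multinomial
  # SE is conservative for the doc-clustered counts (Jensen on p(1-p))
  p <- as.numeric(colMeans(gt$theta_true) %*% gt$phi_true)
  se <- sqrt(p * (1 - p) / N)
  dev <- abs(as.numeric(counts) / N - p)
  expect_lt(mean(dev > 3 * se + 1e-12), 0.02)
})

test_that("infeasible simulation configs fail validation", {
  expect_error(simulation_config(disease_fraction = 1.5), "\\[0, 1\\]")
  bad <- default_concept_table()
  bad$weights[1] <- bad$weights[1] + 0.5
  expect_error(simulation_config(concepts = bad), "sum to 1")
  bad2 <- default_concept_table()
  bad2$target_valence[1] <- 0.9
  expect_error(simulation_config(concepts = bad2), "attainable")
  expect_error(noise_config(tag_rate = 2), "\\[0, 1\\]")
})
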