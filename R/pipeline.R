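#' Run the full analysis pipeline
#'
#' Orchestrates clean -> match -> coverage -> sentiment -> topics over a
#' corpus and writes the three report files (`coverage.csv`, `sentiment.csv`,
#' `topics.csv`) plus a run summary (`run_summary.json`, `run_summary.txt`)
#' to `out_dir`. Inputs may be given as objects or as file paths
#' (JSON Lines corpus, TSV lexicons); all referenced paths are checked before
#' any stage runs. Every stage is a pure function of its inputs and the seed,
#' so re-running with identical inputs reproduces the reports byte for byte.
#'
#' @param corpus A `news_corpus` or path to a JSON Lines corpus file.
#' @param lexicon A `concept_lexicon` or path to the synonym TSV.
#' @param chain A `mapping_chain` or length-2 character vector
#'   `c(cui_icd, icd_phewas)` of TSV paths.
#' @param valence_lexicon A `valence_lexicon` or path to the valence TSV.
#' @param out_dir Output directory (created if needed); `NULL` skips all file
#'   output.
#' @param cleaning A [cleaning_config()].
#' @param policy Concept attribution policy (see [articles_by_concept()]).
#' @param neutral_band Neutral band for [sentiment_band()].
#' @param topic_k,topic_alpha,topic_beta,topic_iterations,topic_mode,top_n
#'   Topic model settings (see [fit_lda()] and [topics_per_concept()]).
#' @param min_docs Minimum articles for a concept/period topic group.
#' @param seed Integer seed driving the topic sampler.
#' @param report_digits Decimals for percentages in written reports
#'   (rates use 2; coverage and sentiment summaries use `report_digits`).
#' @return Object of class `pipeline_run`: list with `summary` (per-period
#'   table), `coverage`, `sentiment`, `topics` (data frames), `counters`
#'   (per-stage counts), `manifest` (files written) and `mentions`.
#' @export
run_pipeline <- function(corpus, lexicon, chain, valence_lexicon = NULL,
                         out_dir = NULL,
                         cleaning = cleaning_config(),
                         policy = c("definitive_only", "expand_ambiguous"),
                         neutral_band = c(-0.05, 0.05),
                         topic_k = 1L, topic_alpha = 50 / topic_k,
                         topic_beta = 0.01, topic_iterations = 200L,
                         topic_mode = "gibbs", top_n = 50L, min_docs = 2L,
                         seed = 1L, report_digits = 1L) {
  policy <- match.arg(policy)

  # resolve inputs; fail on missing paths before any stage runs
  if (is.character(corpus)) {
    if (!file.exists(corpus)) stop("corpus path not found: ", corpus,
                                   call. = FALSE)
  }
  if (is.character(lexicon) && !file.exists(lexicon)) {
    stop("lexicon path not found: ", lexicon, call. = FALSE)
  }
  if (is.character(chain)) {
    missing_p <- chain[!file.exists(chain)]
    if (length(missing_p)) stop("mapping table not found: ", missing_p[[1L]],
                                call. = FALSE)
  }
  if (is.character(valence_lexicon) && !file.exists(valence_lexicon)) {
    stop("valence lexicon path not found: ", valence_lexicon, call. = FALSE)
  }
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  if (is.character(lexicon)) lexicon <- load_lexicon(lexicon)
  if (is.character(chain)) chain <- load_chain(chain[[1L]], chain[[2L]])
  if (is.null(valence_lexicon)) {
    valence_lexicon <- default_valence_lexicon()
  } else if (is.character(valence_lexicon)) {
    valence_lexicon <- load_valence_lexicon(valence_lexicon)
  }
  stopifnot(inherits(corpus, "news_corpus"),
            inherits(lexicon, "concept_lexicon"),
            inherits(chain, "mapping_chain"),
            inherits(valence_lexicon, "valence_lexicon"))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # clean
  cleaned <- run_stage("clean", clean_corpus(corpus, cleaning))
  corpus <- cleaned$corpus
  a <- corpus$articles
  period_of <- setNames(a$period, a$article_id)

  # sentence split + match
  sentences <- run_stage("match", {
    s <- lapply(a$clean_text, split_sentences)
    names(s) <- a$article_id
    s
  })
  mentions <- run_stage("match", find_mentions(sentences, lexicon, chain))

  # coverage
  cov <- run_stage("coverage", {
    per_period <- split(seq_len(nrow(mentions)), period_of[mentions$article_id])
    concept_articles <- list()
    denominators <- integer(0)
    for (pd in corpus$periods$label) {
      idx <- per_period[[pd]]
      sub <- mentions[idx %||% integer(0), , drop = FALSE]
      ab <- articles_by_concept(sub, policy)
      concept_articles[[pd]] <- ab$concepts
      denominators[[pd]] <- length(ab$all_articles)
    }
    nonzero <- denominators > 0L
    cov_df <- if (any(nonzero)) {
      concept_coverage(concept_articles[nonzero], denominators[nonzero])
    } else {
      data.frame(phewas_code = character(), period = character(),
                 n_articles = integer(), coverage_pct = numeric(),
                 stringsAsFactors = FALSE)
    }
    list(df = cov_df, concept_articles = concept_articles,
         denominators = denominators)
  })
  name_of <- setNames(chain$icd_to_phewas$phewas_name,
                      chain$icd_to_phewas$phewas)
  cov_df <- cov$df
  cov_df$phewas_name <- unname(name_of[cov_df$phewas_code])
  cov_df <- cov_df[, c("phewas_code", "phewas_name", "period", "n_articles",
                       "coverage_pct")]

  # sentiment
  senti <- run_stage("sentiment", {
    scores <- score_mention_sentences(sentences, mentions, valence_lexicon,
                                      policy)
    cs <- concept_sentiment(scores, period_of)
    cs$band <- if (nrow(cs)) sentiment_band(cs$mean_compound, neutral_band)
               else character(0)
    cs
  })

  # topics
  topics <- run_stage("topics", {
    suppressMessages(topics_per_concept(
      corpus, cov$concept_articles, lexicon, K = topic_k,
      alpha = topic_alpha, beta = topic_beta, iterations = topic_iterations,
      mode = topic_mode, top_n = top_n, min_docs = min_docs, seed = seed))
  })

  summary_df <- summarize_run(corpus, mentions, policy)
  counters <- c(cleaned$report,
                n_articles = nrow(a),
                n_mentions = nrow(mentions),
                n_concepts = length(unique(cov_df$phewas_code)),
                n_scored_sentences = sum(senti$n_sentences))

  manifest <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cov_out <- cov_df
    cov_out$coverage_pct <- round(cov_out$coverage_pct, report_digits)
    senti_out <- senti
    if (nrow(senti_out)) {
      senti_out$mean_compound <- round(senti_out$mean_compound, 2L)
    }
    topics_out <- topics
    if (nrow(topics_out)) topics_out$permille <- round(topics_out$permille, 1L)
    files <- c(coverage = "coverage.csv", sentiment = "sentiment.csv",
               topics = "topics.csv", summary_json = "run_summary.json",
               summary_txt = "run_summary.txt")
    paths <- file.path(out_dir, files)
    names(paths) <- names(files)
    write.csv(cov_out, paths[["coverage"]], row.names = FALSE)
    write.csv(senti_out, paths[["sentiment"]], row.names = FALSE)
    write.csv(topics_out, paths[["topics"]], row.names = FALSE)
    jsonlite::write_json(list(summary = summary_df,
                              counters = as.list(counters)),
                         paths[["summary_json"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    txt <- c("pipeline run summary",
             sprintf("%s: %d articles, %d disease-mentioning, rate %.2f%%, %d concepts",
                     summary_df$period, summary_df$n_articles,
                     summary_df$n_disease_articles, summary_df$rate_pct,
                     summary_df$n_concepts),
             sprintf("%s=%s", names(counters), counters))
    writeLines(txt, paths[["summary_txt"]])
    manifest <- unname(paths)
  }

  structure(list(summary = summary_df, coverage = cov_df, sentiment = senti,
                 topics = topics, counters = counters, manifest = manifest,
                 mentions = mentions,
                 concept_articles = cov$concept_articles,
                 denominators = cov$denominators,
                 corpus = corpus),
            class = "pipeline_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run over", sum(x$summary$n_articles), "articles\n")
  print(x$summary, row.names = FALSE)
  if (length(x$manifest)) {
    cat("reports:\n")
    for (p in x$manifest) cat(" ", p, "\n")
  }
  invisible(x)
}

#' Per-period run summary
#'
#' One row per period: total articles, articles mentioning any disease, the
#' disease-article rate (percent, 2 decimals), and the number of distinct
#' PheWAS concepts attributed under the policy.
#'
#' @param corpus A `news_corpus`.
#' @param mentions Data frame from [find_mentions()].
#' @param policy Attribution policy.
#' @return Data frame with columns `period`, `n_articles`,
#'   `n_disease_articles`, `rate_pct`, `n_concepts`.
#' @export
summarize_run <- function(corpus, mentions,
                          policy = c("definitive_only", "expand_ambiguous")) {
  policy <- match.arg(policy)
  a <- corpus$articles
  period_of <- setNames(a$period, a$article_id)
  out <- data.frame(period = corpus$periods$label,
                    n_articles = 0L, n_disease_articles = 0L,
                    rate_pct = 0, n_concepts = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    pd <- out$period[i]
    out$n_articles[i] <- sum(a$period == pd)
    sub <- mentions[period_of[mentions$article_id] == pd, , drop = FALSE]
    ab <- articles_by_concept(sub, policy)
    out$n_disease_articles[i] <- length(ab$all_articles)
    out$rate_pct[i] <- if (out$n_articles[i] > 0L) {
      disease_article_rate(out$n_disease_articles[i], out$n_articles[i])
    } else NA_real_
    out$n_concepts[i] <- length(ab$concepts)
  }
  out
}
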