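#' Default synthetic concept table
#'
#' The disease concepts, synonyms, mapping-chain rows, per-period planting
#' weights and target sentence valences used by the synthetic corpus
#' generator. The table exercises the structures the terminology stage must
#' handle: multi-word synonyms (2 and 3 words), several synonyms per concept,
#' a multiple-to-one CUI/ICD collapse ("avian influenza" reaches the
#' influenza PheWAS code through a second ICD code), an ambiguous synonym
#' ("cancer" reaches two PheWAS codes; planting weight zero) and an unmapped
#' synonym ("malaise", no ICD row).
#'
#' @return A list with `lexicon`, `cui_icd`, `icd_phewas` data frames,
#'   `weights` (period-constant named planting weights over definitively
#'   mapped concepts) and `target_valence` (named numeric, the planted mean
#'   sentence compound per concept).
#' @export
default_concept_table <- function() {
  lexicon <- data.frame(
    synonym = c("influenza", "flu", "avian influenza",
                "lung cancer", "pulmonary carcinoma",
                "diabetes", "diabetes mellitus",
                "asthma",
                "depression", "major depressive disorder",
                "zika", "zika virus", "zika virus infection",
                "cancer", "cancer",
                "malaise"),
    cui = c("C0021400", "C0021400", "C0016627",
            "C0024121", "C0024121",
            "C0011849", "C0011849",
            "C0004096",
            "C0011570", "C0011570",
            "C0276289", "C0276289", "C0276289",
            "C0006826", "C1306459",
            "C0231218"),
    stringsAsFactors = FALSE)
  cui_icd <- data.frame(
    cui = c("C0021400", "C0016627", "C0024121", "C0011849", "C0004096",
            "C0011570", "C0276289", "C0006826", "C1306459"),
    icd = c("487.0", "487.1", "162.9", "250.0", "493.9",
            "296.2", "066.3", "199.1", "239.9"),
    stringsAsFactors = FALSE)
  icd_phewas <- data.frame(
    icd = c("487.0", "487.1", "162.9", "250.0", "493.9", "296.2", "066.3",
            "199.1", "239.9"),
    phewas = c("481", "481", "165.1", "250.2", "495", "296.2", "052.1",
               "199", "199.4"),
    phewas_name = c("influenza", "influenza", "lung cancer",
                    "diabetes mellitus", "asthma", "depression",
                    "zika virus infection", "other malignant neoplasm",
                    "neoplasm of uncertain behavior"),
    stringsAsFactors = FALSE)
  weights <- c("481" = 0.25, "165.1" = 0.20, "250.2" = 0.15, "495" = 0.10,
               "296.2" = 0.15, "052.1" = 0.15)
  target_valence <- c("481" = -0.40, "165.1" = -0.55, "250.2" = -0.10,
                      "495" = 0.00, "296.2" = -0.50, "052.1" = -0.45)
  list(lexicon = lexicon, cui_icd = cui_icd, icd_phewas = icd_phewas,
       weights = weights, target_valence = target_valence)
}

# Deterministic pronounceable pseudo-words, disjoint from `reserved`.
pseudo_words <- function(n, reserved = character()) {
  cand <- .newsdx_env$pseudo_candidates
  if (is.null(cand)) {
    cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
              "v", "z", "br", "dr", "gl", "kr", "pl", "tr")
    vow <- c("a", "e", "i", "o", "u")
    syl <- as.vector(outer(cons, vow, paste0))
    ns <- length(syl)
    # stride through the ns^2 syllable pairs with a step coprime to ns^2 so
    # the sequence is deterministic but not alphabetically clumped
    total <- ns * ns
    idx <- ((seq_len(total) - 1L) * 37L) %% total
    cand <- paste0(syl[(idx %/% ns) + 1L], syl[(idx %% ns) + 1L])
    cand <- c(cand, paste0(cand, vow[(idx %% 5L) + 1L]))
    cand <- cand[nchar(cand) >= 4L & !duplicated(cand)]
    .newsdx_env$pseudo_candidates <- cand
  }
  cand <- cand[!(cand %in% reserved)]
  if (length(cand) < n) stop("pseudo-word space exhausted", call. = FALSE)
  cand[seq_len(n)]
}

#' Planted topic-word distributions
#'
#' Builds `K` well-separated topic-word distributions over a vocabulary of
#' size `V`: each topic concentrates 95% of its mass on its own block of
#' roughly `V / K` words (with random within-block proportions) and spreads
#' the remaining 5% uniformly, so distinct topics have low cosine similarity
#' while every word keeps nonzero probability.
#'
#' @param K Number of topics.
#' @param V Vocabulary size.
#' @param seed Optional integer seed.
#' @return A `K x V` matrix; rows sum to 1.
#' @export
planted_topic_model <- function(K, V, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(K >= 1L, V >= K)
  phi <- matrix(0.05 / V, nrow = K, ncol = V)
  bounds <- floor(seq(0, V, length.out = K + 1L))
  for (t in seq_len(K)) {
    block <- (bounds[t] + 1L):bounds[t + 1L]
    w <- runif(length(block), 0.5, 1.5)
    phi[t, block] <- phi[t, block] + 0.95 * w / sum(w)
  }
  phi / rowSums(phi)
}

#' Sample documents from a planted LDA model
#'
#' Generates token-index documents from the LDA generative process: for each
#' document a topic mixture `theta_d ~ Dirichlet(alpha)` is drawn, then each
#' token draws a topic from `theta_d` and a word from that topic's row of
#' `phi`.
#'
#' @param phi `K x V` topic-word matrix (rows sum to 1).
#' @param alpha Symmetric Dirichlet concentration for the document mixtures.
#' @param D Number of documents.
#' @param doc_len Tokens per document (scalar or length-`D`).
#' @param seed Optional integer seed.
#' @return A list with `docs` (list of 1-based word-index vectors) and
#'   `theta` (`D x K` matrix of the drawn mixtures).
#' @export
simulate_lda_docs <- function(phi, alpha, D, doc_len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(phi); V <- ncol(phi)
  doc_len <- rep_len(doc_len, D)
  theta <- matrix(rgamma(D * K, shape = alpha), nrow = D)
  theta <- theta / rowSums(theta)
  docs <- vector("list", D)
  for (d in seq_len(D)) {
    zt <- sample.int(K, doc_len[d], replace = TRUE, prob = theta[d, ])
    widx <- integer(doc_len[d])
    for (t in unique(zt)) {
      sel <- zt == t
      widx[sel] <- sample.int(V, sum(sel), replace = TRUE, prob = phi[t, ])
    }
    docs[[d]] <- widx
  }
  list(docs = docs, theta = theta)
}

#' Noise configuration for the synthetic generator
#'
#' Per-article injection probabilities for each Reuters-style noise pattern.
#' All-zero rates make [make_noise()] the identity.
#'
#' @param tag_rate Agency tag appended to a random sentence.
#' @param byline_rate Editorial byline sentence appended.
#' @param comment_rate Boilerplate comment sentence appended.
#' @param link_rate A planted literal `"link"` token replaced by a URL.
#' @param repeat_rate A run of repeated special characters inserted between
#'   sentences.
#' @param delimiter_rate A sentence terminator replaced by `*` or `>`.
#' @return A named list of rates, class `noise_config`.
#' @export
noise_config <- function(tag_rate = 0.3, byline_rate = 0.2,
                         comment_rate = 0.1, link_rate = 0.5,
                         repeat_rate = 0.1, delimiter_rate = 0.1) {
  rates <- c(tag_rate = tag_rate, byline_rate = byline_rate,
             comment_rate = comment_rate, link_rate = link_rate,
             repeat_rate = repeat_rate, delimiter_rate = delimiter_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("noise rates must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(rates), class = "noise_config")
}

#' Inject Reuters-style noise into a clean article text
#'
#' Adds the noise patterns the cleaning stage is built to remove: agency
#' tags, editorial byline sentences, boilerplate comments, URLs, runs of
#' repeated special characters, and `*`/`>` sentence delimiters. Every
#' injection is recorded, and each is constructed to be exactly reversible by
#' [clean_text()]: `clean_text(make_noise(x))$text == clean_text(x)$text`.
#' URL injection therefore replaces an existing literal token `"link"` (the
#' cleaning stage's URL placeholder) rather than adding new content; texts
#' without such a token receive no URL noise.
#'
#' @param text A clean (lowercase, period-terminated) article text.
#' @param config A [noise_config()].
#' @return A list with `text` (the noisy article) and `log` (data frame of
#'   injections: `type`, `detail`).
#' @export
make_noise <- function(text, config = noise_config()) {
  stopifnot(is.character(text), length(text) == 1L,
            inherits(config, "noise_config"))
  log <- list()
  note <- function(type, detail) log[[length(log) + 1L]] <<- c(type, detail)
  sents <- split_raw_sentences(text)
  n <- length(sents)

  if (n >= 2L && runif(1) < config$delimiter_rate) {
    i <- sample.int(n - 1L, 1L)
    ch <- sample(c("*", ">"), 1L)
    if (endsWith(sents[i], ".")) {
      sents[i] <- paste0(substr(sents[i], 1L, nchar(sents[i]) - 1L), ch)
      note("delimiter", ch)
    }
  }
  if (n >= 1L && runif(1) < config$tag_rate) {
    i <- sample.int(n, 1L)
    tag <- sample(c("(Reuters)", "(Reuters Life)"), 1L)
    sents[i] <- paste(sents[i], tag)
    note("tag", tag)
  }
  body <- paste(sents, collapse = " ")
  if (n >= 2L && runif(1) < config$repeat_rate) {
    run <- paste(rep(sample(c("-", "="), 1L),
                     sample(5:15, 1L)), collapse = "")
    pos <- regexpr(". ", body, fixed = TRUE)
    if (pos > 0L) {
      body <- paste0(substr(body, 1L, pos), " ", run,
                     substr(body, pos + 1L, nchar(body)))
      note("repeat_run", run)
    }
  }
  if (runif(1) < config$link_rate) {
    m <- regexpr("(?<![a-z0-9_])link(?![a-z0-9_])", body, perl = TRUE)
    if (m > 0L) {
      url <- paste0("http://", paste(pseudo_words(2L), collapse = "."),
                    ".com/", pseudo_words(1L))
      body <- paste0(substr(body, 1L, m - 1L), url,
                     substr(body, m + 4L, nchar(body)))
      note("link", url)
    }
  }
  if (runif(1) < config$byline_rate) {
    name <- paste(tools_toupper_first(pseudo_words(2L)),
                  collapse = " ")
    body <- paste0(body, " Editing by ", name, ".")
    note("byline", name)
  }
  if (runif(1) < config$comment_rate) {
    body <- paste0(body, " Click on the codes in brackets to see stories.")
    note("comment", "boilerplate")
  }
  log_df <- if (length(log)) {
    data.frame(type = vapply(log, `[`, character(1L), 1L),
               detail = vapply(log, `[`, character(1L), 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(type = character(), detail = character(),
               stringsAsFactors = FALSE)
  }
  list(text = body, log = log_df)
}

tools_toupper_first <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

#' Simulation configuration
#'
#' Study conditions for the synthetic news corpus. The defaults emulate the
#' structure of the yearly Reuters archives the pipeline targets: three
#' one-year periods (1996/1997, 2008, 2016), with per-period
#' disease-mentioning article fractions of 0.44%, 0.57% and 0.81% -- the
#' rates reported for those archives -- over a 300-word background
#' vocabulary, with multi-word disease synonyms and configurable noise.
#'
#' @param seed Integer seed fixing the full output.
#' @param periods A [period_table()].
#' @param n_articles Articles per period (recycled).
#' @param disease_fraction Fraction of each period's articles that mention a
#'   disease (recycled).
#' @param concepts Concept table as from [default_concept_table()].
#' @param K_true,n_vocab,alpha_true Planted topic model: number of background
#'   topics, vocabulary size, document-mixture Dirichlet concentration.
#' @param doc_sentences,sentence_len Sentences per article and background
#'   tokens per sentence.
#' @param noise A [noise_config()]; `NULL` disables noise.
#' @param link_plant_rate Fraction of articles given a literal `"link"`
#'   token (the URL-noise anchor).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              periods = period_table(
                                c("1996/1997", "2008", "2016"),
                                c("1996-08-20", "2008-01-01", "2016-01-01"),
                                c("1997-08-19", "2008-12-31", "2016-12-31")),
                              n_articles = 1000L,
                              disease_fraction = c(0.0044, 0.0057, 0.0081),
                              concepts = default_concept_table(),
                              K_true = 3L, n_vocab = 300L, alpha_true = 0.1,
                              doc_sentences = 8L, sentence_len = 10L,
                              noise = noise_config(),
                              link_plant_rate = 0.3) {
  np <- nrow(periods)
  n_articles <- rep_len(as.integer(n_articles), np)
  disease_fraction <- rep_len(disease_fraction, np)
  if (any(disease_fraction < 0 | disease_fraction > 1)) {
    stop("disease_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(concepts$weights) - 1) > 1e-9) {
    stop("concept planting weights must sum to 1", call. = FALSE)
  }
  if (any(abs(concepts$target_valence) > 0.613)) {
    stop("target valences must be attainable by the two-word pool (|v| <= 0.613)",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), periods = periods,
                 n_articles = n_articles,
                 disease_fraction = disease_fraction, concepts = concepts,
                 K_true = as.integer(K_true), n_vocab = as.integer(n_vocab),
                 alpha_true = alpha_true,
                 doc_sentences = as.integer(doc_sentences),
                 sentence_len = as.integer(sentence_len),
                 noise = noise, link_plant_rate = link_plant_rate),
            class = "simulation_config")
}

# The two-word valence pool used for sentiment planting. Single-word
# compounds are +/- 3 / sqrt(3^2 + 15) ~ +/- 0.6124; mixing the two words
# with probability p hits any target mean in between exactly in expectation.
.valence_pool <- function() {
  c(zorgood = 3.0, zorbad = -3.0, milgood = 1.5, milbad = -1.5)
}

#' Generate a synthetic news corpus with ground truth
#'
#' Builds a corpus whose every downstream quantity is known by construction:
#' background text drawn from a planted LDA model; designated disease
#' articles receive synonym insertions at recorded sentence positions; one
#' valence-pool word is inserted into each mention sentence with mixing
#' probabilities chosen so the expected sentence compound equals the
#' concept's target valence; Reuters-style noise injected per the noise
#' config. The same seed reproduces the output byte for byte.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, writes `corpus.jsonl`,
#'   `lexicon.tsv`, `cui_icd.tsv`, `icd_phewas.tsv`, `valence.tsv`,
#'   `ground_truth.json` and `config.json` there.
#' @return A list with `corpus` (a `news_corpus`, raw text noisy, clean text
#'   unset), `lexicon`, `chain`, `valence_lexicon`, `ground_truth` and
#'   `paths` (named file paths, or `NULL`).
#' @export
simulate_corpus <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  con <- config$concepts

  reserved <- unique(c(unlist(strsplit(con$lexicon$synonym, " ")),
                       names(.valence_pool()), "link", "editing", "by",
                       "click", "reuters", .abbreviations,
                       default_stopwords()))
  vocab <- pseudo_words(config$n_vocab, reserved = reserved)
  phi_true <- planted_topic_model(config$K_true, config$n_vocab)

  # synonym -> phewas resolution for the planting weights (definitive only)
  lex_obj <- structure(con$lexicon, class = c("concept_lexicon", "data.frame"))
  chain_obj <- structure(list(cui_to_icd = con$cui_icd,
                              icd_to_phewas = con$icd_phewas),
                         class = "mapping_chain")
  res <- resolve_all(lex_obj, chain_obj)
  def_syn <- names(res)[vapply(res, function(r) r$mapping_class == "definitive",
                               logical(1L))]
  syn_by_concept <- split(def_syn, vapply(res[def_syn], function(r) {
    r$phewas_set
  }, character(1L)))
  plant_codes <- names(con$weights)
  missing_codes <- setdiff(plant_codes, names(syn_by_concept))
  if (length(missing_codes)) {
    stop("no definitive synonym for planted concept ", missing_codes[[1L]],
         call. = FALSE)
  }

  pool <- .valence_pool()
  pool_compound <- pool / sqrt(pool^2 + 15)
  cA <- pool_compound[["zorgood"]]; cB <- pool_compound[["zorbad"]]

  articles <- list()
  gt_mentions <- list()
  noise_logs <- list()
  period_stats <- list()
  thetas <- list()
  clean_texts <- character(0)
  aid_counter <- 0L

  for (pi in seq_len(nrow(config$periods))) {
    plab <- config$periods$label[pi]
    n <- config$n_articles[pi]
    n_dis <- round(config$disease_fraction[pi] * n)
    dis_idx <- if (n_dis > 0L) sort(sample.int(n, n_dis)) else integer()
    dates <- config$periods$start_date[pi] +
      sample.int(as.integer(config$periods$end_date[pi] -
                            config$periods$start_date[pi]) + 1L, n,
                 replace = TRUE) - 1L
    concept_of <- character(0)
    if (n_dis > 0L) {
      concept_of <- sample(plant_codes, n_dis, replace = TRUE,
                           prob = con$weights)
    }
    di <- 0L
    for (ai in seq_len(n)) {
      aid_counter <- aid_counter + 1L
      aid <- sprintf("a%06d", aid_counter)
      # background sentences from the planted topic model
      theta_d <- rgamma(config$K_true, shape = config$alpha_true)
      theta_d <- theta_d / sum(theta_d)
      thetas[[aid_counter]] <- theta_d
      n_tok <- config$doc_sentences * config$sentence_len
      zt <- sample.int(config$K_true, n_tok, replace = TRUE, prob = theta_d)
      widx <- integer(n_tok)
      for (t in unique(zt)) {
        sel <- zt == t
        widx[sel] <- sample.int(config$n_vocab, sum(sel), replace = TRUE,
                                prob = phi_true[t, ])
      }
      sents <- split(vocab[widx],
                     rep(seq_len(config$doc_sentences),
                         each = config$sentence_len))
      names(sents) <- NULL
      is_dis <- ai %in% dis_idx
      if (is_dis) {
        di <- di + 1L
        ph <- concept_of[di]
        syn <- sample(syn_by_concept[[ph]], 1L)
        syn_toks <- strsplit(syn, " ", fixed = TRUE)[[1L]]
        ms <- sample.int(config$doc_sentences, 1L)
        toks <- sents[[ms]]
        # valence word first, then the synonym, so the recorded span is final
        target <- con$target_valence[[ph]]
        p <- (target - cB) / (cA - cB)
        vword <- if (runif(1) < p) "zorgood" else "zorbad"
        toks <- append(toks, vword, after = sample.int(length(toks) + 1L, 1L) - 1L)
        ins <- sample.int(length(toks) + 1L, 1L) - 1L
        toks <- append(toks, syn_toks, after = ins)
        sents[[ms]] <- toks
        start <- if (ins == 0L) 1L else {
          sum(nchar(toks[seq_len(ins)])) + ins + 1L
        }
        end <- start + nchar(syn)
        gt_mentions[[length(gt_mentions) + 1L]] <- data.frame(
          article_id = aid, period = plab, phewas = ph, synonym = syn,
          sentence_index = ms, start = start, end = end,
          stringsAsFactors = FALSE)
      }
      # plant a literal "link" token in a non-mention sentence
      if (runif(1) < config$link_plant_rate && config$doc_sentences >= 2L) {
        cand <- seq_len(config$doc_sentences)
        if (is_dis) cand <- setdiff(cand, ms)
        ls <- if (length(cand) == 1L) cand else sample(cand, 1L)
        pos <- sample.int(length(sents[[ls]]), 1L)
        sents[[ls]][pos] <- "link"
      }
      clean <- paste(vapply(sents, function(s) {
        paste0(paste(s, collapse = " "), ".")
      }, character(1L)), collapse = " ")
      clean_texts[[aid]] <- clean
      raw <- clean
      if (!is.null(config$noise)) {
        nz <- make_noise(clean, config$noise)
        raw <- nz$text
        if (nrow(nz$log)) {
          nz$log$article_id <- aid
          noise_logs[[length(noise_logs) + 1L]] <- nz$log
        }
      }
      articles[[aid_counter]] <- data.frame(
        article_id = aid, date = dates[ai], period = plab, raw_text = raw,
        clean_text = NA_character_, stringsAsFactors = FALSE)
    }
    period_stats[[plab]] <- list(n_total = n, n_disease = n_dis)
  }

  articles_df <- do.call(rbind, articles)
  corpus <- news_corpus(articles_df, periods = config$periods)
  mentions_df <- if (length(gt_mentions)) {
    do.call(rbind, gt_mentions)
  } else {
    data.frame(article_id = character(), period = character(),
               phewas = character(), synonym = character(),
               sentence_index = integer(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  }
  counts <- if (nrow(mentions_df)) {
    agg <- aggregate(article_id ~ period + phewas, mentions_df,
                     function(x) length(unique(x)))
    names(agg)[3L] <- "n_articles"
    agg
  } else {
    data.frame(period = character(), phewas = character(),
               n_articles = integer(), stringsAsFactors = FALSE)
  }

  valence_tab <- data.frame(term = names(pool), valence = unname(pool),
                            stringsAsFactors = FALSE)
  ground_truth <- list(
    mentions = mentions_df,
    concept_counts = counts,
    denominators = setNames(
      vapply(period_stats, function(s) s$n_disease, numeric(1L)),
      names(period_stats)),
    totals = setNames(
      vapply(period_stats, function(s) s$n_total, numeric(1L)),
      names(period_stats)),
    phi_true = phi_true, theta_true = do.call(rbind, thetas), vocab = vocab,
    clean_text = clean_texts,
    target_valence = con$target_valence,
    noise_log = if (length(noise_logs)) do.call(rbind, noise_logs) else NULL)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(corpus = file.path(dir, "corpus.jsonl"),
               lexicon = file.path(dir, "lexicon.tsv"),
               cui_icd = file.path(dir, "cui_icd.tsv"),
               icd_phewas = file.path(dir, "icd_phewas.tsv"),
               valence = file.path(dir, "valence.tsv"),
               ground_truth = file.path(dir, "ground_truth.json"),
               config = file.path(dir, "config.json"))
    write_corpus(corpus, paths[["corpus"]])
    write_tsv <- function(df, path) {
      con_f <- file(path, open = "wb")
      on.exit(close(con_f), add = TRUE)
      writeLines(c(paste(names(df), collapse = "\t"),
                   do.call(paste, c(unname(as.list(df)), sep = "\t"))),
                 con_f, useBytes = TRUE)
    }
    write_tsv(con$lexicon, paths[["lexicon"]])
    write_tsv(con$cui_icd, paths[["cui_icd"]])
    write_tsv(con$icd_phewas, paths[["icd_phewas"]])
    write_tsv(valence_tab, paths[["valence"]])
    jsonlite::write_json(ground_truth, paths[["ground_truth"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_out <- config
    cfg_out$periods <- data.frame(label = config$periods$label,
                                  start_date = format(config$periods$start_date),
                                  end_date = format(config$periods$end_date),
                                  stringsAsFactors = FALSE)
    jsonlite::write_json(unclass(cfg_out), paths[["config"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  list(corpus = corpus, lexicon = load_lexicon_df(con$lexicon),
       chain = chain_obj,
       valence_lexicon = structure(list(valence = pool,
                                        boosters = numeric(0),
                                        negations = character(0)),
                                   class = "valence_lexicon"),
       ground_truth = ground_truth, paths = paths)
}

# In-memory equivalent of load_lexicon() for an already-built table.
load_lexicon_df <- function(df) {
  df$synonym <- squish(tolower(df$synonym))
  df <- unique(df)
  rownames(df) <- NULL
  structure(df, class = c("concept_lexicon", "data.frame"))
}
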