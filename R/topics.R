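#' Concatenate multi-word disease names
#'
#' Replaces every occurrence of a multi-word lexicon synonym in cleaned text
#' with its underscore-joined single-token form (e.g. "lung cancer" becomes
#' "lung_cancer"), so compound disease concepts survive word tokenization and
#' can surface as topic terms. Matching uses the same token-anchored,
#' longest-match-first rule as mention detection; single-word synonyms are
#' left unchanged.
#'
#' @param texts Character vector of cleaned lowercase texts (articles or
#'   sentences).
#' @param lexicon A [load_lexicon()] result.
#' @return Character vector with compound names concatenated.
#' @examples
#' # lexicon containing "lung cancer":
#' # concat_compound_terms("lung cancer trial", lex)  ->  "lung_cancer trial"
#' @export
concat_compound_terms <- function(texts, lexicon) {
  syns <- unique(lexicon$synonym)
  multi <- syns[grepl(" ", syns, fixed = TRUE)]
  if (!length(multi)) return(texts)
  # longest-first so nested synonyms resolve like the mention matcher
  syns <- syns[order(-nchar(syns), syns)]
  pats <- paste0("(?<![a-z0-9_])", escape_regex(syns), "(?![a-z0-9_])")
  vapply(texts, function(text) {
    if (is.na(text) || !nzchar(text)) return(text)
    hit <- vapply(multi, grepl, logical(1L), x = text, fixed = TRUE,
                  USE.NAMES = FALSE)
    if (!any(hit)) return(text)
    cand_start <- integer(); cand_len <- integer(); cand_syn <- character()
    for (j in seq_along(syns)) {
      m <- gregexpr(pats[j], text, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      cand_start <- c(cand_start, as.integer(m))
      cand_len <- c(cand_len, attr(m, "match.length"))
      cand_syn <- c(cand_syn, rep(syns[j], length(m)))
    }
    if (!length(cand_start)) return(text)
    ord <- order(-cand_len, cand_start)
    taken <- logical(nchar(text))
    repl <- list()
    for (ci in ord) {
      s <- cand_start[ci]; e <- s + cand_len[ci] - 1L
      if (any(taken[s:e])) next
      taken[s:e] <- TRUE
      if (grepl(" ", cand_syn[ci], fixed = TRUE)) {
        repl[[length(repl) + 1L]] <- c(s, e)
      }
    }
    if (!length(repl)) return(text)
    # apply right-to-left so offsets stay valid
    starts <- vapply(repl, `[[`, numeric(1L), 1L)
    for (ci in order(-starts)) {
      s <- repl[[ci]][1L]; e <- repl[[ci]][2L]
      seg <- gsub(" ", "_", substr(text, s, e), fixed = TRUE)
      text <- paste0(substr(text, 1L, s - 1L), seg,
                     substr(text, e + 1L, nchar(text)))
    }
    text
  }, character(1L), USE.NAMES = FALSE)
}

# Package stopword list and lemmatizer exception table, loaded once per
# session from inst/extdata.
.newsdx_env <- new.env(parent = emptyenv())

#' Default English stopword list
#'
#' The standard English stopword list shipped with the package
#' (`extdata/stopwords_en.txt`), used before topic modeling.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  if (is.null(.newsdx_env$stopwords)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "newsdx",
                        mustWork = TRUE)
    .newsdx_env$stopwords <- readLines(path, warn = FALSE)
  }
  .newsdx_env$stopwords
}

#' Default lemmatizer exception table
#'
#' Irregular form -> lemma pairs shipped with the package
#' (`extdata/lemma_exceptions.tsv`), consulted before the suffix rules.
#'
#' @return Named character vector (names are inflected forms).
#' @export
default_lemma_exceptions <- function() {
  if (is.null(.newsdx_env$lemma)) {
    path <- system.file("extdata", "lemma_exceptions.tsv", package = "newsdx",
                        mustWork = TRUE)
    tab <- read_tsv_checked(path, c("form", "lemma"))
    .newsdx_env$lemma <- setNames(tab$lemma, tab$form)
  }
  .newsdx_env$lemma
}

# Lookup-table + suffix-rule lemmatizer: exceptions first, then plural and
# simple verb-inflection rules. Deliberately conservative -- topic modeling
# only needs inflectional variants of the same word to collapse.
lemmatize_token <- function(tok, exceptions) {
  hit <- unname(exceptions[tok])
  if (length(hit) == 1L && !is.na(hit)) return(hit)
  n <- nchar(tok)
  if (n > 4L && endsWith(tok, "ies")) return(paste0(substr(tok, 1L, n - 3L), "y"))
  if (n > 4L && endsWith(tok, "ied")) return(paste0(substr(tok, 1L, n - 3L), "y"))
  if (n > 5L && grepl("(sh|ch|ss|x|z)es$", tok)) return(substr(tok, 1L, n - 2L))
  if (n > 4L && endsWith(tok, "uses")) return(substr(tok, 1L, n - 2L))
  if (n > 3L && endsWith(tok, "s") && !grepl("(ss|us|is)$", tok)) {
    return(substr(tok, 1L, n - 1L))
  }
  if (n > 5L && endsWith(tok, "ing")) {
    stem <- substr(tok, 1L, n - 3L)
    m <- nchar(stem)
    if (m > 2L && substr(stem, m, m) == substr(stem, m - 1L, m - 1L) &&
        !grepl("(ll|ss)$", stem)) {
      stem <- substr(stem, 1L, m - 1L)
    }
    return(stem)
  }
  if (n > 4L && endsWith(tok, "ed")) {
    stem <- substr(tok, 1L, n - 2L)
    m <- nchar(stem)
    if (m > 2L && substr(stem, m, m) == substr(stem, m - 1L, m - 1L) &&
        !grepl("(ll|ss)$", stem)) {
      stem <- substr(stem, 1L, m - 1L)
    }
    return(stem)
  }
  tok
}

#' Tokenize text for topic modeling
#'
#' Word tokenization of cleaned text with stopword removal and lemmatization.
#' Underscore-joined compound tokens (from [concat_compound_terms()] or
#' phrase detection) pass through untouched.
#'
#' @param text A single cleaned character string.
#' @param stopwords Character vector of stopwords to drop.
#' @param lemma_exceptions Named character vector of irregular form -> lemma
#'   pairs.
#' @return Character vector of tokens.
#' @examples
#' # tokenize_for_topics("the studies of drugs")  ->  c("study", "drug")
#' @export
tokenize_for_topics <- function(text, stopwords = default_stopwords(),
                                lemma_exceptions = default_lemma_exceptions()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- regmatches(text, gregexpr("[a-z0-9_]+", text, perl = TRUE))[[1L]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character())
  res <- character(0)
  for (tok in toks) {
    if (grepl("_", tok, fixed = TRUE)) {       # compound term: pass through
      res <- c(res, tok)
    } else if (!(tok %in% stopwords)) {
      lt <- lemmatize_token(tok, lemma_exceptions)
      if (!(lt %in% stopwords)) res <- c(res, lt)
    }
  }
  res
}

#' Merge frequent adjacent token pairs into phrases
#'
#' Collocation-based phrase detection for topic modeling. In each pass,
#' adjacent pairs (a, b) whose score
#' `(count(ab) - min_count) * N / (count(a) * count(b))` -- with `N` the
#' number of distinct tokens in the current pass -- reaches `threshold` are
#' merged left-to-right into a single `a_b` token. `ngram_max - 1` passes
#' allow phrases of up to `ngram_max` words.
#'
#' @param docs List of character token vectors.
#' @param ngram_max Maximum phrase length in words (1-4); 1 disables merging.
#' @param min_count Minimum pair count before a pair can score.
#' @param threshold Score threshold for merging.
#' @return List of token vectors with detected phrases merged.
#' @export
detect_phrases <- function(docs, ngram_max = 4L, min_count = 5L,
                           threshold = 10) {
  stopifnot(ngram_max >= 1L, ngram_max <= 4L)
  if (ngram_max == 1L || !length(docs)) return(docs)
  for (pass in seq_len(ngram_max - 1L)) {
    all_tokens <- unlist(docs, use.names = FALSE)
    if (length(all_tokens) < 2L) break
    uni <- table(all_tokens)
    n_vocab <- length(uni)
    pair_keys <- unlist(lapply(docs, function(d) {
      if (length(d) < 2L) return(character())
      paste(d[-length(d)], d[-1L], sep = "\r")
    }), use.names = FALSE)
    if (!length(pair_keys)) break
    bi <- table(pair_keys)
    merged_any <- FALSE
    docs <- lapply(docs, function(d) {
      if (length(d) < 2L) return(d)
      out <- character(0)
      i <- 1L
      while (i <= length(d)) {
        if (i < length(d)) {
          key <- paste(d[i], d[i + 1L], sep = "\r")
          cab <- bi[key]
          if (!is.na(cab)) {
            score <- (as.numeric(cab) - min_count) * n_vocab /
              (as.numeric(uni[d[i]]) * as.numeric(uni[d[i + 1L]]))
            if (score >= threshold) {
              out <- c(out, paste(d[i], d[i + 1L], sep = "_"))
              merged_any <<- TRUE
              i <- i + 2L
              next
            }
          }
        }
        out <- c(out, d[i])
        i <- i + 1L
      }
      out
    })
    if (!merged_any) break
  }
  docs
}

#' Index tokenized documents against a vocabulary
#'
#' @param doc_tokens List of character token vectors, one per document.
#' @return Object of class `tokenized_docs`: list with `vocab` (sorted term
#'   vector), `docs` (list of 1-based integer index vectors) and `D`.
#' @export
tokenized_docs <- function(doc_tokens) {
  stopifnot(is.list(doc_tokens))
  vocab <- sort(unique(unlist(doc_tokens, use.names = FALSE)))
  docs <- lapply(doc_tokens, function(d) match(d, vocab))
  structure(list(vocab = vocab, docs = docs, D = length(docs)),
            class = "tokenized_docs")
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Latent Dirichlet allocation with symmetric Dirichlet priors `alpha` on the
#' document-topic distributions and `beta` on the topic-word distributions.
#' Inference integrates out the Dirichlet parameters and resamples each
#' token's topic from its full conditional, proportional to
#' `(n_dt + alpha) * (n_wt + beta) / (n_t + V * beta)` with the token's own
#' assignment removed from the counts. `mode = "icm"` instead assigns each
#' token the argmax of that conditional (iterated conditional modes), the
#' deterministic hill-climbing variant of the same update. After the sweeps,
#' point estimates are `phi[w, t] = (n_wt + beta) / (n_t + V beta)` and
#' `theta[d, t] = (n_dt + alpha) / (n_d + K alpha)`. With `K = 1` every
#' assignment is forced and `phi` is the closed-form smoothed unigram
#' distribution `(count(w) + beta) / (N + V beta)`.
#'
#' @param docs A [tokenized_docs()] object.
#' @param K Number of topics (>= 1). For concept-level news analysis the
#'   working default is 1: one aggregate topic per concept group.
#' @param alpha Document-topic Dirichlet prior; default `50 / K`.
#' @param beta Topic-word Dirichlet prior; default 0.01.
#' @param iterations Number of full Gibbs sweeps (default 500).
#' @param mode `"gibbs"` (default) or `"icm"`.
#' @param seed Optional integer seed; fixing it makes runs bit-reproducible.
#' @param track_assignments If `TRUE`, also return per-token topic assignment
#'   frequencies (`assign_freq`) and pairwise co-assignment frequencies
#'   (`pair_freq`, the relabelling-invariant `P(z_i == z_j)`) accumulated
#'   over the post-`burnin` sweeps.
#' @param burnin Sweeps discarded before frequency tracking.
#' @return Object of class `lda_topics` with elements `K`, `alpha`, `beta`,
#'   `iterations`, `mode`, `vocab`, `z` (per-document topic assignments),
#'   `n_dt`, `n_wt`, `n_t`, `theta` (D x K), `phi` (V x K), and
#'   `assign_freq` (or `NULL`).
#' @export
fit_lda <- function(docs, K = 1L, alpha = 50 / K, beta = 0.01,
                    iterations = 500L, mode = c("gibbs", "icm"),
                    seed = NULL, track_assignments = FALSE, burnin = 0L) {
  stopifnot(inherits(docs, "tokenized_docs"))
  mode <- match.arg(mode)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0",
                                    call. = FALSE)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  V <- length(docs$vocab)
  if (V == 0L) stop("empty vocabulary", call. = FALSE)
  N <- sum(lengths(docs$docs))
  if (K > N) stop("K exceeds the total number of tokens", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  zero_based <- lapply(docs$docs, function(d) as.integer(d - 1L))
  fit <- .gibbs_lda(zero_based, V, K, alpha, beta, iterations,
                    icm = (mode == "icm"), track = track_assignments,
                    burnin = as.integer(burnin))
  n_dt <- fit$n_dt
  n_wt <- fit$n_wt
  n_t <- as.numeric(fit$n_t)
  n_d <- lengths(docs$docs)
  theta <- (n_dt + alpha) / (n_d + K * alpha)
  phi <- sweep(n_wt + beta, 2L, n_t + V * beta, "/")
  rownames(phi) <- docs$vocab
  structure(list(K = K, alpha = alpha, beta = beta, iterations = iterations,
                 mode = mode, vocab = docs$vocab, z = fit$z,
                 n_dt = n_dt, n_wt = n_wt, n_t = fit$n_t,
                 theta = theta, phi = phi,
                 assign_freq = fit$assign_freq, pair_freq = fit$pair_freq,
                 D = docs$D, N = N, call = match.call()),
            class = "lda_topics")
}

#' @export
print.lda_topics <- function(x, ...) {
  cat(sprintf("LDA topic model (%s): K = %d topics, D = %d docs, V = %d terms, N = %d tokens\n",
              x$mode, x$K, x$D, length(x$vocab), x$N))
  cat(sprintf("priors alpha = %g, beta = %g; %d sweeps\n",
              x$alpha, x$beta, x$iterations))
  invisible(x)
}

#' @export
summary.lda_topics <- function(object, top_n = 10L, ...) {
  cat(sprintf("LDA (%s), K = %d, alpha = %g, beta = %g, %d sweeps\n",
              object$mode, object$K, object$alpha, object$beta,
              object$iterations))
  for (t in seq_len(object$K)) {
    ts <- summarize_topic(object, t, top_n = top_n)
    cat(sprintf("topic %d: %s\n", t,
                paste(sprintf("%s (%.1f)", ts$term, ts$permille),
                      collapse = ", ")))
  }
  invisible(object)
}

#' Top terms of one topic, in permille
#'
#' Ranks a topic's terms by `P(w|t)` descending (ties broken
#' lexicographically) and reports each weight in permille, `1000 * P(w|t)`.
#'
#' @param state A fitted `lda_topics` object.
#' @param topic Topic index in `1..K`.
#' @param top_n Number of terms to keep (default 50); if larger than the
#'   vocabulary, all terms are returned.
#' @return Data frame with columns `rank`, `term`, `permille`.
#' @export
summarize_topic <- function(state, topic, top_n = 50L) {
  stopifnot(inherits(state, "lda_topics"))
  if (topic < 1L || topic > state$K) {
    stop("topic index out of range 1..K", call. = FALSE)
  }
  p <- state$phi[, topic]
  ord <- order(-p, state$vocab)
  n <- min(top_n, length(p))
  idx <- ord[seq_len(n)]
  data.frame(rank = seq_len(n), term = state$vocab[idx],
             permille = 1000 * unname(p[idx]), stringsAsFactors = FALSE)
}

#' Topic summaries per disease concept and period
#'
#' For each (concept, period) group of articles, preprocesses the cleaned
#' article texts (compound-name concatenation, tokenization with stopword
#' removal and lemmatization, optional phrase detection), fits an LDA model
#' (default K = 1: the group's single aggregate topic), and returns the top
#' terms in permille. Groups with fewer than `min_docs` articles are skipped.
#'
#' @param corpus A cleaned `news_corpus`.
#' @param concept_articles Named list: period -> named list phewas code ->
#'   article ids (as used by [concept_coverage()]).
#' @param lexicon A [load_lexicon()] result (for compound-name joining).
#' @param K,alpha,beta,iterations,mode Passed to [fit_lda()].
#' @param top_n Terms per summary.
#' @param ngram_max,phrase_min_count,phrase_threshold Passed to
#'   [detect_phrases()]; `ngram_max = 1` disables phrase detection.
#' @param min_docs Minimum articles per group.
#' @param seed Optional integer seed; per-group fits derive distinct
#'   sub-seeds from it.
#' @return Data frame with columns `phewas_code`, `period`, `rank`, `term`,
#'   `permille`.
#' @export
topics_per_concept <- function(corpus, concept_articles, lexicon,
                               K = 1L, alpha = 50 / K, beta = 0.01,
                               iterations = 500L, mode = "gibbs",
                               top_n = 50L, ngram_max = 1L,
                               phrase_min_count = 5L, phrase_threshold = 10,
                               min_docs = 2L, seed = NULL) {
  stopifnot(inherits(corpus, "news_corpus"))
  a <- corpus$articles
  if (anyNA(a$clean_text)) stop("corpus must be cleaned first", call. = FALSE)
  grouped_ids <- unique(unlist(lapply(concept_articles, function(g) {
    unlist(g, use.names = FALSE)
  }), use.names = FALSE))
  sel <- a$article_id %in% grouped_ids
  texts <- setNames(concat_compound_terms(a$clean_text[sel], lexicon),
                    a$article_id[sel])
  out <- list()
  gi <- 0L
  for (pd in names(concept_articles)) {
    for (ph in names(concept_articles[[pd]])) {
      ids <- concept_articles[[pd]][[ph]]
      if (length(ids) < min_docs) {
        message(sprintf("skipping %s / %s: %d article(s) < min_docs = %d",
                        ph, pd, length(ids), min_docs))
        next
      }
      toks <- lapply(unname(texts[ids]), tokenize_for_topics)
      if (ngram_max > 1L) {
        toks <- detect_phrases(toks, ngram_max, phrase_min_count,
                               phrase_threshold)
      }
      toks <- toks[lengths(toks) > 0L]
      if (!length(toks)) next
      gi <- gi + 1L
      sub_seed <- if (is.null(seed)) NULL else (seed + gi) %% .Machine$integer.max
      fit <- fit_lda(tokenized_docs(toks), K = K, alpha = alpha, beta = beta,
                     iterations = iterations, mode = mode, seed = sub_seed)
      for (t in seq_len(K)) {
        ts <- summarize_topic(fit, t, top_n = top_n)
        ts$phewas_code <- ph
        ts$period <- pd
        out[[length(out) + 1L]] <- ts[, c("phewas_code", "period", "rank",
                                          "term", "permille")]
      }
    }
  }
  if (!length(out)) {
    return(data.frame(phewas_code = character(), period = character(),
                      rank = integer(), term = character(),
                      permille = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
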