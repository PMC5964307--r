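#' Load a sentiment valence lexicon
#'
#' Reads the word lists driving the lexicon-and-rule compound score: a
#' valence TSV (`term`, `valence` in [-4, 4]), an optional booster TSV
#' (`term`, `increment`; positive increments intensify the following
#' sentiment term, negative increments dampen it), and an optional negation
#' list (one term per line). All terms are lowercased.
#'
#' @param valence_path TSV with header `term<TAB>valence`.
#' @param booster_path Optional TSV with header `term<TAB>increment`.
#' @param negation_path Optional plain-text file, one negation term per line.
#' @return Object of class `valence_lexicon`: list with `valence` (named
#'   numeric), `boosters` (named numeric), `negations` (character).
#' @export
load_valence_lexicon <- function(valence_path, booster_path = NULL,
                                 negation_path = NULL) {
  tab <- read_tsv_checked(valence_path, c("term", "valence"))
  val <- suppressWarnings(as.numeric(tab$valence))
  if (anyNA(val)) {
    stop("non-numeric valence at line ",
         which(is.na(val))[[1L]] + 1L, " of ", valence_path, call. = FALSE)
  }
  if (any(abs(val) > 4)) {
    stop("valences must lie in [-4, 4]", call. = FALSE)
  }
  valence <- setNames(val, tolower(trimws(tab$term)))
  boosters <- numeric(0)
  if (!is.null(booster_path)) {
    btab <- read_tsv_checked(booster_path, c("term", "increment"))
    boosters <- setNames(suppressWarnings(as.numeric(btab$increment)),
                         tolower(trimws(btab$term)))
    if (anyNA(boosters)) stop("non-numeric booster increment", call. = FALSE)
  }
  negations <- character(0)
  if (!is.null(negation_path)) {
    negations <- tolower(trimws(readLines(negation_path, warn = FALSE)))
    negations <- negations[nzchar(negations)]
  }
  structure(list(valence = valence, boosters = boosters,
                 negations = negations),
            class = "valence_lexicon")
}

#' A minimal built-in valence lexicon
#'
#' A small general-purpose lexicon (common evaluative words, the standard
#' negators, and a few boosters/dampeners) so the sentiment stage runs out of
#' the box; real analyses should supply a full lexicon via
#' [load_valence_lexicon()].
#'
#' @return A `valence_lexicon`.
#' @export
default_valence_lexicon <- function() {
  valence <- c(
    good = 1.9, great = 3.1, positive = 2.3, hope = 1.9, improve = 1.9,
    success = 2.7, breakthrough = 2.4, cure = 2.3, recovery = 2.1,
    effective = 2.1, safe = 1.8, benefit = 1.9,
    bad = -2.5, death = -2.9, die = -2.9, kill = -3.4, crisis = -2.3,
    outbreak = -1.8, fear = -2.2, risk = -1.1, fail = -2.3, severe = -2.0,
    suffer = -2.1, epidemic = -1.9, fatal = -3.0, threat = -2.1,
    decline = -1.3, loss = -1.7)
  boosters <- c(very = 0.293, extremely = 0.293, highly = 0.293,
                slightly = -0.293, somewhat = -0.293, marginally = -0.293)
  negations <- c("not", "no", "never", "neither", "nor", "cannot", "without",
                 "hardly", "rarely", "n't")
  structure(list(valence = valence, boosters = boosters,
                 negations = negations),
            class = "valence_lexicon")
}

#' Compound sentiment score of a token stream
#'
#' Lexicon-and-rule scoring of one cleaned sentence. Each token found in the
#' valence lexicon contributes its valence, adjusted by two rules: a negation
#' term within the three preceding tokens flips and damps the valence by a
#' factor of -0.74, and each booster/dampener in that window moves the
#' valence toward (away from) its sign by the booster increment (default
#' magnitude 0.293). The adjusted valences are summed to `s` and normalized
#' to `s / sqrt(s^2 + alpha_norm)`, mapping any sum into (-1, 1) with 0 for
#' sentences containing no lexicon term. Capitalization and punctuation
#' emphasis rules are deliberately absent: upstream cleaning lowercases text
#' before scoring, which disables them.
#'
#' @param tokens Character vector of lowercase tokens, in sentence order.
#' @param lexicon A `valence_lexicon`.
#' @param alpha_norm Positive normalization constant (default 15).
#' @return Compound score in `[-1, 1]`.
#' @examples
#' lex <- default_valence_lexicon()
#' score_sentence(c("a", "good", "day"), lex)
#' score_sentence(c("not", "a", "good", "day"), lex)
#' @export
score_sentence <- function(tokens, lexicon, alpha_norm = 15) {
  stopifnot(inherits(lexicon, "valence_lexicon"), alpha_norm > 0)
  if (!length(tokens)) return(0)
  s <- 0
  hit <- FALSE
  for (i in seq_along(tokens)) {
    v <- unname(lexicon$valence[tokens[[i]]])
    if (length(v) != 1L || is.na(v)) next
    hit <- TRUE
    window <- if (i == 1L) character(0) else tokens[max(1L, i - 3L):(i - 1L)]
    for (w in window) {
      b <- unname(lexicon$boosters[w])
      if (length(b) == 1L && !is.na(b) && v != 0) v <- v + sign(v) * b
    }
    if (any(window %in% lexicon$negations)) v <- v * -0.74
    s <- s + v
  }
  if (!hit) return(0)
  s / sqrt(s^2 + alpha_norm)
}

# Word tokens of a cleaned sentence, for sentiment scoring.
sentiment_tokens <- function(sentence) {
  toks <- regmatches(sentence,
                     gregexpr("[a-z0-9_']+", sentence, perl = TRUE))[[1L]]
  toks[nzchar(toks)]
}

#' Score every disease-mentioning sentence in a corpus
#'
#' Computes the compound score for each sentence that carries at least one
#' disease mention (only those sentences enter the per-concept sentiment
#' aggregation), together with the concepts that sentence mentions under the
#' given attribution policy.
#'
#' @param sentences Named list: article id -> character vector of cleaned
#'   sentences.
#' @param mentions Data frame from [find_mentions()].
#' @param lexicon A `valence_lexicon`.
#' @param policy Attribution policy, as in [articles_by_concept()].
#' @param alpha_norm Normalization constant for [score_sentence()].
#' @return Data frame with columns `article_id`, `sentence_index`,
#'   `compound`, and list column `phewas_codes`.
#' @export
score_mention_sentences <- function(sentences, mentions, lexicon,
                                    policy = c("definitive_only",
                                               "expand_ambiguous"),
                                    alpha_norm = 15) {
  policy <- match.arg(policy)
  use <- if (policy == "definitive_only") {
    mentions$mapping_class == "definitive"
  } else {
    mentions$mapping_class != "unmapped"
  }
  m <- mentions[use, , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(article_id = character(), sentence_index = integer(),
                      compound = numeric(), phewas_codes = I(list()),
                      stringsAsFactors = FALSE))
  }
  key <- paste(m$article_id, m$sentence_index, sep = "\r")
  groups <- split(seq_len(nrow(m)), key)
  ids <- vapply(groups, function(ix) m$article_id[ix[[1L]]], character(1L))
  sidx <- vapply(groups, function(ix) m$sentence_index[ix[[1L]]], integer(1L))
  ord <- order(match(ids, names(sentences)), sidx)
  groups <- groups[ord]; ids <- ids[ord]; sidx <- sidx[ord]
  compound <- numeric(length(groups))
  codes <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    sent <- sentences[[ids[[g]]]][[sidx[[g]]]]
    compound[[g]] <- score_sentence(sentiment_tokens(sent), lexicon,
                                    alpha_norm)
    codes[[g]] <- sort(unique(unlist(m$phewas_set[groups[[g]]])))
  }
  out <- data.frame(article_id = ids, sentence_index = sidx,
                    compound = compound, stringsAsFactors = FALSE)
  out$phewas_codes <- I(codes)
  rownames(out) <- NULL
  out
}

#' Per-concept, per-period mean sentiment
#'
#' Averages sentence compound scores over all sentences mentioning a concept
#' within a period. A sentence mentioning k concepts contributes to all k
#' means. Concepts with no scored sentence in a period are omitted rather
#' than zero-filled (no evidence is not neutral evidence).
#'
#' @param sentence_scores Data frame from [score_mention_sentences()].
#' @param article_periods Named character vector: article id -> period label.
#' @return Data frame with columns `phewas_code`, `period`, `n_sentences`,
#'   `mean_compound`.
#' @export
concept_sentiment <- function(sentence_scores, article_periods) {
  if (!nrow(sentence_scores)) {
    return(data.frame(phewas_code = character(), period = character(),
                      n_sentences = integer(), mean_compound = numeric(),
                      stringsAsFactors = FALSE))
  }
  period <- article_periods[sentence_scores$article_id]
  if (anyNA(period)) {
    stop("article without a period label in article_periods", call. = FALSE)
  }
  reps <- lengths(sentence_scores$phewas_codes)
  long <- data.frame(
    phewas_code = unlist(sentence_scores$phewas_codes),
    period = rep(unname(period), reps),
    compound = rep(sentence_scores$compound, reps),
    stringsAsFactors = FALSE)
  agg_n <- aggregate(compound ~ phewas_code + period, long, length)
  agg_m <- aggregate(compound ~ phewas_code + period, long, mean)
  out <- data.frame(phewas_code = agg_n$phewas_code, period = agg_n$period,
                    n_sentences = as.integer(agg_n$compound),
                    mean_compound = agg_m$compound, stringsAsFactors = FALSE)
  out <- out[order(out$phewas_code, out$period), ]
  rownames(out) <- NULL
  out
}

#' Band a mean compound score
#'
#' Labels a mean compound score `negative`, `neutral` or `positive` relative
#' to a neutral band around zero (default `[-0.05, 0.05]`, endpoints
#' inclusive).
#'
#' @param mean_compound Numeric vector of mean compound scores.
#' @param neutral_band Length-2 numeric `c(lo, hi)` with `lo < 0 < hi`.
#' @return Character vector of band labels.
#' @export
sentiment_band <- function(mean_compound, neutral_band = c(-0.05, 0.05)) {
  stopifnot(length(neutral_band) == 2L,
            neutral_band[1L] < 0, neutral_band[2L] > 0)
  ifelse(mean_compound < neutral_band[1L], "negative",
         ifelse(mean_compound > neutral_band[2L], "positive", "neutral"))
}
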