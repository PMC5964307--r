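#' Cleaning configuration
#'
#' Parameters for the ordered newswire cleaning chain. Defaults reproduce the
#' six canonical rules used for Reuters-style archives: strip agency tags,
#' delete editorial byline sentences, delete boilerplate comment sentences,
#' replace hyperlinks with a placeholder word, collapse runs of repeated
#' special characters, turn `*`/`>` sentence delimiters into periods, and
#' finally lowercase everything.
#'
#' @param agency_tags Literal tags removed wherever they occur
#'   (case-insensitive).
#' @param byline_prefixes Sentence-initial cues; a sentence starting with one
#'   is deleted whole.
#' @param comment_patterns Literal trigger phrases; a sentence containing one
#'   is deleted whole.
#' @param link_token Single lowercase word substituted for each URL.
#' @param min_repeat_run Minimum length (>= 3) of a run of one repeated
#'   special character for the run to be collapsed to a space.
#' @param delimiter_chars Characters treated as sentence delimiters and
#'   replaced by a period.
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(agency_tags = c("(Reuters)", "(Reuters Life)",
                                            "(Reuters Health)"),
                            byline_prefixes = c("Editing by", "Reporting by",
                                                "Written by", "Page editor"),
                            comment_patterns = c(
                              "click on the codes in brackets to see stories",
                              "the following statement was released by the rating agency",
                              "note to subscribers"),
                            link_token = "link",
                            min_repeat_run = 3L,
                            delimiter_chars = c("*", ">")) {
  if (length(link_token) != 1L || !grepl("^[a-z]+$", link_token)) {
    stop("link_token must be a single lowercase word", call. = FALSE)
  }
  min_repeat_run <- as.integer(min_repeat_run)
  if (is.na(min_repeat_run) || min_repeat_run < 3L) {
    stop("min_repeat_run must be an integer >= 3", call. = FALSE)
  }
  if (any(nchar(delimiter_chars) != 1L)) {
    stop("delimiter_chars must be single characters", call. = FALSE)
  }
  structure(list(agency_tags = agency_tags,
                 byline_prefixes = byline_prefixes,
                 comment_patterns = comment_patterns,
                 link_token = link_token,
                 min_repeat_run = min_repeat_run,
                 delimiter_chars = delimiter_chars),
            class = "cleaning_config")
}

# Abbreviations that a trailing period does not terminate a sentence after.
# Compared lowercase, without the final period.
.abbreviations <- c("dr", "mr", "mrs", "ms", "st", "no", "vs", "etc", "jr",
                    "sr", "prof", "gen", "gov", "sen", "rep", "col", "inc",
                    "ltd", "co", "corp", "fig", "approx", "dept", "est",
                    "e.g", "i.e", "u.s", "u.k", "u.n", "a.m", "p.m",
                    "jan", "feb", "mar", "apr", "jun", "jul", "aug", "sep",
                    "sept", "oct", "nov", "dec")

# End positions (inclusive, at the last terminator character) of sentence
# boundaries in `text`. A boundary is a run of [.?!] followed by whitespace or
# end-of-text, unless the preceding token is a known abbreviation or a single
# letter (an initial), or the period sits between two digits.
sentence_ends <- function(text) {
  m <- gregexpr("[.?!]+(?=\\s|$)", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  ends <- starts + lens - 1L
  keep <- vapply(seq_along(starts), function(i) {
    s <- starts[i]
    if (ends[i] == nchar(text)) return(TRUE)   # end of text always terminates
    ch <- substr(text, s, s)
    if (ch != ".") return(TRUE)                # ? and ! always split
    before <- substr(text, 1L, s - 1L)
    tok <- sub("^.*[\\s]", "", before, perl = TRUE)
    tok <- tolower(tok)
    if (nchar(tok) == 1L && grepl("^[a-z]$", tok)) return(FALSE)
    !(tok %in% .abbreviations)
  }, logical(1L))
  ends[keep]
}

# Split `text` into sentence substrings (terminators kept, trimmed). Shared by
# split_sentences() and the sentence-deleting cleaning rules.
split_raw_sentences <- function(text) {
  if (!nzchar(text)) return(character())
  ends <- sentence_ends(text)
  if (!length(ends) || ends[length(ends)] < nchar(text)) {
    ends <- c(ends, nchar(text))
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- trimws(substring(text, starts, ends))
  out[nzchar(out)]
}

#' Clean one article text
#'
#' Applies the cleaning rules in a fixed order -- agency tags, byline
#' sentences, comment sentences, hyperlinks, repeated-special-character runs,
#' `*`/`>` delimiters, lowercasing -- then collapses whitespace. Lowercasing
#' comes last because the byline cues are case-sensitive conventions of the
#' source. Cleaning is total (never errors on content) and idempotent.
#'
#' @param raw A single character string (may be empty).
#' @param config A [cleaning_config()].
#' @return A list with `text` (the cleaned string) and `report`, a named
#'   integer vector of per-rule edit counts: `tags_removed`,
#'   `byline_sentences_removed`, `comments_removed`, `links_replaced`,
#'   `repeat_runs_removed`, `delimiters_replaced`.
#' @examples
#' clean_text("Smoking causes cancer. (Reuters)", cleaning_config())
#' @export
clean_text <- function(raw, config = cleaning_config()) {
  stopifnot(is.character(raw), length(raw) == 1L,
            inherits(config, "cleaning_config"))
  if (is.na(raw)) raw <- ""
  report <- c(tags_removed = 0L, byline_sentences_removed = 0L,
              comments_removed = 0L, links_replaced = 0L,
              repeat_runs_removed = 0L, delimiters_replaced = 0L)
  text <- raw

  # 1. agency tags (literal, case-insensitive)
  for (tag in config$agency_tags) {
    pat <- paste0("(?i)", escape_regex(tag))
    n <- count_matches(pat, text)
    if (n) {
      report[["tags_removed"]] <- report[["tags_removed"]] + n
      text <- gsub(pat, "", text, perl = TRUE)
    }
  }

  # 2+3. byline-prefixed and comment-triggered sentences, dropped whole
  if (nzchar(trimws(text))) {
    sents <- split_raw_sentences(text)
    if (length(sents)) {
      lower <- tolower(sents)
      pref <- tolower(config$byline_prefixes)
      is_byline <- Reduce(`|`, lapply(pref, function(p) {
        startsWith(lower, p)
      }), rep(FALSE, length(sents)))
      trig <- tolower(config$comment_patterns)
      is_comment <- Reduce(`|`, lapply(trig, function(p) {
        grepl(p, lower, fixed = TRUE)
      }), rep(FALSE, length(sents))) & !is_byline
      report[["byline_sentences_removed"]] <- sum(is_byline)
      report[["comments_removed"]] <- sum(is_comment)
      text <- paste(sents[!is_byline & !is_comment], collapse = " ")
    }
  }

  # 4. hyperlinks -> link token; trailing sentence punctuation is not part
  # of the URL, so the match must end on an alphanumeric or slash
  url_pat <- "(?:https?://|www\\.)[^[:space:]]*[[:alnum:]/]"
  n <- count_matches(url_pat, text)
  if (n) {
    report[["links_replaced"]] <- n
    text <- gsub(url_pat, config$link_token, text, perl = TRUE)
  }

  # 5. runs of one repeated special character -> single space
  run_pat <- sprintf("([^[:alnum:][:space:]])\\1{%d,}",
                     config$min_repeat_run - 1L)
  n <- count_matches(run_pat, text)
  if (n) {
    report[["repeat_runs_removed"]] <- n
    text <- gsub(run_pat, " ", text, perl = TRUE)
  }

  # 6. sentence delimiters -> period
  for (ch in config$delimiter_chars) {
    n <- count_matches(escape_regex(ch), text)
    if (n) {
      report[["delimiters_replaced"]] <- report[["delimiters_replaced"]] + n
      text <- gsub(ch, ".", text, fixed = TRUE)
    }
  }

  # 7. lowercase, then normalize whitespace
  text <- tolower(text)
  text <- trimws(gsub("[[:space:]]+", " ", text))
  list(text = text, report = report)
}

#' Clean every article in a corpus
#'
#' Runs [clean_text()] over all articles, filling the `clean_text` column,
#' and accumulates the per-rule edit counters.
#'
#' @param corpus A `news_corpus`.
#' @param config A [cleaning_config()].
#' @return A list with `corpus` (clean_text filled) and `report` (summed
#'   counters across articles).
#' @export
clean_corpus <- function(corpus, config = cleaning_config()) {
  stopifnot(inherits(corpus, "news_corpus"))
  total <- c(tags_removed = 0L, byline_sentences_removed = 0L,
             comments_removed = 0L, links_replaced = 0L,
             repeat_runs_removed = 0L, delimiters_replaced = 0L)
  texts <- character(nrow(corpus$articles))
  for (i in seq_len(nrow(corpus$articles))) {
    res <- clean_text(corpus$articles$raw_text[i], config)
    texts[i] <- res$text
    total <- total + res$report
  }
  corpus$articles$clean_text <- texts
  validate_corpus(corpus)
  list(corpus = corpus, report = total)
}

#' Split cleaned text into sentences
#'
#' Rule-based segmentation on `.?!` terminators with an abbreviation guard
#' (e.g. "dr.", "u.s.", single-letter initials) and no splitting inside
#' numbers. Intended for text that has already been cleaned (lowercase,
#' delimiters normalized to periods).
#'
#' @param clean A single cleaned character string.
#' @return Character vector of sentences, terminators kept, no empties;
#'   joining them and collapsing whitespace reproduces the input likewise
#'   collapsed.
#' @examples
#' split_sentences("flu rises. deaths fall.")
#' @export
split_sentences <- function(clean) {
  stopifnot(is.character(clean), length(clean) == 1L)
  if (is.na(clean) || !nzchar(trimws(clean))) return(character())
  split_raw_sentences(clean)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

count_matches <- function(pattern, text) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}
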