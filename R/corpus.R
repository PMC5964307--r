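#' Construct a period table
#'
#' A period is a labelled, inclusive calendar date range. Periods partition a
#' corpus into the study windows over which coverage, sentiment and topics are
#' compared (for yearly news archives, typically one period per archive year).
#'
#' @param label Character vector of unique period labels, e.g. `"1996/1997"`.
#' @param start_date,end_date Dates (or ISO-8601 strings) delimiting each
#'   period; both endpoints are inclusive.
#' @return A data frame with columns `label`, `start_date`, `end_date`.
#' @examples
#' period_table("2016", "2016-01-01", "2016-12-31")
#' @export
period_table <- function(label, start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (anyNA(start_date) || anyNA(end_date)) {
    stop("period dates must be valid ISO-8601 dates", call. = FALSE)
  }
  if (any(start_date > end_date)) {
    stop("period start_date must not be after end_date", call. = FALSE)
  }
  if (anyDuplicated(label)) {
    stop("period labels must be unique", call. = FALSE)
  }
  data.frame(label = as.character(label), start_date = start_date,
             end_date = end_date, stringsAsFactors = FALSE)
}

#' Construct a news corpus
#'
#' Bundles a set of news articles with the period table they are assigned to.
#' Articles carry an identifier, a publication date, a period label, the raw
#' text and (once cleaned) a lowercase clean text.
#'
#' @param articles Data frame with columns `article_id`, `date`, `period`,
#'   `raw_text` and optionally `clean_text` (`NA` when not yet cleaned).
#' @param periods A period table from [period_table()]. If `NULL`, one period
#'   per calendar year present in `articles$date` is inferred.
#' @return An object of class `news_corpus`: a list with elements `articles`
#'   and `periods`.
#' @export
news_corpus <- function(articles, periods = NULL) {
  stopifnot(is.data.frame(articles))
  required <- c("article_id", "date", "period", "raw_text")
  missing_cols <- setdiff(required, names(articles))
  if (length(missing_cols)) {
    stop("articles is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  articles$article_id <- as.character(articles$article_id)
  articles$date <- as.Date(articles$date)
  articles$period <- as.character(articles$period)
  if (is.null(articles$clean_text)) articles$clean_text <- NA_character_
  if (is.null(periods)) {
    yrs <- sort(unique(format(articles$date, "%Y")))
    periods <- if (length(yrs)) {
      period_table(yrs, as.Date(paste0(yrs, "-01-01")),
                   as.Date(paste0(yrs, "-12-31")))
    } else {
      data.frame(label = character(), start_date = as.Date(character()),
                 end_date = as.Date(character()), stringsAsFactors = FALSE)
    }
    if (all(is.na(articles$period)) || all(articles$period == "")) {
      articles$period <- format(articles$date, "%Y")
    }
  }
  corpus <- structure(list(articles = articles, periods = periods),
                      class = "news_corpus")
  validate_corpus(corpus)
  corpus
}

#' Validate a news corpus
#'
#' Checks the corpus invariants: non-empty unique article ids, every article's
#' period label present in the period table, every date inside its period's
#' range, and clean text (when present) free of uppercase letters.
#'
#' @param corpus A `news_corpus`.
#' @return `corpus`, invisibly; errors describe the first violation found.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "news_corpus"))
  a <- corpus$articles
  p <- corpus$periods
  if (nrow(a) == 0L) return(invisible(corpus))
  if (any(!nzchar(a$article_id))) stop("empty article_id", call. = FALSE)
  dup <- a$article_id[duplicated(a$article_id)]
  if (length(dup)) {
    stop("duplicate article id: ", dup[[1L]], call. = FALSE)
  }
  unknown <- setdiff(a$period, p$label)
  if (length(unknown)) {
    stop("article period label not in period table: ", unknown[[1L]],
         call. = FALSE)
  }
  idx <- match(a$period, p$label)
  off <- which(a$date < p$start_date[idx] | a$date > p$end_date[idx])
  if (length(off)) {
    stop("article ", a$article_id[off[[1L]]], " dated outside its period ",
         a$period[off[[1L]]], call. = FALSE)
  }
  cleaned <- !is.na(a$clean_text)
  if (any(grepl("[A-Z]", a$clean_text[cleaned]))) {
    stop("clean_text contains uppercase letters", call. = FALSE)
  }
  invisible(corpus)
}

#' @export
print.news_corpus <- function(x, ...) {
  cat("news_corpus:", nrow(x$articles), "articles,",
      nrow(x$periods), "periods\n")
  for (i in seq_len(nrow(x$periods))) {
    n <- sum(x$articles$period == x$periods$label[i])
    cat(sprintf("  %-12s %s to %s  (%d articles)\n", x$periods$label[i],
                format(x$periods$start_date[i]), format(x$periods$end_date[i]),
                n))
  }
  invisible(x)
}

#' Read a corpus from a JSON Lines file
#'
#' Each line is one JSON object holding one article. Field names are
#' configurable through `schema`; records are kept in file order.
#'
#' @param path Path to a UTF-8 JSON Lines file.
#' @param schema Named character vector mapping the canonical field names
#'   (`id`, `date`, `text`, and optionally `period`, `clean`) to the names
#'   used in the file.
#' @param periods Optional period table; if `NULL` and the file carries no
#'   period field, periods are inferred per calendar year.
#' @return A [news_corpus()].
#' @export
read_corpus <- function(path,
                        schema = c(id = "id", date = "date", text = "text",
                                   period = "period", clean = "clean_text"),
                        periods = NULL) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  get_field <- function(rec, key, line_no, required = TRUE) {
    nm <- if (key %in% names(schema)) schema[[key]] else key
    val <- rec[[nm]]
    if (is.null(val)) {
      if (required) {
        stop(sprintf("line %d: missing field '%s'", line_no, nm),
             call. = FALSE)
      }
      return(NA_character_)
    }
    as.character(val)
  }
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("malformed JSON on line %d: %s", i,
                                   conditionMessage(e)), call. = FALSE)
                    })
    recs[[i]] <- data.frame(
      article_id = get_field(rec, "id", i),
      date = get_field(rec, "date", i),
      period = get_field(rec, "period", i, required = FALSE),
      raw_text = get_field(rec, "text", i),
      clean_text = get_field(rec, "clean", i, required = FALSE),
      stringsAsFactors = FALSE)
  }
  articles <- if (n) do.call(rbind, recs) else
    data.frame(article_id = character(), date = as.Date(character()),
               period = character(), raw_text = character(),
               clean_text = character(), stringsAsFactors = FALSE)
  if (n) {
    dup <- articles$article_id[duplicated(articles$article_id)]
    if (length(dup)) stop("duplicate article id: ", dup[[1L]], call. = FALSE)
  }
  news_corpus(articles, periods = periods)
}

#' Write a corpus to a JSON Lines file
#'
#' One UTF-8 JSON object per line, in article order; a clean-text field is
#' emitted only when present. `read_corpus()` on the result reproduces the
#' corpus field for field.
#'
#' @param corpus A `news_corpus`.
#' @param path Output file path.
#' @return The number of records written, invisibly printed by callers.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "news_corpus"))
  a <- corpus$articles
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write corpus file: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  for (i in seq_len(nrow(a))) {
    rec <- list(id = a$article_id[i], date = format(a$date[i]),
                period = a$period[i], text = a$raw_text[i])
    if (!is.na(a$clean_text[i])) rec$clean_text <- a$clean_text[i]
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE)
    writeLines(line, con, useBytes = TRUE)
  }
  nrow(a)
}
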