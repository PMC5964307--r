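#' Percentage of articles mentioning any disease
#'
#' The disease-article rate for a period: 100 times the number of
#' disease-mentioning articles over the total number of articles, reported to
#' two decimals (the precision conventionally printed for such rates).
#'
#' @param n_disease_articles Number of articles mentioning any disease.
#' @param n_total_articles Total number of articles in the period (> 0).
#' @return A percentage rounded to 2 decimals.
#' @examples
#' disease_article_rate(3516, 806791)   # 0.44
#' @export
disease_article_rate <- function(n_disease_articles, n_total_articles) {
  if (length(n_total_articles) != 1L || n_total_articles <= 0) {
    stop("rate undefined: total article count must be positive",
         call. = FALSE)
  }
  if (n_disease_articles < 0 || n_disease_articles > n_total_articles) {
    stop("disease article count must lie in [0, total]", call. = FALSE)
  }
  round(100 * n_disease_articles / n_total_articles, 2)
}

#' Per-concept, per-period coverage percentages
#'
#' For every (concept, period) pair, the percentage of disease-mentioning
#' articles in that period that mention the concept. Concepts absent from a
#' period appear with zero counts so temporal trends are comparable across
#' the full concept set.
#'
#' @param concept_articles Named list: period label -> named list mapping
#'   phewas code -> character vector of article ids (as built from
#'   [articles_by_concept()] per period).
#' @param denominators Named integer vector: period label -> number of
#'   articles mentioning any disease in that period (all > 0).
#' @return Data frame with columns `phewas_code`, `period`, `n_articles`,
#'   `coverage_pct` (unrounded; round at report time).
#' @export
concept_coverage <- function(concept_articles, denominators) {
  periods <- names(concept_articles)
  if (is.null(periods) || is.null(names(denominators))) {
    stop("concept_articles and denominators must be named by period",
         call. = FALSE)
  }
  missing_den <- setdiff(periods, names(denominators))
  if (length(missing_den)) {
    stop("no denominator for period: ", missing_den[[1L]], call. = FALSE)
  }
  if (any(denominators[periods] <= 0)) {
    bad <- periods[denominators[periods] <= 0][[1L]]
    stop("zero denominator for period: ", bad, call. = FALSE)
  }
  concepts <- sort(unique(unlist(lapply(concept_articles, names))))
  rows <- expand.grid(phewas_code = concepts, period = periods,
                      stringsAsFactors = FALSE)
  rows$n_articles <- mapply(function(ph, pd) {
    length(unique(concept_articles[[pd]][[ph]]))
  }, rows$phewas_code, rows$period)
  rows$coverage_pct <- 100 * rows$n_articles /
    as.numeric(denominators[rows$period])
  rows <- rows[order(rows$phewas_code, match(rows$period, periods)), ]
  rownames(rows) <- NULL
  rows
}

#' Cumulative coverage share of a concept subset
#'
#' The percentage of a period's disease-mentioning articles accounted for by
#' a subset of concepts. Article sets are unioned, not summed, so an article
#' mentioning several of the concepts is counted once.
#'
#' @param concept_article_sets List of character vectors of article ids, one
#'   per concept in the subset (may be empty).
#' @param denominator Number of disease-mentioning articles in the period.
#' @return A percentage rounded to 2 decimals.
#' @export
cumulative_share <- function(concept_article_sets, denominator) {
  if (length(denominator) != 1L || denominator <= 0) {
    stop("denominator must be positive", call. = FALSE)
  }
  n <- length(unique(unlist(concept_article_sets)))
  round(100 * n / denominator, 2)
}

#' Mean and standard deviation of per-period coverages
#'
#' Cross-period location and spread of a concept's coverage percentages.
#' The standard deviation is the sample SD (n - 1 denominator) by default;
#' with only a handful of periods the convention is material, so the
#' population SD is available via `type`.
#'
#' @param pcts Numeric vector of per-period percentages (length >= 2).
#' @param type `"sample"` or `"population"`.
#' @return Named numeric vector `c(mean = ..., sd = ...)`, unrounded.
#' @export
mean_sd <- function(pcts, type = c("sample", "population")) {
  type <- match.arg(type)
  if (length(pcts) < 2L) {
    stop("mean_sd needs at least two period values", call. = FALSE)
  }
  m <- mean(pcts)
  s <- sd(pcts)
  if (type == "population") s <- s * sqrt((length(pcts) - 1) / length(pcts))
  c(mean = m, sd = s)
}

#' Classify a concept's temporal coverage trend
#'
#' Labels a chronological vector of per-period coverage percentages as
#' `increasing`, `decreasing`, `steady` or `fluctuating`. Monotone classes
#' are checked first: the series must rise (fall) at every step by more than
#' `rel_tol` relative change. Otherwise the series is `steady` when its
#' coefficient of variation (sample SD over mean) is at most `cv_threshold`,
#' and `fluctuating` when not. Both criteria are relative, so the class is
#' invariant to rescaling all values by a positive constant.
#'
#' @param pcts Numeric vector, one value per period in chronological order.
#' @param rel_tol Minimum relative step change for a monotone class.
#' @param cv_threshold Coefficient-of-variation bound for `steady`.
#' @return One of `"increasing"`, `"decreasing"`, `"steady"`,
#'   `"fluctuating"`.
#' @examples
#' classify_trend(c(2, 4, 8))            # increasing
#' classify_trend(c(22.2, 7.6, 31.5))    # fluctuating
#' @export
classify_trend <- function(pcts, rel_tol = 0.05, cv_threshold = 0.25) {
  stopifnot(is.numeric(pcts), length(pcts) >= 2L, all(pcts >= 0))
  prev <- pcts[-length(pcts)]
  nxt <- pcts[-1L]
  if (all(nxt > prev * (1 + rel_tol))) return("increasing")
  if (all(nxt < prev * (1 - rel_tol))) return("decreasing")
  m <- mean(pcts)
  if (m == 0) return("steady")
  cv <- sd(pcts) / m
  if (cv <= cv_threshold) "steady" else "fluctuating"
}
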