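#' Load a disease synonym lexicon
#'
#' Reads a two-column TSV (`synonym`, `cui`) mapping surface forms of disease
#' names to concept identifiers. Synonyms are lowercased and
#' whitespace-normalized on load; duplicate (synonym, cui) pairs are dropped.
#' A synonym may map to several CUIs.
#'
#' @param path Path to a TSV file with a header row `synonym<TAB>cui`.
#' @return An object of class `concept_lexicon`: a data frame with columns
#'   `synonym`, `cui`.
#' @export
load_lexicon <- function(path) {
  tab <- read_tsv_checked(path, c("synonym", "cui"))
  if (nrow(tab) == 0L) {
    warning("empty synonym lexicon: ", path, call. = FALSE)
  }
  tab$synonym <- squish(tolower(tab$synonym))
  tab$cui <- trimws(tab$cui)
  if (any(!nzchar(tab$synonym))) {
    stop("lexicon contains an empty synonym", call. = FALSE)
  }
  tab <- unique(tab)
  rownames(tab) <- NULL
  structure(tab, class = c("concept_lexicon", "data.frame"))
}

#' Load the CUI to ICD-9-CM to PheWAS mapping chain
#'
#' Two TSVs: `cui_icd_path` with columns (`cui`, `icd`) -- a multimap, one CUI
#' may map to several ICD-9-CM codes -- and `icd_phewas_path` with columns
#' (`icd`, `phewas`, `phewas_name`), single-valued per ICD code.
#'
#' @param cui_icd_path,icd_phewas_path TSV file paths with header rows.
#' @return An object of class `mapping_chain`: a list with data frames
#'   `cui_to_icd` and `icd_to_phewas`.
#' @export
load_chain <- function(cui_icd_path, icd_phewas_path) {
  cui_icd <- read_tsv_checked(cui_icd_path, c("cui", "icd"))
  icd_ph <- read_tsv_checked(icd_phewas_path, c("icd", "phewas", "phewas_name"))
  for (cn in names(cui_icd)) cui_icd[[cn]] <- trimws(cui_icd[[cn]])
  for (cn in names(icd_ph)) icd_ph[[cn]] <- trimws(icd_ph[[cn]])
  if (any(!nzchar(unlist(cui_icd))) || any(!nzchar(icd_ph$icd)) ||
      any(!nzchar(icd_ph$phewas))) {
    stop("mapping chain contains empty codes", call. = FALSE)
  }
  cui_icd <- unique(cui_icd)
  icd_ph <- unique(icd_ph)
  dup <- icd_ph$icd[duplicated(icd_ph$icd)]
  if (length(dup)) {
    stop("icd_to_phewas must be single-valued per ICD code; duplicated: ",
         dup[[1L]], call. = FALSE)
  }
  rownames(cui_icd) <- rownames(icd_ph) <- NULL
  structure(list(cui_to_icd = cui_icd, icd_to_phewas = icd_ph),
            class = "mapping_chain")
}

#' Resolve a synonym through the mapping chain
#'
#' Follows every path synonym -> CUI -> ICD-9-CM -> PheWAS and takes the union
#' of reachable PheWAS codes. A synonym is `definitive` when exactly one
#' PheWAS code is reachable (one-to-one or multiple-to-one), `ambiguous` when
#' two or more are, and `unmapped` when none is.
#'
#' @param synonym A synonym string (lowercased internally).
#' @param lexicon A [load_lexicon()] result.
#' @param chain A [load_chain()] result.
#' @return A list with `synonym`, `phewas_set` (character vector, sorted) and
#'   `mapping_class`.
#' @export
resolve_synonym <- function(synonym, lexicon, chain) {
  synonym <- squish(tolower(synonym))
  cuis <- lexicon$cui[lexicon$synonym == synonym]
  icds <- chain$cui_to_icd$icd[chain$cui_to_icd$cui %in% cuis]
  ph <- chain$icd_to_phewas$phewas[chain$icd_to_phewas$icd %in% icds]
  ph <- sort(unique(ph))
  cls <- if (length(ph) == 0L) "unmapped"
         else if (length(ph) == 1L) "definitive" else "ambiguous"
  list(synonym = synonym, phewas_set = ph, mapping_class = cls)
}

# Resolve every distinct synonym in the lexicon once; returns a named list of
# resolve_synonym() results keyed by synonym.
resolve_all <- function(lexicon, chain) {
  syns <- unique(lexicon$synonym)
  out <- lapply(syns, resolve_synonym, lexicon = lexicon, chain = chain)
  names(out) <- syns
  out
}

#' Fraction of definitively mapped synonyms
#'
#' Among synonyms whose mapping chain reaches at least one PheWAS code, the
#' fraction reaching exactly one. The complement bounds the error introduced
#' by ambiguous (one-to-multiple) mappings.
#'
#' @inheritParams resolve_synonym
#' @return A number in `[0, 1]`.
#' @export
definitive_fraction <- function(lexicon, chain) {
  if (nrow(lexicon) == 0L) stop("empty lexicon", call. = FALSE)
  res <- resolve_all(lexicon, chain)
  cls <- vapply(res, `[[`, character(1L), "mapping_class")
  mapped <- sum(cls != "unmapped")
  if (mapped == 0L) {
    stop("definitive fraction undefined: no synonym maps to any PheWAS code",
         call. = FALSE)
  }
  sum(cls == "definitive") / mapped
}

#' Find disease mentions in cleaned sentences
#'
#' Dictionary matching of lexicon synonyms against cleaned, lowercase
#' sentences. Matches are anchored at token boundaries (characters outside
#' `[a-z0-9_]`), longest-match-first with ties broken by leftmost start, and
#' non-overlapping within a sentence, so "cancer" is not also counted inside
#' "lung cancer". Multi-word synonyms match across single spaces.
#'
#' @param sentences Named list: article id -> character vector of cleaned
#'   sentences (as from [split_sentences()]).
#' @param lexicon A [load_lexicon()] result.
#' @param chain A [load_chain()] result.
#' @return A data frame of mentions with columns `article_id`,
#'   `sentence_index` (1-based), `start`, `end` (half-open character offsets,
#'   1-based start, `substr(sentence, start, end - 1)` is the matched text),
#'   `synonym`, `mapping_class`, and a list column `phewas_set`.
#' @export
find_mentions <- function(sentences, lexicon, chain) {
  stopifnot(is.list(sentences))
  res <- resolve_all(lexicon, chain)
  syns <- unique(lexicon$synonym)
  syns <- syns[order(-nchar(syns), syns)]
  pats <- paste0("(?<![a-z0-9_])", escape_regex(syns), "(?![a-z0-9_])")
  rows <- list()
  k <- 0L
  for (aid in names(sentences)) {
    sents <- sentences[[aid]]
    if (!length(sents)) next
    # cheap prefilter: skip articles (and synonyms) with no fixed-string hit
    whole <- paste(sents, collapse = " ")
    active <- which(vapply(syns, grepl, logical(1L), x = whole,
                           fixed = TRUE, USE.NAMES = FALSE))
    if (!length(active)) next
    for (si in seq_along(sents)) {
      sent <- sents[[si]]
      # collect all candidate matches of the active synonyms in this sentence
      cand_start <- integer(); cand_len <- integer(); cand_syn <- character()
      for (j in active) {
        m <- gregexpr(pats[j], sent, perl = TRUE)[[1L]]
        if (m[1L] == -1L) next
        cand_start <- c(cand_start, as.integer(m))
        cand_len <- c(cand_len, attr(m, "match.length"))
        cand_syn <- c(cand_syn, rep(syns[j], length(m)))
      }
      if (!length(cand_start)) next
      ord <- order(-cand_len, cand_start)
      taken <- logical(nchar(sent))
      for (ci in ord) {
        s <- cand_start[ci]; e <- s + cand_len[ci] - 1L
        if (any(taken[s:e])) next
        taken[s:e] <- TRUE
        r <- res[[cand_syn[ci]]]
        k <- k + 1L
        rows[[k]] <- list(article_id = aid, sentence_index = si,
                          start = s, end = e + 1L, synonym = cand_syn[ci],
                          mapping_class = r$mapping_class,
                          phewas_set = r$phewas_set)
      }
    }
  }
  if (!k) {
    return(data.frame(article_id = character(), sentence_index = integer(),
                      start = integer(), end = integer(),
                      synonym = character(), mapping_class = character(),
                      phewas_set = I(list()), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    article_id = vapply(rows, `[[`, character(1L), "article_id"),
    sentence_index = vapply(rows, `[[`, integer(1L), "sentence_index"),
    start = vapply(rows, `[[`, integer(1L), "start"),
    end = vapply(rows, `[[`, integer(1L), "end"),
    synonym = vapply(rows, `[[`, character(1L), "synonym"),
    mapping_class = vapply(rows, `[[`, character(1L), "mapping_class"),
    stringsAsFactors = FALSE)
  out$phewas_set <- I(lapply(rows, `[[`, "phewas_set"))
  # stable order: article, sentence, position
  out <- out[order(match(out$article_id, names(sentences)),
                   out$sentence_index, out$start), ]
  rownames(out) <- NULL
  out
}

#' Attribute articles to PheWAS concepts
#'
#' Builds the per-concept article sets used by the coverage statistics. Under
#' `definitive_only` (the default) only mentions whose synonym maps to exactly
#' one PheWAS code contribute to concept sets; under `expand_ambiguous` an
#' ambiguous mention contributes its article to every candidate concept. The
#' set of all disease-mentioning articles counts any article with at least one
#' mention of any mapping class.
#'
#' @param mentions A data frame from [find_mentions()].
#' @param policy `"definitive_only"` or `"expand_ambiguous"`.
#' @return A list with `concepts` (named list: phewas code -> character
#'   vector of article ids) and `all_articles` (character vector of article
#'   ids with any mention).
#' @export
articles_by_concept <- function(mentions, policy = c("definitive_only",
                                                     "expand_ambiguous")) {
  policy <- match.arg(policy)
  all_articles <- unique(mentions$article_id)
  concepts <- list()
  use <- if (policy == "definitive_only") {
    mentions$mapping_class == "definitive"
  } else {
    mentions$mapping_class != "unmapped"
  }
  midx <- which(use)
  for (i in midx) {
    for (ph in mentions$phewas_set[[i]]) {
      concepts[[ph]] <- c(concepts[[ph]], mentions$article_id[i])
    }
  }
  concepts <- lapply(concepts, unique)
  concepts <- concepts[order(names(concepts))]
  list(concepts = concepts, all_articles = all_articles)
}

# --- small shared helpers -------------------------------------------------

squish <- function(x) trimws(gsub("[[:space:]]+", " ", x))

# Strict TSV reader: header must name `cols` in order; every row must have
# exactly that many fields. Errors carry 1-based file line numbers.
read_tsv_checked <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(trimws(header), cols)) {
    stop(sprintf("line 1 of %s: expected header '%s'", path,
                 paste(cols, collapse = "\t")), call. = FALSE)
  }
  body <- lines[-1L]
  if (!length(body)) {
    out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(cols))
  if (length(bad)) {
    stop(sprintf("line %d of %s: expected %d tab-separated fields, found %d",
                 bad[[1L]] + 1L, path, length(cols),
                 lengths(fields)[bad[[1L]]]), call. = FALSE)
  }
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- cols
  out
}
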