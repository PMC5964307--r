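# Shared fixture builders. Everything is generated in code; file-based
# fixtures are written to tempfiles.

write_tsv_tmp <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(c(paste(names(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t"))),
             path)
  path
}

write_jsonl_tmp <- function(records) {
  path <- tempfile(fileext = ".jsonl")
  writeLines(vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE))
  }, character(1L)), path, useBytes = TRUE)
  path
}

# A tiny lexicon/chain pair covering one-to-one, multiple-to-one, ambiguous
# and unmapped synonyms plus nested multi-word names.
tiny_lexicon_files <- function() {
  lex <- data.frame(
    synonym = c("lung cancer", "cancer", "asthma", "flu", "bird flu",
                "mystery illness"),
    cui = c("C1", "C2", "C3", "C4", "C5", "C9"),
    stringsAsFactors = FALSE)
  cui_icd <- data.frame(
    cui = c("C1", "C2", "C2", "C3", "C4", "C5"),
    icd = c("162", "199a", "199b", "493", "487", "487b"),
    stringsAsFactors = FALSE)
  icd_ph <- data.frame(
    icd = c("162", "199a", "199b", "493", "487", "487b"),
    phewas = c("P162", "P199", "P239", "P493", "P487", "P487"),
    phewas_name = c("lung cancer", "other malignant neoplasm",
                    "uncertain neoplasm", "asthma", "influenza", "influenza"),
    stringsAsFactors = FALSE)
  list(lexicon = write_tsv_tmp(lex),
       cui_icd = write_tsv_tmp(cui_icd),
       icd_phewas = write_tsv_tmp(icd_ph))
}

tiny_lexicon <- function() {
  f <- tiny_lexicon_files()
  list(lexicon = load_lexicon(f$lexicon),
       chain = load_chain(f$cui_icd, f$icd_phewas))
}

# Random mapping chain for the definitive-fraction oracle property test.
random_chain_tables <- function(n_syn = 30L) {
  syn <- sprintf("syn%03d", seq_len(n_syn))
  cuis <- sprintf("CU%02d", 1:12)
  icds <- sprintf("I%02d", 1:15)
  phs <- sprintf("PH%d", 1:6)
  lex <- do.call(rbind, lapply(syn, function(s) {
    data.frame(synonym = s,
               cui = sample(cuis, sample(1:2, 1)),
               stringsAsFactors = FALSE)
  }))
  cui_icd <- do.call(rbind, lapply(cuis, function(cu) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    data.frame(cui = cu, icd = sample(icds, k), stringsAsFactors = FALSE)
  }))
  icd_ph <- data.frame(icd = icds,
                       phewas = sample(phs, length(icds), replace = TRUE),
                       phewas_name = "x", stringsAsFactors = FALSE)
  list(lexicon = unique(lex), cui_icd = unique(cui_icd), icd_phewas = icd_ph)
}

# Independent path-enumeration oracle for the definitive-mapping fraction:
# explicit nested loops over every (synonym, cui, icd, phewas) path.
oracle_definitive_fraction <- function(lex, cui_icd, icd_ph) {
  syns <- unique(lex$synonym)
  n_ph <- vapply(syns, function(s) {
    phs <- character(0)
    for (i in which(lex$synonym == s)) {
      cu <- lex$cui[i]
      for (j in which(cui_icd$cui == cu)) {
        ic <- cui_icd$icd[j]
        for (k in which(icd_ph$icd == ic)) {
          phs <- c(phs, icd_ph$phewas[k])
        }
      }
    }
    length(unique(phs))
  }, integer(1L))
  if (!any(n_ph >= 1L)) return(NA_real_)
  sum(n_ph == 1L) / sum(n_ph >= 1L)
}

# Best-permutation mean cosine between planted and fitted topic matrices
# (K x V each), enumerating all K! topic alignments.
best_perm_cosine <- function(phi_true, phi_hat) {
  K <- nrow(phi_true)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  max(vapply(perms(seq_len(K)), function(p) {
    mean(vapply(seq_len(K), function(t) {
      cosine(phi_true[t, ], phi_hat[p[t], ])
    }, numeric(1L)))
  }, numeric(1L)))
}
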