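#' Mine multiword-expression candidates by TF-IDF
#'
#' Ranks the bigrams and trigrams of a weakly labeled corpus by TF-IDF,
#' where term frequency is the raw n-gram count within a domain's
#' megadocument and document frequency is the number of megadocuments
#' containing the n-gram: `tfidf = tf * ln(D / (1 + df))` with `D` the
#' number of megadocuments. The output is a human-review artifact;
#' accepted candidates are merged into the lexicon as keyphrases with
#' [accept_mwes()].
#'
#' @param labeled an `rd_corpus` with a `label` column.
#' @param n_range n-gram sizes, default bigrams and trigrams.
#' @param top_k number of candidates kept per domain (>= 1).
#' @return data frame with columns `domain`, `ngram`, `tf`, `df`,
#'   `tfidf`, sorted by descending score within each domain.
#' @export
mine_mwe_candidates <- function(labeled, n_range = c(2L, 3L), top_k = 50L) {
  stopifnot(inherits(labeled, "rd_corpus"), !is.null(labeled$label))
  if (length(top_k) != 1L || top_k < 1L) {
    stop("top_k must be a positive integer", call. = FALSE)
  }
  if (is.null(labeled$tokens)) labeled <- tokenize_corpus(labeled)
  mds <- split(labeled$tokens, labeled$label)
  # per-domain n-gram counts
  counts <- lapply(mds, function(toklists) {
    grams <- unlist(lapply(toklists, function(t) ngrams(t, n_range)))
    if (!length(grams)) return(integer(0))
    table(grams)
  })
  vocab <- unique(unlist(lapply(counts, names)))
  if (!length(vocab)) {
    return(data.frame(domain = character(0), ngram = character(0),
                      tf = integer(0), df = integer(0), tfidf = numeric(0)))
  }
  present <- vapply(counts, function(ct) vocab %in% names(ct),
                    logical(length(vocab)))
  df <- rowSums(matrix(present, nrow = length(vocab)))
  names(df) <- vocab
  ndocs <- length(counts)
  out <- do.call(rbind, lapply(names(counts), function(d) {
    ct <- counts[[d]]
    if (!length(ct)) return(NULL)
    tf <- as.integer(ct)
    g <- names(ct)
    tfidf <- tf * log(ndocs / (1 + df[g]))
    # with a single megadocument the idf is one negative constant and
    # tf*idf would invert the frequency order; ranking then reduces to
    # raw frequency
    o <- if (ndocs == 1L) order(-tf, g) else order(-tfidf, g)
    utils::head(data.frame(domain = d, ngram = g[o], tf = tf[o],
                           df = as.integer(df[g][o]),
                           tfidf = as.numeric(tfidf[o]),
                           stringsAsFactors = FALSE, row.names = NULL),
                top_k)
  }))
  rownames(out) <- NULL
  out
}

ngrams <- function(toks, n_range) {
  nt <- length(toks)
  unlist(lapply(n_range, function(n) {
    if (nt < n) return(character(0))
    starts <- seq_len(nt - n + 1L)
    vapply(starts, function(s) paste(toks[s:(s + n - 1L)], collapse = " "),
           character(1))
  }))
}

#' Merge multiword expressions into single tokens
#'
#' Replaces every contiguous occurrence of a keyphrase by one
#' underscore-joined token, scanning left to right and preferring
#' longer phrases (trigrams before bigrams) at each position; matches
#' never overlap. Merged tokens are exempt from stemming, so MWEs enter
#' the vector space as non-stemmed unigrams. The operation is
#' idempotent: merged tokens contain underscores and can never match a
#' keyphrase again.
#'
#' @param tokens character vector of normalized tokens.
#' @param keyphrases list of token vectors (or character vector of
#'   space-separated phrases).
#' @return character vector of tokens with MWEs merged.
#' @examples
#' merge_mwes(c("linear", "thinking", "and", "flight", "of", "ideas"),
#'            list(c("linear", "thinking")))
#' @export
merge_mwes <- function(tokens, keyphrases) {
  if (!length(tokens) || !length(keyphrases)) return(tokens)
  if (is.character(keyphrases)) {
    keyphrases <- strsplit(keyphrases, " ", fixed = TRUE)
  }
  keys <- new.env(parent = emptyenv())
  maxlen <- 0L
  for (kp in keyphrases) {
    assign(paste(kp, collapse = " "), TRUE, envir = keys)
    maxlen <- max(maxlen, length(kp))
  }
  out <- character(0)
  i <- 1L
  nt <- length(tokens)
  while (i <= nt) {
    matched <- FALSE
    for (n in seq(min(maxlen, nt - i + 1L), 2L)) {
      if (n < 2L) break
      key <- paste(tokens[i:(i + n - 1L)], collapse = " ")
      if (exists(key, envir = keys, inherits = FALSE)) {
        out <- c(out, gsub(" ", "_", key, fixed = TRUE))
        i <- i + n
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  out
}

#' Apply MWE merging and stemming to a corpus
#'
#' Adds `merged` (tokens after MWE merging) and `stemmed` (Porter-
#' stemmed tokens, merged MWEs exempt) list-columns. Merging runs
#' before stemming so that keyphrases match surface forms.
#'
#' @param corpus an `rd_corpus` (tokenized automatically if needed).
#' @param lexicon an `rd_lexicon` supplying the accepted keyphrases, or
#'   `NULL` to skip merging (stems only).
#' @return the corpus with `merged` and `stemmed` columns.
#' @export
preprocess_corpus <- function(corpus, lexicon = NULL) {
  stopifnot(inherits(corpus, "rd_corpus"))
  if (is.null(corpus$tokens)) corpus <- tokenize_corpus(corpus)
  kp <- if (!is.null(lexicon)) lexicon_keyphrase_tokens(lexicon) else list()
  merged <- lapply(corpus$tokens, merge_mwes, keyphrases = kp)
  corpus$merged <- I(merged)
  corpus$stemmed <- I(lapply(merged, stem_tokens))
  corpus
}
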