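#' Weakly label a corpus with a domain lexicon
#'
#' A sentence is matched to domain D when it contains one of D's
#' keywords as a whole token, or one of D's keyphrases as a contiguous
#' token span. Sentences matching no domain are excluded; sentences
#' matching two or more domains are also excluded so that every
#' training sentence carries exactly one label and megadocuments stay
#' clean (the single-label construction is a deliberate property of the
#' weak-supervision design, not of the annotation scheme).
#'
#' @param corpus an `rd_corpus`; tokenized automatically if needed.
#' @param lexicon an `rd_lexicon`.
#' @param use_mwes if `FALSE`, keyphrases are ignored and only keywords
#'   match (for ablation of the MWE contribution).
#' @return an `rd_corpus` restricted to matched sentences, with a
#'   `label` column (single domain per sentence). The excluded
#'   sentences are attached as `attr(, "excluded")`, a data frame with
#'   columns `id` and `reason` (`"no_match"` or `"ambiguous"`).
#' @export
match_sentences <- function(corpus, lexicon, use_mwes = TRUE) {
  stopifnot(inherits(corpus, "rd_corpus"), inherits(lexicon, "rd_lexicon"))
  if (is.null(corpus$tokens)) corpus <- tokenize_corpus(corpus)
  domains <- names(lexicon$entries)
  kw <- lapply(lexicon$entries, `[[`, "keywords")
  kp <- lapply(lexicon$entries, function(e) {
    if (use_mwes) strsplit(e$keyphrases, " ", fixed = TRUE) else list()
  })
  hits <- lapply(corpus$tokens, function(toks) {
    if (!length(toks)) return(character(0))
    found <- vapply(domains, function(d) {
      if (any(toks %in% kw[[d]])) return(TRUE)
      for (phrase in kp[[d]]) {
        if (has_span(toks, phrase)) return(TRUE)
      }
      FALSE
    }, logical(1))
    domains[found]
  })
  nhit <- lengths(hits)
  keep <- nhit == 1L
  labeled <- corpus[keep, , drop = FALSE]
  labeled$label <- vapply(hits[keep], identity, character(1))
  class(labeled) <- class(corpus)
  excl <- data.frame(
    id = corpus$id[!keep],
    reason = ifelse(nhit[!keep] == 0L, "no_match", "ambiguous"),
    stringsAsFactors = FALSE
  )
  attr(labeled, "excluded") <- excl
  labeled
}

# contiguous-span containment of `phrase` (token vector) in `toks`
has_span <- function(toks, phrase) {
  np <- length(phrase); nt <- length(toks)
  if (np > nt) return(FALSE)
  starts <- which(toks == phrase[1L])
  starts <- starts[starts <= nt - np + 1L]
  for (s in starts) {
    if (all(toks[s:(s + np - 1L)] == phrase)) return(TRUE)
  }
  FALSE
}

#' Group a weakly labeled corpus into per-domain megadocuments
#'
#' A megadocument is the concatenation of all training sentences of one
#' domain; it is the document unit for TF-IDF mining, the aggregation
#' unit for the cosine baseline, and the clustering unit for RBF
#' prototype selection. Every labeled sentence belongs to exactly one
#' megadocument.
#'
#' @param labeled an `rd_corpus` with a single-label `label` column, as
#'   returned by [match_sentences()].
#' @return a named list (one element per domain present) of
#'   `rd_corpus` objects; class `rd_megadocs`.
#' @export
build_megadocuments <- function(labeled) {
  stopifnot(inherits(labeled, "rd_corpus"), !is.null(labeled$label))
  assert_domains(labeled$label, allow_other = FALSE)
  idx <- split(seq_len(nrow(labeled)), labeled$label)
  out <- lapply(idx, function(i) {
    md <- labeled[i, , drop = FALSE]
    class(md) <- class(labeled)
    md
  })
  structure(out, class = "rd_megadocs")
}

#' @export
print.rd_megadocs <- function(x, ...) {
  cat("<rd_megadocs>\n")
  for (d in names(x)) cat(sprintf("  %-15s %5d sentences\n", d, nrow(x[[d]])))
  invisible(x)
}
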