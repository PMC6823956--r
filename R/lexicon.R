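#' Domain lexicons
#'
#' A domain lexicon maps each of the seven risk factor domains to the
#' clinician-curated single-token keywords and 2-3 token keyphrases
#' (multiword expressions) used for weak supervision. Strings are
#' normalized with the package tokenizer, so matching is case- and
#' punctuation-insensitive.
#'
#' @param entries named list; one element per domain, each a list with
#'   character vectors `keywords` and `keyphrases`.
#' @return an object of class `rd_lexicon`.
#' @examples
#' lex <- domain_lexicon(list(
#'   Substance = list(keywords = c("cocaine", "marijuana", "etoh"),
#'                    keyphrases = "substance abuse"),
#'   Mood = list(keywords = c("depressed", "anxious"),
#'               keyphrases = c("panic attack", "mood swings"))
#' ))
#' lex
#' @export
domain_lexicon <- function(entries) {
  stopifnot(is.list(entries), length(entries) >= 1)
  assert_domains(names(entries), allow_other = FALSE)
  norm1 <- function(x) {
    toks <- tokenize_text(as.character(x))
    vapply(toks, paste, character(1), collapse = " ")
  }
  entries <- lapply(entries, function(e) {
    kw <- unique(norm1(e$keywords %||% character(0)))
    kp <- unique(norm1(e$keyphrases %||% character(0)))
    kw <- kw[nzchar(kw)]
    kp <- kp[nzchar(kp)]
    if (any(grepl(" ", kw))) {
      stop("keywords must be single tokens", call. = FALSE)
    }
    nt <- lengths(strsplit(kp, " ", fixed = TRUE))
    if (any(nt < 2 | nt > 3)) {
      stop("keyphrases must have 2 or 3 tokens", call. = FALSE)
    }
    if (!length(kw) && !length(kp)) {
      stop("empty lexicon entry", call. = FALSE)
    }
    list(keywords = kw, keyphrases = kp)
  })
  structure(list(entries = entries), class = "rd_lexicon")
}

#' @export
print.rd_lexicon <- function(x, ...) {
  cat("<rd_lexicon>\n")
  for (d in names(x$entries)) {
    e <- x$entries[[d]]
    cat(sprintf("  %-15s %3d keywords, %3d keyphrases\n", d,
                length(e$keywords), length(e$keyphrases)))
  }
  invisible(x)
}

#' Read and write domain lexicons
#'
#' Two on-disk dialects: JSON (`domain -> {"keywords": [...],
#' "keyphrases": [...]}`) and a two-column TSV (`domain`, `phrase`)
#' where multi-token phrases are treated as keyphrases.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"` or `"tsv"`.
#' @return an `rd_lexicon`.
#' @export
read_lexicon <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path)) "tsv" else "json"
  }
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    entries <- lapply(raw, function(e) {
      list(keywords = as.character(e$keywords %||% character(0)),
           keyphrases = as.character(e$keyphrases %||% character(0)))
    })
    return(domain_lexicon(entries))
  }
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 2)
  names(tab)[1:2] <- c("domain", "phrase")
  entries <- lapply(split(tab$phrase, tab$domain), function(ph) {
    nt <- lengths(tokenize_text(ph))
    list(keywords = ph[nt == 1], keyphrases = ph[nt >= 2])
  })
  domain_lexicon(entries)
}

#' @rdname read_lexicon
#' @param lexicon an `rd_lexicon`.
#' @export
write_lexicon <- function(lexicon, path, format = c("auto", "json", "tsv")) {
  stopifnot(inherits(lexicon, "rd_lexicon"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path)) "tsv" else "json"
  }
  if (format == "json") {
    jsonlite::write_json(lexicon$entries, path, auto_unbox = FALSE,
                         pretty = TRUE)
  } else {
    rows <- do.call(rbind, lapply(names(lexicon$entries), function(d) {
      e <- lexicon$entries[[d]]
      data.frame(domain = d, phrase = c(e$keywords, e$keyphrases),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Merge accepted MWE candidates into a lexicon
#'
#' Models the human-review step of MWE mining as an accept list: the
#' accepted bigrams/trigrams become keyphrases of their domain.
#'
#' @param lexicon an `rd_lexicon`.
#' @param accepted data frame with columns `domain` and `ngram`
#'   (space-separated), e.g. a filtered result of
#'   [mine_mwe_candidates()].
#' @return the updated `rd_lexicon`.
#' @export
accept_mwes <- function(lexicon, accepted) {
  stopifnot(inherits(lexicon, "rd_lexicon"),
            all(c("domain", "ngram") %in% names(accepted)))
  entries <- lexicon$entries
  for (d in unique(accepted$domain)) {
    add <- accepted$ngram[accepted$domain == d]
    if (is.null(entries[[d]])) {
      entries[[d]] <- list(keywords = character(0), keyphrases = character(0))
    }
    entries[[d]]$keyphrases <- unique(c(entries[[d]]$keyphrases, add))
  }
  domain_lexicon(entries)
}

# keyphrases of a lexicon as token sequences, optionally per domain
lexicon_keyphrase_tokens <- function(lexicon) {
  kp <- unique(unlist(lapply(lexicon$entries, `[[`, "keyphrases")))
  strsplit(kp, " ", fixed = TRUE)
}
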