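#' Normalize and tokenize clinical sentences
#'
#' Lowercases, strips punctuation and splits on whitespace. Characters
#' that carry clinical meaning inside a token (`/`, `-`, `+`, as in
#' `SI/HI`, `goal-directed`, `A+Ox3`) are preserved when internal and
#' stripped when leading or trailing. Tokenization is deterministic;
#' empty or whitespace-only input yields an empty token list.
#'
#' @param text character vector of raw sentences.
#' @return a list of character vectors, one per input sentence.
#' @examples
#' tokenize_text("No SI, No HI, No hallucinations")
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text))
  text <- tolower(text)
  text <- gsub("[^a-z0-9/+-]+", " ", text)
  toks <- strsplit(trimws(text), " +")
  lapply(toks, function(t) {
    if (length(t) == 1L && !nzchar(t)) return(character(0))
    t <- gsub("^[/+-]+|[/+-]+$", "", t)
    t[nzchar(t)]
  })
}

#' Tokenize a sentence corpus
#'
#' Adds a `tokens` list-column to a corpus (see [as_corpus()]).
#'
#' @param corpus an `rd_corpus`.
#' @return the corpus with a `tokens` column.
#' @export
tokenize_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "rd_corpus"))
  corpus$tokens <- I(tokenize_text(corpus$text))
  corpus
}
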