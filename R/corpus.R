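#' Sentence corpora
#'
#' A corpus is a data frame with class `rd_corpus`: one row per
#' sentence, columns `id` and `text`, plus list-columns added by the
#' pipeline (`tokens`, `merged`, `stemmed`, `labels`). Input is assumed
#' pre-split into sentences, matching the sentence-level design of the
#' annotation task.
#'
#' @param text character vector of sentences.
#' @param id optional ids; defaults to `s1, s2, ...`.
#' @param labels optional list of character vectors of domain labels
#'   (gold corpora; ordered by prevalence, `Other` allowed).
#' @return an `rd_corpus` data frame.
#' @export
as_corpus <- function(text, id = NULL, labels = NULL) {
  stopifnot(is.character(text))
  if (is.null(id)) id <- paste0("s", seq_along(text))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate sentence ids", call. = FALSE)
  if (length(id) != length(text)) stop("id/text length mismatch", call. = FALSE)
  out <- data.frame(id = id, text = text, stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(text))
    labels <- lapply(labels, as.character)
    for (l in labels) assert_domains(l)
    out$labels <- I(labels)
  }
  class(out) <- c("rd_corpus", "data.frame")
  out
}

#' @export
print.rd_corpus <- function(x, n = 6L, ...) {
  cat(sprintf("<rd_corpus: %d sentences%s>\n", nrow(x),
              if (!is.null(x$labels)) ", labeled" else ""))
  show <- utils::head(x, n)
  for (i in seq_len(nrow(show))) {
    lab <- if (!is.null(show$labels)) {
      paste0(" [", paste(show$labels[[i]], collapse = ","), "]")
    } else if (!is.null(show$label)) {
      paste0(" [", show$label[i], "]")
    } else ""
    cat(sprintf("  %s%s: %s\n", show$id[i], lab,
                substr(show$text[i], 1, 60)))
  }
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' Read and write sentence corpora
#'
#' JSONL corpora have one object per line with fields `id`, `text` and
#' optionally `labels` (an array of domain names). Plain-text corpora
#' are one sentence per line and receive automatic ids.
#'
#' @param path file path.
#' @param format `"jsonl"`, `"txt"`, or `"auto"` (by extension).
#' @return an `rd_corpus`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "txt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path)) "jsonl" else "txt"
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "txt") return(as_corpus(lines))
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  ids <- vapply(recs, function(r) as.character(r$id %||% NA_character_),
                character(1))
  if (anyNA(ids)) ids <- paste0("s", seq_along(recs))
  text <- vapply(recs, function(r) as.character(r$text), character(1))
  labels <- NULL
  if (any(vapply(recs, function(r) !is.null(r$labels), logical(1)))) {
    labels <- lapply(recs, function(r) as.character(r$labels %||% character(0)))
  }
  as_corpus(text, ids, labels)
}

#' @rdname read_corpus
#' @param corpus an `rd_corpus` to write (JSONL; includes `labels` or a
#'   weak `label` column when present).
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "rd_corpus"))
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(id = corpus$id[i], text = corpus$text[i])
    if (!is.null(corpus$labels)) {
      rec$labels <- corpus$labels[[i]]
    } else if (!is.null(corpus$label)) {
      rec$labels <- corpus$label[i]
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
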