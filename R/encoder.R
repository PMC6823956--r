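#' Sentence encoders
#'
#' Encoders turn sentences into fixed-width real vectors. Two kinds are
#' supported behind one contract:
#'
#' * `hash_encoder()` — a deterministic, fully offline bag-of-tokens
#'   encoder: each token is hashed (together with the seed) to a
#'   reproducible pattern of +1/-1 over the `dimension` slots, token
#'   vectors are summed and the result L2-normalized. Random signed
#'   projections of this kind make sentences sharing no tokens nearly
#'   orthogonal at moderate dimension, which is the property the
#'   downstream models need. It consumes merged+stemmed tokens. By
#'   default tokens are weighted by smoothed inverse document
#'   frequency fitted on a reference corpus with [fit_idf()]
#'   (`log((1 + N) / (1 + df)) + 1`, the vector-space convention this
#'   family of similarity models descends from), so frequent
#'   quotidian tokens contribute little and rare clinical tokens --
#'   including merged multiword expressions -- dominate the sentence
#'   vector. Until `fit_idf()` is called (or with
#'   `weighting = "none"`) all tokens weigh 1.
#' * `pretrained_encoder()` — an adapter wrapping any external
#'   sentence-embedding function (e.g. a 512-dimensional pretrained
#'   universal sentence encoder). The adapter receives raw text; its
#'   internals are out of scope for this package.
#'
#' @param dimension embedding width (default 512; at least 8 for the
#'   hashed encoder).
#' @param seed integer controlling the hashed token patterns.
#' @param weighting `"idf"` (apply inverse-document-frequency weights
#'   once fitted) or `"none"`.
#' @return an `rd_encoder` object.
#' @examples
#' enc <- hash_encoder(dimension = 64, seed = 1)
#' X <- encode_sentences(as_corpus(c("no si no hi", "used marijuana")), enc)
#' dim(X)
#' @export
hash_encoder <- function(dimension = 512L, seed = 1L,
                         weighting = c("idf", "none")) {
  stopifnot(dimension >= 8L)
  structure(list(kind = "hashed_fallback", dimension = as.integer(dimension),
                 seed = as.integer(seed), weighting = match.arg(weighting),
                 idf = NULL),
            class = "rd_encoder")
}

#' Fit inverse-document-frequency weights on a reference corpus
#'
#' Computes smoothed IDF weights `log((1 + N) / (1 + df)) + 1` over
#' the sentences of a corpus (document = sentence) and stores them in
#' the encoder. Tokens unseen in the reference corpus receive the
#' maximum weight `log(1 + N) + 1`. The reference corpus is normally
#' the weakly labeled training corpus, so train and test sentences are
#' embedded in the same weighted space.
#'
#' @param encoder a hashed `rd_encoder`.
#' @param corpus an `rd_corpus` (or list of token vectors).
#' @return the encoder with fitted `idf` weights.
#' @export
fit_idf <- function(encoder, corpus) {
  stopifnot(inherits(encoder, "rd_encoder"),
            encoder$kind == "hashed_fallback")
  toklists <- if (inherits(corpus, "rd_corpus")) {
    if (is.null(corpus$tokens)) corpus <- tokenize_corpus(corpus)
    corpus$stemmed %||% corpus$merged %||% corpus$tokens
  } else corpus
  N <- length(toklists)
  df <- table(unlist(lapply(toklists, unique)))
  w <- log((1 + N) / (1 + as.numeric(df))) + 1
  encoder$idf <- stats::setNames(w, names(df))
  encoder$idf_default <- log(1 + N) + 1
  encoder
}

#' @rdname hash_encoder
#' @param fun function mapping a character vector of raw sentences to a
#'   numeric matrix with `dimension` columns.
#' @export
pretrained_encoder <- function(fun, dimension = 512L) {
  stopifnot(is.function(fun), dimension >= 1L)
  structure(list(kind = "pretrained_adapter", dimension = as.integer(dimension),
                 fun = fun),
            class = "rd_encoder")
}

#' @export
print.rd_encoder <- function(x, ...) {
  cat(sprintf("<rd_encoder: %s, dimension %d>\n", x$kind, x$dimension))
  invisible(x)
}

#' Embed one token list with the hashed encoder
#'
#' Sums the signed hash vectors of the tokens and L2-normalizes. The
#' empty token list yields the zero vector, flagged via
#' `attr(, "degenerate")`.
#'
#' @param tokens character vector.
#' @param dimension embedding width (>= 8).
#' @param seed integer seed.
#' @return numeric vector of length `dimension`.
#' @export
fallback_embed <- function(tokens, dimension = 512L, seed = 1L) {
  enc <- hash_encoder(dimension, seed)
  m <- encode_token_lists(list(tokens), enc)
  v <- m[1L, ]
  attr(v, "degenerate") <- attr(m, "degenerate")[1L]
  v
}

#' Encode a corpus into an embedding matrix
#'
#' One row per sentence; row names are sentence ids. The hashed
#' encoder consumes the most processed token column available
#' (`stemmed`, then `merged`, then `tokens`); a pretrained adapter
#' consumes raw text.
#'
#' @param corpus an `rd_corpus` (or a list of token vectors).
#' @param encoder an `rd_encoder`.
#' @return numeric matrix, `nrow(corpus)` x `encoder$dimension`, with a
#'   logical `degenerate` attribute marking zero-norm (empty) rows.
#' @export
encode_sentences <- function(corpus, encoder) {
  stopifnot(inherits(encoder, "rd_encoder"))
  if (encoder$kind == "pretrained_adapter") {
    if (!inherits(corpus, "rd_corpus")) {
      stop("the pretrained adapter requires an rd_corpus with raw text",
           call. = FALSE)
    }
    X <- encoder$fun(corpus$text)
    if (!is.matrix(X) || ncol(X) != encoder$dimension ||
        nrow(X) != nrow(corpus)) {
      stop("adapter returned a malformed embedding matrix", call. = FALSE)
    }
    rownames(X) <- corpus$id
    attr(X, "degenerate") <- rowSums(X != 0) == 0
    return(X)
  }
  if (inherits(corpus, "rd_corpus")) {
    if (is.null(corpus$tokens)) corpus <- tokenize_corpus(corpus)
    toklists <- corpus$stemmed %||% corpus$merged %||% corpus$tokens
    ids <- corpus$id
  } else {
    toklists <- corpus
    ids <- NULL
  }
  X <- encode_token_lists(toklists, encoder)
  rownames(X) <- ids
  X
}

encode_token_lists <- function(toklists, encoder) {
  d <- encoder$dimension
  use_idf <- identical(encoder$weighting, "idf") && !is.null(encoder$idf)
  idf <- encoder$idf
  idf_default <- encoder$idf_default
  cache <- new.env(parent = emptyenv())
  X <- matrix(0, nrow = length(toklists), ncol = d)
  degen <- logical(length(toklists))
  with_seed(encoder$seed, {
    for (i in seq_along(toklists)) {
      toks <- toklists[[i]]
      if (!length(toks)) {
        degen[i] <- TRUE
        next
      }
      v <- numeric(d)
      for (tok in toks) {
        tv <- get0(tok, envir = cache, inherits = FALSE)
        if (is.null(tv)) {
          set.seed(token_seed(tok, encoder$seed))
          tv <- sample(c(-1, 1), d, replace = TRUE)
          assign(tok, tv, envir = cache)
        }
        w <- 1
        if (use_idf) w <- idf[tok] %|na|% idf_default
        v <- v + w * tv
      }
      X[i, ] <- l2_normalize(v)
    }
  })
  attr(X, "degenerate") <- degen
  X
}
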