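test_that("MWE merging replaces contiguous spans with underscore tokens", {
  expect_equal(
    merge_mwes(c("linear", "thinking", "and", "flight", "of", "ideas"),
               list(c("linear", "thinking"))),
    c("linear_thinking", "and", "flight", "of", "ideas"))
  expect_equal(merge_mwes(c("no", "hits", "here"), list(c("panic", "attack"))),
               c("no", "hits", "here"))
  expect_equal(merge_mwes(character(0), list(c("a", "b"))), character(0))
})

test_that("merging is leftmost-first, longest-first and non-overlapping", {
  # overlapping candidates: leftmost wins
  expect_equal(merge_mwes(c("a", "b", "c"), list(c("a", "b"), c("b", "c"))),
               c("a_b", "c"))
  # trigram beats its bigram prefix at the same position
  expect_equal(merge_mwes(c("a", "b", "c"), list(c("a", "b"), c("a", "b", "c"))),
               "a_b_c")
  # repeated occurrences all merge
  expect_equal(merge_mwes(c("a", "b", "x", "a", "b"), list(c("a", "b"))),
               c("a_b", "x", "a_b"))
})

test_that("merging is idempotent and sound on generated corpora", {
  set.seed(11)
  bundle <- generate_bundle(synth_config(n_train = 80, n_test = 10, seed = 11))
  kp <- lapply(unlist(lapply(bundle$lexicon$entries, `[[`, "keyphrases")),
               function(p) strsplit(p, " ")[[1]])
  for (i in seq_len(40)) {
    toks <- tokenize_text(bundle$train$text[i])[[1]]
    once <- merge_mwes(toks, kp)
    expect_identical(merge_mwes(once, kp), once)
    # soundness: each merged token splits back into a contiguous span
    for (m in grep("_", once, fixed = TRUE, value = TRUE)) {
      parts <- strsplit(m, "_", fixed = TRUE)[[1]]
      expect_true(riskdomains:::has_span(toks, parts))
    }
  }
})

test_that("TF-IDF mining ranks a domain-specific bigram above ubiquitous ones", {
  text <- character(0); labels <- character(0)
  doms <- risk_domains()
  for (d in doms) {
    n <- if (d == "Mood") 30L else 5L
    for (i in seq_len(n)) {
      s <- if (d == "Mood") paste(paste0("v", i), "panic attack",
                                  paste0("u", i), "common filler")
           else paste("routine", tolower(d), paste0("w", i), "common filler")
      text <- c(text, s); labels <- c(labels, d)
    }
  }
  corp <- tokenize_corpus(as_corpus(text))
  corp$label <- labels
  cand <- mine_mwe_candidates(corp, top_k = 500L)
  mood <- cand[cand$domain == "Mood", ]
  expect_equal(mood$ngram[1], "panic attack")
  # "common filler" occurs in all 7 megadocuments -> negative idf
  expect_true(mood$tfidf[mood$ngram == "panic attack"] >
                mood$tfidf[mood$ngram == "common filler"])
})

test_that("single-domain corpus reduces ranking to raw frequency", {
  corp <- tokenize_corpus(as_corpus(c("a b a b", "a b c", "c d")))
  corp$label <- rep("Substance", 3)
  cand <- mine_mwe_candidates(corp, n_range = 2L, top_k = 5L)
  expect_equal(cand$ngram[1], "a b")
  expect_true(all(diff(cand$tf) <= 0))
  # idf is one constant across all candidates in this degenerate case
  expect_equal(length(unique(round(cand$tfidf / cand$tf, 12))), 1L)
})

test_that("top_k is validated and short sentences yield no n-grams", {
  corp <- tokenize_corpus(as_corpus("a"))
  corp$label <- "Mood"
  expect_error(mine_mwe_candidates(corp, top_k = 0), "positive")
  expect_equal(nrow(mine_mwe_candidates(corp, top_k = 5)), 0L)
})

test_that("mining matches a brute-force TF-IDF enumeration on small corpora", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 40L
    labels <- sample(risk_domains(), n, replace = TRUE)
    toklists <- lapply(seq_len(n), function(i) {
      sample(letters[1:8], sample(4:9, 1), replace = TRUE)
    })
    corp <- as_corpus(vapply(toklists, paste, character(1), collapse = " "))
    corp <- tokenize_corpus(corp)
    corp$label <- labels
    got <- mine_mwe_candidates(corp, top_k = 1000L)
    want <- oracle_tfidf(toklists, labels)
    for (d in unique(labels)) {
      g <- got[got$domain == d, ]
      w <- want[want$domain == d, ]
      expect_equal(nrow(g), nrow(w))
      ord <- match(g$ngram, w$ngram)
      expect_false(anyNA(ord))
      expect_equal(g$tf, w$tf[ord])
      expect_equal(g$tfidf, unname(w$tfidf[ord]), tolerance = 1e-12)
      # descending score order within the domain
      expect_true(all(diff(g$tfidf) <= 1e-12))
    }
  }
})
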