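test_that("regeneration with the same config is identical", {
  cfg <- synth_config(n_train = 120, n_test = 40, seed = 99)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$train$text, b2$train$text)
  expect_identical(b1$test$text, b2$test$text)
  expect_identical(b1$lexicon$entries, b2$lexicon$entries)
  expect_identical(b1$annotations$annotations, b2$annotations$annotations)
  # a different seed changes the corpus
  b3 <- generate_bundle(synth_config(n_train = 120, n_test = 40, seed = 100))
  expect_false(identical(b1$train$text, b3$train$text))
})

test_that("zero overlap gives pairwise disjoint domain vocabularies", {
  b <- generate_bundle(synth_config(n_train = 20, n_test = 10, overlap = 0,
                                    seed = 2))
  v <- b$vocabularies
  for (i in 1:6) for (j in (i + 1):7) {
    expect_equal(length(intersect(v[[i]], v[[j]])), 0L)
  }
  # and no domain token is a background token
  expect_equal(length(intersect(unlist(v), b$background)), 0L)
})

test_that("configured pairwise overlaps are realized exactly", {
  b <- generate_bundle(synth_config(n_train = 20, n_test = 10, overlap = 0.2,
                                    vocab_size = 60, seed = 3))
  v <- b$vocabularies
  trio <- c("Interpersonal", "Mood", "ThoughtContent")
  for (i in 1:2) for (j in (i + 1):3) {
    got <- length(intersect(v[[trio[i]]], v[[trio[j]]])) / 60
    expect_equal(got, 0.2, tolerance = 1e-12)
  }
  expect_equal(length(intersect(v$Substance, v$Mood)), 0L)
  expect_true(all(lengths(v) == 60L))
})

test_that("overlap changes are paired: non-clique domains are untouched", {
  b0 <- generate_bundle(synth_config(n_train = 150, n_test = 50, overlap = 0,
                                     seed = 4))
  b5 <- generate_bundle(synth_config(n_train = 150, n_test = 50, overlap = 0.5,
                                     seed = 4))
  expect_identical(b0$vocabularies$Substance, b5$vocabularies$Substance)
  expect_identical(b0$vocabularies$Appearance, b5$vocabularies$Appearance)
  # sentences whose gold domains avoid the trio are byte-identical
  trio <- c("Interpersonal", "Mood", "ThoughtContent")
  nontrio <- vapply(b0$train$labels, function(l) !any(l %in% trio), logical(1))
  expect_identical(b0$train$text[nontrio], b5$train$text[nontrio])
  expect_identical(b0$train$labels, b5$train$labels)
})

test_that("other_rate = 1 yields an all-Other gold corpus", {
  b <- generate_bundle(synth_config(n_train = 10, n_test = 30, other_rate = 1,
                                    seed = 5))
  expect_true(all(vapply(b$test$labels, identical, logical(1), y = "Other")))
})

test_that("every non-Other sentence carries a cue for each gold domain", {
  b <- generate_bundle(synth_config(n_train = 150, n_test = 60, seed = 6))
  toks <- tokenize_text(b$test$text)
  for (i in seq_len(nrow(b$test))) {
    for (d in setdiff(b$test$labels[[i]], "Other")) {
      has_tok <- any(toks[[i]] %in% b$vocabularies[[d]])
      has_mwe <- any(vapply(strsplit(b$mwes[[d]], " "), function(p) {
        riskdomains:::has_span(toks[[i]], p)
      }, logical(1)))
      expect_true(has_tok || has_mwe)
    }
  }
})

test_that("weak labeling recovers most single-domain training sentences", {
  b <- generate_bundle(synth_config(seed = 13, overlap = 0))
  lab <- match_sentences(b$train, b$lexicon)
  single <- lengths(b$train$labels) == 1 &
    !vapply(b$train$labels, function(l) "Other" %in% l, logical(1))
  truth <- vapply(b$train$labels[single], `[`, character(1), 1)
  got <- lab$label[match(b$train$id[single], lab$id)]
  expect_gte(mean(!is.na(got) & got == truth), 0.9)
})

test_that("noise-free annotators agree perfectly; noisy ones do not", {
  b <- generate_bundle(synth_config(n_train = 20, n_test = 150, seed = 8))
  a0 <- simulate_annotators(b$test, k = 3, noise = 0, seed = 1)
  expect_equal(fleiss_kappa(a0), 1)
  a1 <- simulate_annotators(b$test, k = 3, noise = 0.4, seed = 1)
  expect_lt(fleiss_kappa(a1), 1)
})

test_that("noise = 1 with a uniform kernel gives chance-level agreement", {
  b <- generate_bundle(synth_config(n_train = 20, n_test = 1000, seed = 9))
  a <- simulate_annotators(b$test, k = 3, noise = 1, seed = 2,
                           kernel = "uniform")
  expect_lt(abs(fleiss_kappa(a, "first_label")), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(overlap = 1.2))
  expect_error(synth_config(sentence_length = c(1, 5)))
  expect_error(synth_config(other_rate = -0.1))
  O <- matrix(0.4, 7, 7); diag(O) <- 0
  expect_error(synth_config(overlap = O), "exceed")
})
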