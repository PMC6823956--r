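test_that("prototype selection respects the k = n and k = 1 limits", {
  set.seed(2)
  X <- matrix(rnorm(5 * 8), 5, 8)
  y <- rep("Mood", 5)
  P <- select_prototypes(X, y, k_per_domain = 5L, seed = 1)
  expect_equal(P[order(P[, 1]), ], X[order(X[, 1]), ], ignore_attr = TRUE)
  P1 <- select_prototypes(X, y, k_per_domain = 1L, seed = 1)
  expect_equal(as.numeric(P1), colMeans(X), tolerance = 1e-12)
  expect_equal(attr(P1, "domain"), "Mood")
})

test_that("undersized megadocuments are rejected naming the domain", {
  X <- matrix(rnorm(6 * 4), 6, 4)
  y <- c(rep("Mood", 4), rep("Substance", 2))
  expect_error(select_prototypes(X, y, k_per_domain = 3L), "Substance")
})

test_that("k-means matches exhaustive 2-partition search on small instances", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 10L
    X <- rbind(matrix(rnorm(5 * 2, mean = 0, sd = 0.3), 5, 2),
               matrix(rnorm(5 * 2, mean = 4, sd = 0.3), 5, 2))[sample(n), ]
    got <- select_prototypes(X, rep("Mood", n), k_per_domain = 2L, seed = seed)
    want <- oracle_kmeans2(X)$centers
    got <- got[order(got[, 1]), ]
    want <- want[order(want[, 1]), ]
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
})

test_that("the shared width follows the distance rule and its geometry", {
  expect_equal(compute_width(rbind(c(0, 0), c(2, 0))), 1)
  # unit simplex: pairwise distance sqrt(2), m = 3
  simplex <- diag(3)
  expect_equal(compute_width(simplex), sqrt(2) / sqrt(6), tolerance = 1e-12)
  # homogeneity: scaling inputs by c scales sigma by c
  set.seed(5)
  P <- matrix(rnorm(12), 4, 3)
  expect_equal(compute_width(3.7 * P), 3.7 * compute_width(P),
               tolerance = 1e-12)
  expect_error(compute_width(rbind(c(1, 1))), "at least 2")
  expect_error(compute_width(rbind(c(1, 1), c(1, 1))), "identical")
})

test_that("Gaussian activations are bounded, peaked at prototypes, monotone", {
  P <- rbind(c(0, 0), c(3, 0))
  A <- rbf_hidden(c(0, 0), P, width = 1)
  expect_equal(A[1, 1], 1)
  # distance sigma*sqrt(2) -> activation exp(-1)
  A2 <- rbf_hidden(c(sqrt(2), 0), P, width = 1)
  expect_equal(A2[1, 1], exp(-1), tolerance = 1e-12)
  d <- seq(0, 3, by = 0.25)
  act <- vapply(d, function(x) rbf_hidden(c(x, 0), P, 1)[1, 1], numeric(1))
  expect_true(all(diff(act) < 0))
  expect_true(all(act > 0 & act <= 1))
})

test_that("the RBF output layer has the expected parameter count and fits", {
  bundle <- generate_bundle(synth_config(n_train = 500, n_test = 30,
                                         overlap = 0, mwe_only_rate = 0,
                                         seed = 21))
  lab <- preprocess_corpus(match_sentences(bundle$train, bundle$lexicon),
                           bundle$lexicon)
  enc <- fit_idf(hash_encoder(128, seed = 21), lab)
  X <- encode_sentences(lab, enc)
  k <- min(20L, min(table(lab$label)))
  cfg <- rbf_config(input_nodes = 128L, prototypes_per_domain = k, seed = 21)
  protos <- select_prototypes(X, lab$label, k, seed = 21)
  width <- compute_width(protos, m = 2)
  Y <- riskdomains:::one_hot(lab$label, intersect(risk_domains(),
                                                  unique(lab$label)))
  fit <- train_rbf(X, Y, cfg, protos, width)
  expect_equal(length(fit$params$W) + length(fit$params$b), 7L * k * 7L + 7L)
  S <- riskdomains:::rbf_scores(fit, X)
  expect_gte(mean(colnames(S)[max.col(S)] == lab$label), 0.9)
  # deterministic refit
  fit2 <- train_rbf(X, Y, cfg, protos, width)
  expect_identical(fit$params, fit2$params)
})
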