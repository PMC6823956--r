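mk_table <- function(...) {
  ann <- list(...)
  n <- length(ann[[1]])
  annotation_table(paste0("i", seq_len(n)), ann)
}

test_that("perfect agreement fixes every statistic at 1", {
  labs <- list("Mood", c("Substance", "Mood"), "Other", "Mood")
  tab <- mk_table(labs, labs, labs)
  expect_equal(fleiss_kappa(tab), 1)
  expect_equal(multi_kappa(tab), 1)
  expect_equal(unname(agreement_counts(tab)["n_total_agreement"]), 4)
  adj <- adjudicate(tab)
  expect_equal(length(adj$review), 0L)
  acc <- annotator_accuracy(tab, adj$gold)
  expect_equal(acc$mean, 1)
})

test_that("balanced two-category perfect split has kappa 1", {
  a <- c(rep(list("Mood"), 3), rep(list("Substance"), 3))
  tab <- mk_table(a, a, a)
  expect_equal(fleiss_kappa(tab), 1)
  expect_equal(multi_kappa(tab), 1)
})

test_that("kappas match independent brute-force implementations", {
  # fixed 6-item, 3-annotator, 3-category table
  a1 <- list("Mood", "Mood", "Substance", "Other", "Substance", "Mood")
  a2 <- list("Mood", "Substance", "Substance", "Other", "Mood", "Mood")
  a3 <- list("Mood", "Mood", "Other", "Other", "Substance", "Substance")
  tab <- mk_table(a1, a2, a3)
  cats <- annotation_cats(tab)
  expect_equal(fleiss_kappa(tab), oracle_fleiss(cats), tolerance = 1e-10)
  expect_equal(multi_kappa(tab), oracle_multikappa(cats), tolerance = 1e-10)
  # near-identical marginals: the two statistics nearly coincide
  expect_lt(abs(fleiss_kappa(tab) - multi_kappa(tab)), 0.01)
})

test_that("kappas equal the oracle on random multilabel tables", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:10, 1)
    ann <- lapply(1:3, function(a) {
      lapply(seq_len(n), function(i) {
        sample(all_domains(), sample(1:2, 1, prob = c(0.8, 0.2)))
      })
    })
    tab <- annotation_table(paste0("x", seq_len(n)), ann)
    cats <- annotation_cats(tab)
    if (length(unique(as.vector(cats))) < 2) next
    expect_equal(fleiss_kappa(tab), oracle_fleiss(cats), tolerance = 1e-10)
    expect_equal(multi_kappa(tab), oracle_multikappa(cats), tolerance = 1e-10)
    # first-label view agrees with its own oracle reduction
    cats1 <- vapply(seq_len(3), function(j) {
      vapply(tab$annotations[[j]], function(l) l[1], character(1))
    }, character(n))
    if (length(unique(as.vector(cats1))) >= 2) {
      expect_equal(fleiss_kappa(tab, "first_label"), oracle_fleiss(cats1),
                   tolerance = 1e-10)
    }
  }
})

test_that("independent random annotation gives chance-level kappa", {
  set.seed(42)
  ann <- lapply(1:3, function(a) {
    lapply(1:1000, function(i) sample(all_domains(), 1))
  })
  tab <- annotation_table(paste0("i", 1:1000), ann)
  expect_lt(abs(fleiss_kappa(tab)), 0.05)
  expect_lt(abs(multi_kappa(tab)), 0.05)
})

test_that("degenerate single-category tables are rejected", {
  a <- rep(list("Mood"), 3)
  tab <- mk_table(a, a, a)
  expect_error(fleiss_kappa(tab), "undefined")
  expect_error(multi_kappa(tab), "undefined")
})

test_that("total agreement and disagreement follow the set definitions", {
  tab <- mk_table(
    list("Mood", "Mood", c("Mood", "ThoughtContent"), "Mood"),
    list("Mood", "Substance", "Mood", c("Mood", "Substance")),
    list("Mood", "Appearance", "Mood", "Substance")
  )
  counts <- agreement_counts(tab)
  # item 1: identical sets; item 2: pairwise disjoint; items 3-4: partial
  expect_equal(unname(counts["n_total_agreement"]), 1)
  expect_equal(unname(counts["n_total_disagreement"]), 1)
})

test_that("majority adjudication resolves 2-of-3 and routes the rest", {
  tab <- mk_table(
    list("Substance", "Mood", "Appearance"),
    list("Substance", "Occupation", c("Appearance", "Mood")),
    list("Mood", "Interpersonal", "Other")
  )
  adj <- adjudicate(tab)
  expect_equal(adj$gold$labels[[which(adj$gold$id == "i1")]], "Substance")
  expect_setequal(adj$review, c("i2", "i3"))
  # ordering of a multilabel set is ignored for the majority test
  tab2 <- mk_table(list(c("Mood", "Substance")), list(c("Substance", "Mood")),
                   list("Other"))
  adj2 <- adjudicate(tab2)
  expect_setequal(adj2$gold$labels[[1]], c("Mood", "Substance"))
})

test_that("annotator accuracy is strict set equality against gold", {
  gold <- data.frame(id = paste0("i", 1:10), stringsAsFactors = FALSE)
  gold$labels <- I(rep(list("Mood"), 10))
  right <- rep(list("Mood"), 10)
  mostly <- c(rep(list("Mood"), 7), rep(list("Substance"), 3))
  wrong <- rep(list("Substance"), 10)
  tab <- annotation_table(gold$id, list(a = right, b = mostly, c = wrong))
  acc <- annotator_accuracy(tab, gold)
  expect_equal(unname(acc$per_annotator), c(1, 0.7, 0))
  expect_equal(acc$mean, mean(c(1, 0.7, 0)))
})

test_that("the full agreement report assembles all statistics", {
  bundle <- generate_bundle(synth_config(n_train = 30, n_test = 120, seed = 3))
  rep0 <- agreement_report(simulate_annotators(bundle$test, noise = 0,
                                               seed = 5),
                           gold = bundle$test)
  expect_equal(rep0$fleiss_kappa, 1)
  expect_equal(rep0$mean_accuracy, 1)
  expect_equal(rep0$n_total_agreement, 120)
  repn <- agreement_report(bundle$annotations, gold = bundle$test)
  expect_lt(repn$fleiss_kappa, 1)
  expect_gt(repn$fleiss_kappa, 0.3)
  expect_lt(repn$mean_accuracy, 1)
})

test_that("annotation CSV round trip preserves the table and gold", {
  bundle <- generate_bundle(synth_config(n_train = 30, n_test = 15, seed = 4))
  f <- tempfile(fileext = ".csv")
  write_annotations(bundle$annotations, f, gold = bundle$test)
  back <- read_annotations(f)
  expect_equal(back$table$ids, bundle$annotations$ids)
  expect_identical(back$table$annotations, bundle$annotations$annotations)
  expect_equal(back$gold$labels[[3]], bundle$test$labels[[3]])
})

test_that("confusion concentrated on overlapping pairs shows up in disagreements", {
  bundle <- generate_bundle(synth_config(n_train = 30, n_test = 400, seed = 6))
  ann <- simulate_annotators(bundle$test, noise = 0.5, seed = 7,
                             overlap = bundle$config$overlap)
  gold1 <- vapply(bundle$test$labels, `[`, character(1), 1)
  trio <- c("Interpersonal", "Mood", "ThoughtContent")
  # count label substitutions whose replacement is a trio partner
  subs <- table(trio_sub = unlist(lapply(seq_along(gold1), function(i) {
    lapply(ann$annotations, function(a) {
      l <- a[[i]][1]
      if (l != gold1[i] && gold1[i] %in% trio) l %in% trio else NA
    })
  })))
  expect_gt(subs["TRUE"], subs["FALSE"])
})
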