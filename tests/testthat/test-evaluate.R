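mk_gold <- function(labels, ids = NULL) {
  ids <- ids %||% paste0("s", seq_along(labels))
  g <- data.frame(id = ids, stringsAsFactors = FALSE)
  g$labels <- I(labels)
  g
}
mk_pred <- function(labels, ids = NULL) {
  ids <- ids %||% paste0("s", seq_along(labels))
  p <- data.frame(id = ids, stringsAsFactors = FALSE)
  p$labels <- I(labels)
  p$is_other <- vapply(labels, function(l) identical(l, "Other"), logical(1))
  class(p) <- c("rd_prediction", "data.frame")
  p
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("perfect prediction scores 1 everywhere", {
  labs <- list("Mood", c("Substance", "Mood"), "Other", "Appearance")
  ev <- suppressWarnings(evaluate_predictions(mk_gold(labs), mk_pred(labs)))
  expect_equal(unname(ev$macro), c(1, 1, 1))
  expect_equal(unname(ev$macro_incl_other), c(1, 1, 1))
  expect_equal(ev$first_domain_accuracy, 1)
})

test_that("an all-Other predictor has zero recall on the risk domains", {
  gold <- mk_gold(list("Mood", "Substance", "Appearance"))
  pred <- mk_pred(list("Other", "Other", "Other"))
  ev <- suppressWarnings(evaluate_predictions(gold, pred))
  rows <- ev$per_domain[ev$per_domain$support > 0 &
                          ev$per_domain$domain != "Other", ]
  expect_true(all(rows$recall == 0))
})

test_that("extra predicted labels cost precision only in their domain", {
  gold <- mk_gold(list("Appearance"))
  pred <- mk_pred(list(c("Appearance", "Mood")))
  ev <- suppressWarnings(evaluate_predictions(gold, pred))
  pa <- ev$per_domain[ev$per_domain$domain == "Appearance", ]
  pm <- ev$per_domain[ev$per_domain$domain == "Mood", ]
  expect_equal(pa$precision, 1); expect_equal(pa$recall, 1)
  expect_equal(pm$precision, 0); expect_equal(pm$support, 0)
  # zero-support domains are excluded from the macro mean with a warning
  expect_warning(evaluate_predictions(gold, pred), "zero-support")
})

test_that("confusion counts sum to the gold support and match hand counts", {
  gold <- mk_gold(list("Mood", "Mood", c("Mood", "Substance"), "Other",
                       "Appearance"))
  pred <- mk_pred(list("Mood", "Substance", "Mood", "Other", "Other"))
  conf <- confusion_detail(gold, pred)
  expect_equal(conf$tp[conf$domain == "Mood"], 2)
  expect_equal(conf$fn[conf$domain == "Mood"], 1)
  expect_equal(conf$fp[conf$domain == "Substance"], 1)
  expect_equal(conf$fn[conf$domain == "Substance"], 1)
  expect_equal(conf$fn[conf$domain == "Appearance"], 1)
  expect_equal(conf$tp[conf$domain == "Other"], 1)
  expect_equal(conf$fp[conf$domain == "Other"], 1)
  gold_support <- vapply(all_domains(), function(d) {
    sum(vapply(gold$labels, function(l) d %in% l, logical(1)))
  }, numeric(1))
  expect_equal(conf$tp + conf$fn, unname(gold_support))
})

test_that("evaluation matches a brute-force oracle on random fixtures", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 100L
    doms <- all_domains()
    gold_labs <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.08) "Other" else {
        sample(risk_domains(), sample(1:2, 1, prob = c(0.9, 0.1)))
      }
    })
    pred_labs <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.15) "Other" else {
        sample(risk_domains(), sample(1:2, 1, prob = c(0.8, 0.2)))
      }
    })
    ev <- suppressWarnings(evaluate_predictions(mk_gold(gold_labs),
                                                mk_pred(pred_labs)))
    want <- oracle_eval(gold_labs, pred_labs, doms)
    got <- ev$per_domain
    expect_equal(got$precision, unname(want[, "precision"]))
    expect_equal(got$recall, unname(want[, "recall"]))
    expect_equal(got$f1, unname(want[, "f1"]))
    expect_equal(got$support, unname(want[, "support"]))
    keep <- want[seq_len(7), "support"] > 0
    expect_equal(unname(ev$macro["f1"]), mean(want[seq_len(7), "f1"][keep]))
    # metric bounds and harmonic identity
    expect_true(all(got$f1 >= 0 & got$f1 <= 1))
    pr <- got$precision + got$recall
    expect_equal(got$f1[pr > 0],
                 2 * got$precision[pr > 0] * got$recall[pr > 0] / pr[pr > 0])
  }
})

test_that("id mismatches and duplicates are rejected", {
  gold <- mk_gold(list("Mood", "Substance"))
  pred <- mk_pred(list("Mood"), ids = "s1")
  expect_error(evaluate_predictions(gold, pred), "id sets differ")
  dup <- mk_pred(list("Mood", "Mood"), ids = c("s1", "s1"))
  expect_error(evaluate_predictions(gold, dup), "duplicate")
})

test_that("first-domain accuracy scores the most prevalent gold domain", {
  gold <- mk_gold(list(c("Mood", "Substance"), "Appearance"))
  pred <- mk_pred(list("Substance", c("Appearance", "Mood")))
  ev <- suppressWarnings(evaluate_predictions(gold, pred))
  # first gold domain Mood missing from prediction 1, Appearance present in 2
  expect_equal(ev$first_domain_accuracy, 0.5)
})
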