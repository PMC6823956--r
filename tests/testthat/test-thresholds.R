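test_that("thresholds reproduce mean + alpha * population sd exactly", {
  S <- matrix(c(0.2, 0.4, 0.6), ncol = 1,
              dimnames = list(NULL, "Mood"))
  th <- compute_thresholds(S, alpha = 0.5, population = "train_all")
  expect_equal(th$table$mean, 0.4)
  expect_equal(th$table$sd, sqrt(mean((c(0.2, 0.4, 0.6) - 0.4)^2)))
  expect_equal(th$table$threshold, 0.4 + 0.5 * 0.16329932, tolerance = 1e-7)
  # alpha = 0 collapses to the mean
  th0 <- compute_thresholds(S, alpha = 0, population = "train_all")
  expect_equal(th0$table$threshold, 0.4)
})

test_that("thresholds satisfy the formula to machine precision", {
  set.seed(8)
  S <- matrix(runif(700), 100, 7, dimnames = list(NULL, risk_domains()))
  y <- sample(risk_domains(), 100, replace = TRUE)
  for (pop in c("train_all", "train_balanced", "train_in_domain",
                "train_out_domain")) {
    th <- compute_thresholds(S, alpha = 1.25, population = pop, labels = y)
    expect_true(all(abs(th$table$threshold -
                          (th$table$mean + 1.25 * th$table$sd)) < 1e-12))
  }
})

test_that("degenerate populations are rejected", {
  S <- matrix(0.5, 1, 1, dimnames = list(NULL, "Mood"))
  expect_error(compute_thresholds(S, 0.5, population = "train_all"),
               "fewer than 2")
  expect_error(compute_thresholds(matrix(runif(10), 5, 2,
                                         dimnames = list(NULL, c("Mood", "Substance"))),
                                  0.5, population = "train_in_domain"),
               "labels")
})

test_that("meeting the threshold is inclusive and labels sort by score", {
  th <- structure(list(table = data.frame(domain = c("Mood", "Substance"),
                                          mean = 0, sd = 0,
                                          n = 10, threshold = c(0.5, 0.7)),
                       alpha = 0, population = "train_all"),
                  class = "rd_thresholds")
  S <- rbind(a = c(Mood = 0.5, Substance = 0.69),
             b = c(Mood = 0.9, Substance = 0.95),
             c = c(Mood = 0.1, Substance = 0.2))
  pred <- predict_labels(S, th)
  expect_equal(pred$labels[[1]], "Mood")            # exactly at threshold
  expect_equal(pred$labels[[2]], c("Substance", "Mood"))  # ordered by score
  expect_equal(pred$labels[[3]], "Other")
  expect_equal(pred$is_other, c(FALSE, FALSE, TRUE))
})

test_that("label sets shrink monotonically in alpha down to all-Other", {
  set.seed(17)
  S <- matrix(runif(350), 50, 7, dimnames = list(NULL, risk_domains()))
  rownames(S) <- paste0("s", 1:50)
  y <- sample(risk_domains(), 50, replace = TRUE)
  alphas <- c(-1e6, -2, 0, 0.5, 1.25, 3, 1e6)
  prev <- NULL
  for (a in alphas) {
    th <- compute_thresholds(S, alpha = a, population = "train_all",
                             labels = y)
    pred <- predict_labels(S, th)
    sets <- lapply(pred$labels, setdiff, y = "Other")
    if (!is.null(prev)) {
      for (i in seq_along(sets)) {
        expect_true(all(sets[[i]] %in% prev[[i]]))
      }
    }
    prev <- sets
  }
  # extremes: alpha -> -Inf gives all 7 labels, alpha -> +Inf gives Other
  th_lo <- compute_thresholds(S, alpha = -1e6, population = "train_all")
  expect_true(all(lengths(predict_labels(S, th_lo)$labels) == 7L))
  th_hi <- compute_thresholds(S, alpha = 1e6, population = "train_all")
  expect_true(all(predict_labels(S, th_hi)$is_other))
})

test_that("the balanced population is invariant to class-imbalance inflation", {
  set.seed(23)
  base <- matrix(runif(70), 10, 7, dimnames = list(NULL, risk_domains()))
  y <- rep(risk_domains(), length.out = 10)
  # replicate one whole class: raw pooling drifts, balanced does not
  idx <- c(seq_len(10), rep(which(y == "Mood"), 10))
  th_bal <- compute_thresholds(base[idx, ], 0.5, "train_balanced",
                               labels = y[idx])
  th_ref <- compute_thresholds(base, 0.5, "train_balanced", labels = y)
  expect_equal(th_bal$table$threshold, th_ref$table$threshold,
               tolerance = 1e-10)
})
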