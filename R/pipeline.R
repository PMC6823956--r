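#' Run the full domain-classification pipeline
#'
#' Chains every stage on a corpus bundle: weak labeling of the
#' training pool against the lexicon, MWE merging and stemming,
#' sentence encoding, fitting the requested classifiers, open-world
#' thresholding, prediction on the test corpus and macro evaluation
#' against the gold labels.
#'
#' @param bundle an `rd_bundle` from [generate_bundle()], or a list
#'   with elements `lexicon`, `train` (unlabeled corpus) and `test`
#'   (gold-labeled corpus).
#' @param methods classifiers to fit.
#' @param use_mwes if `FALSE`, lexicon keyphrases are ignored in both
#'   matching and merging (ablation of the MWE contribution).
#' @param encoder an `rd_encoder`; default a 512-dimensional hashed
#'   encoder seeded from `seed`.
#' @param alphas named threshold constants per method.
#' @param k_per_domain RBF prototypes per domain; default 100, capped
#'   at the smallest megadocument size.
#' @param threshold_population see [compute_thresholds()].
#' @param seed integer seed for training stochasticity.
#' @return an `rd_pipeline` list: `fits`, `predictions`, `evals`
#'   (per method), `weak_labels` (the labeled training corpus with its
#'   exclusion log), and `label_counts`.
#' @examples
#' bundle <- generate_bundle(synth_config(n_train = 300, n_test = 80,
#'                                        seed = 7))
#' res <- domain_pipeline(bundle, methods = "cosine",
#'                        encoder = hash_encoder(128, seed = 7))
#' res$evals$cosine$macro
#' @export
domain_pipeline <- function(bundle, methods = c("cosine", "mlp", "rbf"),
                            use_mwes = TRUE, encoder = NULL,
                            alphas = c(cosine = 0.5, mlp = 0.5, rbf = 1.25),
                            k_per_domain = 100L,
                            threshold_population = "train_balanced",
                            seed = 13L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(encoder)) encoder <- hash_encoder(512L, seed = seed)
  lexicon <- bundle$lexicon
  if (!use_mwes) {
    lexicon <- domain_lexicon(lapply(lexicon$entries, function(e) {
      list(keywords = e$keywords, keyphrases = character(0))
    }))
  }

  train <- match_sentences(bundle$train, lexicon, use_mwes = use_mwes)
  if (!nrow(train)) stop("weak labeling matched no sentences", call. = FALSE)
  train <- preprocess_corpus(train, lexicon)
  test <- preprocess_corpus(bundle$test, lexicon)

  if (encoder$kind == "hashed_fallback" &&
      identical(encoder$weighting, "idf") && is.null(encoder$idf)) {
    encoder <- fit_idf(encoder, train)
  }
  Xtr <- encode_sentences(train, encoder)
  Xte <- encode_sentences(test, encoder)
  k_cap <- min(table(train$label))
  k_use <- min(k_per_domain, k_cap)

  fits <- list(); preds <- list(); evals <- list()
  for (m in methods) {
    fit <- domain_classifier(Xtr, labels = train$label, method = m,
                             alpha = unname(alphas[m]),
                             threshold_population = threshold_population,
                             k_per_domain = if (m == "rbf") k_use else NULL,
                             seed = seed)
    fit$encoder <- encoder
    fit$lexicon <- lexicon
    S <- score_matrix(fit$model, m, Xte)
    rownames(S) <- test$id
    pred <- predict_labels(S, fit$thresholds)
    fits[[m]] <- fit
    preds[[m]] <- pred
    evals[[m]] <- evaluate_predictions(bundle$test, pred)
  }
  structure(list(fits = fits, predictions = preds, evals = evals,
                 weak_labels = train,
                 label_counts = table(train$label),
                 encoder = encoder, use_mwes = use_mwes, seed = seed),
            class = "rd_pipeline")
}

#' @export
print.rd_pipeline <- function(x, ...) {
  cat("<rd_pipeline>\n")
  cat(sprintf("  weakly labeled training sentences: %d\n",
              nrow(x$weak_labels)))
  for (m in names(x$evals)) {
    mac <- x$evals[[m]]$macro
    cat(sprintf("  %-7s macro P/R/F1 = %.3f / %.3f / %.3f\n", m,
                mac["precision"], mac["recall"], mac["f1"]))
  }
  invisible(x)
}
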