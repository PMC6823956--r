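#' Fit an open-world risk factor domain classifier
#'
#' The central fitting function of the package. Given a weakly labeled
#' training corpus (or a precomputed embedding matrix with labels), it
#' fits one of three sentence classifiers over the seven risk factor
#' domains:
#'
#' * `"cosine"` — the similarity baseline: each domain is represented
#'   by its megadocument vector (normalized centroid of member
#'   embeddings, or `aggregate = "max"` for the exact pairwise
#'   variant) and sentences are scored by cosine similarity;
#' * `"mlp"` — a three-layer perceptron with sigmoid outputs
#'   ([mlp_config()]);
#' * `"rbf"` — a radial basis function network with per-domain k-means
#'   prototypes and a shared distance-derived width ([rbf_config()]).
#'
#' All three produce per-domain real-valued scores that are converted
#' to open-world multilabel predictions by per-domain thresholds
#' `mean + alpha * sd` fitted on the training scores (see
#' [compute_thresholds()]); a sentence meeting no threshold is
#' `Other`.
#'
#' @param x an `rd_corpus` with a single-label `label` column (from
#'   [match_sentences()]), or a numeric embedding matrix.
#' @param labels training labels when `x` is a matrix.
#' @param method `"mlp"`, `"rbf"` or `"cosine"`.
#' @param encoder an `rd_encoder` used to embed corpora (and new text
#'   in `predict()`); required when `x` is a corpus.
#' @param lexicon optional `rd_lexicon`; stored so that `predict()`
#'   applies the same MWE merging to new sentences.
#' @param alpha threshold constant; defaults to 0.5 (mlp, cosine) or
#'   1.25 (rbf).
#' @param threshold_population see [compute_thresholds()].
#' @param config an [mlp_config()] or [rbf_config()]; layer widths are
#'   aligned to the data automatically when left at defaults.
#' @param k_per_domain RBF prototypes per domain (default from
#'   `config`).
#' @param aggregate megadocument aggregation for the cosine baseline.
#' @param seed integer seed for the stochastic components.
#' @return an object of class `rd_classifier` with `print()`,
#'   `summary()`, `predict()`, `coef()` and `plot()` methods.
#' @examples
#' bundle <- generate_bundle(synth_config(n_train = 200, n_test = 50,
#'                                        vocab_size = 30, seed = 1))
#' enc <- hash_encoder(dimension = 128, seed = 1)
#' train <- preprocess_corpus(match_sentences(bundle$train, bundle$lexicon),
#'                            bundle$lexicon)
#' fit <- domain_classifier(train, method = "cosine", encoder = enc,
#'                          lexicon = bundle$lexicon)
#' fit
#' @export
domain_classifier <- function(x, labels = NULL,
                              method = c("mlp", "rbf", "cosine"),
                              encoder = NULL, lexicon = NULL,
                              alpha = NULL,
                              threshold_population = "train_balanced",
                              config = NULL, k_per_domain = NULL,
                              aggregate = c("centroid", "max"),
                              seed = 13L) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  cl <- match.call()

  if (inherits(x, "rd_corpus")) {
    if (is.null(x$label)) {
      stop("training corpus must carry a single-label `label` column; ",
           "see match_sentences()", call. = FALSE)
    }
    if (is.null(encoder)) encoder <- hash_encoder(seed = seed)
    if (is.null(x$stemmed)) x <- preprocess_corpus(x, lexicon)
    labels <- x$label
    X <- encode_sentences(x, encoder)
  } else {
    X <- x
    if (is.null(labels) || length(labels) != nrow(X)) {
      stop("matrix input requires one label per row", call. = FALSE)
    }
  }
  assert_domains(labels, allow_other = FALSE)
  label_order <- intersect(risk_domains(), unique(labels))

  if (is.null(alpha)) alpha <- if (method == "rbf") 1.25 else 0.5

  model <- switch(method,
    cosine = {
      members <- lapply(label_order, function(d) X[labels == d, , drop = FALSE])
      names(members) <- label_order
      centroids <- do.call(rbind, lapply(members, megadocument_vector))
      rownames(centroids) <- label_order
      list(kind = "cosine", centroids = centroids,
           members = if (aggregate == "max") members else NULL,
           aggregate = aggregate)
    },
    mlp = {
      if (is.null(config)) {
        config <- mlp_config(input_nodes = ncol(X),
                             output_nodes = length(label_order), seed = seed)
      }
      train_mlp(X, one_hot(labels, label_order), config)
    },
    rbf = {
      if (is.null(config)) {
        config <- rbf_config(input_nodes = ncol(X),
                             output_nodes = length(label_order), seed = seed)
      }
      if (!is.null(k_per_domain)) {
        config$prototypes_per_domain <- as.integer(k_per_domain)
        config$hidden_nodes <- as.integer(k_per_domain * config$output_nodes)
      }
      protos <- select_prototypes(X, labels, config$prototypes_per_domain,
                                  seed = config$seed)
      m_div <- switch(config$width_rule,
                      dmax_half = 2,       # sigma = d_max / 2
                      dmax_sqrt2m = nrow(protos),
                      dmax_sqrt2k = config$prototypes_per_domain,
                      custom = NA)
      width <- if (config$width_rule == "custom") config$width
               else compute_width(protos, m = m_div)
      train_rbf(X, one_hot(labels, label_order), config, protos, width)
    })

  train_scores <- score_matrix(model, method, X)
  thresholds <- compute_thresholds(train_scores, alpha = alpha,
                                   population = threshold_population,
                                   labels = labels)

  structure(list(method = method, model = model, encoder = encoder,
                 lexicon = lexicon, label_order = label_order,
                 thresholds = thresholds, alpha = alpha,
                 train_score_summary = summarize_scores(train_scores, labels),
                 n_train = nrow(X), call = cl),
            class = "rd_classifier")
}

score_matrix <- function(model, method, X) {
  switch(method,
         cosine = cosine_score_matrix(X, model),
         mlp = mlp_scores(model, X),
         rbf = rbf_scores(model, X))
}

summarize_scores <- function(S, labels) {
  doms <- colnames(S)
  t(vapply(doms, function(d) {
    c(in_domain = mean(S[labels == d, d]),
      out_domain = mean(S[labels != d, d]))
  }, numeric(2)))
}

#' Predict risk factor domains for new sentences
#'
#' Applies the training-time preprocessing (tokenization, MWE merging
#' with the stored lexicon, stemming), embeds the sentences with the
#' stored encoder, scores them and applies the per-domain thresholds.
#'
#' @param object an `rd_classifier`.
#' @param newdata an `rd_corpus`, a character vector of sentences, or
#'   an embedding matrix.
#' @param type `"labels"` for open-world multilabel predictions,
#'   `"scores"` for the raw per-domain score matrix.
#' @param alpha optional override of the threshold constant; the
#'   thresholds are re-derived from the stored training-score
#'   statistics.
#' @param ... unused.
#' @return an `rd_prediction` (or score matrix).
#' @export
predict.rd_classifier <- function(object, newdata,
                                  type = c("labels", "scores"),
                                  alpha = NULL, ...) {
  type <- match.arg(type)
  if (is.character(newdata)) newdata <- as_corpus(newdata)
  if (inherits(newdata, "rd_corpus")) {
    if (is.null(object$encoder)) {
      stop("classifier was fit on a matrix; pass an embedding matrix",
           call. = FALSE)
    }
    if (is.null(newdata$stemmed)) {
      newdata <- preprocess_corpus(newdata, object$lexicon)
    }
    X <- encode_sentences(newdata, object$encoder)
  } else {
    X <- newdata
  }
  S <- score_matrix(object$model, object$method, X)
  if (type == "scores") return(S)
  th <- object$thresholds
  if (!is.null(alpha)) {
    tab <- th$table
    tab$threshold <- tab$mean + alpha * tab$sd
    th <- structure(list(table = tab, alpha = alpha,
                         population = th$population),
                    class = "rd_thresholds")
  }
  predict_labels(S, th)
}

#' @export
print.rd_classifier <- function(x, ...) {
  cat(sprintf("<rd_classifier: %s>\n", x$method))
  cat(sprintf("  domains: %s\n", paste(x$label_order, collapse = ", ")))
  cat(sprintf("  trained on %d sentences; alpha = %g (%s population)\n",
              x$n_train, x$alpha, x$thresholds$population))
  invisible(x)
}

#' @export
summary.rd_classifier <- function(object, ...) {
  cat(sprintf("Open-world domain classifier (%s)\n", object$method))
  cat(sprintf("  training sentences: %d\n", object$n_train))
  if (object$method == "mlp") {
    cfg <- object$model$config
    cat(sprintf("  topology: %d -> %d (ReLU) -> %d (sigmoid); %d parameters\n",
                cfg$input_nodes, cfg$hidden_nodes, cfg$output_nodes,
                n_parameters(object$model)))
    cat(sprintf("  final training loss: %.4f\n",
                utils::tail(object$model$loss_history, 1)))
  } else if (object$method == "rbf") {
    cfg <- object$model$config
    cat(sprintf("  topology: %d -> %d (RBF, width %.4f) -> %d (linear)\n",
                cfg$input_nodes, cfg$hidden_nodes, object$model$width,
                cfg$output_nodes))
    cat(sprintf("  final training loss (MSE): %.4f\n",
                utils::tail(object$model$loss_history, 1)))
  } else {
    cat(sprintf("  megadocument aggregation: %s\n", object$model$aggregate))
  }
  cat("\nPer-domain thresholds:\n")
  print(object$thresholds$table, digits = 4)
  cat("\nMean training score by domain (in vs out of domain):\n")
  print(round(object$train_score_summary, 4))
  invisible(object)
}

#' @export
coef.rd_classifier <- function(object, ...) {
  switch(object$method,
         cosine = object$model$centroids,
         mlp = object$model$params,
         rbf = object$model$params)
}

#' Plot training-score distributions and thresholds
#'
#' One panel per domain: histogram of the training scores for that
#' domain over all training sentences, with the decision threshold as
#' a vertical line.
#'
#' @param x an `rd_classifier`.
#' @param scores optional score matrix (defaults to nothing being
#'   recomputed; pass `predict(fit, data, type = "scores")`).
#' @param ... passed to `hist()`.
#' @export
plot.rd_classifier <- function(x, scores = NULL, ...) {
  tab <- x$thresholds$table
  if (is.null(scores)) {
    graphics::barplot(stats::setNames(tab$threshold, tab$domain),
                      las = 2, ylab = "threshold",
                      main = sprintf("%s thresholds (alpha = %g)",
                                     x$method, x$alpha))
    return(invisible(x))
  }
  old <- graphics::par(mfrow = grDevices::n2mfrow(ncol(scores)))
  on.exit(graphics::par(old))
  for (d in colnames(scores)) {
    graphics::hist(scores[, d], breaks = 30, main = d, xlab = "score", ...)
    graphics::abline(v = tab$threshold[tab$domain == d], col = 2, lwd = 2)
  }
  invisible(x)
}
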