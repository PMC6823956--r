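#' Per-domain open-world score thresholds
#'
#' Risk factor domains differ in how homogeneous their language is, so
#' raw scores are not comparable across domains. Each domain therefore
#' gets its own threshold `mean + alpha * sd` computed from a score
#' population on the training corpus, with one shared constant `alpha`
#' (0.5 for the MLP, 1.25 for the RBF network). At prediction time a
#' sentence is assigned every domain whose score meets its threshold;
#' a sentence that meets none is `Other`.
#'
#' Four training-score populations are supported. `"train_balanced"`
#' (the default) pools the scores for domain D over all training
#' sentences but weights each label class equally (weight
#' `1 / (K * n_k)` for a sentence of class k), so the threshold is a
#' mixture of the domain's response to in-domain and out-of-domain
#' text that does not drift when weak labeling yields unbalanced
#' megadocuments. `"train_all"` pools all training sentences
#' unweighted; `"train_in_domain"` restricts to the sentences labeled
#' D (which places the threshold above the typical in-domain score
#' and is mainly useful for sensitivity analysis);
#' `"train_out_domain"` uses only the sentences not labeled D.
#' Standard deviations are population SDs (divide by n, or the
#' weighted analogue).
#'
#' @param scores numeric matrix of per-domain scores (columns named by
#'   domain) on the training corpus.
#' @param alpha the threshold constant.
#' @param labels training labels (required for
#'   `population = "train_in_domain"`).
#' @param population which score population defines each domain's mean
#'   and SD.
#' @return an `rd_thresholds` object: a per-domain table of `mean`,
#'   `sd`, `n` and `threshold`, plus `alpha` and `population`.
#' @export
compute_thresholds <- function(scores, alpha,
                               population = c("train_balanced", "train_all",
                                              "train_in_domain",
                                              "train_out_domain"),
                               labels = NULL) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)),
            is.numeric(alpha), length(alpha) == 1L)
  population <- match.arg(population)
  if (population != "train_all" && is.null(labels)) {
    stop("population = \"", population, "\" requires labels", call. = FALSE)
  }
  doms <- colnames(scores)
  w <- NULL
  if (population == "train_balanced") {
    cls <- table(labels)
    w <- as.numeric(1 / (length(cls) * cls[labels]))
  }
  stats_tab <- do.call(rbind, lapply(doms, function(d) {
    x <- switch(population,
                train_balanced = scores[, d],
                train_all = scores[, d],
                train_in_domain = scores[labels == d, d],
                train_out_domain = scores[labels != d, d])
    if (length(x) < 2L) {
      stop("fewer than 2 scores in the ", d, " population", call. = FALSE)
    }
    if (is.null(w)) {
      mu <- mean(x)
      sd_pop <- sqrt(mean((x - mu)^2))
    } else {
      mu <- sum(w * x) / sum(w)
      sd_pop <- sqrt(sum(w * (x - mu)^2) / sum(w))
    }
    data.frame(domain = d, mean = mu, sd = sd_pop, n = length(x),
               threshold = mu + alpha * sd_pop, stringsAsFactors = FALSE)
  }))
  rownames(stats_tab) <- NULL
  structure(list(table = stats_tab, alpha = alpha, population = population),
            class = "rd_thresholds")
}

#' @export
print.rd_thresholds <- function(x, ...) {
  cat(sprintf("<rd_thresholds: alpha = %g, population = %s>\n",
              x$alpha, x$population))
  print(x$table, digits = 4)
  invisible(x)
}

#' Convert scores into open-world multilabel predictions
#'
#' Assigns every domain whose score meets (`>=`) its threshold; a
#' sentence meeting no threshold is labeled `Other`.
#'
#' @param scores per-domain score matrix with sentence ids as row
#'   names (a single named vector is also accepted).
#' @param thresholds an `rd_thresholds` object.
#' @return an `rd_prediction` data frame: `id`, `labels` (list of
#'   domain sets, ordered by decreasing score), `is_other`.
#' @export
predict_labels <- function(scores, thresholds) {
  stopifnot(inherits(thresholds, "rd_thresholds"))
  if (is.null(dim(scores))) scores <- t(as.matrix(scores))
  th <- stats::setNames(thresholds$table$threshold, thresholds$table$domain)
  doms <- colnames(scores)
  stopifnot(all(doms %in% names(th)))
  th <- th[doms]
  ids <- rownames(scores) %||% paste0("s", seq_len(nrow(scores)))
  labels <- lapply(seq_len(nrow(scores)), function(i) {
    hit <- scores[i, ] >= th
    if (!any(hit)) return("Other")
    doms[hit][order(-scores[i, hit])]
  })
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  out$labels <- I(labels)
  out$is_other <- vapply(labels, function(l) identical(l, "Other"), logical(1))
  class(out) <- c("rd_prediction", "data.frame")
  out
}

#' @export
print.rd_prediction <- function(x, n = 6L, ...) {
  cat(sprintf("<rd_prediction: %d sentences, %d Other>\n",
              nrow(x), sum(x$is_other)))
  show <- utils::head(x, n)
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  %s: %s\n", show$id[i],
                paste(show$labels[[i]], collapse = ", ")))
  }
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}
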