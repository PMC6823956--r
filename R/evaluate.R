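#' Evaluate multilabel predictions against a gold standard
#'
#' Computes per-domain precision, recall and F1 by set membership (a
#' domain counts as a true positive for a sentence when it appears in
#' both the gold label set and the predicted set), plus
#' macro-averaged metrics: the unweighted mean over the seven risk
#' factor domains (primary) and, alongside, the mean including the
#' `Other` class. Gold label order (prevalence) is ignored for
#' scoring; a secondary first-domain accuracy — the fraction of
#' sentences whose first (most prevalent) gold domain appears in the
#' predicted set — is reported to mirror first-domain-only views of
#' the task.
#'
#' Domains with zero gold support get precision/recall/F1 of 0 and are
#' excluded from the macro means with a warning.
#'
#' @param gold an `rd_corpus` with a `labels` list-column (ordered,
#'   `Other` allowed), or a data frame with `id` and `labels`.
#' @param pred an `rd_prediction` (or data frame with `id` and
#'   `labels`).
#' @return an `rd_eval` object: `per_domain` table (domain, precision,
#'   recall, f1, support), `macro`, `macro_incl_other`,
#'   `first_domain_accuracy` and the confusion counts.
#' @export
evaluate_predictions <- function(gold, pred) {
  gold_ids <- as.character(gold$id)
  pred_ids <- as.character(pred$id)
  if (anyDuplicated(gold_ids) || anyDuplicated(pred_ids)) {
    stop("duplicate sentence ids", call. = FALSE)
  }
  if (!setequal(gold_ids, pred_ids)) {
    stop("gold and prediction id sets differ", call. = FALSE)
  }
  gl <- lapply(gold$labels, unique)
  pl <- lapply(pred$labels[match(gold_ids, pred_ids)], unique)

  conf <- confusion_detail(gold, pred)
  per <- conf
  per$precision <- ifelse(per$tp + per$fp > 0, per$tp / (per$tp + per$fp), 0)
  per$recall <- ifelse(per$tp + per$fn > 0, per$tp / (per$tp + per$fn), 0)
  per$f1 <- ifelse(per$precision + per$recall > 0,
                   2 * per$precision * per$recall / (per$precision + per$recall),
                   0)
  per$support <- per$tp + per$fn

  zero <- per$domain[per$support == 0]
  if (length(zero)) {
    warning("zero-support domain(s) excluded from macro averages: ",
            paste(zero, collapse = ", "), call. = FALSE)
  }
  macro_over <- function(doms) {
    rows <- per[per$domain %in% doms & per$support > 0, , drop = FALSE]
    c(precision = mean(rows$precision), recall = mean(rows$recall),
      f1 = mean(rows$f1))
  }
  first_gold <- vapply(gold$labels, function(l) l[1], character(1))
  fda <- mean(mapply(function(g1, p) g1 %in% p, first_gold, pl))

  structure(list(
    per_domain = per[, c("domain", "precision", "recall", "f1", "support")],
    macro = macro_over(risk_domains()),
    macro_incl_other = macro_over(all_domains()),
    first_domain_accuracy = fda,
    confusion = conf
  ), class = "rd_eval")
}

#' Per-domain confusion counts
#'
#' Audit table of true positives, false positives and false negatives
#' per domain (including `Other`); `tp + fn` equals the gold support.
#'
#' @inheritParams evaluate_predictions
#' @return data frame with columns `domain`, `tp`, `fp`, `fn`.
#' @export
confusion_detail <- function(gold, pred) {
  gold_ids <- as.character(gold$id)
  pred_ids <- as.character(pred$id)
  if (anyDuplicated(gold_ids) || anyDuplicated(pred_ids)) {
    stop("duplicate sentence ids", call. = FALSE)
  }
  if (!setequal(gold_ids, pred_ids)) {
    stop("gold and prediction id sets differ", call. = FALSE)
  }
  gl <- lapply(gold$labels, unique)
  pl <- lapply(pred$labels[match(gold_ids, pred_ids)], unique)
  doms <- all_domains()
  tab <- t(vapply(doms, function(d) {
    ing <- vapply(gl, function(l) d %in% l, logical(1))
    inp <- vapply(pl, function(l) d %in% l, logical(1))
    c(tp = sum(ing & inp), fp = sum(!ing & inp), fn = sum(ing & !inp))
  }, numeric(3)))
  data.frame(domain = doms, tp = tab[, "tp"], fp = tab[, "fp"],
             fn = tab[, "fn"], row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.rd_eval <- function(x, ...) {
  cat("<rd_eval>\n")
  print(transform(x$per_domain,
                  precision = round(precision, 3),
                  recall = round(recall, 3), f1 = round(f1, 3)))
  cat(sprintf("\nmacro (7 risk domains): P = %.3f  R = %.3f  F1 = %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("macro (incl. Other):    P = %.3f  R = %.3f  F1 = %.3f\n",
              x$macro_incl_other["precision"], x$macro_incl_other["recall"],
              x$macro_incl_other["f1"]))
  cat(sprintf("first-domain accuracy:  %.3f\n", x$first_domain_accuracy))
  invisible(x)
}

#' Write an evaluation report
#'
#' CSV layout mirrors the standard results table (one row per domain
#' plus macro rows); JSON carries the full object.
#'
#' @param eval an `rd_eval`.
#' @param path output path (`.csv` or `.json`).
#' @param model optional model name recorded in the CSV.
#' @export
write_eval_report <- function(eval, path, model = "") {
  stopifnot(inherits(eval, "rd_eval"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      per_domain = eval$per_domain,
      macro = as.list(eval$macro),
      macro_incl_other = as.list(eval$macro_incl_other),
      first_domain_accuracy = eval$first_domain_accuracy
    ), path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- rbind(
      data.frame(model = model, domain = eval$per_domain$domain,
                 precision = eval$per_domain$precision,
                 recall = eval$per_domain$recall,
                 f1 = eval$per_domain$f1, stringsAsFactors = FALSE),
      data.frame(model = model, domain = "MACRO",
                 precision = eval$macro["precision"],
                 recall = eval$macro["recall"],
                 f1 = eval$macro["f1"], stringsAsFactors = FALSE)
    )
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}
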