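#' Annotation tables
#'
#' Holds the ordered domain label lists assigned by k annotators to
#' each sentence, the raw material for inter-annotator agreement and
#' gold-standard adjudication. Every annotator labels every item;
#' label lists are non-empty, duplicate-free and drawn from the eight
#' labels (seven risk domains plus `Other`).
#'
#' @param ids character vector of sentence ids.
#' @param annotations list with one element per annotator (named, or
#'   auto-named `annotator_1..k`), each a list of character vectors of
#'   ordered labels.
#' @return an `rd_annotation` object.
#' @export
annotation_table <- function(ids, annotations) {
  stopifnot(length(annotations) >= 2)
  if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
    names(annotations) <- paste0("annotator_", seq_along(annotations))
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate item ids", call. = FALSE)
  annotations <- lapply(annotations, function(a) {
    stopifnot(length(a) == length(ids))
    lapply(a, function(l) {
      l <- as.character(l)
      if (!length(l)) stop("empty label list", call. = FALSE)
      if (anyDuplicated(l)) stop("duplicate labels in one list", call. = FALSE)
      assert_domains(l)
      l
    })
  })
  structure(list(ids = ids, annotations = annotations),
            class = "rd_annotation")
}

#' @export
print.rd_annotation <- function(x, ...) {
  cat(sprintf("<rd_annotation: %d items, %d annotators (%s)>\n",
              length(x$ids), length(x$annotations),
              paste(names(x$annotations), collapse = ", ")))
  invisible(x)
}

#' Read and write annotation CSVs
#'
#' Columns: `id`, optionally `text`, one column per annotator with
#' labels as ordered semicolon-separated lists, optionally `gold`.
#'
#' @param path file path.
#' @return `read_annotations()`: a list with `table`
#'   (`rd_annotation`) and `gold` (an `rd_corpus`-style data frame or
#'   `NULL`).
#' @export
read_annotations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(tab))
  ann_cols <- setdiff(names(tab), c("id", "text", "gold"))
  if (length(ann_cols) < 2) stop("need at least 2 annotator columns",
                                 call. = FALSE)
  split_labels <- function(x) lapply(strsplit(x, ";", fixed = TRUE), trimws)
  annotations <- lapply(tab[ann_cols], split_labels)
  at <- annotation_table(tab$id, annotations)
  gold <- NULL
  if ("gold" %in% names(tab)) {
    gold <- data.frame(id = as.character(tab$id), stringsAsFactors = FALSE)
    gold$labels <- I(split_labels(tab$gold))
  }
  list(table = at, gold = gold)
}

#' @rdname read_annotations
#' @param table an `rd_annotation`.
#' @param gold optional gold data frame (`id`, `labels`).
#' @export
write_annotations <- function(table, path, gold = NULL) {
  stopifnot(inherits(table, "rd_annotation"))
  out <- data.frame(id = table$ids, stringsAsFactors = FALSE)
  for (a in names(table$annotations)) {
    out[[a]] <- vapply(table$annotations[[a]], paste, character(1),
                       collapse = ";")
  }
  if (!is.null(gold)) {
    out$gold <- vapply(gold$labels[match(table$ids, gold$id)], paste,
                       character(1), collapse = ";")
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# reduce each ordered label list to one categorical unit
reduce_view <- function(labels, view) {
  if (view == "first_label") return(labels[[1]][1])
  paste(sort(unique(labels[[1]])), collapse = "+")
}

annotation_categories <- function(table, view) {
  k <- length(table$annotations)
  n <- length(table$ids)
  cats <- matrix("", n, k)
  for (j in seq_len(k)) {
    cats[, j] <- vapply(seq_len(n), function(i) {
      reduce_view(table$annotations[[j]][i], view)
    }, character(1))
  }
  cats
}

#' Fleiss's kappa
#'
#' Chance-corrected agreement for more than two annotators:
#' `kappa = (P_bar - Pe_bar) / (1 - Pe_bar)`, where `P_bar` is the
#' mean over items of the proportion of agreeing annotator pairs and
#' `Pe_bar` the sum of squared pooled category proportions. The
#' categorical unit is controlled by `view`: `"label_set"` treats each
#' distinct (unordered) label set as one category, matching overall
#' agreement on a multilabel task; `"first_label"` uses only the first
#' (most prevalent) domain.
#'
#' @param table an `rd_annotation`.
#' @param view `"label_set"` or `"first_label"`.
#' @return kappa (<= 1; 1 on perfect agreement).
#' @export
fleiss_kappa <- function(table, view = c("label_set", "first_label")) {
  view <- match.arg(view)
  cats <- annotation_categories(table, view)
  k <- ncol(cats)
  levs <- sort(unique(as.vector(cats)))
  counts <- t(apply(cats, 1, function(r) {
    tabulate(match(r, levs), nbins = length(levs))
  }))
  if (length(levs) == 1L) counts <- matrix(counts, ncol = 1L)
  P_i <- (rowSums(counts^2) - k) / (k * (k - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(counts) / (nrow(counts) * k)
  Pe <- sum(p_j^2)
  if (1 - Pe < .Machine$double.eps) {
    stop("chance agreement is 1 (all mass on one category); ",
         "kappa undefined", call. = FALSE)
  }
  (P_bar - Pe) / (1 - Pe)
}

#' Davies-Fleiss multi-rater kappa
#'
#' Generalization of Cohen's kappa to k annotators: observed agreement
#' is the mean pairwise agreement (as in Fleiss's kappa), while chance
#' agreement uses annotator-specific marginals, averaged over all
#' annotator pairs: `Pe = mean over pairs (a,b) of
#' sum_c p_c^(a) p_c^(b)`.
#'
#' @inheritParams fleiss_kappa
#' @return kappa (<= 1; 1 on perfect agreement).
#' @export
multi_kappa <- function(table, view = c("label_set", "first_label")) {
  view <- match.arg(view)
  cats <- annotation_categories(table, view)
  n <- nrow(cats); k <- ncol(cats)
  levs <- sort(unique(as.vector(cats)))
  # observed mean pairwise agreement
  pair_agree <- 0
  npairs <- 0L
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      pair_agree <- pair_agree + mean(cats[, a] == cats[, b])
      npairs <- npairs + 1L
    }
  }
  P_obs <- pair_agree / npairs
  # chance agreement from annotator-specific marginals
  marg <- lapply(seq_len(k), function(j) {
    table(factor(cats[, j], levels = levs)) / n
  })
  Pe <- 0
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      Pe <- Pe + sum(marg[[a]] * marg[[b]])
    }
  }
  Pe <- Pe / npairs
  if (1 - Pe < .Machine$double.eps) {
    stop("chance agreement is 1 (all mass on one category); ",
         "kappa undefined", call. = FALSE)
  }
  (P_obs - Pe) / (1 - Pe)
}

#' Total agreement and total disagreement counts
#'
#' Total agreement: every annotator assigned the identical label set
#' (the complete set-theoretic intersection equals each annotator's
#' set). Total disagreement: every pair of annotators has an empty
#' intersection.
#'
#' @param table an `rd_annotation`.
#' @return named vector `c(n_total_agreement, n_total_disagreement)`.
#' @export
agreement_counts <- function(table) {
  stopifnot(inherits(table, "rd_annotation"))
  n <- length(table$ids)
  k <- length(table$annotations)
  sets <- lapply(seq_len(n), function(i) {
    lapply(table$annotations, function(a) sort(unique(a[[i]])))
  })
  agree <- vapply(sets, function(s) {
    all(vapply(s[-1], identical, logical(1), y = s[[1]]))
  }, logical(1))
  disagree <- vapply(sets, function(s) {
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (length(intersect(s[[a]], s[[b]]))) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  c(n_total_agreement = sum(agree), n_total_disagreement = sum(disagree))
}

#' Majority adjudication of an annotation table
#'
#' Items where at least two annotators assigned the identical label
#' set take that set as gold; remaining items are routed to a manual
#' review list rather than silently labeled.
#'
#' @param table an `rd_annotation` (3 annotators, so that majority is
#'   well defined).
#' @return list with `gold` (data frame `id`, `labels` for the
#'   majority-resolved items) and `review` (ids needing expert
#'   adjudication).
#' @export
adjudicate <- function(table) {
  stopifnot(inherits(table, "rd_annotation"))
  if (length(table$annotations) != 3) {
    stop("majority adjudication expects exactly 3 annotators", call. = FALSE)
  }
  n <- length(table$ids)
  gold_labels <- vector("list", n)
  resolved <- logical(n)
  for (i in seq_len(n)) {
    s <- lapply(table$annotations, function(a) sort(unique(a[[i]])))
    keys <- vapply(s, paste, character(1), collapse = "+")
    tk <- table(keys)
    top <- names(tk)[which.max(tk)]
    if (max(tk) >= 2) {
      gold_labels[[i]] <- strsplit(top, "+", fixed = TRUE)[[1]]
      resolved[i] <- TRUE
    }
  }
  gold <- data.frame(id = table$ids[resolved], stringsAsFactors = FALSE)
  gold$labels <- I(gold_labels[resolved])
  list(gold = gold, review = table$ids[!resolved])
}

#' Per-annotator accuracy against the gold standard
#'
#' An annotator is correct on an item when their label set equals the
#' gold set exactly (strict matching); a relaxed variant scores the
#' first label only.
#'
#' @param table an `rd_annotation`.
#' @param gold data frame with `id` and `labels` covering all items.
#' @return list with `per_annotator` (strict accuracies), `mean`
#'   (their average: the human-parity baseline for the classification
#'   task), and `first_label` variants.
#' @export
annotator_accuracy <- function(table, gold) {
  stopifnot(inherits(table, "rd_annotation"))
  idx <- match(table$ids, gold$id)
  if (anyNA(idx)) stop("gold does not cover all items", call. = FALSE)
  gl <- lapply(gold$labels[idx], function(l) sort(unique(l)))
  g1 <- vapply(gold$labels[idx], function(l) l[1], character(1))
  strict <- vapply(table$annotations, function(a) {
    mean(vapply(seq_along(a), function(i) {
      identical(sort(unique(a[[i]])), gl[[i]])
    }, logical(1)))
  }, numeric(1))
  first <- vapply(table$annotations, function(a) {
    mean(vapply(seq_along(a), function(i) a[[i]][1] == g1[i], logical(1)))
  }, numeric(1))
  list(per_annotator = strict, mean = mean(strict),
       per_annotator_first_label = first, mean_first_label = mean(first))
}

#' Full inter-annotator agreement report
#'
#' Convenience wrapper computing both kappas under both views, the
#' total agreement/disagreement counts, and (when gold is available)
#' mean annotator accuracy.
#'
#' @param table an `rd_annotation`.
#' @param gold optional gold data frame.
#' @return an `rd_agreement` list.
#' @export
agreement_report <- function(table, gold = NULL) {
  counts <- agreement_counts(table)
  out <- list(
    fleiss_kappa = fleiss_kappa(table, "label_set"),
    multi_kappa = multi_kappa(table, "label_set"),
    fleiss_kappa_first = fleiss_kappa(table, "first_label"),
    multi_kappa_first = multi_kappa(table, "first_label"),
    n_total_agreement = unname(counts["n_total_agreement"]),
    n_total_disagreement = unname(counts["n_total_disagreement"]),
    n_items = length(table$ids)
  )
  if (!is.null(gold)) {
    acc <- annotator_accuracy(table, gold)
    out$mean_accuracy <- acc$mean
    out$mean_accuracy_first_label <- acc$mean_first_label
  }
  structure(out, class = "rd_agreement")
}

#' @export
print.rd_agreement <- function(x, ...) {
  cat("<rd_agreement>\n")
  cat(sprintf("  Fleiss's kappa:      %.3f (label sets), %.3f (first label)\n",
              x$fleiss_kappa, x$fleiss_kappa_first))
  cat(sprintf("  multi-kappa:         %.3f (label sets), %.3f (first label)\n",
              x$multi_kappa, x$multi_kappa_first))
  cat(sprintf("  total agreement:     %d / %d\n", x$n_total_agreement,
              x$n_items))
  cat(sprintf("  total disagreement:  %d / %d\n", x$n_total_disagreement,
              x$n_items))
  if (!is.null(x$mean_accuracy)) {
    cat(sprintf("  mean accuracy:       %.3f (strict), %.3f (first label)\n",
                x$mean_accuracy, x$mean_accuracy_first_label))
  }
  invisible(x)
}
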