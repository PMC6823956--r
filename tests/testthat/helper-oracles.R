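# Independent brute-force oracles and small fixture builders shared by
# the unit and acceptance tests. These deliberately re-derive each
# quantity from first principles, without calling the package
# implementation under test.

# all n-grams of sizes in n_range from one token vector
oracle_ngrams <- function(toks, n_range = c(2L, 3L)) {
  out <- character(0)
  for (n in n_range) {
    if (length(toks) >= n) {
      for (s in seq_len(length(toks) - n + 1L)) {
        out <- c(out, paste(toks[s:(s + n - 1L)], collapse = " "))
      }
    }
  }
  out
}

# brute-force per-domain TF-IDF with tf = raw megadocument count and
# idf = ln(D / (1 + df))
oracle_tfidf <- function(toklists, labels) {
  doms <- sort(unique(labels))
  counts <- lapply(doms, function(d) {
    grams <- unlist(lapply(toklists[labels == d], oracle_ngrams))
    table(grams)
  })
  names(counts) <- doms
  vocab <- sort(unique(unlist(lapply(counts, names))))
  df <- vapply(vocab, function(g) {
    sum(vapply(counts, function(ct) g %in% names(ct), logical(1)))
  }, numeric(1))
  out <- list()
  for (d in doms) {
    ct <- counts[[d]]
    if (!length(ct)) next
    g <- names(ct)
    out[[d]] <- data.frame(
      domain = d, ngram = g, tf = as.integer(ct),
      tfidf = as.integer(ct) * log(length(doms) / (1 + df[g])),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

# brute-force Fleiss's kappa from a matrix of category assignments
# (rows = items, cols = annotators)
oracle_fleiss <- function(cats) {
  k <- ncol(cats)
  levs <- sort(unique(as.vector(cats)))
  counts <- t(apply(cats, 1, function(r) {
    vapply(levs, function(l) sum(r == l), numeric(1))
  }))
  if (length(levs) == 1L) counts <- matrix(counts, ncol = 1L)
  P_i <- (rowSums(counts^2) - k) / (k * (k - 1))
  p_j <- colSums(counts) / (nrow(cats) * k)
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

# brute-force Davies-Fleiss multi-rater kappa (annotator-specific
# marginals in the chance term, averaged over annotator pairs)
oracle_multikappa <- function(cats) {
  n <- nrow(cats); k <- ncol(cats)
  levs <- sort(unique(as.vector(cats)))
  obs <- 0; chance <- 0; npair <- 0
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      obs <- obs + mean(cats[, a] == cats[, b])
      pa <- vapply(levs, function(l) mean(cats[, a] == l), numeric(1))
      pb <- vapply(levs, function(l) mean(cats[, b] == l), numeric(1))
      chance <- chance + sum(pa * pb)
      npair <- npair + 1
    }
  }
  obs <- obs / npair; chance <- chance / npair
  (obs - chance) / (1 - chance)
}

# reduce an rd_annotation to a category matrix the way the package
# defines the label_set view (sorted unique labels joined)
annotation_cats <- function(table) {
  k <- length(table$annotations)
  n <- length(table$ids)
  m <- matrix("", n, k)
  for (j in seq_len(k)) {
    m[, j] <- vapply(table$annotations[[j]], function(l) {
      paste(sort(unique(l)), collapse = "+")
    }, character(1))
  }
  m
}

# brute-force multilabel evaluation by per-sentence membership checks
oracle_eval <- function(gold_labels, pred_labels, domains) {
  per <- lapply(domains, function(d) {
    tp <- fp <- fn <- 0
    for (i in seq_along(gold_labels)) {
      ing <- d %in% gold_labels[[i]]
      inp <- d %in% pred_labels[[i]]
      tp <- tp + (ing && inp)
      fp <- fp + (!ing && inp)
      fn <- fn + (ing && !inp)
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f,
      support = tp + fn)
  })
  do.call(rbind, per)
}

# exhaustive best 2-means solution over all binary partitions
oracle_kmeans2 <- function(X) {
  n <- nrow(X)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    c1 <- colMeans(X[grp, , drop = FALSE])
    c2 <- colMeans(X[!grp, , drop = FALSE])
    ss <- sum(sweep(X[grp, , drop = FALSE], 2, c1)^2) +
      sum(sweep(X[!grp, , drop = FALSE], 2, c2)^2)
    if (is.null(best) || ss < best$ss) {
      best <- list(ss = ss, centers = rbind(c1, c2))
    }
  }
  best
}

# tiny deterministic labeled corpus: n sentences per domain, each
# sentence made of that domain's marker tokens plus shared filler
tiny_labeled_corpus <- function(n_per_domain = 4L, domains = risk_domains()) {
  text <- character(0); labels <- character(0)
  for (d in domains) {
    for (i in seq_len(n_per_domain)) {
      text <- c(text, paste(tolower(d), paste0(tolower(d), "tok", i),
                            "filler common words"))
      labels <- c(labels, d)
    }
  }
  corp <- as_corpus(text)
  corp <- tokenize_corpus(corp)
  corp$label <- labels
  corp
}
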