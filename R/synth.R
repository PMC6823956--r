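#' Configuration for the synthetic EHR-like corpus generator
#'
#' The generator emulates the statistical shape of sentence-level
#' psychiatric EHR data without shipping any clinical text: seven
#' domain vocabularies with controllable pairwise overlap, a shared
#' background ("quotidian") vocabulary, clinically styled multiword
#' expressions whose component tokens are themselves background words
#' (so the parts are uninformative in isolation), sentences drawn from
#' one or two domains with length variation, and out-of-domain
#' background-only sentences for the `Other` class.
#'
#' Defaults describe the study conditions the package is exercised
#' under: 2000 training and 500 test sentences, moderate vocabulary
#' overlap (0.2) among the Interpersonal/Mood/ThoughtContent trio that
#' is known to occupy one noisy region of embedding space, a ~5%
#' multilabel rate and ~6% `Other` rate (matching the rough
#' proportions of an adjudicated psychiatric gold standard), sentence
#' lengths of 8-30 tokens, and a planted lexicon covering only part of
#' each vocabulary so weak labeling is imperfect by design.
#'
#' @param n_train,n_test corpus sizes.
#' @param vocab_size tokens per domain vocabulary.
#' @param background_size shared background vocabulary size.
#' @param overlap 7x7 symmetric matrix (zero diagonal) of pairwise
#'   shared-vocabulary fractions, or a single number applied to the
#'   Interpersonal/Mood/ThoughtContent trio.
#' @param mwe_per_domain multiword expressions planted per domain.
#' @param mwe_rate probability a sentence contains one of its domain's
#'   MWEs in addition to domain unigrams.
#' @param mwe_only_rate probability a non-Other sentence carries its
#'   domain signal *only* through an MWE (no domain unigrams at all),
#'   emulating clinical phrases whose component words are quotidian --
#'   such sentences are invisible to keyword-only matching and to
#'   models that do not merge MWEs.
#' @param multilabel_rate probability a non-Other sentence draws from
#'   two domains.
#' @param other_rate probability of a background-only sentence.
#' @param sentence_length `c(min, max)` token counts (min >= 3).
#' @param domain_token_rate per-slot probability of drawing from the
#'   domain vocabulary rather than the background.
#' @param keyword_coverage fraction of each domain's unique tokens
#'   exported to the planted lexicon as keywords.
#' @param core_keyword_coverage fraction of a shared-core vocabulary
#'   exported as keywords by each member of an overlap clique;
#'   clinicians cannot fully avoid shared vocabulary, so some
#'   exported keywords are ambiguous between overlapping domains.
#' @param mwe_coverage fraction of each domain's MWEs exported as
#'   keyphrases.
#' @param seed integer seed; regeneration with the same config is
#'   identical.
#' @return an `rd_synth_config` list.
#' @export
synth_config <- function(n_train = 2000L, n_test = 500L, vocab_size = 60L,
                         background_size = 150L, overlap = 0.2,
                         mwe_per_domain = 3L, mwe_rate = 0.6,
                         mwe_only_rate = 0.22,
                         multilabel_rate = 0.05, other_rate = 0.06,
                         sentence_length = c(8L, 30L),
                         domain_token_rate = 0.6,
                         keyword_coverage = 0.5, mwe_coverage = 2 / 3,
                         core_keyword_coverage = 0.25,
                         seed = 13L) {
  domains <- risk_domains()
  if (is.matrix(overlap)) {
    stopifnot(nrow(overlap) == 7, ncol(overlap) == 7,
              isTRUE(all.equal(overlap, t(overlap))),
              all(diag(overlap) == 0), all(overlap >= 0 & overlap <= 1))
    O <- overlap
    clique <- NULL
  } else {
    stopifnot(length(overlap) == 1, overlap >= 0, overlap <= 1)
    O <- matrix(0, 7, 7)
    trio <- match(c("Interpersonal", "Mood", "ThoughtContent"), domains)
    O[trio, trio] <- overlap
    diag(O) <- 0
    clique <- if (overlap > 0) trio else NULL
  }
  dimnames(O) <- list(domains, domains)
  if (any(rowSums(O) > 1)) {
    stop("row overlap fractions exceed the domain vocabulary", call. = FALSE)
  }
  stopifnot(n_train >= 1, n_test >= 1, vocab_size >= 4, background_size >= 10,
            mwe_per_domain >= 1, mwe_rate >= 0, mwe_rate <= 1,
            mwe_only_rate >= 0, mwe_only_rate <= 1,
            multilabel_rate >= 0, multilabel_rate <= 1,
            other_rate >= 0, other_rate <= 1,
            length(sentence_length) == 2, sentence_length[1] >= 3,
            sentence_length[2] >= sentence_length[1],
            domain_token_rate > 0, domain_token_rate <= 1,
            keyword_coverage > 0, keyword_coverage <= 1,
            core_keyword_coverage >= 0, core_keyword_coverage <= 1,
            mwe_coverage >= 0, mwe_coverage <= 1)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 domains = domains, vocab_size = as.integer(vocab_size),
                 background_size = as.integer(background_size), overlap = O,
                 mwe_per_domain = as.integer(mwe_per_domain),
                 mwe_rate = mwe_rate, mwe_only_rate = mwe_only_rate,
                 multilabel_rate = multilabel_rate,
                 other_rate = other_rate,
                 sentence_length = as.integer(sentence_length),
                 domain_token_rate = domain_token_rate,
                 keyword_coverage = keyword_coverage,
                 core_keyword_coverage = core_keyword_coverage,
                 mwe_coverage = mwe_coverage, overlap_clique = clique,
                 seed = as.integer(seed)),
            class = "rd_synth_config")
}

# pronounceable word-like strings, unique within the call
make_words <- function(n, min_len = 5L, max_len = 9L) {
  cons <- strsplit("bcdfghjklmnprstvz", "")[[1]]
  vow <- strsplit("aeiou", "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    w <- vapply(seq_len(need * 2L), function(i) {
      len <- sample(min_len:max_len, 1L)
      ch <- character(len)
      for (p in seq_len(len)) {
        ch[p] <- if (p %% 2L == 1L) sample(cons, 1L) else sample(vow, 1L)
      }
      paste(ch, collapse = "")
    }, character(1))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Generate a synthetic corpus bundle
#'
#' Produces everything the pipeline consumes: a planted (partial)
#' lexicon, an unlabeled training pool whose latent truth is recorded
#' in a `labels` column, a gold-labeled test corpus including `Other`
#' and multilabel sentences, and a simulated 3-annotator annotation
#' table over the test corpus.
#'
#' Construction guarantees: domain vocabularies realize the configured
#' pairwise overlaps exactly; MWEs are 2-3 token sequences unique to a
#' domain but built from background tokens; every non-Other sentence
#' contains at least one token (or MWE) of each of its gold domains.
#'
#' Overlap is a paired manipulation: each domain owns a fixed base
#' block of words, and a pairwise overlap is realized by replacing the
#' tail of one domain's block with words donated from its partner's
#' head, with every construction phase drawing from its own seeded
#' RNG substream. Changing the overlap of one domain pair therefore
#' leaves the vocabularies and the generated sentences of all other
#' domains byte-identical, so overlap experiments compare like with
#' like instead of resampling the whole corpus.
#'
#' @param config an [synth_config()].
#' @param annotator_noise per-item probability that a simulated
#'   annotator deviates from gold (see [simulate_annotators()]).
#' @return an `rd_bundle` list: `lexicon`, `train`, `test`,
#'   `annotations`, `vocabularies`, `mwes`, `config`.
#' @export
generate_bundle <- function(config = synth_config(), annotator_noise = 0.2) {
  stopifnot(inherits(config, "rd_synth_config"))
  with_seed(config$seed, {
    doms <- config$domains
    V <- config$vocab_size

    # ---- vocabularies with exact pairwise overlap ----
    # Fixed per-domain base blocks; a pair's overlap replaces the
    # receiver's tail slice with words donated from the donor's head,
    # so non-participating domains are untouched by the overlap knob.
    n_shared <- matrix(0L, 7, 7, dimnames = dimnames(config$overlap))
    for (i in 1:6) for (j in (i + 1):7) {
      n_shared[i, j] <- as.integer(round(config$overlap[i, j] * V))
    }
    words <- make_words(config$background_size + 7L * V)
    background <- words[seq_len(config$background_size)]
    blocks <- split(words[-seq_len(config$background_size)],
                    rep(seq_len(7), each = V))
    vocabs <- stats::setNames(blocks, doms)
    core <- stats::setNames(rep(list(character(0)), 7), doms)
    core_share <- stats::setNames(numeric(7), doms)
    if (!is.null(config$overlap_clique)) {
      # equal pairwise overlap among a clique of domains is realized
      # as one shared core: the first member donates its head block to
      # the others' tails, so every pair shares exactly those words
      # while each member keeps V - s unique tokens. This is the
      # "common noisy region" structure: confusable domains share a
      # core vocabulary rather than pairwise-private fragments.
      cl <- config$overlap_clique
      ns <- as.integer(round(config$overlap[cl[1], cl[2]] * V))
      if (ns > 0) {
        shared_core <- blocks[[cl[1]]][seq_len(ns)]
        for (j in cl[-1]) {
          vocabs[[j]][(V - ns + 1L):V] <- shared_core
        }
        for (j in cl) {
          core[[j]] <- shared_core
          core_share[j] <- ns / V
        }
      }
    } else {
      donated <- integer(7)   # words given away from the head
      received <- integer(7)  # tail positions replaced so far
      for (i in 1:6) for (j in (i + 1):7) {
        ns <- n_shared[i, j]
        if (ns > 0) {
          if (donated[i] + ns + received[i] > V ||
              received[j] + ns + donated[j] > V) {
            stop("overlap fractions too large for the vocabulary size",
                 call. = FALSE)
          }
          share <- blocks[[i]][(donated[i] + 1L):(donated[i] + ns)]
          vocabs[[j]][(V - received[j] - ns + 1L):(V - received[j])] <- share
          donated[i] <- donated[i] + ns
          received[j] <- received[j] + ns
        }
      }
    }

    # domain-specific register: the vocabulary minus any shared core.
    # Unvoiced sentences draw domain tokens from this register only;
    # core-voiced sentences draw from the shared core only.
    uvocab <- lapply(doms, function(d) setdiff(vocabs[[d]], core[[d]]))
    names(uvocab) <- doms

    # unique tokens (appearing in exactly one domain, never background)
    all_dom_tokens <- unlist(vocabs)
    uniq_tokens <- lapply(vocabs, function(v) {
      v[!v %in% all_dom_tokens[duplicated(all_dom_tokens)]]
    })

    # Background usage is Zipf-distributed, like real quotidian
    # vocabulary: a few words carry most of the filler mass while the
    # tail is individually rare.
    bg_prob <- (1 / seq_along(background))
    bg_prob <- bg_prob / sum(bg_prob)
    draw_bg <- function(n) sample(background, n, replace = TRUE, prob = bg_prob)

    # ---- MWEs: 2-3 background tokens, sequence unique to a domain ----
    # Components come from the rarer half of the background: words that
    # are unremarkable in isolation but, as a collocation, mark one
    # domain (the "quotidian parts, clinical whole" property).
    mwe_pool <- background[seq(ceiling(length(background) / 2),
                               length(background))]
    mwes <- stats::setNames(vector("list", 7), doms)
    seen <- character(0)
    for (d in doms) {
      out <- character(0)
      while (length(out) < config$mwe_per_domain) {
        len <- sample(2:3, 1L)
        seq_toks <- sample(mwe_pool, len)
        key <- paste(seq_toks, collapse = " ")
        if (!key %in% seen) {
          seen <- c(seen, key)
          out <- c(out, key)
        }
      }
      mwes[[d]] <- out
    }

    # ---- planted (partial) lexicon ----
    # Keywords are drawn from the domain's unique tokens when it has
    # any; a domain whose vocabulary is entirely shared (extreme
    # overlap) exports shared tokens instead, so its weak labels are
    # noisy and partly ambiguous -- the realistic failure mode of
    # keyword supervision in overlapping domains. Each domain samples
    # from its own seeded substream, keeping the other domains'
    # lexicon entries invariant under overlap changes.
    entries <- lapply(seq_along(doms), function(k) {
      d <- doms[k]
      set.seed(config$seed %% 100000L + 200L + k)
      pool <- if (length(uniq_tokens[[d]]) >= 2) uniq_tokens[[d]] else vocabs[[d]]
      nk <- max(1L, round(config$keyword_coverage * length(pool)))
      kw <- sample(pool, nk)
      nck <- round(config$core_keyword_coverage * length(core[[d]]))
      if (nck > 0) kw <- c(kw, sample(core[[d]], nck))
      nm <- round(config$mwe_coverage * config$mwe_per_domain)
      list(keywords = kw,
           keyphrases = if (nm > 0) sample(mwes[[d]], nm) else character(0))
    })
    names(entries) <- doms
    lexicon <- domain_lexicon(entries)
    set.seed(config$seed %% 100000L + 300L)

    draw_sentence <- function() {
      L <- sample(config$sentence_length[1]:config$sentence_length[2], 1L)
      if (stats::runif(1) < config$other_rate) {
        return(list(tokens = draw_bg(L), labels = "Other"))
      }
      two <- stats::runif(1) < config$multilabel_rate
      labs <- sample(doms, if (two) 2L else 1L)
      mwe_only <- stats::runif(1) < config$mwe_only_rate
      # phrase-borne mentions are terse ("denies panic attacks"): the
      # MWE carries the whole clinical meaning in a short sentence
      if (mwe_only) L <- sample(3:5, 1L)
      # Core-voiced sentences: with probability equal to the domain's
      # shared-core fraction, a clique-domain sentence expresses its
      # content entirely in the shared core vocabulary, so nothing in
      # it separates the overlapping domains. The voicing draw is
      # consumed for every sentence and all token draws use a single
      # uniform each, keeping the RNG stream identical across overlap
      # settings (paired corpora).
      u_voice <- stats::runif(1)
      ridx <- function(n) max(1L, ceiling(stats::runif(1) * n))
      toks <- character(L)
      for (p in seq_len(L)) {
        u_slot <- stats::runif(1)
        if (!mwe_only && u_slot < config$domain_token_rate) {
          src <- if (two && stats::runif(1) < 1 / 3) labs[2] else labs[1]
          if (u_voice < core_share[src]) {
            toks[p] <- core[[src]][ridx(length(core[[src]]))]
          } else {
            toks[p] <- uvocab[[src]][ridx(length(uvocab[[src]]))]
          }
        } else {
          toks[p] <- draw_bg(1L)
        }
      }
      # MWE per gold domain: always present in MWE-only sentences,
      # otherwise with probability mwe_rate; inserted at a random spot
      for (d in labs) {
        if (mwe_only || stats::runif(1) < config$mwe_rate) {
          mt <- strsplit(sample(mwes[[d]], 1L), " ", fixed = TRUE)[[1]]
          at <- sample(seq_len(length(toks) + 1L), 1L)
          toks <- append(toks, mt, after = at - 1L)
        }
      }
      # guarantee at least one cue (domain unigram or MWE) per domain;
      # the repair draws are made unconditionally so that the RNG
      # stream is identical whether or not a repair is needed
      if (!mwe_only) {
        for (d in labs) {
          slot <- ridx(length(toks))
          repl <- if (u_voice < core_share[d]) {
            core[[d]][ridx(length(core[[d]]))]
          } else {
            uvocab[[d]][ridx(length(uvocab[[d]]))]
          }
          if (!any(toks %in% vocabs[[d]])) toks[slot] <- repl
        }
      }
      # order labels by prevalence within the sentence
      if (length(labs) == 2L) {
        cnt <- vapply(labs, function(d) sum(toks %in% vocabs[[d]]), numeric(1))
        labs <- labs[order(-cnt)]
      }
      list(tokens = toks, labels = labs)
    }

    make_corpus <- function(n, prefix) {
      sent <- lapply(seq_len(n), function(i) draw_sentence())
      as_corpus(vapply(sent, function(s) paste(s$tokens, collapse = " "),
                       character(1)),
                id = paste0(prefix, seq_len(n)),
                labels = lapply(sent, `[[`, "labels"))
    }
    train <- make_corpus(config$n_train, "tr")
    test <- make_corpus(config$n_test, "te")

    annotations <- simulate_annotators(test, k = 3L, noise = annotator_noise,
                                       seed = config$seed + 1L,
                                       overlap = config$overlap)

    structure(list(lexicon = lexicon, train = train, test = test,
                   annotations = annotations, vocabularies = vocabs,
                   background = background, mwes = mwes, config = config),
              class = "rd_bundle")
  })
}

#' @export
print.rd_bundle <- function(x, ...) {
  cat(sprintf("<rd_bundle: %d train / %d test sentences, seed %d>\n",
              nrow(x$train), nrow(x$test), x$config$seed))
  invisible(x)
}

#' Simulate noisy annotators over a gold corpus
#'
#' Each annotator reproduces the gold label list with probability
#' `1 - noise` per item; otherwise the first label is replaced by a
#' draw from a confusion kernel concentrated on high-overlap domain
#' pairs (uniform over the remaining labels when no overlap structure
#' is supplied or `kernel = "uniform"`).
#'
#' @param gold an `rd_corpus` with a `labels` column (or data frame
#'   with `id`, `labels`).
#' @param k number of annotators (>= 2).
#' @param noise per-item deviation probability in `[0, 1]`.
#' @param seed integer seed.
#' @param overlap optional 7x7 overlap matrix used to build the
#'   confusion kernel.
#' @param kernel `"overlap"` (default) or `"uniform"`.
#' @return an `rd_annotation`.
#' @export
simulate_annotators <- function(gold, k = 3L, noise = 0.2, seed = 13L,
                                overlap = NULL,
                                kernel = c("overlap", "uniform")) {
  kernel <- match.arg(kernel)
  stopifnot(k >= 2, noise >= 0, noise <= 1)
  labs8 <- all_domains()
  K <- matrix(1 / 7, 8, 8, dimnames = list(labs8, labs8))
  diag(K) <- 0
  K <- K / rowSums(K)
  if (kernel == "overlap" && !is.null(overlap) && any(overlap > 0)) {
    for (d in rownames(overlap)) {
      partners <- colnames(overlap)[overlap[d, ] > 0]
      if (length(partners)) {
        row <- stats::setNames(rep(0.3 / 7, 8), labs8)
        row[partners] <- 0.7 / length(partners)
        row[d] <- 0
        K[d, ] <- row / sum(row)
      }
    }
  }
  with_seed(seed, {
    annotations <- lapply(seq_len(k), function(a) {
      lapply(seq_len(nrow(gold)), function(i) {
        l <- gold$labels[[i]]
        if (stats::runif(1) >= noise) return(l)
        repl <- sample(labs8, 1L, prob = K[l[1], ])
        unique(c(repl, l[-1]))
      })
    })
    annotation_table(gold$id, annotations)
  })
}
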