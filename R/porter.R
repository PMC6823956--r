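# Porter (1980) suffix-stripping stemmer.
#
# No stemming library ships with base R, so the classic algorithm is
# implemented here directly: steps 1a-5b with the measure m, vowel,
# double-consonant and cvc conditions. Tokens containing characters
# outside a-z (digits, merged-MWE underscores, clinical tokens like
# "a+ox3") are returned unchanged; merged multiword expressions are
# deliberately never stemmed.

p_is_cons <- function(ch, i) {
  c <- ch[i]
  if (c %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c == "y") {
    if (i == 1L) return(TRUE)
    return(!p_is_cons(ch, i - 1L))
  }
  TRUE
}

p_types <- function(word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  vapply(seq_along(ch), function(i) p_is_cons(ch, i), logical(1))
}

# measure m: number of vowel->consonant transitions in [C](VC)^m[V]
p_measure <- function(word) {
  if (!nzchar(word)) return(0L)
  cons <- p_types(word)
  r <- rle(cons)
  v <- r$values
  m <- 0L
  for (i in seq_along(v)) {
    if (i < length(v) && !v[i] && v[i + 1L]) m <- m + 1L
  }
  m
}

p_has_vowel <- function(word) {
  if (!nzchar(word)) return(FALSE)
  any(!p_types(word))
}

# *d : ends with a double consonant
p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  cons <- p_types(word)
  cons[n]
}

# *o : ends cvc where the final consonant is not w, x or y
p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cons <- p_types(word)
  if (!(cons[n - 2L] && !cons[n - 1L] && cons[n])) return(FALSE)
  !(substr(word, n, n) %in% c("w", "x", "y"))
}

p_ends <- function(word, suffix) {
  n <- nchar(word); s <- nchar(suffix)
  n > s && substr(word, n - s + 1L, n) == suffix
}

p_stem_part <- function(word, suffix) {
  substr(word, 1L, nchar(word) - nchar(suffix))
}

# apply the first matching (suffix -> replacement) rule whose stem
# satisfies `cond`; rules are tried longest suffix first
p_rule_table <- function(word, rules, cond) {
  ord <- order(-nchar(names(rules)))
  for (suf in names(rules)[ord]) {
    if (p_ends(word, suf)) {
      stem <- p_stem_part(word, suf)
      if (cond(stem)) return(paste0(stem, rules[[suf]]))
      return(word)
    }
  }
  word
}

porter_stem_one <- function(word) {
  if (nchar(word) <= 2L || grepl("[^a-z]", word)) return(word)

  # step 1a
  if (p_ends(word, "sses")) {
    word <- paste0(p_stem_part(word, "sses"), "ss")
  } else if (p_ends(word, "ies")) {
    word <- paste0(p_stem_part(word, "ies"), "i")
  } else if (!p_ends(word, "ss") && p_ends(word, "s")) {
    word <- p_stem_part(word, "s")
  }

  # step 1b
  fired <- FALSE
  if (p_ends(word, "eed")) {
    stem <- p_stem_part(word, "eed")
    if (p_measure(stem) > 0L) word <- paste0(stem, "ee")
  } else if (p_ends(word, "ed") && p_has_vowel(p_stem_part(word, "ed"))) {
    word <- p_stem_part(word, "ed"); fired <- TRUE
  } else if (p_ends(word, "ing") && p_has_vowel(p_stem_part(word, "ing"))) {
    word <- p_stem_part(word, "ing"); fired <- TRUE
  }
  if (fired) {
    if (p_ends(word, "at") || p_ends(word, "bl") || p_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (p_double_cons(word) &&
               !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z"))) {
      word <- substr(word, 1L, nchar(word) - 1L)
    } else if (p_measure(word) == 1L && p_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c
  if (p_ends(word, "y") && p_has_vowel(p_stem_part(word, "y"))) {
    word <- paste0(p_stem_part(word, "y"), "i")
  }

  # step 2
  word <- p_rule_table(word, list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), function(stem) p_measure(stem) > 0L)

  # step 3
  word <- p_rule_table(word, list(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  ), function(stem) p_measure(stem) > 0L)

  # step 4
  n0 <- nchar(word)
  word <- p_rule_table(word, list(
    al = "", ance = "", ence = "", er = "", ic = "", able = "",
    ible = "", ant = "", ement = "", ment = "", ent = "", ou = "",
    ism = "", ate = "", iti = "", ous = "", ive = "", ize = ""
  ), function(stem) p_measure(stem) > 1L)
  if (nchar(word) == n0 && p_ends(word, "ion")) {
    stem <- p_stem_part(word, "ion")
    if (p_measure(stem) > 1L &&
        substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) {
      word <- stem
    }
  }

  # step 5a
  if (p_ends(word, "e")) {
    stem <- p_stem_part(word, "e")
    m <- p_measure(stem)
    if (m > 1L || (m == 1L && !p_cvc(stem))) word <- stem
  }
  # step 5b
  if (p_measure(word) > 1L && p_double_cons(word) &&
      substr(word, nchar(word), nchar(word)) == "l") {
    word <- substr(word, 1L, nchar(word) - 1L)
  }
  word
}

#' Porter-stem tokens
#'
#' Applies the Porter suffix-stripping algorithm to each token. Merged
#' multiword-expression tokens (containing `_`) and tokens with
#' non-alphabetic characters pass through unchanged, so MWEs remain
#' non-stemmed unigrams.
#'
#' @param tokens character vector of tokens.
#' @return character vector of stemmed tokens.
#' @examples
#' stem_tokens(c("hallucinations", "depressed", "panic_attack"))
#' @export
stem_tokens <- function(tokens) {
  if (!length(tokens)) return(character(0))
  vapply(tokens, porter_stem_one, character(1), USE.NAMES = FALSE)
}
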