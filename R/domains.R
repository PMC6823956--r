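#' The seven risk factor domains
#'
#' Clinically defined topics whose presence in an EHR sentence the
#' classifiers detect: Appearance, Mood, Interpersonal, Occupation,
#' Thought Content, Thought Process and Substance. An eighth label,
#' `"Other"`, is the open-world fallback for sentences matching none of
#' the seven; it is never a training label.
#'
#' @return `risk_domains()` returns the 7 domain names in their
#'   canonical order; `all_domains()` appends `"Other"`.
#' @examples
#' risk_domains()
#' @export
risk_domains <- function() {
  c("Appearance", "Mood", "Interpersonal", "Occupation",
    "ThoughtContent", "ThoughtProcess", "Substance")
}

#' @rdname risk_domains
#' @export
all_domains <- function() c(risk_domains(), "Other")

assert_domains <- function(x, allow_other = TRUE) {
  ok <- if (allow_other) all_domains() else risk_domains()
  bad <- setdiff(x, ok)
  if (length(bad)) {
    stop("unknown domain label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}
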