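#' Megadocument vector
#'
#' Aggregates the member-sentence embedding vectors of one domain
#' megadocument into a single unit vector: the L2-normalized centroid
#' (mean). This is the domain representation used by the cosine
#' similarity baseline.
#'
#' @param vectors numeric matrix of member-sentence embeddings (rows).
#' @return unit-norm numeric vector.
#' @export
megadocument_vector <- function(vectors) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (nrow(vectors) == 0) stop("empty megadocument", call. = FALSE)
  l2_normalize(colMeans(vectors))
}

#' Cosine similarity scores against domain vectors
#'
#' @param v a sentence embedding vector.
#' @param domain_vectors matrix with one row per domain (row names are
#'   domain labels).
#' @return named numeric vector of cosine similarities in `[-1, 1]`. A
#'   zero-norm input scores 0 everywhere with attribute
#'   `degenerate = TRUE`.
#' @export
cosine_scores <- function(v, domain_vectors) {
  stopifnot(length(v) == ncol(domain_vectors))
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    out <- stats::setNames(rep(0, nrow(domain_vectors)),
                           rownames(domain_vectors))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  dn <- sqrt(rowSums(domain_vectors^2))
  out <- as.numeric(domain_vectors %*% v) / (dn * nv)
  stats::setNames(out, rownames(domain_vectors))
}

# score matrix for the cosine baseline model
# aggregate = "centroid": cosine against normalized megadocument centroids
# aggregate = "max": exact pairwise mode, max cosine over member sentences
cosine_score_matrix <- function(X, model) {
  if (model$aggregate == "centroid") {
    C <- model$centroids
    dn <- sqrt(rowSums(C^2))
    xn <- sqrt(rowSums(X^2))
    S <- tcrossprod(X, C) / outer(xn, dn)
    S[xn == 0, ] <- 0
  } else {
    S <- matrix(0, nrow(X), length(model$members))
    colnames(S) <- names(model$members)
    xn <- sqrt(rowSums(X^2))
    for (j in seq_along(model$members)) {
      M <- model$members[[j]]
      mn <- sqrt(rowSums(M^2))
      sim <- tcrossprod(X, M) / outer(xn, mn)
      S[, j] <- apply(sim, 1, max)
    }
    S[xn == 0, ] <- 0
  }
  colnames(S) <- rownames(model$centroids)
  S
}
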