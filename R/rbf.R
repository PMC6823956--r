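#' RBF network configuration
#'
#' The radial basis function classifier: 512 inputs with dropout 0.2,
#' 700 Gaussian hidden units whose prototype vectors come from
#' per-domain k-means (100 prototypes for each of the 7 domains) and
#' share one distance-derived width, and 7 linear output nodes trained
#' with mean squared error under Adam for 50 epochs at batch size 128.
#' Only the output layer is fit; the prototypes stay fixed.
#'
#' @param input_nodes,output_nodes layer widths.
#' @param prototypes_per_domain k-means clusters per domain; the hidden
#'   layer has `7 * prototypes_per_domain` units.
#' @param input_dropout dropout rate on the input layer.
#' @param width_rule how the shared width is derived from the maximum
#'   pairwise prototype distance `d_max`: `"dmax_half"` for
#'   `d_max / 2` (the default; with many prototypes it keeps the
#'   Gaussian responses of typical in-domain distances well away from
#'   underflow), `"dmax_sqrt2m"` for the classical
#'   `d_max / sqrt(2 m)` heuristic (`m` = number of prototypes),
#'   `"dmax_sqrt2k"` for `d_max / sqrt(2 k)` with `k` the prototypes
#'   per domain, or `"custom"` with an explicit `width`. The
#'   square-root heuristics were designed for networks with a handful
#'   of centers; at several hundred prototypes they shrink the width
#'   so far that every activation underflows, so the proportional rule
#'   is the default.
#' @param width explicit width when `width_rule = "custom"`.
#' @param epochs,batch_size,learning_rate training schedule (Adam).
#' @param seed integer seed (k-means restarts, dropout, batch order).
#' @return an `rd_rbf_config` list.
#' @export
rbf_config <- function(input_nodes = 512L, prototypes_per_domain = 100L,
                       output_nodes = 7L, input_dropout = 0.2,
                       width_rule = c("dmax_half", "dmax_sqrt2m", "dmax_sqrt2k", "custom"),
                       width = NULL, epochs = 50L, batch_size = 128L,
                       learning_rate = 1e-3, seed = 13L) {
  width_rule <- match.arg(width_rule)
  stopifnot(input_nodes > 0, prototypes_per_domain > 0, output_nodes > 0,
            input_dropout >= 0, input_dropout < 1, epochs > 0,
            batch_size > 0)
  if (width_rule == "custom" && (is.null(width) || width <= 0)) {
    stop("width_rule = \"custom\" requires a positive width", call. = FALSE)
  }
  structure(list(input_nodes = as.integer(input_nodes),
                 prototypes_per_domain = as.integer(prototypes_per_domain),
                 hidden_nodes = as.integer(output_nodes * prototypes_per_domain),
                 output_nodes = as.integer(output_nodes),
                 input_dropout = input_dropout,
                 width_rule = width_rule, width = width,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "rd_rbf_config")
}

#' Select RBF prototype vectors by per-domain k-means
#'
#' Runs k-means independently on each domain megadocument's sentence
#' embeddings and pools the centroids. Each run is seeded with
#' k-means++ starting centers; 10 restarts are performed and the
#' solution with the best total within-cluster sum of squares kept.
#'
#' @param X embedding matrix of the training sentences.
#' @param labels single domain label per row of `X`.
#' @param k_per_domain clusters per domain; each domain must have at
#'   least this many sentences.
#' @param seed integer seed.
#' @return numeric matrix of `k_per_domain * n_domains` prototype rows,
#'   with the source domain in `attr(, "domain")`.
#' @export
select_prototypes <- function(X, labels, k_per_domain, seed = 13L) {
  stopifnot(is.matrix(X), nrow(X) == length(labels), k_per_domain >= 1)
  doms <- unique(labels)
  small <- doms[vapply(doms, function(d) sum(labels == d), integer(1)) < k_per_domain]
  if (length(small)) {
    stop("megadocument smaller than k_per_domain for domain(s): ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    protos <- vector("list", length(doms))
    for (j in seq_along(doms)) {
      Xd <- X[labels == doms[j], , drop = FALSE]
      if (k_per_domain == nrow(Xd)) {
        protos[[j]] <- Xd  # each sentence its own cluster
      } else {
        best <- NULL
        for (r in 1:10) {
          init <- kmeanspp_centers(Xd, k_per_domain)
          km <- suppressWarnings(stats::kmeans(Xd, centers = init,
                                               iter.max = 100))
          if (is.null(best) || km$tot.withinss < best$tot.withinss) {
            best <- km
          }
        }
        protos[[j]] <- best$centers
      }
    }
    P <- do.call(rbind, protos)
    rownames(P) <- NULL
    attr(P, "domain") <- rep(doms, each = k_per_domain)
    P
  })
}

# k-means++ seeding: first center uniform, then each next center
# drawn with probability proportional to squared distance from the
# nearest center chosen so far
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k > 1) {
    d2 <- cross_sqdist(X, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j, ] <- X[sample.int(n, 1L), ]
      } else {
        centers[j, ] <- X[sample.int(n, 1L, prob = d2), ]
      }
      d2 <- pmin(d2, cross_sqdist(X, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

#' Shared RBF width from prototype geometry
#'
#' All hidden units share one width derived from the maximum pairwise
#' Euclidean distance between the k-means centroids:
#' `sigma = d_max / sqrt(2 m)`, the classical heuristic, where `m` is
#' the divisor count passed in (`rbf_config()` chooses the number of
#' prototypes or the per-domain cluster count depending on
#' `width_rule`). The width is homogeneous of degree 1 in the input
#' scale.
#'
#' @param prototypes prototype matrix (>= 2 rows, not all identical).
#' @param m divisor inside the square root; defaults to the number of
#'   prototypes.
#' @return positive scalar width.
#' @examples
#' compute_width(rbind(c(0, 0), c(2, 0)))  # d_max = 2, m = 2 -> 1
#' @export
compute_width <- function(prototypes, m = nrow(prototypes)) {
  if (is.null(dim(prototypes)) || nrow(prototypes) < 2) {
    stop("need at least 2 prototypes", call. = FALSE)
  }
  d_max <- sqrt(max(cross_sqdist(prototypes, prototypes)))
  if (d_max == 0) stop("all prototypes identical (d_max = 0)", call. = FALSE)
  d_max / sqrt(2 * m)
}

#' Gaussian RBF hidden-layer activations
#'
#' `a_j = exp(-||v - p_j||^2 / (2 sigma^2))`: each activation lies in
#' `(0, 1]`, equals 1 exactly at the prototype, and decreases
#' monotonically with Euclidean distance.
#'
#' @param X embedding matrix (or a single vector).
#' @param prototypes prototype matrix.
#' @param width shared width `sigma`.
#' @return activation matrix, one column per hidden unit.
#' @export
rbf_hidden <- function(X, prototypes, width) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == ncol(prototypes), width > 0)
  exp(-cross_sqdist(X, prototypes) / (2 * width^2))
}

#' Train the RBF domain classifier
#'
#' Fits the linear output layer (hidden units -> 7 domains) by
#' mini-batch gradient descent on mean squared error; prototypes and
#' width are fixed inputs. Input dropout is applied to the embedding
#' before the hidden activations are computed.
#'
#' Hidden activations are mean-centered with their training means
#' before the readout (the means are absorbed into the output bias,
#' so the fitted model is the same linear readout of the Gaussian
#' activations). Centering removes the large common-mode activation
#' that every sentence induces across all prototypes, which otherwise
#' dominates the curvature and leaves the minority activation
#' patterns badly underfit within the fixed training schedule.
#'
#' @param X embedding matrix.
#' @param Y one-hot label matrix (column names give the label order).
#' @param config an [rbf_config()].
#' @param prototypes prototype matrix from [select_prototypes()].
#' @param width shared width from [compute_width()].
#' @return an `rd_rbf` model.
#' @export
train_rbf <- function(X, Y, config = rbf_config(), prototypes, width) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  if (nrow(X) == 0) stop("empty training set", call. = FALSE)
  if (ncol(X) != config$input_nodes) {
    stop("input dimension does not match config", call. = FALSE)
  }
  if (nrow(prototypes) != config$hidden_nodes) {
    stop("prototype count does not match hidden_nodes", call. = FALSE)
  }
  n <- nrow(X)
  h <- nrow(prototypes)
  center <- colMeans(rbf_hidden(X, prototypes, width))
  with_seed(config$seed, {
    params <- list(W = glorot_uniform(h, config$output_nodes),
                   b = numeric(config$output_nodes))
    opt <- adam_new(params)
    loss_history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      epoch_loss <- 0
      for (idx in minibatches(n, config$batch_size)) {
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        nb <- length(idx)
        mi <- dropout_mask(nb, config$input_nodes, config$input_dropout)
        if (!is.null(mi)) Xb <- Xb * mi
        A <- sweep(rbf_hidden(Xb, prototypes, width), 2, center)
        out <- sweep(A %*% params$W, 2, params$b, "+")
        err <- out - Yb
        epoch_loss <- epoch_loss + sum(err^2)
        dOut <- 2 * err / (nb * ncol(Yb))
        grads <- list(W = crossprod(A, dOut), b = colSums(dOut))
        upd <- adam_step(opt, params, grads, lr = config$learning_rate)
        opt <- upd$state
        params <- upd$params
      }
      loss_history[epoch] <- epoch_loss / (n * ncol(Y))
    }
    structure(list(kind = "rbf", params = params, prototypes = prototypes,
                   width = width, center = center,
                   label_order = colnames(Y), config = config,
                   loss_history = loss_history),
              class = "rd_rbf")
  })
}

# inference-mode per-domain scores (linear outputs, unbounded reals)
rbf_scores <- function(model, X) {
  if (ncol(X) != model$config$input_nodes) {
    stop("embedding dimension does not match the trained model",
         call. = FALSE)
  }
  A <- rbf_hidden(X, model$prototypes, model$width)
  A <- sweep(A, 2, model$center %||% 0)
  S <- sweep(A %*% model$params$W, 2, model$params$b, "+")
  colnames(S) <- model$label_order
  S
}
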