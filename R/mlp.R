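#' MLP configuration
#'
#' The three-layer multilayer perceptron used for domain
#' classification: 512 inputs with dropout 0.2, a 250-unit ReLU hidden
#' layer with dropout 0.5, and 7 sigmoid output nodes (one per risk
#' factor domain) trained with cross entropy under Adam for 60 epochs
#' at batch size 128. Sigmoid outputs give independent per-domain
#' likelihoods without softmax normalization across classes, which is
#' what the open-world thresholding step consumes.
#'
#' Two cross-entropy variants are provided. `loss = "node_ce"` (the
#' default) applies cross entropy to every output node independently
#' (binary cross entropy against the one-hot target), which keeps the
#' sigmoid activations calibrated as absolute per-domain likelihoods
#' -- the property the mean-plus-alpha-sigma thresholding relies on.
#' `loss = "categorical_ce"` is categorical cross entropy as the
#' common deep-learning frameworks define it over non-softmax outputs
#' (activations rescaled to sum to one inside the loss); it optimizes
#' only the relative score ordering, so its gradient vanishes once the
#' correct domain dominates and hard sentences keep low absolute
#' scores. Both train to the same argmax behaviour; the per-node
#' variant is the default because open-world thresholding consumes
#' absolute scores.
#'
#' @param input_nodes,hidden_nodes,output_nodes layer widths.
#' @param input_dropout,hidden_dropout dropout rates in `[0, 1)`.
#' @param epochs,batch_size,learning_rate training schedule (Adam).
#' @param loss `"node_ce"` (per-node cross entropy, calibrated
#'   likelihoods) or `"categorical_ce"` (sum-normalized categorical
#'   cross entropy).
#' @param seed integer seed controlling initialization, dropout and
#'   batch order.
#' @return an `rd_mlp_config` list.
#' @export
mlp_config <- function(input_nodes = 512L, hidden_nodes = 250L,
                       output_nodes = 7L, input_dropout = 0.2,
                       hidden_dropout = 0.5, epochs = 60L,
                       batch_size = 128L, learning_rate = 1e-3,
                       loss = c("node_ce", "categorical_ce"),
                       seed = 13L) {
  loss <- match.arg(loss)
  stopifnot(input_nodes > 0, hidden_nodes > 0, output_nodes > 0,
            input_dropout >= 0, input_dropout < 1,
            hidden_dropout >= 0, hidden_dropout < 1,
            epochs > 0, batch_size > 0)
  structure(list(input_nodes = as.integer(input_nodes),
                 hidden_nodes = as.integer(hidden_nodes),
                 output_nodes = as.integer(output_nodes),
                 input_dropout = input_dropout,
                 hidden_dropout = hidden_dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed)),
            class = "rd_mlp_config")
}

mlp_loss <- function(P, Y, loss) {
  if (loss == "categorical_ce") {
    # framework-style categorical cross entropy over non-softmax
    # outputs: activations rescaled to sum to one inside the loss
    Pn <- pmax(P / rowSums(P), 1e-12)
    -mean(rowSums(Y * log(Pn)))
  } else {
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    -mean(rowSums(Y * log(P) + (1 - Y) * log(1 - P)))
  }
}

# d(loss)/d(pre-sigmoid activation), averaged over the batch
mlp_dZ <- function(P, Y, loss) {
  if (loss == "categorical_ce") {
    s <- rowSums(P)
    ((P / s) - Y) * (1 - P) / nrow(P)
  } else {
    (P - Y) / nrow(P)
  }
}

#' Train the MLP domain classifier
#'
#' @param X embedding matrix (rows = training sentences).
#' @param Y one-hot label matrix over the 7 domains (single-label
#'   training data); column names give the label order.
#' @param config an [mlp_config()].
#' @return an `rd_mlp` model (weights, label order, per-epoch loss).
#' @export
train_mlp <- function(X, Y, config = mlp_config()) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  if (nrow(X) == 0) stop("empty training set", call. = FALSE)
  if (ncol(X) != config$input_nodes) {
    stop("input dimension does not match config", call. = FALSE)
  }
  if (ncol(Y) != config$output_nodes) {
    stop("label dimension does not match config", call. = FALSE)
  }
  n <- nrow(X)
  with_seed(config$seed, {
    params <- list(
      W1 = glorot_uniform(config$input_nodes, config$hidden_nodes),
      b1 = numeric(config$hidden_nodes),
      W2 = glorot_uniform(config$hidden_nodes, config$output_nodes),
      b2 = numeric(config$output_nodes)
    )
    opt <- adam_new(params)
    loss_history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      for (idx in minibatches(n, config$batch_size)) {
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        nb <- length(idx)
        mi <- dropout_mask(nb, config$input_nodes, config$input_dropout)
        if (!is.null(mi)) Xb <- Xb * mi
        Z1 <- sweep(Xb %*% params$W1, 2, params$b1, "+")
        H <- relu(Z1)
        mh <- dropout_mask(nb, config$hidden_nodes, config$hidden_dropout)
        Hd <- if (is.null(mh)) H else H * mh
        Z2 <- sweep(Hd %*% params$W2, 2, params$b2, "+")
        P <- sigmoid(Z2)
        dZ2 <- mlp_dZ(P, Yb, config$loss)
        grads <- list(
          W1 = NULL, b1 = NULL,
          W2 = crossprod(Hd, dZ2),
          b2 = colSums(dZ2)
        )
        dH <- tcrossprod(dZ2, params$W2)
        if (!is.null(mh)) dH <- dH * mh
        dZ1 <- dH * (Z1 > 0)
        grads$W1 <- crossprod(Xb, dZ1)
        grads$b1 <- colSums(dZ1)
        upd <- adam_step(opt, params, grads, lr = config$learning_rate)
        opt <- upd$state
        params <- upd$params
      }
      loss_history[epoch] <- mlp_loss(mlp_forward(X, params), Y, config$loss)
    }
    structure(list(kind = "mlp", params = params,
                   label_order = colnames(Y), config = config,
                   loss_history = loss_history),
              class = "rd_mlp")
  })
}

mlp_forward <- function(X, params) {
  H <- relu(sweep(X %*% params$W1, 2, params$b1, "+"))
  sigmoid(sweep(H %*% params$W2, 2, params$b2, "+"))
}

# inference-mode per-domain scores (sigmoid activations in (0,1))
mlp_scores <- function(model, X) {
  if (ncol(X) != model$config$input_nodes) {
    stop("embedding dimension does not match the trained model",
         call. = FALSE)
  }
  S <- mlp_forward(X, model$params)
  colnames(S) <- model$label_order
  S
}

# dense-layer parameter count (weights + biases)
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}
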