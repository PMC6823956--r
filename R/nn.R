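# Shared neural-network machinery: Adam optimizer, initialization,
# activations and dropout. Written against plain BLAS matrix algebra;
# at the corpus sizes this package targets (10^3-10^4 sentences of
# dimension 512) this trains in seconds and keeps the package free of
# deep-learning runtime dependencies.

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# one Adam update; lr etc. follow the common framework defaults
adam_step <- function(state, params, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

glorot_uniform <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

relu <- function(z) {
  z[z < 0] <- 0
  z
}

# inverted dropout mask (scales kept units by 1/(1-rate))
dropout_mask <- function(n, m, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(n * m, 1L, 1 - rate), n, m) / (1 - rate)
}

# one-hot encode training labels over a fixed label order
one_hot <- function(labels, label_order) {
  Y <- matrix(0, length(labels), length(label_order),
              dimnames = list(NULL, label_order))
  idx <- match(labels, label_order)
  if (anyNA(idx)) stop("label outside label order", call. = FALSE)
  Y[cbind(seq_along(labels), idx)] <- 1
  Y
}

minibatches <- function(n, batch_size) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}
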