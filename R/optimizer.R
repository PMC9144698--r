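# Adam optimizer over the model's weight list.

adam_init <- function(weights) {
  zero <- lapply(weights, function(w) {
    if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else numeric(length(w))
  })
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(weights)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    weights[[k]] <- weights[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}
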