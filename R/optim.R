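# Adam optimizer over a flat named list of parameter arrays.

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0) # preserves shape attributes
  list(m = zeros, v = zeros, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}
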