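# Primitive differentiable ops for the transformer. Each *_fwd returns the
# output plus whatever the matching *_bwd needs; gradients are exact
# (verified against finite differences in the test suite).

rowscale <- function(M, v) M * rep(v, each = nrow(M))

linear_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y <- Y + rep(b, each = nrow(Y))
  Y
}

linear_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

LN_EPS <- 1e-5

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(Y = rowscale(xhat, g) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- rowscale(dY, g)
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

gelu_fwd <- function(X) {
  Phi <- stats::pnorm(X)
  list(Y = X * Phi, Phi = Phi, X = X)
}

gelu_bwd <- function(dY, cache) {
  dY * (cache$Phi + cache$X * stats::dnorm(cache$X))
}

relu_fwd <- function(X) {
  m <- X > 0
  list(Y = X * m, mask = m)
}

relu_bwd <- function(dY, cache) dY * cache$mask

softmax_rows <- function(X) {
  m <- X[, 1]
  for (k in seq_len(ncol(X))[-1]) m <- pmax(m, X[, k])
  e <- exp(X - m)
  e / rowSums(e)
}

# AdamW with decoupled weight decay (applied to 2D weights only)
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && grepl("_w$", nm) && !is.null(dim(params[[nm]])))
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}
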