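# Internal neural-network primitives for CLA-PTNet: 1-D convolution with
# batch normalization and ELU (CBE), an LSTM long-dependency encoder (LDE),
# position-aware time-weighted self-attention (PTW-SA) and a linear head.
# All forward passes return caches for analytic backpropagation; gradients
# are verified against central finite differences in the test suite.
# Hot paths avoid ifelse/sweep/apply and batch the big matrix products.

sigmoid <- function(x) 1 / (1 + exp(-x))

elu_forward <- function(x) {
  y <- x
  neg <- which(x < 0)
  y[neg] <- exp(x[neg]) - 1
  g <- array(1, dim(x) %||% length(x))
  g[neg] <- y[neg] + 1
  list(out = y, grad = g)
}

# x: (B, t, c_in) array; W: (k, c_in, c_out); symmetric zero padding keeps
# the sequence length (k must be odd); compiled kernels.
conv1d_forward <- function(x, W, b) {
  list(out = conv1d_forward_cpp(x, W, b), cache = list(x = x))
}

conv1d_backward <- function(d_out, W, cache) {
  r <- conv1d_backward_cpp(d_out, cache$x, W)
  list(dx = r$dx, dW = r$dW, db = as.numeric(r$db))
}

# z: (B*t, c) matrix; per-channel batch normalization over the batch x time
# axis, with running statistics for evaluation mode.
bn_forward <- function(z, gamma, beta, buffers, training, momentum = 0.1,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(z)
    v <- colMeans(z^2) - mu^2
    buffers$mean <- (1 - momentum) * buffers$mean + momentum * mu
    buffers$var <- (1 - momentum) * buffers$var + momentum * v
  } else {
    mu <- buffers$mean
    v <- buffers$var
  }
  inv_std <- 1 / sqrt(v + eps)
  m <- nrow(z)
  xhat <- (z - matrix(mu, m, length(mu), byrow = TRUE)) *
    matrix(inv_std, m, length(mu), byrow = TRUE)
  out <- xhat * matrix(gamma, m, length(mu), byrow = TRUE) +
    matrix(beta, m, length(mu), byrow = TRUE)
  list(out = out, buffers = buffers,
       cache = list(xhat = xhat, inv_std = inv_std, training = training))
}

bn_backward <- function(dy, gamma, cache) {
  xhat <- cache$xhat
  m <- nrow(dy); cc <- ncol(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  gmat <- matrix(gamma, m, cc, byrow = TRUE)
  ivs <- matrix(cache$inv_std, m, cc, byrow = TRUE)
  if (cache$training) {
    dxhat <- dy * gmat
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dz <- (dxhat - matrix(s1 / m, m, cc, byrow = TRUE) -
             xhat * matrix(s2 / m, m, cc, byrow = TRUE)) * ivs
  } else {
    dz <- dy * gmat * ivs
  }
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

# CBE block: stacked (conv1d -> BN -> ELU); x: (B, t) input series.
cbe_block_forward <- function(x, conv_params, buffers, training) {
  B <- nrow(x); t <- ncol(x)
  a <- array(x, c(B, t, 1L))
  caches <- vector("list", length(conv_params))
  for (l in seq_along(conv_params)) {
    p <- conv_params[[l]]
    cv <- conv1d_forward(a, p$W, p$b)
    c_out <- dim(p$W)[3]
    z <- matrix(cv$out, B * t, c_out)
    bn <- bn_forward(z, p$gamma, p$beta, buffers[[l]], training)
    buffers[[l]] <- bn$buffers
    el <- elu_forward(bn$out)
    a <- array(el$out, c(B, t, c_out))
    caches[[l]] <- list(conv = cv$cache, bn = bn$cache, elu_grad = el$grad)
  }
  list(out = a, buffers = buffers, caches = caches)
}

cbe_block_backward <- function(d_out, conv_params, caches) {
  grads <- vector("list", length(conv_params))
  da <- d_out
  for (l in rev(seq_along(conv_params))) {
    p <- conv_params[[l]]
    ch <- caches[[l]]
    B <- dim(ch$conv$x)[1]; t <- dim(ch$conv$x)[2]
    c_out <- dim(p$W)[3]
    dz_elu <- matrix(da, B * t, c_out) * ch$elu_grad
    bnb <- bn_backward(dz_elu, p$gamma, ch$bn)
    cvb <- conv1d_backward(array(bnb$dz, c(B, t, c_out)), p$W, ch$conv)
    grads[[l]] <- list(W = cvb$dW, b = cvb$db,
                       gamma = bnb$dgamma, beta = bnb$dbeta)
    da <- cvb$dx
  }
  list(dx = da, grads = grads)
}

# Single LSTM layer over (B, t, c) input; returns the full hidden-state
# sequence (B, t, d). Gate order in the 4d blocks: input, forget, output,
# candidate; forget-gate bias is initialized at +1 elsewhere. The time loop
# runs in compiled code (src/nn_kernels.cpp); gradients are validated
# against finite differences in the test suite.
lstm_layer_forward <- function(x, p) {
  r <- lstm_forward_cpp(x, p$Wx, p$Wh, p$b)
  list(out = r$out, cache = list(x = x, r = r))
}

lstm_layer_backward <- function(dH, p, cache) {
  r <- cache$r
  bk <- lstm_backward_cpp(dH, cache$x, p$Wx, p$Wh, r$gi, r$gf, r$go, r$gg,
                          r$tc, r$Cst, r$out)
  list(dx = bk$dx,
       grads = list(Wx = bk$dWx, Wh = bk$dWh, b = as.numeric(bk$db)))
}

# LDE block: stacked LSTM layers, then ELU, then (training-mode) inverted
# dropout on the hidden-state sequence.
lde_block_forward <- function(x, lstm_params, dropout, training) {
  caches <- vector("list", length(lstm_params))
  a <- x
  for (l in seq_along(lstm_params)) {
    ls <- lstm_layer_forward(a, lstm_params[[l]])
    caches[[l]] <- ls$cache
    a <- ls$out
  }
  el <- elu_forward(a)
  out <- el$out
  mask <- NULL
  if (training && dropout > 0) {
    mask <- array(stats::rbinom(length(out), 1L, 1 - dropout) / (1 - dropout),
                  dim(out))
    out <- out * mask
  }
  list(out = out, caches = caches, elu_grad = el$grad, mask = mask)
}

lde_block_backward <- function(d_out, lstm_params, fw) {
  da <- d_out
  if (!is.null(fw$mask)) da <- da * fw$mask
  da <- da * fw$elu_grad
  grads <- vector("list", length(lstm_params))
  for (l in rev(seq_along(lstm_params))) {
    bk <- lstm_layer_backward(da, lstm_params[[l]], fw$caches[[l]])
    grads[[l]] <- bk$grads
    da <- bk$dx
  }
  list(dx = da, grads = grads)
}

softmax_rows <- function(S) {
  n <- nrow(S)
  mx <- S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

# PTW-SA over a batch (B, t, d): H' = H + P; Q/K/V projections of H'; key
# rows rescaled by the learnable time weights before scoring; compiled
# kernels do the per-sample t x t attention products.
ptwsa_block_forward <- function(H, p, scale) {
  r <- ptwsa_forward_cpp(H, p$P, p$Wq, p$Wk, p$Wv, p$w_time, scale)
  list(out = r$out, cache = r)
}

ptwsa_block_backward <- function(dO, p, cache, scale) {
  bk <- ptwsa_backward_cpp(dO, p$P, p$Wq, p$Wk, p$Wv, p$w_time, scale,
                           cache$Hp, cache$Qa, cache$Ka, cache$Va, cache$Kpa,
                           cache$Wc)
  list(dx = bk$dx,
       grads = list(P = bk$P, Wq = bk$Wq, Wk = bk$Wk, Wv = bk$Wv,
                    w_time = as.numeric(bk$w_time)))
}

# pooling of the attention output (B, t, d) -> (B, d)
pool_forward <- function(O, mode) {
  B <- dim(O)[1]; t <- dim(O)[2]; d <- dim(O)[3]
  if (mode == "mean") {
    Om <- matrix(aperm(O, c(2L, 1L, 3L)), t, B * d)
    matrix(colMeans(Om), B, d)
  } else {
    matrix(O[, t, ], B, d)
  }
}

pool_backward <- function(dpooled, t, mode) {
  B <- nrow(dpooled); d <- ncol(dpooled)
  dO <- array(0, c(B, t, d))
  if (mode == "mean") {
    for (i in seq_len(t)) dO[, i, ] <- dpooled / t
  } else {
    dO[, t, ] <- dpooled
  }
  dO
}

# ---- full network ----------------------------------------------------------

claptnet_forward_pass <- function(x, params, buffers, cfg, training) {
  cbe <- cbe_block_forward(x, params$conv, buffers$bn, training)
  lde <- lde_block_forward(cbe$out, params$lstm, cfg$dropout, training)
  scale <- attention_scale_value(cfg)
  att <- ptwsa_block_forward(lde$out, params$attn, scale)
  pooled <- pool_forward(att$out, cfg$pooling)
  yhat <- as.numeric(pooled %*% params$head$W + params$head$b)
  list(yhat = yhat, buffers = list(bn = cbe$buffers),
       cache = list(cbe = cbe, lde = lde, att = att, pooled = pooled,
                    t = ncol(x), scale = scale))
}

claptnet_backward_pass <- function(dy, params, cfg, cache) {
  B <- length(dy)
  dpooled <- matrix(dy, B, 1) %*% t(params$head$W)
  gW_head <- crossprod(cache$pooled, matrix(dy, B, 1))
  gb_head <- sum(dy)
  dO <- pool_backward(dpooled, cache$t, cfg$pooling)
  att_b <- ptwsa_block_backward(dO, params$attn, cache$att$cache, cache$scale)
  lde_b <- lde_block_backward(att_b$dx, params$lstm, cache$lde)
  cbe_b <- cbe_block_backward(lde_b$dx, params$conv, cache$cbe$caches)
  list(conv = cbe_b$grads, lstm = lde_b$grads, attn = att_b$grads,
       head = list(W = gW_head, b = gb_head))
}

attention_scale_value <- function(cfg) {
  switch(cfg$attention_scale,
         sqrt_d = sqrt(cfg$lstm_hidden),
         d = cfg$lstm_hidden)
}

# ---- parameter plumbing ----------------------------------------------------

# flatten a nested list of numeric arrays into a flat named list (stable
# depth-first order) and back; used by the Adam update and tidy()
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    v <- p[[nm]]
    if (is.list(v)) {
      if (is.null(names(v))) names(v) <- sprintf("l%d", seq_along(v))
      out <- c(out, flatten_params(v, key))
    } else {
      out[[key]] <- v
    }
  }
  out
}

assign_flat <- function(p, flat, prefix = "") {
  for (nm in names(p)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    v <- p[[nm]]
    if (is.list(v)) {
      if (is.null(names(v))) names(v) <- sprintf("l%d", seq_along(v))
      p[[nm]] <- assign_flat(v, flat, key)
    } else {
      p[[nm]] <- flat[[key]]
    }
  }
  p
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       step = 0L)
}

adam_update <- function(flat, grads_flat, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (nm in names(flat)) {
    g <- grads_flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    flat[[nm]] <- flat[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(flat = flat, state = state)
}
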