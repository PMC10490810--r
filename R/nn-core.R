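# Minimal neural-network primitives (1-D conv, pooling, dense layers,
# Adam) used by the CNN and LSTM beat classifiers.
#
# Convolutional activations use a flat layout: a matrix of shape
# (batch * length) x channels, rows ordered batch-fastest. In this
# layout im2col is plain row indexing (row (b, l + k - 1) of the input
# is row (b, l) shifted by B * (k - 1)) and the convolution output
# X_col %*% W is already the next layer's activation.

nn_init <- function(nrow, ncol, fan_in, kind = c("he", "glorot")) {
  kind <- match.arg(kind)
  s <- if (kind == "he") sqrt(2 / fan_in) else sqrt(1 / fan_in)
  matrix(rnorm(nrow * ncol, 0, s), nrow, ncol)
}

# a: (B*L) x Cin, W: (K*Cin) x Cout with column order k fastest within c
conv1d_forward <- function(a, W, b, B, L) {
  Cin <- ncol(a)
  K <- nrow(W) / Cin
  Lout <- L - K + 1
  xcol <- .im2col_1d(a, B, L, K)
  y <- xcol %*% W
  y <- y + rep(b, each = nrow(y))
  list(out = y, xcol = xcol, B = B, L = L, Lout = Lout, K = K, Cin = Cin)
}

conv1d_backward <- function(dout, cache, W, need_dx = TRUE) {
  dW <- crossprod(cache$xcol, dout)
  db <- colSums(dout)
  if (!need_dx) return(list(dA = NULL, dW = dW, db = db))
  dxcol <- tcrossprod(dout, W)
  dA <- .col2im_1d(dxcol, cache$B, cache$L, cache$K, cache$Cin)
  list(dA = dA, dW = dW, db = db)
}

relu_forward <- function(a) {
  mask <- a > 0
  list(out = a * mask, mask = mask)
}

dropout_forward <- function(a, p, training) {
  if (!training || p <= 0) return(list(out = a, mask = NULL))
  mask <- (matrix(runif(length(a)), nrow(a)) > p) / (1 - p)
  list(out = a * mask, mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# length-2 max pooling in the flat layout; L must be even
maxpool2_forward <- function(a, B, L) {
  L2 <- L %/% 2L
  s <- seq_len(B * L2)
  r1 <- s + B * (ceiling(s / B) - 1L)  # rows (b, 2m - 1)
  r2 <- r1 + B
  a1 <- a[r1, , drop = FALSE]
  a2 <- a[r2, , drop = FALSE]
  sel <- a1 >= a2
  list(out = pmax(a1, a2), sel = sel, r1 = r1, r2 = r2, L = L, B = B)
}

maxpool2_backward <- function(dout, cache) {
  dA <- matrix(0, cache$B * cache$L, ncol(dout))
  dA[cache$r1, ] <- dout * cache$sel
  dA[cache$r2, ] <- dout * (!cache$sel)
  dA
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean weighted cross-entropy + gradient w.r.t. logits
xent_grad <- function(logits, y_idx, class_w = NULL) {
  p <- softmax_rows(logits)
  B <- nrow(p)
  w <- if (is.null(class_w)) rep(1, B) else class_w[y_idx]
  picked <- p[cbind(seq_len(B), y_idx)]
  loss <- -sum(w * log(pmax(picked, 1e-12))) / sum(w)
  g <- p
  g[cbind(seq_len(B), y_idx)] <- g[cbind(seq_len(B), y_idx)] - 1
  g <- g * (w / sum(w))
  list(loss = loss, grad = g)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}
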