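#' LSTM hyperparameter specification
#'
#' A beat is consumed as a sequence of `seq_len` steps; the 250 samples
#' are cut into consecutive chunks of `250 / seq_len` values, so
#' `seq_len = 250` feeds scalar steps and `seq_len = 25` feeds 10-sample
#' frames (cheaper, same information). The final hidden state goes
#' through dropout and a dense softmax layer.
#'
#' @param hidden hidden-state width.
#' @param seq_len number of time steps (must divide the beat length).
#' @param dropout dropout probability on the final hidden state.
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size training schedule.
#' @param seed integer seed fixing initialization and shuffling.
#' @return an `lstm_spec` list.
#' @export
lstm_spec <- function(hidden = 64, seq_len = 250, dropout = 0.5,
                      learning_rate = 0.001, epochs = 100, batch_size = 64,
                      seed = 2020) {
  structure(list(hidden = as.integer(hidden), seq_len = as.integer(seq_len),
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "lstm_spec")
}

#' One LSTM cell step
#'
#' Gate equations of the standard cell:
#' `f_t = sigma(W_f [h_prev, x_t] + b_f)`,
#' `i_t = sigma(W_i [h_prev, x_t] + b_i)`,
#' `chat_t = tanh(W_c [h_prev, x_t] + b_c)`,
#' `c_t = f_t * c_prev + i_t * chat_t`,
#' `o_t = sigma(W_o [h_prev, x_t] + b_o)`,
#' `h_t = o_t * tanh(c_t)`.
#'
#' @param x_t input vector (length d) or matrix (batch x d).
#' @param h_prev,c_prev previous hidden / cell state, vector (length h)
#'   or matrix (batch x h).
#' @param params list with `W_f`, `W_i`, `W_c`, `W_o` (each h x (h + d),
#'   acting on the concatenated `[h_prev, x_t]`) and biases `b_f`, `b_i`,
#'   `b_c`, `b_o` (length h).
#' @return list with `h`, `c` and the gate activations `f`, `i`, `chat`,
#'   `o` (same shape as `h`).
#' @export
lstm_cell <- function(x_t, h_prev, c_prev, params) {
  vec_in <- is.null(dim(x_t))
  if (vec_in) {
    x_t <- matrix(x_t, 1); h_prev <- matrix(h_prev, 1)
    c_prev <- matrix(c_prev, 1)
  }
  if (ncol(x_t) + ncol(h_prev) != ncol(params$W_f))
    stop_invalid("lstm_cell: [h, x] width %d does not match W columns %d",
                 ncol(x_t) + ncol(h_prev), ncol(params$W_f))
  z <- cbind(h_prev, x_t)
  sig <- function(u) 1 / (1 + exp(-u))
  n_r <- nrow(z)
  f <- sig(tcrossprod(z, params$W_f) + rep(params$b_f, each = n_r))
  i <- sig(tcrossprod(z, params$W_i) + rep(params$b_i, each = n_r))
  chat <- tanh(tcrossprod(z, params$W_c) + rep(params$b_c, each = n_r))
  o <- sig(tcrossprod(z, params$W_o) + rep(params$b_o, each = n_r))
  c_t <- f * c_prev + i * chat
  h_t <- o * tanh(c_t)
  if (vec_in) {
    list(h = drop(h_t), c = drop(c_t), f = drop(f), i = drop(i),
         chat = drop(chat), o = drop(o))
  } else {
    list(h = h_t, c = c_t, f = f, i = i, chat = chat, o = o)
  }
}

lstm_init_params <- function(hidden, input_size, n_classes) {
  hd <- hidden + input_size
  gi <- function() nn_init(hidden, hd, hd, kind = "glorot")
  params <- list(W_f = gi(), W_i = gi(), W_c = gi(), W_o = gi(),
                 b_f = rep(1, hidden),   # forget bias 1: retain by default
                 b_i = rep(0, hidden), b_c = rep(0, hidden),
                 b_o = rep(0, hidden),
                 W_out = nn_init(hidden, n_classes, hidden),
                 b_out = rep(0, n_classes))
  params
}

# reshape beats (B x 250) into a list of T step matrices (B x d)
lstm_steps <- function(x, seq_len) {
  d <- ncol(x) / seq_len
  if (d != round(d))
    stop_invalid("seq_len %d does not divide the beat length %d", seq_len,
                 ncol(x))
  lapply(seq_len(seq_len), function(t)
    x[, ((t - 1) * d + 1):(t * d), drop = FALSE])
}

lstm_forward <- function(steps, params, hidden) {
  B <- nrow(steps[[1]])
  h <- matrix(0, B, hidden); c <- matrix(0, B, hidden)
  caches <- vector("list", length(steps))
  for (t in seq_along(steps)) {
    z <- cbind(h, steps[[t]])
    out <- lstm_cell(steps[[t]], h, c, params)
    caches[[t]] <- list(z = z, f = out$f, i = out$i, chat = out$chat,
                        o = out$o, c_prev = c, c = out$c)
    h <- out$h; c <- out$c
  }
  list(h = h, caches = caches)
}

lstm_backward <- function(dh_last, steps, params, caches, hidden) {
  B <- nrow(dh_last)
  d <- ncol(steps[[1]])
  zero_like <- function(p) p * 0
  g <- lapply(params[c("W_f", "W_i", "W_c", "W_o")], zero_like)
  gb <- lapply(params[c("b_f", "b_i", "b_c", "b_o")], zero_like)
  dh <- dh_last
  dc <- matrix(0, B, hidden)
  for (t in rev(seq_along(steps))) {
    cc <- caches[[t]]
    tc <- tanh(cc$c)
    do <- dh * tc
    dct <- dh * cc$o * (1 - tc^2) + dc
    df <- dct * cc$c_prev
    di <- dct * cc$chat
    dchat <- dct * cc$i
    dc <- dct * cc$f
    dzf <- df * cc$f * (1 - cc$f)
    dzi <- di * cc$i * (1 - cc$i)
    dzc <- dchat * (1 - cc$chat^2)
    dzo <- do * cc$o * (1 - cc$o)
    g$W_f <- g$W_f + crossprod(dzf, cc$z)
    g$W_i <- g$W_i + crossprod(dzi, cc$z)
    g$W_c <- g$W_c + crossprod(dzc, cc$z)
    g$W_o <- g$W_o + crossprod(dzo, cc$z)
    gb$b_f <- gb$b_f + colSums(dzf)
    gb$b_i <- gb$b_i + colSums(dzi)
    gb$b_c <- gb$b_c + colSums(dzc)
    gb$b_o <- gb$b_o + colSums(dzo)
    dz <- dzf %*% params$W_f + dzi %*% params$W_i +
      dzc %*% params$W_c + dzo %*% params$W_o
    dh <- dz[, seq_len(hidden), drop = FALSE]
  }
  c(g, gb)
}

train_lstm_impl <- function(x, y_idx, n_classes, spec, class_w = NULL) {
  set.seed(spec$seed)
  d <- ncol(x) / spec$seq_len
  if (d != round(d))
    stop_invalid("seq_len %d does not divide the beat length %d",
                 spec$seq_len, ncol(x))
  params <- lstm_init_params(spec$hidden, d, n_classes)
  opt <- adam_new(params)
  n <- nrow(x)
  losses <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    total <- 0
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1, n)]
      steps <- lstm_steps(x[idx, , drop = FALSE], spec$seq_len)
      fw <- lstm_forward(steps, params, spec$hidden)
      dp <- dropout_forward(fw$h, spec$dropout, training = TRUE)
      logits <- dp$out %*% params$W_out +
        rep(params$b_out, each = nrow(dp$out))
      ce <- xent_grad(logits, y_idx[idx], class_w)
      dW_out <- crossprod(dp$out, ce$grad)
      db_out <- colSums(ce$grad)
      dh <- tcrossprod(ce$grad, params$W_out)
      if (!is.null(dp$mask)) dh <- dh * dp$mask
      grads <- lstm_backward(dh, steps, params, fw$caches, spec$hidden)
      grads$W_out <- dW_out
      grads$b_out <- db_out
      st <- adam_step(params, grads, opt, spec$learning_rate)
      params <- st$params
      opt <- st$state
      total <- total + ce$loss * length(idx)
    }
    losses[ep] <- total / n
  }
  list(params = params, loss = losses)
}

predict_lstm_impl <- function(fit, x, spec, chunk = 512L) {
  out <- NULL
  for (start in seq(1, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(x))
    steps <- lstm_steps(x[idx, , drop = FALSE], spec$seq_len)
    fw <- lstm_forward(steps, fit$params, spec$hidden)
    logits <- fw$h %*% fit$params$W_out +
      rep(fit$params$b_out, each = nrow(fw$h))
    out <- rbind(out, softmax_rows(logits))
  }
  out
}
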