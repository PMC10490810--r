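#' CNN hyperparameter specification
#'
#' The base architecture is four convolution layers, two pooling layers
#' and four fully connected layers: conv(11x1) + dropout, conv(3x1),
#' pool, conv(3x1), pool, conv(3x1), then fully connected widths
#' 128-64-32-classes. The `aami` variant enlarges the intermediate
#' kernels to 9x1, 6x1, 3x1 to widen the feature-extraction window while
#' keeping kernels small.
#'
#' @param variant `"base"` or `"aami"`.
#' @param channels output channels of the four convolution layers.
#' @param fc widths of the first three fully connected layers.
#' @param dropout dropout probability (after conv-1 and after each fully
#'   connected layer except the last).
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size training schedule.
#' @param seed integer seed fixing initialization and shuffling.
#' @param kernels optional explicit kernel sizes (overrides `variant`).
#' @return a `cnn_spec` list.
#' @export
cnn_spec <- function(variant = c("base", "aami"), channels = c(8, 16, 16, 16),
                     fc = c(128, 64, 32), dropout = 0.5,
                     learning_rate = 0.001, epochs = 100, batch_size = 64,
                     seed = 2020, kernels = NULL) {
  variant <- match.arg(variant)
  if (is.null(kernels))
    kernels <- if (variant == "base") c(11, 3, 3, 3) else c(11, 9, 6, 3)
  structure(list(variant = variant, kernels = kernels, channels = channels,
                 fc = fc, dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "cnn_spec")
}

cnn_init_params <- function(spec, input_len, n_classes) {
  k <- spec$kernels; ch <- spec$channels
  cin <- c(1, ch[-length(ch)])
  params <- list()
  L <- input_len
  for (i in 1:4) {
    fan <- k[i] * cin[i]
    params[[paste0("Wc", i)]] <- nn_init(fan, ch[i], fan)
    params[[paste0("bc", i)]] <- rep(0, ch[i])
    L <- L - k[i] + 1
    if (i %in% c(2, 3)) L <- L %/% 2
  }
  widths <- c(L * ch[4], spec$fc, n_classes)
  for (i in seq_len(length(widths) - 1)) {
    params[[paste0("Wf", i)]] <- nn_init(widths[i], widths[i + 1], widths[i])
    params[[paste0("bf", i)]] <- rep(0, widths[i + 1])
  }
  params
}

cnn_forward <- function(x, params, spec, training = FALSE) {
  B <- nrow(x)
  L <- ncol(x)
  a <- matrix(as.vector(x), ncol = 1)  # flat (B*L) x 1, batch-fastest rows
  cache <- list()
  for (i in 1:4) {
    cv <- conv1d_forward(a, params[[paste0("Wc", i)]], params[[paste0("bc", i)]],
                         B, L)
    L <- cv$Lout
    rl <- relu_forward(cv$out)
    a <- rl$out
    cache[[paste0("conv", i)]] <- cv
    cache[[paste0("relu", i)]] <- rl$mask
    if (i == 1) {
      dp <- dropout_forward(a, spec$dropout, training)
      a <- dp$out
      cache$drop1 <- dp$mask
    }
    if (i %in% c(2, 3)) {
      trunc <- L %% 2L == 1L
      if (trunc) {  # rows of the last position are the trailing B rows
        a <- a[seq_len(B * (L - 1L)), , drop = FALSE]
        L <- L - 1L
      }
      pl <- maxpool2_forward(a, B, L)
      pl$trunc <- trunc
      a <- pl$out
      L <- L %/% 2L
      cache[[paste0("pool", i)]] <- pl
    }
  }
  cache$flat_L <- L
  cache$flat_C <- ncol(a)
  h <- matrix(as.vector(a), nrow = B)  # B x (L*C)
  n_fc <- sum(grepl("^Wf", names(params)))
  for (i in seq_len(n_fc)) {
    z <- h %*% params[[paste0("Wf", i)]]
    z <- z + rep(params[[paste0("bf", i)]], each = nrow(z))
    if (i < n_fc) {
      rl <- relu_forward(z)
      dp <- dropout_forward(rl$out, spec$dropout, training)
      cache[[paste0("fc_in", i)]] <- h
      cache[[paste0("fc_relu", i)]] <- rl$mask
      cache[[paste0("fc_drop", i)]] <- dp$mask
      h <- dp$out
    } else {
      cache[[paste0("fc_in", i)]] <- h
      h <- z
    }
  }
  list(logits = h, cache = cache, B = B)
}

cnn_backward <- function(dlogits, params, spec, cache, B) {
  grads <- list()
  n_fc <- sum(grepl("^Wf", names(params)))
  dh <- dlogits
  for (i in rev(seq_len(n_fc))) {
    hin <- cache[[paste0("fc_in", i)]]
    grads[[paste0("Wf", i)]] <- crossprod(hin, dh)
    grads[[paste0("bf", i)]] <- colSums(dh)
    dh <- tcrossprod(dh, params[[paste0("Wf", i)]])
    if (i > 1) {
      mask <- cache[[paste0("fc_drop", i - 1)]]
      if (!is.null(mask)) dh <- dh * mask
      dh <- dh * cache[[paste0("fc_relu", i - 1)]]
    }
  }
  da <- matrix(as.vector(dh), B * cache$flat_L, cache$flat_C)
  for (i in 4:1) {
    if (i %in% c(2, 3)) {
      pl <- cache[[paste0("pool", i)]]
      da <- maxpool2_backward(da, pl)
      if (pl$trunc)  # restore the dropped odd position with zero gradient
        da <- rbind(da, matrix(0, B, ncol(da)))
    }
    if (i == 1 && !is.null(cache$drop1)) da <- da * cache$drop1
    da <- da * cache[[paste0("relu", i)]]
    bk <- conv1d_backward(da, cache[[paste0("conv", i)]],
                          params[[paste0("Wc", i)]], need_dx = i > 1)
    grads[[paste0("Wc", i)]] <- bk$dW
    grads[[paste0("bc", i)]] <- bk$db
    da <- bk$dA
  }
  grads
}

train_cnn_impl <- function(x, y_idx, n_classes, spec, class_w = NULL) {
  set.seed(spec$seed)
  params <- cnn_init_params(spec, ncol(x), n_classes)
  opt <- adam_new(params)
  n <- nrow(x)
  losses <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    total <- 0
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1, n)]
      fw <- cnn_forward(x[idx, , drop = FALSE], params, spec, training = TRUE)
      ce <- xent_grad(fw$logits, y_idx[idx], class_w)
      grads <- cnn_backward(ce$grad, params, spec, fw$cache, fw$B)
      st <- adam_step(params, grads, opt, spec$learning_rate)
      params <- st$params
      opt <- st$state
      total <- total + ce$loss * length(idx)
    }
    losses[ep] <- total / n
  }
  list(params = params, loss = losses)
}

predict_cnn_impl <- function(fit, x, spec, chunk = 512L) {
  out <- NULL
  for (start in seq(1, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(x))
    fw <- cnn_forward(x[idx, , drop = FALSE], fit$params, spec,
                      training = FALSE)
    out <- rbind(out, softmax_rows(fw$logits))
  }
  out
}
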