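# Minimal CNN layer framework with hand-written backpropagation.
#
# A layer is an environment carrying parameters, gradients and a forward
# cache. Parameters are themselves environments (fields: v value, g gradient,
# plus optimizer state) so that a single object is shared between the layer
# and the optimizer. Feature batches are numeric arrays dim (H, W, C, N).

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$v <- value
  p$g <- NULL
  p$frozen <- FALSE
  p
}

he_init <- function(n_out, fan_in, gain = 2) {
  w <- numeric(as.double(n_out) * fan_in)
  w <- fill_rnorm_cpp(w, sqrt(gain / fan_in))
  dim(w) <- c(n_out, fan_in)
  w
}

nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L,
                    pad = (k - 1L) %/% 2L, bias = FALSE) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"
  l$in_ch <- in_ch; l$out_ch <- out_ch
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$W <- new_param(he_init(out_ch, in_ch * k * k))
  l$b <- if (bias) new_param(numeric(out_ch)) else NULL
  l$frozen <- FALSE
  l
}

nn_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  l <- new.env(parent = emptyenv())
  l$type <- "bn"
  l$ch <- ch; l$eps <- eps; l$momentum <- momentum
  l$gamma <- new_param(rep(1, ch))
  l$beta <- new_param(numeric(ch))
  l$run_mean <- numeric(ch)
  l$run_var <- rep(1, ch)
  l$frozen <- FALSE
  l
}

nn_relu <- function() {
  l <- new.env(parent = emptyenv())
  l$type <- "relu"; l$frozen <- FALSE
  l
}

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  l <- new.env(parent = emptyenv())
  l$type <- "maxpool"
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$frozen <- FALSE
  l
}

# Residual block: y = relu(branch(x) + shortcut(x)).
nn_resblock <- function(branch, shortcut = NULL) {
  l <- new.env(parent = emptyenv())
  l$type <- "resblock"
  l$branch <- branch       # list of layers
  l$shortcut <- shortcut   # list of layers or NULL (identity)
  l$frozen <- FALSE
  l
}

nn_fc <- function(in_dim, out_dim) {
  l <- new.env(parent = emptyenv())
  l$type <- "fc"
  l$W <- new_param(he_init(out_dim, in_dim, gain = 1))
  l$b <- new_param(numeric(out_dim))
  l$frozen <- FALSE
  l
}

layer_forward <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = {
      if (training && !l$frozen) l$x_cache <- x
      l$xdim <- dim(x)
      conv2d_forward_cpp(x, dim(x), l$W$v,
                        if (is.null(l$b)) NULL else l$b$v,
                        l$k, l$k, l$stride, l$pad)
    },
    bn = bn_forward(l, x, training),
    relu = {
      y <- relu_forward_cpp(x)
      if (training) l$y_cache <- y
      y
    },
    maxpool = {
      r <- maxpool_forward_cpp(x, dim(x), l$k, l$stride, l$pad)
      if (training) { l$argmax <- r$argmax; l$xdim <- dim(x); l$odim <- dim(r$y) }
      r$y
    },
    resblock = {
      if (training && !l$frozen) l$x_cache_dim <- dim(x)
      f <- x
      for (s in l$branch) f <- layer_forward(s, f, training)
      sh <- x
      if (!is.null(l$shortcut)) for (s in l$shortcut) sh <- layer_forward(s, sh, training)
      y <- add_relu_cpp(f, sh)
      if (training) l$y_cache <- y
      y
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      gr <- conv2d_backward_weight_cpp(dy, l$x_cache, l$xdim, l$out_ch,
                                       l$k, l$k, l$stride, l$pad,
                                       !is.null(l$b))
      l$W$g <- acc_grad(l$W$g, gr$dw)
      if (!is.null(l$b)) l$b$g <- acc_grad(l$b$g, gr$db)
      conv2d_backward_input_cpp(dy, l$xdim, l$W$v, l$k, l$k, l$stride, l$pad)
    },
    bn = bn_backward(l, dy),
    relu = relu_backward_cpp(dy, l$y_cache),
    maxpool = maxpool_backward_cpp(dy, l$argmax, l$xdim, l$odim[1], l$odim[2]),
    resblock = {
      dy <- relu_backward_cpp(dy, l$y_cache)
      dsh <- dy
      if (!is.null(l$shortcut))
        for (s in rev(l$shortcut)) dsh <- layer_backward(s, dsh)
      df <- dy
      for (s in rev(l$branch)) df <- layer_backward(s, df)
      df + dsh
    },
    stop("unknown layer type: ", l$type)
  )
}

acc_grad <- function(g, d) if (is.null(g)) d else g + d

# Batch norm over (H, W, N) per channel. Frozen or eval mode uses running
# statistics; backward is only defined for batch-statistics mode, which is
# the only mode in which gradients are ever requested.
bn_forward <- function(l, x, training) {
  use_batch <- training && !l$frozen
  if (!use_batch)
    return(bn_forward_eval_cpp(x, dim(x), l$gamma$v, l$beta$v,
                               l$run_mean, l$run_var, l$eps))
  r <- bn_forward_train_cpp(x, dim(x), l$gamma$v, l$beta$v, l$eps)
  l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * r$mean
  l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * r$var
  l$xhat <- r$xhat
  l$ivar <- r$ivar
  l$dims <- dim(x)
  r$y
}

bn_backward <- function(l, dy) {
  r <- bn_backward_cpp(dy, l$xhat, l$dims, l$gamma$v, l$ivar)
  l$gamma$g <- acc_grad(l$gamma$g, r$dgamma)
  l$beta$g <- acc_grad(l$beta$g, r$dbeta)
  r$dx
}

net_forward <- function(layers, x, training = FALSE) {
  for (l in layers) x <- layer_forward(l, x, training)
  x
}

net_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

# Recursively collect parameter environments of a layer list.
collect_params <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "resblock") {
      out <- c(out, collect_params(l$branch))
      if (!is.null(l$shortcut)) out <- c(out, collect_params(l$shortcut))
    } else {
      for (nm in c("W", "b", "gamma", "beta")) {
        p <- l[[nm]]
        if (!is.null(p) && is.environment(p)) out <- c(out, list(p))
      }
    }
  }
  out
}

set_frozen <- function(layers, frozen = TRUE) {
  for (l in layers) {
    l$frozen <- frozen
    if (l$type == "resblock") {
      set_frozen(l$branch, frozen)
      if (!is.null(l$shortcut)) set_frozen(l$shortcut, frozen)
    }
  }
  for (p in collect_params(layers)) p$frozen <- frozen
  invisible(layers)
}

zero_grads <- function(params) for (p in params) p$g <- NULL

# Adam update; skips frozen parameters.
adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, t = 1) {
  for (p in params) {
    if (p$frozen || is.null(p$g)) next
    g <- p$g
    if (weight_decay > 0) g <- g + weight_decay * p$v
    if (is.null(p$m1)) { p$m1 <- g * 0; p$m2 <- g * 0 }
    p$m1 <- beta1 * p$m1 + (1 - beta1) * g
    p$m2 <- beta2 * p$m2 + (1 - beta2) * g * g
    mhat <- p$m1 / (1 - beta1^t)
    vhat <- p$m2 / (1 - beta2^t)
    p$v <- p$v - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(params)
}

# SGD with momentum; skips frozen parameters.
sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 0) {
  for (p in params) {
    if (p$frozen || is.null(p$g)) next
    g <- p$g
    if (weight_decay > 0) g <- g + weight_decay * p$v
    if (is.null(p$m1)) p$m1 <- g * 0
    p$m1 <- momentum * p$m1 + g
    p$v <- p$v - lr * p$m1
  }
  invisible(params)
}

# Softmax cross-entropy on a 2 x N (or K x N) logit matrix.
# labels are 0-based class indices. Returns loss, probabilities and dlogits.
softmax_xent <- function(logits, labels, class_weights = NULL) {
  K <- nrow(logits); N <- ncol(logits)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  idx <- cbind(labels + 1L, seq_len(N))
  w <- if (is.null(class_weights)) rep(1, N) else class_weights[labels + 1L]
  loss <- sum(-log(pmax(p[idx], 1e-12)) * w) / sum(w)
  onehot <- matrix(0, K, N)
  onehot[idx] <- 1
  dlogits <- sweep(p - onehot, 2, w, "*") / sum(w)
  list(loss = loss, p = p, dlogits = dlogits)
}

# Deterministic scalar fingerprint of a parameter set (order-sensitive
# weighted sum; any parameter change perturbs it with probability ~1).
checksum_params <- function(params) {
  s <- 0
  i <- 0
  for (p in params) {
    i <- i + 1
    v <- as.numeric(p$v)
    s <- s + sum(v * sin(seq_along(v) * 0.1 + i))
  }
  s
}
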