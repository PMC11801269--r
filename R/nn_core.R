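# Compact reverse-mode layer toolkit used by every encoder in the model.
# Parameters are nested lists of numeric arrays; gradients mirror that
# structure exactly, so the optimizer can walk both trees in lock-step.

# He-uniform initialization for a fan_in x fan_out weight matrix
init_mat <- function(fan_in, fan_out, scale = NULL) {
  s <- scale %||% sqrt(6 / fan_in)
  matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

init_dense <- function(d_in, d_out) {
  list(W = init_mat(d_in, d_out), b = numeric(d_out))
}

# y = act(x %*% W + b); returns output plus the cache backward needs
dense_forward <- function(x, layer, act = c("relu", "linear", "sigmoid")) {
  act <- match.arg(act)
  a <- x %*% layer$W
  a <- sweep(a, 2, layer$b, "+")
  y <- switch(act, relu = relu(a), linear = a, sigmoid = sigmoid(a))
  list(y = y, x = x, y_act = y, act = act)
}

dense_backward <- function(dy, cache, layer) {
  da <- switch(cache$act,
    relu = dy * (cache$y_act > 0),
    linear = dy,
    sigmoid = dy * cache$y_act * (1 - cache$y_act))
  list(
    dx = da %*% t(layer$W),
    grad = list(W = crossprod(cache$x, da), b = colSums(da))
  )
}

# Parameter trees are nested lists whose numeric leaves are trainable;
# non-numeric leaves (architecture fields such as a conv node's type,
# stride or activation) pass through every tree operation unchanged.
zeros_like <- function(p) {
  if (is.list(p)) {
    r <- lapply(p, zeros_like)
    attributes(r) <- attributes(p)
    r
  } else if (is.numeric(p)) {
    z <- p
    z[] <- 0
    z
  } else p
}

# walk two trees in lock-step, pairing children by name when available;
# a missing counterpart for a numeric leaf acts as zero
tree_apply <- function(a, b, f) {
  if (is.list(a)) {
    nm <- names(a)
    r <- vector("list", length(a))
    bn <- names(b)
    for (i in seq_along(a)) {
      bb <- if (!is.null(nm) && nzchar(nm[i]) && !is.null(bn)) b[[nm[i]]]
        else if (i <= length(b)) b[[i]] else NULL
      r[[i]] <- tree_apply(a[[i]], bb, f)
    }
    attributes(r) <- attributes(a)        # keep names/class (encoding banks)
    r
  } else if (is.numeric(a)) {
    f(a, b %||% 0)
  } else a
}

tree_axpy <- function(a, b, alpha = 1) tree_apply(a, b, function(x, y) x + alpha * y)

# max |leaf| over a parameter tree (used in determinism / gradient tests)
tree_max_abs_diff <- function(a, b) {
  if (is.list(a)) {
    if (!length(a)) return(0)
    max(vapply(seq_along(a),
               function(i) tree_max_abs_diff(a[[i]], b[[i]]),
               numeric(1)))
  } else if (!is.numeric(a) || length(a) == 0) 0
  else max(abs(a - b))
}

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = zeros_like(params), v = zeros_like(params))
}

adam_step <- function(params, grads, opt) {
  opt$t <- opt$t + 1
  opt$m <- tree_apply(opt$m, grads, function(m, g) opt$beta1 * m + (1 - opt$beta1) * g)
  opt$v <- tree_apply(opt$v, grads, function(v, g) opt$beta2 * v + (1 - opt$beta2) * g * g)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  step <- tree_apply(opt$m, opt$v, function(m, v)
    opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps))
  params <- tree_apply(params, step, function(p, s) p - s)
  list(params = params, opt = opt)
}

# binary cross-entropy; returns loss and d loss / d prob (mean reduction)
bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  list(
    loss = -mean(y * log(p) + (1 - y) * log(1 - p)),
    dprob = (p - y) / (p * (1 - p)) / length(y)
  )
}
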