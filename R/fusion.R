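# Fusion of modality representations, the two-layer classification head and
# the Meta module that synthesizes a replacement vector for one missing
# modality. Fixed modality order for concatenation and gating: C, P, M, I.

FUSION_METHODS <- c("summation", "multiplication", "gating", "concatenation")

#' Configure the fusion stage
#'
#' @param method One of \code{"summation"}, \code{"multiplication"},
#'   \code{"gating"}, \code{"concatenation"}.
#' @param modalities Active modality set, subset of \code{c("C","P","M","I")}.
#' @param d_rep Per-modality representation dimension (equal across
#'   modalities; required by the non-concatenation methods).
#' @param hidden Classifier hidden width (default 64).
#' @param dropout Dropout rate on the classifier hidden layer (default 0).
#' @return A \code{fusion_config} list.
#' @export
fusion_config <- function(method = "concatenation",
                          modalities = c("C", "P", "M", "I"),
                          d_rep = 32, hidden = 64, dropout = 0) {
  method <- match.arg(method, FUSION_METHODS)
  modalities <- ALL_MODALITIES[ALL_MODALITIES %in% modalities]
  assert_that(length(modalities) >= 1, "need at least one active modality")
  structure(list(method = method, modalities = modalities, d_rep = d_rep,
                 hidden = hidden, dropout = dropout),
            class = "fusion_config")
}

fused_dim <- function(config) {
  if (config$method == "concatenation") config$d_rep * length(config$modalities)
  else config$d_rep
}

init_fusion <- function(config) {
  p <- list()
  if (config$method == "gating") {
    k <- length(config$modalities)
    p$gate <- init_dense(k * config$d_rep, k * config$d_rep)
  }
  # zero output layer: every input starts at probability 0.5, which keeps
  # the initial loss at log 2 regardless of representation magnitudes
  p$clf <- list(l1 = init_dense(fused_dim(config), config$hidden),
                l2 = list(W = matrix(0, config$hidden, 1), b = 0))
  p
}

init_meta <- function(config, hidden = 64) {
  k <- length(config$modalities)
  assert_that(k >= 2, "Meta module needs >=2 active modalities")
  metas <- list()
  for (m in config$modalities)
    metas[[m]] <- list(l1 = init_dense((k - 1) * config$d_rep, hidden),
                       l2 = init_dense(hidden, config$d_rep))
  metas
}

#' Fuse modality representations into one multimodal vector
#'
#' Summation and multiplication are elementwise; gating computes one sigmoid
#' gate vector per modality from the concatenation of all representations
#' and fuses as the gated sum; concatenation stacks vectors in the fixed
#' order C, P, M, I. An all-zero representation therefore annihilates the
#' multiplication fusion - the mechanism behind its degraded accuracy.
#'
#' @param reps Named list (or single-row matrices) of per-modality
#'   representations covering the active set.
#' @param config A [fusion_config()].
#' @param params Fusion parameters (needed for gating); from
#'   \code{init_fusion}.
#' @return Numeric vector (or matrix for multi-row input) of the fused
#'   representation.
#' @export
fuse <- function(reps, config, params = NULL) {
  reps <- lapply(reps[config$modalities], function(r) {
    if (is.null(dim(r))) matrix(r, 1) else r
  })
  assert_that(!any(vapply(reps, is.null, TRUE)),
              "representations missing for part of the active set")
  if (config$method != "concatenation") {
    dims <- vapply(reps, ncol, 1L)
    assert_that(length(unique(dims)) == 1,
                "%s fusion requires equal d_rep across modalities", config$method)
  }
  out <- fuse_forward(reps, config, params)$fused
  if (nrow(out) == 1) drop(out) else out
}

fuse_forward <- function(reps, config, params) {
  mods <- config$modalities
  H <- reps[mods]
  cache <- list(H = H)
  fused <- switch(config$method,
    summation = Reduce(`+`, H),
    multiplication = Reduce(`*`, H),
    concatenation = do.call(cbind, H),
    gating = {
      X <- do.call(cbind, H)
      gc <- dense_forward(X, params$gate, "sigmoid")
      k <- length(mods); d <- config$d_rep
      f <- 0
      for (i in seq_along(mods)) {
        cols <- ((i - 1) * d + 1):(i * d)
        f <- f + gc$y[, cols, drop = FALSE] * H[[i]]
      }
      cache$gate_cache <- gc
      cache$X <- X
      f
    })
  cache$fused <- fused
  cache
}

# returns per-modality gradients dH (named list) and fusion param grads
fuse_backward <- function(dfused, cache, config, params) {
  mods <- config$modalities
  H <- cache$H
  d <- config$d_rep
  grad <- list()
  dH <- switch(config$method,
    summation = {
      r <- lapply(mods, function(m) dfused)
      names(r) <- mods; r
    },
    multiplication = {
      r <- list()
      for (i in seq_along(mods)) {
        others <- Reduce(`*`, H[-i], matrix(1, nrow(dfused), ncol(dfused)))
        r[[mods[i]]] <- dfused * others
      }
      r
    },
    concatenation = {
      r <- list()
      for (i in seq_along(mods))
        r[[mods[i]]] <- dfused[, ((i - 1) * d + 1):(i * d), drop = FALSE]
      r
    },
    gating = {
      gc <- cache$gate_cache
      k <- length(mods)
      dG <- matrix(0, nrow(dfused), k * d)
      r <- list()
      for (i in seq_along(mods)) {
        cols <- ((i - 1) * d + 1):(i * d)
        g <- gc$y[, cols, drop = FALSE]
        r[[mods[i]]] <- dfused * g
        dG[, cols] <- dfused * H[[i]]
      }
      gb <- dense_backward(dG, gc, params$gate)
      grad$gate <- gb$grad
      dX <- gb$dx
      for (i in seq_along(mods)) {
        cols <- ((i - 1) * d + 1):(i * d)
        r[[mods[i]]] <- r[[mods[i]]] + dX[, cols, drop = FALSE]
      }
      r
    })
  list(dH = dH, grad = grad)
}

#' Two-layer classification head
#'
#' \code{hidden} fully connected layer with ReLU followed by a single output
#' unit with sigmoid: the model's progression probability.
#'
#' @param fused Fused representation vector or matrix (rows = patients).
#' @param params Classifier parameters (\code{l1}, \code{l2}) from
#'   \code{init_fusion()$clf}.
#' @return Probabilities in (0, 1).
#' @export
classify <- function(fused, params) {
  if (is.null(dim(fused))) fused <- matrix(fused, 1)
  assert_that(ncol(fused) == nrow(params$l1$W),
              "fused width %d does not match trained input width %d",
              ncol(fused), nrow(params$l1$W))
  drop(clf_forward(fused, params)$p)
}

clf_forward <- function(fused, params, drop_mask = NULL) {
  c1 <- dense_forward(fused, params$l1, "relu")
  h <- c1$y
  if (!is.null(drop_mask)) h <- h * drop_mask
  c2 <- dense_forward(h, params$l2, "sigmoid")
  list(p = c2$y, c1 = c1, c2 = c2, h = h, drop_mask = drop_mask)
}

clf_backward <- function(dp, cache, params) {
  b2 <- dense_backward(dp, cache$c2, params$l2)
  dh <- b2$dx
  if (!is.null(cache$drop_mask)) dh <- dh * cache$drop_mask
  b1 <- dense_backward(dh, cache$c1, params$l1)
  list(grad = list(l1 = b1$grad, l2 = b2$grad), dfused = b1$dx)
}

meta_forward <- function(X, mp) {
  c1 <- dense_forward(X, mp$l1, "relu")
  c2 <- dense_forward(c1$y, mp$l2, "relu")
  list(rep = c2$y, c1 = c1, c2 = c2)
}

meta_backward <- function(drep, cache, mp) {
  b2 <- dense_backward(drep, cache$c2, mp$l2)
  b1 <- dense_backward(b2$dx, cache$c1, mp$l1)
  list(grad = list(l1 = b1$grad, l2 = b2$grad), dX = b1$dx)
}

#' Synthesize a replacement representation for one missing modality
#'
#' The Meta module maps the concatenation (fixed order C, P, M, I) of the
#' other active modalities' representations to a replacement vector for the
#' target modality. Only single-modality missingness is supported; two or
#' more missing active modalities is an unsupported case.
#'
#' @param available Named list of the present modalities' representations.
#' @param target The missing modality to synthesize.
#' @param params Meta parameters (from a trained model:
#'   \code{model$params$meta}).
#' @param config The model's [fusion_config()].
#' @return Numeric vector (or matrix) of the target modality's \code{d_rep}.
#' @export
impute_modality <- function(available, target, params, config) {
  mods <- config$modalities
  assert_that(target %in% mods, "target %s is not in the active set", target)
  others <- setdiff(mods, target)
  miss <- setdiff(others, names(available))
  if (length(miss))
    stop_flex("unsupported case: more than one missing modality (also missing: %s)",
              paste(miss, collapse = ", "))
  X <- do.call(cbind, lapply(available[others], function(r)
    if (is.null(dim(r))) matrix(r, 1) else r))
  out <- meta_forward(X, params[[target]])$rep
  if (nrow(out) == 1) drop(out) else out
}
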