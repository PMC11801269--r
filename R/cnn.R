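# Image branch: configurable convolutional backbones over pathology tiles,
# tile-level pooling (mean or attention) and projection to d_rep.
# Backbones are layer graphs over the C++ conv/pool kernels; ResNet variants
# use bias-convolutions without batch normalization (batches here are small
# tile stacks) and a 2x2 stride-2 max pool.

conv_node <- function(kh, cin, cout, stride = 1, pad = NULL, act = "relu") {
  pad <- pad %||% ((kh - 1) %/% 2)
  fan_in <- kh * kh * cin
  list(type = "conv", stride = stride, pad = pad, act = act,
       W = array(runif(kh * kh * cin * cout, -sqrt(6 / fan_in), sqrt(6 / fan_in)),
                 c(kh, kh, cin, cout)),
       b = numeric(cout))
}

pool_node <- function() list(type = "pool")

block_node <- function(kind, cin, cout, stride = 1) {
  if (kind == "basic") {
    down <- if (stride != 1 || cin != cout) conv_node(1, cin, cout, stride, 0, "linear")
    list(type = "block", kind = kind,
         convs = list(conv_node(3, cin, cout, stride, act = "relu"),
                      conv_node(3, cout, cout, 1, act = "linear")),
         down = down)
  } else {                                  # bottleneck, expansion 4
    mid <- cout %/% 4
    down <- if (stride != 1 || cin != cout) conv_node(1, cin, cout, stride, 0, "linear")
    list(type = "block", kind = kind,
         convs = list(conv_node(1, cin, mid, 1, 0, "relu"),
                      conv_node(3, mid, mid, stride, act = "relu"),
                      conv_node(1, mid, cout, 1, 0, "linear")),
         down = down)
  }
}

resnet_layers <- function(blocks, kind, in_channels) {
  widths <- if (kind == "basic") c(64, 128, 256, 512) else c(256, 512, 1024, 2048)
  layers <- list(conv_node(7, in_channels, 64, stride = 2, pad = 3), pool_node())
  cin <- 64
  for (s in 1:4) {
    for (b in seq_len(blocks[s])) {
      stride <- if (s > 1 && b == 1) 2 else 1
      layers[[length(layers) + 1]] <- block_node(kind, cin, widths[s], stride)
      cin <- widths[s]
    }
  }
  layers
}

vgg_layers <- function(in_channels) {
  cfg <- c(64, 64, NA, 128, 128, NA, 256, 256, 256, NA,
           512, 512, 512, NA, 512, 512, 512)
  layers <- list(); cin <- in_channels
  for (v in cfg) {
    if (is.na(v)) layers[[length(layers) + 1]] <- pool_node()
    else {
      layers[[length(layers) + 1]] <- conv_node(3, cin, v)
      cin <- v
    }
  }
  layers
}

# two pools only: the tap point keeps a quarter of the tile resolution,
# which the SCDA localization needs
tiny_layers <- function(in_channels) {
  list(conv_node(3, in_channels, 4), pool_node(),
       conv_node(3, 4, 8), pool_node(),
       conv_node(3, 8, 16),
       conv_node(3, 16, 16))
}

backbone_emb_dim <- function(architecture) {
  switch(architecture, tiny_cnn = 16, vgg16 = 512,
         resnet18 = 512, resnet34 = 512, resnet50 = 2048)
}

#' Configure the image-branch backbone
#'
#' @param architecture One of \code{"tiny_cnn"} (a 4-conv-layer desk-scale
#'   backbone), \code{"resnet18"}, \code{"resnet34"}, \code{"resnet50"},
#'   \code{"vgg16"}. The feature-map tap point is the last convolutional
#'   stage, which always retains spatial extent (required by SCDA).
#' @param pooling Tile-level pooling across a patient's tiles: \code{"mean"}
#'   (default) or \code{"attention"}.
#' @param d_rep Output representation dimension (default 32).
#' @param in_channels Input channels (default 3).
#' @return A \code{backbone_config} list.
#' @export
backbone_config <- function(architecture = c("tiny_cnn", "resnet18", "resnet34",
                                             "resnet50", "vgg16"),
                            pooling = c("mean", "attention"),
                            d_rep = 32, in_channels = 3) {
  architecture <- match.arg(architecture)
  pooling <- match.arg(pooling)
  structure(list(architecture = architecture, pooling = pooling,
                 d_rep = d_rep, in_channels = in_channels),
            class = "backbone_config")
}

#' Initialize backbone parameters
#'
#' Weights are drawn from the current RNG state (seed upstream for
#' reproducibility); no pretrained weights are downloaded.
#'
#' @param config A [backbone_config()].
#' @return Parameter list: \code{layers}, \code{proj}, and for attention
#'   pooling a query vector \code{attn_q}.
#' @export
init_backbone <- function(config) {
  layers <- switch(config$architecture,
    tiny_cnn = tiny_layers(config$in_channels),
    vgg16 = vgg_layers(config$in_channels),
    resnet18 = resnet_layers(c(2, 2, 2, 2), "basic", config$in_channels),
    resnet34 = resnet_layers(c(3, 4, 6, 3), "basic", config$in_channels),
    resnet50 = resnet_layers(c(3, 4, 6, 3), "bottleneck", config$in_channels))
  emb <- backbone_emb_dim(config$architecture)
  params <- list(layers = layers, proj = init_dense(emb, config$d_rep))
  if (config$pooling == "attention") params$attn_q <- list(q = numeric(emb))
  params
}

conv_fw <- function(x, node) {
  y <- .conv2d_forward(x, node$W, node$b, node$stride, node$pad)
  if (node$act == "relu") y <- relu(y)
  y
}

conv_bw <- function(x, y, dy, node) {
  if (node$act == "relu") dy <- dy * (y > 0)
  g <- .conv2d_backward(x, node$W, dy, node$stride, node$pad)
  list(dx = g$dx, grad = list(W = g$dw, b = g$db))
}

node_forward <- function(x, node) {
  if (node$type == "conv") {
    list(y = conv_fw(x, node), x = x)
  } else if (node$type == "pool") {
    p <- .maxpool2_forward(x)
    list(y = p$y, idx = p$idx, xdim = dim(x))
  } else {                                  # residual block
    cc <- list(); h <- x
    for (cv in node$convs) {
      cc[[length(cc) + 1]] <- list(x = h)
      h <- conv_fw(h, cv)
      cc[[length(cc)]]$y <- h
    }
    sc <- if (!is.null(node$down)) {
      s <- conv_fw(x, node$down)
      list(x = x, y = s)
    } else NULL
    skip <- if (is.null(sc)) x else sc$y
    y <- relu(h + skip)
    list(y = y, convs = cc, down = sc, x = x)
  }
}

node_backward <- function(dy, cache, node) {
  if (node$type == "conv") {
    conv_bw(cache$x, cache$y, dy, node)
  } else if (node$type == "pool") {
    list(dx = .maxpool2_backward(dy, cache$idx, as.integer(cache$xdim)),
         grad = list())
  } else {
    dy <- dy * (cache$y > 0)
    dskip <- dy
    dh <- dy
    gconvs <- vector("list", length(node$convs))
    for (i in rev(seq_along(node$convs))) {
      bw <- conv_bw(cache$convs[[i]]$x, cache$convs[[i]]$y, dh, node$convs[[i]])
      gconvs[[i]] <- bw$grad
      dh <- bw$dx
    }
    gdown <- NULL
    dx <- dh
    if (!is.null(node$down)) {
      bwd <- conv_bw(cache$down$x, cache$down$y, dskip, node$down)
      gdown <- bwd$grad
      dx <- dx + bwd$dx
    } else dx <- dx + dskip
    g <- list(convs = gconvs)
    if (!is.null(gdown)) g$down <- gdown
    list(dx = dx, grad = g)
  }
}

# pull only trainable leaves from a node (mirrors node_grad structure)
node_params <- function(node) {
  if (node$type == "conv") list(W = node$W, b = node$b)
  else if (node$type == "pool") list()
  else {
    g <- list(convs = lapply(node$convs, function(cv) list(W = cv$W, b = cv$b)))
    if (!is.null(node$down)) g$down <- list(W = node$down$W, b = node$down$b)
    g
  }
}

node_set_params <- function(node, p) {
  if (node$type == "conv") { node$W <- p$W; node$b <- p$b }
  else if (node$type == "block") {
    for (i in seq_along(node$convs)) {
      node$convs[[i]]$W <- p$convs[[i]]$W
      node$convs[[i]]$b <- p$convs[[i]]$b
    }
    if (!is.null(node$down)) { node$down$W <- p$down$W; node$down$b <- p$down$b }
  }
  node
}

# forward a tile stack (H x W x C x N) to per-tile embeddings (N x emb)
cnn_forward <- function(x, params) {
  caches <- vector("list", length(params$layers))
  h <- x
  for (i in seq_along(params$layers)) {
    caches[[i]] <- node_forward(h, params$layers[[i]])
    h <- caches[[i]]$y
  }
  fmap <- h                                 # tap point: last conv stage
  d <- dim(fmap)
  # global average pool over H, W
  emb <- matrix(0, d[4], d[3])
  for (n in seq_len(d[4])) emb[n, ] <- colMeans(matrix(fmap[, , , n], d[1] * d[2], d[3]))
  list(emb = emb, fmap = fmap, caches = caches)
}

cnn_backward <- function(demb, cache, params) {
  d <- dim(cache$fmap)
  dfmap <- array(0, d)
  for (n in seq_len(d[4]))
    dfmap[, , , n] <- array(rep(demb[n, ] / (d[1] * d[2]), each = d[1] * d[2]),
                            d[1:3])
  grads <- vector("list", length(params$layers))
  dh <- dfmap
  for (i in rev(seq_along(params$layers))) {
    bw <- node_backward(dh, cache$caches[[i]], params$layers[[i]])
    grads[[i]] <- bw$grad
    dh <- bw$dx
  }
  list(layer_grads = grads, dx = dh)
}

# pool per-tile embeddings into per-patient vectors.
# groups: integer vector mapping each tile row to a patient slot 1..n
tile_pool_forward <- function(emb, groups, n, params, pooling) {
  d <- ncol(emb)
  pooled <- matrix(0, n, d)
  cache <- list(groups = groups, n = n, pooling = pooling, emb = emb)
  if (pooling == "mean") {
    cnt <- tabulate(groups, n)
    for (g in seq_len(n)) if (cnt[g] > 0)
      pooled[g, ] <- colMeans(emb[groups == g, , drop = FALSE])
    cache$cnt <- cnt
  } else {                                  # attention
    s <- drop(emb %*% params$attn_q$q)
    w <- numeric(length(s))
    for (g in seq_len(n)) {
      i <- which(groups == g)
      if (!length(i)) next
      e <- exp(s[i] - max(s[i]))
      w[i] <- e / sum(e)
      pooled[g, ] <- colSums(emb[i, , drop = FALSE] * w[i])
    }
    cache$w <- w; cache$s <- s
  }
  list(pooled = pooled, cache = cache)
}

tile_pool_backward <- function(dpooled, cache, params) {
  emb <- cache$emb; groups <- cache$groups
  demb <- matrix(0, nrow(emb), ncol(emb))
  dq <- NULL
  if (cache$pooling == "mean") {
    for (g in seq_len(cache$n)) {
      i <- which(groups == g)
      if (!length(i)) next
      demb[i, ] <- matrix(dpooled[g, ] / length(i), length(i), ncol(emb),
                          byrow = TRUE)
    }
  } else {
    dq <- numeric(ncol(emb))
    for (g in seq_len(cache$n)) {
      i <- which(groups == g)
      if (!length(i)) next
      w <- cache$w[i]
      dp <- dpooled[g, ]
      de_direct <- outer(w, dp)
      dw <- drop(emb[i, , drop = FALSE] %*% dp)
      ds <- w * (dw - sum(w * dw))          # softmax backward
      demb[i, ] <- de_direct + outer(ds, params$attn_q$q)
      dq <- dq + drop(t(emb[i, , drop = FALSE]) %*% ds)
    }
  }
  list(demb = demb, dq = dq)
}

#' Encode a patient's pathology tiles into a modality representation
#'
#' Runs each tile through the backbone, pools tile embeddings (mean by
#' default) and projects to \code{d_rep}. Deterministic given parameters.
#'
#' @param tiles An [image_set()] or a list of tile arrays
#'   \code{c(H, W, 3)}.
#' @param config A [backbone_config()].
#' @param params Parameters from [init_backbone()].
#' @return Numeric vector of length \code{d_rep}.
#' @export
encode_tiles <- function(tiles, config, params) {
  if (inherits(tiles, "image_set")) tiles <- tiles$tiles
  assert_that(length(tiles) >= 1, "zero tiles: route patient to the Meta module")
  x <- simplify2array(tiles)                # H x W x C x N
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  fw <- cnn_forward(x, params)
  pool <- tile_pool_forward(fw$emb, rep(1L, dim(x)[4]), 1L, params, config$pooling)
  pc <- dense_forward(pool$pooled, params$proj, "relu")
  drop(pc$y)
}

#' Tap-point spatial feature map for one tile
#'
#' Returns the activation map of the last convolutional stage, the input to
#' SCDA heat-map construction.
#'
#' @param tile Numeric array \code{c(H, W, 3)}.
#' @param config A [backbone_config()].
#' @param params Parameters from [init_backbone()].
#' @return Array \code{c(H', W', channels)}.
#' @export
feature_map <- function(tile, config, params) {
  x <- array(tile, c(dim(tile), 1))
  fw <- cnn_forward(x, params)
  d <- dim(fw$fmap)
  assert_that(d[1] >= 1 && d[2] >= 1, "tap point lost spatial extent")
  array(fw$fmap[, , , 1], d[1:3])
}
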