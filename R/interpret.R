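# Integrated Gradients attribution (per feature, per modality, per
# population) and SCDA-style heat maps with region-of-interest extraction.

#' Integrated Gradients for an arbitrary differentiable function
#'
#' Computes \code{IG_i = (x_i - x'_i) * mean_k dF/dx_i} with the gradient
#' evaluated at \code{x' + (k/steps) (x - x')}, \code{k = 1..steps}. For a
#' linear F this is exact at any step count; the completeness axiom
#' (attributions sum to \code{F(x) - F(x')}) holds up to the Riemann-sum
#' error.
#'
#' @param f Function taking an input like \code{x} and returning
#'   \code{list(value = scalar, grad = same shape as x)}. \code{x} may be a
#'   numeric array or a named list of numeric arrays.
#' @param x Input sample.
#' @param baseline Baseline of the same shape as \code{x}.
#' @param steps Number of path steps (>= 1); default 50.
#' @return List with \code{attributions} (shape of \code{x}),
#'   \code{value}, \code{baseline_value} and \code{completeness_gap}
#'   (absolute difference between the attribution sum and
#'   \code{value - baseline_value}).
#' @export
integrated_gradients <- function(f, x, baseline, steps = 50) {
  assert_that(steps >= 1, "steps must be >= 1")
  islist <- is.list(x)
  lin <- function(a, b, t) if (islist)
    tree_apply(b, a, function(bb, aa) bb + t * (aa - bb)) else baseline + t * (x - baseline)
  acc <- NULL
  for (k in seq_len(steps)) {
    g <- f(lin(x, baseline, k / steps))$grad
    acc <- if (is.null(acc)) g else
      if (islist) tree_apply(acc, g, `+`) else acc + g
  }
  mean_g <- if (islist) tree_apply(acc, acc, function(a, b) a / steps) else acc / steps
  attr_ <- if (islist)
    tree_apply(tree_apply(x, baseline, `-`), mean_g, `*`)
  else (x - baseline) * mean_g
  v1 <- f(x)$value
  v0 <- f(baseline)$value
  sum_tree <- function(z) if (is.list(z)) sum(vapply(z, sum_tree, numeric(1))) else sum(z)
  total <- sum_tree(attr_)
  list(attributions = attr_, value = v1, baseline_value = v0,
       completeness_gap = abs(total - (v1 - v0)))
}

# forward/backward of the full model for ONE patient, as a function of the
# attribution-level inputs: per-feature embeddings (tabular) and the
# standardized tile stack (image). Missing modalities go through Meta.
ig_model_fun <- function(model, prep, i) {
  config <- model$config
  mods <- config$modalities
  present <- prep$present[i, ]
  function(inputs) {
    H <- list(); caches <- list()
    for (m in mods) {
      if (!present[[m]]) { H[[m]] <- matrix(0, 1, config$d_rep); next }
      if (m == "I") {
        x <- inputs$I
        fw <- cnn_forward(x, model$params$img)
        pool <- tile_pool_forward(fw$emb, rep(1L, dim(x)[4]), 1L,
                                  model$params$img, config$tile_pooling)
        pc <- dense_forward(pool$pooled, model$params$img$proj, "relu")
        H[[m]] <- pc$y
        caches[[m]] <- list(cnn = fw, pool = pool, proj = pc)
      } else if (config$fet_pathway == "encoded") {
        U <- array(inputs[[m]], c(1, dim(inputs[[m]])))   # 1 x d_enc x F
        fw <- fet_forward_embedded(U, model$params$enc[[m]])
        H[[m]] <- fw$rep
        caches[[m]] <- fw
      } else {
        fw <- mlp_forward(matrix(inputs[[m]], 1), model$params$enc[[m]])
        H[[m]] <- fw$rep
        caches[[m]] <- fw
      }
    }
    meta_caches <- list()
    for (m in mods) {
      if (present[[m]]) next
      if (config$use_meta && !is.null(model$params$meta)) {
        others <- setdiff(mods, m)
        X <- do.call(cbind, H[others])
        mc <- meta_forward(X, model$params$meta[[m]])
        H[[m]] <- mc$rep
        meta_caches[[m]] <- list(cache = mc, others = others)
      }
    }
    fc <- fuse_forward(H, model$fcfg, model$params$fusion)
    cc <- clf_forward(fc$fused, model$params$clf)
    # backward to the inputs
    cb <- clf_backward(matrix(1, 1, 1), cc, model$params$clf)
    fb <- fuse_backward(cb$dfused, fc, model$fcfg, model$params$fusion)
    dH <- fb$dH
    for (m in names(meta_caches)) {
      mb <- meta_backward(dH[[m]], meta_caches[[m]]$cache,
                          model$params$meta[[m]])
      d <- config$d_rep
      for (j in seq_along(meta_caches[[m]]$others)) {
        o <- meta_caches[[m]]$others[j]
        dH[[o]] <- dH[[o]] + mb$dX[, ((j - 1) * d + 1):(j * d), drop = FALSE]
      }
    }
    grad <- list()
    for (m in mods) {
      if (!present[[m]]) next
      if (m == "I") {
        pb <- dense_backward(dH[[m]], caches$I$proj, model$params$img$proj)
        poolb <- tile_pool_backward(pb$dx, caches$I$pool$cache, model$params$img)
        cbk <- cnn_backward(poolb$demb, caches$I$cnn, model$params$img)
        grad$I <- cbk$dx
      } else if (config$fet_pathway == "encoded") {
        bk <- fet_backward_embedded(dH[[m]], caches[[m]],
                                    model$params$enc[[m]])
        grad[[m]] <- array(bk$dU[1, , ], dim(bk$dU)[2:3])
      } else {
        bk <- mlp_backward(dH[[m]], caches[[m]], model$params$enc[[m]])
        grad[[m]] <- drop(bk$dX)
      }
    }
    list(value = drop(cc$p), grad = grad)
  }
}

# attribution-level inputs and baselines for one patient
ig_inputs <- function(model, prep, i) {
  config <- model$config
  x <- list(); b <- list()
  for (m in tab_active(config)) {
    if (!prep$present[i, m]) next
    if (config$fet_pathway == "encoded") {
      bank <- model$params$enc[[m]]
      U <- fet_embed(prep$tab[[m]]$V[i, , drop = FALSE],
                     prep$tab[[m]]$S[i, , drop = FALSE], bank)
      x[[m]] <- array(U[1, , ], dim(U)[2:3])           # d_enc x F
      b[[m]] <- t(bank$Miss)                           # missing-bucket input
    } else if (config$fet_pathway == "hashed") {
      x[[m]] <- prep$tab[[m]]$X[i, ]
      b[[m]] <- rep(missing_code(), length(x[[m]]))
    } else {
      x[[m]] <- prep$tab[[m]]$X[i, ]
      b[[m]] <- rep(0, length(x[[m]]))
    }
  }
  if ("I" %in% config$modalities && prep$present[i, "I"]) {
    x$I <- prep$img[[i]]
    b$I <- array(0, dim(x$I))
  }
  list(x = x, baseline = b)
}

#' Integrated-Gradients attribution report for a cohort
#'
#' Attributes each patient's predicted progression probability to the
#' model-level inputs: for tabular modalities each feature's embedded
#' vector, against the feature's learned missing-bucket embedding as
#' baseline (for the ablation pathways, the mapped/standardized scalars
#' against the missing code / zero); for the image modality each pixel of
#' the standardized tile stack against an all-zero tensor. Per-feature
#' attributions are the sums over the embedding dimensions, so the
#' completeness axiom carries over.
#'
#' @param model A trained \code{flex_model}.
#' @param cohort A \code{flex_cohort}.
#' @param ids Patient ids to attribute (default: all).
#' @param steps IG path steps (default 50).
#' @return An \code{attribution_report}: per patient, per-feature
#'   attributions for each tabular modality, per-tile pixel attributions for
#'   the image modality, the prediction, and the completeness gap.
#' @export
attribute_patients <- function(model, cohort, ids = NULL, steps = 50) {
  prep <- prepare_inputs(model, cohort)
  pid <- cohort$patients$patient_id
  ids <- ids %||% pid
  out <- list()
  for (id in ids) {
    i <- match(id, pid)
    assert_that(!is.na(i), "unknown patient id %s", id)
    io <- ig_inputs(model, prep, i)
    if (!length(io$x)) {
      warning(sprintf("patient %s: no attributable modality inputs", id))
      next
    }
    f <- ig_model_fun(model, prep, i)
    ig <- integrated_gradients(f, io$x, io$baseline, steps)
    ent <- list(label = cohort$patients$label[i], value = ig$value,
                baseline_value = ig$baseline_value,
                completeness_gap = ig$completeness_gap,
                tabular = list(), image = NULL)
    for (m in intersect(names(ig$attributions), TABULAR_MODALITIES)) {
      a <- ig$attributions[[m]]
      fa <- if (is.matrix(a)) colSums(a) else a      # sum over enc dims
      names(fa) <- if (!is.null(model$mappers[[m]]))
        model$mappers[[m]]$feature_names else names(model$scalers[[m]]$mean)
      ent$tabular[[m]] <- fa
    }
    if (!is.null(ig$attributions$I)) {
      aI <- ig$attributions$I
      tiles <- lapply(seq_len(dim(aI)[4]), function(t)
        apply(aI[, , , t, drop = FALSE], c(1, 2), sum))
      ent$image <- list(tiles = tiles, total = sum(aI),
                        n_inputs = length(aI))
    }
    out[[id]] <- ent
  }
  structure(list(patients = out, modalities = model$config$modalities,
                 steps = steps),
            class = "attribution_report")
}

#' Per-patient and population modal importance
#'
#' A modality's score for a patient is the mean absolute attribution over
#' that modality's inputs (signed means available via \code{signed}).
#' Population summaries report the median per modality within the
#' progression group, the non-progression group and all patients.
#'
#' @param report An [attribute_patients()] report.
#' @param signed Use signed means instead of absolute (default FALSE).
#' @return List with \code{per_patient} (data.frame: patient_id, label,
#'   modality, score) and \code{summary} (data.frame of group medians).
#' @export
modal_importance <- function(report, signed = FALSE) {
  agg <- function(v) if (signed) mean(v) else mean(abs(v))
  rows <- list()
  for (id in names(report$patients)) {
    ent <- report$patients[[id]]
    for (m in names(ent$tabular))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = id, label = ent$label, modality = m,
        score = agg(ent$tabular[[m]]))
    if (!is.null(ent$image))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = id, label = ent$label, modality = "I",
        score = agg(unlist(ent$image$tiles)))
  }
  per <- do.call(rbind, rows)
  groups <- list(progression = per$label == 1,
                 `non-progression` = per$label == 0,
                 all = rep(TRUE, nrow(per)))
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    sub <- per[groups[[g]], , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(group = g, modality = sort(unique(sub$modality)),
               median_score = vapply(sort(unique(sub$modality)), function(m)
                 median(sub$score[sub$modality == m]), numeric(1)))
  }))
  list(per_patient = per, summary = summ)
}

#' Rank features of one modality by median attribution magnitude
#'
#' @param report An [attribute_patients()] report.
#' @param modality Tabular modality to rank.
#' @param signed Rank by signed median instead of median absolute value.
#' @return data.frame (feature, median_score) sorted descending, ties
#'   broken by feature name.
#' @export
rank_features <- function(report, modality, signed = FALSE) {
  mats <- lapply(report$patients, function(e) e$tabular[[modality]])
  mats <- mats[!vapply(mats, is.null, TRUE)]
  assert_that(length(mats) >= 1, "no patient carries modality %s", modality)
  A <- do.call(rbind, mats)
  med <- apply(if (signed) A else abs(A), 2, median)
  ord <- order(-med, colnames(A))
  data.frame(feature = colnames(A)[ord], median_score = unname(med[ord]),
             row.names = NULL)
}

# ---- SCDA heat maps ---------------------------------------------------

bilinear_upsample <- function(mat, H, W) {
  h <- nrow(mat); w <- ncol(mat)
  if (h == H && w == W) return(mat)
  ri <- pmin(pmax((seq_len(H) - 0.5) * h / H + 0.5, 1), h)
  ci <- pmin(pmax((seq_len(W) - 0.5) * w / W + 0.5, 1), w)
  r0 <- pmin(floor(ri), h - 1L); r0[r0 < 1] <- 1
  c0 <- pmin(floor(ci), w - 1L); c0[c0 < 1] <- 1
  fr <- ri - r0; fc <- ci - c0
  if (h == 1) { r0 <- rep(1, H); fr <- rep(0, H) }
  if (w == 1) { c0 <- rep(1, W); fc <- rep(0, W) }
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  m00 <- mat[r0, c0, drop = FALSE]; m10 <- mat[r1, c0, drop = FALSE]
  m01 <- mat[r0, c1, drop = FALSE]; m11 <- mat[r1, c1, drop = FALSE]
  FR <- matrix(fr, H, W); FC <- matrix(fc, H, W, byrow = TRUE)
  m00 * (1 - FR) * (1 - FC) + m10 * FR * (1 - FC) +
    m01 * (1 - FR) * FC + m11 * FR * FC
}

nearest_upsample <- function(mat, H, W) {
  ri <- pmin(pmax(ceiling(seq_len(H) * nrow(mat) / H), 1), nrow(mat))
  ci <- pmin(pmax(ceiling(seq_len(W) * ncol(mat) / W), 1), ncol(mat))
  mat[ri, ci, drop = FALSE]
}

# largest 4-connected TRUE component (BFS); empty in, empty out
largest_component <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  cur <- 0L; best <- 0L; best_size <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start; labels[start] <- cur; size <- 0L
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      size <- size + 1L
      r <- (v - 1L) %% h + 1L; cc <- (v - 1L) %/% h + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr < 1 || rr > h || c2 < 1 || c2 > w) next
        u <- (c2 - 1L) * h + rr
        if (mask[u] && labels[u] == 0L) {
          labels[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
    if (size > best_size) { best_size <- size; best <- cur }
  }
  labels == best & best > 0L
}

#' SCDA heat map and region of interest for one tile
#'
#' Sums the tap-point feature map over channels, thresholds the aggregate
#' at its mean (strict inequality), keeps the largest 4-connected
#' above-threshold component as the ROI mask, and bilinearly upsamples the
#' relevance scores to tile resolution.
#'
#' @param model A trained \code{flex_model} with an image branch, or a list
#'   \code{list(config = backbone_config, params = init_backbone(...))}.
#' @param tile Raw tile array \code{c(H, W, 3)} in \code{[0, 1]}.
#' @return A \code{scda_heatmap}: \code{score} (tap-resolution aggregate),
#'   \code{threshold}, \code{mask} (tap resolution), \code{heat} and
#'   \code{mask_full} (tile resolution).
#' @export
scda_heatmap <- function(model, tile) {
  if (inherits(model, "flex_model")) {
    assert_that("I" %in% model$config$modalities, "model has no image branch")
    sc <- model$scalers$I
    x <- tile
    for (ch in 1:3) x[, , ch] <- (x[, , ch] - sc$mean[ch]) / sc$sd[ch]
    fmap <- feature_map(x, model$backbone_cfg, model$params$img)
  } else {
    fmap <- feature_map(tile, model$config, model$params)
  }
  S <- apply(fmap, c(1, 2), sum)
  thr <- mean(S)
  above <- S > thr
  mask <- largest_component(above)
  H <- dim(tile)[1]; W <- dim(tile)[2]
  structure(list(score = S, threshold = thr, mask = mask,
                 heat = bilinear_upsample(S, H, W),
                 mask_full = nearest_upsample(mask, H, W) > 0),
            class = "scda_heatmap")
}

#' Intersection-over-union of two binary masks
#' @param a,b Logical matrices of identical shape.
#' @return IoU in \code{[0, 1]} (0 when the union is empty).
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Render a heat map as a red-blue PNG with the ROI outlined
#'
#' Red marks strong relevance, blue weak; the ROI mask boundary is drawn in
#' green.
#'
#' @param heatmap An [scda_heatmap()].
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
render_heatmap <- function(heatmap, path) {
  h <- heatmap$heat
  rng <- range(h)
  z <- if (diff(rng) < 1e-12) matrix(0.5, nrow(h), ncol(h))
    else (h - rng[1]) / diff(rng)
  img <- array(0, c(nrow(h), ncol(h), 3))
  img[, , 1] <- z                       # red = strong correlation
  img[, , 3] <- 1 - z                   # blue = weak correlation
  m <- heatmap$mask_full
  edge <- m & !(shift_mask(m, 1, 0) & shift_mask(m, -1, 0) &
                  shift_mask(m, 0, 1) & shift_mask(m, 0, -1))
  img[, , 2][edge] <- 1
  img[, , 1][edge] <- 0
  img[, , 3][edge] <- 0
  png::writePNG(img, path)
  invisible(path)
}

shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}
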