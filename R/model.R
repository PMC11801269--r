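# End-to-end model: per-modality encoders (FET pathways for tabular data,
# CNN backbone for tiles), fusion, two-layer classifier and the Meta
# missing-modality module, trained jointly by backpropagation with Adam.

#' Model / training configuration
#'
#' @param modalities Active modality set, subset of \code{c("C","P","M","I")}.
#' @param fet_pathway Tabular encoder pathway: \code{"encoded"} (hash
#'   mapping + trainable ten-dimensional encodings, the full FET),
#'   \code{"hashed"} (bucket midpoints through a plain feedforward encoder)
#'   or \code{"raw"} (standardized raw values through the same encoder).
#' @param fusion Fusion operator; see [fusion_config()].
#' @param backbone Image backbone architecture; see [backbone_config()].
#' @param tile_pooling \code{"mean"} or \code{"attention"}.
#' @param d_rep Shared modality representation dimension (default 32).
#' @param d_enc FET encoding dimension (default 10).
#' @param n_buckets Hash-mapper buckets (default 16).
#' @param hidden Classifier hidden width (default 64).
#' @param dropout Classifier hidden dropout rate (default 0).
#' @param shared_fc Share the per-feature FC layer across features?
#' @param use_meta Train the Meta missing-modality module (default TRUE
#'   when >= 2 modalities are active).
#' @param lambda_meta Weight of the Meta reconstruction loss (default 0.5).
#' @param lr,epochs,batch_size Adam learning rate, epoch and batch budget.
#' @param val_fraction Fraction of the training data held out for early
#'   stopping (0 disables early stopping).
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return A \code{flex_config} list.
#' @export
flex_config <- function(modalities = c("C", "P", "M", "I"),
                        fet_pathway = c("encoded", "hashed", "raw"),
                        fusion = "concatenation",
                        backbone = "tiny_cnn",
                        tile_pooling = "mean",
                        d_rep = 32, d_enc = 10, n_buckets = 16,
                        hidden = 64, dropout = 0, shared_fc = FALSE,
                        use_meta = NULL, lambda_meta = 0.5,
                        lr = 1e-3, epochs = 50, batch_size = 32,
                        val_fraction = 0.2, patience = 10,
                        seed = 1) {
  fet_pathway <- match.arg(fet_pathway)
  modalities <- ALL_MODALITIES[ALL_MODALITIES %in% modalities]
  assert_that(length(modalities) >= 1, "need at least one modality")
  assert_that(epochs >= 1 && batch_size >= 1 && n_buckets >= 2 && d_rep >= 1,
              "counts must be positive")
  use_meta <- use_meta %||% (length(modalities) >= 2)
  structure(list(modalities = modalities, fet_pathway = fet_pathway,
                 fusion = fusion, backbone = backbone,
                 tile_pooling = tile_pooling,
                 d_rep = d_rep, d_enc = d_enc, n_buckets = n_buckets,
                 hidden = hidden, dropout = dropout, shared_fc = shared_fc,
                 use_meta = use_meta && length(modalities) >= 2,
                 lambda_meta = lambda_meta,
                 lr = lr, epochs = epochs, batch_size = batch_size,
                 val_fraction = val_fraction, patience = patience,
                 seed = seed),
            class = "flex_config")
}

tab_active <- function(config) intersect(config$modalities, TABULAR_MODALITIES)

# ---- preprocessing (fitted on training data only) ---------------------

fit_preprocessors <- function(cohort, config) {
  mappers <- list(); scalers <- list()
  for (m in tab_active(config)) {
    t <- cohort$tables[[m]]
    assert_that(!is.null(t), "cohort lacks tabular modality %s", m)
    if (config$fet_pathway %in% c("encoded", "hashed"))
      mappers[[m]] <- fit_hash_mapper(t, config$n_buckets)
    if (config$fet_pathway == "raw") {
      mu <- apply(t$values, 2, function(x) mean(x, na.rm = TRUE))
      sdv <- apply(t$values, 2, function(x) {
        s <- sd(x, na.rm = TRUE)
        if (!is.finite(s) || s < 1e-12) 1 else s
      })
      scalers[[m]] <- list(mean = mu, sd = sdv)
    }
  }
  if ("I" %in% config$modalities) {
    px <- c(0, 0, 0); px2 <- c(0, 0, 0); npx <- 0
    for (is in cohort$images) for (tl in is$tiles) {
      for (ch in 1:3) {
        px[ch] <- px[ch] + sum(tl[, , ch])
        px2[ch] <- px2[ch] + sum(tl[, , ch]^2)
      }
      npx <- npx + prod(dim(tl)[1:2])
    }
    mu <- px / npx
    sdv <- sqrt(pmax(px2 / npx - mu^2, 1e-6))
    scalers$I <- list(mean = mu, sd = sdv)
  }
  list(mappers = mappers, scalers = scalers)
}

# assemble aligned model inputs for every patient of a cohort
prepare_inputs <- function(model, cohort) {
  config <- model$config
  pat <- cohort$patients
  n <- nrow(pat)
  mods <- config$modalities
  present <- matrix(FALSE, n, length(mods), dimnames = list(NULL, mods))
  tab <- list()
  for (m in tab_active(config)) {
    t <- cohort$tables[[m]]
    present[, m] <- pat[[paste0("has_", m)]]
    fn <- if (!is.null(model$mappers[[m]])) model$mappers[[m]]$feature_names
      else names(model$scalers[[m]]$mean)
    X <- matrix(NA_real_, n, length(fn), dimnames = list(pat$patient_id, fn))
    if (!is.null(t)) {
      sub <- t$values[intersect(t$patient_ids, pat$patient_id), fn, drop = FALSE]
      X[rownames(sub), ] <- sub
    }
    if (config$fet_pathway %in% c("encoded", "hashed")) {
      ft <- feature_table(m, pat$patient_id, fn, X)
      mapped <- apply_hash_map(model$mappers[[m]], ft)$values
      rowNA <- !present[, m]
      mapped[rowNA, ] <- missing_code()
      if (config$fet_pathway == "encoded") {
        vs <- mapped_to_vs(mapped)
        tab[[m]] <- list(V = vs$V, S = vs$S)
      } else tab[[m]] <- list(X = mapped)
    } else {
      sc <- model$scalers[[m]]
      Z <- sweep(sweep(X, 2, sc$mean, "-"), 2, sc$sd, "/")
      Z[is.na(Z)] <- 0
      tab[[m]] <- list(X = Z)
    }
  }
  img <- NULL
  if ("I" %in% mods) {
    present[, "I"] <- pat$has_I
    sc <- model$scalers$I
    img <- vector("list", n)
    for (i in seq_len(n)) {
      pid <- pat$patient_id[i]
      if (!pat$has_I[i] || is.null(cohort$images[[pid]])) next
      tiles <- cohort$images[[pid]]$tiles
      x <- simplify2array(tiles)
      if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
      for (ch in 1:3) x[, , ch, ] <- (x[, , ch, ] - sc$mean[ch]) / sc$sd[ch]
      img[[i]] <- x
    }
  }
  n_missing <- rowSums(!present)
  assert_that(all(n_missing <= 1),
              "unsupported case: %d patient(s) missing more than one active modality",
              sum(n_missing > 1))
  list(tab = tab, img = img, present = present, labels = pat$label, n = n)
}

# ---- forward / backward over a batch ----------------------------------

encoder_forward <- function(model, prep, idx, m) {
  config <- model$config
  if (m == "I") {
    rows <- which(prep$present[idx, "I"])
    n <- length(idx)
    rep_m <- matrix(0, n, config$d_rep)
    if (!length(rows))
      return(list(rep = rep_m, cache = NULL, rows = rows))
    stacks <- prep$img[idx[rows]]
    counts <- vapply(stacks, function(x) dim(x)[4], 1L)
    x <- array(0, c(dim(stacks[[1]])[1:3], sum(counts)))
    groups <- integer(sum(counts)); off <- 0
    for (j in seq_along(stacks)) {
      k <- counts[j]
      x[, , , off + seq_len(k)] <- stacks[[j]]
      groups[off + seq_len(k)] <- j
      off <- off + k
    }
    fw <- cnn_forward(x, model$params$img)
    pool <- tile_pool_forward(fw$emb, groups, length(rows), model$params$img,
                              config$tile_pooling)
    pc <- dense_forward(pool$pooled, model$params$img$proj, "relu")
    rep_m[rows, ] <- pc$y
    list(rep = rep_m, rows = rows,
         cache = list(cnn = fw, pool = pool, proj = pc, x = x))
  } else {
    rows <- which(prep$present[idx, m])
    n <- length(idx)
    rep_m <- matrix(0, n, config$d_rep)
    if (!length(rows)) return(list(rep = rep_m, cache = NULL, rows = rows))
    enc <- model$params$enc[[m]]
    if (config$fet_pathway == "encoded") {
      V <- prep$tab[[m]]$V[idx[rows], , drop = FALSE]
      S <- prep$tab[[m]]$S[idx[rows], , drop = FALSE]
      fw <- fet_forward(V, S, enc)
    } else {
      X <- prep$tab[[m]]$X[idx[rows], , drop = FALSE]
      fw <- mlp_forward(X, enc)
    }
    rep_m[rows, ] <- fw$rep
    list(rep = rep_m, rows = rows, cache = fw)
  }
}

encoder_backward <- function(model, ec, dHm, m) {
  config <- model$config
  if (!length(ec$rows)) return(NULL)
  d <- dHm[ec$rows, , drop = FALSE]
  if (m == "I") {
    pb <- dense_backward(d, ec$cache$proj, model$params$img$proj)
    poolb <- tile_pool_backward(pb$dx, ec$cache$pool$cache, model$params$img)
    cb <- cnn_backward(poolb$demb, ec$cache$cnn, model$params$img)
    g <- list(layers = cb$layer_grads, proj = pb$grad)
    if (!is.null(model$params$img$attn_q)) g$attn_q <- list(q = poolb$dq)
    g
  } else if (config$fet_pathway == "encoded") {
    fet_backward(d, ec$cache, model$params$enc[[m]])$grad
  } else {
    mlp_backward(d, ec$cache, model$params$enc[[m]])$grad
  }
}

model_forward <- function(model, prep, idx, train = FALSE,
                          impute = c("meta", "zero"), drop_modality = NULL) {
  impute <- match.arg(impute)
  config <- model$config
  mods <- config$modalities
  fcfg <- model$fcfg
  enc_caches <- list(); H <- list()
  present <- prep$present[idx, , drop = FALSE]
  if (!is.null(drop_modality)) present[, drop_modality] <- FALSE
  for (m in mods) {
    ec <- encoder_forward(model, prep, idx, m)
    if (!is.null(drop_modality) && m %in% drop_modality) {
      ec$rep[] <- 0
      ec$rows <- integer(0)
      ec$cache <- NULL
    }
    enc_caches[[m]] <- ec
    H[[m]] <- ec$rep
  }
  meta_caches <- list()
  if (length(mods) >= 2) {
    for (m in mods) {
      miss_rows <- which(!present[, m])
      if (!length(miss_rows)) next
      if (impute == "meta" && config$use_meta && !is.null(model$params$meta)) {
        others <- setdiff(mods, m)
        X <- do.call(cbind, lapply(others, function(o)
          H[[o]][miss_rows, , drop = FALSE]))
        mc <- meta_forward(X, model$params$meta[[m]])
        H[[m]][miss_rows, ] <- mc$rep
        meta_caches[[m]] <- list(rows = miss_rows, cache = mc, others = others)
      }                                     # impute == "zero": leave zeros
    }
  }
  fc <- fuse_forward(H, fcfg, model$params$fusion)
  drop_mask <- NULL
  if (train && config$dropout > 0) {
    drop_mask <- matrix(rbinom(length(idx) * config$hidden, 1,
                               1 - config$dropout) / (1 - config$dropout),
                        length(idx), config$hidden)
  }
  cc <- clf_forward(fc$fused, model$params$clf, drop_mask)
  list(p = drop(cc$p), H = H, enc_caches = enc_caches,
       meta_caches = meta_caches, fuse_cache = fc, clf_cache = cc,
       present = present)
}

model_backward <- function(model, fwd, dp, prep, idx) {
  config <- model$config
  mods <- config$modalities
  grads <- list()
  cb <- clf_backward(matrix(dp, ncol = 1), fwd$clf_cache, model$params$clf)
  grads$clf <- cb$grad
  fb <- fuse_backward(cb$dfused, fwd$fuse_cache, model$fcfg,
                      model$params$fusion)
  if (length(fb$grad)) grads$fusion <- fb$grad
  dH <- fb$dH
  # imputed rows: gradient reaches the Meta net and the other encoders
  meta_grads <- NULL
  for (m in names(fwd$meta_caches)) {
    mcinfo <- fwd$meta_caches[[m]]
    mb <- meta_backward(dH[[m]][mcinfo$rows, , drop = FALSE], mcinfo$cache,
                        model$params$meta[[m]])
    if (is.null(meta_grads)) meta_grads <- zeros_like(model$params$meta)
    meta_grads[[m]] <- tree_axpy(meta_grads[[m]], mb$grad)
    dH[[m]][mcinfo$rows, ] <- 0
    d <- config$d_rep
    for (j in seq_along(mcinfo$others)) {
      o <- mcinfo$others[j]
      cols <- ((j - 1) * d + 1):(j * d)
      dH[[o]][mcinfo$rows, ] <- dH[[o]][mcinfo$rows, , drop = FALSE] +
        mb$dX[, cols, drop = FALSE]
    }
  }
  for (m in mods) {
    g <- encoder_backward(model, fwd$enc_caches[[m]], dH[[m]], m)
    if (is.null(g)) next
    if (m == "I") grads$img <- g else grads$enc[[m]] <- g
  }
  list(grads = grads, meta_grads = meta_grads)
}

# Meta auxiliary reconstruction loss on rows complete in all modalities;
# inputs and targets are detached, so only Meta parameters receive gradient
meta_aux <- function(model, fwd) {
  config <- model$config
  mods <- config$modalities
  complete <- which(rowSums(!fwd$present) == 0)
  if (!length(complete) || !config$use_meta || length(mods) < 2)
    return(list(loss = 0, grads = NULL))
  grads <- zeros_like(model$params$meta)
  loss <- 0
  for (m in mods) {
    others <- setdiff(mods, m)
    X <- do.call(cbind, lapply(others, function(o)
      fwd$H[[o]][complete, , drop = FALSE]))
    target <- fwd$H[[m]][complete, , drop = FALSE]
    mc <- meta_forward(X, model$params$meta[[m]])
    diff <- mc$rep - target
    loss <- loss + mean(diff^2)
    mb <- meta_backward(2 * diff / length(diff), mc, model$params$meta[[m]])
    grads[[m]] <- mb$grad
  }
  list(loss = loss / length(mods),
       grads = tree_apply(grads, grads, function(a, b) a / length(mods)))
}

#' Train the multimodal model end-to-end
#'
#' Fits hash mappers / standardization on the supplied cohort (callers doing
#' cross-validation pass the training fold only), initializes all trainable
#' state (encoding banks, backbone, fusion, classifier, Meta) and updates it
#' jointly with Adam on binary cross-entropy plus the weighted Meta
#' reconstruction loss. Fully reproducible given \code{config$seed}.
#'
#' @param cohort A \code{flex_cohort} (training data).
#' @param config A [flex_config()].
#' @return A \code{flex_model}: config, fitted preprocessors, parameters and
#'   per-epoch training history.
#' @export
flex_train <- function(cohort, config = flex_config()) {
  assert_that(inherits(config, "flex_config"), "config must come from flex_config()")
  labs <- cohort$patients$label
  if (length(unique(labs)) < 2)
    stop_flex("training split contains a single class (prevalence %.2f); refusing to fit",
              mean(labs))
  with_seed(config$seed, {
    prep_fit <- fit_preprocessors(cohort, config)
    model <- structure(list(config = config,
                            fcfg = fusion_config(config$fusion,
                                                 config$modalities,
                                                 config$d_rep, config$hidden,
                                                 config$dropout),
                            mappers = prep_fit$mappers,
                            scalers = prep_fit$scalers),
                       class = "flex_model")
    params <- list()
    for (m in tab_active(config)) {
      fn <- if (!is.null(model$mappers[[m]])) model$mappers[[m]]$feature_names
        else names(model$scalers[[m]]$mean)
      params$enc[[m]] <- if (config$fet_pathway == "encoded")
        encoding_bank(fn, config$d_enc, config$d_rep, config$shared_fc)
      else mlp_encoder(length(fn), d_rep = config$d_rep)
    }
    if ("I" %in% config$modalities) {
      bc <- backbone_config(config$backbone, config$tile_pooling,
                            config$d_rep)
      model$backbone_cfg <- bc
      params$img <- init_backbone(bc)
    }
    params$fusion <- init_fusion(model$fcfg)
    params$clf <- params$fusion$clf
    params$fusion$clf <- NULL
    if (length(params$fusion) == 0) params$fusion <- NULL
    if (config$use_meta) params$meta <- init_meta(model$fcfg)
    model$params <- params

    prep <- prepare_inputs(model, cohort)
    n <- prep$n
    # optional internal early-stopping split (stratified)
    use_es <- config$val_fraction > 0 && is.finite(config$patience) &&
      n >= 20 && min(table(prep$labels)) >= 5
    if (use_es) {
      folds <- stratified_folds(prep$labels,
                                k = max(2, round(1 / config$val_fraction)),
                                seed = derive_seed(config$seed, 17))
      val_idx <- which(folds == 1)
      tr_idx <- which(folds != 1)
    } else {
      tr_idx <- seq_len(n); val_idx <- integer(0)
    }

    opt <- adam_init(model$params, lr = config$lr)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          bce = numeric(0), meta_mse = numeric(0),
                          val_auroc = numeric(0))
    best <- list(auroc = -Inf, params = model$params, epoch = 0)
    wait <- 0
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_bce <- 0; ep_meta <- 0
      for (b in batches) {
        fwd <- model_forward(model, prep, b, train = TRUE)
        bl <- bce_loss(fwd$p, prep$labels[b])
        aux <- meta_aux(model, fwd)
        loss <- bl$loss + config$lambda_meta * aux$loss
        bw <- model_backward(model, fwd, bl$dprob, prep, b)
        grads <- bw$grads
        if (config$use_meta) {
          mg <- bw$meta_grads %||% zeros_like(model$params$meta)
          if (!is.null(aux$grads))
            mg <- tree_axpy(mg, aux$grads, config$lambda_meta)
          grads$meta <- mg
        }
        grads <- align_grads(model$params, grads)
        st <- adam_step(model$params, grads, opt)
        model$params <- st$params
        opt <- st$opt
        ep_loss <- ep_loss + loss * length(b)
        ep_bce <- ep_bce + bl$loss * length(b)
        ep_meta <- ep_meta + aux$loss * length(b)
      }
      ep_loss <- ep_loss / length(ord)
      ep_bce <- ep_bce / length(ord)
      ep_meta <- ep_meta / length(ord)
      val_auc <- NA_real_
      if (use_es) {
        vp <- model_forward(model, prep, val_idx, train = FALSE)$p
        val_auc <- auroc(vp, prep$labels[val_idx])
        if (val_auc > best$auroc + 1e-6) {
          best <- list(auroc = val_auc, params = model$params, epoch = epoch)
          wait <- 0
        } else wait <- wait + 1
      }
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss,
                                           bce = ep_bce, meta_mse = ep_meta,
                                           val_auroc = val_auc))
      if (use_es && wait >= config$patience) break
    }
    if (use_es && best$auroc > -Inf) model$params <- best$params
    model$history <- history
    model$n_train <- n
    model$fit_ids <- cohort$patients$patient_id
    model
  })
}

# grads may omit frozen/unused components; fill with zeros in param order
align_grads <- function(params, grads) {
  out <- list()
  for (nm in names(params)) {
    if (is.null(grads[[nm]])) out[[nm]] <- zeros_like(params[[nm]])
    else if (is.list(params[[nm]]) && !is.null(names(params[[nm]])) &&
             nm %in% c("enc")) {
      sub <- list()
      for (k in names(params[[nm]]))
        sub[[k]] <- grads[[nm]][[k]] %||% zeros_like(params[[nm]][[k]])
      out[[nm]] <- sub
    } else out[[nm]] <- grads[[nm]]
  }
  out
}

#' @export
print.flex_model <- function(x, ...) {
  cat(sprintf("<flex_model: %s | pathway %s | fusion %s%s | trained on %d patients>\n",
              paste(x$config$modalities, collapse = "+"),
              x$config$fet_pathway, x$config$fusion,
              if ("I" %in% x$config$modalities)
                paste0(" | backbone ", x$config$backbone) else "",
              x$n_train %||% 0))
  invisible(x)
}

#' Predict progression probabilities for a cohort
#'
#' @param model A trained \code{flex_model}.
#' @param cohort A \code{flex_cohort}.
#' @param impute Replacement strategy for a missing modality:
#'   \code{"meta"} (Meta module) or \code{"zero"} (zero vector).
#' @param drop_modality Optionally treat one modality as missing for every
#'   patient (used to probe Meta imputation on complete data).
#' @return Named numeric vector of probabilities in (0, 1).
#' @export
flex_predict <- function(model, cohort, impute = c("meta", "zero"),
                         drop_modality = NULL) {
  impute <- match.arg(impute)
  prep <- prepare_inputs(model, cohort)
  p <- numeric(prep$n)
  chunks <- split(seq_len(prep$n), ceiling(seq_len(prep$n) / 256))
  for (b in chunks)
    p[b] <- model_forward(model, prep, b, train = FALSE, impute = impute,
                          drop_modality = drop_modality)$p
  names(p) <- cohort$patients$patient_id
  p
}

#' Per-modality representations for a cohort
#'
#' Runs the trained encoders in eval mode and returns each modality's
#' representation matrix (zero rows where the modality is absent).
#'
#' @param model A trained \code{flex_model}.
#' @param cohort A \code{flex_cohort}.
#' @return List with \code{reps} (named list of patients x d_rep matrices)
#'   and \code{present} (logical matrix).
#' @export
representations <- function(model, cohort) {
  prep <- prepare_inputs(model, cohort)
  reps <- list()
  for (m in model$config$modalities) {
    rep_m <- matrix(0, prep$n, model$config$d_rep)
    chunks <- split(seq_len(prep$n), ceiling(seq_len(prep$n) / 256))
    for (b in chunks)
      rep_m[b, ] <- encoder_forward(model, prep, b, m)$rep
    reps[[m]] <- rep_m
  }
  list(reps = reps, present = prep$present)
}
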