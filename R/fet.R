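# Feature Encoding Trainer: trainable ten-dimensional per-feature encodings
# over hash-mapped scalars, plus the two ablation pathways (raw standardized
# values; hash-mapped midpoints without trainable encodings).
#
# Encoded pathway, for one patient and features f = 1..F:
#   u_f = v_f * e_f                    (observed; v_f = bucket midpoint)
#   u_f = m_f                          (missing-bucket cell)
#   h_f = relu(u_f %*% W_f + b_f)      (per-feature learnable FC layer)
#   z   = sum_f h_f                    (order-invariant aggregation)
#   r   = relu(z %*% P + p0)           (projection to d_rep)

#' Initialize an encoding bank for one tabular modality
#'
#' Holds the FET's trainable state: a \code{d_enc}-dimensional encoding
#' vector per feature (default 10), a learned missing-bucket encoding per
#' feature, a per-feature learnable fully connected layer (optionally shared
#' across features), and the modality-level projection to \code{d_rep}.
#'
#' @param feature_names Character vector of feature names.
#' @param d_enc Encoding dimension (default 10).
#' @param d_rep Modality representation dimension (default 32).
#' @param shared_fc Share one FC layer across features? Default FALSE
#'   (unshared, one layer per feature).
#' @return An object of class \code{encoding_bank} (nested parameter list).
#' @export
encoding_bank <- function(feature_names, d_enc = 10, d_rep = 32,
                          shared_fc = FALSE) {
  nf <- length(feature_names)
  fc <- if (shared_fc) list(init_dense(d_enc, d_enc))
    else lapply(seq_len(nf), function(i) init_dense(d_enc, d_enc))
  structure(list(
    E = init_mat(nf, d_enc, scale = sqrt(3 / d_enc)),
    Miss = init_mat(nf, d_enc, scale = sqrt(3 / d_enc)),
    fc = fc,
    proj = init_dense(d_enc, d_rep)
  ), feature_names = feature_names, d_enc = d_enc, d_rep = d_rep,
     shared_fc = shared_fc, class = c("encoding_bank", "list"))
}

# embed mapped scalars: returns n x d_enc x F array of per-feature inputs
fet_embed <- function(V, S, bank) {
  n <- nrow(V); nf <- ncol(V); d <- ncol(bank$E)
  U <- array(0, c(n, d, nf))
  for (f in seq_len(nf)) {
    U[, , f] <- outer(V[, f] * S[, f], bank$E[f, ]) +
      outer(1 - S[, f], bank$Miss[f, ])
  }
  U
}

fc_layer <- function(bank, f) {
  if (isTRUE(attr(bank, "shared_fc"))) bank$fc[[1]] else bank$fc[[f]]
}

# forward from the embedded tensor (n x d_enc x F); also the IG entry point
fet_forward_embedded <- function(U, bank) {
  n <- dim(U)[1]; d <- dim(U)[2]; nf <- dim(U)[3]
  Z <- matrix(0, n, d)
  caches <- vector("list", nf)
  for (f in seq_len(nf)) {
    Uf <- matrix(U[, , f], nrow = n, ncol = d)
    cf <- dense_forward(Uf, fc_layer(bank, f), "relu")
    caches[[f]] <- cf
    Z <- Z + cf$y
  }
  pc <- dense_forward(Z, bank$proj, "relu")
  list(rep = pc$y, fc_caches = caches, proj_cache = pc, U = U)
}

# backward: returns gradient tree mirroring the bank, plus dU (for IG)
fet_backward_embedded <- function(drep, cache, bank) {
  n <- dim(cache$U)[1]; d <- dim(cache$U)[2]; nf <- dim(cache$U)[3]
  pb <- dense_backward(drep, cache$proj_cache, bank$proj)
  dZ <- pb$dx
  shared <- isTRUE(attr(bank, "shared_fc"))
  dfc <- if (shared) list(list(W = matrix(0, d, d), b = numeric(d)))
    else vector("list", nf)
  dU <- array(0, c(n, d, nf))
  for (f in seq_len(nf)) {
    fb <- dense_backward(dZ, cache$fc_caches[[f]], fc_layer(bank, f))
    if (shared) {
      dfc[[1]]$W <- dfc[[1]]$W + fb$grad$W
      dfc[[1]]$b <- dfc[[1]]$b + fb$grad$b
    } else dfc[[f]] <- fb$grad
    dU[, , f] <- fb$dx
  }
  list(grad = list(E = NULL, Miss = NULL, fc = dfc, proj = pb$grad), dU = dU)
}

# full forward from mapped values: adds encoding/missing-vector gradients
fet_forward <- function(V, S, bank) {
  U <- fet_embed(V, S, bank)
  out <- fet_forward_embedded(U, bank)
  out$V <- V; out$S <- S
  out
}

fet_backward <- function(drep, cache, bank) {
  bk <- fet_backward_embedded(drep, cache, bank)
  nf <- ncol(cache$V); d <- dim(cache$U)[2]
  dE <- matrix(0, nf, d); dM <- matrix(0, nf, d)
  for (f in seq_len(nf)) {
    dUf <- matrix(bk$dU[, , f], ncol = d)
    dE[f, ] <- colSums(dUf * (cache$V[, f] * cache$S[, f]))
    dM[f, ] <- colSums(dUf * (1 - cache$S[, f]))
  }
  bk$grad$E <- dE
  bk$grad$Miss <- dM
  bk
}

#' Encode a hash-mapped table into modality representations (FET pathway)
#'
#' The "Encoding training" pathway: each mapped scalar scales its feature's
#' trainable ten-dimensional encoding (missing-bucket cells contribute the
#' feature's learned missing encoding instead), passes through the feature's
#' learnable FC layer, is summed over features, and projected to
#' \code{d_rep}.
#'
#' @param mapped A mapped table from [apply_hash_map()] (or its values
#'   matrix), one row per patient.
#' @param bank An [encoding_bank()] covering the table's features.
#' @return Numeric matrix, patients x \code{d_rep}.
#' @export
encode_modality <- function(mapped, bank) {
  vals <- if (inherits(mapped, "feature_table")) mapped$values else as.matrix(mapped)
  fn <- attr(bank, "feature_names")
  assert_that(identical(sort(colnames(vals)), sort(fn)) ||
                ncol(vals) == length(fn) && is.null(colnames(vals)),
              "bank does not cover the supplied features")
  if (!is.null(colnames(vals))) vals <- vals[, fn, drop = FALSE]
  vs <- mapped_to_vs(vals)
  fet_forward(vs$V, vs$S, bank)$rep
}

# ---- ablation pathways ------------------------------------------------

#' Initialize a plain two-layer feedforward encoder (ablation pathways)
#' @param n_features Input width.
#' @param d_hidden Hidden width (default 32).
#' @param d_rep Output representation dimension (default 32).
#' @return Parameter list with layers \code{l1}, \code{l2}.
#' @export
mlp_encoder <- function(n_features, d_hidden = 32, d_rep = 32) {
  list(l1 = init_dense(n_features, d_hidden), l2 = init_dense(d_hidden, d_rep))
}

mlp_forward <- function(X, enc) {
  c1 <- dense_forward(X, enc$l1, "relu")
  c2 <- dense_forward(c1$y, enc$l2, "relu")
  list(rep = c2$y, c1 = c1, c2 = c2)
}

mlp_backward <- function(drep, cache, enc) {
  b2 <- dense_backward(drep, cache$c2, enc$l2)
  b1 <- dense_backward(b2$dx, cache$c1, enc$l1)
  list(grad = list(l1 = b1$grad, l2 = b2$grad), dX = b1$dx)
}

#' Encode standardized raw values ("Raw data" ablation pathway)
#'
#' Feeds per-feature standardized raw values (training-split mean/sd;
#' missing cells at the standardized mean, i.e. zero) through a plain
#' two-layer feedforward encoder. No bucketing, no trainable feature
#' identity.
#'
#' @param X Numeric matrix patients x features (already standardized,
#'   missing as 0).
#' @param encoder An [mlp_encoder()].
#' @return Numeric matrix patients x \code{d_rep}.
#' @export
encode_modality_raw <- function(X, encoder) mlp_forward(as.matrix(X), encoder)$rep

#' Encode hash-mapped midpoints without trainable encodings
#' ("Hash mapping" ablation pathway)
#'
#' Bucket midpoints (missing cells carry [missing_code()]) feed the same
#' plain feedforward encoder; there are no per-feature trainable encodings.
#'
#' @param mapped Mapped values matrix from [apply_hash_map()].
#' @param encoder An [mlp_encoder()].
#' @return Numeric matrix patients x \code{d_rep}.
#' @export
encode_modality_hashed_only <- function(mapped, encoder) {
  vals <- if (inherits(mapped, "feature_table")) mapped$values else as.matrix(mapped)
  mlp_forward(vals, encoder)$rep
}
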