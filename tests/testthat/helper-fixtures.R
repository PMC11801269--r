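# shared fixtures and independent oracles used across test files

tiny_table <- function(n = 6, p = 3, modality = "C", seed = 1,
                       missing = 0) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n * p), n, p)
    if (missing > 0) vals[runif(n * p) < missing] <- NA
    feature_table(modality, sprintf("S%02d", seq_len(n)),
                  sprintf("%s_v%d", tolower(modality), seq_len(p)), vals)
  })
}

# brute-force AUROC: all positive/negative pairs, ties count one half
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force SCDA pipeline: channel sum, strict mean threshold, largest
# 4-connected component by iterative label propagation
scda_brute <- function(fmap) {
  S <- matrix(0, dim(fmap)[1], dim(fmap)[2])
  for (ch in seq_len(dim(fmap)[3])) S <- S + fmap[, , ch]
  above <- S > mean(S)
  lab <- matrix(0L, nrow(S), ncol(S))
  nextl <- 0L
  repeat {
    todo <- which(above & lab == 0L)
    if (!length(todo)) break
    nextl <- nextl + 1L
    frontier <- todo[1]
    lab[frontier] <- nextl
    repeat {
      grew <- FALSE
      for (v in which(lab == nextl)) {
        r <- (v - 1) %% nrow(S) + 1; cc <- (v - 1) %/% nrow(S) + 1
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- r + d[1]; c2 <- cc + d[2]
          if (rr < 1 || rr > nrow(S) || c2 < 1 || c2 > ncol(S)) next
          u <- (c2 - 1) * nrow(S) + rr
          if (above[u] && lab[u] == 0L) { lab[u] <- nextl; grew <- TRUE }
        }
      }
      if (!grew) break
    }
  }
  if (nextl == 0L) return(list(S = S, mask = above & FALSE))
  sizes <- tabulate(lab[lab > 0], nextl)
  list(S = S, mask = lab == which.max(sizes))
}

# direct (nested-loop) convolution with replicate padding, one image
conv_brute <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; K <- dim(w)[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, K))
  cl <- function(v, hi) min(max(v, 1), hi)
  for (k in seq_len(K)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    acc <- b[k]
    for (c in seq_len(C)) for (i in seq_len(kh)) for (j in seq_len(kw)) {
      hi <- cl((ho - 1) * stride - pad + i, H)
      wi <- cl((wo - 1) * stride - pad + j, W)
      acc <- acc + x[hi, wi, c] * w[i, j, c, k]
    }
    y[ho, wo, k] <- acc
  }
  y
}

small_cohort <- function(n = 40, seed = 1, tiles = 1, lesion = 0.8,
                         modalities_missing = c(C = 0, P = 0, M = 0, I = 0)) {
  generate_cohort(sim_config(
    n_patients = n, n_features = c(C = 6, P = 8, M = 8),
    informative = c(C = 2, P = 2, M = 2), effect_size = 1,
    tile_size = 16, tiles_per_patient = tiles, lesion_signal = lesion,
    missing_rate = modalities_missing, seed = seed))
}

quick_cfg <- function(modalities, epochs = 3, seed = 1, lr = 2e-3, ...) {
  flex_config(modalities = modalities, epochs = epochs, batch_size = 16,
              lr = lr, val_fraction = 0, patience = Inf, seed = seed, ...)
}
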