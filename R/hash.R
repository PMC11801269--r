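# Hash mapping: the first FET stage. Each feature's empirical distribution
# (training split only) is cut into B equal-probability buckets; a value is
# replaced by its bucket's probability-mass midpoint (k + 0.5) / B, putting
# every modality on one [0, 1] scale while preserving within-feature order.

#' Fit a quantile hash mapper on a training-split feature table
#'
#' Per feature, boundaries are the empirical quantiles at probabilities
#' \code{k/B}, \code{k = 1..B-1}. A constant feature collapses to a single
#' bucket (every value maps to 0.5). Missing cells are ignored during
#' fitting; a feature with no observed value is an error.
#'
#' @param table A [feature_table()] (training split only, to avoid leakage).
#' @param n_buckets Number of buckets \code{B >= 2} (default 16).
#' @return An object of class \code{hash_mapper}.
#' @export
fit_hash_mapper <- function(table, n_buckets = 16) {
  assert_that(n_buckets >= 2, "n_buckets must be >= 2")
  bounds <- list()
  for (f in table$feature_names) {
    x <- table$values[, f]
    x <- x[!is.na(x)]
    if (!length(x))
      stop_flex("feature '%s' has no observed value; cannot fit hash mapper", f)
    if (length(unique(x)) == 1) {
      bounds[[f]] <- numeric(0)            # constant -> single bucket
    } else {
      b <- unname(quantile(x, probs = seq_len(n_buckets - 1) / n_buckets,
                           type = 7, names = FALSE))
      bounds[[f]] <- cummax(b)             # enforce non-decreasing
    }
  }
  structure(list(n_buckets = n_buckets, boundaries = bounds,
                 feature_names = table$feature_names,
                 modality_id = table$modality_id,
                 n_fit = length(table$patient_ids),
                 fit_ids = table$patient_ids),
            class = "hash_mapper")
}

#' Map a feature table onto the common unit bucket-midpoint scale
#'
#' Values are replaced by their bucket midpoint; values outside the fitted
#' range clamp to the extreme buckets; missing cells become the reserved
#' [missing_code()], never a numeric midpoint. Monotone within each feature.
#'
#' @param mapper A fitted [fit_hash_mapper()].
#' @param table A [feature_table()] over the same features.
#' @return A \code{feature_table}-like object whose \code{values} are bucket
#'   midpoints, with missing cells equal to [missing_code()].
#' @export
apply_hash_map <- function(mapper, table) {
  assert_that(identical(sort(mapper$feature_names), sort(table$feature_names)),
              "mapper was fitted on a different feature set (%s)",
              table$modality_id)
  B <- mapper$n_buckets
  out <- matrix(NA_real_, nrow(table$values), ncol(table$values),
                dimnames = dimnames(table$values))
  for (f in table$feature_names) {
    x <- table$values[, f]
    b <- mapper$boundaries[[f]]
    if (length(b) == 0) {
      mid <- rep(0.5, length(x))
    } else {
      k <- findInterval(x, b)              # 0 .. length(b)
      nb <- length(b) + 1                  # effective bucket count
      mid <- (k + 0.5) / nb
    }
    mid[is.na(x)] <- missing_code()
    out[, f] <- mid
  }
  res <- table
  res$values <- out
  res$mapped <- TRUE
  res
}

# split a mapped matrix into (values, presence) with missing -> 0
mapped_to_vs <- function(values) {
  S <- (values != missing_code()) * 1
  V <- values
  V[S == 0] <- 0
  list(V = V, S = S)
}

#' Serialize a hash mapper to JSON
#'
#' @param mapper A [fit_hash_mapper()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hash_mapper <- function(mapper, path) {
  jsonlite::write_json(
    list(n_buckets = mapper$n_buckets, modality_id = mapper$modality_id,
         feature_names = mapper$feature_names, n_fit = mapper$n_fit,
         fit_ids = mapper$fit_ids, boundaries = mapper$boundaries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hash mapper from JSON
#' @param path Path written by [write_hash_mapper()].
#' @return A \code{hash_mapper}.
#' @export
read_hash_mapper <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n_buckets = x$n_buckets,
                 boundaries = lapply(x$boundaries, as.numeric),
                 feature_names = x$feature_names, modality_id = x$modality_id,
                 n_fit = x$n_fit, fit_ids = x$fit_ids),
            class = "hash_mapper")
}
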