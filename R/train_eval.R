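# Stratified cross-validation, the six-metric evaluation table, and
# rank-based AUROC/AUPRC computed in-package.

#' Label-stratified k-fold assignment
#'
#' Patients are dealt into folds class by class; within each class, base
#' counts are equal and remainders go to the folds with the smallest running
#' totals, so fold sizes differ by at most one patient overall and per
#' class.
#'
#' @param labels 0/1 vector.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the within-class shuffles.
#' @return Integer vector of fold ids in \code{1..k}, aligned with
#'   \code{labels}.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  n <- length(labels)
  assert_that(k >= 2 && k <= n, "need 2 <= k <= n (k=%d, n=%d)", k, n)
  fold <- integer(n)
  totals <- integer(k)
  with_seed(seed, {
    classes <- sort(unique(labels))
    counts <- vapply(classes, function(cl) sum(labels == cl), 1L)
    for (cl in classes[order(counts)]) {
      idx <- sample(which(labels == cl))
      nc <- length(idx)
      base <- nc %/% k
      extra <- nc %% k
      gets <- rep(base, k)
      if (extra > 0) {
        lucky <- order(totals, seq_len(k))[seq_len(extra)]
        gets[lucky] <- gets[lucky] + 1
      }
      pos <- 1
      for (f in seq_len(k)) {
        if (gets[f] == 0) next
        take <- idx[pos:(pos + gets[f] - 1)]
        fold[take] <- f
        pos <- pos + gets[f]
        totals[f] <- totals[f] + gets[f]
      }
    }
  })
  fold
}

#' Area under the ROC curve (rank statistic; ties count one half)
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUROC in \code{[0, 1]}.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0, "AUROC undefined: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step interpolation)
#'
#' @inheritParams auroc
#' @return AUPRC in \code{[0, 1]}.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  assert_that(n1 > 0, "AUPRC undefined without positive labels")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)   # one point per threshold
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp); rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Six-metric performance table
#'
#' AUROC, AUPRC, and accuracy, sensitivity, specificity and F1 at the 0.5
#' probability threshold.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels, aligned with \code{scores}; both classes
#'   required.
#' @return Named numeric vector of the six metrics.
#' @export
compute_metrics <- function(scores, labels) {
  assert_that(length(scores) == length(labels), "scores and labels differ in length")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  c(auroc = auroc(scores, labels), auprc = auprc(scores, labels),
    accuracy = (tp + tn) / length(labels), sensitivity = sens,
    specificity = spec, f1 = f1)
}

#' Stratified k-fold cross-validation of the multimodal model
#'
#' For each fold, hash mappers / standardization constants and all trainable
#' state are fitted on the training split only; the held-out fold is mapped
#' with the frozen preprocessors and scored. Default \code{k = 5}.
#'
#' @param cohort A \code{flex_cohort}.
#' @param k Number of folds (default 5).
#' @param config A [flex_config()]; \code{config$seed} controls fold
#'   assignment and per-fold training seeds.
#' @return A \code{flex_cv} object: per-fold scores/labels/metrics, metric
#'   mean and spread, the fold assignment and per-fold models' fit tags.
#' @export
cross_validate <- function(cohort, k = 5, config = flex_config()) {
  labs <- cohort$patients$label
  assert_that(k <= length(labs), "k exceeds the number of patients")
  assert_that(min(table(labs)) >= k,
              "both classes need at least k members for stratified %d-fold CV", k)
  fold <- stratified_folds(labs, k, seed = derive_seed(config$seed, 99))
  per_fold <- list()
  for (f in seq_len(k)) {
    tr <- cohort_subset(cohort, which(fold != f))
    te <- cohort_subset(cohort, which(fold == f))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, f)
    model <- flex_train(tr, cfg)
    p <- flex_predict(model, te)
    per_fold[[f]] <- list(fold = f, scores = p,
                          labels = te$patients$label,
                          patient_ids = te$patients$patient_id,
                          metrics = compute_metrics(p, te$patients$label),
                          fit_ids = model$fit_ids,
                          mappers = model$mappers)
  }
  mt <- do.call(rbind, lapply(per_fold, `[[`, "metrics"))
  rownames(mt) <- paste0("fold", seq_len(k))
  structure(list(folds = per_fold, fold_assignment = fold,
                 metrics = mt,
                 mean = colMeans(mt), sd = apply(mt, 2, sd),
                 config = config, k = k,
                 patient_ids = cohort$patients$patient_id),
            class = "flex_cv")
}

#' @export
print.flex_cv <- function(x, ...) {
  cat(sprintf("<%d-fold CV: mean AUROC %.3f (sd %.3f)>\n", x$k,
              x$mean["auroc"], x$sd["auroc"]))
  print(round(x$metrics, 3))
  invisible(x)
}

#' Post-hoc subgroup performance over a cross-validation result
#'
#' Pools out-of-fold scores and computes the metric table within each level
#' of a patient grouping (e.g. sex, diagnosis, age band).
#'
#' @param cv A \code{flex_cv} from [cross_validate()].
#' @param groups Named vector (patient_id -> group label).
#' @return Matrix of metrics, one row per group level.
#' @export
subgroup_metrics <- function(cv, groups) {
  ids <- unlist(lapply(cv$folds, `[[`, "patient_ids"))
  sc <- unlist(lapply(cv$folds, `[[`, "scores"))
  lab <- unlist(lapply(cv$folds, `[[`, "labels"))
  g <- groups[ids]
  lv <- sort(unique(g))
  out <- t(vapply(lv, function(l)
    compute_metrics(sc[g == l], lab[g == l]), numeric(6)))
  rownames(out) <- lv
  out
}
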