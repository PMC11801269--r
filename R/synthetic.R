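# Synthetic multi-modal cohort generator. Emulates the stated structure of
# the real data: clinical features mostly binary (Bernoulli) and Gaussian,
# proteomic/metabolomic features long-tailed (log-normal, per-feature
# scaled); pathology tiles are textured rasters where progression patients
# carry a bright ellipsoidal lesion blob. Labels follow a logistic model on
# standardized planted informative features, with the intercept calibrated
# to a target prevalence of 0.41 (mirroring a 106/259 class split).

#' Simulation configuration
#'
#' @param n_patients Number of patients.
#' @param n_features Named counts per tabular modality, e.g.
#'   \code{c(C = 20, P = 30, M = 30)}.
#' @param informative Named counts of label-informative features per
#'   modality (each \code{<= n_features}).
#' @param effect_size Log-odds contribution per standardized informative
#'   feature; scalar or named per-modality vector.
#' @param prevalence Target label prevalence (default 0.41, the 106/259
#'   split).
#' @param tile_size Tile side length in pixels (default 32).
#' @param tiles_per_patient Tiles per patient (default 4).
#' @param lesion_signal Probability that a progression patient's tile
#'   carries a planted lesion blob, in \code{[0, 1]}.
#' @param missing_rate Named per-modality rates in \code{[0, 1]} over
#'   \code{C, P, M, I}; each patient loses at most one modality.
#' @param cell_missing_rate Fraction of individual tabular cells blanked to
#'   missing sentinels (default 0).
#' @param outlier_rate Fraction of proteomic/metabolomic cells multiplied by
#'   a large factor, emulating heavy-tail contamination (default 0).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_patients = 300,
                       n_features = c(C = 20, P = 30, M = 30),
                       informative = c(C = 5, P = 5, M = 5),
                       effect_size = 1.0,
                       prevalence = 0.41,
                       tile_size = 32,
                       tiles_per_patient = 4,
                       lesion_signal = 0.8,
                       missing_rate = c(C = 0, P = 0, M = 0, I = 0),
                       cell_missing_rate = 0,
                       outlier_rate = 0,
                       seed = 1) {
  nf <- c(C = 20, P = 30, M = 30); nf[names(n_features)] <- n_features
  inf <- c(C = 0, P = 0, M = 0); inf[names(informative)] <- informative
  es <- c(C = 0, P = 0, M = 0)
  es[] <- if (is.null(names(effect_size))) effect_size else 0
  if (!is.null(names(effect_size))) es[names(effect_size)] <- effect_size
  mr <- c(C = 0, P = 0, M = 0, I = 0); mr[names(missing_rate)] <- missing_rate
  assert_that(n_patients >= 1 && all(nf >= 1), "degenerate config: need >=1 patient and >=1 feature")
  assert_that(all(inf <= nf), "informative features must be <= n_features")
  assert_that(all(mr >= 0 & mr <= 1) && lesion_signal >= 0 && lesion_signal <= 1 &&
                cell_missing_rate >= 0 && cell_missing_rate <= 1 &&
                outlier_rate >= 0 && outlier_rate <= 1,
              "all rates must lie in [0, 1]")
  assert_that(tile_size >= 8 && tiles_per_patient >= 1, "invalid tile settings")
  structure(list(n_patients = n_patients, n_features = nf, informative = inf,
                 effect_size = es, prevalence = prevalence,
                 tile_size = tile_size, tiles_per_patient = tiles_per_patient,
                 lesion_signal = lesion_signal, missing_rate = mr,
                 cell_missing_rate = cell_missing_rate,
                 outlier_rate = outlier_rate, seed = seed),
            class = "sim_config")
}

# smooth random texture on a T x T grid (coarse noise upsampled bilinearly)
random_texture <- function(ts) {
  coarse <- max(4, ts %/% 8)
  g <- matrix(rnorm(coarse^2, 0, 1), coarse, coarse)
  bilinear_upsample(g, ts, ts)
}

#' True lesion mask for a planted ellipse
#'
#' @param tile_size Tile side length.
#' @param lesion List with \code{cx, cy, a, b, angle} (pixel units, radians)
#'   as recorded in the generator's truth manifest.
#' @return Logical matrix \code{tile_size x tile_size}.
#' @export
lesion_mask <- function(tile_size, lesion) {
  idx <- seq_len(tile_size) - 0.5
  X <- matrix(idx, tile_size, tile_size)          # row coordinate
  Y <- matrix(idx, tile_size, tile_size, byrow = TRUE)
  dx <- X - lesion$cx; dy <- Y - lesion$cy
  u <- cos(lesion$angle) * dx + sin(lesion$angle) * dy
  v <- -sin(lesion$angle) * dx + cos(lesion$angle) * dy
  (u / lesion$a)^2 + (v / lesion$b)^2 <= 1
}

# lesion scale is calibrated to the SCDA operating granularity: the
# mean-threshold ROI of a trained backbone covers roughly a third of a
# tile, so localizable lesions must occupy a commensurate area
draw_lesion_params <- function(ts) {
  a <- runif(1, 0.20, 0.30) * ts
  list(cx = runif(1, 0.3 * ts, 0.7 * ts), cy = runif(1, 0.3 * ts, 0.7 * ts),
       a = a, b = a * runif(1, 0.6, 1), angle = runif(1, 0, pi))
}

make_tile <- function(ts, lesion = NULL) {
  base <- runif(1, 0.3, 0.5)
  img <- base + 0.06 * random_texture(ts) + matrix(rnorm(ts * ts, 0, 0.03), ts, ts)
  if (!is.null(lesion)) {
    m <- lesion_mask(ts, lesion)
    img[m] <- img[m] + 0.5
  }
  img <- pmin(pmax(img, 0), 1)
  arr <- array(0, c(ts, ts, 3))
  for (ch in 1:3) arr[, , ch] <- pmin(pmax(img + rnorm(1, 0, 0.02), 0), 1)
  arr
}

#' Generate a synthetic multi-modal cohort
#'
#' Clinical features are half Bernoulli (success probabilities drawn from
#' U\[0.1, 0.5\]) and half Gaussian; proteomic and metabolomic features are
#' per-feature-scaled log-normal(0, 1) (long-tailed). The latent logit is
#' the sum of \code{effect_size} times each standardized informative feature
#' plus an intercept calibrated so that mean predicted prevalence matches
#' \code{config$prevalence}; labels are Bernoulli draws from it. Progression
#' patients' tiles carry a bright ellipsoidal lesion with probability
#' \code{lesion_signal}. Per-modality records are then deleted at
#' \code{missing_rate} (at most one modality per patient). Fully
#' reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @return A \code{flex_cohort} whose \code{truth} attribute records the
#'   planted ground truth (informative feature names, effect sizes,
#'   intercept, per-tile lesion parameters, seed).
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must come from sim_config()")
  with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("PT%04d", seq_len(n))
    tabs <- list(); truth_feats <- list(); lin <- numeric(n)
    for (m in TABULAR_MODALITIES) {
      nf <- config$n_features[[m]]
      fn <- sprintf("%s_f%02d", tolower(m), seq_len(nf))
      X <- matrix(0, n, nf)
      bern_p <- NULL
      if (m == "C") {
        nbin <- ceiling(nf / 2)
        bern_p <- numeric(nbin)
        for (j in seq_len(nf)) {
          if (j <= nbin) {
            bern_p[j] <- runif(1, 0.1, 0.5)
            X[, j] <- rbinom(n, 1, bern_p[j])
          } else X[, j] <- rnorm(n, runif(1, -2, 2), runif(1, 0.5, 2))
        }
        attr_bin <- nbin
      } else {
        for (j in seq_len(nf)) {
          s <- 10^runif(1, -1, 2)
          X[, j] <- s * rlnorm(n, 0, 1)
        }
        attr_bin <- 0
      }
      k <- config$informative[[m]]
      inf_idx <- if (k > 0) sort(sample.int(nf, k)) else integer(0)
      if (k > 0) {
        # risk scales with log-abundance for the long-tailed omics features
        base <- if (m == "C") X[, inf_idx, drop = FALSE]
          else log(X[, inf_idx, drop = FALSE])
        Z <- scale(base)
        Z[!is.finite(Z)] <- 0
        lin <- lin + config$effect_size[[m]] * rowSums(Z)
      }
      # measurement-noise contamination, applied after the latent signal
      if (m != "C" && config$outlier_rate > 0) {
        hit <- matrix(runif(n * nf) < config$outlier_rate, n, nf)
        X[hit] <- X[hit] * runif(sum(hit), 10, 100)
      }
      truth_feats[[m]] <- list(informative = fn[inf_idx],
                               effect_size = config$effect_size[[m]],
                               n_binary = attr_bin, bernoulli_p = bern_p)
      if (config$cell_missing_rate > 0)
        X[matrix(runif(n * nf) < config$cell_missing_rate, n, nf)] <- NA
      tabs[[m]] <- feature_table(m, ids, fn, X)
    }
    intercept <- if (sd(lin) < 1e-12) qlogis(config$prevalence) else
      uniroot(function(a) mean(plogis(lin + a)) - config$prevalence,
              c(-30, 30))$root
    labels <- rbinom(n, 1, plogis(lin + intercept))
    names(labels) <- ids

    images <- list(); lesions <- list()
    ts <- config$tile_size
    for (i in seq_len(n)) {
      tiles <- list(); les <- vector("list", config$tiles_per_patient)
      for (t in seq_len(config$tiles_per_patient)) {
        lp <- if (labels[i] == 1 && runif(1) < config$lesion_signal)
          draw_lesion_params(ts) else NULL
        les[t] <- list(lp)                # keep NULL slots (lesion-free)
        tiles[[t]] <- make_tile(ts, lp)
      }
      images[[ids[i]]] <- image_set(ids[i], tiles, "20x")
      lesions[[ids[i]]] <- les
    }

    # modality-level missingness: each patient loses at most one modality
    complete <- ids
    for (m in ALL_MODALITIES) {
      r <- config$missing_rate[[m]]
      if (r <= 0) next
      k <- floor(r * n)
      drop_ids <- sample(complete, min(k, length(complete)))
      complete <- setdiff(complete, drop_ids)
      if (m == "I") images[drop_ids] <- NULL
      else {
        t <- tabs[[m]]
        keep <- !(t$patient_ids %in% drop_ids)
        tabs[[m]] <- feature_table(m, t$patient_ids[keep], t$feature_names,
                                   t$values[keep, , drop = FALSE])
      }
    }

    cohort <- assemble_cohort(tables = tabs, images = images, labels = labels)
    attr(cohort, "truth") <- list(
      seed = config$seed, prevalence_target = config$prevalence,
      intercept = intercept, features = truth_feats, lesions = lesions,
      tile_size = ts, config = unclass(config))
    cohort
  })
}

#' Write a cohort to the on-disk multi-modal layout
#'
#' Emits exactly the external file layout the readers consume: one CSV per
#' tabular modality, \code{labels.csv}, per-patient PNG tiles with an
#' \code{images_manifest.csv}, and (for synthetic cohorts) a
#' \code{truth.json} ground-truth manifest.
#'
#' @param cohort A \code{flex_cohort}.
#' @param out_dir Output directory.
#' @param force Overwrite an existing cohort directory? Default FALSE.
#' @return Invisibly, a character vector manifest of files written.
#' @export
write_cohort <- function(cohort, out_dir, force = FALSE) {
  marker <- file.path(out_dir, "labels.csv")
  if (file.exists(marker) && !force)
    stop_flex("cohort already present in %s; use force = TRUE to overwrite", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fname <- c(C = "clinical.csv", P = "proteomics.csv", M = "metabolomics.csv")
  for (m in names(cohort$tables)) {
    p <- file.path(out_dir, fname[[m]])
    write_feature_table(cohort$tables[[m]], p)
    files <- c(files, p)
  }
  lab <- cohort$patients[, c("patient_id", "label")]
  write.csv(lab, marker, row.names = FALSE)
  files <- c(files, marker)
  if (!is.null(cohort$images) && length(cohort$images)) {
    man <- data.frame(patient_id = character(0), tile_path = character(0),
                      magnification_tag = character(0))
    for (pid in names(cohort$images)) {
      is <- cohort$images[[pid]]
      dir.create(file.path(out_dir, "images", pid), recursive = TRUE,
                 showWarnings = FALSE)
      for (t in seq_along(is$tiles)) {
        rel <- file.path("images", pid, sprintf("tile_%03d.png", t))
        png::writePNG(is$tiles[[t]], file.path(out_dir, rel))
        man <- rbind(man, data.frame(patient_id = pid, tile_path = rel,
                                     magnification_tag = is$magnification_tag))
      }
    }
    mp <- file.path(out_dir, "images_manifest.csv")
    write.csv(man, mp, row.names = FALSE)
    files <- c(files, mp)
  }
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    tp <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    files <- c(files, tp)
  }
  invisible(files)
}

#' Load a cohort from the on-disk layout written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A \code{flex_cohort}; a \code{truth.json}, if present, is
#'   reattached as the \code{truth} attribute.
#' @export
load_cohort <- function(dir) {
  fname <- c(C = "clinical.csv", P = "proteomics.csv", M = "metabolomics.csv")
  tabs <- list()
  for (m in names(fname)) {
    p <- file.path(dir, fname[[m]])
    if (file.exists(p)) tabs[[m]] <- load_feature_table(p, m)
  }
  mp <- file.path(dir, "images_manifest.csv")
  images <- if (file.exists(mp)) load_image_sets(mp) else NULL
  lab <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  cohort <- assemble_cohort(tables = unname(tabs), images = images, labels = lab)
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp))
    attr(cohort, "truth") <- jsonlite::read_json(tp, simplifyVector = TRUE)
  cohort
}
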