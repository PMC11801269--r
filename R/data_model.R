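# Domain containers and file readers/writers: per-modality feature tables,
# per-patient pathology tile sets, and the aligned multi-modal cohort.

TABULAR_MODALITIES <- c("C", "P", "M")
ALL_MODALITIES <- c("C", "P", "M", "I")

#' Construct a per-modality feature table
#'
#' A feature table holds one tabular modality: clinical (\code{"C"}),
#' proteomic (\code{"P"}) or metabolomic (\code{"M"}) measurements for a set
#' of patients. Missing cells are carried as \code{NA} sentinels; no
#' imputation happens at this stage.
#'
#' @param modality_id One of \code{"C"}, \code{"P"}, \code{"M"}.
#' @param patient_ids Character vector of unique patient identifiers.
#' @param feature_names Character vector of unique feature names.
#' @param values Numeric matrix, patients x features; \code{NA} = missing.
#' @return An object of class \code{feature_table}.
#' @export
feature_table <- function(modality_id, patient_ids, feature_names, values) {
  modality_id <- match.arg(modality_id, TABULAR_MODALITIES)
  patient_ids <- trimws(as.character(patient_ids))
  feature_names <- as.character(feature_names)
  values <- as.matrix(values)
  assert_that(!anyDuplicated(patient_ids),
              "duplicate patient IDs in %s table: %s", modality_id,
              paste(unique(patient_ids[duplicated(patient_ids)]), collapse = ", "))
  assert_that(!anyDuplicated(feature_names),
              "duplicate feature names in %s table", modality_id)
  assert_that(nrow(values) == length(patient_ids) &&
              ncol(values) == length(feature_names),
              "values matrix is %dx%d but table declares %d patients x %d features",
              nrow(values), ncol(values), length(patient_ids), length(feature_names))
  assert_that(is.numeric(values), "values must be numeric")
  dimnames(values) <- list(patient_ids, feature_names)
  structure(list(modality_id = modality_id, patient_ids = patient_ids,
                 feature_names = feature_names, values = values),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table %s: %d patients x %d features, %d missing cells>\n",
              x$modality_id, length(x$patient_ids), length(x$feature_names),
              sum(is.na(x$values))))
  invisible(x)
}

#' Read a tabular modality from CSV/TSV
#'
#' Expects a UTF-8 header row whose first column is \code{patient_id};
#' remaining columns must be numeric, with empty cells (or \code{NA})
#' recording missing measurements. Missing cells are kept as explicit
#' sentinels, never zero-filled.
#'
#' @param path Path to a CSV (or TSV, chosen by extension) file.
#' @param modality_id One of \code{"C"}, \code{"P"}, \code{"M"}.
#' @return A [feature_table()].
#' @export
load_feature_table <- function(path, modality_id) {
  assert_that(file.exists(path), "file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  colClasses = "character", fileEncoding = "UTF-8")
  assert_that(ncol(raw) >= 2, "%s: need patient_id plus >=1 feature column", path)
  ids <- trimws(raw[[1]])
  feats <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(feats))
  for (j in seq_along(feats)) {
    cell <- trimws(raw[[j + 1]])
    empty <- is.na(cell) | cell == "" | toupper(cell) == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop_flex("%s: non-numeric value '%s' at row %d, column '%s'",
                path, cell[bad[1]], bad[1], feats[j])
    vals[, j] <- ifelse(empty, NA_real_, num)
  }
  feature_table(modality_id, ids, feats, vals)
}

#' Write a feature table to CSV
#'
#' Inverse of [load_feature_table()]: missing sentinels become empty cells.
#'
#' @param table A [feature_table()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(patient_id = table$patient_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a per-patient pathology tile set
#'
#' @param patient_id Patient identifier.
#' @param tiles List of numeric arrays of identical shape
#'   \code{c(height, width, 3)}, values in \code{[0, 1]}.
#' @param magnification_tag Free-form magnification label, e.g. "20x".
#' @return An object of class \code{image_set}.
#' @export
image_set <- function(patient_id, tiles, magnification_tag = "20x") {
  assert_that(length(tiles) >= 1, "image_set needs at least one tile")
  dims <- lapply(tiles, dim)
  assert_that(all(vapply(dims, length, 1L) == 3),
              "tiles must be height x width x channel arrays")
  ref <- dims[[1]]
  assert_that(all(vapply(dims, function(d) all(d == ref), TRUE)),
              "all tiles of patient %s must share one shape", patient_id)
  structure(list(patient_id = trimws(as.character(patient_id)), tiles = tiles,
                 magnification_tag = magnification_tag),
            class = "image_set")
}

#' Read pathology tiles listed in a manifest CSV
#'
#' The manifest has columns \code{patient_id}, \code{tile_path} (relative to
#' the manifest's directory) and \code{magnification_tag}; tiles are PNG
#' files.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return Named list of [image_set()] objects, one per patient.
#' @export
load_image_sets <- function(manifest_path) {
  assert_that(file.exists(manifest_path), "manifest not found: %s", manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  assert_that(all(c("patient_id", "tile_path") %in% colnames(man)),
              "manifest needs patient_id and tile_path columns")
  root <- dirname(manifest_path)
  out <- list()
  for (pid in unique(trimws(man$patient_id))) {
    rows <- man[trimws(man$patient_id) == pid, , drop = FALSE]
    tiles <- lapply(rows$tile_path, function(p) {
      arr <- png::readPNG(file.path(root, p))
      if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
      arr[, , 1:3, drop = FALSE]
    })
    tag <- if ("magnification_tag" %in% colnames(man)) rows$magnification_tag[1] else "20x"
    out[[pid]] <- image_set(pid, tiles, tag)
  }
  out
}

#' Assemble an aligned multi-modal cohort
#'
#' Aligns feature tables and tile sets by patient ID (exact string match
#' after whitespace stripping), attaches binary progression labels, and sets
#' per-modality presence flags from actual data availability. Patients
#' lacking a modality are retained with the flag false; the missing-modality
#' Meta pathway handles them downstream.
#'
#' @param tables List of [feature_table()] objects (distinct modalities).
#' @param images Named list of [image_set()] objects, or \code{NULL}.
#' @param labels Named vector (or two-column data.frame \code{patient_id},
#'   \code{label}) mapping every patient with any data to 0/1.
#' @return An object of class \code{flex_cohort} with elements
#'   \code{patients} (data.frame: patient_id, label, has_C/P/M/I),
#'   \code{tables} (per-modality [feature_table()]) and \code{images}.
#' @export
assemble_cohort <- function(tables = list(), images = NULL, labels) {
  if (is.data.frame(labels)) {
    lab <- labels[[2]]
    names(lab) <- trimws(as.character(labels[[1]]))
    labels <- lab
  }
  names(labels) <- trimws(names(labels))
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  tabs <- list()
  for (t in tables) {
    assert_that(inherits(t, "feature_table"), "tables must be feature_table objects")
    assert_that(is.null(tabs[[t$modality_id]]),
                "two tables share modality %s", t$modality_id)
    tabs[[t$modality_id]] <- t
  }
  all_ids <- unique(c(unlist(lapply(tabs, `[[`, "patient_ids")),
                      names(images %||% list())))
  missing_lab <- setdiff(all_ids, names(labels))
  if (length(missing_lab))
    stop_flex("patients have data but no label: %s",
              paste(missing_lab, collapse = ", "))
  ids <- sort(intersect(names(labels), all_ids))
  pat <- data.frame(patient_id = ids, label = as.integer(labels[ids]),
                    stringsAsFactors = FALSE)
  for (m in TABULAR_MODALITIES)
    pat[[paste0("has_", m)]] <- if (is.null(tabs[[m]])) FALSE
      else ids %in% tabs[[m]]$patient_ids
  pat$has_I <- if (is.null(images)) FALSE else ids %in% names(images)
  none <- !(pat$has_C | pat$has_P | pat$has_M | pat$has_I)
  assert_that(!any(none), "patients with no modality at all: %s",
              paste(pat$patient_id[none], collapse = ", "))
  structure(list(patients = pat, tables = tabs, images = images),
            class = "flex_cohort")
}

#' @export
print.flex_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf("<flex_cohort: %d patients, prevalence %.2f; C:%d P:%d M:%d I:%d>\n",
              nrow(p), mean(p$label), sum(p$has_C), sum(p$has_P),
              sum(p$has_M), sum(p$has_I)))
  invisible(x)
}

# subset a cohort by patient index (keeps tables/images aligned)
cohort_subset <- function(cohort, idx) {
  pat <- cohort$patients[idx, , drop = FALSE]
  rownames(pat) <- NULL
  tabs <- lapply(cohort$tables, function(t) {
    keep <- t$patient_ids %in% pat$patient_id
    feature_table(t$modality_id, t$patient_ids[keep], t$feature_names,
                  t$values[keep, , drop = FALSE])
  })
  imgs <- if (is.null(cohort$images)) NULL
    else cohort$images[intersect(names(cohort$images), pat$patient_id)]
  structure(list(patients = pat, tables = tabs, images = imgs),
            class = "flex_cohort")
}

#' Resolve duplicate patient records
#'
#' When a patient appears more than once in a labels file, progression-group
#' records are prioritized, then earlier acquisition times.
#'
#' @param labels data.frame with columns \code{patient_id}, \code{label} and
#'   optionally \code{acquisition_time} (sortable).
#' @return Deduplicated data.frame, one row per patient.
#' @export
deduplicate_patients <- function(labels) {
  ord <- order(trimws(labels$patient_id), -labels$label,
               if (!is.null(labels$acquisition_time)) labels$acquisition_time
               else seq_len(nrow(labels)))
  lab <- labels[ord, , drop = FALSE]
  lab <- lab[!duplicated(trimws(lab$patient_id)), , drop = FALSE]
  rownames(lab) <- NULL
  lab
}
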