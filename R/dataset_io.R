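# The in-memory patch-dataset container and its plain-text on-disk form
# (manifest.csv + packed patches.csv), shared by the extraction and
# synthetic-data paths so training and evaluation consume either.

#' Construct a labeled patch dataset
#'
#' @param patches 3-D array `(n, size, size)` of normalized intensities in
#'   `[0,1]`.
#' @param labels integer vector over {0,1}; 1 = nodule.
#' @param exam_ids character vector assigning each patch to a CT exam
#'   (scan/case), the denominator unit of the FP/exam metric.
#' @param manifest optional per-patch data.frame
#'   (case_id, slice_id, label, center_row, center_col, patch_path); built
#'   from the other arguments when omitted.
#' @return a `patch_dataset` list.
#' @export
patch_dataset <- function(patches, labels, exam_ids, manifest = NULL) {
  stopifnot(length(dim(patches)) == 3L, dim(patches)[2] == dim(patches)[3])
  n <- dim(patches)[1]
  labels <- as.integer(labels)
  exam_ids <- as.character(exam_ids)
  stopifnot(length(labels) == n, length(exam_ids) == n,
            all(labels %in% c(0L, 1L)))
  if (n > 0 && (min(patches) < -1e-9 || max(patches) > 1 + 1e-9))
    stop("patch intensities must lie in [0,1]; normalize first")
  if (is.null(manifest))
    manifest <- data.frame(case_id = exam_ids,
                           slice_id = rep(NA_character_, n),
                           label = labels,
                           center_row = rep(NA_integer_, n),
                           center_col = rep(NA_integer_, n),
                           patch_path = rep(NA_character_, n),
                           stringsAsFactors = FALSE)
  structure(list(patches = patches, labels = labels, exam_ids = exam_ids,
                 manifest = manifest),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  n <- dim(x$patches)[1]
  cat(sprintf("patch_dataset: %d patches (%dx%d), %d nodule / %d nonnodule, %d exams\n",
              n, dim(x$patches)[2], dim(x$patches)[3],
              sum(x$labels == 1L), sum(x$labels == 0L),
              length(unique(x$exam_ids))))
  invisible(x)
}

#' @export
length.patch_dataset <- function(x) dim(x$patches)[1]

#' Subset a patch dataset by index
#'
#' @param dataset a [patch_dataset()].
#' @param idx integer or logical index over patches.
#' @export
dataset_subset <- function(dataset, idx) {
  patch_dataset(dataset$patches[idx, , , drop = FALSE],
                dataset$labels[idx], dataset$exam_ids[idx],
                dataset$manifest[idx, , drop = FALSE])
}

#' Class bookkeeping of a manifest
#'
#' Counts nodule and nonnodule rows of a manifest (or dataset) and their
#' total, the accounting used to verify that no annotation is silently
#' dropped between extraction and training.
#'
#' @param x a manifest data.frame with a `label` column, or a
#'   [patch_dataset()].
#' @return named vector `c(nodule, nonnodule, total)`.
#' @export
manifest_class_counts <- function(x) {
  if (inherits(x, "patch_dataset")) x <- x$manifest
  n1 <- sum(x$label == 1L); n0 <- sum(x$label == 0L)
  c(nodule = n1, nonnodule = n0, total = n1 + n0)
}

fmt_num <- function(x) sprintf("%.9g", x)

#' Write a patch dataset to a directory
#'
#' Emits `manifest.csv` (header
#' `case_id,slice_id,label,center_row,center_col,patch_path`) and
#' `patches.csv`, one row per patch holding the column-major flattened
#' pixels at 9 significant digits. Output is byte-deterministic for a given
#' dataset.
#'
#' @param dataset a [patch_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- dataset$manifest
  m$patch_path <- sprintf("patches.csv:%d", seq_len(nrow(m)))
  header <- "case_id,slice_id,label,center_row,center_col,patch_path"
  lines <- sprintf("%s,%s,%d,%s,%s,%s", m$case_id,
                   ifelse(is.na(m$slice_id), "", m$slice_id), m$label,
                   ifelse(is.na(m$center_row), "", as.character(m$center_row)),
                   ifelse(is.na(m$center_col), "", as.character(m$center_col)),
                   m$patch_path)
  writeLines(c(header, lines), file.path(dir, "manifest.csv"))
  n <- dim(dataset$patches)[1]
  plines <- vapply(seq_len(n), function(i)
    paste(fmt_num(as.numeric(dataset$patches[i, , ])), collapse = ","),
    character(1))
  writeLines(plines, file.path(dir, "patches.csv"))
  invisible(dir)
}

#' Read a patch dataset written by [write_dataset()]
#'
#' @param dir directory holding `manifest.csv` and `patches.csv`.
#' @return a [patch_dataset()].
#' @export
read_dataset <- function(dir) {
  m <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE,
                colClasses = c(case_id = "character", slice_id = "character",
                               patch_path = "character"))
  plines <- readLines(file.path(dir, "patches.csv"))
  if (length(plines) != nrow(m))
    stop("patches.csv row count does not match the manifest")
  size <- as.integer(sqrt(length(strsplit(plines[1], ",", fixed = TRUE)[[1]])))
  arr <- array(0, dim = c(nrow(m), size, size))
  for (i in seq_along(plines))
    arr[i, , ] <- matrix(as.numeric(strsplit(plines[i], ",", fixed = TRUE)[[1]]),
                         size, size)
  patch_dataset(arr, m$label, m$case_id, m)
}
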