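# ROI patch extraction from LIDC-style annotations. Coordinates are 0-based
# (row, col) with pixel-center semantics; crops are half-open [r0, r0+size).

round_half_up <- function(x) floor(x + 0.5)

#' Parse an LIDC-dialect annotation document
#'
#' Reads the per-case XML markup: `readingSession` elements containing
#' `unblindedReadNodule` entries (freehand contours as `edgeMap` vertex
#' lists, one `roi` per slice) and `nonNodule` entries (a single `locus`
#' centroid mark). `xCoord` is the 0-based column and `yCoord` the 0-based
#' row, following the image convention of the source markup.
#'
#' @param x a file path, an XML string, or an `xml2` document.
#' @return list of annotation records, each a list with `case_id`,
#'   `slice_id`, `kind` (`"nodule"`/`"nonnodule"`), `id`, and `contour`
#'   (an `m x 2` matrix of 0-based (row, col) vertices; a single row for
#'   centroid marks). An empty document yields an empty list.
#' @export
parse_annotations <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  case_node <- xml2::xml_find_first(doc, ".//SeriesInstanceUid")
  case_id <- if (inherits(case_node, "xml_missing")) NA_character_ else
    xml2::xml_text(case_node)
  num_child <- function(node, name, context) {
    child <- xml2::xml_find_first(node, paste0("./", name))
    if (inherits(child, "xml_missing"))
      stop(sprintf("malformed annotation: <%s> missing <%s>", context, name))
    v <- suppressWarnings(as.numeric(xml2::xml_text(child)))
    if (is.na(v))
      stop(sprintf("malformed annotation: non-numeric <%s> inside <%s>",
                   name, context))
    v
  }
  records <- list()
  for (session in xml2::xml_find_all(doc, ".//readingSession")) {
    for (nod in xml2::xml_find_all(session, "./unblindedReadNodule")) {
      nid <- xml2::xml_text(xml2::xml_find_first(nod, "./noduleID"))
      rois <- xml2::xml_find_all(nod, "./roi")
      if (!length(rois))
        stop("malformed annotation: <unblindedReadNodule> without <roi>")
      for (roi in rois) {
        slice <- xml2::xml_text(xml2::xml_find_first(roi, "./imageSOP_UID"))
        edges <- xml2::xml_find_all(roi, "./edgeMap")
        if (!length(edges))
          stop("malformed annotation: <roi> without <edgeMap> vertices")
        contour <- t(vapply(edges, function(e)
          c(num_child(e, "yCoord", "edgeMap"), num_child(e, "xCoord", "edgeMap")),
          numeric(2)))
        colnames(contour) <- c("row", "col")
        records[[length(records) + 1L]] <- list(
          case_id = case_id, slice_id = slice, kind = "nodule",
          id = nid, contour = contour)
      }
    }
    for (nn in xml2::xml_find_all(session, "./nonNodule")) {
      slice <- xml2::xml_text(xml2::xml_find_first(nn, "./imageSOP_UID"))
      locus <- xml2::xml_find_first(nn, "./locus")
      if (inherits(locus, "xml_missing"))
        stop("malformed annotation: <nonNodule> missing <locus>")
      contour <- matrix(c(num_child(locus, "yCoord", "locus"),
                          num_child(locus, "xCoord", "locus")),
                        nrow = 1, dimnames = list(NULL, c("row", "col")))
      records[[length(records) + 1L]] <- list(
        case_id = case_id, slice_id = slice, kind = "nonnodule",
        id = xml2::xml_text(xml2::xml_find_first(nn, "./nonNoduleID")),
        contour = contour)
    }
  }
  records
}

#' Geometric center of an annotated region
#'
#' Arithmetic mean of the contour vertices, rounded half-up to integer pixel
#' coordinates; a single centroid mark is returned as-is.
#'
#' @param contour `m x 2` matrix of (row, col) vertices.
#' @return integer (row, col) pair.
#' @export
geometric_center <- function(contour) {
  stopifnot(nrow(contour) >= 1)
  as.integer(round_half_up(colMeans(contour)))
}

#' Bounding-box extent of an annotated region
#'
#' @param contour `m x 2` matrix of (row, col) vertices.
#' @return integer (height, width) = max - min + 1 per axis.
#' @export
region_extent <- function(contour) {
  stopifnot(nrow(contour) >= 1)
  as.integer(apply(contour, 2, function(v) max(v) - min(v) + 1))
}

#' Cut a fixed-size ROI patch around a region center
#'
#' Applies the size rule: if the region's bounding box fits within
#' `patch_size` on both axes, a direct `patch_size` crop centered on the
#' geometric center is taken; otherwise a `2*patch_size` crop is taken and
#' mean-downsampled back to `patch_size` (for the default 32, a 64x64 crop
#' downsampled to 32x32). Which branch ran is recorded in the `"branch"`
#' attribute (`"direct"` or `"downsample"`) and depends only on the extent,
#' never on intensities. A crop of side `s` centered at `c` covers the
#' half-open range `[c - s/2, c + s/2)`; parts outside the slice are padded
#' with `pad_value` (air-equivalent, the normalization window floor).
#'
#' @param slice 2-D numeric matrix of raw slice intensities.
#' @param center integer (row, col), 0-based, inside the slice.
#' @param extent integer (height, width) from [region_extent()].
#' @param patch_size output side, 32 or 64.
#' @param pad_value intensity used outside the slice.
#' @return `patch_size` square matrix of raw intensities with attribute
#'   `"branch"`.
#' @export
extract_patch <- function(slice, center, extent, patch_size = 32L,
                          pad_value = 0) {
  slice <- as.matrix(slice)
  if (center[1] < 0 || center[2] < 0 ||
      center[1] >= nrow(slice) || center[2] >= ncol(slice))
    stop(sprintf("center (%d, %d) lies outside the %dx%d slice",
                 center[1], center[2], nrow(slice), ncol(slice)))
  branch <- if (all(extent <= patch_size)) "direct" else "downsample"
  size <- if (branch == "direct") patch_size else 2L * patch_size
  half <- size %/% 2L
  out <- matrix(pad_value, size, size)
  r <- (center[1] - half):(center[1] + half - 1L)  # 0-based source rows
  cc <- (center[2] - half):(center[2] + half - 1L)
  rok <- r >= 0 & r < nrow(slice)
  cok <- cc >= 0 & cc < ncol(slice)
  out[rok, cok] <- slice[r[rok] + 1L, cc[cok] + 1L]
  if (branch == "downsample") out <- downsample_2x(out)
  attr(out, "branch") <- branch
  out
}

#' Mean-downsample a patch by a factor of 2
#'
#' Non-overlapping 2x2 mean pooling, chosen over interpolation because it
#' preserves the image mean exactly.
#'
#' @param patch square matrix with even side (64x64 in the default pipeline).
#' @return matrix of half the side length with the same overall mean.
#' @export
downsample_2x <- function(patch) {
  patch <- as.matrix(patch)
  n <- nrow(patch)
  if (n != ncol(patch) || n %% 2L != 0L)
    stop(sprintf("downsample_2x needs an even square input, got %dx%d",
                 nrow(patch), ncol(patch)))
  o <- seq(1L, n, by = 2L)
  (patch[o, o] + patch[o + 1L, o] + patch[o, o + 1L] + patch[o + 1L, o + 1L]) / 4
}

#' Map raw intensities into the unit interval with a fixed linear window
#'
#' `(raw - window[1]) / (window[2] - window[1])`, clamped to `[0,1]`. The
#' window is fixed per dataset (not per patch) so normalization is
#' reproducible and monotone; for calibrated CT arrays in Hounsfield units a
#' `c(-1000, 400)` lung window is the conventional choice, while fixtures
#' stored in `[0,1]` use the identity window.
#'
#' @param raw numeric matrix of raw intensities.
#' @param window length-2 numeric (floor, ceiling), floor < ceiling.
#' @return matrix of the same shape with values in `[0,1]`.
#' @export
normalize_patch <- function(raw, window = c(0, 1)) {
  stopifnot(length(window) == 2, window[2] > window[1])
  pmin(pmax((raw - window[1]) / (window[2] - window[1]), 0), 1)
}

read_slice <- function(slice) {
  if (is.character(slice)) {
    if (!grepl("\\.png$", slice, ignore.case = TRUE))
      stop("slice paths must point to grayscale PNG files")
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to read PNG slices")
    img <- png::readPNG(slice)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(img)
  }
  as.matrix(slice)
}

#' Build a labeled patch dataset from annotated cases
#'
#' Applies [geometric_center()], [region_extent()], [extract_patch()] and
#' [normalize_patch()] to every annotation of every case, in deterministic
#' order (case, slice, center row, center col). Annotations whose slice is
#' missing are skipped and counted.
#'
#' @param cases list of cases; each case is a list with `case_id`, `slices`
#'   (named list of matrices or PNG paths, names matching the annotations'
#'   `slice_id`), and `annotations` (records from [parse_annotations()], or
#'   an XML path/string to parse).
#' @param mode patch side, 32 or 64.
#' @param window intensity window passed to [normalize_patch()]; its floor
#'   is also the out-of-slice padding value.
#' @return a [patch_dataset()] whose manifest has one row per extracted
#'   patch and an attribute `skipped` counting missing-slice annotations.
#' @export
build_dataset <- function(cases, mode = 32L, window = c(0, 1)) {
  mode <- as.integer(mode)
  stopifnot(mode %in% c(32L, 64L))
  rows <- list(); patches <- list(); skipped <- 0L
  for (case in cases[order(vapply(cases, `[[`, "", "case_id"))]) {
    ann <- case$annotations
    if (is.character(ann) || inherits(ann, "xml_document"))
      ann <- parse_annotations(ann)
    centers <- t(vapply(ann, function(a) geometric_center(a$contour),
                        integer(2)))
    ord <- order(vapply(ann, `[[`, "", "slice_id"), centers[, 1], centers[, 2])
    for (j in ord) {
      a <- ann[[j]]
      slice <- case$slices[[a$slice_id]]
      if (is.null(slice)) { skipped <- skipped + 1L; next }
      slice <- read_slice(slice)
      raw <- extract_patch(slice, centers[j, ], region_extent(a$contour),
                           patch_size = mode, pad_value = window[1])
      patches[[length(patches) + 1L]] <- normalize_patch(raw, window)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case$case_id, slice_id = a$slice_id,
        label = as.integer(a$kind == "nodule"),
        center_row = centers[j, 1], center_col = centers[j, 2],
        patch_path = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    message(sprintf("build_dataset: skipped %d annotation(s) with missing slices",
                    skipped))
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), slice_id = character(),
               label = integer(), center_row = integer(),
               center_col = integer(), patch_path = character())
  arr <- array(0, dim = c(length(patches), mode, mode))
  for (i in seq_along(patches)) arr[i, , ] <- patches[[i]]
  ds <- patch_dataset(arr, manifest$label, manifest$case_id, manifest)
  attr(ds, "skipped") <- skipped
  ds
}
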