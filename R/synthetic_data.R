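# Synthetic patch and fixture generation. The generator targets the
# topology/contrast classes a nodule classifier must separate — compact
# blobs (solid), mixed-core blobs (semisolid), faint wide blobs (ground
# glass opacity) versus elongated vessel-like ridges and textured background
# — not radiological realism in Hounsfield units.

BG_LEVEL <- 0.35

sep_params <- function(separation) {
  switch(separation,
         high = list(amp = 1.0, noise = 0.05),
         medium = list(amp = 0.45, noise = 0.10),
         low = list(amp = 0.06, noise = 0.15),
         stop(sprintf("unknown separation level '%s'", separation)))
}

gaussian_blob <- function(size, center, sigma_r, sigma_c = sigma_r,
                          theta = 0) {
  r <- matrix(seq_len(size) - 1 - center[1], size, size)
  cc <- matrix(seq_len(size) - 1 - center[2], size, size, byrow = TRUE)
  u <- cos(theta) * r + sin(theta) * cc
  v <- -sin(theta) * r + cos(theta) * cc
  exp(-(u^2 / (2 * sigma_r^2) + v^2 / (2 * sigma_c^2)))
}

#' Generate one synthetic labeled patch
#'
#' Appearance classes: `solid` is a bright compact Gaussian blob; `semisolid`
#' a blob with a brighter off-center core over a wider halo; `ggo` a
#' low-contrast wide blob; `vessel` a high-eccentricity anisotropic ridge at
#' random orientation; `background` textured noise with faint wide
#' fluctuations. All sit on Gaussian background noise and are clamped to
#' `[0,1]`. The `separation` level scales signal amplitude against noise
#' (contrast-to-noise roughly 10 / 2 / 0.2 for high / medium / low). Draws
#' come from the caller's RNG stream: seed upstream for reproducibility.
#'
#' @param kind `"solid"`, `"semisolid"`, `"ggo"`, `"vessel"` or
#'   `"background"`.
#' @param separation `"high"`, `"medium"` or `"low"`.
#' @param patch_size 32 or 64.
#' @return `patch_size` square matrix in `[0,1]`.
#' @export
generate_patch <- function(kind, separation = "high", patch_size = 32L) {
  sp <- sep_params(separation)
  s <- patch_size
  ctr <- (s - 1) / 2 + runif(2, -2, 2)
  sc <- s / 32  # widths scale with patch side
  signal <- switch(kind,
    solid = runif(1, 0.45, 0.60) * gaussian_blob(s, ctr, runif(1, 2.5, 4.0) * sc),
    semisolid = {
      core_ctr <- ctr + runif(2, -1.5, 1.5)
      runif(1, 0.20, 0.30) * gaussian_blob(s, ctr, runif(1, 4.0, 6.0) * sc) +
        runif(1, 0.30, 0.40) * gaussian_blob(s, core_ctr, runif(1, 1.2, 2.0) * sc)
    },
    ggo = runif(1, 0.18, 0.28) * gaussian_blob(s, ctr, runif(1, 6.0, 9.0) * sc),
    vessel = runif(1, 0.40, 0.55) *
      gaussian_blob(s, ctr, runif(1, 10, 18) * sc, runif(1, 1.2, 2.2) * sc,
                    theta = runif(1, 0, pi)),
    background = {
      tex <- matrix(0, s, s)
      for (b in seq_len(3))
        tex <- tex + runif(1, -0.05, 0.05) *
          gaussian_blob(s, runif(2, 0, s - 1), runif(1, 4, 10) * sc)
      tex
    },
    stop(sprintf("unknown patch kind '%s'", kind)))
  raw <- BG_LEVEL + sp$amp * signal +
    matrix(rnorm(s * s, sd = sp$noise), s, s)
  pmin(pmax(raw, 0), 1)
}

#' Describe a synthetic dataset
#'
#' Defaults mirror the nodule : nonnodule imbalance of large annotated CT
#' collections (roughly 1.88 : 1, i.e. 40772 : 21720 scaled down) at a total
#' of 600 patches.
#'
#' @param n_nodules,n_nonnodules class counts.
#' @param nodule_mix named weights over solid/semisolid/ggo (sum 1).
#' @param nonnodule_mix named weights over vessel/background (sum 1).
#' @param separation `"high"`, `"medium"` or `"low"`.
#' @param patch_size 32 or 64.
#' @param exams number of synthetic exam ids; patches are assigned
#'   round-robin so grouped splits are deterministic.
#' @param seed RNG seed.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_nodules = 391L, n_nonnodules = 209L,
                           nodule_mix = c(solid = 0.45, semisolid = 0.30,
                                          ggo = 0.25),
                           nonnodule_mix = c(vessel = 0.6, background = 0.4),
                           separation = c("high", "medium", "low"),
                           patch_size = 32L, exams = 20L, seed = 1L) {
  separation <- match.arg(separation)
  stopifnot(n_nodules >= 0, n_nonnodules >= 0,
            abs(sum(nodule_mix) - 1) < 1e-8,
            abs(sum(nonnodule_mix) - 1) < 1e-8,
            patch_size %in% c(32L, 64L), exams >= 1)
  structure(list(n_nodules = as.integer(n_nodules),
                 n_nonnodules = as.integer(n_nonnodules),
                 nodule_mix = nodule_mix, nonnodule_mix = nonnodule_mix,
                 separation = separation, patch_size = as.integer(patch_size),
                 exams = as.integer(exams), seed = as.integer(seed)),
            class = "generator_spec")
}

#' Class counts mirroring the reference nodule : nonnodule imbalance
#'
#' Scales the 40772 : 21720 ratio down to `n_total` patches with half-up
#' rounding of the nodule share.
#'
#' @param n_total total patch count.
#' @param nodules,nonnodules the reference class counts.
#' @return named vector `c(nodule, nonnodule)` summing to `n_total`.
#' @export
mirror_ratio_counts <- function(n_total, nodules = 40772L,
                                nonnodules = 21720L) {
  n1 <- as.integer(floor(n_total * nodules / (nodules + nonnodules) + 0.5))
  c(nodule = n1, nonnodule = as.integer(n_total) - n1)
}

spec_plan <- function(spec) {
  n <- spec$n_nodules + spec$n_nonnodules
  if (n == 0L) stop("generate_dataset: zero total patches")
  kinds <- c(sample(names(spec$nodule_mix), spec$n_nodules, replace = TRUE,
                    prob = spec$nodule_mix),
             sample(names(spec$nonnodule_mix), spec$n_nonnodules,
                    replace = TRUE, prob = spec$nonnodule_mix))
  labels <- c(rep(1L, spec$n_nodules), rep(0L, spec$n_nonnodules))
  exam_ids <- sprintf("SYN-EXAM%03d", ((seq_len(n) - 1L) %% spec$exams) + 1L)
  list(kinds = kinds, labels = labels, exam_ids = exam_ids)
}

#' Manifest of a synthetic dataset without materializing pixels
#'
#' Draws the same class/kind/exam plan as [generate_dataset()] and returns
#' the manifest alone; useful for bookkeeping checks at full collection
#' scale.
#'
#' @param spec a [generator_spec()].
#' @return manifest data.frame with a `kind` column appended.
#' @export
generate_manifest <- function(spec) {
  set.seed(spec$seed)
  plan <- spec_plan(spec)
  data.frame(case_id = plan$exam_ids, slice_id = NA_character_,
             label = plan$labels, center_row = NA_integer_,
             center_col = NA_integer_, patch_path = NA_character_,
             kind = plan$kinds, stringsAsFactors = FALSE)
}

#' Generate a labeled synthetic patch dataset
#'
#' Deterministic from the generator spec's seed; nodule patches first, then
#' nonnodules, with exam ids assigned round-robin. The manifest schema
#' matches [build_dataset()]'s, so training and evaluation consume either
#' source interchangeably.
#'
#' @param spec a [generator_spec()].
#' @return a [patch_dataset()] with the drawn `kind` per patch kept in the
#'   manifest.
#' @export
generate_dataset <- function(spec) {
  set.seed(spec$seed)
  plan <- spec_plan(spec)
  n <- length(plan$labels)
  arr <- array(0, dim = c(n, spec$patch_size, spec$patch_size))
  for (i in seq_len(n))
    arr[i, , ] <- generate_patch(plan$kinds[i], spec$separation,
                                 spec$patch_size)
  manifest <- data.frame(case_id = plan$exam_ids, slice_id = NA_character_,
                         label = plan$labels, center_row = NA_integer_,
                         center_col = NA_integer_,
                         patch_path = NA_character_, kind = plan$kinds,
                         stringsAsFactors = FALSE)
  patch_dataset(arr, plan$labels, plan$exam_ids, manifest)
}

circle_contour <- function(center, radius, n_vertices = 16L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(row = round_half_up(center[1] + radius * sin(theta)),
        col = round_half_up(center[2] + radius * cos(theta)))
}

nodule_xml <- function(id, slice_id, contour) {
  edges <- sprintf("        <edgeMap><xCoord>%d</xCoord><yCoord>%d</yCoord></edgeMap>",
                   contour[, "col"], contour[, "row"])
  c(sprintf("    <unblindedReadNodule>"),
    sprintf("      <noduleID>%s</noduleID>", id),
    "      <roi>",
    sprintf("        <imageSOP_UID>%s</imageSOP_UID>", slice_id),
    edges,
    "      </roi>",
    "    </unblindedReadNodule>")
}

nonnodule_xml <- function(id, slice_id, center) {
  c("    <nonNodule>",
    sprintf("      <nonNoduleID>%s</nonNoduleID>", id),
    sprintf("      <imageSOP_UID>%s</imageSOP_UID>", slice_id),
    sprintf("      <locus><xCoord>%d</xCoord><yCoord>%d</yCoord></locus>",
            center[2], center[1]),
    "    </nonNodule>")
}

#' Generate synthetic slices with matching LIDC-dialect annotations
#'
#' Plants blobs at known centers on synthetic CT-like slices and serializes
#' matching annotation XML: freehand circle contours for regions with a
#' measurable margin, single centroid marks for small nodules, and `locus`
#' marks for nonnodules. Each case also records the planted ground truth so
#' round-trip tests can compare recovered centers. Case 1 always contains a
#' region larger than 32x32, exercising the 64-to-32 downsampling branch.
#'
#' @param n_cases number of synthetic cases (>= 1).
#' @param seed RNG seed.
#' @param slice_size square slice side in pixels.
#' @return list of cases, each a list with `case_id`, `slices` (named list
#'   of matrices), `annotations` (XML string) and `planted` (data.frame of
#'   kind, slice_id, center_row, center_col, radius).
#' @export
generate_annotation_fixture <- function(n_cases = 3L, seed = 1L,
                                        slice_size = 128L) {
  stopifnot(n_cases >= 1)
  set.seed(seed)
  lapply(seq_len(n_cases), function(ci) {
    case_id <- sprintf("SYN-CASE%03d", ci)
    mk_slice <- function() pmin(pmax(
      BG_LEVEL + matrix(rnorm(slice_size^2, sd = 0.03),
                        slice_size, slice_size), 0), 1)
    s1 <- mk_slice(); s2 <- mk_slice()
    jit <- function(p) as.integer(p + sample(-3:3, 2, replace = TRUE))
    plant <- function(slice, center, sigma, amp)
      pmin(slice + amp * gaussian_blob(slice_size, center, sigma), 1)

    med_c <- jit(c(34, 34)); med_r <- sample(5:10, 1)
    s1 <- plant(s1, med_c, med_r / 2, 0.5)
    small_c <- jit(c(92, 92))
    s1 <- plant(s1, small_c, 1.5, 0.5)
    nn_c <- jit(c(64, 40))
    s2 <- plant(s2, nn_c, 2.5, 0.4)

    body <- c(nodule_xml("N1", "S1", circle_contour(med_c, med_r)),
              nodule_xml("N2", "S1",
                         matrix(small_c, 1,
                                dimnames = list(NULL, c("row", "col")))),
              nonnodule_xml("NN1", "S2", nn_c))
    planted <- data.frame(
      kind = c("nodule", "nodule", "nonnodule"),
      slice_id = c("S1", "S1", "S2"),
      center_row = c(med_c[1], small_c[1], nn_c[1]),
      center_col = c(med_c[2], small_c[2], nn_c[2]),
      radius = c(med_r, 0L, 0L), stringsAsFactors = FALSE)
    if (ci == 1L) {
      big_c <- jit(c(64, 88)); big_r <- 20L
      s2 <- plant(s2, big_c, big_r / 2, 0.45)
      body <- c(body, nodule_xml("N3", "S2", circle_contour(big_c, big_r)))
      planted <- rbind(planted, data.frame(
        kind = "nodule", slice_id = "S2", center_row = big_c[1],
        center_col = big_c[2], radius = big_r))
    }
    xml <- paste(c("<LidcReadMessage>",
                   "  <ResponseHeader>",
                   sprintf("    <SeriesInstanceUid>%s</SeriesInstanceUid>",
                           case_id),
                   "  </ResponseHeader>",
                   "  <readingSession>", body, "  </readingSession>",
                   "</LidcReadMessage>"), collapse = "\n")
    list(case_id = case_id, slices = list(S1 = s1, S2 = s2),
         annotations = xml, planted = planted)
  })
}
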