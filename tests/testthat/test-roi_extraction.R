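fixture_xml <- function() {
  paste(
    "<LidcReadMessage>",
    "  <ResponseHeader><SeriesInstanceUid>CASE-A</SeriesInstanceUid></ResponseHeader>",
    "  <readingSession>",
    "    <unblindedReadNodule><noduleID>N1</noduleID><roi>",
    "      <imageSOP_UID>S1</imageSOP_UID>",
    "      <edgeMap><xCoord>10</xCoord><yCoord>20</yCoord></edgeMap>",
    "      <edgeMap><xCoord>12</xCoord><yCoord>20</yCoord></edgeMap>",
    "      <edgeMap><xCoord>12</xCoord><yCoord>24</yCoord></edgeMap>",
    "      <edgeMap><xCoord>10</xCoord><yCoord>24</yCoord></edgeMap>",
    "      <edgeMap><xCoord>11</xCoord><yCoord>22</yCoord></edgeMap>",
    "    </roi></unblindedReadNodule>",
    "    <unblindedReadNodule><noduleID>N2</noduleID><roi>",
    "      <imageSOP_UID>S2</imageSOP_UID>",
    "      <edgeMap><xCoord>40</xCoord><yCoord>50</yCoord></edgeMap>",
    "    </roi></unblindedReadNodule>",
    "    <nonNodule><nonNoduleID>NN1</nonNoduleID>",
    "      <imageSOP_UID>S1</imageSOP_UID>",
    "      <locus><xCoord>33</xCoord><yCoord>44</yCoord></locus>",
    "    </nonNodule>",
    "  </readingSession>",
    "</LidcReadMessage>", sep = "\n")
}

test_that("parse_annotations reads nodules, nonnodules and contours", {
  rec <- parse_annotations(fixture_xml())
  expect_length(rec, 3L)
  expect_equal(vapply(rec, `[[`, "", "kind"),
               c("nodule", "nodule", "nonnodule"))
  expect_equal(vapply(rec, `[[`, "", "case_id"), rep("CASE-A", 3))
  expect_equal(nrow(rec[[1]]$contour), 5L)
  expect_equal(rec[[1]]$contour[1, ], c(row = 20, col = 10))
  expect_equal(rec[[3]]$contour[1, ], c(row = 44, col = 33))
  expect_length(parse_annotations("<LidcReadMessage></LidcReadMessage>"), 0L)
})

test_that("malformed markup is rejected with the offending element named", {
  bad <- "<LidcReadMessage><readingSession><unblindedReadNodule>
          <noduleID>N1</noduleID><roi><imageSOP_UID>S</imageSOP_UID>
          <edgeMap><xCoord>1</xCoord></edgeMap></roi>
          </unblindedReadNodule></readingSession></LidcReadMessage>"
  expect_error(parse_annotations(bad), "edgeMap")
  bad2 <- "<LidcReadMessage><readingSession><nonNodule>
           <imageSOP_UID>S</imageSOP_UID></nonNodule>
           </readingSession></LidcReadMessage>"
  expect_error(parse_annotations(bad2), "locus")
})

test_that("geometric_center is the rounded vertex mean", {
  expect_equal(geometric_center(cbind(10, 20)), c(10L, 20L))
  sq <- cbind(c(0, 0, 10, 10), c(0, 10, 0, 10))
  expect_equal(geometric_center(sq), c(5L, 5L))
  set.seed(201)
  for (i in 1:20) {
    v <- matrix(sample.int(100, 10), 5, 2)
    expect_equal(geometric_center(v),
                 as.integer(floor(colMeans(v) + 0.5)))
  }
  # half-up rounding at .5
  expect_equal(geometric_center(cbind(c(1, 2), c(1, 2))), c(2L, 2L))
})

test_that("region_extent is the bounding-box size", {
  expect_equal(region_extent(cbind(7, 3)), c(1L, 1L))
  sq <- cbind(c(0, 0, 10, 10), c(0, 10, 0, 10))
  expect_equal(region_extent(sq), c(11L, 11L))
  set.seed(202)
  for (i in 1:20) {
    v <- matrix(sample.int(60, 12), 6, 2)
    expect_equal(region_extent(v),
                 as.integer(c(diff(range(v[, 1])) + 1, diff(range(v[, 2])) + 1)))
  }
})

test_that("the size rule picks the crop branch from the extent alone", {
  set.seed(203)
  slice <- matrix(runif(200 * 200), 200, 200)
  p1 <- extract_patch(slice, c(100L, 100L), c(12L, 12L))
  expect_equal(attr(p1, "branch"), "direct")
  expect_equal(dim(p1), c(32L, 32L))
  # direct crop copies the slice window [c-16, c+16) verbatim
  expect_equal(unclass(p1)[1:32, 1:32],
               slice[85:116, 85:116], ignore_attr = TRUE)
  p2 <- extract_patch(slice, c(100L, 100L), c(40L, 40L))
  expect_equal(attr(p2, "branch"), "downsample")
  expect_equal(dim(p2), c(32L, 32L))
  expect_equal(unclass(p2)[1:32, 1:32],
               downsample_2x(slice[69:132, 69:132]), ignore_attr = TRUE)
  # boundary: extent exactly 32 stays on the direct branch
  expect_equal(attr(extract_patch(slice, c(100L, 100L), c(32L, 32L)), "branch"),
               "direct")
  expect_equal(attr(extract_patch(slice, c(100L, 100L), c(33L, 12L)), "branch"),
               "downsample")
  expect_error(extract_patch(slice, c(300L, 10L), c(5L, 5L)), "outside")
})

test_that("crops near the slice edge are padded with the window floor", {
  slice <- matrix(0.8, 40, 40)
  p <- extract_patch(slice, c(2L, 2L), c(10L, 10L), pad_value = 0.1)
  expect_equal(dim(p), c(32L, 32L))
  expect_equal(unclass(p)[1, 1], 0.1)       # above/left of the slice
  expect_equal(unclass(p)[20, 20], 0.8)     # inside
  # constant slice, interior crop: patch constant at the slice value
  pc <- extract_patch(matrix(0.42, 100, 100), c(50L, 50L), c(8L, 8L))
  expect_true(all(pc == 0.42))
})

test_that("downsample_2x mean pooling preserves the mean exactly", {
  expect_true(all(downsample_2x(matrix(3.5, 64, 64)) == 3.5))
  board <- matrix(c(0, 1), 64, 64)  # 2x2-period checkerboard rows
  board[, seq(2, 64, 2)] <- 1 - board[, seq(2, 64, 2)]
  expect_true(all(downsample_2x(board) == 0.5))
  set.seed(204)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_equal(mean(downsample_2x(x)), mean(x), tolerance = 1e-13)
  expect_equal(dim(downsample_2x(x)), c(32L, 32L))
  expect_error(downsample_2x(matrix(0, 63, 63)), "even")
})

test_that("normalization maps the window linearly onto [0,1] with clamping", {
  w <- c(-1000, 400)
  expect_equal(normalize_patch(matrix(-1000, 2, 2), w), matrix(0, 2, 2))
  expect_equal(normalize_patch(matrix(400, 2, 2), w), matrix(1, 2, 2))
  expect_equal(normalize_patch(matrix(-300, 2, 2), w), matrix(0.5, 2, 2))
  expect_equal(normalize_patch(matrix(-2000, 2, 2), w), matrix(0, 2, 2))
  expect_equal(normalize_patch(matrix(900, 2, 2), w), matrix(1, 2, 2))
  set.seed(205)
  raw <- matrix(rnorm(100, sd = 1000), 10, 10)
  nm <- normalize_patch(raw, w)
  expect_true(all(nm >= 0 & nm <= 1))
  expect_true(all(diff(nm[order(raw)]) >= 0))  # monotone
})

test_that("build_dataset emits one manifest row per resolvable annotation", {
  fix <- generate_annotation_fixture(n_cases = 3L, seed = 206L)
  ds <- build_dataset(fix)
  planted <- do.call(rbind, lapply(fix, `[[`, "planted"))
  expect_equal(nrow(ds$manifest), nrow(planted))  # 3+3+4 with the large extra
  expect_equal(sum(ds$manifest$label == 1L),
               sum(planted$kind == "nodule"))
  expect_equal(dim(ds$patches)[2:3], c(32L, 32L))
  expect_true(all(ds$patches >= 0 & ds$patches <= 1))
  # determinism: rebuilding writes byte-identical manifests
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(ds, d1)
  write_dataset(build_dataset(generate_annotation_fixture(3L, seed = 206L)), d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(readLines(file.path(d1, "patches.csv")),
                   readLines(file.path(d2, "patches.csv")))
})

test_that("missing slices are skipped with an accounting message", {
  fix <- generate_annotation_fixture(n_cases = 1L, seed = 207L)
  fix[[1]]$slices$S2 <- NULL
  expect_message(ds <- build_dataset(fix), "skipped 2")
  expect_equal(attr(ds, "skipped"), 2L)
  expect_equal(nrow(ds$manifest), 2L)  # the two S1 nodules survive
})

test_that("datasets round-trip through the on-disk text format", {
  spec <- generator_spec(n_nodules = 6L, n_nonnodules = 4L, exams = 3L,
                         seed = 208L)
  ds <- generate_dataset(spec)
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$exam_ids, ds$exam_ids)
  expect_equal(back$patches, ds$patches, tolerance = 1e-8)
})
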