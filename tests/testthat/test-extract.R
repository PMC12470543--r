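# Extraction pipeline: ROI screening, smoothing, Otsu, watershed
# separation, routing/binning, centring and ground-truth closure.

test_that("ROI screening applies the width, artifact and clump bounds", {
  sc <- generateScene(smearScene(widthPx = 2200L, heightPx = 400L,
                                 nCells = 12L, seed = 21L))
  expect_true(roiScreen(sc$image)$passed)
  # narrow crop of the same scene fails on width alone
  expect_false(roiScreen(sc$image[, 1:1000])$passed)
  expect_error(roiScreen(matrix(numeric(0), 0, 0)), "empty image")
})

test_that("a clumped scene fails the 15% clump bound", {
  img <- generateScene(smearScene(nCells = 30L, seed = 4L))$image
  clumped <- rbcmorph:::.drawEllipse(img, 300, 400, 90, 90, 0, 120)
  rep <- roiScreen(clumped, widthRange = c(100L, 8000L))
  expect_gt(rep$clumpFraction, 0.15)
  expect_false(rep$passed)
  # the same scene without the clump passes at the relaxed width
  expect_true(roiScreen(img, widthRange = c(100L, 8000L))$passed)
})

test_that("mean-shift smoothing preserves constants, steps, shape and dtype", {
  const <- matrix(120, 40, 40)
  expect_equal(meanShiftFilter(const, 5, 20), const)
  # two-level step larger than the range radius survives within +/- 1
  step <- cbind(matrix(50, 40, 20), matrix(200, 40, 20))
  sm <- meanShiftFilter(step, 5, 20)
  expect_equal(dim(sm), dim(step))
  expect_true(max(abs(sm - step)) <= 1)
  expect_error(meanShiftFilter(const, -1, 20), "positive")
})

test_that("Otsu threshold matches the brute-force between-class argmax", {
  bruteOtsu <- function(v) {
    h <- tabulate(as.integer(v) + 1L, 256L)
    best <- -Inf; bestT <- 0L
    for (t in 0:254) {
      w0 <- sum(h[1:(t + 1)]); w1 <- sum(h) - w0
      if (w0 == 0 || w1 == 0) next
      mu0 <- sum(h[1:(t + 1)] * (0:t)) / w0
      mu1 <- sum(h[(t + 2):256] * ((t + 1):255)) / w1
      s <- w0 * w1 * (mu0 - mu1)^2
      if (s > best) { best <- s; bestT <- t }
    }
    bestT
  }
  set.seed(31)
  for (i in 1:5) {
    v <- c(round(rnorm(400, 80, 12)), round(rnorm(600, 190, 18)))
    v <- pmin(255, pmax(0, v))
    g <- matrix(v, 40)
    expect_identical(attr(binarizeOtsu(g), "threshold"), bruteOtsu(v))
  }
})

test_that("Otsu separates bimodal input, flips under inversion, rejects constants", {
  g <- matrix(c(rep(50, 500), rep(200, 500)), 50)
  m <- binarizeOtsu(g, "dark")
  thr <- attr(m, "threshold")
  expect_gte(thr, 50); expect_lt(thr, 200)
  expect_equal(sum(m), 500)
  inv <- binarizeOtsu(255 - g, "dark")
  expect_equal(as.vector(inv), as.vector(!m))
  expect_error(binarizeOtsu(matrix(7, 10, 10)), "degenerate histogram")
})

test_that("watershed separation splits disk doublets and triplets, not singles", {
  two <- diskMask(100, 140, list(c(50, 45), c(50, 75)), c(20, 20))
  parts <- separateTouching(two)
  expect_length(parts, 2L)
  areas <- vapply(parts, sum, numeric(1))
  expect_true(all(abs(areas - pi * 400) / (pi * 400) < 0.15))

  three <- diskMask(100, 200, list(c(50, 45), c(50, 75), c(50, 105)),
                    c(20, 20, 20))
  expect_length(separateTouching(three), 3L)

  one <- diskMask(80, 80, list(c(40, 40)), 20)
  p1 <- separateTouching(one)
  expect_length(p1, 1L)
  expect_identical(p1[[1]], one)
  # elongated single cells stay whole too
  pencil <- ellipseMask(80, 120, c(40, 60), 40, 20, 15)
  expect_length(separateTouching(pencil), 1L)
  expect_error(separateTouching(matrix(FALSE, 5, 5)), "empty component")
})

test_that("routing and binning follow the border/size rules", {
  dims <- c(500L, 600L)
  r <- routeAndBin(c(100, 100, 120, 118), dims)
  expect_equal(r$category, "single"); expect_equal(r$sizeBin, 32L)
  r <- routeAndBin(c(0, 100, 30, 130), dims)
  expect_equal(r$category, "touching_edge"); expect_true(is.na(r$sizeBin))
  r <- routeAndBin(c(10, 10, 22, 24), dims)
  expect_equal(r$category, "small"); expect_equal(r$sizeBin, 32L)
  r <- routeAndBin(c(10, 10, 1110, 200), c(2000L, 2000L))
  expect_equal(r$category, "single"); expect_equal(r$sizeBin, "oversize")
  r <- routeAndBin(c(100, 100, 160, 150), dims, nParts = 2L)
  expect_equal(r$category, "extracted_cluster")
  expect_equal(r$sizeBin, 128L)
  r <- routeAndBin(c(100, 100, 160, 150), dims, nParts = 1L,
                   degenerate = TRUE)
  expect_equal(r$category, "overlapping")
})

test_that("centring is exact, idempotent and conserves pixels", {
  cell <- matrix(0, 20, 20)
  cell[6:15, 4:13] <- 140
  patch <- centerOnCanvas(cell, cell > 0, 32L)
  cen <- rbcmorph:::.centroid(patch > 0)
  expect_true(all(abs(cen - 16.5) <= 1))
  expect_equal(sum(patch), sum(cell))
  # idempotence
  again <- centerOnCanvas(patch, patch > 0, 32L)
  expect_identical(again, patch)
  expect_error(centerOnCanvas(cell, cell > 0, 8L), "larger than canvas")
})

test_that("extraction recovers isolated synthetic cells exactly", {
  sc <- generateScene(smearScene(nCells = 25L, seed = 2L))
  res <- extractCells(sc$image, config = list(meanShift = FALSE))
  expect_equal(unname(res$summary[["Single Cells"]]), 25L)
  expect_equal(sum(res$summary), 25L)
  # per-cell centroid error <= 2 px against ground truth
  err <- vapply(seq_len(nrow(sc$truth)), function(i) {
    min(sqrt((res$records$centroid_row - sc$truth$row[i])^2 +
               (res$records$centroid_col - sc$truth$col[i])^2))
  }, numeric(1))
  expect_lt(max(err), 2)
  # every single-cell patch mask is one connected component
  nComp <- vapply(res$patches, function(p) {
    max(rbcmorph:::.label(p > 0))
  }, numeric(1))
  expect_true(all(nComp == 1))
})

test_that("border cells and separable doublets shift category counts exactly", {
  sc <- generateScene(smearScene(nCells = 29L, seed = 6L,
                                 borderCells = 3L,
                                 overlapFraction = 4 / 29))
  res <- extractCells(sc$image, config = list(meanShift = FALSE))
  expect_equal(unname(res$summary[["Single Cells"]]), 25L)
  expect_equal(unname(res$summary[["Extracted Cells"]]), 4L)
  expect_equal(unname(res$summary[["Touching Edge"]]), 3L)
  expect_equal(unname(res$summary[["Overlapping"]]), 0L)
})

test_that("debris routes to the small category and totals stay conserved", {
  sc <- generateScene(smearScene(nCells = 10L, debrisCount = 4L,
                                 seed = 14L))
  res <- extractCells(sc$image, config = list(meanShift = FALSE,
                                              minAreaPx = 1L))
  expect_equal(unname(res$summary[["Single Cells"]]), 10L)
  expect_equal(unname(res$summary[["Small Cells"]]), 4L)
  expect_equal(sum(res$summary), nrow(res$records))
  expect_equal(length(res$patches), nrow(res$records))
})

test_that("extraction writes a deterministic directory tree with summary", {
  sc <- generateScene(smearScene(nCells = 6L, seed = 17L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  extractCells(sc$image, config = list(meanShift = FALSE), outDir = d1)
  extractCells(sc$image, config = list(meanShift = FALSE), outDir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  expect_true("summary.csv" %in% basename(f1))
  expect_true("qc_montage.png" %in% basename(f1))
  pngs <- file.path(d1, grep("single/", f1, value = TRUE))
  expect_true(all(tools::md5sum(pngs) ==
                    tools::md5sum(file.path(d2, grep("single/", f1,
                                                     value = TRUE)))))
  # constant image warns and yields an empty result
  expect_warning(res0 <- extractCells(matrix(200, 50, 50),
                                      config = list(meanShift = FALSE)),
                 "foreground")
  expect_equal(nrow(res0$records), 0L)
})
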