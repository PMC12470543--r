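# Ellipse morphometrics: direct least-squares fit, AR/size/ER metrics,
# the 72-way taxonomy and the batch classification pipeline.

test_that("direct least-squares fit recovers circles and ellipses", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  circ <- cbind(100 + 20 * sin(th), 120 + 20 * cos(th))
  f <- fitEllipse(circ)
  expect_lt(abs(majorAxisPx(f) - 40) / 40, 0.01)
  expect_lt(abs(minorAxisPx(f) - 40) / 40, 0.01)

  # parametric sampling oracle: rotated ellipses with known axes
  for (ang in c(0, 30, 115)) {
    a <- 40; b <- 20
    ca <- cos(ang * pi / 180); sa <- sin(ang * pi / 180)
    x <- a * cos(th); y <- b * sin(th)
    pts <- cbind(200 + x * sa + y * ca, 300 + x * ca - y * sa)
    f <- fitEllipse(pts)
    expect_lt(abs(majorAxisPx(f) - 80) / 80, 0.03)
    expect_lt(abs(minorAxisPx(f) - 40) / 40, 0.03)
  }
})

test_that("contours shorter than 5 points are skipped, not fitted", {
  expect_message(res <- fitEllipse(cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))),
                 "fewer than 5")
  expect_null(res)
})

test_that("morphometrics match analytic values on rendered shapes", {
  # disk radius 25 px at the default pixel scale
  m <- renderedEllipse(120, 120, c(60.5, 60.5), 25, 25)
  cont <- rbcmorph:::.contours(binarizeOtsu(m, "bright"))[[1]]
  f <- fitEllipse(cont$points, pixelCorrection = 1)
  met <- computeMorphoMetrics(f, cont$mask, 0.1658)
  expect_lt(abs(aspectRatio(met) - 1), 0.03)
  expect_gt(areaRatio(met), 0.97)
  expect_lt(abs(majorAxisUm(met) - 8.29), 0.25)

  # full axes 80 x 40: AR = 2, ER = b/a = 0.5
  m2 <- renderedEllipse(140, 140, c(70.5, 70.5), 40, 20, 25)
  cont2 <- rbcmorph:::.contours(binarizeOtsu(m2, "bright"))[[1]]
  f2 <- fitEllipse(cont2$points, pixelCorrection = 1)
  met2 <- computeMorphoMetrics(f2, cont2$mask)
  expect_lt(abs(aspectRatio(met2) - 2), 0.06)
  expect_lt(abs(areaRatio(met2) - 0.5), 0.03)
  expect_gt(met2@intersectionAreaPx / met2@cellAreaPx, 0.95)
  expect_error(computeMorphoMetrics(f2, matrix(FALSE, 10, 10)),
               "empty mask")
})

test_that("rendered ellipses recover axes within 3% and ER within 0.03", {
  worstAxis <- 0; worstEr <- 0
  for (s in 1:12) {
    set.seed(100 + s)
    a <- runif(1, 12, 45); b <- runif(1, 10, a); ang <- runif(1, 0, 180)
    m <- renderedEllipse(140, 140, c(70.5, 70.5), a, b, ang)
    cont <- rbcmorph:::.contours(binarizeOtsu(m, "bright"))[[1]]
    f <- fitEllipse(cont$points, pixelCorrection = 1)
    met <- computeMorphoMetrics(f, cont$mask)
    worstAxis <- max(worstAxis, abs(majorAxisPx(f) - 2 * a) / (2 * a),
                     abs(minorAxisPx(f) - 2 * b) / (2 * b))
    worstEr <- max(worstEr, abs(areaRatio(met) - b / a))
  }
  expect_lt(worstAxis, 0.03)
  expect_lt(worstEr, 0.03)
})

test_that("pixel ER agrees with the shoelace polygon area within 2%", {
  # Pick's relation for a lattice polygon through boundary pixel centres:
  # lattice points inside or on the polygon = shoelace + B/2 + 1, which is
  # what pixel counting measures
  for (s in 1:5) {
    set.seed(200 + s)
    a <- runif(1, 15, 40); b <- runif(1, 12, a)
    m <- renderedEllipse(120, 120, c(60.5, 60.5), a, b, runif(1, 0, 180))
    cont <- rbcmorph:::.contours(binarizeOtsu(m, "bright"))[[1]]
    pts <- unique(cont$points)
    px <- pts[, 2]; py <- pts[, 1]
    shoelace <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
    polygonArea <- shoelace + nrow(pts) / 2 + 1
    pixelArea <- sum(cont$mask)
    expect_lt(abs(pixelArea - polygonArea) / pixelArea, 0.02)
  }
})

test_that("classifyCell reproduces the printed decision rules", {
  expect_equal(classifyCell(1.00, 7.0, 1.00), "Normal/Circle 095/Area 100/")
  expect_equal(classifyCell(1.50, 5.0, 0.85), "Micro/Oval 040/Area 090/")
  expect_equal(classifyCell(2.00, 9.0, 0.75), "Macro/Pencil/Area 080/")
  # all three descriptors exactly at their inclusive boundaries
  expect_equal(classifyCell(1.05, 8.0, 0.80), "Normal/Circle 095/Area 080/")
  expect_error(classifyCell(NaN, 7, 0.9), "finite")
  expect_error(classifyCell(0.9, 7, 0.9), "AR")
})

test_that("the 72-way partition is total and boundary-exact on a grid", {
  # independent transcription of the decision table
  refClassify <- function(ar, l, er) {
    er <- min(er, 1)
    r <- if (ar <= 1.05) "Circle 095/" else if (ar <= 1.10) "Circle 090/"
    else if (ar <= 1.20) "Circle 080/" else if (ar <= 1.40) "Oval 060/"
    else if (ar <= 1.60) "Oval 040/" else "Pencil/"
    g <- if (l < 6.0) "Micro/" else if (l <= 8.0) "Normal/" else "Macro/"
    a <- if (er <= 0.80) "Area 080/" else if (er <= 0.90) "Area 090/"
    else if (er <= 0.95) "Area 095/" else "Area 100/"
    paste0(g, r, a)
  }
  eps <- c(-1e-9, 0, 1e-9)
  ars <- sort(c(1, outer(c(1.05, 1.10, 1.20, 1.40, 1.60), eps, "+"), 1.8))
  lens <- sort(c(outer(c(6.0, 8.0), eps, "+"), 4, 10))
  ers <- sort(c(outer(c(0.80, 0.90, 0.95), eps, "+"), 0.5, 1.0))
  grid <- expand.grid(ar = ars, l = lens, er = ers)
  got <- classifyCell(grid$ar, grid$l, grid$er)
  want <- mapply(refClassify, grid$ar, grid$l, grid$er)
  expect_identical(got, unname(want))
  # totality: the observed paths are a subset of the declared 72
  expect_true(all(got %in% classPaths()))
  expect_equal(length(classPaths()), 72L)
  expect_false(anyDuplicated(classPaths()) > 0)
})

test_that("classification is scale-equivariant in the documented sense", {
  set.seed(5)
  for (i in 1:20) {
    ar <- runif(1, 1, 2); l <- runif(1, 4, 10); er <- runif(1, 0.4, 1)
    p1 <- classifyCell(ar, l, er, parts = TRUE)
    # multiplying both axes by c leaves AR (hence shape group) unchanged
    p2 <- classifyCell(ar, l * 1.7, er, parts = TRUE)
    expect_identical(p1$shape_group, p2$shape_group)
    # growing the pixel size can only move the size group upward
    sizes <- c("Micro/", "Normal/", "Macro/")
    expect_gte(match(p2$size_group, sizes), match(p1$size_group, sizes))
  }
})

test_that("ER quality screen keeps only ER strictly above the bound", {
  expect_true(screenQuality(0.9))
  expect_false(screenQuality(0.50))    # boundary value is dropped
  expect_false(screenQuality(0.2))
  m <- renderedEllipse(120, 120, c(60.5, 60.5), 25, 25)
  cont <- rbcmorph:::.contours(binarizeOtsu(m, "bright"))[[1]]
  f <- fitEllipse(cont$points, pixelCorrection = 1)
  expect_true(screenQuality(computeMorphoMetrics(f, cont$mask)))
})

test_that("batch pipeline routes synthetic patches to their truth classes", {
  classes <- c("Normal/Circle 095/Area 100/", "Micro/Oval 040/Area 080/",
               "Macro/Circle 090/Area 095/", "Normal/Pencil/Area 080/")
  fx <- writeFixtureSet(classes, 100L)
  out <- withr::local_tempdir()
  met <- runEllipsePipeline(fx$dir, outDir = out)
  expect_equal(nrow(met), 100L)
  expect_gte(sum(met$class_path == fx$truth[met$file]), 97L)
  # kept files are routed into their class paths on disk
  routed <- list.files(out, pattern = "^p.*\\.png$", recursive = TRUE)
  expect_equal(length(routed), sum(met$kept))
  expect_true(file.exists(file.path(out, "ellipse_metrics.csv")))
})

test_that("pipeline handles multi-blob patches, empty and missing dirs", {
  d <- withr::local_tempdir()
  two <- matrix(0, 128, 128)
  two <- rbcmorph:::.drawEllipse(two, 40, 40, 18, 16, 10, 160)
  two <- rbcmorph:::.drawEllipse(two, 90, 90, 18, 15, 40, 160)
  writeImage8(two, file.path(d, "two.png"))
  met <- runEllipsePipeline(d)
  expect_equal(nrow(met), 2L)          # one CSV row per contour

  empty <- withr::local_tempdir()
  expect_equal(nrow(runEllipsePipeline(empty)), 0L)
  expect_warning(runEllipsePipeline(file.path(empty, "nope")),
                 "folder not found")
})
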