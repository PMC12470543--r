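# Synthetic smear generator: seeded, ground-truthed scenes and single-cell
# patch fixtures that emulate the statistical structure the extraction and
# morphometric stages assume (elliptical cells 6-8 um with central pallor,
# micro/macro outliers, touching doublets, border-truncated cells, debris).

# render one anti-aliased ellipse (optionally chord-cut at v <= cutV on the
# minor axis) onto `img`, blending by 2x2 supersampled coverage.
# (rowc, colc) centre, a/b semi-axes in px, angle in degrees.
.drawEllipse <- function(img, rowc, colc, a, b, angleDeg, cellLevel,
                         pallorDepth = 0, pallorLevel = 190, cutV = Inf) {
  th <- angleDeg * pi / 180
  pad <- ceiling(max(a, b)) + 2L
  r0 <- max(1L, floor(rowc - pad)); r1 <- min(nrow(img), ceiling(rowc + pad))
  c0 <- max(1L, floor(colc - pad)); c1 <- min(ncol(img), ceiling(colc + pad))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)

  cov <- 0
  for (dr in c(-0.25, 0.25)) {
    for (dc in c(-0.25, 0.25)) {
      dx <- cc + dc - colc
      dy <- rr + dr - rowc
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      cov <- cov + ((u / a)^2 + (v / b)^2 <= 1 & v <= cutV) / 4
    }
  }
  # central pallor: intensity climbs back toward pallorLevel inside the
  # normalised radius 0.6 core, mimicking the biconcave dimple
  dx <- cc - colc; dy <- rr - rowc
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  w <- pmax(0, (0.6 - rho) / 0.6)^2
  cellI <- cellLevel + pallorDepth * (pallorLevel - cellLevel) * w
  sub <- img[r0:r1, c0:c1]
  img[r0:r1, c0:c1] <- sub * (1 - cov) + cellI * cov
  img
}

# sample one cell geometry from scene parameters (RNG already seeded)
.sampleCellGeom <- function(scene) {
  diam <- if (scene@outlierFraction > 0 &&
              runif(1) < scene@outlierFraction) {
    if (runif(1) < 0.5) runif(1, 4.0, 5.5) else runif(1, 8.5, 11.0)
  } else {
    runif(1, scene@diamRangeUm[1], scene@diamRangeUm[2])
  }
  ar <- runif(1, scene@arRange[1], scene@arRange[2])
  a <- diam / scene@pixelSizeUm / 2          # semi-major, px
  list(a = a, b = a / ar, ar = ar,
       angle = runif(1, 0, 180),
       pallor = runif(1, scene@pallorRange[1], scene@pallorRange[2]))
}

#' Render a synthetic smear scene with per-cell ground truth
#'
#' Places `nCells` elliptical cells (darker than background, optional
#' central pallor) by rejection sampling so that interior cells never
#' touch, then adds the requested touching doublets, border-truncated
#' cells and debris blobs, and finally overlays Gaussian noise. All
#' randomness is driven by the scene's single seed, so identical requests
#' yield bit-identical images and truth tables.
#'
#' @param scene a [SmearScene-class] request.
#' @return list with `image` (numeric matrix, 0..255) and `truth`, a
#'   data.frame with one row per rendered cell:
#'   `id, row, col, axis_major_px, axis_minor_px, angle_deg, pallor,
#'   truth_class` (1-based pixel-centre coordinates; `truth_class` is the
#'   [classifyCell()] path of the cell's analytic descriptors, with
#'   analytic ER = Lminor / Lmajor). Border-truncated doublet partners and
#'   debris are rendered but only cells appear in `truth`.
#' @examples
#' sc <- generateScene(smearScene(nCells = 5L, seed = 7L))
#' dim(sc$image); nrow(sc$truth)
#' @export
generateScene <- function(scene) {
  stopifnot(is(scene, "SmearScene"))
  validObject(scene)
  .withSeed(scene@seed, {
    img <- matrix(scene@backgroundLevel, scene@heightPx, scene@widthPx)
    placed <- matrix(numeric(0), 0, 3)  # row, col, clearance radius

    canPlace <- function(r, c, rad, except = 0L) {
      if (nrow(placed) == 0L) return(TRUE)
      d2 <- (placed[, 1] - r)^2 + (placed[, 2] - c)^2
      clear <- d2 > (placed[, 3] + rad + 2)^2
      if (except > 0L) clear[except] <- TRUE
      all(clear)
    }
    nPairs <- floor(scene@overlapFraction * scene@nCells / 2)
    nSingles <- scene@nCells - 2L * nPairs
    cells <- list()
    addCell <- function(geom, r, c) {
      cells[[length(cells) + 1L]] <<- c(
        row = r, col = c, a = geom$a, b = geom$b, ar = geom$ar,
        angle = geom$angle, pallor = geom$pallor)
      placed <<- rbind(placed, c(r, c, geom$a))
    }
    placeInterior <- function(geom, near = NULL) {
      margin <- geom$a + 2
      for (att in seq_len(200L)) {
        if (is.null(near)) {
          r <- runif(1, 1 + margin, scene@heightPx - margin)
          c <- runif(1, 1 + margin, scene@widthPx - margin)
          if (canPlace(r, c, geom$a)) return(c(r, c))
        } else {
          d <- runif(1, 0.6, 0.9) * (near$b + geom$b)
          phi <- runif(1, 0, 2 * pi)
          r <- near$row + d * sin(phi)
          c <- near$col + d * cos(phi)
          inb <- r > margin & r < scene@heightPx - margin &
            c > margin & c < scene@widthPx - margin
          # overlap only the intended partner, keep clear of everyone else
          if (inb && canPlace(r, c, geom$a, except = near$index)) {
            return(c(r, c))
          }
        }
      }
      stop("scene too dense: cell placement failed after bounded attempts")
    }

    for (i in seq_len(nSingles)) {
      g <- .sampleCellGeom(scene)
      rc <- placeInterior(g)
      addCell(g, rc[1], rc[2])
    }
    for (i in seq_len(nPairs)) {
      g1 <- .sampleCellGeom(scene)
      rc1 <- placeInterior(g1)
      addCell(g1, rc1[1], rc1[2])
      g2 <- .sampleCellGeom(scene)
      rc2 <- placeInterior(
        g2, near = list(row = rc1[1], col = rc1[2], b = g1$b,
                        index = nrow(placed)))
      addCell(g2, rc2[1], rc2[2])
    }
    # border-truncated cells: centre within half a semi-minor axis of an
    # edge so the mask bounding box always crosses the frame
    for (i in seq_len(scene@borderCells)) {
      g <- .sampleCellGeom(scene)
      side <- sample(4L, 1L)
      off <- runif(1, -0.3, 0.3) * g$b
      if (side == 1L) { r <- 1 + off; c <- runif(1, g$a + 2, scene@widthPx - g$a - 2) }
      if (side == 2L) { r <- scene@heightPx - off; c <- runif(1, g$a + 2, scene@widthPx - g$a - 2) }
      if (side == 3L) { c <- 1 + off; r <- runif(1, g$a + 2, scene@heightPx - g$a - 2) }
      if (side == 4L) { c <- scene@widthPx - off; r <- runif(1, g$a + 2, scene@heightPx - g$a - 2) }
      for (att in seq_len(50L)) {
        if (canPlace(r, c, g$a)) break
        if (side <= 2L) c <- runif(1, g$a + 2, scene@widthPx - g$a - 2)
        else r <- runif(1, g$a + 2, scene@heightPx - g$a - 2)
        if (att == 50L) stop("scene too dense: border cell placement failed")
      }
      addCell(g, r, c)
    }

    for (cl in cells) {
      img <- .drawEllipse(img, cl["row"], cl["col"], cl["a"], cl["b"],
                          cl["angle"], scene@cellLevel, cl["pallor"],
                          scene@pallorLevel)
    }
    # debris: small dark non-cellular blobs, 2-8 px across
    for (i in seq_len(scene@debrisCount)) {
      rad <- runif(1, 1, 4)
      for (att in seq_len(200L)) {
        r <- runif(1, rad + 2, scene@heightPx - rad - 2)
        c <- runif(1, rad + 2, scene@widthPx - rad - 2)
        if (canPlace(r, c, rad)) break
        if (att == 200L) stop("scene too dense: debris placement failed")
      }
      placed <- rbind(placed, c(r, c, rad))
      img <- .drawEllipse(img, r, c, rad, rad, 0, 100)
    }

    if (scene@noiseSigma > 0) {
      img <- img + matrix(rnorm(length(img), 0, scene@noiseSigma),
                          nrow(img))
    }
    img <- .clamp8(img)

    truth <- if (length(cells)) {
      m <- do.call(rbind, cells)
      arv <- m[, "ar"]
      data.frame(
        id = seq_len(nrow(m)),
        row = m[, "row"], col = m[, "col"],
        axis_major_px = 2 * m[, "a"], axis_minor_px = 2 * m[, "b"],
        angle_deg = m[, "angle"], pallor = m[, "pallor"],
        truth_class = classifyCell(arv, 2 * m[, "a"] * scene@pixelSizeUm,
                                   pmin(1, 1 / arv)),
        stringsAsFactors = FALSE)
    } else {
      data.frame(id = integer(), row = numeric(), col = numeric(),
                 axis_major_px = numeric(), axis_minor_px = numeric(),
                 angle_deg = numeric(), pallor = numeric(),
                 truth_class = character(), stringsAsFactors = FALSE)
    }
    list(image = img, truth = truth)
  })
}

#' Write / read a scene ground-truth table
#'
#' CSV with header
#' `id,row,col,axis_major_px,axis_minor_px,angle_deg,pallor,truth_class`.
#'
#' @param truth data.frame as returned by [generateScene()].
#' @param path CSV file path.
#' @return `path` (write) or the truth data.frame (read).
#' @export
writeTruthCsv <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthCsv
#' @export
readTruthCsv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# named morphology tags -> representative class paths
.fixtureTags <- c(
  normocyte = "Normal/Circle 095/Area 100/",
  microcyte = "Micro/Circle 095/Area 100/",
  macrocyte = "Macro/Circle 095/Area 100/",
  spherocyte = "Micro/Circle 095/Area 100/",
  elliptocyte = "Normal/Oval 060/Area 080/",
  drepanocyte = "Normal/Pencil/Area 080/",
  pencil = "Normal/Pencil/Area 080/")

# representative values inside each group's bin
.shapeMid <- c("Circle 095/" = 1.02, "Circle 090/" = 1.075,
               "Circle 080/" = 1.15, "Oval 060/" = 1.30,
               "Oval 040/" = 1.50, "Pencil/" = 1.80)
.sizeMid <- c("Micro/" = 5.0, "Normal/" = 7.0, "Macro/" = 9.5)
.areaBin <- list("Area 080/" = c(0, 0.80), "Area 090/" = c(0.80, 0.90),
                 "Area 095/" = c(0.90, 0.95), "Area 100/" = c(0.95, 1))

#' Build a single-cell patch fixture for a morphometric class
#'
#' Renders one centred cell on a black canvas, as the extraction stage
#' would emit it. Geometry (aspect ratio, micrometre size) is drawn near
#' the middle of the requested class bins with a small seeded jitter. When
#' the requested area group demands an ER below the analytic value of a
#' full ellipse (Lminor/Lmajor), a chord cut parallel to the major axis
#' removes the required area, emulating an incomplete contour. Special
#' tag `"fragment"` renders a half-disk (ER far below the quality screen).
#'
#' @param truthClass a [classifyCell()] class path (one of [classPaths()])
#'   or a named morphology tag
#'   (`r paste(names(rbcmorph:::.fixtureTags), collapse = ", ")`, `fragment`).
#' @param canvasPx canvas side in pixels (default 128).
#' @param seed integer seed (jitter determinism).
#' @param pixelSizeUm micrometres per pixel.
#' @param pallorDepth central pallor depth in [0, 1] (default 0: solid
#'   cells keep the binarised mask simply connected).
#' @return list with `patch` (canvasPx x canvasPx matrix, 0..255) and
#'   `spec`, a one-row truth data.frame in the [generateScene()] layout.
#' @export
makePatchFixture <- function(truthClass, canvasPx = 128L, seed = 1L,
                             pixelSizeUm = 0.1658, pallorDepth = 0) {
  canvasPx <- as.integer(canvasPx)
  fragment <- identical(truthClass, "fragment")
  if (!fragment && truthClass %in% names(.fixtureTags)) {
    truthClass <- .fixtureTags[[truthClass]]
  }
  if (!fragment && !truthClass %in% classPaths()) {
    stop("unknown class token '", truthClass, "'; valid tokens are the 72 ",
         "classPaths() entries or tags: ",
         paste(c(names(.fixtureTags), "fragment"), collapse = ", "))
  }
  .withSeed(seed, {
    if (fragment) {
      diam <- runif(1, 6, 8)
      a <- diam / pixelSizeUm / 2
      b <- a
      ar <- 1
      cutV <- 0       # half disk
      angle <- runif(1, 0, 180)
      cls <- NA_character_
    } else {
      sizeG <- sub("^((Micro|Normal|Macro)/).*", "\\1", truthClass)
      shapeG <- sub("^.*?/((Circle|Oval|Pencil)[^/]*/).*", "\\1", truthClass)
      areaG <- sub("^.*(Area [0-9]+/)$", "\\1", truthClass)
      ar <- .shapeMid[[shapeG]] * runif(1, 0.99, 1.01)
      ar <- max(1, ar)
      diam <- .sizeMid[[sizeG]] * runif(1, 0.98, 1.02)
      a <- diam / pixelSizeUm / 2
      b <- a / ar
      angle <- runif(1, 0, 180)
      erFull <- b / a
      bin <- .areaBin[[areaG]]
      cutV <- Inf
      if (erFull <= bin[1]) {
        stop("infeasible class '", truthClass, "': a full ellipse of this ",
             "shape has ER ", round(erFull, 3), ", below the requested ",
             "area group")
      }
      if (erFull > bin[2]) {
        # chord cut at v <= cutV so the remaining area hits the bin middle
        targetEr <- mean(c(max(bin[1], 0.6 * bin[2]), bin[2]))
        target <- targetEr * pi * a^2
        f <- function(t) {
          a * b * (pi / 2 + asin(t) + t * sqrt(1 - t^2)) - target
        }
        lo <- -0.999; hi <- 0.999
        for (it in 1:60) {
          mid <- (lo + hi) / 2
          if (f(mid) < 0) lo <- mid else hi <- mid
        }
        cutV <- ((lo + hi) / 2) * b
      }
      cls <- truthClass
    }
    if (2 * a + 4 > canvasPx) {
      stop("cell of ", round(2 * a), " px does not fit the ", canvasPx,
           " px canvas")
    }
    ctr <- (canvasPx + 1) / 2
    patch <- matrix(0, canvasPx, canvasPx)
    patch <- .drawEllipse(patch, ctr, ctr, a, b, angle, 160,
                          pallorDepth, 210, cutV = cutV)
    patch <- .clamp8(patch)
    spec <- data.frame(
      id = 1L, row = ctr, col = ctr, axis_major_px = 2 * a,
      axis_minor_px = 2 * b, angle_deg = angle, pallor = pallorDepth,
      truth_class = cls, stringsAsFactors = FALSE)
    list(patch = patch, spec = spec)
  })
}
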