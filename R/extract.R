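# Single-cell patch extraction: ROI screening, mean-shift smoothing, Otsu
# binarisation, watershed separation of touching cells, category routing,
# size binning and centred patch export.

.categories <- c("single", "extracted_cluster", "overlapping", "small",
                 "touching_edge", "other")
.categoryColumns <- c(single = "Single Cells",
                      extracted_cluster = "Extracted Cells",
                      overlapping = "Overlapping",
                      small = "Small Cells",
                      touching_edge = "Touching Edge",
                      other = "Other")

#' Screen a region of interest for extraction suitability
#'
#' A candidate ROI passes when (i) its width lies between 2000 and 8000
#' pixels, (ii) implausible foreground (artifact/debris: components smaller
#' than 25 px^2 or with solidity below 0.5) makes up at most 10% of the
#' foreground, and (iii) clumped foreground (components larger than 3x the
#' median plausible single-cell area) makes up at most 15%.
#'
#' @param image numeric matrix or RGB array, 0..255.
#' @param widthRange inclusive accepted width bounds in pixels.
#' @param artifactMax maximum artifact foreground fraction.
#' @param clumpMax maximum clumped foreground fraction.
#' @return list of class `RoiScreenReport` with `widthPx, heightPx,
#'   artifactFraction, clumpFraction, passed`.
#' @export
roiScreen <- function(image, widthRange = c(2000L, 8000L),
                      artifactMax = 0.10, clumpMax = 0.15) {
  gray <- toGray(image)
  if (length(gray) == 0L) stop("empty image")
  widthPx <- ncol(gray)
  heightPx <- nrow(gray)

  artifactFraction <- 0
  clumpFraction <- 0
  if (length(unique(as.vector(round(gray)))) >= 2L) {
    mask <- binarizeOtsu(gray, foreground = "dark")
    lab <- .label(mask)
    n <- max(lab)
    if (n > 0) {
      areas <- tabulate(lab[lab > 0], nbins = n)
      solidity <- vapply(seq_len(n), function(i) {
        w <- which(lab == i, arr.ind = TRUE)
        if (nrow(w) < 3L) return(0)
        h <- chull(w[, 2], w[, 1])
        hx <- w[h, 2]; hy <- w[h, 1]
        hullArea <- abs(sum(hx * c(hy[-1], hy[1]) -
                              c(hx[-1], hx[1]) * hy)) / 2
        if (hullArea <= 0) 1 else min(1, nrow(w) / hullArea)
      }, numeric(1))
      plausible <- areas >= 25 & solidity >= 0.5
      total <- sum(areas)
      artifactFraction <- sum(areas[!plausible]) / total
      if (any(plausible)) {
        medArea <- median(areas[plausible])
        clumpFraction <- sum(areas[plausible & areas > 3 * medArea]) / total
      }
    }
  }
  passed <- widthPx >= widthRange[1] && widthPx <= widthRange[2] &&
    artifactFraction <= artifactMax && clumpFraction <= clumpMax
  structure(list(widthPx = widthPx, heightPx = heightPx,
                 artifactFraction = artifactFraction,
                 clumpFraction = clumpFraction, passed = passed),
            class = "RoiScreenReport")
}

#' @export
print.RoiScreenReport <- function(x, ...) {
  cat(sprintf(
    "RoiScreenReport: %d x %d px | artifact %.3f | clump %.3f | %s\n",
    x$widthPx, x$heightPx, x$artifactFraction, x$clumpFraction,
    if (x$passed) "PASSED" else "REJECTED"))
  invisible(x)
}

#' Edge-preserving mean-shift smoothing
#'
#' Iterative intensity mode-seeking within a spatial window: each pixel
#' converges to the mean of nearby pixels whose intensity lies within
#' `rangeRadius`, flattening staining texture while leaving steps larger
#' than `rangeRadius` intact. RGB arrays are filtered per channel.
#'
#' @param image numeric matrix or RGB array, 0..255.
#' @param spatialRadius window radius in pixels (> 0).
#' @param rangeRadius intensity radius (> 0).
#' @param maxIter mode-seeking iterations per pixel.
#' @return smoothed image, same shape and scale as the input.
#' @export
meanShiftFilter <- function(image, spatialRadius = 10L, rangeRadius = 20,
                            maxIter = 5L) {
  if (spatialRadius <= 0 || rangeRadius <= 0) {
    stop("spatialRadius and rangeRadius must be positive")
  }
  if (is.matrix(image)) {
    return(.meanShiftCpp(image, as.integer(spatialRadius), rangeRadius,
                         as.integer(maxIter)))
  }
  if (is.array(image) && length(dim(image)) == 3L) {
    out <- image
    for (ch in seq_len(dim(image)[3])) {
      out[, , ch] <- .meanShiftCpp(image[, , ch], as.integer(spatialRadius),
                                   rangeRadius, as.integer(maxIter))
    }
    return(out)
  }
  stop("'image' must be a matrix or rows x cols x channels array")
}

#' Otsu binarisation
#'
#' Chooses the 8-bit threshold maximising the between-class variance of the
#' intensity histogram and returns the mask of the requested side:
#' `"dark"` foreground for smear scenes (stained cells darker than
#' background) or `"bright"` for extracted patches (cell on black canvas).
#'
#' @param gray numeric matrix, 0..255, with at least two distinct values.
#' @param foreground `"dark"` or `"bright"`.
#' @return logical mask with attribute `"threshold"` (the cut value `t`:
#'   dark foreground is `gray <= t`, bright is `gray > t`).
#' @export
binarizeOtsu <- function(gray, foreground = c("dark", "bright")) {
  foreground <- match.arg(foreground)
  v <- as.integer(round(pmin(255, pmax(0, gray))))
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0) < 2L) stop("degenerate histogram: image is constant")
  p <- h / sum(h)
  omega <- cumsum(p)                 # class 0 mass for cuts t = 0..255
  mu <- cumsum(p * (0:255))
  muT <- mu[256]
  t <- 0:254
  w0 <- omega[t + 1L]
  valid <- w0 > 0 & w0 < 1
  sigmaB <- rep(-Inf, 255)
  sigmaB[valid] <- (muT * w0[valid] - mu[t + 1L][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  thr <- t[which.max(sigmaB)]
  mask <- if (foreground == "dark") {
    matrix(v <= thr, nrow(gray))
  } else {
    matrix(v > thr, nrow(gray))
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Separate a touching-cell component by distance-transform watershed
#'
#' Computes the Euclidean distance transform of the component and floods
#' it with a hierarchical watershed: local maxima whose prominence above
#' the connecting saddle is below `tolerance` are merged, so single cells
#' (including elongated ones, whose distance ridge is flat) stay whole
#' while touching doublets and chains split at their necks. When a
#' multi-region split produces a degenerate region (below `minRegionPx`),
#' the component is deemed unsplittable: the original mask is returned
#' with attribute `"degenerate" = TRUE` so the router can file it as
#' overlapping.
#'
#' @param mask logical matrix holding exactly one connected foreground
#'   component.
#' @param tolerance minimum peak prominence (in distance units, px) for a
#'   region to remain separate.
#' @param ext neighbourhood radius for maxima detection.
#' @param minRegionPx smallest acceptable sub-region area in px^2.
#' @return list of logical sub-masks (same dimensions as `mask`), with
#'   attributes `"nMarkers"` and `"degenerate"`.
#' @export
separateTouching <- function(mask, tolerance = 0.5, ext = 1L,
                             minRegionPx = 25L) {
  mask <- mask > 0
  if (!any(mask)) stop("empty component")
  done <- function(parts, nMarkers, degenerate) {
    attr(parts, "nMarkers") <- nMarkers
    attr(parts, "degenerate") <- degenerate
    parts
  }
  # work on the padded bounding box for speed, paste parts back after
  bb <- .bbox(mask)
  r0 <- max(1L, bb[1] - 1L); r1 <- min(nrow(mask), bb[3] + 2L)
  c0 <- max(1L, bb[2] - 1L); c1 <- min(ncol(mask), bb[4] + 2L)
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  dist <- EBImage::distmap(.toEBI(sub * 255))
  ws <- .fromEBI(EBImage::watershed(dist, tolerance = tolerance,
                                    ext = as.integer(ext)), scale = 1)
  nReg <- max(ws)
  if (nReg <= 1L) return(done(list(mask), max(1L, nReg), FALSE))
  parts <- lapply(seq_len(nReg), function(i) {
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    m[r0:r1, c0:c1] <- ws == i
    m
  })
  if (any(vapply(parts, sum, numeric(1)) < minRegionPx)) {
    return(done(list(mask), nReg, TRUE))
  }
  done(parts, nReg, FALSE)
}

#' Route a component into a category and size bin
#'
#' Categories follow the extraction procedure: components whose bounding
#' box touches any image border are `touching_edge`; parts of a
#' successfully separated multi-cell component are `extracted_cluster`;
#' multi-peak components that resisted separation are `overlapping`;
#' remaining components are `small` (max bounding-box side <= 16 px) or
#' `single`. The size bin is the patch canvas side: <= 16 -> 32 ("small"),
#' then the smallest of 32/128/256/512/1024 that holds the bounding box,
#' else `"oversize"` (kept at native size).
#'
#' @param bbox 0-based half-open `(row0, col0, row1, col1)` bounding box.
#' @param imgDim image dimensions `c(rows, cols)`.
#' @param nParts number of sub-masks the component was separated into.
#' @param degenerate TRUE when multi-peak separation failed.
#' @return list with `category` (one of single, extracted_cluster,
#'   overlapping, small, touching_edge, other) and `sizeBin` (canvas side,
#'   or `NA` for touching_edge, or `"oversize"`).
#' @export
routeAndBin <- function(bbox, imgDim, nParts = 1L, degenerate = FALSE) {
  touches <- bbox[1] == 0 || bbox[2] == 0 ||
    bbox[3] == imgDim[1] || bbox[4] == imgDim[2]
  side <- max(bbox[3] - bbox[1], bbox[4] - bbox[2])
  bins <- c(32L, 128L, 256L, 512L, 1024L)
  sizeBin <- if (side <= 16) {
    32L
  } else {
    hit <- bins[bins >= side]
    if (length(hit)) hit[1] else "oversize"
  }
  category <- if (touches) {
    "touching_edge"
  } else if (degenerate) {
    "overlapping"
  } else if (nParts >= 2L) {
    "extracted_cluster"
  } else if (side <= 16) {
    "small"
  } else {
    "single"
  }
  list(category = category,
       sizeBin = if (category == "touching_edge") NA else sizeBin)
}

#' Centre masked cell pixels on a black canvas
#'
#' Copies `pixels[mask]` onto a `canvasSide` square of zeros, shifting by
#' whole pixels so the mask centroid lands within 1 px of the canvas
#' centre. Integer shifting preserves pixel values exactly, making the
#' operation idempotent and conserving the foreground pixel sum.
#'
#' @param pixels numeric matrix of image intensities.
#' @param mask logical matrix congruent with `pixels`.
#' @param canvasSide output canvas side in pixels.
#' @return `canvasSide` x `canvasSide` numeric matrix.
#' @export
centerOnCanvas <- function(pixels, mask, canvasSide) {
  mask <- mask > 0
  bb <- .bbox(mask)
  h <- bb[3] - bb[1]
  w <- bb[4] - bb[2]
  if (h > canvasSide || w > canvasSide) {
    stop("cell (", h, " x ", w, " px) larger than canvas ", canvasSide)
  }
  ctr <- (canvasSide + 1) / 2
  cen <- .centroid(mask)
  # clamp the integer shift so tight-fitting cells stay on canvas
  dr <- min(max(round(ctr - cen["row"]), 1 - (bb[1] + 1)),
            canvasSide - bb[3])
  dc <- min(max(round(ctr - cen["col"]), 1 - (bb[2] + 1)),
            canvasSide - bb[4])
  w2 <- which(mask, arr.ind = TRUE)
  rr <- w2[, 1] + dr
  cc <- w2[, 2] + dc
  out <- matrix(0, canvasSide, canvasSide)
  out[cbind(rr, cc)] <- pixels[w2]
  out
}

#' Extract single-cell patches from a smear image
#'
#' The full extraction pipeline: mean-shift smoothing, grayscale
#' conversion, Otsu binarisation (dark foreground), connected components,
#' per-component watershed separation, category routing, size binning and
#' centring on black canvases. Optionally writes the
#' `<outDir>/<category>/<sizeBin>/` directory tree, a `summary.csv` in the
#' per-sample category-count layout, and a QC montage of the intermediate
#' stages.
#'
#' @param image numeric matrix or RGB array (0..255), or a PNG path.
#' @param config list of options: `spatialRadius`, `rangeRadius`,
#'   `meanShift` (logical, default TRUE), `minSepFactor`, `minRegionPx`,
#'   `minAreaPx` (components below this are dropped as noise, default 4).
#' @param outDir output directory (`NULL` keeps everything in memory).
#' @param sourceId token used in record and file names.
#' @return list with `records` (data.frame: `source_id, category,
#'   size_bin, row0, col0, row1, col1, centroid_row, centroid_col`),
#'   `patches` (list of centred patch matrices, one per record) and
#'   `summary` (named category counts using the standard column names).
#' @export
extractCells <- function(image, config = list(), outDir = NULL,
                         sourceId = "roi") {
  if (is.character(image)) image <- readImage8(image, gray = FALSE)
  cfg <- utils::modifyList(
    list(spatialRadius = 10L, rangeRadius = 20, meanShift = TRUE,
         tolerance = 0.5, ext = 1L, minRegionPx = 25L, minAreaPx = 4L),
    config)
  original <- image
  filtered <- if (isTRUE(cfg$meanShift)) {
    meanShiftFilter(image, cfg$spatialRadius, cfg$rangeRadius)
  } else {
    image
  }
  gray <- toGray(filtered)
  grayOrig <- toGray(original)
  if (length(unique(as.vector(round(gray)))) < 2L) {
    warning("zero foreground: image is constant")
    empty <- .emptyExtraction()
    return(empty)
  }
  mask <- binarizeOtsu(gray, foreground = "dark")
  lab <- .label(mask)
  n <- max(lab)
  if (n == 0L) {
    warning("zero foreground components found")
    return(.emptyExtraction())
  }

  records <- list()
  patches <- list()
  imgDim <- dim(gray)
  for (i in seq_len(n)) {
    comp <- lab == i
    if (sum(comp) < cfg$minAreaPx) next
    bb <- .bbox(comp)
    touches <- bb[1] == 0 || bb[2] == 0 ||
      bb[3] == imgDim[1] || bb[4] == imgDim[2]
    parts <- if (touches) list(comp) else {
      separateTouching(comp, tolerance = cfg$tolerance, ext = cfg$ext,
                       minRegionPx = cfg$minRegionPx)
    }
    degenerate <- isTRUE(attr(parts, "degenerate"))
    for (part in parts) {
      pbb <- .bbox(part)
      rb <- routeAndBin(pbb, imgDim, nParts = length(parts),
                        degenerate = degenerate)
      canvas <- if (identical(rb$sizeBin, "oversize") ||
                    is.na(rb$sizeBin[1])) {
        max(pbb[3] - pbb[1], pbb[4] - pbb[2])
      } else {
        as.integer(rb$sizeBin)
      }
      patch <- centerOnCanvas(grayOrig, part, canvas)
      cen <- .centroid(part)
      records[[length(records) + 1L]] <- data.frame(
        source_id = sourceId, category = rb$category,
        size_bin = as.character(rb$sizeBin),
        row0 = pbb[1], col0 = pbb[2], row1 = pbb[3], col1 = pbb[4],
        centroid_row = cen["row"], centroid_col = cen["col"],
        stringsAsFactors = FALSE, row.names = NULL)
      patches[[length(records)]] <- patch
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    .emptyExtraction()$records
  summary <- .summarizeExtraction(records)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(nrow(records))) {
      sub <- file.path(outDir, records$category[k],
                       ifelse(is.na(records$size_bin[k]), "native",
                              records$size_bin[k]))
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      writeImage8(patches[[k]],
                  file.path(sub, sprintf("%s_%04d.png", sourceId, k)))
    }
    write.csv(as.data.frame(as.list(summary), check.names = FALSE),
              file.path(outDir, "summary.csv"), row.names = FALSE)
    .writeQcMontage(grayOrig, toGray(filtered), gray, mask, lab,
                    file.path(outDir, "qc_montage.png"))
  }
  list(records = records, patches = patches, summary = summary)
}

.emptyExtraction <- function() {
  records <- data.frame(
    source_id = character(), category = character(), size_bin = character(),
    row0 = integer(), col0 = integer(), row1 = integer(), col1 = integer(),
    centroid_row = numeric(), centroid_col = numeric(),
    stringsAsFactors = FALSE)
  list(records = records, patches = list(),
       summary = .summarizeExtraction(records))
}

# category counts in the standard column layout
.summarizeExtraction <- function(records) {
  counts <- vapply(.categories, function(cat) sum(records$category == cat),
                   integer(1))
  names(counts) <- .categoryColumns[.categories]
  counts
}

# five-panel QC strip: original / filtered / gray / mask / contour overlay
.writeQcMontage <- function(original, filtered, gray, mask, lab, path) {
  edge <- mask & !(
    .fromEBI(EBImage::erode(.toEBI(mask * 255),
                            EBImage::makeBrush(3L, "box")), 1) > 0.5)
  overlay <- gray
  overlay[edge] <- 255
  panels <- list(original, filtered, gray, mask * 255, overlay)
  target <- 200L
  small <- lapply(panels, function(p) {
    .fromEBI(EBImage::resize(.toEBI(p), w = target,
                             h = round(target * nrow(p) / ncol(p))))
  })
  h <- max(vapply(small, nrow, integer(1)))
  strip <- do.call(cbind, lapply(small, function(p) {
    rbind(p, matrix(0, h - nrow(p), ncol(p)))
  }))
  writeImage8(strip, path)
}
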