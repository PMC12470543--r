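# Ellipse-based morphometrics: direct least-squares ellipse fitting,
# AR/size/ER descriptors, the 72-way morphological taxonomy and the batch
# classification pipeline.

#' Fit an ellipse to contour points by direct least squares
#'
#' Fits the conic \eqn{Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0} under the
#' ellipse constraint \eqn{B^2 - 4AC < 0} (Fitzgibbon's direct method),
#' after centring and scaling the points for numerical stability. Axis
#' lengths are returned as full lengths with the major axis the larger.
#'
#' @param points numeric matrix with columns (row, col): contour pixel
#'   coordinates. At least 5 points are required; with fewer the fit is
#'   underdetermined and `NULL` is returned with a message, so callers can
#'   skip the contour.
#' @param pixelCorrection amount added to both axis lengths after the
#'   fit. Traced raster contours run through the centres of boundary
#'   pixels, half a pixel inside the true cell outline at either end, so
#'   callers fitting mask contours pass 1 (as [runEllipsePipeline()]
#'   does); exact geometric points need no correction (the default 0).
#' @return an [EllipseFit-class], or `NULL` when the contour is too short
#'   or degenerate.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 40)
#' pts <- cbind(50 + 20 * sin(th), 60 + 20 * cos(th))
#' fitEllipse(pts)
#' @export
fitEllipse <- function(points, pixelCorrection = 0) {
  points <- as.matrix(points)
  if (nrow(points) < 5L) {
    message("fitEllipse: contour has fewer than 5 points; skipped")
    return(NULL)
  }
  # x = col, y = row for the algebra; reported centre is (row, col)
  x <- points[, 2]
  y <- points[, 1]
  mx <- mean(x); my <- mean(y)
  s <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (s < .Machine$double.eps) return(NULL)
  xs <- (x - mx) / s
  ys <- (y - my) / s

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(NULL)
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C), C the ellipse-constraint matrix
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) return(NULL)
  a1 <- vecs[, ok[1]]
  coef <- c(a1, as.vector(Tm %*% a1))  # A B C D E F in scaled frame

  # un-scale: substitute xs = (x - mx)/s, ys = (y - my)/s
  A <- coef[1] / s^2
  B <- coef[2] / s^2
  C <- coef[3] / s^2
  D <- coef[4] / s - 2 * A * mx - B * my
  E <- coef[5] / s - 2 * C * my - B * mx
  Fc <- coef[6] + A * mx^2 + B * mx * my + C * my^2 -
    coef[4] * mx / s - coef[5] * my / s

  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # quadratic form about the centre
  F0 <- Fc + (D * cx + E * cy) / 2
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  eq <- eigen(Q, symmetric = TRUE)
  semi2 <- -F0 / eq$values
  if (any(!is.finite(semi2)) || any(semi2 <= 0)) return(NULL)
  semi <- sqrt(semi2)
  iMaj <- which.max(semi)
  vMaj <- eq$vectors[, iMaj]           # (x, y) direction of the major axis
  ang <- atan2(vMaj[2], vMaj[1]) * 180 / pi
  ang <- ang %% 180

  new("EllipseFit", center = c(row = cy, col = cx),
      LmajorPx = 2 * max(semi) + pixelCorrection,
      LminorPx = 2 * min(semi) + pixelCorrection,
      angleDeg = ang)
}

# logical mask of the fitted ellipse interior on an nrow x ncol grid
.ellipseMask <- function(fit, dim) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  th <- fit@angleDeg * pi / 180
  dx <- cols - fit@center["col"]
  dy <- rows - fit@center["row"]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / (fit@LmajorPx / 2))^2 + (v / (fit@LminorPx / 2))^2 <= 1
}

#' Compute morphometric descriptors from a fit and a cell mask
#'
#' Derives the aspect ratio AR = Lmajor / Lminor, the micrometre-scale
#' major-axis length, and the ellipse-to-cell area ratio
#' ER = cell area / (pi * (Lmajor / 2)^2), i.e. the cell's pixel area
#' relative to the circle circumscribed on the fitted major axis. The
#' contour/ellipse intersection area is recorded as a diagnostic. ER values
#' marginally above 1 (raster effects on near-perfect disks) are clamped
#' to 1.
#'
#' @param fit an [EllipseFit-class].
#' @param mask logical (or 0/1) matrix: the filled cell mask the contour
#'   was traced from.
#' @param pixelSizeUm micrometres per pixel (> 0).
#' @return a [MorphoMetrics-class].
#' @export
computeMorphoMetrics <- function(fit, mask, pixelSizeUm = 0.1658) {
  stopifnot(is(fit, "EllipseFit"))
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be > 0")
  mask <- mask > 0
  area <- sum(mask)
  if (area == 0) stop("empty mask")
  emask <- .ellipseMask(fit, dim(mask))
  er <- area / (pi * (fit@LmajorPx / 2)^2)
  new("MorphoMetrics",
      LmajorUm = fit@LmajorPx * pixelSizeUm,
      AR = fit@LmajorPx / fit@LminorPx,
      ER = min(1, er),
      cellAreaPx = area,
      intersectionAreaPx = sum(mask & emask))
}

#' Classify a cell into the 72-way morphometric taxonomy
#'
#' Threshold rules on three descriptors produce a directory-style class
#' path `<size><shape><area>`:
#' \itemize{
#'   \item shape (AR): <= 1.05 "Circle 095/", <= 1.10 "Circle 090/",
#'     <= 1.20 "Circle 080/", <= 1.40 "Oval 060/", <= 1.60 "Oval 040/",
#'     else "Pencil/";
#'   \item size (Lmajor, um): < 6.0 "Micro/", <= 8.0 "Normal/", else
#'     "Macro/" (the hematological microcytic / normocytic / macrocytic
#'     bands);
#'   \item area completeness (ER): <= 0.80 "Area 080/", <= 0.90
#'     "Area 090/", <= 0.95 "Area 095/", else "Area 100/".
#' }
#' All boundaries are inclusive on the printed "<=" side; the 3 x 6 x 4
#' paths partition the whole input space.
#'
#' @param ar aspect ratio(s), >= 1.
#' @param lengthUm major-axis length(s) in micrometres, > 0.
#' @param er ellipse-to-cell area ratio(s) in (0, 1]; values slightly above
#'   1 from discretisation are clamped to 1.
#' @param parts if TRUE return a data.frame with the three group columns
#'   alongside the path.
#' @return character vector of class paths, or a data.frame when
#'   `parts = TRUE`.
#' @examples
#' classifyCell(1.00, 7.0, 1.00)  # "Normal/Circle 095/Area 100/"
#' classifyCell(1.50, 5.0, 0.85)  # "Micro/Oval 040/Area 090/"
#' @export
classifyCell <- function(ar, lengthUm, er, parts = FALSE) {
  n <- max(length(ar), length(lengthUm), length(er))
  ar <- rep_len(ar, n); lengthUm <- rep_len(lengthUm, n)
  er <- rep_len(er, n)
  if (any(!is.finite(ar)) || any(!is.finite(lengthUm)) ||
      any(!is.finite(er))) {
    stop("classifyCell: inputs must be finite")
  }
  if (any(ar < 1 - 1e-9)) stop("classifyCell: AR must be >= 1")
  if (any(lengthUm <= 0)) stop("classifyCell: lengthUm must be > 0")
  er <- pmin(er, 1)
  if (any(er <= 0)) stop("classifyCell: ER must be > 0")

  shapeLabels <- c("Circle 095/", "Circle 090/", "Circle 080/",
                   "Oval 060/", "Oval 040/", "Pencil/")
  sizeLabels <- c("Micro/", "Normal/", "Macro/")
  areaLabels <- c("Area 080/", "Area 090/", "Area 095/", "Area 100/")

  shape <- shapeLabels[
    findInterval(ar, c(1.05, 1.10, 1.20, 1.40, 1.60), left.open = TRUE) + 1L]
  size <- sizeLabels[1L + (lengthUm >= 6.0) + (lengthUm > 8.0)]
  areag <- areaLabels[
    findInterval(er, c(0.80, 0.90, 0.95), left.open = TRUE) + 1L]
  path <- paste0(size, shape, areag)
  if (parts) {
    data.frame(size_group = size, shape_group = shape, area_group = areag,
               path = path, stringsAsFactors = FALSE)
  } else {
    path
  }
}

#' All 72 class paths of the morphometric taxonomy
#'
#' @return character vector of the 3 x 6 x 4 = 72 class paths, in
#'   size-major order.
#' @export
classPaths <- function() {
  sizes <- c("Micro/", "Normal/", "Macro/")
  shapes <- c("Circle 095/", "Circle 090/", "Circle 080/",
              "Oval 060/", "Oval 040/", "Pencil/")
  areas <- c("Area 080/", "Area 090/", "Area 095/", "Area 100/")
  as.vector(t(outer(as.vector(t(outer(sizes, shapes, paste0))), areas,
                    paste0)))
}

#' Quality screen on the ellipse-to-cell area ratio
#'
#' Cells are kept only when ER strictly exceeds `erMin`. The default 0.50
#' is the empirically calibrated cut below which contours are dominated by
#' fragments, overlaps or incomplete boundaries rather than single cells.
#'
#' @param metrics a [MorphoMetrics-class], or a numeric ER value/vector.
#' @param erMin exclusive lower ER bound (default 0.50).
#' @return logical: keep the cell?
#' @export
screenQuality <- function(metrics, erMin = 0.50) {
  er <- if (is(metrics, "MorphoMetrics")) metrics@ER else as.numeric(metrics)
  er > erMin
}

# per-component outer contours of a binary mask: list of
# list(points = (row, col) matrix, mask = filled component mask)
.contours <- function(mask) {
  lab <- .label(mask)
  n <- max(lab)
  if (n == 0) return(list())
  oc <- EBImage::ocontour(EBImage::Image(t(lab)))
  lapply(seq_len(n), function(i) {
    xy <- oc[[i]]
    list(points = cbind(row = xy[, 2] + 1, col = xy[, 1] + 1),
         mask = lab == i)
  })
}

# draw the fitted ellipse outline and both axes onto a grayscale patch,
# returning an RGB array for the annotated overlay
.annotateFit <- function(patch, fit, metrics) {
  rgb <- array(patch, c(dim(patch), 3))
  th <- seq(0, 2 * pi, length.out = 360)
  a <- fit@LmajorPx / 2
  b <- fit@LminorPx / 2
  ang <- fit@angleDeg * pi / 180
  ex <- fit@center["col"] + a * cos(th) * cos(ang) - b * sin(th) * sin(ang)
  ey <- fit@center["row"] + a * cos(th) * sin(ang) + b * sin(th) * cos(ang)
  axes <- rbind(
    cbind(fit@center["row"] + c(-a, a) * sin(ang),
          fit@center["col"] + c(-a, a) * cos(ang)),
    cbind(fit@center["row"] + c(-b, b) * cos(ang),
          fit@center["col"] - c(-b, b) * sin(ang)))
  tpts <- rbind(cbind(ey, ex),
                cbind(seq(axes[1, 1], axes[2, 1], length.out = 100),
                      seq(axes[1, 2], axes[2, 2], length.out = 100)),
                cbind(seq(axes[3, 1], axes[4, 1], length.out = 100),
                      seq(axes[3, 2], axes[4, 2], length.out = 100)))
  rr <- round(tpts[, 1]); cc <- round(tpts[, 2])
  keep <- rr >= 1 & rr <= nrow(patch) & cc >= 1 & cc <= ncol(patch)
  idx <- cbind(rr[keep], cc[keep])
  rgb[cbind(idx, 1)] <- 255
  rgb[cbind(idx, 2)] <- 40
  rgb[cbind(idx, 3)] <- 40
  rgb
}

#' Run the ellipse classification pipeline over patch directories
#'
#' For every PNG patch: grayscale, Otsu binarisation (bright foreground on
#' the black patch background), contour tracing, guarded ellipse fit
#' (contours shorter than 5 points are skipped and logged), morphometric
#' computation, ER quality screen and 72-way classification. Kept cells are
#' routed into `<outDir>/<size>/<shape>/<area>/`, one CSV row is logged per
#' contour, and annotated overlays can be written alongside.
#'
#' @param inputDirs character vector of directories holding single-cell
#'   patches; missing directories produce a warning and are skipped.
#' @param outDir output root (created). `NULL` disables file routing.
#' @param pixelSizeUm micrometres per pixel.
#' @param erMin exclusive ER quality bound; screened-out cells are logged
#'   with `kept = FALSE` and not routed.
#' @param annotate write Fig.-style annotated overlays under
#'   `<outDir>/annotated/`.
#' @return data.frame of per-cell metrics (also written to
#'   `<outDir>/ellipse_metrics.csv` when `outDir` is set) with columns
#'   `file, Lmajor_px, Lminor_px, Lmajor_um, AR, ER, intersection_area_px,
#'   class_path, kept`.
#' @export
runEllipsePipeline <- function(inputDirs, outDir = NULL,
                               pixelSizeUm = 0.1658, erMin = 0.50,
                               annotate = FALSE) {
  rows <- list()
  for (d in inputDirs) {
    if (!dir.exists(d)) {
      warning("folder not found: ", d)
      next
    }
    files <- list.files(d, pattern = "\\.png$", full.names = TRUE)
    for (f in files) {
      patch <- readImage8(f)
      if (length(unique(as.vector(round(patch)))) < 2L) next
      mask <- binarizeOtsu(patch, foreground = "bright")
      for (cont in .contours(mask)) {
        fit <- fitEllipse(cont$points, pixelCorrection = 1)
        if (is.null(fit)) next
        met <- computeMorphoMetrics(fit, cont$mask, pixelSizeUm)
        kept <- screenQuality(met, erMin)
        cls <- classifyCell(met@AR, met@LmajorUm, met@ER)
        rows[[length(rows) + 1L]] <- data.frame(
          file = basename(f), Lmajor_px = fit@LmajorPx,
          Lminor_px = fit@LminorPx, Lmajor_um = met@LmajorUm,
          AR = met@AR, ER = met@ER,
          intersection_area_px = met@intersectionAreaPx,
          class_path = cls, kept = kept, stringsAsFactors = FALSE)
        if (!is.null(outDir) && kept) {
          dest <- file.path(outDir, cls)
          dir.create(dest, recursive = TRUE, showWarnings = FALSE)
          file.copy(f, file.path(dest, basename(f)), overwrite = TRUE)
        }
        if (!is.null(outDir) && annotate) {
          adir <- file.path(outDir, "annotated")
          dir.create(adir, recursive = TRUE, showWarnings = FALSE)
          writeImage8(.annotateFit(patch, fit, met),
                      file.path(adir, basename(f)))
        }
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    file = character(), Lmajor_px = numeric(), Lminor_px = numeric(),
    Lmajor_um = numeric(), AR = numeric(), ER = numeric(),
    intersection_area_px = numeric(), class_path = character(),
    kept = logical(), stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res, file.path(outDir, "ellipse_metrics.csv"),
              row.names = FALSE)
  }
  res
}
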