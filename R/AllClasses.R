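# S4 classes for the central data objects, with validity checks, show
# methods and accessor generics.

#' SmearScene: a synthetic smear rendering request
#'
#' Describes one synthetic region-of-interest: canvas size, pixel scale,
#' Wright-Giemsa-like intensity model and the statistical structure of the
#' cell population (size/aspect-ratio ranges, central pallor, overlap
#' doublets, border-truncated cells, debris). [generateScene()] renders it
#' into an 8-bit image plus a per-cell ground-truth table.
#'
#' @slot widthPx,heightPx canvas dimensions in pixels.
#' @slot pixelSizeUm physical pixel size, micrometres per pixel.
#' @slot backgroundLevel,cellLevel,pallorLevel intensity model (0..255);
#'   cells render darker than background, central pallor lifts the cell
#'   centre back toward `pallorLevel`.
#' @slot noiseSigma additive Gaussian noise standard deviation.
#' @slot nCells number of interior cells to place.
#' @slot diamRangeUm major-axis diameter range of normal cells, micrometres.
#' @slot arRange aspect-ratio (major/minor) sampling range.
#' @slot pallorRange central-pallor depth sampling range, in [0, 1].
#' @slot outlierFraction fraction of cells drawn as micro/macro size
#'   outliers instead of from `diamRangeUm`.
#' @slot overlapFraction fraction of cells placed as touching doublets.
#' @slot borderCells number of additional cells truncated by the frame.
#' @slot debrisCount number of small non-cellular debris blobs.
#' @slot roiLike if TRUE the canvas must satisfy the ROI screening width
#'   bounds (2000..8000 px).
#' @slot seed integer seed driving all randomness of the scene.
#' @export
setClass("SmearScene", representation(
  widthPx = "integer", heightPx = "integer", pixelSizeUm = "numeric",
  backgroundLevel = "numeric", cellLevel = "numeric", pallorLevel = "numeric",
  noiseSigma = "numeric", nCells = "integer", diamRangeUm = "numeric",
  arRange = "numeric", pallorRange = "numeric", outlierFraction = "numeric",
  overlapFraction = "numeric", borderCells = "integer", debrisCount = "integer",
  roiLike = "logical", seed = "integer"
))

setValidity("SmearScene", function(object) {
  msg <- character()
  if (object@widthPx < 32L || object@heightPx < 32L) {
    msg <- c(msg, "canvas must be at least 32 x 32 px")
  }
  if (object@roiLike &&
      (object@widthPx < 2000L || object@widthPx > 8000L)) {
    msg <- c(msg, "ROI-like scenes require width between 2000 and 8000 px")
  }
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (any(object@diamRangeUm <= 0) || diff(object@diamRangeUm) < 0) {
    msg <- c(msg, "diamRangeUm must be a positive increasing range")
  }
  if (object@arRange[1] < 1 || diff(object@arRange) < 0) {
    msg <- c(msg, "arRange must be an increasing range with minimum >= 1")
  }
  if (object@overlapFraction < 0 || object@overlapFraction > 1) {
    msg <- c(msg, "overlapFraction must lie in [0, 1]")
  }
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@debrisCount < 0L || object@borderCells < 0L) {
    msg <- c(msg, "debrisCount and borderCells must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SmearScene request
#'
#' Defaults encode the study conditions the pipeline assumes: 0.1658 um/px
#' scanning scale, normocytic cells of 6-8 um major diameter with mild
#' ellipticity, background ~220 / cell body ~120 / pallor toward ~190
#' stained-smear contrast, and light sensor noise.
#'
#' @param widthPx,heightPx canvas size in pixels.
#' @param nCells number of interior cells.
#' @param pixelSizeUm micrometres per pixel.
#' @param backgroundLevel,cellLevel,pallorLevel intensity model (0..255).
#' @param noiseSigma Gaussian noise sd (0..255 scale).
#' @param diamRangeUm,arRange,pallorRange per-cell sampling ranges.
#' @param outlierFraction,overlapFraction,borderCells,debrisCount scene
#'   composition controls (see class slots).
#' @param roiLike enforce ROI screening width bounds.
#' @param seed integer seed.
#' @return a validated [SmearScene-class] object.
#' @export
smearScene <- function(widthPx = 800L, heightPx = 600L, nCells = 25L,
                       pixelSizeUm = 0.1658, backgroundLevel = 220,
                       cellLevel = 120, pallorLevel = 190, noiseSigma = 3,
                       diamRangeUm = c(6, 8), arRange = c(1.0, 1.15),
                       pallorRange = c(0.2, 0.5), outlierFraction = 0,
                       overlapFraction = 0, borderCells = 0L,
                       debrisCount = 0L, roiLike = FALSE, seed = 1L) {
  new("SmearScene",
      widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      pixelSizeUm = pixelSizeUm, backgroundLevel = backgroundLevel,
      cellLevel = cellLevel, pallorLevel = pallorLevel,
      noiseSigma = noiseSigma, nCells = as.integer(nCells),
      diamRangeUm = diamRangeUm, arRange = arRange,
      pallorRange = pallorRange, outlierFraction = outlierFraction,
      overlapFraction = overlapFraction, borderCells = as.integer(borderCells),
      debrisCount = as.integer(debrisCount), roiLike = roiLike,
      seed = as.integer(seed))
}

setMethod("show", "SmearScene", function(object) {
  cat(sprintf("SmearScene %d x %d px (%.4f um/px), %d cells, seed %d\n",
              object@widthPx, object@heightPx, object@pixelSizeUm,
              object@nCells, object@seed))
  cat(sprintf("  overlap %.2f | border cells %d | debris %d | noise sd %.1f\n",
              object@overlapFraction, object@borderCells, object@debrisCount,
              object@noiseSigma))
})

#' EllipseFit: a fitted ellipse
#'
#' Result of the direct least-squares conic fit to a cell contour. Axis
#' lengths are full lengths (diameters), with the major axis the larger of
#' the two by construction.
#'
#' @slot center fitted centre, (row, col) pixels.
#' @slot LmajorPx,LminorPx full major/minor axis lengths in pixels.
#' @slot angleDeg major-axis orientation, degrees in [0, 180).
#' @export
setClass("EllipseFit", representation(
  center = "numeric", LmajorPx = "numeric", LminorPx = "numeric",
  angleDeg = "numeric"
))

setValidity("EllipseFit", function(object) {
  msg <- character()
  if (length(object@center) != 2L) msg <- c(msg, "center must be (row, col)")
  if (!is.finite(object@LmajorPx) || !is.finite(object@LminorPx) ||
      object@LminorPx <= 0 || object@LmajorPx < object@LminorPx) {
    msg <- c(msg, "axis lengths must satisfy Lmajor >= Lminor > 0")
  }
  if (object@angleDeg < 0 || object@angleDeg >= 180) {
    msg <- c(msg, "angleDeg must lie in [0, 180)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf(
    "EllipseFit: centre (%.1f, %.1f), Lmajor %.2f px, Lminor %.2f px, %1.f deg\n",
    object@center[1], object@center[2], object@LmajorPx, object@LminorPx,
    object@angleDeg))
})

#' MorphoMetrics: morphometric descriptors of one cell
#'
#' Aspect ratio AR = Lmajor / Lminor, micrometre major-axis length, and the
#' ellipse-to-cell area ratio ER = cell area / (pi * (Lmajor / 2)^2), the
#' area of the cell relative to the circle circumscribed on the major axis.
#' Low ER flags fragmented or incomplete contours.
#'
#' @slot LmajorUm major-axis length in micrometres.
#' @slot AR aspect ratio (>= 1).
#' @slot ER ellipse-to-cell area ratio, clamped to (0, 1].
#' @slot cellAreaPx foreground pixel count of the cell mask.
#' @slot intersectionAreaPx pixel count of the contour/ellipse intersection
#'   (diagnostic).
#' @export
setClass("MorphoMetrics", representation(
  LmajorUm = "numeric", AR = "numeric", ER = "numeric",
  cellAreaPx = "numeric", intersectionAreaPx = "numeric"
))

setValidity("MorphoMetrics", function(object) {
  msg <- character()
  if (!is.finite(object@AR) || object@AR < 1) msg <- c(msg, "AR must be >= 1")
  if (!is.finite(object@ER) || object@ER <= 0 || object@ER > 1) {
    msg <- c(msg, "ER must lie in (0, 1]")
  }
  if (object@LmajorUm <= 0) msg <- c(msg, "LmajorUm must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MorphoMetrics", function(object) {
  cat(sprintf(
    "MorphoMetrics: Lmajor %.2f um, AR %.3f, ER %.3f, area %d px\n",
    object@LmajorUm, object@AR, object@ER, as.integer(object@cellAreaPx)))
})

#' Autoencoder: a dense or convolutional autoencoder handle
#'
#' Holds the architecture token, the weight list and the configuration used
#' to build it. The encoder half is applied with [encodeLatent()].
#'
#' @slot arch "dense" or "conv".
#' @slot params named list of weight matrices/arrays.
#' @slot config the [aeConfig()] list used to build the model.
#' @export
setClass("Autoencoder", representation(
  arch = "character", params = "list", config = "list"
))

setMethod("show", "Autoencoder", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("Autoencoder (%s): input %d x %d, latent dim %d, %s parameters\n",
              object@arch, object@config$inputSide, object@config$inputSide,
              latentDim(object), format(np, big.mark = ",")))
})

#' ClusterRun: one k-means clustering of a latent matrix
#'
#' @slot k number of clusters.
#' @slot labels integer cluster labels in [0, k), one per sample.
#' @slot silhouette mean silhouette width of the partition.
#' @slot dbi Davies-Bouldin index of the partition.
#' @slot seed seed used for the k-means++ initialisation.
#' @export
setClass("ClusterRun", representation(
  k = "integer", labels = "integer", silhouette = "numeric",
  dbi = "numeric", seed = "integer"
))

setValidity("ClusterRun", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (length(object@labels) &&
      (min(object@labels) < 0L || max(object@labels) >= object@k)) {
    msg <- c(msg, "labels must lie in [0, k)")
  }
  if (!is.finite(object@silhouette) || object@silhouette < -1 ||
      object@silhouette > 1) {
    msg <- c(msg, "silhouette must lie in [-1, 1]")
  }
  if (!is.finite(object@dbi) || object@dbi < 0) {
    msg <- c(msg, "dbi must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterRun", function(object) {
  cat(sprintf("ClusterRun: k = %d, n = %d, silhouette %.4f, DBI %.4f\n",
              object@k, length(object@labels), object@silhouette, object@dbi))
})

#' AugmentPlan: a deterministic scale/rotate/flip augmentation recipe
#'
#' Every input patch is expanded into S x R x (F + 1) variants: each scale,
#' each of R evenly spaced rotations, emitted unflipped plus once per
#' requested flip.
#'
#' @slot scales scale factors (subset of the canonical
#'   0.98/0.99/1.00/1.01 set, or any factors that keep the cell on canvas).
#' @slot numRotations number R of evenly spaced rotation angles
#'   i * (360 / R) degrees, i = 0..R-1.
#' @slot flips subset of c("vertical", "horizontal", "both").
#' @slot canvas output canvas side, pixels.
#' @export
setClass("AugmentPlan", representation(
  scales = "numeric", numRotations = "integer", flips = "character",
  canvas = "integer"
))

setValidity("AugmentPlan", function(object) {
  msg <- character()
  if (length(object@scales) < 1L || any(object@scales <= 0)) {
    msg <- c(msg, "scales must be positive")
  }
  if (object@numRotations < 1L) msg <- c(msg, "numRotations must be >= 1")
  if (length(object@flips) &&
      !all(object@flips %in% c("vertical", "horizontal", "both"))) {
    msg <- c(msg, "flips must be a subset of vertical/horizontal/both")
  }
  if (anyDuplicated(object@flips)) msg <- c(msg, "flips must be unique")
  if (object@canvas < 8L) msg <- c(msg, "canvas must be >= 8 px")
  if (length(msg)) msg else TRUE
})

#' Construct an AugmentPlan
#'
#' @param scales numeric scale factors.
#' @param rotations number of evenly spaced rotations R.
#' @param flips character subset of c("vertical", "horizontal", "both");
#'   the default requests all three, matching the flip codes of the
#'   augmentation procedure.
#' @param canvas canvas side in pixels.
#' @return an [AugmentPlan-class] object.
#' @export
augmentPlan <- function(scales = 1.0, rotations = 1L,
                        flips = c("vertical", "horizontal", "both"),
                        canvas = 128L) {
  new("AugmentPlan", scales = scales, numRotations = as.integer(rotations),
      flips = as.character(flips), canvas = as.integer(canvas))
}

setMethod("show", "AugmentPlan", function(object) {
  cat(sprintf("AugmentPlan: S=%d scales, R=%d rotations, F=%d flips -> x%d per input (canvas %d)\n",
              length(object@scales), object@numRotations, length(object@flips),
              length(object@scales) * object@numRotations *
                (length(object@flips) + 1L), object@canvas))
})

# ---- accessor generics -----------------------------------------------------

#' Accessors for rbcmorph S4 objects
#'
#' `majorAxisPx()`/`minorAxisPx()` return full axis lengths of an
#' [EllipseFit-class]; `aspectRatio()`, `areaRatio()` and `majorAxisUm()`
#' read [MorphoMetrics-class]; `clusterLabels()`, `silhouetteOf()` and
#' `daviesBouldinOf()` read [ClusterRun-class]; `latentDim()` reads an
#' [Autoencoder-class].
#'
#' @param x object to access.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("majorAxisPx", function(x) standardGeneric("majorAxisPx"))
#' @rdname accessors
#' @export
setGeneric("minorAxisPx", function(x) standardGeneric("minorAxisPx"))
#' @rdname accessors
#' @export
setGeneric("aspectRatio", function(x) standardGeneric("aspectRatio"))
#' @rdname accessors
#' @export
setGeneric("areaRatio", function(x) standardGeneric("areaRatio"))
#' @rdname accessors
#' @export
setGeneric("majorAxisUm", function(x) standardGeneric("majorAxisUm"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("silhouetteOf", function(x) standardGeneric("silhouetteOf"))
#' @rdname accessors
#' @export
setGeneric("daviesBouldinOf", function(x) standardGeneric("daviesBouldinOf"))
#' @rdname accessors
#' @export
setGeneric("latentDim", function(x) standardGeneric("latentDim"))

#' @rdname accessors
setMethod("majorAxisPx", "EllipseFit", function(x) x@LmajorPx)
#' @rdname accessors
setMethod("minorAxisPx", "EllipseFit", function(x) x@LminorPx)
#' @rdname accessors
setMethod("aspectRatio", "MorphoMetrics", function(x) x@AR)
#' @rdname accessors
setMethod("areaRatio", "MorphoMetrics", function(x) x@ER)
#' @rdname accessors
setMethod("majorAxisUm", "MorphoMetrics", function(x) x@LmajorUm)
#' @rdname accessors
setMethod("clusterLabels", "ClusterRun", function(x) x@labels)
#' @rdname accessors
setMethod("silhouetteOf", "ClusterRun", function(x) x@silhouette)
#' @rdname accessors
setMethod("daviesBouldinOf", "ClusterRun", function(x) x@dbi)
#' @rdname accessors
setMethod("latentDim", "Autoencoder", function(x) {
  if (x@arch == "dense") {
    x@config$latentDim
  } else {
    as.integer(x@config$convFilters[2] * (x@config$inputSide / 4)^2)
  }
})
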